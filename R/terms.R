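#' @title Symbolic terms
#' @description Internal utilities for the small term language used to name
#'   threads, links and stimuli: a term is either an atom (`forward`, `3`)
#'   or a functor with arguments (`sense(right(3))`). Single upper-case
#'   letters from the variable alphabet (`F`-`Z` excluding `P`, `Q`, `R`,
#'   which the field's circuit diagrams reserve for thread names, as are
#'   `A`-`E`) are variables; `_` is the anonymous wildcard and matches
#'   exactly one term. Variables may occur in functor position (`F(X)`
#'   matches `right(3)` binding `F = right`, `X = 3`).
#' @name terms
#' @keywords internal
NULL

VAR_ALPHABET <- setdiff(LETTERS[6:26], c("P", "Q", "R"))

term_is_var <- function(name) {
  name == "_" || name %in% VAR_ALPHABET
}

#' Parse a term string into a nested structure
#'
#' @param x a term string such as `"sense(right(3))"`.
#' @return a list with fields `f` (functor or atom name) and `args`
#'   (list of sub-terms, possibly empty).
#' @keywords internal
.term_cache <- new.env(parent = emptyenv())

term_parse <- function(x) {
  hit <- .term_cache[[x]]
  if (!is.null(hit)) return(hit)
  y <- gsub("[[:space:]]", "", x)
  res <- term_parse_at(y, 1L)
  if (res$pos != nchar(y) + 1L) {
    stop("malformed term: ", x, call. = FALSE)
  }
  .term_cache[[x]] <- res$term
  res$term
}

term_parse_at <- function(x, pos) {
  n <- nchar(x)
  start <- pos
  while (pos <= n && !substr(x, pos, pos) %in% c("(", ")", ",")) {
    pos <- pos + 1L
  }
  name <- substr(x, start, pos - 1L)
  if (!nzchar(name)) stop("malformed term: ", x, call. = FALSE)
  args <- list()
  if (pos <= n && substr(x, pos, pos) == "(") {
    pos <- pos + 1L
    repeat {
      sub <- term_parse_at(x, pos)
      args[[length(args) + 1L]] <- sub$term
      pos <- sub$pos
      ch <- substr(x, pos, pos)
      if (ch == ",") {
        pos <- pos + 1L
      } else if (ch == ")") {
        pos <- pos + 1L
        break
      } else {
        stop("malformed term: ", x, call. = FALSE)
      }
    }
  }
  list(term = list(f = name, args = args), pos = pos)
}

term_deparse <- function(t) {
  if (length(t$args) == 0L) return(t$f)
  paste0(t$f, "(", paste(vapply(t$args, term_deparse, ""), collapse = ","), ")")
}

#' Match a pattern term against an instance term
#'
#' One-sided matching: variables may occur in `pattern` only. Returns a named
#' list of bindings (variable name -> bound term string) or `NULL` when the
#' match fails. `_` matches any single term without binding.
#' @keywords internal
term_match <- function(pattern, instance, bindings = list()) {
  p <- if (is.character(pattern)) term_parse(pattern) else pattern
  i <- if (is.character(instance)) term_parse(instance) else instance
  term_match_rec(p, i, bindings)
}

term_match_rec <- function(p, i, b) {
  if (p$f == "_" && length(p$args) == 0L) return(b)
  if (term_is_var(p$f)) {
    if (length(p$args) == 0L) {
      # variable binds the whole term
      val <- term_deparse(i)
      if (!is.null(b[[p$f]]) && b[[p$f]] != val) return(NULL)
      b[[p$f]] <- val
      return(b)
    }
    # functor-position variable binds the functor name
    if (!is.null(b[[p$f]]) && b[[p$f]] != i$f) return(NULL)
    b[[p$f]] <- i$f
  } else if (p$f != i$f) {
    return(NULL)
  }
  if (length(p$args) != length(i$args)) return(NULL)
  for (k in seq_along(p$args)) {
    b <- term_match_rec(p$args[[k]], i$args[[k]], b)
    if (is.null(b)) return(NULL)
  }
  b
}

# Two-sided unification test (no binding propagation needed by callers):
# TRUE when the two patterns have a common instance. Variables and `_` on
# either side match any single term.
term_unifies <- function(a, b) {
  ta <- if (is.character(a)) term_parse(a) else a
  tb <- if (is.character(b)) term_parse(b) else b
  term_unifies_rec(ta, tb)
}

term_unifies_rec <- function(a, b) {
  a_any <- term_is_var(a$f) && length(a$args) == 0L
  b_any <- term_is_var(b$f) && length(b$args) == 0L
  if (a_any || b_any) return(TRUE)
  a_fv <- term_is_var(a$f)
  b_fv <- term_is_var(b$f)
  if (!a_fv && !b_fv && a$f != b$f) return(FALSE)
  if (length(a$args) != length(b$args)) return(FALSE)
  for (k in seq_along(a$args)) {
    if (!term_unifies_rec(a$args[[k]], b$args[[k]])) return(FALSE)
  }
  TRUE
}

#' Substitute bindings into a term string
#' @keywords internal
term_subst <- function(x, bindings) {
  t <- if (is.character(x)) term_parse(x) else x
  term_deparse(term_subst_rec(t, bindings))
}

term_subst_rec <- function(t, b) {
  if (term_is_var(t$f) && t$f != "_" && !is.null(b[[t$f]])) {
    bound <- term_parse(b[[t$f]])
    if (length(t$args) == 0L) return(bound)
    t$f <- bound$f  # functor-position variable
  }
  t$args <- lapply(t$args, term_subst_rec, b = b)
  t
}

# Specificity of a pattern: number of ground (non-variable) nodes. Ground
# code/links outrank wildcard ones during deduction and link resolution.
term_specificity <- function(x) {
  t <- if (is.character(x)) term_parse(x) else x
  spec_rec <- function(t) {
    own <- if (term_is_var(t$f)) 0L else 1L
    own + sum(vapply(t$args, spec_rec, 0L))
  }
  spec_rec(t)
}

term_is_ground <- function(x) {
  t <- if (is.character(x)) term_parse(x) else x
  g <- function(t) !term_is_var(t$f) && all(vapply(t$args, g, TRUE))
  g(t)
}

term_vars <- function(x) {
  t <- if (is.character(x)) term_parse(x) else x
  v <- function(t) {
    own <- if (term_is_var(t$f) && t$f != "_") t$f else character()
    c(own, unlist(lapply(t$args, v)))
  }
  unique(v(t))
}
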