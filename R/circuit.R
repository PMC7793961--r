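#' Thread patterns and circuits
#'
#' A circuit is a set of named thread patterns (each enclosing a finite
#' instruction body), a table of weighted, threshold-gated links between
#' thread patterns, and the set of entry threads that external stimuli can
#' fire. Thread heads may be parameterized with variables (`sense(F(X))`)
#' that are bound when an instance is activated; link endpoints may be
#' ground (`sense(right(3))`) or wildcard (`sense(right(_))`) — wildcard
#' links are the substrate of generalized (rule) learning, ground links of
#' instantiated learning.
#'
#' @param head head pattern string, e.g. `"detect(F(X))"`.
#' @param ... instruction nodes built with the [instructions] constructors,
#'   in body order.
#' @return `vm_thread()`: a thread pattern; `vm_circuit()`: a circuit.
#' @examples
#' p <- vm_thread("P", i_send("Q"))
#' q <- vm_thread("Q", i_receive("P"), i_emit("excite"))
#' circ <- vm_circuit(p, q, links = vm_links(vm_link("P", "Q", weight = 1)),
#'                    entry = "P")
#' validate_circuit(circ)
#' @export
vm_thread <- function(head, ...) {
  body <- list(...)
  stopifnot(length(body) >= 1L)
  for (k in seq_along(body)) {
    if (!inherits(body[[k]], "vm_instr")) {
      stop("thread body elements must be vm_instr nodes", call. = FALSE)
    }
    if (is.null(body[[k]]$br) && is.na(body[[k]]$nxt) &&
        body[[k]]$op != "stop") {   # stop is terminal
      body[[k]]$nxt <- k + 1L
    }
  }
  structure(list(head = head, body = body), class = "vm_thread")
}

#' Declare a link
#'
#' A link is OPEN iff `weight > threshold`, otherwise CLOSED. `delta_up`
#' and `delta_down` are the ltp increment and ltd decrement applied by
#' plasticity (defaults reproduce one-shot path switching: a single
#' coincidence flips a path between closed 0 and open 1 around the 0.5
#' threshold).
#'
#' @param from,to endpoint patterns (ground or wildcard).
#' @param weight initial weight (dimensionless).
#' @param threshold gating threshold.
#' @param delta_up,delta_down ltp/ltd step sizes (> 0).
#' @export
vm_link <- function(from, to, weight = 1, threshold = 0.5,
                    delta_up = 1, delta_down = 1) {
  stopifnot(delta_up > 0, delta_down > 0)
  structure(list(from = from, to = to, weight = weight, threshold = threshold,
                 delta_up = delta_up, delta_down = delta_down),
            class = "vm_link")
}

#' @rdname vm_link
#' @param ... `vm_link` objects.
#' @export
vm_links <- function(...) {
  ls <- list(...)
  for (l in ls) stopifnot(inherits(l, "vm_link"))
  ls
}

#' Construct a circuit
#'
#' @param ... thread patterns built with [vm_thread()].
#' @param links list of links from [vm_links()].
#' @param entry character vector of entry (sense) thread patterns that
#'   external stimuli may fire.
#' @param name optional circuit name.
#' @export
vm_circuit <- function(..., links = list(), entry = character(), name = "circuit") {
  threads <- list(...)
  if (length(threads) == 1L && is.list(threads[[1]]) &&
      !inherits(threads[[1]], "vm_thread")) {
    threads <- threads[[1]]
  }
  for (t in threads) stopifnot(inherits(t, "vm_thread"))
  names(threads) <- vapply(threads, function(t) t$head, "")
  structure(list(threads = threads, links = links, entry = entry, name = name),
            class = "vm_circuit")
}

#' @export
print.vm_circuit <- function(x, ...) {
  cat("<vm_circuit> ", x$name, ": ", length(x$threads), " threads, ",
      length(x$links), " links\n", sep = "")
  invisible(x)
}

#' Link table of a circuit
#'
#' @param circuit a [vm_circuit()].
#' @return a tibble with one row per declared link: endpoints, weight,
#'   threshold, plasticity steps, and open/closed status.
#' @export
link_table <- function(circuit) {
  ls <- circuit$links
  tibble::tibble(
    from = vapply(ls, `[[`, "", "from"),
    to = vapply(ls, `[[`, "", "to"),
    weight = vapply(ls, `[[`, 0, "weight"),
    threshold = vapply(ls, `[[`, 0, "threshold"),
    delta_up = vapply(ls, `[[`, 0, "delta_up"),
    delta_down = vapply(ls, `[[`, 0, "delta_down"),
    open = vapply(ls, function(l) l$weight > l$threshold, TRUE)
  )
}

#' Validate a circuit
#'
#' Structural checks: every `receive(source)` must have a declared link
#' whose endpoints unify with (source, receiving thread); every `join` peer
#' must name a declared thread (its tokens come from that thread's `merge`
#' or excite emissions); link endpoints must unify with declared thread
#' heads; `choice` alternatives must be non-empty; `check` conditions must
#' name a known environment predicate (`on`, `at`); branch and `nxt`
#' targets must lie within `1 .. length(body) + 1`; body variables must be
#' bound by the head, a prior `choice`, or a prior `join`.
#'
#' @param circuit a [vm_circuit()].
#' @return a character vector of diagnostics; empty when the circuit is
#'   valid ([compile_circuit()] succeeds exactly in that case).
#' @export
validate_circuit <- function(circuit) {
  stopifnot(inherits(circuit, "vm_circuit"))
  diags <- character()
  heads <- vapply(circuit$threads, `[[`, "", "head")

  thread_declared <- function(pat) {
    any(vapply(heads, function(h) term_unifies(h, pat), TRUE))
  }

  for (l in circuit$links) {
    if (!thread_declared(l$from)) {
      diags <- c(diags, paste0("link endpoint names no declared thread: ", l$from))
    }
    if (!thread_declared(l$to)) {
      diags <- c(diags, paste0("link endpoint names no declared thread: ", l$to))
    }
  }

  link_exists <- function(from_pat, to_pat) {
    any(vapply(circuit$links, function(l) {
      term_unifies(l$from, from_pat) && term_unifies(l$to, to_pat)
    }, TRUE))
  }

  for (th in circuit$threads) {
    n <- length(th$body)
    bound <- term_vars(th$head)
    for (k in seq_along(th$body)) {
      ins <- th$body[[k]]
      targets <- if (!is.null(ins$br)) unlist(ins$br) else ins$nxt
      targets <- targets[!is.na(targets)]
      if (any(targets < 1L | targets > n + 1L)) {
        diags <- c(diags, paste0(th$head, "[", k, "]: control target out of range"))
      }
      if (ins$op == "receive") {
        src <- ins$args$source
        if (!link_exists(src, th$head)) {
          diags <- c(diags, paste0(th$head, "[", k, "]: receive(", src,
                                   ") has no matching declared link"))
        }
      }
      if (ins$op == "join") {
        if (!thread_declared(ins$args$peer) &&
            !ins$args$peer %in% c("positive", "negative")) {
          diags <- c(diags, paste0(th$head, "[", k, "]: join peer undeclared: ",
                                   ins$args$peer))
        }
      }
      if (ins$op == "choice") {
        if (length(ins$args$alternatives) == 0L) {
          diags <- c(diags, paste0(th$head, "[", k, "]: empty choice"))
        }
        bound <- union(bound, ins$args$var)
      }
      if (ins$op == "join") {
        bound <- union(bound, term_vars(ins$args$peer))
      }
      if (ins$op == "check") {
        pred <- term_parse(ins$args$condition)$f
        if (!pred %in% c("on", "at")) {
          diags <- c(diags, paste0(th$head, "[", k, "]: unknown predicate ", pred))
        }
      }
      if (ins$op %in% c("send", "fire")) {
        used <- term_vars(unlist(ins$args, use.names = FALSE)[1])
        free <- setdiff(used, bound)
        if (length(free) > 0L) {
          diags <- c(diags, paste0(th$head, "[", k, "]: unbound variable(s) ",
                                   paste(free, collapse = ", ")))
        }
      }
    }
  }
  diags
}

#' Compile a circuit into the code repository
#'
#' Every instruction node receives its (thread, T) index; code entries are
#' tagged with the specificity of their head so that contextual deduction
#' prefers ground code over wildcard code. The compiled repository retains
#' the full structure, so [decompile_circuit()] reproduces an equivalent
#' circuit.
#'
#' @param circuit a valid [vm_circuit()].
#' @return a code repository (named list keyed by head pattern), class
#'   `vm_code`.
#' @export
compile_circuit <- function(circuit) {
  diags <- validate_circuit(circuit)
  if (length(diags) > 0L) {
    stop("circuit does not compile:\n  ", paste(diags, collapse = "\n  "),
         call. = FALSE)
  }
  heads <- vapply(circuit$threads, `[[`, "", "head")
  if (anyDuplicated(heads)) {
    stop("duplicate thread pattern: ",
         heads[duplicated(heads)][1], call. = FALSE)
  }
  code <- lapply(circuit$threads, function(th) {
    body <- th$body
    for (k in seq_along(body)) body[[k]]$index <- k
    list(head = th$head,
         head_term = term_parse(th$head),
         specificity = term_specificity(th$head),
         body = body)
  })
  structure(list(code = code,
                 links = circuit$links,
                 entry = circuit$entry,
                 name = circuit$name),
            class = "vm_code")
}

#' Decompile a code repository back into a circuit
#'
#' Round-trip companion of [compile_circuit()]:
#' `decompile_circuit(compile_circuit(c))` is structurally equal to `c`.
#'
#' @param code a `vm_code` repository.
#' @export
decompile_circuit <- function(code) {
  stopifnot(inherits(code, "vm_code"))
  threads <- lapply(code$code, function(entry) {
    body <- lapply(entry$body, function(ins) { ins$index <- NULL; ins })
    structure(list(head = entry$head, body = body), class = "vm_thread")
  })
  names(threads) <- vapply(threads, `[[`, "", "head")
  structure(list(threads = threads, links = code$links, entry = code$entry,
                 name = code$name),
            class = "vm_circuit")
}

#' Render a circuit as a DOT graph
#'
#' Threads become nodes; synaptic links become edges labelled `->=>-`
#' (dashed when CLOSED); ltp/ltd instructions become modulation edges
#' labelled `/|\` pointing from the modulating thread to the modulated
#' link's recipient.
#'
#' @param circuit a [vm_circuit()].
#' @return a single string holding the DOT source.
#' @export
render_circuit <- function(circuit) {
  stopifnot(inherits(circuit, "vm_circuit"))
  q <- function(x) paste0("\"", x, "\"")
  lines <- c(paste0("digraph ", q(circuit$name), " {"))
  for (h in names(circuit$threads)) {
    lines <- c(lines, paste0("  ", q(h), ";"))
  }
  for (l in circuit$links) {
    style <- if (l$weight > l$threshold) "solid" else "dashed"
    lines <- c(lines, paste0("  ", q(l$from), " -> ", q(l$to),
                             " [label=\"->=>-\", style=", style, "];"))
  }
  for (th in circuit$threads) {
    for (ins in th$body) {
      if (ins$op %in% c("ltp", "ltd")) {
        lines <- c(lines, paste0(
          "  ", q(th$head), " -> ", q(ins$args$to),
          " [label=\"/|\\\\ ", ins$op, "(", ins$args$from, "->", ins$args$to,
          ")\", style=dotted];"))
      }
    }
  }
  paste(c(lines, "}"), collapse = "\n")
}
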