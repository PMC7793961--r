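#' Read and write circuit files
#'
#' Circuits are stored in a small structured text format, one block per
#' thread and an explicit links section, diffable and writable by hand:
#'
#' ```
#' circuit transmission
#'
#' thread P {
#'   1: send(Q)
#' }
#'
#' thread Q {
#'   1: receive(P)
#'   2: emit(excite)
#' }
#'
#' link P -> Q weight=1 threshold=0.5
#' entry P
#' ```
#'
#' Branching instructions use the form
#' `2: check(on(F(X))) ? excite -> 4 : inhibit -> 3`; a trailing `-> n`
#' overrides the default fall-through to the following instruction (used
#' for loop-backs). `write_circuit()` and `read_circuit()` round-trip.
#'
#' @param path file path.
#' @param circuit a [vm_circuit()].
#' @return `read_circuit()` returns a [vm_circuit()]; `write_circuit()`
#'   returns `path` invisibly.
#' @export
read_circuit <- function(path) {
  lines <- readLines(path, warn = FALSE)
  parse_circuit_text(lines)
}

#' @rdname read_circuit
#' @export
write_circuit <- function(circuit, path) {
  writeLines(format_circuit_text(circuit), path)
  invisible(path)
}

#' @rdname read_circuit
#' @export
format_circuit_text <- function(circuit) {
  stopifnot(inherits(circuit, "vm_circuit"))
  out <- c(paste0("circuit ", circuit$name), "")
  for (th in circuit$threads) {
    out <- c(out, paste0("thread ", th$head, " {"))
    for (k in seq_along(th$body)) {
      out <- c(out, paste0("  ", k, ": ", format_instr_text(th$body[[k]], k)))
    }
    out <- c(out, "}", "")
  }
  for (l in circuit$links) {
    out <- c(out, paste0("link ", l$from, " -> ", l$to,
                         " weight=", format(l$weight),
                         " threshold=", format(l$threshold),
                         " delta_up=", format(l$delta_up),
                         " delta_down=", format(l$delta_down)))
  }
  for (e in circuit$entry) out <- c(out, paste0("entry ", e))
  out
}

format_instr_text <- function(ins, k) {
  core <- switch(ins$op,
    send = paste0("send(", ins$args$target, ")"),
    receive = paste0("receive(", ins$args$source, ")"),
    join = paste0("join(", ins$args$peer, ")"),
    merge = paste0("merge(", ins$args$peer, ")"),
    fire = paste0("fire(", ins$args$thread, ")"),
    choice = paste0("choice([", paste(ins$args$alternatives, collapse = ","),
                    "]->", ins$args$var, ")"),
    check = paste0("check(", ins$args$condition, ")"),
    drive = "drive",
    switch = "switch",
    emit = paste0("emit(", ins$args$stimulus, ")"),
    clear = "clear",
    stop = "stop",
    ltp = paste0("ltp(", ins$args$from, "->", ins$args$to, ")"),
    ltd = paste0("ltd(", ins$args$from, "->", ins$args$to, ")"),
    stop("unknown opcode: ", ins$op)
  )
  if (!is.null(ins$br)) {
    paste0(core, " ? ",
           paste(names(ins$br), unlist(ins$br), sep = " -> ", collapse = " : "))
  } else if (ins$op == "stop" || is.na(ins$nxt)) {
    core
  } else if (ins$nxt == k + 1L) {
    core
  } else {
    paste0(core, " -> ", ins$nxt)
  }
}

parse_circuit_text <- function(lines) {
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  name <- "circuit"
  threads <- list()
  links <- list()
  entry <- character()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    ln <- lines[i]
    if (!nzchar(ln)) { i <- i + 1L; next }
    if (grepl("^circuit\\s+", ln)) {
      name <- sub("^circuit\\s+", "", ln)
    } else if (grepl("^thread\\s+", ln)) {
      head <- sub("\\{\\s*$", "", sub("^thread\\s+", "", ln))
      head <- trimws(head)
      body <- list()
      i <- i + 1L
      while (i <= n && !grepl("^\\}", lines[i])) {
        bl <- lines[i]
        if (nzchar(bl)) {
          m <- regmatches(bl, regexec("^(\\d+):\\s*(.*)$", bl))[[1]]
          if (length(m) != 3L) stop("cannot parse instruction line: ", bl, call. = FALSE)
          idx <- as.integer(m[2])
          body[[idx]] <- parse_instr_text(m[3], idx)
        }
        i <- i + 1L
      }
      threads[[length(threads) + 1L]] <- structure(
        list(head = head, body = body), class = "vm_thread")
    } else if (grepl("^link\\s+", ln)) {
      m <- regmatches(ln, regexec(
        "^link\\s+(\\S+)\\s*->\\s*(\\S+)\\s*(.*)$", ln))[[1]]
      if (length(m) != 4L) stop("cannot parse link line: ", ln, call. = FALSE)
      kv <- list(weight = 1, threshold = 0.5, delta_up = 1, delta_down = 1)
      for (pair in strsplit(trimws(m[4]), "\\s+")[[1]]) {
        if (!nzchar(pair)) next
        parts <- strsplit(pair, "=", fixed = TRUE)[[1]]
        kv[[parts[1]]] <- as.numeric(parts[2])
      }
      links[[length(links) + 1L]] <- vm_link(
        m[2], m[3], weight = kv$weight, threshold = kv$threshold,
        delta_up = kv$delta_up, delta_down = kv$delta_down)
    } else if (grepl("^entry\\s+", ln)) {
      entry <- c(entry, sub("^entry\\s+", "", ln))
    } else {
      stop("cannot parse circuit line: ", ln, call. = FALSE)
    }
    i <- i + 1L
  }
  names(threads) <- vapply(threads, `[[`, "", "head")
  structure(list(threads = threads, links = links, entry = entry, name = name),
            class = "vm_circuit")
}

parse_instr_text <- function(text, idx) {
  text <- trimws(text)
  br <- NULL
  if (grepl("?", text, fixed = TRUE)) {
    parts <- strsplit(text, "?", fixed = TRUE)[[1]]
    core <- trimws(parts[1])
    br <- list()
    for (arm in strsplit(trimws(parts[2]), ":", fixed = TRUE)[[1]]) {
      am <- regmatches(arm, regexec("^\\s*(\\w+)\\s*->\\s*(\\d+)\\s*$", arm))[[1]]
      if (length(am) != 3L) stop("cannot parse branch arm: ", arm, call. = FALSE)
      br[[am[2]]] <- as.integer(am[3])
    }
  } else {
    core <- text
    nxt <- NA_integer_
    # a trailing " -> n" (spaces required) sets an explicit control target;
    # "->" inside argument lists (ltp, choice) is written without spaces
    tm <- regmatches(text, regexec("^(.*\\S)\\s+->\\s+(\\d+)$", text))[[1]]
    if (length(tm) == 3L) {
      core <- tm[2]
      nxt <- as.integer(tm[3])
    }
  }
  op <- sub("\\(.*$", "", core)
  argstr <- if (grepl("(", core, fixed = TRUE)) {
    sub("^[^(]*\\((.*)\\)$", "\\1", core)
  } else ""
  ins <- switch(op,
    send = i_send(argstr),
    receive = i_receive(argstr),
    join = i_join(argstr),
    merge = i_merge(argstr),
    fire = i_fire(argstr),
    choice = {
      cm <- regmatches(argstr, regexec("^\\[(.*)\\]->(\\w+)$", argstr))[[1]]
      if (length(cm) != 3L) stop("cannot parse choice: ", argstr, call. = FALSE)
      i_choice(strsplit(cm[2], ",", fixed = TRUE)[[1]], var = cm[3])
    },
    check = i_check(argstr, excite = br$excite, inhibit = br$inhibit),
    drive = i_drive(moved = br$excite, limit = br$inhibit),
    switch = i_switch(positive = br$positive, negative = br$negative),
    emit = i_emit(argstr),
    clear = i_clear(),
    stop = i_stop(),
    ltp = {
      pp <- strsplit(argstr, "->", fixed = TRUE)[[1]]
      i_ltp(trimws(pp[1]), trimws(pp[2]))
    },
    ltd = {
      pp <- strsplit(argstr, "->", fixed = TRUE)[[1]]
      i_ltd(trimws(pp[1]), trimws(pp[2]))
    },
    stop("unknown opcode in circuit file: ", op, call. = FALSE)
  )
  if (is.null(ins$br) && ins$op != "stop") {
    ins$nxt <- if (exists("nxt", inherits = FALSE) && !is.na(nxt)) nxt else idx + 1L
  }
  ins
}
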