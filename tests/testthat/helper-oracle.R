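# Independent brute-force interpreter: expands the global machine state
# explicitly, pass by pass, under the canonical scheduler order. Written as
# pure-functional state stepping over plain lists; shares only the circuit
# data structures with the package. Supports the non-environment opcode
# subset (emit, send, receive, fire, merge, stop) over ground thread names.
oracle_run <- function(circuit, stimuli = character(), max_passes = 200L) {
  link_key <- function(from, to) paste0(from, "|", to)
  links <- list()
  for (l in circuit$links) {
    links[[link_key(l$from, l$to)]] <- list(weight = l$weight,
                                            threshold = l$threshold,
                                            queue = 0L)
  }
  st <- list(order = character(), inst = list(), links = links,
             events = list(), knocks = character(), stopped = FALSE)

  activate <- function(st, nm) {
    cur <- st$inst[[nm]]
    if (!is.null(cur)) {
      if (cur$done) {
        cur$pc <- 1L
        cur$done <- FALSE
        st$inst[[nm]] <- cur
      }
      return(st)
    }
    st$inst[[nm]] <- list(pc = 1L, done = FALSE)
    st$order <- c(st$order, nm)
    st
  }

  event <- function(st, thread, stimulus, origin = "thread") {
    st$events[[length(st$events) + 1L]] <- list(
      seq = 0L, thread = thread, stimulus = stimulus, origin = origin)
    st
  }

  pass <- 0L
  repeat {
    pass <- pass + 1L
    if (pass > max_passes) break
    progress <- FALSE
    if (pass == 1L && length(stimuli) > 0L) {
      for (t in stimuli) st <- activate(st, t)
      progress <- TRUE
    }
    snapshot <- st$order
    for (nm in snapshot) {
      cur <- st$inst[[nm]]
      if (cur$done) next
      body <- circuit$threads[[nm]]$body
      if (cur$pc > length(body)) {
        st$inst[[nm]]$done <- TRUE
        next
      }
      ins <- body[[cur$pc]]
      ok <- TRUE
      if (ins$op == "emit") {
        st <- event(st, nm, ins$args$stimulus)
      } else if (ins$op == "send") {
        key <- link_key(nm, ins$args$target)
        l <- st$links[[key]]
        l$queue <- l$queue + 1L
        st$links[[key]] <- l
        if (l$weight > l$threshold) {
          st <- activate(st, ins$args$target)
        } else {
          st$knocks <- c(st$knocks, ins$args$target)
        }
      } else if (ins$op == "receive") {
        key <- link_key(ins$args$source, nm)
        l <- st$links[[key]]
        if (!is.null(l) && l$queue >= 1L && l$weight > l$threshold) {
          l$queue <- l$queue - 1L
          st$links[[key]] <- l
        } else {
          ok <- FALSE
        }
      } else if (ins$op == "fire") {
        st <- activate(st, ins$args$thread)
      } else if (ins$op == "merge") {
        # token board unused by this opcode subset
      } else if (ins$op == "stop") {
        st$stopped <- TRUE
        st <- event(st, nm, "stop")
      } else {
        stop("oracle does not support opcode ", ins$op)
      }
      if (ok) {
        progress <- TRUE
        cur <- st$inst[[nm]]
        nxt <- ins$nxt
        if (is.na(nxt) || nxt > length(body)) {
          cur$done <- TRUE
        } else {
          cur$pc <- as.integer(nxt)
        }
        st$inst[[nm]] <- cur
      }
    }
    if (!progress) break
  }
  for (k in st$knocks) st <- event(st, k, "inhibit", origin = "gate")

  tibble::tibble(
    seq = vapply(st$events, function(e) e$seq, 0L),
    thread = vapply(st$events, `[[`, "", "thread"),
    stimulus = vapply(st$events, `[[`, "", "stimulus"),
    origin = vapply(st$events, `[[`, "", "origin")
  )
}
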