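# Random small circuits (ground thread names, linear bodies) for the
# round-trip and oracle-equivalence properties.
random_circuit <- function(n_threads = sample(2:4, 1), max_len = 5L) {
  nms <- paste0("t", seq_len(n_threads))
  pairs <- character()
  threads <- lapply(nms, function(nm) {
    len <- sample.int(max_len, 1L)
    body <- vector("list", len)
    for (k in seq_len(len)) {
      op <- sample(c("emit", "send", "receive", "fire", "stop"), 1L,
                   prob = c(0.35, 0.25, 0.2, 0.15, 0.05))
      other <- sample(setdiff(nms, nm), 1L)
      body[[k]] <- switch(op,
        emit = i_emit(sample(c("excite", "inhibit"), 1L)),
        send = { pairs <<- c(pairs, paste0(nm, "|", other)); i_send(other) },
        receive = { pairs <<- c(pairs, paste0(other, "|", nm)); i_receive(other) },
        fire = i_fire(other),
        stop = i_stop())
    }
    do.call(vm_thread, c(list(nm), body))
  })
  links <- lapply(unique(pairs), function(p) {
    ends <- strsplit(p, "|", fixed = TRUE)[[1]]
    vm_link(ends[1], ends[2], weight = sample(c(0, 1), 1L))
  })
  do.call(vm_circuit, c(threads, list(links = links, entry = "t1",
                                      name = "random")))
}

run_oracle_case <- function(circuit, entry = "t1", max_passes = 200L) {
  m <- new_model(circuit, stimuli = tibble::tibble(
    target = entry, stimulus = "excite", at_pass = 1L))
  vm_run(m, max_cycles = max_passes)
  tr <- tibble::as_tibble(vm_trace(m))
  class(tr) <- c("tbl_df", "tbl", "data.frame")
  tr[, c("seq", "thread", "stimulus", "origin")]
}

# Convenience: run a library circuit with an explicit stimulus schedule.
run_with_stimuli <- function(circuit, ..., id = "test") {
  run_scenario(list(circuit = circuit, id = id, stimuli = list(...)))
}

stim <- function(target, stimulus = "excite", at_pass = 1L) {
  list(target = target, stimulus = stimulus, at_pass = at_pass)
}
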