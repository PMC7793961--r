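# Trace/model invariants asserted across every run the suite produces:
# event ordering, clock monotonicity (+1 per successful instruction),
# signal conservation, and gating soundness (no thread fired through a
# link that was closed whenever it carried the activation).
expect_run_invariants <- function(report) {
  trace <- report$trace
  # events ordered by non-decreasing stream sequence
  expect_true(all(diff(trace$seq) >= 0L),
              label = paste0(report$id, ": trace seq non-decreasing"))

  clocks <- model_clocks(report$model)
  expect_true(all(clocks$clock == clocks$successes),
              label = paste0(report$id, ": clock = +1 per success"))
  expect_true(all(clocks$clock >= 0L),
              label = paste0(report$id, ": clocks non-negative"))

  w <- report$weights
  expect_true(all(w$receives <= w$sends),
              label = paste0(report$id, ": receives <= sends"))
  expect_true(all(w$queued == w$sends - w$receives & w$queued >= 0L),
              label = paste0(report$id, ": queue conservation"))

  # gating soundness: an instance activated by a synaptic send must have at
  # least one inbound link that was open at some point of the run
  for (k in seq_len(nrow(clocks))) {
    if (clocks$activated_by[k] != "send" || clocks$clock[k] == 0L) next
    inbound <- w[vapply(seq_len(nrow(w)), function(j) {
      mesovm:::term_unifies(w$to[j], clocks$thread[k])
    }, TRUE), ]
    expect_true(any(inbound$before > inbound$threshold |
                      inbound$after > inbound$threshold),
                label = paste0(report$id, ": ", clocks$thread[k],
                               " executed only behind an open gate"))
  }

  # a cleared run shows exactly one clear, simultaneous with the
  # synchronized excite pair
  if (report$outcome == "cleared" && any(grepl("^detect", trace$thread))) {
    clears <- trace[trace$stimulus == "clear", ]
    expect_identical(nrow(clears), 1L,
                     label = paste0(report$id, ": exactly one clear"))
    expect_true(clears$seq %in% report$synchro_events$seq,
                label = paste0(report$id, ": clear simultaneous with synchro"))
  }
  invisible(report)
}
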