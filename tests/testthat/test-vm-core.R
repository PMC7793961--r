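test_that("an empty circuit halts quiescent with an empty trace", {
  m <- new_model(vm_circuit(links = list(), entry = character(), name = "empty"))
  vm_run(m)
  expect_identical(nrow(vm_trace(m)), 0L)
  expect_false(m$truncated)
  expect_true(m$halted)
})

test_that("a forced wrong-direction run ends in stop with no synchro event", {
  rep <- run_scenario(list(circuit = "random_detector", fire = "right(3)",
                           choice = "backward", id = "wrong"))
  expect_identical(rep$outcome, "missed")
  expect_identical(utils::tail(rep$trace$stimulus, 1), "stop")
  expect_identical(nrow(rep$synchro_events), 0L)
  expect_false(rep$truncated)
})

test_that("runs are deterministic: same seed, bitwise-identical traces", {
  sc <- list(circuit = "random_detector", fire = "right(3)", seed = 11,
             id = "det")
  expect_identical(run_scenario(sc)$trace, run_scenario(sc)$trace)
  # and with forced choices the seed is immaterial
  figs1 <- run_scenario(figure_scenario("fig10"))
  figs2 <- run_scenario(figure_scenario("fig10"))
  expect_identical(figs1$trace, figs2$trace)
})

test_that("external stimuli are captured in FIFO order and unknowns drop", {
  circ <- vm_circuit(
    vm_thread("P", i_emit("excite")),
    vm_thread("Q", i_emit("inhibit")),
    links = list(), entry = c("P", "Q"), name = "fifo")
  m <- new_model(circ, stimuli = tibble::tibble(
    target = c("P", "Q", "nowhere"), stimulus = "excite", at_pass = 1L))
  vm_run(m)
  captured <- vapply(m$pending_stimuli, `[[`, "", "target")
  expect_identical(captured, c("P", "Q", "nowhere"))
  # the canonical order follows arrival order
  expect_identical(m$order, c("P", "Q"))
  # a stimulus naming no declared thread is logged and dropped, not an error
  expect_length(m$dropped_stimuli, 1L)
  expect_match(m$dropped_stimuli, "nowhere")
  # no-stimulus model stays unchanged
  m2 <- new_model(circ)
  vm_run(m2)
  expect_identical(nrow(vm_trace(m2)), 0L)
})

test_that("clocks advance by one per successful instruction and block on failure", {
  rep <- run_with_stimuli("transmission", stim("P"))
  clocks <- model_clocks(rep$model)
  expect_identical(clocks$clock[clocks$thread == "P"], 1L)
  expect_identical(clocks$clock[clocks$thread == "Q"], 2L)

  # a receive with nothing to consume fails and leaves the clock unchanged
  waiting <- vm_circuit(
    vm_thread("P", i_emit("excite")),
    vm_thread("Q", i_receive("P"), i_emit("excite")),
    links = vm_links(vm_link("P", "Q", weight = 1)),
    entry = c("P", "Q"), name = "waiting")
  m <- new_model(waiting, stimuli = tibble::tibble(
    target = c("P", "Q"), stimulus = "excite", at_pass = 1L))
  vm_run(m)
  clocks <- model_clocks(m)
  expect_identical(clocks$clock[clocks$thread == "Q"], 0L)
  expect_false(clocks$done[clocks$thread == "Q"])
})

test_that("a non-quiescing circuit is truncated at max_cycles, distinctly", {
  spinner <- vm_circuit(
    vm_thread("P", i_emit("excite", nxt = 1)),
    links = list(), entry = "P", name = "spinner")
  m <- new_model(spinner, stimuli = tibble::tibble(
    target = "P", stimulus = "excite", at_pass = 1L))
  vm_run(m, max_cycles = 25L)
  expect_true(m$truncated)
  expect_lte(m$pass, 25L)
  # bounded progress: at most one pass per cycle budget
  m2 <- new_model(spinner, stimuli = tibble::tibble(
    target = "P", stimulus = "excite", at_pass = 1L))
  vm_run(m2, max_cycles = 10L)
  expect_lte(m2$pass, 10L)
})

test_that("deduction walks the instruction tree and exhausts to NULL", {
  circ <- vm_circuit(
    vm_thread("P", i_emit("excite"), i_emit("inhibit"), i_stop()),
    links = list(), entry = "P", name = "linear")
  m <- new_model(circ)
  ins <- deduce_instruction(m, "P", T = 0)
  expect_identical(ins$args$stimulus, "excite")
  expect_identical(deduce_instruction(m, "P", T = 2)$op, "stop")
  expect_null(deduce_instruction(m, "P", T = 3))
  expect_null(deduce_instruction(m, "unknown"))
})

test_that("reflect reports the synchronized events of the current cycle", {
  m <- new_model(build_transmission(), stimuli = tibble::tibble(
    target = "P", stimulus = "excite", at_pass = 1L))
  seen <- list()
  for (k in 1:4) {
    m$pass <- m$pass + 1L
    vm_sense(m)
    vm_react(m)
    seen[[k]] <- vm_reflect(m)
  }
  # Q's excite surfaces in exactly one cycle's reflection
  n_events <- vapply(seen, nrow, 0L)
  expect_identical(sum(n_events), 1L)
  hit <- seen[[which(n_events == 1L)]]
  expect_identical(hit$thread, "Q")
  expect_identical(hit$stimulus, "excite")
})

test_that("simultaneous events share one stream sequence number", {
  rep <- run_scenario(list(circuit = "random_detector", fire = "right(3)",
                           choice = "forward", id = "sync"))
  tr <- rep$trace
  at3 <- tr[tr$seq == 3L & tr$stimulus == "excite", ]
  expect_identical(sort(at3$thread), c("detect(right(3))", "move(forward)"))
  expect_identical(rep$synchro_events$seq, 3L)
  expect_identical(rep$synchro_events$coordinate, "right(3)")
  # wrong-direction run: every I in 1..7 pairs a move excite with a
  # detect inhibit (hand-simulation oracle of the seven-position track)
  wrong <- run_scenario(list(circuit = "random_detector", fire = "right(3)",
                             choice = "backward", id = "pairs"))
  for (i in 1:7) {
    sl <- wrong$trace[wrong$trace$seq == i, ]
    expect_setequal(paste(sl$thread, sl$stimulus),
                    c("move(backward) excite", "detect(right(3)) inhibit"))
  }
})
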