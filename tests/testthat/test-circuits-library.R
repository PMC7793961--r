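test_that("synaptic transmission: one stimulus fires Q once; closed gate blocks", {
  rep <- run_with_stimuli("transmission", stim("P"))
  expect_identical(format_trace(rep$trace), "0: Q:excite")

  none <- run_scenario(list(circuit = "transmission", id = "none"))
  expect_identical(nrow(none$trace), 0L)
  expect_identical(none$outcome, "idle")

  blocked <- run_with_stimuli(build_transmission(weight = 0), stim("P"))
  expect_false(any(blocked$trace$origin == "thread"))
})

test_that("classical conditioning: cs acquires the reflex after one pairing", {
  # us alone: the unconditioned withdrawal reflex
  us <- run_with_stimuli("classical_conditioning", stim("sense(us)"))
  expect_true(any(us$trace$thread == "motor(us)" &
                    us$trace$stimulus == "excite"))

  # cs alone before pairing: only the weak (blocked-gate) response
  cs_pre <- run_with_stimuli("classical_conditioning", stim("sense(cs)"))
  expect_false(any(cs_pre$trace$stimulus == "excite"))

  # one pairing with cs slightly preceding us, then cs alone triggers motor(cs)
  pairing <- run_with_stimuli("classical_conditioning",
                              stim("sense(cs)", at_pass = 1L),
                              stim("sense(us)", at_pass = 2L))
  cs_post <- run_with_stimuli(pairing$circuit, stim("sense(cs)"))
  expect_true(any(cs_post$trace$thread == "motor(cs)" &
                    cs_post$trace$stimulus == "excite" &
                    cs_post$trace$origin == "thread"))
})

test_that("operant conditioning: negative stimuli open reject instead", {
  neg <- run_with_stimuli("operant_conditioning",
                          stim("sense"),
                          stim(NA_character_, "negative"))
  w <- neg$weights
  expect_true(w$open[w$to == "reject"])
  expect_false(w$open[w$to == "learn"])
  expect_false(w$open[w$to == "accept"])

  # no reinforcement: weights unchanged
  none <- run_with_stimuli("operant_conditioning", stim("sense"))
  expect_identical(none$weights$before, none$weights$after)
})

test_that("the random detector reproduces the published wrong-direction trace", {
  rep <- run_scenario(figure_scenario("fig10"))
  expect_identical(format_trace(rep$trace), c(
    "0: sense(right(3)):fetch(backward)",
    as.vector(rbind(sprintf("%d: move(backward):excite", 1:7),
                    sprintf("%d: detect(right(3)):inhibit", 1:7))),
    "8: move(backward):inhibit",
    "9: move(backward):inhibit",
    "9: move(backward):stop"))
  expect_identical(rep$outcome, "missed")
  expect_identical(rep$fetch_count, 1L)
})

test_that("the random detector reproduces the published correct-direction trace", {
  rep <- run_scenario(figure_scenario("fig11"))
  expect_identical(format_trace(rep$trace), c(
    "0: sense(right(3)):fetch(forward)",
    "1: move(forward):excite", "1: detect(right(3)):inhibit",
    "2: move(forward):excite", "2: detect(right(3)):inhibit",
    "3: move(forward):excite", "3: detect(right(3)):excite",
    "3: detect(right(3)):clear", "3: detect(right(3)):stop"))
  expect_identical(rep$outcome, "cleared")
})

test_that("the random detector never changes behavior across runs (no drift)", {
  circ <- build_random_detector()
  first <- run_scenario(list(circuit = circ, fire = "right(3)",
                             choice = "forward", id = "r1"))
  expect_identical(first$weights$before, first$weights$after)
  again <- run_scenario(list(circuit = first$circuit, fire = "right(3)",
                             choice = "backward", id = "r2"))
  expect_identical(again$weights$before, again$weights$after)
  expect_identical(link_table(again$circuit)$weight, link_table(circ)$weight)
})

test_that("instantiated learning opens recall and closes learn at the coordinate", {
  learned <- run_scenario(figure_scenario("fig14"))
  expect_identical(learned$outcome, "cleared")
  w <- link_table(learned$circuit)
  expect_true(w$open[w$from == "sense(right(3))" & w$to == "recall(forward)"])
  expect_false(w$open[w$from == "sense(right(3))" & w$to == "learn(right)"])
  # other coordinates keep their naive wiring
  expect_true(w$open[w$from == "sense(right(2))" & w$to == "learn(right)"])
  expect_false(w$open[w$from == "sense(right(2))" & w$to == "recall(forward)"])
})

test_that("a fire at an unlearned coordinate reverts to random choice", {
  sc14 <- figure_scenario("fig14")
  learned <- run_scenario(sc14)
  sc16 <- figure_scenario("fig16")
  sc16$circuit <- learned$circuit
  failed <- run_scenario(sc16)
  expect_identical(failed$outcome, "missed")
  expect_identical(failed$fetch_count, 1L)
  expect_true(any(failed$trace$thread == "learn(right)" &
                    startsWith(failed$trace$stimulus, "fetch")))
  # failure applies no weight change
  expect_identical(failed$weights$before, failed$weights$after)
})

test_that("generalized learning transfers across coordinates, not directions", {
  learned <- run_scenario(figure_scenario("fig17"))
  circ <- learned$circuit
  other <- run_scenario(list(circuit = circ, fire = "right(5)", id = "r5"))
  expect_identical(other$outcome, "cleared")
  expect_identical(other$fetch_count, 0L)
  expect_false(any(startsWith(other$trace$stimulus, "fetch")))
  # the opposite direction still goes through learn
  left <- run_scenario(list(circuit = other$circuit, fire = "left(4)",
                            choice = "backward", id = "l4"))
  expect_identical(left$fetch_count, 1L)
})
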