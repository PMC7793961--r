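test_that("term matching binds variables and respects the wildcard", {
  b <- mesovm:::term_match("sense(F(X))", "sense(right(3))")
  expect_identical(b$F, "right")
  expect_identical(b$X, "3")
  expect_null(mesovm:::term_match("sense(F(X))", "move(forward)"))
  # "_" matches exactly one term, without binding
  expect_identical(mesovm:::term_match("sense(right(_))", "sense(right(3))"),
                   list())
  expect_null(mesovm:::term_match("sense(_)", "sense(right(3),extra)"))
  # ground patterns outrank wildcard ones
  expect_gt(mesovm:::term_specificity("sense(right(3))"),
            mesovm:::term_specificity("sense(right(_))"))
})

test_that("compilation indexes every instruction and round-trips", {
  circ <- build_transmission()
  code <- compile_circuit(circ)
  expect_named(code$code, c("P", "Q"))
  expect_identical(code$code$P$body[[1]]$op, "send")
  expect_identical(code$code$Q$body[[1]]$index, 1L)
  expect_identical(code$code$Q$body[[2]]$index, 2L)
  expect_identical(decompile_circuit(code), circ)

  # empty circuit compiles to an empty repository
  empty <- vm_circuit(links = list(), entry = character(), name = "empty")
  expect_length(compile_circuit(empty)$code, 0L)
})

test_that("compile/decompile and file round-trips hold on random circuits", {
  set.seed(101)
  for (k in 1:20) {
    circ <- random_circuit()
    expect_identical(validate_circuit(circ), character())
    expect_identical(decompile_circuit(compile_circuit(circ)), circ)
    path <- withr::local_tempfile(fileext = ".circuit")
    write_circuit(circ, path)
    back <- read_circuit(path)
    expect_identical(format_circuit_text(back), format_circuit_text(circ))
    expect_identical(compile_circuit(back)$code, compile_circuit(circ)$code)
  }
})

test_that("library circuits round-trip through the file format", {
  for (build in list(build_classical_conditioning, build_operant_conditioning,
                     build_random_detector,
                     function() build_deterministic_detector(mode = "general"))) {
    circ <- build()
    path <- withr::local_tempfile(fileext = ".circuit")
    write_circuit(circ, path)
    expect_identical(format_circuit_text(read_circuit(path)),
                     format_circuit_text(circ))
  }
})

test_that("validation reports orphan receives and is sound", {
  # a receive with no matching send/link yields one diagnostic naming it
  broken <- vm_circuit(
    vm_thread("P", i_emit("excite")),
    vm_thread("Q", i_receive("P"), i_emit("excite")),
    links = list(), entry = "P", name = "broken")
  diags <- validate_circuit(broken)
  expect_length(diags, 1L)
  expect_match(diags, "receive\\(P\\)")
  expect_error(compile_circuit(broken), "does not compile")

  # well-formed circuits produce no diagnostics
  expect_identical(validate_circuit(build_transmission()), character())
  expect_identical(validate_circuit(build_random_detector()), character())
  expect_identical(validate_circuit(build_deterministic_detector()), character())
})

test_that("validation flags out-of-range targets and unbound variables", {
  bad_target <- vm_circuit(
    vm_thread("P", i_emit("excite", nxt = 9)),
    links = list(), entry = "P", name = "bad")
  expect_match(validate_circuit(bad_target), "out of range")

  unbound <- vm_circuit(
    vm_thread("P", i_fire("move(Y)")),
    vm_thread("move(Y)", i_emit("excite")),
    links = list(), entry = "P", name = "unbound")
  expect_match(validate_circuit(unbound), "unbound variable")
})

test_that("DOT rendering shows synapses and modulation", {
  dot <- render_circuit(build_transmission())
  expect_match(dot, "\"P\" -> \"Q\" \\[label=\"->=>-\"")
  expect_identical(length(gregexpr("->=>-", dot)[[1]]), 1L)

  dot5 <- render_circuit(build_classical_conditioning())
  # the ltp interneuron modulates the sense(cs) -> motor(cs) pathway
  expect_match(dot5, "/\\|\\\\\\\\ ltp\\(sense\\(cs\\)->motor\\(cs\\)\\)")
  # closed pathways are drawn dashed, open ones solid
  expect_match(dot5, "\"sense\\(cs\\)\" -> \"motor\\(cs\\)\".*dashed")
  expect_match(dot5, "\"sense\\(us\\)\" -> \"motor\\(us\\)\".*solid")

  empty <- vm_circuit(links = list(), entry = character(), name = "empty")
  expect_identical(render_circuit(empty), "digraph \"empty\" {\n}")
})

test_that("contextual deduction prefers ground code over wildcard code", {
  circ <- vm_circuit(
    vm_thread("right(3)", i_emit("excite")),
    vm_thread("right(X)", i_emit("inhibit")),
    links = list(), entry = character(), name = "specificity")
  m <- new_model(circ)
  ins <- deduce_instruction(m, "right(3)", T = 0)
  expect_identical(ins$args$stimulus, "excite")
  # the wildcard code still serves other coordinates
  ins5 <- deduce_instruction(m, "right(5)", T = 0)
  expect_identical(ins5$args$stimulus, "inhibit")
})

test_that("equally specific candidate code is a compile-integrity error", {
  circ <- vm_circuit(
    vm_thread("right(X)", i_emit("excite")),
    vm_thread("right(Y)", i_emit("inhibit")),
    links = list(), entry = character(), name = "ambiguous")
  m <- new_model(circ)
  expect_error(deduce_instruction(m, "right(3)"), "code-integrity")
})
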