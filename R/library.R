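#' Prebuilt circuits
#'
#' Builders for the tested library circuits: synaptic transmission,
#' classical conditioning, operant conditioning, the wired (non-plastic)
#' random fire detector, and the plastic deterministic detector in
#' instantiated or general (rule-learning) mode. Each builder returns a
#' [vm_circuit()] sharing the common circuit file format
#' ([write_circuit()]), so library circuits and user circuits are
#' interchangeable.
#'
#' @name circuits_library
NULL

#' Synaptic transmission fragment
#'
#' Two threads: `P` fires on an external stimulus and sends a signal over
#' the `P -> Q` synapse; `Q` waits for the reception and, if the weight
#' stands above the threshold, proceeds (emitting an excite stimulus).
#'
#' @param weight initial `P -> Q` weight (set 0 to force the gate closed).
#' @export
build_transmission <- function(weight = 1) {
  vm_circuit(
    vm_thread("P", i_send("Q")),
    vm_thread("Q", i_receive("P"), i_emit("excite")),
    links = vm_links(vm_link("P", "Q", weight = weight)),
    entry = "P",
    name = "transmission"
  )
}

#' Classical conditioning circuit
#'
#' A light conditioned stimulus `cs` elicits only a weak reflex (its
#' pathway to `motor(cs)` starts closed); a noxious unconditioned stimulus
#' `us` drives `motor(us)` through an open pathway and fires the `ltp`
#' facilitatory interneuron, a coincidence detector: when the `cs` signal
#' is present in the same stream window (cs slightly preceding us), `ltp`
#' reinforces the `sense(cs) -> motor(cs)` pathway, after which `cs` alone
#' triggers the enhanced withdrawal reflex.
#'
#' @export
build_classical_conditioning <- function() {
  vm_circuit(
    vm_thread("sense(cs)",
              i_merge("ltp(cs)"),
              i_send("motor(cs)")),
    vm_thread("sense(us)",
              i_fire("ltp(cs)"),
              i_send("motor(us)")),
    vm_thread("motor(X)",
              i_receive("sense(X)"),
              i_emit("excite")),
    vm_thread("ltp(cs)",
              i_join("sense(cs)"),
              i_ltp("sense(cs)", "motor(cs)")),
    links = vm_links(
      vm_link("sense(cs)", "motor(cs)", weight = 0),
      vm_link("sense(us)", "motor(us)", weight = 1)
    ),
    entry = c("sense(cs)", "sense(us)"),
    name = "classical_conditioning"
  )
}

#' Operant conditioning circuit
#'
#' At the beginning the pathway from `sense` to `learn` is open while the
#' pathways to `accept` and `reject` are closed. The `learn` thread is a
#' fork discriminating between positive and negative external stimuli and
#' directing synaptic plasticity: a positive outcome potentiates the
#' `accept` pathway and depresses the `learn` pathway (and symmetrically
#' for a negative outcome and `reject`), so that subsequent sense events
#' route through the disinhibited action pathway without learning —
#' inhibition allowing for disinhibition.
#'
#' @export
build_operant_conditioning <- function() {
  vm_circuit(
    vm_thread("sense",
              i_send("learn"),
              i_send("accept"),
              i_send("reject")),
    vm_thread("learn",
              i_receive("sense"),
              i_switch(positive = 3, negative = 5),
              i_ltp("sense", "accept"),
              i_ltd("sense", "learn", nxt = 7),
              i_ltp("sense", "reject"),
              i_ltd("sense", "learn")),
    vm_thread("accept",
              i_receive("sense"),
              i_emit("excite")),
    vm_thread("reject",
              i_receive("sense"),
              i_emit("inhibit")),
    links = vm_links(
      vm_link("sense", "learn", weight = 1),
      vm_link("sense", "accept", weight = 0),
      vm_link("sense", "reject", weight = 0)
    ),
    entry = "sense",
    name = "operant_conditioning"
  )
}

# Shared sensory-motor loop of the detector circuits: the detect thread
# re-checks the fire percept after every motor command (cued by the move
# thread) and cues the move thread back, so the two percepts on(F(X)) and
# at(F(X)) are evaluated under the same stream tick; the move thread
# confirms a track-limit inhibit once before committing to stop.
detector_detect_thread <- function() {
  vm_thread("detect(F(X))",
            i_receive("move(_)"),
            i_check("on(F(X))", excite = 4, inhibit = 3),
            i_send("move(_)", nxt = 1),
            i_clear(),
            i_stop())
}

detector_move_thread <- function() {
  vm_thread("move(Y)",
            i_drive(moved = 2, limit = 4),
            i_send("detect(_)"),
            i_receive("detect(_)", nxt = 1),
            i_drive(moved = 2, limit = 5),
            i_stop())
}

detector_protocol_links <- function() {
  list(vm_link("move(_)", "detect(_)", weight = 1),
       vm_link("detect(_)", "move(_)", weight = 1))
}

#' Random fire detector (wired decision tree)
#'
#' The non-plastic circuit: upon perceiving smoke, `sense(F(X))` draws a
#' random gear through `choice([forward,backward])` (producing an internal
#' fetch stimulus), arms the `detect(F(X))` thread, and starts `move(Y)`.
#' The detect and move threads then concurrently produce excite/inhibit
#' stimuli — `check(on(F(X)))` for hitting the fire, positional feedback
#' for track bounds — until either the fire is found (two synchronized
#' excites, then clear) or the track limit forces a stop. The circuit has
#' no plastic link: it cannot change its behavior across runs.
#'
#' @export
build_random_detector <- function() {
  vm_circuit(
    vm_thread("sense(F(X))",
              i_choice(c("forward", "backward"), var = "Y"),
              i_fire("detect(F(X))"),
              i_fire("move(Y)")),
    detector_detect_thread(),
    detector_move_thread(),
    links = detector_protocol_links(),
    entry = "sense(F(X))",
    name = "random_detector"
  )
}

#' Deterministic (plastic) fire detector
#'
#' Embeds the operant-conditioning fork into the random detector: the
#' sense thread now feeds a `learn(F)` pathway (initially open) and
#' `recall(forward)` / `recall(backward)` pathways (initially closed).
#' While unlearned, `learn` draws a random gear (fetch stimulus); when the
#' synchronization thread `synchro` observes the simultaneous excite
#' stimuli of `detect(F(X))` and `move(Y)` it potentiates the
#' `sense -> recall(Y)` link and depresses the `sense -> learn` link, so
#' subsequent fires in a learned situation are found deterministically,
#' with no fetch.
#'
#' In `"instantiated"` mode the plastic links are ground, one per track
#' coordinate: the vehicle learns single moves such as "if
#' detect(right(3)) then move(forward)". In `"general"` mode they are
#' wildcard links (`sense(right(_))`): one successful episode learns the
#' causality rule "if detect(right(_)) then move(forward)", transferring
#' to every coordinate in that direction.
#'
#' @param track_length coordinates per direction (default 7).
#' @param mode `"instantiated"` or `"general"`.
#' @export
build_deterministic_detector <- function(track_length = 7,
                                         mode = c("instantiated", "general")) {
  mode <- match.arg(mode)
  plastic <- list()
  add <- function(l) plastic[[length(plastic) + 1L]] <<- l
  if (mode == "instantiated") {
    for (d in c("right", "left")) {
      for (x in seq_len(track_length)) {
        s <- paste0("sense(", d, "(", x, "))")
        add(vm_link(s, paste0("learn(", d, ")"), weight = 1))
        add(vm_link(s, "recall(forward)", weight = 0))
        add(vm_link(s, "recall(backward)", weight = 0))
      }
    }
  } else {
    for (d in c("right", "left")) {
      s <- paste0("sense(", d, "(_))")
      add(vm_link(s, paste0("learn(", d, ")"), weight = 1))
      add(vm_link(s, "recall(forward)", weight = 0))
      add(vm_link(s, "recall(backward)", weight = 0))
    }
  }
  coord <- if (mode == "instantiated") "sense(F(X))" else "sense(F(_))"
  vm_circuit(
    vm_thread("sense(F(X))",
              i_fire("detect(F(X))"),
              i_send("learn(F)"),
              i_send("recall(forward)"),
              i_send("recall(backward)")),
    vm_thread("learn(F)",
              i_receive("sense(_)"),
              i_choice(c("forward", "backward"), var = "Y"),
              i_fire("move(Y)"),
              i_fire("synchro(Y)")),
    vm_thread("recall(Y)",
              i_receive("sense(_)"),
              i_fire("move(Y)"),
              i_fire("synchro(Y)")),
    detector_detect_thread(),
    detector_move_thread(),
    vm_thread("synchro(Y)",
              i_join("detect(F(X))"),
              i_join("move(Y)"),
              i_ltp(coord, "recall(Y)"),
              i_ltd(coord, "learn(F)")),
    links = c(detector_protocol_links(), plastic),
    entry = "sense(F(X))",
    name = paste0("deterministic_detector_", mode)
  )
}

#' Overwrite a declared link weight
#'
#' @param circuit a [vm_circuit()].
#' @param from,to exact declared endpoint patterns.
#' @param weight new weight.
#' @export
set_link_weight <- function(circuit, from, to, weight) {
  for (k in seq_along(circuit$links)) {
    l <- circuit$links[[k]]
    if (l$from == from && l$to == to) {
      circuit$links[[k]]$weight <- weight
      return(circuit)
    }
  }
  stop("no declared link ", from, " -> ", to, call. = FALSE)
}

# Carry learned weights from a finished model back into the circuit, so
# consecutive runs share plastic state (the environment-side reset between
# trials re-arms the world, not the circuit).
update_circuit_weights <- function(circuit, model) {
  for (k in seq_along(circuit$links)) {
    cl <- circuit$links[[k]]
    for (ml in model$links) {
      if (ml$from == cl$from && ml$to == cl$to) {
        circuit$links[[k]]$weight <- ml$weight
        break
      }
    }
  }
  circuit
}
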