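#' Run the virtual machine
#'
#' Executes the sense-act-reflect cycle over a model until quiescence, an
#' explicit `stop`, or `max_cycles` scheduler passes (reported as
#' truncation). Each cycle captures pending external stimuli (`sense`),
#' performs one deterministic round-robin pass over the runnable thread
#' instances in activation order (`react`: one instruction per instance per
#' pass; a failing instruction leaves the local clock unchanged and is
#' retried on a later pass), and reports the synchronized events recorded
#' under the current stream sequence number (`reflect`).
#'
#' Termination:
#' \itemize{
#'   \item quiescence — a pass in which no stimulus was captured and no
#'     instruction succeeded is a fixpoint: the state can no longer change,
#'     and the run halts normally;
#'   \item `stop` — the stream's motor activity ends; residual signalling
#'     (e.g. plasticity enabled at the synchronization tick) drains to the
#'     fixpoint;
#'   \item truncation at `max_cycles`, flagged in the model and reported
#'     distinctly from normal termination.
#' }
#'
#' @param model a [new_model()].
#' @param max_cycles positive integer bound on scheduler passes.
#' @return the model, invisibly; retrieve the trace with [vm_trace()].
#' @seealso [run_scenario()] for the high-level runner.
#' @export
vm_run <- function(model, max_cycles = 500L) {
  stopifnot(inherits(model, "vm_model"), max_cycles > 0L)
  check_code_integrity(model)
  repeat {
    if (model$pass >= max_cycles) {
      model$truncated <- TRUE
      break
    }
    model$pass <- model$pass + 1L
    captured <- vm_sense(model)
    progressed <- vm_react(model)
    if (!captured && !progressed && !stimuli_pending(model)) {
      break  # fixpoint: quiescent halt
    }
  }
  flush_knocks(model)  # gate events with no later tick report at the final I
  model$halted <- TRUE
  invisible(model)
}

stimuli_pending <- function(model) {
  any(!model$stimuli$delivered)
}

check_code_integrity <- function(model) {
  for (key in names(model$code)) {
    entry <- model$code[[key]]
    n <- length(entry$body)
    for (k in seq_len(n)) {
      ins <- entry$body[[k]]
      if (is.null(ins$op)) {
        stop("code-integrity error: malformed instruction in ", key, call. = FALSE)
      }
      targets <- if (!is.null(ins$br)) unlist(ins$br) else ins$nxt
      targets <- targets[!is.na(targets)]
      if (ins$op != "stop" && length(targets) == 0L && k < n) next
      if (any(targets < 1L | targets > n + 1L)) {
        stop("code-integrity error: control target out of range in ", key,
             call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Capture pending external stimuli
#'
#' Appends every due external stimulus to the model's capture buffer in
#' arrival order and fires the matching declared sense thread. A stimulus
#' naming no declared thread is logged and dropped. `positive` / `negative`
#' reinforcement stimuli are posted as coincidence tokens for the learn
#' fork rather than firing a thread.
#'
#' @param model a [new_model()].
#' @return `TRUE` if any stimulus was captured this cycle.
#' @export
vm_sense <- function(model) {
  if (model$stopped) return(FALSE)
  due <- which(!model$stimuli$delivered & model$stimuli$at_pass <= model$pass)
  if (length(due) == 0L) return(FALSE)
  for (k in due) {
    target <- model$stimuli$target[k]
    stim <- model$stimuli$stimulus[k]
    model$stimuli$delivered[k] <- TRUE
    model$pending_stimuli[[length(model$pending_stimuli) + 1L]] <-
      list(target = target, stimulus = stim, pass = model$pass)
    if (stim %in% c("positive", "negative")) {
      post_token(model, stim)
      next
    }
    hit <- tryCatch(resolve_code(model, target), error = function(e) stop(e))
    if (is.null(hit)) {
      model$dropped_stimuli <- c(
        model$dropped_stimuli,
        paste0("dropped external stimulus for undeclared thread: ", target))
      next
    }
    activate_instance(model, target, by = "external")
  }
  TRUE
}

#' One scheduler pass
#'
#' For each runnable thread instance in canonical (activation) order,
#' deduce the next instruction at the thread's local time `T` and execute
#' it; on success the clock advances by one, on failure the instruction is
#' left in place to be retried. Instances activated during a pass take
#' their first turn on the following pass.
#'
#' @param model a [new_model()].
#' @return `TRUE` if at least one instruction succeeded.
#' @export
vm_react <- function(model) {
  progressed <- FALSE
  for (nm in model$order) {    # snapshot: mid-pass activations wait a pass
    inst <- model$instances[[nm]]
    if (inst$done) next
    entry <- model$code[[inst$key]]
    if (inst$pc > length(entry$body)) {     # instruction tree exhausted
      inst$done <- TRUE
      model$instances[[nm]] <- inst
      next
    }
    ins <- entry$body[[inst$pc]]
    res <- execute_instruction(model, inst, ins)
    inst <- model$instances[[nm]]  # execution may have updated bindings
    if (isTRUE(res$ok)) {
      progressed <- TRUE
      inst$clock <- inst$clock + 1L
      inst$successes <- inst$successes + 1L
      nxt <- if (!is.na(res$pc)) res$pc else ins$nxt
      if (is.na(nxt) || nxt > length(entry$body)) {
        inst$done <- TRUE
      } else {
        inst$pc <- as.integer(nxt)
      }
      model$instances[[nm]] <- inst
    }
  }
  progressed
}

#' Report the events of the current cycle
#'
#' Returns every (I, thread, stimulus) event recorded during the latest
#' scheduler pass; simultaneous events share the stream sequence number.
#'
#' @param model a [new_model()].
#' @return a tibble of trace events (possibly empty).
#' @export
vm_reflect <- function(model) {
  evs <- Filter(function(e) e$pass == model$pass, model$events)
  events_tibble(evs)
}

#' Deduce the next instruction of a thread
#'
#' Contextual deduction: the instruction executed by `thread` at its local
#' time `T` under the thread's current parameter bindings, or `NULL` when
#' the instruction tree is exhausted. For a thread with no active instance
#' the lookup resolves the most specific compiled code for the pattern
#' (ground code outranks wildcard code) and indexes its body directly, so
#' `T` counts from 0 at the first instruction.
#'
#' @param model a [new_model()].
#' @param thread thread instance string.
#' @param T local time (defaults to the instance's current clock).
#' @return a `vm_instr` or `NULL`.
#' @export
deduce_instruction <- function(model, thread, T = NULL) {
  inst <- model$instances[[thread]]
  if (!is.null(inst)) {
    if (!is.null(T) && T != inst$clock) {
      return(NULL)  # only the current local time is deducible in context
    }
    entry <- model$code[[inst$key]]
    if (inst$done || inst$pc > length(entry$body)) return(NULL)
    return(entry$body[[inst$pc]])
  }
  hit <- resolve_code(model, thread)
  if (is.null(hit)) return(NULL)
  body <- model$code[[hit$key]]$body
  idx <- (if (is.null(T)) 0L else as.integer(T)) + 1L
  if (idx < 1L || idx > length(body)) return(NULL)
  body[[idx]]
}

# -- instruction execution ----------------------------------------------------

# Returns list(ok = logical, pc = integer target or NA for fall-through).
execute_instruction <- function(model, inst, ins) {
  ok <- function(pc = NA_integer_) list(ok = TRUE, pc = as.integer(pc))
  fail <- list(ok = FALSE, pc = NA_integer_)

  switch(ins$op,
    fire = {
      tgt <- term_subst(ins$args$thread, inst$bindings)
      activate_instance(model, tgt, by = "fire")
      ok()
    },
    send = {
      tgt <- term_subst(ins$args$target, inst$bindings)
      tgt_resolved <- resolve_recipient(model, tgt)
      li <- resolve_link_idx(model, inst$name, tgt_resolved %||% tgt)
      if (is.null(li)) {
        stop("send over undeclared link: ", inst$name, " -> ", tgt, call. = FALSE)
      }
      l <- model$links[[li]]
      l$queue <- l$queue + 1L
      l$sends <- l$sends + 1L
      model$links[[li]] <- l
      if (link_is_open(l)) {
        if (!is.null(tgt_resolved)) activate_instance(model, tgt_resolved, by = "send")
      } else {
        # closed gate: the signal knocks, the recipient is never fired
        model$knock_buffer[[length(model$knock_buffer) + 1L]] <-
          list(thread = tgt_resolved %||% tgt)
      }
      ok()
    },
    receive = {
      src <- term_subst(ins$args$source, inst$bindings)
      li <- receive_link_idx(model, src, inst$name)
      if (is.null(li)) return(fail)
      l <- model$links[[li]]
      l$queue <- l$queue - 1L
      l$receives <- l$receives + 1L
      model$links[[li]] <- l
      ok()
    },
    join = {
      peer <- term_subst(ins$args$peer, inst$bindings)
      hit <- NULL
      for (tok in model$board) {
        if (tok$seq != model$seq) next
        b <- term_match(peer, tok$emitter, inst$bindings)
        if (!is.null(b)) { hit <- b; break }
      }
      if (is.null(hit)) return(fail)
      inst$bindings <- hit   # join extends the context bindings
      model$instances[[inst$name]] <- inst
      ok()
    },
    merge = {
      post_token(model, inst$name)
      ok()
    },
    choice = {
      alts <- ins$args$alternatives
      pick <- if (!is.null(model$forced_choice)) {
        model$forced_choice
      } else {
        alts[sample.int(length(alts), 1L)]
      }
      if (!pick %in% alts) {
        stop("forced choice ", pick, " is not among the alternatives", call. = FALSE)
      }
      inst$bindings[[ins$args$var]] <- pick
      model$instances[[inst$name]] <- inst
      emit_event(model, inst$name, paste0("fetch(", pick, ")"))
      ok()
    },
    check = {
      if (is.null(model$world)) {
        stop("check without an environment (no world attached)", call. = FALSE)
      }
      pred <- term_parse(ins$args$condition)$f
      res <- switch(pred,
        on = check_on(model$world),
        at = check_at(model$world),
        stop("unknown environment predicate: ", pred, call. = FALSE))
      emit_event(model, inst$name, res)
      if (res == "excite") post_token(model, inst$name)
      ok(ins$br[[res]])
    },
    drive = {
      if (is.null(model$world)) {
        stop("drive without an environment (no world attached)", call. = FALSE)
      }
      if (model$stopped) return(fail)
      gear <- inst$bindings$Y %||% term_parse(inst$name)$args[[1]]$f
      w <- model$world
      w$gear <- gear
      dir <- w$gear_map[[gear]]
      nxt_x <- if (is.null(w$position)) 1L else w$position$x + 1L
      # one motor command = one stream tick, displacement or not
      model$seq <- model$seq + 1L
      flush_knocks(model)
      if (nxt_x <= w$length) {
        move_step(w, gear)
        emit_event(model, inst$name, "excite")
        post_token(model, inst$name)
        ok(ins$br$excite)
      } else {
        emit_event(model, inst$name, "inhibit")
        ok(ins$br$inhibit)
      }
    },
    switch = {
      hit <- NULL
      for (k in seq_along(model$board)) {
        tok <- model$board[[k]]
        if (tok$seq == model$seq && tok$emitter %in% c("positive", "negative")) {
          hit <- k
          break
        }
      }
      if (is.null(hit)) return(fail)
      stim <- model$board[[hit]]$emitter
      model$board[[hit]] <- NULL   # reinforcement is consumed
      ok(ins$br[[stim]])
    },
    emit = {
      stim <- ins$args$stimulus
      emit_event(model, inst$name, stim)
      if (stim == "excite") post_token(model, inst$name)
      ok()
    },
    clear = {
      clear_fire(model$world)
      emit_event(model, inst$name, "clear")
      ok()
    },
    stop = {
      model$stopped <- TRUE
      if (!is.null(model$world)) world_stop(model$world)
      emit_event(model, inst$name, "stop")
      ok()
    },
    ltp = apply_plasticity(model, inst, ins, +1),
    ltd = apply_plasticity(model, inst, ins, -1),
    stop("code-integrity error: unknown opcode ", ins$op, call. = FALSE)
  )
}

apply_plasticity <- function(model, inst, ins, sign) {
  from <- term_subst(ins$args$from, inst$bindings)
  to <- term_subst(ins$args$to, inst$bindings)
  li <- resolve_link_idx(model, from, to)
  if (is.null(li)) {
    stop(if (sign > 0) "ltp" else "ltd", " on undeclared link: ",
         from, " -> ", to, call. = FALSE)
  }
  l <- model$links[[li]]
  before <- l$weight
  l$weight <- l$weight + sign * (if (sign > 0) l$delta_up else l$delta_down)
  model$links[[li]] <- l
  model$weight_log[[length(model$weight_log) + 1L]] <- list(
    op = if (sign > 0) "ltp" else "ltd",
    link = link_id(l), before = before, after = l$weight,
    seq = model$seq, pass = model$pass)
  list(ok = TRUE, pc = NA_integer_)
}

# Resolve a (possibly wildcard) send target to a unique active instance;
# NULL when no active instance matches (the signal waits on the queue).
resolve_recipient <- function(model, tgt) {
  if (term_is_ground(tgt)) return(tgt)
  hits <- character()
  for (nm in model$order) {
    if (!is.null(term_match(tgt, nm))) hits <- c(hits, nm)
  }
  if (length(hits) == 1L) return(hits)
  if (length(hits) == 0L) return(NULL)
  stop("ambiguous send target ", tgt, " (matches: ",
       paste(hits, collapse = ", "), ")", call. = FALSE)
}

# Most specific declared link with a consumable signal for receive(src, self).
receive_link_idx <- function(model, src, self) {
  best <- NULL
  best_spec <- -1L
  for (k in seq_along(model$links)) {
    l <- model$links[[k]]
    if (l$queue >= 1L && link_is_open(l) &&
        term_unifies(l$from, src) && term_unifies(l$to, self)) {
      if (l$spec > best_spec) {
        best <- k
        best_spec <- l$spec
      }
    }
  }
  best
}

`%||%` <- function(a, b) if (is.null(a)) b else a

events_tibble <- function(evs) {
  tibble::tibble(
    seq = vapply(evs, function(e) as.integer(e$seq), 0L),
    thread = vapply(evs, `[[`, "", "thread"),
    stimulus = vapply(evs, `[[`, "", "stimulus"),
    origin = vapply(evs, `[[`, "", "origin"),
    pass = vapply(evs, function(e) as.integer(e$pass), 0L)
  )
}

#' Trace of a model run
#'
#' @param model a [new_model()] after [vm_run()].
#' @return a tibble of trace events `(seq, thread, stimulus, origin, pass)`,
#'   ordered by non-decreasing stream sequence number; events sharing `seq`
#'   are synchronized (simultaneous at the meso scale).
#' @export
vm_trace <- function(model) {
  tr <- events_tibble(model$events)
  class(tr) <- c("vm_trace", class(tr))
  tr
}
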