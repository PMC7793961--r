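#' Virtual-machine instructions
#'
#' Constructors for the instruction nodes that make up a thread body. A body
#' is a finite numbered list of instructions; control flow is explicit:
#' every instruction carries a `nxt` target (default: the following index),
#' and branching instructions (`check`, `drive`, `switch`) carry a branch
#' map from outcome to target index. A target pointing past the end of the
#' body ends the thread; a target pointing backwards forms the
#' resume-detecting / resume-moving loops of sensory and motor threads.
#'
#' Opcodes:
#' \describe{
#'   \item{send(target)}{non-blocking synaptic transmission: enqueue one
#'     signal on the link from this thread to `target`; if the link is OPEN
#'     (weight > threshold) the recipient is fired, otherwise the signal
#'     knocks at the closed gate and an inhibit event is reported.}
#'   \item{receive(source)}{blocking reception: succeeds iff a signal is
#'     queued on the link from `source` and that link is OPEN; consumes one
#'     signal. Fails (and is retried) otherwise.}
#'   \item{join(peer)}{coincidence detection: succeeds iff `peer` has posted
#'     a token (an explicit `merge` or any excite emission) at the current
#'     stream tick.}
#'   \item{merge(peer)}{post a coincidence token for `peer`.}
#'   \item{fire(thread)}{activate a thread instance.}
#'   \item{choice(alternatives, var)}{draw one alternative (or take the
#'     scenario-forced one), bind it to `var`, and emit a `fetch(<choice>)`
#'     stimulus.}
#'   \item{check(condition)}{evaluate an environment predicate (`on(F(X))`:
#'     fire at the vehicle's position; `at(F(X))`: queried position lies on
#'     the track) and emit the resulting excite/inhibit stimulus; branches
#'     on the outcome.}
#'   \item{drive}{the motor primitive: one motor command. Advances the
#'     stream tick, attempts a one-step move in the direction of the
#'     engaged gear, and emits the positional excite (moved) or inhibit
#'     (track limit) feedback; branches on the outcome.}
#'   \item{switch}{the operant learn-fork: branches on a pending positive
#'     or negative external stimulus; fails (retries) while none is
#'     pending.}
#'   \item{emit(stimulus)}{report a stimulus (excite, inhibit, positive,
#'     negative, ...) as a trace event.}
#'   \item{clear}{clear the fire at the vehicle's position.}
#'   \item{stop}{stop the stream: motor activity ends, residual signalling
#'     drains, the run outcome is fixed.}
#'   \item{ltp(from, to) / ltd(from, to)}{long-term potentiation /
#'     depression: increment / decrement the weight of the declared link
#'     matching `from -> to`.}
#' }
#'
#' @param target,source,peer,thread term strings naming thread patterns.
#' @param alternatives character vector of choice alternatives.
#' @param var name of the variable the choice result is bound to.
#' @param condition predicate term such as `"on(F(X))"`.
#' @param stimulus stimulus name.
#' @param from,to link endpoint patterns.
#' @param excite,inhibit,moved,limit,positive,negative,nxt explicit control
#'   targets (instruction indices within the body).
#' @return an instruction node (named list) for use in [vm_thread()].
#' @name instructions
NULL

new_instr <- function(op, args = list(), nxt = NA_integer_, br = NULL) {
  structure(list(op = op, args = args, nxt = nxt, br = br),
            class = "vm_instr")
}

#' @rdname instructions
#' @export
i_send <- function(target, nxt = NA) new_instr("send", list(target = target), as.integer(nxt))

#' @rdname instructions
#' @export
i_receive <- function(source, nxt = NA) new_instr("receive", list(source = source), as.integer(nxt))

#' @rdname instructions
#' @export
i_join <- function(peer, nxt = NA) new_instr("join", list(peer = peer), as.integer(nxt))

#' @rdname instructions
#' @export
i_merge <- function(peer, nxt = NA) new_instr("merge", list(peer = peer), as.integer(nxt))

#' @rdname instructions
#' @export
i_fire <- function(thread, nxt = NA) new_instr("fire", list(thread = thread), as.integer(nxt))

#' @rdname instructions
#' @export
i_choice <- function(alternatives, var = "Y", nxt = NA) {
  stopifnot(length(alternatives) >= 1L)
  new_instr("choice", list(alternatives = alternatives, var = var), as.integer(nxt))
}

#' @rdname instructions
#' @export
i_check <- function(condition, excite, inhibit) {
  new_instr("check", list(condition = condition),
            br = list(excite = as.integer(excite), inhibit = as.integer(inhibit)))
}

#' @rdname instructions
#' @export
i_drive <- function(moved, limit) {
  new_instr("drive", list(),
            br = list(excite = as.integer(moved), inhibit = as.integer(limit)))
}

#' @rdname instructions
#' @export
i_switch <- function(positive, negative) {
  new_instr("switch", list(),
            br = list(positive = as.integer(positive), negative = as.integer(negative)))
}

#' @rdname instructions
#' @export
i_emit <- function(stimulus, nxt = NA) new_instr("emit", list(stimulus = stimulus), as.integer(nxt))

#' @rdname instructions
#' @export
i_clear <- function(nxt = NA) new_instr("clear", list(), as.integer(nxt))

#' @rdname instructions
#' @export
i_stop <- function() new_instr("stop", list())

#' @rdname instructions
#' @export
i_ltp <- function(from, to, nxt = NA) new_instr("ltp", list(from = from, to = to), as.integer(nxt))

#' @rdname instructions
#' @export
i_ltd <- function(from, to, nxt = NA) new_instr("ltd", list(from = from, to = to), as.integer(nxt))

#' @export
format.vm_instr <- function(x, ...) {
  arg_str <- switch(x$op,
    send = , receive = , join = , merge = , fire = unlist(x$args, use.names = FALSE)[1],
    choice = paste0("[", paste(x$args$alternatives, collapse = ","), "]->", x$args$var),
    check = x$args$condition,
    emit = x$args$stimulus,
    ltp = , ltd = paste0(x$args$from, "->", x$args$to),
    ""
  )
  core <- if (nzchar(arg_str)) paste0(x$op, "(", arg_str, ")") else x$op
  flow <- character()
  if (!is.null(x$br)) {
    flow <- paste0(" ? ", paste(names(x$br), unlist(x$br), sep = " -> ", collapse = " : "))
  } else if (!is.na(x$nxt)) {
    flow <- paste0(" -> ", x$nxt)
  }
  paste0(core, flow)
}

#' @export
print.vm_instr <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
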