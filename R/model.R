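#' Machine state
#'
#' `new_model()` instantiates the virtual-machine state for one compiled
#' circuit: the code repository, per-thread-instance local clocks `T`
#' (micro-scale time), the stream sequence counter `I` (meso-scale time),
#' per-link signal queues and weights, the coincidence board, the captured
#' external stimuli, and the event trace under construction. The model is
#' an environment (reference semantics): the kernel mutates it in place and
#' run functions return it invisibly.
#'
#' @param code a compiled circuit from [compile_circuit()] (a raw
#'   [vm_circuit()] is accepted and compiled on the fly).
#' @param world optional [vehicle_world()] for circuits with environment
#'   percepts (`check`, `drive`, `clear`).
#' @param stimuli a data frame / tibble of external stimuli with columns
#'   `target` (thread pattern string, or `NA` for free-floating
#'   positive/negative reinforcement), `stimulus` (stimulus name) and
#'   optionally `at_pass` (scheduler pass at which the stimulus arrives;
#'   default 1).
#' @param forced_choice optional forced outcome for `choice` instructions
#'   (e.g. `"backward"`); `NULL` leaves choices random.
#' @return an environment of class `vm_model`.
#' @export
new_model <- function(code, world = NULL, stimuli = NULL, forced_choice = NULL) {
  if (inherits(code, "vm_circuit")) code <- compile_circuit(code)
  stopifnot(inherits(code, "vm_code"))
  m <- new.env(parent = emptyenv())
  m$code <- code$code
  m$entry <- code$entry
  m$circuit_name <- code$name
  # mutable link records: declared links plus runtime counters
  m$links <- lapply(code$links, function(l) {
    l$queue <- 0L
    l$sends <- 0L
    l$receives <- 0L
    l$spec <- term_specificity(l$from) + term_specificity(l$to)
    l
  })
  m$initial_weights <- vapply(m$links, `[[`, 0, "weight")
  m$world <- world
  m$seq <- 0L                      # stream sequence number I
  m$pass <- 0L                     # scheduler pass counter
  m$instances <- list()
  m$order <- character()           # canonical order = activation order
  m$act_counter <- 0L
  m$board <- list()                # coincidence tokens (emitter, seq, pass)
  m$events <- list()
  m$knock_buffer <- list()         # blocked-gate inhibits awaiting their tick
  m$pending_stimuli <- list()      # captured external inputs, arrival order
  m$dropped_stimuli <- character()
  m$stopped <- FALSE
  m$truncated <- FALSE
  m$halted <- FALSE
  m$forced_choice <- forced_choice
  m$weight_log <- list()
  if (is.null(stimuli)) {
    stimuli <- tibble::tibble(target = character(), stimulus = character(),
                              at_pass = integer())
  }
  stimuli <- tibble::as_tibble(stimuli)
  if (!"at_pass" %in% names(stimuli)) stimuli$at_pass <- 1L
  stimuli$at_pass[is.na(stimuli$at_pass)] <- 1L
  stimuli$delivered <- FALSE
  m$stimuli <- stimuli
  class(m) <- c("vm_model", "environment")
  m
}

#' @export
print.vm_model <- function(x, ...) {
  cat("<vm_model> ", x$circuit_name, ": I = ", x$seq, ", pass = ", x$pass,
      ", ", length(x$instances), " thread instance(s), ",
      length(x$events), " event(s)\n", sep = "")
  invisible(x)
}

# -- code and link resolution -------------------------------------------------

# Most specific code entry whose head matches the instance string; two
# equally specific distinct candidates constitute a compile-integrity error.
resolve_code <- function(model, instance_str) {
  hits <- list()
  for (key in names(model$code)) {
    entry <- model$code[[key]]
    b <- term_match(entry$head_term, instance_str)
    if (!is.null(b) || identical(entry$head, instance_str)) {
      if (is.null(b)) b <- list()
      hits[[length(hits) + 1L]] <- list(key = key, bindings = b,
                                        spec = entry$specificity)
    }
  }
  if (length(hits) == 0L) return(NULL)
  specs <- vapply(hits, `[[`, 0L, "spec")
  best <- which(specs == max(specs))
  if (length(best) > 1L) {
    stop("code-integrity error: equally specific code for ", instance_str,
         " (", paste(vapply(hits[best], `[[`, "", "key"), collapse = ", "), ")",
         call. = FALSE)
  }
  hits[[best]]
}

# Most specific declared link whose endpoints unify with (from, to).
resolve_link_idx <- function(model, from, to) {
  best <- 0L
  best_spec <- -1L
  for (k in seq_along(model$links)) {
    l <- model$links[[k]]
    if (term_unifies(l$from, from) && term_unifies(l$to, to)) {
      if (l$spec > best_spec) {
        best <- k
        best_spec <- l$spec
      }
    }
  }
  if (best == 0L) NULL else best
}

link_is_open <- function(l) l$weight > l$threshold

link_id <- function(l) paste0(l$from, " -> ", l$to)

# -- instance management ------------------------------------------------------

activate_instance <- function(model, instance_str, by = "fire") {
  inst <- model$instances[[instance_str]]
  if (!is.null(inst)) {
    if (inst$done) {          # re-arm a completed thread, clock is cumulative
      inst$pc <- 1L
      inst$done <- FALSE
      model$instances[[instance_str]] <- inst
    }
    return(invisible(TRUE))
  }
  hit <- resolve_code(model, instance_str)
  if (is.null(hit)) {
    stop("no compiled code for thread ", instance_str, call. = FALSE)
  }
  model$act_counter <- model$act_counter + 1L
  model$instances[[instance_str]] <- list(
    name = instance_str,
    key = hit$key,
    bindings = hit$bindings,
    pc = 1L,
    clock = 0L,
    successes = 0L,
    done = FALSE,
    act_seq = model$act_counter,
    activated_by = by
  )
  model$order <- c(model$order, instance_str)
  invisible(TRUE)
}

emit_event <- function(model, thread, stimulus, origin = "thread") {
  model$events[[length(model$events) + 1L]] <- list(
    seq = model$seq, thread = thread, stimulus = stimulus,
    origin = origin, pass = model$pass)
  invisible(NULL)
}

post_token <- function(model, emitter) {
  model$board[[length(model$board) + 1L]] <- list(
    emitter = emitter, seq = model$seq, pass = model$pass)
  invisible(NULL)
}

# Blocked-gate inhibits are meso events occurring between stream ticks; they
# are reported at the following tick (or at the final tick if the stream
# ends first).
flush_knocks <- function(model) {
  for (k in model$knock_buffer) {
    emit_event(model, k$thread, "inhibit", origin = "gate")
  }
  model$knock_buffer <- list()
  invisible(NULL)
}

#' Current link-weight table of a model
#'
#' @param model a [new_model()].
#' @return tibble with link endpoints, weight, threshold, open status and
#'   signal counters (sends, receives, queued).
#' @export
model_links <- function(model) {
  ls <- model$links
  tibble::tibble(
    from = vapply(ls, `[[`, "", "from"),
    to = vapply(ls, `[[`, "", "to"),
    weight = vapply(ls, `[[`, 0, "weight"),
    threshold = vapply(ls, `[[`, 0, "threshold"),
    open = vapply(ls, link_is_open, TRUE),
    queued = vapply(ls, `[[`, 0L, "queue"),
    sends = vapply(ls, `[[`, 0L, "sends"),
    receives = vapply(ls, `[[`, 0L, "receives")
  )
}

#' Per-instance clock table of a model
#'
#' One row per active thread instance: local clock `T`, number of
#' successful instruction executions (always equal to the clock), program
#' position, and activation provenance.
#'
#' @param model a [new_model()].
#' @export
model_clocks <- function(model) {
  is_ <- unname(model$instances[model$order])
  tibble::tibble(
    thread = vapply(is_, `[[`, "", "name"),
    clock = vapply(is_, `[[`, 0L, "clock"),
    successes = vapply(is_, `[[`, 0L, "successes"),
    pc = vapply(is_, `[[`, 0L, "pc"),
    done = vapply(is_, `[[`, TRUE, "done"),
    activated_by = vapply(is_, `[[`, "", "activated_by")
  )
}
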