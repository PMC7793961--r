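#' The vehicle world: a finite bidirectional one-dimensional track
#'
#' The track has discrete coordinates `F(X)` with `F` = right or left and
#' `X = 1..length_per_direction`; `_(0)` is the vehicle's home station. The
#' vehicle has a forward and a backward gear; which direction each gear
#' drives in is the environment's hidden ground truth (forward -> right,
#' backward -> left) — circuits never encode this mapping and must discover
#' it. A fire may burn at one coordinate; its smoke (same direction) is
#' what arms the vehicle's sense thread.
#'
#' @param length_per_direction positive integer track length per direction.
#' @param fire optional fire coordinate as a term string, e.g. `"right(3)"`.
#' @param smoke optional smoke direction (`"right"` or `"left"`); defaults
#'   to the fire's direction.
#' @return an environment of class `vehicle_world` holding the track, the
#'   vehicle state (position, gear, detector flag), the stream sequence
#'   counter and the run outcome.
#' @examples
#' w <- vehicle_world(7, fire = "right(3)")
#' check_on(w)              # "inhibit": vehicle at home
#' move_step(w, "forward")  # home -> right(1)
#' @export
vehicle_world <- function(length_per_direction = 7, fire = NULL, smoke = NULL) {
  stopifnot(length_per_direction >= 1)
  w <- new.env(parent = emptyenv())
  w$length <- as.integer(length_per_direction)
  w$fire <- NULL
  if (!is.null(fire)) {
    ft <- term_parse(fire)
    dir <- ft$f
    x <- as.integer(ft$args[[1]]$f)
    if (!dir %in% c("right", "left")) stop("fire direction must be right or left")
    if (x < 1L || x > w$length) stop("fire lies outside the track")
    w$fire <- list(dir = dir, x = x)
  }
  w$smoke <- if (!is.null(smoke)) smoke else if (!is.null(w$fire)) w$fire$dir else NULL
  if (!is.null(w$smoke) && !is.null(w$fire) && w$smoke != w$fire$dir) {
    stop("smoke direction must equal the fire direction")
  }
  w$gear_map <- c(forward = "right", backward = "left")
  w$position <- NULL          # NULL = home _(0)
  w$gear <- NULL
  w$detector_on <- FALSE
  w$moves <- 0L
  w$seq <- 0L                 # stream sequence number I
  w$cleared <- FALSE
  w$stopped <- FALSE
  w$outcome <- NA_character_
  class(w) <- c("vehicle_world", "environment")
  w
}

position_string <- function(world) {
  if (is.null(world$position)) "_(0)"
  else paste0(world$position$dir, "(", world$position$x, ")")
}

#' @export
print.vehicle_world <- function(x, ...) {
  cat("<vehicle_world> track 1..", x$length, " per direction; vehicle at ",
      position_string(x),
      if (!is.null(x$fire)) paste0("; fire at ", x$fire$dir, "(", x$fire$x, ")")
      else "; no fire",
      "\n", sep = "")
  invisible(x)
}

#' Fire-at-position percept
#'
#' `check_on()` implements the `on(F(X))` predicate: excite iff the
#' vehicle's current position equals the fire position (detector on),
#' inhibit otherwise.
#'
#' @param world a [vehicle_world()].
#' @return `"excite"` or `"inhibit"`.
#' @export
check_on <- function(world) {
  if (is.null(world$position) || is.null(world$fire) || !world$detector_on) {
    return("inhibit")
  }
  same <- identical(world$position$dir, world$fire$dir) &&
    world$position$x == world$fire$x
  if (same) "excite" else "inhibit"
}

#' Track-bounds percept
#'
#' `check_at()` implements the `at(F(X))` predicate for the queried next
#' position: excite iff the coordinate is defined on the track
#' (`X <= length`), inhibit when it would exceed the limit.
#'
#' @param world a [vehicle_world()].
#' @param x coordinate index queried (defaults to one step beyond the
#'   current position in the engaged gear's direction).
#' @return `"excite"` or `"inhibit"`.
#' @export
check_at <- function(world, x = NULL) {
  if (is.null(x)) {
    x <- if (is.null(world$position)) 1L else world$position$x + 1L
  }
  if (x >= 0L && x <= world$length) "excite" else "inhibit"
}

#' Move one step in the engaged gear's direction
#'
#' forward: home -> right(1), right(X) -> right(X+1); backward: home ->
#' left(1), left(X) -> left(X+1). The stream sequence number is incremented
#' after the move. Moving with no gear engaged, or beyond the track limit,
#' is a contract violation (a circuit bug) and raises an error.
#'
#' @param world a [vehicle_world()].
#' @param gear `"forward"` or `"backward"`; defaults to the engaged gear.
#' @return the world, invisibly (reference semantics).
#' @export
move_step <- function(world, gear = world$gear) {
  if (is.null(gear)) {
    stop("move with no gear selected (circuit contract violation)", call. = FALSE)
  }
  world$gear <- gear
  dir <- world$gear_map[[gear]]
  nxt <- if (is.null(world$position)) 1L else world$position$x + 1L
  if (!is.null(world$position) && world$position$dir != dir) {
    stop("gear reversal mid-run is not part of the reported stream", call. = FALSE)
  }
  if (nxt > world$length) {
    stop("move beyond the track limit (circuit contract violation)", call. = FALSE)
  }
  world$position <- list(dir = dir, x = nxt)
  world$moves <- world$moves + 1L
  world$seq <- world$seq + 1L
  invisible(world)
}

#' Clear the fire at the vehicle's position
#'
#' @param world a [vehicle_world()].
#' @return the world, invisibly.
#' @export
clear_fire <- function(world) {
  if (check_on(world) != "excite") {
    stop("clear with no fire at the vehicle's position (contract violation)",
         call. = FALSE)
  }
  world$fire <- NULL
  world$cleared <- TRUE
  invisible(world)
}

#' Stop the run and fix its outcome
#'
#' Outcome is `"cleared"` when the fire was cleared, `"missed"` when the
#' vehicle moved but the fire remains, `"idle"` when no movement occurred.
#'
#' @param world a [vehicle_world()].
#' @return the outcome string, invisibly.
#' @export
world_stop <- function(world) {
  world$stopped <- TRUE
  world$outcome <- if (world$cleared) "cleared"
  else if (world$moves > 0L) "missed"
  else "idle"
  invisible(world$outcome)
}

#' Snapshot of the world state
#'
#' @param world a [vehicle_world()].
#' @return a one-row tibble (position, gear, detector, fire, seq, outcome),
#'   convenient for logging and JSON export.
#' @export
world_snapshot <- function(world) {
  tibble::tibble(
    position = position_string(world),
    gear = if (is.null(world$gear)) NA_character_ else world$gear,
    detector_on = world$detector_on,
    fire = if (is.null(world$fire))
      NA_character_ else paste0(world$fire$dir, "(", world$fire$x, ")"),
    smoke = if (is.null(world$smoke)) NA_character_ else world$smoke,
    moves = world$moves,
    seq = world$seq,
    cleared = world$cleared,
    outcome = world$outcome
  )
}
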