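#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a run report into its event trace
#'
#' @param x a `vm_report` from [run_scenario()] (or a `vm_model`).
#' @param ... unused.
#' @return the trace tibble `(seq, thread, stimulus, origin, pass)`.
#' @method tidy vm_report
#' @export
tidy.vm_report <- function(x, ...) {
  x$trace
}

#' @rdname tidy.vm_report
#' @method tidy vm_model
#' @export
tidy.vm_model <- function(x, ...) {
  vm_trace(x)
}

#' One-row summary of a run report
#'
#' @param x a `vm_report`.
#' @param ... unused.
#' @return a one-row tibble: scenario id, outcome, number of events, the
#'   final stream sequence number, fetch count, number of synchronized
#'   perception events, truncation flag, and the number of plastic links
#'   whose weight changed during the run.
#' @method glance vm_report
#' @export
glance.vm_report <- function(x, ...) {
  tibble::tibble(
    id = x$id,
    outcome = x$outcome,
    n_events = nrow(x$trace),
    max_seq = if (nrow(x$trace) > 0L) max(x$trace$seq) else NA_integer_,
    fetch_count = x$fetch_count,
    n_synchro = nrow(x$synchro_events),
    truncated = x$truncated,
    n_weight_changes = sum(x$weights$before != x$weights$after)
  )
}

#' Plot a trace
#'
#' Events laid out over the stream sequence axis (meso-scale time), one
#' row per thread, coloured by stimulus — the plotted counterpart of the
#' printed `I: thread:stimulus` traces.
#'
#' @param object a trace tibble (`vm_trace`) or a `vm_report`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot vm_trace
#' @export
autoplot.vm_trace <- function(object, ...) {
  threads <- unique(object$thread)
  df <- object
  df$thread <- factor(df$thread, levels = rev(threads))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$seq, y = .data$thread,
                                   colour = .data$stimulus,
                                   shape = .data$origin)) +
    ggplot2::geom_point(size = 3, position = ggplot2::position_jitter(
      width = 0, height = 0.15, seed = 1)) +
    ggplot2::scale_x_continuous(breaks = function(l) {
      seq(floor(l[1]), ceiling(l[2]), by = 1)
    }) +
    ggplot2::labs(x = "stream sequence I", y = NULL,
                  colour = "stimulus", shape = "origin") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.vm_trace
#' @method autoplot vm_report
#' @export
autoplot.vm_report <- function(object, ...) {
  autoplot.vm_trace(object$trace, ...) +
    ggplot2::ggtitle(paste0(object$id, " (", object$outcome, ")"))
}

#' Plot link weights before and after a run
#'
#' @param report a `vm_report`.
#' @return a ggplot showing, for every plastic link that changed, the
#'   weight before and after the run relative to its gating threshold.
#' @export
plot_weight_changes <- function(report) {
  w <- report$weights[report$weights$before != report$weights$after, ]
  if (nrow(w) == 0L) {
    return(ggplot2::ggplot() +
             ggplot2::labs(title = "no weight changes") +
             ggplot2::theme_minimal())
  }
  w$link <- paste(w$from, "->", w$to)
  long <- tibble::tibble(
    link = rep(w$link, 2L),
    when = rep(c("before", "after"), each = nrow(w)),
    weight = c(w$before, w$after),
    threshold = rep(w$threshold, 2L)
  )
  long$when <- factor(long$when, levels = c("before", "after"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$when, y = .data$weight,
                                     group = .data$link)) +
    ggplot2::geom_line(ggplot2::aes(colour = .data$link)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$link), size = 3) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$threshold),
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "link weight",
                  title = "synaptic weight changes (dashed: gating threshold)") +
    ggplot2::theme_minimal()
}
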