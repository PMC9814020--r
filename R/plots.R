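# ggplot2 displays for runs, profiles, and sweeps.

#' Plot a run's predictions against the return
#'
#' A window of the per-step log: the online prediction overlaid on the
#' ground-truth return, with US steps marked.
#'
#' @param object a `cond_run`.
#' @param steps integer range of steps to show (default: the last 300
#'   valid steps).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot cond_run
#' @export
autoplot.cond_run <- function(object, steps = NULL, ...) {
  log <- object$log
  if (is.null(steps)) {
    last_valid <- max(log$step[log$valid])
    steps <- c(max(1L, last_valid - 300L), last_valid)
  }
  dat <- dplyr::filter(log, .data$step >= steps[1], .data$step <= steps[2])
  long <- tidyr::pivot_longer(dat, c("prediction", "return"),
                              names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$value,
                                     color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = dplyr::filter(dat, .data$us > 0),
                        ggplot2::aes(x = .data$step, y = 0),
                        inherit.aes = FALSE, shape = 17) +
    ggplot2::labs(x = "step", y = NULL, color = NULL,
                  title = paste0(object$agent, " on ", object$meta$kind),
                  subtitle = sprintf("MSRE = %.4g", object$msre)) +
    ggplot2::theme_minimal()
}

#' Plot a trial-aligned profile
#'
#' @param object a `cond_profile` from [extract_profile()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot cond_profile
#' @export
autoplot.cond_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("prediction", "return"),
                              names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$offset, y = .data$value,
                                     color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "steps from CS onset", y = NULL, color = NULL,
                  title = "Trial-aligned mean prediction and return") +
    ggplot2::theme_minimal()
}

#' Bar chart of a sweep
#'
#' MSRE (mean over runs, +/- one standard error) per agent.
#'
#' @param sweep a tibble from [sweep_agents()].
#' @return a ggplot.
#' @export
plot_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = stats::reorder(.data$agent,
                                                         .data$msre_mean),
                                      y = .data$msre_mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$msre_mean - .data$stderr,
                                        ymax = .data$msre_mean + .data$stderr),
                           width = 0.2, na.rm = TRUE) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "MSRE (mean over runs, +/- stderr)") +
    ggplot2::theme_minimal()
}
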