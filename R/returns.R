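# Ground-truth returns and the MSRE evaluation protocol. The prediction
# target is the discounted return of the US channel,
#   G_t = sum_k gamma^k US_{t+k+1},
# computed retrospectively from the logged US stream by the backward
# recursion G_t = US_{t+1} + gamma * G_{t+1}. The last H steps of a finite
# stream are masked out because their returns are biased by truncating the
# infinite sum.

#' Discount factor from the expected inter-stimulus interval
#'
#' gamma = 1 - 1/E(ISI), so the prediction horizon of the return matches
#' the ISI (e.g. E(ISI) = 4 gives 0.75, E(ISI) = 10 gives 0.9).
#'
#' @param expected_isi expected ISI in steps, at least 1.
#' @return discount factor in [0, 1).
#' @export
discount_from_expected_isi <- function(expected_isi) {
  if (!is.numeric(expected_isi) || length(expected_isi) != 1L ||
      is.na(expected_isi) || expected_isi < 1)
    stop("`expected_isi` must be a single number >= 1", call. = FALSE)
  1 - 1 / expected_isi
}

#' Compute discounted returns from a US series
#'
#' Backward recursion `G_t = US_{t+1} + gamma * G_{t+1}` with `G = 0` past
#' the end of the series. `valid` is FALSE for the last `H` steps, where
#' `H = ceiling(log(tail_tolerance) / log(gamma))`, bounding the
#' tail-truncation bias by `tail_tolerance` times the maximum achievable
#' return.
#'
#' @param us binary (or numeric cumulant) series.
#' @param gamma discount factor in [0, 1).
#' @param tail_tolerance positive scalar bounding the truncation bias.
#' @return a tibble with columns `value` and `valid`.
#' @examples
#' compute_returns(c(0, 1, 1, 0), gamma = 0.75)$value[1]  # 1 + 0.75
#' @export
compute_returns <- function(us, gamma, tail_tolerance = 1e-8) {
  if (!is.numeric(gamma) || gamma < 0 || gamma >= 1)
    stop("`gamma` must lie in [0, 1)", call. = FALSE)
  if (tail_tolerance <= 0)
    stop("`tail_tolerance` must be positive", call. = FALSE)
  us <- as.numeric(us)
  n <- length(us)
  x <- c(us[-1], 0)
  g <- if (gamma == 0) x
       else rev(as.numeric(stats::filter(rev(x), gamma, method = "recursive")))
  H <- if (gamma == 0) 0L else as.integer(ceiling(log(tail_tolerance) / log(gamma)))
  H <- min(H, n)
  tibble::tibble(value = g,
                 valid = c(rep(TRUE, n - H), rep(FALSE, H)))
}

#' Squared return error
#'
#' @param prediction online prediction V_t.
#' @param return_value ground-truth return G_t.
#' @return elementwise (V_t - G_t)^2.
#' @export
sre <- function(prediction, return_value) {
  stopifnot(length(prediction) == length(return_value))
  (prediction - return_value)^2
}

#' Mean squared return error
#'
#' Average of [sre()] over the steps where the return is valid (all steps
#' are included -- ITI steps too -- except the truncated tail).
#'
#' @inheritParams sre
#' @param valid logical mask of valid steps; defaults to all.
#' @return a scalar.
#' @export
msre <- function(prediction, return_value, valid = NULL) {
  stopifnot(length(prediction) == length(return_value))
  if (is.null(valid)) valid <- rep(TRUE, length(prediction))
  if (!any(valid)) stop("no valid steps to average over", call. = FALSE)
  mean(sre(prediction[valid], return_value[valid]))
}

#' Aggregate MSRE across runs
#'
#' Mean and standard error (sample sd / sqrt(n)) across independent runs.
#' With fewer than two runs the standard error is undefined and reported
#' as NA.
#'
#' @param msre_list numeric vector of per-run MSRE values.
#' @return a one-row tibble with `msre_mean`, `stderr`, `n_runs`.
#' @examples
#' aggregate_runs(c(0, 2))  # mean 1, stderr 1
#' @export
aggregate_runs <- function(msre_list) {
  msre_list <- as.numeric(msre_list)
  n <- length(msre_list)
  if (n < 1) stop("need at least one run", call. = FALSE)
  tibble::tibble(
    msre_mean = mean(msre_list),
    stderr = if (n >= 2) stats::sd(msre_list) / sqrt(n) else NA_real_,
    n_runs = n)
}

# Per-step evaluation log shared by all agents.
build_run_log <- function(stream, predictions, gamma, tail_tolerance = 1e-8) {
  lay <- attr(stream, "layout")
  us <- stream[[lay$names[lay$us]]]
  ret <- compute_returns(us, gamma, tail_tolerance)
  tibble::tibble(
    step = stream$step,
    prediction = as.numeric(predictions),
    us = as.numeric(us),
    return = ret$value,
    valid = ret$valid,
    phase = stream$phase,
    trial_id = stream$trial_id)
}
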