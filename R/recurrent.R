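# Recurrent learners: vanilla RNN, LSTM, GRU state constructors with a
# linear value head, trained fully online on semi-gradient TD(0) targets
# by T-BPTT (overlapping windows, stale boundary state) or RTRL (influence
# matrix, stale Jacobian). Optionally the input observation is augmented
# with the stimulating traces of each channel.

#' Initialize recurrent cell parameters
#'
#' Weights are uniform on (-1/sqrt(n_hidden), 1/sqrt(n_hidden)) using R's
#' global RNG; biases are zero except the LSTM forget gate (1); the value
#' head is zero-initialized so the first predictions are exactly 0.
#' Gate blocks are stacked row-wise in `W`: `[i; f; g; o]` for the LSTM,
#' `[z; r; n]` for the GRU (candidate input `[o_t; r * h_prev]`).
#'
#' @param architecture "rnn", "lstm", or "gru".
#' @param n_input observation dimension fed to the cell (doubled when
#'   trace-augmented).
#' @param n_hidden hidden units (single layer).
#' @return a `cell_params` list with `W`, `b`, `wv`, `bv` and shape fields.
#' @export
cell_init <- function(architecture = c("lstm", "rnn", "gru"), n_input,
                      n_hidden = 16) {
  architecture <- match.arg(architecture)
  gates <- switch(architecture, rnn = 1L, lstm = 4L, gru = 3L)
  n <- as.integer(n_hidden)
  d <- as.integer(n_input)
  m <- d + n
  lim <- 1 / sqrt(n)
  W <- matrix(stats::runif(gates * n * m, -lim, lim), gates * n, m)
  b <- numeric(gates * n)
  if (architecture == "lstm") b[(n + 1):(2 * n)] <- 1
  structure(list(architecture = architecture, n_input = d, n_hidden = n,
                 gates = gates, W = W, b = b, wv = numeric(n), bv = 0),
            class = "cell_params")
}

arch_code <- function(architecture) {
  switch(architecture, rnn = 0L, lstm = 1L, gru = 2L)
}

# Flat layout [vec(W), b, wv, bv]; must match the C++ ParamView.
flatten_params <- function(params) {
  c(as.numeric(params$W), params$b, params$wv, params$bv)
}

unflatten_params <- function(theta, template) {
  gn <- template$gates * template$n_hidden
  m <- template$n_input + template$n_hidden
  template$W <- matrix(theta[seq_len(gn * m)], gn, m)
  template$b <- theta[gn * m + seq_len(gn)]
  template$wv <- theta[gn * m + gn + seq_len(template$n_hidden)]
  template$bv <- theta[length(theta)]
  template
}

#' One recurrent step (reference implementation)
#'
#' Pure-R forward pass of the chosen cell, used as an independent check of
#' the compiled path. Returns the new hidden state (and cell state for the
#' LSTM) and the value prediction `V = wv' h + bv`.
#'
#' @param params a `cell_params` from [cell_init()].
#' @param state list with `h` (and `c` for the LSTM); zeros to start.
#' @param input observation vector of length `n_input`.
#' @return list with `h`, `c`, `V`.
#' @export
cell_forward <- function(params, state, input) {
  n <- params$n_hidden
  d <- params$n_input
  sig <- function(x) 1 / (1 + exp(-x))
  zin <- c(as.numeric(input), state$h)
  if (params$architecture == "rnn") {
    h <- tanh(as.numeric(params$W %*% zin) + params$b)
    cc <- state$c
  } else if (params$architecture == "lstm") {
    a <- as.numeric(params$W %*% zin) + params$b
    i <- sig(a[1:n]); f <- sig(a[(n + 1):(2 * n)])
    g <- tanh(a[(2 * n + 1):(3 * n)]); o <- sig(a[(3 * n + 1):(4 * n)])
    cc <- f * state$c + i * g
    h <- o * tanh(cc)
  } else {
    az <- as.numeric(params$W[1:n, ] %*% zin) + params$b[1:n]
    ar <- as.numeric(params$W[(n + 1):(2 * n), ] %*% zin) + params$b[(n + 1):(2 * n)]
    z <- sig(az); r <- sig(ar)
    zn <- c(as.numeric(input), r * state$h)
    nc <- tanh(as.numeric(params$W[(2 * n + 1):(3 * n), ] %*% zn) +
                 params$b[(2 * n + 1):(3 * n)])
    h <- (1 - z) * nc + z * state$h
    cc <- state$c
  }
  list(h = h, c = cc, V = sum(params$wv * h) + params$bv)
}

#' Compiled forward pass over a sequence
#'
#' @param params a `cell_params`.
#' @param obs matrix of observations, one row per step.
#' @param h0,c0 initial state (zeros by default).
#' @return list with per-step `V`, `H`, and (LSTM) `C`.
#' @export
cell_forward_seq <- function(params, obs, h0 = NULL, c0 = NULL) {
  n <- params$n_hidden
  cell_forward_seq_cpp(flatten_params(params), arch_code(params$architecture),
                       params$n_input, n, obs,
                       h0 %||% numeric(n), c0 %||% numeric(n))
}

#' T-BPTT window loss and gradient
#'
#' The summed semi-gradient TD(0) losses over a truncation window unrolled
#' from a (possibly stale) boundary state: for window steps k = 1..T,
#' `0.5 * (us_k + gamma * stopgrad(V_{k+1}) - V_k)^2`, the newest loss
#' bootstrapping on `v_boot` (the online prediction at the window's edge).
#' `tbptt_window_grad()` returns the exact gradient with respect to the
#' flattened parameters; `window_loss()` the scalar loss (used for
#' finite-difference checks).
#'
#' @param params a `cell_params`.
#' @param obs T x n_input matrix, the window's observations.
#' @param us length-T cumulant vector, `us[k]` observed on leaving window
#'   step k.
#' @param v_boot bootstrap value for the newest step.
#' @param gamma discount factor.
#' @param h0,c0 boundary state entering the window.
#' @return gradient vector (length `n_recurrent_params + n_hidden + 1`) /
#'   scalar loss.
#' @export
tbptt_window_grad <- function(params, obs, us, v_boot, gamma,
                              h0 = NULL, c0 = NULL) {
  n <- params$n_hidden
  as.numeric(tbptt_window_grad_cpp(flatten_params(params),
                                   arch_code(params$architecture),
                                   params$n_input, n,
                                   h0 %||% numeric(n), c0 %||% numeric(n),
                                   obs, us, v_boot, gamma))
}

#' @rdname tbptt_window_grad
#' @export
window_loss <- function(params, obs, us, v_boot, gamma, h0 = NULL, c0 = NULL) {
  n <- params$n_hidden
  window_loss_cpp(flatten_params(params), arch_code(params$architecture),
                  params$n_input, n,
                  h0 %||% numeric(n), c0 %||% numeric(n),
                  obs, us, v_boot, gamma)
}

#' @rdname tbptt_window_grad
#' @param targets externally fixed per-step targets. Because the TD(0)
#'   bootstrap is stop-gradient, central finite differences of
#'   `window_fixed_target_loss()` -- with targets computed once at the base
#'   parameters -- recover exactly the semi-gradient that
#'   `tbptt_window_grad()` returns.
#' @export
window_fixed_target_loss <- function(params, obs, targets, h0 = NULL,
                                     c0 = NULL) {
  n <- params$n_hidden
  window_fixed_target_loss_cpp(flatten_params(params),
                               arch_code(params$architecture),
                               params$n_input, n,
                               h0 %||% numeric(n), c0 %||% numeric(n),
                               obs, targets)
}

#' Per-step TD(0) targets of a window
#'
#' `us[k] + gamma * V_{k+1}` with the newest step bootstrapping on
#' `v_boot`, computed from a forward pass at the supplied parameters.
#'
#' @inheritParams tbptt_window_grad
#' @return numeric vector of targets, one per window step.
#' @export
window_targets <- function(params, obs, us, v_boot, gamma, h0 = NULL,
                           c0 = NULL) {
  fwd <- cell_forward_seq(params, obs, h0, c0)
  T <- nrow(obs)
  us + gamma * c(fwd$V[-1], v_boot)
}

#' Frozen-parameter gradients over a full sequence
#'
#' Two independent routes to the same quantity, the gradient of the summed
#' TD(0) losses over a sequence with parameters held fixed:
#' `full_unroll_grad()` backpropagates from the origin (zero initial
#' state); `rtrl_accum_grad()` accumulates per-step gradients through the
#' forward-propagated influence matrix. They agree to machine precision,
#' which is the package's gradient-correctness oracle for RTRL.
#'
#' @param params a `cell_params`.
#' @param obs full observation sequence, one row per step.
#' @param us cumulant series aligned with `obs` (`us[t]` observed at step t).
#' @param gamma discount factor.
#' @return gradient vector over the flattened parameters.
#' @export
full_unroll_grad <- function(params, obs, us, gamma) {
  as.numeric(full_unroll_grad_cpp(flatten_params(params),
                                  arch_code(params$architecture),
                                  params$n_input, params$n_hidden,
                                  obs, us, gamma))
}

#' @rdname full_unroll_grad
#' @export
rtrl_accum_grad <- function(params, obs, us, gamma) {
  as.numeric(rtrl_accum_grad_cpp(flatten_params(params),
                                 arch_code(params$architecture),
                                 params$n_input, params$n_hidden,
                                 obs, us, gamma))
}

#' Augment observations with stimulating traces
#'
#' Concatenates `[o_t ; y_t]`, one exponentially decaying trace per
#' observation channel, doubling the input dimension; the learner is
#' otherwise unchanged.
#'
#' @param obs observation matrix (one row per step) or a single vector.
#' @param tau trace decay in (0, 1).
#' @param enabled if FALSE, returns `obs` unchanged.
#' @return the augmented input matrix (or vector).
#' @export
augment_with_traces <- function(obs, tau, enabled = TRUE) {
  if (!enabled) return(obs)
  if (is.matrix(obs)) cbind(obs, trace_matrix(obs, tau))
  else {
    y <- trace_update(numeric(length(obs)), obs, numeric(length(obs)), tau)
    c(obs, y)
  }
}

#' Run a recurrent TD(0) agent online
#'
#' The online loop shared with the linear agents: observe, advance the
#' hidden state with the current parameters, predict (logged before any
#' update), and train by the chosen method. With `trainer = "tbptt"` the
#' network is unrolled `tbptt_T` steps back from a stale stored boundary
#' state and all parameters receive one Adam update per step (window
#' losses summed, newest loss bootstrapping on the online prediction).
#' With `trainer = "rtrl"` parameters are updated every step from the
#' forward-propagated influence matrix, which is carried across updates
#' without resetting (stale Jacobian). Eligibility traces are not used
#' (lambda = 0).
#'
#' @param config an environment configuration.
#' @param architecture "rnn", "lstm", or "gru".
#' @param trainer "tbptt" or "rtrl".
#' @param n_hidden hidden units.
#' @param tbptt_T truncation window length (T-BPTT only).
#' @param hyper a [td_hyper()]; `lambda` is ignored (fixed to 0),
#'   `gamma = NULL` uses the environment's default.
#' @param augment if TRUE, feed stimulating traces of each channel as
#'   additional inputs.
#' @param tau trace decay for the augmentation; NULL derives
#'   `1 - 1/E(ISI)` from the environment.
#' @param n_steps stream length.
#' @param seed run seed (environment substream; weight init uses
#'   `seed + 500000`).
#' @param update_stride apply the T-BPTT update every `update_stride`
#'   steps (1 = every step).
#' @return a `cond_run` object.
#' @export
run_recurrent_agent <- function(config, architecture = c("lstm", "rnn", "gru"),
                                trainer = c("tbptt", "rtrl"), n_hidden = 16,
                                tbptt_T = 10, hyper = td_hyper(alpha = 2^-9,
                                                               lambda = 0),
                                augment = FALSE, tau = NULL,
                                n_steps = 10000, seed = 1L,
                                update_stride = 1L) {
  architecture <- match.arg(architecture)
  trainer <- match.arg(trainer)
  stopifnot(inherits(config, "cond_env_config"), tbptt_T >= 1)
  gamma <- hyper$gamma %||% env_gamma(config)
  stream <- generate_stream(config, n_steps, seed)
  obs <- obs_matrix(stream)
  lay <- attr(stream, "layout")
  us <- obs[, lay$us]
  input <- if (augment) {
    cbind(obs, trace_matrix(obs, resolve_tau(tau, config)))
  } else obs

  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(init_seed(seed))
  params <- cell_init(architecture, ncol(input), n_hidden)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())

  hy <- hyper
  hy$gamma <- gamma
  res <- recurrent_agent_cpp(input, us, arch_code(architecture),
                             if (trainer == "tbptt") 0L else 1L,
                             flatten_params(params), as.integer(n_hidden),
                             hyper_to_cpp(hy), as.integer(tbptt_T),
                             as.integer(update_stride))

  label <- paste0(architecture, "/", trainer,
                  if (trainer == "tbptt") paste0("(T=", tbptt_T, ")"),
                  if (augment) "+traces")
  log <- build_run_log(stream, res$pred, gamma)
  new_cond_run(log, agent = label,
               meta = list(kind = config$kind, architecture = architecture,
                           trainer = trainer, n_hidden = n_hidden,
                           tbptt_T = tbptt_T, augment = augment,
                           hyper = hy, gamma = gamma, n_steps = n_steps,
                           seed = as.integer(seed),
                           params = unflatten_params(res$theta, params),
                           config = config))
}
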