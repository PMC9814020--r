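# Fixed (non-learned) state constructors mapping observation streams to
# feature vectors. All of them append a constant bias feature of 1 as the
# last element; multi-channel features are laid out channel-major. Every
# observation channel (CS, US, distractors alike) is treated identically.

# ---- representation specs ------------------------------------------------

new_rep <- function(type, fields = list()) {
  structure(c(list(type = type), fields), class = "cond_rep")
}

#' Fixed representation specifications
#'
#' Constructors for the five fixed representations used with
#' [run_linear_agent()]:
#' \describe{
#'   \item{`rep_presence()`}{the observation bits themselves plus bias; has
#'     no active non-bias feature during a trace interval.}
#'   \item{`rep_trace()`}{the raw stimulating traces plus bias.}
#'   \item{`rep_tilecoded()`}{tile coding of each channel's stimulating
#'     trace: `n_tilings` overlapping tilings of `n_tiles` each, exactly one
#'     active feature per channel per tiling.}
#'   \item{`rep_microstimulus()`}{`n_rbfs` Gaussian basis functions of the
#'     stimulating trace per channel, heights scaled by the trace so the
#'     features unfold sequentially over the trial.}
#'   \item{`rep_esn()`}{an echo state network: fixed random input, internal
#'     (spectral radius < 1, sparse) and prediction-feedback weights; the
#'     hidden state plus bias is the feature vector and only the linear
#'     readout is learned.}
#' }
#' `tau` is the per-step trace decay; `NULL` resolves to
#' `1 - 1/E(ISI)` of the environment at run time (the package's reading of
#' adapting the decay to the ISI; see the methods vignette).
#'
#' @param tau trace decay in (0, 1), or NULL to derive from the
#'   environment's expected ISI.
#' @param n_tilings,n_tiles tile-coding shape (2 tilings by default).
#' @param n_rbfs,sigma microstimulus shape: number of Gaussians per channel
#'   and their standard deviation in trace units (0.8 by default).
#' @param n_hidden,input_scaling,spectral_radius,density echo-state-network
#'   shape: hidden units, scale of the two-point input/feedback weights,
#'   spectral radius of the internal matrix (< 1), and its density.
#' @return a representation specification (class `cond_rep`).
#' @name representations
NULL

#' @rdname representations
#' @export
rep_presence <- function() new_rep("presence")

#' @rdname representations
#' @export
rep_trace <- function(tau = NULL) new_rep("trace", list(tau = tau))

#' @rdname representations
#' @export
rep_tilecoded <- function(tau = NULL, n_tilings = 2, n_tiles = 8) {
  new_rep("tilecoded", list(tau = tau, n_tilings = as.integer(n_tilings),
                            n_tiles = as.integer(n_tiles)))
}

#' @rdname representations
#' @export
rep_microstimulus <- function(tau = NULL, n_rbfs = 8, sigma = 0.8) {
  new_rep("microstimulus", list(tau = tau, n_rbfs = as.integer(n_rbfs),
                                sigma = sigma))
}

#' @rdname representations
#' @export
rep_esn <- function(n_hidden = 40, input_scaling = 0.5,
                    spectral_radius = 0.9, density = 0.1) {
  stopifnot(spectral_radius > 0, spectral_radius < 1,
            density > 0, density <= 1)
  new_rep("esn", list(n_hidden = as.integer(n_hidden),
                      input_scaling = input_scaling,
                      spectral_radius = spectral_radius, density = density))
}

rep_n_features <- function(rep, d) {
  switch(rep$type,
    presence = d + 1L,
    trace = d + 1L,
    tilecoded = d * rep$n_tilings * rep$n_tiles + 1L,
    microstimulus = d * rep$n_rbfs + 1L,
    esn = rep$n_hidden + 1L,
    stop("unknown representation type: ", rep$type))
}

resolve_tau <- function(tau, config) {
  tau <- tau %||% (1 - 1 / expected_isi(config))
  if (tau <= 0 || tau >= 1) stop("`tau` must lie in (0, 1)", call. = FALSE)
  tau
}

# ---- one-step feature constructors (reference implementations) -----------

#' Presence features
#'
#' The observation bits themselves plus a constant bias feature of 1
#' (appended last).
#'
#' @param observation binary observation vector.
#' @return numeric feature vector of length `d + 1`.
#' @export
presence_features <- function(observation) {
  c(as.numeric(observation), 1)
}

#' Update stimulating traces one step
#'
#' Each channel's trace is set to 1 at a rising edge of that channel (onset
#' detected against the previous observation) and otherwise decays by the
#' factor `tau` -- decay proceeds even while the stimulus stays on.
#'
#' @param y current trace values in [0, 1].
#' @param observation current binary observation.
#' @param observation_prev previous observation (zeros before the stream
#'   starts).
#' @param tau decay factor in (0, 1).
#' @return updated trace vector.
#' @examples
#' y <- trace_update(rep(0, 1), 1, 0, 0.9)      # onset -> 1
#' for (i in 1:3) y <- trace_update(y, 0, 0, 0.9)
#' y  # 0.9^3 = 0.729
#' @export
trace_update <- function(y, observation, observation_prev, tau) {
  onset <- observation == 1 & observation_prev == 0
  ifelse(onset, 1, tau * y)
}

#' Stimulating-trace features
#'
#' The raw traces plus bias.
#'
#' @param y trace vector from [trace_update()].
#' @return numeric feature vector of length `d + 1`.
#' @export
trace_features <- function(y) c(as.numeric(y), 1)

#' Tile-coded trace features
#'
#' Discretizes each channel's stimulating trace with `n_tilings`
#' offset tilings of `n_tiles` tiles: per channel and tiling exactly one
#' binary feature is active, at index `floor((y + offset) * n_tiles)`
#' clamped to the last tile, with offsets evenly spaced,
#' `offset_j = j / (n_tilings * n_tiles)`. Features are concatenated
#' channel-major (channel, then tiling, then tile) with the bias last.
#'
#' @param y trace vector.
#' @param n_tilings,n_tiles tiling shape.
#' @return binary feature vector of length
#'   `length(y) * n_tilings * n_tiles + 1`.
#' @export
tile_code_traces <- function(y, n_tilings = 2, n_tiles = 8) {
  d <- length(y)
  x <- numeric(d * n_tilings * n_tiles + 1L)
  for (cch in seq_len(d)) {
    for (j in seq_len(n_tilings) - 1L) {
      offset <- j / (n_tilings * n_tiles)
      idx <- min(floor((y[cch] + offset) * n_tiles), n_tiles - 1L)
      x[((cch - 1L) * n_tilings + j) * n_tiles + idx + 1L] <- 1
    }
  }
  x[length(x)] <- 1
  x
}

#' Microstimulus features
#'
#' Per channel, `n_rbfs` Gaussian basis functions of the stimulating trace
#' with centers equally spaced in (0, 1] and common standard deviation
#' `sigma`, each scaled by the trace height:
#' `feature_i = y * exp(-(y - c_i)^2 / (2 sigma^2))`. As the trace decays
#' the features rise and fall in sequence, spanning the trace interval.
#'
#' @param y trace vector.
#' @param n_rbfs Gaussians per channel.
#' @param sigma standard deviation in trace units.
#' @return numeric feature vector of length `length(y) * n_rbfs + 1`.
#' @export
microstimulus_features <- function(y, n_rbfs = 8, sigma = 0.8) {
  centers <- seq_len(n_rbfs) / n_rbfs
  x <- as.numeric(vapply(seq_along(y), function(cch) {
    y[cch] * exp(-(y[cch] - centers)^2 / (2 * sigma^2))
  }, numeric(n_rbfs)))
  c(x, 1)
}

# Vectorized trace computation over a whole observation matrix; matches
# trace_update step-for-step (used for recurrent input augmentation).
trace_matrix <- function(obs, tau) {
  n <- nrow(obs)
  Y <- matrix(0, n, ncol(obs))
  t_idx <- seq_len(n)
  for (j in seq_len(ncol(obs))) {
    o <- obs[, j]
    onset <- o == 1 & c(0, o[-n]) == 0
    last <- cummax(ifelse(onset, t_idx, 0L))
    Y[, j] <- ifelse(last == 0L, 0, tau^(t_idx - last))
  }
  Y
}

# ---- echo state network --------------------------------------------------

#' Initialize an echo state network
#'
#' Input and feedback weights are drawn from a symmetric two-point
#' distribution (+/- `input_scaling` with equal probability); the internal
#' matrix is sparse with the given density, entries uniform on (-1, 1),
#' rescaled so its spectral radius equals `spectral_radius` (< 1, the echo
#' state property). All three weight groups stay fixed during learning.
#' Uses R's global RNG.
#'
#' @param n_inputs observation dimension.
#' @inheritParams representations
#' @return a list with `W_in` (n_hidden x n_inputs), `W`
#'   (n_hidden x n_hidden), `W_fb` (n_hidden), and the spec fields.
#' @export
esn_init <- function(n_inputs, n_hidden = 40, input_scaling = 0.5,
                     spectral_radius = 0.9, density = 0.1) {
  stopifnot(spectral_radius > 0, spectral_radius < 1)
  W_in <- matrix(sample(c(-1, 1), n_hidden * n_inputs, replace = TRUE) *
                   input_scaling, n_hidden, n_inputs)
  W_fb <- sample(c(-1, 1), n_hidden, replace = TRUE) * input_scaling
  repeat {
    mask <- matrix(stats::rbinom(n_hidden^2, 1L, density), n_hidden, n_hidden)
    W <- matrix(stats::runif(n_hidden^2, -1, 1), n_hidden, n_hidden) * mask
    rho <- max(Mod(eigen(W, only.values = TRUE)$values))
    if (is.finite(rho) && rho > 0) break
  }
  W <- W * (spectral_radius / rho)
  list(W_in = W_in, W = W, W_fb = W_fb,
       n_hidden = as.integer(n_hidden), input_scaling = input_scaling,
       spectral_radius = spectral_radius, density = density)
}

#' Advance an echo state network one step
#'
#' `h <- tanh(W_in o + W h + W_fb V_prev)` where `V_prev` is the previous
#' step's logged prediction (keeping the feedback causal). The feature
#' vector for the linear readout is `c(h, 1)`.
#'
#' @param esn a list from [esn_init()].
#' @param h current hidden state.
#' @param observation observation vector.
#' @param v_prev previous prediction (0 at the first step).
#' @return the new hidden state.
#' @export
esn_step <- function(esn, h, observation, v_prev) {
  as.numeric(tanh(esn$W_in %*% as.numeric(observation) + esn$W %*% h +
                    esn$W_fb * v_prev))
}
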