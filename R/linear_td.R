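# Semi-gradient TD(lambda) with eligibility traces over any fixed
# representation. The update is
#   delta_t = US_{t+1} + gamma V_{t+1} - V_t
#   z_t     = gamma lambda z_{t-1} + x_t
#   w       = w + alpha delta_t z_t               (plain-SGD mode)
# with both values computed from the pre-update weights. In Adam mode the
# pseudo-gradient -delta_t z_t is fed to the bias-corrected
# adaptive-moment rule instead (the optimizer/eligibility interaction is a
# package design choice documented in the methods vignette).

#' TD hyperparameters
#'
#' @param alpha step size in (0, 1].
#' @param lambda eligibility-trace decay in [0, 1] (0.9 for fixed
#'   representations, 0 for the recurrent learners).
#' @param gamma discount factor; NULL resolves to the environment's
#'   default, `1 - 1/E(ISI)`.
#' @param optimizer "adam" (default) or "sgd" (exactly the eligibility
#'   update above).
#' @param beta1,beta2,epsilon Adam moment constants.
#' @return a list of class `td_hyper`.
#' @export
td_hyper <- function(alpha = 2^-8, lambda = 0.9, gamma = NULL,
                     optimizer = c("adam", "sgd"),
                     beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8) {
  stopifnot(alpha > 0, alpha <= 1, lambda >= 0, lambda <= 1)
  if (!is.null(gamma)) stopifnot(gamma >= 0, gamma < 1)
  structure(list(alpha = alpha, lambda = lambda, gamma = gamma,
                 optimizer = match.arg(optimizer),
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon),
            class = "td_hyper")
}

#' Initialize a linear TD learner
#'
#' @param n_features feature dimension.
#' @return a list with weights `w`, eligibility `z`, Adam moments
#'   `m1`, `m2`, and update counter `t`.
#' @export
td_init <- function(n_features) {
  z <- numeric(n_features)
  list(w = z, z = z, m1 = z, m2 = z, t = 0L)
}

#' Linear value prediction
#'
#' @param w weight vector.
#' @param x feature vector of the same length.
#' @return the inner product `V = x' w`.
#' @export
td_predict <- function(w, x) {
  if (length(w) != length(x))
    stop("feature/weight dimension mismatch", call. = FALSE)
  sum(w * x)
}

#' One semi-gradient TD(lambda) update
#'
#' Applies the update for the transition from the step with features `x_t`
#' to the step with features `x_next` and cumulant `us_next`.
#'
#' @param state learner state from [td_init()].
#' @param x_t,x_next feature vectors of two consecutive steps.
#' @param us_next cumulant observed on arrival (the US bit).
#' @param hyper a [td_hyper()] with a concrete `gamma`.
#' @return the updated state, with the TD error in `$delta`.
#' @export
td_update <- function(state, x_t, x_next, us_next, hyper) {
  gamma <- hyper$gamma
  if (is.null(gamma)) stop("`hyper$gamma` must be set", call. = FALSE)
  v_t <- td_predict(state$w, x_t)
  v_next <- td_predict(state$w, x_next)
  delta <- us_next + gamma * v_next - v_t
  if (!is.finite(delta))
    stop("non-finite TD error: run aborted (alpha too large?)", call. = FALSE)
  state$z <- gamma * hyper$lambda * state$z + x_t
  if (hyper$optimizer == "sgd") {
    state$w <- state$w + hyper$alpha * delta * state$z
  } else {
    g <- -delta * state$z
    state$t <- state$t + 1L
    state$m1 <- hyper$beta1 * state$m1 + (1 - hyper$beta1) * g
    state$m2 <- hyper$beta2 * state$m2 + (1 - hyper$beta2) * g^2
    m1h <- state$m1 / (1 - hyper$beta1^state$t)
    m2h <- state$m2 / (1 - hyper$beta2^state$t)
    state$w <- state$w - hyper$alpha * m1h / (sqrt(m2h) + hyper$epsilon)
  }
  state$delta <- delta
  state
}

#' Tabular TD(lambda) over a state/cumulant sequence
#'
#' Plain-SGD temporal-difference learning with one-hot (tabular) features,
#' a per-step step-size schedule, and optional tail averaging of the
#' weight iterates (Polyak averaging). This is exactly the [td_update()]
#' rule specialized to state indicators, run in compiled code; the test
#' suite asserts bitwise agreement with the one-step reference on short
#' sequences. Useful for convergence studies on small Markov reward
#' chains, where the analytic value function `v = (I - gamma P)^-1 P c`
#' is available as an oracle.
#'
#' @param states integer state sequence in `1..n_states`.
#' @param cumulant numeric cumulant series aligned with `states`
#'   (`cumulant[t+1]` is the reward observed on the transition t -> t+1),
#'   or a length-`n_states` vector of per-state cumulants looked up on
#'   arrival.
#' @param gamma discount factor.
#' @param alpha step size: a scalar, one value per step, or NULL to use
#'   the built-in per-state schedule `1/(alpha_c + N(s))^alpha_pow` with
#'   `N(s)` the running visit count (a Robbins-Monro schedule).
#' @param lambda eligibility-trace decay.
#' @param n_states number of states.
#' @param avg_from average the iterates from this step on (0 = no
#'   averaging; the averaged vector is returned as `w_avg`).
#' @param alpha_pow,alpha_c parameters of the built-in schedule (used when
#'   `alpha` is NULL).
#' @return list with the final weights `w` and tail-averaged `w_avg`.
#' @export
run_td_tabular <- function(states, cumulant, gamma, alpha = NULL, lambda = 0,
                           n_states = max(states), avg_from = 0,
                           alpha_pow = 0, alpha_c = 5) {
  n <- length(states)
  if (is.null(alpha)) {
    stopifnot(alpha_pow > 0)
    alpha <- 0
  } else if (length(alpha) == 1L) {
    alpha <- rep(alpha, n)
  }
  stopifnot(length(cumulant) %in% c(n, n_states))
  td_tabular_cpp(as.integer(states), as.numeric(cumulant),
                 as.numeric(alpha), gamma, lambda,
                 as.integer(n_states), as.integer(avg_from),
                 alpha_pow, alpha_c)
}

# ---- the online linear agent --------------------------------------------

# Seeds below 2^31: env stream uses `seed`, learner init (ESN draws) uses
# seed + 500000.
init_seed <- function(seed) as.integer(seed) + 500000L

#' Run a linear TD(lambda) agent online
#'
#' The full online loop: observe, construct features with a fixed
#' representation, predict (logged before updating), and apply one TD
#' update per step. Returns are computed retrospectively from the logged
#' US stream and the run is scored by MSRE over all valid steps.
#'
#' @param config an environment configuration.
#' @param representation a spec from [rep_presence()],
#'   [rep_tilecoded()], [rep_microstimulus()], [rep_trace()], or
#'   [rep_esn()].
#' @param hyper a [td_hyper()]; `gamma = NULL` uses the environment's
#'   default discount.
#' @param n_steps stream length.
#' @param seed run seed (environment substream; learner init uses
#'   `seed + 500000`).
#' @param engine "cpp" (fast path) or "r" (reference loop built from the
#'   exported one-step functions; identical output, used for
#'   cross-checking).
#' @return a `cond_run` object; see [tidy.cond_run()] / [glance.cond_run()].
#' @examples
#' r <- run_linear_agent(trace_conditioning(), rep_microstimulus(),
#'                       n_steps = 2000, seed = 1)
#' glance(r)
#' @export
run_linear_agent <- function(config, representation = rep_microstimulus(),
                             hyper = td_hyper(), n_steps = 10000, seed = 1L,
                             engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(config, "cond_env_config"),
            inherits(representation, "cond_rep"))
  gamma <- hyper$gamma %||% env_gamma(config)
  stream <- generate_stream(config, n_steps, seed)
  obs <- obs_matrix(stream)
  lay <- attr(stream, "layout")
  us <- obs[, lay$us]

  rep <- representation
  if (rep$type %in% c("trace", "tilecoded", "microstimulus"))
    rep$tau <- resolve_tau(rep$tau, config)
  esn <- NULL
  if (rep$type == "esn") {
    withr_seed <- init_seed(seed)
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv(), inherits = FALSE)
    set.seed(withr_seed)
    esn <- esn_init(ncol(obs), rep$n_hidden, rep$input_scaling,
                    rep$spectral_radius, rep$density)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }

  hy <- hyper
  hy$gamma <- gamma
  res <- if (engine == "cpp") {
    linear_agent_cpp(obs, us, rep_to_cpp(rep, esn), hyper_to_cpp(hy))
  } else {
    linear_agent_r(obs, us, rep, esn, hy)
  }

  log <- build_run_log(stream, res$pred, gamma)
  new_cond_run(log,
               agent = paste0("linear/", rep$type),
               meta = list(kind = config$kind, representation = rep,
                           hyper = hy, gamma = gamma, n_steps = n_steps,
                           seed = as.integer(seed), weights = res$w,
                           config = config))
}

rep_to_cpp <- function(rep, esn) {
  out <- list(type = switch(rep$type, presence = 0L, trace = 1L,
                            tilecoded = 2L, microstimulus = 3L, esn = 4L),
              tau = rep$tau %||% 0,
              n_tilings = rep$n_tilings %||% 0L,
              n_tiles = rep$n_tiles %||% 0L,
              n_rbfs = rep$n_rbfs %||% 0L,
              sigma = rep$sigma %||% 0)
  if (!is.null(esn)) {
    out$W_in <- esn$W_in
    out$W <- esn$W
    out$W_fb <- esn$W_fb
  }
  out
}

hyper_to_cpp <- function(hy) {
  list(alpha = hy$alpha, lambda = hy$lambda, gamma = hy$gamma,
       adam = as.integer(hy$optimizer == "adam"),
       beta1 = hy$beta1, beta2 = hy$beta2, epsilon = hy$epsilon)
}

# Reference loop composed from the exported one-step functions; used to
# validate the C++ fast path on short streams.
linear_agent_r <- function(obs, us, rep, esn, hy) {
  n <- nrow(obs)
  d <- ncol(obs)
  featurize <- switch(rep$type,
    presence = function(o, y, h) presence_features(o),
    trace = function(o, y, h) trace_features(y),
    tilecoded = function(o, y, h) tile_code_traces(y, rep$n_tilings, rep$n_tiles),
    microstimulus = function(o, y, h) microstimulus_features(y, rep$n_rbfs, rep$sigma),
    esn = function(o, y, h) c(h, 1))
  st <- td_init(rep_n_features(rep, d))
  y <- numeric(d)
  h <- if (!is.null(esn)) numeric(esn$n_hidden)
  o_prev <- numeric(d)
  x_prev <- NULL
  pred <- numeric(n)
  v_prev <- 0
  for (t in seq_len(n)) {
    o <- obs[t, ]
    if (rep$type %in% c("trace", "tilecoded", "microstimulus"))
      y <- trace_update(y, o, o_prev, rep$tau)
    if (rep$type == "esn")
      h <- esn_step(esn, h, o, v_prev)
    x <- featurize(o, y, h)
    pred[t] <- td_predict(st$w, x)
    if (t > 1L)
      st <- td_update(st, x_prev, x, us[t], hy)
    v_prev <- pred[t]
    x_prev <- x
    o_prev <- o
  }
  list(pred = pred, w = st$w)
}

# ---- run container -------------------------------------------------------

new_cond_run <- function(log, agent, meta) {
  structure(list(log = log, agent = agent, meta = meta,
                 msre = msre(log$prediction, log$return, log$valid)),
            class = "cond_run")
}

#' @export
print.cond_run <- function(x, ...) {
  cat("<cond_run: ", x$agent, " on ", x$meta$kind,
      ", n_steps = ", x$meta$n_steps, ", seed = ", x$meta$seed,
      ">\n  MSRE = ", format(x$msre, digits = 5), "\n", sep = "")
  invisible(x)
}

#' Tidy a benchmark run
#'
#' @param x a `cond_run`.
#' @param ... unused.
#' @return the per-step log: `step`, `prediction`, `us`, `return`,
#'   `valid`, `phase`, `trial_id`.
#' @method tidy cond_run
#' @export
tidy.cond_run <- function(x, ...) x$log

#' One-row summary of a benchmark run
#'
#' @param x a `cond_run`.
#' @param ... unused.
#' @return a tibble with `agent`, `environment`, `msre`, `n_steps`,
#'   `gamma`, `seed`.
#' @method glance cond_run
#' @export
glance.cond_run <- function(x, ...) {
  tibble::tibble(agent = x$agent, environment = x$meta$kind,
                 msre = x$msre, n_steps = x$meta$n_steps,
                 gamma = x$meta$gamma, seed = x$meta$seed)
}

#' Write a run's per-step log to CSV
#'
#' @param run a `cond_run`.
#' @param path output file.
#' @export
write_run_csv <- function(run, path) {
  utils::write.csv(as.data.frame(run$log), path, row.names = FALSE)
  invisible(path)
}
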