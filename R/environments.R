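# Benchmark environments: trace conditioning, noisy patterning, trace
# patterning. Each is a seeded discrete-time generator emitting one binary
# observation vector per step (CS block, then US, then distractor block)
# plus evaluation-only trial annotations that learners never see.

# ---- configuration -------------------------------------------------------

as_int_range <- function(x, what) {
  if (length(x) == 1L) x <- c(x, x)
  if (!is.numeric(x) || length(x) != 2L || anyNA(x) || any(x != floor(x)))
    stop("`", what, "` must be an integer or integer range c(lo, hi)", call. = FALSE)
  if (x[1] > x[2])
    stop("`", what, "`: lower bound exceeds upper bound", call. = FALSE)
  as.integer(x)
}

check_duration <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x))
    stop("`", what, "` must be a single integer >= 1", call. = FALSE)
  as.integer(x)
}

new_env_config <- function(kind, fields) {
  structure(c(list(kind = kind), fields),
            class = c(paste0(kind, "_config"), "cond_env_config"))
}

#' Trace conditioning environment configuration
#'
#' A single conditioned stimulus (CS) is presented for `cs_duration` steps;
#' the unconditioned stimulus (US) follows `isi` steps after CS onset
#' (integer-uniform over the inclusive range) and lasts `us_duration` steps.
#' The inter-trial interval (ITI), measured from US onset to the next CS
#' onset, is integer-uniform over `iti`. Free-running binary distractor
#' channels, one per entry of `distractor_mean_intervals`, turn on at
#' Bernoulli(1/mean) candidate onsets (onsets arriving while a channel is
#' active are ignored) and stay on for `distractor_duration` steps; they run
#' during the ITI as well.
#'
#' Default ranges follow the short inter-stimulus interval setting,
#' ISI ~ U(7, 13), expected ISI 10. Presets: U(14, 26) (medium, E = 20) and
#' U(20, 40) (long, E = 30).
#'
#' @param isi inclusive integer range (or scalar) of the inter-stimulus
#'   interval, CS onset to US onset, in steps.
#' @param iti inclusive integer range of the inter-trial interval, US onset
#'   to next CS onset, in steps.
#' @param cs_duration,us_duration stimulus durations in steps.
#' @param distractor_mean_intervals mean steps between distractor onsets,
#'   one entry per distractor channel.
#' @param distractor_duration distractor activation length in steps.
#' @return an environment configuration for [make_env()] /
#'   [generate_stream()].
#' @seealso [noisy_patterning()], [trace_patterning()]
#' @examples
#' cfg <- trace_conditioning()
#' channel_layout(cfg)$d   # 1 CS + US + 10 distractors = 12
#' @export
trace_conditioning <- function(isi = c(7, 13), iti = c(80, 120),
                               cs_duration = 4, us_duration = 2,
                               distractor_mean_intervals = seq(10, 100, by = 10),
                               distractor_duration = 4) {
  isi <- as_int_range(isi, "isi")
  iti <- as_int_range(iti, "iti")
  cs_duration <- check_duration(cs_duration, "cs_duration")
  us_duration <- check_duration(us_duration, "us_duration")
  distractor_duration <- check_duration(distractor_duration, "distractor_duration")
  if (any(distractor_mean_intervals <= 0))
    stop("`distractor_mean_intervals` must be positive", call. = FALSE)
  if (any(is.finite(distractor_mean_intervals) &
          distractor_mean_intervals < distractor_duration))
    warning("distractor mean interval below its duration: channels will overlap heavily")
  new_env_config("trace_conditioning", list(
    n_cs = 1L, isi = isi, iti = iti,
    cs_duration = cs_duration, us_duration = us_duration,
    distractor_mean_intervals = as.numeric(distractor_mean_intervals),
    distractor_duration = distractor_duration,
    n_distractors = length(distractor_mean_intervals),
    k_patterns = 1L, noise_pct = 0))
}

#' Noisy patterning environment configuration
#'
#' `n_cs` conditioned stimuli are presented simultaneously for
#' `cs_duration` steps at each trial onset. In half of the trials the CS
#' configuration is one of `k_patterns` activation patterns (each with
#' exactly `n_cs/2` active stimuli, drawn without replacement at
#' construction); otherwise it is a uniformly drawn non-activating
#' configuration. The US fires `isi` steps after CS onset iff the
#' configuration is an activation pattern, except that with probability
#' `noise_pct`/100 the outcome is flipped. Distractor channels are
#' trial-locked: each is i.i.d. Bernoulli(0.5) per trial and co-occurs with
#' the CSs. The ISI is fixed (default 4 so the discount factor is
#' 1 - 1/4 = 0.75); the ITI is integer-uniform on `iti`.
#'
#' @param n_cs even number of CS channels.
#' @param k_patterns number of activation patterns, at most
#'   `choose(n_cs, n_cs/2)`.
#' @param n_distractors number of trial-locked distractor channels.
#' @param noise_pct percent of trials whose US outcome is flipped.
#' @param isi fixed inter-stimulus interval in steps.
#' @inheritParams trace_conditioning
#' @return an environment configuration.
#' @examples
#' env_gamma(noisy_patterning())  # 0.75
#' @export
noisy_patterning <- function(n_cs = 8, k_patterns = 8, n_distractors = 10,
                             noise_pct = 10, isi = 4, iti = c(80, 120),
                             cs_duration = 4, us_duration = 2) {
  n_cs <- check_duration(n_cs, "n_cs")
  if (n_cs %% 2L != 0L)
    stop("`n_cs` must be even (activation patterns have n_cs/2 active bits)",
         call. = FALSE)
  k_patterns <- check_duration(k_patterns, "k_patterns")
  if (k_patterns > choose(n_cs, n_cs / 2))
    stop("`k_patterns` exceeds the number of balanced patterns choose(n_cs, n_cs/2)",
         call. = FALSE)
  if (!is.numeric(noise_pct) || noise_pct < 0 || noise_pct > 100)
    stop("`noise_pct` must lie in [0, 100]", call. = FALSE)
  isi <- as_int_range(isi, "isi")
  if (isi[1] != isi[2])
    stop("`isi` is fixed in noisy patterning; supply a single value", call. = FALSE)
  new_env_config("noisy_patterning", list(
    n_cs = n_cs, k_patterns = k_patterns,
    n_distractors = as.integer(n_distractors), noise_pct = noise_pct,
    isi = isi, iti = as_int_range(iti, "iti"),
    cs_duration = check_duration(cs_duration, "cs_duration"),
    us_duration = check_duration(us_duration, "us_duration")))
}

#' Noisy patterning difficulty presets
#'
#' Named configurations of [noisy_patterning()]. The defaults of
#' `noisy_patterning()` follow the one fully described configuration
#' (8 CSs, 8 activation patterns, 10 distractors, 10% noise) and are the
#' `"medium"` preset; the easy and hard settings scale the number of
#' patterns, distractors, and the noise level down/up and are this
#' package's own choices.
#'
#' @param level one of "easy", "medium", "hard".
#' @return an environment configuration.
#' @export
noisy_patterning_preset <- function(level = c("medium", "easy", "hard")) {
  level <- match.arg(level)
  switch(level,
    easy   = noisy_patterning(n_cs = 6, k_patterns = 4, n_distractors = 5,
                              noise_pct = 5),
    medium = noisy_patterning(),
    hard   = noisy_patterning(n_cs = 10, k_patterns = 16, n_distractors = 20,
                              noise_pct = 15))
}

#' Trace patterning environment configuration
#'
#' Combines the pattern logic of [noisy_patterning()] with the stochastic
#' inter-stimulus interval and free-running Poisson distractors of
#' [trace_conditioning()]: the learner must both bridge the trace interval
#' and identify which CS configurations predict the US.
#'
#' @inheritParams noisy_patterning
#' @inheritParams trace_conditioning
#' @return an environment configuration.
#' @export
trace_patterning <- function(n_cs = 8, k_patterns = 8, noise_pct = 10,
                             isi = c(7, 13), iti = c(80, 120),
                             cs_duration = 4, us_duration = 2,
                             distractor_mean_intervals = seq(10, 100, by = 10),
                             distractor_duration = 4) {
  base <- noisy_patterning(n_cs = n_cs, k_patterns = k_patterns,
                           n_distractors = length(distractor_mean_intervals),
                           noise_pct = noise_pct, isi = isi[1], iti = iti,
                           cs_duration = cs_duration, us_duration = us_duration)
  cfg <- new_env_config("trace_patterning", c(
    base[setdiff(names(base), c("kind", "isi"))],
    list(isi = as_int_range(isi, "isi"),
         distractor_mean_intervals = as.numeric(distractor_mean_intervals),
         distractor_duration = check_duration(distractor_duration,
                                              "distractor_duration"))))
  cfg
}

#' Expected inter-stimulus interval of a configuration
#'
#' The mean of the inclusive integer-uniform ISI range (equal to the fixed
#' ISI when the range is degenerate).
#'
#' @param config an environment configuration.
#' @return a scalar.
#' @export
expected_isi <- function(config) {
  stopifnot(inherits(config, "cond_env_config"))
  mean(config$isi)
}

#' Default discount factor of an environment
#'
#' Applies the rule gamma = 1 - 1/E(ISI) to the configuration's ISI, so the
#' prediction horizon of the return matches the inter-stimulus interval
#' (0.75 for the default noisy-patterning ISI of 4).
#'
#' @param config an environment configuration.
#' @return the discount factor in [0, 1).
#' @export
env_gamma <- function(config) {
  discount_from_expected_isi(expected_isi(config))
}

#' Channel layout of an environment
#'
#' Channels are ordered CS block, then US, then distractor block.
#'
#' @param config an environment configuration.
#' @return a list with total dimension `d`, index vectors `cs`,
#'   `us`, `distractors`, and channel `names`.
#' @export
channel_layout <- function(config) {
  stopifnot(inherits(config, "cond_env_config"))
  n_cs <- config$n_cs
  n_d <- config$n_distractors
  d <- n_cs + 1L + n_d
  list(d = d,
       cs = seq_len(n_cs),
       us = n_cs + 1L,
       distractors = if (n_d > 0) n_cs + 1L + seq_len(n_d) else integer(),
       names = c(paste0("cs", seq_len(n_cs)), "us",
                 if (n_d > 0) paste0("d", seq_len(n_d))))
}

#' Channel table of an environment
#'
#' @param config an environment configuration.
#' @return a tibble with one row per observation channel.
#' @export
channels <- function(config) {
  lay <- channel_layout(config)
  tibble::tibble(
    index = seq_len(lay$d),
    name = lay$names,
    role = c(rep("cs", length(lay$cs)), "us",
             rep("distractor", length(lay$distractors))))
}

# ---- primitive samplers --------------------------------------------------

sample_int_range <- function(range, n = 1L) {
  range <- as_int_range(range, "range")
  range[1] + sample.int(range[2] - range[1] + 1L, n, replace = TRUE) - 1L
}

#' Sample inter-stimulus / inter-trial intervals
#'
#' Integer-uniform draws on the inclusive range `[lo, hi]`, using R's global
#' RNG. "Uniform on (80, 120)" is read as discrete uniform on {80, ..., 120}
#' so that the stated expected ISIs (10, 20, 30) hold exactly.
#'
#' @param range inclusive integer range `c(lo, hi)` (or a scalar).
#' @param n number of draws.
#' @return integer vector of length `n`.
#' @export
sample_isi <- function(range, n = 1L) sample_int_range(range, n)

#' @rdname sample_isi
#' @export
sample_iti <- function(range, n = 1L) sample_int_range(range, n)

#' Draw activation patterns
#'
#' Samples `k` distinct CS configurations, each with exactly `n_cs/2` active
#' stimuli, without replacement, using R's global RNG.
#'
#' @param n_cs even number of CS channels.
#' @param k number of patterns, at most `choose(n_cs, n_cs/2)`.
#' @return a `k` x `n_cs` 0/1 integer matrix, one pattern per row.
#' @export
generate_activation_patterns <- function(n_cs, k) {
  stopifnot(n_cs %% 2 == 0)
  total <- choose(n_cs, n_cs / 2)
  if (k > total)
    stop("`k` exceeds the number of balanced patterns (", total, ")", call. = FALSE)
  combos <- utils::combn(n_cs, n_cs / 2)
  pick <- sample.int(ncol(combos), k)
  out <- matrix(0L, k, n_cs)
  for (i in seq_len(k)) out[i, combos[, pick[i]]] <- 1L
  out
}

pattern_key <- function(bits) paste(bits, collapse = "")

#' Sample patterning trials
#'
#' Draws trial CS configurations and US outcomes for a patterning
#' environment: with probability 1/2 a uniformly chosen activation pattern,
#' otherwise a uniformly chosen configuration from the complement of the
#' activation set; the US outcome is pattern membership XOR a noise flip
#' that fires with probability `noise_pct`/100.
#'
#' @param n number of trials.
#' @param patterns activation-pattern matrix from
#'   [generate_activation_patterns()].
#' @param noise_pct percent of trials with flipped outcome.
#' @return a tibble with columns `pattern_active`, `noise_flipped`,
#'   `us_outcome` (logical/integer) and a `cs_bits` matrix attribute
#'   (`n` x `n_cs`).
#' @export
sample_trials <- function(n, patterns, noise_pct = 0) {
  stopifnot(is.matrix(patterns), nrow(patterns) >= 1)
  n_cs <- ncol(patterns)
  keys <- apply(patterns, 1, pattern_key)
  member <- stats::rbinom(n, 1L, 0.5) == 1L
  flip <- stats::rbinom(n, 1L, noise_pct / 100) == 1L
  bits <- matrix(0L, n, n_cs)
  idx_pat <- which(member)
  if (length(idx_pat))
    bits[idx_pat, ] <- patterns[sample.int(nrow(patterns), length(idx_pat),
                                           replace = TRUE), , drop = FALSE]
  idx_non <- which(!member)
  if (length(idx_non)) {
    draw <- matrix(stats::rbinom(length(idx_non) * n_cs, 1L, 0.5),
                   length(idx_non), n_cs)
    bad <- apply(draw, 1, pattern_key) %in% keys
    while (any(bad)) {
      draw[bad, ] <- stats::rbinom(sum(bad) * n_cs, 1L, 0.5)
      bad <- apply(draw, 1, pattern_key) %in% keys
    }
    bits[idx_non, ] <- draw
  }
  out <- tibble::tibble(pattern_active = member,
                        noise_flipped = flip,
                        us_outcome = as.integer(xor(member, flip)))
  attr(out, "cs_bits") <- bits
  out
}

#' One trial draw for a patterning environment
#'
#' Single-trial version of [sample_trials()].
#'
#' @inheritParams sample_trials
#' @return a list with `cs_bits`, `pattern_active`, `noise_flipped`,
#'   `us_outcome`.
#' @export
sample_trial <- function(patterns, noise_pct = 0) {
  tr <- sample_trials(1L, patterns, noise_pct)
  list(cs_bits = attr(tr, "cs_bits")[1, ],
       pattern_active = tr$pattern_active[1],
       noise_flipped = tr$noise_flipped[1],
       us_outcome = tr$us_outcome[1])
}

#' Advance free-running distractor channels one step
#'
#' Per inactive channel, an onset occurs with probability
#' `1/mean_intervals[j]` (a Bernoulli thinning of a Poisson process); an
#' onset sets the channel active for `duration` steps. Candidate onsets are
#' drawn every step for every channel and ignored while a channel is
#' active. Uses R's global RNG.
#'
#' @param timers integer vector of remaining-active steps per channel.
#' @param mean_intervals mean steps between onsets per channel (`Inf`
#'   silences a channel).
#' @param duration activation length in steps.
#' @return list with updated `timers` and the emitted `bits`.
#' @export
distractor_step <- function(timers, mean_intervals, duration) {
  stopifnot(length(timers) == length(mean_intervals))
  p <- ifelse(is.finite(mean_intervals), 1 / mean_intervals, 0)
  onset <- stats::rbinom(length(timers), 1L, p) == 1L
  timers[onset & timers == 0L] <- as.integer(duration)
  bits <- as.integer(timers > 0L)
  list(timers = pmax(timers - 1L, 0L), bits = bits)
}

# Block sampler used by the stream generator: same semantics as
# distractor_step (candidates drawn for every step, onsets ignored while
# active), but one channel at a time over a block of L steps.
distractor_block <- function(timers, mean_intervals, duration, L) {
  m <- length(timers)
  bits <- matrix(0L, L, m)
  for (j in seq_len(m)) {
    p <- if (is.finite(mean_intervals[j])) 1 / mean_intervals[j] else 0
    cand <- which(stats::rbinom(L, 1L, p) == 1L)
    last_end <- 0L
    if (timers[j] > 0L) {
      k <- min(timers[j], L)
      bits[seq_len(k), j] <- 1L
      last_end <- as.integer(timers[j])
    }
    for (i in cand) {
      if (i > last_end) {
        end <- i + duration - 1L
        bits[i:min(end, L), j] <- 1L
        last_end <- as.integer(end)
      }
    }
    timers[j] <- max(0L, last_end - L)
  }
  list(timers = timers, bits = bits)
}

# ---- environment object --------------------------------------------------

# The environment is an R environment (reference semantics) holding the
# resolved config, a growing observation buffer, trial annotations, its own
# RNG state, and the trial-machine scheduling variables. All stochastic
# decisions are made at trial granularity in a fixed order (ISI, trial
# pattern/outcome, ITI, distractor draws), then the per-step block is
# emitted; env_step() iterates over the same buffer generate_stream() fills.

env_rng <- function(env, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv(), inherits = FALSE)
  assign(".Random.seed", env$rng_state, globalenv())
  on.exit({
    env$rng_state <- get(".Random.seed", globalenv(), inherits = FALSE)
    if (had) assign(".Random.seed", old, globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

# Segments are appended as blocks (one per trial) and only materialized
# into flat arrays when a consumer asks; appending is O(1) per trial.
append_block <- function(env, obs_block, phase, trial_id, pattern_active,
                         noise_flipped) {
  k <- length(env$blocks) + 1L
  env$blocks[[k]] <- list(obs = obs_block, phase = phase,
                          trial_id = trial_id,
                          pattern_active = pattern_active,
                          noise_flipped = noise_flipped)
  env$n <- env$n + nrow(obs_block)
}

materialize <- function(env, n_steps) {
  ensure_steps(env, n_steps)
  obs <- do.call(rbind, lapply(env$blocks, `[[`, "obs"))
  lens <- vapply(env$blocks, function(b) nrow(b$obs), integer(1))
  list(obs = obs[seq_len(n_steps), , drop = FALSE],
       phase = unlist(lapply(env$blocks, `[[`, "phase"))[seq_len(n_steps)],
       trial_id = rep(vapply(env$blocks, `[[`, integer(1), "trial_id"),
                      lens)[seq_len(n_steps)],
       pattern_active = rep(vapply(env$blocks, function(b)
         as.logical(b$pattern_active), logical(1)), lens)[seq_len(n_steps)],
       noise_flipped = rep(vapply(env$blocks, function(b)
         as.logical(b$noise_flipped), logical(1)), lens)[seq_len(n_steps)])
}

free_running <- function(config) {
  config$kind %in% c("trace_conditioning", "trace_patterning")
}

# Append one full trial segment: steps from this CS onset up to (but not
# including) the next CS onset. RNG order: ISI, trial draw, ITI, distractors.
add_trial_segment <- function(env) {
  cfg <- env$config
  lay <- env$layout
  env_rng(env, {
    isi <- sample_isi(cfg$isi)
    if (cfg$kind == "trace_conditioning") {
      cs_bits <- 1L
      pattern_active <- TRUE
      noise_flipped <- FALSE
      us_outcome <- 1L
    } else {
      tr <- sample_trial(env$patterns, cfg$noise_pct)
      cs_bits <- tr$cs_bits
      pattern_active <- tr$pattern_active
      noise_flipped <- tr$noise_flipped
      us_outcome <- tr$us_outcome
    }
    iti <- sample_iti(cfg$iti)
    L <- isi + iti
    obs <- matrix(0L, L, lay$d)
    cs_rows <- seq_len(min(cfg$cs_duration, L))
    obs[cs_rows, lay$cs] <- matrix(cs_bits, length(cs_rows), cfg$n_cs,
                                   byrow = TRUE)
    us_rows <- integer()
    if (us_outcome == 1L) {
      us_rows <- (isi + 1L):min(isi + cfg$us_duration, L)
      obs[us_rows, lay$us] <- 1L
    }
    if (cfg$n_distractors > 0) {
      if (free_running(cfg)) {
        blk <- distractor_block(env$dist_timers, cfg$distractor_mean_intervals,
                                cfg$distractor_duration, L)
        env$dist_timers <- blk$timers
        obs[, lay$distractors] <- blk$bits
      } else {
        dbits <- stats::rbinom(cfg$n_distractors, 1L, 0.5)
        obs[cs_rows, lay$distractors] <- matrix(dbits, length(cs_rows),
                                                cfg$n_distractors, byrow = TRUE)
      }
    }
    phase <- rep("iti", L)
    phase[cs_rows] <- "cs"
    if (isi > cfg$cs_duration) phase[(cfg$cs_duration + 1L):isi] <- "gap"
    phase[us_rows] <- "us"
    env$trial <- env$trial + 1L
    append_block(env, obs, phase, env$trial, pattern_active, noise_flipped)
  })
  invisible(env)
}

#' Construct a benchmark environment
#'
#' Builds a seeded environment object. Activation patterns (for patterning
#' benchmarks) are drawn once at construction; the stream before the first
#' CS onset is an initial inter-trial interval. The object has reference
#' semantics: [env_step()] advances it in place. Each environment carries
#' its own RNG state, so interleaved use of R's global RNG does not affect
#' reproducibility.
#'
#' @param config an environment configuration from [trace_conditioning()],
#'   [noisy_patterning()], or [trace_patterning()].
#' @param seed integer seed; identical config + seed gives a bit-identical
#'   observation stream.
#' @return an object of class `cond_env`.
#' @export
make_env <- function(config, seed = 1L) {
  stopifnot(inherits(config, "cond_env_config"))
  lay <- channel_layout(config)
  env <- new.env(parent = emptyenv())
  env$config <- config
  env$layout <- lay
  env$seed <- as.integer(seed)
  env$blocks <- list()
  env$n <- 0L
  env$pos <- 0L
  env$blk_i <- 1L
  env$blk_off <- 0L
  env$trial <- 0L
  env$dist_timers <- integer(config$n_distractors %||% 0L)

  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(env$seed)
  env$rng_state <- get(".Random.seed", globalenv(), inherits = FALSE)
  if (had) assign(".Random.seed", old, globalenv())
  else rm(".Random.seed", envir = globalenv())

  env_rng(env, {
    if (config$kind != "trace_conditioning")
      env$patterns <- generate_activation_patterns(config$n_cs,
                                                   config$k_patterns)
    iti0 <- sample_iti(config$iti)
    if (iti0 > 0) {
      obs <- matrix(0L, iti0, lay$d)
      if (config$n_distractors > 0 && free_running(config)) {
        blk <- distractor_block(env$dist_timers,
                                config$distractor_mean_intervals,
                                config$distractor_duration, iti0)
        env$dist_timers <- blk$timers
        obs[, lay$distractors] <- blk$bits
      }
      append_block(env, obs, rep("iti", iti0), 0L, NA, NA)
    }
  })
  class(env) <- c("cond_env", "environment")
  env
}

ensure_steps <- function(env, n) {
  while (env$n < n) add_trial_segment(env)
  invisible(env)
}

#' Advance an environment one step
#'
#' Emits the next binary observation vector together with the
#' evaluation-only trial annotation (never shown to learners).
#'
#' @param env a `cond_env` from [make_env()].
#' @return a list with `values` (named 0/1 vector of length `d`) and
#'   `annotation` (`step`, `trial_id`, `phase`, `pattern_active`,
#'   `noise_flipped`).
#' @export
env_step <- function(env) {
  stopifnot(inherits(env, "cond_env"))
  env$pos <- env$pos + 1L
  ensure_steps(env, env$pos)
  while (env$blk_off >= nrow(env$blocks[[env$blk_i]]$obs)) {
    env$blk_i <- env$blk_i + 1L
    env$blk_off <- 0L
  }
  env$blk_off <- env$blk_off + 1L
  b <- env$blocks[[env$blk_i]]
  j <- env$blk_off
  list(values = setNames(b$obs[j, ], env$layout$names),
       annotation = list(step = env$pos, trial_id = b$trial_id,
                         phase = b$phase[j],
                         pattern_active = as.logical(b$pattern_active),
                         noise_flipped = as.logical(b$noise_flipped)))
}

#' Reset an environment's read position
#'
#' Rewinds the iterator without touching the generated stream, so the same
#' steps are replayed.
#'
#' @param env a `cond_env`.
#' @export
env_reset <- function(env) {
  env$pos <- 0L
  env$blk_i <- 1L
  env$blk_off <- 0L
  invisible(env)
}

#' Generate an observation stream
#'
#' Produces the first `n_steps` observations of a freshly seeded
#' environment as a tibble: one row per step with the binary channel
#' columns (CS block, `us`, distractor block) and the evaluation-only
#' annotations `phase` ("cs", "gap", "us", "iti"), `trial_id`,
#' `pattern_active`, `noise_flipped`.
#'
#' @param config an environment configuration.
#' @param n_steps number of steps.
#' @param seed integer seed.
#' @return a tibble with attributes `layout`, `config`, `gamma` (the
#'   environment's default discount factor) and, for patterning
#'   environments, `patterns`.
#' @examples
#' s <- generate_stream(trace_conditioning(), 500, seed = 1)
#' table(s$phase)
#' @export
generate_stream <- function(config, n_steps, seed = 1L) {
  env <- make_env(config, seed)
  mat <- materialize(env, n_steps)
  obs <- mat$obs
  colnames(obs) <- env$layout$names
  out <- tibble::as_tibble(as.data.frame(obs))
  out <- tibble::add_column(out, step = seq_len(n_steps), .before = 1)
  out$phase <- mat$phase
  out$trial_id <- mat$trial_id
  out$pattern_active <- mat$pattern_active
  out$noise_flipped <- mat$noise_flipped
  attr(out, "layout") <- env$layout
  attr(out, "config") <- config
  attr(out, "gamma") <- env_gamma(config)
  if (!is.null(env$patterns)) attr(out, "patterns") <- env$patterns
  out
}

#' Extract the observation matrix from a stream
#'
#' @param stream a tibble from [generate_stream()].
#' @return a numeric `n_steps` x `d` matrix of the channel columns.
#' @export
obs_matrix <- function(stream) {
  lay <- attr(stream, "layout")
  stopifnot(!is.null(lay))
  as.matrix(stream[, lay$names])
}

#' Dump a stream to CSV
#'
#' One row per step: step, one column per channel, phase, trial id.
#'
#' @param stream a tibble from [generate_stream()].
#' @param path output file.
#' @export
write_stream_csv <- function(stream, path) {
  utils::write.csv(as.data.frame(stream), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.cond_env <- function(x, ...) {
  cat("<cond_env: ", x$config$kind, ", d = ", x$layout$d,
      ", seed = ", x$seed, ", steps generated = ", x$n, ">\n", sep = "")
  invisible(x)
}

#' @export
print.cond_env_config <- function(x, ...) {
  cat("<", x$kind, " config>\n", sep = "")
  for (f in setdiff(names(x), "kind"))
    cat("  ", f, ": ", paste(format(x[[f]]), collapse = " "), "\n", sep = "")
  invisible(x)
}
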