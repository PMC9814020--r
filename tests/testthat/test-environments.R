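# The three benchmark generators: channel layout, trial timing, stimulus
# durations, distractor statistics, pattern logic, and reproducibility.

test_that("channel layouts match the configured stimulus counts", {
  expect_equal(channel_layout(trace_conditioning())$d, 12)
  expect_equal(channel_layout(noisy_patterning(n_cs = 8,
                                               n_distractors = 10))$d, 19)
  lay <- channel_layout(trace_patterning())
  expect_equal(lay$d, 19)
  expect_setequal(c(lay$cs, lay$us, lay$distractors), seq_len(lay$d))
  ch <- channels(noisy_patterning())
  expect_equal(table(ch$role)[["cs"]], 8)
  expect_equal(table(ch$role)[["distractor"]], 10)
})

test_that("invalid configurations are rejected with the field named", {
  expect_error(trace_conditioning(isi = c(13, 7)), "isi")
  expect_error(trace_conditioning(cs_duration = 0), "cs_duration")
  expect_error(noisy_patterning(n_cs = 7), "n_cs")
  expect_error(noisy_patterning(n_cs = 4, k_patterns = 10), "k_patterns")
  expect_error(noisy_patterning(noise_pct = 150), "noise_pct")
  expect_error(sample_isi(c(5, 3)), "lower bound")
})

test_that("streams are bit-identical under the same seed", {
  for (cfg in list(trace_conditioning(), noisy_patterning(),
                   trace_patterning())) {
    s1 <- generate_stream(cfg, 1000, seed = 42)
    s2 <- generate_stream(cfg, 1000, seed = 42)
    expect_identical(s1, s2)
    s3 <- generate_stream(cfg, 1000, seed = 43)
    expect_false(identical(obs_matrix(s1), obs_matrix(s3)))
  }
})

test_that("env_step replays the same stream as generate_stream", {
  cfg <- trace_patterning()
  s <- generate_stream(cfg, 400, seed = 9)
  env <- make_env(cfg, seed = 9)
  obs <- obs_matrix(s)
  for (i in 1:400) {
    st <- env_step(env)
    expect_equal(unname(st$values), unname(obs[i, ]))
    expect_equal(st$annotation$phase, s$phase[i])
    expect_equal(st$annotation$trial_id, s$trial_id[i])
  }
  env_reset(env)
  st <- env_step(env)
  expect_equal(unname(st$values), unname(obs[1, ]))
})

test_that("CS and US run lengths equal the configured durations", {
  s <- generate_stream(trace_conditioning(), 30000, seed = 3)
  cs_runs <- rle(s$cs1)
  expect_equal(unique(cs_runs$lengths[cs_runs$values == 1]), 4)
  us_runs <- rle(s$us)
  expect_equal(unique(us_runs$lengths[us_runs$values == 1]), 2)
  expect_gt(max(s$trial_id), 100)
  # US is active exactly during the "us" phase, CS during the "cs" phase
  expect_equal(s$us == 1, s$phase == "us")
  expect_equal(s$cs1 == 1, s$phase == "cs")
})

test_that("ISI and ITI samplers are integer-uniform on inclusive ranges", {
  set.seed(1)
  draws <- sample_isi(c(7, 13), n = 10000)
  freq <- table(factor(draws, levels = 7:13)) / 10000
  expect_equal(length(freq), 7L)
  expect_true(all(abs(freq - 1 / 7) < 0.02))
  expect_equal(unique(sample_isi(c(10, 10), n = 50)), 10L)
  itis <- sample_iti(c(80, 120), n = 5000)
  expect_gte(min(itis), 80)
  expect_lte(max(itis), 120)
})

test_that("trial anchoring: ITI spans US onset to next CS onset", {
  s <- generate_stream(trace_conditioning(iti = c(90, 90)), 8000, seed = 5)
  cs_on <- s$step[s$phase == "cs" & c(TRUE, s$phase[-nrow(s)] != "cs")]
  us_on <- s$step[s$phase == "us" & c(TRUE, s$phase[-nrow(s)] != "us")]
  k <- min(length(cs_on) - 1, length(us_on))
  gaps <- cs_on[seq_len(k) + 1] - us_on[seq_len(k)]
  expect_true(all(gaps == 90))
  isis <- us_on[seq_len(k)] - cs_on[seq_len(k)]
  expect_true(all(isis >= 7 & isis <= 13))
})

test_that("free-running distractors respect duration and renewal rate", {
  # renewal oracle: cycle = duration + mean inter-onset wait, so the
  # long-run active fraction is duration / (duration + mean)
  s <- generate_stream(trace_conditioning(), 1e6, seed = 11)
  for (j in c(1, 5, 10)) {
    ch <- s[[paste0("d", j)]]
    runs <- rle(ch)
    # every activation episode lasts exactly 4 steps; abutting episodes
    # (an onset landing right at expiry) concatenate into multiples of 4
    lens <- runs$lengths[runs$values == 1 &
                           seq_along(runs$values) < length(runs$values)]
    expect_true(all(lens %% 4 == 0))
    expect_equal(min(lens), 4)
    frac <- mean(ch)
    oracle <- 4 / (4 + 10 * j)
    expect_lt(abs(frac - oracle) / oracle, 0.1)
  }
  # infinite mean interval silences a channel
  st <- distractor_step(timers = c(0L, 0L), mean_intervals = c(Inf, 2),
                        duration = 3)
  expect_equal(st$bits[1], 0L)
})

test_that("distractor_step matches the documented onset/suppression rule", {
  set.seed(2)
  timers <- 0L
  bits <- integer(200)
  for (t in 1:200) {
    st <- distractor_step(timers, mean_intervals = 5, duration = 4)
    bits[t] <- st$bits
    timers <- st$timers
  }
  runs <- rle(bits)
  lens <- runs$lengths[runs$values == 1]
  expect_true(all(head(lens, -1) %% 4 == 0))  # suppressed onsets never shorten
  expect_true(all(lens[-length(lens)] >= 4))
})

test_that("activation patterns are distinct and balanced", {
  set.seed(7)
  pats <- generate_activation_patterns(8, 8)
  expect_equal(dim(pats), c(8, 8))
  expect_equal(unname(rowSums(pats)), rep(4, 8))
  expect_equal(nrow(unique(pats)), 8)
  set.seed(7)
  expect_identical(pats, generate_activation_patterns(8, 8))
  expect_setequal(apply(generate_activation_patterns(2, 2), 1, paste,
                        collapse = ""), c("10", "01"))
  expect_error(generate_activation_patterns(4, 10), "balanced")
})

test_that("trial sampler: balanced membership, noise flip, outcome rule", {
  set.seed(13)
  pats <- generate_activation_patterns(8, 8)
  tr <- sample_trials(50000, pats, noise_pct = 10)
  expect_lt(abs(mean(tr$pattern_active) - 0.5), 0.01)
  expect_lt(abs(mean(tr$noise_flipped) - 0.10), 0.005)
  expect_equal(tr$us_outcome, as.integer(xor(tr$pattern_active,
                                             tr$noise_flipped)))
  # with zero noise the US outcome equals pattern membership, and the
  # membership implied by the emitted CS bits matches the annotation
  tr0 <- sample_trials(4000, pats, noise_pct = 0)
  bits <- attr(tr0, "cs_bits")
  keys <- apply(pats, 1, paste, collapse = "")
  member <- apply(bits, 1, paste, collapse = "") %in% keys
  expect_equal(tr0$us_outcome, as.integer(member))
  expect_equal(tr0$pattern_active, member)
})

test_that("noiseless patterning streams fire the US iff a pattern occurred", {
  cfg <- noisy_patterning(noise_pct = 0)
  s <- generate_stream(cfg, 60000, seed = 21)
  per_trial <- split(s[s$trial_id > 0, ], s$trial_id[s$trial_id > 0])
  per_trial <- per_trial[vapply(per_trial, nrow, integer(1)) > 10]
  for (tr in per_trial) {
    expect_equal(any(tr$us == 1), tr$pattern_active[1])
  }
})

test_that("noisy-patterning distractors are trial-locked to the CS window", {
  s <- generate_stream(noisy_patterning(), 20000, seed = 2)
  dcols <- as.matrix(s[paste0("d", 1:10)])
  active <- rowSums(dcols) > 0
  expect_true(all(s$phase[active] == "cs"))
})

test_that("trace patterning combines stochastic ISI with pattern logic", {
  cfg <- trace_patterning()
  expect_equal(cfg$n_distractors, 10L)
  s <- generate_stream(cfg, 40000, seed = 4)
  cs_on <- s$step[s$phase == "cs" & c(TRUE, s$phase[-nrow(s)] != "cs")]
  us_on <- s$step[s$phase == "us" & c(TRUE, s$phase[-nrow(s)] != "us")]
  # ISIs measured on US-active trials span the configured range
  us_trials <- s$trial_id[match(us_on, s$step)]
  on_trials <- s$trial_id[match(cs_on, s$step)]
  isis <- us_on - cs_on[match(us_trials, on_trials)]
  expect_true(all(isis >= 7 & isis <= 13))
  expect_gt(length(unique(isis)), 3)
  # distractors run during the ITI (free-running)
  dcols <- as.matrix(s[paste0("d", 1:10)])
  expect_gt(sum(dcols[s$phase == "iti", ]), 0)
})
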