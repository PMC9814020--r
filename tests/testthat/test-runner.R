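# Orchestration: seed policy, reproducible summaries, sweep selection,
# trial-aligned profiles, YAML round trips, and artifact writing.

test_that("run_many uses distinct logged seeds and reproduces exactly", {
  cfg <- trace_conditioning()
  ag <- agent_linear(rep_microstimulus(), td_hyper(alpha = 2^-8))
  rs <- run_many(cfg, ag, n_steps = 3000, n_runs = 3, seed_base = 10)
  expect_equal(tidy(rs)$seed, c(10L, 11L, 12L))
  expect_equal(length(unique(tidy(rs)$msre)), 3)
  rs2 <- run_many(cfg, ag, n_steps = 3000, n_runs = 3, seed_base = 10)
  expect_identical(tidy(rs), tidy(rs2))
  expect_identical(rs$config_digest, rs2$config_digest)
  g <- glance(rs)
  expect_equal(g$msre_mean, mean(tidy(rs)$msre))
  expect_equal(g$stderr, sd(tidy(rs)$msre) / sqrt(3))
})

test_that("sweeps select the lowest-MSRE setting, first on ties", {
  cfg <- trace_conditioning()
  agents <- list(
    small = agent_linear(rep_microstimulus(), td_hyper(alpha = 2^-10)),
    large = agent_linear(rep_microstimulus(), td_hyper(alpha = 2^-4)))
  sw <- sweep_agents(cfg, agents, n_steps = 4000, n_runs = 2, seed_base = 1)
  expect_equal(nrow(sw), 2)
  best <- select_best(sw)
  expect_equal(best$msre_mean, min(sw$msre_mean))
  # selection is a pure function of the summary table
  fake <- sw
  fake$msre_mean <- c(0.5, 0.5)
  expect_equal(select_best(fake)$agent_id, "small")
})

test_that("profiles align on CS onset and peak where the return peaks", {
  cfg <- trace_conditioning(isi = 10)
  r <- run_linear_agent(cfg, rep_microstimulus(), td_hyper(alpha = 2^-8),
                        n_steps = 30000, seed = 2)
  prof <- extract_profile(r, window = c(-5, 30))
  expect_s3_class(prof, "cond_profile")
  expect_equal(prof$offset[1], -5)
  # deterministic ISI: the mean return peaks at offset ISI - 1 from onset
  expect_equal(prof$offset[which.max(prof$return)], 9)
  expect_error(extract_profile(r, window = c(-5, 1e6)), "no complete trials")
})

test_that("presence predictions stay flat through the trace interval", {
  suite <- linear_suite()
  prof <- extract_profile(suite$presence_run, window = c(0, 12))
  gap_mean <- mean(prof$prediction[prof$offset %in% 5:8])
  cs_mean <- mean(prof$prediction[prof$offset %in% 0:3])
  expect_lte(gap_mean, cs_mean)
})

test_that("YAML run configurations round-trip and reproduce results", {
  tmp <- tempfile(fileext = ".yaml")
  rc <- list(config = trace_patterning(n_cs = 4, k_patterns = 2),
             agent = agent_recurrent("gru", "tbptt", n_hidden = 6,
                                     tbptt_T = 3),
             n_steps = 1500L, n_runs = 2L, seed_base = 5L)
  write_run_config(rc, tmp)
  rc2 <- read_run_config(tmp)
  expect_equal(unclass(rc2$config), unclass(rc$config))
  expect_equal(rc2$agent$label, rc$agent$label)
  r1 <- execute_run_config(rc)
  r2 <- execute_run_config(rc2)
  expect_identical(tidy(r1), tidy(r2))
})

test_that("artifacts embed the config and overwriting is refused", {
  out <- file.path(tempfile(), "runA")
  rc <- list(config = trace_conditioning(),
             agent = agent_linear(rep_presence(), td_hyper(alpha = 2^-8)),
             n_steps = 1000L, n_runs = 2L, seed_base = 1L)
  execute_run_config(rc, out_dir = out, keep_logs = TRUE)
  expect_true(file.exists(file.path(out, "summary.json")))
  expect_true(file.exists(file.path(out, "run001.csv")))
  payload <- jsonlite::read_json(file.path(out, "summary.json"))
  expect_equal(payload$environment, "trace_conditioning")
  expect_equal(payload$seed_base, 1L)
  expect_equal(payload$config$kind, "trace_conditioning")
  # every summary number is recomputable from the per-step log alone
  log1 <- utils::read.csv(file.path(out, "run001.csv"))
  expect_equal(payload$per_run[[1]]$msre,
               msre(log1$prediction, log1$return, log1$valid),
               tolerance = 1e-12)
  expect_error(execute_run_config(rc, out_dir = out), "overwrite")
})

test_that("stream and run logs export to CSV", {
  s <- generate_stream(noisy_patterning(), 300, seed = 1)
  f <- tempfile(fileext = ".csv")
  write_stream_csv(s, f)
  back <- utils::read.csv(f)
  expect_equal(nrow(back), 300)
  expect_true(all(c("step", "us", "phase", "trial_id") %in% names(back)))
})

test_that("plot methods return ggplot objects", {
  r <- run_linear_agent(trace_conditioning(), rep_microstimulus(),
                        n_steps = 3000, seed = 1)
  expect_s3_class(autoplot(r), "ggplot")
  expect_s3_class(autoplot(extract_profile(r)), "ggplot")
  ag <- agent_linear(rep_presence())
  sw <- sweep_agents(trace_conditioning(), list(a = ag), n_steps = 1000,
                     n_runs = 2)
  expect_s3_class(plot_sweep(sw), "ggplot")
})
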