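# Recurrent learners: cell forward passes, T-BPTT and RTRL gradients,
# trace augmentation, determinism, and the truncation-length effects.

test_that("compiled forward passes match the R reference gate equations", {
  for (arch in c("rnn", "lstm", "gru")) {
    params <- random_cell(arch, 4, 8, seed = 17)
    set.seed(18)
    obs <- matrix(rbinom(30 * 4, 1, 0.3), 30, 4)
    fwd <- cell_forward_seq(params, obs)
    st <- list(h = numeric(8), c = numeric(8))
    for (k in 1:30) {
      st <- cell_forward(params, st, obs[k, ])
      expect_lt(max(abs(st$h - fwd$H[k, ])), 1e-6)
      expect_lt(abs(st$V - fwd$V[k]), 1e-6)
    }
  }
})

test_that("degenerate cells behave as the gate algebra dictates", {
  # zero weights, zero state -> zero state and V = head bias
  for (arch in c("rnn", "lstm", "gru")) {
    params <- cell_init(arch, 3, 5)
    params$W[] <- 0
    params$b[] <- 0
    params$bv <- 0.7
    out <- cell_forward(params, list(h = numeric(5), c = numeric(5)),
                        c(1, 1, 0))
    expect_equal(out$h, numeric(5))
    expect_equal(out$V, 0.7)
  }
  # GRU gate saturation: update gate ~0 copies the candidate, ~1 keeps
  # the previous state
  params <- random_cell("gru", 3, 5, seed = 3)
  h_prev <- runif(5, -0.5, 0.5)
  params$b[1:5] <- -50  # z -> 0
  out <- cell_forward(params, list(h = h_prev, c = numeric(5)), c(1, 0, 1))
  zin <- c(1, 0, 1)
  r <- 1 / (1 + exp(-(as.numeric(params$W[6:10, ] %*% c(zin, h_prev)) +
                        params$b[6:10])))
  cand <- tanh(as.numeric(params$W[11:15, ] %*% c(zin, r * h_prev)) +
                 params$b[11:15])
  expect_equal(out$h, cand, tolerance = 1e-10)
  params$b[1:5] <- 50   # z -> 1
  out2 <- cell_forward(params, list(h = h_prev, c = numeric(5)), c(1, 0, 1))
  expect_equal(out2$h, h_prev, tolerance = 1e-10)
})

test_that("T-BPTT window gradients match central finite differences", {
  for (arch in c("rnn", "lstm", "gru")) {
    for (T in c(1, 10)) {
      params <- random_cell(arch, 3, 6, seed = 23)
      set.seed(24)
      obs <- matrix(rbinom(T * 3, 1, 0.4), T, 3)
      us <- rbinom(T, 1, 0.3)
      h0 <- runif(6, -0.5, 0.5)
      c0 <- runif(6, -0.5, 0.5)
      g <- tbptt_window_grad(params, obs, us, v_boot = 0.4, gamma = 0.9,
                             h0 = h0, c0 = c0)
      fd <- fd_window_grad(params, obs, us, 0.4, 0.9, h0, c0)
      expect_lt(rel_err(g, fd), 1e-4)
    }
  }
})

test_that("frozen-parameter RTRL equals full-unroll backprop", {
  for (arch in c("rnn", "lstm", "gru")) {
    params <- random_cell(arch, 3, 8, seed = 29)
    set.seed(30)
    obs <- matrix(rbinom(50 * 3, 1, 0.3), 50, 3)
    us <- rbinom(50, 1, 0.2)
    g_rtrl <- rtrl_accum_grad(params, obs, us, 0.9)
    g_bptt <- full_unroll_grad(params, obs, us, 0.9)
    expect_lt(rel_err(g_rtrl, g_bptt), 1e-6)
  }
})

test_that("with zero recurrent weights RTRL reduces to step-local gradients", {
  params <- random_cell("rnn", 3, 6, seed = 5)
  params$W[, 4:9] <- 0  # recurrent columns
  set.seed(6)
  obs <- matrix(rbinom(20 * 3, 1, 0.4), 20, 3)
  us <- rbinom(20, 1, 0.3)
  g <- rtrl_accum_grad(params, obs, us, 0.9)
  # step-local oracle: each V_t depends only on W through step t itself
  fwd <- cell_forward_seq(params, obs)
  P <- length(condbench:::flatten_params(params))
  g_local <- numeric(P)
  n <- params$n_hidden
  for (t in 1:19) {
    delta <- us[t + 1] + 0.9 * fwd$V[t + 1] - fwd$V[t]
    h <- fwd$H[t, ]
    hprev <- if (t == 1) numeric(n) else fwd$H[t - 1, ]
    zin <- c(obs[t, ], hprev)
    da <- params$wv * (1 - h^2)
    gW <- outer(da, zin)
    g_local <- g_local - delta * c(as.numeric(gW), da, h, 1)
  }
  expect_lt(rel_err(g, g_local), 1e-10)
})

test_that("an all-zero US stream with a zero head leaves parameters fixed", {
  set.seed(9)
  obs <- matrix(rbinom(500 * 3, 1, 0.3), 500, 3)
  us <- numeric(500)
  for (trainer in 0:1) {
    params <- cell_init("lstm", 3, 6)
    th0 <- condbench:::flatten_params(params)
    res <- condbench:::recurrent_agent_cpp(
      obs, us, 1L, trainer, th0, 6L,
      condbench:::hyper_to_cpp(td_hyper(alpha = 0.01, lambda = 0, gamma = 0.9)),
      5L, 1L)
    expect_equal(as.numeric(res$theta), th0)
    expect_equal(as.numeric(res$pred), numeric(500))
  }
})

test_that("trace augmentation concatenates per-channel traces", {
  s <- generate_stream(trace_conditioning(), 300, seed = 1)
  obs <- obs_matrix(s)
  aug <- augment_with_traces(obs, tau = 0.9)
  expect_equal(dim(aug), c(300, 24))
  expect_equal(aug[, 1:12], obs)
  expect_equal(unname(aug[, 13:24]), condbench:::trace_matrix(obs, 0.9))
  expect_identical(augment_with_traces(obs, 0.9, enabled = FALSE), obs)
})

test_that("recurrent runs are deterministic given the seed", {
  cfg <- trace_conditioning()
  for (trainer in c("tbptt", "rtrl")) {
    r1 <- run_recurrent_agent(cfg, "gru", trainer, n_hidden = 8, tbptt_T = 5,
                              n_steps = 4000, seed = 11)
    r2 <- run_recurrent_agent(cfg, "gru", trainer, n_hidden = 8, tbptt_T = 5,
                              n_steps = 4000, seed = 11)
    expect_identical(r1$log, r2$log)
    r3 <- run_recurrent_agent(cfg, "gru", trainer, n_hidden = 8, tbptt_T = 5,
                              n_steps = 4000, seed = 12)
    expect_false(identical(r1$log$prediction, r3$log$prediction))
  }
})

test_that("MSRE is non-increasing in the truncation length (up to 1 stderr)", {
  suite <- recurrent_suite()
  Ts <- c("1", "5", "10", "20")
  means <- vapply(suite$tbptt[Ts], mean, numeric(1))
  ses <- vapply(suite$tbptt[Ts], stderr_of, numeric(1))
  for (i in 2:4) {
    expect_lte(means[i], means[i - 1] + ses[i - 1] + ses[i])
  }
})

test_that("trace augmentation rescues a short truncation window", {
  suite <- recurrent_suite()
  aug1 <- mean(suite$aug1)
  t1 <- mean(suite$tbptt[["1"]])
  t10 <- mean(suite$tbptt[["10"]])
  expect_lt(aug1, 1.5 * t10)  # augmented T=1 close to un-augmented T=10
  expect_gt(t1, 2 * aug1)     # un-augmented T=1 is far worse
})
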