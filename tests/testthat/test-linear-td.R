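# Semi-gradient TD(lambda): prediction, eligibility recursion, optimizer
# modes, engine equivalence, and convergence on a known Markov chain.

test_that("linear prediction is the inner product", {
  set.seed(1)
  w <- runif(20)
  x <- runif(20)
  expect_equal(td_predict(w, x), sum(vapply(1:20, function(i) w[i] * x[i],
                                            numeric(1))), tolerance = 1e-12)
  expect_equal(td_predict(numeric(5), runif(5)), 0)
  xb <- c(rep(0, 4), 1)
  expect_equal(td_predict(c(rep(0, 4), 2.5), xb), 2.5)
  expect_error(td_predict(1:3, 1:4), "mismatch")
})

test_that("eligibility recursion follows z <- gamma lambda z + x", {
  hy <- td_hyper(alpha = 0.1, lambda = 0, gamma = 0.9, optimizer = "sgd")
  st <- td_init(3)
  x <- c(1, 0, 2)
  st <- td_update(st, x, c(0, 1, 0), us_next = 1, hy)
  expect_equal(st$z, x)  # lambda = 0: one-step trace
  hy9 <- td_hyper(alpha = 0.1, lambda = 0.9, gamma = 0.9, optimizer = "sgd")
  st <- td_init(3)
  st <- td_update(st, x, numeric(3), 0, hy9)
  z0 <- st$z
  for (k in 1:4) st <- td_update(st, numeric(3), numeric(3), 0, hy9)
  expect_equal(st$z, (0.9 * 0.9)^4 * z0, tolerance = 1e-14)
})

test_that("a zero TD error leaves plain-SGD weights unchanged", {
  hy <- td_hyper(alpha = 0.5, lambda = 0.9, gamma = 0.5, optimizer = "sgd")
  st <- td_init(2)
  st$w <- c(2, 1)  # V(x)=2 at x=(1,0); V=1 at (0,1); us=2-0.5 gives delta 0
  st2 <- td_update(st, c(1, 0), c(0, 1), us_next = 2, hy)
  expect_equal(st2$delta, 2 + 0.5 * 1 - 2)
  st3 <- td_update(st, c(1, 0), c(0, 1), us_next = 2 - 0.5 * 1, hy)
  expect_equal(st3$delta, 0)
  expect_equal(st3$w, st$w)
})

test_that("non-finite TD errors abort the run with a diagnostic", {
  hy <- td_hyper(alpha = 0.5, lambda = 0, gamma = 0.9, optimizer = "sgd")
  st <- td_init(2)
  st$w <- c(Inf, 0)
  expect_error(td_update(st, c(1, 0), c(0, 1), 1, hy), "non-finite")
})

test_that("compiled tabular TD reproduces the one-step reference exactly", {
  n <- 2000
  s <- simulate_chain(n, seed = 4)
  cum <- chain_cumulant[s]
  r <- run_td_tabular(s, cum, chain_gamma, alpha = 0.05)
  X <- diag(5)
  st <- td_init(5)
  hy <- td_hyper(alpha = 0.05, lambda = 0, gamma = chain_gamma,
                 optimizer = "sgd")
  for (t in 1:(n - 1)) st <- td_update(st, X[s[t], ], X[s[t + 1], ],
                                       cum[t + 1], hy)
  expect_equal(as.numeric(r$w), st$w, tolerance = 1e-12)
  # and with eligibility traces
  r9 <- run_td_tabular(s, cum, chain_gamma, alpha = 0.05, lambda = 0.9)
  st9 <- td_init(5)
  hy9 <- td_hyper(alpha = 0.05, lambda = 0.9, gamma = chain_gamma,
                  optimizer = "sgd")
  for (t in 1:(n - 1)) st9 <- td_update(st9, X[s[t], ], X[s[t + 1], ],
                                        cum[t + 1], hy9)
  expect_equal(as.numeric(r9$w), st9$w, tolerance = 1e-12)
})

test_that("tabular TD(0) converges to the analytic chain values", {
  v_true <- chain_value_oracle()
  n <- 2e6
  s <- simulate_chain(n, seed = 1)
  r <- run_td_tabular(s, chain_cumulant, chain_gamma, alpha = NULL,
                      avg_from = round(0.25 * n), alpha_pow = 0.5)
  expect_lt(max(abs(r$w_avg - v_true)), 5e-3)
})

test_that("the R and C++ agent engines agree for every representation", {
  cfg <- trace_conditioning()
  reps <- list(rep_presence(), rep_trace(), rep_tilecoded(),
               rep_microstimulus(), rep_esn(n_hidden = 20))
  for (rp in reps) {
    rr <- run_linear_agent(cfg, rp, td_hyper(alpha = 2^-6), n_steps = 400,
                           seed = 2, engine = "r")
    rc <- run_linear_agent(cfg, rp, td_hyper(alpha = 2^-6), n_steps = 400,
                           seed = 2, engine = "cpp")
    expect_lt(max(abs(rr$log$prediction - rc$log$prediction)), 1e-10)
    expect_lt(max(abs(rr$meta$weights - rc$meta$weights)), 1e-10)
  }
  # and in plain-SGD mode
  rr <- run_linear_agent(cfg, rep_tilecoded(),
                         td_hyper(alpha = 2^-6, optimizer = "sgd"),
                         n_steps = 400, seed = 2, engine = "r")
  rc <- run_linear_agent(cfg, rep_tilecoded(),
                         td_hyper(alpha = 2^-6, optimizer = "sgd"),
                         n_steps = 400, seed = 2, engine = "cpp")
  expect_lt(max(abs(rr$log$prediction - rc$log$prediction)), 1e-10)
})

test_that("linear runs are reproducible and tidy/glance structured", {
  cfg <- trace_conditioning()
  r1 <- run_linear_agent(cfg, rep_microstimulus(), n_steps = 3000, seed = 6)
  r2 <- run_linear_agent(cfg, rep_microstimulus(), n_steps = 3000, seed = 6)
  expect_identical(r1$log, r2$log)
  g <- glance(r1)
  expect_s3_class(g, "tbl_df")
  expect_equal(g$msre, r1$msre)
  expect_named(tidy(r1), c("step", "prediction", "us", "return", "valid",
                           "phase", "trial_id"))
})

test_that("trace-based representations beat presence on short-ISI trace conditioning", {
  suite <- linear_suite()
  expect_lt(suite$best[["microstimulus"]], suite$best[["presence"]] / 2)
  expect_lt(suite$best[["tilecoded"]], suite$best[["presence"]] / 2)
})
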