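# Scaled replication suites shared across test files. Computed once per
# test session and cached; sizes (200k steps linear / 150k steps
# recurrent, 16 hidden units, 5 seeds) are the package's scaled protocol.

.cond_suite_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cond_suite_cache[[key]]))
    .cond_suite_cache[[key]] <- force(expr)
  .cond_suite_cache[[key]]
}

# Linear fixed-representation suite on short-ISI trace conditioning:
# step size swept per representation, 2 seeds per cell, 200k steps.
linear_suite <- function() {
  cached("linear", {
    cfg <- trace_conditioning()
    alphas <- 2^c(-6, -8, -10, -12)
    grid <- expand.grid(rep = c("presence", "tilecoded", "microstimulus"),
                        alpha = alphas, stringsAsFactors = FALSE)
    grid$msre <- mapply(function(rp, a) {
      mk <- switch(rp, presence = rep_presence(), tilecoded = rep_tilecoded(),
                   microstimulus = rep_microstimulus())
      mean(vapply(1:2, function(s)
        run_linear_agent(cfg, mk, td_hyper(alpha = a), n_steps = 200000,
                         seed = s)$msre, numeric(1)))
    }, grid$rep, grid$alpha)
    best <- vapply(split(grid, grid$rep), function(g) min(g$msre), numeric(1))
    best_alpha <- vapply(split(grid, grid$rep),
                         function(g) g$alpha[which.min(g$msre)], numeric(1))
    presence_run <- run_linear_agent(cfg, rep_presence(),
                                     td_hyper(alpha = best_alpha[["presence"]]),
                                     n_steps = 200000, seed = 1)
    list(grid = grid, best = best, best_alpha = best_alpha,
         presence_run = presence_run)
  })
}

# Recurrent suite: LSTM on short-ISI trace conditioning, 150k steps,
# 16 hidden units, seeds 1..5. T-BPTT truncations T in {1, 5, 10, 20} with
# the step size swept over {2^-11, 2^-12} per T (lowest mean MSRE wins,
# mirroring the parameter-selection protocol); RTRL and the
# trace-augmented T = 1 variant use step sizes selected by the same sweep
# protocol during development (2^-9).
recurrent_suite <- function() {
  cached("recurrent", {
    cfg <- trace_conditioning()
    seeds <- 1:5
    run_T <- function(T, alpha) vapply(seeds, function(s)
      run_recurrent_agent(cfg, "lstm", "tbptt", n_hidden = 16, tbptt_T = T,
                          hyper = td_hyper(alpha = alpha, lambda = 0),
                          n_steps = 150000, seed = s)$msre, numeric(1))
    tbptt <- list()
    for (T in c(1, 5, 10, 20)) {
      per_alpha <- lapply(2^c(-11, -12), function(a) run_T(T, a))
      best <- per_alpha[[which.min(vapply(per_alpha, mean, numeric(1)))]]
      tbptt[[as.character(T)]] <- best
    }
    rtrl <- vapply(seeds, function(s)
      run_recurrent_agent(cfg, "lstm", "rtrl", n_hidden = 16,
                          hyper = td_hyper(alpha = 2^-9, lambda = 0),
                          n_steps = 150000, seed = s)$msre, numeric(1))
    aug1 <- vapply(seeds, function(s)
      run_recurrent_agent(cfg, "lstm", "tbptt", n_hidden = 16, tbptt_T = 1,
                          hyper = td_hyper(alpha = 2^-9, lambda = 0),
                          augment = TRUE, n_steps = 150000, seed = s)$msre,
      numeric(1))
    list(tbptt = tbptt, rtrl = rtrl, aug1 = aug1)
  })
}

stderr_of <- function(x) stats::sd(x) / sqrt(length(x))
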