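# Shared oracles and fixtures, all built in code.

# 5-state Markov reward chain with i.i.d. increments (advance 1 step with
# probability 0.7, skip 2 with probability 0.3 around a 5-cycle); cumulant
# is arrival in state 5. The analytic value function v = (I - gamma P)^-1 P c
# is the oracle for TD convergence.
chain_P <- local({
  P <- matrix(0, 5, 5)
  for (s in 1:5) {
    P[s, s %% 5 + 1] <- 0.7
    P[s, (s + 1) %% 5 + 1] <- 0.3
  }
  P
})
chain_cumulant <- c(0, 0, 0, 0, 1)
chain_gamma <- 0.9

chain_value_oracle <- function() {
  solve(diag(5) - chain_gamma * chain_P,
        as.numeric(chain_P %*% chain_cumulant))
}

simulate_chain <- function(n, seed) {
  set.seed(seed)
  inc <- 1L + stats::rbinom(n, 1L, 0.3)
  ((1L + cumsum(c(0L, inc[-n]))) - 1L) %% 5L + 1L
}

# Central finite differences of the fixed-target window loss; equals the
# semi-gradient because the bootstrap is stop-gradient.
fd_window_grad <- function(params, obs, us, v_boot, gamma, h0, c0,
                           eps = 1e-5) {
  targets <- window_targets(params, obs, us, v_boot, gamma, h0, c0)
  th <- condbench:::flatten_params(params)
  vapply(seq_along(th), function(i) {
    tp <- th; tp[i] <- tp[i] + eps
    tm <- th; tm[i] <- tm[i] - eps
    (window_fixed_target_loss(condbench:::unflatten_params(tp, params),
                              obs, targets, h0, c0) -
       window_fixed_target_loss(condbench:::unflatten_params(tm, params),
                                obs, targets, h0, c0)) / (2 * eps)
  }, numeric(1))
}

rel_err <- function(a, b) max(abs(a - b)) / max(1e-12, max(abs(b)))

random_cell <- function(arch, d, n, seed) {
  set.seed(seed)
  params <- cell_init(arch, d, n)
  params$wv <- stats::runif(n, -0.5, 0.5)
  params$bv <- stats::runif(1, -0.2, 0.2)
  params
}
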