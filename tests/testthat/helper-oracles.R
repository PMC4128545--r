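# Independent oracles, implemented from the model definitions without
# reusing the package's computation paths.

# Likelihood of pooled-assay data computed reaction by reaction from the
# three class probabilities, with no aggregation or log-space tricks.
oracle_likelihood <- function(T, data) {
  out <- rep(1, length(T))
  for (i in seq_len(nrow(data))) {
    n <- data$n_plaques[i]
    p <- switch(data$outcome[i],
                ALL_NEG = (1 - T)^n,
                ALL_POS = T^n,
                MIXED   = 1 - (1 - T)^n - T^n)
    out <- out * p
  }
  out
}

# Brute-force MLE: argmax of the oracle likelihood on a dense grid.
oracle_mle <- function(data, grid_points = 1e5 + 1) {
  grid <- seq(0, 1, length.out = grid_points)
  grid[which.max(oracle_likelihood(grid, data))]
}

# Exact credible-interval coverage for a common-pool design: enumerate all
# outcome triples (X, Y, Z) with X + Y + Z = R and weight each interval by
# its multinomial probability.
oracle_exact_coverage <- function(T_true, n, R, level = 0.95) {
  pr <- reaction_class_probs(T_true, n)
  cov <- 0
  for (X in 0:R) for (Y in 0:(R - X)) {
    Z <- R - X - Y
    pxyz <- stats::dmultinom(c(X, Y, Z), prob = pr)
    if (pxyz < 1e-12) next
    ci <- credible_interval(assay_counts(n, X = X, Y = Y, Z = Z),
                            level = level)
    if (ci[1] <= T_true && T_true <= ci[2]) cov <- cov + pxyz
  }
  cov
}

# append one reaction with pool size n to an assay
rbind_assay <- function(data, outcome, n = 10) {
  pooled_assay(c(data$n_plaques, n), c(data$outcome, outcome))
}

default_two_phage_state <- function(phage = 1e4)
  state_vector(B = 2.5e8, R = 2.5e8, P_G = phage, P_W = phage)
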