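test_that("reaction class probabilities match closed forms and sum to one", {
  expect_equal(reaction_class_probs(0, 5), c(A = 1, B = 0, C = 0))
  expect_equal(reaction_class_probs(0.5, 1), c(A = 0.5, B = 0.5, C = 0))
  expect_equal(reaction_class_probs(0.5, 10),
               c(A = 2^-10, B = 2^-10, C = 1 - 2^-9))
  for (T in c(0.01, 0.26, 0.77)) for (n in c(1, 3, 10)) {
    pr <- reaction_class_probs(T, n)
    expect_equal(sum(pr), 1, tolerance = 1e-12)  # C is the complement
    expect_true(all(pr >= 0 & pr <= 1))
  }
  expect_error(reaction_class_probs(1.2, 10), "\\[0, 1\\]")
})

test_that("assay containers validate reactions and aggregate correctly", {
  expect_error(pooled_assay(1, "MIXED"), "impossible")
  expect_error(pooled_assay(0, "ALL_NEG"), ">= 1")
  expect_error(pooled_assay(10, "maybe"), "outcomes")
  d <- pooled_assay(c(10, 10, 1), c("ALL_NEG", "MIXED", "ALL_POS"))
  agg <- assay_summary(d)
  expect_equal(agg$R, agg$X + agg$Y + agg$Z)
  expect_equal(agg$X[agg$n == 10], 1)
  expect_equal(agg$Y[agg$n == 1], 1)
  expect_equal(sum(agg$R), nrow(d))
})

test_that("log-likelihood is additive over reactions with known values", {
  empty <- pooled_assay(integer(), character())
  expect_identical(assay_log_likelihood(c(0, 0.3, 1), empty), c(0, 0, 0))
  one_neg <- assay_counts(10, X = 1)
  expect_equal(assay_log_likelihood(0.1, one_neg), 10 * log(0.9))
  hetero <- pooled_assay(c(10, 1), c("ALL_NEG", "ALL_POS"))
  expect_equal(assay_log_likelihood(0.3, hetero),
               10 * log(0.7) + log(0.3))
  # impossible outcomes give -Inf exactly at the boundary
  expect_identical(assay_log_likelihood(0, assay_counts(5, Y = 1)), -Inf)
  expect_identical(assay_log_likelihood(1, one_neg), -Inf)
})

test_that("MLE handles boundaries, symmetry, and the mixed-pool form", {
  expect_identical(mle_frequency(assay_counts(10, X = 6)), 0)
  expect_identical(mle_frequency(assay_counts(10, Y = 6)), 1)
  expect_equal(mle_frequency(assay_counts(1, X = 5, Y = 5)), 0.5,
               tolerance = 1e-9)
  # X = 1, Z = 5 at n = 10: approximately 1 - (X/(X+Z))^(1/n)
  that <- mle_frequency(assay_counts(10, X = 1, Z = 5))
  expect_equal(that, 1 - (1 / 6)^(1 / 10), tolerance = 1e-4)
  expect_error(mle_frequency(pooled_assay(integer(), character())), "empty")
})

test_that("MLE agrees with the brute-force grid oracle on random datasets", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(1:10, 1)
    R <- sample(1:10, 1)
    outc <- sample(c("ALL_NEG", "ALL_POS", if (n > 1) "MIXED"), R,
                   replace = TRUE)
    d <- pooled_assay(n, outc)
    expect_equal(mle_frequency(d), oracle_mle(d), tolerance = 1e-4)
  }
})

test_that("adding unanimous reactions moves the MLE the right way", {
  set.seed(32)
  for (i in 1:15) {
    d <- pooled_assay(10, sample(c("ALL_NEG", "ALL_POS", "MIXED"),
                                 sample(1:6, 1), replace = TRUE))
    that <- mle_frequency(d)
    up <- mle_frequency(rbind_assay(d, "ALL_POS"))
    down <- mle_frequency(rbind_assay(d, "ALL_NEG"))
    expect_gte(up, that - 1e-9)
    expect_lte(down, that + 1e-9)
  }
})

test_that("posterior density integrates to one and brackets a maximizer", {
  for (d in list(assay_counts(10, X = 6), assay_counts(10, X = 1, Z = 5),
                 assay_counts(1, X = 12, Y = 7),
                 pooled_assay(c(10, 10, 1), c("ALL_NEG", "MIXED",
                                              "ALL_POS")))) {
    est <- estimate_frequency(d)
    h <- est$grid[2] - est$grid[1]
    area <- sum((est$density[-1] + est$density[-length(est$density)]) / 2) * h
    expect_equal(area, 1, tolerance = 1e-6)
    # equal-tail construction: the interval carries `level` posterior mass
    inside <- est$grid >= est$lower & est$grid <= est$upper
    dens_in <- est$density[inside]
    mass <- sum((dens_in[-1] + dens_in[-length(dens_in)]) / 2) * h
    expect_equal(mass, est$level, tolerance = 1e-3)
    expect_lte(est$lower, est$upper)
  }
})

test_that("quadrature intervals match conjugate Beta closed forms", {
  # single-plaque reactions: posterior is Beta(Y + 1, X + 1)
  set.seed(33)
  for (i in 1:10) {
    X <- sample(0:20, 1)
    Y <- sample(0:20, 1)
    if (X + Y == 0) X <- 1
    ci <- credible_interval(assay_counts(1, X = X, Y = Y))
    expect_equal(unname(ci), qbeta(c(0.025, 0.975), Y + 1, X + 1),
                 tolerance = 1e-4)
  }
  # unanimous pooled data: Beta(1, N+1) / Beta(N+1, 1)
  ci_neg <- credible_interval(assay_counts(10, X = 6))
  expect_equal(ci_neg[["upper"]], unanimous_bound(60, 0.95, "all_negative"),
               tolerance = 1e-4)
  ci_pos <- credible_interval(assay_counts(10, Y = 6))
  expect_equal(ci_pos[["lower"]], unanimous_bound(60, 0.95, "all_positive"),
               tolerance = 1e-4)
})

test_that("interval width shrinks as reactions accumulate", {
  widths <- sapply(c(1, 4, 16), function(m) {
    ci <- credible_interval(assay_counts(10, X = 2 * m, Z = 4 * m))
    ci[["upper"]] - ci[["lower"]]
  })
  expect_true(all(diff(widths) < 0))
})

test_that("unanimous bounds follow the stated closed form", {
  expect_equal(unanimous_bound(60, 0.95, "all_negative"), 1 - 0.025^(1 / 61))
  expect_equal(unanimous_bound(60, 0.95, "all_positive"), 0.025^(1 / 61))
  expect_equal(unanimous_bound(1, 0.95, "all_negative"), 1 - 0.025^(1 / 2))
  expect_equal(unanimous_bound(1, 0.95, "all_negative"), 0.8419,
               tolerance = 1e-4)
})

test_that("chi-square frequency test matches hand arithmetic and scales", {
  exact <- chi_square_frequency_test(26, 100, 0.26)
  expect_equal(unname(exact$statistic), 0)
  expect_identical(exact$p.value, 1)
  t36 <- chi_square_frequency_test(36, 60, 0.26)
  hand <- (36 - 15.6)^2 / 15.6 + (24 - 44.4)^2 / 44.4
  expect_equal(unname(t36$statistic), hand)
  expect_equal(unname(t36$statistic), 36.05, tolerance = 1e-3)
  expect_lt(t36$p.value, 1e-4)
  t72 <- chi_square_frequency_test(72, 120, 0.26)
  expect_equal(unname(t72$statistic), 2 * unname(t36$statistic))
  # agrees with the standard Pearson goodness-of-fit implementation
  ref <- suppressWarnings(chisq.test(c(36, 24), p = c(0.26, 0.74)))
  expect_equal(unname(t36$statistic), unname(ref$statistic))
  expect_equal(t36$p.value, ref$p.value)
  # continuity correction can only reduce the statistic
  tc <- chi_square_frequency_test(36, 60, 0.26, correct = TRUE)
  expect_lt(unname(tc$statistic), unname(t36$statistic))
  expect_error(chi_square_frequency_test(10, 60, 0), "strictly between")
})
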