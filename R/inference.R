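.outcomes <- c("ALL_NEG", "ALL_POS", "MIXED")

#' Pooled plaque-assay records
#'
#' A pooled (group-tested) PCR design combines `n` plaque isolates into a
#' single reaction whose product classifies the pool as `ALL_NEG` (no
#' isolate carries the transgene), `ALL_POS` (every isolate carries it),
#' or `MIXED` (both types present). At population transgene frequency `T`
#' (with `U = 1 - T`) these outcomes occur with probabilities `U^n`,
#' `T^n`, and `1 - U^n - T^n`.
#'
#' @param n_plaques Integer pool size(s), one per reaction (recycled);
#'   every pool must have at least one plaque.
#' @param outcome Character vector of outcomes, one per reaction, each one
#'   of `"ALL_NEG"`, `"ALL_POS"`, `"MIXED"`. A `MIXED` outcome is
#'   impossible for a single-plaque reaction and is rejected.
#' @return A data frame of class `pooled_assay` with columns `n_plaques`
#'   and `outcome`.
#' @seealso [assay_counts()] for the aggregate-count constructor,
#'   [estimate_frequency()] for inference.
#' @examples
#' pooled_assay(10, c("ALL_NEG", "MIXED", "ALL_NEG"))
#' @export
pooled_assay <- function(n_plaques, outcome) {
  outcome <- as.character(outcome)
  if (!length(outcome))
    return(structure(data.frame(n_plaques = integer(), outcome = character(),
                                stringsAsFactors = FALSE),
                     class = c("pooled_assay", "data.frame")))
  if (!all(outcome %in% .outcomes))
    stop("outcomes must be one of ", paste(.outcomes, collapse = ", "))
  n_plaques <- rep_len(as.numeric(n_plaques), length(outcome))
  if (any(!is.finite(n_plaques)) || any(n_plaques < 1) ||
      any(n_plaques != round(n_plaques)))
    stop("'n_plaques' must be integers >= 1")
  if (any(n_plaques == 1 & outcome == "MIXED"))
    stop("a MIXED outcome is impossible for a single-plaque reaction")
  structure(data.frame(n_plaques = as.integer(n_plaques), outcome = outcome,
                       stringsAsFactors = FALSE),
            class = c("pooled_assay", "data.frame"))
}

#' Build a pooled assay from aggregate outcome counts
#'
#' Convenience constructor for the common design where every reaction
#' pools the same number of plaques: `X` reactions all-negative, `Y`
#' all-positive, `Z` mixed.
#'
#' @param n Common pool size (plaques per reaction).
#' @param X,Y,Z Counts of `ALL_NEG`, `ALL_POS`, and `MIXED` reactions.
#' @return A [pooled_assay()] with `X + Y + Z` reactions.
#' @examples
#' assay_counts(10, X = 6)          # 6 unanimous-negative pools of 10
#' @export
assay_counts <- function(n, X = 0, Y = 0, Z = 0) {
  stopifnot(X >= 0, Y >= 0, Z >= 0, X + Y + Z >= 1)
  pooled_assay(n, rep(.outcomes, times = c(X, Y, Z)))
}

#' Aggregate a pooled assay by pool size
#'
#' @param data A [pooled_assay()].
#' @return Data frame with one row per distinct pool size and columns
#'   `n`, `X`, `Y`, `Z` (outcome counts) and `R` (reactions).
#' @export
assay_summary <- function(data) {
  stopifnot(inherits(data, "pooled_assay"))
  if (!nrow(data))
    return(data.frame(n = integer(), X = integer(), Y = integer(),
                      Z = integer(), R = integer()))
  out <- lapply(split(data$outcome, data$n_plaques), function(o)
    c(X = sum(o == "ALL_NEG"), Y = sum(o == "ALL_POS"),
      Z = sum(o == "MIXED")))
  n <- as.integer(names(out))
  cnt <- do.call(rbind, out)
  data.frame(n = n, X = cnt[, "X"], Y = cnt[, "Y"], Z = cnt[, "Z"],
             R = rowSums(cnt), row.names = NULL)
}

#' Outcome-class probabilities of one pooled reaction
#'
#' At transgene frequency `T` a pool of `n` plaques is all-negative with
#' probability `A = (1-T)^n`, all-positive with `B = T^n`, and mixed with
#' `C = 1 - A - B` (computed exactly as the complement, so the three
#' probabilities sum to 1).
#'
#' @param T Transgene frequency in \[0, 1\] (scalar).
#' @param n Pool size, integer >= 1.
#' @return Named numeric vector `c(A, B, C)`.
#' @examples
#' reaction_class_probs(0.5, 10)
#' @export
reaction_class_probs <- function(T, n) {
  if (!is.numeric(T) || length(T) != 1L || is.na(T) || T < 0 || T > 1)
    stop("'T' must be a single frequency in [0, 1]")
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("'n' must be a single integer >= 1")
  A <- (1 - T)^n
  B <- T^n
  c(A = A, B = B, C = 1 - A - B)
}

#' Unnormalized log-likelihood of pooled-assay data
#'
#' The likelihood of the reaction outcomes is the multinomial kernel
#' \eqn{M \propto A^X B^Y C^Z} per pool size (the combinatorial constant
#' is omitted), i.e. the sum over reactions of the log probability of the
#' observed class. Heterogeneous pool sizes add their terms. The value is
#' `-Inf` exactly when an observed class has probability zero (e.g. an
#' `ALL_POS` reaction at `T = 0`).
#'
#' @param T Vector of frequencies in \[0, 1\].
#' @param data A [pooled_assay()].
#' @return Numeric vector of log-likelihood values, one per element of `T`.
#' @export
assay_log_likelihood <- function(T, data) {
  stopifnot(inherits(data, "pooled_assay"))
  if (!is.numeric(T) || any(is.na(T)) || any(T < 0) || any(T > 1))
    stop("'T' must be frequencies in [0, 1]")
  agg <- assay_summary(data)
  ll <- numeric(length(T))
  for (i in seq_len(nrow(agg))) {
    n <- agg$n[i]
    if (agg$X[i] > 0) ll <- ll + agg$X[i] * n * log1p(-T)
    if (agg$Y[i] > 0) ll <- ll + agg$Y[i] * n * log(T)
    if (agg$Z[i] > 0) {
      # mixed-class probability 1 - (1-T)^n - T^n, kept accurate near 0/1
      Cn <- -expm1(n * log1p(-T)) - T^n
      Cn[Cn < 0] <- 0
      ll <- ll + agg$Z[i] * log(Cn)
    }
  }
  ll
}

#' Maximum-likelihood transgene frequency
#'
#' Global maximizer of [assay_log_likelihood()] over \[0, 1\], located on
#' a dense uniform grid and refined by golden-section search in the
#' bracketing interval. Unanimous data sit at the boundary (all `ALL_NEG`
#' gives 0, all `ALL_POS` gives 1); exact ties resolve to the smaller
#' frequency.
#'
#' @param data A [pooled_assay()] with at least one reaction.
#' @param grid_points Number of grid points (default 10001).
#' @return The MLE, a frequency in \[0, 1\].
#' @examples
#' mle_frequency(assay_counts(1, X = 5, Y = 5))   # 0.5
#' @export
mle_frequency <- function(data, grid_points = 10001L) {
  stopifnot(inherits(data, "pooled_assay"), grid_points >= 101)
  if (!nrow(data)) stop("cannot estimate a frequency from empty assay data")
  grid <- seq(0, 1, length.out = grid_points)
  ll <- assay_log_likelihood(grid, data)
  i <- which.max(ll)               # first max: ties break toward smaller T
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, grid_points)]
  opt <- optimize(function(t) assay_log_likelihood(t, data),
                  lower = lo, upper = hi, maximum = TRUE, tol = 1e-10)
  if (is.finite(opt$objective) && opt$objective > ll[i]) opt$maximum
  else grid[i]
}

#' Posterior estimate of transgene frequency with credible interval
#'
#' Treats the normalized multinomial likelihood as a posterior density of
#' `T` on \[0, 1\] (flat prior) and returns the maximum-likelihood point
#' estimate together with the equal-tail credible interval: the lower and
#' upper `(1 - level)/2` quantiles of the posterior. The density is
#' normalized by trapezoidal quadrature on a uniform grid and the CDF
#' inverted by monotone interpolation.
#'
#' @param data A [pooled_assay()].
#' @param level Credibility level in (0, 1); default 0.95.
#' @param grid_points Posterior grid size; default `1e5`, at which the
#'   quadrature matches conjugate Beta closed forms to better than 1e-4.
#' @return An object of class `frequency_estimate`: list with `T_hat`,
#'   `lower`, `upper`, `level`, `n_reactions`, `n_plaques`, and the
#'   posterior `grid` and normalized `density` (trapezoidal integral 1).
#' @examples
#' est <- estimate_frequency(assay_counts(10, X = 6))
#' round(est$upper, 2)    # 0.06: upper bound after 60 negative plaques
#' @export
estimate_frequency <- function(data, level = 0.95, grid_points = 1e5) {
  stopifnot(inherits(data, "pooled_assay"))
  if (!nrow(data)) stop("cannot estimate a frequency from empty assay data")
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("'level' must lie strictly between 0 and 1")
  grid_points <- as.integer(grid_points)
  stopifnot(grid_points >= 1001L)
  grid <- seq(0, 1, length.out = grid_points)
  h <- grid[2L] - grid[1L]
  ll <- assay_log_likelihood(grid, data)
  finite <- is.finite(ll)
  if (!any(finite))
    stop("likelihood is zero everywhere: the data are inconsistent")
  dens <- numeric(grid_points)
  dens[finite] <- exp(ll[finite] - max(ll[finite]))
  total <- sum((dens[-1L] + dens[-grid_points]) / 2) * h
  if (total <= 0) stop("posterior mass is zero")
  dens <- dens / total
  cdf <- c(0, cumsum((dens[-1L] + dens[-grid_points]) / 2) * h)
  cdf <- cdf / cdf[grid_points]
  keep <- c(TRUE, diff(cdf) > 0)
  alpha <- (1 - level) / 2
  q <- approx(cdf[keep], grid[keep], xout = c(alpha, 1 - alpha),
              rule = 2, ties = "ordered")$y
  structure(list(T_hat = mle_frequency(data),
                 lower = q[1L], upper = q[2L], level = level,
                 n_reactions = nrow(data),
                 n_plaques = sum(data$n_plaques),
                 grid = grid, density = dens),
            class = "frequency_estimate")
}

#' @export
print.frequency_estimate <- function(x, ...) {
  cat(sprintf(
    "Transgene frequency estimate from %d pooled reactions (%d plaques)\n",
    x$n_reactions, x$n_plaques))
  cat(sprintf("  T_hat = %.4g, %g%% credible interval (%.2f, %.2f)\n",
              x$T_hat, 100 * x$level, x$lower, x$upper))
  invisible(x)
}

#' Equal-tail credible interval for the transgene frequency
#'
#' @param data A [pooled_assay()].
#' @param level Credibility level; default 0.95.
#' @param grid_points Posterior grid size (see [estimate_frequency()]).
#' @return Numeric vector `c(lower, upper)`.
#' @export
credible_interval <- function(data, level = 0.95, grid_points = 1e5) {
  est <- estimate_frequency(data, level = level, grid_points = grid_points)
  c(lower = est$lower, upper = est$upper)
}

#' Closed-form credible bound for unanimous assay outcomes
#'
#' When all `N` screened plaques give the same result the posterior is
#' `(1-T)^N` (all negative) or `T^N` (all positive), i.e. Beta(1, N+1) or
#' Beta(N+1, 1), and the informative equal-tail bound has the closed form
#' `1 - ((1-level)/2)^(1/(N+1))` (upper bound, all-negative) or its mirror
#' `((1-level)/2)^(1/(N+1))` (lower bound, all-positive). Used as an
#' independent check on the quadrature interval.
#'
#' @param total_plaques Total number of screened plaques `N` (>= 1).
#' @param level Credibility level; default 0.95.
#' @param direction `"all_negative"` (returns the upper bound) or
#'   `"all_positive"` (returns the lower bound).
#' @return The bound, a frequency in (0, 1).
#' @examples
#' unanimous_bound(60, 0.95, "all_negative")   # ~0.0587, prints as 0.06
#' @export
unanimous_bound <- function(total_plaques, level = 0.95,
                            direction = c("all_negative", "all_positive")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(total_plaques), length(total_plaques) == 1L,
            total_plaques >= 1, total_plaques == round(total_plaques),
            level > 0, level < 1)
  alpha <- (1 - level) / 2
  a <- alpha^(1 / (total_plaques + 1))
  if (direction == "all_negative") 1 - a else a
}

#' Chi-square test of transgene frequency change
#'
#' Pearson one-degree-of-freedom goodness-of-fit test of an observed
#' count of transgene-positive plaques against an expected frequency:
#' the 2-cell table (positives, negatives) is compared with expected
#' counts `(expected_T * total, (1 - expected_T) * total)`. The Yates
#' continuity correction is off by default.
#'
#' @param positives Observed transgene-positive plaques.
#' @param total Total plaques screened.
#' @param expected_T Expected transgene frequency, strictly inside (0, 1).
#' @param correct Apply the continuity correction? Default `FALSE`.
#' @return An object of class `htest` with the statistic, df = 1, and
#'   p-value.
#' @examples
#' chi_square_frequency_test(36, 60, expected_T = 0.26)
#' @export
chi_square_frequency_test <- function(positives, total, expected_T,
                                      correct = FALSE) {
  stopifnot(length(positives) == 1L, length(total) == 1L,
            positives >= 0, total >= 1, positives <= total,
            positives == round(positives), total == round(total))
  if (!is.numeric(expected_T) || length(expected_T) != 1L ||
      expected_T <= 0 || expected_T >= 1)
    stop("'expected_T' must lie strictly between 0 and 1")
  obs <- c(positives, total - positives)
  expct <- c(expected_T, 1 - expected_T) * total
  dev <- abs(obs - expct)
  if (correct) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / expct)
  structure(list(
    statistic = c("X-squared" = stat),
    parameter = c(df = 1),
    p.value = pchisq(stat, df = 1, lower.tail = FALSE),
    method = paste0("Chi-square goodness-of-fit test of transgene ",
                    "frequency", if (correct) " (continuity-corrected)"),
    data.name = sprintf("%d positives of %d plaques vs expected %g",
                        as.integer(positives), as.integer(total),
                        expected_T),
    observed = obs, expected = expct
  ), class = "htest")
}
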