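# run code under a fixed seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("a single numeric 'seed' is required (no implicit entropy)")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# deterministic sub-seed stream: keeps every derived seed inside 32-bit range
derive_seed <- function(seed, counter) {
  (as.numeric(seed) * 48271 + 10007 * as.numeric(counter)) %% 2147483647
}

#' Design of a synthetic pooled-assay experiment
#'
#' @param T_true True transgene frequency in \[0, 1\].
#' @param n Pool size (plaques per reaction); default 10.
#' @param R Number of reactions; default 6. The `n = 10`, `R = 6` defaults
#'   mirror a typical screen of 60 plaques in six pooled PCRs.
#' @param seed Mandatory RNG seed; all randomness flows from it.
#' @return An `assay_design` object.
#' @export
assay_design <- function(T_true, n = 10, R = 6, seed) {
  if (missing(seed)) stop("'seed' is required")
  stopifnot(is.numeric(T_true), length(T_true) == 1L,
            T_true >= 0, T_true <= 1,
            n >= 1, n == round(n), R >= 1, R == round(R))
  structure(list(T_true = T_true, n = as.integer(n), R = as.integer(R),
                 seed = seed),
            class = "assay_design")
}

#' Sample a pooled assay at known truth
#'
#' Draws `R` independent pooled reactions whose three outcome classes
#' occur with probabilities `(1-T)^n`, `T^n`, `1 - (1-T)^n - T^n` — the
#' sampling model the inference assumes. Reproducible given the design's
#' seed.
#'
#' @param design An [assay_design()], or a true frequency (with `n`, `R`,
#'   `seed` supplied as further arguments).
#' @param ... Passed to [assay_design()] when `design` is a frequency.
#' @return A [pooled_assay()] with attribute `T_true`.
#' @examples
#' sample_pooled_assay(assay_design(0.26, n = 10, R = 6, seed = 1))
#' @export
sample_pooled_assay <- function(design, ...) {
  if (!inherits(design, "assay_design")) design <- assay_design(design, ...)
  pr <- reaction_class_probs(design$T_true, design$n)
  outc <- with_seed(design$seed,
                    sample(.outcomes, design$R, replace = TRUE, prob = pr))
  out <- pooled_assay(design$n, outc)
  attr(out, "T_true") <- design$T_true
  out
}

#' Sample individually screened plaques
#'
#' Binomial draw of transgene-positive plaques among `n_plaques` isolates
#' screened one by one at population frequency `freq`.
#'
#' @param freq True transgene frequency in \[0, 1\].
#' @param n_plaques Number of plaques screened.
#' @param seed Mandatory RNG seed.
#' @return Named integer vector `c(positives, negatives)`.
#' @export
sample_plaque_counts <- function(freq, n_plaques, seed) {
  if (missing(seed)) stop("'seed' is required")
  stopifnot(is.numeric(freq), length(freq) == 1L, freq >= 0, freq <= 1,
            n_plaques >= 1, n_plaques == round(n_plaques))
  pos <- with_seed(seed, rbinom(1L, as.integer(n_plaques), freq))
  c(positives = pos, negatives = as.integer(n_plaques) - pos)
}

#' Sample pooled assays from a simulated competition
#'
#' Emulates plaque-sampling an evolving two-phage population: at each
#' requested time the trajectory's GM frequency becomes the true
#' frequency of a synthetic pooled assay. Requested times snap to the
#' nearest stored output time.
#'
#' @param traj A two-phage `phage_trajectory`.
#' @param times Sampling times (minutes), within the trajectory's span.
#' @param n,R Pooled-assay design per time point.
#' @param seed Mandatory RNG seed; each time point uses a sub-seed derived
#'   from it.
#' @return List of [pooled_assay()] objects with attributes `time` and
#'   `T_true`.
#' @export
assay_from_trajectory <- function(traj, times, n = 10, R = 6, seed) {
  if (missing(seed)) stop("'seed' is required")
  stopifnot(inherits(traj, "phage_trajectory"), is.numeric(times),
            length(times) >= 1L)
  if (!is_two_phage(traj))
    stop("trajectory contains a single phage type; sampling a transgene ",
         "frequency requires both phages")
  if (any(times < min(traj$time)) || any(times > max(traj$time)))
    stop("requested times fall outside the trajectory's span")
  lapply(seq_along(times), function(i) {
    idx <- which.min(abs(traj$time - times[i]))
    f <- traj$gm_frequency[idx]
    if (is.na(f))
      stop("GM frequency is undefined (no phage) at t = ", traj$time[idx])
    a <- sample_pooled_assay(assay_design(f, n = n, R = R,
                                          seed = derive_seed(seed, i)))
    attr(a, "time") <- traj$time[idx]
    a
  })
}

#' Parameter-recovery experiment for the pooled-assay estimator
#'
#' For each true frequency in `T_grid`, repeatedly simulates a pooled
#' assay (`R` reactions of `n` plaques), estimates the frequency, and
#' summarizes estimator quality: bias of the MLE, its root-mean-square
#' error, and the fraction of equal-tail credible intervals (inclusive at
#' the endpoints) that contain the truth. Deterministic given `seed`.
#'
#' Because the data reduce to the outcome-count triple (X, Y, Z), the
#' estimator is evaluated once per distinct triple and weighted by its
#' multiplicity, so large `reps` are cheap. At least 100 replicates are
#' recommended for stable coverage estimates.
#'
#' @param T_grid True frequencies, each strictly inside (0, 1).
#' @param n Pool size; default 10.
#' @param R Reactions per dataset; default 6.
#' @param reps Simulated datasets per frequency.
#' @param seed Mandatory RNG seed.
#' @param level Credibility level; default 0.95.
#' @param grid_points Posterior grid size (see [estimate_frequency()]).
#' @return Data frame with one row per frequency: `T_true`, `n`, `R`,
#'   `reps`, `bias`, `rmse`, `coverage`.
#' @examples
#' recovery_experiment(0.26, n = 10, R = 6, reps = 200, seed = 1)
#' @export
recovery_experiment <- function(T_grid, n = 10, R = 6, reps = 1000, seed,
                                level = 0.95, grid_points = 1e5) {
  if (missing(seed)) stop("'seed' is required")
  stopifnot(is.numeric(T_grid), length(T_grid) >= 1L,
            all(T_grid > 0), all(T_grid < 1),
            n >= 1, n == round(n), R >= 1, R == round(R))
  if (!is.numeric(reps) || length(reps) != 1L || reps < 1 ||
      reps != round(reps))
    stop("'reps' must be a positive integer")
  rows <- lapply(seq_along(T_grid), function(ti) {
    Tt <- T_grid[ti]
    pr <- reaction_class_probs(Tt, n)
    counts <- with_seed(derive_seed(seed, ti),
                        rmultinom(reps, size = R, prob = pr))
    key <- paste(counts[1L, ], counts[2L, ], counts[3L, ])
    tab <- table(key)
    uniq <- do.call(rbind, lapply(strsplit(names(tab), " "), as.integer))
    wt <- as.numeric(tab)
    est <- apply(uniq, 1L, function(xyz) {
      d <- assay_counts(n, X = xyz[1L], Y = xyz[2L], Z = xyz[3L])
      e <- estimate_frequency(d, level = level, grid_points = grid_points)
      c(e$T_hat, e$lower, e$upper)
    })
    that <- est[1L, ]
    covered <- est[2L, ] <= Tt & Tt <= est[3L, ]
    data.frame(T_true = Tt, n = n, R = R, reps = reps,
               bias = sum(wt * (that - Tt)) / reps,
               rmse = sqrt(sum(wt * (that - Tt)^2) / reps),
               coverage = sum(wt * covered) / reps)
  })
  do.call(rbind, rows)
}
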