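#' Random 2x2 tables with positive margins
#'
#' Draws cell probabilities from a symmetric Dirichlet(1,1,1,1), totals
#' uniformly on [20, max_total], cells multinomially, and rejects tables
#' with a zero marginal sum.  A broad prior intended for property tests:
#' every output passes \code{\link{count_table}} validation and supports
#' all factorizations.
#'
#' @param n Number of tables.
#' @param max_total Maximum table total (default 200).
#' @param seed Seed (generators are pure functions of seed and spec).
#' @return A data frame with columns \code{a}, \code{b}, \code{c},
#'   \code{d}.
#' @export
random_tables <- function(n, max_total = 200, seed = 1) {
  if (n < 1) stop_domain("n must be at least 1")
  if (max_total < 4) stop_domain("max_total must be at least 4")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 0))
  out <- matrix(NA_real_, nrow = n, ncol = 4)
  filled <- 0L
  while (filled < n) {
    todo <- n - filled
    g <- matrix(stats::rexp(4 * todo), ncol = 4)  # Dirichlet(1,1,1,1)
    p <- g / rowSums(g)
    tot <- sample(20:max_total, todo, replace = TRUE)
    cells <- t(vapply(seq_len(todo),
                      function(i) stats::rmultinom(1, tot[i], p[i, ])[, 1],
                      numeric(4)))
    ok <- (cells[, 1] + cells[, 3] > 0) & (cells[, 2] + cells[, 4] > 0) &
      (cells[, 1] + cells[, 2] > 0) & (cells[, 3] + cells[, 4] > 0)
    keep <- which(ok)
    if (length(keep) > 0) {
      take <- keep[seq_len(min(length(keep), todo))]
      out[(filled + 1):(filled + length(take)), ] <- cells[take, ]
      filled <- filled + length(take)
    }
  }
  stats::setNames(as.data.frame(out), c("a", "b", "c", "d"))
}

#' Two-class Gaussian covariate data with known density crossings
#'
#' Emulates the structure of real screening data: two broad, largely
#' overlapping class-conditional distributions with unequal class sizes.
#' Draws \code{n_neg} class-0 and \code{n_pos} class-1 Gaussian samples
#' and records the analytic crossing points of the (sample-size-weighted
#' or unweighted) class densities, which are the targets a
#' composition-based split criterion should recover.
#'
#' @param n_neg,n_pos Class sample sizes.
#' @param mean_neg,mean_pos Class means.
#' @param sd_neg,sd_pos Class standard deviations (default 5, 5).
#' @param seed Seed.
#' @return A data frame with columns \code{x}, \code{y} (0/1) and
#'   attributes \code{crossings} (unweighted equal-density points; for
#'   equal sds the midpoint of the means, for unequal sds the roots of
#'   the quadratic; NULL with a flag when the densities never cross) and
#'   \code{crossings_defined}.
#' @export
two_class_dataset <- function(n_neg, n_pos, mean_neg, mean_pos,
                              sd_neg = 5, sd_pos = 5, seed = 1) {
  if (n_neg < 1 || n_pos < 1) stop_domain("class sizes must be >= 1")
  if (sd_neg <= 0 || sd_pos <= 0) stop_domain("sds must be positive")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 1))
  x <- c(stats::rnorm(n_neg, mean_neg, sd_neg),
         stats::rnorm(n_pos, mean_pos, sd_pos))
  y <- c(rep(0L, n_neg), rep(1L, n_pos))
  out <- data.frame(x = x, y = y)
  if (sd_neg == sd_pos) {
    if (mean_neg == mean_pos) {
      attr(out, "crossings") <- NULL
      attr(out, "crossings_defined") <- FALSE
    } else {
      attr(out, "crossings") <- (mean_neg + mean_pos) / 2
      attr(out, "crossings_defined") <- TRUE
    }
  } else {
    # equate the two normal log-densities: quadratic in x
    A <- 1 / sd_pos^2 - 1 / sd_neg^2
    B <- 2 * (mean_neg / sd_neg^2 - mean_pos / sd_pos^2)
    C <- mean_pos^2 / sd_pos^2 - mean_neg^2 / sd_neg^2 +
      2 * log(sd_pos / sd_neg)
    disc <- B^2 - 4 * A * C
    if (disc < 0) {
      attr(out, "crossings") <- NULL
      attr(out, "crossings_defined") <- FALSE
    } else {
      attr(out, "crossings") <- sort((-B + c(-1, 1) * sqrt(disc)) / (2 * A))
      attr(out, "crossings_defined") <- TRUE
    }
  }
  out
}

#' Labeled samples from a class-balance aware logistic model
#'
#' Draws covariate values uniformly on \code{x_range} and labels
#' Bernoulli(1/(1 + (n_neg/n_pos) exp(-b (x - x0)))), the logistic model
#' whose adjusted parameters are exactly (b, x0) and whose value at x0 is
#' the sample-size proportion n_pos/(n_neg + n_pos).  Realized class
#' counts are recorded; fitting then adjusting recovers (b, x0) up to
#' sampling error.
#'
#' @param b Slope (nonzero).
#' @param x0 Midpoint.
#' @param n_neg_target,n_pos_target Intended class sizes (set the
#'   imbalance ratio in the model).
#' @param n Number of samples (default n_neg_target + n_pos_target).
#' @param x_range Covariate range (default x0 +/- 3 natural widths).
#' @param seed Seed.
#' @return A data frame with columns \code{x}, \code{y}; attributes
#'   \code{b}, \code{x0}, \code{a0} (the implied intercept),
#'   \code{n_neg_realized}, \code{n_pos_realized}, and
#'   \code{x0_realized}, the midpoint implied by the realized class
#'   balance -- the quantity \code{\link{adjust_for_sample_size}} can
#'   recover from the sample (it coincides with \code{x0} when the
#'   realized class ratio matches the target).
#' @export
logistic_samples <- function(b, x0, n_neg_target, n_pos_target,
                             n = n_neg_target + n_pos_target,
                             x_range = x0 + c(-3, 3) * max(1, abs(1 / b)) * 3,
                             seed = 1) {
  if (b == 0) stop_domain("b must be nonzero")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 2))
  x <- stats::runif(n, x_range[1], x_range[2])
  ratio <- n_neg_target / n_pos_target
  p <- 1 / (1 + ratio * exp(-b * (x - x0)))
  y <- stats::rbinom(n, 1, p)
  out <- data.frame(x = x, y = y)
  attr(out, "b") <- b
  attr(out, "x0") <- x0
  attr(out, "a0") <- -b * x0 - log(ratio)
  attr(out, "n_neg_realized") <- sum(y == 0)
  attr(out, "n_pos_realized") <- sum(y == 1)
  # the midpoint recoverable from the data: the adjustment divides out the
  # *realized* class balance, which matches the nominal ratio only when the
  # covariate design happens to realize it
  attr(out, "x0_realized") <-
    -(attr(out, "a0") + log(sum(y == 0) / sum(y == 1))) / b
  out
}
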