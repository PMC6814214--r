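#' Define a fixed-margin Monte Carlo sampling scheme
#'
#' A source table plus a resampling scheme describing the stochastic model
#' of the data acquisition:
#' \describe{
#'   \item{fixed_colsums}{column 1 counts ~ Binomial(a+c, a/(a+c)),
#'     column 2 ~ Binomial(b+d, b/(b+d)), independently; column sums are
#'     held at their observed values.}
#'   \item{fixed_rowsums}{the row analog.}
#'   \item{fixed_total}{(a, b, c, d) ~ Multinomial(N, (a, b, c, d)/N); only
#'     the total is held fixed, so margins scatter as well.}
#' }
#' Non-integer margins (e.g. after rescaling) are rounded with a warning,
#' since the sampling distributions are discrete.
#'
#' @param x Source \code{count_table2x2}.
#' @param kind Sampling scheme (see Details).
#' @param n_tables Tables per run (default 10000).
#' @param n_runs Number of independent runs (default 64).
#' @param seed Root seed; per-run substreams are derived from
#'   (seed, run_index), so runs are order-insensitive.
#' @return An \code{mc_scheme} object.
#' @export
mc_scheme <- function(x, kind = c("fixed_colsums", "fixed_rowsums",
                                  "fixed_total"),
                      n_tables = 10000, n_runs = 64, seed = 1) {
  stopifnot(inherits(x, "count_table2x2"))
  kind <- match.arg(kind)
  if (n_tables < 1 || n_runs < 1)
    stop_domain("n_tables and n_runs must be at least 1")
  margins <- switch(kind,
    fixed_colsums = x$col_sums,
    fixed_rowsums = x$row_sums,
    fixed_total = x$n)
  if (any(margins <= 0))
    stop_zero_margin(sprintf("scheme '%s' needs its fixed margins positive", kind))
  cells <- c(x$a, x$b, x$c, x$d)
  if (any(abs(cells - round(cells)) > 1e-9))
    warn_proptab("non-integer counts rounded for discrete sampling")
  structure(list(table = x, kind = kind,
                 n_tables = as.integer(n_tables),
                 n_runs = as.integer(n_runs), seed = seed),
            class = "mc_scheme")
}

#' Draw one run of Monte Carlo tables
#'
#' Reproducible given (scheme seed, run_index).  Cells are returned as
#' parallel vectors for speed; use \code{\link{as_count_table}} on a row
#' when a table object is needed.
#'
#' @param scheme An \code{mc_scheme}.
#' @param run_index Which substream to draw (1-based).
#' @return A data frame with columns \code{a}, \code{b}, \code{c},
#'   \code{d}, one row per sampled table.
#' @export
sample_tables <- function(scheme, run_index = 1) {
  stopifnot(inherits(scheme, "mc_scheme"))
  t <- scheme$table
  n <- scheme$n_tables
  a0 <- round(t$a); b0 <- round(t$b); c0 <- round(t$c); d0 <- round(t$d)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(scheme$seed, run_index))
  out <- switch(scheme$kind,
    fixed_colsums = {
      n1 <- a0 + c0; n2 <- b0 + d0
      a <- stats::rbinom(n, n1, a0 / n1)
      b <- stats::rbinom(n, n2, b0 / n2)
      data.frame(a = a, b = b, c = n1 - a, d = n2 - b)
    },
    fixed_rowsums = {
      n1 <- a0 + b0; n2 <- c0 + d0
      a <- stats::rbinom(n, n1, a0 / n1)
      c <- stats::rbinom(n, n2, c0 / n2)
      data.frame(a = a, b = n1 - a, c = c, d = n2 - c)
    },
    fixed_total = {
      nn <- a0 + b0 + c0 + d0
      m <- stats::rmultinom(n, nn, c(a0, b0, c0, d0) / nn)
      data.frame(a = m[1, ], b = m[2, ], c = m[3, ], d = m[4, ])
    })
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

resolve_statistic <- function(statistic) {
  if (is.character(statistic)) table_statistic(statistic) else statistic
}

#' Monte Carlo distribution of a table statistic
#'
#' Draws all runs of the scheme, evaluates the statistic per table,
#' excludes draws where it is undefined (counting them), and summarizes:
#' per-run mean/median/variance/sd, pooled summaries, a pooled fixed-width
#' histogram, percentile bounds and the normal-approximation mean +/- 2 sd
#' interval.
#'
#' @param scheme An \code{mc_scheme}.
#' @param statistic A statistic name (see \code{\link{table_statistic}})
#'   or a vectorized function \code{f(a, b, c, d)}.
#' @param level Confidence level for the percentile bounds (default 0.95).
#' @param bin_width Histogram bin width (default 0.01).
#' @return An \code{mc_result} with fields \code{per_run} (data frame),
#'   \code{pooled} (mean, median, var, sd, n), \code{histogram},
#'   \code{percentile_ci}, \code{normal_ci}, \code{excluded},
#'   \code{convergence_sd} (sd of per-run means).
#' @export
statistic_distribution <- function(scheme, statistic, level = 0.95,
                                   bin_width = 0.01) {
  stopifnot(inherits(scheme, "mc_scheme"))
  f <- resolve_statistic(statistic)
  stat_id <- if (is.character(statistic)) statistic else "custom"
  per_run <- vector("list", scheme$n_runs)
  pooled <- vector("list", scheme$n_runs)
  excluded <- 0L
  for (r in seq_len(scheme$n_runs)) {
    tab <- sample_tables(scheme, r)
    v <- f(tab$a, tab$b, tab$c, tab$d)
    bad <- !is.finite(v)
    excluded <- excluded + sum(bad)
    v <- v[!bad]
    per_run[[r]] <- data.frame(run = r, n = length(v),
                               mean = mean(v), median = stats::median(v),
                               var = stats::var(v), sd = stats::sd(v))
    pooled[[r]] <- v
  }
  per_run <- do.call(rbind, per_run)
  all_v <- unlist(pooled, use.names = FALSE)
  if (length(all_v) == 0)
    stop_degenerate("all Monte Carlo draws were degenerate for this statistic")
  rng <- range(all_v)
  breaks <- seq(floor(rng[1] / bin_width) * bin_width - bin_width,
                ceiling(rng[2] / bin_width) * bin_width + bin_width,
                by = bin_width)
  if (length(breaks) < 2) breaks <- c(breaks, breaks + bin_width)
  h <- graphics::hist(all_v, breaks = breaks, plot = FALSE)
  alpha <- (1 - level) / 2
  pci <- unname(stats::quantile(all_v, c(alpha, 1 - alpha), type = 7))
  m <- mean(all_v); s <- stats::sd(all_v)
  structure(list(
    statistic = stat_id, level = level,
    per_run = per_run,
    pooled = list(mean = m, median = stats::median(all_v),
                  var = stats::var(all_v), sd = s, n = length(all_v)),
    histogram = list(breaks = h$breaks, counts = h$counts),
    percentile_ci = pci,
    normal_ci = c(m - 2 * s, m + 2 * s),
    excluded = excluded,
    convergence_sd = stats::sd(per_run$mean),
    scheme_kind = scheme$kind, seed = scheme$seed),
    class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("MC distribution of '%s' under %s (%d runs, excluded %d)\n",
              x$statistic, x$scheme_kind, nrow(x$per_run), x$excluded))
  cat(sprintf("  pooled mean %.6g sd %.6g\n", x$pooled$mean, x$pooled$sd))
  cat(sprintf("  %g%% percentile CI [%.6g, %.6g]; mean +/- 2sd [%.6g, %.6g]\n",
              100 * x$level, x$percentile_ci[1], x$percentile_ci[2],
              x$normal_ci[1], x$normal_ci[2]))
  invisible(x)
}

#' Monte Carlo confidence interval for a table statistic
#'
#' Percentile interval from the pooled draws (asymmetric by construction),
#' with the normal-approximation mean +/- 2 sd interval alongside and the
#' sd of per-run means as a convergence diagnostic.
#'
#' @inheritParams statistic_distribution
#' @return A \code{ci_result} with \code{percentile}, \code{normal},
#'   \code{level}, \code{estimate} (statistic on the source table),
#'   \code{convergence_sd}, \code{excluded}.
#' @export
confidence_interval <- function(scheme, statistic, level = 0.95) {
  if (level <= 0 || level >= 1) stop_domain("level must be in (0, 1)")
  dist <- statistic_distribution(scheme, statistic, level = level)
  t <- scheme$table
  f <- resolve_statistic(statistic)
  structure(list(
    statistic = dist$statistic, level = level,
    estimate = f(t$a, t$b, t$c, t$d),
    percentile = dist$percentile_ci,
    normal = dist$normal_ci,
    pooled_mean = dist$pooled$mean, pooled_sd = dist$pooled$sd,
    convergence_sd = dist$convergence_sd,
    excluded = dist$excluded,
    scheme_kind = scheme$kind, seed = scheme$seed),
    class = "ci_result")
}

#' @export
print.ci_result <- function(x, ...) {
  cat(sprintf("%g%% MC CI for '%s' (%s): percentile [%.6g, %.6g], normal [%.6g, %.6g]\n",
              100 * x$level, x$statistic, x$scheme_kind,
              x$percentile[1], x$percentile[2], x$normal[1], x$normal[2]))
  invisible(x)
}
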