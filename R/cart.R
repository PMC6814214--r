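#' Candidate split thresholds for a continuous covariate
#'
#' Midpoints between consecutive distinct sorted values, restricted to
#' splits leaving at least \code{min_node} samples on each side of
#' \code{x <= threshold}.
#'
#' @param x Numeric covariate values.
#' @param min_node Minimum subnode size (default 5).
#' @return Strictly increasing numeric vector of thresholds.
#' @export
candidate_thresholds <- function(x, min_node = 5) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop_domain("x must be finite numeric")
  if (length(x) < 2 * min_node)
    stop_domain("need at least 2 * min_node samples")
  xs <- sort(x)
  n <- length(xs)
  lo <- xs[min_node]          # smallest feasible left-node upper value
  hi <- xs[n - min_node + 1]  # largest feasible right-node lower value
  u <- unique(xs)
  mids <- (u[-1] + u[-length(u)]) / 2
  mids[mids >= lo & mids <= hi]
}

#' Node impurity
#'
#' Gini impurity 1 - sum(p^2) or entropy -sum(p log p) (natural log,
#' 0 log 0 := 0) of a class-proportion vector.
#'
#' @param p Proportion vector summing to 1.
#' @param kind \code{"gini"} or \code{"entropy"}.
#' @return A nonnegative number.
#' @export
impurity <- function(p, kind = c("gini", "entropy")) {
  kind <- match.arg(kind)
  if (abs(sum(p) - 1) > 1e-8 || any(p < 0))
    stop_domain("p must be a proportion vector summing to 1")
  if (kind == "gini") 1 - sum(p^2)
  else -sum(ifelse(p > 0, p * log(p), 0))
}

#' Information gain of a binary split
#'
#' Parent impurity minus size-weighted subnode impurities,
#' IG = I(S) - (n1/n) I(S1) - (n2/n) I(S2), for a 2x2 table whose rows are
#' the subnodes and whose columns are the response classes.  The parent
#' class proportions come from the column sums.  For Gini impurity, IG
#' factors exactly as G(S) * phi^2.
#'
#' @param x A \code{count_table2x2} (rows = subnodes).
#' @param kind \code{"gini"} or \code{"entropy"}.
#' @return A nonnegative number.
#' @export
info_gain <- function(x, kind = c("gini", "entropy")) {
  stopifnot(inherits(x, "count_table2x2"))
  kind <- match.arg(kind)
  if (any(x$row_sums <= 0))
    stop_zero_margin("info_gain needs both subnodes nonempty")
  if (kind == "gini") k_ig_gini(x$a, x$b, x$c, x$d)
  else k_ig_entropy(x$a, x$b, x$c, x$d)
}

#' Binary association scan of one covariate against a binary response
#'
#' For every candidate threshold t, forms the 2x2 table with rows
#' S1 = \{x <= t\}, S2 = \{x > t\} and columns the two response classes
#' (sorted order of the labels), and records the split statistics:
#' information gains (Gini and entropy), phi^2, Yule's Q, the
#' column-sum-invariant subnode-composition coordinates (delta_c, mu_c)
#' from the column-sum dual form, the row-sum-invariant analog delta_r,
#' the marginal ratio omega_M, and the squared margin factor M_c^2 linking
#' phi to delta_c.  Both deltas are oriented subnode-2 minus subnode-1.
#' delta_c is invariant to rebalancing the response classes (duplicating
#' one class), which IG and phi^2 are not.
#'
#' @param x Numeric covariate.
#' @param y Binary response labels (exactly two distinct values; columns
#'   of each split table follow their sorted order).
#' @param min_node Minimum subnode size (default 5).
#' @return An \code{association_scan}: a data frame with one row per
#'   threshold (columns \code{threshold, n1, n2, a, b, c, d, ig_gini,
#'   ig_entropy, phi2, q, delta_c, mu_c, delta_r, omega_m, m_c2}), plus
#'   attributes \code{classes} and \code{min_node}.
#' @export
association_scan <- function(x, y, min_node = 5) {
  if (length(x) != length(y)) stop_domain("x and y lengths differ")
  classes <- sort(unique(y))
  if (length(classes) != 2)
    stop_domain("response must have exactly two classes present")
  thr <- candidate_thresholds(x, min_node)
  if (length(thr) == 0)
    stop_domain("no feasible thresholds under the min_node constraint")
  ord <- order(x)
  xs <- x[ord]
  y1 <- as.integer(y[ord] == classes[1])  # membership in class 1 (column 1)
  cum1 <- cumsum(y1)
  cum2 <- cumsum(1 - y1)
  n1_tot <- cum1[length(cum1)]
  n2_tot <- cum2[length(cum2)]
  # index of the last sample with x <= t for each threshold
  idx <- findInterval(thr, xs)
  a <- cum1[idx]; b <- cum2[idx]
  c <- n1_tot - a; d <- n2_tot - b
  dmc <- k_delta_mu_c(a, b, c, d)
  dmr <- k_delta_mu_r(a, b, c, d)
  out <- data.frame(
    threshold = thr,
    n1 = a + b, n2 = c + d,
    a = a, b = b, c = c, d = d,
    ig_gini = k_ig_gini(a, b, c, d),
    ig_entropy = k_ig_entropy(a, b, c, d),
    phi2 = k_phi(a, b, c, d)^2,
    q = k_yules_q(a, b, c, d),
    delta_c = dmc$delta, mu_c = dmc$mu,
    delta_r = dmr$delta,
    omega_m = k_omega_m(a, b, c, d),
    m_c2 = k_m_factor_csum(a, b, c, d)^2)
  attr(out, "classes") <- classes
  attr(out, "min_node") <- min_node
  class(out) <- c("association_scan", "data.frame")
  out
}

#' Select split thresholds from an association scan
#'
#' \code{global_max} returns the threshold maximizing the measure (ties go
#' to the smallest threshold).  \code{two_sided}, intended for the signed
#' \code{delta_c} criterion whose association graph is typically U-shaped,
#' returns both the maximizing and the minimizing threshold as
#' \code{lower}/\code{upper} candidates.  Each selection is reported with
#' its subnode sizes and class proportions.
#'
#' @param scan An \code{association_scan}.
#' @param measure Column of the scan to optimize (default
#'   \code{"delta_c"}).
#' @param mode \code{"global_max"} or \code{"two_sided"}.
#' @return A data frame with one row per selected split: \code{role},
#'   \code{threshold}, \code{measure}, \code{value}, subnode sizes
#'   \code{n1}, \code{n2} and per-subnode class proportions
#'   \code{s1_p1, s1_p2, s2_p1, s2_p2} (class order = sorted labels).
#' @export
select_splits <- function(scan, measure = "delta_c",
                          mode = c("global_max", "two_sided")) {
  stopifnot(inherits(scan, "association_scan"))
  mode <- match.arg(mode)
  if (!measure %in% names(scan))
    stop_domain(sprintf("unknown measure '%s'", measure))
  v <- scan[[measure]]
  if (all(!is.finite(v))) stop_degenerate("measure undefined at every threshold")
  pick <- function(i, role) {
    r <- scan[i, ]
    data.frame(role = role, threshold = r$threshold,
               measure = measure, value = v[i],
               n1 = r$n1, n2 = r$n2,
               s1_p1 = r$a / r$n1, s1_p2 = r$b / r$n1,
               s2_p1 = r$c / r$n2, s2_p2 = r$d / r$n2)
  }
  if (mode == "global_max") {
    pick(which.max(v), "global_max")  # which.max takes the first (smallest t)
  } else {
    i_max <- which.max(v); i_min <- which.min(v)
    lo <- min(i_max, i_min); hi <- max(i_max, i_min)
    rbind(pick(lo, "lower"), pick(hi, "upper"))
  }
}
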