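FORM_IDS <- c("csum_rows", "csum_cols", "rsum_rows", "rsum_cols", "symmetric")

#' Extract a pair of one-simplex points from a 2x2 table
#'
#' A 2x2 table carries four margin-invariant forms of proportional
#' variation, one per axis of the two factorizations:
#' \describe{
#'   \item{csum_rows}{rows of the column-side \emph{dual} matrix
#'     (column-scaling invariant row composition);
#'     \code{p_alpha} = a-element, \code{p_beta} = c-element.}
#'   \item{csum_cols}{columns of the column-side \emph{unit} matrix;
#'     \code{p_alpha} = b-column first coordinate b/(b+d),
#'     \code{p_beta} = a-column first coordinate a/(a+c).}
#'   \item{rsum_rows}{rows of the row-side \emph{unit} matrix;
#'     \code{p_alpha} = c-row first coordinate c/(c+d),
#'     \code{p_beta} = a-row first coordinate a/(a+b).}
#'   \item{rsum_cols}{columns of the row-side \emph{dual} matrix;
#'     \code{p_alpha} = b-element, \code{p_beta} = a-element (first row).}
#'   \item{symmetric}{the pair (a,b)/(a+b), (b,a)/(a+b) built from row 1;
#'     meaningful for diagonally symmetric tables (e.g. after
#'     \code{\link{yule_symmetrize}}), where it is the single degree of
#'     freedom; \code{p_alpha} = b/(a+b), \code{p_beta} = a/(a+b).}
#' }
#'
#' @param x A \code{count_table2x2}.
#' @param form One of \code{"csum_rows"}, \code{"csum_cols"},
#'   \code{"rsum_rows"}, \code{"rsum_cols"}, \code{"symmetric"}.
#' @return A \code{simplex_pair} with fields \code{p_alpha}, \code{p_beta},
#'   \code{form}.
#' @examples
#' simplex_pair(count_table(10, 30, 30, 20), "csum_rows")
#' @export
simplex_pair <- function(x, form = FORM_IDS) {
  stopifnot(inherits(x, "count_table2x2"))
  form <- match.arg(form)
  a <- x$a; b <- x$b; c <- x$c; d <- x$d
  pp <- switch(form,
    csum_rows = {
      f <- factorize(x, "column", "dual")
      c(f$proportion[1, 1], f$proportion[2, 1])
    },
    csum_cols = {
      f <- factorize(x, "column", "unit")
      c(f$proportion[1, 2], f$proportion[1, 1])
    },
    rsum_rows = {
      f <- factorize(x, "row", "unit")
      c(f$proportion[2, 1], f$proportion[1, 1])
    },
    rsum_cols = {
      f <- factorize(x, "row", "dual")
      c(f$proportion[1, 2], f$proportion[1, 1])
    },
    symmetric = {
      if (a + b <= 0) stop_zero_margin("symmetric form needs a + b > 0")
      c(b / (a + b), a / (a + b))
    })
  structure(list(p_alpha = pp[1], p_beta = pp[2], form = form),
            class = "simplex_pair")
}

#' Center-of-mass coordinates of a simplex pair
#'
#' Reduces two points in the standard one-simplex to the half-difference
#' and mean of their first coordinates: delta = (p_beta - p_alpha)/2,
#' mu = (p_alpha + p_beta)/2, with 0 <= mu - delta <= 1 and
#' 0 <= mu + delta <= 1.  The un-halved difference is exposed as
#' \code{displacement}.  With the \code{\link{simplex_pair}} ordering, the
#' \code{csum_rows} delta is the c-minus-a oriented column-scaling
#' invariant proportional difference.
#'
#' @param sp A \code{simplex_pair}.
#' @return A \code{com_coords} object with \code{delta}, \code{mu},
#'   \code{displacement} and \code{form}.
#' @examples
#' com_coords(simplex_pair(count_table(10, 30, 30, 20), "csum_rows"))
#' @export
com_coords <- function(sp) {
  stopifnot(inherits(sp, "simplex_pair"))
  delta <- (sp$p_beta - sp$p_alpha) / 2
  mu <- (sp$p_beta + sp$p_alpha) / 2
  structure(list(delta = delta, mu = mu, displacement = 2 * delta,
                 form = sp$form),
            class = "com_coords")
}

#' @export
print.com_coords <- function(x, ...) {
  cat(sprintf("center of mass [%s]: delta = %.6f, mu = %.6f\n",
              x$form, x$delta, x$mu))
  invisible(x)
}

#' Odds ratio
#'
#' ad/bc, the unique measure invariant to any row or column rescaling
#' (and hence to unitary diagonal scaling).  Boundary cases: ad > 0 with
#' bc = 0 gives \code{Inf}; ad = 0 with bc > 0 gives 0.
#'
#' @param x A \code{count_table2x2}.
#' @return A nonnegative number, possibly \code{Inf}.
#' @export
odds_ratio <- function(x) {
  stopifnot(inherits(x, "count_table2x2"))
  ad <- x$a * x$d; bc <- x$b * x$c
  if (ad == 0 && bc == 0)
    stop_undefined("odds ratio undefined: ad = bc = 0")
  ad / bc
}

#' Yule's Q
#'
#' (ad - bc)/(ad + bc), the linear-fractional transform (omega-1)/(omega+1)
#' of the odds ratio, computed in the robust difference form so that
#' boundary tables give +/-1 rather than Inf arithmetic.
#'
#' @param x A \code{count_table2x2}.
#' @return A number in [-1, 1].
#' @export
yules_q <- function(x) {
  stopifnot(inherits(x, "count_table2x2"))
  den <- x$a * x$d + x$b * x$c
  if (den == 0)
    stop_undefined("Yule's Q undefined: ad + bc = 0")
  (x$a * x$d - x$b * x$c) / den
}

#' Relative risk
#'
#' Ratio of the first-category proportion to the second-category
#' counterpart for the chosen form of proportional variation.  The default
#' \code{rsum_rows} gives the conventional epidemiological relative risk
#' [a/(a+b)] / [c/(c+d)]; other forms give the analogous first-over-second
#' ratio of that form's simplex points (for \code{csum_rows}, the a-element
#' over the c-element of the column-side dual matrix).
#'
#' @param x A \code{count_table2x2}.
#' @param form A non-symmetric form id (see \code{\link{simplex_pair}}).
#' @return A nonnegative number, \code{Inf} when the reference proportion
#'   is zero with a nonzero numerator.
#' @export
relative_risk <- function(x, form = c("rsum_rows", "csum_rows",
                                      "csum_cols", "rsum_cols")) {
  form <- match.arg(form)
  sp <- simplex_pair(x, form)
  # first category over second: p_beta/p_alpha for the rows forms
  # (p_beta is the a-side point there) and likewise for the cols forms
  num <- sp$p_beta
  den <- sp$p_alpha
  if (form %in% c("csum_rows")) { num <- sp$p_alpha; den <- sp$p_beta }
  if (den == 0 && num == 0)
    stop_undefined("relative risk undefined: both proportions zero")
  num / den
}

#' Effect sizes as perspective functions of (delta, mu)
#'
#' Maps center-of-mass coordinates to the odds ratio, Yule's Q, relative
#' risk and ratio difference:
#' \deqn{\omega = \frac{\delta^2 + \mu(1-\mu) + \delta}
#'                     {\delta^2 + \mu(1-\mu) - \delta},\quad
#'       Q = \frac{\delta}{\delta^2 + \mu(1-\mu)},\quad
#'       \rho = \frac{\mu+\delta}{\mu-\delta},\quad
#'       \beta-\alpha = \frac{2\delta}{1 + \mu(\mu-2) - \delta^2}.}
#' Each is the same displacement seen through a different perspective
#' normalization; rho here is oriented p_beta over p_alpha, consistent with
#' the identity delta (rho + 1) - mu (rho - 1) = 0.
#'
#' @param cc A \code{com_coords} object, or a list with \code{delta} and
#'   \code{mu}.
#' @return A list with \code{omega}, \code{q}, \code{rho},
#'   \code{ratio_diff}.
#' @export
perspective_measures <- function(cc) {
  delta <- cc$delta; mu <- cc$mu
  t0 <- delta^2 + mu * (1 - mu)
  omega <- (t0 + delta) / (t0 - delta)
  q <- if (t0 == 0) NA_real_ else delta / t0
  rho <- (mu + delta) / (mu - delta)
  rd_den <- 1 + mu * (mu - 2) - delta^2  # = (1-p_alpha)(1-p_beta)
  ratio_diff <- 2 * delta / rd_den
  list(omega = omega, q = q, rho = rho, ratio_diff = ratio_diff)
}

#' The phi coefficient
#'
#' Pearson correlation of the binary indicators:
#' (ad - bc)/sqrt((a+b)(c+d)(a+c)(b+d)).  Margin-dependent; see
#' \code{\link{phi_factorization}} for its decomposition into a margin
#' factor times a margin-invariant displacement.
#'
#' @param x A \code{count_table2x2}.
#' @return A number in [-1, 1].
#' @export
phi_coef <- function(x) {
  stopifnot(inherits(x, "count_table2x2"))
  if (any(x$row_sums <= 0) || any(x$col_sums <= 0))
    stop_zero_margin("phi needs all four marginal sums positive")
  k_phi(x$a, x$b, x$c, x$d)
}

#' Factor phi into a margin factor and a proportional displacement
#'
#' phi = M * D where D is the un-halved difference of dual-matrix elements
#' in a-first orientation (\code{rsum}: a-element minus b-element of the
#' row-side dual matrix; \code{csum}: a-element minus c-element of the
#' column-side dual matrix) and M is a positive factor depending only on
#' marginal sums, computed from its closed form.  M = 1 for diagonally
#' symmetric tables, where phi collapses onto the symmetric proportional
#' difference.
#'
#' @param x A \code{count_table2x2}.
#' @param form \code{"rsum"} or \code{"csum"}.
#' @return A list with \code{m_factor}, \code{displacement}, and their
#'   product \code{phi}.
#' @export
phi_factorization <- function(x, form = c("rsum", "csum")) {
  stopifnot(inherits(x, "count_table2x2"))
  form <- match.arg(form)
  if (any(x$row_sums <= 0) || any(x$col_sums <= 0))
    stop_zero_margin("phi factorization needs all four marginal sums positive")
  a <- x$a; b <- x$b; c <- x$c; d <- x$d
  if (form == "rsum") {
    p <- k_rsum_dual(a, b, c, d)
    disp <- p$p_a - p$p_b
    m <- k_m_factor_rsum(a, b, c, d)
  } else {
    p <- k_csum_dual(a, b, c, d)
    disp <- p$p_a - p$p_c
    m <- k_m_factor_csum(a, b, c, d)
  }
  phi <- k_phi(a, b, c, d)
  if (disp != 0 && abs(m * disp - phi) > 1e-8 * max(1, abs(phi)))
    stop_proptab("internal inconsistency: phi != M * D", "proptab_internal_error")
  list(m_factor = m, displacement = disp, phi = phi)
}

#' Symmetric proportional difference
#'
#' For the symmetric form pair built from (x, y) and (y, x), returns
#' delta_s = (x - y)/(x + y), the un-halved displacement.  Applied to a
#' Yule-symmetrized table this is the coefficient of colligation
#' Y = (sqrt(ad) - sqrt(bc))/(sqrt(ad) + sqrt(bc)) =
#' (sqrt(omega) - 1)/(sqrt(omega) + 1), and equals phi of the symmetrized
#' table.
#'
#' @param sp A \code{simplex_pair} with \code{form = "symmetric"}, or a
#'   diagonally symmetric \code{count_table2x2}.
#' @return A number in [-1, 1].
#' @export
delta_s <- function(sp) {
  if (inherits(sp, "count_table2x2")) sp <- simplex_pair(sp, "symmetric")
  stopifnot(inherits(sp, "simplex_pair"))
  if (sp$form != "symmetric")
    stop_domain("delta_s is defined for the symmetric form only")
  sp$p_beta - sp$p_alpha
}

#' Simple matching coefficient and its marginal decompositions
#'
#' s_M = (a+d)/N, with its two expressions as weighted sums of
#' margin-invariant proportions: by columns,
#' s_M = (a+c)/N * a/(a+c) + (b+d)/N * d/(b+d), and by rows,
#' s_M = (a+b)/N * a/(a+b) + (c+d)/N * d/(c+d).  The proportions are
#' invariant to row/column scaling but the weights are not, which is why
#' s_M itself is margin-dependent.
#'
#' @param x A \code{count_table2x2}.
#' @return A list with \code{s_m} and, when the margins allow,
#'   \code{column} and \code{row} decompositions (weights + proportions).
#' @export
simple_matching <- function(x) {
  stopifnot(inherits(x, "count_table2x2"))
  out <- list(s_m = (x$a + x$d) / x$n)
  if (all(x$col_sums > 0)) {
    out$column <- list(weights = x$col_sums / x$n,
                       proportions = c(x$a / x$col_sums[1],
                                       x$d / x$col_sums[2]))
  } else warn_proptab("zero column sum: column decomposition omitted")
  if (all(x$row_sums > 0)) {
    out$row <- list(weights = x$row_sums / x$n,
                    proportions = c(x$a / x$row_sums[1],
                                    x$d / x$row_sums[2]))
  } else warn_proptab("zero row sum: row decomposition omitted")
  out
}

#' Chi-squared association measures for an r x c table
#'
#' Pearson's chi-squared, Cramer's V = sqrt(chi2 / (n (q - 1))) with
#' q = min(r, c), and Goodman-Kruskal tau in both directions
#' (\code{tau_col}: predicting the column category from the row;
#' \code{tau_row}: the converse).  For a 2x2 table V = |phi| and
#' tau_col = tau_row = phi^2; these measures average over the distinct
#' forms of proportional variation.
#'
#' @param m An r x c matrix of nonnegative counts (a
#'   \code{count_table2x2} is accepted).
#' @return A list with \code{chi2}, \code{cramers_v}, \code{tau_col},
#'   \code{tau_row}.
#' @export
rxc_measures <- function(m) {
  if (inherits(m, "count_table2x2")) m <- as.matrix(m)
  m <- as.matrix(m)
  if (any(m < 0)) stop_domain("counts must be nonnegative")
  n <- sum(m)
  rs <- rowSums(m); cs <- colSums(m)
  if (any(rs <= 0) || any(cs <= 0))
    stop_zero_margin("rxc measures need all margins positive")
  expected <- outer(rs, cs) / n
  chi2 <- sum((m - expected)^2 / expected)
  q <- min(dim(m))
  v <- sqrt(chi2 / (n * (q - 1)))
  p <- m / n; pr <- rs / n; pc <- cs / n
  # proportional-prediction error reduction
  tau_col <- (sum(p^2 / matrix(pr, nrow(m), ncol(m))) - sum(pc^2)) /
    (1 - sum(pc^2))
  tau_row <- (sum(p^2 / matrix(pc, nrow(m), ncol(m), byrow = TRUE)) -
                sum(pr^2)) / (1 - sum(pr^2))
  list(chi2 = chi2, cramers_v = v, tau_col = tau_col, tau_row = tau_row)
}

#' Full effect-size report for a 2x2 table
#'
#' Computes every scalar measure and the (delta, mu, displacement, margin
#' factor) set for each of the four margin-invariant forms.  Per-form
#' \code{m_factor} is signed so that \code{phi = m_factor * displacement}
#' holds for the form's own orientation (for \code{csum_rows}, whose delta
#' is c-minus-a, it is the negative of the positive closed-form factor).
#' An optional qualitative label applies the 0.1/0.3/0.5
#' small/medium/large convention to |delta| and |phi|; note that this
#' convention ignores the mu coordinate.
#'
#' @param x A \code{count_table2x2}.
#' @param qualitative Also attach small/medium/large labels (default
#'   FALSE).
#' @return An \code{effect_size_report} list; see Details.
#' @examples
#' rep <- effect_sizes(count_table(10, 30, 30, 20))
#' rep$phi        # -0.35
#' rep$forms$csum_rows$delta  # 0.179028
#' @export
effect_sizes <- function(x, qualitative = FALSE) {
  stopifnot(inherits(x, "count_table2x2"))
  forms <- list()
  om <- k_omega_m(x$a, x$b, x$c, x$d)
  for (form in setdiff(FORM_IDS, "symmetric")) {
    cc <- com_coords(simplex_pair(x, form))
    # closed-form margin factor, signed for the form's own orientation so
    # that phi = m_factor * displacement holds per entry
    m <- switch(form,
      csum_rows = -k_m_factor_csum(x$a, x$b, x$c, x$d),
      csum_cols = 1 / sqrt(om),
      rsum_rows = sqrt(om),
      rsum_cols = k_m_factor_rsum(x$a, x$b, x$c, x$d))
    forms[[form]] <- list(p_alpha = cc$mu - cc$delta,
                          p_beta = cc$mu + cc$delta,
                          delta = cc$delta, mu = cc$mu,
                          displacement = cc$displacement,
                          m_factor = m)
  }
  rxc <- rxc_measures(x)
  omega <- tryCatch(odds_ratio(x), proptab_error = function(e) NA_real_)
  rep <- list(
    table = as.matrix(x),
    omega = omega,
    q = tryCatch(yules_q(x), proptab_error = function(e) NA_real_),
    rho = relative_risk(x),
    ratio_diff = {
      cc <- com_coords(simplex_pair(x, "rsum_rows"))
      perspective_measures(cc)$ratio_diff
    },
    phi = phi_coef(x),
    omega_m = marginal_ratio(x),
    s_m = simple_matching(x)$s_m,
    cramers_v = rxc$cramers_v,
    tau_col = rxc$tau_col,
    tau_row = rxc$tau_row,
    colligation = delta_s(yule_symmetrize(x)),
    forms = forms)
  if (qualitative) {
    lab <- function(v) {
      v <- abs(v)
      if (v >= 0.5) "large" else if (v >= 0.3) "medium"
      else if (v >= 0.1) "small" else "negligible"
    }
    rep$qualitative <- list(
      phi = lab(rep$phi),
      delta = vapply(forms, function(f) lab(f$delta), character(1)),
      note = "0.1/0.3/0.5 thresholds on |delta|, |phi|; mu is ignored")
  }
  class(rep) <- "effect_size_report"
  rep
}

#' @export
print.effect_size_report <- function(x, ...) {
  cat("Effect sizes for 2x2 table\n")
  cat(sprintf("  odds ratio %.6g  Q %.6g  RR %.6g  phi %.6g\n",
              x$omega, x$q, x$rho, x$phi))
  cat(sprintf("  s_M %.6g  omega_M %.6g  V %.6g  tau %.6g\n",
              x$s_m, x$omega_m, x$cramers_v, x$tau_col))
  for (nm in names(x$forms)) {
    f <- x$forms[[nm]]
    cat(sprintf("  %-9s delta %+.6f  mu %.6f  M %+.6f\n",
                nm, f$delta, f$mu, f$m_factor))
  }
  invisible(x)
}
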