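# Vectorized effect-size kernels over parallel cell vectors (a, b, c, d).
# These back the Monte Carlo engine and the CART scan; the scalar operations
# in effect-sizes.R delegate here.  Undefined values propagate as NA/Inf per
# the conventions of the scalar operations.
#
# Orientation: the *_c kernels give the column-scaling-invariant
# center-of-mass coordinates of the column-sum dual form with delta oriented
# c-minus-a (the Fig.-style delta_c,c-a); the *_r kernels give the
# row-scaling-invariant analog from the row-side unit form, likewise
# oriented c-minus-a, so the two deltas compare the same pair of simplex
# points (row 1 vs row 2 composition) under the two invariances.

k_csum_dual <- function(a, b, c, d) {
  # first coordinates of the two rows of the column-side dual matrix
  ac <- a + c; bd <- b + d
  n1 <- a / ac + b / bd
  n2 <- c / ac + d / bd
  p_a <- a / (n1 * ac)
  p_c <- c / (n2 * ac)
  bad <- !(ac > 0 & bd > 0 & n1 > 0 & n2 > 0)
  p_a[bad] <- NA_real_; p_c[bad] <- NA_real_
  list(p_a = p_a, p_c = p_c)
}

k_rsum_dual <- function(a, b, c, d) {
  # first coordinates (row 1) of the two columns of the row-side dual matrix
  ab <- a + b; cd <- c + d
  n1 <- a / ab + c / cd
  n2 <- b / ab + d / cd
  p_a <- a / (n1 * ab)
  p_b <- b / (n2 * ab)
  bad <- !(ab > 0 & cd > 0 & n1 > 0 & n2 > 0)
  p_a[bad] <- NA_real_; p_b[bad] <- NA_real_
  list(p_a = p_a, p_b = p_b)
}

k_delta_mu_c <- function(a, b, c, d) {
  p <- k_csum_dual(a, b, c, d)
  list(delta = (p$p_c - p$p_a) / 2, mu = (p$p_c + p$p_a) / 2)
}

k_delta_mu_r <- function(a, b, c, d) {
  # row-side unit form: class composition of the two rows
  ab <- a + b; cd <- c + d
  p1 <- a / ab
  p2 <- c / cd
  bad <- !(ab > 0 & cd > 0)
  p1[bad] <- NA_real_; p2[bad] <- NA_real_
  list(delta = (p2 - p1) / 2, mu = (p2 + p1) / 2)
}

k_odds_ratio <- function(a, b, c, d) {
  num <- a * d; den <- b * c
  out <- num / den
  out[num == 0 & den == 0] <- NA_real_
  out
}

k_yules_q <- function(a, b, c, d) {
  num <- a * d - b * c
  den <- a * d + b * c
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

k_phi <- function(a, b, c, d) {
  den <- sqrt((a + b) * (c + d)) * sqrt((a + c) * (b + d))
  out <- (a * d - b * c) / den
  out[den == 0] <- NA_real_
  out
}

k_s_m <- function(a, b, c, d) (a + d) / (a + b + c + d)

k_omega_m <- function(a, b, c, d) {
  den <- (a + c) * (b + d)
  out <- (a + b) * (c + d) / den
  out[den == 0] <- NA_real_
  out
}

# Margin factors of the phi = M * D decompositions, a-first orientation:
# D_rsum = a-el - b-el of the row-side dual matrix, D_csum = a-el - c-el of
# the column-side dual matrix; both M are positive for positive margins.
k_m_factor_rsum <- function(a, b, c, d) {
  den <- sqrt((a + b) * (c + d)) * sqrt((a + c) * (b + d))
  (a + c * (a + b) / (c + d)) * (b * (c + d) / (a + b) + d) / den
}

k_m_factor_csum <- function(a, b, c, d) {
  den <- sqrt((a + b) * (c + d)) * sqrt((a + c) * (b + d))
  (a + b * (a + c) / (b + d)) * (c * (b + d) / (a + c) + d) / den
}

# Gini impurity of the parent from column (class) sums, and information
# gains with rows as subnodes and columns as classes.
k_gini_parent <- function(a, b, c, d) {
  n <- a + b + c + d
  2 * (a + c) * (b + d) / n^2
}

k_ig_gini <- function(a, b, c, d) {
  n <- a + b + c + d
  2 / n * ((a + c) * (b + d) / n - a * b / (a + b) - c * d / (c + d))
}

k_ig_entropy <- function(a, b, c, d) {
  n <- a + b + c + d
  xlx <- function(v) ifelse(v > 0, v * log(v), 0)  # 0 log 0 := 0
  h2 <- function(p) -(xlx(p) + xlx(1 - p))
  parent <- h2((a + c) / n)
  (parent
   - (a + b) / n * h2(a / (a + b))
   - (c + d) / n * h2(c / (c + d)))
}

#' Named vectorized table statistics
#'
#' Returns a function of four parallel cell vectors \code{(a, b, c, d)}
#' computing the named statistic per table.  Used as the \code{statistic}
#' argument of the Monte Carlo operations and by the CLI.
#'
#' Available names: \code{"delta_c"}, \code{"mu_c"} (column-sum dual
#' center-of-mass coordinates, delta oriented c-minus-a), \code{"delta_r"},
#' \code{"mu_r"} (row-side unit analog, same orientation),
#' \code{"odds_ratio"}, \code{"q"} (Yule's Q), \code{"phi"}, \code{"s_m"}
#' (simple matching), \code{"omega_m"} (marginal ratio), \code{"n"}.
#'
#' @param name Statistic name (see above).
#' @return A vectorized function \code{f(a, b, c, d)}.
#' @export
table_statistic <- function(name) {
  switch(name,
    delta_c    = function(a, b, c, d) k_delta_mu_c(a, b, c, d)$delta,
    mu_c       = function(a, b, c, d) k_delta_mu_c(a, b, c, d)$mu,
    delta_r    = function(a, b, c, d) k_delta_mu_r(a, b, c, d)$delta,
    mu_r       = function(a, b, c, d) k_delta_mu_r(a, b, c, d)$mu,
    odds_ratio = k_odds_ratio,
    q          = k_yules_q,
    phi        = k_phi,
    s_m        = k_s_m,
    omega_m    = k_omega_m,
    n          = function(a, b, c, d) a + b + c + d,
    stop_domain(sprintf("unknown statistic '%s'", name))
  )
}
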