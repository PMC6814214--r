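#' One-covariate logistic regression by Newton-Raphson
#'
#' Maximum-likelihood fit of P(y = 1 | x) = 1/(1 + exp(-(a0 + b x))).
#' Newton iterations on the two-parameter log-likelihood, converging when
#' the score norm drops below \code{tol}; perfect separation surfaces as a
#' non-convergence error rather than silently divergent coefficients.
#'
#' @param x Numeric covariate.
#' @param y Binary response in \{0, 1\} (or a logical/two-level factor).
#' @param tol Convergence tolerance on the score norm (default 1e-10).
#' @param max_iter Maximum Newton iterations (default 100).
#' @return A \code{logistic_fit} with \code{a0} (intercept), \code{b}
#'   (slope), \code{n_neg}, \code{n_pos}, \code{se} (standard errors),
#'   \code{vcov}, \code{converged}, \code{iterations}, \code{loglik}.
#' @export
fit_logistic <- function(x, y, tol = 1e-10, max_iter = 100) {
  if (length(x) != length(y)) stop_domain("x and y lengths differ")
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop_domain("y must be binary 0/1")
  if (sum(y) == 0 || sum(y) == length(y))
    stop_domain("both classes must be present")
  if (stats::sd(x) == 0) stop_domain("x must not be constant")
  # one covariate: perfect separation is detectable directly
  if (max(x[y == 0]) < min(x[y == 1]) || max(x[y == 1]) < min(x[y == 0]))
    stop_proptab("classes are perfectly separated along x: MLE does not exist",
                 "proptab_convergence_error")
  beta <- c(stats::qlogis(mean(y)), 0)
  X <- cbind(1, x)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    score <- drop(crossprod(X, y - p))
    if (sqrt(sum(score^2)) < tol) { converged <- TRUE; break }
    w <- p * (1 - p)
    info <- crossprod(X * w, X)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step)))
      stop_proptab("Newton step failed: information matrix singular (separation?)",
                   "proptab_convergence_error")
    # damp overly aggressive steps (quasi-separated data)
    if (max(abs(step)) > 10) step <- step * 10 / max(abs(step))
    beta <- beta + step
    if (max(abs(beta)) > 1e6)
      stop_proptab("logistic fit diverged: data may be perfectly separated",
                   "proptab_convergence_error")
  }
  if (!converged)
    stop_proptab(sprintf("logistic fit did not converge in %d iterations (|score| = %.3g); data may be separated",
                         max_iter, sqrt(sum(score^2))),
                 "proptab_convergence_error")
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  vcov <- unname(solve(crossprod(X * (p * (1 - p)), X)))
  structure(list(a0 = unname(beta[1]), b = unname(beta[2]),
                 n_neg = sum(y == 0), n_pos = sum(y == 1),
                 se = unname(sqrt(diag(vcov))), vcov = vcov,
                 converged = converged, iterations = iter,
                 loglik = sum(y * log(p) + (1 - y) * log1p(-p))),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("logistic fit: a0 = %.6g (se %.3g), b = %.6g (se %.3g); n = %d + %d; %d iterations\n",
              x$a0, x$se[1], x$b, x$se[2], x$n_neg, x$n_pos, x$iterations))
  invisible(x)
}

#' Reparameterize a logistic fit into class-balance independent form
#'
#' The intercept of a logistic fit absorbs the class imbalance: writing
#' a0 = -b x0 - log(n_neg/n_pos) defines the midpoint
#' x0 = -(a0 + log(n_neg/n_pos))/b at which the fitted curve passes
#' through the sample-size proportion n_pos/(n_neg + n_pos).  The adjusted
#' (equal-sample-size) curve 1/(1 + exp(-b (x - x0))) crosses 1/2 at x0,
#' and the original curve is 1/(1 + (n_neg/n_pos) exp(-b (x - x0))).
#' (b, x0) are the two sample-size-independent parameters.
#'
#' @param fit A \code{logistic_fit}.
#' @return An \code{adjusted_logistic} with \code{b}, \code{x0},
#'   \code{n_neg}, \code{n_pos}, \code{midpoint_value} =
#'   n_pos/(n_neg + n_pos), and curve functions \code{curve} (original)
#'   and \code{adjusted_curve}.
#' @export
adjust_for_sample_size <- function(fit) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (fit$b == 0) stop_undefined("b = 0: midpoint undefined")
  imb <- log(fit$n_neg / fit$n_pos)
  x0 <- -(fit$a0 + imb) / fit$b
  b <- fit$b
  ratio <- fit$n_neg / fit$n_pos
  # delta-method SE of x0 treating the realized class sizes as fixed
  g <- c(-1 / b, -x0 / b)
  x0_se <- sqrt(drop(t(g) %*% fit$vcov %*% g))
  structure(list(
    b = b, x0 = x0, b_se = fit$se[2], x0_se = x0_se,
    n_neg = fit$n_neg, n_pos = fit$n_pos,
    midpoint_value = fit$n_pos / (fit$n_neg + fit$n_pos),
    curve = function(x) 1 / (1 + ratio * exp(-b * (x - x0))),
    adjusted_curve = function(x) 1 / (1 + exp(-b * (x - x0)))),
    class = "adjusted_logistic")
}

#' @export
print.adjusted_logistic <- function(x, ...) {
  cat(sprintf("adjusted logistic: b = %.6g, x0 = %.6g; curve(x0) = %.6g = n_pos/(n_neg+n_pos)\n",
              x$b, x$x0, x$midpoint_value))
  invisible(x)
}

#' Rebalance an observed class-1 proportion for unequal class sizes
#'
#' Inverse-class-size reweighting: p_adj = p n_neg / (p n_neg +
#' (1 - p) n_pos), so that a proportion equal to the sample-size
#' proportion n_pos/(n_neg + n_pos) -- i.e. equal underlying
#' class-conditional densities -- maps to 1/2.  With n_neg = n_pos it is
#' the identity.
#'
#' @param p Proportion(s) in [0, 1].
#' @param n_neg,n_pos Class sample sizes.
#' @return Adjusted proportion(s) in [0, 1].
#' @export
reweighted_proportion <- function(p, n_neg, n_pos) {
  if (any(p < 0 | p > 1)) stop_domain("p must lie in [0, 1]")
  num <- p * n_neg
  den <- p * n_neg + (1 - p) * n_pos
  if (any(den == 0)) stop_undefined("0/0 in reweighting: degenerate input")
  num / den
}

#' Moving-average class-1 proportion along a covariate
#'
#' Slides a window of \code{window} samples over the rank-ordered
#' covariate and reports the class-1 proportion per window, centered at
#' the window's median x.  A reference curve for logistic fits.
#'
#' @param x Numeric covariate.
#' @param y Binary response in \{0, 1\}.
#' @param window Window size in samples (default ~n/20, odd-rounded).
#' @return A data frame with columns \code{x} (window center) and
#'   \code{proportion}.
#' @export
moving_average_proportion <- function(x, y, window = NULL) {
  if (length(x) != length(y)) stop_domain("x and y lengths differ")
  n <- length(x)
  if (is.null(window)) window <- max(1L, 2L * (n %/% 40L) + 1L)
  window <- as.integer(window)
  if (window < 1) stop_domain("window must be at least 1")
  if (window > n) stop_domain("window larger than the sample")
  ord <- order(x)
  xs <- x[ord]; ys <- as.numeric(y[ord])
  cy <- c(0, cumsum(ys))
  starts <- seq_len(n - window + 1L)
  prop <- (cy[starts + window] - cy[starts]) / window
  centers <- vapply(starts, function(s)
    stats::median(xs[s:(s + window - 1L)]), numeric(1))
  data.frame(x = centers, proportion = prop)
}
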