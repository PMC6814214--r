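#' Build a validated 2x2 contingency table
#'
#' The table of counts follows the standard layout: row 1 = (a, b),
#' row 2 = (c, d); columns are the two response categories, rows the two
#' groups.  Counts are accepted as nonnegative reals (not only integers) so
#' that rescaled and Yule-symmetrized tables are first-class values.
#'
#' @param a,b,c,d Nonnegative finite counts; cell order is row-major
#'   (a, b / c, d).
#' @return An object of class \code{count_table2x2} with fields
#'   \code{a,b,c,d}, \code{row_sums}, \code{col_sums} and total \code{n}.
#' @examples
#' t <- count_table(10, 30, 30, 20)
#' t$row_sums  # 40 50
#' @export
count_table <- function(a, b, c, d) {
  a <- check_scalar(a, "a"); b <- check_scalar(b, "b")
  c <- check_scalar(c, "c"); d <- check_scalar(d, "d")
  if (min(a, b, c, d) < 0)
    stop_domain("all counts must be nonnegative")
  n <- a + b + c + d
  if (n <= 0)
    stop_degenerate("degenerate table: total count is zero")
  structure(
    list(a = a, b = b, c = c, d = d,
         row_sums = c(a + b, c + d),
         col_sums = c(a + c, b + d),
         n = n),
    class = "count_table2x2")
}

#' @export
as.matrix.count_table2x2 <- function(x, ...) {
  matrix(c(x$a, x$b, x$c, x$d), nrow = 2, byrow = TRUE,
         dimnames = list(c("row1", "row2"), c("col1", "col2")))
}

#' Coerce a 2x2 numeric matrix to a count table
#' @param m A 2x2 numeric matrix in the (a, b / c, d) layout.
#' @return A \code{count_table2x2}.
#' @export
as_count_table <- function(m) {
  m <- as.matrix(m)
  if (!is.numeric(m) || any(dim(m) != 2L))
    stop_domain("expected a 2x2 numeric matrix")
  count_table(m[1, 1], m[1, 2], m[2, 1], m[2, 2])
}

#' @export
print.count_table2x2 <- function(x, ...) {
  cat("2x2 contingency table (N =", format(x$n), ")\n")
  print(as.matrix(x))
  cat("row sums:", format(x$row_sums),
      " col sums:", format(x$col_sums), "\n")
  invisible(x)
}

#' Factor a 2x2 table into diagonal marginal-sum and proportion matrices
#'
#' Writes the table T as \code{diag(left) \%*\% P \%*\% diag(right)} where one
#' diagonal carries the chosen marginal sums and P is a proportion matrix
#' whose designated axis (rows or columns) consists of points in the
#' standard one-simplex.  For \code{side = "column"} the right diagonal is
#' the column sums; \code{mode = "unit"} sets the normalizers n1 = n2 = 1 so
#' the columns of P sum to 1, while \code{mode = "dual"} chooses
#' n1 = a/(a+c) + b/(b+d), n2 = c/(a+c) + d/(b+d) so the *rows* of P sum
#' to 1 -- the column-scaling-invariant representation of row composition.
#' \code{side = "row"} is the transpose-symmetric construction.
#'
#' @param x A \code{count_table2x2}.
#' @param side Which marginal sums to factor out: \code{"column"} or
#'   \code{"row"}.
#' @param mode \code{"unit"} or \code{"dual"} normalizers (see Details).
#' @return A \code{table_factorization} with fields \code{left_diag},
#'   \code{proportion}, \code{right_diag}, \code{n1}, \code{n2},
#'   \code{side}, \code{mode}.
#' @examples
#' f <- factorize(count_table(10, 30, 30, 20), "column", "dual")
#' rowSums(f$proportion)  # 1 1
#' @export
factorize <- function(x, side = c("column", "row"), mode = c("unit", "dual")) {
  stopifnot(inherits(x, "count_table2x2"))
  side <- match.arg(side)
  mode <- match.arg(mode)
  a <- x$a; b <- x$b; c <- x$c; d <- x$d
  if (side == "column") {
    if (any(x$col_sums <= 0))
      stop_zero_margin("factorization by column sums needs positive column sums")
    if (mode == "unit") {
      n1 <- 1; n2 <- 1
    } else {
      n1 <- a / (a + c) + b / (b + d)
      n2 <- c / (a + c) + d / (b + d)
      if (n1 <= 0 || n2 <= 0)
        stop_degenerate("zero dual normalizer: a table row is empty")
    }
    prop <- matrix(c(a / (n1 * (a + c)), b / (n1 * (b + d)),
                     c / (n2 * (a + c)), d / (n2 * (b + d))),
                   nrow = 2, byrow = TRUE)
    left <- c(n1, n2)
    right <- x$col_sums
  } else {
    if (any(x$row_sums <= 0))
      stop_zero_margin("factorization by row sums needs positive row sums")
    if (mode == "unit") {
      n1 <- 1; n2 <- 1
    } else {
      n1 <- a / (a + b) + c / (c + d)
      n2 <- b / (a + b) + d / (c + d)
      if (n1 <= 0 || n2 <= 0)
        stop_degenerate("zero dual normalizer: a table column is empty")
    }
    prop <- matrix(c(a / (n1 * (a + b)), b / (n2 * (a + b)),
                     c / (n1 * (c + d)), d / (n2 * (c + d))),
                   nrow = 2, byrow = TRUE)
    left <- x$row_sums
    right <- c(n1, n2)
  }
  structure(
    list(side = side, mode = mode, left_diag = left, proportion = prop,
         right_diag = right, n1 = n1, n2 = n2, source = as.matrix(x)),
    class = "table_factorization")
}

#' Reconstruct the source table from a factorization
#' @param f A \code{table_factorization}.
#' @return The 2x2 numeric matrix \code{diag(left) P diag(right)}.
#' @export
reconstruct <- function(f) {
  stopifnot(inherits(f, "table_factorization"))
  diag(f$left_diag) %*% f$proportion %*% diag(f$right_diag)
}

#' @export
print.table_factorization <- function(x, ...) {
  cat(sprintf("%s-sum factorization (%s normalizers; n1 = %.6g, n2 = %.6g)\n",
              x$side, x$mode, x$n1, x$n2))
  print(x$proportion)
  invisible(x)
}

#' Unitary diagonal scaling of a 2x2 table
#'
#' Maps (a, b, c, d) to (k a, b/j, j c, d/k) for j, k > 0.  This scaling
#' sweeps out the equivalence class of tables sharing the odds ratio
#' ad/bc, which it preserves exactly, while proportions and margins change.
#'
#' @param x A \code{count_table2x2}.
#' @param j,k Positive scale factors for the off-diagonal and diagonal.
#' @return The scaled \code{count_table2x2}.
#' @export
u_scale <- function(x, j, k) {
  stopifnot(inherits(x, "count_table2x2"))
  j <- check_scalar(j, "j"); k <- check_scalar(k, "k")
  if (j <= 0 || k <= 0) stop_domain("u_scale needs j > 0 and k > 0")
  count_table(k * x$a, x$b / j, j * x$c, x$d / k)
}

#' Yule symmetrization of a 2x2 table
#'
#' Geometric averaging of the diagonal and off-diagonal products: returns
#' the table (sqrt(ad), sqrt(bc) / sqrt(bc), sqrt(ad)), the unique
#' diagonally symmetric member of the odds-ratio equivalence class.  All
#' four marginal sums equal sqrt(ad) + sqrt(bc); the proportional
#' difference of this table is the coefficient of colligation.
#'
#' @param x A \code{count_table2x2}.
#' @return A diagonally symmetric \code{count_table2x2}.
#' @export
yule_symmetrize <- function(x) {
  stopifnot(inherits(x, "count_table2x2"))
  s_ad <- sqrt(x$a * x$d)
  s_bc <- sqrt(x$b * x$c)
  count_table(s_ad, s_bc, s_bc, s_ad)
}

#' Marginal-sum ratio product
#'
#' omega_M = (a+b)(c+d) / ((a+c)(b+d)) quantifies the imbalance between row
#' and column sums; it equals 1 when the row-sum pair matches the
#' column-sum pair and enters the margin factors of the phi decomposition.
#'
#' @param x A \code{count_table2x2}.
#' @return A positive number.
#' @export
marginal_ratio <- function(x) {
  stopifnot(inherits(x, "count_table2x2"))
  if (any(x$col_sums <= 0) || any(x$row_sums <= 0))
    stop_zero_margin("marginal_ratio needs all four marginal sums positive")
  prod(x$row_sums) / prod(x$col_sums)
}
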