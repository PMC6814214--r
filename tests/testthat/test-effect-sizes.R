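test_that("simplex_pair extracts the documented coordinates per form", {
  t <- fig_table()
  sp <- simplex_pair(t, "csum_rows")
  expect_equal(sp$p_alpha, 10 / (0.85 * 40), tolerance = 1e-9)  # 0.294118
  expect_equal(sp$p_beta, 30 / (1.15 * 40), tolerance = 1e-9)   # 0.652174
  sp <- simplex_pair(t, "csum_cols")
  expect_equal(c(sp$p_alpha, sp$p_beta), c(0.6, 0.25), tolerance = 1e-12)
  sp <- simplex_pair(t, "rsum_rows")
  expect_equal(c(sp$p_alpha, sp$p_beta), c(0.6, 0.25), tolerance = 1e-12)
  sp <- simplex_pair(t, "rsum_cols")
  expect_equal(c(sp$p_alpha, sp$p_beta),
               c(30 / (1.15 * 40), 10 / (0.85 * 40)), tolerance = 1e-9)
  u <- count_table(5, 5, 5, 5)
  for (form in c("csum_rows", "csum_cols", "rsum_rows", "rsum_cols"))
    expect_equal(unlist(simplex_pair(u, form)[c("p_alpha", "p_beta")]),
                 c(p_alpha = 0.5, p_beta = 0.5), tolerance = 1e-12)
})

test_that("com_coords gives the published center-of-mass values", {
  cc <- com_coords(simplex_pair(fig_table(), "csum_rows"))
  expect_equal(cc$delta, 0.179028, tolerance = 1e-6)
  expect_equal(cc$mu, 0.473146, tolerance = 1e-6)
  expect_equal(cc$displacement, 2 * cc$delta)
  flat <- com_coords(structure(list(p_alpha = 0.3, p_beta = 0.3,
                                    form = "csum_cols"),
                               class = "simplex_pair"))
  expect_equal(flat$delta, 0)
  expect_equal(flat$mu, 0.3)
  ext <- com_coords(structure(list(p_alpha = 0, p_beta = 1,
                                   form = "csum_cols"),
                              class = "simplex_pair"))
  expect_equal(c(ext$delta, ext$mu), c(0.5, 0.5))
})

test_that("scalar measures match direct arithmetic and boundaries", {
  t <- fig_table()
  expect_equal(odds_ratio(t), 2 / 9, tolerance = 1e-12)
  expect_equal(odds_ratio(count_table(5, 5, 5, 5)), 1)
  expect_equal(odds_ratio(count_table(2, 0, 0, 3)), Inf)
  expect_equal(odds_ratio(count_table(0, 2, 3, 0)), 0)
  expect_error(odds_ratio(count_table(0, 2, 0, 2)),
               class = "proptab_undefined_error")

  expect_equal(yules_q(t), -7 / 11, tolerance = 1e-12)
  expect_equal(yules_q(count_table(5, 5, 5, 5)), 0)
  expect_equal(yules_q(count_table(2, 0, 0, 3)), 1)
  expect_error(yules_q(count_table(0, 2, 0, 2)),
               class = "proptab_undefined_error")

  expect_equal(relative_risk(t), 0.25 / 0.6, tolerance = 1e-12)
  expect_equal(relative_risk(count_table(5, 5, 5, 5)), 1)
  expect_equal(relative_risk(t, "csum_rows"),
               (10 / (0.85 * 40)) / (30 / (1.15 * 40)), tolerance = 1e-12)

  expect_equal(phi_coef(t), -0.35, tolerance = 1e-12)
  expect_equal(phi_coef(count_table(2, 0, 0, 3)), 1)
  expect_equal(phi_coef(count_table(5, 5, 5, 5)), 0)
  expect_error(phi_coef(count_table(0, 5, 0, 5)),
               class = "proptab_zero_margin_error")
})

test_that("perspective measures reproduce table-level statistics", {
  # published example, delta flipped to a-minus-c orientation
  cc <- com_coords(simplex_pair(fig_table(), "csum_rows"))
  pm <- perspective_measures(list(delta = -cc$delta, mu = cc$mu))
  expect_equal(pm$omega, 2 / 9, tolerance = 1e-9)
  expect_equal(pm$q, -7 / 11, tolerance = 1e-9)

  null_pm <- perspective_measures(list(delta = 0, mu = 0.3))
  expect_equal(unlist(null_pm), c(omega = 1, q = 0, rho = 1, ratio_diff = 0))

  tabs <- property_tables(1000)
  for (i in seq_len(nrow(tabs))) {
    t <- row_table(tabs, i)
    cc <- com_coords(simplex_pair(t, "csum_rows"))
    pm <- perspective_measures(list(delta = -cc$delta, mu = cc$mu))
    ad <- t$a * t$d; bc <- t$b * t$c
    if (bc > 0) expect_rel(pm$omega, ad / bc, 1e-10)
    expect_rel(pm$q, (ad - bc) / (ad + bc), 1e-10)
  }
})

test_that("the linear-fractional identities hold for every form", {
  tabs <- property_tables(400, seed = 77)
  for (i in seq_len(nrow(tabs))) {
    t <- row_table(tabs, i)
    for (form in c("csum_rows", "csum_cols", "rsum_rows", "rsum_cols")) {
      sp <- simplex_pair(t, form)
      cc <- com_coords(sp)
      pm <- perspective_measures(cc)
      # delta^2 - delta/Q + mu(1-mu) = 0
      if (is.finite(pm$q) && pm$q != 0)
        expect_rel(cc$delta^2 - cc$delta / pm$q + cc$mu * (1 - cc$mu), 0, 1e-10)
      # delta (rho + 1) - mu (rho - 1) = 0
      if (is.finite(pm$rho))
        expect_rel(cc$delta * (pm$rho + 1) - cc$mu * (pm$rho - 1), 0, 1e-10)
      # ratio difference equals the definitional beta - alpha (away from
      # the simplex boundary, where both forms blow up)
      if (sp$p_alpha < 1 - 1e-6 && sp$p_beta < 1 - 1e-6) {
        beta_alpha <- sp$p_beta / (1 - sp$p_beta) - sp$p_alpha / (1 - sp$p_alpha)
        expect_rel(pm$ratio_diff, beta_alpha, 1e-10)
      }
    }
  }
})

test_that("phi factors into a margin factor times a displacement", {
  t <- fig_table()
  pf <- phi_factorization(t, "rsum")
  expect_equal(pf$displacement, -0.358056, tolerance = 1e-6)
  expect_equal(pf$m_factor, 0.9775, tolerance = 1e-10)  # 1955/2000
  expect_equal(pf$m_factor * pf$displacement, -0.35, tolerance = 1e-10)
  expect_equal(phi_factorization(t, "csum")$m_factor, 0.9775,
               tolerance = 1e-10)

  sym <- count_table(4, 9, 9, 4)  # diagonally symmetric: M = 1, D = phi
  for (form in c("rsum", "csum")) {
    pf <- phi_factorization(sym, form)
    expect_equal(pf$m_factor, 1, tolerance = 1e-12)
    expect_equal(pf$displacement, phi_coef(sym), tolerance = 1e-12)
  }

  tabs <- property_tables(1000)
  for (i in seq_len(nrow(tabs))) {
    t <- row_table(tabs, i)
    for (form in c("rsum", "csum")) {
      pf <- phi_factorization(t, form)
      expect_rel(pf$m_factor * pf$displacement, phi_coef(t), 1e-10)
    }
  }
})

test_that("delta_s of the symmetrized table is the coefficient of colligation", {
  t <- fig_table()
  expect_equal(delta_s(yule_symmetrize(t)),
               (sqrt(200) - 30) / (sqrt(200) + 30), tolerance = 1e-9)
  expect_equal(delta_s(yule_symmetrize(count_table(2, 0, 0, 3))), 1)
  expect_equal(delta_s(yule_symmetrize(count_table(3, 3, 3, 3))), 0)

  tabs <- property_tables(300, seed = 42)
  for (i in seq_len(nrow(tabs))) {
    t <- row_table(tabs, i)
    w <- t$a * t$d / (t$b * t$c)
    if (!is.finite(w)) next
    expect_rel(delta_s(yule_symmetrize(t)),
               (sqrt(w) - 1) / (sqrt(w) + 1), 1e-10)
    # and it equals phi of the symmetrized table
    ys <- yule_symmetrize(t)
    if (all(ys$row_sums > 0) && all(ys$col_sums > 0))
      expect_rel(delta_s(ys), phi_coef(ys), 1e-10)
  }
})

test_that("simple matching decomposes by rows and columns", {
  t <- fig_table()
  sm <- simple_matching(t)
  expect_equal(sm$s_m, 1 / 3, tolerance = 1e-12)
  expect_equal(sum(sm$row$weights * sm$row$proportions), sm$s_m,
               tolerance = 1e-12)
  expect_equal(sum(sm$column$weights * sm$column$proportions), sm$s_m,
               tolerance = 1e-12)
  expect_equal(sm$row$weights, c(40, 50) / 90)
  expect_equal(sm$row$proportions, c(0.25, 0.4))
  expect_equal(simple_matching(count_table(5, 5, 5, 5))$s_m, 0.5)
  # doubling row 1 changes s_M: margin dependence witness
  expect_equal(simple_matching(count_table(20, 60, 30, 20))$s_m, 40 / 130,
               tolerance = 1e-12)
})

test_that("rxc measures collapse to phi for 2x2 and match a brute-force tau", {
  t <- fig_table()
  r <- rxc_measures(t)
  expect_equal(r$cramers_v, 0.35, tolerance = 1e-10)
  expect_equal(r$tau_col, 0.1225, tolerance = 1e-10)
  expect_equal(r$tau_row, 0.1225, tolerance = 1e-10)
  expect_equal(r$chi2, 90 * 0.1225, tolerance = 1e-10)

  u <- rxc_measures(count_table(5, 5, 5, 5))
  expect_equal(c(u$chi2, u$cramers_v, u$tau_col, u$tau_row), rep(0, 4))

  # independent brute-force Goodman-Kruskal tau from its definition:
  # expected proportion of wrong guesses under proportional prediction,
  # unconditionally vs conditionally on the other variable
  gk_tau <- function(m, predict_cols = TRUE) {
    if (!predict_cols) m <- t(m)
    p <- m / sum(m)
    err_uncond <- 0
    for (j in seq_len(ncol(p))) err_uncond <- err_uncond +
        sum(p[, j]) * (1 - sum(p[, j]))
    err_cond <- 0
    for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
      pi <- sum(p[i, ])
      err_cond <- err_cond + p[i, j] * (1 - p[i, j] / pi)
    }
    (err_uncond - err_cond) / err_uncond
  }
  m23 <- matrix(c(2, 3, 5, 4, 1, 5), nrow = 2, byrow = TRUE)
  r23 <- rxc_measures(m23)
  expect_equal(r23$tau_col, gk_tau(m23, TRUE), tolerance = 1e-12)
  expect_equal(r23$tau_row, gk_tau(m23, FALSE), tolerance = 1e-12)
  expect_equal(r23$chi2, suppressWarnings(chisq.test(m23, correct = FALSE))$statistic[[1]],
               tolerance = 1e-10)

  tabs <- property_tables(200, seed = 8)
  for (i in seq_len(nrow(tabs))) {
    t <- row_table(tabs, i)
    r <- rxc_measures(t)
    phi <- phi_coef(t)
    expect_rel(r$cramers_v, abs(phi), 1e-10)
    expect_rel(r$tau_col, phi^2, 1e-10)
    expect_rel(r$tau_row, phi^2, 1e-10)
  }
})

test_that("invariance matrix: what scaling leaves what unchanged", {
  t <- fig_table()
  set.seed(31)
  tabs <- property_tables(100, seed = 31)
  for (i in seq_len(nrow(tabs))) {
    tt <- row_table(tabs, i)
    s <- runif(1, 0.2, 5)
    tc <- count_table(tt$a, s * tt$b, tt$c, s * tt$d)  # rescale column 2
    for (form in c("csum_rows", "csum_cols")) {
      c0 <- com_coords(simplex_pair(tt, form))
      c1 <- com_coords(simplex_pair(tc, form))
      expect_rel(c(c1$delta, c1$mu), c(c0$delta, c0$mu), 1e-12)
    }
    tr <- count_table(tt$a, tt$b, s * tt$c, s * tt$d)  # rescale row 2
    for (form in c("rsum_rows", "rsum_cols")) {
      c0 <- com_coords(simplex_pair(tt, form))
      c1 <- com_coords(simplex_pair(tr, form))
      expect_rel(c(c1$delta, c1$mu), c(c0$delta, c0$mu), 1e-12)
    }
    # omega and Q invariant under u-scaling
    j <- runif(1, 0.2, 5); k <- runif(1, 0.2, 5)
    tu <- u_scale(tt, j, k)
    if (tt$b * tt$c > 0) expect_rel(odds_ratio(tu), odds_ratio(tt), 1e-10)
    expect_rel(yules_q(tu), yules_q(tt), 1e-10)
  }
  # explicit non-invariance witnesses under u_scale(j = 2, k = 3):
  # phi moves by ~0.06, RR by ~0.32, s_M by ~0.005 -- all clearly nonzero
  tu <- u_scale(t, 2, 3)
  expect_gt(abs(phi_coef(tu) - phi_coef(t)), 1e-3)
  expect_gt(abs(simple_matching(tu)$s_m - simple_matching(t)$s_m), 1e-3)
  expect_gt(abs(relative_risk(tu) - relative_risk(t)), 1e-3)
})

test_that("the effect-size report is internally consistent", {
  t <- fig_table()
  rep <- effect_sizes(t, qualitative = TRUE)
  expect_equal(rep$omega, 2 / 9, tolerance = 1e-12)
  expect_equal(rep$phi, -0.35, tolerance = 1e-12)
  expect_equal(rep$omega_m, 1)
  for (form in names(rep$forms)) {
    f <- rep$forms[[form]]
    expect_equal(f$m_factor * f$displacement, rep$phi, tolerance = 1e-10)
    expect_true(abs(f$delta) <= 0.5 + 1e-12)
    expect_true(f$mu >= 0 && f$mu <= 1)
  }
  expect_equal(rep$forms$csum_rows$delta, 0.179028, tolerance = 1e-6)
  expect_equal(rep$qualitative$phi, "medium")
})
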