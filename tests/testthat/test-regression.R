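test_that("OLS matches the normal-equations oracle to high precision", {
  set.seed(61)
  n <- 50
  X <- cbind(intercept = 1, a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- drop(X %*% c(2, 1, -1, 0.5)) + rnorm(n)
  f <- fit_ols(y, X)
  XtXi <- solve(t(X) %*% X)
  beta_o <- drop(XtXi %*% t(X) %*% y)
  res_o <- y - drop(X %*% beta_o)
  s2_o <- sum(res_o^2) / (n - 4)
  expect_equal(unname(f$coefficients), unname(beta_o), tolerance = 1e-10)
  expect_equal(unname(f$se), unname(sqrt(diag(s2_o * XtXi))), tolerance = 1e-10)
  r2_o <- 1 - sum(res_o^2) / sum((y - mean(y))^2)
  expect_equal(f$adj_r2, 1 - (1 - r2_o) * (n - 1) / (n - 4), tolerance = 1e-10)
  ll_o <- -n / 2 * (log(2 * pi) + log(sum(res_o^2) / n) + 1)
  expect_equal(f$aic, 2 * 5 - 2 * ll_o, tolerance = 1e-10)

  # exact linear data
  f0 <- fit_ols(drop(X %*% c(1, 2, 3, 4)), X)
  expect_equal(max(abs(f0$residuals)), 0, tolerance = 1e-10)
  expect_equal(f0$r2, 1, tolerance = 1e-12)

  # intercept-only model estimates the mean
  fm <- fit_ols(y, cbind(intercept = rep(1, n), z = rnorm(n) * 0 + rnorm(n)))
  fi <- fit_ols(y, matrix(1, n, 1, dimnames = list(NULL, "intercept")))
  expect_equal(unname(fi$coefficients), mean(y), tolerance = 1e-12)

  Xbad <- cbind(X, dup = X[, "a"])
  expect_error(fit_ols(y, Xbad), "dup")
})

test_that("SAR profile likelihood reduces to OLS at rho = 0 and matches GLS at fixed rho", {
  lat <- generate_lattice(8, 8, 2)
  W <- row_standardize(contiguity_weights(lat, "rook"))
  X <- std_design(lat, seed = 71)
  tr <- truth_record("sar_lag", c(1, -0.5, 0.3), rho = 0.4, sigma2 = 1, seed = 72)
  y <- simulate_outcome(lat, X, W, tr)

  f0 <- fit_sar_lag(y, X, W, rho_fixed = 0, compute_se = FALSE)
  ols <- fit_ols(y, X)
  expect_equal(f0$loglik, ols$loglik, tolerance = 1e-10)  # log-det term vanishes
  expect_equal(unname(f0$coefficients), unname(ols$coefficients), tolerance = 1e-10)

  rho <- 0.3
  fr <- fit_sar_lag(y, X, W, rho_fixed = rho, compute_se = FALSE)
  yf <- y - rho * spatial_lag(W, y)
  expect_equal(unname(fr$coefficients),
               unname(solve(t(X) %*% X, t(X) %*% yf)[, 1]), tolerance = 1e-10)

  expect_error(fit_sar_lag(y, X, contiguity_weights(lat, "rook")),
               "row-standardized")
})

test_that("SAR maximum likelihood recovers a known lag coefficient", {
  lat <- generate_lattice(15, 15, 3)
  W <- row_standardize(contiguity_weights(lat, "rook"))
  X <- std_design(lat, seed = 81)
  tr <- truth_record("sar_lag", c(1, -0.5, 0.3), rho = 0.6, sigma2 = 1, seed = 82)
  y <- simulate_outcome(lat, X, W, tr)
  f <- fit_sar_lag(y, X, W)
  expect_lt(abs(f$rho - 0.6), 3 * f$rho_se)
  expect_true(all(f$se > 0))
  expect_false(f$boundary)
  # deterministic: repeated fits are identical
  expect_identical(f$rho, fit_sar_lag(y, X, W)$rho)
})

test_that("GWR equals the per-unit weighted-least-squares oracle", {
  lat <- generate_lattice(5, 5, 5)
  co <- as.matrix(lat$units[c("cx", "cy")])
  set.seed(91)
  X <- cbind(intercept = 1, x1 = rnorm(25), x2 = rnorm(25))
  y <- drop(X %*% c(1, 2, -1)) + rnorm(25)
  g <- fit_gwr(y, X, co, fraction = 0.4)
  for (i in 1:25) {
    kw <- adaptive_kernel(co, i, 0.4)
    expect_equal(unname(g$beta[i, ]), unname(oracle_wls(X, y, kw$w)),
                 tolerance = 1e-10)
  }
  # residuals equal (I - S) y with hat rows assembled independently
  S <- t(vapply(1:25, function(i) {
    w <- adaptive_kernel(co, i, 0.4)$w
    Xw <- X * w
    drop(X[i, ] %*% solve(t(X) %*% Xw, t(Xw)))
  }, numeric(25)))
  expect_equal(g$residuals, drop((diag(25) - S) %*% y), tolerance = 1e-8)
  expect_equal(g$trS, sum(diag(S)), tolerance = 1e-8)
})

test_that("GWR collapses to OLS in the uniform-kernel limit", {
  lat <- generate_lattice(6, 4, 2)
  co <- as.matrix(lat$units[c("cx", "cy")])
  X <- std_design(lat, seed = 95)
  set.seed(96)
  y <- drop(X %*% c(1, 0.5, -0.5)) + rnorm(24)
  g <- fit_gwr(y, X, co, fraction = 1, kernel = "uniform")
  ols <- fit_ols(y, X)
  expect_lt(max(abs(sweep(g$beta, 2, ols$coefficients))), 1e-8)
  expect_equal(g$trS, ncol(X), tolerance = 1e-8)
  expect_equal(g$aic, ols$aic, tolerance = 1e-8)
})

test_that("bandwidth selection widens on stationary data and narrows under gradients", {
  lat <- generate_lattice(12, 12, 3)
  co <- as.matrix(lat$units[c("cx", "cy")])
  X <- std_design(lat, seed = 101, spatial_share = 0.5)
  n <- nrow(X)
  stat_tr <- truth_record("iid", c(1, -0.5, 0.3), sigma2 = 0.5, seed = 102)
  y_stat <- simulate_outcome(lat, X, truth = stat_tr)
  gu <- coef_surface_linear(lat, 0, 1, 0)
  B <- cbind(1, -0.5 + 1.5 * gu, 0.3)
  vc_tr <- truth_record("varying_coefficients", beta = B, sigma2 = 0.5, seed = 102)
  y_vc <- simulate_outcome(lat, X, truth = vc_tr)
  bw_stat <- select_bandwidth(y_stat, X, co, search = c(0.06, 1))
  bw_vc <- select_bandwidth(y_vc, X, co, search = c(0.06, 1))
  # stationary truth: wide window whose criterion is flat up to the global fit
  expect_gt(bw_stat$fraction, 0.3)
  aicc_global <- spalos:::gwr_aicc_at_k(y_stat, X, co, n, 0L)
  expect_lt(aicc_global - bw_stat$aicc, 2)
  expect_lt(bw_vc$fraction, bw_stat$fraction)

  pt <- select_bandwidth(y_stat, X, co, search = c(0.25, 0.25))
  expect_equal(pt$k, ceiling(0.25 * n))  # collapsed interval returns that point
  expect_error(select_bandwidth(y_stat, X, co, search = c(0.001, 0.002)),
               "infeasible")
  expect_error(fit_gwr(y_stat, X, co, fraction = 0.01), "minimum feasible")
})

test_that("GWR significance adjustment and ridge options behave sanely", {
  lat <- generate_lattice(6, 6, 2)
  co <- as.matrix(lat$units[c("cx", "cy")])
  X <- std_design(lat, seed = 131)
  set.seed(132)
  y <- drop(X %*% c(1, 0.5, -0.5)) + rnorm(36)
  g0 <- fit_gwr(y, X, co, fraction = 0.4)
  gbh <- fit_gwr(y, X, co, fraction = 0.4, adjust = "BH")
  expect_true(all(gbh$p >= g0$p - 1e-15))       # BH never shrinks p-values
  expect_lte(sum(gbh$significant), sum(g0$significant))
  # a tiny ridge leaves a well-conditioned fit essentially unchanged
  gr <- fit_gwr(y, X, co, fraction = 0.4, ridge = 1e-10)
  expect_equal(gr$beta, g0$beta, tolerance = 1e-6)
  # an exactly collinear design fails without ridge and runs with it
  Xc <- cbind(X, dup = X[, 2])
  expect_error(fit_gwr(y, Xc, co, fraction = 0.5), "singular")
  expect_s3_class(fit_gwr(y, Xc, co, fraction = 0.5, ridge = 1e-6), "gwr_fit")
})
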