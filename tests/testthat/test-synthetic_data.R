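test_that("lattice construction counts fine and coarse units correctly", {
  lat <- generate_lattice(4, 4, 2)
  expect_equal(nrow(lat$units), 16)
  expect_equal(length(unique(lat$units$coarse_id)), 4)
  expect_equal(unname(table(lat$units$coarse_id)), rep(4L, 4),
               ignore_attr = TRUE)

  lat2 <- generate_lattice(2, 2, 2)
  nm <- nesting_map(lat2)
  expect_length(nm, 4)
  expect_equal(length(unique(nm)), 1)

  expect_error(generate_lattice(3, 4, 2), "divide")
  expect_error(generate_lattice(1, 4, 1), ">= 2")
})

test_that("lattice polygons tile without overlap and centroids sit in cells", {
  lat <- generate_lattice(3, 2, 1)
  expect_false(anyDuplicated(lat$units$unit_id) > 0)
  areas <- vapply(seq_len(nrow(lat$units)), function(i) {
    ring <- unit_polygon(lat, i)
    # shoelace
    abs(sum(ring[-nrow(ring), 1] * ring[-1, 2] -
              ring[-1, 1] * ring[-nrow(ring), 2])) / 2
  }, numeric(1))
  expect_equal(sum(areas), lat$nx * lat$ny)  # exact tiling of the extent
  expect_true(all(lat$units$cx > 0 & lat$units$cx < lat$nx))
})

test_that("population generator matches its stated distribution moments", {
  lat <- generate_lattice(40, 25, 5)  # 1000 units
  pop <- generate_population(lat, mean_pop = 50, dispersion = Inf, seed = 7)
  # Poisson limit: each group mean within 3 standard errors of mean_pop
  se <- sqrt(50 / 1000)
  for (cc in c("pop_75_84", "pop_85_94", "pop_95p"))
    expect_lt(abs(mean(pop[[cc]]) - 50), 3 * se)
  # overdispersed draws have variance well above the mean
  pod <- generate_population(lat, mean_pop = 50, dispersion = 1, seed = 7)
  expect_gt(stats::var(pod$pop_75_84), 2 * mean(pod$pop_75_84))

  expect_identical(generate_population(lat, 50, 1.2, seed = 3),
                   generate_population(lat, 50, 1.2, seed = 3))
  expect_error(generate_population(lat, 0), "mean_pop")
})

test_that("covariate generator respects correlation targets and bounds", {
  lat <- generate_lattice(40, 25, 5)
  cv <- generate_covariates(lat, diag(3), seed = 5, spatial_share = 0)
  M <- as.matrix(cv[, -1])
  expect_true(all(M > 0 & M < 100))
  cors <- stats::cor(M)
  expect_true(all(abs(cors[upper.tri(cors)]) < 0.1))

  # strongly correlated pair triggers the downstream VIF screen
  R <- matrix(c(1, 0.98, 0.98, 1), 2)
  cv2 <- generate_covariates(lat, R, seed = 5, spatial_share = 0)
  M2 <- as.matrix(cv2[, -1])
  expect_gt(oracle_vif(M2, 1), 10)

  expect_identical(generate_covariates(lat, diag(2), seed = 9),
                   generate_covariates(lat, diag(2), seed = 9))
  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(generate_covariates(lat, bad), "semi-definite")
})

test_that("outcome simulation honours its degeneracies and error contracts", {
  lat <- generate_lattice(6, 6, 2)
  W <- row_standardize(contiguity_weights(lat, "rook"))
  X <- std_design(lat, seed = 2)
  beta <- c(1, -0.5, 0.3)

  y0 <- simulate_outcome(lat, X, truth = truth_record("iid", beta, sigma2 = 0, seed = 4))
  expect_equal(unname(y0), drop(X %*% beta), tolerance = 1e-12)

  t_iid <- truth_record("iid", beta, sigma2 = 1, seed = 11)
  t_sar0 <- truth_record("sar_lag", beta, rho = 0, sigma2 = 1, seed = 11)
  expect_equal(simulate_outcome(lat, X, truth = t_iid),
               simulate_outcome(lat, X, W, t_sar0), tolerance = 1e-12)

  expect_error(truth_record("sar_lag", beta, rho = 1.0), "rho")
  expect_error(simulate_outcome(lat, X, contiguity_weights(lat, "rook"),
                                truth_record("sar_lag", beta, rho = 0.5)),
               "row-standardized")
})

test_that("spatial-lag data induce positive OLS residual autocorrelation", {
  lat <- generate_lattice(20, 20, 4)
  W <- row_standardize(contiguity_weights(lat, "rook"))
  X <- std_design(lat, seed = 21)
  tr <- truth_record("sar_lag", c(1, -0.5, 0.3), rho = 0.7, sigma2 = 1, seed = 22)
  y <- simulate_outcome(lat, X, W, tr)
  m <- morans_i(fit_ols(y, X)$residuals, W, n_perm = 0)
  expect_gt(m$I, 0)
  expect_lt(m$p_analytic, 0.01)
})
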