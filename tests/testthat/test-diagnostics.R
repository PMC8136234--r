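test_that("global Moran's I reproduces closed-form values", {
  Wt <- row_standardize(grid_contiguity(6, 6, "rook", torus = TRUE))
  ix <- rep(1:6, 6); iy <- rep(1:6, each = 6)
  chk <- ifelse((ix + iy) %% 2 == 0, 1, -1)
  m <- morans_i(chk, Wt, n_perm = 99, seed = 2)
  expect_equal(m$I, -1, tolerance = 1e-12)       # every neighbour is opposite
  expect_equal(m$expected, -1 / 35)

  set.seed(3)
  W <- row_standardize(grid_contiguity(5, 5, "rook"))
  x <- rnorm(25)
  m2 <- morans_i(x, W, n_perm = 0)
  expect_equal(m2$I, oracle_moran(x, W), tolerance = 1e-12)
  expect_error(morans_i(rep(2, 25), W), "constant")
})

test_that("the permutation null is centred on -1/(n-1)", {
  W <- row_standardize(grid_contiguity(8, 8, "rook"))
  set.seed(4)
  x <- rnorm(64)
  m <- morans_i(x, W, n_perm = 999, seed = 5)
  se_mc <- sd(m$I_perm) / sqrt(length(m$I_perm))
  expect_lt(abs(mean(m$I_perm) - (-1 / 63)), 3 * se_mc)
  expect_gte(m$p_permutation, 1 / 1000)
  # seed-deterministic
  expect_identical(m$p_permutation,
                   morans_i(x, W, n_perm = 999, seed = 5)$p_permutation)
})

test_that("Moran's I of a lag-process surface increases with rho", {
  lat <- generate_lattice(10, 10, 2)
  W <- row_standardize(contiguity_weights(lat, "rook"))
  X0 <- matrix(0, 100, 1)
  means <- vapply(c(0, 0.4, 0.8), function(rho) {
    mean(vapply(1:30, function(r) {
      tr <- truth_record("sar_lag", beta = 0, rho = rho, sigma2 = 1,
                         seed = 5000 + 100 * rho + r)
      morans_i(simulate_outcome(lat, X0, W, tr), W, n_perm = 0)$I
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("local Moran satisfies the sum identity and labels sign quadrants", {
  W <- row_standardize(grid_contiguity(7, 5, "queen"))
  set.seed(6)
  x <- rnorm(35)
  cm <- local_morans(x, W, n_perm = 99, seed = 7)
  expect_equal(sum(cm$table$local_i), 35 * cm$I_global, tolerance = 1e-10)
  expect_equal(cm$I_global, oracle_moran(x, W), tolerance = 1e-12)

  # antithetic checkerboard: only HL/LH can be significant
  Wt <- row_standardize(grid_contiguity(8, 8, "rook", torus = TRUE))
  ix <- rep(1:8, 8); iy <- rep(1:8, each = 8)
  chk <- ifelse((ix + iy) %% 2 == 0, 1, -1) + rnorm(64, 0, 1e-6)
  cmc <- local_morans(chk, Wt, n_perm = 199, alpha = 0.05, seed = 8)
  expect_equal(sum(cmc$table$local_i), 64 * cmc$I_global, tolerance = 1e-10)
  expect_true(all(cmc$table$label %in% c("HL", "LH", "none")))
  expect_gt(sum(cmc$table$label != "none"), 0)
})

test_that("a planted hot block is recovered as an HH core", {
  lat <- generate_lattice(10, 10, 2)
  W <- row_standardize(contiguity_weights(lat, "rook"))
  set.seed(99)
  x <- rnorm(100, 0, 0.5)
  blk <- which(lat$units$ix %in% 4:6 & lat$units$iy %in% 4:6)
  x[blk] <- 3 + rnorm(9, 0, 0.2)
  cm <- local_morans(x, W, n_perm = 999, alpha = 0.01, seed = 7)
  core <- which(lat$units$ix == 5 & lat$units$iy == 5)
  expect_equal(cm$table$label[core], "HH")
  expect_lt(cm$table$p[core], 0.01)
  # ring just outside the block sits in the low-high quadrant
  z <- x - mean(x)
  lag <- spatial_lag(W, z)
  ring <- which(pmax(abs(lat$units$ix - 5), abs(lat$units$iy - 5)) == 2)
  face <- ring[abs(lat$units$ix[ring] - 5) + abs(lat$units$iy[ring] - 5) == 2 &
                 (lat$units$ix[ring] == 5 | lat$units$iy[ring] == 5)]
  expect_true(all(z[face] < 0 & lag[face] > 0))   # LH quadrant
  expect_true(all(cm$table$label[ring] %in% c("LH", "none")))
  # far field stays unlabelled
  far <- which(pmax(abs(lat$units$ix - 5), abs(lat$units$iy - 5)) >= 4)
  expect_true(all(cm$table$label[far] == "none"))
})

test_that("the GWR Monte-Carlo p-value respects the permutation floor", {
  lat <- generate_lattice(10, 10, 2)
  co <- as.matrix(lat$units[c("cx", "cy")])
  X <- std_design(lat, seed = 11, spatial_share = 0.5)
  gu <- coef_surface_linear(lat, 0, 1, 0)
  tr <- truth_record("varying_coefficients",
                     beta = cbind(1, -0.5 + 2 * gu, 0.3),
                     sigma2 = 0.05, seed = 12)
  y <- simulate_outcome(lat, X, truth = tr)
  mc <- gwr_monte_carlo(y, X, co, fraction = 0.2, n_perm = 19, seed = 13)
  # the gradient coefficient beats all 19 permutations: p at its floor 1/20
  expect_equal(mc$table$p[2], 1 / 20)
  expect_true(all(mc$table$p >= 1 / 20 & mc$table$p <= 1))
  expect_error(gwr_monte_carlo(y, X, co, fraction = 0.2, n_perm = 5), "19")
})

test_that("model comparison ranks by AIC with stable ties", {
  lat <- generate_lattice(6, 6, 2)
  W <- row_standardize(contiguity_weights(lat, "rook"))
  set.seed(14)
  mock <- function(name, aic, n = 36) {
    structure(list(model = name, adj_r2 = 0.5, aic = aic,
                   residuals = rnorm(n), n = n), class = "global_fit")
  }
  fits <- list(ols = mock("ols", 3285.273), sar = mock("sar", 2238.65),
               gwr = mock("gwr", 539.139))
  cmp <- compare_models(fits, W, n_perm = 0)
  expect_identical(cmp$model, c("gwr", "sar", "ols"))
  expect_identical(cmp$rank, 1:3)

  tied <- compare_models(list(first = mock("a", 10), second = mock("a", 10)),
                         W, n_perm = 0)
  expect_identical(tied$model, c("first", "second"))
  expect_error(compare_models(list(a = mock("a", 1), b = mock("b", 2, n = 20)),
                              W, n_perm = 0), "different unit sets")
})

test_that("scale comparison reports percent changes and significance counts", {
  f1 <- structure(list(coefficients = c(i = 1, x = 2), se = c(i = 1, x = 1),
                       model = "ols"), class = "global_fit")
  f2 <- structure(list(coefficients = c(i = 1, x = 2), se = c(i = 2, x = 2),
                       model = "ols"), class = "global_fit")
  sc <- scale_comparison(f1, f2)
  expect_equal(sc$table$se_change_pct, c(-50, -50))
  expect_equal(sc$table$beta_change_pct, c(0, 0))
  same <- scale_comparison(f1, f1)
  expect_true(all(same$table$se_change_pct == 0))
  f3 <- f2; names(f3$coefficients) <- c("i", "zzz")
  expect_error(scale_comparison(f1, f3), "coefficient names")
})
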