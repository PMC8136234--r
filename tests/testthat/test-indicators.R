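pop1 <- data.frame(unit_id = "U1", pop_75_84 = 8, pop_85_94 = 0, pop_95p = 0)

test_that("the LOS indicator follows its printed definition", {
  stays <- data.frame(unit_id = "U1", age_group = "75_84",
                      avg_stay = 2.0, n_inpatients = 3)
  expect_equal(compute_los(stays, pop1)$los, 0.25)   # 2.0 / 8

  # no inpatients anywhere -> zero indicator
  empty <- data.frame(unit_id = character(), age_group = character(),
                      avg_stay = numeric(), n_inpatients = integer())
  expect_equal(compute_los(empty, pop1)$los, 0)

  pop3 <- data.frame(unit_id = "U1", pop_75_84 = 100, pop_85_94 = 50, pop_95p = 10)
  stays3 <- data.frame(unit_id = "U1",
                       age_group = c("75_84", "85_94", "95p"),
                       avg_stay = c(10, 20, 30), n_inpatients = c(5, 5, 5))
  expect_equal(compute_los(stays3, pop3)$los, 0.1 + 0.4 + 3.0)

  # total-days mode multiplies by inpatient counts first
  expect_equal(compute_los(stays3, pop3, mode = "total_days")$los,
               (10 * 5) / 100 + (20 * 5) / 50 + (30 * 5) / 10)

  bad_pop <- data.frame(unit_id = "U1", pop_75_84 = 0, pop_85_94 = 5, pop_95p = 0)
  expect_error(compute_los(stays, bad_pop), "zero population")
})

test_that("the indicator is additive over groups and degree-1 in stay length", {
  set.seed(17)
  pop <- data.frame(unit_id = paste0("U", 1:6),
                    pop_75_84 = sample(5:50, 6), pop_85_94 = sample(5:50, 6),
                    pop_95p = sample(1:20, 6))
  stays <- expand.grid(unit_id = pop$unit_id,
                       age_group = c("75_84", "85_94", "95p"),
                       stringsAsFactors = FALSE)
  stays$avg_stay <- runif(nrow(stays), 1, 30)
  stays$n_inpatients <- sample(1:9, nrow(stays), replace = TRUE)
  full <- compute_los(stays, pop)$los
  parts <- Reduce(`+`, lapply(c("75_84", "85_94", "95p"), function(g)
    compute_los(stays[stays$age_group == g, ], pop)$los))
  expect_equal(full, parts, tolerance = 1e-12)
  doubled <- stays; doubled$avg_stay <- 2 * stays$avg_stay
  expect_equal(compute_los(doubled, pop)$los, 2 * full, tolerance = 1e-12)
})

test_that("stay tables built from a LOS vector reproduce it exactly", {
  lat <- generate_lattice(4, 4, 2)
  pop <- generate_population(lat, 40, 2, seed = 3)
  los <- setNames(rexp(16, 1), pop$unit_id)
  stays <- stays_from_los(los, pop)
  expect_equal(compute_los(stays, pop)$los, unname(los), tolerance = 1e-12)
})

test_that("log transform applies the configured zero policy", {
  expect_equal(log_transform(1)$values, 0)
  lt <- log_transform(c(a = 0, b = 2), policy = "drop")
  expect_false(lt$kept[["a"]])
  expect_true(is.na(lt$values[["a"]]))
  expect_equal(log_transform(0, policy = "offset", offset = 0.01)$values,
               log(0.01))
  expect_error(log_transform(c(u1 = 0, u2 = 1), policy = "error"), "u1")
})

test_that("VIF screening matches the auxiliary-regression oracle", {
  set.seed(23)
  n <- 200
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n))))[, 2:4]  # orthogonal, centred
  colnames(Q) <- c("a", "b", "c")
  v0 <- vif_screen(Q)
  expect_equal(unname(v0$vif), rep(1, 3), tolerance = 1e-10)
  expect_identical(v0$retained, c("a", "b", "c"))

  # exact linear combination is removed first
  X <- cbind(Q, d = Q[, 1] + 2 * Q[, 2])
  v1 <- vif_screen(X)
  expect_true(is.infinite(max(v1$vif_initial)))
  expect_true(v1$removed[1] %in% c("a", "b", "d"))
  expect_true(all(v1$vif < 10))

  # two-column closed form 1/(1 - r^2)
  z1 <- rnorm(n); z2 <- 0.9 * z1 + sqrt(1 - 0.81) * rnorm(n)
  X2 <- cbind(p = z1, q = z2)
  r <- cor(z1, z2)
  v2 <- vif_screen(X2, threshold = Inf)
  expect_equal(unname(v2$vif), rep(1 / (1 - r^2), 2), tolerance = 1e-10)
  expect_equal(unname(v2$vif[1]), oracle_vif(X2, 1), tolerance = 1e-10)

  # invariance to column rescaling
  v3 <- vif_screen(sweep(X2, 2, c(100, 0.001), "*"), threshold = Inf)
  expect_equal(v2$vif, v3$vif, tolerance = 1e-8, ignore_attr = TRUE)

  expect_error(vif_screen(cbind(x = rep(1, n), y = rnorm(n))), "constant")
})

test_that("LOS summaries agree with direct computation", {
  set.seed(5)
  v <- rlnorm(200)
  s <- los_summary(v)
  expect_equal(s$n, 200)
  expect_equal(s$mean, mean(v))
  expect_equal(s$sd, sd(v))
  expect_equal(s$median, unname(quantile(v, 0.5)))
  expect_equal(s$max, max(v))
})
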