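#' Global Moran's I with analytic and permutation inference
#'
#' `I = (n/S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z = x - mean(x)`
#' and `S0 = sum_ij w_ij`. The analytic p-value uses the normal
#' approximation under the randomization assumption; the permutation
#' p-value is two-sided around the randomization expectation `-1/(n-1)`:
#' `p = (1 + #{|I_perm - E| >= |I_obs - E|}) / (n_perm + 1)`.
#'
#' @param x Per-unit numeric vector with positive variance.
#' @param W Row-standardized `spw` weights.
#' @param n_perm Number of random permutations (0 disables).
#' @param seed Integer seed for the permutations.
#' @return An object of class `moran_result`: `I`, `expected`, `variance`,
#'   `z`, `p_analytic`, `p_permutation`, `n_perm`, `seed`.
#' @export
morans_i <- function(x, W, n_perm = 999, seed = 1L) {
  stopifnot(inherits(W, "spw"))
  n <- length(x)
  if (length(W$ids) != n) stop("x and W have different lengths")
  if (stats::var(x) == 0)
    stop("x is constant: spatial autocorrelation is undefined at zero variance")
  Wm <- spw_matrix(W)
  z <- x - mean(x)
  S0 <- spw_total(W)
  m2 <- sum(z^2)
  I_of <- function(zz) (n / S0) * sum(zz * as.numeric(Wm %*% zz)) / sum(zz^2)
  I <- I_of(z)
  # randomization moments
  Wd <- Wm + Matrix::t(Wm)
  S1 <- sum(Wd * Wd) / 2
  rs <- Matrix::rowSums(Wm); cs <- Matrix::colSums(Wm)
  S2 <- sum((rs + cs)^2)
  b2 <- n * sum(z^4) / m2^2
  EI <- -1 / (n - 1)
  VI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
           b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
  zstat <- (I - EI) / sqrt(VI)
  p_an <- 2 * stats::pnorm(-abs(zstat))
  p_perm <- NA_real_
  Iperm <- NULL
  if (n_perm > 0) {
    set.seed(as.integer(seed))
    Iperm <- vapply(seq_len(n_perm), function(m) I_of(z[sample.int(n)]),
                    numeric(1))
    p_perm <- (1 + sum(abs(Iperm - EI) >= abs(I - EI))) / (n_perm + 1)
  }
  structure(list(I = I, expected = EI, variance = VI, z = zstat,
                 p_analytic = p_an, p_permutation = p_perm,
                 n_perm = n_perm, seed = seed, I_perm = Iperm),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Global Moran's I = %.4f (E = %.4f, z = %.3f, p_analytic = %.4g",
              x$I, x$expected, x$z, x$p_analytic))
  if (!is.na(x$p_permutation))
    cat(sprintf(", p_perm = %.4g [%d perms]", x$p_permutation, x$n_perm))
  cat(")\n")
  invisible(x)
}

#' Local Moran's I (LISA) cluster map
#'
#' `I_i = (z_i / m2) sum_j w_ij z_j` with `m2 = sum(z^2)/n`. Inference is by
#' conditional permutation (the focal value is held fixed and the remaining
#' values are permuted among the other units), the GeoDa convention, with
#' the p-value one-sided in the direction of the observed local statistic.
#' Units with `p_i < alpha` are labelled by the sign quadrant of
#' `(z_i, lag z_i)`: HH, LL, HL or LH; all other units are `"none"`.
#'
#' @param x Per-unit numeric vector with positive variance.
#' @param W Row-standardized `spw` weights.
#' @param n_perm Number of conditional permutations per unit.
#' @param alpha Label significance level (default 0.01).
#' @param seed Integer seed.
#' @return An object of class `cluster_map`: data frame `table` with
#'   `unit_id`, `local_i`, `p`, `label`, plus `I_global`, `alpha`, `n_perm`.
#' @export
local_morans <- function(x, W, n_perm = 999, alpha = 0.01, seed = 1L) {
  stopifnot(inherits(W, "spw"))
  n <- length(x)
  if (length(W$ids) != n) stop("x and W have different lengths")
  if (stats::var(x) == 0) stop("x is constant")
  z <- x - mean(x)
  m2 <- sum(z^2) / n
  lag <- spatial_lag(W, z)
  Ii <- z / m2 * lag
  set.seed(as.integer(seed))
  p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    wi <- W$wts[[i]]
    ki <- length(wi)
    if (ki == 0) next
    zo <- z[-i]
    lag_perm <- vapply(seq_len(n_perm), function(m)
      sum(wi * zo[sample.int(n - 1, ki)]), numeric(1))
    Ip <- z[i] / m2 * lag_perm
    if (Ii[i] >= 0) p[i] <- (1 + sum(Ip >= Ii[i])) / (n_perm + 1)
    else            p[i] <- (1 + sum(Ip <= Ii[i])) / (n_perm + 1)
  }
  label <- rep("none", n)
  sig <- !is.na(p) & p < alpha
  label[sig & z > 0 & lag > 0] <- "HH"
  label[sig & z < 0 & lag < 0] <- "LL"
  label[sig & z > 0 & lag < 0] <- "HL"
  label[sig & z < 0 & lag > 0] <- "LH"
  I_global <- (n / spw_total(W)) * sum(z * lag) / sum(z^2)
  structure(list(table = data.frame(unit_id = W$ids, local_i = Ii, p = p,
                                    label = label, stringsAsFactors = FALSE),
                 I_global = I_global, alpha = alpha, n_perm = n_perm,
                 seed = seed),
            class = "cluster_map")
}

#' @export
print.cluster_map <- function(x, ...) {
  cat("LISA cluster map (alpha =", x$alpha, ",", x$n_perm, "permutations)\n")
  print(table(x$table$label))
  cat("sum(I_i) =", round(sum(x$table$local_i), 4),
      " n * I_global =", round(nrow(x$table) * x$I_global, 4), "\n")
  invisible(x)
}

#' Monte-Carlo test of GWR coefficient spatial variability
#'
#' Tests, per coefficient, whether the spatial variation of the local GWR
#' estimates exceeds what is expected in the absence of spatial structure.
#' The observed statistic is the variance across units of `beta_k(i)`. Under
#' the null, the geographical coordinates carry no information, so they are
#' permuted jointly (one random permutation of the coordinate rows per
#' iteration), the GWR is refitted at the same adaptive neighbour count, and
#' the statistic recomputed. `p = (1 + #{stat_perm >= stat_obs}) /
#' (n_perm + 1)`.
#'
#' @param y,X,centroids,fraction,kernel As in [fit_gwr()].
#' @param n_perm Number of coordinate permutations (>= 19).
#' @return An object of class `variability_test`: data frame `table` with
#'   `coefficient`, `observed_var`, `p`; plus `n_perm`, `seed`.
#' @export
gwr_monte_carlo <- function(y, X, centroids, fraction, n_perm = 99,
                            kernel = c("gaussian", "bisquare"), seed = 1L) {
  kernel <- match.arg(kernel)
  if (n_perm < 19) stop("n_perm must be >= 19")
  X <- as.matrix(X); centroids <- as.matrix(centroids)
  n <- length(y); p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p) - 1L)
  k <- gwr_k(fraction, n, p, kernel)
  kern_code <- match(kernel, c("gaussian", "bisquare", "uniform")) - 1L
  stat_of <- function(co) {
    B <- gwr_core(X, y, co, k, kern_code, 0L)$beta
    apply(B, 2, stats::var)
  }
  obs <- stat_of(centroids)
  set.seed(as.integer(seed))
  ge <- rep(0L, p)
  for (m in seq_len(n_perm)) {
    sp <- stat_of(centroids[sample.int(n), , drop = FALSE])
    ge <- ge + as.integer(sp >= obs)
  }
  pvals <- (1 + ge) / (n_perm + 1)
  structure(list(table = data.frame(coefficient = colnames(X),
                                    observed_var = obs, p = pvals,
                                    stringsAsFactors = FALSE),
                 n_perm = n_perm, seed = seed, fraction = fraction),
            class = "variability_test")
}

#' @export
print.variability_test <- function(x, ...) {
  cat("GWR Monte-Carlo non-stationarity test (", x$n_perm, "permutations)\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Model comparison report
#'
#' Tabulates adjusted R2, AIC (plus AICc for GWR) and residual Moran's I for
#' a set of fitted models sharing the same units and outcome, ranked by AIC
#' (lowest first; ties keep input order). GWR residuals are taken from the
#' accumulated hat rows, `(I - S) y`, and tested with the same weights as
#' the global models for comparability.
#'
#' @param fits Named list of `global_fit` / `gwr_fit` objects.
#' @param W Row-standardized `spw` weights used for the residual Moran
#'   tests.
#' @param n_perm Permutations for the residual Moran tests.
#' @param seed Integer seed.
#' @return An object of class `model_comparison` (a data frame with one row
#'   per model, ordered by AIC, plus a `rank` column).
#' @export
compare_models <- function(fits, W, n_perm = 999, seed = 1L) {
  stopifnot(is.list(fits), length(fits) >= 1)
  if (is.null(names(fits)))
    names(fits) <- vapply(fits, function(f) f$model, character(1))
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) != 1)
    stop("fits cover different unit sets (n = ",
         paste(unique(ns), collapse = ", "), ")")
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    mi <- morans_i(f$residuals, W, n_perm = n_perm, seed = seed)
    data.frame(model = names(fits)[i],
               adj_r2 = f$adj_r2,
               aic = f$aic,
               aicc = if (!is.null(f$aicc)) f$aicc else NA_real_,
               resid_moran_i = mi$I,
               resid_moran_p = if (n_perm > 0) mi$p_permutation else mi$p_analytic,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ord <- order(tab$aic)                   # stable: ties keep input order
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  class(tab) <- c("model_comparison", "data.frame")
  tab
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison (ranked by AIC):\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Fine-versus-coarse scale comparison of a global fit
#'
#' Per-coefficient percent change in the estimate,
#' `(fine - coarse) / |coarse| * 100`, and in the standard error, plus
#' counts of significant coefficients (two-sided normal approximation) at
#' alpha 0.05 and 0.01 at each scale.
#'
#' @param fit_fine,fit_coarse `global_fit` objects over the same covariate
#'   set.
#' @return An object of class `scale_comparison`: data frame `table` and
#'   significance counts `n_sig`.
#' @export
scale_comparison <- function(fit_fine, fit_coarse) {
  cn <- names(fit_fine$coefficients)
  if (!identical(cn, names(fit_coarse$coefficients)))
    stop("coefficient names differ between scales")
  pf <- 2 * stats::pnorm(-abs(fit_fine$coefficients / fit_fine$se))
  pc <- 2 * stats::pnorm(-abs(fit_coarse$coefficients / fit_coarse$se))
  tab <- data.frame(
    coefficient = cn,
    beta_fine = unname(fit_fine$coefficients),
    beta_coarse = unname(fit_coarse$coefficients),
    beta_change_pct = unname((fit_fine$coefficients - fit_coarse$coefficients) /
                               abs(fit_coarse$coefficients) * 100),
    se_fine = unname(fit_fine$se),
    se_coarse = unname(fit_coarse$se),
    se_change_pct = unname((fit_fine$se - fit_coarse$se) /
                             fit_coarse$se * 100),
    stringsAsFactors = FALSE
  )
  n_sig <- c(fine_05 = sum(pf < 0.05), coarse_05 = sum(pc < 0.05),
             fine_01 = sum(pf < 0.01), coarse_01 = sum(pc < 0.01))
  structure(list(table = tab, n_sig = n_sig), class = "scale_comparison")
}

#' @export
print.scale_comparison <- function(x, ...) {
  cat("Scale comparison (fine vs coarse):\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat("significant coefficients:",
      paste(names(x$n_sig), x$n_sig, sep = "=", collapse = "  "), "\n")
  invisible(x)
}
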