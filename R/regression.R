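#' Ordinary least squares fit
#'
#' QR-based least squares with classical standard errors
#' `se = sqrt(diag(sigma2_hat (X'X)^{-1}))`, `sigma2_hat = RSS / (n - p)`,
#' adjusted R2 `1 - (1 - R2)(n - 1)/(n - p)` and Gaussian log-likelihood AIC
#' `2k - 2 logLik` with `k = p + 1` (all coefficients plus the error
#' variance).
#'
#' @param y Numeric response vector.
#' @param X Design matrix including the intercept column; must have full
#'   column rank.
#' @return An object of class `global_fit` with elements `model`,
#'   `coefficients`, `se`, `sigma2`, `residuals`, `fitted`, `r2`, `adj_r2`,
#'   `loglik`, `aic`, `n`, `p`.
#' @export
fit_ols <- function(y, X) {
  X <- as.matrix(X)
  n <- length(y); p <- ncol(X)
  if (nrow(X) != n) stop("y and X have different lengths")
  if (n <= p + 1) stop("need n > p + 1 observations")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p) - 1L)
  qx <- qr(X)
  if (qx$rank < p) {
    dep <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    stop("design matrix is rank deficient; dependent column(s): ",
         paste(dep, collapse = ", "))
  }
  beta <- qr.coef(qx, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  sigma2 <- rss / (n - p)
  XtXinv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * diag(XtXinv))
  r2 <- 1 - rss / tss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p)
  loglik <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  structure(list(model = "ols", coefficients = stats::setNames(beta, colnames(X)),
                 se = stats::setNames(se, colnames(X)), sigma2 = sigma2,
                 vcov = sigma2 * XtXinv,
                 residuals = res, fitted = fitted, r2 = r2, adj_r2 = adj_r2,
                 loglik = loglik, aic = 2 * (p + 1) - 2 * loglik,
                 n = n, p = p),
            class = "global_fit")
}

#' @export
print.global_fit <- function(x, ...) {
  cat("Model:", toupper(x$model), " n =", x$n, "\n")
  tab <- data.frame(coef = x$coefficients, se = x$se)
  print(round(tab, 4))
  if (!is.null(x$rho))
    cat("rho =", round(x$rho, 4), "( se", round(x$rho_se, 4), ")\n")
  cat("adj R2 =", round(x$adj_r2, 4), " AIC =", round(x$aic, 3),
      " logLik =", round(x$loglik, 3), "\n")
  invisible(x)
}

# Real eigenvalues of a row-standardized contiguity matrix via the similar
# symmetric matrix D^{1/2} W D^{-1/2} when the underlying binary relation is
# symmetric; falls back to a dense nonsymmetric eigendecomposition.
spw_eigenvalues <- function(W) {
  deg <- lengths(W$nb)
  if (any(deg == 0)) stop("eigenvalue bounds undefined with isolated units")
  Wm <- as.matrix(spw_matrix(W))
  s <- sqrt(deg)
  Msym <- sweep(sweep(Wm, 1, s, "*"), 2, s, "/")
  if (isTRUE(all.equal(Msym, t(Msym), tolerance = 1e-10))) {
    eigen(Msym, symmetric = TRUE, only.values = TRUE)$values
  } else {
    ev <- eigen(Wm, only.values = TRUE)$values
    if (any(abs(Im(ev)) > 1e-8))
      warning("complex eigenvalues of W; using real parts")
    sort(Re(ev), decreasing = TRUE)
  }
}

# Golden-section minimization of a univariate function on [lo, hi].
golden_section <- function(f, lo, hi, tol = 1e-8, maxit = 200L) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  it <- 0L
  while (b - a > tol && it < maxit) {
    if (f1 <= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    }
    it <- it + 1L
  }
  xm <- (a + b) / 2
  list(minimum = xm, objective = f(xm))
}

#' Maximum-likelihood spatial-lag (SAR) fit
#'
#' Fits `y = rho W y + X beta + eps` by profile maximum likelihood. The
#' concentrated log-likelihood over rho,
#' `L(rho) = const - (n/2) log(RSS(rho)/n) + log|I - rho W|`,
#' uses the closed-form residual cross-products of the regressions of `y`
#' and `Wy` on `X`, and the log-determinant from the (real) eigenvalues of
#' the row-standardized weight matrix. rho is searched on the eigenvalue
#' support `(1/lambda_min, 1)` by golden-section to tolerance 1e-8.
#' Asymptotic standard errors come from the inverse information matrix of
#' `(beta, rho, sigma2)`.
#'
#' @param y Numeric response vector.
#' @param X Design matrix including the intercept.
#' @param W Row-standardized `spw` weights.
#' @param ev Optional precomputed eigenvalues of `W` (reused across
#'   replicate fits on a fixed lattice).
#' @param rho_fixed If supplied, skips the likelihood search and profiles at
#'   this rho (the filtered-regression / GLS solution).
#' @param compute_se Compute asymptotic standard errors (inverts a dense
#'   n x n matrix; disable in tight simulation loops).
#' @param tol Golden-section tolerance on rho.
#' @return A `global_fit` with additional elements `rho`, `rho_se`,
#'   `loglik`, `aicc = NULL`, residuals `y - rho W y - X beta`, fitted
#'   values `rho W y + X beta`, and a `boundary` flag set when the optimum
#'   lies at the search boundary. `adj_r2` is a pseudo value based on the
#'   squared correlation of observed and fitted outcomes.
#' @export
fit_sar_lag <- function(y, X, W, ev = NULL, rho_fixed = NULL,
                        compute_se = TRUE, tol = 1e-8) {
  stopifnot(inherits(W, "spw"))
  if (W$style != "row_standardized")
    stop("W must be row-standardized for the SAR lag model")
  X <- as.matrix(X)
  n <- length(y); p <- ncol(X)
  if (length(W$ids) != n) stop("W and y have different lengths")
  if (n <= p + 2) stop("need n > p + 2 observations")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p) - 1L)
  Wm <- spw_matrix(W)
  Wy <- as.numeric(Wm %*% y)
  qx <- qr(X)
  if (qx$rank < p) stop("design matrix is rank deficient")
  b0 <- qr.coef(qx, y);  e0 <- y - drop(X %*% b0)
  b1 <- qr.coef(qx, Wy); e1 <- Wy - drop(X %*% b1)
  c00 <- sum(e0^2); c01 <- sum(e0 * e1); c11 <- sum(e1^2)
  if (is.null(ev)) ev <- spw_eigenvalues(W)
  lo <- 1 / min(ev) + 1e-9
  hi <- 1 - 1e-9
  rss_of <- function(rho) c00 - 2 * rho * c01 + rho^2 * c11
  negll_conc <- function(rho)
    (n / 2) * log(rss_of(rho) / n) - sum(log(1 - rho * ev))

  boundary <- FALSE
  if (is.null(rho_fixed)) {
    opt <- golden_section(negll_conc, lo, hi, tol = tol)
    rho <- opt$minimum
    if (rho - lo < 1e-5 || hi - rho < 1e-5) {
      boundary <- TRUE
      warning("SAR optimum at the rho search boundary")
    }
  } else {
    if (rho_fixed <= lo || rho_fixed >= hi)
      stop("rho_fixed outside the feasible interval (", signif(lo, 4), ", 1)")
    rho <- rho_fixed
  }
  beta <- b0 - rho * b1
  res <- e0 - rho * e1                    # y - rho W y - X beta
  rss <- sum(res^2)
  sigma2 <- rss / n
  loglik <- -n / 2 * (log(2 * pi * sigma2) + 1) + sum(log(1 - rho * ev))
  k <- p + 2                              # beta, rho, sigma2
  fitted <- rho * Wy + drop(X %*% beta)
  r2 <- stats::cor(y, fitted)^2
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p - 1)

  se <- rep(NA_real_, p); rho_se <- NA_real_; vcov <- NULL
  if (compute_se) {
    A <- diag(n) - rho * as.matrix(Wm)
    WA <- as.matrix(Wm %*% solve(A))
    Xb <- drop(X %*% beta)
    P <- drop(WA %*% Xb)
    trWA <- sum(diag(WA))
    trWA2 <- sum(WA * t(WA))              # tr(WA %*% WA)
    trWAtWA <- sum(WA * WA)               # tr(WA' WA)
    info <- matrix(0, p + 2, p + 2)
    info[1:p, 1:p] <- crossprod(X) / sigma2
    info[1:p, p + 1] <- info[p + 1, 1:p] <- drop(crossprod(X, P)) / sigma2
    info[p + 1, p + 1] <- trWA2 + trWAtWA + sum(P^2) / sigma2
    info[p + 1, p + 2] <- info[p + 2, p + 1] <- trWA / sigma2
    info[p + 2, p + 2] <- n / (2 * sigma2^2)
    vcov <- solve(info)
    se <- sqrt(diag(vcov)[1:p])
    rho_se <- sqrt(vcov[p + 1, p + 1])
  }
  structure(list(model = "sar_lag",
                 coefficients = stats::setNames(beta, colnames(X)),
                 se = stats::setNames(se, colnames(X)),
                 rho = rho, rho_se = rho_se, sigma2 = sigma2, vcov = vcov,
                 residuals = res, fitted = fitted, r2 = r2, adj_r2 = adj_r2,
                 loglik = loglik, aic = 2 * k - 2 * loglik,
                 boundary = boundary, rho_interval = c(lo, hi),
                 n = n, p = p),
            class = "global_fit")
}

#' Geographically weighted regression fit
#'
#' Local weighted least squares at every unit with an adaptive kernel
#' ([adaptive_kernel()]): `beta(i) = (X'W_i X)^{-1} X'W_i y`. The hat rows
#' `s_i = x_i (X'W_i X)^{-1} X'W_i` give the effective number of parameters
#' `tr(S)`; `sigma2_hat = RSS / (n - tr(S))`; per-coefficient standard
#' errors come from the sandwich `C_i C_i' sigma2_hat` with
#' `C_i = (X'W_i X)^{-1} X'W_i`, and pseudo-t `beta_k(i)/se_k(i)` is flagged
#' significant at `alpha` (default 0.05, unadjusted across units).
#' `AICc = 2n log(sigma_hat) + n log(2 pi) + n (n + tr(S))/(n - 2 - tr(S))`;
#' an OLS-comparable `aic = 2 (tr(S) + 1) - 2 logLik(RSS/n)` is also
#' reported, which reduces exactly to the OLS AIC in the uniform-kernel
#' limit.
#'
#' @param y Numeric response vector.
#' @param X Design matrix including the intercept.
#' @param centroids Two-column coordinate matrix.
#' @param fraction Adaptive bandwidth as a fraction of n; the neighbour
#'   count is `k = ceiling(fraction * n)` and must be at least `p + 2`.
#' @param kernel `"gaussian"` (default), `"bisquare"` or `"uniform"` (all
#'   weights one: the global OLS limit).
#' @param alpha Significance level for the pseudo-t flags.
#' @param adjust Multiple-testing adjustment for the per-unit significance
#'   flags: `"none"` (default, the convention for local-coefficient maps)
#'   or `"BH"` (Benjamini-Hochberg across units, per coefficient).
#' @param ridge Optional nonnegative ridge added to the local `X'WX` before
#'   solving; 0 (default) means singular local designs are an error. Enable
#'   only deliberately: regularization changes the local estimand.
#' @return An object of class `gwr_fit`: per-unit coefficient matrix `beta`,
#'   `se`, `tstat`, `significant`, `local_r2`, `bandwidth` (per-unit),
#'   `hat_diag`, `trS`, `trStS`, `sigma2`, `residuals`, `fitted`, `rss`,
#'   `r2`, `adj_r2` (using effective degrees of freedom
#'   `n - 2 tr(S) + tr(S'S)`), `aic`, `aicc`, `fraction`, `k`.
#' @export
fit_gwr <- function(y, X, centroids, fraction,
                    kernel = c("gaussian", "bisquare", "uniform"),
                    alpha = 0.05, adjust = c("none", "BH"), ridge = 0) {
  kernel <- match.arg(kernel)
  adjust <- match.arg(adjust)
  if (ridge < 0) stop("ridge must be >= 0")
  X <- as.matrix(X); centroids <- as.matrix(centroids)
  n <- length(y); p <- ncol(X)
  if (nrow(X) != n || nrow(centroids) != n)
    stop("y, X and centroids must have matching lengths")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p) - 1L)
  k <- gwr_k(fraction, n, p, kernel)
  kern_code <- match(kernel, c("gaussian", "bisquare", "uniform")) - 1L
  core <- gwr_core(X, y, centroids, k, kern_code, 2L, ridge)
  core[c("yhat", "hat_diag", "bandwidth", "local_r2")] <-
    lapply(core[c("yhat", "hat_diag", "bandwidth", "local_r2")], as.numeric)
  res <- y - core$yhat
  rss <- sum(res^2)
  trS <- sum(core$hat_diag)
  if (n - trS <= 2) stop("effective degrees of freedom too small; increase fraction")
  sigma2 <- rss / (n - trS)
  se <- sqrt(core$cc * sigma2)
  tstat <- core$beta / se
  pvals <- 2 * stats::pnorm(-abs(tstat))
  if (adjust == "BH") pvals <- apply(pvals, 2, stats::p.adjust, method = "BH")
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  edf <- n - 2 * trS + core$trStS
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (edf - 1)
  aicc <- 2 * n * log(sqrt(sigma2)) + n * log(2 * pi) +
    n * (n + trS) / (n - 2 - trS)
  loglik_ml <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  aic <- 2 * (trS + 1) - 2 * loglik_ml
  dimnames(core$beta) <- dimnames(se) <- dimnames(tstat) <-
    list(NULL, colnames(X))
  structure(list(model = "gwr", beta = core$beta, se = se, tstat = tstat,
                 p = pvals, significant = pvals < alpha,
                 local_r2 = core$local_r2, bandwidth = core$bandwidth,
                 hat_diag = core$hat_diag, trS = trS, trStS = core$trStS,
                 sigma2 = sigma2, residuals = res, fitted = core$yhat,
                 rss = rss, r2 = r2, adj_r2 = adj_r2, aic = aic, aicc = aicc,
                 fraction = fraction, k = k, kernel = kernel, alpha = alpha,
                 n = n, p = p),
            class = "gwr_fit")
}

#' @export
print.gwr_fit <- function(x, ...) {
  cat("GWR fit: n =", x$n, " k =", x$k,
      sprintf("(fraction %.4g, %s kernel)\n", x$fraction, x$kernel))
  cat("tr(S) =", round(x$trS, 2), " adj R2 =", round(x$adj_r2, 4),
      " AICc =", round(x$aicc, 3), " AIC =", round(x$aic, 3), "\n")
  cat("coefficient ranges:\n")
  print(apply(x$beta, 2, range))
  invisible(x)
}

# neighbour count from a bandwidth fraction, with feasibility check
gwr_k <- function(fraction, n, p, kernel = "gaussian") {
  if (kernel == "uniform") return(n)
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  k <- as.integer(ceiling(fraction * n))
  if (k < p + 2)
    stop("fraction * n = ", k, " < p + 2 = ", p + 2,
         "; minimum feasible fraction is ", signif((p + 2) / n, 4))
  k
}

# AICc of a GWR fit at a given neighbour count (light evaluation)
gwr_aicc_at_k <- function(y, X, centroids, k, kern_code) {
  n <- length(y)
  core <- gwr_core(X, y, centroids, k, kern_code, 1L)
  rss <- sum((y - core$yhat)^2)
  trS <- sum(core$hat_diag)
  if (n - trS <= 2 || rss <= 0) return(Inf)
  sigma2 <- rss / (n - trS)
  2 * n * log(sqrt(sigma2)) + n * log(2 * pi) + n * (n + trS) / (n - 2 - trS)
}

#' Select the GWR adaptive bandwidth by AICc
#'
#' Minimizes the corrected Akaike criterion over the adaptive neighbour
#' count. A coarse scan over log-spaced candidate counts brackets the
#' minimum, which is then refined by golden-section over the integer
#' neighbour count; when no interior bracket exists the scan falls back to a
#' dense grid of 40 log-spaced fractions. Deterministic.
#'
#' @param y,X,centroids As in [fit_gwr()].
#' @param search Length-2 numeric, lower/upper bandwidth fractions.
#' @param kernel `"gaussian"` or `"bisquare"`.
#' @return List with `fraction`, `k`, `aicc` and `method`
#'   (`"golden_section"` or `"grid"`).
#' @export
select_bandwidth <- function(y, X, centroids, search = c(0.05, 1),
                             kernel = c("gaussian", "bisquare")) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X); centroids <- as.matrix(centroids)
  n <- length(y); p <- ncol(X)
  kern_code <- match(kernel, c("gaussian", "bisquare", "uniform")) - 1L
  klo <- max(p + 2L, as.integer(ceiling(search[1] * n)))
  khi <- as.integer(ceiling(search[2] * n))
  if (khi < klo) stop("search interval infeasible: lower bound k = ", klo,
                      " exceeds upper bound k = ", khi)
  if (khi == klo)
    return(list(fraction = klo / n, k = klo,
                aicc = gwr_aicc_at_k(y, X, centroids, klo, kern_code),
                method = "point"))
  cache <- new.env(parent = emptyenv())
  f <- function(k) {
    key <- as.character(k)
    if (is.null(cache[[key]]))
      cache[[key]] <- gwr_aicc_at_k(y, X, centroids, as.integer(k), kern_code)
    cache[[key]]
  }
  ks <- unique(round(exp(seq(log(klo), log(khi), length.out = 12))))
  vals <- vapply(ks, f, numeric(1))
  imin <- which.min(vals)
  if (imin == 1 || imin == length(ks)) {
    # minimum at the scan edge: refine the edge cell by a dense grid
    ks2 <- unique(round(exp(seq(log(klo), log(khi), length.out = 40))))
    vals2 <- vapply(ks2, f, numeric(1))
    kbest <- ks2[which.min(vals2)]
    return(list(fraction = kbest / n, k = kbest, aicc = f(kbest),
                method = "grid"))
  }
  a <- ks[imin - 1]; b <- ks[imin + 1]
  gr <- (sqrt(5) - 1) / 2
  x1 <- round(b - gr * (b - a)); x2 <- round(a + gr * (b - a))
  while (b - a > 2) {
    if (x1 == x2) x2 <- x1 + 1L
    if (f(x1) <= f(x2)) { b <- x2 } else { a <- x1 }
    x1 <- round(b - gr * (b - a)); x2 <- round(a + gr * (b - a))
  }
  cand <- a:b
  kbest <- cand[which.min(vapply(cand, f, numeric(1)))]
  list(fraction = kbest / n, k = kbest, aicc = f(kbest),
       method = "golden_section")
}
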