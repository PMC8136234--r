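# Shared fixtures and independent oracles.
# Oracles deliberately avoid the package's computation paths: dense matrix
# algebra and explicit loops only.

# standardized covariate design (intercept + 2 columns) on a lattice
std_design <- function(lattice, seed, spatial_share = 0.3) {
  cv <- generate_covariates(lattice, diag(2), seed = seed,
                            spatial_share = spatial_share)
  cbind(intercept = 1,
        x1 = as.numeric(scale(cv$non_owner)),
        x2 = as.numeric(scale(cv$precarious)))
}

# dense spatial lag oracle
oracle_lag <- function(W, x) as.numeric(as.matrix(spw_matrix(W)) %*% x)

# global Moran's I by dense double loop
oracle_moran <- function(x, W) {
  Wm <- as.matrix(spw_matrix(W))
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in 1:n) for (j in 1:n) num <- num + Wm[i, j] * z[i] * z[j]
  (n / sum(Wm)) * num / sum(z^2)
}

# weighted least squares by explicit normal equations
oracle_wls <- function(X, y, w) {
  Xw <- X * w
  solve(t(X) %*% Xw, t(Xw) %*% y)[, 1]
}

# E2SFCA by explicit two-step double loop
oracle_e2sfca <- function(cap, P, tt, zones) {
  zw <- function(t) {
    for (z in seq_len(nrow(zones)))
      if (t <= zones$threshold[z]) return(zones$weight[z])
    0
  }
  nj <- length(cap); ni <- length(P)
  R <- numeric(nj)
  for (j in 1:nj) {
    d <- 0
    for (i in 1:ni) d <- d + P[i] * zw(tt[i, j])
    R[j] <- cap[j] / d
  }
  A <- numeric(ni)
  for (i in 1:ni) {
    for (j in 1:nj) A[i] <- A[i] + R[j] * zw(tt[i, j])
    A[i] <- 10000 * A[i]
  }
  A
}

# VIF by auxiliary regression through lm()
oracle_vif <- function(X, k) {
  df <- as.data.frame(X)
  names(df) <- paste0("v", seq_len(ncol(X)))
  f <- stats::as.formula(paste0("v", k, " ~ ",
                                paste0("v", setdiff(seq_len(ncol(X)), k),
                                       collapse = " + ")))
  1 / (1 - summary(stats::lm(f, df))$r.squared)
}
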