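#' Generate a two-level regular areal lattice
#'
#' Builds a regular grid of square fine units (census-block analogues) nested
#' in square blocks of coarse units (postal-code analogues). Every fine unit
#' belongs to exactly one coarse unit; polygons tile the region without
#' overlap. Cell side length is 1 map unit; centroids are at cell centres.
#'
#' @param n_fine_x,n_fine_y Number of fine units along each axis (>= 2).
#' @param coarse_block Side length, in fine units, of each coarse block; must
#'   divide both `n_fine_x` and `n_fine_y`.
#' @param seed Integer seed, kept for interface uniformity (the lattice itself
#'   is deterministic).
#' @return An object of class `area_lattice`: a list with `units` (data frame
#'   with `unit_id`, `coarse_id`, centroid coordinates `cx`, `cy` and grid
#'   indices `ix`, `iy`), dimensions `nx`, `ny`, `coarse_block` and
#'   `cell_size`.
#' @examples
#' lat <- generate_lattice(4, 4, 2)
#' nrow(lat$units)                   # 16 fine units
#' length(unique(lat$units$coarse_id))  # 4 coarse units
#' @export
generate_lattice <- function(n_fine_x, n_fine_y, coarse_block, seed = 1L) {
  stopifnot(length(n_fine_x) == 1, length(n_fine_y) == 1, length(coarse_block) == 1)
  if (n_fine_x < 2 || n_fine_y < 2)
    stop("n_fine_x and n_fine_y must both be >= 2")
  if (n_fine_x %% coarse_block != 0 || n_fine_y %% coarse_block != 0)
    stop("coarse_block (", coarse_block, ") must divide both grid dimensions (",
         n_fine_x, ", ", n_fine_y, ")")
  ix <- rep(seq_len(n_fine_x), times = n_fine_y)
  iy <- rep(seq_len(n_fine_y), each = n_fine_x)
  cbx <- (ix - 1L) %/% coarse_block + 1L
  cby <- (iy - 1L) %/% coarse_block + 1L
  n_cbx <- n_fine_x %/% coarse_block
  coarse_idx <- (cby - 1L) * n_cbx + cbx
  units <- data.frame(
    unit_id   = sprintf("I%04d", seq_along(ix)),
    coarse_id = sprintf("C%03d", coarse_idx),
    cx = ix - 0.5,
    cy = iy - 0.5,
    ix = ix,
    iy = iy,
    stringsAsFactors = FALSE
  )
  structure(
    list(units = units, nx = as.integer(n_fine_x), ny = as.integer(n_fine_y),
         coarse_block = as.integer(coarse_block), cell_size = 1,
         seed = as.integer(seed)),
    class = "area_lattice"
  )
}

#' @export
print.area_lattice <- function(x, ...) {
  cat("Areal lattice:", x$nx, "x", x$ny, "fine units (",
      nrow(x$units), "total ) nested in",
      length(unique(x$units$coarse_id)), "coarse units of",
      x$coarse_block, "x", x$coarse_block, "cells\n")
  invisible(x)
}

#' Fine-to-coarse nesting map of a lattice
#'
#' @param lattice An `area_lattice`.
#' @return Named character vector mapping each fine `unit_id` to its
#'   `coarse_id`.
#' @export
nesting_map <- function(lattice) {
  stopifnot(inherits(lattice, "area_lattice"))
  stats::setNames(lattice$units$coarse_id, lattice$units$unit_id)
}

#' Polygon ring of one fine unit
#'
#' Closed ring (first vertex repeated) of the square cell, counter-clockwise.
#' @param lattice An `area_lattice`.
#' @param i Row index of the unit.
#' @return 5 x 2 numeric matrix of (x, y) vertices.
#' @export
unit_polygon <- function(lattice, i) {
  h <- lattice$cell_size / 2
  cx <- lattice$units$cx[i]; cy <- lattice$units$cy[i]
  cbind(x = cx + h * c(-1, 1, 1, -1, -1),
        y = cy + h * c(-1, -1, 1, 1, -1))
}

#' Generate elderly population counts per unit
#'
#' Draws per-unit counts for the three elderly age groups (75-84, 85-94
#' and 95-plus years) from a negative binomial distribution. Census counts are
#' overdispersed relative to Poisson, hence the negative binomial; as
#' `dispersion` tends to infinity the draws approach Poisson with mean
#' `mean_pop` per group.
#'
#' @param lattice An `area_lattice`.
#' @param mean_pop Mean count per age group per unit (> 0).
#' @param dispersion Negative binomial size parameter; `Inf` gives Poisson.
#' @param seed Integer seed.
#' @return Data frame with `unit_id`, `pop_75_84`, `pop_85_94`, `pop_95p`.
#'   Units whose total would be zero are given a single 75-84 inhabitant so
#'   every unit can enter the modelling stage.
#' @export
generate_population <- function(lattice, mean_pop = 60, dispersion = 1.2, seed = 1L) {
  stopifnot(inherits(lattice, "area_lattice"))
  if (mean_pop <= 0) stop("mean_pop must be > 0")
  if (dispersion <= 0) stop("dispersion must be > 0")
  n <- nrow(lattice$units)
  set.seed(as.integer(seed))
  draw <- function() {
    if (is.infinite(dispersion)) stats::rpois(n, mean_pop)
    else stats::rnbinom(n, mu = mean_pop, size = dispersion)
  }
  out <- data.frame(unit_id = lattice$units$unit_id,
                    pop_75_84 = draw(), pop_85_94 = draw(), pop_95p = draw(),
                    stringsAsFactors = FALSE)
  tot <- out$pop_75_84 + out$pop_85_94 + out$pop_95p
  out$pop_75_84[tot == 0] <- 1L
  out
}

#' Total elderly population per unit
#' @param population A population table from [generate_population()].
#' @return Named numeric vector of total >= 75 population per unit.
#' @export
total_population <- function(population) {
  stats::setNames(population$pop_75_84 + population$pop_85_94 + population$pop_95p,
                  population$unit_id)
}

#' Generate bounded percentage covariates with a target correlation
#'
#' Draws latent Gaussian fields per covariate (optionally with a smooth
#' spatial component), imposes the target cross-correlation by a Cholesky
#' factor, and maps each column to the (0, 100) percentage scale by a
#' logistic transform `100 * plogis(mu_k + sd_k * z)`. With the default
#' latent scale the transform is close to linear, so realized Pearson
#' correlations track the target to within about +/- 0.1 for n >= 400.
#'
#' @param lattice An `area_lattice`.
#' @param target_correlation Symmetric positive semi-definite correlation
#'   matrix with unit diagonal; its dimension sets the number of covariates.
#' @param seed Integer seed.
#' @param spatial_share Fraction (in `[0, 1)`) of latent variance carried by a
#'   smooth random surface of the centroid coordinates; 0 gives i.i.d. fields.
#' @param names Column names; defaults to `non_owner`, `precarious` and
#'   accessibility placeholders `acc1`, `acc2`, ...
#' @param location,scale Latent logistic location/scale per column, recycled.
#'   Defaults centre `non_owner` near 40% and `precarious` near 15%.
#' @return Data frame with `unit_id` and one percentage column per covariate.
#' @export
generate_covariates <- function(lattice,
                                target_correlation = diag(2),
                                seed = 1L,
                                spatial_share = 0.3,
                                names = NULL,
                                location = NULL,
                                scale = 0.25) {
  stopifnot(inherits(lattice, "area_lattice"))
  R <- as.matrix(target_correlation)
  p <- nrow(R)
  if (!isTRUE(all.equal(R, t(R), tolerance = 1e-10)))
    stop("target_correlation must be symmetric")
  if (any(abs(diag(R) - 1) > 1e-10))
    stop("target_correlation must have unit diagonal")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("target_correlation is not positive semi-definite (min eigenvalue ",
         signif(min(ev), 3), ")")
  if (spatial_share < 0 || spatial_share >= 1)
    stop("spatial_share must be in [0, 1)")
  n <- nrow(lattice$units)
  u <- lattice$units$cx; v <- lattice$units$cy
  us <- as.numeric(scale(u)); vs <- as.numeric(scale(v))
  set.seed(as.integer(seed))
  M <- matrix(0, n, p)
  for (k in seq_len(p)) {
    e <- stats::rnorm(n)
    if (spatial_share > 0) {
      a <- stats::rnorm(4)
      om <- stats::runif(2, 1, 3)
      ph <- stats::runif(2, 0, 2 * pi)
      g <- a[1] * us + a[2] * vs +
        a[3] * sin(om[1] * us + ph[1]) + a[4] * cos(om[2] * vs + ph[2])
      g <- as.numeric(scale(g))
      M[, k] <- sqrt(1 - spatial_share) * e + sqrt(spatial_share) * g
    } else {
      M[, k] <- e
    }
  }
  # impose cross-correlation: columns of M are independent, unit variance
  U <- tryCatch(chol(R), error = function(e) {
    es <- eigen(R, symmetric = TRUE)
    chol(es$vectors %*% diag(pmax(es$values, 1e-10)) %*% t(es$vectors))
  })
  Z <- M %*% U
  if (is.null(names)) {
    base <- c("non_owner", "precarious")
    names <- c(base[seq_len(min(p, 2))],
               if (p > 2) paste0("acc", seq_len(p - 2)))
  }
  if (is.null(location)) {
    loc0 <- c(stats::qlogis(0.40), stats::qlogis(0.15))
    location <- c(loc0[seq_len(min(p, 2))], rep(0, max(0, p - 2)))
  }
  location <- rep_len(location, p)
  scale <- rep_len(scale, p)
  out <- data.frame(unit_id = lattice$units$unit_id, stringsAsFactors = FALSE)
  for (k in seq_len(p))
    out[[names[k]]] <- 100 * stats::plogis(location[k] + scale[k] * Z[, k])
  out
}

#' Generate provider sites with capacities
#'
#' Scatters provider locations uniformly over the lattice extent and draws
#' log-normal capacities (bed counts or full-time-equivalent practitioners).
#'
#' @param lattice An `area_lattice`.
#' @param n_providers Number of providers (>= 1).
#' @param capacity_mean Mean capacity per provider (> 0).
#' @param capacity_cv Coefficient of variation of capacity.
#' @param seed Integer seed.
#' @return Data frame with `provider_id`, `u`, `v`, `capacity`.
#' @export
generate_providers <- function(lattice, n_providers = 5, capacity_mean = 100,
                               capacity_cv = 0.5, seed = 1L) {
  stopifnot(inherits(lattice, "area_lattice"))
  if (n_providers < 1) stop("n_providers must be >= 1")
  if (capacity_mean <= 0) stop("capacity_mean must be > 0")
  set.seed(as.integer(seed))
  sdl <- sqrt(log(1 + capacity_cv^2))
  mul <- log(capacity_mean) - sdl^2 / 2
  data.frame(
    provider_id = sprintf("P%03d", seq_len(n_providers)),
    u = stats::runif(n_providers, 0, lattice$nx * lattice$cell_size),
    v = stats::runif(n_providers, 0, lattice$ny * lattice$cell_size),
    capacity = stats::rlnorm(n_providers, mul, sdl),
    stringsAsFactors = FALSE
  )
}

#' Ground-truth record for simulated outcomes
#'
#' Bundles the generating process and its parameters; together with a lattice
#' and covariates it fully determines a simulated outcome (same seed, same
#' output).
#'
#' @param process One of `"iid"`, `"sar_lag"`, `"varying_coefficients"`.
#' @param beta Coefficient vector (`iid`, `sar_lag`) or an n x p matrix of
#'   per-unit coefficient surfaces (`varying_coefficients`).
#' @param rho Spatial autoregressive coefficient in (-1, 1); used by
#'   `sar_lag` only.
#' @param sigma2 Innovation variance (>= 0).
#' @param seed Integer seed.
#' @return An object of class `truth_record`.
#' @export
truth_record <- function(process = c("iid", "sar_lag", "varying_coefficients"),
                         beta, rho = 0, sigma2 = 1, seed = 1L) {
  process <- match.arg(process)
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  structure(list(process = process, beta = beta, rho = rho,
                 sigma2 = sigma2, seed = as.integer(seed)),
            class = "truth_record")
}

#' Simulate a per-unit outcome under a known spatial process
#'
#' Generates the (log-scale) outcome under one of three processes:
#' * `iid`: `y = X beta + eps`;
#' * `sar_lag`: `y = (I - rho W)^{-1} (X beta + eps)` with row-standardized
#'   weights `W`;
#' * `varying_coefficients`: `y_i = sum_k beta_k(u_i, v_i) x_ik + eps_i`
#'   with per-unit coefficient surfaces.
#' Innovations are i.i.d. Gaussian with variance `sigma2`.
#'
#' @param lattice An `area_lattice`.
#' @param X Numeric design matrix (include an intercept column if wanted);
#'   column count must match the truth's `beta`.
#' @param W Spatial weights (class `spw`), required and row-standardized for
#'   `sar_lag`.
#' @param truth A [truth_record()].
#' @return Numeric outcome vector named by `unit_id`.
#' @export
simulate_outcome <- function(lattice, X, W = NULL, truth) {
  stopifnot(inherits(lattice, "area_lattice"), inherits(truth, "truth_record"))
  X <- as.matrix(X)
  n <- nrow(lattice$units)
  if (nrow(X) != n) stop("X must have one row per fine unit")
  set.seed(truth$seed)
  eps <- stats::rnorm(n, 0, sqrt(truth$sigma2))
  y <- switch(truth$process,
    iid = {
      if (length(truth$beta) != ncol(X)) stop("length(beta) must match ncol(X)")
      drop(X %*% truth$beta) + eps
    },
    sar_lag = {
      if (length(truth$beta) != ncol(X)) stop("length(beta) must match ncol(X)")
      if (is.null(W)) stop("W is required for process = 'sar_lag'")
      if (W$style != "row_standardized")
        stop("W must be row-standardized for process = 'sar_lag'")
      if (abs(truth$rho) >= 1) stop("|rho| must be < 1")
      A <- Matrix::Diagonal(n) - truth$rho * spw_matrix(W)
      mu <- drop(X %*% truth$beta) + eps
      sol <- tryCatch(Matrix::solve(A, mu),
                      error = function(e) stop("(I - rho W) is singular: ",
                                               conditionMessage(e)))
      as.numeric(sol)
    },
    varying_coefficients = {
      B <- as.matrix(truth$beta)
      if (!all(dim(B) == dim(X)))
        stop("beta must be an n x p matrix matching X for varying_coefficients")
      rowSums(X * B) + eps
    })
  stats::setNames(y, lattice$units$unit_id)
}

#' Linear coefficient surface over a lattice
#'
#' Convenience builder of a per-unit coefficient surface
#' `b(u, v) = intercept + slope_u * u* + slope_v * v*` where `u*`, `v*` are
#' standardized centroid coordinates. Used to define spatially varying ground
#' truth for non-stationarity experiments.
#'
#' @param lattice An `area_lattice`.
#' @param intercept,slope_u,slope_v Surface parameters.
#' @return Numeric vector of per-unit coefficients.
#' @export
coef_surface_linear <- function(lattice, intercept = 0, slope_u = 1, slope_v = 0) {
  us <- as.numeric(scale(lattice$units$cx))
  vs <- as.numeric(scale(lattice$units$cy))
  intercept + slope_u * us + slope_v * vs
}
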