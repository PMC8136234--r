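#' Spatial weights objects
#'
#' A `spw` object stores a sparse neighbour structure: ordered unit `ids`, a
#' list of integer neighbour indices per unit, a parallel list of nonnegative
#' weights and a `style` (`"binary"` or `"row_standardized"`). Contiguity
#' weights are symmetric before standardization and never include
#' self-neighbours.
#'
#' @param ids Character vector of unit identifiers (unique).
#' @param nb List of integer neighbour index vectors, one per unit.
#' @param wts List of numeric weight vectors, parallel to `nb`.
#' @param style `"binary"` or `"row_standardized"`.
#' @return An object of class `spw`.
#' @export
spw <- function(ids, nb, wts, style = c("binary", "row_standardized")) {
  style <- match.arg(style)
  stopifnot(length(ids) == length(nb), length(nb) == length(wts))
  if (anyDuplicated(ids)) stop("unit ids must be unique")
  for (i in seq_along(nb)) {
    if (any(nb[[i]] == i)) stop("self-neighbour found at unit ", ids[i])
    if (length(nb[[i]]) != length(wts[[i]]))
      stop("neighbour/weight length mismatch at unit ", ids[i])
    if (any(wts[[i]] < 0)) stop("negative weight at unit ", ids[i])
  }
  structure(list(ids = as.character(ids), nb = nb, wts = wts, style = style),
            class = "spw")
}

#' @export
print.spw <- function(x, ...) {
  deg <- lengths(x$nb)
  cat("Spatial weights (", x$style, "): ", length(x$ids), " units, ",
      sum(deg), " links, ", sum(deg == 0), " isolated\n", sep = "")
  invisible(x)
}

#' Contiguity weights for a regular lattice
#'
#' Rook contiguity links polygons sharing an edge of positive length; queen
#' contiguity additionally links polygons touching at a corner. On the
#' regular grid produced by [generate_lattice()] this reduces to 4- and
#' 8-neighbourhoods. Result is binary (weight 1 per link).
#'
#' @param lattice An `area_lattice`.
#' @param rule `"rook"` or `"queen"`.
#' @return A binary `spw`.
#' @export
contiguity_weights <- function(lattice, rule = c("rook", "queen")) {
  stopifnot(inherits(lattice, "area_lattice"))
  rule <- match.arg(rule)
  if (nrow(lattice$units) < 2) stop("lattice must have at least 2 units")
  grid_contiguity(lattice$nx, lattice$ny, rule = rule, torus = FALSE,
                  ids = lattice$units$unit_id)
}

#' Contiguity weights on an nx x ny grid
#'
#' Lower-level constructor used by [contiguity_weights()]; with
#' `torus = TRUE` opposite edges of the grid are glued, which is useful for
#' exact analytic checks (e.g. a checkerboard having global Moran's I of -1).
#'
#' @param nx,ny Grid dimensions.
#' @param rule `"rook"` or `"queen"`.
#' @param torus Wrap neighbourhoods around the grid edges.
#' @param ids Optional unit ids (default `I0001`, ...). Units are ordered
#'   row-major: index `(iy - 1) * nx + ix`.
#' @return A binary `spw`.
#' @export
grid_contiguity <- function(nx, ny, rule = c("rook", "queen"), torus = FALSE,
                            ids = NULL) {
  rule <- match.arg(rule)
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx * ny < 2) stop("grid must have at least 2 units")
  if (is.null(ids)) ids <- sprintf("I%04d", seq_len(nx * ny))
  offs <- if (rule == "rook") {
    cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  } else {
    as.matrix(expand.grid(dx = -1:1, dy = -1:1))[-5, , drop = FALSE]
  }
  nb <- vector("list", nx * ny)
  for (iy in seq_len(ny)) {
    for (ix in seq_len(nx)) {
      jx <- ix + offs[, 1]; jy <- iy + offs[, 2]
      if (torus) {
        jx <- (jx - 1L) %% nx + 1L
        jy <- (jy - 1L) %% ny + 1L
      }
      ok <- jx >= 1 & jx <= nx & jy >= 1 & jy <= ny
      idx <- sort(unique((jy[ok] - 1L) * nx + jx[ok]))
      nb[[(iy - 1L) * nx + ix]] <- idx[idx != (iy - 1L) * nx + ix]
    }
  }
  spw(ids, nb, lapply(nb, function(v) rep(1, length(v))), style = "binary")
}

#' Row-standardize spatial weights
#'
#' Divides each unit's weights by their sum so nonempty rows sum to one
#' (within 1e-12). Isolated units keep empty rows and are flagged in the
#' `isolated` attribute. Idempotent.
#'
#' @param W A `spw` object.
#' @return A `spw` with `style = "row_standardized"`.
#' @export
row_standardize <- function(W) {
  stopifnot(inherits(W, "spw"))
  wts <- lapply(W$wts, function(v) if (length(v)) v / sum(v) else v)
  out <- spw(W$ids, W$nb, wts, style = "row_standardized")
  attr(out, "isolated") <- W$ids[lengths(W$nb) == 0]
  out
}

#' Sparse matrix form of spatial weights
#'
#' @param W A `spw` object.
#' @return A `dgCMatrix` with rows/columns ordered as `W$ids`.
#' @export
spw_matrix <- function(W) {
  stopifnot(inherits(W, "spw"))
  n <- length(W$ids)
  i <- rep(seq_len(n), lengths(W$nb))
  j <- unlist(W$nb, use.names = FALSE)
  x <- unlist(W$wts, use.names = FALSE)
  if (length(i) == 0)
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(n, n)))
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
}

#' Spatial lag of a per-unit vector
#'
#' Computes `(W x)_i = sum_j w_ij x_j`. With row-standardized weights this is
#' the neighbourhood average, so a constant vector is returned unchanged.
#'
#' @param W A `spw` object.
#' @param x Numeric vector aligned with `W$ids`; if named, names must match
#'   `W$ids` exactly (same order) or an error is raised.
#' @return Numeric vector of spatial lags.
#' @export
spatial_lag <- function(W, x) {
  stopifnot(inherits(W, "spw"))
  if (length(x) != length(W$ids)) stop("x and W have different lengths")
  if (!is.null(names(x)) && !identical(names(x), W$ids))
    stop("names of x do not align with W ids; align or drop names")
  as.numeric(spw_matrix(W) %*% x)
}

#' Total weight S0 of a spatial weights object
#' @param W A `spw` object.
#' @return Sum of all weights.
#' @export
spw_total <- function(W) sum(unlist(W$wts, use.names = FALSE))

#' Adaptive kernel weights around one focal unit
#'
#' Adaptive scheme: the bandwidth at the focal unit is the distance to its
#' k-th nearest neighbour, `k = ceiling(fraction * n)` (the focal unit itself
#' counts as its own 1st nearest neighbour at distance 0). The default
#' Gaussian kernel `w = exp(-(d/b)^2 / 2)` is untruncated beyond the k-th
#' neighbour; a truncated bisquare `(1 - (d/b)^2)^2` on `d < b` is available.
#' Weight at zero distance is 1 and weights are non-increasing in distance.
#' Distance ties at the k-th position are resolved deterministically (the
#' bandwidth is the k-th order statistic, which is tie-invariant).
#'
#' @param centroids Two-column matrix of (u, v) coordinates.
#' @param focal Index (or id position) of the focal unit.
#' @param fraction Fraction of n defining k, in (0, 1].
#' @param kernel `"gaussian"`, `"bisquare"` or `"uniform"` (all weights 1,
#'   the global-model limit).
#' @return List with `focal`, `w` (length-n weights), `bandwidth`, `k`.
#' @export
adaptive_kernel <- function(centroids, focal, fraction,
                            kernel = c("gaussian", "bisquare", "uniform")) {
  kernel <- match.arg(kernel)
  centroids <- as.matrix(centroids)
  n <- nrow(centroids)
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  k <- as.integer(ceiling(fraction * n))
  d <- sqrt((centroids[, 1] - centroids[focal, 1])^2 +
            (centroids[, 2] - centroids[focal, 2])^2)
  if (kernel == "uniform")
    return(list(focal = focal, w = rep(1, n), bandwidth = Inf, k = n))
  b <- sort(d, partial = k)[k]
  if (b <= 0) stop("bandwidth is zero: k coincident points at the focal unit")
  w <- if (kernel == "gaussian") {
    exp(-0.5 * (d / b)^2)
  } else {
    wv <- (1 - (d / b)^2)^2
    wv[d >= b] <- 0
    wv
  }
  list(focal = focal, w = w, bandwidth = b, k = k)
}

#' Write spatial weights as a sparse triplet CSV
#'
#' Columns `i`, `j`, `w` with unit ids; a `# style:` comment line preserves
#' the standardization style so the file round-trips losslessly.
#'
#' @param W A `spw` object.
#' @param path Output file path.
#' @export
write_weights_csv <- function(W, path) {
  stopifnot(inherits(W, "spw"))
  n <- length(W$ids)
  df <- data.frame(
    i = rep(W$ids, lengths(W$nb)),
    j = W$ids[unlist(W$nb, use.names = FALSE)],
    w = unlist(W$wts, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# style: ", W$style), con)
  writeLines(paste0("# ids: ", paste(W$ids, collapse = ",")), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read spatial weights from a sparse triplet CSV
#' @param path File written by [write_weights_csv()].
#' @return A `spw` object.
#' @export
read_weights_csv <- function(path) {
  hdr <- readLines(path, n = 2)
  style <- sub("^# style: ", "", hdr[1])
  ids <- strsplit(sub("^# ids: ", "", hdr[2]), ",", fixed = TRUE)[[1]]
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  n <- length(ids)
  nb <- rep(list(integer()), n)
  wts <- rep(list(numeric()), n)
  if (nrow(df)) {
    ii <- match(df$i, ids); jj <- match(df$j, ids)
    if (anyNA(ii) || anyNA(jj)) stop("triplet file references unknown ids")
    sp <- split(seq_len(nrow(df)), ii)
    for (nm in names(sp)) {
      k <- as.integer(nm)
      ord <- order(jj[sp[[nm]]])
      nb[[k]] <- jj[sp[[nm]]][ord]
      wts[[k]] <- df$w[sp[[nm]]][ord]
    }
  }
  spw(ids, nb, wts, style = style)
}

#' Subset spatial weights to a set of retained units
#'
#' Drops the excluded units and their links, reindexes neighbours, and --
#' for row-standardized input -- re-standardizes the remaining rows. Units
#' left without neighbours become isolated (empty rows).
#'
#' @param W A `spw` object.
#' @param keep Logical vector over `W$ids` (or integer indices) of units to
#'   retain.
#' @return A `spw` over the retained units, in their original order.
#' @export
spw_subset <- function(W, keep) {
  stopifnot(inherits(W, "spw"))
  idx <- if (is.logical(keep)) which(keep) else as.integer(keep)
  if (length(idx) < 2) stop("fewer than 2 units retained")
  map <- rep(NA_integer_, length(W$ids))
  map[idx] <- seq_along(idx)
  nb <- vector("list", length(idx))
  wts <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    old <- W$nb[[idx[j]]]
    ok <- !is.na(map[old])
    nb[[j]] <- map[old[ok]]
    wts[[j]] <- W$wts[[idx[j]]][ok]
  }
  out <- spw(W$ids[idx], nb, wts,
             style = if (W$style == "row_standardized") "binary" else W$style)
  if (W$style == "row_standardized") out <- row_standardize(out) else out
}
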