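#' Write a region (lattice + unit table) as GeoJSON
#'
#' One polygon feature per fine unit; properties carry `unit_id`,
#' `coarse_id` and every additional column of `table`.
#'
#' @param lattice An `area_lattice`.
#' @param table Optional data frame keyed by `unit_id` with per-unit
#'   variables.
#' @param path Output `.geojson` path.
#' @export
write_region_geojson <- function(lattice, table = NULL, path) {
  stopifnot(inherits(lattice, "area_lattice"))
  units <- lattice$units
  if (!is.null(table)) {
    if (anyDuplicated(table$unit_id)) stop("duplicate unit_id in table")
    idx <- match(units$unit_id, table$unit_id)
    if (anyNA(idx)) stop("table is missing unit(s): ",
                         paste(units$unit_id[is.na(idx)], collapse = ", "))
    extra <- table[idx, setdiff(names(table), "unit_id"), drop = FALSE]
  } else {
    extra <- NULL
  }
  features <- lapply(seq_len(nrow(units)), function(i) {
    ring <- unit_polygon(lattice, i)
    props <- c(list(unit_id = units$unit_id[i], coarse_id = units$coarse_id[i]),
               if (!is.null(extra)) as.list(extra[i, , drop = FALSE]))
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(r) unname(ring[r, ])))),
         properties = props)
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Read a region from GeoJSON
#'
#' Rebuilds the lattice (unit ids, coarse ids, centroids from the polygon
#' vertices) and the per-unit attribute table written by
#' [write_region_geojson()].
#'
#' @param path GeoJSON path.
#' @return List with `lattice` (an `area_lattice`; grid dimensions inferred
#'   from the centroids) and `table` (data frame of properties).
#' @export
read_region <- function(path) {
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(fc$type) || fc$type != "FeatureCollection")
    stop("not a GeoJSON FeatureCollection")
  feats <- fc$features
  n <- length(feats)
  if (n == 0) stop("empty FeatureCollection")
  rows <- lapply(feats, function(f) {
    if (is.null(f$properties$unit_id)) stop("feature missing unit_id property")
    if (is.null(f$geometry) || f$geometry$type != "Polygon")
      stop("malformed geometry for unit ", f$properties$unit_id)
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(v) as.numeric(unlist(v))))
    if (nrow(ring) < 4) stop("degenerate ring for unit ", f$properties$unit_id)
    verts <- unique(ring)
    c(list(cx = mean(verts[, 1]), cy = mean(verts[, 2])),
      lapply(f$properties, function(p) if (is.null(p)) NA else p))
  })
  tab <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  if (anyDuplicated(tab$unit_id)) stop("duplicate unit_id in GeoJSON")
  xs <- sort(unique(tab$cx)); ys <- sort(unique(tab$cy))
  nx <- length(xs); ny <- length(ys)
  cell <- if (nx > 1) min(diff(xs)) else if (ny > 1) min(diff(ys)) else 1
  units <- data.frame(unit_id = tab$unit_id,
                      coarse_id = tab$coarse_id,
                      cx = tab$cx, cy = tab$cy,
                      ix = match(tab$cx, xs), iy = match(tab$cy, ys),
                      stringsAsFactors = FALSE)
  ord <- order(units$iy, units$ix)
  units <- units[ord, , drop = FALSE]
  rownames(units) <- NULL
  lattice <- structure(list(units = units, nx = nx, ny = ny,
                            coarse_block = NA_integer_, cell_size = cell,
                            seed = NA_integer_),
                       class = "area_lattice")
  table <- tab[ord, setdiff(names(tab), c("cx", "cy")), drop = FALSE]
  rownames(table) <- NULL
  list(lattice = lattice, table = table)
}

#' Write a per-unit table as CSV (15-significant-digit round trip)
#' @param table Data frame.
#' @param path Output path.
#' @export
write_unit_csv <- function(table, path) {
  num <- vapply(table, is.numeric, logical(1))
  out <- table
  out[num] <- lapply(table[num], function(v) sprintf("%.15g", v))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-unit table written by [write_unit_csv()]
#' @param path CSV path.
#' @return Data frame.
#' @export
read_unit_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a ground-truth sidecar file
#'
#' Serializes a [truth_record()] (and any extra run metadata) as JSON next
#' to the simulated data, so every simulated outcome is traceable.
#'
#' @param truth A `truth_record`.
#' @param path Output path.
#' @param extra Optional named list of additional metadata.
#' @export
write_truth_json <- function(truth, path, extra = NULL) {
  stopifnot(inherits(truth, "truth_record"))
  payload <- c(unclass(truth), extra)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
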