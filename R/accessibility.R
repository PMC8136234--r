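#' Travel-time matrix between units and providers
#'
#' On synthetic data travel time is the centroid-to-provider Euclidean
#' distance divided by a constant speed.
#'
#' @param lattice An `area_lattice`.
#' @param providers Provider table with columns `u`, `v`.
#' @param speed Map units per minute (> 0).
#' @return Numeric matrix (units x providers) of minutes, with dimnames.
#' @export
travel_time <- function(lattice, providers, speed = 1) {
  stopifnot(inherits(lattice, "area_lattice"), speed > 0)
  du <- outer(lattice$units$cx, providers$u, "-")
  dv <- outer(lattice$units$cy, providers$v, "-")
  tt <- sqrt(du^2 + dv^2) / speed
  dimnames(tt) <- list(lattice$units$unit_id, providers$provider_id)
  tt
}

#' Enhanced two-step floating catchment area (E2SFCA) accessibility index
#'
#' Step 1: each provider's capacity is divided by the zone-weighted demand in
#' its catchment, `R_j = capacity_j / sum_i P_i w(t_ij)`. Step 2: each unit
#' sums the weighted provider ratios in its catchment,
#' `A_i = 10000 * sum_j R_j w(t_ij)`. The decay `w(t)` is a step function
#' over travel-time zones: `w(t)` is the weight of the first zone whose
#' threshold is `>= t`, and zero beyond the last threshold. The result is a
#' capacity-per-10,000-inhabitants index (beds or practitioners).
#'
#' @param providers Data frame with `provider_id` and `capacity` (>= 0).
#' @param demand Either a population table (as from [generate_population()])
#'   or a named numeric vector of per-unit demand.
#' @param traveltime Units x providers matrix of minutes (as from
#'   [travel_time()]).
#' @param zones Data frame with strictly increasing `threshold` (minutes) and
#'   non-increasing `weight` in (0, 1]. Default zones 10/20/30 minutes with
#'   weights 1.0/0.6/0.3 are a documented stand-in for published E2SFCA
#'   configurations.
#' @param drop_empty_providers A provider whose catchment holds zero weighted
#'   demand has an undefined ratio; by default this is an error, with
#'   `drop_empty_providers = TRUE` such providers contribute nothing.
#' @return Data frame with `unit_id` and `access` (capacity per 10,000).
#' @export
e2sfca <- function(providers, demand, traveltime,
                   zones = data.frame(threshold = c(10, 20, 30),
                                      weight = c(1.0, 0.6, 0.3)),
                   drop_empty_providers = FALSE) {
  if (any(providers$capacity < 0)) stop("capacities must be >= 0")
  if (any(traveltime < 0)) stop("travel times must be >= 0")
  if (is.data.frame(demand)) {
    P <- total_population(demand)
  } else {
    P <- demand
  }
  if (is.null(names(P)) || !setequal(names(P), rownames(traveltime)))
    P <- stats::setNames(as.numeric(P), rownames(traveltime))
  P <- P[rownames(traveltime)]
  if (any(diff(zones$threshold) <= 0)) stop("zone thresholds must be strictly increasing")
  if (any(zones$weight <= 0) || any(zones$weight > 1)) stop("zone weights must be in (0, 1]")
  if (any(diff(zones$weight) > 0)) stop("zone weights must be non-increasing")

  # step-function decay: innermost zone containing t wins; t == threshold is
  # inside the zone, beyond the last threshold the weight is 0
  Wz <- matrix(0, nrow(traveltime), ncol(traveltime))
  for (z in rev(seq_len(nrow(zones))))
    Wz[traveltime <= zones$threshold[z]] <- zones$weight[z]

  denom <- as.numeric(crossprod(Wz, P))          # per provider: sum_i P_i w_ij
  if (any(denom == 0)) {
    if (!drop_empty_providers)
      stop("provider(s) with zero weighted demand in catchment: ",
           paste(providers$provider_id[denom == 0], collapse = ", "),
           " (set drop_empty_providers = TRUE to drop them)")
    denom[denom == 0] <- Inf
  }
  R <- providers$capacity / denom
  A <- 10000 * as.numeric(Wz %*% R)
  data.frame(unit_id = rownames(traveltime), access = A, stringsAsFactors = FALSE)
}

#' Population-weighted aggregation to the coarse scale
#'
#' Summarizes a fine-unit variable at the coarse scale as the
#' population-weighted mean within each coarse unit.
#'
#' @param values Numeric vector per fine unit.
#' @param population Nonnegative weights per fine unit.
#' @param nesting Named character vector mapping fine ids to coarse ids (as
#'   from [nesting_map()]); order must match `values`.
#' @return Named numeric vector per coarse unit (sorted by coarse id).
#' @export
aggregate_to_coarse <- function(values, population, nesting) {
  if (length(values) != length(nesting) || length(population) != length(nesting))
    stop("values, population and nesting must have equal length")
  if (any(population < 0)) stop("populations must be >= 0")
  psum <- tapply(population, nesting, sum)
  if (any(psum == 0))
    stop("coarse unit(s) with all-zero population: ",
         paste(names(psum)[psum == 0], collapse = ", "))
  vsum <- tapply(values * population, nesting, sum)
  out <- stats::setNames(as.numeric(vsum / psum), names(vsum))
  out[sort(names(out))]
}

#' Disaggregation to the fine scale
#'
#' Gives every fine unit the value of its enclosing coarse unit, unchanged
#' (the homogeneous-disaggregation convention for variables only available
#' at the coarse scale).
#'
#' @param values Named numeric vector per coarse unit.
#' @param nesting Named character vector mapping fine ids to coarse ids.
#' @return Numeric vector per fine unit, named by fine id.
#' @export
disaggregate_to_fine <- function(values, nesting) {
  if (is.null(names(values))) stop("coarse values must be named by coarse id")
  miss <- setdiff(unique(nesting), names(values))
  if (length(miss))
    stop("missing coarse value(s) for: ", paste(miss, collapse = ", "))
  stats::setNames(as.numeric(values[nesting]), names(nesting))
}
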