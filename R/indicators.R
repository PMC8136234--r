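#' Age-standardized length-of-stay indicator
#'
#' Computes the per-unit LOS indicator over the three elderly age groups
#' (75-84, 85-94, >= 95): the default `"eq1"` mode sums, over groups, the
#' group's average stay length divided by the group's total population,
#' `LOS_i = sum_g avg_stay_gi / P_gi`. The alternative `"total_days"` mode
#' uses total inpatient days instead of the per-inpatient average in the
#' numerator, `sum_g avg_stay_gi * n_inpatients_gi / P_gi`; it is never
#' substituted silently.
#'
#' Missing (unit, group) rows are treated as zero inpatients and contribute
#' nothing. A group with inpatients but zero population is an error.
#'
#' @param stays Long data frame with `unit_id`, `age_group` (one of
#'   `"75_84"`, `"85_94"`, `"95p"`), `avg_stay` (days, >= 0) and
#'   `n_inpatients` (count).
#' @param population Population table with `unit_id`, `pop_75_84`,
#'   `pop_85_94`, `pop_95p`.
#' @param mode `"eq1"` (default) or `"total_days"`.
#' @return Data frame with `unit_id` and `los` (>= 0), one row per unit in
#'   `population`.
#' @export
compute_los <- function(stays, population, mode = c("eq1", "total_days")) {
  mode <- match.arg(mode)
  groups <- c("75_84", "85_94", "95p")
  popcols <- c("75_84" = "pop_75_84", "85_94" = "pop_85_94", "95p" = "pop_95p")
  if (!all(stays$age_group %in% groups))
    stop("age_group must be one of: ", paste(groups, collapse = ", "))
  if (any(stays$avg_stay < 0)) stop("avg_stay must be >= 0")
  if (anyDuplicated(stays[c("unit_id", "age_group")]))
    stop("duplicate (unit_id, age_group) rows in stays")
  los <- stats::setNames(rep(0, nrow(population)), population$unit_id)
  for (g in groups) {
    sg <- stays[stays$age_group == g & stays$n_inpatients > 0, , drop = FALSE]
    if (!nrow(sg)) next
    idx <- match(sg$unit_id, population$unit_id)
    if (anyNA(idx))
      stop("stays reference unknown unit(s): ",
           paste(sg$unit_id[is.na(idx)], collapse = ", "))
    P <- population[[popcols[[g]]]][idx]
    if (any(P == 0))
      stop("zero population in group ", g, " with inpatients at unit(s): ",
           paste(sg$unit_id[P == 0], collapse = ", "))
    num <- if (mode == "eq1") sg$avg_stay else sg$avg_stay * sg$n_inpatients
    los[sg$unit_id] <- los[sg$unit_id] + num / P
  }
  data.frame(unit_id = population$unit_id, los = as.numeric(los),
             stringsAsFactors = FALSE)
}

#' Build a stay table that reproduces a given LOS vector
#'
#' Inverse plumbing for simulation studies: constructs a stay table such
#' that [compute_los()] (mode `"eq1"`) returns exactly `los`. Each age group
#' with positive population receives an equal share of the indicator.
#'
#' @param los Named numeric vector (or data frame with `unit_id`, `los`).
#' @param population Population table.
#' @return Long stay table suitable for [compute_los()].
#' @export
stays_from_los <- function(los, population) {
  if (is.data.frame(los)) los <- stats::setNames(los$los, los$unit_id)
  los <- los[population$unit_id]
  groups <- c("75_84", "85_94", "95p")
  popcols <- c("pop_75_84", "pop_85_94", "pop_95p")
  pos <- sapply(popcols, function(cc) population[[cc]] > 0)
  npos <- rowSums(pos)
  out <- do.call(rbind, lapply(seq_along(groups), function(k) {
    keep <- pos[, k] & los > 0
    data.frame(unit_id = population$unit_id[keep],
               age_group = groups[k],
               avg_stay = los[keep] / npos[keep] * population[[popcols[k]]][keep],
               n_inpatients = pmax(1L, population[[popcols[k]]][keep] %/% 10L),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Natural log transform with explicit zero policy
#'
#' @param values Finite numeric vector.
#' @param policy How to handle non-positive entries: `"drop"` (mask them
#'   out, the default), `"error"`, or `"offset"` (add `offset` before the
#'   log).
#' @param offset Positive constant used when `policy = "offset"`.
#' @return List with `values` (log scale; `NA` where dropped) and `kept`
#'   (logical mask of retained units).
#' @export
log_transform <- function(values, policy = c("drop", "error", "offset"),
                          offset = 0.01) {
  policy <- match.arg(policy)
  if (any(!is.finite(values))) stop("values must be finite")
  bad <- values <= 0
  if (policy == "error" && any(bad)) {
    who <- if (!is.null(names(values))) names(values)[bad] else which(bad)
    stop("non-positive value(s) at: ", paste(who, collapse = ", "))
  }
  if (policy == "offset") {
    if (offset <= 0) stop("offset must be > 0")
    return(list(values = log(values + offset), kept = rep(TRUE, length(values))))
  }
  out <- ifelse(bad, NA_real_, log(pmax(values, .Machine$double.xmin)))
  list(values = out, kept = !bad)
}

#' Variance inflation factor screen
#'
#' `VIF_k = 1 / (1 - R2_k)` where `R2_k` comes from regressing column k on
#' all remaining columns (with intercept). Columns are removed greedily --
#' highest VIF first, recomputing after each removal -- until all VIF fall
#' below the threshold (10 by convention).
#'
#' @param X Numeric matrix or data frame of covariates (n > p + 1, no
#'   constant columns).
#' @param threshold VIF threshold (default 10).
#' @return List with `retained` (column names kept), `vif` (final VIF values
#'   of retained columns), `removed` (names in removal order) and
#'   `vif_initial`.
#' @export
vif_screen <- function(X, threshold = 10) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) <= ncol(X) + 1) stop("need n > p + 1 observations")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ", paste(colnames(X)[sds == 0], collapse = ", "))
  vif_of <- function(M) {
    if (ncol(M) < 2) return(stats::setNames(rep(1, ncol(M)), colnames(M)))
    sapply(seq_len(ncol(M)), function(k) {
      fit <- stats::lm.fit(cbind(1, M[, -k, drop = FALSE]), M[, k])
      rss <- sum(fit$residuals^2)
      tss <- sum((M[, k] - mean(M[, k]))^2)
      r2 <- 1 - rss / tss
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }) |> stats::setNames(colnames(M))
  }
  vif0 <- vif_of(X)
  keep <- X
  removed <- character()
  repeat {
    v <- vif_of(keep)
    if (all(v < threshold) || ncol(keep) == 1) break
    worst <- names(v)[which.max(v)]
    removed <- c(removed, worst)
    keep <- keep[, setdiff(colnames(keep), worst), drop = FALSE]
  }
  list(retained = colnames(keep), vif = vif_of(keep),
       removed = removed, vif_initial = vif0)
}

#' Descriptive summary of a LOS vector
#'
#' N, min, mean, standard deviation, quartiles, median and max, in the
#' reporting style customary for small-area LOS tables.
#'
#' @param los Numeric vector (or data frame with a `los` column).
#' @return One-row data frame.
#' @export
los_summary <- function(los) {
  if (is.data.frame(los)) los <- los$los
  q <- stats::quantile(los, c(0.25, 0.5, 0.75), names = FALSE)
  data.frame(n = length(los), min = min(los), mean = mean(los),
             sd = stats::sd(los), q25 = q[1], median = q[2], q75 = q[3],
             max = max(los))
}
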