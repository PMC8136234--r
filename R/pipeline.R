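#' Pipeline run configuration
#'
#' A `run_config` fully determines a pipeline run (it is serialized verbatim
#' into the output directory). All randomness flows from the single `seed`
#' through fixed per-stage substreams.
#'
#' @param seed Master integer seed.
#' @param nx,ny,coarse_block Lattice specification (see
#'   [generate_lattice()]).
#' @param mean_pop,dispersion Population generator parameters.
#' @param cov_correlation Target correlation between the two socioeconomic
#'   covariates (non-owner, precarious).
#' @param spatial_share Smooth-surface share of the covariate fields.
#' @param n_hospitals,beds_mean Hospital-bed provider generator parameters.
#' @param n_gp,gp_mean Primary-care provider generator parameters.
#' @param speed Travel speed (map units per minute).
#' @param zones E2SFCA travel-time zones (data frame `threshold`, `weight`).
#' @param process,rho,beta,sigma2 Outcome ground truth; `beta` is on the
#'   model scale `(intercept, ln_isa, precarious, non_owner, ln_apl)`. For
#'   `process = "varying_coefficients"` the intercept and `ln_apl` slopes
#'   are given linear spatial gradients of amplitude `vc_amplitude`.
#' @param vc_amplitude Gradient amplitude for varying-coefficient truth.
#' @param rule Contiguity rule, `"rook"` (default, as is standard for
#'   lattice LOS analyses) or `"queen"`.
#' @param log_policy Zero handling for log transforms (see
#'   [log_transform()]).
#' @param vif_threshold VIF screening threshold.
#' @param bw_search Bandwidth search bounds (fractions of n).
#' @param kernel GWR kernel.
#' @param alpha_gwr,alpha_lisa Significance levels for GWR pseudo-t flags
#'   and LISA labels.
#' @param n_perm_moran,n_perm_mc Permutation counts for Moran/LISA and the
#'   GWR Monte-Carlo test.
#' @param input_dir If non-NULL, load a previously written region and
#'   provider files from this directory instead of simulating.
#' @param outdir Output directory (created if missing).
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       nx = 12L, ny = 12L, coarse_block = 3L,
                       mean_pop = 60, dispersion = 1.2,
                       cov_correlation = 0.4, spatial_share = 0.4,
                       n_hospitals = 4L, beds_mean = 400,
                       n_gp = 12L, gp_mean = 30,
                       speed = 0.6,
                       zones = data.frame(threshold = c(10, 20, 30),
                                          weight = c(1.0, 0.6, 0.3)),
                       process = c("sar_lag", "iid", "varying_coefficients"),
                       rho = 0.5,
                       beta = c(intercept = 3.6, ln_isa = -0.3,
                                precarious = 0.02, non_owner = -0.01,
                                ln_apl = -0.4),
                       sigma2 = 0.1, vc_amplitude = 0.5,
                       rule = c("rook", "queen"),
                       log_policy = c("drop", "offset", "error"),
                       vif_threshold = 10,
                       bw_search = c(0.1, 1), kernel = "gaussian",
                       alpha_gwr = 0.05, alpha_lisa = 0.01,
                       n_perm_moran = 199L, n_perm_mc = 49L,
                       input_dir = NULL,
                       outdir = tempfile("spalos_run_")) {
  process <- match.arg(process)
  rule <- match.arg(rule)
  log_policy <- match.arg(log_policy)
  structure(as.list(environment()), class = "run_config")
}

stage_seed <- function(seed, offset) (as.integer(seed) * 101L + offset) %% 2147483646L + 1L

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "': ", conditionMessage(e), call. = FALSE))
}

align_table <- function(tab, ids, what) {
  idx <- match(ids, tab$unit_id)
  if (anyNA(idx)) stop(what, " is missing unit(s): ",
                       paste(ids[is.na(idx)], collapse = ", "))
  out <- tab[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full LOS spatial-analysis pipeline
#'
#' Executes, in order: simulate (or load) the region; E2SFCA accessibility
#' for hospital beds and primary care; LOS indicator construction and log
#' transform; VIF screening; OLS at the coarse and fine scales; SAR by
#' maximum likelihood; GWR bandwidth selection and fit; global and local
#' Moran diagnostics of the residuals; the GWR Monte-Carlo
#' non-stationarity test; model and scale comparison reports. Every stage's
#' outputs are written to `config$outdir` together with the verbatim
#' configuration, the ground truth sidecar and a manifest of file MD5
#' hashes. Any stage error aborts with the stage name.
#'
#' @param config A [run_config()].
#' @return (Invisibly) the artifact bundle: a named list of all in-memory
#'   stage results plus `files` (paths written).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  put <- function(name) {
    files <<- c(files, file.path(cfg$outdir, name))
    file.path(cfg$outdir, name)
  }

  ## -- simulate or load ------------------------------------------------
  if (is.null(cfg$input_dir)) {
    lattice <- with_stage("simulate", generate_lattice(cfg$nx, cfg$ny, cfg$coarse_block))
    population <- with_stage("simulate",
      generate_population(lattice, cfg$mean_pop, cfg$dispersion,
                          seed = stage_seed(cfg$seed, 1L)))
    R2 <- matrix(c(1, cfg$cov_correlation, cfg$cov_correlation, 1), 2)
    covariates <- with_stage("simulate",
      generate_covariates(lattice, R2, seed = stage_seed(cfg$seed, 2L),
                          spatial_share = cfg$spatial_share))
    hospitals <- with_stage("simulate",
      generate_providers(lattice, cfg$n_hospitals, cfg$beds_mean,
                         seed = stage_seed(cfg$seed, 3L)))
    gps <- with_stage("simulate",
      generate_providers(lattice, cfg$n_gp, cfg$gp_mean,
                         seed = stage_seed(cfg$seed, 4L)))
  } else {
    region <- with_stage("load", read_region(file.path(cfg$input_dir, "region.geojson")))
    lattice <- region$lattice
    tab <- align_table(region$table, lattice$units$unit_id, "region table")
    population <- tab[c("unit_id", "pop_75_84", "pop_85_94", "pop_95p")]
    covariates <- tab[c("unit_id", "non_owner", "precarious")]
    hosp_path <- file.path(cfg$input_dir, "providers_beds.csv")
    gp_path <- file.path(cfg$input_dir, "providers_gp.csv")
    if (!file.exists(hosp_path))
      stop("pipeline stage 'accessibility': provider file not found: ", hosp_path,
           call. = FALSE)
    if (!file.exists(gp_path))
      stop("pipeline stage 'accessibility': provider file not found: ", gp_path,
           call. = FALSE)
    hospitals <- utils::read.csv(hosp_path, stringsAsFactors = FALSE)
    gps <- utils::read.csv(gp_path, stringsAsFactors = FALSE)
  }
  ids <- lattice$units$unit_id
  n <- length(ids)

  ## -- accessibility ----------------------------------------------------
  acc <- with_stage("accessibility", {
    tt_h <- travel_time(lattice, hospitals, speed = cfg$speed)
    tt_g <- travel_time(lattice, gps, speed = cfg$speed)
    isa <- e2sfca(hospitals, population, tt_h, zones = cfg$zones,
                  drop_empty_providers = TRUE)
    apl <- e2sfca(gps, population, tt_g, zones = cfg$zones,
                  drop_empty_providers = TRUE)
    list(isa = isa, apl = apl)
  })

  ## -- weights ----------------------------------------------------------
  W <- with_stage("weights", {
    row_standardize(contiguity_weights(lattice, rule = cfg$rule))
  })

  ## -- outcome (simulated) / indicators ---------------------------------
  ln_isa <- with_stage("indicators",
    log_transform(stats::setNames(acc$isa$access, acc$isa$unit_id),
                  policy = cfg$log_policy)$values)
  ln_apl <- with_stage("indicators",
    log_transform(stats::setNames(acc$apl$access, acc$apl$unit_id),
                  policy = cfg$log_policy)$values)
  Xmodel <- cbind(intercept = 1, ln_isa = ln_isa,
                  precarious = covariates$precarious,
                  non_owner = covariates$non_owner, ln_apl = ln_apl)

  keep_acc <- stats::complete.cases(Xmodel)

  if (is.null(cfg$input_dir)) {
    truth <- with_stage("simulate", {
      if (cfg$process == "varying_coefficients") {
        B <- matrix(rep(cfg$beta, each = n), n)
        B[, 1] <- cfg$beta[1] + cfg$vc_amplitude * coef_surface_linear(lattice, 0, 1, 1)
        B[, 5] <- cfg$beta[5] + cfg$vc_amplitude * coef_surface_linear(lattice, 0, 1, -1)
        truth_record("varying_coefficients", beta = B, sigma2 = cfg$sigma2,
                     seed = stage_seed(cfg$seed, 5L))
      } else {
        truth_record(cfg$process, beta = cfg$beta,
                     rho = if (cfg$process == "sar_lag") cfg$rho else 0,
                     sigma2 = cfg$sigma2, seed = stage_seed(cfg$seed, 5L))
      }
    })
    Xsim <- Xmodel
    Xsim[!keep_acc, ] <- 0        # placeholders; masked units get no outcome
    y_ln <- with_stage("simulate", simulate_outcome(lattice, Xsim, W, truth))
    los_true <- exp(y_ln)
    los_true[!keep_acc] <- 0      # excluded by the log mask downstream
    stays <- with_stage("indicators", stays_from_los(los_true, population))
  } else {
    truth <- NULL
    stays <- with_stage("load", {
      sp <- file.path(cfg$input_dir, "stays.csv")
      if (!file.exists(sp)) stop("stay table not found: ", sp)
      utils::read.csv(sp, stringsAsFactors = FALSE)
    })
  }
  los <- with_stage("indicators", compute_los(stays, population))
  lt <- with_stage("indicators",
    log_transform(stats::setNames(los$los, los$unit_id), policy = cfg$log_policy))
  ln_los <- lt$values

  ## -- modelling mask (accessibility + LOS exclusions) -------------------
  keep <- keep_acc & lt$kept
  if (sum(keep) < ncol(Xmodel) + 3)
    stop("pipeline stage 'indicators': too few units remain after log-policy ",
         "exclusions (", sum(keep), ")", call. = FALSE)
  Wk <- if (all(keep)) W else spw_subset(W, keep)
  cok <- as.matrix(lattice$units[keep, c("cx", "cy")])
  ln_los_k <- ln_los[keep]

  ## -- VIF screen --------------------------------------------------------
  vif <- with_stage("vif_screen",
    vif_screen(Xmodel[keep, -1, drop = FALSE], threshold = cfg$vif_threshold))
  Xfit <- cbind(intercept = 1, Xmodel[keep, vif$retained, drop = FALSE])

  ## -- global fits: coarse and fine scale --------------------------------
  nest <- nesting_map(lattice)[keep]
  pop_tot <- total_population(population)[keep]
  fits <- with_stage("fit", {
    ols_fine <- fit_ols(ln_los_k, Xfit)
    los_coarse <- aggregate_to_coarse(los$los[keep], pop_tot, nest)
    Xc <- cbind(intercept = 1,
                apply(Xfit[, -1, drop = FALSE], 2, function(v)
                  aggregate_to_coarse(v, pop_tot, nest)))
    ln_los_coarse <- log_transform(los_coarse, policy = cfg$log_policy)$values
    ols_coarse <- fit_ols(ln_los_coarse, Xc)
    sar_fine <- fit_sar_lag(ln_los_k, Xfit, Wk)
    bw <- select_bandwidth(ln_los_k, Xfit, cok,
                           search = cfg$bw_search, kernel = cfg$kernel)
    gwr_fine <- fit_gwr(ln_los_k, Xfit, cok,
                        fraction = bw$fraction, kernel = cfg$kernel,
                        alpha = cfg$alpha_gwr)
    list(ols_fine = ols_fine, ols_coarse = ols_coarse, sar = sar_fine,
         bw = bw, gwr = gwr_fine)
  })

  ## -- diagnostics --------------------------------------------------------
  diag <- with_stage("diagnose", {
    moran_los <- morans_i(ln_los_k, Wk, n_perm = cfg$n_perm_moran,
                          seed = stage_seed(cfg$seed, 6L))
    cmp <- compare_models(list(ols = fits$ols_fine, sar = fits$sar,
                               gwr = fits$gwr), Wk,
                          n_perm = cfg$n_perm_moran,
                          seed = stage_seed(cfg$seed, 7L))
    lisa <- local_morans(fits$ols_fine$residuals, Wk,
                         n_perm = cfg$n_perm_moran, alpha = cfg$alpha_lisa,
                         seed = stage_seed(cfg$seed, 8L))
    mc <- gwr_monte_carlo(ln_los_k, Xfit, cok,
                          fraction = fits$bw$fraction, n_perm = cfg$n_perm_mc,
                          seed = stage_seed(cfg$seed, 9L))
    sc <- scale_comparison(fits$ols_fine, fits$ols_coarse)
    list(moran_los = moran_los, comparison = cmp, lisa = lisa, mc = mc,
         scale = sc)
  })

  ## -- write artifacts ----------------------------------------------------
  with_stage("report", {
    unit_table <- data.frame(unit_id = ids,
                             population[match(ids, population$unit_id),
                                        c("pop_75_84", "pop_85_94", "pop_95p")],
                             covariates[match(ids, covariates$unit_id),
                                        c("non_owner", "precarious")],
                             isa = acc$isa$access, apl = acc$apl$access,
                             los = los$los, ln_los = ln_los,
                             modelled = keep,
                             stringsAsFactors = FALSE)
    write_region_geojson(lattice, unit_table, put("region.geojson"))
    write_unit_csv(unit_table, put("unit_table.csv"))
    write_unit_csv(stays, put("stays.csv"))
    write_unit_csv(hospitals, put("providers_beds.csv"))
    write_unit_csv(gps, put("providers_gp.csv"))
    write_weights_csv(W, put("weights.csv"))
    coef_tab <- data.frame(
      coefficient = names(fits$ols_fine$coefficients),
      ols_fine = unname(fits$ols_fine$coefficients),
      ols_fine_se = unname(fits$ols_fine$se),
      ols_coarse = unname(fits$ols_coarse$coefficients),
      ols_coarse_se = unname(fits$ols_coarse$se),
      sar = unname(fits$sar$coefficients),
      sar_se = unname(fits$sar$se), stringsAsFactors = FALSE)
    write_unit_csv(coef_tab, put("global_coefficients.csv"))
    ids_k <- ids[keep]
    gwr_tab <- data.frame(unit_id = ids_k, fits$gwr$beta,
                          se = fits$gwr$se, local_r2 = fits$gwr$local_r2,
                          bandwidth = fits$gwr$bandwidth,
                          stringsAsFactors = FALSE)
    write_unit_csv(gwr_tab, put("gwr_local.csv"))
    gwr_full <- data.frame(unit_id = ids, stringsAsFactors = FALSE)
    for (cc in colnames(fits$gwr$beta))
      gwr_full[[cc]] <- fits$gwr$beta[match(ids, ids_k), cc]
    write_region_geojson(lattice, gwr_full, put("gwr_local.geojson"))
    cmp_df <- as.data.frame(diag$comparison)
    write_unit_csv(cmp_df, put("model_comparison.csv"))
    write_unit_csv(diag$lisa$table, put("lisa.csv"))
    lisa_full <- data.frame(
      unit_id = ids,
      lisa_label = ifelse(ids %in% diag$lisa$table$unit_id,
                          diag$lisa$table$label[match(ids, diag$lisa$table$unit_id)],
                          "none"),
      stringsAsFactors = FALSE)
    write_region_geojson(lattice, lisa_full, put("lisa.geojson"))
    write_unit_csv(diag$mc$table, put("gwr_monte_carlo.csv"))
    write_unit_csv(diag$scale$table, put("scale_comparison.csv"))
    summary_lines <- c(
      sprintf("units: %d fine (%d modelled, %d excluded), %d coarse",
              n, sum(keep), sum(!keep), length(unique(nest))),
      sprintf("VIF retained: %s", paste(vif$retained, collapse = ", ")),
      sprintf("Moran's I of ln LOS: %.4f (p = %.4g)", diag$moran_los$I,
              diag$moran_los$p_permutation),
      sprintf("SAR rho = %.4f (se %.4f)%s", fits$sar$rho, fits$sar$rho_se,
              if (isTRUE(fits$sar$boundary)) " [boundary]" else ""),
      sprintf("GWR bandwidth fraction = %.4f (k = %d, AICc = %.3f, %s)",
              fits$bw$fraction, fits$bw$k, fits$bw$aicc, fits$bw$method),
      sprintf("adj R2: OLS %.4f | SAR %.4f | GWR %.4f",
              fits$ols_fine$adj_r2, fits$sar$adj_r2, fits$gwr$adj_r2),
      sprintf("AIC:    OLS %.3f | SAR %.3f | GWR %.3f (AICc %.3f)",
              fits$ols_fine$aic, fits$sar$aic, fits$gwr$aic, fits$gwr$aicc))
    if (!is.null(truth) && truth$process == "sar_lag") {
      summary_lines <- c(summary_lines,
        sprintf("parameter recovery: rho_true = %.4f, rho_hat = %.4f (se %.4f)",
                truth$rho, fits$sar$rho, fits$sar$rho_se))
    }
    writeLines(summary_lines, put("summary.txt"))
    cfg_out <- cfg
    cfg_out$zones <- NULL
    jsonlite::write_json(c(unclass(cfg_out),
                           list(zones = cfg$zones)),
                         put("config.json"), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE, null = "null")
    if (!is.null(truth)) {
      tr <- truth
      if (is.matrix(tr$beta)) tr$beta <- "per-unit surface (see config)"
      write_truth_json(tr, put("truth.json"))
    }
    manifest <- data.frame(file = basename(files),
                           md5 = unname(tools::md5sum(files)),
                           stringsAsFactors = FALSE)
    utils::write.csv(manifest, file.path(cfg$outdir, "manifest.csv"),
                     row.names = FALSE)
    files <<- c(files, file.path(cfg$outdir, "manifest.csv"))
  })

  invisible(list(config = cfg, lattice = lattice, population = population,
                 covariates = covariates, providers = list(beds = hospitals, gp = gps),
                 accessibility = acc, weights = W, los = los, ln_los = ln_los,
                 truth = truth, vif = vif, fits = fits, diagnostics = diag,
                 files = files))
}
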