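#' Cohort pipeline: geometry -> splenectomy -> hemodynamics -> ALWSS -> stats
#'
#' `run_patient()` carries one patient record through the full
#' reduced-order workflow and returns the postoperative WSS metrics;
#' `run_cohort()` does so for a whole (synthetic or CSV-supplied) cohort,
#' attaches thrombosis labels from the logistic risk model on the computed
#' ALWSS, and runs the evaluation statistics. Outputs are deterministic
#' given the configuration and seed.
#'
#' @name pipeline
NULL

#' Pipeline run configuration
#'
#' @param cohort a [cohort_config()], or a path to a cohort CSV with the
#'   columns produced by [sample_cohort()].
#' @param carreau a [carreau_params()].
#' @param outlet_pressure_pa outlet pressure at the PV distal end, Pa.
#' @param split a [flow_split()].
#' @param postop_flow_mode `"subtract_sv"` or `"renormalize"` (see
#'   [boundary_conditions()]).
#' @param dx surface strip width, m.
#' @param stump_model `"stasis"` or `"decay"` (see [compute_wss_field()]).
#' @param fraction low-WSS fraction of the space-averaged WSS.
#' @param vessel_defaults fixed dimensions for veins not sampled per
#'   patient (see [default_vessel_params()]).
#' @param label_seed_offset offset added to the cohort seed for the label
#'   draw, so covariate sampling and label noise are independent streams.
#' @param out_dir optional output directory; when set, `run_cohort()`
#'   writes `cohort_metrics.csv` and `cohort_stats.json` there.
#' @return an object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       carreau = carreau_params(),
                       outlet_pressure_pa = 3332.9,
                       split = flow_split(),
                       postop_flow_mode = c("subtract_sv", "renormalize"),
                       dx = 0.001,
                       stump_model = c("stasis", "decay"),
                       fraction = 0.2,
                       vessel_defaults = default_vessel_params(),
                       label_seed_offset = 1000L,
                       out_dir = NULL) {
  structure(list(
    cohort = cohort, carreau = carreau,
    outlet_pressure_pa = outlet_pressure_pa, split = split,
    postop_flow_mode = match.arg(postop_flow_mode), dx = dx,
    stump_model = match.arg(stump_model), fraction = fraction,
    vessel_defaults = vessel_defaults,
    label_seed_offset = as.integer(label_seed_offset),
    out_dir = out_dir
  ), class = "run_config")
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' Recognized top-level blocks mirror the [run_config()] arguments:
#' `cohort` (n, seed, anatomy_probs, beta0, beta1), `carreau` (mu0,
#' mu_inf, lambda_s, n), `boundary` (outlet_pressure_mmhg or
#' outlet_pressure_pa, flow_split, postop_flow_mode), `dx_mm`,
#' `stump_model`, `fraction`. Clinical units (mmHg, mm) are converted to
#' SI internally.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  # YAML 1.1 parses a bare `n` key as the boolean FALSE; both the cohort
  # size and the Carreau power index are named `n`, so restore them
  fix_n_key <- function(x) {
    if (!is.list(x)) return(x)
    names(x)[names(x) %in% c("FALSE", "no")] <- "n"
    lapply(x, fix_n_key)
  }
  raw <- fix_n_key(raw)
  args <- list()
  if (!is.null(raw$cohort))
    args$cohort <- do.call(cohort_config, raw$cohort)
  if (!is.null(raw$carreau))
    args$carreau <- do.call(carreau_params, raw$carreau)
  b <- raw$boundary
  if (!is.null(b)) {
    if (!is.null(b$outlet_pressure_mmhg))
      args$outlet_pressure_pa <- mmhg_to_pa(b$outlet_pressure_mmhg)
    if (!is.null(b$outlet_pressure_pa))
      args$outlet_pressure_pa <- b$outlet_pressure_pa
    if (!is.null(b$flow_split))
      args$split <- do.call(flow_split, as.list(b$flow_split))
    if (!is.null(b$postop_flow_mode))
      args$postop_flow_mode <- b$postop_flow_mode
  }
  if (!is.null(raw$dx_mm)) args$dx <- raw$dx_mm / 1000
  if (!is.null(raw$stump_model)) args$stump_model <- raw$stump_model
  if (!is.null(raw$fraction)) args$fraction <- raw$fraction
  do.call(run_config, args)
}

#' Build the preoperative tree for one cohort patient
#'
#' Patient-sampled PV/SV dimensions override the fixed defaults for the
#' remaining veins.
#'
#' @param patient one row of a cohort data.frame.
#' @param cfg a [run_config()].
#' @return a preoperative `portal_tree`.
#' @export
patient_tree <- function(patient, cfg = run_config()) {
  vd <- cfg$vessel_defaults
  d <- vd$diameters
  l <- vd$lengths
  t <- vd$tortuosities
  d["PV"] <- patient$pv_diameter_m
  d["SV"] <- patient$sv_diameter_m
  l["SV"] <- patient$sv_length_m
  t["SV"] <- patient$sv_tortuosity
  build_tree(d, l, t, anatomy_type = patient$anatomy_type)
}

#' Run the full reduced-order workflow for one patient
#'
#' Builds the preoperative tree, applies the virtual splenectomy, assigns
#' inlet flows from the preoperative PV velocity, solves the flow and WSS
#' field on the postoperative tree, and computes the WSS metrics.
#'
#' @param patient one row of a cohort data.frame.
#' @param cfg a [run_config()].
#' @return one-row data.frame: `id`, `anatomy_type`, `mean_wss_pa`,
#'   `threshold_pa`, `alwss_cm2`, `total_area_cm2`.
#' @export
run_patient <- function(patient, cfg = run_config()) {
  res <- tryCatch({
    pre <- patient_tree(patient, cfg)
    post <- apply_splenectomy(pre)
    bc <- boundary_conditions(
      pv_velocity = patient$pv_velocity_m_s,
      outlet_pressure = cfg$outlet_pressure_pa,
      split = cfg$split, postop_flow_mode = cfg$postop_flow_mode
    )
    inflows <- assign_inlet_flows(post, bc)
    flows <- solve_flows(post, inflows)
    field <- compute_wss_field(post, flows, cfg$carreau, cfg$dx,
                               cfg$stump_model)
    wss_metrics(field, cfg$fraction)
  }, error = function(e) {
    stop("patient ", patient$id, ": ", conditionMessage(e), call. = FALSE)
  })
  data.frame(id = patient$id, anatomy_type = patient$anatomy_type,
             mean_wss_pa = res$mean_wss_pa, threshold_pa = res$threshold_pa,
             alwss_cm2 = res$alwss_cm2, total_area_cm2 = res$total_area_cm2,
             stringsAsFactors = FALSE)
}

#' Run the workflow over a cohort and evaluate the score
#'
#' Generates (or loads) the cohort, computes per-patient metrics, draws
#' thrombosis labels from the logistic model on the computed ALWSS, and
#' evaluates: ROC/AUC with the accuracy-optimal threshold, Pearson
#' correlations of ALWSS against SV diameter and PV velocity, Mood's
#' median tests of each covariate between outcome groups, and per-anatomy-
#' type ALWSS summaries. With fewer than 2 patients or single-class
#' labels the statistics are skipped with a warning and metrics are still
#' returned.
#'
#' @param cfg a [run_config()].
#' @return list with `cohort` (covariates + labels), `metrics`
#'   (per-patient metric rows), `stats` (evaluation report, or NULL), and
#'   `provenance` (package version, config hash, split used).
#' @export
run_cohort <- function(cfg = run_config()) {
  cohort <- if (is.character(cfg$cohort)) {
    read.csv(cfg$cohort, stringsAsFactors = FALSE)
  } else {
    sample_cohort(cfg$cohort)
  }
  metrics <- do.call(rbind, lapply(seq_len(nrow(cohort)), function(i)
    run_patient(cohort[i, ], cfg)))
  if (!is.null(cohort$label)) {
    labels <- as.integer(cohort$label)
  } else if (inherits(cfg$cohort, "cohort_config")) {
    cc <- cfg$cohort
    labels <- generate_labels(metrics$alwss_cm2, cc$beta0, cc$beta1,
                              seed = cc$seed + cfg$label_seed_offset)
  } else {
    labels <- rep(NA_integer_, nrow(cohort))
  }
  cohort$label <- labels
  stats <- NULL
  if (nrow(cohort) >= 2 && length(unique(stats::na.omit(labels))) == 2) {
    stats <- analyze_cohort(cohort, metrics)
  } else {
    warning("fewer than 2 patients or single-class labels; ",
            "statistics skipped", call. = FALSE)
  }
  prov <- list(
    package_version = as.character(utils::packageVersion("portalwss")),
    config_hash = config_hash(cfg),
    flow_split = as.list(unclass(cfg$split)),
    postop_flow_mode = cfg$postop_flow_mode,
    stump_model = cfg$stump_model
  )
  out <- list(cohort = cohort, metrics = metrics, stats = stats,
              provenance = prov)
  if (!is.null(cfg$out_dir)) write_cohort_outputs(out, cfg)
  out
}

#' Evaluation statistics for a scored cohort
#'
#' @param cohort cohort data.frame with covariates and a binary `label`
#'   column.
#' @param metrics per-patient metrics from [run_patient()] rows.
#' @return list with `roc`, `pearson_alwss_sv_diameter`,
#'   `pearson_alwss_pv_velocity`, `moods_tests` (per covariate, NA on
#'   degenerate tables), `alwss_by_anatomy_type`, `prevalence`.
#' @export
analyze_cohort <- function(cohort, metrics) {
  labels <- as.integer(cohort$label)
  scores <- metrics$alwss_cm2
  roc <- roc_auc(scores, labels)
  safe_mood <- function(x) {
    tryCatch(moods_median_test(x[labels == 0L], x[labels == 1L]),
             error = function(e) list(chi2 = NA_real_, p = NA_real_,
                                      error = conditionMessage(e)))
  }
  covs <- list(
    pv_velocity_m_s = cohort$pv_velocity_m_s,
    pv_diameter_m = cohort$pv_diameter_m,
    sv_diameter_m = cohort$sv_diameter_m,
    sv_length_m = cohort$sv_length_m,
    sv_distance_m = cohort$sv_length_m / cohort$sv_tortuosity,
    alwss_cm2 = scores
  )
  by_type <- lapply(split(scores, cohort$anatomy_type), function(v)
    list(n = length(v), mean = mean(v), sd = if (length(v) > 1) sd(v)
         else NA_real_, median = median(v)))
  list(
    roc = roc,
    pearson_alwss_sv_diameter = pearson_r(cohort$sv_diameter_m, scores),
    pearson_alwss_pv_velocity = pearson_r(cohort$pv_velocity_m_s, scores),
    moods_tests = lapply(covs, safe_mood),
    alwss_by_anatomy_type = by_type,
    prevalence = mean(labels)
  )
}

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  cfg2 <- cfg
  cfg2$out_dir <- NULL
  jsonlite::write_json(
    rapply(unclass(cfg2), function(x)
      if (is.numeric(x)) signif(x, 15) else x, how = "replace"),
    tf, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}

write_cohort_outputs <- function(result, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- cbind(result$cohort, result$metrics[,
    c("mean_wss_pa", "threshold_pa", "alwss_cm2", "total_area_cm2")])
  tab$config_hash <- result$provenance$config_hash
  tab$package_version <- result$provenance$package_version
  write.csv(tab, file.path(cfg$out_dir, "cohort_metrics.csv"),
            row.names = FALSE)
  report <- list(provenance = result$provenance)
  if (!is.null(result$stats)) {
    s <- result$stats
    report$auc <- s$roc$auc
    report$roc_points <- s$roc$points
    report$best_threshold_cm2 <- s$roc$best_threshold
    report$correctly_classified_ratio <- s$roc$correctly_classified_ratio
    report$pearson_alwss_sv_diameter <- s$pearson_alwss_sv_diameter
    report$pearson_alwss_pv_velocity <- s$pearson_alwss_pv_velocity
    report$moods_tests <- lapply(s$moods_tests, function(m)
      m[c("chi2", "p")])
    report$alwss_by_anatomy_type <- s$alwss_by_anatomy_type
    report$prevalence <- s$prevalence
  }
  jsonlite::write_json(report, file.path(cfg$out_dir, "cohort_stats.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE, pretty = TRUE)
  invisible(result)
}

#' Sweep ALWSS over splenic vein diameter
#'
#' Holds every other covariate at its reference value and sweeps the SV
#' diameter, returning the computed ALWSS at each diameter. Used to probe
#' the model's monotone dependence of ALWSS on SV diameter.
#'
#' @param diameters_m SV diameters to sweep (m).
#' @param patient reference patient row; defaults to a mid-range patient
#'   (PV velocity 0.15 m/s, PV diameter 13 mm, SV length 100 mm,
#'   tortuosity 1.3, anatomy type 1).
#' @param cfg a [run_config()].
#' @return data.frame with `sv_diameter_m` and `alwss_cm2`.
#' @export
sweep_sv_diameter <- function(diameters_m = seq(0.008, 0.020, by = 0.001),
                              patient = NULL, cfg = run_config()) {
  if (is.null(patient))
    patient <- data.frame(id = "SWEEP", pv_velocity_m_s = 0.15,
                          pv_diameter_m = 0.013, sv_diameter_m = NA,
                          sv_length_m = 0.100, sv_tortuosity = 1.3,
                          anatomy_type = 1L, stringsAsFactors = FALSE)
  rows <- lapply(diameters_m, function(d) {
    p <- patient
    p$sv_diameter_m <- d
    m <- run_patient(p, cfg)
    data.frame(sv_diameter_m = d, alwss_cm2 = m$alwss_cm2)
  })
  do.call(rbind, rows)
}
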