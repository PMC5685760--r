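#' Pipeline configuration
#'
#' Everything needed to run the cohort analysis end to end, either from
#' a precomputed feature table or from per-patient NIfTI volume/label
#' pairs. All randomized stages (permutations, bootstrap) draw from the
#' explicit `seed`.
#'
#' @param cohort data.frame with `patient_id`, `time_months`, `event`
#'   and the marker columns (alternative to `cohort_csv`).
#' @param cohort_csv path to a cohort CSV with the same columns.
#' @param volumes_dir,labels_dir optional directories of per-patient
#'   NIfTI pairs (`<patient_id>.nii[.gz]`); when given, features are
#'   extracted from the images and joined to the cohort table by
#'   `patient_id`.
#' @param markers marker columns analyzed (cutoffs, Cox, composite
#'   score).
#' @param model_sets named list of predictor sets for the discrimination
#'   report; default: each marker alone plus the nested combinations.
#' @param reference_model reference model name for comparisons.
#' @param thresholds_pct HF thresholds (image mode).
#' @param mtv_threshold_mode `"background_2sd"` or `"fixed"` (with
#'   `mtv_threshold_value`) for the image-mode MTV isocontour.
#' @param mtv_threshold_value fixed SUV threshold when mode is "fixed".
#' @param stepwise_alpha entry alpha for forward stepwise Cox.
#' @param dichotomize dichotomize markers at their Contal-O'Quigley
#'   cutoffs before the Cox stages (the reported hazard ratios are then
#'   high-vs-low); FALSE fits the continuous markers.
#' @param B_boot bootstrap resamples for iAUC difference CIs.
#' @param seed master seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = NULL, cohort_csv = NULL,
                            volumes_dir = NULL, labels_dir = NULL,
                            markers = c("nodal_suvmax", "wbmtv", "hf"),
                            model_sets = NULL,
                            reference_model = NULL,
                            thresholds_pct = c(40, 50, 60, 70, 80),
                            mtv_threshold_mode = c("background_2sd", "fixed"),
                            mtv_threshold_value = NULL,
                            stepwise_alpha = 0.05,
                            dichotomize = TRUE,
                            B_boot = 500,
                            seed = 1L) {
  mtv_threshold_mode <- match.arg(mtv_threshold_mode)
  if (is.null(cohort) && is.null(cohort_csv))
    stop("provide a cohort table or a cohort CSV path")
  if (is.null(model_sets)) {
    model_sets <- c(
      lapply(stats::setNames(markers, markers), identity),
      if (length(markers) >= 2)
        stats::setNames(list(markers[1:2]),
                        paste(markers[1:2], collapse = "+")),
      if (length(markers) >= 3) c(
        stats::setNames(list(markers[c(1, 3)]),
                        paste(markers[c(1, 3)], collapse = "+")),
        stats::setNames(list(markers), paste(markers, collapse = "+"))))
  }
  if (is.null(reference_model)) reference_model <- names(model_sets)[1]
  structure(list(cohort = cohort, cohort_csv = cohort_csv,
                 volumes_dir = volumes_dir, labels_dir = labels_dir,
                 markers = markers, model_sets = model_sets,
                 reference_model = reference_model,
                 thresholds_pct = thresholds_pct,
                 mtv_threshold_mode = mtv_threshold_mode,
                 mtv_threshold_value = mtv_threshold_value,
                 stepwise_alpha = stepwise_alpha,
                 dichotomize = dichotomize,
                 B_boot = B_boot, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read and validate a cohort CSV
#'
#' Requires columns `patient_id`, `time_months`, `event`; every other
#' column is treated as a feature/covariate. Duplicate patient ids,
#' non-positive times, non-0/1 events and non-numeric feature cells are
#' errors naming the offender.
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(df)
}

#' @rdname read_cohort
#' @param df an in-memory cohort data.frame.
#' @export
validate_cohort <- function(df) {
  need <- c("patient_id", "time_months", "event")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing required columns: ",
                         paste(miss, collapse = ", "))
  dup <- df$patient_id[duplicated(df$patient_id)]
  if (length(dup)) stop("duplicate patient_id: ",
                        paste(unique(dup), collapse = ", "))
  if (!is.numeric(df$time_months) || any(is.na(df$time_months)) ||
      any(df$time_months <= 0))
    stop("time_months must be positive numeric")
  if (!all(df$event %in% c(0, 1))) stop("event must be 0/1")
  for (nm in setdiff(names(df), need)) {
    if (!is.numeric(df[[nm]]) && !is.character(df[[nm]]) &&
        !is.factor(df[[nm]]))
      stop("column ", nm, " has unsupported type")
  }
  df
}

# image-mode feature extraction: one volume/label NIfTI pair per patient
extract_cohort_features <- function(volumes_dir, labels_dir,
                                    thresholds_pct, mtv_threshold = NULL) {
  vols <- list.files(volumes_dir, pattern = "\\.nii(\\.gz)?$",
                     full.names = TRUE)
  if (!length(vols)) stop("no NIfTI volumes found in ", volumes_dir)
  rows <- lapply(vols, function(vp) {
    id <- sub("\\.nii(\\.gz)?$", "", basename(vp))
    lp <- file.path(labels_dir, basename(vp))
    if (!file.exists(lp))
      stop("no label image for patient ", id, " (expected ", lp, ")")
    ph <- read_phantom_nifti(vp, lp)
    f <- extract_features(ph$volume, ph$lesions, thresholds_pct,
                          mtv_threshold = mtv_threshold)
    cbind(data.frame(patient_id = id), as.data.frame(f))
  })
  do.call(rbind, rows)
}

# tiny stable rolling hash of a string, for provenance
.config_hash <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 4294967291
  sprintf("%010.0f", h)
}

#' Run the full prognostic analysis pipeline
#'
#' Stages: (optional) image-based feature extraction; two-group
#' comparison of every feature by recurrence status; Spearman
#' correlations among the markers; a Contal-O'Quigley cutoff per marker;
#' univariate Cox per marker (dichotomized at its cutoff by default);
#' forward stepwise multivariable Cox over the markers; the
#' discrimination report over the configured model sets; Cox-coefficient
#' risk weights, the composite weighted score, and three risk groups
#' with their log-rank test. Deterministic given the config (seeded
#' bootstrap; no timestamps inside numeric tables).
#'
#' @param config a [pipeline_config()].
#' @return object of class `analysis_report`: named list of tables
#'   (`cohort_summary`, `correlations`, `cutoffs`, `cox_univariate`,
#'   `cox_multivariate`, `stepwise_trace`, `discrimination`,
#'   `risk_groups`, `risk_weights`) plus `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- if (!is.null(config$cohort)) validate_cohort(config$cohort)
            else read_cohort(config$cohort_csv)

  if (!is.null(config$volumes_dir)) {
    thr <- if (config$mtv_threshold_mode == "fixed")
      config$mtv_threshold_value else NULL
    feats <- extract_cohort_features(config$volumes_dir, config$labels_dir,
                                     config$thresholds_pct, thr)
    cohort <- merge(cohort, feats, by = "patient_id", sort = TRUE)
  }
  if (sum(cohort$event) == 0)
    stop("cohort has zero events: survival stages cannot run")
  markers <- config$markers
  miss <- setdiff(markers, names(cohort))
  if (length(miss)) stop("marker columns missing from cohort: ",
                         paste(miss, collapse = ", "))
  time <- cohort$time_months; event <- cohort$event

  feat_cols <- setdiff(names(cohort), c("patient_id", "time_months", "event"))
  summary_tab <- compare_groups(cohort[, feat_cols, drop = FALSE], event)
  correlations <- correlate_features(cohort[, markers, drop = FALSE])

  cut_rows <- lapply(markers, function(m) {
    co <- contal_oquigley(time, event, cohort[[m]])
    data.frame(marker = m, cutoff = co$cutoff, max_stat = co$max_stat,
               p_corrected = co$p_corrected, sensitivity = co$sensitivity,
               specificity = co$specificity, auc = co$auc_binary)
  })
  cutoffs <- do.call(rbind, cut_rows)

  xmat <- cohort[, markers, drop = FALSE]
  if (config$dichotomize) {
    for (m in markers)
      xmat[[m]] <- as.numeric(cohort[[m]] > cutoffs$cutoff[cutoffs$marker == m])
  }
  uni_rows <- lapply(markers, function(m) {
    fit <- cox_fit(time, event, xmat[, m, drop = FALSE])
    data.frame(marker = m, hr = unname(fit$hr), lower95 = fit$ci95[1, 1],
               upper95 = fit$ci95[1, 2], p = unname(fit$p))
  })
  cox_univariate <- do.call(rbind, uni_rows)

  sw <- forward_stepwise_cox(time, event, xmat, markers,
                             alpha_enter = config$stepwise_alpha)
  cox_multivariate <- if (is.null(sw$fit)) {
    data.frame(marker = character(0), hr = numeric(0), lower95 = numeric(0),
               upper95 = numeric(0), p = numeric(0))
  } else data.frame(marker = names(sw$fit$beta), hr = unname(sw$fit$hr),
                    lower95 = sw$fit$ci95[, 1], upper95 = sw$fit$ci95[, 2],
                    p = unname(sw$fit$p), row.names = NULL)

  discrimination <- discrimination_report(
    cohort, config$model_sets, config$reference_model,
    B = config$B_boot, seed = config$seed)

  # composite weighted score from the all-marker Cox fit
  full_fit <- cox_fit(time, event, xmat)
  ref_marker <- if (length(markers) >= 2) markers[2] else markers[1]
  weights <- risk_weights(full_fit, reference = ref_marker)
  score <- as.matrix(xmat) %*% weights
  groups <- tryCatch(
    assign_risk_groups(as.vector(score), time, event, n_groups = 3),
    error = function(e) assign_risk_groups(as.vector(score), time, event,
                                           n_groups = 2))
  lr <- attr(groups, "logrank")
  km_rows <- lapply(levels(groups), function(g) {
    idx <- groups == g
    data.frame(group = g, n = sum(idx), events = sum(event[idx]),
               median_score = stats::median(score[idx]))
  })
  risk_groups <- do.call(rbind, km_rows)
  attr(risk_groups, "logrank") <- lr

  cfg_json <- jsonlite::toJSON(
    config[setdiff(names(config), c("cohort"))],
    auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  provenance <- list(config_hash = .config_hash(as.character(cfg_json)),
                     seed = config$seed,
                     n_patients = nrow(cohort),
                     n_events = sum(event),
                     package_version = as.character(utils::packageVersion("hfpet")),
                     r_version = R.version.string)

  structure(list(cohort_summary = summary_tab,
                 correlations = correlations,
                 cutoffs = cutoffs,
                 cox_univariate = cox_univariate,
                 cox_multivariate = cox_multivariate,
                 stepwise_trace = sw$trace,
                 discrimination = discrimination,
                 risk_weights = data.frame(marker = names(weights),
                                           weight = unname(weights)),
                 risk_groups = risk_groups,
                 logrank_groups = data.frame(chi2 = lr$chi2, df = lr$df,
                                             p = lr$p),
                 provenance = provenance),
            class = "analysis_report")
}

#' Write an analysis report to disk
#'
#' One CSV per numeric table plus a JSON provenance block. Written at
#' full precision so identical runs are byte-identical.
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- setdiff(names(report), "provenance")
  paths <- character(0)
  for (nm in tables) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(report[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  pj <- file.path(dir, "provenance.json")
  jsonlite::write_json(report$provenance, pj, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, pj))
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Analysis report —", x$provenance$n_patients, "patients,",
      x$provenance$n_events, "events\n")
  cat("\nCutoffs (Contal-O'Quigley):\n"); print(x$cutoffs)
  cat("\nMultivariable Cox (forward stepwise):\n"); print(x$cox_multivariate)
  cat("\nDiscrimination:\n"); print(x$discrimination)
  invisible(x)
}
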