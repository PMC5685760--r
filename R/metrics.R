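#' Standardized uptake value from activity concentration
#'
#' SUV = activity concentration (MBq/g) / (injected dose (MBq) / body
#' weight (g)); dimensionless.
#'
#' @param activity_conc activity concentration in MBq/g.
#' @param injected_dose injected dose in MBq, > 0.
#' @param body_weight body weight in g, > 0.
#' @return SUV (same length as `activity_conc`).
#' @export
compute_suv <- function(activity_conc, injected_dose, body_weight) {
  if (any(injected_dose <= 0)) stop("injected dose must be positive")
  if (any(body_weight <= 0)) stop("body weight must be positive")
  activity_conc / (injected_dose / body_weight)
}

#' MTV isocontour threshold from the mediastinal background
#'
#' Mean SUV of the background reference region plus `n_sd` standard
#' deviations (sample SD by default, the convention in the surrounding
#' survival/biostatistics software; population SD available).
#'
#' @param volume an [suv_volume()].
#' @param lesions a [lesion_set()] with one background-role region.
#' @param n_sd number of SDs above the mean (default 2).
#' @param sd_type `"sample"` (n-1 denominator) or `"population"`.
#' @return SUV threshold (scalar).
#' @export
background_threshold <- function(volume, lesions, n_sd = 2,
                                 sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  m <- role_mask(lesions, "background")
  if (!any(m)) stop("background region is empty")
  x <- volume$values[m]
  s <- if (length(x) < 2L) 0
       else if (sd_type == "sample") stats::sd(x)
       else sqrt(mean((x - mean(x))^2))
  mean(x) + n_sd * s
}

#' Metabolic parameters of a single lesion
#'
#' SUVmax over the lesion mask; MTV as the volume of mask voxels with
#' SUV >= threshold (inclusive: ties belong to the lesion); SUVmean over
#' those MTV voxels; TLG = MTV x SUVmean. If no voxel passes the
#' threshold, MTV and TLG are 0 and SUVmean is reported as 0 with
#' `empty_mtv = TRUE` (rather than NaN) so TLG stays defined. The mask is
#' taken as the containment contract: all supra-threshold voxels inside it
#' count, with no connected-component filtering.
#'
#' @param volume an [suv_volume()].
#' @param mask logical array (same shape) delimiting the lesion VOI.
#' @param threshold SUV threshold, >= 0.
#' @return object of class `lesion_metrics`: list with `suv_max`,
#'   `suv_mean`, `mtv_cm3`, `tlg`, `threshold_used`, `n_voxels`,
#'   `empty_mtv`.
#' @export
lesion_metrics <- function(volume, mask, threshold) {
  if (!identical(dim(mask), dim(volume$values)))
    stop("mask shape does not match the volume")
  if (!any(mask)) stop("lesion mask is empty")
  if (threshold < 0) stop("threshold must be >= 0")
  v <- volume$values[mask]
  suv_max <- max(v)
  sel <- v >= threshold
  n <- sum(sel)
  mtv <- n * voxel_volume_mm3(volume) / 1000
  suv_mean <- if (n == 0L) 0 else mean(v[sel])
  structure(list(suv_max = suv_max, suv_mean = suv_mean,
                 mtv_cm3 = mtv, tlg = mtv * suv_mean,
                 threshold_used = threshold, n_voxels = n,
                 empty_mtv = n == 0L),
            class = "lesion_metrics")
}

#' Aggregate lesion metrics to patient level
#'
#' Nodal SUVmax is the maximum across nodes (0 when there are none),
#' nodal MTV/TLG are sums, and whole-body MTV/TLG are the primary value
#' plus the nodal sum — exactly additive by construction.
#'
#' @param primary `lesion_metrics` of the primary tumor.
#' @param nodes list of `lesion_metrics`, one per regional node.
#' @param hf optional heterogeneity factor of the primary (from
#'   [fit_hf()]), carried through.
#' @return object of class `patient_features`: named list of the
#'   patient-level metabolic parameters.
#' @export
aggregate_patient <- function(primary, nodes = list(), hf = NULL) {
  stopifnot(inherits(primary, "lesion_metrics"))
  nodal_suv_max <- if (length(nodes)) max(vapply(nodes, `[[`, 0, "suv_max")) else 0
  nodal_mtv <- sum(vapply(nodes, `[[`, 0, "mtv_cm3"))
  nodal_tlg <- sum(vapply(nodes, `[[`, 0, "tlg"))
  structure(list(
    primary_suvmax = primary$suv_max,
    primary_suvmean = primary$suv_mean,
    primary_mtv_cm3 = primary$mtv_cm3,
    primary_tlg = primary$tlg,
    nodal_suvmax = nodal_suv_max,
    nodal_mtv_cm3 = nodal_mtv,
    nodal_tlg = nodal_tlg,
    wb_mtv_cm3 = primary$mtv_cm3 + nodal_mtv,
    wb_tlg = primary$tlg + nodal_tlg,
    hf = if (is.null(hf)) NA_real_ else hf$hf),
    class = "patient_features")
}

#' Full per-patient feature extraction from a volume + lesion set
#'
#' Computes the background-derived MTV threshold, per-lesion metrics for
#' the primary and every node, the heterogeneity factor of the primary,
#' and aggregates to patient level.
#'
#' @param volume an [suv_volume()].
#' @param lesions a [lesion_set()].
#' @param thresholds_pct HF thresholds, % of SUVmax.
#' @param mtv_threshold optional fixed SUV threshold; default is
#'   [background_threshold()] (background mean + 2 SD).
#' @return a `patient_features` object.
#' @export
extract_features <- function(volume, lesions,
                             thresholds_pct = c(40, 50, 60, 70, 80),
                             mtv_threshold = NULL) {
  thr <- if (is.null(mtv_threshold)) background_threshold(volume, lesions)
         else mtv_threshold
  primary <- lesion_metrics(volume, role_mask(lesions, "primary"), thr)
  nodes <- lapply(node_labels(lesions), function(l)
    lesion_metrics(volume, role_mask(lesions, label = l), thr))
  hf <- hf_for_patient(volume, lesions, thresholds_pct)
  aggregate_patient(primary, nodes, hf = hf)
}

#' @export
as.data.frame.patient_features <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}
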