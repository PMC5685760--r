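#' Volume-threshold function of a lesion
#'
#' For each relative threshold t (% of the measured SUVmax inside the
#' mask), the volume of mask voxels with SUV >= (t/100) * SUVmax, in cm^3.
#' The default thresholds are 40, 50, 60, 70 and 80% of SUVmax: values
#' below 40% admit too much background activity and values above 80%
#' leave volumes dominated by partial-volume effects, so both ends are
#' excluded from the heterogeneity analysis.
#'
#' @param volume an [suv_volume()].
#' @param mask logical array delimiting the lesion (primary tumor).
#' @param thresholds_pct strictly increasing thresholds in (0, 100].
#' @return object of class `vt_curve`: data.frame with `threshold_pct`
#'   and `volume_cm3` (non-increasing in threshold), with the measured
#'   SUVmax as attribute `suv_max`.
#' @export
volume_threshold_curve <- function(volume, mask,
                                   thresholds_pct = c(40, 50, 60, 70, 80)) {
  if (!any(mask)) stop("lesion mask is empty")
  if (any(thresholds_pct <= 0 | thresholds_pct > 100))
    stop("thresholds must be in (0, 100]")
  if (length(thresholds_pct) < 2L || any(diff(thresholds_pct) <= 0))
    stop("need >= 2 strictly increasing thresholds")
  v <- volume$values[mask]
  suv_max <- max(v)
  vv <- voxel_volume_mm3(volume) / 1000
  vols <- vapply(thresholds_pct,
                 function(t) sum(v >= t / 100 * suv_max) * vv, 0)
  structure(data.frame(threshold_pct = thresholds_pct, volume_cm3 = vols),
            suv_max = suv_max, class = c("vt_curve", "data.frame"))
}

#' Heterogeneity factor from a volume-threshold curve
#'
#' Ordinary least squares of volume (cm^3) on threshold (percentage
#' points); the heterogeneity factor is the absolute slope |dV/dT| in
#' cm^3 per percentage point. A steeper volume loss across thresholds
#' means more heterogeneous uptake; a uniform lesion has HF = 0. Zero
#' volumes at high thresholds (small tumors) are legitimate points and
#' are kept in the fit.
#'
#' @param curve a `vt_curve` (or data.frame with `threshold_pct`,
#'   `volume_cm3`).
#' @return object of class `hf_result`: list with `slope_cm3_per_pct`,
#'   `intercept_cm3`, `hf`, `r2`.
#' @export
fit_hf <- function(curve) {
  x <- curve$threshold_pct; y <- curve$volume_cm3
  if (length(unique(x)) < 2L)
    stop("need >= 2 distinct thresholds to fit the volume-threshold slope")
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss < 1e-12) 1 else 1 - sum(stats::residuals(fit)^2) / tss
  structure(list(slope_cm3_per_pct = slope,
                 intercept_cm3 = unname(stats::coef(fit)[1]),
                 hf = abs(slope), r2 = r2),
            class = "hf_result")
}

#' Heterogeneity factor of a patient's primary tumor
#'
#' Composition of [volume_threshold_curve()] and [fit_hf()] on the
#' primary-tumor mask. Thresholds are relative to the measured (post-
#' noise) SUVmax within the mask, as a scanner workstation would use, so
#' the HF is invariant to a global rescaling of all SUVs.
#'
#' @param volume an [suv_volume()].
#' @param lesions a [lesion_set()].
#' @param thresholds_pct thresholds, % of SUVmax.
#' @return an `hf_result`, with the curve attached as attribute `curve`.
#' @export
hf_for_patient <- function(volume, lesions,
                           thresholds_pct = c(40, 50, 60, 70, 80)) {
  curve <- volume_threshold_curve(volume, role_mask(lesions, "primary"),
                                  thresholds_pct)
  res <- fit_hf(curve)
  attr(res, "curve") <- curve
  res
}
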