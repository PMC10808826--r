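#' Low wall shear stress area metrics
#'
#' The risk score is the area of low wall shear stress (ALWSS): the wall
#' area of the whole postoperative portal venous surface (stump included)
#' exposed to WSS strictly below a patient-specific threshold, set as 20%
#' of the area-weighted space-averaged WSS of the same surface. Areas are
#' reported in cm^2 and stresses in Pa, matching clinical convention.
#'
#' @name wss_metrics
NULL

#' Area-weighted space-averaged wall shear stress
#'
#' @param field a `wss_field`.
#' @return mean WSS in Pa, `sum(tau_i * area_i) / sum(area_i)`.
#' @export
space_averaged_wss <- function(field) {
  strips <- field$strips
  if (is.null(strips) || nrow(strips) == 0 || sum(strips$area_m2) <= 0)
    stop("WSS field is empty", call. = FALSE)
  sum(strips$tau_w_pa * strips$area_m2) / sum(strips$area_m2)
}

#' Patient-specific low-WSS threshold
#'
#' @param mean_wss space-averaged WSS, Pa (>= 0).
#' @param fraction fraction of the mean defining "low" (default 0.2).
#' @return threshold in Pa.
#' @export
low_wss_threshold <- function(mean_wss, fraction = 0.2) {
  if (mean_wss < 0) stop("mean_wss must be >= 0", call. = FALSE)
  if (!(fraction > 0 && fraction < 1))
    stop("fraction must be in (0, 1)", call. = FALSE)
  fraction * mean_wss
}

#' Area of low wall shear stress (ALWSS)
#'
#' Sums the areas of all strips with WSS strictly below the threshold
#' (ties at the threshold are excluded; in particular a zero threshold
#' yields zero area even on stagnant strips).
#'
#' @param field a `wss_field`.
#' @param threshold threshold WSS, Pa (>= 0).
#' @return low-WSS area in cm^2.
#' @export
alwss <- function(field, threshold) {
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  strips <- field$strips
  m2_to_cm2(sum(strips$area_m2[strips$tau_w_pa < threshold]))
}

#' All WSS metrics for a field
#'
#' @param field a `wss_field`.
#' @param fraction low-WSS fraction of the mean (default 0.2).
#' @return list with `mean_wss_pa`, `threshold_pa`, `alwss_cm2`,
#'   `total_area_cm2`.
#' @export
wss_metrics <- function(field, fraction = 0.2) {
  mean_wss <- space_averaged_wss(field)
  thr <- low_wss_threshold(mean_wss, fraction)
  list(
    mean_wss_pa = mean_wss,
    threshold_pa = thr,
    alwss_cm2 = alwss(field, thr),
    total_area_cm2 = m2_to_cm2(sum(field$strips$area_m2))
  )
}
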