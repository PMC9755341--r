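# Heart-to-mediastinum ratio computation and pathological classification.
#
# H/M is the mean counts per pixel in the cardiac ROI divided by the mean
# counts per pixel in the mediastinal ROI (mean, not integrated, counts:
# ROI areas differ between methods and raters).  Classification uses the
# published cut-offs with a strict inequality: early H/M < 1.9 or late
# H/M < 1.7 is pathological; a ratio exactly at the cut-off is not.

#' Heart-to-mediastinum ratio
#'
#' @param image A [planar_image()] or numeric matrix.
#' @param cardiac_roi,mediastinal_roi ROI objects.
#' @return The dimensionless H/M ratio.
#' @export
hm_ratio <- function(image, cardiac_roi, mediastinal_roi) {
  h <- mean_counts(image, cardiac_roi)
  m <- mean_counts(image, mediastinal_roi)
  if (!is.finite(m) || m <= 0) {
    stop_mibg("mibg_division", "mediastinal ROI has zero mean counts")
  }
  h / m
}

#' Default pathological cut-offs
#'
#' Early H/M below 1.9 or late H/M below 1.7 is classified pathological
#' (reduced cardiac sympathetic innervation).
#'
#' @return Named numeric vector with elements `early` and `late`.
#' @export
default_cutoffs <- function() c(early = 1.9, late = 1.7)

#' Classify early/late H/M ratios against the pathological cut-offs
#'
#' @param early_hm,late_hm Positive H/M ratios.  Either may be `NA` to skip
#'   that phase.
#' @param cutoffs Named numeric vector with `early` and `late` cut-offs.
#' @return List of class `hm_classification` with logical elements
#'   `early_pathological` and `late_pathological` plus the cut-offs used.
#' @export
classify_hm <- function(early_hm, late_hm = NA_real_,
                        cutoffs = default_cutoffs()) {
  if (!all(cutoffs > 0)) {
    stop_mibg("mibg_argument", "cut-offs must be positive")
  }
  check_ratio <- function(r, what) {
    if (!is.na(r) && (!is.finite(r) || r <= 0)) {
      stop_mibg("mibg_argument", "%s H/M ratio must be positive", what)
    }
  }
  check_ratio(early_hm, "early")
  check_ratio(late_hm, "late")
  structure(
    list(
      early_pathological = if (is.na(early_hm)) NA else
        early_hm < cutoffs[["early"]],
      late_pathological = if (is.na(late_hm)) NA else
        late_hm < cutoffs[["late"]],
      cutoff_early = cutoffs[["early"]],
      cutoff_late = cutoffs[["late"]]
    ),
    class = "hm_classification"
  )
}
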