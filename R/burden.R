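#' Per-patient AF burden from both sources
#'
#' AF burden is the percentage of analyzable monitored time spent in AF. Both
#' burdens use the analyzable mask as denominator (consistent with the
#' exclusion rule applied to every other metric): the Holter burden is
#' annotated AF time within the mask, the ICM burden is detected AF time
#' within the mask, each divided by total mask time.
#'
#' @param icm_log a synchronized [icm_log()].
#' @param track the patient's [annotation_track()].
#' @param retained_only use only classifier-retained episodes.
#' @return one-row data.frame: `patient_id`, `holter_burden_pct`,
#'   `icm_burden_pct`, `mask_s`, `undefined` (TRUE when the mask is empty).
#' @export
compute_burdens <- function(icm_log, track, retained_only = FALSE) {
  mask <- build_mask(track)
  if (mask$total_s <= 0)
    return(data.frame(patient_id = track$patient_id, holter_burden_pct = NA_real_,
                      icm_burden_pct = NA_real_, mask_s = 0, undefined = TRUE))
  af <- iv_length(iv_intersect(track_intervals(track, "AF"), mask$intervals))
  icm <- iv_length(iv_intersect(log_intervals(icm_log, retained_only), mask$intervals))
  data.frame(patient_id = track$patient_id,
             holter_burden_pct = 100 * af / mask$total_s,
             icm_burden_pct = 100 * icm / mask$total_s,
             mask_s = mask$total_s, undefined = FALSE)
}

#' Burden agreement: Pearson correlation and Bland-Altman analysis
#'
#' Differences are taken as ICM minus Holter, so a negative bias means the
#' device under-detects AF time. Limits of agreement are
#' `bias +/- 1.96 * sd(d)` with the sample (n-1) standard deviation.
#'
#' @param pairs data.frame of [compute_burdens()] rows.
#' @return list with `n`, `pearson_r`, `bias_pct`, `loa_low`, `loa_high`,
#'   `sd_diff`, `flag` (`"ok"` or `"zero_variance"`; `r` is NA when either
#'   axis has no variance).
#' @export
burden_agreement <- function(pairs) {
  pairs <- pairs[!pairs$undefined, , drop = FALSE]
  if (nrow(pairs) < 3L) stop("burden agreement needs >= 3 patients with a non-empty mask")
  h <- pairs$holter_burden_pct
  i <- pairs$icm_burden_pct
  d <- i - h
  bias <- mean(d)
  sdd <- stats::sd(d)
  zero_var <- stats::sd(h) == 0 || stats::sd(i) == 0
  r <- if (zero_var) NA_real_ else stats::cor(h, i)
  list(n = nrow(pairs), pearson_r = r, bias_pct = bias,
       loa_low = bias - 1.96 * sdd, loa_high = bias + 1.96 * sdd,
       sd_diff = sdd, flag = if (zero_var) "zero_variance" else "ok")
}
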