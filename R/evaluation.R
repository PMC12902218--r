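#' Analyzable time mask
#'
#' AF detection performance is assessed only on Holter time that is neither
#' uninterpretable (noise, lead disconnection) nor annotated as atrial
#' tachycardia / atrial flutter: both are excluded from the recording span
#' before any metric is computed.
#'
#' @param track an [annotation_track()].
#' @return an `analyzable_mask`: list with `patient_id`, `intervals` (disjoint
#'   sorted [iv()]) and `total_s`.
#' @export
build_mask <- function(track) {
  stopifnot(inherits(track, "annotation_track"))
  excl <- iv_union(track_intervals(track, "UNINTERPRETABLE"),
                   track_intervals(track, "ATFL"))
  m <- iv_setdiff(iv(0, track$span_s), excl)
  structure(list(patient_id = track$patient_id, intervals = m,
                 total_s = iv_length(m)),
            class = "analyzable_mask")
}

#' True AF events eligible for episode-level assessment
#'
#' Annotated AF intervals whose *unclipped* duration is at least
#' `min_duration_s` (the device's 2-minute detection floor applies to the
#' annotation, not to what remains after masking), clipped to the analyzable
#' mask. An event whose clipped remnant is empty lies entirely in excluded
#' time and is dropped from assessment; an event split by an excluded segment
#' keeps its identity as one event with several clipped segments.
#'
#' @param track an [annotation_track()].
#' @param min_duration_s eligibility threshold on the annotated duration (s).
#' @param mask optional precomputed [build_mask()] result.
#' @return list of events, each `list(event_id, start_s, end_s, duration_s,
#'   segments)` with `segments` the mask-clipped [iv()].
#' @export
true_af_events <- function(track, min_duration_s = 120, mask = NULL) {
  if (is.null(mask)) mask <- build_mask(track)
  af <- track_intervals(track, "AF")
  out <- list()
  for (k in seq_len(nrow(af))) {
    if (af[k, 2L] - af[k, 1L] < min_duration_s - 1e-9) next
    seg <- iv_intersect(iv(af[k, 1L], af[k, 2L]), mask$intervals)
    if (nrow(seg) == 0L) next
    out[[length(out) + 1L]] <- list(
      event_id = sprintf("%s-A%03d", track$patient_id, k),
      start_s = unname(af[k, 1L]), end_s = unname(af[k, 2L]),
      duration_s = unname(af[k, 2L] - af[k, 1L]), segments = seg)
  }
  out
}

#' Match ICM episodes against annotated AF events
#'
#' Episode-level scoring for one patient, on synchronized time. Each ICM
#' episode receives exactly one status: `excluded` if it lies entirely outside
#' the analyzable mask, `true_positive` if its mask-clipped interval overlaps
#' any true AF event by more than `min_overlap_s` (default: any positive
#' overlap), else `false_positive`. A true AF event counts as detected when at
#' least one episode overlaps it; several episodes may match one event (each
#' stays an independent true positive — episodes and events are counted on
#' their own denominators), and one episode spanning several events is a
#' single true positive.
#'
#' @param icm_log a synchronized [icm_log()] (see [apply_sync()]).
#' @param track the patient's [annotation_track()].
#' @param min_overlap_s minimum overlap (s) to qualify as a match; 0 = any
#'   positive overlap.
#' @param retained_only score only episodes retained by the AI classifier
#'   (`ai_retained` missing counts as retained): the post-classification view.
#' @param min_event_duration_s eligibility threshold for true events.
#' @return an `episode_match`: list with `patient_id`, `events` (data.frame:
#'   `event_id`, `duration_s`, `detected`, `n_matching`), `episodes`
#'   (data.frame: `episode_id`, `duration_s`, `status`, `cause_label`,
#'   `ai_retained`, `matched_events`) and `mask`.
#' @export
match_episodes <- function(icm_log, track, min_overlap_s = 0,
                           retained_only = FALSE, min_event_duration_s = 120) {
  stopifnot(inherits(icm_log, "icm_log"), inherits(track, "annotation_track"))
  mask <- build_mask(track)
  events <- true_af_events(track, min_event_duration_s, mask)
  ep <- icm_log$episodes
  if (retained_only && nrow(ep))
    ep <- ep[is.na(ep$ai_retained) | ep$ai_retained, , drop = FALSE]

  n_ep <- nrow(ep)
  status <- character(n_ep)
  matched <- character(n_ep)
  ev_hit <- integer(length(events))
  for (i in seq_len(n_ep)) {
    clipped <- iv_intersect(iv(ep$start_s[i], ep$end_s[i]), mask$intervals)
    if (nrow(clipped) == 0L) { status[i] <- "excluded"; matched[i] <- ""; next }
    hits <- which(vapply(events, function(e)
      iv_length(iv_intersect(clipped, e$segments)) > min_overlap_s, logical(1)))
    if (length(hits)) {
      status[i] <- "true_positive"
      matched[i] <- paste(vapply(events[hits], `[[`, "", "event_id"), collapse = ";")
      ev_hit[hits] <- ev_hit[hits] + 1L
    } else {
      status[i] <- "false_positive"
      matched[i] <- ""
    }
  }
  structure(list(
    patient_id = track$patient_id,
    events = data.frame(
      event_id = vapply(events, `[[`, "", "event_id"),
      duration_s = vapply(events, `[[`, 0, "duration_s"),
      detected = ev_hit > 0L, n_matching = ev_hit,
      stringsAsFactors = FALSE),
    episodes = data.frame(
      episode_id = as.character(ep$episode_id),
      duration_s = ep$end_s - ep$start_s,
      status = status,
      cause_label = as.character(ep$cause_label),
      ai_retained = ep$ai_retained,
      matched_events = matched,
      stringsAsFactors = FALSE),
    mask = mask), class = "episode_match")
}

#' Episode-based sensitivity and PPV across a cohort
#'
#' Episode sensitivity is the proportion of true AF events detected; episode
#' PPV is the proportion of (non-excluded) ICM episodes that are true
#' positives. Each is reported three ways: `gross` (pooled numerators and
#' denominators across patients, exact binomial CI), `patient_average`
#' (unweighted mean of per-patient proportions over patients with a defined
#' denominator, normal-approximation CI), and `gee` (cluster-adjusted, see
#' [gee_proportion()]).
#'
#' @param matches list of [match_episodes()] results, one per patient.
#' @param ci_method binomial CI method for the gross rows.
#' @return data.frame of metric estimates (one row per metric x estimator).
#' @export
episode_metrics <- function(matches, ci_method = "clopper-pearson") {
  stopifnot(length(matches) >= 1L)
  det <- vapply(matches, function(m) sum(m$events$detected), numeric(1))
  nev <- vapply(matches, function(m) nrow(m$events), numeric(1))
  tp <- vapply(matches, function(m) sum(m$episodes$status == "true_positive"), numeric(1))
  pos <- vapply(matches, function(m) sum(m$episodes$status %in%
                                           c("true_positive", "false_positive")), numeric(1))
  rbind(clustered_metric_rows("episode_sensitivity", det, nev, ci_method),
        clustered_metric_rows("episode_ppv", tp, pos, ci_method))
}

#' Duration-based confusion and metrics
#'
#' Time-overlap scoring on synchronized clocks: within the analyzable mask,
#' `tp` is time both annotated and detected as AF, `fp` detected but not
#' annotated, `fn` annotated but not detected, `tn` neither. Per patient the
#' four components partition the mask exactly. Cohort metrics pool seconds
#' across patients: sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, PPV
#' `tp/(tp+fp)`, NPV `tn/(tn+fn)`, accuracy `(tp+tn)/mask`.
#'
#' @param logs a synchronized [icm_log()] or list of them.
#' @param tracks the matching [annotation_track()] or list.
#' @param retained_only use only classifier-retained episodes (post-AI view).
#' @return list with `confusion` (data.frame, one row per patient: `tp_s`,
#'   `fp_s`, `tn_s`, `fn_s`, `mask_s`) and `metrics` (data.frame of pooled
#'   estimates; zero-denominator metrics are flagged undefined).
#' @export
duration_metrics <- function(logs, tracks, retained_only = FALSE) {
  if (inherits(logs, "icm_log")) logs <- list(logs)
  if (inherits(tracks, "annotation_track")) tracks <- list(tracks)
  stopifnot(length(logs) == length(tracks))
  confusion <- do.call(rbind, lapply(seq_along(logs), function(i) {
    track <- tracks[[i]]
    mask <- build_mask(track)
    af <- iv_intersect(track_intervals(track, "AF"), mask$intervals)
    icm <- iv_intersect(log_intervals(logs[[i]], retained_only), mask$intervals)
    tp <- iv_length(iv_intersect(af, icm))
    fp <- iv_length(iv_setdiff(icm, af))
    fn <- iv_length(iv_setdiff(af, icm))
    tn <- mask$total_s - tp - fp - fn
    data.frame(patient_id = track$patient_id, tp_s = tp, fp_s = fp,
               tn_s = tn, fn_s = fn, mask_s = mask$total_s,
               stringsAsFactors = FALSE)
  }))
  tot <- colSums(confusion[, c("tp_s", "fp_s", "tn_s", "fn_s", "mask_s")])
  drow <- function(name, num, den) {
    if (den <= 0) metric_row(name, "gross", undefined = TRUE)
    else metric_row(name, "gross", num / den, k = num, n = den)
  }
  metrics <- rbind(
    drow("duration_sensitivity", tot[["tp_s"]], tot[["tp_s"]] + tot[["fn_s"]]),
    drow("duration_specificity", tot[["tn_s"]], tot[["tn_s"]] + tot[["fp_s"]]),
    drow("duration_ppv", tot[["tp_s"]], tot[["tp_s"]] + tot[["fp_s"]]),
    drow("duration_npv", tot[["tn_s"]], tot[["tn_s"]] + tot[["fn_s"]]),
    drow("duration_accuracy", tot[["tp_s"]] + tot[["tn_s"]], tot[["mask_s"]]))
  list(confusion = confusion, metrics = metrics)
}

#' Patient-based (diagnostic) metrics
#'
#' Classifies every patient by truth (at least one eligible true AF event) and
#' by device (at least one non-excluded ICM episode — after classification,
#' at least one retained non-excluded episode), then reports sensitivity,
#' specificity, PPV and NPV of the resulting 2x2 table with exact binomial
#' CIs. Zero-denominator metrics are flagged undefined.
#'
#' @param matches list of [match_episodes()] results (built with
#'   `retained_only = TRUE` for the post-classification view).
#' @param ci_method binomial CI method.
#' @return data.frame of metric estimates plus attribute `table` (the 2x2
#'   counts: tp, fp, tn, fn patients).
#' @export
patient_diagnostics <- function(matches, ci_method = "clopper-pearson") {
  truth <- vapply(matches, function(m) nrow(m$events) > 0L, logical(1))
  device <- vapply(matches, function(m)
    any(m$episodes$status %in% c("true_positive", "false_positive")), logical(1))
  counts <- c(tp = sum(truth & device), fp = sum(!truth & device),
              tn = sum(!truth & !device), fn = sum(truth & !device))
  metrics <- rbind(
    patient_metric_row("patient_sensitivity", counts[["tp"]],
                       counts[["tp"]] + counts[["fn"]], ci_method),
    patient_metric_row("patient_specificity", counts[["tn"]],
                       counts[["tn"]] + counts[["fp"]], ci_method),
    patient_metric_row("patient_ppv", counts[["tp"]],
                       counts[["tp"]] + counts[["fp"]], ci_method),
    patient_metric_row("patient_npv", counts[["tn"]],
                       counts[["tn"]] + counts[["fn"]], ci_method))
  attr(metrics, "table") <- counts
  metrics
}

patient_metric_row <- function(name, k, n, ci_method) {
  if (n == 0) return(metric_row(name, "gross", undefined = TRUE))
  ci <- ci_proportion(k, n, ci_method)
  metric_row(name, "gross", k / n, ci[["low"]], ci[["high"]], k, n)
}

#' Gross episode PPV by episode-duration threshold
#'
#' Restricts the episode-level PPV to ICM episodes lasting at least each
#' threshold (device floor 2 min, then 10 min, 1 h, 24 h by default); false
#' positives are typically short, so PPV rises with the threshold. Empty
#' strata are flagged undefined.
#'
#' @param matches list of [match_episodes()] results.
#' @param thresholds_s duration thresholds in seconds.
#' @return data.frame: `threshold_s`, `tp`, `fp`, `ppv`, `undefined`.
#' @export
ppv_by_duration <- function(matches, thresholds_s = c(120, 600, 3600, 86400)) {
  ep <- do.call(rbind, lapply(matches, `[[`, "episodes"))
  do.call(rbind, lapply(thresholds_s, function(th) {
    sub <- ep[ep$duration_s >= th & ep$status %in% c("true_positive", "false_positive"), ,
              drop = FALSE]
    tp <- sum(sub$status == "true_positive"); n <- nrow(sub)
    data.frame(threshold_s = th, tp = tp, fp = n - tp,
               ppv = if (n > 0) tp / n else NA_real_, undefined = n == 0)
  }))
}

#' False-positive rejection by cause
#'
#' For classifier-scored logs: among episodes scored `false_positive` in the
#' pre-classification matching, the fraction rejected (`ai_retained == FALSE`)
#' overall and per ground-truth cause label.
#'
#' @param matches list of pre-classification [match_episodes()] results built
#'   from classified logs (episodes carry `ai_retained`).
#' @return data.frame: `cause`, `n_fp`, `n_rejected`, `rejection_rate`.
#' @export
fp_rejection_by_cause <- function(matches) {
  ep <- do.call(rbind, lapply(matches, `[[`, "episodes"))
  fp <- ep[ep$status == "false_positive", , drop = FALSE]
  fp$rejected <- !is.na(fp$ai_retained) & !fp$ai_retained
  causes <- c("all", sort(unique(fp$cause_label[!is.na(fp$cause_label)])))
  do.call(rbind, lapply(causes, function(cs) {
    sub <- if (cs == "all") fp else fp[!is.na(fp$cause_label) & fp$cause_label == cs, ,
                                       drop = FALSE]
    data.frame(cause = cs, n_fp = nrow(sub), n_rejected = sum(sub$rejected),
               rejection_rate = if (nrow(sub)) mean(sub$rejected) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}
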