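#' Annotation track: gold-standard Holter labels for one patient
#'
#' An annotation track holds the core-lab style labelled intervals of one
#' multi-day Holter recording: AF, atrial tachycardia/flutter (ATFL),
#' uninterpretable ECG, and other rhythms, as half-open `[start_s, end_s)`
#' intervals in seconds from the start of the recording.
#'
#' @param patient_id character scalar.
#' @param span_s recording length in seconds; the recording span is `[0, span_s)`.
#' @param events data.frame with columns `label`, `start_s`, `end_s`. Labels
#'   must be among `AF`, `ATFL`, `UNINTERPRETABLE`, `OTHER`. Events are stored
#'   sorted by start; same-label events must not overlap and must lie within
#'   the recording span.
#' @return an object of class `annotation_track`.
#' @export
annotation_track <- function(patient_id, span_s, events = NULL) {
  if (is.null(events)) {
    events <- data.frame(label = character(), start_s = numeric(), end_s = numeric())
  }
  stopifnot(is.character(patient_id), length(patient_id) == 1L,
            is.numeric(span_s), length(span_s) == 1L, span_s > 0)
  events <- as.data.frame(events)[, c("label", "start_s", "end_s")]
  events$label <- as.character(events$label)
  bad <- setdiff(unique(events$label), c("AF", "ATFL", "UNINTERPRETABLE", "OTHER"))
  if (length(bad)) stop("unknown annotation label(s): ", paste(bad, collapse = ", "))
  if (nrow(events)) {
    if (any(events$end_s <= events$start_s)) stop("annotation event with end <= start")
    if (any(events$start_s < 0) || any(events$end_s > span_s + 1e-9))
      stop("annotation event outside recording span")
    events <- events[order(events$start_s, events$end_s), , drop = FALSE]
    rownames(events) <- NULL
    for (lab in unique(events$label)) {
      ev <- events[events$label == lab, , drop = FALSE]
      if (nrow(ev) > 1L && any(ev$start_s[-1L] < ev$end_s[-nrow(ev)] - 1e-9))
        stop("overlapping ", lab, " events in annotation track ", patient_id)
    }
  }
  structure(list(patient_id = patient_id, span_s = as.numeric(span_s), events = events),
            class = "annotation_track")
}

track_intervals <- function(track, label) {
  ev <- track$events[track$events$label %in% label, , drop = FALSE]
  iv(ev$start_s, ev$end_s)
}

#' @export
print.annotation_track <- function(x, ...) {
  cat(sprintf("<annotation_track> patient %s, span %.1f h, %d events (%s)\n",
              x$patient_id, x$span_s / 3600, nrow(x$events),
              paste(sprintf("%s:%d", names(table(x$events$label)),
                            as.integer(table(x$events$label))), collapse = " ")))
  invisible(x)
}

#' ICM episode log: device-detected AF episodes for one patient
#'
#' Episode start/end times are on the ICM clock, which may be offset (and
#' drift) relative to the Holter clock until [apply_sync()] is used. Each
#' episode may carry a stored electrogram snippet (in `egm`, keyed by
#' `episode_id`), an AI score/retained flag once classified, and — in
#' synthetic cohorts — a ground-truth `cause_label`.
#'
#' @param patient_id character scalar.
#' @param episodes data.frame with columns `episode_id`, `start_s`, `end_s` and
#'   optionally `egm_path`, `ai_score`, `ai_retained`, `cause_label`.
#' @param egm optional named list of [egm_snippet()] objects keyed by episode id.
#' @param min_duration_s minimum episode duration enforced (device programming;
#'   default 120 s). Set to 0 to disable for threshold experiments.
#' @return an object of class `icm_log`.
#' @export
icm_log <- function(patient_id, episodes = NULL, egm = NULL, min_duration_s = 120) {
  if (is.null(episodes)) {
    episodes <- data.frame(episode_id = character(), start_s = numeric(), end_s = numeric())
  }
  stopifnot(is.character(patient_id), length(patient_id) == 1L)
  episodes <- as.data.frame(episodes)
  for (col in c("egm_path", "cause_label")) {
    if (is.null(episodes[[col]])) episodes[[col]] <- rep(NA_character_, nrow(episodes))
  }
  if (is.null(episodes$ai_score)) episodes$ai_score <- rep(NA_real_, nrow(episodes))
  if (is.null(episodes$ai_retained)) episodes$ai_retained <- rep(NA, nrow(episodes))
  episodes <- episodes[, c("episode_id", "start_s", "end_s", "egm_path",
                           "ai_score", "ai_retained", "cause_label")]
  episodes$episode_id <- as.character(episodes$episode_id)
  episodes$ai_retained <- as.logical(episodes$ai_retained)
  if (nrow(episodes)) {
    if (anyDuplicated(episodes$episode_id)) stop("duplicate episode ids")
    dur <- episodes$end_s - episodes$start_s
    if (any(dur < min_duration_s - 1e-9))
      stop(sprintf("episode shorter than %g s in log %s (min duration %.1f s)",
                   min_duration_s, patient_id, min(dur)))
    episodes <- episodes[order(episodes$start_s, episodes$end_s), , drop = FALSE]
    rownames(episodes) <- NULL
  }
  structure(list(patient_id = patient_id, episodes = episodes, egm = egm),
            class = "icm_log")
}

log_intervals <- function(log, retained_only = FALSE) {
  ep <- log$episodes
  if (retained_only && nrow(ep)) ep <- ep[is.na(ep$ai_retained) | ep$ai_retained, , drop = FALSE]
  iv(ep$start_s, ep$end_s)
}

#' @export
print.icm_log <- function(x, ...) {
  cat(sprintf("<icm_log> patient %s, %d episodes%s\n", x$patient_id, nrow(x$episodes),
              if (!is.null(x$egm)) sprintf(" (%d EGM snippets)", length(x$egm)) else ""))
  invisible(x)
}
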