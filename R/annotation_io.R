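#' Read and write annotation tracks and ICM episode logs
#'
#' Event streams are exchanged as plain CSV (RFC 4180, UTF-8, '.' decimal):
#'
#' * `annotations.csv`: `patient_id,label,start_s,end_s`
#' * `icm_episodes.csv`:
#'   `patient_id,episode_id,start_s,end_s,egm_path,ai_score,ai_retained,cause_label`
#'
#' Times are written with three decimal places (millisecond resolution); since
#' the generator quantizes event times to 1 ms, write→read is bit-identical.
#' Electrogram arrays live in separate one-value-per-line text files with a
#' JSON sidecar, keeping the event CSVs small.
#'
#' @param path file path.
#' @param span_s recording span in seconds; if `NULL` on read, the span is
#'   taken from the file's largest end time (rounded up to the next minute).
#' @name annotation_io
NULL

fmt_s <- function(x) sprintf("%.3f", x)

read_csv_strict <- function(path, cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(path, ": missing column(s) ", paste(missing, collapse = ", "))
  df
}

parse_num <- function(x, what, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !(is.na(x) | x == ""))
  if (length(bad))
    stop(sprintf("%s: malformed %s at data line %d (value '%s')",
                 path, what, bad[1L], x[bad[1L]]))
  out
}

#' @rdname annotation_io
#' @return `read_annotation_track()`: an [annotation_track()]. Files holding
#'   several patients are rejected; use [read_annotation_tracks()].
#' @export
read_annotation_track <- function(path, span_s = NULL) {
  tracks <- read_annotation_tracks(path, span_s)
  if (length(tracks) != 1L)
    stop(path, ": expected one patient, found ", length(tracks))
  tracks[[1L]]
}

#' @rdname annotation_io
#' @return `read_annotation_tracks()`: named list of tracks, one per patient.
#' @export
read_annotation_tracks <- function(path, span_s = NULL) {
  df <- read_csv_strict(path, c("patient_id", "label", "start_s", "end_s"))
  df$start_s <- parse_num(df$start_s, "start_s", path)
  df$end_s <- parse_num(df$end_s, "end_s", path)
  if (any(is.na(df$start_s)) || any(is.na(df$end_s)))
    stop(path, ": empty start/end time")
  spans <- attr(span_s, "by_patient")
  out <- lapply(split(df, df$patient_id), function(d) {
    sp <- if (!is.null(spans)) spans[[d$patient_id[1L]]]
          else if (!is.null(span_s)) span_s
          else ceiling(max(d$end_s) / 60) * 60
    annotation_track(d$patient_id[1L], sp,
                     d[, c("label", "start_s", "end_s")])
  })
  out[order(names(out))]
}

#' @rdname annotation_io
#' @param track an [annotation_track()] (or list of tracks) to serialize.
#' @param append append to an existing file without rewriting the header.
#' @export
write_annotation_track <- function(track, path, append = FALSE) {
  if (inherits(track, "annotation_track")) track <- list(track)
  rows <- do.call(rbind, lapply(track, function(tr) {
    if (!nrow(tr$events)) return(NULL)
    data.frame(patient_id = tr$patient_id, label = tr$events$label,
               start_s = fmt_s(tr$events$start_s), end_s = fmt_s(tr$events$end_s))
  }))
  if (is.null(rows))
    rows <- data.frame(patient_id = character(), label = character(),
                       start_s = character(), end_s = character())
  utils::write.table(rows, path, sep = ",", row.names = FALSE, quote = FALSE,
                     col.names = !append, append = append)
  invisible(path)
}

#' @rdname annotation_io
#' @param min_duration_s device episode duration floor used for validation on
#'   read (default 120 s); set to 0 for threshold experiments.
#' @return `read_icm_log()` / `read_icm_logs()`: [icm_log()] object(s). EGM
#'   snippets are not loaded eagerly; use [read_egm()] on `egm_path`.
#' @export
read_icm_log <- function(path, min_duration_s = 120) {
  logs <- read_icm_logs(path, min_duration_s)
  if (length(logs) != 1L)
    stop(path, ": expected one patient, found ", length(logs))
  logs[[1L]]
}

#' @rdname annotation_io
#' @export
read_icm_logs <- function(path, min_duration_s = 120) {
  df <- read_csv_strict(path, c("patient_id", "episode_id", "start_s", "end_s"))
  df$start_s <- parse_num(df$start_s, "start_s", path)
  df$end_s <- parse_num(df$end_s, "end_s", path)
  df$ai_score <- if (is.null(df$ai_score)) NA_real_ else parse_num(df$ai_score, "ai_score", path)
  df$ai_retained <- if (is.null(df$ai_retained)) NA else as.logical(df$ai_retained)
  for (col in c("egm_path", "cause_label")) {
    if (is.null(df[[col]])) df[[col]] <- NA_character_
    df[[col]][df[[col]] %in% ""] <- NA_character_
  }
  out <- lapply(split(df, df$patient_id), function(d)
    icm_log(d$patient_id[1L],
            d[, c("episode_id", "start_s", "end_s", "egm_path",
                  "ai_score", "ai_retained", "cause_label")],
            min_duration_s = min_duration_s))
  out[order(names(out))]
}

#' @rdname annotation_io
#' @param log an [icm_log()] (or list of logs) to serialize.
#' @export
write_icm_log <- function(log, path, append = FALSE) {
  if (inherits(log, "icm_log")) log <- list(log)
  rows <- do.call(rbind, lapply(log, function(lg) {
    ep <- lg$episodes
    if (!nrow(ep)) return(NULL)
    data.frame(patient_id = lg$patient_id, episode_id = ep$episode_id,
               start_s = fmt_s(ep$start_s), end_s = fmt_s(ep$end_s),
               egm_path = ifelse(is.na(ep$egm_path), "", ep$egm_path),
               ai_score = ifelse(is.na(ep$ai_score), "",
                                 sprintf("%.17g", ep$ai_score)),
               ai_retained = ifelse(is.na(ep$ai_retained), "",
                                    as.character(ep$ai_retained)),
               cause_label = ifelse(is.na(ep$cause_label), "", ep$cause_label))
  }))
  if (is.null(rows))
    rows <- data.frame(patient_id = character(), episode_id = character(),
                       start_s = character(), end_s = character(),
                       egm_path = character(), ai_score = character(),
                       ai_retained = character(), cause_label = character())
  utils::write.table(rows, path, sep = ",", row.names = FALSE, quote = FALSE,
                     col.names = !append, append = append)
  invisible(path)
}

#' @rdname annotation_io
#' @param snippet an [egm_snippet()] as produced by [synthesize_egm()].
#' @param patient_id,episode_id identifiers recorded in the JSON sidecar.
#' @export
write_egm <- function(snippet, path, patient_id = NA, episode_id = NA) {
  writeLines(sprintf("%.6g", snippet$samples), path)
  side <- list(sample_rate = snippet$sample_rate, rhythm_label = snippet$rhythm_label,
               pretrigger_s = snippet$pretrigger_s, posttrigger_s = snippet$posttrigger_s,
               patient_id = patient_id, episode_id = episode_id)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname annotation_io
#' @export
read_egm <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"))
  structure(list(samples = as.numeric(readLines(path)),
                 sample_rate = side$sample_rate, rhythm_label = side$rhythm_label,
                 pretrigger_s = side$pretrigger_s, posttrigger_s = side$posttrigger_s,
                 rr = NULL),
            class = "egm_snippet")
}

#' Write a generated cohort to a directory
#'
#' Produces `annotations.csv`, `icm_episodes.csv`, a `manifest.json` (patient
#' list, recording spans, file paths, generator config echo) and, when the
#' cohort carries electrograms, one `egm/<episode_id>.txt` (+ `.json` sidecar)
#' per episode.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_annotation_track(cohort$tracks, file.path(dir, "annotations.csv"))
  logs <- cohort$logs
  has_egm <- any(vapply(logs, function(l) length(l$egm) > 0, logical(1)))
  if (has_egm) {
    dir.create(file.path(dir, "egm"), showWarnings = FALSE)
    logs <- lapply(logs, function(lg) {
      if (length(lg$egm)) {
        for (eid in names(lg$egm)) {
          rel <- file.path("egm", paste0(eid, ".txt"))
          write_egm(lg$egm[[eid]], file.path(dir, rel), lg$patient_id, eid)
          lg$episodes$egm_path[lg$episodes$episode_id == eid] <- rel
        }
      }
      lg
    })
  }
  write_icm_log(logs, file.path(dir, "icm_episodes.csv"))
  manifest <- list(
    patients = lapply(cohort$truth, function(tr)
      list(patient_id = tr$patient_id, span_s = tr$span_s)),
    files = list(annotations = "annotations.csv", icm_episodes = "icm_episodes.csv"),
    config = unclass(cohort$config))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @param min_duration_s episode duration floor passed to the log reader.
#' @return `read_cohort()`: list with `tracks`, `logs`, `manifest` (no ground
#'   truth — truth is not serialized; it exists only inside the generator).
#' @export
read_cohort <- function(dir, min_duration_s = 120) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  spans <- lapply(manifest$patients, function(p) p$span_s)
  names(spans) <- vapply(manifest$patients, `[[`, "", "patient_id")
  span_arg <- structure(0, by_patient = spans)
  tracks <- read_annotation_tracks(file.path(dir, "annotations.csv"), span_arg)
  logs <- read_icm_logs(file.path(dir, "icm_episodes.csv"), min_duration_s)
  # patients without events/episodes have no CSV rows: restore empty containers
  for (pid in names(spans)) {
    if (is.null(tracks[[pid]])) tracks[[pid]] <- annotation_track(pid, spans[[pid]])
    if (is.null(logs[[pid]])) logs[[pid]] <- icm_log(pid)
  }
  list(tracks = tracks[order(names(tracks))], logs = logs[order(names(logs))],
       manifest = manifest)
}
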