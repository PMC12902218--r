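#' Cohort generator configuration
#'
#' Collects every parameter of the synthetic monitoring cohort. Defaults
#' emulate a 1-month Holter validation visit in an AF-indicated ICM cohort:
#' 3–7-day recordings, AF in a minority of patients (0.29), heavy-tailed
#' episode durations truncated at the device's 2-minute detection floor, a
#' small per-episode miss probability, device false positives at a fraction
#' of an episode per day caused by sinus arrhythmia / ectopy / noise, a few
#' percent of uninterpretable Holter time, occasional AT/AFL, and an unknown
#' clock offset between the ICM and the Holter recorder.
#'
#' @param n_patients number of patients.
#' @param recording_days_range min/max Holter duration in days (uniform draw).
#' @param prob_af_patient probability a patient has true AF during the recording.
#' @param episode_duration_law list `(meanlog, sdlog)` of the lognormal true-AF
#'   episode duration in seconds, truncated at `>= 120` s by resampling.
#' @param episodes_per_af_patient_law list `(lambda)`: episode count per AF
#'   patient is `1 + Poisson(lambda)`.
#' @param miss_prob probability an episode goes undetected. Under the default
#'   Bernoulli model it applies to every episode; under the logistic model it
#'   is the miss probability at the reference duration (600 s), with miss
#'   odds decreasing in log-duration (slope `miss_logistic_slope`), because
#'   real devices miss short episodes more.
#' @param miss_model `"bernoulli"` (duration-independent, default) or `"logistic"`.
#' @param miss_logistic_slope log-odds decrease per unit log-duration (logistic model).
#' @param boundary_jitter_sd Gaussian jitter (s) on detected episode boundaries.
#' @param fp_rate_per_day Poisson rate of false episodes per monitored day.
#' @param fp_cause_mix probability triple over causes
#'   `(sinus_arrhythmia, ectopy, noise)`; must sum to 1.
#' @param fp_duration_law list `(meanlog, sdlog)` of false-episode durations in
#'   seconds, truncated at `>= 120` s (false episodes are mostly short).
#' @param uninterpretable_frac fraction of Holter time annotated uninterpretable.
#' @param atfl_frac fraction of Holter time annotated AT/AFL.
#' @param allow_uninterp_in_af if `TRUE`, uninterpretable segments may fall
#'   inside true AF intervals (used to exercise the masking rules); by default
#'   they are kept outside AF so the 2-minute truth definition stays clean.
#' @param clock_offset_range interval (s) for the per-patient clock offset: the
#'   ICM clock runs behind the Holter clock by `offset` seconds, so the
#'   alignment stage should recover `+offset`.
#' @param clock_drift_ppm linear ICM clock drift in parts per million.
#' @param egm_sample_rate electrogram sampling rate, Hz.
#' @param seed integer; the same seed and config give a bit-identical cohort.
#' @return a validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 30,
                          recording_days_range = c(3, 7),
                          prob_af_patient = 0.29,
                          episode_duration_law = list(meanlog = log(1800), sdlog = 1.0),
                          episodes_per_af_patient_law = list(lambda = 12),
                          miss_prob = 0.006,
                          miss_model = c("bernoulli", "logistic"),
                          miss_logistic_slope = 1.5,
                          boundary_jitter_sd = 5,
                          fp_rate_per_day = 0.31,
                          fp_cause_mix = c(sinus_arrhythmia = 0.385, ectopy = 0.315, noise = 0.300),
                          fp_duration_law = list(meanlog = log(180), sdlog = 0.5),
                          uninterpretable_frac = 0.03,
                          atfl_frac = 0.02,
                          allow_uninterp_in_af = FALSE,
                          clock_offset_range = c(-60, 60),
                          clock_drift_ppm = 0,
                          egm_sample_rate = 64,
                          seed = 1L) {
  miss_model <- match.arg(miss_model)
  cfg <- list(n_patients = as.integer(n_patients),
              recording_days_range = as.numeric(recording_days_range),
              prob_af_patient = prob_af_patient,
              episode_duration_law = episode_duration_law,
              episodes_per_af_patient_law = episodes_per_af_patient_law,
              miss_prob = miss_prob, miss_model = miss_model,
              miss_logistic_slope = miss_logistic_slope,
              boundary_jitter_sd = boundary_jitter_sd,
              fp_rate_per_day = fp_rate_per_day,
              fp_cause_mix = fp_cause_mix,
              fp_duration_law = fp_duration_law,
              uninterpretable_frac = uninterpretable_frac,
              atfl_frac = atfl_frac,
              allow_uninterp_in_af = allow_uninterp_in_af,
              clock_offset_range = as.numeric(clock_offset_range),
              clock_drift_ppm = clock_drift_ppm,
              egm_sample_rate = egm_sample_rate,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  probs <- c(prob_af_patient = cfg$prob_af_patient, miss_prob = cfg$miss_prob,
             uninterpretable_frac = cfg$uninterpretable_frac, atfl_frac = cfg$atfl_frac)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  if (length(cfg$fp_cause_mix) != 3L || any(cfg$fp_cause_mix < 0) ||
      abs(sum(cfg$fp_cause_mix) - 1) > 1e-8)
    stop("fp_cause_mix must be 3 non-negative probabilities summing to 1")
  if (cfg$n_patients < 1L) stop("n_patients must be >= 1")
  rr <- cfg$recording_days_range
  if (length(rr) != 2L || rr[1] <= 0 || rr[2] < rr[1])
    stop("recording_days_range must be an increasing positive pair of days")
  if (cfg$fp_rate_per_day < 0 || cfg$boundary_jitter_sd < 0)
    stop("rates and jitter sd must be non-negative")
  if (length(cfg$clock_offset_range) != 2L ||
      cfg$clock_offset_range[2] < cfg$clock_offset_range[1])
    stop("clock_offset_range must be an increasing pair of seconds")
  # reject configs whose expected AF time cannot fit the shortest recording
  e_dur <- exp(cfg$episode_duration_law$meanlog + cfg$episode_duration_law$sdlog^2 / 2)
  e_n <- 1 + cfg$episodes_per_af_patient_law$lambda
  min_span <- rr[1] * 86400
  if (e_dur * e_n > 0.9 * min_span)
    stop(sprintf(paste0("expected AF time per AF patient (%.0f s) exceeds 90%% of the ",
                        "shortest recording span (%.0f s); shorten episodes or reduce counts"),
                 e_dur * e_n, min_span))
  invisible(cfg)
}

# lognormal draw truncated at >= lo by resampling
rlnorm_trunc <- function(n, meanlog, sdlog, lo = 120) {
  x <- rlnorm(n, meanlog, sdlog)
  for (i in 1:100) {
    bad <- x < lo
    if (!any(bad)) break
    x[bad] <- rlnorm(sum(bad), meanlog, sdlog)
  }
  pmax(x, lo)
}

# place intervals of the given durations disjointly inside [0, span) via
# random gap splitting (always feasible when sum(durations) < span)
place_by_gaps <- function(durations, span) {
  n <- length(durations)
  if (n == 0L) return(iv())
  free <- span - sum(durations)
  g <- rexp(n + 1L)
  g <- g / sum(g) * free
  starts <- cumsum(g[seq_len(n)]) + c(0, cumsum(durations))[seq_len(n)]
  iv(starts, starts + durations)
}

# rejection-place intervals of given durations inside [0, span), disjoint from
# `occupied`; pieces that cannot be placed after `tries` attempts are dropped
place_by_rejection <- function(durations, span, occupied, tries = 100L) {
  placed <- iv()
  occ <- iv_normalize(occupied)
  for (d in durations) {
    if (d >= span) next
    for (k in seq_len(tries)) {
      s <- runif(1, 0, span - d)
      cand <- iv(s, s + d)
      if (!any(iv_overlaps_any(cand, occ))) {
        placed <- rbind(placed, cand)
        occ <- iv_union(occ, cand)
        break
      }
    }
  }
  as_iv(placed)
}

#' Generate a synthetic monitoring cohort
#'
#' Draws, for each patient: a ground-truth rhythm timeline (true AF and AT/AFL
#' intervals on the Holter clock), the Holter annotation track (truth plus
#' uninterpretable segments), and the ICM episode log. The ICM log is derived
#' from the truth by the configured error modes: each true AF episode is
#' independently missed with `miss_prob`; survivors get Gaussian boundary
#' jitter (re-truncated to the 2-minute device floor); false episodes arrive
#' as a Poisson process with cause labels drawn from `fp_cause_mix`; and all
#' episode timestamps are moved onto the ICM clock (per-patient offset plus
#' linear drift). Every episode can carry a synthesized electrogram snippet.
#'
#' All event times are quantized to 1 ms so that cohorts round-trip exactly
#' through the CSV writers.
#'
#' @param config a [cohort_config()].
#' @param egm generate electrogram snippets for every episode (`TRUE`,
#'   default). Set `FALSE` for evaluation-only experiments where waveforms
#'   are not needed.
#' @return list of class `cohort` with elements `truth` (per-patient list of
#'   `patient_id`, `span_s`, `af`, `atfl` interval sets), `tracks`
#'   (list of [annotation_track()]), `logs` (list of [icm_log()]; each log
#'   carries attributes `sync_truth` = the offset the alignment stage should
#'   recover and `drift_ppm`), and `config`.
#' @export
generate_cohort <- function(config, egm = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  set.seed(config$seed)
  ms <- function(x) round(x, 3)
  truth <- vector("list", config$n_patients)
  tracks <- vector("list", config$n_patients)
  logs <- vector("list", config$n_patients)
  causes <- c("sinus_arrhythmia", "ectopy", "noise")

  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("P%03d", p)
    span <- ms(runif(1, config$recording_days_range[1], config$recording_days_range[2]) * 86400)
    has_af <- runif(1) < config$prob_af_patient

    af <- iv()
    if (has_af) {
      n_ep <- 1L + rpois(1, config$episodes_per_af_patient_law$lambda)
      dur <- ms(rlnorm_trunc(n_ep, config$episode_duration_law$meanlog,
                             config$episode_duration_law$sdlog))
      # heavy-tailed draws can exceed the span: drop longest-first until they fit
      while (sum(dur) > 0.9 * span && length(dur) > 1L) dur <- dur[-which.max(dur)]
      if (sum(dur) > 0.9 * span) dur <- ms(0.9 * span)
      starts <- pmin(ms(place_by_gaps(dur, span)[, 1L]), span - dur)
      af <- iv(starts, ms(starts + dur))
    }

    atfl <- place_by_rejection(
      runif(max(0L, round(config$atfl_frac * span / 450)), 120, 780), span, af)
    if (nrow(atfl)) atfl <- iv(ms(atfl[, 1L]), ms(atfl[, 2L]))
    occupied_for_uninterp <- if (config$allow_uninterp_in_af) atfl else iv_union(af, atfl)
    uninterp <- place_by_rejection(
      runif(max(0L, round(config$uninterpretable_frac * span / 300)), 60, 540),
      span, occupied_for_uninterp)
    if (nrow(uninterp)) uninterp <- iv(ms(uninterp[, 1L]), ms(uninterp[, 2L]))

    truth[[p]] <- list(patient_id = pid, span_s = span, af = af, atfl = atfl)
    ev <- rbind(
      if (nrow(af)) data.frame(label = "AF", start_s = af[, 1L], end_s = af[, 2L]),
      if (nrow(atfl)) data.frame(label = "ATFL", start_s = atfl[, 1L], end_s = atfl[, 2L]),
      if (nrow(uninterp)) data.frame(label = "UNINTERPRETABLE",
                                     start_s = uninterp[, 1L], end_s = uninterp[, 2L]))
    tracks[[p]] <- annotation_track(pid, span, ev)

    # --- device detections, on the Holter clock first ---
    det <- iv(); det_from <- integer(0)
    if (nrow(af)) {
      dur <- af[, 2L] - af[, 1L]
      p_miss <- switch(config$miss_model,
        bernoulli = rep(config$miss_prob, nrow(af)),
        logistic = plogis(qlogis(pmin(pmax(config$miss_prob, 1e-12), 1 - 1e-12)) -
                          config$miss_logistic_slope * (log(dur) - log(600))))
      detected <- runif(nrow(af)) >= p_miss
      for (k in which(detected)) {
        s <- af[k, 1L] + rnorm(1, 0, config$boundary_jitter_sd)
        e <- af[k, 2L] + rnorm(1, 0, config$boundary_jitter_sd)
        s <- max(0, s)
        if (e - s < 120) e <- s + 120
        det <- rbind(det, iv(s, e))
        det_from <- c(det_from, k)
      }
      det <- as_iv(det)
    }
    n_fp <- rpois(1, config$fp_rate_per_day * span / 86400)
    fp_dur <- if (n_fp) rlnorm_trunc(n_fp, config$fp_duration_law$meanlog,
                                     config$fp_duration_law$sdlog) else numeric(0)
    fp <- place_by_rejection(fp_dur, span, det)
    fp_cause <- if (nrow(fp)) sample(causes, nrow(fp), replace = TRUE,
                                     prob = config$fp_cause_mix) else character(0)

    all_iv <- rbind(det, fp)
    cause_label <- c(rep("true_af", nrow(det)), fp_cause)
    offset <- runif(1, config$clock_offset_range[1], config$clock_offset_range[2])
    ep <- data.frame(start_s = numeric(0), end_s = numeric(0),
                     cause_label = character(0))
    if (nrow(all_iv)) {
      ord <- order(all_iv[, 1L])
      to_icm <- function(t) (t - offset) / (1 + config$clock_drift_ppm * 1e-6)
      st <- to_icm(all_iv[ord, 1L])
      en <- pmax(to_icm(all_iv[ord, 2L]), st + 120)  # device floor holds on its own clock
      ep <- data.frame(start_s = ms(st), end_s = ms(en),
                       cause_label = cause_label[ord])
      ep$episode_id <- sprintf("%s-E%03d", pid, seq_len(nrow(ep)))
    } else ep$episode_id <- character(0)

    snippets <- NULL
    if (egm && nrow(ep)) {
      snippets <- lapply(seq_len(nrow(ep)), function(k)
        synthesize_egm(ep$cause_label[k], 90, config$egm_sample_rate,
                       seed = sample.int(.Machine$integer.max, 1)))
      names(snippets) <- ep$episode_id
    }
    # jittered episodes may undershoot the device floor by <1 ms after rounding
    logs[[p]] <- icm_log(pid, ep, egm = snippets, min_duration_s = 120 - 1e-3)
    attr(logs[[p]], "sync_truth") <- offset
    attr(logs[[p]], "drift_ppm") <- config$clock_drift_ppm
  }
  names(truth) <- names(tracks) <- names(logs) <- vapply(truth, `[[`, "", "patient_id")
  structure(list(truth = truth, tracks = tracks, logs = logs, config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  n_af <- sum(vapply(x$truth, function(t) nrow(t$af) > 0, logical(1)))
  n_ep <- sum(vapply(x$logs, function(l) nrow(l$episodes), integer(1)))
  cat(sprintf("<cohort> %d patients (%d with AF), %d ICM episodes, seed %d\n",
              x$config$n_patients, n_af, n_ep, x$config$seed))
  invisible(x)
}
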