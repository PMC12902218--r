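#' Synthesize a device-style electrogram snippet
#'
#' Builds a phenomenological single-channel electrogram for one detected
#' episode: QRS-like wavelets placed at RR intervals drawn from a
#' rhythm-dependent point process, plus baseline wander and sensor noise.
#' The snippet emulates the device's stored-EGM window: 30 s pre-trigger plus
#' 60 s post-trigger (90 s total).
#'
#' Rhythm models:
#' * `true_af` — RR intervals i.i.d. lognormal around 0.7 s with coefficient
#'   of variation about 0.25 and no periodic modulation (irregularly
#'   irregular ventricular response).
#' * `sinus_arrhythmia` — regular mean RR (0.8 s) slowly modulated by a
#'   respiratory-frequency sinusoid (0.25 Hz, 15 % amplitude), the classic
#'   cyclic RR pattern that devices mistake for AF.
#' * `ectopy` — regular RR with premature beats (shortened coupling interval
#'   followed by a compensatory pause) at a fixed per-beat rate (0.15).
#' * `noise` — an underlying regular rhythm overlaid with broadband noise
#'   bursts and large baseline wander (lead noise / oversensing).
#'
#' The synthesis is phenomenological, not electrophysiological: it gives the
#' false-positive classifier class-separable rhythm and morphology structure
#' at desk scale, nothing more.
#'
#' @param rhythm_label one of `"true_af"`, `"sinus_arrhythmia"`, `"ectopy"`,
#'   `"noise"`.
#' @param duration_s snippet length in seconds; the device window is 90 s.
#' @param sample_rate sampling rate in Hz.
#' @param seed optional integer; when given, the snippet is a deterministic
#'   function of `(rhythm_label, duration_s, sample_rate, seed)` and the
#'   caller's RNG state is left untouched.
#' @return an `egm_snippet`: list with `samples` (numeric vector of length
#'   `duration_s * sample_rate`), `sample_rate`, `rhythm_label`,
#'   `pretrigger_s` (30), `posttrigger_s` (60) and the generating `rr`
#'   sequence (seconds).
#' @aliases egm_snippet
#' @export
synthesize_egm <- function(rhythm_label, duration_s = 90, sample_rate = 64, seed = NULL) {
  labels <- c("true_af", "sinus_arrhythmia", "ectopy", "noise")
  if (!is.character(rhythm_label) || length(rhythm_label) != 1L || !rhythm_label %in% labels)
    stop("unknown rhythm_label: ", paste(rhythm_label, collapse = ","),
         " (expected one of ", paste(labels, collapse = ", "), ")")
  stopifnot(duration_s > 0, sample_rate > 0)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }

  n_beats_max <- ceiling(duration_s / 0.3) + 10L
  rr <- switch(rhythm_label,
    true_af = rlnorm(n_beats_max, meanlog = log(0.7), sdlog = 0.25),
    sinus_arrhythmia = {
      base <- 0.8
      rr <- numeric(n_beats_max); t <- 0
      for (k in seq_len(n_beats_max)) {
        rr[k] <- base * (1 + 0.15 * sin(2 * pi * 0.25 * t)) + rnorm(1, 0, 0.008)
        t <- t + rr[k]
      }
      rr
    },
    ectopy = {
      rr <- 0.8 + rnorm(n_beats_max, 0, 0.01)
      k <- 1L
      while (k <= n_beats_max - 1L) {
        if (runif(1) < 0.15) {          # premature beat + compensatory pause
          rr[k] <- rr[k] * 0.6
          rr[k + 1L] <- rr[k + 1L] * 1.4
          k <- k + 2L
        } else k <- k + 1L
      }
      rr
    },
    noise = 0.85 + rnorm(n_beats_max, 0, 0.015)
  )
  rr <- pmax(rr, 0.25)
  beat_t <- cumsum(rr)
  keep <- beat_t < duration_s
  beat_t <- beat_t[keep]

  n <- round(duration_s * sample_rate)
  t <- (seq_len(n) - 1L) / sample_rate
  x <- numeric(n)
  sigma <- 0.025                                   # QRS wavelet width, s
  half <- ceiling(4 * sigma * sample_rate)
  amp <- 1 + rnorm(length(beat_t), 0, 0.05)
  for (b in seq_along(beat_t)) {
    ctr <- round(beat_t[b] * sample_rate) + 1L
    idx <- max(1L, ctr - half):min(n, ctr + half)
    u <- (t[idx] - beat_t[b]) / sigma
    x[idx] <- x[idx] - amp[b] * u * exp(-u^2 / 2)  # biphasic (Gaussian-derivative) deflection
  }
  x <- x + 0.05 * sin(2 * pi * 0.33 * t + runif(1, 0, 2 * pi))   # baseline wander
  x <- x + rnorm(n, 0, 0.03)                                     # sensor noise floor
  if (rhythm_label == "noise") {
    x <- x + 0.35 * sin(2 * pi * 0.4 * t + runif(1, 0, 2 * pi))  # severe wander
    n_burst <- sample(3:6, 1)
    for (j in seq_len(n_burst)) {                                # broadband artifact bursts
      b0 <- runif(1, 0, duration_s - 5)
      blen <- runif(1, 1, 5)
      idx <- which(t >= b0 & t < b0 + blen)
      x[idx] <- x[idx] + rnorm(length(idx), 0, 0.6)
    }
  }
  structure(list(samples = x, sample_rate = sample_rate, rhythm_label = rhythm_label,
                 pretrigger_s = 30, posttrigger_s = 60, rr = rr[keep]),
            class = "egm_snippet")
}

#' @export
print.egm_snippet <- function(x, ...) {
  cat(sprintf("<egm_snippet> %s, %d samples @ %g Hz, %d beats\n",
              x$rhythm_label, length(x$samples), x$sample_rate, length(x$rr)))
  invisible(x)
}

# coefficient of variation of the generating RR sequence
rr_cv <- function(snippet) stats::sd(snippet$rr) / mean(snippet$rr)
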