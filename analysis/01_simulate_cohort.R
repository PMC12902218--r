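#!/usr/bin/env Rscript
# Stage 1 — simulate the monitoring cohort.
#
# Generates the default evaluation cohort (30 patients, 3-7-day Holter
# recordings, AF prevalence 0.29, device false positives from sinus
# arrhythmia / ectopy / noise, unknown per-patient clock offset) and writes
# the two event-stream artifacts plus the manifest under results/cohort/.
# Electrograms are synthesized later, where they are needed (stage 3).

suppressPackageStartupMessages(library(icmeval))

seed <- 1L
cfg <- cohort_config(seed = seed)
cohort <- generate_cohort(cfg, egm = FALSE)

dir.create("results", showWarnings = FALSE)
write_cohort(cohort, "results/cohort")

n_af <- sum(vapply(cohort$truth, function(t) nrow(t$af) > 0, logical(1)))
n_ep <- sum(vapply(cohort$logs, function(l) nrow(l$episodes), integer(1)))
n_fp <- sum(vapply(cohort$logs, function(l)
  sum(l$episodes$cause_label != "true_af"), integer(1)))
cat(sprintf("cohort: %d patients (%d with AF), %d ICM episodes (%d false)\n",
            cfg$n_patients, n_af, n_ep, n_fp))
cat(sprintf("total recording: %.1f days; written to results/cohort/\n",
            sum(vapply(cohort$truth, `[[`, 0, "span_s")) / 86400))
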