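#!/usr/bin/env Rscript
# Stage 2 — align the ICM clock to the Holter clock.
#
# Each patient's device log carries an unknown clock offset relative to the
# Holter recorder. The offset is estimated by maximizing interval overlap
# between shifted device episodes and annotated AF, then checked against the
# offset the generator actually injected. Patients without annotated AF
# cannot be aligned and are flagged.

suppressPackageStartupMessages(library(icmeval))

cohort <- generate_cohort(cohort_config(seed = 1L), egm = FALSE)

rows <- do.call(rbind, lapply(names(cohort$logs), function(pid) {
  s <- suppressWarnings(estimate_offset(cohort$logs[[pid]], cohort$tracks[[pid]]))
  data.frame(patient_id = pid, flag = s$flag,
             estimated_offset_s = s$offset_s,
             true_offset_s = attr(cohort$logs[[pid]], "sync_truth"),
             quality = s$quality)
}))
rows$abs_error_s <- ifelse(rows$flag == "ok",
                           abs(rows$estimated_offset_s - rows$true_offset_s), NA)

dir.create("results", showWarnings = FALSE)
write.csv(rows, "results/alignment.csv", row.names = FALSE)

ok <- rows$flag == "ok"
cat(sprintf("aligned %d/%d patients (others have no annotated AF to match)\n",
            sum(ok), nrow(rows)))
cat(sprintf("offset recovery: mean |error| %.2f s, max %.2f s (injected range +/-60 s)\n",
            mean(rows$abs_error_s[ok]), max(rows$abs_error_s[ok])))
cat("per-patient table in results/alignment.csv\n")
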