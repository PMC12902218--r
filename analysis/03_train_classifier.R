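#!/usr/bin/env Rscript
# Stage 3 — train the false-positive classifier.
#
# A disjoint cohort (emulating development on a separate remote-monitoring
# corpus) provides labelled electrogram snippets: device detections whose
# cause is true AF versus sinus arrhythmia, ectopy or noise. The 1-D CNN is
# trained with focal loss and a patient-level train/validation split, and the
# operating threshold is chosen to reject as many false episodes as possible
# without losing a single validation true episode.

suppressPackageStartupMessages(library(icmeval))

run <- run_config(seed = 1L)                 # same derived seeds as stage 4
tc <- generate_cohort(run$train_cohort, egm = TRUE)

snippets <- list(); labels <- numeric(); pids <- character()
for (lg in tc$logs) {
  for (eid in names(lg$egm)) {
    snippets[[length(snippets) + 1L]] <- lg$egm[[eid]]
    labels <- c(labels, as.numeric(
      lg$episodes$cause_label[lg$episodes$episode_id == eid] == "true_af"))
    pids <- c(pids, lg$patient_id)
  }
}
cat(sprintf("training corpus: %d snippets (%d true AF, %d false) from %d patients\n",
            length(labels), sum(labels), sum(labels == 0), length(unique(pids))))

trained <- train_fp_classifier(snippets, labels, pids, run$classifier, verbose = TRUE)

dir.create("results", showWarnings = FALSE)
write.csv(data.frame(score = trained$validation$scores,
                     label = trained$validation$labels),
          "results/classifier_validation_scores.csv", row.names = FALSE)
jsonlite::write_json(list(
  validation_auroc = trained$validation$auroc,
  operating_threshold = trained$operating_threshold,
  n_train = sum(!trained$split), n_validation = sum(trained$split),
  loss_history = trained$validation$history),
  "results/classifier_summary.json", auto_unbox = TRUE, digits = NA,
  dataframe = "rows", pretty = TRUE)

cat(sprintf("validation AUROC %.3f; operating threshold %.3f\n",
            trained$validation$auroc, trained$operating_threshold))
cat("summary in results/classifier_summary.json\n")
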