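test_that("error-free configuration reproduces ground truth exactly", {
  cfg <- cohort_config(n_patients = 8, miss_prob = 0, fp_rate_per_day = 0,
                       boundary_jitter_sd = 0, clock_offset_range = c(0, 0),
                       seed = 5)
  co <- generate_cohort(cfg, egm = FALSE)
  for (pid in names(co$logs)) {
    af <- co$truth[[pid]]$af
    li <- icmeval:::log_intervals(co$logs[[pid]])
    expect_equal(nrow(li), nrow(af))
    if (nrow(af)) expect_equal(unclass(li)[, ], unclass(af)[, ], tolerance = 1e-12)
  }
})

test_that("AF-free cohorts contain only cause-labelled false episodes", {
  cfg <- cohort_config(n_patients = 10, prob_af_patient = 0, fp_rate_per_day = 2,
                       seed = 9)
  co <- generate_cohort(cfg, egm = FALSE)
  for (pid in names(co$tracks)) {
    expect_equal(sum(co$tracks[[pid]]$events$label == "AF"), 0)
    causes <- co$logs[[pid]]$episodes$cause_label
    expect_true(all(causes %in% c("sinus_arrhythmia", "ectopy", "noise")))
  }
  expect_gt(sum(vapply(co$logs, function(l) nrow(l$episodes), integer(1))), 0)
})

test_that("annotated AF time is conserved and episodes respect the device floor", {
  co <- generate_cohort(cohort_config(n_patients = 12, seed = 21), egm = FALSE)
  for (pid in names(co$tracks)) {
    tr <- co$tracks[[pid]]
    af_truth <- iv_length(co$truth[[pid]]$af)
    af_track <- sum(with(tr$events[tr$events$label == "AF", ], end_s - start_s))
    expect_equal(af_track, af_truth, tolerance = 1e-9)
    truth_af <- co$truth[[pid]]$af
    if (nrow(truth_af))
      expect_true(all(truth_af[, 2] - truth_af[, 1] >= 120 - 1e-3))
    ep <- co$logs[[pid]]$episodes
    if (nrow(ep)) expect_true(all(ep$end_s - ep$start_s >= 120 - 1e-3))
  }
})

test_that("identical seed and config give a bit-identical cohort", {
  cfg <- cohort_config(n_patients = 4, seed = 33, fp_rate_per_day = 1)
  a <- generate_cohort(cfg, egm = TRUE)
  b <- generate_cohort(cfg, egm = TRUE)
  expect_identical(a$truth, b$truth)
  for (pid in names(a$logs)) {
    expect_identical(a$logs[[pid]]$episodes, b$logs[[pid]]$episodes)
    expect_identical(lapply(a$logs[[pid]]$egm, `[[`, "samples"),
                     lapply(b$logs[[pid]]$egm, `[[`, "samples"))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(fp_cause_mix = c(0.5, 0.5, 0.5)), "summing to 1")
  expect_error(cohort_config(miss_prob = 1.5), "\\[0, 1\\]")
  expect_error(cohort_config(
    episode_duration_law = list(meanlog = log(40000), sdlog = 1),
    episodes_per_af_patient_law = list(lambda = 20)), "exceeds 90%")
  expect_error(cohort_config(recording_days_range = c(7, 3)), "increasing")
})

test_that("duration-dependent miss model misses short episodes more often", {
  cfg <- cohort_config(n_patients = 40, prob_af_patient = 1, miss_prob = 0.3,
                       miss_model = "logistic", fp_rate_per_day = 0,
                       boundary_jitter_sd = 0, clock_offset_range = c(0, 0),
                       episode_duration_law = list(meanlog = log(600), sdlog = 1.2),
                       seed = 77)
  co <- generate_cohort(cfg, egm = FALSE)
  dur <- c(); det <- c()
  for (pid in names(co$logs)) {
    af <- co$truth[[pid]]$af
    di <- icmeval:::log_intervals(co$logs[[pid]])
    for (k in seq_len(nrow(af))) {
      dur <- c(dur, af[k, 2] - af[k, 1])
      det <- c(det, any(icmeval:::iv_overlaps_any(iv(af[k, 1], af[k, 2]), di)))
    }
  }
  short <- dur < stats::median(dur)
  expect_gt(mean(det[!short]), mean(det[short]))
})
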