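test_that("perfect detections at zero offset give offset 0 and quality 1", {
  co <- generate_cohort(cohort_config(n_patients = 6, prob_af_patient = 1,
                                      miss_prob = 0, fp_rate_per_day = 0,
                                      boundary_jitter_sd = 0,
                                      clock_offset_range = c(0, 0), seed = 8),
                        egm = FALSE)
  for (pid in names(co$logs)) {
    s <- estimate_offset(co$logs[[pid]], co$tracks[[pid]])
    expect_equal(s$offset_s, 0, tolerance = 1e-6)
    expect_equal(s$quality, 1, tolerance = 1e-9)
    expect_equal(s$flag, "ok")
  }
})

test_that("an injected 37.5 s offset is recovered within the grid step", {
  co <- generate_cohort(cohort_config(n_patients = 5, prob_af_patient = 1,
                                      miss_prob = 0, fp_rate_per_day = 0.3,
                                      boundary_jitter_sd = 0,
                                      clock_offset_range = c(37.5, 37.5), seed = 15),
                        egm = FALSE)
  for (pid in names(co$logs)) {
    s <- estimate_offset(co$logs[[pid]], co$tracks[[pid]], step_s = 0.5)
    expect_lt(abs(s$offset_s - 37.5), 0.5)
  }
})

test_that("offset recovery tolerates boundary jitter in most replicates", {
  hits <- vapply(1:100, function(r) {
    co <- generate_cohort(cohort_config(
      n_patients = 1, prob_af_patient = 1, miss_prob = 0, fp_rate_per_day = 0,
      boundary_jitter_sd = 2,
      episodes_per_af_patient_law = list(lambda = 19),
      episode_duration_law = list(meanlog = log(400), sdlog = 0.5),
      clock_offset_range = c(-80, 80), seed = 5000 + r), egm = FALSE)
    s <- estimate_offset(co$logs[[1]], co$tracks[[1]])
    abs(s$offset_s - attr(co$logs[[1]], "sync_truth")) < 3
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("apply_sync shifts boundaries, preserves durations, and is consistent with re-estimation", {
  co <- generate_cohort(cohort_config(n_patients = 4, prob_af_patient = 1,
                                      miss_prob = 0.05, fp_rate_per_day = 0.5,
                                      clock_offset_range = c(-50, 50), seed = 23),
                        egm = FALSE)
  id_sync <- structure(list(patient_id = "x", offset_s = 0, drift_ppm = 0,
                            quality = 1, flag = "ok"), class = "sync_estimate")
  for (pid in names(co$logs)) {
    lg <- co$logs[[pid]]
    id_sync$patient_id <- pid
    expect_identical(apply_sync(lg, id_sync)$episodes, lg$episodes)
    ten <- id_sync; ten$offset_s <- 10
    shifted <- apply_sync(lg, ten)
    expect_equal(shifted$episodes$start_s, lg$episodes$start_s + 10)
    s <- estimate_offset(lg, co$tracks[[pid]])
    if (s$flag != "ok") next
    synced <- apply_sync(lg, s)
    expect_equal(synced$episodes$end_s - synced$episodes$start_s,
                 lg$episodes$end_s - lg$episodes$start_s, tolerance = 1e-12)
    res <- estimate_offset(synced, co$tracks[[pid]])
    expect_lt(abs(res$offset_s), 0.5 + 1e-9)
  }
})

test_that("degenerate inputs are flagged rather than estimated", {
  lg <- icm_log("P1")
  tr <- make_track(5000, af = cbind(100, 400))
  expect_warning(s <- estimate_offset(lg, tr), "empty ICM log")
  expect_equal(s$flag, "empty_icm_log")
  tr2 <- make_track(5000)
  lg2 <- make_log(cbind(100, 300))
  s2 <- estimate_offset(lg2, tr2)
  expect_equal(s2$flag, "no_af_annotation")
  expect_equal(s2$offset_s, 0)
  expect_equal(s2$quality, 0)
})
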