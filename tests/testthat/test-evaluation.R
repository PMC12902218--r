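test_that("the analyzable mask removes uninterpretable and AT/AFL time", {
  tr <- make_track(1000, uninterp = cbind(100, 200), atfl = cbind(150, 300))
  m <- build_mask(tr)
  expect_equal(unclass(m$intervals)[, ], cbind(start = c(0, 300), end = c(100, 1000)))
  expect_equal(m$total_s, 800)
  expect_equal(build_mask(make_track(1000))$total_s, 1000)
  # exclusions covering the whole span leave an empty mask
  tr2 <- make_track(500, uninterp = cbind(0, 500))
  expect_equal(build_mask(tr2)$total_s, 0)
})

test_that("true events apply the 2-minute floor to the annotation, not the clip", {
  expect_length(true_af_events(make_track(1000, af = cbind(0, 119))), 0)
  expect_length(true_af_events(make_track(1000, af = cbind(0, 300))), 1)
  # event split by an excluded segment stays one event with two segments
  tr <- make_track(1000, af = cbind(0, 300), uninterp = cbind(100, 200))
  ev <- true_af_events(tr)
  expect_length(ev, 1)
  expect_equal(nrow(ev[[1]]$segments), 2L)
  expect_equal(iv_length(ev[[1]]$segments), 200)
  expect_equal(ev[[1]]$duration_s, 300)
  # clipped remnant below 2 min is still an event (annotation was eligible)
  tr2 <- make_track(1000, af = cbind(0, 180), uninterp = cbind(100, 1000))
  expect_length(true_af_events(tr2), 1)
  # event wholly inside excluded time drops from assessment
  tr3 <- make_track(1000, af = cbind(100, 300), uninterp = cbind(50, 350))
  expect_length(true_af_events(tr3), 0)
})

test_that("episode matching assigns exactly one status per episode", {
  tr <- make_track(2000, af = cbind(350, 900), atfl = cbind(1200, 1500))
  lg <- make_log(rbind(c(100, 400),     # overlaps AF tail -> TP
                       c(1250, 1450),   # inside ATFL -> excluded
                       c(1600, 1800)))  # clean non-AF time -> FP
  m <- match_episodes(lg, tr)
  expect_equal(m$episodes$status, c("true_positive", "excluded", "false_positive"))
  expect_true(m$events$detected[1])
  expect_equal(sum(m$episodes$status == "true_positive"), 1)
  # an event fully masked out drops; an episode overlapping only masked AF time
  # has no in-mask AF to match and scores as a false positive
  tr4 <- make_track(2000, af = cbind(350, 900), uninterp = cbind(300, 920))
  m4 <- match_episodes(make_log(cbind(100, 400)), tr4)
  expect_equal(nrow(m4$events), 0L)
  expect_equal(m4$episodes$status, "false_positive")
})

test_that("five events with four detected and one spurious episode give 4/5 and 4/5", {
  af <- cbind(seq(0, 4) * 2000 + 100, seq(0, 4) * 2000 + 500)
  tr <- make_track(12000, af = af)
  lg <- make_log(rbind(af[1:4, ] + 20, c(9000, 9200)))
  m <- match_episodes(lg, tr)
  em <- episode_metrics(list(m))
  gross <- function(nm) em$point[em$name == nm & em$estimator == "gross"]
  expect_equal(gross("episode_sensitivity"), 4 / 5)
  expect_equal(gross("episode_ppv"), 4 / 5)
})

test_that("gross pools episodes while patient-average weights patients equally", {
  # patient A: PPV 1/2; patient B: PPV 9/10
  mk <- function(pid, n_tp, n_fp) {
    af <- cbind(seq_len(n_tp) * 3000, seq_len(n_tp) * 3000 + 600)
    span <- (n_tp + n_fp + 2) * 3000
    tr <- make_track(span, af = af, pid = pid)
    fp <- cbind(seq_len(n_fp) * 3000 + (n_tp * 3000) + 1500,
                seq_len(n_fp) * 3000 + (n_tp * 3000) + 1800)
    lg <- make_log(rbind(af + 10, fp), pid = pid)
    match_episodes(lg, tr)
  }
  em <- episode_metrics(list(mk("A", 1, 1), mk("B", 9, 1)))
  expect_equal(em$point[em$name == "episode_ppv" & em$estimator == "gross"], 10 / 12)
  expect_equal(em$point[em$name == "episode_ppv" & em$estimator == "patient_average"], 0.7)
  # fully correct detection: every estimator equals 1
  em2 <- episode_metrics(list(mk("C", 3, 0), mk("D", 2, 0)))
  for (e in c("gross", "patient_average", "gee"))
    expect_equal(em2$point[em2$name == "episode_ppv" & em2$estimator == e], 1)
})

test_that("duration confusion matches hand arithmetic and the grid oracle", {
  tr <- make_track(1000, af = cbind(0, 400))
  lg <- make_log(cbind(100, 500))
  dm <- duration_metrics(lg, tr)
  expect_equal(dm$confusion$tp_s, 300)
  expect_equal(dm$confusion$fp_s, 100)
  expect_equal(dm$confusion$fn_s, 100)
  expect_equal(dm$confusion$tn_s, 500)
  pt <- function(nm) dm$metrics$point[dm$metrics$name == nm]
  expect_equal(pt("duration_sensitivity"), 0.75)
  expect_equal(pt("duration_specificity"), 5 / 6)
  expect_equal(pt("duration_ppv"), 0.75)
  expect_equal(pt("duration_npv"), 5 / 6)
  expect_equal(pt("duration_accuracy"), 0.8)
})

test_that("degenerate duration inputs are undefined-flagged, never silent", {
  tr <- make_track(1000)                       # no AF, no detections
  dm <- duration_metrics(icm_log("P1"), tr)
  expect_equal(dm$metrics$point[dm$metrics$name == "duration_specificity"], 1)
  expect_true(dm$metrics$undefined[dm$metrics$name == "duration_sensitivity"])
  expect_true(dm$metrics$undefined[dm$metrics$name == "duration_ppv"])
  # empty mask: everything undefined
  tr2 <- make_track(500, uninterp = cbind(0, 500))
  dm2 <- duration_metrics(icm_log("P1"), tr2)
  expect_true(all(dm2$metrics$undefined))
})

test_that("patient-level 2x2 enumerates a hand-built cohort", {
  tp <- match_episodes(make_log(cbind(120, 400), pid = "TP"),
                       make_track(3000, af = cbind(100, 420), pid = "TP"))
  tn <- match_episodes(icm_log("TN"), make_track(3000, pid = "TN"))
  fp <- match_episodes(make_log(cbind(500, 700), pid = "FP"),
                       make_track(3000, pid = "FP"))
  pd <- patient_diagnostics(list(tp, tn, fp))
  pt <- function(nm) pd$point[pd$name == nm]
  expect_equal(pt("patient_sensitivity"), 1)
  expect_equal(pt("patient_specificity"), 1 / 2)
  expect_equal(pt("patient_ppv"), 1 / 2)
  expect_equal(pt("patient_npv"), 1)
  expect_equal(as.integer(attr(pd, "table")), c(1L, 1L, 1L, 0L))
  # all AF-free, no detections: specificity 1, sensitivity undefined
  pd2 <- patient_diagnostics(list(tn))
  expect_equal(pt2 <- pd2$point[pd2$name == "patient_specificity"], 1)
  expect_true(pd2$undefined[pd2$name == "patient_sensitivity"])
})

test_that("PPV by duration threshold is monotone when false episodes are short", {
  af <- cbind(c(1, 5, 9, 13) * 4000, c(1, 5, 9, 13) * 4000 + 3600)
  tr <- make_track(60000, af = af)
  fp <- cbind(c(3, 7, 11) * 4000, c(3, 7, 11) * 4000 + c(150, 200, 400))
  lg <- make_log(rbind(af, fp))
  m <- match_episodes(lg, tr)
  tab <- ppv_by_duration(list(m), thresholds_s = c(60, 120, 600, 3600, 86400))
  expect_equal(tab$ppv[1], 4 / 7)              # below every duration: overall PPV
  expect_true(all(diff(tab$ppv[!tab$undefined]) >= -1e-12))
  expect_true(tab$undefined[tab$threshold_s == 86400])
})
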