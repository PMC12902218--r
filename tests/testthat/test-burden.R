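test_that("burden percentages follow the mask-denominator definition", {
  tr <- make_track(1000, af = cbind(0, 400))
  lg <- make_log(cbind(100, 400))
  b <- compute_burdens(lg, tr)
  expect_equal(b$holter_burden_pct, 40)
  expect_equal(b$icm_burden_pct, 30)
  # no AF, no detections
  b0 <- compute_burdens(icm_log("P1"), make_track(1000))
  expect_equal(c(b0$holter_burden_pct, b0$icm_burden_pct), c(0, 0))
  # empty mask is undefined
  b1 <- compute_burdens(icm_log("P1"), make_track(500, uninterp = cbind(0, 500)))
  expect_true(b1$undefined)
  # excluded time does not count toward either numerator or denominator
  tr2 <- make_track(1000, af = cbind(0, 400), atfl = cbind(500, 750))
  b2 <- compute_burdens(make_log(cbind(0, 400)), tr2)
  expect_equal(b2$holter_burden_pct, 100 * 400 / 750)
  expect_equal(b2$icm_burden_pct, 100 * 400 / 750)
})

test_that("agreement statistics match direct formula evaluation", {
  pairs <- data.frame(patient_id = letters[1:4],
                      holter_burden_pct = c(10, 20, 30, 40),
                      icm_burden_pct = c(11, 19, 32, 38),
                      undefined = FALSE)
  a <- burden_agreement(pairs)
  d <- pairs$icm_burden_pct - pairs$holter_burden_pct
  expect_equal(a$bias_pct, mean(d))
  expect_equal(a$loa_low, mean(d) - 1.96 * sd(d))
  expect_equal(a$loa_high, mean(d) + 1.96 * sd(d))
  expect_equal(a$pearson_r, cor(pairs$holter_burden_pct, pairs$icm_burden_pct))
  # differences (1,-1,2,-2): bias 0, sd sqrt(10/3), limits +/- 1.96*sd
  p2 <- data.frame(patient_id = letters[1:4], holter_burden_pct = c(10, 20, 30, 40),
                   icm_burden_pct = c(11, 19, 32, 38), undefined = FALSE)
  p2$icm_burden_pct <- p2$holter_burden_pct + c(1, -1, 2, -2)
  a2 <- burden_agreement(p2)
  expect_equal(a2$bias_pct, 0)
  expect_equal(a2$sd_diff, sqrt(10 / 3), tolerance = 1e-12)
  expect_equal(a2$loa_high, 1.96 * sqrt(10 / 3), tolerance = 1e-12)
  # identical vectors: r = 1, bias 0, zero-width limits
  p3 <- data.frame(patient_id = letters[1:3], holter_burden_pct = c(5, 10, 20),
                   icm_burden_pct = c(5, 10, 20), undefined = FALSE)
  a3 <- burden_agreement(p3)
  expect_equal(a3$pearson_r, 1)
  expect_equal(c(a3$bias_pct, a3$loa_low, a3$loa_high), c(0, 0, 0))
})

test_that("correlation is affine-invariant and limits cover ~95% of Gaussian differences", {
  set.seed(17)
  h <- runif(50, 0, 60)
  i <- h + rnorm(50, -1, 3)
  p <- data.frame(patient_id = as.character(1:50), holter_burden_pct = h,
                  icm_burden_pct = i, undefined = FALSE)
  a <- burden_agreement(p)
  p_scaled <- p
  p_scaled$holter_burden_pct <- 2 * h + 7
  p_scaled$icm_burden_pct <- 2 * i + 7
  expect_equal(burden_agreement(p_scaled)$pearson_r, a$pearson_r, tolerance = 1e-12)
  # coverage of the limits over many simulated patients
  d <- rnorm(1000, -0.9, 4)
  p4 <- data.frame(patient_id = as.character(1:1000), holter_burden_pct = 30,
                   icm_burden_pct = 30 + d, undefined = FALSE)
  p4$holter_burden_pct <- runif(1000, 10, 50)
  p4$icm_burden_pct <- p4$holter_burden_pct + d
  a4 <- burden_agreement(p4)
  cover <- mean(d >= a4$loa_low & d <= a4$loa_high)
  expect_gte(cover, 0.93)
  expect_lte(cover, 0.97)
})

test_that("degenerate burden inputs are flagged", {
  p <- data.frame(patient_id = as.character(1:3), holter_burden_pct = c(10, 10, 10),
                  icm_burden_pct = c(10, 10, 10), undefined = FALSE)
  a <- burden_agreement(p)
  expect_equal(a$flag, "zero_variance")
  expect_true(is.na(a$pearson_r))
  expect_error(burden_agreement(p[1:2, ]), ">= 3 patients")
})
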