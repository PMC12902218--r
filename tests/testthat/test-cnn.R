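test_that("focal loss collapses to half of cross-entropy at gamma 0, alpha 0.5", {
  set.seed(3)
  p <- runif(10, 0.01, 0.99)
  y <- rbinom(10, 1, 0.5)
  bce <- -(y * log(p) + (1 - y) * log(1 - p))
  expect_lt(max(abs(focal_loss(p, y, gamma = 0, alpha = 0.5) - 0.5 * bce)), 1e-10)
  # perfect predictions drive the loss to zero
  expect_lt(max(focal_loss(c(1 - 1e-9, 1e-9), c(1, 0))), 1e-6)
  # focusing down-weights easy examples relative to hard ones
  expect_lt(focal_loss(0.9, 1, gamma = 2, alpha = 0.25),
            focal_loss(0.6, 1, gamma = 2, alpha = 0.25))
})

tiny_cfg <- function(...) {
  cnn_config(n_conv_blocks = 2, filters_per_block = c(2, 3), kernel_size = 3,
             dropout_per_block = c(0, 0), pool_every = 2, pool_size = 2,
             dense_units = 4, epochs = 1, batch_size = 4, seed = 11, ...)
}

test_that("model building is seeded, shape-checked and produces sane scores", {
  m1 <- build_cnn(tiny_cfg(), 16)
  m2 <- build_cnn(tiny_cfg(), 16)
  expect_identical(m1$params, m2$params)
  # zero input, any batch size: one finite score per snippet in (0,1)
  for (n in c(1, 5)) {
    s <- icmeval:::cnn_forward(m1, array(0, c(16, 1, n)))$scores
    expect_length(s, n)
    expect_true(all(is.finite(s) & s > 0 & s < 1))
  }
  expect_error(build_cnn(tiny_cfg(), 17), "incompatible with pooling")
  expect_error(cnn_config(filters_per_block = c(32, 16, 8, 8, 8, 8)), "non-decreasing")
})

test_that("backpropagation matches numerical gradients on a tiny network", {
  cfg <- tiny_cfg()
  model <- build_cnn(cfg, 16)
  set.seed(21)
  X <- array(rnorm(16 * 1 * 3), c(16, 1, 3))
  y <- c(1, 0, 1)
  loss_at <- function(m) {
    fw <- icmeval:::cnn_forward(m, X, training = TRUE)
    mean(focal_loss(fw$scores, y, cfg$focal_gamma, cfg$focal_alpha))
  }
  fw <- icmeval:::cnn_forward(model, X, training = TRUE)
  grads <- icmeval:::cnn_backward(fw$model, y, fw)
  h <- 1e-5
  for (nm in c("conv1_W", "conv2_b", "bn1_gamma", "bn2_beta", "dense1_W", "out_W")) {
    idx <- seq_len(min(4, length(model$params[[nm]])))
    for (i in idx) {
      mp <- model; mp$params[[nm]][i] <- mp$params[[nm]][i] + h
      mm <- model; mm$params[[nm]][i] <- mm$params[[nm]][i] - h
      num <- (loss_at(mp) - loss_at(mm)) / (2 * h)
      ana <- grads[[nm]][i]
      expect_lt(abs(num - ana) / (abs(num) + 1e-4), 1e-3)
    }
  }
})

test_that("threshold selection maximizes rejection at zero true-positive loss", {
  scores <- c(0.9, 0.8, 0.85, 0.2, 0.3, 0.1)
  labels <- c(1, 1, 1, 0, 0, 0)
  th <- select_threshold(scores, labels)
  expect_equal(th, (0.3 + 0.8) / 2)                      # midway between the clouds
  expect_equal(sum(scores[labels == 0] >= th), 0)        # 100% rejection
  expect_equal(sum(scores[labels == 1] >= th), 3)        # zero TP loss
  # brute-force scan: no candidate threshold rejects more false episodes
  # while keeping every true episode
  cand <- sort(unique(c(scores, th)))
  best <- max(vapply(cand, function(t)
    if (all(scores[labels == 1] >= t)) sum(scores[labels == 0] < t) else -1L,
    numeric(1)))
  expect_equal(sum(scores[labels == 0] < th), best)
  # partially overlapping clouds: margin falls back to the small default
  s2 <- c(0.6, 0.7, 0.65, 0.8)
  l2 <- c(1, 0, 0, 1)
  th2 <- select_threshold(s2, l2)
  expect_equal(th2, 0.6 - 1e-6)
  # degenerate: identical scores retain everything
  th2 <- select_threshold(rep(0.5, 6), labels)
  expect_true(all(rep(0.5, 6) >= th2))
  expect_equal(select_threshold(scores, labels, policy = "fixed", fixed_value = 0.42), 0.42)
})

test_that("training on a separable desk-scale set is deterministic and selective", {
  set.seed(1)
  n_per <- 24
  snips <- c(lapply(seq_len(n_per), function(i)
    synthesize_egm("true_af", 90, 16, seed = i)),
    lapply(seq_len(n_per), function(i)
      synthesize_egm("sinus_arrhythmia", 90, 16, seed = 500 + i)))
  labels <- rep(c(1, 0), each = n_per)
  pids <- paste0("P", rep(1:12, length.out = 2 * n_per))
  cfg <- cnn_config(n_conv_blocks = 3, filters_per_block = c(8, 8, 16),
                    kernel_size = 7, dropout_per_block = c(0.05, 0.1, 0.15),
                    pool_every = 2, pool_size = 4, dense_units = 16,
                    epochs = 3, batch_size = 16, seed = 42)
  tr1 <- train_fp_classifier(snips, labels, pids, cfg)
  tr2 <- train_fp_classifier(snips, labels, pids, cfg)
  expect_identical(tr1$model$params, tr2$model$params)
  expect_identical(tr1$operating_threshold, tr2$operating_threshold)
  # no training patient appears in validation
  expect_false(any(pids[tr1$split] %in% pids[!tr1$split]))
  # zero-TP-loss policy retains every validation true episode
  val_true <- tr1$validation$scores[tr1$validation$labels == 1]
  expect_true(all(val_true >= tr1$operating_threshold))
  expect_gt(tr1$validation$auroc, 0.8)
  expect_error(train_fp_classifier(snips[1:n_per], labels[1:n_per], pids[1:n_per], cfg),
               "both classes")
})

test_that("classification only selects the retained subset of a log", {
  set.seed(2)
  co <- generate_cohort(cohort_config(n_patients = 2, prob_af_patient = 1,
                                      fp_rate_per_day = 1, seed = 6,
                                      egm_sample_rate = 16,
                                      recording_days_range = c(1, 2)), egm = TRUE)
  n_per <- 16
  snips <- c(lapply(seq_len(n_per), function(i) synthesize_egm("true_af", 90, 16, seed = i)),
             lapply(seq_len(n_per), function(i) synthesize_egm("sinus_arrhythmia", 90, 16,
                                                               seed = 300 + i)))
  cfg <- cnn_config(n_conv_blocks = 2, filters_per_block = c(8, 8), kernel_size = 7,
                    dropout_per_block = c(0, 0), pool_every = 1, pool_size = 4,
                    dense_units = 8, epochs = 2, batch_size = 8, seed = 13)
  trained <- train_fp_classifier(snips, rep(c(1, 0), each = n_per),
                                 paste0("Q", rep(1:8, length.out = 2 * n_per)), cfg)
  lg <- co$logs[[1]]
  out <- classify_log(lg, trained)
  expect_identical(out$episodes$start_s, lg$episodes$start_s)
  expect_identical(out$episodes$end_s, lg$episodes$end_s)
  expect_true(all(out$episodes$ai_score > 0 & out$episodes$ai_score < 1))
  expect_identical(out$episodes$ai_retained,
                   out$episodes$ai_score >= trained$operating_threshold)
  # threshold 0 retains everything; threshold 1 rejects everything scored
  t0 <- trained; t0$operating_threshold <- 0
  expect_true(all(classify_log(lg, t0)$episodes$ai_retained))
  t1 <- trained; t1$operating_threshold <- 1 + 1e-9
  expect_false(any(classify_log(lg, t1)$episodes$ai_retained))
  # missing snippet: fail-safe retention with a warning
  lg_miss <- lg
  lg_miss$egm[[1]] <- NULL
  expect_warning(miss <- classify_log(lg_miss, trained), "retained by default")
  eid <- setdiff(lg$episodes$episode_id, names(lg_miss$egm))
  expect_true(miss$episodes$ai_retained[miss$episodes$episode_id == eid])
  expect_true(is.na(miss$episodes$ai_score[miss$episodes$episode_id == eid]))
})
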