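#' Configuration of the 1-D CNN false-positive classifier
#'
#' The classifier scores each device-detected episode's stored electrogram as
#' true AF (score near 1) or false detection (score near 0). The network is a
#' stack of `[Conv1D -> ReLU -> BatchNorm -> Dropout]` blocks with filter
#' counts and dropout rates increasing with depth, max-pooling every
#' `pool_every` blocks, global average pooling, fully connected layers, and a
#' single sigmoid output. It is trained with binary focal cross-entropy and
#' Adam. Defaults are sized for desk-scale CPU training on a few hundred
#' synthetic snippets.
#'
#' @param n_conv_blocks number of convolutional blocks.
#' @param filters_per_block non-decreasing integer vector, one per block.
#' @param kernel_size odd convolution kernel length in samples.
#' @param dropout_per_block non-decreasing dropout rates in `[0, 1)`, one per block.
#' @param pool_every max-pool after every this many blocks.
#' @param pool_size pooling window (= stride).
#' @param dense_units widths of the fully connected layers after pooling.
#' @param focal_gamma focusing parameter of the focal loss (>= 0).
#' @param focal_alpha class-balance weight in (0, 1) on the positive class.
#' @param learning_rate,epochs,batch_size Adam training parameters.
#' @param val_frac fraction of *patients* held out for validation.
#' @param seed RNG seed for initialization, shuffling, dropout and the split.
#' @param threshold_policy `"max_rejection_zero_tp_loss"` (largest threshold
#'   retaining every validation true episode, minus a safety margin) or
#'   `"fixed"`.
#' @param fixed_threshold operating threshold when the policy is `"fixed"`.
#' @param threshold_margin safety margin subtracted under the zero-TP-loss policy.
#' @return a validated list of class `cnn_config`.
#' @export
cnn_config <- function(n_conv_blocks = 6,
                       filters_per_block = c(16, 16, 32, 32, 64, 64),
                       kernel_size = 9,
                       dropout_per_block = c(0.10, 0.15, 0.20, 0.25, 0.30, 0.35),
                       pool_every = 2,
                       pool_size = 4,
                       dense_units = c(64, 16),
                       focal_gamma = 2,
                       focal_alpha = 0.25,
                       learning_rate = 1e-3,
                       epochs = 8,
                       batch_size = 32,
                       val_frac = 0.25,
                       seed = 1L,
                       threshold_policy = c("max_rejection_zero_tp_loss", "fixed"),
                       fixed_threshold = 0.5,
                       threshold_margin = 1e-6) {
  threshold_policy <- match.arg(threshold_policy)
  stopifnot(length(filters_per_block) == n_conv_blocks,
            length(dropout_per_block) == n_conv_blocks,
            kernel_size %% 2 == 1, focal_gamma >= 0,
            focal_alpha > 0, focal_alpha < 1,
            all(dropout_per_block >= 0), all(dropout_per_block < 1))
  if (is.unsorted(filters_per_block))
    stop("filters_per_block must be non-decreasing with depth")
  if (is.unsorted(dropout_per_block))
    stop("dropout_per_block must be non-decreasing with depth")
  structure(list(n_conv_blocks = n_conv_blocks, filters_per_block = filters_per_block,
                 kernel_size = kernel_size, dropout_per_block = dropout_per_block,
                 pool_every = pool_every, pool_size = pool_size,
                 dense_units = dense_units, focal_gamma = focal_gamma,
                 focal_alpha = focal_alpha, learning_rate = learning_rate,
                 epochs = epochs, batch_size = batch_size, val_frac = val_frac,
                 seed = as.integer(seed), threshold_policy = threshold_policy,
                 fixed_threshold = fixed_threshold, threshold_margin = threshold_margin),
            class = "cnn_config")
}

#' Build an untrained CNN
#'
#' Initializes all parameters (He-scaled Gaussians for weights, zeros for
#' biases, unit batch-norm scale) for a given input length. Two builds with
#' the same config seed give identical initial parameters.
#'
#' @param config a [cnn_config()].
#' @param input_len snippet length in samples (90 s x sample rate); must be
#'   divisible by `pool_size` at every pooling stage.
#' @return list of class `cnn_model` with `config`, `input_len`, `params`.
#' @export
build_cnn <- function(config, input_len) {
  stopifnot(inherits(config, "cnn_config"), input_len >= 1)
  n_pools <- sum(seq_len(config$n_conv_blocks) %% config$pool_every == 0)
  L <- input_len
  for (j in seq_len(n_pools)) {
    if (L %% config$pool_size != 0)
      stop(sprintf("input length %d incompatible with pooling depth (stage %d leaves length %d, not divisible by %d)",
                   input_len, j, L, config$pool_size))
    L <- L / config$pool_size
  }
  set.seed(config$seed)
  params <- list()
  c_in <- 1L
  for (b in seq_len(config$n_conv_blocks)) {
    c_out <- config$filters_per_block[b]
    k <- config$kernel_size
    params[[paste0("conv", b, "_W")]] <-
      array(rnorm(k * c_in * c_out, 0, sqrt(2 / (k * c_in))), dim = c(k, c_in, c_out))
    params[[paste0("conv", b, "_b")]] <- numeric(c_out)
    params[[paste0("bn", b, "_gamma")]] <- rep(1, c_out)
    params[[paste0("bn", b, "_beta")]] <- numeric(c_out)
    params[[paste0("bn", b, "_rmean")]] <- numeric(c_out)
    params[[paste0("bn", b, "_rvar")]] <- rep(1, c_out)
    c_in <- c_out
  }
  d_in <- c_in
  for (d in seq_along(config$dense_units)) {
    d_out <- config$dense_units[d]
    params[[paste0("dense", d, "_W")]] <-
      matrix(rnorm(d_in * d_out, 0, sqrt(2 / d_in)), d_in, d_out)
    params[[paste0("dense", d, "_b")]] <- numeric(d_out)
    d_in <- d_out
  }
  params$out_W <- matrix(rnorm(d_in, 0, sqrt(2 / d_in)), d_in, 1)
  params$out_b <- 0
  structure(list(config = config, input_len = as.integer(input_len), params = params),
            class = "cnn_model")
}

#' Binary focal cross-entropy
#'
#' `FL(p, y) = -alpha * y * (1 - p)^gamma * log(p)
#'             - (1 - alpha) * (1 - y) * p^gamma * log(1 - p)`.
#' With `gamma = 0`, `alpha = 0.5` this is half the ordinary binary
#' cross-entropy.
#'
#' @param p predicted probabilities in (0, 1).
#' @param y binary labels (0/1).
#' @param gamma focusing parameter.
#' @param alpha positive-class weight.
#' @return elementwise loss vector.
#' @export
focal_loss <- function(p, y, gamma = 2, alpha = 0.25) {
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  -alpha * y * (1 - p)^gamma * log(p) - (1 - alpha) * (1 - y) * p^gamma * log(1 - p)
}

focal_loss_grad <- function(p, y, gamma, alpha) {
  eps <- 1e-7
  p <- pmin(pmax(p, eps), 1 - eps)
  gpos <- alpha * (gamma * (1 - p)^(pmax(gamma - 1, 0)) * log(p) - (1 - p)^gamma / p)
  gneg <- (1 - alpha) * (-gamma * p^(pmax(gamma - 1, 0)) * log(1 - p) + p^gamma / (1 - p))
  y * gpos + (1 - y) * gneg
}

bn_channel_stats <- function(X) {
  # X: L x C x N cube; per-channel mean and (biased) variance over L and N
  C <- dim(X)[2]
  mu <- numeric(C); v <- numeric(C)
  for (c in seq_len(C)) {
    x <- X[, c, ]
    mu[c] <- mean(x)
    v[c] <- mean((x - mu[c])^2)
  }
  list(mean = mu, var = v)
}

cnn_forward <- function(model, X, training = FALSE) {
  cfg <- model$config
  p <- model$params
  eps <- 1e-5
  nb <- cfg$n_conv_blocks
  cache <- list(inputs = vector("list", nb), relu = vector("list", nb),
                bn = vector("list", nb), drop = vector("list", nb),
                pool = vector("list", nb), pooled = logical(nb))
  A <- X
  for (b in seq_len(cfg$n_conv_blocks)) {
    cache$inputs[[b]] <- A
    Z <- conv1d_fwd(A, p[[paste0("conv", b, "_W")]], p[[paste0("conv", b, "_b")]])
    R <- pmax(Z, 0)
    cache$relu[[b]] <- Z > 0
    if (training) {
      st <- bn_channel_stats(R)
      mu <- st$mean; v <- st$var
      model$params[[paste0("bn", b, "_rmean")]] <-
        0.9 * p[[paste0("bn", b, "_rmean")]] + 0.1 * mu
      model$params[[paste0("bn", b, "_rvar")]] <-
        0.9 * p[[paste0("bn", b, "_rvar")]] + 0.1 * v
    } else {
      mu <- p[[paste0("bn", b, "_rmean")]]
      v <- p[[paste0("bn", b, "_rvar")]]
    }
    gam <- p[[paste0("bn", b, "_gamma")]]
    bet <- p[[paste0("bn", b, "_beta")]]
    dims <- dim(R)
    inv_sd <- 1 / sqrt(v + eps)
    xhat <- sweep(sweep(R, 2, mu, "-"), 2, inv_sd, "*")
    B <- sweep(sweep(xhat, 2, gam, "*"), 2, bet, "+")
    cache$bn[[b]] <- list(xhat = xhat, inv_sd = inv_sd, mu = mu)
    if (training && cfg$dropout_per_block[b] > 0) {
      keep <- array(runif(length(B)) >= cfg$dropout_per_block[b], dims)
      B <- B * keep / (1 - cfg$dropout_per_block[b])
      cache$drop[[b]] <- keep
    }
    if (b %% cfg$pool_every == 0) {
      pl <- maxpool_fwd(B, cfg$pool_size)
      cache$pool[[b]] <- list(idx = pl$idx, lin = dim(B)[1])
      cache$pooled[b] <- TRUE
      A <- pl$Y
    } else {
      A <- B
    }
  }
  cache$conv_out <- A
  Lf <- dim(A)[1]
  Fm <- t(matrix(apply(A, 3, colMeans), nrow = dim(A)[2]))   # N x C global average pooling
  cache$gap_len <- Lf
  acts <- list(Fm)
  H <- Fm
  for (d in seq_along(cfg$dense_units)) {
    Zd <- sweep(H %*% p[[paste0("dense", d, "_W")]], 2, p[[paste0("dense", d, "_b")]], "+")
    H <- pmax(Zd, 0)
    acts[[d + 1L]] <- H
    cache[[paste0("dense_relu", d)]] <- Zd > 0
  }
  z <- as.numeric(H %*% p$out_W + p$out_b)
  cache$dense_acts <- acts
  list(scores = stats::plogis(z), logits = z, cache = cache, model = model)
}

cnn_backward <- function(model, y, fw) {
  cfg <- model$config
  p <- model$params
  cache <- fw$cache
  n <- length(y)
  grads <- list()
  dp <- focal_loss_grad(fw$scores, y, cfg$focal_gamma, cfg$focal_alpha) / n
  dz <- dp * fw$scores * (1 - fw$scores)     # through the sigmoid
  H_last <- cache$dense_acts[[length(cache$dense_acts)]]
  grads$out_W <- t(H_last) %*% matrix(dz, ncol = 1)
  grads$out_b <- sum(dz)
  dH <- matrix(dz, ncol = 1) %*% t(p$out_W)
  for (d in rev(seq_along(cfg$dense_units))) {
    dZd <- dH * cache[[paste0("dense_relu", d)]]
    A_prev <- cache$dense_acts[[d]]
    grads[[paste0("dense", d, "_W")]] <- t(A_prev) %*% dZd
    grads[[paste0("dense", d, "_b")]] <- colSums(dZd)
    dH <- dZd %*% t(p[[paste0("dense", d, "_W")]])
  }
  # undo global average pooling: spread dF over the pooled length
  A <- cache$conv_out
  Lf <- dim(A)[1]; C <- dim(A)[2]
  dA <- array(0, dim(A))
  for (i in seq_len(n)) dA[, , i] <- matrix(dH[i, ] / Lf, Lf, C, byrow = TRUE)
  for (b in rev(seq_len(cfg$n_conv_blocks))) {
    if (cache$pooled[b])
      dA <- maxpool_bwd(dA, cache$pool[[b]]$idx, cache$pool[[b]]$lin)
    if (!is.null(cache$drop[[b]]))
      dA <- dA * cache$drop[[b]] / (1 - cfg$dropout_per_block[b])
    bn <- cache$bn[[b]]
    gam <- p[[paste0("bn", b, "_gamma")]]
    C_b <- length(gam)
    m <- dim(dA)[1] * dim(dA)[3]
    dgam <- numeric(C_b); dbet <- numeric(C_b)
    dR <- array(0, dim(dA))
    for (c in seq_len(C_b)) {
      dYc <- dA[, c, ]; xh <- bn$xhat[, c, ]
      dgam[c] <- sum(dYc * xh)
      dbet[c] <- sum(dYc)
      dxh <- dYc * gam[c]
      dR[, c, ] <- bn$inv_sd[c] * (dxh - mean(dxh) - xh * mean(dxh * xh))
    }
    grads[[paste0("bn", b, "_gamma")]] <- dgam
    grads[[paste0("bn", b, "_beta")]] <- dbet
    dZ <- dR * cache$relu[[b]]
    cb <- conv1d_bwd(cache$inputs[[b]], p[[paste0("conv", b, "_W")]], dZ)
    grads[[paste0("conv", b, "_W")]] <- cb$dW
    grads[[paste0("conv", b, "_b")]] <- cb$db
    dA <- cb$dX
  }
  grads
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# stack snippets into a standardized L x 1 x N cube
snippets_to_cube <- function(snippets) {
  lens <- vapply(snippets, function(s) length(s$samples), integer(1))
  if (length(unique(lens)) != 1L)
    stop("snippets must be length-homogeneous (got lengths ",
         paste(unique(lens), collapse = ", "), ")")
  L <- lens[1L]
  X <- array(0, c(L, 1L, length(snippets)))
  for (i in seq_along(snippets)) {
    x <- snippets[[i]]$samples
    X[, 1L, i] <- (x - mean(x)) / (stats::sd(x) + 1e-8)
  }
  X
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC with midrank tie handling.
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels binary labels (1 = positive).
#' @return AUROC in `[0, 1]`; NA if one class is absent.
#' @export
auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels != 1]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# assign whole patients to train/validation, keeping both classes on each side
split_patients <- function(patient_ids, labels, val_frac) {
  pts <- unique(patient_ids)
  if (length(pts) < 2L) stop("patient-level split needs >= 2 patients")
  for (attempt in 1:50) {
    shuffled <- sample(pts)
    n_val <- max(1L, round(val_frac * length(pts)))
    val_pts <- shuffled[seq_len(n_val)]
    in_val <- patient_ids %in% val_pts
    if (length(unique(labels[in_val])) == 2L && length(unique(labels[!in_val])) == 2L)
      return(in_val)
  }
  stop("could not build a patient-level split with both classes on each side")
}

#' Train the false-positive classifier
#'
#' Fits the CNN on labelled electrogram snippets with binary focal
#' cross-entropy and Adam, using a patient-level train/validation split (no
#' patient contributes snippets to both sides), then selects the operating
#' threshold on the validation set according to the configured policy.
#'
#' @param snippets list of `egm_snippet` objects (length-homogeneous).
#' @param labels binary vector: 1 = true AF, 0 = false detection.
#' @param patient_ids character vector, one id per snippet.
#' @param config a [cnn_config()].
#' @param verbose print per-epoch losses.
#' @return list of class `trained_classifier`: `model` (with fitted
#'   parameters), `operating_threshold`, `validation` (scores, labels,
#'   AUROC, loss history), `split` (logical validation mask).
#' @export
train_fp_classifier <- function(snippets, labels, patient_ids, config = cnn_config(),
                                verbose = FALSE) {
  labels <- as.numeric(labels)
  stopifnot(length(snippets) == length(labels), length(labels) == length(patient_ids))
  if (length(unique(labels)) < 2L)
    stop("training set must contain both classes")
  set.seed(config$seed)
  in_val <- split_patients(patient_ids, labels, config$val_frac)
  X_all <- snippets_to_cube(snippets)
  model <- build_cnn(config, dim(X_all)[1])
  set.seed(config$seed + 1L)   # build_cnn reseeds; new stream for shuffling/dropout
  idx_tr <- which(!in_val); idx_va <- which(in_val)
  state <- list(m = list(), v = list())
  t_step <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(), val_loss = numeric())
  for (ep in seq_len(config$epochs)) {
    ord <- sample(idx_tr)
    ep_loss <- 0; n_seen <- 0
    for (start in seq(1, length(ord), by = config$batch_size)) {
      bi <- ord[start:min(start + config$batch_size - 1L, length(ord))]
      Xb <- X_all[, , bi, drop = FALSE]
      yb <- labels[bi]
      fw <- cnn_forward(model, Xb, training = TRUE)
      model <- fw$model                       # running BN stats updated
      grads <- cnn_backward(model, yb, fw)
      t_step <- t_step + 1L
      upd <- adam_step(model$params, grads, state, config$learning_rate, t_step)
      model$params <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + sum(focal_loss(fw$scores, yb, config$focal_gamma,
                                          config$focal_alpha))
      n_seen <- n_seen + length(bi)
    }
    val_scores <- predict_cnn(model, X_all[, , idx_va, drop = FALSE])
    val_loss <- mean(focal_loss(val_scores, labels[idx_va],
                                config$focal_gamma, config$focal_alpha))
    history <- rbind(history, data.frame(epoch = ep, train_loss = ep_loss / n_seen,
                                         val_loss = val_loss))
    if (verbose)
      message(sprintf("epoch %d: train loss %.5f, val loss %.5f", ep,
                      ep_loss / n_seen, val_loss))
  }
  val_scores <- predict_cnn(model, X_all[, , idx_va, drop = FALSE])
  thr <- select_threshold(val_scores, labels[idx_va], config$threshold_policy,
                          config$fixed_threshold, config$threshold_margin)
  structure(list(model = model, config = config, operating_threshold = thr,
                 validation = list(scores = val_scores, labels = labels[idx_va],
                                   auroc = auroc(val_scores, labels[idx_va]),
                                   history = history),
                 split = in_val),
            class = "trained_classifier")
}

predict_cnn <- function(model, X, chunk = 64L) {
  n <- dim(X)[3]
  out <- numeric(n)
  for (start in seq(1, n, by = chunk)) {
    ix <- start:min(start + chunk - 1L, n)
    out[ix] <- cnn_forward(model, X[, , ix, drop = FALSE], training = FALSE)$scores
  }
  out
}

#' Score electrogram snippets with a trained classifier
#'
#' @param trained a [train_fp_classifier()] result.
#' @param snippets list of `egm_snippet` objects.
#' @return numeric scores in (0, 1).
#' @export
predict_egm_scores <- function(trained, snippets) {
  predict_cnn(trained$model, snippets_to_cube(snippets))
}

#' Select the operating threshold
#'
#' Under the `max_rejection_zero_tp_loss` policy the threshold rejects as many
#' validation false episodes as possible subject to retaining (score >=
#' threshold) every validation true episode. Any value up to the minimum true
#' score achieves that maximum, so the safety margin is taken as half the gap
#' down to the highest rejected false score: the threshold sits midway between
#' the two score clouds, which keeps true episodes from unseen patients away
#' from the cut while rejecting the same validation false episodes. When no
#' false score lies below the minimum true score the fallback margin `margin`
#' is subtracted instead. Under `fixed` the user value is returned.
#'
#' @param scores validation scores.
#' @param labels validation labels (1 = true AF).
#' @param policy `"max_rejection_zero_tp_loss"` or `"fixed"`.
#' @param fixed_value threshold used under the fixed policy.
#' @param margin fallback safety margin.
#' @return threshold in (0, 1).
#' @export
select_threshold <- function(scores, labels,
                             policy = "max_rejection_zero_tp_loss",
                             fixed_value = 0.5, margin = 1e-6) {
  if (policy == "fixed") return(fixed_value)
  if (!any(labels == 1)) stop("threshold selection needs >= 1 true episode")
  min_true <- min(scores[labels == 1])
  below <- scores[labels != 1 & scores < min_true]
  if (length(below)) (max(below) + min_true) / 2 else min_true - margin
}

#' Classify an ICM episode log
#'
#' Scores every episode's electrogram and sets `ai_score` and `ai_retained`
#' (`score >= operating_threshold`). Episode boundaries and ordering are
#' untouched: the classifier only selects the retained subset. An episode
#' without a snippet is retained by default (fail-safe toward sensitivity)
#' with an NA score and a warning.
#'
#' @param icm_log an [icm_log()]; snippets are taken from the in-memory `egm`
#'   store or read from `egm_path` relative to `egm_dir`.
#' @param trained a [train_fp_classifier()] result.
#' @param egm_dir base directory for `egm_path` resolution.
#' @return the log with `ai_score` and `ai_retained` filled in.
#' @export
classify_log <- function(icm_log, trained, egm_dir = NULL) {
  stopifnot(inherits(icm_log, "icm_log"), inherits(trained, "trained_classifier"))
  ep <- icm_log$episodes
  if (!nrow(ep)) return(icm_log)
  snips <- vector("list", nrow(ep))
  for (i in seq_len(nrow(ep))) {
    eid <- ep$episode_id[i]
    if (!is.null(icm_log$egm[[eid]])) snips[[i]] <- icm_log$egm[[eid]]
    else if (!is.na(ep$egm_path[i]) && !is.null(egm_dir) &&
             file.exists(file.path(egm_dir, ep$egm_path[i])))
      snips[[i]] <- read_egm(file.path(egm_dir, ep$egm_path[i]))
  }
  have <- !vapply(snips, is.null, logical(1))
  if (any(!have))
    warning(sum(!have), " episode(s) without an EGM snippet in log ",
            icm_log$patient_id, "; retained by default")
  scores <- rep(NA_real_, nrow(ep))
  if (any(have)) scores[have] <- predict_egm_scores(trained, snips[have])
  ep$ai_score <- scores
  ep$ai_retained <- ifelse(have, scores >= trained$operating_threshold, TRUE)
  out <- icm_log(icm_log$patient_id, ep, egm = icm_log$egm, min_duration_s = 0)
  for (a in c("sync", "sync_truth", "drift_ppm"))
    if (!is.null(attr(icm_log, a))) attr(out, a) <- attr(icm_log, a)
  out
}

#' @export
print.trained_classifier <- function(x, ...) {
  cat(sprintf("<trained_classifier> %d conv blocks, threshold %.4f, validation AUROC %.3f\n",
              x$config$n_conv_blocks, x$operating_threshold, x$validation$auroc))
  invisible(x)
}
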