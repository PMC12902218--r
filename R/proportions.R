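#' Confidence interval for a binomial proportion
#'
#' @param k number of successes.
#' @param n number of trials (> 0).
#' @param method `"clopper-pearson"` (exact, default) or `"wilson"`.
#' @param conf confidence level (default 0.95).
#' @return numeric `c(low, high)`; `c(NA, NA)` when `n == 0`.
#' @export
ci_proportion <- function(k, n, method = c("clopper-pearson", "wilson"), conf = 0.95) {
  method <- match.arg(method)
  if (n == 0) return(c(low = NA_real_, high = NA_real_))
  stopifnot(k >= 0, k <= n)
  a <- 1 - conf
  if (method == "clopper-pearson") {
    low <- if (k == 0) 0 else stats::qbeta(a / 2, k, n - k + 1)
    high <- if (k == n) 1 else stats::qbeta(1 - a / 2, k + 1, n - k)
  } else {
    ci <- stats::prop.test(k, n, conf.level = conf, correct = FALSE)$conf.int
    low <- ci[1L]; high <- ci[2L]
  }
  c(low = low, high = high)
}

#' Cluster-adjusted proportion via intercept-only logistic GEE
#'
#' Estimates a common proportion from clustered binary outcomes (episodes
#' nested in patients) by generalized estimating equations with an
#' exchangeable working correlation, the standard adjustment for multiple
#' episodes per subject. For an intercept-only logistic model the estimating
#' equation reduces to a weighted mean of cluster proportions with weights
#' `n_i / (1 + (n_i - 1) * alpha)`; `alpha` is the moment estimator from
#' pairwise products of Pearson residuals, and the two are iterated to
#' convergence. The 95% CI comes from the robust (sandwich) standard error on
#' the logit scale, back-transformed.
#'
#' When every outcome is a success (or every one a failure) the logit diverges;
#' the function falls back to the pooled exact binomial interval with a
#' warning, flagging the estimate as degenerate.
#'
#' @param successes integer vector, successes per cluster.
#' @param trials integer vector, trials per cluster (same length, all >= 1).
#' @param conf confidence level.
#' @return list with `point`, `ci_low`, `ci_high`, `alpha` (working
#'   correlation), `flag` (`"ok"` or `"degenerate_fallback"`).
#' @export
gee_proportion <- function(successes, trials, conf = 0.95) {
  stopifnot(length(successes) == length(trials), all(trials >= 1),
            all(successes >= 0), all(successes <= trials))
  keep <- trials > 0
  k <- successes[keep]; n <- trials[keep]
  m <- length(n)
  if (m < 2L) stop("gee_proportion needs >= 2 clusters")
  K <- sum(k); N <- sum(n)
  if (K == 0 || K == N) {
    warning("all-", if (K == 0) "failure" else "success",
            " data: logit degenerate; falling back to pooled exact binomial")
    ci <- ci_proportion(K, N)
    return(list(point = K / N, ci_low = ci[["low"]], ci_high = ci[["high"]],
                alpha = NA_real_, flag = "degenerate_fallback"))
  }
  mu <- K / N
  alpha <- 0
  for (iter in 1:50) {
    w <- n / (1 + (n - 1) * alpha)
    mu_new <- sum((w / n) * k) / sum(w)            # weighted mean of cluster proportions
    v <- mu_new * (1 - mu_new)
    # moment estimator of the exchangeable correlation from Pearson residuals
    sum_r <- (k - n * mu_new) / sqrt(v)
    sum_r2 <- (k * (1 - mu_new)^2 + (n - k) * mu_new^2) / v
    phi <- sum(sum_r2) / (N - 1)
    pair_sum <- sum((sum_r^2 - sum_r2) / 2)
    n_pairs <- sum(n * (n - 1) / 2)
    alpha_new <- if (n_pairs > 1) pair_sum / (phi * (n_pairs - 1)) else 0
    alpha_new <- min(max(alpha_new, -0.99), 0.999)
    done <- abs(mu_new - mu) < 1e-12 && abs(alpha_new - alpha) < 1e-10
    mu <- mu_new; alpha <- alpha_new
    if (done) break
  }
  v <- mu * (1 - mu)
  w <- n / (1 + (n - 1) * alpha)
  # sandwich variance of the intercept on the logit scale:
  # bread B = v * sum(w_i); meat M = sum(w_i^2 (kbar_i - mu)^2), kbar_i = k_i/n_i
  B <- abs(v * sum(w))       # |bread|: negative alpha can flip its sign
  M <- sum((w * (k / n - mu))^2)
  se_logit <- sqrt(M) / B
  z <- stats::qnorm(1 - (1 - conf) / 2)
  lg <- stats::qlogis(mu)
  list(point = mu, ci_low = stats::plogis(lg - z * se_logit),
       ci_high = stats::plogis(lg + z * se_logit), alpha = alpha, flag = "ok")
}

# one MetricEstimate row; undefined (zero-denominator) estimates carry NA
# points and undefined = TRUE, never silent 0/0
metric_row <- function(name, estimator, point = NA_real_, ci_low = NA_real_,
                       ci_high = NA_real_, k = NA_real_, n = NA_real_,
                       undefined = FALSE) {
  data.frame(name = name, estimator = estimator, point = point,
             ci_low = ci_low, ci_high = ci_high, k = k, n = n,
             undefined = undefined, stringsAsFactors = FALSE)
}

# gross + patient-average + GEE rows for one clustered proportion
clustered_metric_rows <- function(name, k_by_cluster, n_by_cluster,
                                  ci_method = "clopper-pearson") {
  K <- sum(k_by_cluster); N <- sum(n_by_cluster)
  rows <- if (N == 0) {
    metric_row(name, "gross", undefined = TRUE)
  } else {
    ci <- ci_proportion(K, N, ci_method)
    metric_row(name, "gross", K / N, ci[["low"]], ci[["high"]], K, N)
  }
  use <- n_by_cluster > 0
  props <- k_by_cluster[use] / n_by_cluster[use]
  m <- length(props)
  rows <- rbind(rows, if (m == 0) {
    metric_row(name, "patient_average", undefined = TRUE)
  } else {
    se <- if (m > 1) stats::sd(props) / sqrt(m) else NA_real_
    metric_row(name, "patient_average", mean(props),
               if (m > 1) max(0, mean(props) - 1.96 * se) else NA_real_,
               if (m > 1) min(1, mean(props) + 1.96 * se) else NA_real_,
               sum(k_by_cluster[use]), sum(n_by_cluster[use]))
  })
  rows <- rbind(rows, if (sum(use) < 2) {
    metric_row(name, "gee", undefined = TRUE)
  } else {
    g <- suppressWarnings(gee_proportion(k_by_cluster[use], n_by_cluster[use]))
    metric_row(name, "gee", g$point, g$ci_low, g$ci_high, K, N)
  })
  rows
}
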