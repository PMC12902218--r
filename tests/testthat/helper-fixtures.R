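# fixtures are built in code: small tracks/logs, random interval sets, and a
# brute-force discretization oracle for all interval measures

make_track <- function(span = 1000, af = NULL, atfl = NULL, uninterp = NULL,
                       pid = "P1") {
  ev <- rbind(
    if (!is.null(af)) data.frame(label = "AF", start_s = af[, 1], end_s = af[, 2]),
    if (!is.null(atfl)) data.frame(label = "ATFL", start_s = atfl[, 1], end_s = atfl[, 2]),
    if (!is.null(uninterp)) data.frame(label = "UNINTERPRETABLE",
                                       start_s = uninterp[, 1], end_s = uninterp[, 2]))
  annotation_track(pid, span, ev)
}

make_log <- function(episodes, pid = "P1", cause = NULL, retained = NULL) {
  n <- nrow(episodes)
  icm_log(pid, data.frame(
    episode_id = sprintf("%s-E%02d", pid, seq_len(n)),
    start_s = episodes[, 1], end_s = episodes[, 2],
    cause_label = if (is.null(cause)) rep(NA_character_, n) else cause,
    ai_retained = if (is.null(retained)) rep(NA, n) else retained),
    min_duration_s = 0)
}

# random disjoint interval set inside [0, span)
random_intervals <- function(n, span, min_len = 5, max_len = span / 4) {
  if (n == 0) return(cbind(numeric(0), numeric(0)))
  lens <- runif(n, min_len, min(max_len, span / (n + 1)))
  free <- span - sum(lens)
  g <- rexp(n + 1); g <- g / sum(g) * free
  starts <- cumsum(g[seq_len(n)]) + c(0, cumsum(lens))[seq_len(n)]
  cbind(starts, starts + lens)
}

# brute-force measure of a set expression on a 0.1 s grid (midpoint sampling);
# f takes a logical membership matrix of the grid for each interval set
grid_measure <- function(span, step = 0.1, ...) {
  sets <- list(...)
  mid <- seq(step / 2, span, by = step)
  member <- lapply(sets, function(s) {
    m <- rep(FALSE, length(mid))
    s <- as.matrix(s)
    for (k in seq_len(nrow(s))) m <- m | (mid >= s[k, 1] & mid < s[k, 2])
    m
  })
  names(member) <- names(sets)
  member
}

# a small generated patient: returns list(track, synced log) with known truth
quick_patient <- function(seed, n_patients = 1, ...) {
  cfg <- cohort_config(n_patients = n_patients, seed = seed, ...)
  generate_cohort(cfg, egm = FALSE)
}

# deterministic clustered binomial datasets shared with the external GEE
# reference fit (frozen expected values in test-proportions.R)
make_gee_datasets <- function() {
  set.seed(2024)
  lapply(1:20, function(d) {
    m <- sample(5:15, 1)
    n <- sample(1:20, m, replace = TRUE)
    p_clust <- rbeta(m, 4, 2)
    k <- rbinom(m, n, p_clust)
    list(k = k, n = n)
  })
}
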