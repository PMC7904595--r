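# Shared fixtures, all built in code. Small grids keep simulation-based
# tests fast; the full-size default cohort is built once (memoized) for
# the acceptance suite.

.fixture_env <- new.env(parent = emptyenv())

# quick series from a real or complex matrix (channels x TRs)
fs <- function(mat, tr = 1, ...) {
  FidnavSeries(mat, tr_seconds = tr, ...)
}

# small phantom + coil array reused across simulator tests
small_scene <- function(n_channels = 8L) {
  key <- paste0("scene", n_channels)
  if (is.null(.fixture_env[[key]])) {
    ph <- makePhantom(grid_shape = c(16L, 16L, 16L),
                      semi_axes_mm = c(60, 70, 65), spacing_mm = 12)
    co <- makeCoilArray(ph, n_channels = n_channels, seed = 11)
    .fixture_env[[key]] <- list(phantom = ph, coils = co)
  }
  .fixture_env[[key]]
}

# small simulated series
small_sim <- function(profile = "still", magnitude = 1, n_tr = 12L,
                      noise = NULL, seed = 5L, event_times = NULL,
                      n_channels = 8L) {
  sc <- small_scene(n_channels)
  traj <- sampleTrajectory(profile, magnitude = magnitude, n_tr = n_tr,
                           event_times = event_times, seed = seed)
  forwardFidnav(sc$phantom, sc$coils, traj, tr_seconds = 1.54,
                noise = noise, seed = seed)
}

# the full-size default cohort with scores, generated once per test run
default_cohort_scored <- function() {
  if (is.null(.fixture_env$cohort)) {
    coh <- generateCohort(seed = 101L)
    scores <- scoreCohort(coh$series, coh$manifest$grade,
                          weighting = coh$weighting)
    .fixture_env$cohort <- list(cohort = coh, scores = scores)
  }
  .fixture_env$cohort
}

# independent AUC oracle: tie-corrected Mann-Whitney pair counting
mann_whitney_auc <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  pairs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(pairs)
}

# independent Youden oracle: exhaustive grid search over candidate
# thresholds (all observed scores plus a sentinel above the maximum)
grid_youden <- function(scores, positive) {
  cand <- c(sort(unique(scores)), max(scores) + 1)
  j <- vapply(cand, function(c) {
    se <- mean(scores[positive] >= c)
    sp <- mean(scores[!positive] < c)
    se + sp - 1
  }, numeric(1))
  list(j = max(j), threshold = cand[which.max(j)])
}
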