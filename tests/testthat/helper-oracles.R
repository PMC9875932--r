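# Independent oracles and fixture builders shared across test files.

# Exhaustive Floyd-Warshall all-pairs shortest paths; the independent
# reference for the BFS-based global-efficiency implementation.
fwDistances <- function(A) {
  N <- nrow(A)
  D <- matrix(Inf, N, N)
  D[A != 0] <- 1
  diag(D) <- 0
  for (k in seq_len(N))
    for (i in seq_len(N))
      for (j in seq_len(N))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

fwGlobalEfficiency <- function(A) {
  N <- nrow(A)
  inv <- 1 / fwDistances(A)
  diag(inv) <- 0
  sum(inv) / (N * (N - 1))
}

# Random symmetric adjacency matrix on n nodes with edge probability p.
randomAdjacency <- function(n, p, seed) {
  withr::local_seed(seed)
  A <- matrix(FALSE, n, n)
  up <- upper.tri(A)
  A[up] <- runif(sum(up)) < p
  A | t(A)
}

# Random valid correlation matrix on n variables (sample correlation of
# random Gaussian data; guarantees symmetry and unit diagonal).
randomCorrelation <- function(n, nObs = 50, seed = 1) {
  withr::local_seed(seed)
  stats::cor(matrix(rnorm(nObs * n), nObs, n))
}

# Hand-built long-format cohort: `sessions` is a named-per-subject integer
# vector; groups is a parallel character vector. One method/image type,
# slope per group, no noise unless sd > 0.
makeCohortTable <- function(sessions, groups, slopes = NULL, nROI = 3,
                            method = "DL", imageType = "pre", sd = 0,
                            seed = 1) {
  withr::local_seed(seed)
  rois <- sprintf("roi%02d", seq_len(nROI))
  rows <- list()
  for (i in seq_along(sessions)) {
    nS <- sessions[i]
    ages <- 40 + i / 10 + seq_len(nS)
    slope <- if (is.null(slopes)) -0.01 else slopes[i]
    for (s in seq_len(nS)) {
      thick <- 2.5 + slope * (ages[s] - ages[1]) +
        if (sd > 0) rnorm(nROI, 0, sd) else 0
      rows[[paste(i, s)]] <- data.frame(
        subject_id = sprintf("sub%03d", i), group = groups[i],
        session_index = s, age = ages[s], image_type = imageType,
        method = method, roi = rois, thickness_mm = thick,
        stringsAsFactors = FALSE)
    }
  }
  MorphTable(do.call(rbind, rows))
}

# Small default-structured synthetic cohort for integration-style tests.
smallStudy <- function(seed = 1, nPPMS = 4, nRRMS = 12) {
  dsc <- defaultStudyConfig(seed = seed)
  cfg <- CohortConfig(nPPMS = nPPMS, nRRMS = nRRMS, seed = seed)
  truth <- generateTrueCohort(cfg)
  list(config = cfg, models = dsc$models, truth = truth,
       obs = simulateMeasurements(truth, dsc$models, seed = seed))
}
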