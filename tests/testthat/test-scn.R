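test_that("residuals are zero when thickness is exactly linear in age", {
  d <- morphData(makeCohortTable(rep(4, 5), rep("RRMS", 5), nROI = 4))
  # strictly linear-in-age data per region, same line for every subject
  d$thickness_mm <- 2.5 - 0.01 * d$age +
    0.1 * match(d$roi, sort(unique(d$roi)))
  res <- residualizeAge(MorphTable(d), "DL", "pre")
  expect_lt(max(abs(residualValues(res))), 1e-10)
})

test_that("with no age effect residuals equal centered thickness", {
  # every subject has the same two ages, constant thickness per subject:
  # the age-thickness covariance is exactly zero, so the OLS slope is 0
  # and the residual is the column-centered thickness
  offsets <- c(-0.1, 0.0, 0.1)
  rows <- do.call(rbind, lapply(1:3, function(i)
    data.frame(subject_id = sprintf("s%d", i), group = "RRMS",
               session_index = 1:2, age = c(40, 41), image_type = "pre",
               method = "DL", roi = "roiA",
               thickness_mm = 2.5 + offsets[i])))
  res <- residualizeAge(MorphTable(rows), "DL", "pre")
  expect_equal(as.vector(residualValues(res)), rep(offsets, each = 2),
               tolerance = 1e-12)
})

test_that("residualization removes a known age trend, leaving noise", {
  withr::local_seed(10)
  n <- 300
  ages <- runif(n, 30, 60)
  rows <- data.frame(
    subject_id = sprintf("s%03d", seq_len(n)), group = "RRMS",
    session_index = 1L, age = ages, image_type = "pre", method = "DL",
    roi = rep("roiA", n),
    thickness_mm = 3.5 - 0.012 * ages + rnorm(n, 0, 0.01))
  res <- residualizeAge(MorphTable(rows), "DL", "pre")
  R <- residualValues(res)[, 1]
  expect_lt(abs(cor(R, ages)), 1e-10)          # trend fully removed
  expect_equal(sd(R), 0.01, tolerance = 0.15)  # only the noise remains
})

test_that("residualization is invariant to adding per-region linear age terms", {
  st <- smallStudy(seed = 12, nPPMS = 3, nRRMS = 8)
  d <- morphData(st$obs)
  res1 <- residualizeAge(st$obs, "DL", "pre")
  # add an arbitrary per-region affine function of age
  rois <- sort(unique(d$roi))
  a <- seq_along(rois) / 100
  b <- rev(seq_along(rois)) / 50
  i <- match(d$roi, rois)
  d2 <- d
  d2$thickness_mm <- d$thickness_mm + a[i] + b[i] * d$age
  res2 <- residualizeAge(MorphTable(d2), "DL", "pre")
  expect_equal(residualValues(res2), residualValues(res1),
               tolerance = 1e-9)
  expect_equal(correlationMatrix(res2), correlationMatrix(res1),
               tolerance = 1e-8)
})

test_that("constant age is a degenerate design for residualization", {
  d <- morphData(makeCohortTable(rep(3, 4), rep("RRMS", 4)))
  d <- d[d$session_index == 1, ]
  d$age <- 40
  expect_error(residualizeAge(MorphTable(d), "DL", "pre"), "constant age")
})

test_that("correlation matrix is symmetric, unit-diagonal, and exact for clones", {
  withr::local_seed(30)
  R <- matrix(rnorm(200), 50, 4)
  R <- cbind(R, R[, 1])  # clone column
  colnames(R) <- paste0("r", 1:5)
  C <- correlationMatrix(R)
  expect_identical(C, t(C))
  expect_equal(unname(diag(C)), rep(1, 5))
  expect_equal(C[1, 5], 1)
  expect_error(correlationMatrix(cbind(R, r6 = rep(1, 50))), "r6")
})

test_that("independent columns give near-zero off-diagonal correlation", {
  withr::local_seed(31)
  C <- correlationMatrix(matrix(rnorm(10000 * 6), 10000, 6))
  expect_lt(max(abs(C[upper.tri(C)])), 0.05)
})

test_that("thresholding produces the enumerated edge set", {
  vals <- c(0.9, 0.6, 0.4, 0.2, 0.1, 0.05)
  C <- diag(4)
  C[upper.tri(C)] <- vals
  C <- C + t(C) - diag(4)
  g <- thresholdGraph(C, 0.5)
  expect_equal(sum(adjacency(g)) / 2, 2)  # entries >= 0.5: 0.9 and 0.6
  full <- thresholdGraph(matrix(1, 3, 3), 0.5)
  expect_equal(sum(adjacency(full)) / 2, 3)
  empty <- thresholdGraph(C, 0.95)
  expect_equal(sum(adjacency(empty)), 0)
  expect_error(thresholdGraph(matrix(c(1, 0.5, 0.2, 1), 2, 2), 0.5),
               "symmetric")
  expect_error(thresholdGraph(C, 1.5), "\\[0, 1\\]")
})

test_that("global efficiency matches closed-form values on canonical graphs", {
  K3 <- matrix(TRUE, 3, 3); diag(K3) <- FALSE
  expect_equal(globalEfficiency(K3), 1.0)
  expect_equal(globalEfficiency(matrix(FALSE, 4, 4)), 0.0)
  P3 <- matrix(FALSE, 3, 3)
  P3[1, 2] <- P3[2, 1] <- P3[2, 3] <- P3[3, 2] <- TRUE
  expect_equal(globalEfficiency(P3), 5 / 6)
  expect_error(globalEfficiency(matrix(FALSE, 1, 1)), "2 nodes")
})

test_that("global efficiency equals the Floyd-Warshall oracle on 200 random graphs", {
  for (i in 1:200) {
    n <- 2 + (i %% 11)
    A <- randomAdjacency(n, p = (i %% 7 + 1) / 8, seed = 1000 + i)
    expect_identical(globalEfficiency(A), fwGlobalEfficiency(A))
  }
})

test_that("efficiency is in [0,1], 1 iff complete, 0 iff edgeless", {
  for (i in 1:25) {
    A <- randomAdjacency(8, p = i / 26, seed = 400 + i)
    e <- globalEfficiency(A)
    expect_gte(e, 0)
    expect_lte(e, 1)
    complete <- all(A[upper.tri(A)])
    edgeless <- !any(A)
    expect_equal(e == 1, complete)
    expect_equal(e == 0, edgeless)
  }
})

test_that("efficiency curves are non-increasing in tau for arbitrary input", {
  for (s in 1:5) {
    C <- randomCorrelation(10, nObs = 30, seed = 600 + s)
    curve <- efficiencyCurve(C)
    expect_equal(nrow(curve), 100)
    expect_true(all(diff(curve$e_glob) <= 1e-12))
  }
  ones <- matrix(1, 5, 5)
  expect_true(all(efficiencyCurve(ones)$e_glob == 1))
})

test_that("subsample bands: rank-1 residuals give zero band, same seed same band", {
  withr::local_seed(50)
  base <- rnorm(40)
  R <- matrix(rep(base, 5), 40, 5)
  colnames(R) <- paste0("r", 1:5)
  res <- new("ResidualMatrix", imageIds = sprintf("i%02d", 1:40),
             roiNames = colnames(R), residuals = R,
             info = data.frame(subject_id = sprintf("i%02d", 1:40),
                               group = "RRMS", session_index = 1,
                               age = seq_len(40), image_type = "pre",
                               method = "DL"))
  band <- subsampleBand(res, reps = 20, tauGrid = c(0.1, 0.5, 0.9), seed = 2)
  expect_equal(band$band_sd, rep(0, 3))
  st <- smallStudy(seed = 60, nPPMS = 0, nRRMS = 10)
  resDL <- residualizeAge(st$obs, "DL", "pre")
  b1 <- subsampleBand(resDL, reps = 15, tauGrid = c(0.3, 0.5), seed = 9)
  b2 <- subsampleBand(resDL, reps = 15, tauGrid = c(0.3, 0.5), seed = 9)
  expect_identical(b1, b2)
})

test_that("bands shrink as the image count grows at fixed fraction", {
  bandAt <- function(nSub, seed) {
    st <- smallStudy(seed = seed, nPPMS = 0, nRRMS = nSub)
    res <- residualizeAge(st$obs, "DL", "pre")
    mean(subsampleBand(res, reps = 30, tauGrid = c(0.2, 0.3, 0.4),
                       seed = 3)$band_sd)
  }
  expect_gt(bandAt(8, 70), bandAt(60, 70))
})

test_that("group contrast flags PPMS > RRMS under the default covariance model", {
  st <- smallStudy(seed = 80, nPPMS = 9, nRRMS = 66)
  gc <- groupContrast(st$obs, methods = "DL")
  cmp <- attr(gc, "comparison")
  expect_equal(nrow(gc), 4)  # 2 image types x 2 groups
  expect_true(all(cmp$ppms_gt_rrms))
})

test_that("identical group distributions give similar efficiencies", {
  # same loading scale for both groups: no built-in group difference
  cfg <- CohortConfig(nPPMS = 30, nRRMS = 30,
                      loadingScale = c(PPMS = 0.2, RRMS = 0.2),
                      slopeMean = c(PPMS = -0.003, RRMS = -0.003),
                      seed = 90)
  truth <- generateTrueCohort(cfg)
  obs <- simulateMeasurements(
    truth, list(MeasurementModel("DL", "pre", noiseSD = 0.236)), seed = 1)
  gc <- groupContrast(obs, methods = "DL", imageTypes = "pre", reps = 25,
                      seed = 4)
  diff <- abs(gc$e_glob[gc$group == "PPMS"] - gc$e_glob[gc$group == "RRMS"])
  bands <- sum(gc$band_sd)
  expect_lt(diff, 4 * max(bands, 0.02))
})

test_that("pooled and per-group residualization both produce full output", {
  st <- smallStudy(seed = 95, nPPMS = 5, nRRMS = 12)
  for (mode in c("per-group", "pooled")) {
    gc <- groupContrast(st$obs, methods = c("DL", "FS"),
                        residualize = mode)
    expect_equal(nrow(gc), 8)  # 2 methods x 2 image types x 2 groups
    expect_true(all(gc$e_glob >= 0 & gc$e_glob <= 1))
  }
})

test_that("missing group is an error for the group contrast", {
  st <- smallStudy(seed = 97, nPPMS = 0, nRRMS = 6)
  expect_error(groupContrast(st$obs), "both groups")
})
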