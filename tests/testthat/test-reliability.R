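test_that("pearsonPaired handles exact linearity and degenerate input", {
  expect_equal(pearsonPaired(c(1, 2, 3), c(2, 4, 6)), 1.0)
  expect_error(pearsonPaired(c(1, 2, 3), c(5, 5, 5)), "zero variance")
  expect_error(pearsonPaired(c(1, 2), c(3, 4)), "at least 3")
})

test_that("pearson is symmetric and affine-invariant; ICC(C,2) is not scale-invariant", {
  withr::local_seed(21)
  x <- rnorm(200, 2.5, 0.1)
  y <- x + rnorm(200, 0, 0.05)
  expect_equal(pearsonPaired(x, y), pearsonPaired(y, x))
  expect_equal(pearsonPaired(2 + 3 * x, y), pearsonPaired(x, y))
  expect_equal(iccConsistency(x + 5, y + 5), iccConsistency(x, y))
  expect_false(isTRUE(all.equal(iccConsistency(3 * x, y),
                                iccConsistency(x, y))))
})

test_that("consistency ICC ignores a constant rater offset and is 1 for identity", {
  withr::local_seed(4)
  x <- rnorm(50, 2.5, 0.1)
  expect_equal(iccConsistency(x, x), 1.0)
  expect_equal(iccConsistency(x, x + 0.17), 1.0)
  # absolute agreement is penalized by the same offset
  expect_lt(iccAgreement(x, x + 0.17), 1.0)
  expect_equal(iccAgreement(x, x), 1.0)
})

test_that("ANOVA ICC(C,2) matches stats::aov mean squares on small data", {
  withr::local_seed(12)
  n <- 20
  x <- rnorm(n, 2.5, 0.1)
  y <- x + rnorm(n, 0, 0.05)
  long <- data.frame(value = c(x, y),
                     subject = factor(rep(seq_len(n), 2)),
                     rater = factor(rep(c("a", "b"), each = n)))
  ms <- anova(aov(value ~ subject + rater, data = long))[["Mean Sq"]]
  expected <- (ms[1] - ms[3]) / ms[1]
  expect_equal(iccConsistency(x, y), expected, tolerance = 1e-12)
})

test_that("ICC(C,2) agrees with the Spearman-Brown closed form 2r/(1+r)", {
  p <- simulateAttenuationPairs(10000, noiseSD = 0.0295, seed = 6)
  r <- pearsonPaired(p$x, p$y)
  expect_equal(iccConsistency(p$x, p$y), 2 * r / (1 + r), tolerance = 0.005)
})

test_that("attenuation is monotone: larger noise gives smaller correlation", {
  rs <- vapply(c(0.01, 0.03, 0.06, 0.12), function(sd) {
    mean(vapply(1:20, function(s) {
      p <- simulateAttenuationPairs(2000, noiseSD = sd,
                                    seed = splitSeed(42, s, round(sd * 1e4)))
      pearsonPaired(p$x, p$y)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(rs) < 0))
})

test_that("Bland-Altman bias and limits behave on constant and identical differences", {
  ba <- blandAltman(c(2.0, 2.4, 2.8), c(2.2, 2.6, 3.0))
  expect_equal(ba$bias, 0.2)
  expect_equal(ba$loa, c(0.2, 0.2))
  x <- c(2.1, 2.5, 2.9)
  ba0 <- blandAltman(x, x)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa, c(0, 0))
  # bias is exactly the difference of means, LoA midpoint is the bias
  withr::local_seed(3)
  a <- rnorm(50, 2.5, 0.1); b <- a + rnorm(50, 0.17, 0.05)
  bab <- blandAltman(a, b)
  expect_equal(bab$bias, mean(b) - mean(a), tolerance = 1e-12)
  expect_equal(mean(bab$loa), bab$bias, tolerance = 1e-12)
})

test_that("subject-wise correlations are 1 for identical or offset region vectors", {
  truth <- generateTrueCohort(CohortConfig(nPPMS = 1, nRRMS = 2, seed = 2))
  obs <- simulateMeasurements(truth, list(
    MeasurementModel("DL", "pre", noiseSD = 0),
    MeasurementModel("DL", "CE", noiseSD = 0, biasMean = 0.06, biasSD = 0)
  ), seed = 1)
  sw <- subjectWiseCorrelations(obs, "DL")
  expect_true(all(sw$r > 1 - 1e-12))
  expect_true(all(sw$n_roi == 64))
})

test_that("lower-noise method has higher median subject-wise correlation", {
  st <- smallStudy(seed = 14, nPPMS = 3, nRRMS = 10)
  swDL <- subjectWiseCorrelations(st$obs, "DL")
  swFS <- subjectWiseCorrelations(st$obs, "FS")
  expect_gt(median(swDL$r), median(swFS$r))
})

test_that("sessions with too few common regions are skipped with a warning", {
  d <- morphData(smallStudy(seed = 5, nPPMS = 1, nRRMS = 2)$obs)
  d <- d[d$method == "DL", ]
  # cripple one session's CE side down to 2 regions
  drop <- d$subject_id == "sub001" & d$session_index == 1 &
    d$image_type == "CE" & !d$roi %in% d$roi[1:2]
  expect_warning(sw <- subjectWiseCorrelations(MorphTable(d[!drop, ]), "DL"),
                 "skipped")
  expect_false(any(sw$subject_id == "sub001" & sw$session_index == 1))
})

test_that("pairImages drops failure-affected sessions and counts them", {
  truth <- generateTrueCohort(CohortConfig(nPPMS = 3, nRRMS = 20, seed = 8))
  obs <- simulateMeasurements(truth, list(
    MeasurementModel("FS", "pre", noiseSD = 0.1),
    MeasurementModel("FS", "CE", noiseSD = 0.1, biasMean = 0.17,
                     failureRate = 0.2)
  ), seed = 3)
  p <- pairImages(obs, "FS")
  d <- morphData(obs)
  nPre <- nrow(unique(d[d$image_type == "pre",
                        c("subject_id", "session_index")]))
  expect_lt(nrow(p), nPre)
  expect_equal(attr(p, "n_dropped"), nPre - nrow(p))
})

test_that("identical-params subset filters sessions by the flag", {
  st <- smallStudy(seed = 10)
  all <- pairImages(st$obs, "DL", subset = "all")
  sub <- pairImages(st$obs, "DL", subset = "identical-params")
  expect_lt(nrow(sub), nrow(all))
  flags <- unique(morphData(st$obs)[, c("subject_id", "session_index",
                                        "identical_params")])
  mg <- merge(sub, flags, by = c("subject_id", "session_index"))
  expect_true(all(mg$identical_params))
})

test_that("comparing a series with itself gives zero difference and p near 1", {
  p <- simulateAttenuationPairs(200, noiseSD = 0.03, seed = 4)
  cmp <- compareDependentCorrelations(p, p, nBoot = 500, seed = 1)
  expect_equal(cmp$delta_r, 0)
  expect_gt(cmp$p_value, 0.99)
  st <- compareDependentCorrelations(p, p, method = "steiger")
  expect_equal(st$statistic, 0)
  expect_equal(st$p_value, 1)
})

test_that("bootstrap comparison is seeded-deterministic and detects a real gap", {
  withr::local_seed(77)
  n <- 454
  latent <- rnorm(n, 2.5, 0.10)
  mk <- function(sd) data.frame(label = sprintf("s%03d", 1:n),
                                x = latent + rnorm(n, 0, sd),
                                y = latent + rnorm(n, 0, sd))
  a <- mk(0.0295)
  b <- mk(0.0577)
  c1 <- compareDependentCorrelations(a, b, nBoot = 1000, seed = 5)
  c2 <- compareDependentCorrelations(a, b, nBoot = 1000, seed = 5)
  expect_identical(c1, c2)
  expect_gt(c1$delta_r, 0)
  expect_lt(c1$p_value, 0.05)
  expect_lt(compareDependentCorrelations(a, b, method = "steiger")$p_value,
            0.05)
})

test_that("mismatched series labels raise an alignment error", {
  p <- simulateAttenuationPairs(50, noiseSD = 0.03, seed = 4)
  q <- p
  q$label <- paste0("other", seq_len(nrow(q)))
  expect_error(compareDependentCorrelations(p, q), "alignment")
})

test_that("reliability report covers every method and subset with valid stats", {
  st <- smallStudy(seed = 20, nPPMS = 3, nRRMS = 12)
  rep <- reliabilityReport(st$obs)
  expect_setequal(rep$method, c("DL", "FS"))
  expect_setequal(rep$subset, c("all", "identical-params"))
  expect_true(all(rep$pearson_r >= -1 & rep$pearson_r <= 1))
  expect_true(all(rep$icc_c2 <= 1))
  expect_true(all(rep$ba_loa_low <= rep$ba_loa_high))
  # DL (lower noise) beats FS on the same truth
  expect_gt(rep$pearson_r[rep$method == "DL" & rep$subset == "all"],
            rep$pearson_r[rep$method == "FS" & rep$subset == "all"])
})
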