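#' Generate the noise-free ("true") longitudinal cohort
#'
#' Draws a synthetic longitudinal cortical-thickness cohort from the model
#' \deqn{T_{ijr} = \mu_r + b_i + \beta_i (a_{ij} - a_{i0}) +
#'   \lambda_g \sum_f L_{if} w_{rf} + u_{ir}}
#' where \eqn{\mu_r} is the region mean, \eqn{b_i \sim N(0,\sigma_s^2)} a
#' global subject offset, \eqn{\beta_i} the subject's annual atrophy slope
#' drawn from its group's slope distribution, \eqn{L_{if}} standard-normal
#' latent factor scores with fixed non-negative region weights \eqn{w_{rf}}
#' (inducing cross-region covariance, stronger in the group with the larger
#' loading scale \eqn{\lambda_g}), and \eqn{u_{ir} \sim N(0,\sigma_u^2)} a
#' subject-by-region offset. Visit ages start uniformly in the configured
#' baseline range and advance by jittered group-specific intervals.
#'
#' Each subject draws from its own seeded substream (see
#' \code{\link{splitSeed}}), so the table is deterministic given the
#' configuration and enlarging the cohort never perturbs existing subjects.
#' Rows carry \code{method = "TRUE"} and \code{image_type = "pre"}; a
#' per-session logical \code{identical_params} marks the
#' identical-acquisition-parameter subset.
#'
#' @param config a \linkS4class{CohortConfig}.
#' @return A \linkS4class{MorphTable} of noise-free thickness values.
#' @examples
#' tab <- generateTrueCohort(CohortConfig(nPPMS = 2, nRRMS = 3))
#' nSubjects(tab)
#' @export
generateTrueCohort <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  rois <- config@roiNames
  nroi <- length(rois)
  mu <- config@muROI[rois]
  nsub <- config@nPPMS + config@nRRMS
  groups <- rep(c("PPMS", "RRMS"), c(config@nPPMS, config@nRRMS))

  # fixed region weights, shared by all subjects and both groups
  W <- withSeed(splitSeed(config@seed, 0, 0), {
    if (config@nFactors > 0)
      matrix(abs(stats::rnorm(nroi * config@nFactors)) /
               sqrt(config@nFactors), nroi, config@nFactors)
    else
      matrix(0, nroi, 0)
  })

  parts <- vector("list", nsub)
  for (i in seq_len(nsub)) {
    g <- groups[i]
    parts[[i]] <- withSeed(splitSeed(config@seed, 1, i), {
      nS <- 3L + stats::rpois(1L, max(config@sessionMean[[g]] - 3, 0))
      age0 <- stats::runif(1, config@baselineAgeRange[1],
                           config@baselineAgeRange[2])
      gaps <- config@sessionInterval[[g]] * stats::runif(nS - 1, 0.8, 1.2)
      ages <- age0 + cumsum(c(0, pmax(gaps, 1e-6)))
      b <- stats::rnorm(1, 0, config@sigmaSubject)
      beta <- stats::rnorm(1, config@slopeMean[[g]], config@slopeSD[[g]])
      L <- stats::rnorm(config@nFactors)
      u <- stats::rnorm(nroi, 0, config@sigmaROI)
      idp <- stats::runif(nS) < config@identicalParamsRate
      fac <- if (config@nFactors > 0)
        config@loadingScale[[g]] * drop(W %*% L) else numeric(nroi)
      # sessions x regions
      thick <- outer(beta * (ages - age0), rep(1, nroi)) +
        matrix(mu + b + fac + u, nS, nroi, byrow = TRUE)
      list(
        subject_id = rep(sprintf("sub%03d", i), nS * nroi),
        group = rep(g, nS * nroi),
        session_index = rep(seq_len(nS), each = nroi),
        age = rep(ages, each = nroi),
        roi = rep(rois, nS),
        thickness_mm = as.vector(t(thick)),
        identical_params = rep(idp, each = nroi)
      )
    })
  }
  d <- data.frame(
    subject_id = unlist(lapply(parts, `[[`, "subject_id")),
    group = unlist(lapply(parts, `[[`, "group")),
    session_index = unlist(lapply(parts, `[[`, "session_index")),
    age = unlist(lapply(parts, `[[`, "age")),
    image_type = "pre",
    method = "TRUE",
    roi = unlist(lapply(parts, `[[`, "roi")),
    thickness_mm = pmax(unlist(lapply(parts, `[[`, "thickness_mm")), 1e-3),
    identical_params = unlist(lapply(parts, `[[`, "identical_params")),
    stringsAsFactors = FALSE
  )
  MorphTable(d)
}

#' Simulate measurements of a true cohort under one or more models
#'
#' For each measurement model, observed thickness is
#' \eqn{Y = T + \delta_i [\mathrm{CE}] + \varepsilon} with
#' \eqn{\varepsilon \sim N(0, \mathrm{noiseSD}^2)} independent per row and
#' \eqn{\delta_i \sim N(\mathrm{biasMean}, \mathrm{biasSD}^2)} drawn once per
#' subject and model (so agreement plots reflect between-subject bias
#' spread). For contrast-enhanced models, each session's rows are dropped
#' with probability \code{failureRate}, emulating processing failures.
#' Output concatenates all models' rows; randomness comes from per
#' (subject, model) substreams of \code{seed}.
#'
#' @param trueTable a noise-free \linkS4class{MorphTable} from
#'   \code{\link{generateTrueCohort}}.
#' @param models non-empty list of \linkS4class{MeasurementModel}s.
#' @param seed integer seed for the measurement randomness.
#' @return A \linkS4class{MorphTable} of observed measurements.
#' @examples
#' truth <- generateTrueCohort(CohortConfig(nPPMS = 1, nRRMS = 2))
#' obs <- simulateMeasurements(truth,
#'   list(MeasurementModel("DL", "pre", noiseSD = 0.1)), seed = 7)
#' @export
simulateMeasurements <- function(trueTable, models, seed = 1L) {
  stopifnot(is(trueTable, "MorphTable"), length(models) >= 1)
  for (m in models) {
    stopifnot(is(m, "MeasurementModel"))
    if (!m@imageType %in% c("pre", "CE"))
      stop("unknown image_type label: ", m@imageType)
  }
  d <- morphData(trueTable)
  subjects <- unique(d$subject_id)
  rowsBySubject <- split(seq_len(nrow(d)),
                         factor(d$subject_id, levels = subjects))
  out <- vector("list", length(models))
  for (j in seq_along(models)) {
    m <- models[[j]]
    md <- d
    md$image_type <- m@imageType
    md$method <- m@method
    keep <- rep(TRUE, nrow(md))
    for (i in seq_along(subjects)) {
      rows <- rowsBySubject[[i]]
      withSeed(splitSeed(seed, 2, i, j), {
        delta <- if (m@imageType == "CE")
          stats::rnorm(1, m@biasMean, m@biasSD) else 0
        eps <- stats::rnorm(length(rows), 0, m@noiseSD)
        md$thickness_mm[rows] <- md$thickness_mm[rows] + delta + eps
        if (m@imageType == "CE" && m@failureRate > 0) {
          sess <- unique(md$session_index[rows])
          failed <- sess[stats::runif(length(sess)) < m@failureRate]
          if (length(failed))
            keep[rows[md$session_index[rows] %in% failed]] <- FALSE
        }
      })
    }
    md <- md[keep, , drop = FALSE]
    md$thickness_mm <- pmax(md$thickness_mm, 1e-3)
    out[[j]] <- md
  }
  MorphTable(do.call(rbind, out))
}

#' Simulate paired noisy measurements of a latent quantity
#'
#' Calibration helper behind the test-retest attenuation experiments: draws
#' \code{n} latent values \eqn{T \sim N(\mu, \sigma_T^2)} and returns two
#' observed copies \eqn{x = T + \varepsilon_1}, \eqn{y = T + \varepsilon_2}
#' with independent \eqn{\varepsilon \sim N(0, \sigma_e^2)}. The population
#' correlation between the copies is
#' \eqn{\sigma_T^2 / (\sigma_T^2 + \sigma_e^2)}.
#'
#' @param n number of pairs.
#' @param noiseSD per-copy measurement noise SD (mm).
#' @param latentMean,latentSD latent distribution parameters (mm).
#' @param seed integer seed.
#' @return data.frame with columns \code{label}, \code{x}, \code{y}.
#' @examples
#' p <- simulateAttenuationPairs(454, noiseSD = 0.0295, seed = 1)
#' pearsonPaired(p$x, p$y)
#' @export
simulateAttenuationPairs <- function(n, noiseSD, latentMean = 2.5,
                                     latentSD = 0.10, seed = 1L) {
  stopifnot(n >= 3, noiseSD >= 0, latentSD >= 0)
  withSeed(seed, {
    latent <- stats::rnorm(n, latentMean, latentSD)
    data.frame(
      label = sprintf("pair%05d", seq_len(n)),
      x = latent + stats::rnorm(n, 0, noiseSD),
      y = latent + stats::rnorm(n, 0, noiseSD)
    )
  })
}
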