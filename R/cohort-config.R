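# Desikan-Killiany-style parcellation, 32 regions per hemisphere (64 total).
# Typical adult mean cortical thickness per region in mm, same values mirrored
# across hemispheres; magnitudes in the usual 1.6-3.3 mm range.
dkRegionMeans <- c(
  bankssts = 2.40, caudalanteriorcingulate = 2.60, caudalmiddlefrontal = 2.50,
  cuneus = 1.80, entorhinal = 3.30, fusiform = 2.70, inferiorparietal = 2.40,
  inferiortemporal = 2.70, isthmuscingulate = 2.40, lateraloccipital = 2.10,
  lateralorbitofrontal = 2.60, lingual = 1.90, medialorbitofrontal = 2.40,
  middletemporal = 2.80, parahippocampal = 2.70, paracentral = 2.40,
  parsopercularis = 2.50, parsorbitalis = 2.60, parstriangularis = 2.40,
  pericalcarine = 1.60, postcentral = 2.00, posteriorcingulate = 2.40,
  precentral = 2.50, precuneus = 2.30, rostralanteriorcingulate = 2.80,
  rostralmiddlefrontal = 2.30, superiorfrontal = 2.70, superiorparietal = 2.10,
  superiortemporal = 2.80, supramarginal = 2.50, transversetemporal = 2.30,
  insula = 3.00
)

#' Default 64-region cortical parcellation labels
#'
#' Desikan-Killiany-style gyral labels, 32 per hemisphere, prefixed
#' \code{lh_}/\code{rh_}.
#'
#' @return Character vector of 64 unique region labels.
#' @examples
#' length(defaultROINames())
#' @export
defaultROINames <- function() {
  c(paste0("lh_", names(dkRegionMeans)), paste0("rh_", names(dkRegionMeans)))
}

defaultMuROI <- function() {
  rois <- defaultROINames()
  stats::setNames(rep(unname(dkRegionMeans), 2), rois)
}

#' Construct a synthetic-cohort configuration
#'
#' All parameters of the longitudinal synthetic cohort; see
#' \linkS4class{CohortConfig} for the meaning and units of each. Defaults
#' emulate the evaluated MS study cohort: 9 PPMS and 66 RRMS patients,
#' roughly six sessions each at ~1-year (PPMS) and ~6-month (RRMS)
#' intervals, 64 Desikan-Killiany-style regions, annual thinning of
#' -0.012 mm/year (PPMS) and -0.003 mm/year (RRMS) with between-subject SD
#' 0.0296 mm/year, and a latent-factor model with stronger loadings in the
#' PPMS group so its structural covariance is higher.
#'
#' @param nPPMS,nRRMS group sizes.
#' @param sessionMean named numeric (PPMS, RRMS), mean sessions per subject;
#'   drawn as 3 + Poisson(mean - 3).
#' @param sessionInterval named numeric (PPMS, RRMS), mean inter-visit
#'   interval in years.
#' @param baselineAgeRange numeric length 2, years.
#' @param roiNames region labels (unique).
#' @param muROI named numeric, mean thickness per region (mm); must cover
#'   \code{roiNames}.
#' @param sigmaSubject between-subject SD of the global offset (mm).
#' @param sigmaROI SD of the subject-by-region idiosyncratic offset (mm).
#' @param slopeMean,slopeSD named numeric (PPMS, RRMS), slope distribution
#'   (mm/year).
#' @param nFactors latent covariance factors.
#' @param loadingScale named numeric (PPMS, RRMS), factor-loading magnitude.
#' @param identicalParamsRate fraction of sessions flagged as having
#'   identical acquisition parameters.
#' @param seed master seed.
#' @return A validated \linkS4class{CohortConfig}.
#' @examples
#' cfg <- CohortConfig(nPPMS = 2, nRRMS = 5)
#' cfg
#' @export
CohortConfig <- function(nPPMS = 9L,
                         nRRMS = 66L,
                         sessionMean = c(PPMS = 6, RRMS = 6),
                         sessionInterval = c(PPMS = 1.0, RRMS = 0.5),
                         baselineAgeRange = c(25, 60),
                         roiNames = defaultROINames(),
                         muROI = defaultMuROI(),
                         sigmaSubject = 0.10,
                         sigmaROI = 0.05,
                         slopeMean = c(PPMS = -0.012, RRMS = -0.003),
                         slopeSD = c(PPMS = 0.0296, RRMS = 0.0296),
                         nFactors = 3L,
                         loadingScale = c(PPMS = 0.30, RRMS = 0.20),
                         identicalParamsRate = 213 / 454,
                         seed = 1L) {
  new("CohortConfig",
      nPPMS = as.integer(nPPMS), nRRMS = as.integer(nRRMS),
      sessionMean = sessionMean, sessionInterval = sessionInterval,
      baselineAgeRange = as.numeric(baselineAgeRange),
      roiNames = roiNames, muROI = muROI,
      sigmaSubject = sigmaSubject, sigmaROI = sigmaROI,
      slopeMean = slopeMean, slopeSD = slopeSD,
      nFactors = as.integer(nFactors), loadingScale = loadingScale,
      identicalParamsRate = identicalParamsRate,
      seed = as.integer(seed))
}

#' Construct a measurement model
#'
#' @param method method label (e.g. "DL", "FS").
#' @param imageType "pre" or "CE".
#' @param noiseSD per-region measurement noise SD, mm.
#' @param biasMean mean systematic CE thickness offset, mm (0 for "pre").
#' @param biasSD between-subject SD of the offset, mm.
#' @param failureRate probability a CE session fails processing.
#' @return A validated \linkS4class{MeasurementModel}.
#' @examples
#' MeasurementModel("DL", "CE", noiseSD = 0.236, biasMean = 0.06,
#'                  biasSD = 0.02)
#' @export
MeasurementModel <- function(method, imageType,
                             noiseSD = 0, biasMean = 0, biasSD = 0,
                             failureRate = 0) {
  new("MeasurementModel", method = method, imageType = imageType,
      noiseSD = noiseSD, biasMean = biasMean, biasSD = biasSD,
      failureRate = failureRate)
}

#' Packaged study-default configuration and measurement models
#'
#' The cohort configuration and the four measurement models (deep-learning-
#' like and FreeSurfer-like, each on non-enhanced and contrast-enhanced
#' images) that define the packaged study conditions. Noise SDs are chosen
#' so that the 64-region global mean thickness carries a per-image
#' measurement noise SD of 0.0295 mm (DL-like) and 0.0577 mm (FS-like),
#' i.e. per-region SDs of 8 times those values; CE bias means are 0.06 mm
#' (DL-like) and 0.17 mm (FS-like); the FS-like CE model drops sessions at
#' rate 17/454 to emulate processing failures.
#'
#' @param seed master seed stored in the configuration.
#' @return List with elements \code{config} (a \linkS4class{CohortConfig})
#'   and \code{models} (list of four \linkS4class{MeasurementModel}s).
#' @examples
#' dsc <- defaultStudyConfig()
#' dsc$config
#' @export
defaultStudyConfig <- function(seed = 1L) {
  nroi <- length(defaultROINames())
  scale <- sqrt(nroi)  # per-region SD giving the target global-mean noise SD
  list(
    config = CohortConfig(seed = seed),
    models = list(
      MeasurementModel("DL", "pre", noiseSD = 0.0295 * scale),
      MeasurementModel("DL", "CE", noiseSD = 0.0295 * scale,
                       biasMean = 0.06, biasSD = 0.02),
      MeasurementModel("FS", "pre", noiseSD = 0.0577 * scale),
      MeasurementModel("FS", "CE", noiseSD = 0.0577 * scale,
                       biasMean = 0.17, biasSD = 0.05,
                       failureRate = 17 / 454)
    )
  )
}
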