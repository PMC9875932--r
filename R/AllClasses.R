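#' @import methods
NULL

#' CohortConfig: parameters of the synthetic longitudinal cohort
#'
#' Holds every parameter of the synthetic-cohort generator: group sizes
#' (primary-progressive and relapsing-remitting MS), visit schedules,
#' per-region mean cortical thickness, between-subject spread, group-specific
#' annual atrophy-slope distributions, and the latent-factor model that
#' induces cross-region covariance (the substrate of structural covariance
#' networks). Construct with \code{\link{CohortConfig}}.
#'
#' @slot nPPMS number of primary-progressive subjects.
#' @slot nRRMS number of relapsing-remitting subjects.
#' @slot sessionMean named numeric (PPMS, RRMS): mean number of imaging
#'   sessions per subject; counts are drawn as 3 + Poisson(mean - 3) so every
#'   subject has at least three time points available in expectation terms.
#' @slot sessionInterval named numeric (PPMS, RRMS): mean inter-visit
#'   interval in years.
#' @slot baselineAgeRange numeric length 2, years; baseline ages are uniform
#'   on this range.
#' @slot roiNames character vector of unique region labels.
#' @slot muROI named numeric, mean thickness per region in mm.
#' @slot sigmaSubject between-subject SD of the global thickness offset, mm.
#' @slot sigmaROI SD of the per-subject, per-region idiosyncratic offset, mm.
#' @slot slopeMean named numeric (PPMS, RRMS): mean annual atrophy slope,
#'   mm/year (negative = thinning).
#' @slot slopeSD named numeric (PPMS, RRMS): between-subject SD of the slope,
#'   mm/year.
#' @slot nFactors number of latent covariance factors.
#' @slot loadingScale named numeric (PPMS, RRMS): factor-loading magnitude
#'   (mm per unit factor score).
#' @slot identicalParamsRate fraction of sessions flagged as acquired with
#'   identical sequence parameters (the subset analysed separately).
#' @slot seed master seed for all generator randomness.
#' @name CohortConfig-class
#' @aliases CohortConfig-class
#' @exportClass CohortConfig
setClass("CohortConfig",
  slots = c(
    nPPMS = "integer",
    nRRMS = "integer",
    sessionMean = "numeric",
    sessionInterval = "numeric",
    baselineAgeRange = "numeric",
    roiNames = "character",
    muROI = "numeric",
    sigmaSubject = "numeric",
    sigmaROI = "numeric",
    slopeMean = "numeric",
    slopeSD = "numeric",
    nFactors = "integer",
    loadingScale = "numeric",
    identicalParamsRate = "numeric",
    seed = "integer"
  )
)

setValidity("CohortConfig", function(object) {
  grp <- c("PPMS", "RRMS")
  msgs <- character()
  add <- function(cond, m) if (!isTRUE(cond)) msgs <<- c(msgs, m)
  add(object@nPPMS >= 0L, "nPPMS: must be >= 0")
  add(object@nRRMS >= 0L, "nRRMS: must be >= 0")
  add(object@nPPMS + object@nRRMS >= 1L, "nPPMS + nRRMS: must be >= 1")
  for (s in c("sessionMean", "sessionInterval", "slopeMean", "slopeSD",
              "loadingScale")) {
    v <- slot(object, s)
    add(all(grp %in% names(v)), paste0(s, ": must be named with PPMS and RRMS"))
  }
  add(all(object@sessionMean >= 3), "sessionMean: must be >= 3")
  add(all(object@sessionInterval >= 0), "sessionInterval: must be >= 0")
  add(all(object@slopeSD >= 0), "slopeSD: must be >= 0")
  add(object@sigmaSubject >= 0, "sigmaSubject: must be >= 0")
  add(object@sigmaROI >= 0, "sigmaROI: must be >= 0")
  add(length(object@baselineAgeRange) == 2 &&
        diff(object@baselineAgeRange) >= 0,
      "baselineAgeRange: must be (low, high) with low <= high")
  add(!anyDuplicated(object@roiNames), "roiNames: labels must be unique")
  add(length(object@roiNames) >= 1, "roiNames: need at least one region")
  add(all(object@roiNames %in% names(object@muROI)),
      "muROI: must name every region in roiNames")
  add(all(object@muROI[object@roiNames] > 0), "muROI: must be > 0 for every ROI")
  add(object@nFactors >= 0L, "nFactors: must be >= 0")
  add(object@identicalParamsRate >= 0 && object@identicalParamsRate <= 1,
      "identicalParamsRate: must be in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' MeasurementModel: noise and bias of one method on one image type
#'
#' Describes how one morphometry method measures one image type: additive
#' Gaussian measurement noise per region, a systematic contrast-induced
#' thickness bias (contrast-enhanced images only) with between-subject
#' spread, and a per-session processing failure rate. Construct with
#' \code{\link{MeasurementModel}}.
#'
#' @slot method method label, e.g. "DL" or "FS".
#' @slot imageType "pre" (non-enhanced) or "CE" (contrast-enhanced).
#' @slot noiseSD SD of the per-region measurement noise, mm.
#' @slot biasMean mean systematic thickness offset on CE images, mm; must be
#'   0 for image type "pre".
#' @slot biasSD between-subject SD of the offset, mm.
#' @slot failureRate probability that a CE session fails processing and its
#'   rows are dropped.
#' @name MeasurementModel-class
#' @aliases MeasurementModel-class
#' @exportClass MeasurementModel
setClass("MeasurementModel",
  slots = c(
    method = "character",
    imageType = "character",
    noiseSD = "numeric",
    biasMean = "numeric",
    biasSD = "numeric",
    failureRate = "numeric"
  )
)

setValidity("MeasurementModel", function(object) {
  msgs <- character()
  if (!object@imageType %in% c("pre", "CE"))
    msgs <- c(msgs, "imageType must be 'pre' or 'CE'")
  if (object@noiseSD < 0) msgs <- c(msgs, "noiseSD must be >= 0")
  if (object@biasSD < 0) msgs <- c(msgs, "biasSD must be >= 0")
  if (object@failureRate < 0 || object@failureRate >= 1)
    msgs <- c(msgs, "failureRate must be in [0, 1)")
  if (object@imageType == "pre" && object@biasMean != 0)
    msgs <- c(msgs, "biasMean must be 0 for image type 'pre'")
  if (length(msgs)) msgs else TRUE
})

#' MorphTable: long-format morphometry measurements
#'
#' One row per (subject, session, image type, method, region) with the
#' subject's group, age at acquisition in years and cortical thickness in mm.
#' An optional logical column \code{identical_params} marks sessions acquired
#' with identical sequence parameters. Construct with \code{\link{MorphTable}}
#' or read from CSV with \code{\link{readMorphTable}}.
#'
#' @slot data data.frame with columns \code{subject_id}, \code{group},
#'   \code{session_index}, \code{age}, \code{image_type}, \code{method},
#'   \code{roi}, \code{thickness_mm} and optionally \code{identical_params}.
#' @name MorphTable-class
#' @aliases MorphTable-class
#' @exportClass MorphTable
setClass("MorphTable", slots = c(data = "data.frame"))

morphRequiredCols <- c("subject_id", "group", "session_index", "age",
                       "image_type", "method", "roi", "thickness_mm")

setValidity("MorphTable", function(object) {
  d <- object@data
  msgs <- character()
  missing <- setdiff(morphRequiredCols, names(d))
  if (length(missing))
    return(paste("missing columns:", paste(missing, collapse = ", ")))
  if (nrow(d) == 0) return("table has no rows")
  if (!is.numeric(d$age) || !is.numeric(d$thickness_mm))
    msgs <- c(msgs, "age and thickness_mm must be numeric")
  else {
    if (any(!is.finite(d$thickness_mm)) || any(d$thickness_mm <= 0))
      msgs <- c(msgs, "thickness_mm must be finite and > 0 on every row")
    # one age per (subject, session), strictly increasing with session_index
    key <- paste(d$subject_id, d$session_index, sep = "\r")
    if (any(tapply(d$age, key, function(a) max(a) - min(a)) > 0))
      msgs <- c(msgs, "a (subject, session) pair maps to more than one age")
    sess <- d[!duplicated(key), c("subject_id", "session_index", "age")]
    sess <- sess[order(sess$subject_id, sess$session_index), ]
    same <- sess$subject_id[-1] == sess$subject_id[-nrow(sess)]
    if (nrow(sess) > 1 && any(same & diff(sess$age) <= 0))
      msgs <- c(msgs, "ages must be strictly increasing with session_index within each subject")
  }
  if (!all(d$image_type %in% c("pre", "CE")))
    msgs <- c(msgs, "image_type must be 'pre' or 'CE'")
  if (length(msgs)) msgs else TRUE
})

#' ResidualMatrix: age-adjusted thickness residuals, image x region
#'
#' Thickness residuals after regressing each region's values on age over a
#' set of images (one image = one subject-session-imagetype-method
#' observation). The residuals feed the structural-covariance-network
#' correlation matrices. Produced by \code{\link{residualizeAge}}.
#'
#' @slot imageIds character, one id per image (row).
#' @slot roiNames character, one label per region (column).
#' @slot residuals numeric matrix, images x regions, mm.
#' @slot info data.frame with per-image subject_id, group, session_index,
#'   age, image_type, method.
#' @name ResidualMatrix-class
#' @aliases ResidualMatrix-class
#' @exportClass ResidualMatrix
setClass("ResidualMatrix",
  slots = c(
    imageIds = "character",
    roiNames = "character",
    residuals = "matrix",
    info = "data.frame"
  )
)

setValidity("ResidualMatrix", function(object) {
  msgs <- character()
  if (nrow(object@residuals) != length(object@imageIds))
    msgs <- c(msgs, "residuals rows must match imageIds")
  if (ncol(object@residuals) != length(object@roiNames))
    msgs <- c(msgs, "residuals columns must match roiNames")
  if (anyNA(object@residuals))
    msgs <- c(msgs, "residuals must have no missing entries")
  if (nrow(object@info) != length(object@imageIds))
    msgs <- c(msgs, "info rows must match imageIds")
  if (length(msgs)) msgs else TRUE
})

#' SCNGraph: thresholded structural covariance network
#'
#' Binary undirected graph over cortical regions: an edge joins two regions
#' when the correlation of their age-adjusted thickness residuals is at
#' least the threshold tau. Produced by \code{\link{thresholdGraph}}.
#'
#' @slot roiNames node labels.
#' @slot adjacency symmetric logical matrix with all-FALSE diagonal.
#' @slot threshold the correlation threshold tau in [0, 1].
#' @name SCNGraph-class
#' @aliases SCNGraph-class
#' @exportClass SCNGraph
setClass("SCNGraph",
  slots = c(
    roiNames = "character",
    adjacency = "matrix",
    threshold = "numeric"
  )
)

setValidity("SCNGraph", function(object) {
  A <- object@adjacency
  msgs <- character()
  if (!is.logical(A)) msgs <- c(msgs, "adjacency must be a logical matrix")
  if (nrow(A) != ncol(A)) msgs <- c(msgs, "adjacency must be square")
  if (nrow(A) != length(object@roiNames))
    msgs <- c(msgs, "adjacency dimension must match roiNames")
  if (is.logical(A) && nrow(A) == ncol(A)) {
    if (!identical(A, t(A))) msgs <- c(msgs, "adjacency must be symmetric")
    if (any(diag(A))) msgs <- c(msgs, "adjacency diagonal must be empty")
  }
  if (object@threshold < 0 || object@threshold > 1)
    msgs <- c(msgs, "threshold must be in [0, 1]")
  if (length(msgs)) msgs else TRUE
})
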