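#' Extract the measurement table
#'
#' @param x a \linkS4class{MorphTable}.
#' @return The underlying long-format data.frame.
#' @name morphData
#' @aliases morphData,MorphTable-method
#' @export
setMethod("morphData", "MorphTable", function(x) x@data)

#' Region labels
#'
#' @param x a \linkS4class{CohortConfig}, \linkS4class{MorphTable},
#'   \linkS4class{ResidualMatrix} or \linkS4class{SCNGraph}.
#' @return Character vector of region labels.
#' @name roiNames
#' @aliases roiNames,CohortConfig-method roiNames,MorphTable-method
#'   roiNames,ResidualMatrix-method roiNames,SCNGraph-method
#' @export
setMethod("roiNames", "CohortConfig", function(x) x@roiNames)

#' @rdname roiNames
#' @export
setMethod("roiNames", "MorphTable", function(x) sort(unique(x@data$roi)))

#' @rdname roiNames
#' @export
setMethod("roiNames", "ResidualMatrix", function(x) x@roiNames)

#' @rdname roiNames
#' @export
setMethod("roiNames", "SCNGraph", function(x) x@roiNames)

#' Number of distinct subjects
#'
#' @param x a \linkS4class{MorphTable}.
#' @return Integer count of distinct subject ids.
#' @name nSubjects
#' @aliases nSubjects,MorphTable-method
#' @export
setMethod("nSubjects", "MorphTable",
          function(x) length(unique(x@data$subject_id)))

#' Adjacency matrix of a structural covariance network
#'
#' @param x a \linkS4class{SCNGraph}.
#' @return Symmetric logical matrix; TRUE marks an edge.
#' @name adjacency
#' @aliases adjacency,SCNGraph-method
#' @export
setMethod("adjacency", "SCNGraph", function(x) x@adjacency)

#' Correlation threshold of a graph
#'
#' @param x a \linkS4class{SCNGraph}.
#' @return The threshold tau used to binarize the correlation matrix.
#' @name graphThreshold
#' @aliases graphThreshold,SCNGraph-method
#' @export
setMethod("graphThreshold", "SCNGraph", function(x) x@threshold)

#' Residual matrix values
#'
#' @param x a \linkS4class{ResidualMatrix}.
#' @return Numeric matrix of age-adjusted residuals, images x regions.
#' @name residualValues
#' @aliases residualValues,ResidualMatrix-method
#' @export
setMethod("residualValues", "ResidualMatrix", function(x) x@residuals)

#' Per-image metadata of a residual matrix
#'
#' @param x a \linkS4class{ResidualMatrix}.
#' @return data.frame with one row per image (subject, group, session, age,
#'   image type, method).
#' @name imageInfo
#' @aliases imageInfo,ResidualMatrix-method
#' @export
setMethod("imageInfo", "ResidualMatrix", function(x) x@info)

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig:", object@nPPMS, "PPMS +", object@nRRMS, "RRMS subjects\n")
  cat("  sessions: mean", object@sessionMean[["PPMS"]], "@",
      object@sessionInterval[["PPMS"]], "y (PPMS), mean",
      object@sessionMean[["RRMS"]], "@",
      object@sessionInterval[["RRMS"]], "y (RRMS)\n")
  cat("  regions:", length(object@roiNames),
      "| slope means (mm/y):", object@slopeMean[["PPMS"]], "(PPMS)",
      object@slopeMean[["RRMS"]], "(RRMS)\n")
  cat("  factors:", object@nFactors, "| seed:", object@seed, "\n")
})

setMethod("show", "MeasurementModel", function(object) {
  cat(sprintf("MeasurementModel %s/%s: noise SD %.4g mm, bias %.3g mm (SD %.3g), failure rate %.3g\n",
              object@method, object@imageType, object@noiseSD,
              object@biasMean, object@biasSD, object@failureRate))
})

setMethod("show", "MorphTable", function(object) {
  d <- object@data
  cat("MorphTable:", nrow(d), "rows,", length(unique(d$subject_id)),
      "subjects,", length(unique(d$roi)), "regions\n")
  cat("  methods:", paste(sort(unique(d$method)), collapse = ", "), "\n")
  cat("  image types:", paste(sort(unique(d$image_type)), collapse = ", "),
      "\n")
})

setMethod("show", "ResidualMatrix", function(object) {
  cat("ResidualMatrix:", nrow(object@residuals), "images x",
      ncol(object@residuals), "regions (age-adjusted thickness, mm)\n")
})

setMethod("show", "SCNGraph", function(object) {
  A <- object@adjacency
  cat(sprintf("SCNGraph: %d nodes, %d edges at threshold %.2f\n",
              nrow(A), sum(A) / 2, object@threshold))
})
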