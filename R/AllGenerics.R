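#' @rdname morphData
#' @export
setGeneric("morphData", function(x) standardGeneric("morphData"))

#' @rdname roiNames
#' @export
setGeneric("roiNames", function(x) standardGeneric("roiNames"))

#' @rdname nSubjects
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' @rdname adjacency
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @rdname graphThreshold
#' @export
setGeneric("graphThreshold", function(x) standardGeneric("graphThreshold"))

#' @rdname residualValues
#' @export
setGeneric("residualValues", function(x) standardGeneric("residualValues"))

#' @rdname imageInfo
#' @export
setGeneric("imageInfo", function(x) standardGeneric("imageInfo"))
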