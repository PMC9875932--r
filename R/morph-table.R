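#' Construct a MorphTable from a long-format data.frame
#'
#' @param data data.frame with columns \code{subject_id}, \code{group},
#'   \code{session_index}, \code{age}, \code{image_type}, \code{method},
#'   \code{roi}, \code{thickness_mm}, optionally \code{identical_params}.
#' @return A validated \linkS4class{MorphTable}.
#' @export
MorphTable <- function(data) {
  keep <- intersect(c(morphRequiredCols, "identical_params"), names(data))
  d <- as.data.frame(data)[, keep, drop = FALSE]
  for (col in c("subject_id", "group", "image_type", "method", "roi"))
    d[[col]] <- as.character(d[[col]])
  d$session_index <- as.integer(d$session_index)
  rownames(d) <- NULL
  new("MorphTable", data = d)
}

#' Write a measurement table to CSV
#'
#' UTF-8 comma-separated with header
#' \code{subject_id,group,session_index,age,image_type,method,roi,thickness_mm}
#' (plus \code{identical_params} when present). Numeric values are written
#' with 6 significant digits. Leading \code{#} comment lines record the
#' seed and configuration hash when supplied, so outputs are traceable.
#'
#' @param x a \linkS4class{MorphTable}.
#' @param path output file.
#' @param seed optional master seed to record in the header comment.
#' @param configHash optional configuration hash to record.
#' @return \code{path}, invisibly.
#' @export
writeMorphTable <- function(x, path, seed = NULL, configHash = NULL) {
  stopifnot(is(x, "MorphTable"))
  d <- morphData(x)
  d$age <- signif(d$age, 6)
  d$thickness_mm <- signif(d$thickness_mm, 6)
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(seed) || !is.null(configHash)) {
    tag <- c(if (!is.null(seed)) paste0("seed=", seed),
             if (!is.null(configHash)) paste0("config=", configHash))
    writeLines(paste("#", paste(tag, collapse = " ")), con)
  }
  utils::write.csv(d, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a measurement table from CSV
#'
#' Counterpart of \code{\link{writeMorphTable}}; \code{#} comment lines are
#' skipped and column types are fixed so that labels (including the literal
#' method label \code{"TRUE"} used for noise-free tables) are never coerced.
#'
#' @param path CSV file written by \code{\link{writeMorphTable}} or following
#'   the same layout.
#' @return A validated \linkS4class{MorphTable}.
#' @export
readMorphTable <- function(path) {
  classes <- c(subject_id = "character", group = "character",
               session_index = "integer", age = "numeric",
               image_type = "character", method = "character",
               roi = "character", thickness_mm = "numeric",
               identical_params = "logical")
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(morphRequiredCols, names(d))
  if (length(missing))
    stop("not a measurement table: missing columns ",
         paste(missing, collapse = ", "))
  for (col in names(d))
    if (col %in% names(classes))
      d[[col]] <- methods::as(d[[col]], classes[[col]])
  MorphTable(d)
}
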