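#' Read a FreeSurfer aparc surface-statistics file
#'
#' Parses the \code{?h.aparc.stats} format: \code{#}-prefixed headers, a
#' \code{# ColHeaders} line naming the whitespace-delimited body columns,
#' one row per cortical region. Per-region thickness comes from the
#' \code{ThickAvg} column keyed by \code{StructName}; parsing is driven by
#' the ColHeaders positions, so column order does not matter. The global
#' mean is taken from the \code{# Measure Cortex, MeanThickness} header line
#' when present (FreeSurfer's own area-weighted value), otherwise computed
#' as the \code{SurfArea}-weighted mean of the region values.
#'
#' @param path stats file.
#' @return List with \code{roi} (named numeric, mm), \code{global_mean}
#'   (mm) and \code{global_source} ("header" or "area-weighted").
#' @export
readAparcStats <- function(path) {
  lines <- readLines(path, warn = FALSE)
  chIdx <- grep("^#\\s*ColHeaders", lines)
  if (length(chIdx) == 0)
    stop("format error: no '# ColHeaders' line in ", path)
  chIdx <- chIdx[1]
  cols <- strsplit(sub("^#\\s*ColHeaders\\s+", "", lines[chIdx]),
                   "\\s+")[[1]]
  need <- function(col) {
    i <- match(col, cols)
    if (is.na(i))
      stop("format error: missing ", col, " column in ColHeaders (line ",
           chIdx, ")")
    i
  }
  iName <- need("StructName")
  iThick <- need("ThickAvg")
  bodyIdx <- which(!grepl("^\\s*(#|$)", lines))
  if (length(bodyIdx) == 0) stop("format error: no data rows in ", path)
  body <- utils::read.table(text = lines[bodyIdx], stringsAsFactors = FALSE)
  if (ncol(body) != length(cols))
    stop("format error: body has ", ncol(body), " columns but ColHeaders ",
         "names ", length(cols), " (line ", bodyIdx[1], ")")
  names(body) <- cols
  roi <- stats::setNames(as.numeric(body[[iThick]]),
                         as.character(body[[iName]]))
  mt <- grep("^#\\s*Measure Cortex,\\s*MeanThickness", lines, value = TRUE)
  if (length(mt)) {
    fields <- strsplit(mt[1], ",")[[1]]
    gm <- suppressWarnings(as.numeric(trimws(fields[4])))
    if (is.na(gm))
      stop("format error: unparsable MeanThickness header line")
    src <- "header"
  } else {
    iArea <- match("SurfArea", cols)
    if (is.na(iArea))
      stop("format error: no MeanThickness header and no SurfArea column ",
           "for the area-weighted fallback")
    gm <- stats::weighted.mean(roi, as.numeric(body[[iArea]]))
    src <- "area-weighted"
  }
  list(roi = roi, global_mean = gm, global_source = src)
}

#' Read a per-subject morphometry result CSV
#'
#' One-row CSV whose numeric columns are region thicknesses (the layout
#' emitted by DL-based per-subject result tables). Non-numeric metadata
#' columns are ignored with a notice; duplicate region columns are an
#' error; region names are preserved verbatim.
#'
#' @param path CSV file with a header row.
#' @return Named numeric vector of region thickness values.
#' @export
readDLDirectStats <- function(path) {
  d <- tryCatch(
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("format error reading ", path, ": ",
                             conditionMessage(e)))
  if (nrow(d) == 0 || ncol(d) == 0)
    stop("format error: no data rows in ", path)
  if (nrow(d) > 1)
    stop("expected a single result row, got ", nrow(d))
  dup <- names(d)[duplicated(names(d))]
  if (length(dup))
    stop("duplicate region columns: ", paste(unique(dup), collapse = ", "))
  numeric <- vapply(d, is.numeric, logical(1))
  if (any(!numeric))
    message("ignoring non-numeric columns: ",
            paste(names(d)[!numeric], collapse = ", "))
  if (!any(numeric)) stop("format error: no numeric region columns")
  vals <- unlist(d[1, numeric, drop = FALSE])
  stats::setNames(as.numeric(vals), names(d)[numeric])
}

#' Read a cohort configuration from a key-value file
#'
#' Plain-text \code{key = value} lines mirroring the
#' \code{\link{CohortConfig}} argument names. Scalar values are parsed by
#' type; comma-separated values become vectors; \code{PPMS:x, RRMS:y} pairs
#' become named vectors; \code{roiNames} and \code{muROI} accept
#' comma-separated lists (\code{name:value} pairs for \code{muROI}). Lines
#' starting with \code{#} are comments.
#'
#' @param path config file.
#' @return A validated \linkS4class{CohortConfig}.
#' @export
readCohortConfig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    items <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    if (all(grepl(":", items, fixed = TRUE))) {
      parts <- strsplit(items, ":", fixed = TRUE)
      nm <- trimws(vapply(parts, `[`, character(1), 1))
      vv <- trimws(vapply(parts, `[`, character(1), 2))
      num <- suppressWarnings(as.numeric(vv))
      args[[key]] <- stats::setNames(if (anyNA(num)) vv else num, nm)
    } else {
      num <- suppressWarnings(as.numeric(items))
      args[[key]] <- if (anyNA(num)) items else num
    }
  }
  known <- names(formals(CohortConfig))
  unknown <- setdiff(names(args), known)
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  do.call(CohortConfig, args)
}

configHash <- function(object) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(configAsList(object), tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

configAsList <- function(x) {
  if (is(x, "CohortConfig") || is(x, "MeasurementModel")) {
    out <- lapply(slotNames(x), function(s) slot(x, s))
    names(out) <- slotNames(x)
    out
  } else if (is.list(x)) {
    lapply(x, configAsList)
  } else x
}

writeCommentedCSV <- function(d, path, seed, hash, digits = 6) {
  num <- vapply(d, is.numeric, logical(1)) &
    !vapply(d, is.integer, logical(1))
  d[num] <- lapply(d[num], signif, digits = digits)
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# seed=", seed, " config=", hash), con)
  utils::write.csv(d, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full evaluation pipeline
#'
#' Executes simulate (or load) -> paired reliability -> atrophy rates ->
#' structural covariance networks, writing all artifacts to \code{outDir}:
#' \code{cohort.csv} (the measurement table), \code{reliability.csv} and
#' \code{reliability.json}, \code{rates.csv} (per-patient global rates),
#' \code{table1.csv} (group means and effect sizes), \code{regional_rates.csv},
#' \code{scn_curves.csv} (per group/method/image-type efficiency curves with
#' subsampling SD bands) and \code{manifest.json} (config echo, seed,
#' package version). Every CSV carries a \code{# seed=... config=...} header
#' comment; re-running with identical inputs is byte-identical.
#'
#' @param outDir output directory (created if needed).
#' @param seed master seed for simulation and subsampling.
#' @param mode \code{"simulate"} draws a synthetic cohort; \code{"load"}
#'   reads \code{inputPath}.
#' @param config a \linkS4class{CohortConfig} (simulate mode); default
#'   \code{defaultStudyConfig(seed)$config}.
#' @param models list of \linkS4class{MeasurementModel}s (simulate mode).
#' @param inputPath measurement-table CSV (load mode).
#' @param minTimepoints atrophy-rate time-point filter.
#' @param tauStar reference threshold reported in the group contrast.
#' @param tauStep threshold-grid step for the efficiency curves.
#' @param fraction,reps subsampling parameters for the SD bands.
#' @param residualize \code{"per-group"} or \code{"pooled"} age fit.
#' @param verbose log stage progress to stderr.
#' @return Invisibly, a named list of artifact paths.
#' @export
runPipeline <- function(outDir, seed = 1L, mode = c("simulate", "load"),
                        config = NULL, models = NULL, inputPath = NULL,
                        minTimepoints = 3, tauStar = 0.5, tauStep = 0.01,
                        fraction = 0.8, reps = 1000,
                        residualize = c("per-group", "pooled"),
                        verbose = TRUE) {
  mode <- match.arg(mode)
  residualize <- match.arg(residualize)
  say <- function(...) if (verbose) message("[cemorph] ", ...)
  stage <- function(name, expr) {
    say("stage: ", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  if (mode == "simulate") {
    if (is.null(config) || is.null(models)) {
      dsc <- defaultStudyConfig(seed = seed)
      if (is.null(config)) config <- dsc$config
      if (is.null(models)) models <- dsc$models
    }
    hash <- configHash(list(config = config, models = models))
    tab <- stage("simulate", {
      truth <- generateTrueCohort(config)
      simulateMeasurements(truth, models, seed = splitSeed(seed, 9))
    })
  } else {
    if (is.null(inputPath) || !file.exists(inputPath))
      stop("load mode requires an existing inputPath")
    hash <- unname(tools::md5sum(inputPath))
    tab <- stage("load", readMorphTable(inputPath))
  }
  paths$cohort <- file.path(outDir, "cohort.csv")
  writeMorphTable(tab, paths$cohort, seed = seed, configHash = hash)

  rel <- stage("reliability", reliabilityReport(tab))
  paths$reliability_csv <- writeCommentedCSV(
    rel, file.path(outDir, "reliability.csv"), seed, hash)
  paths$reliability_json <- file.path(outDir, "reliability.json")
  jsonlite::write_json(list(seed = seed, config = hash, results = rel),
                       paths$reliability_json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  rates <- stage("atrophy", computeAtrophyRates(
    tab, minTimepoints = minTimepoints, scope = "global"))
  paths$rates <- writeCommentedCSV(rates, file.path(outDir, "rates.csv"),
                                   seed, hash)
  ge <- stage("effects", groupEffectTable(rates))
  # flat layout: means block then effects block
  flat <- rbind(
    data.frame(block = "mean_slope", method = ge$means$method,
               a = ge$means$group, b = ge$means$image_type,
               value = ge$means$mean_slope, n = ge$means$n,
               stringsAsFactors = FALSE),
    data.frame(block = "cohens_d", method = ge$effects$method,
               a = ge$effects$contrast, b = ge$effects$stratum,
               value = ge$effects$cohens_d,
               n = ge$effects$n_a + ge$effects$n_b,
               stringsAsFactors = FALSE)
  )
  paths$table1 <- writeCommentedCSV(flat, file.path(outDir, "table1.csv"),
                                    seed, hash)
  regional <- stage("regional", regionalAtrophyMap(
    tab, minTimepoints = minTimepoints))
  paths$regional <- writeCommentedCSV(
    regional, file.path(outDir, "regional_rates.csv"), seed, hash)

  curves <- stage("scn", {
    d <- morphData(tab)
    methods <- setdiff(sort(unique(d$method)), "TRUE")
    itypes <- intersect(c("pre", "CE"), unique(d$image_type))
    grid <- seq(0, 0.99, by = tauStep)
    out <- list()
    for (m in methods) for (it in itypes) for (g in c("PPMS", "RRMS")) {
      if (!any(d$method == m & d$image_type == it & d$group == g)) next
      res <- if (residualize == "per-group")
        residualizeAge(tab, m, it, group = g)
      else {
        pooled <- residualizeAge(tab, m, it)
        keep <- imageInfo(pooled)$group == g
        new("ResidualMatrix", imageIds = pooled@imageIds[keep],
            roiNames = pooled@roiNames,
            residuals = residualValues(pooled)[keep, , drop = FALSE],
            info = imageInfo(pooled)[keep, , drop = FALSE])
      }
      band <- subsampleBand(res, fraction = fraction, reps = reps,
                            tauGrid = grid,
                            seed = splitSeed(seed, 7, match(m, methods),
                                             match(it, itypes),
                                             match(g, c("PPMS", "RRMS"))))
      band$group <- g
      band$method <- m
      band$image_type <- it
      out[[paste(m, it, g)]] <- band[, c("group", "method", "image_type",
                                         "tau", "e_glob", "band_sd")]
    }
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  })
  paths$scn_curves <- writeCommentedCSV(
    curves, file.path(outDir, "scn_curves.csv"), seed, hash)

  paths$manifest <- file.path(outDir, "manifest.json")
  manifest <- list(
    seed = seed, mode = mode, config_hash = hash,
    package = "cemorph",
    version = as.character(utils::packageVersion("cemorph")),
    parameters = list(min_timepoints = minTimepoints, tau_star = tauStar,
                      tau_step = tauStep, fraction = fraction, reps = reps,
                      residualize = residualize),
    config = if (mode == "simulate")
      configAsList(list(config = config, models = models)) else inputPath,
    artifacts = vapply(paths, basename, character(1))
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  say("done: ", length(paths), " artifacts in ", outDir)
  invisible(paths)
}
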