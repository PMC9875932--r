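#' Ordinary least-squares slope of thickness on age
#'
#' Fits the per-patient line thickness ~ age across all time points; the
#' slope is the annual atrophy rate in mm/year.
#'
#' @param ages visit ages in years, at least two distinct values.
#' @param values thickness measurements in mm, same length.
#' @return Named numeric: \code{slope} (mm/year) and \code{intercept} (mm,
#'   value at age 0).
#' @examples
#' fitPatientSlope(c(40, 41, 42), c(2.50, 2.49, 2.48))
#' @export
fitPatientSlope <- function(ages, values) {
  stopifnot(length(ages) == length(values), length(ages) >= 2)
  if (anyNA(ages) || anyNA(values)) stop("missing values are not allowed")
  ca <- ages - mean(ages)
  ssa <- sum(ca^2)
  if (ssa == 0) stop("degenerate design: all ages identical")
  slope <- sum(ca * (values - mean(values))) / ssa
  c(slope = slope, intercept = mean(values) - slope * mean(ages))
}

#' Per-patient annual atrophy rates
#'
#' For every (subject, method, image type) series -- and per region when
#' \code{scope} includes \code{"roi"} -- fits thickness on age across the
#' available time points and keeps subjects with at least
#' \code{minTimepoints} sessions in that series. Time points are counted per
#' series, so a subject whose contrast-enhanced sessions were lost to
#' processing failures can still contribute non-enhanced rates. The number
#' of excluded series is stored in the \code{n_excluded} attribute.
#'
#' @param table a \linkS4class{MorphTable}.
#' @param minTimepoints minimum sessions per series (default 3, inclusive).
#' @param scope \code{"global"} (mean over regions), \code{"roi"}
#'   (per-region), or \code{"both"}.
#' @return data.frame with columns \code{subject_id}, \code{group},
#'   \code{method}, \code{image_type}, \code{scope}, \code{slope} (mm/year),
#'   \code{intercept} (mm), \code{n_timepoints}.
#' @export
computeAtrophyRates <- function(table, minTimepoints = 3,
                                scope = c("global", "roi", "both")) {
  scope <- match.arg(scope)
  d <- morphData(table)
  if (nrow(d) == 0) stop("empty measurement table")

  excluded <- 0L
  # Vectorized per-series OLS: one slope per key, rowsum-based.
  collect <- function(key, subject, group, method, itype, scopeLab,
                      age, value) {
    f <- factor(key, levels = unique(key))
    i <- as.integer(f)
    n <- tabulate(i)
    meanA <- as.vector(rowsum(age, f, reorder = FALSE)) / n
    meanV <- as.vector(rowsum(value, f, reorder = FALSE)) / n
    ca <- age - meanA[i]
    cv <- value - meanV[i]
    ssa <- as.vector(rowsum(ca^2, f, reorder = FALSE))
    sav <- as.vector(rowsum(ca * cv, f, reorder = FALSE))
    keep <- n >= minTimepoints
    excluded <<- excluded + sum(!keep)
    if (any(keep & ssa == 0)) stop("degenerate design: all ages identical")
    first <- !duplicated(i)
    slope <- sav / ssa
    data.frame(
      subject_id = subject[first], group = group[first],
      method = method[first], image_type = itype[first],
      scope = scopeLab[first], slope = slope,
      intercept = meanV - slope * meanA, n_timepoints = n,
      stringsAsFactors = FALSE
    )[keep, , drop = FALSE]
  }

  out <- list()
  if (scope %in% c("global", "both")) {
    gm <- stats::aggregate(
      thickness_mm ~ subject_id + group + method + image_type +
        session_index + age, data = d, FUN = mean)
    out$global <- collect(
      paste(gm$subject_id, gm$method, gm$image_type, sep = "\r"),
      gm$subject_id, gm$group, gm$method, gm$image_type,
      rep("global", nrow(gm)), gm$age, gm$thickness_mm)
  }
  if (scope %in% c("roi", "both")) {
    out$roi <- collect(
      paste(d$subject_id, d$method, d$image_type, d$roi, sep = "\r"),
      d$subject_id, d$group, d$method, d$image_type, d$roi,
      d$age, d$thickness_mm)
  }
  res <- do.call(rbind, out)
  if (is.null(res) || nrow(res) == 0)
    stop("no series passed the ", minTimepoints, "-time-point filter")
  rownames(res) <- NULL
  attr(res, "n_excluded") <- excluded
  res
}

#' Cohen's d effect size
#'
#' Classic pooled-SD form:
#' \deqn{d = (\bar a - \bar b) / s_p, \quad
#'   s_p^2 = \frac{(n_a - 1) s_a^2 + (n_b - 1) s_b^2}{n_a + n_b - 2}.}
#' With \code{paired = TRUE}, the paired variant
#' \code{mean(a - b) / sd(a - b)} is used instead.
#'
#' @param a,b numeric samples, each of length >= 2 (equal lengths when
#'   paired).
#' @param paired use the paired variant.
#' @return Signed effect size; its sign matches \code{mean(a) - mean(b)}.
#' @examples
#' cohensD(c(1, 2, 3), c(2, 3, 4))
#' @export
cohensD <- function(a, b, paired = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (anyNA(a) || anyNA(b)) stop("missing values are not allowed")
  if (paired) {
    stopifnot(length(a) == length(b))
    s <- stats::sd(a - b)
    if (s == 0) stop("undefined effect size: zero SD of differences")
    return(mean(a - b) / s)
  }
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
    (na + nb - 2)
  if (sp2 == 0) stop("undefined effect size: zero pooled SD")
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Group-effect summary of atrophy rates
#'
#' Per method, the layout of the study's atrophy-rate table: mean slope per
#' group and image type, the PPMS-vs-RRMS effect size per image type, and
#' the pre-vs-CE effect size per group. Cells without subjects and contrasts
#' with zero pooled SD are reported as NA (absent), never as zero. The
#' pre-vs-CE contrast uses the unpaired pooled-SD form by default; set
#' \code{pairedImageTypes = TRUE} for the paired variant (computed on
#' subjects with both series).
#'
#' @param rates data.frame from \code{\link{computeAtrophyRates}} (global
#'   scope rows are used).
#' @param pairedImageTypes use the paired Cohen's d for the pre-vs-CE
#'   contrast.
#' @return List with \code{means} (method, group, image_type, mean_slope,
#'   n) and \code{effects} (method, contrast, stratum, mean_a, mean_b,
#'   n_a, n_b, cohens_d).
#' @export
groupEffectTable <- function(rates, pairedImageTypes = FALSE) {
  r <- rates[rates$scope == "global", , drop = FALSE]
  if (nrow(r) == 0) stop("no global-scope rates")
  groups <- c("PPMS", "RRMS")
  itypes <- intersect(c("pre", "CE"), unique(r$image_type))
  methods <- sort(unique(r$method))

  safeD <- function(a, b, paired = FALSE) {
    if (length(a) < 2 || length(b) < 2) return(NA_real_)
    tryCatch(cohensD(a, b, paired = paired), error = function(e) NA_real_)
  }

  means <- list()
  effects <- list()
  for (m in methods) {
    rm <- r[r$method == m, ]
    for (g in groups) for (it in itypes) {
      s <- rm$slope[rm$group == g & rm$image_type == it]
      means[[paste(m, g, it)]] <- data.frame(
        method = m, group = g, image_type = it,
        mean_slope = if (length(s)) mean(s) else NA_real_,
        n = length(s), stringsAsFactors = FALSE)
    }
    for (it in itypes) {
      a <- rm$slope[rm$group == "PPMS" & rm$image_type == it]
      b <- rm$slope[rm$group == "RRMS" & rm$image_type == it]
      effects[[paste(m, "grp", it)]] <- data.frame(
        method = m, contrast = "PPMS-RRMS", stratum = it,
        mean_a = if (length(a)) mean(a) else NA_real_,
        mean_b = if (length(b)) mean(b) else NA_real_,
        n_a = length(a), n_b = length(b),
        cohens_d = safeD(a, b), stringsAsFactors = FALSE)
    }
    if (all(c("pre", "CE") %in% itypes)) {
      for (g in groups) {
        rg <- rm[rm$group == g, ]
        if (pairedImageTypes) {
          wide <- merge(rg[rg$image_type == "pre", c("subject_id", "slope")],
                        rg[rg$image_type == "CE", c("subject_id", "slope")],
                        by = "subject_id", suffixes = c("_pre", "_ce"))
          a <- wide$slope_pre; b <- wide$slope_ce
          dd <- if (nrow(wide) >= 2) safeD(a, b, paired = TRUE) else NA_real_
        } else {
          a <- rg$slope[rg$image_type == "pre"]
          b <- rg$slope[rg$image_type == "CE"]
          dd <- safeD(a, b)
        }
        effects[[paste(m, "it", g)]] <- data.frame(
          method = m, contrast = "pre-CE", stratum = g,
          mean_a = if (length(a)) mean(a) else NA_real_,
          mean_b = if (length(b)) mean(b) else NA_real_,
          n_a = length(a), n_b = length(b),
          cohens_d = dd, stringsAsFactors = FALSE)
      }
    }
  }
  list(means = do.call(rbind, c(means, list(make.row.names = FALSE))),
       effects = do.call(rbind, c(effects, list(make.row.names = FALSE))))
}

#' Regional mean atrophy rates
#'
#' Mean per-region slope across subjects passing the time-point filter, for
#' every (method, image type, group, region) cell; the tabular counterpart
#' of a regional atrophy-rate map.
#'
#' @param table a \linkS4class{MorphTable}.
#' @param minTimepoints minimum sessions per series.
#' @return data.frame with \code{method}, \code{image_type}, \code{group},
#'   \code{roi}, \code{mean_slope} (mm/year), \code{n_subjects}.
#' @export
regionalAtrophyMap <- function(table, minTimepoints = 3) {
  rates <- computeAtrophyRates(table, minTimepoints = minTimepoints,
                               scope = "roi")
  agg <- stats::aggregate(slope ~ method + image_type + group + scope,
                          data = rates, FUN = mean)
  n <- stats::aggregate(slope ~ method + image_type + group + scope,
                        data = rates, FUN = length)
  names(agg)[names(agg) == "slope"] <- "mean_slope"
  names(agg)[names(agg) == "scope"] <- "roi"
  agg$n_subjects <- n$slope
  agg <- agg[order(agg$method, agg$image_type, agg$group, agg$roi), ]
  rownames(agg) <- NULL
  agg
}
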