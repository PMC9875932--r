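#' Pearson correlation between paired measurements
#'
#' Sample product-moment correlation between the two sides of a paired
#' series (e.g. non-enhanced vs contrast-enhanced global mean thickness).
#' Degenerate input is an error, never a silent 0 or 1.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Correlation coefficient in [-1, 1].
#' @examples
#' pearsonPaired(c(1, 2, 3), c(2, 4, 6))
#' @export
pearsonPaired <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 pairs")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("undefined correlation: zero variance on one side")
  stats::cor(x, y)
}

# Balanced two-way ANOVA mean squares for an n x k ratings matrix:
# rows = subjects, columns = raters/image types, one observation per cell.
twoWayMeanSquares <- function(Y) {
  n <- nrow(Y)
  k <- ncol(Y)
  m <- mean(Y)
  ssSub <- k * sum((rowMeans(Y) - m)^2)
  ssRat <- n * sum((colMeans(Y) - m)^2)
  ssTot <- sum((Y - m)^2)
  ssErr <- ssTot - ssSub - ssRat
  list(
    msSub = ssSub / (n - 1),
    msRat = ssRat / (k - 1),
    msErr = ssErr / ((n - 1) * (k - 1)),
    n = n, k = k
  )
}

ratingsMatrix <- function(x, y) {
  if (is.matrix(x)) {
    stopifnot(is.null(y), ncol(x) >= 2)
    Y <- x
  } else {
    stopifnot(length(x) == length(y))
    Y <- cbind(x, y)
  }
  if (anyNA(Y)) stop("missing values are not allowed")
  if (nrow(Y) < 3) stop("need at least 3 subjects")
  Y
}

#' Consistency intraclass correlation for the mean of k ratings
#'
#' ICC(C,k) from the two-way mixed-effects ANOVA decomposition with subjects
#' as rows and raters (here: the two image types) as columns:
#' \deqn{ICC(C,k) = (MS_{BS} - MS_E) / MS_{BS}}
#' where \eqn{MS_{BS}} is the between-subjects mean square and \eqn{MS_E}
#' the residual mean square after removing the rater effect. With k = 2 and
#' equal variances this equals the Spearman-Brown step-up of the Pearson
#' correlation, \eqn{2r/(1+r)}. Consistency ICC ignores fixed rater offsets,
#' so a constant contrast-induced bias does not lower it.
#'
#' @param x numeric vector (first rating) or an n x k ratings matrix.
#' @param y numeric vector (second rating) when \code{x} is a vector.
#' @return ICC(C,k), at most 1.
#' @examples
#' p <- simulateAttenuationPairs(454, noiseSD = 0.0295, seed = 1)
#' iccConsistency(p$x, p$y)
#' @export
iccConsistency <- function(x, y = NULL) {
  ms <- twoWayMeanSquares(ratingsMatrix(x, y))
  if (ms$msSub == 0)
    stop("undefined ICC: between-subjects mean square is zero")
  (ms$msSub - ms$msErr) / ms$msSub
}

#' Absolute-agreement intraclass correlation for the mean of k ratings
#'
#' ICC(A,k) from the same two-way ANOVA decomposition; unlike the
#' consistency form it penalizes fixed rater offsets:
#' \deqn{ICC(A,k) = (MS_{BS} - MS_E) / (MS_{BS} + (MS_R - MS_E)/n).}
#' Provided for completeness; reports use the consistency form.
#'
#' @inheritParams iccConsistency
#' @return ICC(A,k), at most 1.
#' @export
iccAgreement <- function(x, y = NULL) {
  ms <- twoWayMeanSquares(ratingsMatrix(x, y))
  denom <- ms$msSub + (ms$msRat - ms$msErr) / ms$n
  if (denom == 0) stop("undefined ICC: zero denominator")
  (ms$msSub - ms$msErr) / denom
}

#' Bland-Altman bias and limits of agreement
#'
#' Bias is the mean difference \code{mean(y - x)}; the limits of agreement
#' are bias +/- 1.96 times the sample SD of the differences (denominator
#' n - 1).
#'
#' @param x,y paired measurements (x = reference, y = comparison), length
#'   >= 2.
#' @return List with \code{bias}, \code{loa} (low, high) and \code{sd} of
#'   the differences, all in the units of the input.
#' @examples
#' blandAltman(c(2.0, 2.4, 2.8), c(2.2, 2.6, 3.0))
#' @export
blandAltman <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2) stop("need at least 2 pairs")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  d <- y - x
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa = c(bias - 1.96 * s, bias + 1.96 * s), sd = s)
}

#' Extract paired pre/CE global-mean series from a measurement table
#'
#' Computes the per-image global mean thickness (unweighted mean over
#' regions), then inner-joins non-enhanced and contrast-enhanced values on
#' (subject, session) for one method. Sessions with a missing side (e.g.
#' simulated processing failures) are dropped; the number dropped is
#' reported in the \code{n_dropped} attribute.
#'
#' @param table a \linkS4class{MorphTable}.
#' @param method method label to extract.
#' @param subset \code{"all"} or \code{"identical-params"} (keeps only
#'   sessions flagged \code{identical_params}).
#' @return data.frame with columns \code{label}, \code{subject_id},
#'   \code{session_index}, \code{x} (pre) and \code{y} (CE), in mm.
#' @export
pairImages <- function(table, method, subset = c("all", "identical-params")) {
  subset <- match.arg(subset)
  d <- morphData(table)
  d <- d[d$method == method, , drop = FALSE]
  if (nrow(d) == 0) stop("no rows for method '", method, "'")
  if (subset == "identical-params") {
    if (is.null(d$identical_params))
      stop("table has no identical_params column")
    d <- d[d$identical_params, , drop = FALSE]
  }
  gm <- stats::aggregate(
    thickness_mm ~ subject_id + session_index + image_type, data = d,
    FUN = mean)
  pre <- gm[gm$image_type == "pre", ]
  ce <- gm[gm$image_type == "CE", ]
  mg <- merge(pre[, c("subject_id", "session_index", "thickness_mm")],
              ce[, c("subject_id", "session_index", "thickness_mm")],
              by = c("subject_id", "session_index"),
              suffixes = c("_pre", "_ce"))
  mg <- mg[order(mg$subject_id, mg$session_index), ]
  out <- data.frame(
    label = paste(mg$subject_id, mg$session_index, sep = ":"),
    subject_id = mg$subject_id,
    session_index = mg$session_index,
    x = mg$thickness_mm_pre,
    y = mg$thickness_mm_ce,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_dropped") <- nrow(pre) + nrow(ce) - 2L * nrow(out)
  out
}

#' Subject-wise cross-region correlations between image types
#'
#' For each (subject, session) with both image types under one method, the
#' Pearson correlation between the two region-wise thickness vectors.
#' Sessions with fewer than 3 common regions are skipped with a warning.
#'
#' @param table a \linkS4class{MorphTable}.
#' @param method method label.
#' @return data.frame with \code{subject_id}, \code{session_index},
#'   \code{n_roi}, \code{r}.
#' @export
subjectWiseCorrelations <- function(table, method) {
  d <- morphData(table)
  d <- d[d$method == method, , drop = FALSE]
  if (nrow(d) == 0) stop("no rows for method '", method, "'")
  pre <- d[d$image_type == "pre", ]
  ce <- d[d$image_type == "CE", ]
  mg <- merge(pre[, c("subject_id", "session_index", "roi", "thickness_mm")],
              ce[, c("subject_id", "session_index", "roi", "thickness_mm")],
              by = c("subject_id", "session_index", "roi"),
              suffixes = c("_pre", "_ce"))
  if (nrow(mg) == 0) stop("no paired sessions for method '", method, "'")
  keyed <- split(mg, paste(mg$subject_id, mg$session_index, sep = "\r"))
  skipped <- 0L
  rows <- lapply(keyed, function(s) {
    if (nrow(s) < 3) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    data.frame(subject_id = s$subject_id[1],
               session_index = s$session_index[1],
               n_roi = nrow(s),
               r = stats::cor(s$thickness_mm_pre, s$thickness_mm_ce),
               stringsAsFactors = FALSE)
  })
  if (skipped > 0)
    warning(skipped, " session(s) skipped: fewer than 3 common regions")
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no session had 3 or more common regions")
  out <- out[order(out$subject_id, out$session_index), ]
  rownames(out) <- NULL
  out
}

# Steiger's (1980) test for two dependent, non-overlapping correlations
# r(x1,y1) vs r(x2,y2) measured on the same subjects, using the
# Pearson-Filon covariance with the pooled correlation plugged in.
steigerZ <- function(xa, ya, xb, yb) {
  n <- length(xa)
  r12 <- stats::cor(xa, ya)
  r34 <- stats::cor(xb, yb)
  r13 <- stats::cor(xa, xb); r14 <- stats::cor(xa, yb)
  r23 <- stats::cor(ya, xb); r24 <- stats::cor(ya, yb)
  psi <- ((r13 - r14 * r34) * (r24 - r23 * r34) +
          (r14 - r13 * r34) * (r23 - r24 * r34) +
          (r13 - r12 * r23) * (r24 - r12 * r14) +
          (r14 - r12 * r24) * (r23 - r12 * r13)) / 2
  rbar <- (r12 + r34) / 2
  cc <- psi / ((1 - rbar^2)^2)
  dz <- atanh(r12) - atanh(r34)
  denom <- 2 - 2 * cc
  z <- if (denom <= 0) {
    # perfectly dependent series (e.g. a series compared with itself)
    if (dz == 0) 0 else sign(dz) * Inf
  } else sqrt(n - 3) * dz / sqrt(denom)
  list(statistic = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Compare two dependent correlations measured on the same subjects
#'
#' Tests whether the pre/CE correlation of method A differs from that of
#' method B when both are computed on the same sessions. The default is a
#' subject-level bootstrap of the difference on the Fisher-z scale: sessions
#' are resampled with replacement, both correlations recomputed, and the
#' two-sided p-value taken from the sign distribution of the bootstrap
#' differences. Steiger's z test for dependent non-overlapping correlations
#' is available as a parametric cross-check.
#'
#' @param seriesA,seriesB data.frames as returned by \code{\link{pairImages}}
#'   (columns \code{label}, \code{x}, \code{y}), sharing the same labels.
#' @param nBoot bootstrap resamples.
#' @param seed integer seed for the bootstrap.
#' @param method \code{"bootstrap"} (default) or \code{"steiger"}.
#' @return List with \code{delta_r} (observed r_A - r_B), \code{delta_z}
#'   (Fisher-z scale), \code{p_value}, \code{method} and \code{n}.
#' @export
compareDependentCorrelations <- function(seriesA, seriesB, nBoot = 5000,
                                         seed = 1L,
                                         method = c("bootstrap", "steiger")) {
  method <- match.arg(method)
  common <- intersect(seriesA$label, seriesB$label)
  if (length(common) < 3)
    stop("alignment error: fewer than 3 shared labels between the series")
  if (length(common) < max(nrow(seriesA), nrow(seriesB)))
    message("aligning on ", length(common), " shared labels (",
            max(nrow(seriesA), nrow(seriesB)) - length(common), " unmatched)")
  a <- seriesA[match(common, seriesA$label), ]
  b <- seriesB[match(common, seriesB$label), ]
  ra <- pearsonPaired(a$x, a$y)
  rb <- pearsonPaired(b$x, b$y)
  out <- list(delta_r = ra - rb, delta_z = atanh(ra) - atanh(rb),
              method = method, n = length(common))
  if (method == "steiger") {
    st <- steigerZ(a$x, a$y, b$x, b$y)
    out$statistic <- st$statistic
    out$p_value <- st$p_value
    return(out)
  }
  n <- length(common)
  dz <- withSeed(splitSeed(seed, 4), {
    vapply(seq_len(nBoot), function(r) {
      idx <- sample.int(n, n, replace = TRUE)
      sa <- suppressWarnings(stats::cor(a$x[idx], a$y[idx]))
      sb <- suppressWarnings(stats::cor(b$x[idx], b$y[idx]))
      if (is.na(sa) || is.na(sb)) return(NA_real_)
      atanh(min(sa, 1 - 1e-12)) - atanh(min(sb, 1 - 1e-12))
    }, numeric(1))
  })
  dz <- dz[!is.na(dz)]
  out$p_value <- min(1, 2 * min(mean(dz <= 0), mean(dz >= 0)))
  out$n_boot <- length(dz)
  out
}

#' Paired-agreement report for every method in a table
#'
#' One row per method and pair subset with the sample size, Pearson r,
#' consistency ICC for the mean of two ratings, and Bland-Altman bias and
#' limits of agreement of the pre vs CE global mean thickness.
#'
#' @param table a \linkS4class{MorphTable} containing pre and CE rows.
#' @param methods method labels to report; default all methods with both
#'   image types (the noise-free \code{"TRUE"} label is excluded).
#' @param subsets pair subsets to report; \code{"identical-params"} rows are
#'   emitted only when the table carries the flag.
#' @return data.frame with columns \code{method}, \code{subset},
#'   \code{n_pairs}, \code{n_dropped}, \code{pearson_r}, \code{icc_c2},
#'   \code{ba_bias}, \code{ba_loa_low}, \code{ba_loa_high}.
#' @export
reliabilityReport <- function(table, methods = NULL,
                              subsets = c("all", "identical-params")) {
  d <- morphData(table)
  if (is.null(methods)) {
    both <- intersect(unique(d$method[d$image_type == "pre"]),
                      unique(d$method[d$image_type == "CE"]))
    methods <- setdiff(both, "TRUE")
  }
  if (length(methods) == 0) stop("no method has both image types")
  if (is.null(d$identical_params))
    subsets <- setdiff(subsets, "identical-params")
  rows <- list()
  for (m in methods) {
    for (s in subsets) {
      p <- pairImages(table, m, subset = s)
      ba <- blandAltman(p$x, p$y)
      rows[[paste(m, s)]] <- data.frame(
        method = m, subset = s,
        n_pairs = nrow(p),
        n_dropped = attr(p, "n_dropped"),
        pearson_r = pearsonPaired(p$x, p$y),
        icc_c2 = iccConsistency(p$x, p$y),
        ba_bias = ba$bias,
        ba_loa_low = ba$loa[1],
        ba_loa_high = ba$loa[2],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
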