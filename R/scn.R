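#' Age-residualized thickness matrix for network construction
#'
#' Selects the images (subject-session observations of one method and image
#' type, optionally one group), regresses each region's thickness on age by
#' ordinary least squares over the selected images, and returns the
#' residuals in image x region layout. Each region's residual column has
#' mean zero on the fitted set. Structural covariance is then the
#' correlation of these columns across images: every image, not every
#' subject, is an observation.
#'
#' @param table a \linkS4class{MorphTable}.
#' @param method method label to select.
#' @param imageType image type to select ("pre" or "CE").
#' @param group optional group label; NULL pools all groups into one fit
#'   (used for pooled residualization before splitting networks by group).
#' @return A \linkS4class{ResidualMatrix}.
#' @export
residualizeAge <- function(table, method, imageType, group = NULL) {
  d <- morphData(table)
  sel <- d$method == method & d$image_type == imageType
  if (!is.null(group)) sel <- sel & d$group %in% group
  d <- d[sel, , drop = FALSE]
  if (nrow(d) == 0) stop("no images match the selection")
  rois <- sort(unique(d$roi))
  id <- paste(d$subject_id, d$session_index, d$image_type, d$method,
              sep = ":")
  ids <- unique(id)
  if (length(ids) < 3) stop("need at least 3 images, got ", length(ids))
  Y <- matrix(NA_real_, length(ids), length(rois),
              dimnames = list(ids, rois))
  Y[cbind(match(id, ids), match(d$roi, rois))] <- d$thickness_mm
  if (anyNA(Y))
    stop("incomplete region coverage: some images lack some regions")
  first <- !duplicated(id)
  info <- data.frame(
    image_id = ids,
    subject_id = d$subject_id[first], group = d$group[first],
    session_index = d$session_index[first], age = d$age[first],
    image_type = d$image_type[first], method = d$method[first],
    stringsAsFactors = FALSE
  )
  info <- info[match(ids, info$image_id), ]
  age <- info$age
  if (stats::var(age) == 0) stop("degenerate design: constant age")
  X <- cbind(1, age)
  beta <- solve(crossprod(X), crossprod(X, Y))
  R <- Y - X %*% beta
  new("ResidualMatrix", imageIds = ids, roiNames = rois, residuals = R,
      info = info[, setdiff(names(info), "image_id")])
}

#' Inter-regional correlation matrix
#'
#' Pearson correlation across images for every pair of regions' residual
#' columns: the structural covariance matrix.
#'
#' @param residuals a \linkS4class{ResidualMatrix} or a numeric matrix
#'   (images x regions).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlationMatrix <- function(residuals) {
  R <- if (is(residuals, "ResidualMatrix")) residualValues(residuals)
       else as.matrix(residuals)
  if (nrow(R) < 3) stop("need at least 3 images")
  sds <- apply(R, 2, stats::sd)
  if (any(sds == 0))
    stop("constant residual column for region(s): ",
         paste(colnames(R)[sds == 0], collapse = ", "))
  C <- stats::cor(R)
  # enforce exact symmetry against floating-point asymmetry
  (C + t(C)) / 2
}

#' Threshold a correlation matrix into a binary undirected graph
#'
#' An edge joins regions i and j (i != j) iff their correlation is at least
#' tau. Thresholding uses the signed correlation, so negative correlations
#' never create edges.
#'
#' @param corr symmetric correlation matrix with unit diagonal.
#' @param tau threshold in [0, 1].
#' @return A \linkS4class{SCNGraph}.
#' @examples
#' C <- diag(3); C[upper.tri(C)] <- C[lower.tri(C)] <- 0.6
#' thresholdGraph(C, 0.5)
#' @export
thresholdGraph <- function(corr, tau) {
  corr <- as.matrix(corr)
  if (nrow(corr) != ncol(corr) || max(abs(corr - t(corr))) > 1e-8)
    stop("correlation matrix must be symmetric")
  if (max(abs(diag(corr) - 1)) > 1e-8)
    stop("correlation matrix must have unit diagonal")
  if (tau < 0 || tau > 1) stop("threshold must be in [0, 1]")
  A <- corr >= tau
  diag(A) <- FALSE
  A <- A | t(A)  # guard exact symmetry for borderline float comparisons
  A <- A & t(A)
  nm <- colnames(corr)
  if (is.null(nm)) nm <- sprintf("n%02d", seq_len(ncol(corr)))
  dimnames(A) <- list(nm, nm)
  new("SCNGraph", roiNames = nm, adjacency = A, threshold = tau)
}

# All-pairs shortest-path lengths of an unweighted undirected graph by
# simultaneous breadth-first expansion (boolean matrix powers). Inf marks
# disconnected pairs.
apspDistances <- function(A) {
  N <- nrow(A)
  Anum <- matrix(as.numeric(A), N, N)
  D <- matrix(Inf, N, N)
  diag(D) <- 0
  reach <- diag(N) > 0
  d <- 0
  while (d < N) {
    d <- d + 1
    newreach <- (reach %*% Anum > 0) | reach
    fresh <- newreach & !reach
    if (!any(fresh)) break
    D[fresh] <- d
    reach <- newreach
  }
  D
}

#' Global efficiency of a binary undirected graph
#'
#' \deqn{E_{glob} = \frac{1}{N(N-1)} \sum_{i \ne j} \frac{1}{d_{ij}}}
#' with \eqn{d_{ij}} the unweighted shortest-path length (breadth-first
#' search from every node) and \eqn{1/\infty = 0} for disconnected pairs,
#' so the metric is finite on disconnected graphs. Equals 1 for a complete
#' graph and 0 for an edgeless one.
#'
#' @param graph a \linkS4class{SCNGraph} or a symmetric logical/0-1
#'   adjacency matrix with empty diagonal.
#' @return Efficiency in [0, 1].
#' @examples
#' A <- matrix(FALSE, 3, 3); A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- TRUE
#' globalEfficiency(A)  # path graph on 3 nodes: 5/6
#' @export
globalEfficiency <- function(graph) {
  A <- if (is(graph, "SCNGraph")) adjacency(graph) else {
    M <- as.matrix(graph) != 0
    if (nrow(M) != ncol(M) || !identical(M, t(M)))
      stop("adjacency must be a symmetric square matrix")
    diag(M) <- FALSE
    M
  }
  N <- nrow(A)
  if (N < 2) stop("need at least 2 nodes")
  D <- apspDistances(A)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (N * (N - 1))
}

#' Global efficiency over a threshold grid
#'
#' Applies \code{\link{thresholdGraph}} and \code{\link{globalEfficiency}}
#' at each threshold of the grid (default 0 to 0.99 in steps of 0.01). The
#' curve is non-increasing in tau because raising the threshold only removes
#' edges.
#'
#' @param corr symmetric correlation matrix with unit diagonal.
#' @param tauGrid thresholds within [0, 1].
#' @return data.frame with columns \code{tau} and \code{e_glob}.
#' @export
efficiencyCurve <- function(corr, tauGrid = seq(0, 0.99, by = 0.01)) {
  if (any(tauGrid < 0 | tauGrid > 1)) stop("tauGrid must lie in [0, 1]")
  e <- vapply(tauGrid,
              function(t) globalEfficiency(thresholdGraph(corr, t)),
              numeric(1))
  data.frame(tau = tauGrid, e_glob = e)
}

#' Subsampling error bands for the efficiency curve
#'
#' Point estimate from the full image set; uncertainty from repeatedly
#' rebuilding the network from a random subset of the images (default 80%
#' of the images, 1000 times, drawn without replacement) and taking the
#' per-threshold sample SD of the resulting efficiency curves.
#'
#' @param residuals a \linkS4class{ResidualMatrix}.
#' @param fraction fraction of images per subsample.
#' @param reps number of subsamples.
#' @param tauGrid thresholds within [0, 1].
#' @param seed integer seed.
#' @return data.frame with columns \code{tau}, \code{e_glob} (full-set
#'   estimate) and \code{band_sd}.
#' @export
subsampleBand <- function(residuals, fraction = 0.8, reps = 1000,
                          tauGrid = seq(0, 0.99, by = 0.01), seed = 1L) {
  stopifnot(is(residuals, "ResidualMatrix"))
  R <- residualValues(residuals)
  n <- nrow(R)
  m <- floor(fraction * n)
  if (m < 3) stop("too few images: ", m, " per subsample")
  full <- efficiencyCurve(correlationMatrix(R), tauGrid)
  if (reps < 1) {
    full$band_sd <- NA_real_
    return(full)
  }
  curves <- matrix(NA_real_, reps, length(tauGrid))
  for (r in seq_len(reps)) {
    idx <- withSeed(splitSeed(seed, 5, r), sample.int(n, m))
    curves[r, ] <- efficiencyCurve(correlationMatrix(R[idx, , drop = FALSE]),
                                   tauGrid)$e_glob
  }
  full$band_sd <- apply(curves, 2, stats::sd)
  full
}

#' Group contrast of network efficiency at a reference threshold
#'
#' Builds one structural covariance network per (group, method, image type),
#' reports global efficiency at the reference threshold \code{tauStar} with
#' an optional subsampling SD band, and flags for each method and image type
#' whether the PPMS network is more efficient than the RRMS network.
#'
#' @param table a \linkS4class{MorphTable} with both groups.
#' @param tauStar reference threshold (default 0.5).
#' @param methods method labels; default every non-"TRUE" method present.
#' @param imageTypes image types to analyse.
#' @param reps subsamples for the SD band; 0 disables the band.
#' @param fraction subsample fraction.
#' @param seed integer seed for the subsampling.
#' @param residualize \code{"per-group"} fits the age model within each
#'   group's images; \code{"pooled"} fits one age model across groups, then
#'   splits the residuals.
#' @return data.frame with one row per (group, method, image type):
#'   \code{e_glob} at \code{tauStar} and \code{band_sd}; the
#'   \code{"comparison"} attribute tabulates PPMS-vs-RRMS per method and
#'   image type.
#' @export
groupContrast <- function(table, tauStar = 0.5, methods = NULL,
                          imageTypes = c("pre", "CE"), reps = 0,
                          fraction = 0.8, seed = 1L,
                          residualize = c("per-group", "pooled")) {
  residualize <- match.arg(residualize)
  d <- morphData(table)
  groups <- sort(unique(d$group))
  if (!all(c("PPMS", "RRMS") %in% groups))
    stop("both groups (PPMS, RRMS) must be present")
  if (is.null(methods))
    methods <- setdiff(sort(unique(d$method)), "TRUE")
  imageTypes <- intersect(imageTypes, unique(d$image_type))
  rows <- list()
  for (m in methods) for (it in imageTypes) {
    pooledRes <- if (residualize == "pooled")
      residualizeAge(table, m, it) else NULL
    for (g in c("PPMS", "RRMS")) {
      res <- if (residualize == "per-group")
        residualizeAge(table, m, it, group = g)
      else {
        keep <- imageInfo(pooledRes)$group == g
        new("ResidualMatrix",
            imageIds = pooledRes@imageIds[keep],
            roiNames = pooledRes@roiNames,
            residuals = residualValues(pooledRes)[keep, , drop = FALSE],
            info = imageInfo(pooledRes)[keep, , drop = FALSE])
      }
      if (reps > 0) {
        band <- subsampleBand(res, fraction = fraction, reps = reps,
                              tauGrid = tauStar,
                              seed = splitSeed(seed, 6, match(m, methods),
                                               match(it, imageTypes),
                                               match(g, c("PPMS", "RRMS"))))
        e <- band$e_glob[1]
        sd <- band$band_sd[1]
      } else {
        e <- globalEfficiency(thresholdGraph(correlationMatrix(res), tauStar))
        sd <- NA_real_
      }
      rows[[paste(g, m, it)]] <- data.frame(
        group = g, method = m, image_type = it, tau = tauStar,
        e_glob = e, band_sd = sd, n_images = length(res@imageIds),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  cmp <- do.call(rbind, lapply(split(out, paste(out$method, out$image_type)),
    function(s) data.frame(
      method = s$method[1], image_type = s$image_type[1],
      e_ppms = s$e_glob[s$group == "PPMS"],
      e_rrms = s$e_glob[s$group == "RRMS"],
      ppms_gt_rrms = s$e_glob[s$group == "PPMS"] >
        s$e_glob[s$group == "RRMS"],
      stringsAsFactors = FALSE)))
  rownames(cmp) <- NULL
  attr(out, "comparison") <- cmp
  out
}
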