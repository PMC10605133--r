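# Normalization, scaling and unsupervised projection for species x sample
# concentration matrices. Samples are the observations, species the
# variables; centering/scaling is therefore per species (per row of the
# input matrix). Default workflow: median normalization -> Pareto scaling
# -> PCA, with 95% confidence ellipses per group on the score plot.

#' Median normalization of sample columns
#'
#' Divides each sample column by its median and rescales by the global
#' median of the sample medians, so all column medians become equal while
#' the overall scale of the matrix is preserved.
#'
#' @param x numeric items x samples matrix, or [LipidomicsExperiment-class].
#' @return matrix of the same shape.
#' @export
normalizeMedian <- function(x) {
  mat <- if (is(x, "LipidomicsExperiment")) concentrations(x) else
    as.matrix(x)
  med <- apply(mat, 2, stats::median)
  if (any(med <= 0))
    .err("sample median <= 0; cannot median-normalize",
         "lipidflow_zero_median")
  sweep(mat, 2, med, `/`) * stats::median(med)
}

#' Autoscaling and Pareto scaling of variables
#'
#' Centers every item (row) at zero and divides by its standard deviation
#' (`"autoscale"`, giving unit variance) or the square root of its standard
#' deviation (`"pareto"`, damping the dominance of high-abundance lipids;
#' the scaled variance equals the original standard deviation). Constant
#' rows map to all zeros.
#'
#' @param x numeric items x samples matrix, or [LipidomicsExperiment-class].
#' @param method `"pareto"` (default), `"autoscale"` or `"none"`
#'   (centering only).
#' @return matrix of the same shape with attribute `"scaling"` recording
#'   the applied step and `"constantRows"` listing zero-variance items.
#' @export
scaleFeatures <- function(x, method = c("pareto", "autoscale", "none")) {
  method <- match.arg(method)
  mat <- if (is(x, "LipidomicsExperiment")) concentrations(x) else
    as.matrix(x)
  if (ncol(mat) < 2L)
    .err("scaling needs at least two samples", "lipidflow_too_few_samples")
  ctr <- mat - rowMeans(mat)
  s <- apply(mat, 1, stats::sd)
  const <- s == 0
  div <- switch(method, pareto = sqrt(s), autoscale = s, none = rep(1, nrow(mat)))
  div[const | div == 0] <- 1
  out <- ctr / div
  out[const, ] <- 0
  structure(out, scaling = method,
            constantRows = rownames(mat)[const])
}

#' Principal component analysis of a scaled lipid matrix
#'
#' PCA with samples as observations and lipid items as variables. The input
#' is expected to be centered per item (see [scaleFeatures()]); no further
#' centering or scaling is applied. For reproducibility each component's
#' sign is fixed so that its largest-magnitude loading is positive.
#'
#' @param scaled items x samples matrix, centered per item.
#' @param nComponents number of components to keep (capped at the matrix
#'   rank).
#' @return list of class `"lipidPCA"`: `scores` (samples x components),
#'   `loadings` (items x components, orthonormal columns),
#'   `explainedVariance` (fraction per retained component, relative to the
#'   total variance).
#' @export
lipidPCA <- function(scaled, nComponents = NULL) {
  X <- t(as.matrix(scaled))          # samples x items
  if (nrow(X) < 3L)
    .err("PCA needs at least three samples", "lipidflow_too_few_samples")
  sv <- svd(X)
  totVar <- sum(sv$d^2)
  rank <- sum(sv$d > sv$d[1] * 1e-10)
  k <- if (is.null(nComponents)) rank else min(nComponents, rank)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {            # deterministic sign convention
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(scores) <- list(rownames(X), paste0("PC", seq_len(k)))
  dimnames(loadings) <- list(colnames(X), paste0("PC", seq_len(k)))
  structure(list(scores = scores, loadings = loadings,
                 explainedVariance = (sv$d[seq_len(k)]^2) / totVar),
            class = "lipidPCA")
}

#' @export
print.lipidPCA <- function(x, ...) {
  cat("PCA:", nrow(x$scores), "samples,", nrow(x$loadings), "items,",
      ncol(x$scores), "components\n")
  cat("  explained variance:",
      paste0(sprintf("%.1f%%", 100 * x$explainedVariance), collapse = " "),
      "\n")
  invisible(x)
}

#' Group confidence ellipse on a 2-D score plot
#'
#' Ellipse enclosing a group's scores with the requested confidence under a
#' bivariate normal model: eigendecomposition of the group's 2-D score
#' covariance with the chi-squared(2) quantile setting the radius.
#'
#' @param scores numeric n x 2 matrix of component scores for one group.
#' @param level confidence level, default 0.95.
#' @return list with `center` (length 2), `radii` (semi-axis lengths),
#'   `angle` (radians, orientation of the major axis) and `level`.
#' @export
confidenceEllipse <- function(scores, level = 0.95) {
  scores <- as.matrix(scores)
  stopifnot(ncol(scores) == 2L)
  if (nrow(scores) < 3L)
    .err("confidence ellipse needs n >= 3", "lipidflow_too_few_samples")
  ctr <- colMeans(scores)
  eg <- eigen(stats::cov(scores), symmetric = TRUE)
  r <- sqrt(pmax(eg$values, 0) * stats::qchisq(level, df = 2))
  list(center = ctr, radii = r,
       angle = atan2(eg$vectors[2, 1], eg$vectors[1, 1]), level = level)
}

#' Select top differential species and cluster for a heatmap
#'
#' Selects the `k` most significant items by ascending two-group p-value
#' (ties broken by descending absolute log2 fold change, then by name),
#' standardizes each selected row, and builds row and column dendrograms
#' with complete linkage on Euclidean distances (correlation distance
#' available).
#'
#' @param x a [LipidomicsExperiment-class] or items x samples matrix.
#' @param group per-sample group labels (from the object if omitted).
#' @param k number of items to keep (default 50; clamped to the number of
#'   items with a message).
#' @param caseGroup case group label.
#' @param distance `"euclidean"` (default) or `"correlation"`
#'   (1 - Pearson).
#' @param test passed to [compareGroups()].
#' @return list of class `"lipidHeatmap"`: `items`, `values` (standardized
#'   k x samples matrix), `rowDendrogram`/`colDendrogram` (`hclust`),
#'   `rowOrder`/`colOrder`, `pValues`.
#' @export
heatmapSelectCluster <- function(x, group = NULL, k = 50,
                                 caseGroup = "HOM",
                                 distance = c("euclidean", "correlation"),
                                 test = "welch") {
  distance <- match.arg(distance)
  if (is(x, "LipidomicsExperiment")) {
    if (is.null(group)) group <- as.character(sampleGroups(x))
    mat <- concentrations(x)
  } else mat <- as.matrix(x)
  cmp <- compareGroups(mat, group = group, caseGroup = caseGroup,
                       test = test)
  ord <- order(cmp$pValue, -abs(cmp$log2FC), cmp$item, na.last = TRUE)
  if (k > nrow(mat)) {
    message("k = ", k, " exceeds ", nrow(mat), " items; clamped")
    k <- nrow(mat)
  }
  sel <- ord[seq_len(k)]
  vals <- scaleFeatures(mat[sel, , drop = FALSE], "autoscale")
  dfun <- function(m) {
    if (distance == "euclidean") stats::dist(m)
    else stats::as.dist(1 - stats::cor(t(m)))
  }
  rowD <- stats::hclust(dfun(vals), method = "complete")
  colD <- stats::hclust(dfun(t(vals)), method = "complete")
  structure(list(items = rownames(mat)[sel], values = vals,
                 rowDendrogram = rowD, colDendrogram = colD,
                 rowOrder = rowD$order, colOrder = colD$order,
                 pValues = cmp$pValue[sel]),
            class = "lipidHeatmap")
}

#' @export
print.lipidHeatmap <- function(x, ...) {
  cat("Heatmap selection:", length(x$items), "items x",
      ncol(x$values), "samples (complete linkage)\n")
  invisible(x)
}
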