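# Class-level aggregation and two-group statistics. The summary table
# layout mirrors the field's standard per-class report: group means,
# dispersion, raw two-sided p with significance stars (* <0.05, ** <0.01,
# *** <0.001) and percent composition per group.

#' Significance stars from p-values
#'
#' @param p numeric vector of p-values.
#' @return character vector: `"***"` p < 0.001, `"**"` p < 0.01, `"*"`
#'   p < 0.05, `""` otherwise (and for `NA`).
#' @export
starsFromP <- function(p) {
  out <- rep("", length(p))
  out[!is.na(p) & p < 0.05] <- "*"
  out[!is.na(p) & p < 0.01] <- "**"
  out[!is.na(p) & p < 0.001] <- "***"
  out
}

#' Per-class concentration totals
#'
#' Sums species concentrations within each lipid class, per sample. The
#' grand total (sum over classes, equal to the sum over species) is
#' attached as attribute `"grandTotal"`.
#'
#' @param x a [LipidomicsExperiment-class], or a numeric species x samples
#'   matrix with `classes` giving each row's class code.
#' @param classes class code per row (matrix method; defaults to parsing
#'   the rownames).
#' @return class x samples numeric matrix with attribute `grandTotal`
#'   (named numeric, one value per sample).
#' @examples
#' m <- matrix(c(1, 2, 4, 8), 2, 2,
#'             dimnames = list(c("PC 16:0_18:1", "PC 18:0_18:1"),
#'                             c("s1", "s2")))
#' classTotals(m)
#' @rdname classTotals
#' @export
setMethod("classTotals", "LipidomicsExperiment", function(x, ...) {
  classTotals(concentrations(x), classes = lipidClasses(x))
})

#' @rdname classTotals
#' @export
setMethod("classTotals", "matrix", function(x, classes = NULL, ...) {
  if (is.null(classes))
    classes <- parseLipidNames(rownames(x))$classCode
  stopifnot(length(classes) == nrow(x))
  totals <- rowsum(x, group = classes)
  totals <- totals[order(rownames(totals)), , drop = FALSE]
  structure(totals, grandTotal = colSums(totals))
})

#' Grand total per sample
#' @param totals output of [classTotals()].
#' @return named numeric vector of per-sample totals.
#' @export
grandTotals <- function(totals) {
  gt <- attr(totals, "grandTotal")
  if (is.null(gt)) gt <- colSums(totals)
  gt
}

.twoGroupTest <- function(v, group, caseGroup, test) {
  a <- v[group == caseGroup]
  b <- v[group != caseGroup]
  if (length(a) < 2L || length(b) < 2L)
    .err("both groups need n >= 2", "lipidflow_too_few_samples")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    # degenerate: no variance anywhere -> p undefined (NA), not an error
    return(c(t = NA_real_, p = NA_real_))
  }
  ht <- stats::t.test(a, b, var.equal = (test == "student"))
  c(t = unname(ht$statistic), p = ht$p.value)
}

#' Two-group comparison of classes or species
#'
#' Two-sided t-test per item (row) between a case and a control group, with
#' group means, dispersions, log2 fold change, significance stars and
#' percent composition per group. The default is Welch's t on the raw
#' concentration scale; Student's t and log-scale testing are options, as
#' is Benjamini-Hochberg adjustment of the reported p-values.
#'
#' @param x a [LipidomicsExperiment-class], a [classTotals()] matrix, or any
#'   item x samples matrix.
#' @param group per-sample group labels (taken from the object when `x` is
#'   a `LipidomicsExperiment`).
#' @param caseGroup label of the case group (default `"HOM"`).
#' @param test `"welch"` (default) or `"student"`.
#' @param transform `"none"` (default) or `"log"` (natural log of values,
#'   requires positivity).
#' @param dispersion `"sem"` (standard error of the mean, default) or
#'   `"sd"`.
#' @param adjust `"none"` (default, matching raw per-item stars) or `"BH"`.
#' @return `data.frame` with columns `item`, `meanCase`, `meanControl`,
#'   `dispCase`, `dispControl`, `log2FC`, `tStatistic`, `pValue`, `stars`,
#'   `pctCase`, `pctControl`. Items with zero variance in both groups get
#'   `pValue = NA`.
#' @export
compareGroups <- function(x, group = NULL, caseGroup = "HOM",
                          test = c("welch", "student"),
                          transform = c("none", "log"),
                          dispersion = c("sem", "sd"),
                          adjust = c("none", "BH")) {
  test <- match.arg(test)
  transform <- match.arg(transform)
  dispersion <- match.arg(dispersion)
  adjust <- match.arg(adjust)
  if (is(x, "LipidomicsExperiment")) {
    if (is.null(group)) group <- as.character(sampleGroups(x))
    x <- concentrations(x)
  }
  group <- as.character(group)
  stopifnot(length(group) == ncol(x))
  if (!caseGroup %in% group)
    .err(paste("case group", caseGroup, "not present"),
         "lipidflow_bad_group")
  vals <- if (transform == "log") log(x) else x
  tests <- t(apply(vals, 1, .twoGroupTest, group = group,
                   caseGroup = caseGroup, test = test))
  isCase <- group == caseGroup
  disp <- function(m) {
    s <- apply(m, 1, stats::sd)
    if (dispersion == "sem") s / sqrt(ncol(m)) else s
  }
  mCase <- rowMeans(x[, isCase, drop = FALSE])
  mCtrl <- rowMeans(x[, !isCase, drop = FALSE])
  p <- stats::p.adjust(tests[, "p"], method = adjust)
  # fold change is only meaningful for positive concentration means
  lfc <- rep(NA_real_, length(mCase))
  pos <- mCase > 0 & mCtrl > 0
  lfc[pos] <- log2(mCase[pos] / mCtrl[pos])
  data.frame(
    item = rownames(x),
    meanCase = mCase, meanControl = mCtrl,
    dispCase = disp(x[, isCase, drop = FALSE]),
    dispControl = disp(x[, !isCase, drop = FALSE]),
    log2FC = lfc,
    tStatistic = tests[, "t"], pValue = p, stars = starsFromP(p),
    pctCase = 100 * mCase / sum(mCase),
    pctControl = 100 * mCtrl / sum(mCtrl),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' One-way ANOVA across three or more groups
#'
#' Classic one-way fixed-effects ANOVA F-test per item. With exactly two
#' groups the F statistic is the square of Student's t and the p-values
#' coincide.
#'
#' @inheritParams compareGroups
#' @param varEqual assume equal variances (classic ANOVA, default `TRUE`);
#'   `FALSE` gives Welch's ANOVA.
#' @return `data.frame` with `item`, `fStatistic`, `pValue`, `stars`.
#' @export
anovaGroups <- function(x, group = NULL, varEqual = TRUE) {
  if (is(x, "LipidomicsExperiment")) {
    if (is.null(group)) group <- as.character(sampleGroups(x))
    x <- concentrations(x)
  }
  group <- factor(group)
  stopifnot(length(group) == ncol(x))
  if (nlevels(group) < 2L)
    .err("ANOVA needs at least two groups", "lipidflow_bad_group")
  res <- t(apply(x, 1, function(v) {
    if (all(tapply(v, group, stats::var) == 0))
      return(c(f = NA_real_, p = NA_real_))
    ht <- stats::oneway.test(v ~ group, var.equal = varEqual)
    c(f = unname(ht$statistic), p = ht$p.value)
  }))
  data.frame(item = rownames(x), fStatistic = res[, "f"],
             pValue = res[, "p"], stars = starsFromP(res[, "p"]),
             row.names = NULL, stringsAsFactors = FALSE)
}
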