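# Psychosine vs lipid-class correlation across samples (both groups
# pooled): per class a Pearson (default, on log concentrations) or
# Spearman coefficient with its p-value and a signed association label.

#' Correlate psychosine with lipid-class totals
#'
#' @param psy named per-sample psychosine concentrations
#'   ([quantifyPsy()] output).
#' @param totals class x samples matrix ([classTotals()] output); columns
#'   are matched to `names(psy)`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param logTransform correlate on the natural-log scale (default `TRUE`;
#'   applies to Pearson only — Spearman is rank-based and unaffected).
#'   Zero or negative values fall back to the raw scale for that class with
#'   a warning.
#' @param alpha significance level for the sign label (default 0.05).
#' @return `data.frame` with `classCode`, `method`, `coefficient`,
#'   `pValue` and `label` (`"positive"`, `"negative"`, `"none"`). Constant
#'   class vectors yield `NA` coefficients and label `"none"`.
#' @export
psyClassCorrelation <- function(psy, totals, method = c("pearson",
                                                        "spearman"),
                                logTransform = TRUE, alpha = 0.05) {
  method <- match.arg(method)
  if (!is.null(names(psy)) && !is.null(colnames(totals))) {
    common <- intersect(names(psy), colnames(totals))
    if (length(common) < 3L)
      .err("need >= 3 paired samples", "lipidflow_too_few_samples")
    psy <- psy[common]
    totals <- totals[, common, drop = FALSE]
  } else if (length(psy) != ncol(totals) || length(psy) < 3L)
    .err("need >= 3 paired samples", "lipidflow_too_few_samples")
  if (stats::sd(psy) == 0)
    .err("psychosine vector is constant", "lipidflow_constant_vector")
  xs <- as.numeric(psy)
  useLog <- logTransform && method == "pearson"
  if (useLog && all(xs > 0)) xs <- log(xs)
  res <- lapply(seq_len(nrow(totals)), function(i) {
    v <- totals[i, ]
    if (stats::sd(v) == 0) {
      warning("constant class vector: ", rownames(totals)[i])
      return(c(r = NA_real_, p = NA_real_))
    }
    vv <- if (useLog && all(v > 0)) log(v) else v
    ct <- suppressWarnings(stats::cor.test(xs, vv, method = method,
                                           exact = FALSE))
    c(r = unname(ct$estimate), p = ct$p.value)
  })
  res <- do.call(rbind, res)
  lab <- rep("none", nrow(res))
  sig <- !is.na(res[, "p"]) & res[, "p"] < alpha
  lab[sig & res[, "r"] > 0] <- "positive"
  lab[sig & res[, "r"] < 0] <- "negative"
  data.frame(classCode = rownames(totals), method = method,
             coefficient = res[, "r"], pValue = res[, "p"], label = lab,
             row.names = NULL, stringsAsFactors = FALSE)
}
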