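# Reaction-activation scoring. For every catalogued transformation
# reactant -> product, the per-sample weight is the ratio of the product
# pool's abundance to the reactant pool's abundance. A two-sided t-test on
# log2 weights between case and control groups yields p; the Z-score is the
# signed standard-normal quantile of the two-sided p (sign = direction of
# the case-minus-control mean difference), a deterministic monotone
# transform of p. Log2 makes activation and suppression symmetric.

#' Default class-level reaction catalog
#'
#' Catalogued transformations between glycerophospholipid pools with their
#' enzymes and coding genes: CDP-diacylglycerol synthase routes from PA,
#' phospholipase D routes to PA, phosphatidylserine synthases, PG synthesis
#' from PC and cardiolipin, and phospholipase A lysolipid formation. Users
#' extend or replace the catalog via [ReactionCatalog()] or a CSV read with
#' [readReactionCatalog()].
#'
#' @return A [ReactionCatalog-class] with scope `"class"`.
#' @examples
#' defaultClassCatalog()
#' @export
defaultClassCatalog <- function() {
  ReactionCatalog(data.frame(
    reactant = c("PA", "PA", "PI", "PC", "PC", "PE", "PA", "PC", "CL",
                 "PC"),
    product  = c("PG", "PI", "PA", "PA", "PS", "PS", "PS", "PG", "PG",
                 "LPC"),
    enzyme   = c("phosphatidate cytidylyltransferase",
                 "phosphatidate cytidylyltransferase",
                 "phospholipase D", "phospholipase D",
                 "phosphatidylserine synthase 1",
                 "phosphatidylserine synthase 2",
                 "phosphatidate cytidylyltransferase + PS synthase",
                 "phospholipase D1/D4/D6",
                 "mitoguardin + mitochondrial cardiolipin hydrolase",
                 "phospholipase A"),
    gene     = c("CDS", "CDS", "PLD", "PLD", "PSS1", "PSS2",
                 "CDS;PSS1;PSS2", "PLD1;PLD4;PLD6", "MIGA;PLD6", "PLA"),
    stringsAsFactors = FALSE), scope = "class")
}

#' Per-sample product/reactant weights for catalogued reactions
#'
#' @param totals pool x samples abundance matrix ([classTotals()] output or
#'   [chainAbundance()] output).
#' @param catalog a [ReactionCatalog-class]; edges whose reactant or
#'   product pool is absent from `totals` are skipped with a warning.
#' @return edge x samples matrix of weights, rownames `"PA->PG"` style.
#'   Samples where either pool is non-positive get `NA` for that edge.
#' @examples
#' tot <- matrix(c(1, 2, 2, 2), 2, 2,
#'               dimnames = list(c("PA", "PG"), c("s1", "s2")))
#' computeReactionWeights(tot, defaultClassCatalog())
#' @export
computeReactionWeights <- function(totals, catalog) {
  stopifnot(is(catalog, "ReactionCatalog"))
  e <- catalog@edges
  present <- e$reactant %in% rownames(totals) &
    e$product %in% rownames(totals)
  if (any(!present))
    warning("edges skipped (pool absent from data): ",
            paste(paste0(e$reactant[!present], "->", e$product[!present]),
                  collapse = ", "))
  e <- e[present, , drop = FALSE]
  if (!nrow(e))
    return(matrix(numeric(), 0, ncol(totals),
                  dimnames = list(NULL, colnames(totals))))
  num <- totals[e$product, , drop = FALSE]
  den <- totals[e$reactant, , drop = FALSE]
  w <- num / den
  w[num <= 0 | den <= 0] <- NA    # excluded sample for that edge
  rownames(w) <- paste0(e$reactant, "->", e$product)
  w
}

#' Score reactions as activated or suppressed between two groups
#'
#' Welch two-sided t-test on log2 weights (case vs control) per edge. The
#' Z-score is the signed probit of the two-sided p-value; an edge is called
#' `"activated"` when the case-group mean log-weight exceeds the control's
#' and p is below `threshold`, `"suppressed"` in the opposite direction,
#' `"unchanged"` otherwise.
#'
#' @param weights edge x samples matrix from [computeReactionWeights()].
#' @param group per-sample group labels.
#' @param caseGroup case group label (default `"HOM"`).
#' @param threshold significance threshold for calls (default 0.05). A
#'   stricter reporting tier can be applied downstream by filtering on
#'   `pValue`.
#' @param logScale test on log2 weights (default `TRUE`); `FALSE` tests raw
#'   weights.
#' @param test `"welch"` or `"student"`.
#' @return `data.frame` with `edge`, `reactant`, `product`,
#'   `meanLogWeightCase`, `meanLogWeightControl`, `log2WeightRatio`,
#'   `tStatistic`, `pValue`, `zScore`, `call`.
#' @export
scoreReactions <- function(weights, group, caseGroup = "HOM",
                           threshold = 0.05, logScale = TRUE,
                           test = c("welch", "student")) {
  test <- match.arg(test)
  group <- as.character(group)
  stopifnot(length(group) == ncol(weights))
  if (!caseGroup %in% group)
    .err(paste("case group", caseGroup, "not present"),
         "lipidflow_bad_group")
  rn <- rownames(weights)
  parts <- strsplit(rn, "->", fixed = TRUE)
  out <- data.frame(
    edge = rn,
    reactant = vapply(parts, `[`, "", 1L),
    product = vapply(parts, `[`, "", 2L),
    meanLogWeightCase = NA_real_, meanLogWeightControl = NA_real_,
    log2WeightRatio = NA_real_, tStatistic = NA_real_, pValue = NA_real_,
    zScore = NA_real_, call = "unchanged",
    row.names = NULL, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(weights))) {
    w <- weights[i, ]
    ok <- !is.na(w)
    a <- w[ok & group == caseGroup]
    b <- w[ok & group != caseGroup]
    if (length(a) < 2L || length(b) < 2L) next
    if (logScale) { a <- log2(a); b <- log2(b) }
    out$meanLogWeightCase[i] <- mean(a)
    out$meanLogWeightControl[i] <- mean(b)
    out$log2WeightRatio[i] <- mean(a) - mean(b)
    if (stats::var(a) == 0 && stats::var(b) == 0) next
    ht <- stats::t.test(a, b, var.equal = (test == "student"))
    out$tStatistic[i] <- unname(ht$statistic)
    out$pValue[i] <- ht$p.value
    # signed probit of the two-sided p: monotone in p, sign = direction
    out$zScore[i] <- sign(mean(a) - mean(b)) *
      stats::qnorm(1 - ht$p.value / 2)
    if (ht$p.value < threshold)
      out$call[i] <- if (mean(a) > mean(b)) "activated" else "suppressed"
  }
  out
}

#' Annotate scored reactions with enzymes and genes
#'
#' @param scores output of [scoreReactions()].
#' @param catalog the [ReactionCatalog-class] the weights came from.
#' @return the score table with `enzyme` and `gene` columns merged in,
#'   ordered by p-value.
#' @export
annotateReactions <- function(scores, catalog) {
  e <- catalog@edges
  e$edge <- paste0(e$reactant, "->", e$product)
  keep <- setdiff(names(e), c("reactant", "product"))
  out <- merge(scores, e[, keep, drop = FALSE], by = "edge",
               all.x = TRUE, sort = FALSE)
  out[order(out$pValue), , drop = FALSE]
}

#' Export a scored reaction network as a directed graph
#'
#' Builds an [igraph::igraph] graph whose vertices are the pools and whose
#' edges carry the statistics and the activation call; optionally writes it
#' to GraphML or an edge-list file.
#'
#' @param annotated output of [annotateReactions()] (or [scoreReactions()]).
#' @param file optional output path.
#' @param format `"graphml"` or `"edgelist"` (ignored when `file` is
#'   `NULL`).
#' @return the igraph object, invisibly when writing to file.
#' @export
exportReactionGraph <- function(annotated, file = NULL,
                                format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  cols <- c("reactant", "product",
            intersect(c("enzyme", "gene", "pValue", "zScore", "tStatistic",
                        "call"), names(annotated)))
  g <- igraph::graph_from_data_frame(annotated[, cols, drop = FALSE],
                                     directed = TRUE)
  if (!is.null(file)) {
    igraph::write_graph(g, file, format = format)
    return(invisible(g))
  }
  g
}
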