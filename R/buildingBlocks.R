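# Fatty-acyl building-block analysis: chain abundance matrices
# (multiplicity-weighted sums of species concentrations), chain-length and
# unsaturation profiles, and elongation / desaturation / beta-oxidation
# networks scored with the same product/reactant weight machinery as the
# class-level networks.

.chainLabel <- function(carbons, doubleBonds) {
  paste0(carbons, ":", doubleBonds)
}

#' Chain (building-block) abundance matrix
#'
#' For every fatty-acyl chain observed in molecular-species-level lipids,
#' the per-sample abundance is the sum over species containing the chain of
#' multiplicity times the species concentration (`"PA 18:1_18:1"`
#' contributes twice to 18:1). Sphingoid long-chain bases are excluded by
#' default so the matrix reflects fatty-acid chains; ether chains count
#' with their `(carbons, doubleBonds)` signature.
#'
#' @param x a [LipidomicsExperiment-class].
#' @param classCode optional single class code restricting the analysis to
#'   one lipid class.
#' @param includeSphingoid include sphingoid bases (default `FALSE`).
#' @param multiplicity weight chains by their multiplicity within a species
#'   (default `TRUE`); `FALSE` counts each distinct chain once per species.
#' @return chain x samples numeric matrix, rownames `"18:1"` style, sorted
#'   by carbons then double bonds.
#' @rdname chainAbundance
#' @export
setMethod("chainAbundance", "LipidomicsExperiment",
function(x, classCode = NULL, includeSphingoid = FALSE,
         multiplicity = TRUE, ...) {
  rd <- rowData(x)
  keep <- rd$annotationLevel == "molecular-species"
  if (!is.null(classCode)) {
    if (!classCode %in% rd$classCode)
      .err(paste("class", classCode, "absent from experiment"),
           "lipidflow_class_absent")
    keep <- keep & rd$classCode == classCode
  }
  conc <- concentrations(x)[keep, , drop = FALSE]
  chains <- rd$chains[keep]
  classes <- rd$classCode[keep]
  rows <- list()
  for (i in seq_along(chains)) {
    ch <- chains[[i]]
    if (!includeSphingoid && classes[i] %in% .sphingoidClasses)
      ch <- ch[-1L, , drop = FALSE]
    if (!nrow(ch)) next
    lab <- .chainLabel(ch$carbons, ch$doubleBonds)
    mult <- table(lab)
    if (!multiplicity) mult[] <- 1L
    for (l in names(mult))
      rows[[length(rows) + 1L]] <-
        c(list(label = l, mult = as.integer(mult[[l]])), list(row = i))
  }
  if (!length(rows))
    return(matrix(numeric(), 0, ncol(conc),
                  dimnames = list(NULL, colnames(conc))))
  lab <- vapply(rows, `[[`, "", "label")
  contrib <- conc[vapply(rows, `[[`, 0L, "row"), , drop = FALSE] *
    vapply(rows, `[[`, 0L, "mult")
  ab <- rowsum(contrib, group = lab)
  cd <- do.call(rbind, strsplit(rownames(ab), ":", fixed = TRUE))
  ord <- order(as.integer(cd[, 1]), as.integer(cd[, 2]))
  ab[ord, , drop = FALSE]
})

#' Chain-length and unsaturation profiles with per-bin tests
#'
#' Aggregates the chain abundance matrix along one axis — total carbon
#' count (`"length"`) or number of double bonds (`"unsaturation"`) — and
#' compares the two groups per bin.
#'
#' @param chainAb chain x samples matrix from [chainAbundance()].
#' @param group per-sample group labels.
#' @param axis `"length"` or `"unsaturation"`.
#' @param caseGroup case group label.
#' @param ... passed to [compareGroups()] (test, transform, dispersion).
#' @return `data.frame` as from [compareGroups()] with `item` the bin value
#'   (carbon count or double-bond count) in increasing order.
#' @export
chainProfiles <- function(chainAb, group, axis = c("length",
                                                   "unsaturation"),
                          caseGroup = "HOM", ...) {
  axis <- match.arg(axis)
  cd <- do.call(rbind, strsplit(rownames(chainAb), ":", fixed = TRUE))
  bin <- as.integer(cd[, if (axis == "length") 1 else 2])
  binned <- rowsum(chainAb, group = bin)
  binned <- binned[order(as.integer(rownames(binned))), , drop = FALSE]
  compareGroups(binned, group = group, caseGroup = caseGroup, ...)
}

# default enzyme annotations keyed by (type, substrate chain); chains not
# listed fall back to the generic family label
.chainEnzymeLookup <- function() {
  data.frame(
    type = c("desaturation", "desaturation", "desaturation",
             "desaturation", "desaturation",
             "elongation", "elongation", "elongation"),
    substrate = c("18:0", "16:0", "18:1", "18:2", "22:2",
                  "16:0", "16:1", "22:0"),
    enzyme = c("stearoyl-CoA desaturase", "stearoyl-CoA desaturase",
               "delta-6 desaturase", "delta-6 desaturase",
               "delta-5 desaturase",
               "elongase", "elongase", "elongase"),
    gene = c("SCD1", "SCD1", "FADS2 (D6D)", "FADS2 (D6D)", "FADS1 (D5D)",
             "ELOVL1;ELOVL3;ELOVL6", "ELOVL1;ELOVL3;ELOVL6",
             "ELOVL1;ELOVL3;ELOVL6"),
    stringsAsFactors = FALSE)
}

#' Chain-level reaction catalog from observed chains
#'
#' Generates directed edges between observed building blocks only:
#' elongation `(c, d) -> (c+2, d)`, desaturation `(c, d) -> (c, d+1)`, and
#' beta-oxidation `(c, d) -> (c-2, d)` for substrates with at least
#' `betaOxMinCarbons` carbons (long chains, where the figure-level logic of
#' chain shortening operates; lowering the bound saturates the network).
#' Enzyme/gene labels come from a lookup keyed by (type, substrate chain):
#' SCD1 for 16:0/18:0 desaturation, D6D (FADS2) for 18:1/18:2, D5D (FADS1)
#' for 22:2, ELOVL1/3/6 for 16:x and 22:0 elongation, with generic family
#' labels elsewhere.
#'
#' @param chains character vector of observed chain labels (`"18:1"`), e.g.
#'   `rownames(chainAbundance(x))`.
#' @param betaOxMinCarbons minimum substrate carbons for beta-oxidation
#'   edges (default 20).
#' @param enzymeLookup optional replacement lookup `data.frame` with
#'   columns `type`, `substrate`, `enzyme`, `gene`.
#' @return A [ReactionCatalog-class] with scope `"chain"` and an extra
#'   `type` column.
#' @export
chainCatalog <- function(chains, betaOxMinCarbons = 20,
                         enzymeLookup = .chainEnzymeLookup()) {
  cd <- do.call(rbind, strsplit(chains, ":", fixed = TRUE))
  obs <- data.frame(carbons = as.integer(cd[, 1]),
                    doubleBonds = as.integer(cd[, 2]),
                    label = chains, stringsAsFactors = FALSE)
  edges <- list()
  addEdge <- function(type, sub, prodC, prodD) {
    prod <- .chainLabel(prodC, prodD)
    if (!prod %in% obs$label) return()
    edges[[length(edges) + 1L]] <<- data.frame(
      reactant = sub, product = prod, type = type,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(obs))) {
    c0 <- obs$carbons[i]; d0 <- obs$doubleBonds[i]; l0 <- obs$label[i]
    addEdge("elongation", l0, c0 + 2L, d0)
    addEdge("desaturation", l0, c0, d0 + 1L)
    if (c0 >= betaOxMinCarbons) addEdge("betaOxidation", l0, c0 - 2L, d0)
  }
  e <- if (length(edges)) do.call(rbind, edges) else
    data.frame(reactant = character(), product = character(),
               type = character(), stringsAsFactors = FALSE)
  generic <- c(elongation = "elongase", desaturation = "desaturase",
               betaOxidation = "beta-oxidation")
  genericGene <- c(elongation = "ELOVL", desaturation = "FADS/SCD",
                   betaOxidation = "ACOX/HADH")
  e$enzyme <- unname(generic[e$type])
  e$gene <- unname(genericGene[e$type])
  m <- match(paste(e$type, e$reactant),
             paste(enzymeLookup$type, enzymeLookup$substrate))
  hit <- !is.na(m)
  e$enzyme[hit] <- enzymeLookup$enzyme[m[hit]]
  e$gene[hit] <- enzymeLookup$gene[m[hit]]
  ReactionCatalog(e[, c("reactant", "product", "enzyme", "gene", "type")],
                  scope = "chain")
}

#' Score the elongation/desaturation/beta-oxidation network
#'
#' Applies the product/reactant weight statistic ([scoreReactions()]) to a
#' chain abundance matrix over the catalog of transformations between
#' observed chains, and annotates each scored edge with its enzyme and
#' gene.
#'
#' @param chainAb chain x samples matrix from [chainAbundance()].
#' @param group per-sample group labels.
#' @param caseGroup case group label.
#' @param threshold significance threshold for calls.
#' @param catalog optional pre-built chain [ReactionCatalog-class];
#'   defaults to [chainCatalog()] on the observed chains.
#' @param ... passed to [scoreReactions()] (`logScale`, `test`).
#' @return annotated score `data.frame` (see [scoreReactions()]) with
#'   `type`, `enzyme`, `gene` columns.
#' @export
chainNetwork <- function(chainAb, group, caseGroup = "HOM",
                         threshold = 0.05, catalog = NULL, ...) {
  if (is.null(catalog)) catalog <- chainCatalog(rownames(chainAb))
  w <- computeReactionWeights(chainAb, catalog)
  s <- scoreReactions(w, group = group, caseGroup = caseGroup,
                      threshold = threshold, ...)
  annotateReactions(s, catalog)
}

#' Chain network within a single lipid class
#'
#' Restricts the chain abundance to species of one class and scores the
#' elongation/desaturation network inside it.
#'
#' @param x a [LipidomicsExperiment-class].
#' @param classCode lipid class code (e.g. `"PC"`, `"PE-O"`).
#' @param group per-sample group labels (from the object if omitted).
#' @param ... passed to [chainNetwork()].
#' @return annotated score `data.frame`; zero rows when the class exposes
#'   fewer than two distinct chains.
#' @export
chainNetworkWithinClass <- function(x, classCode, group = NULL, ...) {
  if (is.null(group)) group <- as.character(sampleGroups(x))
  ab <- chainAbundance(x, classCode = classCode)
  if (nrow(ab) < 2L)
    return(data.frame(edge = character(), reactant = character(),
                      product = character(), pValue = numeric(),
                      call = character(), stringsAsFactors = FALSE))
  chainNetwork(ab, group = group, ...)
}
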