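#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData assayNames
NULL

.err <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "lipidflowError")))
}

#' LipidSpecies: a parsed lipid shorthand name
#'
#' Structured representation of one lipid molecular species: its class code,
#' its acyl/sphingoid chains (carbons, double bonds, hydroxylation, ether
#' linkage), whether sn-positions are known (`/` separator) or not (`_`),
#' and the annotation level (`"molecular-species"`, `"sum-composition"` or
#' `"class-only"`).
#'
#' @slot rawName the name as read from input.
#' @slot classCode short class symbol from [lipidClassRegistry()].
#' @slot chains `data.frame` with one row per chain and columns `carbons`,
#'   `doubleBonds`, `oxidation`, `etherLinked`.
#' @slot snPositionsKnown `TRUE` when chains were `/`-separated.
#' @slot annotationLevel one of `"molecular-species"`, `"sum-composition"`,
#'   `"class-only"`.
#' @seealso [parseLipidName()], [formatLipidName()], [buildingBlocks()]
#' @export
setClass("LipidSpecies",
  representation(rawName = "character", classCode = "character",
                 chains = "data.frame", snPositionsKnown = "logical",
                 annotationLevel = "character"))

setValidity("LipidSpecies", function(object) {
  ch <- object@chains
  msg <- character()
  need <- c("carbons", "doubleBonds", "oxidation", "etherLinked")
  if (!all(need %in% names(ch)))
    msg <- c(msg, "chains must have carbons/doubleBonds/oxidation/etherLinked")
  else if (nrow(ch)) {
    if (any(ch$carbons < 1)) msg <- c(msg, "chain carbons must be >= 1")
    if (any(ch$doubleBonds < 0)) msg <- c(msg, "doubleBonds must be >= 0")
    if (any(ch$doubleBonds > ch$carbons / 2))
      msg <- c(msg, "doubleBonds cannot exceed carbons/2")
  }
  if (!object@annotationLevel %in%
      c("molecular-species", "sum-composition", "class-only"))
    msg <- c(msg, "invalid annotationLevel")
  if (length(msg)) msg else TRUE
})

setMethod("show", "LipidSpecies", function(object) {
  cat("LipidSpecies:", formatLipidName(object), "\n")
  cat("  class:", object@classCode,
      "| level:", object@annotationLevel,
      "| sn known:", object@snPositionsKnown, "\n")
  if (nrow(object@chains)) {
    lab <- paste0(ifelse(object@chains$etherLinked, "O-", ""),
                  object@chains$carbons, ":", object@chains$doubleBonds,
                  ifelse(object@chains$oxidation > 0,
                         paste0(";O", ifelse(object@chains$oxidation > 1,
                                             object@chains$oxidation, "")),
                         ""))
    cat("  chains:", paste(lab, collapse = ", "), "\n")
  }
})

#' LipidomicsExperiment: species-by-sample concentrations with metadata
#'
#' A [SummarizedExperiment::SummarizedExperiment] carrying one assay,
#' `"concentration"` (ug lipid / ug protein), whose rows are lipid molecular
#' species and columns are samples. Row metadata holds the parsed
#' nomenclature (class code, annotation level, chain list); column metadata
#' holds the sample group (e.g. WT/HOM), tissue and protein amount.
#'
#' Construct with [LipidomicsExperiment()]; access with [concentrations()],
#' [sampleGroups()], [lipidClasses()].
#' @export
setClass("LipidomicsExperiment", contains = "SummarizedExperiment")

setValidity("LipidomicsExperiment", function(object) {
  msg <- character()
  if (!"concentration" %in% assayNames(object))
    msg <- c(msg, "assay 'concentration' is required")
  else {
    a <- assay(object, "concentration")
    if (any(a < 0, na.rm = TRUE)) msg <- c(msg, "concentrations must be >= 0")
  }
  if (!"group" %in% names(colData(object)))
    msg <- c(msg, "colData must contain 'group'")
  if (!"classCode" %in% names(rowData(object)))
    msg <- c(msg, "rowData must contain 'classCode'")
  if (length(msg)) msg else TRUE
})

#' Construct a LipidomicsExperiment
#'
#' @param concentration numeric species x samples matrix (ug/ug protein),
#'   rownames are shorthand species names, colnames sample IDs.
#' @param sampleData `data.frame` with one row per sample; must contain
#'   `group`; typically also `tissue`, `proteinAmount` (ug) and
#'   `extractVolume` (mL). Matched to columns by `sampleID` column or
#'   rownames.
#' @param registry class registry, see [lipidClassRegistry()].
#' @param provenance `"semi-quantified"` or `"supplied"`.
#' @return A [LipidomicsExperiment-class] object.
#' @examples
#' m <- matrix(c(1, 2, 3, 4), 2, 2,
#'             dimnames = list(c("PC 16:0_18:1", "PE 18:0_20:4"),
#'                             c("s1", "s2")))
#' md <- data.frame(sampleID = c("s1", "s2"), group = c("WT", "HOM"))
#' LipidomicsExperiment(m, md)
#' @export
LipidomicsExperiment <- function(concentration, sampleData,
                                 registry = lipidClassRegistry(),
                                 provenance = c("supplied",
                                                "semi-quantified")) {
  provenance <- match.arg(provenance)
  concentration <- as.matrix(concentration)
  if (is.null(rownames(concentration)))
    stop("concentration matrix needs species rownames")
  if ("sampleID" %in% names(sampleData))
    rownames(sampleData) <- sampleData$sampleID
  if (is.null(colnames(concentration)))
    colnames(concentration) <- rownames(sampleData)
  sampleData <- sampleData[colnames(concentration), , drop = FALSE]
  if (anyNA(sampleData$group))
    .err("sample metadata does not cover all samples",
         "lipidflow_metadata_mismatch")
  parsed <- parseLipidNames(rownames(concentration), registry = registry)
  se <- SummarizedExperiment(
    assays = SimpleList(concentration = concentration),
    rowData = parsed,
    colData = DataFrame(sampleData))
  obj <- new("LipidomicsExperiment", se)
  S4Vectors::metadata(obj) <- list(provenance = provenance,
                                   units = "ug lipid / ug protein")
  obj
}

setMethod("show", "LipidomicsExperiment", function(object) {
  cat("LipidomicsExperiment with", nrow(object), "lipid species and",
      ncol(object), "samples\n")
  cat("  classes:", paste(sort(unique(rowData(object)$classCode)),
                          collapse = " "), "\n")
  if ("group" %in% names(colData(object))) {
    tb <- table(colData(object)$group)
    cat("  groups:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
  }
  cat("  units:", S4Vectors::metadata(object)$units, "\n")
})

#' ReactionCatalog: directed reactant-to-product transformations
#'
#' A catalog of catalogued biochemical transformations, either between lipid
#' classes (scope `"class"`) or between fatty-acyl building blocks (scope
#' `"chain"`), each annotated with the enzyme name and coding gene symbol(s).
#'
#' @slot edges `data.frame` with columns `reactant`, `product`, `enzyme`,
#'   `gene` and (chain scope) `type`.
#' @slot scope `"class"` or `"chain"`.
#' @seealso [defaultClassCatalog()], [chainCatalog()]
#' @export
setClass("ReactionCatalog",
  representation(edges = "data.frame", scope = "character"))

setValidity("ReactionCatalog", function(object) {
  e <- object@edges
  msg <- character()
  if (!all(c("reactant", "product", "enzyme", "gene") %in% names(e)))
    msg <- c(msg, "edges need reactant/product/enzyme/gene columns")
  else if (nrow(e) && any(e$reactant == e$product))
    msg <- c(msg, "reactant must differ from product")
  if (!object@scope %in% c("class", "chain"))
    msg <- c(msg, "scope must be 'class' or 'chain'")
  if (length(msg)) msg else TRUE
})

#' @describeIn ReactionCatalog-class number of edges
#' @param x a `ReactionCatalog`
#' @export
setMethod("length", "ReactionCatalog", function(x) nrow(x@edges))

#' Edge table of a ReactionCatalog
#' @param catalog a [ReactionCatalog-class]
#' @return `data.frame` of edges.
#' @export
catalogEdges <- function(catalog) catalog@edges

setMethod("show", "ReactionCatalog", function(object) {
  cat("ReactionCatalog (", object@scope, "-level): ", nrow(object@edges),
      " edges\n", sep = "")
  if (nrow(object@edges))
    cat(" ", paste(utils::head(paste0(object@edges$reactant, "->",
                                      object@edges$product), 12),
                   collapse = " "), if (nrow(object@edges) > 12) "...", "\n")
})

ReactionCatalog <- function(edges, scope = "class") {
  new("ReactionCatalog", edges = as.data.frame(edges), scope = scope)
}
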