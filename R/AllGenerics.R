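#' @rdname concentrations
#' @export
setGeneric("concentrations", function(x) standardGeneric("concentrations"))

#' @rdname sampleGroups
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname lipidClasses
#' @export
setGeneric("lipidClasses", function(x) standardGeneric("lipidClasses"))

#' @rdname classTotals
#' @export
setGeneric("classTotals", function(x, ...) standardGeneric("classTotals"))

#' @rdname chainAbundance
#' @export
setGeneric("chainAbundance",
           function(x, ...) standardGeneric("chainAbundance"))

#' Concentration matrix of a LipidomicsExperiment
#'
#' @param x a [LipidomicsExperiment-class]
#' @return numeric species x samples matrix, ug lipid / ug protein.
#' @export
setMethod("concentrations", "LipidomicsExperiment",
          function(x) assay(x, "concentration"))

#' Sample group labels
#'
#' @param x a [LipidomicsExperiment-class]
#' @return factor of per-sample group labels (e.g. WT/HOM).
#' @export
setMethod("sampleGroups", "LipidomicsExperiment",
          function(x) factor(colData(x)$group))

#' Lipid class code of every species row
#'
#' @param x a [LipidomicsExperiment-class]
#' @return character vector of class codes, one per row.
#' @export
setMethod("lipidClasses", "LipidomicsExperiment",
          function(x) rowData(x)$classCode)
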