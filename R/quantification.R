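# Internal-standard semi-quantification:
#   conc(i, s) = area(i, s) / area(IS_class(i), s)
#               * spike(class(i)) * extractVolume(s) / proteinAmount(s)
# with the class-matched deuterated standard as denominator. Ratios make the
# result invariant to per-sample global intensity scaling.

.checkMeta <- function(meta, samples) {
  if ("sampleID" %in% names(meta)) rownames(meta) <- meta$sampleID
  missing <- setdiff(samples, rownames(meta))
  if (length(missing))
    .err(paste("no metadata for samples:", paste(missing, collapse = ", ")),
         "lipidflow_metadata_mismatch")
  meta <- meta[samples, , drop = FALSE]
  if (is.null(meta$proteinAmount) || any(meta$proteinAmount <= 0))
    .err("proteinAmount must be present and > 0", "lipidflow_bad_metadata")
  if (is.null(meta$extractVolume)) meta$extractVolume <- 1
  meta
}

#' Semi-quantify a peak-area feature table against internal standards
#'
#' Converts peak areas to concentrations using the class-matched deuterated
#' internal standard: analyte area divided by the IS area in the same
#' sample, multiplied by the IS in-extract concentration, the extract
#' volume, and divided by the protein amount of the sample. IS rows are
#' excluded from the output.
#'
#' @param areas species x samples matrix of non-negative peak areas; IS rows
#'   are identified by the names in `isMap$isName`.
#' @param isMap internal-standard map, see [defaultISMap()].
#' @param sampleData sample metadata with `sampleID`, `group`,
#'   `proteinAmount` (ug) and optionally `extractVolume` (mL, default 1).
#' @param registry class registry used to parse species names.
#' @return A [LipidomicsExperiment-class] with assay `"concentration"`
#'   in ug lipid / ug protein.
#' @examples
#' ft <- matrix(c(50, 100), 2, 1,
#'              dimnames = list(c("PC 16:0_18:1", "IS PC 15:0_18:1(d7)"),
#'                              "s1"))
#' md <- data.frame(sampleID = "s1", group = "WT", proteinAmount = 100,
#'                  extractVolume = 1)
#' concentrations(semiQuantify(ft, defaultISMap(), md))  # 0.5 ug/ug
#' @export
semiQuantify <- function(areas, isMap = defaultISMap(), sampleData,
                         registry = lipidClassRegistry()) {
  areas <- as.matrix(areas)
  if (any(areas < 0)) .err("peak areas must be >= 0", "lipidflow_bad_areas")
  meta <- .checkMeta(sampleData, colnames(areas))
  isRows <- rownames(areas) %in% isMap$isName
  analytes <- rownames(areas)[!isRows & !rownames(areas) %in%
                                c("PSY-d5")]
  parsed <- parseLipidNames(analytes, registry = registry)
  cls <- parsed$classCode
  # PSY is quantified by the targeted route (quantifyPsy), in its own units
  analytes <- analytes[cls != "PSY"]
  cls <- cls[cls != "PSY"]
  idx <- match(cls, isMap$classCode)
  if (anyNA(idx))
    .err(paste("no internal standard mapped for class:",
               paste(unique(cls[is.na(idx)]), collapse = ", ")),
         "lipidflow_missing_is")
  isArea <- areas[isMap$isName[idx], colnames(areas), drop = FALSE]
  badIS <- unique(isMap$isName[idx])[!unique(isMap$isName[idx]) %in%
                                       rownames(areas)]
  if (length(badIS))
    .err(paste("internal standard rows absent from table:",
               paste(badIS, collapse = ", ")), "lipidflow_missing_is")
  zeroIS <- colnames(areas)[apply(isArea == 0, 2, any)]
  if (length(zeroIS))
    .err(paste("zero internal-standard area invalidates sample(s):",
               paste(zeroIS, collapse = ", ")), "lipidflow_zero_is_area")
  conc <- areas[analytes, , drop = FALSE] / isArea
  conc <- conc * isMap$spike[idx] * isMap$responseFactor[idx]
  conc <- sweep(conc, 2, meta$extractVolume / meta$proteinAmount, `*`)
  LipidomicsExperiment(conc, meta, registry = registry,
                       provenance = "semi-quantified")
}

#' Quantify psychosine against its deuterated standard
#'
#' Targeted quantification of psychosine (PSY) using the PSY-d5 internal
#' standard spiked at a known concentration (default 125 ng/mL in extract):
#' PSY area / PSY-d5 area x spike x extract volume / protein amount.
#'
#' @param areas feature table containing rows `psyName` and `psyISName`.
#' @param sampleData sample metadata as in [semiQuantify()].
#' @param spike PSY-d5 in-extract concentration, ng/mL.
#' @param psyName,psyISName row names of the analyte and standard.
#' @return named numeric vector of per-sample PSY concentrations,
#'   ng PSY / ug protein (attribute `units`).
#' @examples
#' ft <- matrix(c(200, 100), 2, 1,
#'              dimnames = list(c("PSY 18:1;O2", "PSY-d5"), "s1"))
#' md <- data.frame(sampleID = "s1", group = "HOM", proteinAmount = 125,
#'                  extractVolume = 1)
#' quantifyPsy(ft, md)  # 2 ng/ug
#' @export
quantifyPsy <- function(areas, sampleData, spike = 125,
                        psyName = grep("^PSY(?! ?-? ?d5)", rownames(areas),
                                       perl = TRUE, value = TRUE),
                        psyISName = "PSY-d5") {
  areas <- as.matrix(areas)
  if (length(psyName) != 1L || !psyName %in% rownames(areas))
    .err("PSY row not found (or ambiguous) in feature table",
         "lipidflow_missing_is")
  if (!psyISName %in% rownames(areas))
    .err("PSY-d5 row not found in feature table", "lipidflow_missing_is")
  meta <- .checkMeta(sampleData, colnames(areas))
  isArea <- areas[psyISName, ]
  if (any(isArea == 0))
    .err(paste("zero PSY-d5 area invalidates sample(s):",
               paste(colnames(areas)[isArea == 0], collapse = ", ")),
         "lipidflow_zero_is_area")
  psy <- areas[psyName, ] / isArea * spike *
    meta$extractVolume / meta$proteinAmount
  structure(psy, units = "ng PSY / ug protein")
}

#' Handle missing or absent values in a concentration matrix
#'
#' Deterministic strategies for zeros/NAs: `"none"` passes the matrix
#' through; `"half-min"` replaces missing cells of a species with half its
#' smallest positive value; `"presence-filter"` drops species observed in
#' fewer than `presenceThreshold` of samples. Imputed cells are reported via
#' a message and the `"imputed"` attribute.
#'
#' @param x a [LipidomicsExperiment-class] or numeric matrix.
#' @param strategy one of `"none"`, `"half-min"`, `"presence-filter"`.
#' @param presenceThreshold minimum fraction of samples with a positive
#'   value (presence-filter strategy).
#' @return object of the same type as `x`.
#' @export
handleMissing <- function(x, strategy = c("none", "half-min",
                                          "presence-filter"),
                          presenceThreshold = 0.5) {
  strategy <- match.arg(strategy)
  mat <- if (is(x, "LipidomicsExperiment")) concentrations(x) else as.matrix(x)
  missing <- is.na(mat) | mat == 0
  if (strategy == "none") return(x)
  if (strategy == "half-min") {
    nImputed <- 0L
    for (i in which(rowSums(missing) > 0)) {
      pos <- mat[i, !missing[i, ]]
      if (!length(pos))
        .err(paste("species with no observed value:", rownames(mat)[i]),
             "lipidflow_all_missing")
      mat[i, missing[i, ]] <- min(pos) / 2
      nImputed <- nImputed + sum(missing[i, ])
    }
    message(nImputed, " cells imputed at half species minimum")
    out <- mat
  } else {
    keep <- rowMeans(!missing) >= presenceThreshold
    message(sum(!keep), " species dropped below presence threshold ",
            presenceThreshold)
    out <- mat[keep, , drop = FALSE]
  }
  if (is(x, "LipidomicsExperiment")) {
    meta <- as.data.frame(colData(x))
    LipidomicsExperiment(out, meta,
                         provenance = S4Vectors::metadata(x)$provenance)
  } else out
}
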