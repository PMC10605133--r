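# File I/O in the dialects the pipeline documents (CSV/TSV, header row,
# species names in the first column, UTF-8, decimal point) and an
# end-to-end orchestrator driven by a single config with one seed.

.readDelim <- function(path) {
  sepGuess <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE))
    "\t" else ","
  utils::read.table(path, header = TRUE, sep = sepGuess, quote = "\"",
                    check.names = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Read a peak-area or concentration feature table
#'
#' First column: species shorthand names; remaining columns: samples.
#' Duplicate species names or duplicate sample columns are errors.
#'
#' @param path CSV (or `.tsv`/`.txt` tab-separated) file.
#' @return numeric species x samples matrix.
#' @export
readFeatureTable <- function(path) {
  df <- .readDelim(path)
  if (ncol(df) < 2L)
    .err(paste("no sample columns in", path), "lipidflow_parse_error")
  if (anyDuplicated(df[[1]]))
    .err(paste("duplicate species names in", path,  ":",
               paste(unique(df[[1]][duplicated(df[[1]])]), collapse = ", ")),
         "lipidflow_duplicate_species")
  if (anyDuplicated(colnames(df)[-1]))
    .err(paste("duplicate sample columns in", path),
         "lipidflow_duplicate_sample")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m))
    .err(paste("non-numeric cells in", path), "lipidflow_parse_error")
  rownames(m) <- df[[1]]
  m
}

#' Read sample metadata
#'
#' Requires columns `sampleID` and `group`; `tissue`, `proteinAmount`,
#' `extractVolume` are used when present.
#'
#' @param path CSV/TSV file.
#' @return `data.frame` with rownames set to `sampleID`.
#' @export
readSampleMetadata <- function(path) {
  df <- .readDelim(path)
  if (!all(c("sampleID", "group") %in% names(df)))
    .err("metadata needs sampleID and group columns",
         "lipidflow_parse_error")
  if (anyDuplicated(df$sampleID))
    .err("duplicate sampleID in metadata", "lipidflow_duplicate_sample")
  rownames(df) <- df$sampleID
  df
}

#' Read an internal-standard map (YAML, JSON or CSV)
#'
#' Expects fields/columns `classCode`, `isName`, `spike` (and optionally
#' `unit`, `responseFactor`).
#'
#' @param path `.yaml`/`.yml`, `.json` or `.csv` file.
#' @return `data.frame` in [defaultISMap()] layout.
#' @export
readISMap <- function(path) {
  df <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    do.call(rbind.data.frame, yaml::read_yaml(path))
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path)
  else .readDelim(path)
  if (!all(c("classCode", "isName", "spike") %in% names(df)))
    .err("IS map needs classCode, isName, spike", "lipidflow_parse_error")
  if (is.null(df$unit)) df$unit <- "ug/mL"
  if (is.null(df$responseFactor)) df$responseFactor <- 1
  df
}

#' Read a reaction catalog from CSV/TSV
#'
#' Columns `reactant`, `product`, `enzyme`, `gene` (and `type` for chain
#' catalogs).
#'
#' @param path CSV/TSV file.
#' @param scope `"class"` or `"chain"`.
#' @return A [ReactionCatalog-class].
#' @export
readReactionCatalog <- function(path, scope = c("class", "chain")) {
  ReactionCatalog(.readDelim(path), scope = match.arg(scope))
}

#' Write a concentration matrix with a units header
#'
#' @param x [LipidomicsExperiment-class] or matrix.
#' @param path output CSV path (a `# units:` comment line precedes the
#'   header).
#' @param units units string for the header line.
#' @export
writeConcentrationMatrix <- function(x, path,
                                     units = "ug lipid / ug protein") {
  mat <- if (is(x, "LipidomicsExperiment")) concentrations(x) else
    as.matrix(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# units:", units), con)
  df <- data.frame(species = rownames(mat),
                   signif(mat, 12), check.names = FALSE)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
}

.writeCSV <- function(df, path) {
  num <- vapply(df, is.numeric, NA)
  df[num] <- lapply(df[num], signif, digits = 12)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end: obtain concentrations (reading a
#' feature table + metadata + IS map, or simulating from a design),
#' class-profile statistics, multivariate analysis (median normalization,
#' Pareto scaling, PCA, heatmap selection), class reaction network, chain
#' profiles and networks, and psychosine correlation. Every stage writes
#' CSV outputs under `outDir` and is recorded in a machine-readable run
#' report.
#'
#' @param config named list (or path to a YAML/JSON file) with entries:
#'   `featureTable`, `sampleMetadata`, `isMap` (paths; omit all three to
#'   simulate), `tissue`, `seed`, `caseGroup`, `threshold`, `highlight`,
#'   `heatmapK`, `scaling`, `correlationMethod`, `stages` (character
#'   vector subset of `c("profile", "multivariate", "network", "chains",
#'   "correlation")`), `outDir`.
#' @return the run report (named list), invisibly; also written as
#'   `report.json` in `outDir`.
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) jsonlite::fromJSON(config)
    else yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(list(
    tissue = "SN", seed = 1L, speciesPerClass = 12, caseGroup = "HOM",
    threshold = 0.05,
    highlight = 0.02, heatmapK = 50, scaling = "pareto",
    correlationMethod = "pearson",
    stages = c("profile", "multivariate", "network", "chains",
               "correlation"),
    outDir = "lipidflow-out"), config)
  stopifnot(cfg$threshold > 0, cfg$threshold < 1)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  report <- list(package = "lipidflow",
                 version = as.character(utils::packageVersion("lipidflow")),
                 seed = cfg$seed,
                 parameters = cfg[c("tissue", "caseGroup", "threshold",
                                    "highlight", "heatmapK", "scaling",
                                    "correlationMethod")],
                 stages = list())
  set.seed(cfg$seed)

  # --- quantify (or simulate) ------------------------------------------
  if (!is.null(cfg$featureTable)) {
    areas <- readFeatureTable(cfg$featureTable)
    meta <- readSampleMetadata(cfg$sampleMetadata)
    ismap <- if (is.null(cfg$isMap)) defaultISMap() else readISMap(cfg$isMap)
    le <- semiQuantify(areas, ismap, meta)
    psy <- tryCatch(quantifyPsy(areas, meta,
                                spike = ismap$spike[ismap$classCode ==
                                                      "PSY"]),
                    lipidflowError = function(e) NULL)
  } else {
    design <- syntheticDesign(cfg$tissue, seed = cfg$seed,
                              speciesPerClass = cfg$speciesPerClass)
    ft <- generateFeatureTable(design)
    le <- semiQuantify(ft$areas, defaultISMap(), ft$sampleData)
    psy <- quantifyPsy(ft$areas, ft$sampleData)
  }
  writeConcentrationMatrix(le, file.path(cfg$outDir, "concentrations.csv"))
  group <- as.character(sampleGroups(le))
  report$stages$quantify <- list(species = nrow(le), samples = ncol(le),
                                 classes = length(unique(lipidClasses(le))))

  totals <- classTotals(le)
  if ("profile" %in% cfg$stages) {
    cmp <- compareGroups(totals, group, caseGroup = cfg$caseGroup)
    cmp$grandTotalCase <- sum(cmp$meanCase)
    cmp$grandTotalControl <- sum(cmp$meanControl)
    .writeCSV(cmp, file.path(cfg$outDir, "class_profile.csv"))
    spp <- compareGroups(le, caseGroup = cfg$caseGroup)
    .writeCSV(spp, file.path(cfg$outDir, "species_profile.csv"))
    report$stages$profile <- list(classes = nrow(cmp),
                                  significant = sum(cmp$stars != ""))
  }
  if ("multivariate" %in% cfg$stages) {
    norm <- normalizeMedian(le)
    scl <- scaleFeatures(norm, cfg$scaling)
    pca <- lipidPCA(scl)
    .writeCSV(data.frame(sampleID = rownames(pca$scores), pca$scores,
                         group = group),
              file.path(cfg$outDir, "pca_scores.csv"))
    .writeCSV(data.frame(item = rownames(pca$loadings), pca$loadings),
              file.path(cfg$outDir, "pca_loadings.csv"))
    .writeCSV(data.frame(component = seq_along(pca$explainedVariance),
                         explainedVariance = pca$explainedVariance),
              file.path(cfg$outDir, "pca_explained.csv"))
    hm <- heatmapSelectCluster(le, group, k = cfg$heatmapK,
                               caseGroup = cfg$caseGroup)
    .writeCSV(data.frame(item = hm$items, hm$values, check.names = FALSE),
              file.path(cfg$outDir, "heatmap_matrix.csv"))
    .writeCSV(data.frame(rowOrder = hm$rowOrder,
                         item = hm$items[hm$rowOrder]),
              file.path(cfg$outDir, "heatmap_row_order.csv"))
    report$stages$multivariate <- list(
      pc1ExplainedPct = round(100 * pca$explainedVariance[1], 1),
      heatmapItems = length(hm$items))
  }
  if ("network" %in% cfg$stages) {
    cat <- defaultClassCatalog()
    w <- suppressWarnings(computeReactionWeights(totals, cat))
    sc <- annotateReactions(
      scoreReactions(w, group, caseGroup = cfg$caseGroup,
                     threshold = cfg$threshold), cat)
    sc$highlighted <- !is.na(sc$pValue) & sc$pValue < cfg$highlight
    .writeCSV(sc, file.path(cfg$outDir, "class_network.csv"))
    exportReactionGraph(sc, file.path(cfg$outDir, "class_network.graphml"))
    report$stages$network <- list(edges = nrow(sc),
                                  called = sum(sc$call != "unchanged"))
  }
  if ("chains" %in% cfg$stages) {
    ab <- chainAbundance(le)
    for (ax in c("length", "unsaturation"))
      .writeCSV(chainProfiles(ab, group, ax, caseGroup = cfg$caseGroup),
                file.path(cfg$outDir, paste0("chain_", ax, ".csv")))
    cn <- chainNetwork(ab, group, caseGroup = cfg$caseGroup,
                       threshold = cfg$threshold)
    .writeCSV(cn, file.path(cfg$outDir, "chain_network.csv"))
    report$stages$chains <- list(chains = nrow(ab), edges = nrow(cn),
                                 called = sum(cn$call != "unchanged"))
  }
  if ("correlation" %in% cfg$stages && !is.null(psy)) {
    cor <- psyClassCorrelation(psy, totals,
                               method = cfg$correlationMethod)
    .writeCSV(cor, file.path(cfg$outDir, "psy_correlation.csv"))
    report$stages$correlation <- list(
      classes = nrow(cor),
      negative = sum(cor$label == "negative"),
      positive = sum(cor$label == "positive"))
  }
  jsonlite::write_json(report, file.path(cfg$outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
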