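# Synthetic two-group lipidomics data with planted ground truth. Class
# baselines and HOM/WT effect ratios default to the published per-tissue
# class means; species within a class share the class baseline through a
# Dirichlet split; sample noise is log-normal with a CV parameter,
# mean-corrected so expected class totals hit the design targets. The
# chain pool concentrates sampling weight on 16- and 18-carbon chains with
# 0-1 double bonds, matching the dominant building blocks of nervous
# tissue.

#' Default fatty-acyl chain pool
#'
#' Chains available to the generator with their sampling weights. Weight is
#' concentrated on C16/C18 chains with zero or one double bond; longer and
#' polyunsaturated chains (through 24:6) are present at low weight so that
#' elongation/desaturation/beta-oxidation edges are observable.
#'
#' @return `data.frame` with `carbons`, `doubleBonds`, `weight`.
#' @export
defaultChainPool <- function() {
  data.frame(
    carbons     = c(14, 16, 16, 18, 18, 18, 18, 20, 20, 20, 20, 22, 22,
                    22, 22, 22, 24, 24, 24),
    doubleBonds = c(0, 0, 1, 0, 1, 2, 3, 0, 1, 3, 4, 0, 1, 2, 3, 6, 0,
                    1, 6),
    weight      = c(0.02, 0.18, 0.08, 0.13, 0.20, 0.07, 0.02, 0.03, 0.03,
                    0.02, 0.04, 0.03, 0.02, 0.015, 0.015, 0.03, 0.02,
                    0.02, 0.01),
    stringsAsFactors = FALSE)
}

.psyDefaults <- data.frame(
  tissue = c("B", "C", "SC", "SN"),
  psyWT = c(0.02, 0.02, 0.05, 0.08),   # ng/ug protein, package choice
  psyRatio = c(8, 10, 22, 27),          # HOM/WT; SC and SN as published
  stringsAsFactors = FALSE)

#' Design of a synthetic two-group lipidomics study
#'
#' Captures everything the generator needs: per-class WT baselines and
#' HOM/WT effect ratios (defaulting to the published per-tissue class
#' means, or to a null design with all ratios 1), species counts, the
#' chain pool, the log-normal noise level, group sizes and the seed.
#'
#' @param tissue tissue template: `"B"`, `"C"`, `"SC"` or `"SN"` (default).
#' @param effects `"reference"` uses the published HOM/WT ratios per class;
#'   `"null"` sets every class ratio to 1 (no planted effects).
#' @param speciesPerClass species generated per class (default 12, landing
#'   the total species count in the published 219-246 range).
#' @param nWT,nHOM group sizes (defaults 5 and 4).
#' @param cv coefficient of variation of the log-normal sample noise
#'   (default 0.2).
#' @param psyWT,psyRatio WT psychosine level (ng/ug) and HOM/WT ratio;
#'   defaults per tissue (SC ~22, SN ~27).
#' @param chainPool chain pool `data.frame`, see [defaultChainPool()].
#' @param seed integer seed driving all generator randomness.
#' @return list of class `"syntheticDesign"`.
#' @examples
#' d <- syntheticDesign("SN", seed = 7)
#' round(d$classBaselines[1:4], 3)
#' @export
syntheticDesign <- function(tissue = "SN",
                            effects = c("reference", "null"),
                            speciesPerClass = 12, nWT = 5, nHOM = 4,
                            cv = 0.2, psyWT = NULL, psyRatio = NULL,
                            chainPool = defaultChainPool(), seed = 1L) {
  tissue <- match.arg(tissue, c("B", "C", "SC", "SN"))
  effects <- match.arg(effects)
  ref <- referenceClassMeans(tissue)
  baselines <- stats::setNames(ref$meanWT, ref$classCode)
  ratios <- if (effects == "reference")
    stats::setNames(ref$meanHOM / ref$meanWT, ref$classCode)
  else stats::setNames(rep(1, nrow(ref)), ref$classCode)
  if (any(baselines <= 0) || any(ratios <= 0))
    .err("baselines and ratios must be positive", "lipidflow_bad_design")
  pd <- .psyDefaults[.psyDefaults$tissue == tissue, ]
  structure(list(
    tissue = tissue, effects = effects,
    classBaselines = baselines, classEffectRatios = ratios,
    speciesPerClass = speciesPerClass, nWT = nWT, nHOM = nHOM, cv = cv,
    psyWT = if (is.null(psyWT)) pd$psyWT else psyWT,
    psyRatio = if (is.null(psyRatio)) pd$psyRatio else psyRatio,
    chainPool = chainPool,
    plantedClassEdges = data.frame(reactant = character(),
                                   product = character(),
                                   fold = numeric(),
                                   stringsAsFactors = FALSE),
    plantedChainEffects = data.frame(substrate = character(),
                                     product = character(),
                                     fold = numeric(),
                                     stringsAsFactors = FALSE),
    seed = as.integer(seed)), class = "syntheticDesign")
}

#' Plant a class-level reaction effect in a design
#'
#' Scales the product class of a catalogued transformation by `fold` in
#' the case (HOM) group and records the planted edge in the ground truth.
#' A fold of 1 leaves the design unchanged (but still records nothing).
#'
#' @param design a [syntheticDesign()].
#' @param reactant,product lipid class codes of the edge.
#' @param fold case-group fold change applied to the product class.
#' @return the modified design.
#' @examples
#' d <- plantReactionEffect(syntheticDesign("SN", effects = "null"),
#'                          "PA", "PG", 3)
#' @export
plantReactionEffect <- function(design, reactant, product, fold) {
  stopifnot(inherits(design, "syntheticDesign"))
  if (!reactant %in% names(design$classBaselines) ||
      !product %in% names(design$classBaselines))
    .err(paste("edge classes not in design:", reactant, "->", product),
         "lipidflow_unknown_edge")
  if (fold != 1) {
    design$classEffectRatios[product] <-
      design$classEffectRatios[product] * fold
    design$plantedClassEdges <- rbind(
      design$plantedClassEdges,
      data.frame(reactant = reactant, product = product, fold = fold,
                 stringsAsFactors = FALSE))
  }
  design
}

#' Plant a chain-level (building-block) effect in a design
#'
#' Plants a case-group fold change on one building-block pool. The
#' generator realizes it through *pure carrier* species — species whose
#' fatty-acyl chains all equal the product chain (e.g. `CE 18:2`,
#' `PA 18:2_18:2` for 18:2) — scaled by a compensating factor so that the
#' product chain's total abundance is multiplied by exactly `fold` while
#' every other chain pool is left untouched (species mixing the product
#' chain with other chains are not scaled, so there is no spillover into
#' co-occurring pools). The generator guarantees at least one single-chain
#' carrier species exists for each planted product chain.
#'
#' @param design a [syntheticDesign()].
#' @param substrate,product chain labels (`"18:1"`, `"18:2"`).
#' @param fold case-group fold change for the product chain pool.
#' @return the modified design.
#' @export
plantChainEffect <- function(design, substrate, product, fold) {
  stopifnot(inherits(design, "syntheticDesign"))
  poolLabels <- .chainLabel(design$chainPool$carbons,
                            design$chainPool$doubleBonds)
  if (!substrate %in% poolLabels || !product %in% poolLabels)
    .err(paste("edge chains not in pool:", substrate, "->", product),
         "lipidflow_unknown_edge")
  if (fold != 1)
    design$plantedChainEffects <- rbind(
      design$plantedChainEffects,
      data.frame(substrate = substrate, product = product, fold = fold,
                 stringsAsFactors = FALSE))
  design
}

# sample `n` distinct chain index combinations of size `size` from the pool
.sampleChainSets <- function(pool, n, size) {
  labels <- .chainLabel(pool$carbons, pool$doubleBonds)
  seen <- character()
  out <- list()
  tries <- 0L
  while (length(out) < n && tries < n * 60L) {
    tries <- tries + 1L
    idx <- sample.int(nrow(pool), size, replace = (size > 2L),
                      prob = pool$weight)
    idx <- idx[order(pool$carbons[idx], pool$doubleBonds[idx])]
    key <- paste(labels[idx], collapse = "_")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- idx
  }
  out
}

.speciesNamesForClass <- function(cls, n, pool, registry) {
  reg <- registry[registry$code == cls, ]
  labels <- .chainLabel(pool$carbons, pool$doubleBonds)
  if (cls %in% .sphingoidClasses) {
    # fixed 18:1;O2 long-chain base plus one N-acyl chain
    sets <- .sampleChainSets(pool, min(n, nrow(pool)), 1L)
    base <- sub("-O$", "", cls)
    return(vapply(sets, function(i)
      paste0(base, " 18:1;O2/", labels[i]), ""))
  }
  k <- reg$expectedChainCount
  maxN <- if (k == 1L) nrow(pool) else n
  sets <- .sampleChainSets(pool, min(n, maxN), k)
  ether <- grepl("-O$", cls)
  base <- sub("-O$", "", cls)
  vapply(sets, function(idx) {
    toks <- labels[idx]
    if (ether) toks[1] <- paste0("O-", toks[1])
    paste(base, paste(toks, collapse = "_"))
  }, "")
}

#' Generate a synthetic concentration matrix with ground truth
#'
#' Draws valid shorthand species names per class from the chain pool,
#' splits each class baseline across its species with a Dirichlet weight
#' vector, applies the class effect ratios (and any planted class or chain
#' effects) to the case group, and adds mean-corrected log-normal sample
#' noise so that expected class totals equal the design targets. Also
#' draws per-sample psychosine levels from the design's PSY model.
#'
#' @param design a [syntheticDesign()].
#' @param seed overrides `design$seed`.
#' @return list with `experiment` (a [LipidomicsExperiment-class]),
#'   `sampleData`, `psy` (true per-sample psychosine, ng/ug), and `truth`
#'   (species means per group, class baselines/ratios, planted edges,
#'   seed).
#' @export
generateConcentrations <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "syntheticDesign"))
  set.seed(seed)
  registry <- lipidClassRegistry()
  pool <- design$chainPool
  nWT <- design$nWT; nHOM <- design$nHOM
  samples <- c(paste0("WT", seq_len(nWT)), paste0("HOM", seq_len(nHOM)))
  group <- rep(c("WT", "HOM"), c(nWT, nHOM))
  classes <- names(design$classBaselines)
  allNames <- character(); allClass <- character()
  meansWT <- numeric(); meansHOM <- numeric()
  for (cls in classes) {
    nm <- .speciesNamesForClass(cls, design$speciesPerClass, pool,
                                registry)
    # planted chain effects need a pure carrier: force one CE species per
    # planted product chain (single-chain class, so no other pool touched)
    if (nrow(design$plantedChainEffects) && cls == "CE") {
      slot <- length(nm)
      for (prod in unique(design$plantedChainEffects$product)) {
        target <- paste("CE", prod)
        if (!target %in% nm) {
          nm[slot] <- target
          slot <- slot - 1L
        }
      }
    }
    w <- stats::rgamma(length(nm), shape = 2, rate = 1)   # Dirichlet split
    share <- w / sum(w)
    mWT <- design$classBaselines[[cls]] * share
    mHOM <- mWT * design$classEffectRatios[[cls]]
    allNames <- c(allNames, nm); allClass <- c(allClass, rep(cls, length(nm)))
    meansWT <- c(meansWT, mWT); meansHOM <- c(meansHOM, mHOM)
  }
  # chain-level planted effects: scale only pure carrier species (all
  # acyl chains equal to the product chain) with a compensating factor so
  # the product pool moves by exactly `fold` and no other pool moves
  if (nrow(design$plantedChainEffects)) {
    parsed <- lapply(allNames, .parseName, registry = registry)
    acylLabels <- lapply(parsed, function(rec) {
      ch <- rec$chains
      if (rec$classCode %in% .sphingoidClasses)
        ch <- ch[-1L, , drop = FALSE]
      .chainLabel(ch$carbons, ch$doubleBonds)
    })
    for (j in seq_len(nrow(design$plantedChainEffects))) {
      prod <- design$plantedChainEffects$product[j]
      fold <- design$plantedChainEffects$fold[j]
      contrib <- vapply(acylLabels, function(l) sum(l == prod), 0)
      pure <- vapply(acylLabels, function(l)
        length(l) > 0L && all(l == prod), NA)
      aTot <- sum(contrib * meansWT)
      aPure <- sum(contrib[pure] * meansWT[pure])
      if (aPure <= 0)
        .err(paste("no pure carrier species for planted chain", prod),
             "lipidflow_bad_design")
      f <- 1 + (fold - 1) * aTot / aPure
      meansHOM[pure] <- meansHOM[pure] * f
    }
  }
  sdlog <- sqrt(log(1 + design$cv^2))
  n <- length(allNames)
  noise <- matrix(exp(stats::rnorm(n * length(samples), 0, sdlog) -
                        sdlog^2 / 2), n, length(samples))
  conc <- cbind(matrix(meansWT, n, nWT), matrix(meansHOM, n, nHOM)) * noise
  dimnames(conc) <- list(allNames, samples)
  sampleData <- data.frame(
    sampleID = samples, group = group, tissue = design$tissue,
    proteinAmount = round(stats::runif(length(samples), 80, 120), 1),
    extractVolume = 1, stringsAsFactors = FALSE)
  psyMeans <- design$psyWT * ifelse(group == "HOM", design$psyRatio, 1)
  psyNoise <- exp(stats::rnorm(length(samples), 0, sdlog) - sdlog^2 / 2)
  psy <- stats::setNames(psyMeans * psyNoise, samples)
  exp <- LipidomicsExperiment(conc, sampleData, registry = registry)
  list(experiment = exp, sampleData = sampleData, psy = psy,
       truth = list(speciesMeansWT = stats::setNames(meansWT, allNames),
                    speciesMeansHOM = stats::setNames(meansHOM, allNames),
                    speciesClass = stats::setNames(allClass, allNames),
                    classBaselines = design$classBaselines,
                    classEffectRatios = design$classEffectRatios,
                    plantedClassEdges = design$plantedClassEdges,
                    plantedChainEffects = design$plantedChainEffects,
                    psyMeans = stats::setNames(psyMeans, samples),
                    seed = seed))
}

#' Generate a peak-area feature table that inverts semi-quantification
#'
#' Builds internal-standard rows and analyte peak areas such that
#' [semiQuantify()] recovers the generated concentration matrix exactly
#' (up to float tolerance) and [quantifyPsy()] recovers the planted
#' psychosine levels: `area = conc x protein / (volume x spike) x IS
#' area`, with per-sample IS areas drawn log-normally around `isAreaBase`.
#'
#' @param design a [syntheticDesign()].
#' @param isMap internal-standard map, see [defaultISMap()].
#' @param isAreaBase typical IS peak area (arbitrary units).
#' @param isCV CV of the per-sample IS area variation.
#' @param seed overrides `design$seed`.
#' @return list with `areas` (feature table including IS and PSY rows),
#'   `sampleData`, `experiment` (the underlying true
#'   [LipidomicsExperiment-class]), `psy` and `truth`.
#' @export
generateFeatureTable <- function(design, isMap = defaultISMap(),
                                 isAreaBase = 1e6, isCV = 0.1,
                                 seed = design$seed) {
  sim <- generateConcentrations(design, seed = seed)
  conc <- concentrations(sim$experiment)
  meta <- sim$sampleData
  cls <- lipidClasses(sim$experiment)
  idx <- match(cls, isMap$classCode)
  if (anyNA(idx))
    .err("class without internal standard in map", "lipidflow_missing_is")
  isNames <- unique(c(isMap$isName[idx], "PSY-d5"))
  sdlog <- sqrt(log(1 + isCV^2))
  isAreas <- matrix(
    isAreaBase * exp(stats::rnorm(length(isNames) * ncol(conc), 0, sdlog)),
    length(isNames), ncol(conc), dimnames = list(isNames, colnames(conc)))
  perSample <- meta$proteinAmount / meta$extractVolume
  areas <- conc / (isMap$spike[idx] * isMap$responseFactor[idx])
  areas <- sweep(areas, 2, perSample, `*`) *
    isAreas[isMap$isName[idx], , drop = FALSE]
  psySpike <- isMap$spike[match("PSY", isMap$classCode)]
  psyArea <- sim$psy / psySpike * perSample * isAreas["PSY-d5", ]
  areas <- rbind(areas, `PSY 18:1;O2` = psyArea, isAreas)
  list(areas = areas, sampleData = meta, experiment = sim$experiment,
       psy = sim$psy, truth = sim$truth)
}
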