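# Shorthand nomenclature: "CLASS C1:D1_C2:D2" where C = chain carbons,
# D = double bonds; "_" separates chains with unknown sn-positions, "/"
# with known positions; "O-" marks an ether-linked chain, "P-" a
# plasmalogen (parsed as O- with one extra double bond); ";O"/";O2" are
# hydroxyl counts; the "d18:1"/"t18:0" sphingoid dialect is accepted and
# normalized to ";O2"/";O3".

.chainPattern <- "^(?:([OPdt])-?)?([0-9]+):([0-9]+)(?:;O([0-9]*))?$"

.parseChainTokens <- function(tokens, rawName) {
  m <- regmatches(tokens, regexec(.chainPattern, tokens))
  bad <- lengths(m) == 0L
  if (any(bad))
    .err(sprintf("malformed chain token '%s' in '%s'",
                 tokens[bad][1], rawName), "lipidflow_malformed_chain")
  mm <- matrix(unlist(m), ncol = 5L, byrow = TRUE)
  prefix <- mm[, 2]
  carbons <- as.integer(mm[, 3])
  db <- as.integer(mm[, 4])
  ox <- integer(length(tokens))
  hasO <- grepl(";O", tokens, fixed = TRUE)
  ox[hasO] <- ifelse(mm[hasO, 5] == "", 1L, as.integer(mm[hasO, 5]))
  ether <- prefix %in% c("O", "P")
  db <- db + (prefix == "P")            # plasmalogen -> O- with +1 bond
  ox[prefix == "d"] <- 2L               # dihydroxy base dialect
  ox[prefix == "t"] <- 3L               # trihydroxy base dialect
  if (any(carbons < 1L) || any(db > carbons / 2))
    .err(sprintf("implausible chain in '%s'", rawName),
         "lipidflow_malformed_chain")
  structure(list(carbons = carbons, doubleBonds = db, oxidation = ox,
                 etherLinked = ether),
            class = "data.frame", row.names = seq_along(carbons))
}

.emptyChains <- structure(
  list(carbons = integer(), doubleBonds = integer(),
       oxidation = integer(), etherLinked = logical()),
  class = "data.frame", row.names = integer())

# core parser returning a plain record; parseLipidName wraps it in S4
.parseName <- function(name, registry) {
  raw <- trimws(name)
  tokens <- strsplit(raw, " ", fixed = TRUE)[[1]]
  tokens <- tokens[nzchar(tokens)]
  cls <- NA_character_
  rest <- character()
  for (take in rev(seq_len(min(2L, length(tokens))))) {
    cand <- paste(tokens[seq_len(take)], collapse = " ")
    if (cand %in% registry$code) {
      cls <- cand
      rest <- tokens[-seq_len(take)]
      break
    }
  }
  if (is.na(cls))
    .err(sprintf("unknown lipid class in '%s'", raw),
         "lipidflow_unknown_class")
  chainPart <- paste(rest, collapse = " ")
  if (!nzchar(chainPart))
    return(list(rawName = raw, classCode = cls, chains = .emptyChains,
                snPositionsKnown = FALSE, annotationLevel = "class-only"))
  snKnown <- grepl("/", chainPart, fixed = TRUE)
  sep <- if (snKnown) "/" else "_"
  chains <- .parseChainTokens(strsplit(chainPart, sep, fixed = TRUE)[[1]],
                              raw)
  if (any(chains$etherLinked) && cls %in% c("PC", "PE", "PI"))
    cls <- paste0(cls, "-O")
  expected <- registry$expectedChainCount[registry$code == cls]
  if (cls %in% c("PC-O", "PE-O", "PI-O") && !any(chains$etherLinked))
    chains$etherLinked[1] <- TRUE   # "PC-O 16:1_18:1" style input
  level <- if (nrow(chains) == expected) "molecular-species"
           else if (nrow(chains) == 1L && expected > 1L) "sum-composition"
           else .err(sprintf(
             "'%s': %d chains but class %s expects %d", raw, nrow(chains),
             cls, expected), "lipidflow_chain_count_mismatch")
  list(rawName = raw, classCode = cls, chains = chains,
       snPositionsKnown = snKnown, annotationLevel = level)
}

#' Parse a lipid shorthand name
#'
#' Splits a shorthand name such as `"PE O-16:1_18:1"` into its class code
#' and chain composition. `"_"`-separated chains are flagged as sn-position
#' unknown, `"/"`-separated as known. An `"O-"` prefix marks an ether
#' linkage and maps PC/PE/PI to the distinct ether subclasses PC-O/PE-O/
#' PI-O; a `"P-"` (plasmalogen) prefix is normalized to `"O-"` with one
#' additional double bond on that chain. Sphingoid bases may be written
#' either with the hydroxyl suffix (`"18:1;O2"`) or in the `"d18:1"`
#' dialect. A name carrying fewer chains than the class expects (e.g.
#' `"SM 34:1"`) is accepted at sum-composition level; a bare class code is
#' accepted at class-only level.
#'
#' @param name a single shorthand name.
#' @param registry class registry, see [lipidClassRegistry()].
#' @return A [LipidSpecies-class] object.
#' @examples
#' parseLipidName("PE O-16:1_18:1")
#' parseLipidName("CE 20:4")
#' parseLipidName("SM 18:1;O2/16:0")
#' @export
parseLipidName <- function(name, registry = lipidClassRegistry()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  rec <- .parseName(name, registry)
  new("LipidSpecies", rawName = rec$rawName, classCode = rec$classCode,
      chains = rec$chains, snPositionsKnown = rec$snPositionsKnown,
      annotationLevel = rec$annotationLevel)
}

#' Parse many lipid shorthand names
#'
#' Vectorized wrapper around [parseLipidName()] returning row metadata
#' suitable for a [LipidomicsExperiment-class].
#'
#' @param names character vector of shorthand names.
#' @param registry class registry.
#' @param onUnknown `"error"` (default) to fail on an unknown class token,
#'   `"skip"` to drop such rows with a warning. Silent drops corrupt class
#'   totals, so skipping is opt-in.
#' @return A [S4Vectors::DataFrame] with columns `rawName`, `classCode`,
#'   `snPositionsKnown`, `annotationLevel` and a list column `chains`.
#' @examples
#' parseLipidNames(c("PC 16:0_18:1", "CE 22:6"))
#' @export
parseLipidNames <- function(names, registry = lipidClassRegistry(),
                            onUnknown = c("error", "skip")) {
  onUnknown <- match.arg(onUnknown)
  parsed <- vector("list", length(names))
  keep <- rep(TRUE, length(names))
  if (onUnknown == "error") {
    for (i in seq_along(names))
      parsed[[i]] <- .parseName(names[i], registry)
  } else {
    for (i in seq_along(names)) {
      parsed[[i]] <- tryCatch(.parseName(names[i], registry),
        lipidflow_unknown_class = function(e) {
          keep[i] <<- FALSE
          NULL
        })
    }
  }
  if (!all(keep))
    warning(sum(!keep), " species with unknown class skipped: ",
            paste(utils::head(names[!keep], 5), collapse = ", "))
  parsed <- parsed[keep]
  DataFrame(
    rawName = vapply(parsed, `[[`, "", "rawName"),
    classCode = vapply(parsed, `[[`, "", "classCode"),
    snPositionsKnown = vapply(parsed, `[[`, NA, "snPositionsKnown"),
    annotationLevel = vapply(parsed, `[[`, "", "annotationLevel"),
    chains = I(lapply(parsed, `[[`, "chains")),
    row.names = names[keep])
}

.formatChain <- function(carbons, doubleBonds, oxidation, etherLinked) {
  paste0(ifelse(etherLinked, "O-", ""), carbons, ":", doubleBonds,
         ifelse(oxidation > 0,
                paste0(";O", ifelse(oxidation > 1, oxidation, "")), ""))
}

#' Format a LipidSpecies back to shorthand
#'
#' Inverse of [parseLipidName()]: `parseLipidName(formatLipidName(s))`
#' reproduces `s` for every valid species. Ether subclasses are written in
#' the `"PC O-16:1_18:1"` style; hydroxyls as `";O"`/`";O2"` (the canonical
#' form of the `d`/`t` dialect).
#'
#' @param species a [LipidSpecies-class].
#' @return the shorthand name, a character scalar.
#' @examples
#' formatLipidName(parseLipidName("PA 18:0_18:1"))
#' @export
formatLipidName <- function(species) {
  stopifnot(is(species, "LipidSpecies"))
  cls <- sub("-O$", "", species@classCode)
  ch <- species@chains
  if (!nrow(ch)) return(species@classCode)
  sep <- if (species@snPositionsKnown) "/" else "_"
  paste(cls, paste(.formatChain(ch$carbons, ch$doubleBonds, ch$oxidation,
                                ch$etherLinked), collapse = sep))
}

#' Fatty-acyl building blocks of a species
#'
#' Decomposes a molecular-species-level lipid into its chain building
#' blocks, one `(carbons, doubleBonds)` entry per chain with duplicates
#' preserved (`"PA 18:1_18:1"` yields 18:1 twice). Sphingoid long-chain
#' bases (the first chain of Cer/HexCer/SHexCer/SM/PSY species) can be
#' excluded to restrict the decomposition to fatty-acid chains.
#'
#' @param species a [LipidSpecies-class] at molecular-species level.
#' @param includeSphingoid keep sphingoid bases (default `TRUE`).
#' @return `data.frame` with columns `carbons`, `doubleBonds` and `label`
#'   (`"18:1"` style), one row per retained chain.
#' @examples
#' buildingBlocks(parseLipidName("PA 18:1_18:1"))
#' @export
buildingBlocks <- function(species, includeSphingoid = TRUE) {
  stopifnot(is(species, "LipidSpecies"))
  if (species@annotationLevel != "molecular-species")
    .err(sprintf("'%s' is %s-level; building blocks need molecular species",
                 species@rawName, species@annotationLevel),
         "lipidflow_sum_composition_only")
  ch <- species@chains
  if (!includeSphingoid && species@classCode %in% .sphingoidClasses)
    ch <- ch[-1L, , drop = FALSE]
  data.frame(carbons = ch$carbons, doubleBonds = ch$doubleBonds,
             label = paste0(ch$carbons, ":", ch$doubleBonds))
}
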