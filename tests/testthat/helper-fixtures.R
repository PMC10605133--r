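# Shared fixtures: a shorthand corpus in the canonical dialect (hydroxyls
# as ";O2", ether as "O-"), an independent random-species generator, and a
# tiny fully hand-checkable concentration matrix.

corpusNames <- c(
  "PE O-16:1_18:1", "PE O-18:1_18:1", "PE O-18:2_18:1",
  "PC 16:0_18:1", "PC 18:0_18:1", "PC O-16:1_20:4",
  "CE 20:4", "CE 18:2", "CE 22:6",
  "PS 18:1_18:1", "PS 18:0_18:1",
  "PA 18:0_18:1", "PA 18:1_18:1", "PA 18:1_22:0", "PA 18:0_20:4",
  "PG 16:0_18:1", "PI 18:0_20:4", "PI O-16:0_18:1",
  "DG 16:0_18:1", "CL 16:0_18:1_18:1_18:2",
  "LPC 18:1", "LPE 18:0", "LPI 20:4",
  "SM 18:1;O2/16:0", "Cer 18:1;O2/24:1", "HexCer 18:1;O2/24:1",
  "SHexCer 18:1;O2/24:1", "PSY 18:1;O2")

# random valid species built directly from slots, independent of the parser
randomSpecies <- function(registry = lipidClassRegistry()) {
  reg <- registry[sample.int(nrow(registry), 1L), ]
  sphingo <- reg$code %in% c("Cer", "HexCer", "SHexCer", "SM", "PSY")
  ether <- grepl("-O$", reg$code)
  k <- reg$expectedChainCount
  mk <- function() {
    c0 <- sample(seq(12L, 24L, 2L), 1L)
    data.frame(carbons = c0,
               doubleBonds = sample(0:min(4L, c0 %/% 2L), 1L),
               oxidation = 0L, etherLinked = FALSE)
  }
  chains <- do.call(rbind, replicate(k, mk(), simplify = FALSE))
  if (sphingo) {
    chains$carbons[1] <- 18L; chains$doubleBonds[1] <- 1L
    chains$oxidation[1] <- 2L
  }
  if (ether) chains$etherLinked[1] <- TRUE
  new("LipidSpecies", rawName = "", classCode = reg$code, chains = chains,
      snPositionsKnown = if (k > 1L) sample(c(TRUE, FALSE), 1L) else FALSE,
      annotationLevel = "molecular-species")
}

expect_species_equal <- function(a, b) {
  expect_identical(a@classCode, b@classCode)
  expect_identical(a@snPositionsKnown, b@snPositionsKnown)
  expect_identical(a@annotationLevel, b@annotationLevel)
  expect_equal(a@chains[c("carbons", "doubleBonds", "oxidation",
                          "etherLinked")],
               b@chains[c("carbons", "doubleBonds", "oxidation",
                          "etherLinked")],
               ignore_attr = TRUE)
}

# 4-species, 3-sample matrix with hand-computable totals
toyMatrix <- function() {
  matrix(c(1, 2, 3,
           4, 5, 6,
           0.5, 0.5, 1,
           2, 1, 1),
         nrow = 4, byrow = TRUE,
         dimnames = list(c("PC 16:0_18:1", "PC 18:0_18:1",
                           "PA 18:1_18:1", "PE 18:0_20:4"),
                         c("s1", "s2", "s3")))
}

toyMeta <- function(n = 9, nCase = 4) {
  data.frame(sampleID = paste0("s", seq_len(n)),
             group = rep(c("WT", "HOM"), c(n - nCase, nCase)),
             tissue = "SN", proteinAmount = 100, extractVolume = 1,
             stringsAsFactors = FALSE)
}
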