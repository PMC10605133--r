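mkTotals <- function() {
  matrix(c(1, 2, 4, 1,     # PA
           2, 2, 2, 3,     # PG
           4, 8, 4, 6),    # PC
         3, 4, byrow = TRUE,
         dimnames = list(c("PA", "PG", "PC"), paste0("s", 1:4)))
}

test_that("weights are the hand-computed product/reactant ratios", {
  cat <- ReactionCatalog(data.frame(
    reactant = c("PA", "PC"), product = c("PG", "PA"),
    enzyme = c("e1", "e2"), gene = c("g1", "g2")))
  w <- computeReactionWeights(mkTotals(), cat)
  expect_equal(unname(w["PA->PG", ]), c(2, 1, 0.5, 3))
  expect_equal(unname(w["PC->PA", ]), c(0.25, 0.25, 1, 1/6))
  # absent pool: edge skipped with a warning
  cat2 <- ReactionCatalog(data.frame(
    reactant = c("PA", "CL"), product = c("PG", "PG"),
    enzyme = "e", gene = "g"))
  expect_warning(w2 <- computeReactionWeights(mkTotals(), cat2),
                 "CL->PG")
  expect_equal(rownames(w2), "PA->PG")
})

test_that("weights are invariant to per-sample global rescaling", {
  tot <- mkTotals()
  tot2 <- sweep(tot, 2, c(2, 0.5, 7, 1), `*`)
  cat <- defaultClassCatalog()
  expect_equal(suppressWarnings(computeReactionWeights(tot2, cat)),
               suppressWarnings(computeReactionWeights(tot, cat)))
})

test_that("identical groups give no calls; label swap flips every call", {
  set.seed(20)
  # identical group values
  w0 <- matrix(rep(c(1.2, 0.7, 2.1, 1.2, 0.7, 2.1), 2), 2, 6,
               byrow = TRUE, dimnames = list(c("PA->PG", "PC->PA"),
                                             paste0("s", 1:6)))
  s0 <- scoreReactions(w0, rep(c("WT", "HOM"), each = 3))
  expect_true(all(s0$call == "unchanged"))

  tot <- matrix(rlnorm(30, 1, 0.3), 3, 10,
                dimnames = list(c("PA", "PG", "PC"), paste0("s", 1:10)))
  tot["PG", 6:10] <- tot["PG", 6:10] * 4
  g <- rep(c("WT", "HOM"), each = 5)
  w <- suppressWarnings(computeReactionWeights(tot, defaultClassCatalog()))
  fwd <- scoreReactions(w, g, caseGroup = "HOM")
  rev <- scoreReactions(w, ifelse(g == "HOM", "WT", "HOM"),
                        caseGroup = "HOM")
  expect_equal(fwd$pValue, rev$pValue)
  expect_equal(fwd$zScore, -rev$zScore)
  swap <- c(activated = "suppressed", suppressed = "activated",
            unchanged = "unchanged")
  expect_identical(unname(swap[fwd$call]), rev$call)
  expect_identical(fwd$call[fwd$edge == "PA->PG"], "activated")
})

test_that("the Z-score is the signed probit of the two-sided p", {
  set.seed(22)
  tot <- matrix(rlnorm(40, 0, 0.4), 4, 10,
                dimnames = list(c("PA", "PG", "PC", "PE"),
                                paste0("s", 1:10)))
  g <- rep(c("WT", "HOM"), each = 5)
  s <- scoreReactions(
    suppressWarnings(computeReactionWeights(tot, defaultClassCatalog())),
    g)
  ok <- !is.na(s$pValue)
  expect_equal(abs(s$zScore[ok]), qnorm(1 - s$pValue[ok] / 2))
  expect_equal(sign(s$zScore[ok]), sign(s$log2WeightRatio[ok]))
})

test_that("annotation attaches the catalogued enzymes and genes", {
  tot <- mkTotals()
  tot <- rbind(tot, LPC = c(1, 1, 2, 1))
  g <- c("WT", "WT", "HOM", "HOM")
  cat <- defaultClassCatalog()
  s <- annotateReactions(
    scoreReactions(suppressWarnings(computeReactionWeights(tot, cat)), g),
    cat)
  expect_identical(s$gene[s$edge == "PA->PG"], "CDS")
  expect_match(s$enzyme[s$edge == "PA->PG"], "cytidylyltransferase")
  expect_identical(s$gene[s$edge == "PC->LPC"], "PLA")
  expect_match(s$enzyme[s$edge == "PC->LPC"], "phospholipase A")
})

test_that("empty score tables export to valid, empty graph files", {
  empty <- data.frame(edge = character(), reactant = character(),
                      product = character(), pValue = numeric(),
                      call = character(), stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".graphml")
  g <- exportReactionGraph(empty, f)
  expect_true(file.exists(f))
  expect_equal(igraph::gorder(exportReactionGraph(empty)), 0)
  unlink(f)
})

test_that("a planted 3x product fold change is recovered as activated", {
  set.seed(23)
  hits <- 0L
  reps <- 40
  for (i in seq_len(reps)) {
    d <- plantReactionEffect(
      syntheticDesign("SN", effects = "null", seed = sample.int(1e6, 1)),
      "PA", "PG", 3)
    sim <- generateConcentrations(d)
    tot <- classTotals(sim$experiment)
    s <- scoreReactions(
      suppressWarnings(computeReactionWeights(tot, defaultClassCatalog())),
      sim$sampleData$group)
    if (s$call[s$edge == "PA->PG"] == "activated") hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.8)
})
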