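mkExperiment <- function(names, conc, meta = NULL) {
  if (is.null(meta))
    meta <- data.frame(sampleID = colnames(conc),
                       group = rep(c("WT", "HOM"),
                                   length.out = ncol(conc)),
                       proteinAmount = 100)
  rownames(conc) <- names
  LipidomicsExperiment(conc, meta)
}

test_that("chain abundance equals the incidence-matrix product", {
  set.seed(30)
  names <- c("PC 16:0_18:1", "PC 18:0_18:1", "PA 18:1_18:1",
             "PE 18:0_20:4", "PC 16:0_16:0", "PS 18:0_18:1",
             "PG 16:0_18:2", "PI 18:1_20:4", "DG 16:0_18:1",
             "CE 18:2")
  conc <- matrix(rlnorm(10 * 4), 10, 4,
                 dimnames = list(names, paste0("s", 1:4)))
  le <- mkExperiment(names, conc)
  ab <- chainAbundance(le)
  # brute-force incidence matrix (chains x species, multiplicity counts)
  chainList <- lapply(names, function(n)
    buildingBlocks(parseLipidName(n))$label)
  chains <- sort(unique(unlist(chainList)))
  inc <- vapply(chainList, function(ch)
    vapply(chains, function(k) sum(ch == k), 0), numeric(length(chains)))
  oracle <- inc %*% conc
  rownames(oracle) <- chains
  expect_equal(unclass(ab)[rownames(ab), ], oracle[rownames(ab), ],
               ignore_attr = TRUE)
  expect_setequal(rownames(ab), chains)
})

test_that("chain totals conserve multiplicity-weighted species sums", {
  d <- syntheticDesign("SN", seed = 31)
  sim <- generateConcentrations(d)
  le <- sim$experiment
  ab <- chainAbundance(le, includeSphingoid = TRUE)
  conc <- concentrations(le)
  nChains <- vapply(rownames(conc), function(n)
    nrow(buildingBlocks(parseLipidName(n))), 0L)
  expect_equal(unname(colSums(ab)), unname(colSums(conc * nChains)),
               tolerance = 1e-12)
})

test_that("sphingoid bases are excluded by default, kept on request", {
  names <- c("SM 18:1;O2/16:0", "Cer 18:1;O2/24:1")
  conc <- matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE,
                 dimnames = list(names, c("s1", "s2")))
  le <- mkExperiment(names, conc)
  exF <- chainAbundance(le)
  expect_setequal(rownames(exF), c("16:0", "24:1"))
  inT <- chainAbundance(le, includeSphingoid = TRUE)
  expect_equal(unname(inT["18:1", ]), c(1 + 3, 2 + 4))  # SM + Cer bases
})

test_that("profiles bin on length and unsaturation with group tests", {
  names <- c("PC 16:0_18:1", "PA 18:1_18:1")
  conc <- matrix(rep(c(2, 1), 6), 2, 6, byrow = FALSE,
                 dimnames = list(NULL, paste0("s", 1:6)))
  conc[] <- c(2, 1)
  le <- mkExperiment(names, conc,
                     meta = data.frame(sampleID = paste0("s", 1:6),
                                       group = rep(c("WT", "HOM"),
                                                   each = 3),
                                       proteinAmount = 100))
  ab <- chainAbundance(le)
  len <- chainProfiles(ab, rep(c("WT", "HOM"), each = 3), "length")
  expect_equal(len$item, c("16", "18"))
  uns <- chainProfiles(ab, rep(c("WT", "HOM"), each = 3), "unsaturation")
  expect_equal(uns$item, c("0", "1"))
  # 16 appears once (in PC at conc 2); 18 three times (PC once, PA twice)
  expect_equal(len$meanControl, c(2, 2 + 2 * 1))
})

test_that("catalog edges connect only observed chains with enzyme labels", {
  chains <- c("16:0", "16:1", "18:0", "18:1", "18:2", "18:3", "22:0",
              "22:2", "22:3", "24:0", "24:6", "22:6")
  cat <- chainCatalog(chains)
  e <- catalogEdges(cat)
  expect_true(all(e$reactant %in% chains & e$product %in% chains))
  lab <- paste0(e$reactant, "->", e$product)
  expect_identical(e$gene[lab == "18:1->18:2"], "FADS2 (D6D)")
  expect_identical(e$gene[lab == "18:0->18:1"], "SCD1")
  expect_identical(e$gene[lab == "22:2->22:3"], "FADS1 (D5D)")
  expect_identical(e$gene[lab == "22:0->24:0"], "ELOVL1;ELOVL3;ELOVL6")
  expect_identical(e$type[lab == "24:6->22:6"], "betaOxidation")
  # beta-oxidation only from substrates with >= 20 carbons
  expect_false(any(e$type == "betaOxidation" &
                     as.integer(sub(":.*", "", e$reactant)) < 20))
  expect_true("16:0->16:1" %in% lab)            # desaturation present
})

test_that("a planted chain desaturation effect is called with its enzyme", {
  set.seed(33)
  hits <- 0L; reps <- 30
  for (i in seq_len(reps)) {
    d <- plantChainEffect(
      syntheticDesign("SN", effects = "null", seed = sample.int(1e6, 1)),
      "18:1", "18:2", 2)
    sim <- generateConcentrations(d)
    ab <- chainAbundance(sim$experiment)
    cn <- chainNetwork(ab, sim$sampleData$group)
    row <- cn[cn$edge == "18:1->18:2", ]
    if (nrow(row) == 1 && row$call == "activated") {
      hits <- hits + 1L
      expect_identical(row$gene, "FADS2 (D6D)")
    }
  }
  expect_gte(hits / reps, 0.8)
})

test_that("within-class suppression of 18:0 -> 18:1 maps to SCD1", {
  set.seed(34)
  # PC-only data with the 18:1 pool halved in HOM
  names <- c("PC 18:0_18:0", "PC 18:0_18:1", "PC 18:1_18:1",
             "PC 16:0_18:0", "PC 16:0_16:0", "PC 16:0_18:1")
  n <- 10
  conc <- matrix(rlnorm(length(names) * n, 0, 0.15), length(names), n,
                 dimnames = list(names, paste0("s", 1:n)))
  g <- rep(c("WT", "HOM"), each = 5)
  has181 <- grepl("18:1", names)
  conc[has181, g == "HOM"] <- conc[has181, g == "HOM"] / 2
  le <- mkExperiment(names, conc,
                     meta = data.frame(sampleID = paste0("s", 1:n),
                                       group = g, proteinAmount = 100))
  s <- chainNetworkWithinClass(le, "PC", group = g)
  row <- s[s$edge == "18:0->18:1", ]
  expect_identical(row$call, "suppressed")
  expect_identical(row$gene, "SCD1")
  # with a single class, within-class equals the global chain network
  glob <- chainNetwork(chainAbundance(le), g)
  expect_equal(s[order(s$edge), c("edge", "pValue", "call")],
               glob[order(glob$edge), c("edge", "pValue", "call")],
               ignore_attr = TRUE)
})

test_that("classes with one chain type give an empty edge set", {
  names <- c("LPC 18:1", "PC 16:0_18:1")
  conc <- matrix(1:8, 2, 4, dimnames = list(names, paste0("s", 1:4)))
  le <- mkExperiment(names, conc)
  out <- chainNetworkWithinClass(le, "LPC",
                                 group = rep(c("WT", "HOM"), each = 2))
  expect_equal(nrow(out), 0)
  expect_error(chainAbundance(le, classCode = "PE"),
               class = "lipidflow_class_absent")
})
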