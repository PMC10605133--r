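mkTable <- function(areas, isRow = "IS PC 15:0_18:1(d7)") {
  rbind(areas, matrix(1e6, 1, ncol(areas),
                      dimnames = list(isRow, colnames(areas))))
}

test_that("semi-quantification follows the ratio formula", {
  # analyte area equal to IS area, spike 100 ug/mL, 1 mL, 100 ug protein
  ft <- mkTable(matrix(1e6, 1, 1,
                       dimnames = list("PC 16:0_18:1", "s1")))
  md <- data.frame(sampleID = "s1", group = "WT", proteinAmount = 100,
                   extractVolume = 1)
  le <- semiQuantify(ft, defaultISMap(), md)
  expect_equal(unname(concentrations(le)[1, 1]), 1.0)
  # IS rows are excluded from the output
  expect_equal(rownames(le), "PC 16:0_18:1")
})

test_that("concentrations are invariant to per-sample area scaling", {
  set.seed(1)
  areas <- matrix(runif(6, 1e4, 1e6), 3, 2,
                  dimnames = list(c("PC 16:0_18:1", "PC 18:0_18:1",
                                    "PE 18:0_20:4"), c("a", "b")))
  ft <- rbind(areas,
              `IS PC 15:0_18:1(d7)` = c(2e6, 3e6),
              `IS PE 15:0_18:1(d7)` = c(1e6, 5e6))
  md <- data.frame(sampleID = c("a", "b"), group = c("WT", "HOM"),
                   proteinAmount = c(80, 120), extractVolume = 1)
  base <- concentrations(semiQuantify(ft, defaultISMap(), md))
  scaled <- ft
  scaled[, "a"] <- scaled[, "a"] * 7.3
  rescaled <- concentrations(semiQuantify(scaled, defaultISMap(), md))
  expect_equal(rescaled, base)
  # linearity: scaling one analyte's area scales its concentration
  lin <- ft
  lin["PC 16:0_18:1", ] <- lin["PC 16:0_18:1", ] * 3
  out <- concentrations(semiQuantify(lin, defaultISMap(), md))
  expect_equal(out["PC 16:0_18:1", ], base["PC 16:0_18:1", ] * 3)
  expect_equal(out["PE 18:0_20:4", ], base["PE 18:0_20:4", ])
})

test_that("generator-built feature tables invert to the planted matrix", {
  d <- syntheticDesign("SN", seed = 5)
  ft <- generateFeatureTable(d)
  le <- semiQuantify(ft$areas, defaultISMap(), ft$sampleData)
  truth <- concentrations(ft$experiment)
  expect_equal(rownames(le), rownames(truth))
  relErr <- abs(concentrations(le) - truth) / truth
  expect_lt(max(relErr), 1e-10)
})

test_that("missing IS mapping and zero IS areas are hard errors", {
  ft <- mkTable(matrix(1, 1, 1, dimnames = list("PC 16:0_18:1", "s1")))
  md <- data.frame(sampleID = "s1", group = "WT", proteinAmount = 100)
  bad <- defaultISMap()
  bad <- bad[bad$classCode != "PC", ]
  expect_error(semiQuantify(ft, bad, md), class = "lipidflow_missing_is")
  ftz <- ft
  ftz["IS PC 15:0_18:1(d7)", 1] <- 0
  expect_error(semiQuantify(ftz, defaultISMap(), md),
               class = "lipidflow_zero_is_area")
})

test_that("psychosine quantification uses the PSY-d5 ratio", {
  ft <- matrix(c(200, 100), 2, 1,
               dimnames = list(c("PSY 18:1;O2", "PSY-d5"), "s1"))
  md <- data.frame(sampleID = "s1", group = "HOM", proteinAmount = 125,
                   extractVolume = 1)
  expect_equal(as.numeric(quantifyPsy(ft, md)), 2.0)  # 2x the 125 ng/mL spike
  ft["PSY 18:1;O2", 1] <- 0
  expect_equal(as.numeric(quantifyPsy(ft, md)), 0)    # zero area is valid
})

test_that("psychosine group ratio is recovered from synthetic designs", {
  # HOM/WT ratio estimated as mean of per-replicate ratio of group means
  set.seed(99)
  est <- vapply(1:30, function(i) {
    d <- syntheticDesign("SN", nWT = 5, nHOM = 5,
                         seed = sample.int(1e6, 1))
    ft <- generateFeatureTable(d)
    psy <- quantifyPsy(ft$areas, ft$sampleData)
    g <- ft$sampleData$group
    mean(psy[g == "HOM"]) / mean(psy[g == "WT"])
  }, 0)
  expect_lt(abs(mean(est) - 27) / 27, 0.1)
})

test_that("missing-value strategies are deterministic and reported", {
  m <- matrix(c(0, 2, 4, 1, 1, 1, 0, 0, 5), 3, 3, byrow = TRUE,
              dimnames = list(c("PC 16:0_18:1", "PC 18:0_18:1",
                                "PA 18:1_18:1"), c("a", "b", "c")))
  expect_identical(handleMissing(m, "none"), m)
  out <- suppressMessages(handleMissing(m, "half-min"))
  expect_equal(out["PC 16:0_18:1", "a"], 1)       # min(2, 4)/2
  expect_equal(out["PA 18:1_18:1", c("a", "b")], c(a = 2.5, b = 2.5))
  kept <- suppressMessages(handleMissing(m, "presence-filter",
                                         presenceThreshold = 0.5))
  expect_equal(rownames(kept), c("PC 16:0_18:1", "PC 18:0_18:1"))
})
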