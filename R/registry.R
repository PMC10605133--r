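#' Lipid class registry
#'
#' The registry of lipid classes understood by the shorthand parser and the
#' class-level statistics: 19 classes routinely annotated in nervous-tissue
#' untargeted lipidomics plus psychosine (PSY), the targeted lysosphingolipid.
#' Ether-linked subclasses (PC-O, PE-O, PI-O) are distinct codes because
#' class-level statistics treat them separately from their diacyl parents.
#'
#' @param extra optional `data.frame` with columns `code`, `fullName`,
#'   `expectedChainCount`, `category` appended to the built-in registry,
#'   e.g. to accept additional class tokens emitted by alignment software.
#' @return A `data.frame` with columns `code` (short class symbol),
#'   `fullName`, `expectedChainCount` (number of acyl/sphingoid chains in a
#'   molecular-species annotation) and `category`.
#' @examples
#' head(lipidClassRegistry())
#' @export
lipidClassRegistry <- function(extra = NULL) {
  reg <- data.frame(
    code = c("CE", "Cer", "CL", "DG", "PC-O", "PE-O", "PI-O", "HexCer",
             "LPC", "LPE", "LPI", "PA", "PC", "PE", "PG", "PI", "PS",
             "SHexCer", "SM", "PSY"),
    fullName = c("Cholesteryl ester", "Ceramide", "Cardiolipin",
                 "Diacylglycerol", "Ether-linked phosphatidylcholine",
                 "Ether-linked phosphatidylethanolamine",
                 "Ether-linked phosphatidylinositol", "Hexosylceramide",
                 "Lysophosphatidylcholine", "Lysophosphatidylethanolamine",
                 "Lysophosphatidylinositol", "Phosphatidic acid",
                 "Phosphatidylcholine", "Phosphatidylethanolamine",
                 "Phosphatidylglycerol", "Phosphatidylinositol",
                 "Phosphatidylserine", "Sulfatide", "Sphingomyelin",
                 "Psychosine"),
    expectedChainCount = c(1L, 2L, 4L, 2L, 2L, 2L, 2L, 2L,
                           1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 1L),
    category = c("sterol", "sphingolipid", "glycerophospholipid",
                 "glycerolipid", "glycerophospholipid", "glycerophospholipid",
                 "glycerophospholipid", "sphingolipid",
                 "glycerophospholipid", "glycerophospholipid",
                 "glycerophospholipid", "glycerophospholipid",
                 "glycerophospholipid", "glycerophospholipid",
                 "glycerophospholipid", "glycerophospholipid",
                 "glycerophospholipid", "sphingolipid", "sphingolipid",
                 "sphingolipid"),
    stringsAsFactors = FALSE
  )
  if (!is.null(extra)) {
    stopifnot(all(c("code", "fullName", "expectedChainCount", "category")
                  %in% names(extra)))
    reg <- rbind(reg, extra[, names(reg)])
  }
  if (anyDuplicated(reg$code))
    stop("duplicate class codes in registry")
  reg
}

# classes whose first chain is a sphingoid long-chain base
.sphingoidClasses <- c("Cer", "HexCer", "SHexCer", "SM", "PSY")

#' Published per-class concentration means for the Twitcher vs wild-type study
#'
#' Per-class mean concentrations (ug lipid / ug protein) for four nervous
#' system tissues — brain (B), cerebellum (C), spinal cord (SC), sciatic
#' nerve (SN) — in wild-type (WT) and Twitcher homozygote (HOM) mice,
#' together with the published significance stars from per-class t-tests
#' (`*` p < 0.05, `**` p < 0.01, `***` p < 0.001). The ether-linked
#' phosphatidylinositol class (PI-O) was detected only in spinal cord; its
#' rows for the other tissues are absent. These values serve as the default
#' baselines and HOM/WT effect ratios of the synthetic-data generator and as
#' the worked example for class-total aggregation.
#'
#' @param tissue optional tissue code (`"B"`, `"C"`, `"SC"`, `"SN"`) to
#'   subset to; `NULL` returns all tissues.
#' @return A `data.frame` with columns `tissue`, `classCode`, `meanWT`,
#'   `meanHOM` (ug/ug protein) and `stars`.
#' @examples
#' sn <- referenceClassMeans("SN")
#' sum(sn$meanWT)   # grand total, WT sciatic nerve
#' @export
referenceClassMeans <- function(tissue = NULL) {
  cls18 <- c("CE", "Cer", "CL", "DG", "PC-O", "PE-O", "HexCer", "LPC",
             "LPE", "LPI", "PA", "PC", "PE", "PG", "PI", "PS", "SHexCer",
             "SM")
  cls19 <- append(cls18, "PI-O", after = 6L)  # SC only, after PE-O
  tab <- rbind(
    data.frame(tissue = "B", classCode = cls18,
      meanWT  = c(0.087, 0.022, 0.330, 0.115, 0.077, 3.670, 0.029, 0.231,
                  0.406, 0.029, 0.052, 8.254, 2.612, 0.082, 0.438, 3.071,
                  0.021, 0.614),
      meanHOM = c(0.115, 0.023, 0.327, 0.101, 0.076, 3.483, 0.023, 0.239,
                  0.409, 0.024, 0.046, 7.902, 2.590, 0.089, 0.364, 3.009,
                  0.018, 0.617),
      stars   = c("", "", "", "", "", "", "", "", "", "", "", "", "", "",
                  "", "", "*", ""),
      stringsAsFactors = FALSE),
    data.frame(tissue = "C", classCode = cls18,
      meanWT  = c(0.131, 0.055, 0.182, 0.210, 0.908, 5.619, 0.040, 0.251,
                  0.380, 0.042, 0.158, 8.312, 3.254, 0.096, 0.925, 4.182,
                  0.032, 0.186),
      meanHOM = c(0.182, 0.050, 0.203, 0.137, 0.863, 4.557, 0.028, 0.262,
                  0.405, 0.033, 0.092, 7.994, 2.822, 0.097, 0.817, 3.832,
                  0.023, 0.194),
      stars   = c("", "", "", "", "", "*", "*", "", "", "", "", "", "", "",
                  "", "", "***", ""),
      stringsAsFactors = FALSE),
    data.frame(tissue = "SC", classCode = cls19,
      meanWT  = c(0.137, 0.063, 0.143, 0.445, 0.245, 10.399, 0.198, 0.151,
                  0.598, 1.065, 0.054, 2.891, 9.829, 4.621, 0.184, 1.421,
                  6.569, 0.058, 0.893),
      meanHOM = c(0.730, 0.054, 0.217, 0.251, 0.218, 8.169, 0.176, 0.128,
                  0.505, 0.853, 0.040, 1.065, 8.323, 3.724, 0.227, 1.194,
                  5.589, 0.044, 1.056),
      stars   = c("*", "", "", "*", "", "*", "", "", "", "", "*", "*", "*",
                  "", "", "", "", "", ""),
      stringsAsFactors = FALSE),
    data.frame(tissue = "SN", classCode = cls18,
      meanWT  = c(0.169, 0.011, 0.142, 0.466, 0.613, 12.154, 0.193, 0.480,
                  0.424, 0.035, 4.295, 14.912, 3.277, 0.059, 1.146, 2.740,
                  0.070, 2.468),
      meanHOM = c(2.351, 0.012, 0.246, 0.174, 0.287, 4.209, 0.102, 0.401,
                  0.232, 0.023, 0.342, 6.426, 1.245, 0.164, 0.684, 2.980,
                  0.037, 1.771),
      stars   = c("**", "", "", "***", "**", "***", "***", "", "*", "*",
                  "*", "***", "**", "**", "*", "", "**", ""),
      stringsAsFactors = FALSE)
  )
  if (!is.null(tissue)) {
    tissue <- match.arg(tissue, c("B", "C", "SC", "SN"))
    tab <- tab[tab$tissue == tissue, , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}

#' Default internal-standard map
#'
#' Maps each lipid class to its class-matched deuterated internal standard
#' and the standard's effective concentration in the extraction mixture.
#' The default mirrors a 14-component deuterated lipid mix spiked at
#' 100 ug/mL (per component) plus deuterated psychosine (PSY-d5) at
#' 125 ng/mL. Classes without a marked species in the mix (ether
#' phospholipids, hexosylceramide, sulfatide) fall back to the nearest
#' chemistry: diacyl parents for the ether classes and the ceramide standard
#' for the glycosphingolipids; a per-class `responseFactor` is exposed to
#' model the resulting over/under-estimation.
#'
#' @param spikeConcentration in-extract concentration of each mix component,
#'   ug/mL.
#' @param dilutionFactor extra dilution applied to the mix before spiking
#'   (divides `spikeConcentration`).
#' @param psySpike in-extract concentration of the deuterated psychosine
#'   standard, ng/mL.
#' @param responseFactors optional named numeric vector (class code ->
#'   multiplier) applied to the computed concentrations of that class.
#' @return A `data.frame` with columns `classCode`, `isName`, `spike`
#'   (ug/mL; ng/mL for PSY), `unit` and `responseFactor`.
#' @examples
#' defaultISMap()[1:4, ]
#' @export
defaultISMap <- function(spikeConcentration = 100, dilutionFactor = 1,
                         psySpike = 125, responseFactors = NULL) {
  std <- c(
    CE      = "IS CE 18:1(d7)",
    Cer     = "IS Cer 18:1;O2/15:0(d7)",
    CL      = "IS CL 15:0(d5)",
    DG      = "IS DG 15:0_18:1(d7)",
    `PC-O`  = "IS PC 15:0_18:1(d7)",
    `PE-O`  = "IS PE 15:0_18:1(d7)",
    `PI-O`  = "IS PI 15:0_18:1(d7)",
    HexCer  = "IS Cer 18:1;O2/15:0(d7)",
    LPC     = "IS LPC 18:1(d7)",
    LPE     = "IS LPE 18:1(d7)",
    LPI     = "IS LPI 18:1(d7)",
    PA      = "IS PA 15:0_18:1(d7)",
    PC      = "IS PC 15:0_18:1(d7)",
    PE      = "IS PE 15:0_18:1(d7)",
    PG      = "IS PG 15:0_18:1(d7)",
    PI      = "IS PI 15:0_18:1(d7)",
    PS      = "IS PS 15:0_18:1(d7)",
    SHexCer = "IS Cer 18:1;O2/15:0(d7)",
    SM      = "IS SM 18:1;O2/18:1(d9)",
    PSY     = "PSY-d5"
  )
  map <- data.frame(
    classCode = names(std),
    isName = unname(std),
    spike = c(rep(spikeConcentration / dilutionFactor, length(std) - 1L),
              psySpike),
    unit = c(rep("ug/mL", length(std) - 1L), "ng/mL"),
    responseFactor = 1,
    stringsAsFactors = FALSE
  )
  if (!is.null(responseFactors)) {
    idx <- match(names(responseFactors), map$classCode)
    if (anyNA(idx)) stop("responseFactors names must be class codes")
    map$responseFactor[idx] <- responseFactors
  }
  map
}
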