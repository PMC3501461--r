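mkElements <- function(labels, kinds = rep("pfam", length(labels))) {
  data.frame(label = labels, kind = kinds,
             start = seq(1, by = 100, length.out = length(labels)),
             end = seq(50, by = 100, length.out = length(labels)),
             orientation = NA_character_, signal_peptide = FALSE)
}

test_that("function annotation takes the union over auxiliary domains", {
  expect_equal(annotateFunctions(mkElements(c("Bac_PepC14", "WD40",
                                              "TPR_1"))),
               "protein-protein interaction")
  expect_equal(annotateFunctions(mkElements("Bac_PepC14")), "unknown")
  # one domain can carry several functions
  expect_setequal(annotateFunctions(mkElements(c("Bac_PepC14", "DEAD"))),
                  c("helicase", "NTPase"))
  # unannotated domains are unknown rather than an error
  expect_equal(annotateFunctions(mkElements(c("Bac_PepC14",
                                              "Mystery_99"))),
               "unknown")
  # monotone: adding a domain never removes a label
  before <- annotateFunctions(mkElements(c("Bac_PepC14", "WD40")))
  after <- annotateFunctions(mkElements(c("Bac_PepC14", "WD40", "NACHT")))
  expect_true(all(before %in% after))
})

test_that("localization partitions proteins into the five categories", {
  tmhOnly <- mkElements(c("Bac_PepC14", "TMH"), c("pfam", "tmh"))
  expect_equal(classifyLocalization(tmhOnly), "Membrane")
  expect_equal(classifyLocalization(mkElements("Bac_PepC14")), "Unknown")
  both <- mkElements(c("Bac_PepC14", "CHASE2", "TMH"),
                     c("pfam", "pfam", "tmh"))
  expect_equal(classifyLocalization(both), "Membrane and extracellular")
  expect_equal(classifyLocalization(mkElements(c("Bac_PepC14",
                                                 "CHASE2"))),
               "Extracellular")
  expect_equal(classifyLocalization(mkElements(c("Bac_PepC14", "GUN4"))),
               "Intracellular")
})

test_that("molecular weight sums average residue masses plus water", {
  expect_equal(round(molecularWeight(""), 2), 18.02)
  expect_equal(round(molecularWeight("G"), 2), 75.07)
  expect_equal(round(molecularWeight("GG"), 2), 132.12)
  # additivity: MW(a + b) = MW(a) + MW(b) - water
  set.seed(2)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (k in 1:10) {
    a <- paste(sample(aa20, 15, replace = TRUE), collapse = "")
    b <- paste(sample(aa20, 25, replace = TRUE), collapse = "")
    expect_equal(molecularWeight(paste0(a, b)),
                 molecularWeight(a) + molecularWeight(b) - 18.01524)
  }
  expect_error(molecularWeight("GXG"), "non-standard residue")
  expect_gt(molecularWeight("GXG", allowX = TRUE), molecularWeight("GG"))
})
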