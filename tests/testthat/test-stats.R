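test_that("per-genome abundance normalises to metacaspases per 1000
           proteins", {
  genomes <- data.frame(
    genome_id = c("g1", "g2"), organism = "o",
    group = "Bacteroidetes", superkingdom = "Bacteria",
    protein_count = c(6747L, 3000L))
  arch <- data.frame(protein_id = sprintf("p%02d", 1:28),
                     genome_id = "g1", canonical = "Bac_PepC14",
                     is_metacaspase = TRUE)
  ab <- genomeAbundance(arch, genomes)
  expect_equal(ab$abundance_2dp[ab$genome_id == "g1"], 4.15)
  expect_equal(ab$metacaspase_count[ab$genome_id == "g2"], 0L)
  expect_equal(ab$abundance[ab$genome_id == "g2"], 0)
  expect_equal(ab$abundance, 1000 * ab$metacaspase_count /
                 ab$protein_count, tolerance = 1e-12)

  arch$genome_id <- "gX"
  expect_error(genomeAbundance(arch, genomes), "missing")
})

test_that("group summaries fold small metacaspase-free groups into
           Other and order by mean abundance", {
  genomes <- data.frame(
    genome_id = sprintf("g%02d", 1:10), organism = "o",
    group = c(rep("Cyanobacteria", 4), rep("Firmicutes", 3),
              rep("Tenericutes", 3)),
    superkingdom = "Bacteria", protein_count = 1000L)
  arch <- data.frame(protein_id = c("a", "b", "c"),
                     genome_id = c("g01", "g01", "g05"),
                     canonical = "Bac_PepC14", is_metacaspase = TRUE)
  ab <- genomeAbundance(arch, genomes)
  gs <- groupSummary(ab)
  # Tenericutes: 3 genomes, no metacaspases -> folded into Other
  expect_false("Tenericutes" %in% gs$group)
  expect_true("Other" %in% gs$group)
  expect_equal(sum(gs$n_genomes), 10L)
  cy <- gs[gs$group == "Cyanobacteria", ]
  expect_equal(cy$mean_abundance, mean(c(2, 0, 0, 0)))
  # ordered by descending mean abundance, Other last
  expect_equal(gs$group[1], "Cyanobacteria")
  expect_equal(gs$group[nrow(gs)], "Other")
  # abundance bins partition genomes within each group
  binCols <- grep("^bin_", names(gs), value = TRUE)
  expect_equal(rowSums(gs[, binCols]), gs$n_genomes,
               ignore_attr = TRUE)
  # mean invariant under genome order
  gs2 <- groupSummary(ab[sample(nrow(ab)), ])
  expect_equal(gs2$mean_abundance, gs$mean_abundance)
})

test_that("survey percentages use half-away-from-zero rounding", {
  expect_identical(surveyPercentage(267, 1463, 0), 18)
  expect_identical(surveyPercentage(73, 671, 1), 10.9)
  expect_identical(surveyPercentage(0, 10, 1), 0)
  expect_identical(surveyPercentage(5, 1000, 1), 0.5)  # exact half, up
  expect_error(surveyPercentage(1, 0), "zero denominator")
  # complements sum to 100 within one rounding step
  set.seed(6)
  for (k in 1:50) {
    b <- sample(10:2000, 1)
    a <- sample(0:b, 1)
    s <- surveyPercentage(a, b, 1) + surveyPercentage(b - a, b, 1)
    expect_true(abs(s - 100) <= 0.1)
  }
})
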