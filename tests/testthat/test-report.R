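test_that("config validation fills defaults and rejects bad values", {
  cfg <- validateConfig(NULL)
  expect_equal(cfg$max_i_evalue, 0.01)
  expect_equal(cfg$min_score_bias_ratio, 10)
  expect_equal(cfg$low_coverage_threshold, 0.60)
  expect_equal(cfg$conflict_fraction, 0.25)
  expect_equal(cfg$identity_threshold, 0.90)

  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", f)
  expect_equal(validateConfig(f), cfg)  # empty file -> all defaults
  writeLines("identity_threshold: 1.5", f)
  expect_error(validateConfig(f), "identity_threshold")
  writeLines("no_such_option: 1", f)
  expect_error(validateConfig(f), "unknown config key")
})

test_that("an overridden conflict fraction propagates to resolution", {
  # two domains overlapping 40% of the shorter: conflict at 0.25,
  # no conflict at 0.5
  aa <- Biostrings::AAStringSet(c(p1 = paste(rep("A", 200),
                                             collapse = "")))
  S4Vectors::mcols(aa)$genome_id <- "g1"
  hits <- rbind(
    makeHit("p1", "WD40", model_length = 100L, hmm_to = 100L,
            env_from = 1L, env_to = 100L, i_evalue = 1e-10),
    makeHit("p1", "Sel1", model_length = 100L, hmm_to = 100L,
            env_from = 61L, env_to = 160L, i_evalue = 1e-5))
  genomes <- data.frame(genome_id = "g1", organism = "o",
                        group = "Cyanobacteria",
                        superkingdom = "Bacteria",
                        protein_count = 100L)
  survey <- MetacaspaseSurvey(aa, hits, genomes = genomes,
                              annotations = defaultDomainAnnotations())
  strict <- runSurvey(survey)
  expect_equal(nrow(architectures(strict)), 1L)
  expect_equal(architectures(strict)$canonical, "WD40")
  loose <- runSurvey(survey, list(conflict_fraction = 0.5))
  expect_equal(architectures(loose)$canonical, "WD40|Sel1")
})

test_that("the report's totals match the planted manifest", {
  outdir <- withr::local_tempdir()
  truth <- simulateSurvey(simulationConfig(seed = 41, nGenomes = 60),
                          outdir)
  report <- runSurvey(readSurvey(outdir))
  planted <- plantedTruth(truth)
  t <- surveyTotals(report)
  expect_equal(t$metacaspases, nrow(planted))
  perGenome <- table(planted$genome_id)
  expect_equal(t$metacaspase_genomes, length(perGenome))
  expect_equal(t$single_carriers, sum(perGenome == 1))
  expect_equal(t$multi_carriers, sum(perGenome >= 2))
  expect_equal(t$metacaspase_genome_pct,
               surveyPercentage(length(perGenome), t$genomes, 0))
  expect_equal(t$dyad_positive,
               sum(planted$dyad_status == "Positive"))
})

test_that("a survey of pure decoys reports zero metacaspase genomes", {
  outdir <- withr::local_tempdir()
  simulateSurvey(simulationConfig(seed = 3, nGenomes = 20,
                                  pPositiveGenome = 0, decoyHitRate = 3),
                 outdir)
  report <- runSurvey(readSurvey(outdir))
  t <- surveyTotals(report)
  expect_equal(t$metacaspases, 0L)
  expect_equal(t$metacaspase_genomes, 0L)
  expect_equal(t$metacaspase_genome_pct, 0)
})

test_that("re-running the pipeline writes bit-identical reports", {
  outdir <- withr::local_tempdir()
  simulateSurvey(simulationConfig(seed = 9, nGenomes = 30), outdir)
  survey <- readSurvey(outdir)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writeSurveyReport(runSurvey(survey), d1)
  writeSurveyReport(runSurvey(survey), d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  expect_true(file.exists(file.path(d1, "report.json")))
})
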