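test_that("identical seed and config give byte-identical outputs", {
  cfg <- simulationConfig(seed = 1, nGenomes = 10, pPositiveGenome = 0.5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulateSurvey(cfg, d1)
  simulateSurvey(cfg, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
})

test_that("screening accepts exactly the planted hits, decoys fail", {
  outdir <- withr::local_tempdir()
  truth <- simulateSurvey(simulationConfig(seed = 5, nGenomes = 60,
                                           decoyHitRate = 2), outdir)
  hits <- readDomainHits(file.path(outdir, "hits.tsv"))
  sc <- screenHits(hits)
  manifest <- truth@hits
  expect_gt(sum(!manifest$planted), 10)  # decoys actually present
  key <- function(h) paste(h$protein_id, h$domain_name, h$env_from)
  expect_setequal(key(sc$accepted), key(manifest[manifest$planted, ]))
  expect_setequal(key(sc$rejected), key(manifest[!manifest$planted, ]))
})

test_that("planted dyad statuses are recovered exactly", {
  outdir <- withr::local_tempdir()
  truth <- simulateSurvey(
    simulationConfig(seed = 17, nGenomes = 80, pDyadNegative = 0.25),
    outdir)
  survey <- readSurvey(outdir)
  planted <- plantedTruth(truth)
  hits <- screenHits(domainHits(survey))$accepted
  mcHits <- hits[hits$domain_name == METACASPASE_LABEL &
                   hits$protein_id %in% planted$protein_id, ]
  env <- extractEnvelopes(mcHits, proteins(survey))
  dy <- classifyDyads(setNames(env$envelope, env$protein_id),
                      defaultDyadReference())
  m <- match(planted$protein_id, dy$protein_id)
  expect_false(anyNA(m))
  expect_equal(dy$status[m], planted$dyad_status)
  # the planted Negative count is recovered exactly
  expect_equal(sum(dy$status == "Negative"),
               sum(planted$dyad_status == "Negative"))
})

test_that("a degenerate empty survey yields an empty but valid report", {
  rec <- endToEndRecovery(simulationConfig(seed = 2, nGenomes = 0,
                                           decoyHitRate = 0),
                          outdir = withr::local_tempdir())
  expect_equal(rec$n_planted, 0L)
  expect_true(is.na(rec$identification))
})

test_that("palette validation rejects unknown domain names", {
  pal <- defaultArchitecturePalette()
  pal[[1]]$elements$label <- "Nonexistent_domain"
  expect_error(simulationConfig(palette = pal), "unknown domain name")
  pal2 <- defaultArchitecturePalette()
  pal2[[1]]$weight <- 0.9
  expect_error(simulationConfig(palette = pal2), "sum to 1")
})

test_that("full pipeline recovery is exact on a small survey", {
  rec <- endToEndRecovery(simulationConfig(seed = 23, nGenomes = 60),
                          outdir = withr::local_tempdir())
  expect_gt(rec$n_planted, 5)
  expect_equal(rec$identification, 1)
  expect_equal(rec$architecture, 1)
  expect_equal(rec$dyad, 1)
  expect_equal(rec$operon, 1)
  expect_equal(rec$abundance, 1)
})
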