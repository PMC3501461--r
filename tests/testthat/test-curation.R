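test_that("envelope extraction uses inclusive 1-based slices", {
  p <- Biostrings::AAStringSet(c(p1 = "MAAACHWWW"))
  h <- makeHit("p1", model_length = 3L, hmm_to = 3L, env_from = 4L,
               env_to = 6L)
  expect_equal(extractEnvelopes(h, p)$envelope, "ACH")
  h$env_to <- 50L
  expect_error(extractEnvelopes(h, p), "envelope out of range")
  h$protein_id <- "p9"
  expect_error(extractEnvelopes(h, p), "no sequence for protein p9")
})

test_that("extracted envelopes equal the planted domain segments", {
  outdir <- withr::local_tempdir()
  truth <- simulateSurvey(simulationConfig(seed = 13, nGenomes = 40),
                          outdir)
  survey <- readSurvey(outdir)
  hits <- domainHits(survey)
  ref <- defaultDyadReference()
  mcHits <- hits[hits$domain_name == METACASPASE_LABEL &
                   hits$protein_id %in% plantedTruth(truth)$protein_id, ]
  env <- extractEnvelopes(mcHits, proteins(survey))
  expect_gt(nrow(env), 10)
  # positive-dyad envelopes are exactly the reference sequence
  status <- plantedTruth(truth)$dyad_status[
    match(env$protein_id, plantedTruth(truth)$protein_id)]
  expect_true(all(env$envelope[status == "Positive"] == ref@sequence))
  # negative ones differ from it in exactly one position
  neg <- env$envelope[status == "Negative"]
  diffs <- vapply(neg, function(e)
    sum(strsplit(e, "")[[1]] != strsplit(ref@sequence, "")[[1]]), 0)
  expect_true(all(diffs == 1))
})

test_that("the dyad filter retains exactly the Positive envelopes", {
  ref <- defaultDyadReference()
  mut <- function(pos, to) {
    s <- strsplit(ref@sequence, "")[[1]]
    s[pos] <- to
    paste(s, collapse = "")
  }
  env <- data.frame(
    protein_id = sprintf("p%02d", 1:40),
    env_from = 1L, env_to = 252L,
    envelope = c(rep(ref@sequence, 25), rep(mut(ref@hisPos, "Y"), 10),
                 rep(mut(ref@cysPos, "S"), 5)),
    stringsAsFactors = FALSE)
  kept <- dyadFilter(env, ref)
  expect_equal(nrow(kept), 25L)
  expect_equal(kept$protein_id, sprintf("p%02d", 1:25))
  expect_equal(dyadFilter(kept, ref), kept)  # idempotent
})

test_that("greedy clustering joins at the identity threshold", {
  env <- data.frame(protein_id = c("a", "b"), env_from = 1L,
                    env_to = 10L,
                    envelope = c("AAAAAAAAAA", "AAAAAAAAAA"))
  cl <- clusterRepresentatives(env)
  expect_equal(nrow(cl$representatives), 1L)

  env$envelope <- c("AAAAAAAAAA", "AAAAAAAAAC")  # identity 9/10 = 0.90
  cl2 <- clusterRepresentatives(env, identityThreshold = 0.90)
  expect_equal(max(cl2$members$cluster), 1L)
  cl3 <- clusterRepresentatives(env, identityThreshold = 0.95)
  expect_equal(max(cl3$members$cluster), 2L)
})

test_that("clustering satisfies the membership rule post-hoc and the
           cluster count is monotone in the threshold", {
  set.seed(8)
  base <- strsplit("ACDEFGHIKLMNPQRSTVWYACDEFGHIKL", "")[[1]]
  envs <- vapply(1:12, function(i) {
    s <- base
    nmut <- sample(0:8, 1)
    if (nmut > 0) {
      at <- sample(length(s), nmut)
      s[at] <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                      nmut, replace = TRUE)
    }
    paste(s, collapse = "")
  }, "")
  env <- data.frame(protein_id = sprintf("p%02d", 1:12), env_from = 1L,
                    env_to = 30L, envelope = envs)
  prev <- 0L
  for (thr in c(0.5, 0.7, 0.9, 1.0)) {
    cl <- clusterRepresentatives(env, thr)
    expect_true(checkClusterMembership(cl$members, thr))
    k <- nrow(cl$representatives)
    expect_gte(k, prev)  # stricter identity -> at least as many clusters
    prev <- k
  }
})

test_that("the full curation pass composes and reports quality", {
  outdir <- withr::local_tempdir()
  truth <- simulateSurvey(simulationConfig(seed = 31, nGenomes = 30),
                          outdir)
  survey <- readSurvey(outdir)
  accepted <- screenHits(domainHits(survey))$accepted
  mcHits <- accepted[accepted$domain_name == METACASPASE_LABEL, ]
  cur <- curateTrainingSet(mcHits, proteins(survey),
                           defaultDyadReference())
  planted <- plantedTruth(truth)
  expect_equal(cur$n_dyad_positive,
               sum(planted$dyad_status == "Positive"))
  # all Positive envelopes are identical -> a single representative
  expect_equal(nrow(cur$representatives), 1L)
  expect_equal(cur$report$identity, 1)
  expect_equal(cur$report$terminal_gap_fraction, 0)
})
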