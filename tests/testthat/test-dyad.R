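B62 <- metacaspase:::blosum62()

test_that("global alignment is optimal and deterministic", {
  self <- globalAlign("ACH", "ACH")
  expect_equal(self$aligned_a, "ACH")
  expect_equal(self$score, B62["A", "A"] + B62["C", "C"] + B62["H", "H"])

  gapped <- globalAlign("ACGH", "ACH")
  expect_equal(gapped$score,
               bruteForceAlignScore("ACGH", "ACH", B62, 8))
  expect_equal(nchar(gapped$aligned_a), nchar(gapped$aligned_b))

  expect_error(globalAlign("AC1H", "ACH"), "not in substitution matrix")
  expect_error(globalAlign("", "ACH"), "non-empty")
})

test_that("alignment scores match brute-force enumeration on random pairs", {
  set.seed(5)
  aa <- rownames(B62)[1:20]
  for (k in 1:50) {
    a <- paste(sample(aa, sample(1:8, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aa, sample(1:8, 1), replace = TRUE), collapse = "")
    expect_equal(globalAlign(a, b)$score,
                 bruteForceAlignScore(a, b, B62, 8))
    # symmetry under argument swap (BLOSUM62 is symmetric)
    expect_equal(globalAlign(a, b)$score, globalAlign(b, a)$score)
  }
})

test_that("dyad classification reads the catalytic columns", {
  ref <- defaultDyadReference()
  expect_equal(classifyDyad(ref@sequence, ref)$status, "Positive")

  s <- strsplit(ref@sequence, "")[[1]]
  s[ref@cysPos] <- "S"
  r <- classifyDyad(paste(s, collapse = ""), ref)
  expect_equal(r$status, "Negative")
  expect_equal(r$residue_at_cys, "S")
  expect_equal(r$residue_at_his, "H")

  s <- strsplit(ref@sequence, "")[[1]]
  s[ref@hisPos] <- "Y"
  r2 <- classifyDyad(paste(s, collapse = ""), ref)
  expect_equal(r2$status, "Negative")
  expect_equal(r2$residue_at_his, "Y")

  # an envelope covering only the far C-terminus leaves both catalytic
  # columns in a terminal gap: Negative with low confidence
  tail <- substr(ref@sequence, 200, 252)
  r3 <- classifyDyad(tail, ref)
  expect_equal(r3$status, "Negative")
  expect_true(r3$low_confidence)
})

test_that("a small annotated reference works end to end", {
  ref <- DyadReference("MAHACA", cysPos = 5, hisPos = 3)
  expect_equal(classifyDyad("MAHACA", ref)$status, "Positive")
  expect_equal(classifyDyad("MAYACA", ref)$status, "Negative")
  expect_error(DyadReference("MAAACA", cysPos = 5, hisPos = 3),
               "must be 'H'")
  expect_error(DyadReference("MAHAAA", cysPos = 5, hisPos = 3),
               "must be 'C'")
})

test_that("substitution profiles tally conservation per group", {
  ref <- defaultDyadReference()
  mut <- function(pos, to) {
    s <- strsplit(ref@sequence, "")[[1]]
    s[pos] <- to
    paste(s, collapse = "")
  }
  envs <- c(rep(ref@sequence, 9),
            mut(ref@cysPos, "S"), mut(ref@cysPos, "S"),
            mut(ref@cysPos, "S"), mut(ref@cysPos, "G"),
            mut(ref@hisPos, "Y"), mut(ref@hisPos, "Y"),
            mut(ref@hisPos, "R"))
  names(envs) <- sprintf("p%02d", seq_along(envs))
  dy <- classifyDyads(envs, ref)
  groups <- c(rep("Alphaproteobacteria", 12), rep("Cyanobacteria", 4))
  # Alphaproteobacteria: 9 of 12 positive = 75%
  prof <- substitutionProfile(dy, groups)
  alpha <- prof$by_group[prof$by_group$group == "Alphaproteobacteria", ]
  expect_equal(alpha$conservation_pct, 75)
  # counts aggregate: weighted group positives equal the overall total
  expect_equal(sum(prof$by_group$n_positive), 9)
  # among cysteine substitutions, 3 of 4 are serine = 75%
  sset <- prof$cys_substitutions
  expect_equal(sset$count[sset$residue == "S"], 3L)
  expect_equal(sset$percent[sset$residue == "S"],
               surveyPercentage(3, 4, 0))
  hset <- prof$his_substitutions
  expect_equal(hset$count[hset$residue == "Y"], 2L)
})
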