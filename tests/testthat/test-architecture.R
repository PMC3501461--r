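test_that("overlap conflicts resolve by lowest E-value", {
  disjoint <- rbind(
    makeHit(domain_name = "A", env_from = 1L, env_to = 100L),
    makeHit(domain_name = "B", env_from = 120L, env_to = 160L))
  expect_equal(nrow(resolveDomainConflicts(disjoint)), 2L)

  # overlap 20 residues = 20% of A (len 100) but 50% of B (len 40):
  # conflict under the either-one rule; A has the lower E-value
  pair <- rbind(
    makeHit(domain_name = "A", env_from = 1L, env_to = 100L,
            i_evalue = 1e-5),
    makeHit(domain_name = "B", env_from = 81L, env_to = 120L,
            i_evalue = 1e-3))
  out <- resolveDomainConflicts(pair)
  expect_equal(out$domain_name, "A")
})

test_that("conflict resolution matches the declarative oracle and is
           order-independent", {
  set.seed(99)
  for (rep in 1:60) {
    hits <- randomHitSet(sample(1:8, 1))
    got <- resolveDomainConflicts(hits)
    want <- subsetConflictOracle(hits)
    expect_equal(got, want, ignore_attr = TRUE)
    perm <- hits[sample(nrow(hits)), , drop = FALSE]
    expect_equal(resolveDomainConflicts(perm), got, ignore_attr = TRUE)
    # post-hoc: no surviving pair violates the overlap rule
    if (nrow(got) > 1) {
      for (i in seq_len(nrow(got) - 1)) for (j in (i + 1):nrow(got)) {
        ov <- min(got$env_to[i], got$env_to[j]) -
          max(got$env_from[i], got$env_from[j]) + 1
        lmin <- min(got$env_to[i] - got$env_from[i],
                    got$env_to[j] - got$env_from[j]) + 1
        expect_lte(ov, 0.25 * lmin)
      }
    }
  }
})

test_that("helices integrate with Pfam precedence and orientation", {
  surv <- makeHit("p1", "CHASE2", env_from = 1L, env_to = 100L)
  seg <- data.frame(protein_id = "p1",
                    kind = c("inside", "helix", "outside"),
                    start = c(1L, 11L, 34L), end = c(10L, 33L, 200L))
  el <- integrateTopology(surv, seg)
  expect_equal(el$kind, "pfam")  # helix inside the domain is dropped

  # lone N-terminal helix preceding the domain: retained signal peptide
  surv2 <- makeHit("p1", "Bac_PepC14", env_from = 40L, env_to = 290L)
  seg2 <- data.frame(protein_id = "p1",
                     kind = c("inside", "helix", "outside"),
                     start = c(1L, 5L, 28L), end = c(4L, 27L, 300L))
  el2 <- integrateTopology(surv2, seg2)
  tmh <- el2[el2$kind == "tmh", ]
  expect_equal(nrow(tmh), 1L)
  expect_true(tmh$signal_peptide)
  expect_equal(tmh$orientation, "iTMHo")  # inside before, outside after

  seg3 <- seg2
  seg3$kind <- c("outside", "helix", "inside")
  el3 <- integrateTopology(surv2, seg3)
  expect_equal(el3$orientation[el3$kind == "tmh"], "oTMHi")

  expect_error(integrateTopology(surv,
    data.frame(protein_id = "pX", kind = "helix", start = 1L, end = 21L)),
    "different proteins")
})

test_that("architectures collapse repeats and apply the acceptance rule", {
  el <- data.frame(label = c("WD40", "WD40", "WD40"), kind = "pfam",
                   start = c(1L, 50L, 100L), end = c(40L, 90L, 140L),
                   orientation = NA_character_, signal_peptide = FALSE)
  a <- buildArchitecture(el, "p1")
  expect_equal(nrow(a$elements), 1L)
  expect_equal(a$elements$repeat_count, 3L)
  expect_equal(a$canonical, "WD40")
  expect_false(a$is_metacaspase)

  el2 <- data.frame(label = c("Bac_PepC14", "FGE-sulfatase"),
                    kind = "pfam", start = c(1L, 300L),
                    end = c(252L, 480L), orientation = NA_character_,
                    signal_peptide = FALSE)
  a2 <- buildArchitecture(el2, "p2")
  expect_equal(a2$canonical, "Bac_PepC14|FGE-sulfatase")
  expect_true(a2$is_metacaspase)

  # canonical key ignores repeat counts: collapsing is idempotent
  a3 <- buildArchitecture(a$elements, "p1")
  expect_equal(a3$canonical, a$canonical)
  expect_equal(a3$elements$repeat_count, 1L)

  empty <- el[0, ]
  a4 <- buildArchitecture(empty, "p0")
  expect_equal(a4$canonical, "")
  expect_false(a4$is_metacaspase)
})

test_that("a metacaspase hit displaced in conflict resolution excludes
           the sequence from the survey", {
  hits <- rbind(
    makeHit("p1", "TPR_1", env_from = 1L, env_to = 260L,
            i_evalue = 1e-20),
    makeHit("p1", "Bac_PepC14", model_length = 252L, hmm_to = 240L,
            env_from = 10L, env_to = 250L, i_evalue = 1e-6))
  surv <- resolveDomainConflicts(hits)
  a <- buildArchitecture(integrateTopology(surv), "p1")
  expect_equal(a$canonical, "TPR_1")
  expect_false(a$is_metacaspase)
})

test_that("the architecture census counts keys, groups and prevalence", {
  arch <- data.frame(
    protein_id = sprintf("p%d", 1:5),
    genome_id = c("g1", "g1", "g1", "g2", "g2"),
    canonical = c("A|B", "A|B", "A|B", "A|B", "C"),
    is_metacaspase = TRUE, n_elements = 2L, has_tmh = FALSE)
  genomes <- data.frame(genome_id = c("g1", "g2"), organism = "o",
                        group = c("Cyanobacteria", "Firmicutes"),
                        superkingdom = "Bacteria", protein_count = 1000L)
  elements <- data.frame(protein_id = c("p1", "p2", "p3", "p4", "p5"),
                         label = c("WD40", "WD40", "WD40", "WD40", "Sel1"),
                         kind = "pfam", start = 1L, end = 40L,
                         orientation = NA, signal_peptide = FALSE,
                         repeat_count = 1L)
  cen <- architectureCensus(arch, elements, genomes,
                            metacaspaseLabel = "ZZZ")
  ab <- cen$census[cen$census$canonical == "A|B", ]
  expect_equal(ab$n_sequences, 4L)
  expect_equal(ab$n_groups, 2L)
  expect_false(ab$group_unique)
  expect_true(cen$census$group_unique[cen$census$canonical == "C"])
  wd <- cen$prevalence[cen$prevalence$domain_name == "WD40", ]
  expect_equal(wd$n_sequences, 4L)
  expect_equal(wd$percent, surveyPercentage(4, 5, 1))
})

test_that("per-domain prevalence reproduces printed-style percentages", {
  # 73 of 671 metacaspases carrying a domain reports as 10.9%
  expect_equal(surveyPercentage(73, 671, 1), 10.9)
})
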