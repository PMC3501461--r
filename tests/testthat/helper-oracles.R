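# Independent oracles and small fixture builders used across the suite.

# Convenience hit constructor
makeHit <- function(protein_id = "p1", domain_name = "dom",
                    model_length = 100L, hmm_from = 1L,
                    hmm_to = model_length, env_from = 1L,
                    env_to = 100L, i_evalue = 1e-10, score = 100,
                    bias = 0) {
  data.frame(protein_id = protein_id, domain_name = domain_name,
             model_length = as.integer(model_length),
             hmm_from = as.integer(hmm_from), hmm_to = as.integer(hmm_to),
             env_from = as.integer(env_from), env_to = as.integer(env_to),
             i_evalue = i_evalue, score = score, bias = bias,
             stringsAsFactors = FALSE)
}

# Brute-force global alignment score by exhaustive path enumeration
# (no dynamic-programming table, no memoisation).
bruteForceAlignScore <- function(a, b, submat, gap) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0)
      best <- max(best, rec(i - 1, j - 1) + submat[av[i], bv[j]])
    if (i > 0) best <- max(best, rec(i - 1, j) - gap)
    if (j > 0) best <- max(best, rec(i, j - 1) - gap)
    best
  }
  rec(length(av), length(bv))
}

# Declarative oracle for overlap-conflict resolution: enumerate all
# subsets of hits and find those that are (1) conflict-free and
# (2) complete -- every excluded hit conflicts with a strictly
# better-ranked member of the subset. Returns the surviving protein-level
# hit rows; asserts the solution is unique.
subsetConflictOracle <- function(hits, frac = 0.25) {
  n <- nrow(hits)
  if (n == 0) return(hits)
  len <- hits$env_to - hits$env_from + 1
  ord <- order(hits$i_evalue, -len, hits$domain_name, hits$env_from,
               hits$env_to)
  h <- hits[ord, , drop = FALSE]
  conf <- function(i, j) {
    ov <- min(h$env_to[i], h$env_to[j]) -
      max(h$env_from[i], h$env_from[j]) + 1
    li <- h$env_to[i] - h$env_from[i] + 1
    lj <- h$env_to[j] - h$env_from[j] + 1
    ov > 0 && ov > frac * min(li, lj)
  }
  solutions <- list()
  for (mask in 0:(2^n - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    ok <- TRUE
    if (length(S) > 1)
      for (i in S) for (j in S)
        if (i < j && conf(i, j)) { ok <- FALSE }
    if (!ok) next
    for (k in setdiff(seq_len(n), S)) {
      better <- S[S < k]
      if (length(better) == 0 ||
          !any(vapply(better, function(j) conf(k, j), TRUE))) {
        ok <- FALSE
        break
      }
    }
    if (ok) solutions[[length(solutions) + 1]] <- S
  }
  stopifnot(length(solutions) == 1)
  out <- h[solutions[[1]], , drop = FALSE]
  out[order(out$env_from, out$env_to), , drop = FALSE]
}

randomHitSet <- function(n, proteinId = "p1") {
  from <- sample(1:150, n, replace = TRUE)
  len <- sample(10:80, n, replace = TRUE)
  makeHit(protein_id = proteinId,
          domain_name = sample(c("A", "B", "C", "D"), n, replace = TRUE),
          model_length = len, hmm_from = 1L, hmm_to = len,
          env_from = from, env_to = from + len - 1L,
          i_evalue = signif(10^runif(n, -30, -2), 3),
          score = round(runif(n, 50, 200), 1), bias = 0)
}

# Post-hoc check of the greedy clustering membership rule:
# each member is >= threshold-identical to its representative and
# < threshold to every cluster founded earlier than its own.
checkClusterMembership <- function(members, threshold) {
  reps <- members[members$is_representative, , drop = FALSE]
  reps <- reps[order(reps$cluster), , drop = FALSE]
  for (i in seq_len(nrow(members))) {
    m <- members[i, ]
    idSelf <- metacaspase::alignmentIdentity(
      reps$envelope[reps$cluster == m$cluster], m$envelope)
    if (idSelf < threshold && !m$is_representative) return(FALSE)
    earlier <- reps[reps$cluster < m$cluster, , drop = FALSE]
    for (j in seq_len(nrow(earlier))) {
      if (metacaspase::alignmentIdentity(earlier$envelope[j],
                                         m$envelope) >= threshold)
        return(FALSE)
    }
  }
  TRUE
}

# Minimal hand-built survey: two genomes, one metacaspase with an
# N-terminal helix, one decoy-only genome.
tinySurvey <- function() {
  ref <- defaultDyadReference()
  mcSeq <- paste0(paste(rep("A", 40), collapse = ""), ref@sequence,
                  paste(rep("G", 20), collapse = ""))
  aa <- Biostrings::AAStringSet(c(p1 = mcSeq, p2 = "MKKLLVVAAGG"))
  S4Vectors::mcols(aa)$genome_id <- c("g1", "g2")
  hits <- rbind(
    makeHit("p1", METACASPASE_LABEL, 252L, 1L, 240L, 41L, 292L,
            i_evalue = 1e-30, score = 150, bias = 0.5),
    makeHit("p2", "WD40", 40L, 1L, 40L, 2L, 11L, i_evalue = 0.5,
            score = 30, bias = 1))
  topo <- data.frame(protein_id = "p1",
                     kind = c("inside", "helix", "outside"),
                     start = c(1L, 6L, 29L), end = c(5L, 28L, 312L),
                     stringsAsFactors = FALSE)
  genomes <- data.frame(
    genome_id = c("g1", "g2"), organism = c("Org one", "Org two"),
    group = c("Cyanobacteria", "Firmicutes"),
    superkingdom = "Bacteria", protein_count = c(3000L, 2500L),
    stringsAsFactors = FALSE)
  MetacaspaseSurvey(aa, hits, topo, genomes,
                    annotations = defaultDomainAnnotations())
}
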