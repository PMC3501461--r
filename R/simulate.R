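# Synthetic survey generator. Emits every input the pipeline consumes --
# FASTA proteins, per-domain hit table, topology segments, genome and
# operon tables, annotations -- together with a planted ground-truth
# manifest, so that end-to-end recovery can be scored exactly.

GROUP_POOL <- data.frame(
  group = c("Cyanobacteria", "Alphaproteobacteria", "Deltaproteobacteria",
            "Gammaproteobacteria", "Firmicutes", "Bacteroidetes",
            "Actinobacteria", "Chloroflexi", "Spirochaetes",
            "Euryarchaeota"),
  superkingdom = c(rep("Bacteria", 9), "Archaea"),
  stringsAsFactors = FALSE)

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Default architecture palette of the synthetic survey
#'
#' Each entry plants one architecture: \code{key} is the canonical key
#' the pipeline must recover after conflict resolution and topology
#' integration; \code{weight}s sum to one; \code{elements} lists the
#' planted parts N to C with roles \code{pfam} (hit that passes screening
#' and survives), \code{conflict_pfam} (passing hit placed to overlap the
#' preceding domain by more than the conflict fraction, with a strictly
#' higher E-value, so it must lose), \code{tmh} (helix that must be
#' retained) and \code{shadow_tmh} (helix placed inside the preceding
#' Pfam domain, so it must be dropped). \code{startSide} seeds the
#' topology alternation.
#'
#' @return list of palette entries.
#' @export
defaultArchitecturePalette <- function() {
  el <- function(label, role, len)
    data.frame(label = label, role = role, len = len,
               stringsAsFactors = FALSE)
  list(
    list(key = "Bac_PepC14", weight = 0.45, startSide = "inside",
         elements = el("Bac_PepC14", "pfam", 252)),
    list(key = "TMH|Bac_PepC14", weight = 0.12, startSide = "outside",
         elements = rbind(el("TMH", "tmh", 21),
                          el("Bac_PepC14", "pfam", 252))),
    list(key = "Bac_PepC14|FGE-sulfatase", weight = 0.10,
         startSide = "inside",
         elements = rbind(el("Bac_PepC14", "pfam", 252),
                          el("FGE-sulfatase", "pfam", 180))),
    list(key = "Bac_PepC14|NACHT|WD40", weight = 0.10,
         startSide = "inside",
         elements = rbind(el("Bac_PepC14", "pfam", 252),
                          el("NACHT", "pfam", 160),
                          el("WD40", "pfam", 40),
                          el("WD40", "pfam", 40),
                          el("WD40", "pfam", 40))),
    list(key = "Polysacc_deac_1|Bac_PepC14|TPR_1", weight = 0.08,
         startSide = "inside",
         elements = rbind(el("Polysacc_deac_1", "pfam", 115),
                          el("Bac_PepC14", "pfam", 252),
                          el("TPR_1", "pfam", 34))),
    list(key = "Bac_PepC14|TMH", weight = 0.07, startSide = "inside",
         elements = rbind(el("Bac_PepC14", "pfam", 252),
                          el("TMH", "tmh", 21))),
    list(key = "Bac_PepC14|CHASE2|TMH", weight = 0.05,
         startSide = "inside",
         elements = rbind(el("Bac_PepC14", "pfam", 252),
                          el("CHASE2", "pfam", 200),
                          el("Sel1", "conflict_pfam", 80),
                          el("TMH", "shadow_tmh", 21),
                          el("TMH", "tmh", 21))),
    list(key = "Bac_PepC14|Amidase_2", weight = 0.03,
         startSide = "inside",
         elements = rbind(el("Bac_PepC14", "pfam", 252),
                          el("Amidase_2", "pfam", 125)))
  )
}

#' Configuration of the synthetic survey generator
#'
#' Defaults emulate the aggregate structure of a finished-genome survey:
#' 18\% of genomes carry at least one metacaspase, copy numbers follow a
#' zero-truncated geometric distribution, 16\% of planted domains carry a
#' substituted catalytic dyad (cysteine to serine, histidine to
#' tyrosine as the canonical substitutions), and about half of the
#' metacaspases in operon-covered genomes sit inside predicted operons.
#'
#' @param seed master seed; identical seed + config give byte-identical
#'   output files.
#' @param nGenomes number of genomes.
#' @param pPositiveGenome probability a genome carries metacaspases
#'   (default 0.18).
#' @param copyNumberMean mean of the zero-truncated geometric copy-number
#'   distribution (default 2.5).
#' @param proteomeSizeRange integer range of proteome sizes
#'   (default 2000-8000).
#' @param palette architecture palette
#'   (\code{\link{defaultArchitecturePalette}}).
#' @param pDyadNegative probability a planted metacaspase domain has a
#'   substituted dyad; scalar, or named by group (default 0.16).
#' @param decoyHitRate expected number of sub-threshold decoy hits per
#'   genome (default 1).
#' @param pInOperon probability a metacaspase in an operon-covered genome
#'   lies inside a predicted operon (default 0.47).
#' @param pOperonComembership probability a further in-operon metacaspase
#'   of the same genome joins the previous metacaspase's operon rather
#'   than founding its own (default 0.15; operons hold at most three).
#' @param operonCoverage fraction of genomes covered by operon
#'   predictions (default 0.75).
#' @param nGroups number of taxonomic groups drawn from the built-in pool
#'   (default 6).
#' @return validated config list of class \code{simulationConfig}.
#' @export
simulationConfig <- function(seed = 1L, nGenomes = 50L,
                             pPositiveGenome = 0.18,
                             copyNumberMean = 2.5,
                             proteomeSizeRange = c(2000L, 8000L),
                             palette = defaultArchitecturePalette(),
                             pDyadNegative = 0.16,
                             decoyHitRate = 1,
                             pInOperon = 0.47,
                             pOperonComembership = 0.15,
                             operonCoverage = 0.75,
                             nGroups = 6L) {
  probs <- c(pPositiveGenome, pDyadNegative, pInOperon,
             pOperonComembership, operonCoverage)
  stopifnot(all(probs >= 0 & probs <= 1), nGenomes >= 0,
            copyNumberMean >= 1, decoyHitRate >= 0,
            nGroups >= 1, nGroups <= nrow(GROUP_POOL),
            length(proteomeSizeRange) == 2,
            proteomeSizeRange[1] <= proteomeSizeRange[2])
  w <- vapply(palette, function(p) p$weight, 0)
  if (abs(sum(w) - 1) > 1e-8)
    stop("palette weights must sum to 1")
  known <- c(METACASPASE_LABEL, defaultDomainAnnotations()$domain_name,
             "TMH")
  for (p in palette)
    if (!all(p$elements$label %in% known))
      stop("palette references unknown domain name: ",
           setdiff(p$elements$label, known)[1])
  structure(list(seed = as.integer(seed), nGenomes = as.integer(nGenomes),
                 pPositiveGenome = pPositiveGenome,
                 copyNumberMean = copyNumberMean,
                 proteomeSizeRange = as.integer(proteomeSizeRange),
                 palette = palette, pDyadNegative = pDyadNegative,
                 decoyHitRate = decoyHitRate, pInOperon = pInOperon,
                 pOperonComembership = pOperonComembership,
                 operonCoverage = operonCoverage,
                 nGroups = as.integer(nGroups)),
            class = "simulationConfig")
}

randSeq <- function(n) paste(sample(AA20, n, replace = TRUE),
                             collapse = "")

logUnif <- function(n, lo, hi) 10^runif(n, log10(lo), log10(hi))

# zero-truncated geometric with the given mean (mean = 1/p, support 1,2,..)
rZTGeom <- function(n, mean) 1L + rgeom(n, prob = 1 / mean)

plantDomainSequence <- function(ref, negative) {
  s <- strsplit(ref@sequence, "")[[1]]
  status <- "Positive"
  if (negative) {
    status <- "Negative"
    which <- sample(c("C", "H"), 1)  # both residues equally prone
    if (which == "C") {
      repl <- if (runif(1) < 0.43) "S" else
        sample(setdiff(AA20, c("C", "S")), 1)
      s[ref@cysPos] <- repl
    } else {
      repl <- if (runif(1) < 0.63) "Y" else
        sample(setdiff(AA20, c("H", "Y")), 1)
      s[ref@hisPos] <- repl
    }
  }
  list(sequence = paste(s, collapse = ""), status = status)
}

passingHit <- function(protein_id, domain_name, model_length, hmm_to,
                       env_from, env_to, evalueRange) {
  score <- runif(1, 60, 300)
  bias <- if (runif(1) < 0.3) 0 else runif(1, 0.01, score / 20)
  data.frame(protein_id = protein_id, domain_name = domain_name,
             model_length = as.integer(model_length), hmm_from = 1L,
             hmm_to = as.integer(hmm_to), env_from = as.integer(env_from),
             env_to = as.integer(env_to),
             i_evalue = logUnif(1, evalueRange[1], evalueRange[2]),
             score = round(score, 1), bias = round(bias, 2),
             stringsAsFactors = FALSE)
}

# Lay out one palette entry: returns sequence, hits, topology segments and
# the intended truth (canonical key, dyad status, surviving hit flags).
plantProtein <- function(pid, entry, ref, negativeDyad) {
  pos <- 1L
  linker <- 20L
  parts <- list()  # residue chunks
  hits <- list()
  helices <- list()  # (start, end, retained)
  lastPfam <- NULL
  dyadStatus <- NA_character_
  n <- nrow(entry$elements)
  for (k in seq_len(n)) {
    e <- entry$elements[k, ]
    if (e$role %in% c("pfam", "tmh")) {
      start <- pos + linker
      end <- start + e$len - 1L
      pos <- end
    } else if (e$role == "conflict_pfam") {
      # fully inside the previous pfam domain's second half
      start <- lastPfam$start + (lastPfam$len %/% 2L)
      end <- start + e$len - 1L
      stopifnot(end <= lastPfam$end)
    } else if (e$role == "shadow_tmh") {
      start <- lastPfam$start + 5L
      end <- start + e$len - 1L
    }
    if (e$role %in% c("pfam", "conflict_pfam")) {
      if (e$label == METACASPASE_LABEL) {
        pd <- plantDomainSequence(ref, negativeDyad)
        dyadStatus <- pd$status
        parts[[length(parts) + 1]] <- list(start = start, seq = pd$sequence)
        hit <- passingHit(pid, e$label, 252L, sample(230:252, 1),
                          start, end, c(1e-40, 1e-10))
      } else {
        range <- if (e$role == "conflict_pfam") c(1e-8, 1e-3) else
          c(1e-40, 1e-10)
        hit <- passingHit(pid, e$label, e$len, e$len, start, end, range)
      }
      hit$survives <- e$role == "pfam"
      hits[[length(hits) + 1]] <- hit
      if (e$role == "pfam")
        lastPfam <- list(start = start, end = end, len = e$len)
    } else {
      helices[[length(helices) + 1]] <-
        list(start = start, end = end, retained = e$role == "tmh")
    }
  }
  totalLen <- pos + linker
  # i.i.d. background overwritten by the planted metacaspase domain
  s <- sample(AA20, totalLen, replace = TRUE)
  for (p in parts) {
    chunk <- strsplit(p$seq, "")[[1]]
    s[p$start:(p$start + length(chunk) - 1L)] <- chunk
  }
  topo <- plantTopology(pid, helices, totalLen, entry$startSide)
  list(sequence = paste(s, collapse = ""),
       hits = do.call(rbind, hits), topology = topo,
       dyad_status = dyadStatus, canonical = entry$key)
}

plantTopology <- function(pid, helices, totalLen, startSide) {
  if (length(helices) == 0) return(emptyTopologyTable())
  ord <- order(vapply(helices, `[[`, 0, "start"))
  helices <- helices[ord]
  side <- startSide
  rows <- list()
  pos <- 1L
  for (h in helices) {
    if (h$start > pos)
      rows[[length(rows) + 1]] <- data.frame(
        protein_id = pid, kind = side, start = pos,
        end = h$start - 1L, stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      protein_id = pid, kind = "helix", start = h$start, end = h$end,
      stringsAsFactors = FALSE)
    side <- if (side == "inside") "outside" else "inside"
    pos <- h$end + 1L
  }
  if (pos <= totalLen)
    rows[[length(rows) + 1]] <- data.frame(
      protein_id = pid, kind = side, start = pos, end = totalLen,
      stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

NEIGHBOR_DOMAINS <- data.frame(
  label = c("Sigma70_r2", "Lactamase_B", "Amidase_2", "OmpA", "TrmE"),
  len = c(70L, 210L, 125L, 95L, 150L), stringsAsFactors = FALSE)

#' Generate a complete synthetic survey with planted ground truth
#'
#' Writes \code{proteins.fasta}, \code{hits.tsv}, \code{topology.tsv},
#' \code{genomes.tsv}, \code{operons.tsv}, \code{annotations.tsv} and
#' \code{manifest.tsv} into \code{outdir}, and returns the
#' \linkS4class{SurveyTruth}. Planted metacaspase hits satisfy the
#' screening thresholds (E-value below 0.01, score/bias ratio at least
#' 10); decoy hits violate at least one of them. Deterministic given the
#' config's seed.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param outdir output directory (created if needed).
#' @return A \linkS4class{SurveyTruth}, invisibly carrying the config.
#' @export
simulateSurvey <- function(config = simulationConfig(),
                           outdir = tempfile("survey")) {
  stopifnot(inherits(config, "simulationConfig"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ref <- defaultDyadReference()
  # derived per-stage streams so partial regeneration is stable
  stageSeed <- function(offset) (config$seed * 7L + offset) %% .Machine$integer.max

  set.seed(stageSeed(1L))
  n <- config$nGenomes
  gidx <- if (n > 0) sample.int(config$nGroups, n, replace = TRUE) else
    integer(0)
  genomes <- data.frame(
    genome_id = sprintf("g%04d", seq_len(n)),
    organism = sprintf("Synthetica simulans str. %04d", seq_len(n)),
    group = GROUP_POOL$group[gidx],
    superkingdom = GROUP_POOL$superkingdom[gidx],
    protein_count = if (n > 0)
      sample(config$proteomeSizeRange[1]:config$proteomeSizeRange[2], n,
             replace = TRUE) else integer(0),
    stringsAsFactors = FALSE)
  positive <- rbinom(n, 1, config$pPositiveGenome) == 1
  copies <- integer(n)
  copies[positive] <- rZTGeom(sum(positive), config$copyNumberMean)

  set.seed(stageSeed(2L))
  w <- vapply(config$palette, function(p) p$weight, 0)
  pNeg <- config$pDyadNegative
  seqs <- character(0); seqIds <- character(0); seqGenome <- character(0)
  hitRows <- list(); topoRows <- list(); truthRows <- list()
  for (i in which(positive)) {
    gid <- genomes$genome_id[i]
    pn <- if (!is.null(names(pNeg))) {
      if (genomes$group[i] %in% names(pNeg)) pNeg[[genomes$group[i]]]
      else 0
    } else pNeg
    for (k in seq_len(copies[i])) {
      pid <- sprintf("%s_mc%02d", gid, k)
      entry <- config$palette[[sample.int(length(w), 1, prob = w)]]
      planted <- plantProtein(pid, entry, ref, runif(1) < pn)
      seqs <- c(seqs, planted$sequence)
      seqIds <- c(seqIds, pid)
      seqGenome <- c(seqGenome, gid)
      h <- planted$hits
      h$planted <- TRUE
      hitRows[[length(hitRows) + 1]] <- h
      if (nrow(planted$topology) > 0)
        topoRows[[length(topoRows) + 1]] <- planted$topology
      truthRows[[length(truthRows) + 1]] <- data.frame(
        protein_id = pid, genome_id = gid, group = genomes$group[i],
        canonical = planted$canonical, dyad_status = planted$dyad_status,
        operon_id = NA_character_, stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truthRows)
  if (is.null(truth))
    truth <- data.frame(protein_id = character(), genome_id = character(),
                        group = character(), canonical = character(),
                        dyad_status = character(),
                        operon_id = character())

  # decoy hits: each violates at least one screening threshold
  set.seed(stageSeed(3L))
  for (i in seq_len(n)) {
    nd <- rpois(1, config$decoyHitRate)
    for (k in seq_len(nd)) {
      pid <- sprintf("%s_decoy%02d", genomes$genome_id[i], k)
      plen <- sample(150:400, 1)
      seqs <- c(seqs, randSeq(plen))
      seqIds <- c(seqIds, pid)
      seqGenome <- c(seqGenome, genomes$genome_id[i])
      dom <- sample(c(METACASPASE_LABEL, "WD40", "TPR_1", "Sel1"), 1)
      mlen <- if (dom == METACASPASE_LABEL) 252L else 40L
      envLen <- min(plen - 10L, mlen)
      envFrom <- sample.int(plen - envLen, 1)
      score <- runif(1, 40, 200)
      failRatio <- runif(1) < 0.5
      h <- data.frame(
        protein_id = pid, domain_name = dom, model_length = mlen,
        hmm_from = 1L, hmm_to = as.integer(envLen),
        env_from = envFrom, env_to = envFrom + envLen - 1L,
        i_evalue = if (failRatio) logUnif(1, 1e-20, 1e-3) else
          logUnif(1, 0.02, 10),
        score = round(score, 1),
        bias = if (failRatio) round(score / runif(1, 2, 8), 2) else
          round(runif(1, 0, score / 20), 2),
        planted = FALSE, survives = FALSE, stringsAsFactors = FALSE)
      hitRows[[length(hitRows) + 1]] <- h
    }
  }

  # operons: cover a fraction of genomes; assign metacaspases and plant
  # annotated neighbor genes
  set.seed(stageSeed(4L))
  operonRows <- list()
  covered <- genomes$genome_id[runif(n) < config$operonCoverage]
  opCounter <- 0L
  for (gid in covered) {
    mcs <- truth$protein_id[truth$genome_id == gid]
    if (length(mcs) == 0) next
    inOp <- mcs[runif(length(mcs)) < config$pInOperon]
    currentOp <- NULL
    opSize <- 0L
    for (pid in inOp) {
      if (!is.null(currentOp) && opSize < 3L &&
          runif(1) < config$pOperonComembership) {
        oid <- currentOp
        opSize <- opSize + 1L
      } else {
        opCounter <- opCounter + 1L
        oid <- sprintf("op%05d", opCounter)
        currentOp <- oid
        opSize <- 1L
      }
      truth$operon_id[truth$protein_id == pid] <- oid
    }
    for (oid in unique(truth$operon_id[truth$genome_id == gid &
                                       !is.na(truth$operon_id)])) {
      members <- truth$protein_id[!is.na(truth$operon_id) &
                                    truth$operon_id == oid]
      nNb <- sample(1:3, 1)
      nbIds <- character(nNb)
      for (j in seq_len(nNb)) {
        nb <- NEIGHBOR_DOMAINS[sample.int(nrow(NEIGHBOR_DOMAINS), 1), ]
        nbId <- sprintf("%s_nb%02d", oid, j)
        plen <- nb$len + 60L
        seqs <- c(seqs, randSeq(plen))
        seqIds <- c(seqIds, nbId)
        seqGenome <- c(seqGenome, gid)
        h <- passingHit(nbId, nb$label, nb$len, nb$len, 31L,
                        30L + nb$len, c(1e-30, 1e-5))
        h$planted <- TRUE
        h$survives <- TRUE
        hitRows[[length(hitRows) + 1]] <- h
        nbIds[j] <- nbId
      }
      geneOrder <- sample(c(members, nbIds))
      strand <- sample(c("+", "-"), 1)
      base <- opCounter * 10000L
      operonRows[[length(operonRows) + 1]] <- data.frame(
        operon_id = oid, genome_id = gid, gene_id = geneOrder,
        rank = seq_along(geneOrder), strand = strand,
        start = base + (seq_along(geneOrder) - 1L) * 1200L,
        end = base + seq_along(geneOrder) * 1200L - 100L,
        stringsAsFactors = FALSE)
    }
  }
  operons <- do.call(rbind, operonRows)
  if (is.null(operons)) operons <- emptyOperonTable()

  hits <- do.call(rbind, hitRows)
  if (is.null(hits)) {
    hits <- emptyHitTable()
    hits$planted <- logical(0)
    hits$survives <- logical(0)
  }
  genomes$protein_count <- pmax(genomes$protein_count,
                                as.integer(table(factor(seqGenome,
                                  levels = genomes$genome_id))))
  truthGenomes <- genomes
  truthGenomes$metacaspase_count <- as.integer(
    table(factor(truth$genome_id, levels = genomes$genome_id)))

  # write everything
  if (length(seqs) > 0) {
    aa <- AAStringSet(setNames(seqs, seqIds))
    mcols(aa)$genome_id <- seqGenome
    writeProteinFasta(aa, file.path(outdir, "proteins.fasta"))
  } else {
    file.create(file.path(outdir, "proteins.fasta"))
  }
  writeDomainHits(hits[, HIT_COLUMNS, drop = FALSE],
                  file.path(outdir, "hits.tsv"))
  topo <- do.call(rbind, topoRows)
  if (is.null(topo)) topo <- emptyTopologyTable()
  writeTopology(topo, file.path(outdir, "topology.tsv"))
  writeGenomeTable(genomes, file.path(outdir, "genomes.tsv"))
  writeOperonTable(operons, file.path(outdir, "operons.tsv"))
  writeDomainAnnotations(rbind(defaultDomainAnnotations(),
                               defaultNeighborAnnotations()),
                         file.path(outdir, "annotations.tsv"))
  writeTSV(truth, file.path(outdir, "manifest.tsv"))

  out <- new("SurveyTruth", metacaspases = truth, hits = hits,
             genomes = truthGenomes, config = unclass(config))
  attr(out, "outdir") <- outdir
  invisible(out)
}

#' Run the full pipeline on a synthetic survey and score recovery
#'
#' Generates (or reuses) a synthetic survey, runs screening, architecture
#' resolution, dyad classification, operon mapping and abundance
#' aggregation on the written files, and reports the exact-match recovery
#' rate of each surface against the planted truth.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param outdir where to generate the survey.
#' @param truth optionally, a \linkS4class{SurveyTruth} already generated
#'   into \code{outdir}.
#' @return list with recovery rates in [0, 1]:
#'   \code{identification} (metacaspase set, exact both ways),
#'   \code{architecture} (canonical keys), \code{dyad} (statuses),
#'   \code{operon} (all operon summary numbers equal),
#'   \code{abundance} (per-genome counts equal), plus \code{report}
#'   (the \linkS4class{SurveyReport}) and \code{n_planted}.
#' @export
endToEndRecovery <- function(config = simulationConfig(),
                             outdir = tempfile("survey"),
                             truth = NULL) {
  if (is.null(truth))
    truth <- simulateSurvey(config, outdir)
  planted <- truth@metacaspases
  if (nrow(planted) == 0 && length(readLines(
        file.path(outdir, "proteins.fasta"))) == 0) {
    return(list(identification = NA_real_, architecture = NA_real_,
                dyad = NA_real_, operon = NA_real_, abundance = NA_real_,
                report = NULL, n_planted = 0L))
  }
  survey <- readSurvey(outdir)
  report <- runSurvey(survey)
  arch <- architectures(report)
  found <- arch$protein_id[arch$is_metacaspase]
  idRate <- length(intersect(found, planted$protein_id)) /
    length(union(found, planted$protein_id))
  m <- match(planted$protein_id, arch$protein_id)
  archRate <- mean(!is.na(m) & arch$canonical[m] == planted$canonical)
  dy <- dyadResults(report)
  md <- match(planted$protein_id, dy$protein_id)
  dyadRate <- mean(!is.na(md) & dy$status[md] == planted$dyad_status)
  # operon summary from truth
  gidMap <- setNames(planted$genome_id, planted$protein_id)
  coveredGenomes <- unique(operonTable(survey)$genome_id)
  inCov <- planted[planted$genome_id %in% coveredGenomes, , drop = FALSE]
  tPerOp <- table(inCov$operon_id[!is.na(inCov$operon_id)])
  tSummary <- c(sum(!is.na(inCov$operon_id)), length(tPerOp),
                sum(tPerOp > 1), if (length(tPerOp)) max(tPerOp) else 0L)
  s <- report@operonSummary
  pSummary <- c(s$n_in_operons, s$n_operons, s$n_multi_operons,
                s$max_per_operon)
  operonRate <- mean(pSummary == tSummary)
  ab <- report@abundance
  tCounts <- truth@genomes$metacaspase_count[
    match(ab$genome_id, truth@genomes$genome_id)]
  abundanceRate <- mean(ab$metacaspase_count == tCounts)
  list(identification = idRate, architecture = archRate,
       dyad = dyadRate, operon = operonRate, abundance = abundanceRate,
       report = report, n_planted = nrow(planted))
}
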