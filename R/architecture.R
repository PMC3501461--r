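# Domain-architecture assembly: overlap-conflict resolution among accepted
# Pfam hits, integration of transmembrane helices (Pfam domains take
# precedence), repeat collapsing and the metacaspase acceptance rule.

#' Default label of the bacterial metacaspase profile
#' @export
METACASPASE_LABEL <- "Bac_PepC14"

#' Resolve overlapping Pfam domain hits on one protein
#'
#' Two hits conflict when their envelope overlap exceeds
#' \code{conflictFraction} of the envelope length of either one of them
#' (equivalently, overlap / min(lenA, lenB) > conflictFraction). Hits are
#' taken greedily in ascending E-value — ties broken by longer envelope,
#' then lexicographic domain name, then envelope start — and a hit is
#' kept only if it conflicts with no previously kept hit. This is the
#' deterministic fixed point of repeatedly discarding the higher-E member
#' of any conflicting pair.
#'
#' @param hits accepted hits of a single protein.
#' @param conflictFraction overlap fraction defining a conflict
#'   (default 0.25).
#' @return surviving hits, sorted by \code{env_from}.
#' @export
resolveDomainConflicts <- function(hits, conflictFraction = 0.25) {
  stopifnot(conflictFraction > 0, conflictFraction <= 1)
  if (nrow(hits) == 0) return(hits)
  if (length(unique(hits$protein_id)) > 1)
    stop("all hits must share one protein_id")
  len <- hits$env_to - hits$env_from + 1
  ord <- order(hits$i_evalue, -len, hits$domain_name, hits$env_from,
               hits$env_to)
  hits <- hits[ord, , drop = FALSE]
  keep <- integer(0)
  for (i in seq_len(nrow(hits))) {
    ok <- TRUE
    for (j in keep) {
      if (hitsConflict(hits[i, ], hits[j, ], conflictFraction)) {
        ok <- FALSE
        break
      }
    }
    if (ok) keep <- c(keep, i)
  }
  out <- hits[keep, , drop = FALSE]
  out <- out[order(out$env_from, out$env_to), , drop = FALSE]
  rownames(out) <- NULL
  out
}

hitsConflict <- function(a, b, conflictFraction) {
  ov <- min(a$env_to, b$env_to) - max(a$env_from, b$env_from) + 1
  if (ov <= 0) return(FALSE)
  la <- a$env_to - a$env_from + 1
  lb <- b$env_to - b$env_from + 1
  ov > conflictFraction * min(la, lb)
}

#' Integrate predicted transmembrane helices into a resolved architecture
#'
#' Helices that overlap a surviving Pfam domain by one residue or more are
#' dropped (the Pfam domain takes precedence). Retained helices become
#' \code{tmh} elements; their orientation is read from the flanking
#' topology segments (\code{iTMHo} when the N-terminal side is inside,
#' \code{oTMHi} when outside). A retained helix starting at residue 30 or
#' earlier, when it is the protein's only predicted helix, is flagged as a
#' putative signal peptide.
#'
#' @param survivors conflict-resolved hits of one protein
#'   (\code{\link{resolveDomainConflicts}}).
#' @param segments topology segments of the same protein (may be empty).
#' @param signalPeptideMaxStart latest start for the signal-peptide flag
#'   (default 30).
#' @return element \code{data.frame} with columns \code{label},
#'   \code{kind} (\code{pfam}/\code{tmh}), \code{start}, \code{end},
#'   \code{orientation}, \code{signal_peptide}, sorted N to C.
#' @export
integrateTopology <- function(survivors, segments = emptyTopologyTable(),
                              signalPeptideMaxStart = 30L) {
  pid <- unique(c(survivors$protein_id, segments$protein_id))
  if (length(pid) > 1)
    stop("hits and topology refer to different proteins: ",
         paste(pid, collapse = ", "))
  el <- data.frame(label = character(), kind = character(),
                   start = integer(), end = integer(),
                   orientation = character(), signal_peptide = logical(),
                   stringsAsFactors = FALSE)
  if (nrow(survivors) > 0)
    el <- rbind(el, data.frame(label = survivors$domain_name,
                               kind = "pfam", start = survivors$env_from,
                               end = survivors$env_to, orientation = NA_character_,
                               signal_peptide = FALSE,
                               stringsAsFactors = FALSE))
  helices <- segments[segments$kind == "helix", , drop = FALSE]
  nPredicted <- nrow(helices)
  if (nPredicted > 0) {
    for (k in seq_len(nPredicted)) {
      h <- helices[k, ]
      clash <- nrow(survivors) > 0 &&
        any(pmin(survivors$env_to, h$end) -
              pmax(survivors$env_from, h$start) + 1 >= 1)
      if (clash) next
      el <- rbind(el, data.frame(
        label = "TMH", kind = "tmh", start = h$start, end = h$end,
        orientation = helixOrientation(h, segments),
        signal_peptide = nPredicted == 1 &&
          h$start <= signalPeptideMaxStart,
        stringsAsFactors = FALSE))
    }
  }
  el <- el[order(el$start, el$end), , drop = FALSE]
  rownames(el) <- NULL
  el
}

helixOrientation <- function(h, segments) {
  before <- segments[segments$kind != "helix" & segments$end < h$start, ,
                     drop = FALSE]
  after <- segments[segments$kind != "helix" & segments$start > h$end, ,
                    drop = FALSE]
  nSide <- if (nrow(before) > 0) before$kind[nrow(before)] else NA
  cSide <- if (nrow(after) > 0) after$kind[1] else NA
  if (identical(nSide, "inside") || identical(cSide, "outside"))
    return("iTMHo")
  if (identical(nSide, "outside") || identical(cSide, "inside"))
    return("oTMHi")
  NA_character_
}

#' Build the final architecture of one protein
#'
#' Collapses maximal runs of identical consecutive labels into single
#' elements with a repeat count, derives the canonical architecture key
#' ('|'-joined labels N to C, repeat counts ignored) and applies the
#' acceptance rule: a protein counts as a metacaspase only if the
#' bacterial metacaspase domain is present in the final, conflict-resolved
#' architecture.
#'
#' @param elements element table from \code{\link{integrateTopology}}
#'   (or a bare pfam element table), ordered N to C.
#' @param proteinId protein identifier to record.
#' @param metacaspaseLabel domain label defining a metacaspase
#'   (default \code{"Bac_PepC14"}).
#' @param includeOrientation if \code{TRUE}, TMH elements contribute their
#'   orientation label (\code{iTMHo}/\code{oTMHi}) to the canonical key
#'   instead of plain \code{TMH}.
#' @return list with \code{protein_id}, \code{elements} (with
#'   \code{repeat_count}), \code{canonical} and \code{is_metacaspase}.
#' @examples
#' el <- data.frame(label = c("WD40", "WD40", "WD40"), kind = "pfam",
#'                  start = c(1, 50, 100), end = c(40, 90, 140),
#'                  orientation = NA, signal_peptide = FALSE)
#' buildArchitecture(el, "p1")$canonical
#' @export
buildArchitecture <- function(elements, proteinId = NA_character_,
                              metacaspaseLabel = METACASPASE_LABEL,
                              includeOrientation = FALSE) {
  if (nrow(elements) == 0)
    return(list(protein_id = proteinId,
                elements = cbind(elements, repeat_count = integer(0)),
                canonical = "", is_metacaspase = FALSE))
  elements <- elements[order(elements$start, elements$end), , drop = FALSE]
  key <- elements$label
  if (includeOrientation) {
    tm <- elements$kind == "tmh" & !is.na(elements$orientation)
    key[tm] <- elements$orientation[tm]
  }
  run <- cumsum(c(TRUE, key[-1] != key[-length(key)]))
  merged <- do.call(rbind, lapply(split(seq_along(run), run), function(ix) {
    first <- elements[ix[1], , drop = FALSE]
    first$end <- elements$end[ix[length(ix)]]
    first$signal_peptide <- any(elements$signal_peptide[ix])
    first$repeat_count <- length(ix)
    first
  }))
  rownames(merged) <- NULL
  canonical <- paste(key[!duplicated(run)], collapse = "|")
  list(protein_id = proteinId, elements = merged, canonical = canonical,
       is_metacaspase = metacaspaseLabel %in% elements$label)
}

#' Resolve the architectures of every protein in a survey
#'
#' Runs \code{\link{resolveDomainConflicts}},
#' \code{\link{integrateTopology}} and \code{\link{buildArchitecture}}
#' over all proteins carrying at least one accepted hit or predicted
#' helix.
#'
#' @param accepted screened (accepted) hit table.
#' @param topology topology segment table.
#' @param proteinGenome named character vector mapping protein_id to
#'   genome_id (optional; adds a \code{genome_id} column).
#' @param conflictFraction,metacaspaseLabel,includeOrientation passed
#'   through to the per-protein operations.
#' @return list with \code{architectures} (one row per protein:
#'   \code{protein_id}, \code{genome_id}, \code{canonical},
#'   \code{is_metacaspase}, \code{n_elements}, \code{has_tmh}) and
#'   \code{elements} (one row per merged element with
#'   \code{protein_id}).
#' @export
resolveArchitectures <- function(accepted,
                                 topology = emptyTopologyTable(),
                                 proteinGenome = NULL,
                                 conflictFraction = 0.25,
                                 metacaspaseLabel = METACASPASE_LABEL,
                                 includeOrientation = FALSE) {
  pids <- sort(unique(c(accepted$protein_id, topology$protein_id)))
  archRows <- vector("list", length(pids))
  elRows <- vector("list", length(pids))
  for (k in seq_along(pids)) {
    pid <- pids[k]
    hv <- accepted[accepted$protein_id == pid, , drop = FALSE]
    sv <- resolveDomainConflicts(hv, conflictFraction)
    seg <- topology[topology$protein_id == pid, , drop = FALSE]
    el <- integrateTopology(sv, seg)
    a <- buildArchitecture(el, pid, metacaspaseLabel, includeOrientation)
    archRows[[k]] <- data.frame(
      protein_id = pid,
      genome_id = if (is.null(proteinGenome)) NA_character_ else
        unname(proteinGenome[pid]),
      canonical = a$canonical,
      is_metacaspase = a$is_metacaspase,
      n_elements = nrow(a$elements),
      has_tmh = any(a$elements$kind == "tmh"),
      stringsAsFactors = FALSE)
    if (nrow(a$elements) > 0)
      elRows[[k]] <- cbind(protein_id = pid, a$elements)
  }
  arch <- do.call(rbind, archRows)
  if (is.null(arch))
    arch <- data.frame(protein_id = character(), genome_id = character(),
                       canonical = character(), is_metacaspase = logical(),
                       n_elements = integer(), has_tmh = logical())
  elements <- do.call(rbind, elRows)
  if (is.null(elements))
    elements <- data.frame(protein_id = character(), label = character(),
                           kind = character(), start = integer(),
                           end = integer(), orientation = character(),
                           signal_peptide = logical(),
                           repeat_count = integer())
  rownames(arch) <- rownames(elements) <- NULL
  list(architectures = arch, elements = elements)
}

#' Census of architecture keys and per-domain prevalence
#'
#' Counts, for every canonical architecture key among metacaspase
#' sequences, the number of sequences and the set of taxonomic groups it
#' occurs in, and flags keys unique to a single group. Also tabulates, for
#' each non-metacaspase domain, the number and percentage of metacaspase
#' sequences carrying at least one instance.
#'
#' @param architectures architecture table from
#'   \code{\link{resolveArchitectures}} (with \code{genome_id}).
#' @param elements matching element table.
#' @param genomes genome table (for group lookup).
#' @param metacaspaseLabel the metacaspase domain label.
#' @return list with \code{census} (columns \code{canonical},
#'   \code{n_sequences}, \code{n_groups}, \code{groups},
#'   \code{group_unique}) and \code{prevalence} (columns
#'   \code{domain_name}, \code{n_sequences}, \code{percent} at one
#'   decimal), both sorted by descending sequence count.
#' @export
architectureCensus <- function(architectures, elements, genomes,
                               metacaspaseLabel = METACASPASE_LABEL) {
  mc <- architectures[architectures$is_metacaspase, , drop = FALSE]
  grp <- setNames(genomes$group, genomes$genome_id)
  mc$group <- unname(grp[mc$genome_id])
  census <- do.call(rbind, lapply(split(mc, mc$canonical), function(d) {
    g <- sort(unique(d$group))
    data.frame(canonical = d$canonical[1], n_sequences = nrow(d),
               n_groups = length(g), groups = paste(g, collapse = ";"),
               group_unique = length(g) == 1, stringsAsFactors = FALSE)
  }))
  if (is.null(census))
    census <- data.frame(canonical = character(), n_sequences = integer(),
                         n_groups = integer(), groups = character(),
                         group_unique = logical())
  census <- census[order(-census$n_sequences, census$canonical), ,
                   drop = FALSE]
  el <- elements[elements$protein_id %in% mc$protein_id &
                   elements$kind == "pfam" &
                   elements$label != metacaspaseLabel, , drop = FALSE]
  nmc <- nrow(mc)
  prevalence <- do.call(rbind, lapply(split(el, el$label), function(d) {
    n <- length(unique(d$protein_id))
    data.frame(domain_name = d$label[1], n_sequences = n,
               percent = if (nmc > 0) surveyPercentage(n, nmc, 1) else NA,
               stringsAsFactors = FALSE)
  }))
  if (is.null(prevalence))
    prevalence <- data.frame(domain_name = character(),
                             n_sequences = integer(), percent = numeric())
  prevalence <- prevalence[order(-prevalence$n_sequences,
                                 prevalence$domain_name), , drop = FALSE]
  rownames(census) <- rownames(prevalence) <- NULL
  list(census = census, prevalence = prevalence)
}
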