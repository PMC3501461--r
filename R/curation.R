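# Training-set curation preceding profile construction: envelope
# extraction, dyad filtering, greedy identity clustering with longest-
# sequence representatives, and an alignment quality report for the
# manual-inspection step that stays with a human.

#' Extract domain-envelope sequences
#'
#' Returns the residue slice \code{env_from..env_to} of each hit's
#' protein.
#'
#' @param hits hit \code{data.frame}.
#' @param proteins \code{AAStringSet} named by protein id.
#' @return \code{data.frame} with \code{protein_id}, \code{env_from},
#'   \code{env_to}, \code{envelope}.
#' @examples
#' p <- Biostrings::AAStringSet(c(p1 = "MAAACHWWW"))
#' h <- data.frame(protein_id = "p1", domain_name = "d", model_length = 3L,
#'                 hmm_from = 1L, hmm_to = 3L, env_from = 4L, env_to = 6L,
#'                 i_evalue = 0, score = 50, bias = 0)
#' extractEnvelopes(h, p)$envelope  # "ACH"
#' @export
extractEnvelopes <- function(hits, proteins) {
  if (nrow(hits) == 0)
    return(data.frame(protein_id = character(), env_from = integer(),
                      env_to = integer(), envelope = character()))
  missing <- !(hits$protein_id %in% names(proteins))
  if (any(missing))
    stop("no sequence for protein ", hits$protein_id[missing][1])
  seqs <- as.character(proteins[hits$protein_id])
  lens <- nchar(seqs)
  bad <- hits$env_from < 1 | hits$env_to > lens
  if (any(bad))
    stop("envelope out of range for hit on ", hits$protein_id[bad][1],
         " (", hits$env_from[bad][1], "-", hits$env_to[bad][1], ")")
  data.frame(protein_id = hits$protein_id, env_from = hits$env_from,
             env_to = hits$env_to,
             envelope = substr(seqs, hits$env_from, hits$env_to),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Discard envelopes without an intact catalytic dyad
#'
#' Retains exactly the envelopes whose dyad classification against the
#' reference is Positive. Idempotent.
#'
#' @param envelopes table from \code{\link{extractEnvelopes}}.
#' @param ref a \linkS4class{DyadReference}.
#' @return the retained subset of \code{envelopes}.
#' @export
dyadFilter <- function(envelopes, ref) {
  if (nrow(envelopes) == 0) return(envelopes)
  status <- vapply(envelopes$envelope,
                   function(e) classifyDyad(e, ref)$status, "")
  out <- envelopes[status == "Positive", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy identity clustering with longest representatives
#'
#' Sequences are processed longest-first (ties by protein id); each joins
#' the first existing cluster whose representative shares at least
#' \code{identityThreshold} global-alignment identity (matches divided by
#' the shorter sequence's length), otherwise it founds a new cluster. By
#' construction the representative of each cluster is its longest member,
#' the founder. Deterministic.
#'
#' @param envelopes table from \code{\link{extractEnvelopes}} (or any
#'   table with \code{protein_id} and \code{envelope} columns).
#' @param identityThreshold clustering identity in (0, 1]
#'   (default 0.90).
#' @return list with \code{representatives} (subset of rows founding
#'   clusters, with \code{cluster}) and \code{members} (all rows with
#'   \code{cluster} and \code{is_representative}).
#' @export
clusterRepresentatives <- function(envelopes, identityThreshold = 0.90) {
  stopifnot(identityThreshold > 0, identityThreshold <= 1,
            nrow(envelopes) >= 1)
  ord <- order(-nchar(envelopes$envelope), envelopes$protein_id)
  env <- envelopes[ord, , drop = FALSE]
  cluster <- integer(nrow(env))
  reps <- integer(0)  # row indices of founders, in founding order
  for (i in seq_len(nrow(env))) {
    assigned <- FALSE
    for (ci in seq_along(reps)) {
      idy <- alignmentIdentity(env$envelope[reps[ci]], env$envelope[i])
      if (idy >= identityThreshold) {
        cluster[i] <- ci
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, i)
      cluster[i] <- length(reps)
    }
  }
  members <- cbind(env, cluster = cluster,
                   is_representative = seq_len(nrow(env)) %in% reps)
  rownames(members) <- NULL
  list(representatives = members[members$is_representative, ,
                                 drop = FALSE],
       members = members)
}

#' Alignment quality report for curated envelopes
#'
#' Aligns every envelope to the reference and summarises per-envelope
#' quality: alignment identity, terminal-gap fraction of the envelope
#' row, and aligned length. The removal of low-quality alignment ends is
#' a judgement call that stays manual; this report is its input.
#'
#' @param envelopes table with \code{protein_id}, \code{envelope}.
#' @param ref a \linkS4class{DyadReference}.
#' @return \code{data.frame} with \code{protein_id}, \code{identity},
#'   \code{terminal_gap_fraction}, \code{aligned_length}.
#' @export
curationReport <- function(envelopes, ref) {
  rows <- lapply(seq_len(nrow(envelopes)), function(k) {
    al <- globalAlign(ref@sequence, envelopes$envelope[k])
    rb <- strsplit(al$aligned_b, "")[[1]]
    nonGap <- which(rb != "-")
    term <- if (length(nonGap) == 0) length(rb) else
      (nonGap[1] - 1) + (length(rb) - nonGap[length(nonGap)])
    data.frame(protein_id = envelopes$protein_id[k],
               identity = alignmentIdentity(ref@sequence,
                                            envelopes$envelope[k]),
               terminal_gap_fraction = term / length(rb),
               aligned_length = length(rb), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(protein_id = character(), identity = numeric(),
                      terminal_gap_fraction = numeric(),
                      aligned_length = integer())
  out
}

#' Full curation pass: envelopes -> dyad filter -> clustering
#'
#' Composes the curation steps and returns the representative envelopes
#' ready for external multiple alignment and profile construction, plus
#' the quality report.
#'
#' @param hits accepted metacaspase hits.
#' @param proteins \code{AAStringSet}.
#' @param ref a \linkS4class{DyadReference}.
#' @param identityThreshold clustering identity (default 0.90).
#' @return list with \code{representatives}, \code{members},
#'   \code{report}, \code{n_input}, \code{n_dyad_positive}.
#' @export
curateTrainingSet <- function(hits, proteins, ref,
                              identityThreshold = 0.90) {
  env <- extractEnvelopes(hits, proteins)
  kept <- dyadFilter(env, ref)
  if (nrow(kept) == 0)
    return(list(representatives = kept, members = kept,
                report = curationReport(kept, ref),
                n_input = nrow(env), n_dyad_positive = 0L))
  cl <- clusterRepresentatives(kept, identityThreshold)
  list(representatives = cl$representatives, members = cl$members,
       report = curationReport(cl$representatives, ref),
       n_input = nrow(env), n_dyad_positive = nrow(kept))
}
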