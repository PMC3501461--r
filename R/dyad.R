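# Catalytic-dyad assessment: global (Needleman-Wunsch) alignment of
# metacaspase domain envelopes to an annotated reference, followed by a
# read-off of the residues in the two catalytic columns.

.pkgCache <- new.env(parent = emptyenv())

#' BLOSUM62 substitution matrix (from Biostrings), cached
#' @noRd
blosum62 <- function() {
  if (is.null(.pkgCache$BLOSUM62)) {
    e <- new.env()
    data("BLOSUM62", package = "Biostrings", envir = e)
    .pkgCache$BLOSUM62 <- e$BLOSUM62
  }
  .pkgCache$BLOSUM62
}

# 252-residue synthetic metacaspase-like reference with the catalytic
# histidine at 90 and cysteine at 150. This is a stand-in with annotated
# dyad positions for testing and simulation; real surveys should supply a
# curated Peptidase C14 reference.
SYNTHETIC_REFERENCE <- paste0(
  "GWWFTFFIRRIKDKSVRYLEEYWPDMSLWTPGSQAMQWENDQDQDYAAYYRMHSGILWGYCKNAVWPSDI",
  "SVEWSKVQPIKQNPQMPTGHNQRPFWDRAETFCTHFLPQGATWIAFDQCTRAWVDSPKIRVFLQSYRTIC",
  "SVPLQCWLKCRDQMQGGEFAPAKQQLGKNFCLFCMDRVPLCCSIFFVWTQRMCVAWWCSHTQTNVFKACM",
  "VFMLHLDGLISCEKSTGYRKFICPTCPIFYGYESYTSRWGMQ")

#' Bundled synthetic dyad reference
#'
#' A fixed 252-residue synthetic metacaspase-like sequence with the
#' catalytic histidine annotated at position 90 and the cysteine at 150.
#' It is synthetic: adequate for simulations and tests, but real surveys
#' should construct a \code{\link{DyadReference}} from a curated domain.
#'
#' @return A \linkS4class{DyadReference}.
#' @export
defaultDyadReference <- function() {
  DyadReference(SYNTHETIC_REFERENCE, cysPos = 150L, hisPos = 90L)
}

#' Global pairwise alignment (Needleman-Wunsch)
#'
#' Optimal global alignment under a substitution matrix and a linear gap
#' penalty, with deterministic traceback (diagonal preferred over a gap in
#' the second sequence, preferred over a gap in the first).
#'
#' @param a,b amino-acid strings (non-empty; letters must appear in the
#'   substitution matrix).
#' @param submat substitution matrix with single-letter dimnames
#'   (default BLOSUM62).
#' @param gap linear gap penalty per gapped position, as a positive
#'   number (default 8).
#' @return list with \code{score}, \code{aligned_a}, \code{aligned_b}.
#' @examples
#' globalAlign("ACGH", "ACH")
#' @export
globalAlign <- function(a, b, submat = blosum62(), gap = 8) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (nchar(a) == 0 || nchar(b) == 0)
    stop("sequences must be non-empty")
  .nwAlignCpp(a, b, submat, gap)
}

#' Fraction of identical aligned residues, cd-hit style
#'
#' Global-alignment identity with the length of the shorter sequence as
#' denominator (the convention used for 90\% redundancy clustering).
#'
#' @param a,b amino-acid strings.
#' @inheritParams globalAlign
#' @return identity fraction in [0, 1].
#' @export
alignmentIdentity <- function(a, b, submat = blosum62(), gap = 8) {
  al <- globalAlign(a, b, submat, gap)
  x <- strsplit(al$aligned_a, "")[[1]]
  y <- strsplit(al$aligned_b, "")[[1]]
  matches <- sum(x == y & x != "-")
  matches / min(nchar(a), nchar(b))
}

#' Classify catalytic-dyad conservation of one domain envelope
#'
#' Globally aligns the envelope to the reference and reads the envelope
#' residues aligned to the reference's catalytic cysteine and histidine
#' columns (\code{"-"} when the column falls in a deletion). Status is
#' \code{Positive} iff the cysteine column holds \code{C} and the
#' histidine column holds \code{H}; any substitution, including by a gap,
#' makes it \code{Negative}. When both catalytic columns fall in a
#' terminal gap of the envelope, the call is additionally marked low
#' confidence.
#'
#' @param envelope amino-acid string of the extracted domain envelope.
#' @param ref a \linkS4class{DyadReference}.
#' @inheritParams globalAlign
#' @return list with \code{status} (\code{"Positive"}/\code{"Negative"}),
#'   \code{residue_at_cys}, \code{residue_at_his},
#'   \code{low_confidence}.
#' @export
classifyDyad <- function(envelope, ref, submat = blosum62(), gap = 8) {
  stopifnot(is(ref, "DyadReference"))
  al <- globalAlign(ref@sequence, envelope, submat, gap)
  ra <- strsplit(al$aligned_a, "")[[1]]  # reference row
  rb <- strsplit(al$aligned_b, "")[[1]]  # envelope row
  refcol <- cumsum(ra != "-")
  atCys <- rb[match(ref@cysPos, refcol)]
  atHis <- rb[match(ref@hisPos, refcol)]
  # terminal gap extent of the envelope row
  nonGap <- which(rb != "-")
  lead <- if (length(nonGap) > 0) nonGap[1] - 1 else length(rb)
  trail <- if (length(nonGap) > 0) length(rb) - nonGap[length(nonGap)] else 0
  inTerminal <- function(pos) {
    col <- match(pos, refcol)
    col <= lead || col > length(rb) - trail
  }
  lowConf <- inTerminal(ref@cysPos) && inTerminal(ref@hisPos)
  list(status = if (identical(atCys, "C") && identical(atHis, "H"))
         "Positive" else "Negative",
       residue_at_cys = atCys, residue_at_his = atHis,
       low_confidence = lowConf)
}

#' Classify dyad conservation for a set of envelopes
#'
#' @param envelopes named character vector (names = protein ids) or the
#'   table returned by \code{\link{extractEnvelopes}}.
#' @param ref a \linkS4class{DyadReference}.
#' @inheritParams globalAlign
#' @return \code{data.frame} with one row per envelope:
#'   \code{protein_id}, \code{status}, \code{residue_at_cys},
#'   \code{residue_at_his}, \code{low_confidence}.
#' @export
classifyDyads <- function(envelopes, ref, submat = blosum62(), gap = 8) {
  if (is.data.frame(envelopes))
    envelopes <- setNames(envelopes$envelope, envelopes$protein_id)
  rows <- lapply(seq_along(envelopes), function(k) {
    r <- classifyDyad(envelopes[[k]], ref, submat, gap)
    data.frame(protein_id = names(envelopes)[k], status = r$status,
               residue_at_cys = r$residue_at_cys,
               residue_at_his = r$residue_at_his,
               low_confidence = r$low_confidence,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(protein_id = character(), status = character(),
                      residue_at_cys = character(),
                      residue_at_his = character(),
                      low_confidence = logical())
  out
}

#' Per-group dyad conservation and substitution spectrum
#'
#' Tabulates, per taxonomic group, the fraction of sequences with an
#' intact cysteine-histidine dyad, and over all Negative calls the
#' distribution of residues replacing the cysteine and, separately, the
#' histidine.
#'
#' @param dyad dyad table from \code{\link{classifyDyads}}.
#' @param groups character vector of group labels, parallel to
#'   \code{dyad} rows (or named by protein_id).
#' @return list with \code{by_group} (\code{group}, \code{n},
#'   \code{n_positive}, \code{conservation_pct} at whole percent),
#'   \code{cys_substitutions} and \code{his_substitutions} (residue,
#'   count, percent of that residue's substitutions).
#' @export
substitutionProfile <- function(dyad, groups) {
  if (!is.null(names(groups))) groups <- groups[dyad$protein_id]
  stopifnot(length(groups) == nrow(dyad))
  byGroup <- do.call(rbind, lapply(split(seq_len(nrow(dyad)), groups),
    function(ix) {
      n <- length(ix)
      np <- sum(dyad$status[ix] == "Positive")
      data.frame(group = groups[ix[1]], n = n, n_positive = np,
                 conservation_pct = surveyPercentage(np, n, 0),
                 stringsAsFactors = FALSE)
    }))
  rownames(byGroup) <- NULL
  neg <- dyad[dyad$status == "Negative", , drop = FALSE]
  spectrum <- function(res, intact) {
    sub <- res[res != intact]
    if (length(sub) == 0)
      return(data.frame(residue = character(), count = integer(),
                        percent = numeric()))
    tab <- sort(table(sub), decreasing = TRUE)
    data.frame(residue = names(tab), count = as.integer(tab),
               percent = vapply(as.integer(tab), surveyPercentage, 0,
                                denominator = length(sub), digits = 0),
               stringsAsFactors = FALSE)
  }
  list(by_group = byGroup,
       cys_substitutions = spectrum(neg$residue_at_cys, "C"),
       his_substitutions = spectrum(neg$residue_at_his, "H"))
}
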