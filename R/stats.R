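# Abundance and taxonomic rollups: metacaspases per 1000 proteins,
# per-group summaries with the small-group "Other" fold, and printed-style
# percentage arithmetic.

#' Percentage with half-away-from-zero rounding
#'
#' \code{100 * numerator / denominator}, rounded half away from zero to
#' 0 or 1 decimals — the convention used for survey summaries (e.g.
#' 267 of 1463 genomes prints as 18).
#'
#' @param numerator,denominator non-negative counts;
#'   \code{denominator > 0}.
#' @param digits 0 or 1 decimal places.
#' @return rounded percentage.
#' @examples
#' surveyPercentage(267, 1463, 0)  # 18
#' surveyPercentage(73, 671, 1)    # 10.9
#' @export
surveyPercentage <- function(numerator, denominator, digits = 0) {
  stopifnot(digits %in% c(0, 1))
  if (any(denominator == 0)) stop("zero denominator")
  x <- 100 * numerator / denominator
  roundHalfAway(x, digits)
}

roundHalfAway <- function(x, digits) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Per-genome metacaspase abundance
#'
#' Counts metacaspase-positive proteins per genome and normalises by
#' proteome size: abundance = 1000 * count / protein_count. Every genome
#' in the genome table gets a record (zero counts included).
#'
#' @param architectures architecture table
#'   (\code{\link{resolveArchitectures}}) with \code{genome_id}.
#' @param genomes genome table.
#' @return \code{data.frame}: \code{genome_id}, \code{group},
#'   \code{metacaspase_count}, \code{protein_count}, \code{abundance}
#'   (full precision) and \code{abundance_2dp} (rounded to 2 decimals as
#'   reported).
#' @examples
#' g <- data.frame(genome_id = "g1", organism = "o", group = "Bacteroidetes",
#'                 superkingdom = "Bacteria", protein_count = 6747L)
#' a <- data.frame(protein_id = paste0("p", 1:28), genome_id = "g1",
#'                 canonical = "Bac_PepC14", is_metacaspase = TRUE)
#' genomeAbundance(a, g)$abundance_2dp  # 4.15
#' @export
genomeAbundance <- function(architectures, genomes) {
  mc <- architectures[architectures$is_metacaspase, , drop = FALSE]
  if (nrow(mc) > 0 && anyNA(mc$genome_id))
    stop("metacaspase with no genome assignment")
  unknown <- setdiff(mc$genome_id, genomes$genome_id)
  if (length(unknown) > 0)
    stop("genome ", unknown[1], " carries metacaspases but is missing ",
         "from the genome table")
  counts <- table(factor(mc$genome_id, levels = genomes$genome_id))
  out <- data.frame(
    genome_id = genomes$genome_id, group = genomes$group,
    metacaspase_count = as.integer(counts),
    protein_count = genomes$protein_count, stringsAsFactors = FALSE)
  out$abundance <- 1000 * out$metacaspase_count / out$protein_count
  out$abundance_2dp <- roundHalfAway(out$abundance, 2)
  out
}

#' Per-group abundance summary with abundance bins
#'
#' For each taxonomic group: genome count, unweighted mean of per-genome
#' abundances, metacaspase totals, and the count of genomes per abundance
#' bin (\code{0}, then intervals right-closed at the given edges, then
#' everything above the last edge). Groups with \code{smallGroupMax} or
#' fewer genomes and no metacaspases are folded into \code{"Other"};
#' groups are ordered by descending mean abundance ("Other" last).
#'
#' @param abundance table from \code{\link{genomeAbundance}}.
#' @param binEdges increasing positive bin edges (default
#'   \code{c(0.5, 1)}).
#' @param smallGroupMax largest size of a metacaspase-free group that is
#'   folded into "Other" (default 5).
#' @param pooled if \code{TRUE}, the group mean is pooled
#'   (total metacaspases / total proteins * 1000) instead of the
#'   unweighted mean over genomes.
#' @return \code{data.frame}: \code{group}, \code{n_genomes},
#'   \code{n_metacaspases}, \code{n_positive_genomes},
#'   \code{mean_abundance}, one \code{bin_*} column per category.
#' @export
groupSummary <- function(abundance, binEdges = c(0.5, 1),
                         smallGroupMax = 5, pooled = FALSE) {
  stopifnot(all(diff(binEdges) > 0), all(binEdges > 0))
  grp <- abundance$group
  small <- vapply(split(abundance, grp), function(d)
    nrow(d) <= smallGroupMax && sum(d$metacaspase_count) == 0, TRUE)
  grp[grp %in% names(small)[small]] <- "Other"
  binLabels <- c("bin_zero",
                 paste0("bin_le_", binEdges),
                 paste0("bin_gt_", binEdges[length(binEdges)]))
  rows <- lapply(split(abundance, grp), function(d) {
    ab <- d$abundance
    bins <- c(sum(ab == 0),
              vapply(seq_along(binEdges), function(k) {
                lo <- if (k == 1) 0 else binEdges[k - 1]
                sum(ab > lo & ab <= binEdges[k])
              }, 0),
              sum(ab > binEdges[length(binEdges)]))
    out <- data.frame(
      group = unique(grp[match(d$genome_id, abundance$genome_id)])[1],
      n_genomes = nrow(d),
      n_metacaspases = sum(d$metacaspase_count),
      n_positive_genomes = sum(d$metacaspase_count > 0),
      mean_abundance = if (pooled)
        1000 * sum(d$metacaspase_count) / sum(d$protein_count) else
        mean(ab),
      stringsAsFactors = FALSE)
    out[binLabels] <- as.list(bins)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  isOther <- out$group == "Other"
  out <- rbind(out[!isOther, , drop = FALSE][
    order(-out$mean_abundance[!isOther], out$group[!isOther]), ,
    drop = FALSE], out[isOther, , drop = FALSE])
  rownames(out) <- NULL
  out
}
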