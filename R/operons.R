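# Operon context of metacaspases. Operon predictions are consumed, never
# computed; genomes absent from the operon table are excluded from operon
# denominators.

#' Map metacaspases into predicted operons
#'
#' @param metacaspaseIds protein/gene ids of the identified metacaspases.
#' @param operons long-form operon table (\code{\link{readOperonTable}}).
#' @param proteinGenome optional named vector protein_id -> genome_id;
#'   when given, the summary also reports how many metacaspase-bearing
#'   genomes are covered by the operon predictions.
#' @return list with \code{membership} (per metacaspase:
#'   \code{protein_id}, \code{operon_id} or \code{NA},
#'   \code{in_covered_genome}), \code{per_operon} (metacaspase count per
#'   metacaspase-containing operon) and \code{summary}: a list with
#'   \code{n_metacaspases_covered} (metacaspases in genomes covered by
#'   operon predictions), \code{n_in_operons},
#'   \code{pct_in_operons} (one decimal), \code{n_operons},
#'   \code{n_multi_operons}, \code{max_per_operon},
#'   \code{n_genomes_with_operon_mc}.
#' @export
mapToOperons <- function(metacaspaseIds, operons, proteinGenome = NULL) {
  op <- setNames(operons$operon_id, operons$gene_id)
  covered <- if (!is.null(proteinGenome)) {
    covGenomes <- unique(operons$genome_id)
    unname(proteinGenome[metacaspaseIds]) %in% covGenomes
  } else rep(TRUE, length(metacaspaseIds))
  membership <- data.frame(
    protein_id = metacaspaseIds,
    operon_id = unname(op[metacaspaseIds]),
    in_covered_genome = covered, stringsAsFactors = FALSE)
  inOp <- membership[!is.na(membership$operon_id), , drop = FALSE]
  perOperon <- if (nrow(inOp) > 0) {
    tab <- table(inOp$operon_id)
    data.frame(operon_id = names(tab), metacaspase_count = as.integer(tab),
               stringsAsFactors = FALSE, row.names = NULL)
  } else data.frame(operon_id = character(), metacaspase_count = integer())
  nCov <- sum(covered)
  summary <- list(
    n_metacaspases_covered = nCov,
    n_in_operons = nrow(inOp),
    pct_in_operons = if (nCov > 0)
      surveyPercentage(nrow(inOp), nCov, 1) else NA_real_,
    n_operons = nrow(perOperon),
    n_multi_operons = sum(perOperon$metacaspase_count > 1),
    max_per_operon = if (nrow(perOperon) > 0)
      max(perOperon$metacaspase_count) else 0L,
    n_genomes_with_operon_mc = if (!is.null(proteinGenome))
      length(unique(proteinGenome[inOp$protein_id])) else NA_integer_)
  list(membership = membership, per_operon = perOperon,
       summary = summary)
}

#' Functional annotation of metacaspase operon neighbors
#'
#' Neighbors of each metacaspase-containing operon are annotated with the
#' same hit-screening / architecture machinery as the metacaspases; this
#' function takes their resolved architectures and reports, per operon,
#' the union of neighbor function categories. Operons with no informative
#' neighbor are labelled \code{unknown}. Neighbor genes with no hits at
#' all contribute nothing.
#'
#' @param operons operon table.
#' @param metacaspaseIds ids of the metacaspases themselves (excluded
#'   from the neighbor union).
#' @param neighborElements element table of the neighbors'
#'   resolved architectures (\code{\link{resolveArchitectures}}).
#' @param annotations annotation table; combine
#'   \code{\link{defaultDomainAnnotations}} with
#'   \code{\link{defaultNeighborAnnotations}} for the bundled vocabulary.
#' @return \code{data.frame} per metacaspase-containing operon:
#'   \code{operon_id}, \code{genome_id}, \code{metacaspase_count},
#'   \code{functions} (';'-joined).
#' @export
annotateOperonNeighbors <- function(operons, metacaspaseIds,
                                    neighborElements,
                                    annotations = rbind(
                                      defaultDomainAnnotations(),
                                      defaultNeighborAnnotations())) {
  lut <- functionLookup(annotations)
  mcOperons <- unique(operons$operon_id[operons$gene_id %in%
                                          metacaspaseIds])
  rows <- lapply(mcOperons, function(oid) {
    genes <- operons$gene_id[operons$operon_id == oid]
    neighbors <- setdiff(genes, metacaspaseIds)
    dom <- neighborElements$label[
      neighborElements$protein_id %in% neighbors &
        neighborElements$kind == "pfam"]
    labs <- unique(unlist(lapply(dom[dom %in% names(lut)],
                                 function(d) lut[[d]])))
    labs <- setdiff(labs, "unknown")
    data.frame(operon_id = oid,
               genome_id = operons$genome_id[operons$operon_id == oid][1],
               metacaspase_count = sum(genes %in% metacaspaseIds),
               functions = if (length(labs) == 0) "unknown" else
                 paste(sort(labs), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(operon_id = character(), genome_id = character(),
                      metacaspase_count = integer(),
                      functions = character())
  out[order(out$operon_id), , drop = FALSE]
}
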