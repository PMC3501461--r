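#' @import methods
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet
#' @importFrom utils read.delim write.table data head
#' @importFrom stats rbinom rgeom rpois runif setNames
NULL

#' @useDynLib metacaspase, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

#' Container for one prokaryotic metacaspase survey
#'
#' Bundles everything the survey pipeline consumes: protein sequences (an
#' \linkS4class{AAStringSet} whose names are protein identifiers and whose
#' \code{mcols()$genome_id} records the source genome), the per-domain
#' profile-HMM hit table, predicted membrane-topology segments, the genome
#' table used for taxonomic rollups and abundance normalisation, predicted
#' operons, and the domain function/localization annotation table.
#'
#' @slot proteins \code{AAStringSet} of protein sequences; names are unique
#'   protein identifiers, \code{mcols()$genome_id} the source genome.
#' @slot hits \code{data.frame} of per-domain hits (see
#'   \code{\link{readDomainHits}} for columns).
#' @slot topology \code{data.frame} of topology segments (see
#'   \code{\link{readTopology}}).
#' @slot genomes \code{data.frame} with columns \code{genome_id},
#'   \code{organism}, \code{group}, \code{superkingdom},
#'   \code{protein_count}.
#' @slot operons \code{data.frame} with columns \code{operon_id},
#'   \code{genome_id}, \code{gene_id}, \code{rank}, \code{strand},
#'   \code{start}, \code{end}.
#' @slot annotations \code{data.frame} with columns \code{domain_name},
#'   \code{functions} (';'-joined), \code{localization}.
#'
#' @seealso \code{\link{readSurvey}}, \code{\link{runSurvey}}
#' @export
setClass("MetacaspaseSurvey",
  representation(
    proteins    = "AAStringSet",
    hits        = "data.frame",
    topology    = "data.frame",
    genomes     = "data.frame",
    operons     = "data.frame",
    annotations = "data.frame"
  )
)

setValidity("MetacaspaseSurvey", function(object) {
  msg <- character()
  ids <- names(object@proteins)
  if (length(object@proteins) > 0) {
    if (is.null(ids) || anyNA(ids) || any(ids == ""))
      msg <- c(msg, "all proteins must be named with a protein_id")
    if (anyDuplicated(ids))
      msg <- c(msg, sprintf("duplicate protein_id: %s",
                            ids[duplicated(ids)][1]))
    gid <- mcols(object@proteins)$genome_id
    if (is.null(gid))
      msg <- c(msg, "mcols(proteins)$genome_id is required")
    else if (nrow(object@genomes) > 0 &&
             !all(gid %in% object@genomes$genome_id))
      msg <- c(msg, "every protein genome_id must appear in the genome table")
  }
  if (nrow(object@genomes) > 0 && length(object@proteins) > 0) {
    gid <- mcols(object@proteins)$genome_id
    supplied <- table(gid)
    pc <- setNames(object@genomes$protein_count, object@genomes$genome_id)
    over <- names(supplied)[supplied > pc[names(supplied)]]
    if (length(over) > 0)
      msg <- c(msg, sprintf(
        "genome %s has fewer protein_count than supplied proteins", over[1]))
  }
  if (nrow(object@operons) > 0) {
    if (nrow(object@genomes) > 0 &&
        !all(object@operons$genome_id %in% object@genomes$genome_id))
      msg <- c(msg, "operon genome_id not present in genome table")
    if (anyDuplicated(object@operons$gene_id)) {
      d <- object@operons$gene_id[duplicated(object@operons$gene_id)][1]
      msg <- c(msg, sprintf("gene %s assigned to more than one operon", d))
    }
  }
  if (length(msg) > 0) msg else TRUE
})

#' Annotated reference for catalytic-dyad assessment
#'
#' A curated metacaspase domain sequence with the 1-based positions of the
#' catalytic histidine and cysteine. Envelope sequences are globally aligned
#' to this reference and the residues falling in the two catalytic columns
#' decide dyad conservation.
#'
#' @slot sequence single amino-acid string.
#' @slot cysPos,hisPos 1-based positions of the catalytic residues; the
#'   reference must carry \code{C} and \code{H} there.
#'
#' @seealso \code{\link{classifyDyad}}, \code{\link{defaultDyadReference}}
#' @export
setClass("DyadReference",
  representation(sequence = "character", cysPos = "integer",
                 hisPos = "integer")
)

setValidity("DyadReference", function(object) {
  msg <- character()
  if (length(object@sequence) != 1 || nchar(object@sequence) == 0)
    msg <- c(msg, "sequence must be one non-empty string")
  else {
    n <- nchar(object@sequence)
    if (object@cysPos < 1 || object@cysPos > n ||
        object@hisPos < 1 || object@hisPos > n)
      msg <- c(msg, "catalytic positions must fall inside the sequence")
    else {
      if (substr(object@sequence, object@cysPos, object@cysPos) != "C")
        msg <- c(msg, "reference residue at cysPos must be 'C'")
      if (substr(object@sequence, object@hisPos, object@hisPos) != "H")
        msg <- c(msg, "reference residue at hisPos must be 'H'")
      if (object@cysPos == object@hisPos)
        msg <- c(msg, "cysPos and hisPos must differ")
    }
  }
  if (length(msg) > 0) msg else TRUE
})

#' Survey report: every aggregated table the pipeline produces
#'
#' Returned by \code{\link{runSurvey}}. Each slot is a plain table that can
#' be written to TSV; the \code{totals} slot holds the headline counts
#' (genomes screened, metacaspase-positive genomes, single vs multi-copy
#' carriers, sequences identified).
#'
#' @slot architectures per-protein table: \code{protein_id},
#'   \code{genome_id}, \code{canonical}, \code{is_metacaspase},
#'   \code{n_elements}, \code{has_tmh}.
#' @slot elements per-element table of resolved architectures.
#' @slot dyad per-metacaspase dyad conservation calls.
#' @slot localization per-metacaspase localization categories.
#' @slot functions per-metacaspase ';'-joined function categories.
#' @slot census architecture census (one row per canonical key).
#' @slot prevalence per-domain prevalence among metacaspase sequences.
#' @slot conservation per-group dyad conservation table.
#' @slot abundance per-genome abundance records.
#' @slot groups per-group summary table.
#' @slot operonMembership per-metacaspase operon assignment.
#' @slot operonSummary list of operon headline counts.
#' @slot operonFunctions per-operon neighbor function table.
#' @slot totals list of headline survey counts.
#' @export
setClass("SurveyReport",
  representation(
    architectures    = "data.frame",
    elements         = "data.frame",
    dyad             = "data.frame",
    localization     = "data.frame",
    functions        = "data.frame",
    census           = "data.frame",
    prevalence       = "data.frame",
    conservation     = "data.frame",
    abundance        = "data.frame",
    groups           = "data.frame",
    operonMembership = "data.frame",
    operonSummary    = "list",
    operonFunctions  = "data.frame",
    totals           = "list"
  )
)

#' Planted ground truth of a synthetic survey
#'
#' Emitted by \code{\link{simulateSurvey}} next to the generated input
#' files; records every planted entity exactly once so that pipeline
#' recovery can be scored exactly.
#'
#' @slot metacaspases one row per planted metacaspase: \code{protein_id},
#'   \code{genome_id}, \code{group}, \code{canonical} (intended
#'   post-resolution architecture key), \code{dyad_status},
#'   \code{operon_id} (\code{NA} when not in an operon).
#' @slot hits one row per emitted domain hit with a \code{planted} flag
#'   (\code{TRUE} for hits that must pass screening) and a \code{survives}
#'   flag (\code{TRUE} for hits that must survive overlap resolution).
#' @slot genomes the genome table as written, plus
#'   \code{metacaspase_count}.
#' @slot config the \code{\link{simulationConfig}} list used.
#' @export
setClass("SurveyTruth",
  representation(
    metacaspases = "data.frame",
    hits         = "data.frame",
    genomes      = "data.frame",
    config       = "list"
  )
)

setMethod("show", "MetacaspaseSurvey", function(object) {
  cat("MetacaspaseSurvey\n")
  cat(sprintf("  %d proteins from %d genomes\n",
              length(object@proteins),
              length(unique(mcols(object@proteins)$genome_id))))
  cat(sprintf("  %d domain hits, %d topology segments\n",
              nrow(object@hits), nrow(object@topology)))
  cat(sprintf("  genome table: %d genomes; operon table: %d genes; %d domain annotations\n",
              nrow(object@genomes),
              nrow(object@operons),
              nrow(object@annotations)))
})

setMethod("show", "DyadReference", function(object) {
  cat(sprintf("DyadReference: %d aa, His at %d, Cys at %d\n",
              nchar(object@sequence), object@hisPos, object@cysPos))
})

setMethod("show", "SurveyReport", function(object) {
  t <- object@totals
  cat("SurveyReport\n")
  cat(sprintf("  %d of %d genomes carry metacaspases (%s%%)\n",
              t$metacaspase_genomes, t$genomes,
              format(t$metacaspase_genome_pct)))
  cat(sprintf("  %d metacaspase sequences; %d single-copy carriers, %d with two or more\n",
              t$metacaspases, t$single_carriers, t$multi_carriers))
  cat(sprintf("  %d unique architecture keys (%d group-unique)\n",
              nrow(object@census), sum(object@census$group_unique)))
})

setMethod("show", "SurveyTruth", function(object) {
  cat(sprintf("SurveyTruth: %d planted metacaspases in %d genomes, %d emitted hits\n",
              nrow(object@metacaspases), nrow(object@genomes),
              nrow(object@hits)))
})

#' Construct a MetacaspaseSurvey
#'
#' @param proteins \code{AAStringSet} with names = protein ids and
#'   \code{mcols()$genome_id}.
#' @param hits,topology,genomes,operons,annotations tables as documented in
#'   \linkS4class{MetacaspaseSurvey}; empty tables by default.
#' @return A validated \linkS4class{MetacaspaseSurvey}.
#' @export
MetacaspaseSurvey <- function(proteins = AAStringSet(),
                              hits = emptyHitTable(),
                              topology = emptyTopologyTable(),
                              genomes = emptyGenomeTable(),
                              operons = emptyOperonTable(),
                              annotations = emptyAnnotationTable()) {
  new("MetacaspaseSurvey", proteins = proteins, hits = hits,
      topology = topology, genomes = genomes, operons = operons,
      annotations = annotations)
}

#' Construct a DyadReference
#'
#' @param sequence amino-acid string of the reference domain.
#' @param cysPos,hisPos 1-based positions of the catalytic cysteine and
#'   histidine in \code{sequence}.
#' @return A validated \linkS4class{DyadReference}.
#' @examples
#' DyadReference("MAHACA", cysPos = 5, hisPos = 3)
#' @export
DyadReference <- function(sequence, cysPos, hisPos) {
  new("DyadReference", sequence = toupper(as.character(sequence)),
      cysPos = as.integer(cysPos), hisPos = as.integer(hisPos))
}

#' @rdname MetacaspaseSurvey-accessors
#' @name MetacaspaseSurvey-accessors
#' @title Accessors for survey containers
#' @param x a \linkS4class{MetacaspaseSurvey} or \linkS4class{SurveyReport}.
#' @return The corresponding slot.
NULL

#' @export
#' @rdname MetacaspaseSurvey-accessors
proteins <- function(x) x@proteins

#' @export
#' @rdname MetacaspaseSurvey-accessors
domainHits <- function(x) x@hits

#' @export
#' @rdname MetacaspaseSurvey-accessors
topologySegments <- function(x) x@topology

#' @export
#' @rdname MetacaspaseSurvey-accessors
genomeTable <- function(x) x@genomes

#' @export
#' @rdname MetacaspaseSurvey-accessors
operonTable <- function(x) x@operons

#' @export
#' @rdname MetacaspaseSurvey-accessors
domainAnnotations <- function(x) x@annotations

#' @export
#' @rdname MetacaspaseSurvey-accessors
architectures <- function(x) x@architectures

#' @export
#' @rdname MetacaspaseSurvey-accessors
dyadResults <- function(x) x@dyad

#' @export
#' @rdname MetacaspaseSurvey-accessors
surveyTotals <- function(x) x@totals

#' @export
#' @rdname MetacaspaseSurvey-accessors
plantedTruth <- function(x) x@metacaspases
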