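# Readers and writers for every external format the survey touches:
# FASTA protein sequences, HMMER3-style per-domain hit tables, TMHMM-style
# topology segments, and headered TSV genome/operon/annotation tables.
# All residue and model coordinates are 1-based inclusive throughout.

HIT_COLUMNS <- c("protein_id", "domain_name", "model_length", "hmm_from",
                 "hmm_to", "env_from", "env_to", "i_evalue", "score", "bias")

emptyHitTable <- function() {
  data.frame(protein_id = character(), domain_name = character(),
             model_length = integer(), hmm_from = integer(),
             hmm_to = integer(), env_from = integer(), env_to = integer(),
             i_evalue = numeric(), score = numeric(), bias = numeric(),
             stringsAsFactors = FALSE)
}

emptyTopologyTable <- function() {
  data.frame(protein_id = character(), kind = character(),
             start = integer(), end = integer(), stringsAsFactors = FALSE)
}

emptyGenomeTable <- function() {
  data.frame(genome_id = character(), organism = character(),
             group = character(), superkingdom = character(),
             protein_count = integer(), stringsAsFactors = FALSE)
}

emptyOperonTable <- function() {
  data.frame(operon_id = character(), genome_id = character(),
             gene_id = character(), rank = integer(), strand = character(),
             start = integer(), end = integer(), stringsAsFactors = FALSE)
}

emptyAnnotationTable <- function() {
  data.frame(domain_name = character(), functions = character(),
             localization = character(), stringsAsFactors = FALSE)
}

#' Read protein sequences from FASTA
#'
#' Headers are split into a genome and a protein identifier by a regular
#' expression with two capture groups; the default matches the
#' \code{genome_id|protein_id} convention. Sequences are upper-cased and
#' must use the 20 standard amino-acid letters plus \code{X}.
#'
#' @param path FASTA file.
#' @param headerPattern regex with two capture groups, the first matching
#'   the genome id, the second the protein id.
#' @return \code{AAStringSet} named by protein id, with
#'   \code{mcols()$genome_id}.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">g1|p1", "MACH"), f)
#' readProteinFasta(f)
#' @export
readProteinFasta <- function(path, headerPattern = "^([^|]+)\\|(.+)$") {
  stopifnot(file.exists(path))
  seqs <- readAAStringSet(path)
  if (length(seqs) == 0)
    stop("empty input: no sequences in ", path)
  hdr <- names(seqs)
  m <- regmatches(hdr, regexec(headerPattern, hdr))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop("FASTA header does not match the genome|protein convention: ",
         hdr[bad][1])
  genome <- vapply(m, `[`, "", 2L)
  protein <- vapply(m, `[`, "", 3L)
  if (anyDuplicated(protein))
    stop("duplicate protein_id: ", protein[duplicated(protein)][1])
  seqs <- AAStringSet(toupper(as.character(seqs)))
  checkResidues(as.character(seqs), protein)
  names(seqs) <- protein
  mcols(seqs)$genome_id <- genome
  seqs
}

checkResidues <- function(s, ids, allowX = TRUE) {
  ok <- if (allowX) "^[ACDEFGHIKLMNPQRSTVWYX]+$" else
    "^[ACDEFGHIKLMNPQRSTVWY]+$"
  bad <- !grepl(ok, s)
  if (any(bad))
    stop("non-standard residues in sequence ", ids[bad][1])
  invisible(TRUE)
}

#' Write protein sequences to FASTA
#'
#' Inverse of \code{\link{readProteinFasta}} for the default header
#' convention.
#'
#' @param proteins \code{AAStringSet} with names and
#'   \code{mcols()$genome_id}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeProteinFasta <- function(proteins, path) {
  out <- proteins
  names(out) <- paste0(mcols(proteins)$genome_id, "|", names(proteins))
  writeXStringSet(out, path, width = 70L)
  invisible(path)
}

#' Read a per-domain hit table
#'
#' Accepts two dialects: the full 23-column HMMER3 \code{--domtblout}
#' per-domain table (as written by \code{hmmscan}: the target is the
#' profile, the query the protein) and the package's reduced 10-column TSV
#' (columns \code{protein_id}, \code{domain_name}, \code{model_length},
#' \code{hmm_from}, \code{hmm_to}, \code{env_from}, \code{env_to},
#' \code{i_evalue}, \code{score}, \code{bias}). Comment lines begin with
#' \code{#}. Rows with malformed numeric fields are rejected with their
#' line number; no row is ever silently dropped.
#'
#' @param path hit table file.
#' @return \code{data.frame} with the ten reduced columns.
#' @export
readDomainHits <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  if (!any(keep)) return(emptyHitTable())
  lineno <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  nf <- vapply(fields, length, 1L)
  rows <- vector("list", length(fields))
  for (k in seq_along(fields)) {
    f <- fields[[k]]
    if (nf[k] >= 23) {
      # hmmscan domtblout: target = model, query = protein
      rows[[k]] <- parseHitRow(protein_id = f[4], domain_name = f[1],
        model_length = f[3], hmm_from = f[16], hmm_to = f[17],
        env_from = f[20], env_to = f[21], i_evalue = f[13],
        score = f[14], bias = f[15], line = lineno[k])
    } else if (nf[k] == 10) {
      if (identical(f, HIT_COLUMNS)) { rows[[k]] <- NULL; next }  # header
      rows[[k]] <- parseHitRow(f[1], f[2], f[3], f[4], f[5], f[6], f[7],
                               f[8], f[9], f[10], line = lineno[k])
    } else {
      stop(sprintf("line %d: expected 10 or >=23 fields, found %d",
                   lineno[k], nf[k]))
    }
  }
  hits <- do.call(rbind, rows)
  if (is.null(hits)) return(emptyHitTable())
  rownames(hits) <- NULL
  validateHits(hits)
  hits
}

parseHitRow <- function(protein_id, domain_name, model_length, hmm_from,
                        hmm_to, env_from, env_to, i_evalue, score, bias,
                        line) {
  ints <- suppressWarnings(as.integer(c(model_length, hmm_from, hmm_to,
                                        env_from, env_to)))
  nums <- suppressWarnings(as.numeric(c(i_evalue, score, bias)))
  if (anyNA(ints) || anyNA(nums))
    stop(sprintf("line %d: malformed numeric field", line))
  data.frame(protein_id = protein_id, domain_name = domain_name,
             model_length = ints[1], hmm_from = ints[2], hmm_to = ints[3],
             env_from = ints[4], env_to = ints[5], i_evalue = nums[1],
             score = nums[2], bias = nums[3], stringsAsFactors = FALSE)
}

validateHits <- function(hits, proteins = NULL) {
  with(hits, {
    if (any(model_length <= 0))
      stop("model_length must be positive")
    bad <- hmm_from > hmm_to | hmm_to > model_length
    if (any(bad))
      stop("invalid model coordinates for hit on ", protein_id[bad][1])
    if (any(env_from > env_to | env_from < 1))
      stop("invalid envelope coordinates for hit on ",
           protein_id[env_from > env_to | env_from < 1][1])
    if (any(i_evalue < 0)) stop("negative i_evalue")
    if (any(bias < 0)) stop("negative bias")
  })
  if (!is.null(proteins)) {
    len <- setNames(Biostrings::width(proteins), names(proteins))
    known <- hits$protein_id %in% names(len)
    over <- known & hits$env_to > len[hits$protein_id]
    if (any(over))
      stop("envelope exceeds protein length for ",
           hits$protein_id[over][1])
  }
  invisible(TRUE)
}

#' Write a per-domain hit table (reduced 10-column TSV)
#'
#' @param hits hit \code{data.frame}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeDomainHits <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(HIT_COLUMNS, collapse = "\t")), con)
  if (nrow(hits) > 0) {
    rows <- apply(hits[, HIT_COLUMNS], 1L, function(r)
      paste(trimws(format(r, scientific = NA)), collapse = "\t"))
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read membrane-topology segments (TMHMM-style long format)
#'
#' Expects whitespace-delimited lines \code{protein_id kind start end}
#' where \code{kind} is \code{inside}, \code{TMhelix}/\code{helix} or
#' \code{outside}; \code{#} lines are comments. Segments of one protein
#' must be non-overlapping and alternate sides across each helix.
#'
#' @param path topology file.
#' @return \code{data.frame} with columns \code{protein_id}, \code{kind}
#'   (normalised to \code{inside}/\code{helix}/\code{outside}),
#'   \code{start}, \code{end}, sorted per protein.
#' @export
readTopology <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  if (!any(keep)) return(emptyTopologyTable())
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  lineno <- which(keep)
  nf <- vapply(fields, length, 1L)
  if (any(nf != 4))
    stop(sprintf("line %d: expected 4 fields", lineno[nf != 4][1]))
  df <- data.frame(
    protein_id = vapply(fields, `[`, "", 1L),
    kind = vapply(fields, `[`, "", 2L),
    start = suppressWarnings(as.integer(vapply(fields, `[`, "", 3L))),
    end = suppressWarnings(as.integer(vapply(fields, `[`, "", 4L))),
    stringsAsFactors = FALSE)
  if (anyNA(df$start) || anyNA(df$end))
    stop("malformed topology coordinates")
  df$kind <- normalizeKind(df$kind)
  df <- df[order(df$protein_id, df$start), , drop = FALSE]
  rownames(df) <- NULL
  validateTopology(df)
  df
}

normalizeKind <- function(kind) {
  map <- c(inside = "inside", i = "inside", tmhelix = "helix",
           helix = "helix", outside = "outside", o = "outside")
  out <- map[tolower(kind)]
  if (anyNA(out))
    stop("unknown topology kind: ", kind[is.na(out)][1])
  unname(out)
}

validateTopology <- function(df) {
  if (any(df$start > df$end))
    stop("topology segment with start > end for ",
         df$protein_id[df$start > df$end][1])
  for (pid in unique(df$protein_id)) {
    seg <- df[df$protein_id == pid, , drop = FALSE]
    if (nrow(seg) > 1) {
      if (any(seg$start[-1] <= seg$end[-nrow(seg)]))
        stop("overlapping topology segments for ", pid)
      k <- seg$kind
      for (j in seq_len(nrow(seg) - 1)) {
        if (k[j] != "helix" && k[j + 1] != "helix")
          stop("topology of ", pid,
               " does not alternate: consecutive non-helix segments")
      }
      sides <- k[k != "helix"]
      if (length(sides) > 1 && any(sides[-1] == sides[-length(sides)]))
        stop("topology of ", pid, " does not flip sides across a helix")
    }
  }
  invisible(TRUE)
}

#' Write topology segments
#' @param topology topology \code{data.frame}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeTopology <- function(topology, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#protein_id\tkind\tstart\tend", con)
  if (nrow(topology) > 0)
    writeLines(paste(topology$protein_id, topology$kind, topology$start,
                     topology$end, sep = "\t"), con)
  invisible(path)
}

readHeaderedTSV <- function(path, required) {
  stopifnot(file.exists(path))
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0)
    stop("missing column(s) in ", basename(path), ": ",
         paste(miss, collapse = ", "))
  df[, required, drop = FALSE]
}

#' Read the genome table
#'
#' Headered TSV with columns \code{genome_id}, \code{organism},
#' \code{group} (phylum, or class for Proteobacteria),
#' \code{superkingdom} (\code{Bacteria} or \code{Archaea}) and
#' \code{protein_count} (proteome size used for abundance normalisation).
#'
#' @param path TSV file.
#' @return \code{data.frame}.
#' @export
readGenomeTable <- function(path) {
  df <- readHeaderedTSV(path, names(emptyGenomeTable()))
  if (anyNA(df$protein_count))
    stop("missing protein_count for genome ",
         df$genome_id[is.na(df$protein_count)][1])
  if (any(df$protein_count <= 0)) stop("protein_count must be positive")
  if (anyDuplicated(df$genome_id))
    stop("duplicate genome_id: ", df$genome_id[duplicated(df$genome_id)][1])
  if (!all(df$superkingdom %in% c("Bacteria", "Archaea")))
    stop("superkingdom must be Bacteria or Archaea")
  df
}

#' Read the operon table
#'
#' Headered TSV in long form: one row per gene with columns
#' \code{operon_id}, \code{genome_id}, \code{gene_id}, \code{rank} (order
#' within the operon), \code{strand} and nucleotide \code{start},
#' \code{end}. Each gene may belong to at most one operon.
#'
#' @param path TSV file.
#' @return \code{data.frame} sorted by operon and rank.
#' @export
readOperonTable <- function(path) {
  df <- readHeaderedTSV(path, names(emptyOperonTable()))
  if (nrow(df) == 0) return(emptyOperonTable())
  if (anyDuplicated(df$gene_id))
    stop("gene ", df$gene_id[duplicated(df$gene_id)][1],
         " assigned to more than one operon")
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  df <- df[order(df$operon_id, df$rank), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read the domain annotation table
#'
#' Headered TSV with columns \code{domain_name}, \code{functions}
#' (';'-joined category labels) and \code{localization} (one of
#' \code{intracellular}, \code{membrane}, \code{extracellular}, or empty).
#' Every domain must carry at least one function label; \code{unknown} is
#' exclusive of other labels.
#'
#' @param path TSV file.
#' @return \code{data.frame}.
#' @export
readDomainAnnotations <- function(path) {
  df <- readHeaderedTSV(path, names(emptyAnnotationTable()))
  validateAnnotations(df)
  df
}

validateAnnotations <- function(df) {
  if (nrow(df) == 0) return(invisible(TRUE))
  if (anyDuplicated(df$domain_name))
    stop("duplicate domain annotation: ",
         df$domain_name[duplicated(df$domain_name)][1])
  fl <- strsplit(df$functions, ";", fixed = TRUE)
  n <- vapply(fl, length, 1L)
  if (any(n == 0))
    stop("domain ", df$domain_name[n == 0][1], " has no function label")
  unk <- vapply(fl, function(x) "unknown" %in% x && length(x) > 1, TRUE)
  if (any(unk))
    stop("'unknown' must be the only label for domain ",
         df$domain_name[unk][1])
  loc <- df$localization
  ok <- is.na(loc) | loc %in% c("", "intracellular", "membrane",
                                "extracellular")
  if (!all(ok)) stop("invalid localization: ", loc[!ok][1])
  invisible(TRUE)
}

writeTSV <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname readGenomeTable
#' @param df table to write.
#' @export
writeGenomeTable <- function(df, path) writeTSV(df, path)

#' @rdname readOperonTable
#' @param df table to write.
#' @export
writeOperonTable <- function(df, path) writeTSV(df, path)

#' @rdname readDomainAnnotations
#' @param df table to write.
#' @export
writeDomainAnnotations <- function(df, path) writeTSV(df, path)

#' Read a whole survey from a directory
#'
#' Convenience loader for the file layout written by
#' \code{\link{simulateSurvey}}: \code{proteins.fasta}, \code{hits.tsv},
#' \code{topology.tsv}, \code{genomes.tsv}, \code{operons.tsv},
#' \code{annotations.tsv}. Missing optional files (topology, operons,
#' annotations) yield empty tables; annotations default to the bundled
#' table when absent.
#'
#' @param dir directory containing the survey files.
#' @return A validated \linkS4class{MetacaspaseSurvey}.
#' @export
readSurvey <- function(dir) {
  p <- function(f) file.path(dir, f)
  proteins <- readProteinFasta(p("proteins.fasta"))
  hits <- readDomainHits(p("hits.tsv"))
  validateHits(hits, proteins)
  topology <- if (file.exists(p("topology.tsv")))
    readTopology(p("topology.tsv")) else emptyTopologyTable()
  genomes <- readGenomeTable(p("genomes.tsv"))
  operons <- if (file.exists(p("operons.tsv")))
    readOperonTable(p("operons.tsv")) else emptyOperonTable()
  annotations <- if (file.exists(p("annotations.tsv")))
    readDomainAnnotations(p("annotations.tsv")) else
    defaultDomainAnnotations()
  MetacaspaseSurvey(proteins, hits, topology, genomes, operons,
                    annotations)
}
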