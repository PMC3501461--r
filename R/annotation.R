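# Function categories, sequence-level localization and molecular weight.

#' Function category vocabulary for metacaspase-associated domains
#' @export
FUNCTION_CATEGORIES <- c(
  "protein-protein interaction", "protein modification", "NTPase",
  "enzymatic", "PCD-related", "cell wall binding", "signaling",
  "helicase", "chaperone", "protein-carbohydrate interaction",
  "proteolysis", "unknown")

#' Bundled domain annotation table
#'
#' Function categories and localization for the Pfam domain types most
#' commonly observed alongside the bacterial metacaspase domain. Every
#' function label is drawn from \code{\link{FUNCTION_CATEGORIES}}; any
#' domain not listed here is treated as unknown function at annotation
#' time. Extend with your own TSV via
#' \code{\link{readDomainAnnotations}}.
#'
#' @return annotation \code{data.frame} (\code{domain_name},
#'   \code{functions}, \code{localization}).
#' @export
defaultDomainAnnotations <- function() {
  df <- read.delim(text = "domain_name\tfunctions\tlocalization
WD40\tprotein-protein interaction\t
TPR_1\tprotein-protein interaction\t
TPR_2\tprotein-protein interaction\t
Sel1\tprotein-protein interaction\t
HEAT_PBS\tprotein-protein interaction\t
TIR\tsignaling;protein-protein interaction\t
FGE-sulfatase\tprotein modification\t
Polysacc_deac_1\tenzymatic\t
NACHT\tNTPase;PCD-related\t
NB-ARC\tsignaling;PCD-related\t
AAA\tNTPase;chaperone\t
Amidase_2\tenzymatic;PCD-related;cell wall binding\t
PG_binding_1\tcell wall binding\textracellular
Lipase_GDSL\tenzymatic\t
CHASE2\tsignaling\textracellular
ANF_receptor\tsignaling\textracellular
GGDEF\tsignaling\t
GUN4\tsignaling\tintracellular
Prefoldin_2\tchaperone\tintracellular
Pentapeptide\tunknown\t
Peptidase_C39\tproteolysis\t
DEAD\thelicase;NTPase\t
Lectin_C\tprotein-carbohydrate interaction\t",
    stringsAsFactors = FALSE)
  df$localization[df$localization == ""] <- NA_character_
  validateAnnotations(df)
  df
}

#' Bundled annotations for common operon-neighbor domains
#'
#' Operon neighbors draw on a wider functional vocabulary than the
#' metacaspase-linked domains (transcription, translation, DNA
#' interaction, cell surface). Combine with
#' \code{\link{defaultDomainAnnotations}} when annotating operons.
#'
#' @return annotation \code{data.frame}.
#' @export
defaultNeighborAnnotations <- function() {
  df <- read.delim(text = "domain_name\tfunctions\tlocalization
Sigma70_r2\ttranscription;DNA interaction\t
TrmE\ttranslation\t
Lactamase_B\tenzymatic\t
ATP-sulfurylase\tenzymatic\t
OmpA\tcell surface\tmembrane
RNase_P\ttranslation\t
MreB\tcell division\t",
    stringsAsFactors = FALSE)
  df$localization[df$localization == ""] <- NA_character_
  df
}

functionLookup <- function(annotations) {
  setNames(strsplit(annotations$functions, ";", fixed = TRUE),
           annotations$domain_name)
}

#' Function categories of one architecture
#'
#' Union of function labels over all non-metacaspase Pfam elements;
#' domains absent from the annotation table contribute
#' \code{"unknown"}; an empty union (e.g. a metacaspase-only
#' architecture) yields \code{"unknown"}.
#'
#' @param elements element table of one protein
#'   (\code{\link{integrateTopology}} /
#'   \code{\link{buildArchitecture}} output).
#' @param annotations annotation table.
#' @param metacaspaseLabel the metacaspase domain label.
#' @return character vector of function categories.
#' @export
annotateFunctions <- function(elements,
                              annotations = defaultDomainAnnotations(),
                              metacaspaseLabel = METACASPASE_LABEL) {
  lut <- functionLookup(annotations)
  dom <- elements$label[elements$kind == "pfam" &
                          elements$label != metacaspaseLabel]
  if (length(dom) == 0) return("unknown")
  labs <- unique(unlist(lapply(dom, function(d)
    if (d %in% names(lut)) lut[[d]] else "unknown")))
  sort(labs)
}

#' Sequence-level cellular localization
#'
#' One category per protein, decided from transmembrane elements and the
#' localization annotations of its Pfam domains:
#' \itemize{
#'   \item \code{Membrane and extracellular}: a TMH (or
#'     membrane-annotated domain) together with an
#'     extracellular-annotated domain;
#'   \item \code{Membrane}: a TMH or membrane-annotated domain, no
#'     extracellular domain;
#'   \item \code{Extracellular}: an extracellular domain, no TMH;
#'   \item \code{Intracellular}: only intracellular-annotated domains;
#'   \item \code{Unknown}: no localization evidence at all.
#' }
#'
#' @inheritParams annotateFunctions
#' @return a single category string.
#' @export
classifyLocalization <- function(elements,
                                 annotations = defaultDomainAnnotations(),
                                 metacaspaseLabel = METACASPASE_LABEL) {
  loc <- setNames(annotations$localization, annotations$domain_name)
  dom <- elements$label[elements$kind == "pfam" &
                          elements$label != metacaspaseLabel]
  dloc <- loc[dom[dom %in% names(loc)]]
  dloc <- dloc[!is.na(dloc)]
  hasTMH <- any(elements$kind == "tmh")
  membrane <- hasTMH || any(dloc == "membrane")
  extra <- any(dloc == "extracellular")
  intra <- any(dloc == "intracellular")
  if (membrane && extra) return("Membrane and extracellular")
  if (membrane) return("Membrane")
  if (extra) return("Extracellular")
  if (intra) return("Intracellular")
  "Unknown"
}

# Average residue masses (Da) of the 20 standard amino acids, and water.
RESIDUE_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
WATER_MASS <- 18.01524

#' Molecular weight of a protein chain
#'
#' Sum of average residue masses plus one water. The empty chain weighs
#' one water. \code{X} residues error unless \code{allowX = TRUE}, in
#' which case they contribute the mean residue mass.
#'
#' @param sequence amino-acid string.
#' @param allowX permit \code{X} with an average-mass fallback.
#' @return mass in Da.
#' @examples
#' molecularWeight("G")   # 75.07
#' @export
molecularWeight <- function(sequence, allowX = FALSE) {
  s <- strsplit(toupper(as.character(sequence)), "")[[1]]
  if (length(s) == 0) return(WATER_MASS)
  m <- RESIDUE_MASS[s]
  if (anyNA(m)) {
    bad <- s[is.na(m)]
    if (all(bad == "X") && allowX) {
      m[is.na(m)] <- mean(RESIDUE_MASS)
    } else {
      stop("non-standard residue: ", bad[1])
    }
  }
  sum(m) + WATER_MASS
}
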