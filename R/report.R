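# End-to-end orchestration: identify -> architect -> dyad -> classify ->
# operons -> stats, plus pipeline configuration handling and report
# output.

PIPELINE_DEFAULTS <- list(
  max_i_evalue = 0.01,
  min_score_bias_ratio = 10,
  low_coverage_threshold = 0.60,
  conflict_fraction = 0.25,
  identity_threshold = 0.90,
  metacaspase_label = "Bac_PepC14",
  include_orientation = FALSE,
  signal_peptide_max_start = 30,
  bin_edges = c(0.5, 1),
  small_group_max = 5,
  pooled_group_mean = FALSE)

#' Validate and normalise a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills in the survey defaults
#' (E-value 0.01, score/bias ratio 10, coverage flag 0.60, overlap
#' conflict fraction 0.25, clustering identity 0.90), and rejects unknown
#' keys and out-of-range values.
#'
#' @param config path to a YAML file, a list, or \code{NULL} for pure
#'   defaults.
#' @return normalised config list.
#' @export
validateConfig <- function(config = NULL) {
  cfg <- if (is.null(config)) list()
    else if (is.character(config)) {
      x <- yaml::read_yaml(config)
      if (is.null(x)) list() else x
    } else if (is.list(config)) config
    else stop("config must be a path, a list, or NULL")
  unknown <- setdiff(names(cfg), names(PIPELINE_DEFAULTS))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  out <- utils::modifyList(PIPELINE_DEFAULTS, cfg)
  frac <- c("conflict_fraction", "identity_threshold",
            "low_coverage_threshold")
  for (f in frac)
    if (out[[f]] <= 0 || out[[f]] > 1)
      stop(f, " must be in (0, 1]: ", out[[f]])
  if (out$max_i_evalue <= 0) stop("max_i_evalue must be positive")
  if (out$min_score_bias_ratio <= 0)
    stop("min_score_bias_ratio must be positive")
  out
}

#' Run the full metacaspase survey pipeline
#'
#' Screens the hit table, resolves domain architectures with membrane
#' topology, applies the metacaspase acceptance rule, classifies
#' catalytic-dyad conservation of the metacaspase domain envelopes,
#' assigns function and localization categories, maps metacaspases into
#' operons and aggregates per-genome and per-group abundance.
#'
#' @param survey a \linkS4class{MetacaspaseSurvey}.
#' @param config pipeline configuration (\code{\link{validateConfig}}).
#' @param reference \linkS4class{DyadReference} for dyad assessment.
#' @return A \linkS4class{SurveyReport}.
#' @export
runSurvey <- function(survey, config = validateConfig(),
                      reference = defaultDyadReference()) {
  config <- validateConfig(config)
  hits <- domainHits(survey)
  validateHits(hits, proteins(survey))
  screened <- screenHits(hits, screenConfig(
    config$max_i_evalue, config$min_score_bias_ratio,
    config$low_coverage_threshold))
  proteinGenome <- setNames(mcols(proteins(survey))$genome_id,
                            names(proteins(survey)))
  resolved <- resolveArchitectures(
    screened$accepted, topologySegments(survey), proteinGenome,
    conflictFraction = config$conflict_fraction,
    metacaspaseLabel = config$metacaspase_label,
    includeOrientation = config$include_orientation)
  arch <- resolved$architectures
  elements <- resolved$elements
  mcIds <- arch$protein_id[arch$is_metacaspase]

  # dyad status from the best surviving metacaspase domain envelope
  mcEl <- elements[elements$protein_id %in% mcIds &
                     elements$label == config$metacaspase_label, ,
                   drop = FALSE]
  best <- mcEl[!duplicated(mcEl$protein_id), , drop = FALSE]
  envHits <- data.frame(protein_id = best$protein_id,
                        env_from = best$start, env_to = best$end)
  envs <- extractEnvelopes(envHits, proteins(survey))
  dyad <- classifyDyads(setNames(envs$envelope, envs$protein_id),
                        reference)

  ann <- domainAnnotations(survey)
  if (nrow(ann) == 0) ann <- defaultDomainAnnotations()
  perProtein <- lapply(mcIds, function(pid) {
    el <- elements[elements$protein_id == pid, , drop = FALSE]
    list(functions = paste(annotateFunctions(el, ann,
                                             config$metacaspase_label),
                           collapse = ";"),
         localization = classifyLocalization(el, ann,
                                             config$metacaspase_label))
  })
  functionsTab <- data.frame(
    protein_id = mcIds,
    functions = vapply(perProtein, `[[`, "", "functions"),
    stringsAsFactors = FALSE)
  localizationTab <- data.frame(
    protein_id = mcIds,
    category = vapply(perProtein, `[[`, "", "localization"),
    stringsAsFactors = FALSE)

  cens <- architectureCensus(arch, elements, genomeTable(survey),
                             config$metacaspase_label)
  grp <- setNames(genomeTable(survey)$group,
                  genomeTable(survey)$genome_id)
  conservation <- if (nrow(dyad) > 0)
    substitutionProfile(dyad, unname(grp[arch$genome_id[
      match(dyad$protein_id, arch$protein_id)]]))$by_group
  else data.frame(group = character(), n = integer(),
                  n_positive = integer(), conservation_pct = numeric())

  op <- mapToOperons(mcIds, operonTable(survey), proteinGenome)
  opFun <- annotateOperonNeighbors(operonTable(survey), mcIds, elements,
                                   rbind(ann, defaultNeighborAnnotations()[
                                     !defaultNeighborAnnotations()$domain_name
                                     %in% ann$domain_name, ]))
  ab <- genomeAbundance(arch, genomeTable(survey))
  groups <- groupSummary(ab, binEdges = config$bin_edges,
                         smallGroupMax = config$small_group_max,
                         pooled = config$pooled_group_mean)

  perGenome <- table(factor(arch$genome_id[arch$is_metacaspase],
                            levels = genomeTable(survey)$genome_id))
  nGenomes <- nrow(genomeTable(survey))
  nPos <- sum(perGenome > 0)
  totals <- list(
    genomes = nGenomes,
    metacaspase_genomes = nPos,
    metacaspase_genome_pct = if (nGenomes > 0)
      surveyPercentage(nPos, nGenomes, 0) else NA_real_,
    metacaspases = length(mcIds),
    single_carriers = sum(perGenome == 1),
    multi_carriers = sum(perGenome >= 2),
    dyad_positive = sum(dyad$status == "Positive"),
    dyad_positive_pct = if (nrow(dyad) > 0)
      surveyPercentage(sum(dyad$status == "Positive"), nrow(dyad), 0)
      else NA_real_)

  new("SurveyReport",
      architectures = arch, elements = elements, dyad = dyad,
      localization = localizationTab, functions = functionsTab,
      census = cens$census, prevalence = cens$prevalence,
      conservation = conservation, abundance = ab, groups = groups,
      operonMembership = op$membership, operonSummary = op$summary,
      operonFunctions = opFun, totals = totals)
}

#' Write a survey report to a directory of TSV files
#'
#' One headered TSV per report table plus a machine-readable JSON sidecar
#' (\code{report.json}) with the headline totals and operon summary.
#' Every number in the sidecar is recomputable from the tables.
#'
#' @param report a \linkS4class{SurveyReport}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
writeSurveyReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- c("architectures", "elements", "dyad", "localization",
            "functions", "census", "prevalence", "conservation",
            "abundance", "groups", "operonMembership",
            "operonFunctions")
  for (t in tabs)
    writeTSV(slot(report, t), file.path(dir, paste0(t, ".tsv")))
  jsonlite::write_json(
    list(totals = report@totals, operon_summary = report@operonSummary),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
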