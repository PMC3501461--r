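# Acceptance screening of raw profile-HMM domain hits and model coverage.

#' Screening thresholds for per-domain hits
#'
#' @param maxIEvalue maximum domain independent E-value (default 0.01).
#' @param minScoreBiasRatio minimum bit score / bias ratio (default 10); a
#'   hit with zero bias passes the ratio test (ratio treated as +Inf).
#' @param lowCoverageThreshold profile coverage below which a hit is
#'   flagged as a possible false positive (default 0.60). Flagging never
#'   removes a hit.
#' @return A list of class \code{screenConfig}.
#' @export
screenConfig <- function(maxIEvalue = 0.01, minScoreBiasRatio = 10,
                         lowCoverageThreshold = 0.60) {
  stopifnot(maxIEvalue > 0, minScoreBiasRatio > 0,
            lowCoverageThreshold > 0)
  structure(list(maxIEvalue = maxIEvalue,
                 minScoreBiasRatio = minScoreBiasRatio,
                 lowCoverageThreshold = lowCoverageThreshold),
            class = "screenConfig")
}

#' Screen per-domain hits by E-value and score/bias ratio
#'
#' A hit is accepted iff its domain independent E-value is at or below
#' \code{maxIEvalue} and its score/bias ratio is at or above
#' \code{minScoreBiasRatio}; zero bias counts as an infinite ratio.
#' Screening is total: every input hit lands in exactly one of the two
#' output tables, and each rejected hit carries the first test it failed
#' (\code{"evalue"} or \code{"ratio"}).
#'
#' @param hits hit \code{data.frame} as returned by
#'   \code{\link{readDomainHits}}.
#' @param config a \code{\link{screenConfig}}.
#' @return list with elements \code{accepted} (hit table) and
#'   \code{rejected} (hit table with an extra \code{reason} column).
#' @examples
#' h <- data.frame(protein_id = "p1", domain_name = "Bac_PepC14",
#'                 model_length = 252L, hmm_from = 1L, hmm_to = 230L,
#'                 env_from = 10L, env_to = 260L, i_evalue = 1.7e-37,
#'                 score = 120, bias = 0.1)
#' screenHits(h)$accepted
#' @export
screenHits <- function(hits, config = screenConfig()) {
  ratio <- ifelse(hits$bias == 0, Inf, hits$score / hits$bias)
  passE <- hits$i_evalue <= config$maxIEvalue
  passR <- ratio >= config$minScoreBiasRatio
  ok <- passE & passR
  rejected <- hits[!ok, , drop = FALSE]
  rejected$reason <- ifelse(!passE[!ok], "evalue", "ratio")
  accepted <- hits[ok, , drop = FALSE]
  rownames(accepted) <- rownames(rejected) <- NULL
  list(accepted = accepted, rejected = rejected)
}

#' Profile (HMM) coverage of a domain hit
#'
#' The fraction of the profile's match states spanned by the hit's model
#' alignment: \code{(hmm_to - hmm_from + 1) / model_length}, at full
#' floating precision. Low coverage suggests a partial or spurious match
#' but is only ever flagged, never filtered.
#'
#' @param hits hit \code{data.frame} (or a single-row one).
#' @param lowCoverageThreshold flag threshold (default 0.60).
#' @return numeric vector of coverages with attribute-free values; the
#'   \code{low_coverage} flag vector is attached as
#'   \code{attr(, "low_coverage")}.
#' @examples
#' h <- data.frame(protein_id = "p", domain_name = "d", model_length = 252L,
#'                 hmm_from = 1L, hmm_to = 230L, env_from = 1L,
#'                 env_to = 230L, i_evalue = 0, score = 100, bias = 0)
#' hmmCoverage(h)  # 230/252
#' @export
hmmCoverage <- function(hits, lowCoverageThreshold = 0.60) {
  if (any(hits$model_length <= 0)) stop("model_length must be positive")
  cov <- (hits$hmm_to - hits$hmm_from + 1) / hits$model_length
  attr(cov, "low_coverage") <- cov < lowCoverageThreshold
  cov
}
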