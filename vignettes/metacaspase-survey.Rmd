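---
title: "Surveying prokaryotic metacaspases: methods and design choices"
author: "metacaspase package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveying prokaryotic metacaspases: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metacaspase)
```

## The problem

Metacaspases are the prokaryotic and non-metazoan homologs of caspases:
cysteine proteases of the Peptidase C14 family whose activity depends on
a conserved cysteine–histidine catalytic dyad. Genome-scale surveys of
this family start from profile-HMM searches over predicted proteomes and
then have to answer, per protein: is the hit credible, what is the full
N→C domain architecture once overlapping hits and transmembrane helices
are reconciled, is the catalytic dyad intact, and how do counts
distribute over genomes, taxa and operons. This package implements each
of those decisions as a tested function and composes them with
`runSurvey()`.

## Screening thresholds

Hits are accepted when the domain independent E-value is at most
`max_i_evalue` (default 0.01) and the score/bias ratio is at least
`min_score_bias_ratio` (default 10). Both are configuration, but the
defaults are the survey's operating point and all tests run at them. Two
boundary decisions:

* **Zero bias.** The ratio is undefined at `bias = 0`; we treat it as
  +Inf, i.e. the hit passes the ratio test. A strong hit with no
  composition-bias correction is the best case, not the worst, so
  rejecting it would invert the filter's intent.
* **Low profile coverage.** Hits whose model alignment spans less than
  60 % of the profile's match states are flagged as possible false
  positives but never removed: partial hits are informative and their
  exclusion is a judgement the analyst should make downstream, not the
  screen.

## Overlap conflicts and architecture

Two accepted Pfam domains conflict when their envelope overlap exceeds
`conflict_fraction` (default 0.25) of the length of *either* envelope —
equivalently, overlap / min(lenA, lenB) > 0.25. We read "either one of
them" as *at least one*: the alternative ("both") would almost never
trigger on nested domains, which are exactly the cases the rule exists
for. Resolution is greedy by ascending E-value with a strict total order
(E-value, then longer envelope, then domain name, then coordinates), so
any permutation of the input yields the same survivor set; the greedy
set is the unique conflict-free set in which every excluded hit
conflicts with a better surviving one, which is how the test oracle
checks it by exhaustive subset enumeration.

Transmembrane helices are integrated after Pfam conflicts are settled:
a helix overlapping a surviving Pfam domain by even one residue is
dropped (the Pfam domain takes precedence; no overlap fraction is
defined for this case, so any overlap counts). Retained helices carry an
orientation read from the flanking topology segments (`iTMHo` when the
N-terminal side is predicted inside) and a putative signal-peptide flag
when a protein's only predicted helix starts at residue 30 or earlier.
The flag never removes the helix: signal-peptide status is a likelihood,
not a call we can make from topology alone.

Consecutive repeats of one domain collapse into a single element with a
repeat count; the canonical architecture key joins the collapsed labels
with `|` and ignores repeat counts. By default TMH orientation is *not*
part of the key (a C-terminal `iTMHo` and `oTMHi` helix give the same
key); `include_orientation = TRUE` switches this, since published
unique-architecture counts are ambiguous on the point. A protein enters
the survey as a metacaspase only if the bacterial metacaspase domain
(`Bac_PepC14` by default) survives into its final architecture — a
stronger overlapping domain can displace it and remove the protein from
the survey.

## Dyad assessment

The survey needs exactly two columns of a multiple alignment: the
catalytic cysteine and histidine positions. We therefore replace a
multiple alignment with deterministic pairwise global alignment
(Needleman–Wunsch) of each domain envelope against a single annotated
reference (`DyadReference`), scored with BLOSUM62 and a linear gap
penalty of 8. Traceback ties are broken diagonal-first, so results are
reproducible to the byte. A residue aligned into either catalytic column
decides the call; a gap there counts as substitution-by-deletion
(Negative) — deletions of an active-site residue are not conservation.
When both catalytic columns fall in a terminal gap the call is
additionally marked low-confidence, because the envelope simply does not
cover the catalytic region. The bundled 252-residue reference is
synthetic, with the histidine annotated at position 90 and the cysteine
at 150; real analyses should supply a curated Peptidase C14 domain, and
the dyad positions are deliberately mandatory arguments on
`DyadReference()` rather than defaults.

## Training-set curation

`curateTrainingSet()` reproduces the preparation of a family-specific
profile: envelope extraction, removal of dyad-negative sequences, then
greedy clustering at `identity_threshold` (default 0.90) with identity
defined as alignment matches divided by the *shorter* sequence's length
— the convention of cd-hit-style clustering. Sequences are processed
longest-first and each joins the first cluster whose representative is
close enough, so the representative of every cluster is its longest
member by construction. Manual alignment inspection and end-trimming are
not automated; `curationReport()` emits per-sequence identity and
terminal-gap fractions as the input to that human step.

## Aggregation choices

* Abundance is metacaspases per 1000 proteins,
  `1000 * count / protein_count`, reported at two decimals.
* The per-group mean abundance is the **unweighted mean over genomes**;
  a pooled mode (total counts / total proteins) is available via
  `pooled_group_mean` because the choice is not forced by anything in
  the data.
* Abundance bin edges default to {0}, (0, 0.5], (0.5, 1], > 1
  metacaspases per 1000 proteins. Published figures of this kind do not
  state their edges; these are round values covering the observed
  dynamic range and are fully configurable (`bin_edges`).
* Groups with five or fewer genomes and no metacaspases fold into an
  "Other" row, which sorts last.
* Printed percentages round half away from zero at 0 or 1 decimals
  (`surveyPercentage`). This matches almost all published survey
  arithmetic we checked; the one known exception (237/508 printing as
  46.6 rather than 46.7) appears to be a truncation in the source and is
  documented rather than emulated.

## The synthetic survey generator

`simulateSurvey()` emulates the *statistical structure* the pipeline
assumes, not protein evolution:

* 18 % of genomes carry metacaspases (`pPositiveGenome`), matching the
  headline positive-genome rate of finished-genome surveys; copy numbers
  are zero-truncated geometric with mean 2.5 (roughly 671 family members
  across 267 carriers). A geometric cannot simultaneously match that
  mean and the published single-copy fraction (157/267); we match the
  mean and accept a higher single-copy share.
* Planted metacaspase domains are the bundled reference with, at rate
  `pDyadNegative` (default 0.16, the complement of the ~84 % intact-dyad
  rate), one canonical substitution: C→S with probability 0.43, H→Y with
  probability 0.63, otherwise a random other residue — mirroring the
  reported substitution spectrum.
* The architecture palette plants eight architectures including an
  overlap conflict (a weaker hit nested in a stronger domain that must
  lose), a shadowed helix (must be dropped), a retained C-terminal helix
  and an N-terminal signal-peptide helix, so conflict resolution and
  topology integration are exercised, not just parsed.
* Decoy hits violate at least one screening threshold: E-values drawn
  log-uniform in [0.02, 10] (E-value failures) or bias set so the
  score/bias ratio lands in (2, 8) (ratio failures). Planted hits draw
  E-values log-uniform in [1e-40, 1e-3] subranges and bias so the ratio
  clears 20.
* Operon predictions cover 75 % of genomes; in covered genomes each
  metacaspase is in an operon with probability 0.47, joining the
  previous operon (up to three members) with probability 0.15; operons
  gain one to three annotated neighbor genes.
* Sequence background outside planted domains is i.i.d. uniform over the
  20 residues. No pipeline stage models residue composition beyond the
  two catalytic columns, so richer background would add nothing the
  tests could detect — which also bounds what passing tests show about
  real data: they validate the decision logic exactly, not robustness to
  homology, compositional bias or fragmented gene models.

Randomness uses one master seed with fixed per-stage derived seeds
(genomes, planting, decoys, operons), so identical seed and config give
byte-identical output files and partial inspection is stable.

## Problem sizes and numerical notes

The test suite validates conflict resolution against exhaustive subset
enumeration on hit sets of up to 8 hits over 1000 seeded draws, the
aligner against brute-force path enumeration on sequences up to length
6 over 200 draws, end-to-end planted-truth recovery on a 200-genome
synthetic survey, and the positive-genome rate on a 1000-genome draw
(within three binomial standard deviations of 0.18). These sizes make
the oracles exact while keeping the whole suite under a minute of
compute on one core. All coordinates are 1-based inclusive throughout
(the HMMER and TMHMM convention); coverage and identity are computed at
full double precision and only rounded for display.

## Known limitations

* Dyad calls depend on a single-reference pairwise alignment; highly
  diverged envelopes can misalign the catalytic columns where a curated
  multiple alignment would not. The low-confidence flag catches only the
  extreme (terminal-gap) case.
* Operon predictions and E-values are consumed, never computed; garbage
  in, garbage out.
* The localization rule (Membrane / Extracellular / Membrane and
  extracellular / Intracellular / Unknown) is a declared convention —
  the underlying annotations rarely force a unique assignment.
* The bundled annotation table covers only the domain types most often
  seen with metacaspases; everything else maps to unknown function
  unless the user extends the table.
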