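---
title: "Methods: identification curation, quantitation, and assay generation in pepflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identification curation, quantitation, and assay generation in pepflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepflow)
```

## Scope and data model

pepflow implements the computational core of a discovery-to-targeted
shotgun-proteomics workflow at desk scale. A peptide-spectrum match (PSM) is
one row of a plain data frame carrying the peptide sequence, a canonical
`"pos:mass"` modification string, charge, observed precursor m/z, retention
time in minutes, the search-engine score together with its per-PSM identity
and homology significance thresholds, the semicolon-joined protein
accessions, and a decoy flag. Retention times are minutes everywhere; a
single unit avoids silent 60-fold errors. Proteomes, spectra (MGF),
identifications (canonical CSV, pepXML, protXML), spectral libraries, and
transition lists all pass through the `formats` readers/writers, so every
analysis function consumes only these in-memory types.

## Target-decoy FDR estimation

Decoy PSMs are recognized by an accession prefix (default `DECOY_`,
configurable). With PSMs sorted by score, the estimated false discovery rate
at threshold $s$ is

$$\widehat{FDR}(s) = \frac{\#\{\text{decoys} \ge s\}}{\max(\#\{\text{targets} \ge s\},\,1)},$$

capped at 1, which assumes a concatenated target-decoy search in which the
decoy count estimates the number of false targets above the same threshold.
The q-value of a PSM is the minimum $\widehat{FDR}$ over all thresholds at
which it is accepted, which makes q monotone non-increasing in score; tied
scores share one q-value, so the PSMs at the chosen threshold pass or fail
together. Filtering is done at PSM level, the level at which libraries are
curated here; protein-level reports are then derived from surviving PSMs.
The estimator is exercised against labeled synthetic data: with 500 true
PSMs scored $N(60, 10)$ against 500 false targets and 500 decoys scored
from a shared $N(30, 10)$ null, the realized false-discovery proportion at
the estimated 1% cutoff averages inside $[0.005, 0.015]$ over 20
simulations. Those score distributions are the generator's fixed study
conditions, chosen to give clean but not trivial separation (three standard
deviations between the means, matching a well-calibrated ion-score search).

## Mass arithmetic

Peptide m/z uses monoisotopic residue masses, water 18.010565 Da, and a
proton of 1.007276 Da:
$m/z = (\sum_i m_i + m_{\mathrm{H_2O}} + \sum_j \Delta_j + z\,m_p)/z$.
Fragment ladders cover b and y ions at charges 1-2 with modification deltas
riding on their residues (N-terminal deltas ride with the b series). Mass
accuracy is reported as signed parts-per-million against the theoretical
value. Protein scores are the sum of each distinct peptide's best PSM score
(a Mascot-style convention); sequence coverage is the union of all exact
peptide occurrences, reported as a fraction plus merged 1-based inclusive
intervals.

## Abundance and quantitation

emPAI is the closed form $10^{N_{obs}/N_{obsbl}} - 1$, with the denominator
from an in-silico tryptic digest (cleave C-terminal to K/R, never before P,
no missed cleavages) counted inside a 5-30 residue window — the same window
the library curation uses, so one length convention governs the package;
the window is configurable.

Reporter-ion (iTRAQ/TMT) and SILAC quantitation roll peptide-level ratios
up to proteins by the **median**, not the mean: the roll-up must survive
occasional interference-corrupted PSMs, and the median tolerates up to half
of the ratios being contaminated. PSMs with non-positive reference
intensity are excluded from ratio computation only.

Label-free merging sums peptide abundances to protein level per replicate,
takes the fold change as the ratio of condition means, and computes a
one-way fixed-effects ANOVA on log2 abundances (log2 stabilizes the
multiplicative variance of intensity data; with two groups the F statistic
reduces to the squared equal-variance t statistic, which the tests verify).
Degenerate inputs with zero variance everywhere return $p = 1$. Raw p
values are reported, as in the report tables this mirrors; a
Benjamini-Hochberg column is available but off by default. Proteins backed
by one distinct peptide are flagged so volcano plots can color them
separately. The generator injects a log2 fold change of 2.0 at 20%
multiplicative CV in a 3 vs 3 design over 100 changed and 200 null
proteins; the estimator recovers the effect with median absolute error
well under 0.2 log2 units and null ANOVA p values consistent with
uniformity (Kolmogorov-Smirnov).

Because peptide-to-protein combination for label-free data is performed
upstream by peak-integration software in real deployments, the
sum-then-ratio rule here is the package's own documented choice, not a
reconstruction of any vendor's algorithm.

## Phosphosite reporting

A modification counts as a phosphosite when its delta is within 0.01 Da of
79.966331 (HPO3) **and** it sits on S, T or Y; N-terminal deltas never
qualify. The site-localization confidence is the Mascot delta score: the
difference between the top two localization candidates' scores for one
spectrum. A single unopposed candidate scores as itself — an unambiguous
peptide (only one possible site) has nothing to be confused with, so its
own score is the natural ceiling; ties score 0. PhosphoRS probabilities are
pass-through fields computed upstream. Phosphosites are rendered by
lower-casing the residue, a medium-independent stand-in for underlining.

## Comparative analysis

Samples are compared as key sets — peptide keys include the modification
string by default (an option drops it), protein keys are bare accessions
with no case folding. "Distinct" means present in that sample and absent
from **all** others jointly, not pairwise-unique. The overlap matrix is
symmetric with set sizes on the diagonal, and all outputs are invariant to
sample order.

## Spectral library curation and uniqueness

Library curation applies, per search result: the 1% FDR filter, a score
strictly greater than the PSM's homology threshold, and peptide length
5-30. Strict `>` is the default because that is the stricter reading of the
curation rule; a `greater_equal` switch covers the laxer convention. The
length window is applied after FDR filtering; the two filters commute, so
the output set is unaffected. Surviving PSMs group by (sequence,
modifications, charge) — charge is part of entry identity because
downstream transition m/z depends on it — keeping the highest-scoring
replicate spectrum (best-replicate, not consensus averaging), the
observation count, median retention time, and provenance.

Peptide uniqueness is established by deterministic exact-substring search
over a species proteome, optionally treating I and L as equivalent (they
are isobaric and indistinguishable by mass). For full-length tryptic
peptides this is the decision that a short-peptide homology search
ultimately reduces to, and it is reproducible without external databases;
it does not model near-identical homologs that differ inside the peptide.
The census reports, per species, the distinct peptides mapping into the
proteome and the proteins supported by at least two distinct peptides
(configurable).

The library store is a single text file with `[entries]`, `[peaks]`, and
`[uniqueness]` tab-separated sections, a relational layout whose write/read
round trip is exact (numbers serialized at full precision).

## MRM/SRM assay generation

Assay peptide selection applies five criteria in order: (1) score at or
above the identity threshold; (2) proteins must retain three or more
distinct peptides; (3) the peptide must map to exactly one protein in the
species proteome; (4) no methionine (Met oxidation splits the signal
between two masses); (5) survivors sorted by observation count, top five
kept per protein (configurable). The three-peptide rule is re-checked after
(3)-(4): an assay representing a protein by fewer than three final peptides
would defeat the rule's purpose, so the later filters can retroactively
disqualify a protein. Every candidate carries its selection flag and the
first criterion it failed, which makes the audit table a complete account
of the decision. Ties in observation count break by higher score, then
lexicographic sequence, so selection is deterministic and input-order
invariant.

Transitions come from annotating the best library spectrum against the
theoretical b/y ladder (charges 1-2) within +-0.5 Th — triple-quadrupole
unit-resolution practice — ranking annotated ions by intensity (ties:
lower product m/z first) and keeping the top five, with the product m/z
set to the theoretical value. The exported TSV prints m/z to four decimals.

## The synthetic-data generator

Synthetic proteins are concatenations of random tryptic peptides (interior
residues never K/R, no P after a cleavage site, terminal K/R), so the
in-silico digest recovers exactly the planted peptides and digest-set
membership is an independent oracle for substring mapping. Planted shared
peptides (inserted into two proteins) and Met-bearing peptides give the
uniqueness and Met filters known contaminants that must never reach a
method file. Search results attach true PSMs to real digest peptides and
false/decoy PSMs to interior-shuffled peptides (shuffling, not reversal,
avoids palindromic self-matches at this scale) with scores from the
distributions above; spectra are b/y ladders with log-normal intensities
plus noise peaks kept at least 1 Th away from every ladder ion so
annotation is unambiguous and the recorded intensity ranking is an exact
transition oracle.

What the generator does **not** emulate: realistic fragmentation
propensities, retention-time structure, chimeric spectra, missed
cleavages, or score distributions conditioned on peptide properties.
Passing tests therefore demonstrate the correctness of the filtering,
grouping, ranking and estimation logic under controlled conditions — not
instrument-level performance on real data.

Problem sizes used by the automated checks — 20 simulations of 1500 PSMs
for FDR calibration, a 500-protein proteome for curation and census, an
80-protein proteome with 6 + 6 planted contaminants for the assay
pipeline, and 300 proteins in the quantitation design — are the package's
chosen desk-scale conditions: large enough for stable proportions, small
enough to re-run interactively.

## Numerical choices and degenerate inputs

* FDR capped at 1; zero targets is an error, zero decoys gives all-zero q.
* `empai` requires at least one observable peptide; zero observed gives 0.
* Zero-variance ANOVA returns 1 (no evidence), infinite-F cases return 0.
* Peptides not found in their protein contribute nothing to coverage, with
  a warning.
* Empty candidate sets, empty libraries, and spectra without annotatable
  peaks all return empty, typed results rather than errors.
* All generators restore the caller's RNG state; identical parameters and
  seed give byte-identical output files.

## Known limitations

The uniqueness mapper is exact-match only; homologous peptides differing
by one residue are called unique. PSM-level FDR is the only error control
offered — there is no protein-level FDR model. The label-free merge
assumes exactly two conditions for its fold change (the ANOVA handles any
number). pepXML/protXML ingestion covers the common attribute layout
emitted by the standard pipelines, not every dialect extension.
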