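# pepflow

Desk-scale R toolkit for the computational core of a shotgun-proteomics
workflow: from peptide-spectrum matches (PSMs) through target-decoy FDR
filtering, quantitation, and spectral-library curation, to fully automated
MRM/SRM transition-list generation. It is written for proteomics
bioinformaticians who want the curation and assay-design logic of a core
facility pipeline as composable, testable functions rather than a web
stack.

## What it computes

**FDR filtering.** With decoys flagged by accession prefix, the estimated
false discovery rate at a score threshold *s* is
`#decoys ≥ s / max(#targets ≥ s, 1)`, capped at 1; a PSM's q-value is the
minimum FDR over all thresholds accepting it. `filter_at_fdr()` returns the
targets with q ≤ 0.01 (the curation standard used throughout) and never a
decoy.

**Abundance and quantitation.** emPAI is `10^(N_obs/N_obsbl) − 1` with the
denominator from an in-silico tryptic digest (5–30 residue window).
Reporter-ion (iTRAQ/TMT) and SILAC ratios roll up to proteins by the
median. Label-free tables merge into a report with per-condition means,
fold changes, one-way ANOVA p-values on log2 abundances, a single-peptide
flag, and volcano-plot coordinates.

**Phosphosite reporting.** Phospho PSMs (Δm within 0.01 Da of 79.966331 on
S/T/Y) are reported with the Mascot delta score — the gap between the top
two site-localization candidates — plus pass-through PhosphoRS
probabilities, m/z, and ppm mass accuracy.

**Spectral library and MRM assays.** Libraries keep, per (peptide,
modifications, charge), the best replicate spectrum with observation count
and median retention time, after the 1% FDR, score > homology-threshold,
and length filters. Assay peptides then pass five criteria — identity-score
floor, ≥ 3 peptides per protein, proteome uniqueness (exact substring
matching, optional I/L equivalence), no methionine, top-5 by observation
count — and the most intense b/y ladder ions of the best spectrum become
the exported transitions.

A synthetic-data module (`make_proteome()`, `make_search_result()`,
`make_spectra()`, `make_quant_tables()`) generates all inputs with recorded
ground truth, so the whole pipeline is testable offline.

## Worked example

```r
library(pepflow)

pr  <- make_proteome(60, seed = 42, n_shared = 2, n_met = 3)
sr  <- make_search_result(pr$proteome, n_true = 400, n_false = 150, seed = 43)
flt <- filter_at_fdr(sr$psms, q_max = 0.01)
round(c(targets = flt$n_targets_passing, threshold = flt$score_threshold,
        fdr = flt$fdr_estimate), 4)
#>   targets threshold       fdr
#>  329.0000   50.6973    0.0091

sp  <- make_spectra(sr$psms[sr$psms$spectrum_id %in% sr$truth$true_psm_ids, ],
                    seed = 44)
lib <- curate_library(sr$psms, spectra = sp$spectra)
nrow(lib)
#> [1] 306
library_census(lib, list(synthetica = pr$proteome), min_distinct = 2)
#>      species protein_count peptide_count
#> 1 synthetica            57           297

assay <- select_assay_peptides(lib, pr$proteome)
table(assay$rejection_reason, useNA = "ifany")
#>             contains_met           not_top_ranked               not_unique
#>                      136                        7                        1
#> protein_too_few_peptides                     <NA>
#>                       45                      117

method <- build_method(assay, sp$spectra, n_transitions = 5)
head(method[, c("protein_accession", "peptide_sequence", "precursor_mz",
                "fragment_type", "fragment_index", "product_mz",
                "intensity_rank")], 5)
#>   protein_accession peptide_sequence precursor_mz fragment_type fragment_index
#> 1           SYN0001      ANISTCGSDSR    370.83299             y              7
#> 2           SYN0001      ANISTCGSDSR    370.83299             y              9
#> 3           SYN0001      ANISTCGSDSR    370.83299             y              2
#> 4           SYN0001      ANISTCGSDSR    370.83299             b              3
#> 5           SYN0001      ANISTCGSDSR    370.83299             y              1
#>   product_mz intensity_rank
#> 1  725.28828              1
#> 2  463.20582              2
#> 3  131.57913              3
#> 4  150.08933              4
#> 5  175.11895              5
```

Of the 306 curated entries, 117 survive all five assay filters (`NA`
rejection reason = selected): 136 contain methionine, 45 belong to
proteins left with fewer than three peptides, 1 maps to more than one
protein (a planted shared peptide), and 7 are ranked out beyond the top
five per protein. Each selected peptide contributes its five most intense
annotated fragments to the transition list.

The same stages are scriptable from a shell via the installed `pepflow`
entry point (`exec/pepflow`): `simulate`, `ingest`, `fdr`, `quant`,
`phospho`, `compare`, `build-lib`, `census`, `query`, and `mrm`, each
writing a run-manifest JSON beside its output.

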