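#' Monoisotopic residue masses
#'
#' Named vector of monoisotopic masses (Da) for the 20 standard amino acid
#' residues (as residues, i.e., minus water).
#'
#' @format Named numeric vector, one element per one-letter residue code.
#' @export
AA_MONO <- c(
  G =  57.02146, A =  71.03711, S =  87.03203, P =  97.05276,
  V =  99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
  I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
  K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
  F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

#' @rdname AA_MONO
#' @export
PROTON_MASS <- 1.007276

#' @rdname AA_MONO
#' @export
WATER_MASS <- 18.010565

#' Monoisotopic mass delta of a phospho group (HPO3), Da
#' @export
PHOSPHO_MASS <- 79.966331

# Named modification masses used when annotating deltas read from pepXML.
MOD_MASS_TABLE <- c(
  phospho          = 79.966331,
  oxidation        = 15.994915,
  carbamidomethyl  = 57.021464,
  acetyl           = 42.010565,
  deamidation      =  0.984016,
  methyl           = 14.015650
)

mod_name_for_mass <- function(mass_delta, tol = 0.01) {
  i <- which(abs(MOD_MASS_TABLE - mass_delta) <= tol)
  if (length(i)) names(MOD_MASS_TABLE)[i[1]] else NA_character_
}

#' Parse a canonical modification string
#'
#' Modifications travel as a semicolon-separated `"pos:mass"` string
#' (position 1-based within the peptide, 0 = N-terminus; mass delta in Da,
#' monoisotopic).  Returns a data frame with one row per modification.
#'
#' @param x Character scalar, e.g. `"4:79.966331;1:42.010565"`. Empty string
#'   or `NA` means unmodified.
#' @return `data.frame(position, mass_delta, name)`.
#' @export
parse_modifications <- function(x) {
  if (is.na(x) || !nzchar(x)) {
    return(data.frame(position = integer(), mass_delta = numeric(),
                      name = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  pos  <- vapply(parts, function(p) as.integer(p[1]), integer(1))
  mass <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
  data.frame(position = pos, mass_delta = mass,
             name = vapply(mass, mod_name_for_mass, character(1)),
             stringsAsFactors = FALSE)
}

#' Format a modification data frame back to the canonical string
#' @param mods Data frame as returned by [parse_modifications()].
#' @return Character scalar (`""` when unmodified).
#' @export
format_modifications <- function(mods) {
  if (is.null(mods) || nrow(mods) == 0) return("")
  paste(sprintf("%d:%.6f", mods$position, mods$mass_delta), collapse = ";")
}

#' Theoretical peptide m/z
#'
#' Monoisotopic m/z of a (modified) peptide at a given charge:
#' `(sum(residues) + water + sum(mod deltas) + z * proton) / z`.
#'
#' @param sequence Uppercase amino-acid string (standard 20 residues).
#' @param modifications Canonical modification string or a data frame as
#'   returned by [parse_modifications()]; optional.
#' @param charge Positive integer charge state.
#' @return m/z in Thomson.
#' @export
peptide_mz <- function(sequence, modifications = "", charge = 1L) {
  stopifnot(charge >= 1)
  res <- strsplit(sequence, "")[[1]]
  unknown <- setdiff(res, names(AA_MONO))
  if (length(unknown)) {
    stop("unknown residue(s) in peptide '", sequence, "': ",
         paste(unique(unknown), collapse = ", "))
  }
  if (is.character(modifications)) modifications <- parse_modifications(modifications)
  mod_mass <- if (is.null(modifications)) 0 else sum(modifications$mass_delta)
  (sum(AA_MONO[res]) + WATER_MASS + mod_mass + charge * PROTON_MASS) / charge
}

#' Neutral (uncharged) peptide mass
#' @inheritParams peptide_mz
#' @return Monoisotopic neutral mass in Da.
#' @export
peptide_neutral_mass <- function(sequence, modifications = "") {
  peptide_mz(sequence, modifications, charge = 1L) - PROTON_MASS
}

#' Signed mass accuracy in parts per million
#'
#' @param observed_mz,theoretical_mz m/z values in Thomson;
#'   `theoretical_mz` must be positive.
#' @return `(observed - theoretical) / theoretical * 1e6`.
#' @export
ppm_error <- function(observed_mz, theoretical_mz) {
  stopifnot(all(theoretical_mz > 0))
  (observed_mz - theoretical_mz) / theoretical_mz * 1e6
}

#' Target-decoy q-values for a set of PSMs
#'
#' Sorts PSMs by score (descending) and estimates, at every observed score
#' threshold s, `FDR(s) = #decoys >= s / max(#targets >= s, 1)`, capped at 1.
#' The q-value of a PSM is the minimum estimated FDR over all thresholds at
#' which it is accepted; PSMs sharing a score share a q-value.
#'
#' @param psms PSM data frame with at least `score` (finite numeric) and
#'   `is_decoy` (logical) columns; must contain at least one target.
#' @return The input data frame with a `q_value` column added, carrying a
#'   `"fdr_table"` attribute: a data frame of unique scores with cumulative
#'   target/decoy counts, raw FDR and q-value.
#' @export
compute_qvalues <- function(psms) {
  stopifnot(is.data.frame(psms), all(c("score", "is_decoy") %in% names(psms)))
  if (!any(!psms$is_decoy)) stop("no target PSMs: q-values undefined")
  if (any(!is.finite(psms$score))) stop("non-finite PSM scores")

  ord <- order(psms$score, decreasing = TRUE)
  sc  <- psms$score[ord]
  dec <- psms$is_decoy[ord]
  cum_t <- cumsum(!dec)
  cum_d <- cumsum(dec)
  # evaluate counts at the last index of each tie group so ties share a value
  last_of_score <- !duplicated(sc, fromLast = TRUE)
  fdr <- pmin(cum_d / pmax(cum_t, 1), 1)
  # thresholds exist only at the last index of each tie group; q(s) is the
  # minimum FDR over this and every lower score threshold, so tied PSMs see
  # the same threshold set and share a q-value
  fdr_at_score <- ifelse(last_of_score, fdr, Inf)
  q <- rev(cummin(rev(fdr_at_score)))

  out <- psms
  out$q_value <- NA_real_
  out$q_value[ord] <- q
  tab <- data.frame(score = sc[last_of_score],
                    n_targets = cum_t[last_of_score],
                    n_decoys = cum_d[last_of_score],
                    fdr = fdr[last_of_score],
                    q_value = q[last_of_score])
  attr(out, "fdr_table") <- tab
  out
}

#' Filter PSMs at an FDR bound
#'
#' Computes q-values and returns the target PSMs with `q <= q_max` together
#' with the chosen score threshold.  Decoys are never returned; PSMs tied at
#' the threshold score pass together.
#'
#' @inheritParams compute_qvalues
#' @param q_max Maximum accepted q-value (default 0.01, the 1% FDR
#'   curation standard).
#' @return List with `psms` (passing targets, q_value column included),
#'   `score_threshold`, `n_targets_passing`, `n_decoys_passing` and
#'   `fdr_estimate`.
#' @export
filter_at_fdr <- function(psms, q_max = 0.01) {
  scored <- compute_qvalues(psms)
  pass <- !scored$is_decoy & scored$q_value <= q_max
  passing <- scored[pass, , drop = FALSE]
  attr(passing, "fdr_table") <- NULL
  thr <- if (any(pass)) min(passing$score) else Inf
  n_dec <- sum(scored$is_decoy & scored$score >= thr)
  list(psms = passing,
       score_threshold = thr,
       n_targets_passing = sum(pass),
       n_decoys_passing = n_dec,
       fdr_estimate = n_dec / max(sum(pass), 1))
}

#' Protein sequence coverage from identified peptides
#'
#' Locates every occurrence of each peptide as an exact substring of the
#' protein and reports the fraction of residues covered plus the merged
#' 1-based inclusive intervals.
#'
#' @param protein_sequence Non-empty protein sequence string.
#' @param peptide_sequences Character vector of peptide sequences; peptides
#'   not found contribute nothing (with a warning).
#' @return List with `fraction` in \[0, 1\] and `intervals`, a two-column
#'   matrix (`start`, `end`) of merged covered runs.
#' @export
sequence_coverage <- function(protein_sequence, peptide_sequences) {
  n <- nchar(protein_sequence)
  stopifnot(n > 0)
  covered <- logical(n)
  for (pep in unique(peptide_sequences)) {
    hits <- gregexpr(pep, protein_sequence, fixed = TRUE)[[1]]
    if (hits[1] == -1L) {
      warning("peptide '", pep, "' not found in protein; ignored")
      next
    }
    for (h in hits) covered[h:(h + nchar(pep) - 1L)] <- TRUE
  }
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- cbind(start = starts[r$values], end = ends[r$values])
  list(fraction = mean(covered), intervals = iv)
}

#' Group proteins with identical peptide evidence
#'
#' Proteins whose distinct peptide sets are exactly equal are reported as one
#' indistinguishable group (strict set equality; subset relations do not
#' group).  The group representative is the lexicographically smallest
#' accession.
#'
#' @param peptide_sets Named list: accession -> character vector of distinct
#'   peptide keys.
#' @return Data frame with `representative`, `accessions` (semicolon-joined,
#'   sorted) and `n_members`.
#' @export
group_indistinguishable <- function(peptide_sets) {
  stopifnot(is.list(peptide_sets), !is.null(names(peptide_sets)))
  key <- vapply(peptide_sets,
                function(p) paste(sort(unique(p)), collapse = "\r"),
                character(1))
  groups <- split(names(peptide_sets), key)
  groups <- lapply(groups, sort)
  reps <- vapply(groups, `[`, character(1), 1L)
  out <- data.frame(representative = reps,
                    accessions = vapply(groups, paste, character(1), collapse = ";"),
                    n_members = lengths(groups),
                    stringsAsFactors = FALSE)
  out <- out[order(out$representative), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Split a semicolon-joined field into a character vector ("" -> empty).
split_semi <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
}

#' Build protein-level identifications from filtered PSMs
#'
#' Groups PSMs by protein accession (a PSM shared by several accessions
#' counts for each), computes the distinct peptide count (distinct
#' sequence + modification combinations), a protein score (sum over distinct
#' peptides of each peptide's best PSM score), and, when a proteome is
#' supplied, sequence coverage and emPAI.
#'
#' @param psms PSM data frame (typically the output of [filter_at_fdr()]).
#' @param proteome Optional protein data frame from [read_fasta()]; enables
#'   `coverage_fraction` and `empai` columns.
#' @return Data frame with one row per accession, carrying a `peptide_sets`
#'   attribute (named list accession -> distinct peptide keys) for use with
#'   [group_indistinguishable()].
#' @export
build_protein_identifications <- function(psms, proteome = NULL) {
  if (nrow(psms) == 0) {
    return(data.frame(accession = character(), distinct_peptide_count = integer(),
                      n_psms = integer(), score = numeric()))
  }
  accs <- lapply(psms$protein_accessions, split_semi)
  idx <- rep(seq_len(nrow(psms)), lengths(accs))
  flat <- data.frame(accession = unlist(accs),
                     row = idx, stringsAsFactors = FALSE)
  flat$pepkey <- paste(psms$peptide_sequence[idx], psms$modifications[idx], sep = "|")
  flat$score <- psms$score[idx]
  flat$sequence <- psms$peptide_sequence[idx]

  per_acc <- split(flat, flat$accession)
  rows <- lapply(per_acc, function(d) {
    best_per_pep <- tapply(d$score, d$pepkey, max)
    data.frame(accession = d$accession[1],
               distinct_peptide_count = length(best_per_pep),
               n_psms = nrow(d),
               score = sum(best_per_pep),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  pepsets <- lapply(per_acc, function(d) unique(d$pepkey))
  if (!is.null(proteome)) {
    seq_of <- setNames(proteome$sequence, proteome$accession)
    desc_of <- setNames(proteome$description, proteome$accession)
    out$description <- unname(desc_of[out$accession])
    out$coverage_fraction <- NA_real_
    out$empai <- NA_real_
    for (i in seq_len(nrow(out))) {
      ps <- seq_of[[out$accession[i]]]
      if (is.null(ps) || is.na(ps)) next
      peps <- unique(per_acc[[out$accession[i]]]$sequence)
      out$coverage_fraction[i] <- suppressWarnings(
        sequence_coverage(ps, peps)$fraction)
      n_obs <- length(peps)
      n_obsbl <- observable_peptides(ps)
      if (n_obsbl >= 1) out$empai[i] <- empai(min(n_obs, n_obsbl), n_obsbl)
    }
  }
  attr(out, "peptide_sets") <- pepsets
  out
}
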