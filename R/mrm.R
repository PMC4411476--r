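#' Theoretical b/y fragment ladder
#'
#' Singly- and doubly-charged b and y ion m/z values for a (modified)
#' peptide; fragment indices are 1-based from the respective terminus and
#' run to length - 1.  Modifications are assigned to their residue, so a
#' mod at position p contributes to b ions of index >= p and y ions
#' covering that residue; an N-terminal mod (position 0) rides with the b
#' series.
#'
#' @param sequence Peptide string.
#' @param modifications Canonical modification string or parsed data frame.
#' @param fragment_charges Integer vector of fragment charge states
#'   (default 1:2).
#' @return Data frame `fragment_type`, `fragment_index`, `fragment_charge`,
#'   `mz`.
#' @export
fragment_ladder <- function(sequence, modifications = "",
                            fragment_charges = 1:2) {
  res <- strsplit(sequence, "")[[1]]
  L <- length(res)
  stopifnot(L >= 2)
  masses <- unname(AA_MONO[res])
  if (any(is.na(masses))) stop("unknown residue in '", sequence, "'")
  if (is.character(modifications)) modifications <- parse_modifications(modifications)
  mod_at <- numeric(L)
  nterm_mod <- 0
  if (nrow(modifications)) {
    for (k in seq_len(nrow(modifications))) {
      p <- modifications$position[k]
      if (p == 0) nterm_mod <- nterm_mod + modifications$mass_delta[k]
      else mod_at[p] <- mod_at[p] + modifications$mass_delta[k]
    }
  }
  masses <- masses + mod_at
  b_neutral <- cumsum(masses)[seq_len(L - 1)] + nterm_mod             # b_i: residues 1..i
  y_neutral <- cumsum(rev(masses))[seq_len(L - 1)] + WATER_MASS       # y_i: residues (L-i+1)..L
  rows <- list()
  for (z in fragment_charges) {
    rows[[length(rows) + 1L]] <- data.frame(
      fragment_type = "b", fragment_index = seq_len(L - 1),
      fragment_charge = z, mz = (b_neutral + z * PROTON_MASS) / z,
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      fragment_type = "y", fragment_index = seq_len(L - 1),
      fragment_charge = z, mz = (y_neutral + z * PROTON_MASS) / z,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select assay peptides by the five targeted-proteomics criteria
#'
#' Filters candidate library entries for MRM/SRM assay development, in
#' order: (1) peptide score must be greater than or equal to its identity
#' threshold; (2) a protein must retain three or more distinct peptides;
#' (3) the peptide must map to exactly one protein in the species proteome
#' (proteotypic); (4) peptides containing methionine are excluded (Met
#' oxidation makes transitions unstable); (5) per protein, the survivors
#' are sorted by observation count (descending) and the top
#' `top_n_peptides` are chosen.  The three-peptide rule is re-checked after
#' (3)-(4) so it holds for the final set.  Every candidate is returned with
#' its selection flag and, when rejected, the first criterion it failed.
#'
#' @param candidates Library entry data frame from [curate_library()]
#'   (needs `best_score`, `identity_threshold`, `observation_count`,
#'   `protein_accessions`).
#' @param proteome Proteome data frame for the target species.
#' @param top_n_peptides Peptides retained per protein (default 5).
#' @param il_equivalent Treat I and L as equivalent in the uniqueness scan.
#' @return The candidates with `accession` (unique protein for proteotypic
#'   peptides), `selected` and `rejection_reason`
#'   (`below_identity`, `protein_too_few_peptides`, `not_unique`,
#'   `contains_met`, `not_top_ranked`, or `NA` when selected) columns.
#' @export
select_assay_peptides <- function(candidates, proteome, top_n_peptides = 5,
                                  il_equivalent = FALSE) {
  n <- nrow(candidates)
  out <- candidates
  out$accession <- vapply(out$protein_accessions,
                          function(a) split_semi(a)[1] %||% NA_character_,
                          character(1))
  out$selected <- FALSE
  out$rejection_reason <- NA_character_
  if (n == 0) return(out)
  # stable canonical order so selection is input-order invariant
  ord <- order(out$peptide_sequence, out$modifications, out$charge)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  alive <- rep(TRUE, nrow(out))
  reject <- function(idx, reason) {
    newly <- idx[alive[idx]]
    out$rejection_reason[newly] <<- reason
    alive[newly] <<- FALSE
  }

  # (1) score >= identity threshold
  reject(which(out$best_score < out$identity_threshold), "below_identity")

  count_ok <- function() {
    # distinct peptide sequences per accession among surviving candidates
    tab <- tapply(out$peptide_sequence[alive], out$accession[alive],
                  function(p) length(unique(p)))
    names(tab)[!is.na(tab) & tab >= 3]
  }
  # (2) proteins with >= 3 surviving peptides
  reject(which(alive & !(out$accession %in% count_ok())),
         "protein_too_few_peptides")

  # (3) proteotypic in the species proteome
  hits <- match_accessions(unique(out$peptide_sequence[alive]), proteome,
                           il_equivalent)
  n_hits <- lengths(hits)[out$peptide_sequence]
  reject(which(alive & (is.na(n_hits) | n_hits != 1)), "not_unique")
  # the unique match becomes the peptide's protein assignment
  uniq_acc <- vapply(hits[lengths(hits) == 1], `[`, character(1), 1L)
  assigned <- uniq_acc[out$peptide_sequence[alive]]
  out$accession[alive] <- unname(assigned)

  # (4) no methionine
  reject(which(alive & grepl("M", out$peptide_sequence, fixed = TRUE)),
         "contains_met")

  # (2') re-check the three-peptide rule on the final composition
  reject(which(alive & !(out$accession %in% count_ok())),
         "protein_too_few_peptides")

  # (5) per protein keep the top_n by observation count;
  #     ties by higher score, then lexicographic sequence
  for (acc in unique(out$accession[alive])) {
    idx <- which(alive & out$accession == acc)
    r <- idx[order(-out$observation_count[idx], -out$best_score[idx],
                   out$peptide_sequence[idx])]
    if (length(r) > top_n_peptides) {
      reject(r[(top_n_peptides + 1):length(r)], "not_top_ranked")
    }
  }
  out$selected <- alive
  out
}

`%||%` <- function(a, b) if (length(a) == 0 || is.na(a[1])) b else a

#' Select MRM transitions from a library spectrum
#'
#' Annotates the spectrum's peaks against the peptide's theoretical b/y
#' ladder (charges 1-2) within `tolerance` Th; each theoretical ion takes
#' the most intense matching peak.  Annotated ions are ranked by intensity
#' (ties broken by lower product m/z) and the top `n_transitions` become
#' transitions, with `product_mz` set to the theoretical value.
#'
#' @param assay_peptide One row of [select_assay_peptides()] output (or any
#'   list with `accession`, `peptide_sequence`, `modifications`, `charge`,
#'   `precursor_mz`, `retention_time_median`).
#' @param spectrum The peptide's best library `Spectrum`.
#' @param n_transitions Number of transitions to keep (default 5); if fewer
#'   ions annotate, all are returned with a warning.
#' @param tolerance Fragment match tolerance in Th (default 0.5).
#' @return Transition data frame (columns of the transition TSV).
#' @export
select_transitions <- function(assay_peptide, spectrum, n_transitions = 5,
                               tolerance = 0.5) {
  acc <- assay_peptide$accession
  if (is.null(acc) || is.na(acc)) {
    acc <- split_semi(assay_peptide$protein_accessions)[1] %||% NA_character_
  }
  ladder <- fragment_ladder(assay_peptide$peptide_sequence,
                            assay_peptide$modifications)
  peaks <- spectrum$peaks
  ladder$intensity <- NA_real_
  if (nrow(peaks)) {
    for (i in seq_len(nrow(ladder))) {
      near <- which(abs(peaks[, 1] - ladder$mz[i]) <= tolerance)
      if (length(near)) ladder$intensity[i] <- max(peaks[near, 2])
    }
  }
  ann <- ladder[!is.na(ladder$intensity), , drop = FALSE]
  if (nrow(ann) == 0) {
    warning("no annotatable peaks for ", assay_peptide$peptide_sequence)
    return(empty_transitions())
  }
  ann <- ann[order(-ann$intensity, ann$mz), , drop = FALSE]
  if (nrow(ann) < n_transitions) {
    warning("only ", nrow(ann), " annotated ion(s) available for ",
            assay_peptide$peptide_sequence, " (requested ", n_transitions, ")")
  }
  ann <- utils::head(ann, n_transitions)
  mods <- parse_modifications(assay_peptide$modifications)
  modseq <- if (nrow(mods)) {
    mark <- assay_peptide$peptide_sequence
    # render residue mods in bracket notation, N-term mods as a prefix
    chars <- strsplit(mark, "")[[1]]
    for (k in order(mods$position, decreasing = TRUE)) {
      p <- mods$position[k]
      tag <- sprintf("[%+.4f]", mods$mass_delta[k])
      if (p == 0) chars[1] <- paste0(tag, chars[1])
      else chars[p] <- paste0(chars[p], tag)
    }
    paste(chars, collapse = "")
  } else assay_peptide$peptide_sequence
  data.frame(
    protein_accession = acc,
    peptide_sequence = assay_peptide$peptide_sequence,
    modified_sequence = modseq,
    precursor_charge = assay_peptide$charge,
    precursor_mz = assay_peptide$precursor_mz,
    fragment_type = ann$fragment_type,
    fragment_index = ann$fragment_index,
    fragment_charge = ann$fragment_charge,
    product_mz = ann$mz,
    intensity_rank = seq_len(nrow(ann)),
    library_intensity = ann$intensity,
    retention_time_min = assay_peptide$retention_time_median,
    stringsAsFactors = FALSE)
}

empty_transitions <- function() {
  data.frame(protein_accession = character(), peptide_sequence = character(),
             modified_sequence = character(), precursor_charge = integer(),
             precursor_mz = numeric(), fragment_type = character(),
             fragment_index = integer(), fragment_charge = integer(),
             product_mz = numeric(), intensity_rank = integer(),
             library_intensity = numeric(), retention_time_min = numeric(),
             stringsAsFactors = FALSE)
}

#' Build the full MRM method (transition list)
#'
#' Runs [select_transitions()] for every selected assay peptide against its
#' best library spectrum, concatenates the results in deterministic
#' (accession, peptide, rank) order and optionally writes the transition
#' TSV.
#'
#' @param assay_peptides Output of [select_assay_peptides()]; only rows
#'   with `selected = TRUE` are used.
#' @param spectra `Spectrum` list or [spectra_index()] resolving each
#'   peptide's `best_spectrum_id`.
#' @param n_transitions Transitions per peptide (default 5).
#' @param path Optional output TSV path (via [write_transitions_tsv()]).
#' @param tolerance Fragment match tolerance in Th.
#' @return Transition data frame.
#' @export
build_method <- function(assay_peptides, spectra, n_transitions = 5,
                         path = NULL, tolerance = 0.5) {
  idx <- if (is.null(names(spectra))) spectra_index(spectra) else spectra
  sel <- assay_peptides[assay_peptides$selected, , drop = FALSE]
  rows <- lapply(seq_len(nrow(sel)), function(i) {
    sp <- idx[[sel$best_spectrum_id[i]]]
    if (is.null(sp)) {
      warning("no spectrum for ", sel$peptide_sequence[i], "; skipped")
      return(NULL)
    }
    select_transitions(sel[i, ], sp, n_transitions, tolerance)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) return(empty_transitions())
  out <- out[order(out$protein_accession, out$peptide_sequence,
                   out$intensity_rank), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path)) write_transitions_tsv(out, path)
  out
}
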