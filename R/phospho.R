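#' Identify phospho modifications on a PSM
#'
#' A modification counts as a phosphosite when its mass delta is within
#' +-0.01 Da of 79.966331 (HPO3) and it sits on an S, T or Y residue of the
#' peptide (N-terminal position 0 never qualifies).
#'
#' @param peptide_sequence Peptide string.
#' @param modifications Canonical modification string or parsed data frame.
#' @return Integer vector of 1-based phosphosite positions (may be empty).
#' @export
phospho_positions <- function(peptide_sequence, modifications) {
  if (is.character(modifications)) modifications <- parse_modifications(modifications)
  if (nrow(modifications) == 0) return(integer(0))
  is_p <- abs(modifications$mass_delta - PHOSPHO_MASS) <= 0.01
  pos <- modifications$position[is_p]
  pos <- pos[pos >= 1 & pos <= nchar(peptide_sequence)]
  if (length(pos) == 0) return(integer(0))
  res <- substring(peptide_sequence, pos, pos)
  sort(pos[res %in% c("S", "T", "Y")])
}

#' List phosphoproteins and their phosphopeptide match counts
#'
#' Keeps proteins with at least one PSM carrying a phospho modification on
#' S/T/Y and reports the number of such PSMs per protein.
#'
#' @param psms PSM data frame (typically FDR-filtered).
#' @return Data frame `accession`, `n_phospho_psms`, `n_phosphopeptides`
#'   (distinct phosphopeptide sequence + modification combinations), sorted
#'   by descending count.
#' @export
filter_phosphoproteins <- function(psms) {
  if (nrow(psms) == 0) {
    return(data.frame(accession = character(), n_phospho_psms = integer(),
                      n_phosphopeptides = integer()))
  }
  is_phospho <- vapply(seq_len(nrow(psms)), function(i) {
    length(phospho_positions(psms$peptide_sequence[i], psms$modifications[i])) > 0
  }, logical(1))
  d <- psms[is_phospho, , drop = FALSE]
  if (nrow(d) == 0) {
    return(data.frame(accession = character(), n_phospho_psms = integer(),
                      n_phosphopeptides = integer()))
  }
  accs <- lapply(d$protein_accessions, split_semi)
  idx <- rep(seq_len(nrow(d)), lengths(accs))
  flat <- data.frame(accession = unlist(accs),
                     pepkey = paste(d$peptide_sequence[idx],
                                    d$modifications[idx], sep = "|"),
                     stringsAsFactors = FALSE)
  per <- split(flat, flat$accession)
  out <- data.frame(
    accession = names(per),
    n_phospho_psms = vapply(per, nrow, integer(1)),
    n_phosphopeptides = vapply(per, function(x)
      length(unique(x$pepkey)), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$n_phospho_psms, out$accession), , drop = FALSE]
}

#' Mascot delta score for phosphosite localization
#'
#' Difference between the scores of the best and second-best site
#' localization candidates for one spectrum.  A single (unopposed)
#' candidate scores as itself; tied top candidates score 0.  The score is
#' permutation-invariant and non-negative.
#'
#' @param scores Numeric vector of candidate localization scores (>= 1
#'   candidate).
#' @return Non-negative delta score.
#' @export
md_score <- function(scores) {
  if (length(scores) == 0) stop("md_score needs at least one candidate")
  stopifnot(all(is.finite(scores)))
  s <- sort(scores, decreasing = TRUE)
  if (length(s) == 1) s[1] else s[1] - s[2]
}

#' Render a peptide with phosphosites marked
#'
#' Phosphorylated residues are lower-cased in the plain-text rendering
#' (medium-independent stand-in for underlining).
#'
#' @param peptide_sequence Peptide string.
#' @param positions 1-based phosphosite positions.
#' @return Marked sequence string.
#' @export
mark_phosphosites <- function(peptide_sequence, positions) {
  chars <- strsplit(peptide_sequence, "")[[1]]
  chars[positions] <- tolower(chars[positions])
  paste(chars, collapse = "")
}

#' Phosphopeptide site-localization report
#'
#' One row per phospho-PSM with the marked sequence, search score, Mascot
#' delta score (from per-spectrum localization candidates when available,
#' otherwise the unopposed-assignment convention), pass-through PhosphoRS
#' probabilities, theoretical m/z, neutral ion mass, signed ppm error and
#' charge.
#'
#' @param psms PSM data frame; rows without a phosphosite are dropped.
#' @param site_candidates Optional named list `spectrum_id` -> numeric
#'   vector of candidate localization scores for [md_score()].
#' @return Data frame of report rows.
#' @export
phospho_report <- function(psms, site_candidates = NULL) {
  rows <- list()
  for (i in seq_len(nrow(psms))) {
    pos <- phospho_positions(psms$peptide_sequence[i], psms$modifications[i])
    if (length(pos) == 0) next
    theo <- peptide_mz(psms$peptide_sequence[i], psms$modifications[i],
                       psms$charge[i])
    cand <- if (!is.null(site_candidates) &&
                psms$spectrum_id[i] %in% names(site_candidates)) {
      site_candidates[[psms$spectrum_id[i]]]
    } else psms$score[i]
    rows[[length(rows) + 1L]] <- data.frame(
      spectrum_id = psms$spectrum_id[i],
      peptide_with_sites = mark_phosphosites(psms$peptide_sequence[i], pos),
      site_positions = paste(pos, collapse = ";"),
      mascot_score = psms$score[i],
      md_score = md_score(cand),
      phospho_rs = if (!is.null(psms$phospho_rs)) psms$phospho_rs[i] else "",
      mz = theo,
      ion_mass = theo * psms$charge[i] - psms$charge[i] * PROTON_MASS,
      ppm = ppm_error(psms$precursor_mz_observed[i], theo),
      charge = psms$charge[i],
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(spectrum_id = character(), peptide_with_sites = character(),
                      site_positions = character(), mascot_score = numeric(),
                      md_score = numeric(), phospho_rs = character(),
                      mz = numeric(), ion_mass = numeric(), ppm = numeric(),
                      charge = integer()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
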