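#' Curate a spectral library from search results
#'
#' Applies the library curation pipeline to each search result set
#' independently: filter at `q_max` FDR (target-decoy), keep PSMs whose
#' score beats their homology threshold (strict `>` by default; `>=`
#' available) and whose peptide length lies in `length_range`.  Surviving
#' PSMs from all sets are grouped by (sequence, modifications, charge); each
#' group becomes one entry keeping its highest-scoring replicate spectrum,
#' the observation count (contributing PSMs across all sets), the median
#' retention time, and the union of source samples and protein accessions.
#' Decoys never enter the library.
#'
#' @param psm_sets A PSM data frame (split by `sample_id`) or a list of PSM
#'   data frames, one per search result.
#' @param spectra Optional list of `Spectrum` objects (or a
#'   [spectra_index()]); when supplied, each entry carries its best
#'   replicate's peaks, and PSMs whose `spectrum_id` cannot be resolved are
#'   excluded with a warning.
#' @param q_max FDR bound for [filter_at_fdr()] (default 0.01).
#' @param length_range Inclusive peptide length window, default 5--30.
#' @param score_rule `"greater"` (default) requires score strictly above the
#'   homology threshold; `"greater_equal"` admits equality.
#' @return Library entry data frame (`peptide_sequence`, `modifications`,
#'   `charge`, `precursor_mz`, `retention_time_median`, `best_score`,
#'   `identity_threshold`, `homology_threshold`, `observation_count`,
#'   `best_spectrum_id`, `source_sample_ids`, `protein_accessions`, and a
#'   `peaks` list-column when spectra were given).
#' @export
curate_library <- function(psm_sets, spectra = NULL, q_max = 0.01,
                           length_range = c(5, 30),
                           score_rule = c("greater", "greater_equal")) {
  score_rule <- match.arg(score_rule)
  if (is.data.frame(psm_sets)) {
    psm_sets <- split(psm_sets, psm_sets$sample_id)
  }
  psm_sets <- Filter(function(s) nrow(s) > 0, psm_sets)
  if (length(psm_sets) == 0) return(empty_library())
  idx <- if (!is.null(spectra)) {
    if (is.null(names(spectra))) spectra_index(spectra) else spectra
  } else NULL

  surviving <- lapply(psm_sets, function(set) {
    kept <- filter_at_fdr(set, q_max = q_max)$psms
    beats <- if (score_rule == "greater") {
      kept$score > kept$homology_threshold
    } else {
      kept$score >= kept$homology_threshold
    }
    len <- nchar(kept$peptide_sequence)
    kept[beats & len >= length_range[1] & len <= length_range[2], ,
         drop = FALSE]
  })
  all_psms <- do.call(rbind, c(surviving, list(make.row.names = FALSE)))
  if (is.null(all_psms) || nrow(all_psms) == 0) {
    return(empty_library())
  }
  if (!is.null(idx)) {
    resolvable <- all_psms$spectrum_id %in% names(idx)
    if (any(!resolvable)) {
      warning(sum(!resolvable), " PSM(s) without a resolvable spectrum excluded")
    }
    all_psms <- all_psms[resolvable, , drop = FALSE]
    if (nrow(all_psms) == 0) return(empty_library())
  }
  key <- paste(all_psms$peptide_sequence, all_psms$modifications,
               all_psms$charge, sep = "\r")
  groups <- split(seq_len(nrow(all_psms)), key)
  rows <- lapply(groups, function(g) {
    d <- all_psms[g, , drop = FALSE]
    best <- g[order(-d$score, d$spectrum_id)[1] ]
    b <- all_psms[best, , drop = FALSE]
    data.frame(
      peptide_sequence = b$peptide_sequence,
      modifications = b$modifications,
      charge = b$charge,
      precursor_mz = peptide_mz(b$peptide_sequence, b$modifications, b$charge),
      retention_time_median = stats::median(d$retention_time_min),
      best_score = b$score,
      identity_threshold = b$identity_threshold,
      homology_threshold = b$homology_threshold,
      observation_count = length(g),
      best_spectrum_id = b$spectrum_id,
      source_sample_ids = paste(sort(unique(d$sample_id)), collapse = ";"),
      protein_accessions = paste(
        sort(unique(unlist(lapply(d$protein_accessions, split_semi)))),
        collapse = ";"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$peptide_sequence, out$modifications, out$charge), ,
             drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(idx)) {
    out$peaks <- lapply(out$best_spectrum_id, function(id) idx[[id]]$peaks)
  }
  out
}

empty_library <- function() {
  data.frame(peptide_sequence = character(), modifications = character(),
             charge = integer(), precursor_mz = numeric(),
             retention_time_median = numeric(), best_score = numeric(),
             identity_threshold = numeric(), homology_threshold = numeric(),
             observation_count = integer(), best_spectrum_id = character(),
             source_sample_ids = character(), protein_accessions = character(),
             stringsAsFactors = FALSE)
}

normalize_il <- function(x) chartr("IL", "JJ", x)

#' Map a peptide's uniqueness within a proteome
#'
#' Deterministic exact-substring proteome search: the peptide maps to every
#' protein whose sequence contains it (optionally treating I and L as
#' interchangeable, since they are isobaric).  A peptide matching exactly
#' one protein is proteotypic for that species.
#'
#' @param peptide Peptide sequence string.
#' @param proteome Protein data frame from [read_fasta()] (one species).
#' @param il_equivalent Treat I and L as equivalent when matching.
#' @param species Optional species label copied into the record.
#' @return List (`UniquenessRecord`): `peptide_sequence`, `species`,
#'   `matching_accessions`, `is_unique`.
#' @export
map_uniqueness <- function(peptide, proteome, il_equivalent = FALSE,
                           species = NA_character_) {
  seqs <- proteome$sequence
  pat <- peptide
  if (il_equivalent) {
    seqs <- normalize_il(seqs)
    pat <- normalize_il(pat)
  }
  hit <- grepl(pat, seqs, fixed = TRUE)
  acc <- proteome$accession[hit]
  list(peptide_sequence = peptide, species = species,
       matching_accessions = acc, is_unique = length(acc) == 1L)
}

# Vectorized accession-match lookup: peptide -> character vector of matches.
match_accessions <- function(peptides, proteome, il_equivalent = FALSE) {
  seqs <- proteome$sequence
  if (il_equivalent) seqs <- normalize_il(seqs)
  out <- lapply(if (il_equivalent) normalize_il(peptides) else peptides,
                function(p) proteome$accession[grepl(p, seqs, fixed = TRUE)])
  names(out) <- peptides
  out
}

#' Annotate library entries with per-species uniqueness
#'
#' @param entries Library entry data frame from [curate_library()].
#' @param proteomes Named list of proteome data frames, one per species.
#' @param il_equivalent Treat I and L as equivalent.
#' @return `entries` with a `uniqueness` attribute: data frame `entry_id`
#'   (row index), `species`, `matching_accessions` (semicolon-joined),
#'   `is_unique`.
#' @export
annotate_uniqueness <- function(entries, proteomes, il_equivalent = FALSE) {
  stopifnot(is.list(proteomes), !is.null(names(proteomes)))
  recs <- list()
  for (sp in names(proteomes)) {
    hits <- match_accessions(entries$peptide_sequence, proteomes[[sp]],
                             il_equivalent)
    recs[[sp]] <- data.frame(
      entry_id = seq_len(nrow(entries)),
      species = sp,
      matching_accessions = vapply(hits, paste, character(1), collapse = ";"),
      is_unique = lengths(hits) == 1L,
      stringsAsFactors = FALSE)
  }
  uq <- do.call(rbind, recs)
  rownames(uq) <- NULL
  attr(entries, "uniqueness") <- uq
  entries
}

#' Library census per species
#'
#' For each species proteome: the number of distinct library peptides that
#' map into the proteome, and the number of proteins supported by at least
#' `min_distinct` distinct mapped peptides (the census criterion for a
#' protein to count as identified).
#'
#' @param entries Library entry data frame.
#' @param proteomes Named list of proteome data frames keyed by species.
#' @param min_distinct Minimum distinct peptides per counted protein
#'   (default 2).
#' @param il_equivalent Treat I and L as equivalent when mapping.
#' @return Data frame `species`, `protein_count`, `peptide_count`.
#' @export
library_census <- function(entries, proteomes, min_distinct = 2,
                           il_equivalent = FALSE) {
  rows <- lapply(names(proteomes), function(sp) {
    peps <- unique(entries$peptide_sequence)
    hits <- match_accessions(peps, proteomes[[sp]], il_equivalent)
    mapped <- lengths(hits) > 0
    per_protein <- table(unlist(hits[mapped]))
    data.frame(species = sp,
               protein_count = sum(per_protein >= min_distinct),
               peptide_count = sum(mapped),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(species = character(), protein_count = integer(),
                      peptide_count = integer())
  }
  rownames(out) <- NULL
  out
}

#' Query a spectral library
#'
#' Conjunctive filters over library entries: exact accession, exact gene
#' symbol, case-insensitive protein-name substring, and peptide-sequence
#' substring.  At least one filter must be given (a full dump requires
#' `allow_all = TRUE`).  Name and gene filters need the `proteome` argument
#' for accession metadata.
#'
#' @param entries Library entry data frame.
#' @param proteome Optional proteome data frame supplying `description` and
#'   `gene_symbol` per accession.
#' @param accession Exact accession filter.
#' @param name Case-insensitive protein-name (description) substring.
#' @param sequence Peptide-sequence substring (uppercased before matching).
#' @param gene Exact gene-symbol filter.
#' @param allow_all Explicitly permit an unfiltered dump.
#' @return Matching entry rows (provenance columns included).
#' @export
query_library <- function(entries, proteome = NULL, accession = NULL,
                          name = NULL, sequence = NULL, gene = NULL,
                          allow_all = FALSE) {
  if (is.null(accession) && is.null(name) && is.null(sequence) &&
      is.null(gene) && !allow_all) {
    stop("refusing a full library dump: give at least one filter ",
         "or set allow_all = TRUE")
  }
  keep <- rep(TRUE, nrow(entries))
  entry_accs <- lapply(entries$protein_accessions, split_semi)
  if (!is.null(accession)) {
    keep <- keep & vapply(entry_accs, function(a) accession %in% a, logical(1))
  }
  if (!is.null(sequence)) {
    keep <- keep & grepl(toupper(sequence), entries$peptide_sequence,
                         fixed = TRUE)
  }
  if (!is.null(name) || !is.null(gene)) {
    if (is.null(proteome)) {
      stop("name/gene filters require the proteome for accession metadata")
    }
    desc_of <- setNames(proteome$description, proteome$accession)
    gene_of <- setNames(proteome$gene_symbol, proteome$accession)
    if (!is.null(name)) {
      keep <- keep & vapply(entry_accs, function(a) {
        any(grepl(name, desc_of[a], ignore.case = TRUE), na.rm = TRUE)
      }, logical(1))
    }
    if (!is.null(gene)) {
      keep <- keep & vapply(entry_accs, function(a) {
        any(gene_of[a] == gene, na.rm = TRUE)
      }, logical(1))
    }
  }
  out <- entries[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
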