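#' Pairwise comparative analysis of samples
#'
#' Compares two or more filtered samples at peptide or protein level:
#' reports the keys distinct to each sample (present in that sample and in
#' no other), the keys common to all samples, and the full pairwise overlap
#' matrix.
#'
#' @param samples Named list of PSM data frames (one per sample), already
#'   filtered as desired.
#' @param level `"peptide"` (key = sequence, with modifications by default)
#'   or `"protein"` (key = accession; no case folding).
#' @param include_modifications At peptide level, include the modification
#'   string in the key (default) or compare bare sequences.
#' @return `ComparisonResult` list: `sample_ids`, `level`,
#'   `sets` (key sets per sample), `distinct_per_sample`, `common_all`,
#'   `pairwise_overlap` (symmetric count matrix, diagonal = set sizes).
#' @export
compare_samples <- function(samples, level = c("peptide", "protein"),
                            include_modifications = TRUE) {
  level <- match.arg(level)
  if (length(samples) < 2) stop("need at least 2 samples to compare")
  if (is.null(names(samples)) || any(!nzchar(names(samples)))) {
    names(samples) <- paste0("sample_", seq_along(samples))
  }
  sets <- lapply(samples, function(d) {
    if (level == "peptide") {
      if (include_modifications) {
        unique(paste(d$peptide_sequence, d$modifications, sep = "|"))
      } else unique(d$peptide_sequence)
    } else {
      unique(unlist(lapply(d$protein_accessions, split_semi)))
    }
  })
  n <- length(sets)
  distinct <- lapply(seq_len(n), function(i) {
    setdiff(sets[[i]], unlist(sets[-i]))
  })
  names(distinct) <- names(sets)
  common <- Reduce(intersect, sets)
  overlap <- matrix(0L, n, n, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    overlap[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  }
  structure(list(sample_ids = names(sets), level = level, sets = sets,
                 distinct_per_sample = distinct, common_all = common,
                 pairwise_overlap = overlap),
            class = "ComparisonResult")
}

#' @export
print.ComparisonResult <- function(x, ...) {
  cat(sprintf("<ComparisonResult> %d samples at %s level\n",
              length(x$sample_ids), x$level))
  cat(sprintf("  common to all: %d\n", length(x$common_all)))
  for (s in x$sample_ids) {
    cat(sprintf("  %s: %d keys, %d distinct\n", s, length(x$sets[[s]]),
                length(x$distinct_per_sample[[s]])))
  }
  invisible(x)
}

#' Cross-technique protein-level comparison
#'
#' Compares samples that may come from different result types (e.g. a
#' MudPIT discovery run against an iTRAQ quantitation run) after
#' normalizing every sample to its bare protein accession set.
#'
#' @inheritParams compare_samples
#' @return `ComparisonResult` at protein level.
#' @export
cross_technique_compare <- function(samples) {
  norm <- lapply(samples, function(d) {
    if (!is.null(d$protein_accessions)) {
      d
    } else if (!is.null(d$accession)) {
      # protein-level table (e.g. protXML or a quant report)
      data.frame(protein_accessions = d$accession, stringsAsFactors = FALSE)
    } else {
      stop("sample has neither protein_accessions nor accession column")
    }
  })
  compare_samples(norm, level = "protein")
}

#' Write a comparison result as TSV
#'
#' Per-sample distinct lists plus the overlap matrix; for up to 3 samples a
#' Venn-style region count summary is appended.
#'
#' @param result `ComparisonResult` from [compare_samples()].
#' @param path Output path.
#' @export
write_comparison_tsv <- function(result, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# comparison at ", result$level, " level"), con)
  writeLines("[overlap_matrix]", con)
  m <- result$pairwise_overlap
  writeLines(paste(c("sample", colnames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(rownames(m)[i], m[i, ]), collapse = "\t"), con)
  }
  writeLines("[common_all]", con)
  writeLines(result$common_all, con)
  for (s in result$sample_ids) {
    writeLines(paste0("[distinct:", s, "]"), con)
    writeLines(result$distinct_per_sample[[s]], con)
  }
  if (length(result$sample_ids) <= 3) {
    writeLines("[venn_counts]", con)
    sets <- result$sets
    n <- length(sets)
    universe <- unique(unlist(sets))
    member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
    if (length(universe) == 1) member <- matrix(member, nrow = 1)
    pattern <- apply(member, 1, function(r) paste(as.integer(r), collapse = ""))
    tab <- table(pattern)
    writeLines(paste("region", "count", sep = "\t"), con)
    for (p in names(tab)) writeLines(paste(p, tab[[p]], sep = "\t"), con)
  }
  invisible(path)
}
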