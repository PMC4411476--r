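#' Exponentially modified protein abundance index
#'
#' `empai = 10^(n_observed / n_observable) - 1`, a label-free estimate of
#' absolute protein abundance from the fraction of its observable peptides
#' actually observed.
#'
#' @param n_observed Number of distinct observed peptides (0 <= n_observed
#'   <= n_observable).
#' @param n_observable Number of peptides the protein could yield under the
#'   digest and length window (>= 1).
#' @return Non-negative emPAI value.
#' @export
empai <- function(n_observed, n_observable) {
  if (any(n_observable < 1)) stop("n_observable must be >= 1")
  stopifnot(all(n_observed >= 0), all(n_observed <= n_observable))
  10^(n_observed / n_observable) - 1
}

#' In-silico tryptic digest
#'
#' Cleaves C-terminal to K or R except when the next residue is P (no missed
#' cleavages).
#'
#' @param sequence Protein sequence string.
#' @return Character vector of peptide fragments in order.
#' @export
tryptic_digest <- function(sequence) {
  frags <- strsplit(gsub("(?<=[KR])(?!P)", "\r", sequence, perl = TRUE),
                    "\r", fixed = TRUE)[[1]]
  frags[nzchar(frags)]
}

#' Count observable tryptic peptides (emPAI denominator)
#'
#' @param protein_sequence Protein sequence string.
#' @param length_range Inclusive peptide length window counted as
#'   observable; defaults to the 5--30 residue library window.
#' @return Integer count of digest fragments inside the window.
#' @export
observable_peptides <- function(protein_sequence, length_range = c(5, 30)) {
  frags <- tryptic_digest(protein_sequence)
  sum(nchar(frags) >= length_range[1] & nchar(frags) <= length_range[2])
}

#' Reporter-ion design
#'
#' @param channels Character vector of reporter channel labels (e.g.
#'   `c("113", "114", ...)` for iTRAQ 8-plex or TMT tags).
#' @param reference Reference channel label (must be one of `channels`).
#' @param conditions Optional named character vector channel -> condition.
#' @return `ReporterDesign` list.
#' @export
reporter_design <- function(channels, reference, conditions = NULL) {
  stopifnot(reference %in% channels)
  if (!is.null(conditions)) stopifnot(all(channels %in% names(conditions)))
  structure(list(channels = channels, reference = reference,
                 conditions = conditions), class = "ReporterDesign")
}

#' Per-protein reporter-ion ratios (iTRAQ/TMT)
#'
#' For each PSM, channel ratios are intensity relative to the reference
#' channel; PSMs with non-positive reference intensity are excluded with a
#' warning.  Peptide ratios roll up to the protein as the median (robust to
#' outlying PSMs).  A PSM shared by several accessions contributes to each.
#'
#' @param psms PSM data frame with `reporter_<channel>` intensity columns.
#' @param design [reporter_design()] object.
#' @return Data frame: `accession`, `n_psms_used`, one `ratio_<channel>`
#'   column per non-reference channel.
#' @export
reporter_protein_ratios <- function(psms, design) {
  stopifnot(inherits(design, "ReporterDesign"))
  cols <- paste0("reporter_", design$channels)
  missing_cols <- setdiff(cols, names(psms))
  if (length(missing_cols)) {
    stop("PSMs lack reporter column(s): ", paste(missing_cols, collapse = ", "))
  }
  ref_col <- paste0("reporter_", design$reference)
  usable <- !is.na(psms[[ref_col]]) & psms[[ref_col]] > 0
  if (any(!usable)) {
    warning(sum(!usable), " PSM(s) with non-positive reference intensity excluded")
  }
  d <- psms[usable, , drop = FALSE]
  other <- setdiff(design$channels, design$reference)
  accs <- lapply(d$protein_accessions, split_semi)
  idx <- rep(seq_len(nrow(d)), lengths(accs))
  flat_acc <- unlist(accs)
  out <- lapply(split(idx, flat_acc), function(rows) {
    ratios <- vapply(other, function(ch) {
      r <- d[[paste0("reporter_", ch)]][rows] / d[[ref_col]][rows]
      stats::median(r, na.rm = TRUE)
    }, numeric(1))
    c(n_psms_used = length(rows), ratios)
  })
  if (!length(out)) {
    warning("no protein had a usable PSM")
    return(data.frame(accession = character()))
  }
  res <- data.frame(accession = names(out), do.call(rbind, out),
                    stringsAsFactors = FALSE)
  names(res) <- c("accession", "n_psms_used", paste0("ratio_", other))
  rownames(res) <- NULL
  res
}

#' Per-protein SILAC heavy/light ratios
#'
#' Median over the peptide-level `heavy_light_ratio` values of each
#' protein's PSMs; PSMs with missing ratios are skipped, and proteins with
#' no usable PSM are omitted with a warning.
#'
#' @param psms PSM data frame with a `heavy_light_ratio` column.
#' @return Data frame `accession`, `heavy_light_ratio`, `n_psms_used`.
#' @export
silac_protein_ratios <- function(psms) {
  stopifnot("heavy_light_ratio" %in% names(psms))
  usable <- !is.na(psms$heavy_light_ratio)
  d <- psms[usable, , drop = FALSE]
  accs <- lapply(d$protein_accessions, split_semi)
  idx <- rep(seq_len(nrow(d)), lengths(accs))
  flat_acc <- unlist(accs)
  dropped <- setdiff(unlist(lapply(psms$protein_accessions[!usable], split_semi)),
                     flat_acc)
  if (length(dropped)) {
    warning("protein(s) without usable SILAC ratio omitted: ",
            paste(utils::head(dropped, 3), collapse = ", "))
  }
  per <- split(idx, flat_acc)
  data.frame(accession = names(per),
             heavy_light_ratio = vapply(per, function(rows)
               stats::median(d$heavy_light_ratio[rows]), numeric(1)),
             n_psms_used = lengths(per),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' One-way ANOVA p-value on log2 abundances
#'
#' Equal-variance one-way fixed-effects F test across condition groups,
#' applied to log2-transformed abundances (variance stabilization for
#' intensity data).  Degenerate inputs with zero between- and within-group
#' variance return p = 1; zero within-group variance with a real group
#' difference returns p = 0.
#'
#' @param groups List of numeric vectors (raw abundances, > 0), one per
#'   condition; at least 2 groups of >= 2 replicates.
#' @return p-value in \[0, 1\].
#' @export
anova_pvalue <- function(groups) {
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 2))
  vals <- log2(unlist(groups))
  grp <- factor(rep(seq_along(groups), lengths(groups)))
  gm <- tapply(vals, grp, mean)
  within_ss <- sum((vals - gm[grp])^2)
  between_ss <- sum(tapply(vals, grp, length) * (gm - mean(vals))^2)
  if (within_ss < 1e-300) {
    return(if (between_ss < 1e-300) 1 else 0)
  }
  stats::oneway.test(vals ~ grp, var.equal = TRUE)$p.value
}

#' Merge a label-free quantitation table with identification evidence
#'
#' Joins peptide-level abundances (upstream peak-integration export) with
#' protein identification evidence into the label-free report: per protein
#' and replicate, abundance is the sum of its peptide abundances; fold
#' change is the ratio of condition mean abundances (second condition over
#' first, in order of appearance); the ANOVA p-value comes from
#' [anova_pvalue()] over replicate-level protein abundances; proteins backed
#' by a single distinct peptide are flagged.
#'
#' @param quant_table Data frame with columns `accession`,
#'   `peptide_sequence`, `condition`, `replicate`, `abundance` and optional
#'   `isotope_dot_product` (carried through as a mean).
#' @param identifications Optional protein data frame (e.g. from
#'   [build_protein_identifications()]) supplying `score`, `description`
#'   and `distinct_peptide_count`; accessions present only in the quant
#'   table are kept with empty score fields and a warning.
#' @return Data frame of report rows: `accession`, `description`,
#'   `distinct_peptide_count`, `mean_<condition>` columns, `fold_change`,
#'   `log2_fold_change`, `anova_p`, `flag_single_peptide`.
#' @export
merge_labelfree <- function(quant_table, identifications = NULL) {
  need <- c("accession", "peptide_sequence", "condition", "replicate", "abundance")
  missing_cols <- setdiff(need, names(quant_table))
  if (length(missing_cols)) {
    stop("quant table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  conds <- unique(quant_table$condition)
  stopifnot(length(conds) >= 2)
  per_acc <- split(quant_table, quant_table$accession)
  id_idx <- if (!is.null(identifications)) {
    match(names(per_acc), identifications$accession)
  } else rep(NA_integer_, length(per_acc))
  unmatched <- names(per_acc)[is.na(id_idx)]
  if (!is.null(identifications) && length(unmatched)) {
    warning("quant accession(s) without identification evidence: ",
            paste(utils::head(unmatched, 3), collapse = ", "))
  }
  rows <- vector("list", length(per_acc))
  for (k in seq_along(per_acc)) {
    d <- per_acc[[k]]
    # protein abundance per (condition, replicate) = sum over peptides
    rep_ab <- tapply(d$abundance, list(d$condition, d$replicate), sum)
    groups <- lapply(conds, function(cc) {
      v <- rep_ab[cc, ]
      v[!is.na(v)]
    })
    names(groups) <- conds
    cond_means <- vapply(groups, mean, numeric(1))
    fc <- unname(cond_means[2] / cond_means[1])
    p <- if (all(lengths(groups) >= 2)) anova_pvalue(groups) else NA_real_
    npep <- if (!is.na(id_idx[k])) {
      identifications$distinct_peptide_count[id_idx[k]]
    } else length(unique(d$peptide_sequence))
    row <- data.frame(accession = d$accession[1], stringsAsFactors = FALSE)
    row$description <- if (!is.na(id_idx[k]) &&
                           !is.null(identifications$description)) {
      identifications$description[id_idx[k]]
    } else ""
    row$score <- if (!is.na(id_idx[k]) && !is.null(identifications$score)) {
      identifications$score[id_idx[k]]
    } else NA_real_
    row$distinct_peptide_count <- npep
    for (cc in conds) row[[paste0("mean_", cc)]] <- unname(cond_means[cc])
    row$fold_change <- fc
    row$log2_fold_change <- log2(fc)
    row$anova_p <- p
    row$flag_single_peptide <- npep == 1
    if ("isotope_dot_product" %in% names(d)) {
      row$isotope_dot_product <- mean(d$isotope_dot_product, na.rm = TRUE)
    }
    rows[[k]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Volcano-plot coordinate table
#'
#' Maps report rows to `(log2 fold change, -log10 p)` points, preserving
#' the single-peptide flag used for color coding; rows with non-positive
#' fold change are excluded with a warning.
#'
#' @param rows Report data frame from [merge_labelfree()] (needs
#'   `fold_change`, `anova_p`, `flag_single_peptide`).
#' @param adjust Add a Benjamini-Hochberg adjusted p column (off by
#'   default; the report displays raw ANOVA p).
#' @return Data frame `accession` (if present), `log2_fold_change`,
#'   `neg_log10_p`, `flag_single_peptide` (+ `p_adjusted` when requested).
#' @export
volcano_table <- function(rows, adjust = FALSE) {
  ok <- !is.na(rows$fold_change) & rows$fold_change > 0
  if (any(!ok)) {
    warning(sum(!ok), " row(s) with non-positive fold change excluded")
  }
  d <- rows[ok, , drop = FALSE]
  out <- data.frame(log2_fold_change = log2(d$fold_change),
                    neg_log10_p = -log10(d$anova_p),
                    flag_single_peptide = d$flag_single_peptide,
                    stringsAsFactors = FALSE)
  if (!is.null(d$accession)) out <- cbind(accession = d$accession, out)
  if (adjust) out$p_adjusted <- stats::p.adjust(d$anova_p, method = "BH")
  rownames(out) <- NULL
  out
}
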