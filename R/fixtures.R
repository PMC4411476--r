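# Synthetic-data generators with recorded ground truth.  Every generator is
# a pure function of (parameters, seed): the seed is applied locally and the
# caller's RNG state is restored on exit.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# One random tryptic peptide: interior residues (no K/R, no leading P so the
# preceding cleavage site stays a cleavage site) plus a K/R terminus.
random_tryptic_peptide <- function(len) {
  interior <- c("A", "C", "D", "E", "F", "G", "H", "I", "L", "M", "N", "Q",
                "S", "T", "V", "W", "Y")
  first <- sample(interior, 1)          # interior set already excludes P
  rest <- if (len > 2) {
    sample(c(interior, "P"), len - 2, replace = TRUE)
  } else character(0)
  paste0(paste(c(first, rest), collapse = ""), sample(c("K", "R"), 1))
}

#' Generate a synthetic proteome
#'
#' Proteins are concatenations of random tryptic peptides (lengths drawn so
#' the digest averages 10--15 residues), so the in-silico digest recovers
#' exactly the peptides the generator planted.  Optionally plants shared
#' peptides (the same tryptic peptide inserted into two proteins, breaking
#' proteotypicity) and methionine-containing peptides, both recorded in the
#' ground truth.
#'
#' @param n_proteins Number of proteins (>= 1).
#' @param mean_length Target mean protein length in residues (default 360).
#' @param seed Integer seed.
#' @param n_shared Number of planted shared peptides (each present in
#'   exactly 2 proteins).
#' @param n_met Number of planted Met-containing peptides.
#' @param species Species tag written into each record.
#' @return List with `proteome` (data frame as from [read_fasta()]) and
#'   `truth` (`planted_shared_peptides`, `planted_met_peptides`, `seed`).
#' @export
make_proteome <- function(n_proteins, mean_length = 360, seed = 1,
                          n_shared = 0, n_met = 0, species = "synthetica") {
  stopifnot(n_proteins >= 1)
  with_seed(seed, {
    peps_per_protein <- max(2L, round(mean_length / 12))
    prot_peps <- lapply(seq_len(n_proteins), function(i) {
      lens <- pmin(pmax(round(stats::rnorm(peps_per_protein, 12, 4)), 6), 25)
      vapply(lens, random_tryptic_peptide, character(1))
    })
    shared <- character(0)
    if (n_shared > 0) {
      stopifnot(n_proteins >= 2)
      for (k in seq_len(n_shared)) {
        pep <- random_tryptic_peptide(sample(8:16, 1))
        pair <- sample(n_proteins, 2)
        for (p in pair) {
          at <- sample(length(prot_peps[[p]]) + 1, 1)
          prot_peps[[p]] <- append(prot_peps[[p]], pep, after = at - 1)
        }
        shared <- c(shared, pep)
      }
    }
    met <- character(0)
    if (n_met > 0) {
      for (k in seq_len(n_met)) {
        len <- sample(8:16, 1)
        pep <- random_tryptic_peptide(len)
        at_m <- sample(seq_len(len - 1), 1)
        substr(pep, at_m, at_m) <- "M"
        p <- sample(n_proteins, 1)
        at <- sample(length(prot_peps[[p]]) + 1, 1)
        prot_peps[[p]] <- append(prot_peps[[p]], pep, after = at - 1)
        met <- c(met, pep)
      }
    }
    proteome <- data.frame(
      accession = sprintf("SYN%04d", seq_len(n_proteins)),
      description = sprintf("synthetic protein %d", seq_len(n_proteins)),
      gene_symbol = sprintf("SYNG%d", seq_len(n_proteins)),
      species = species,
      sequence = vapply(prot_peps, paste, character(1), collapse = ""),
      stringsAsFactors = FALSE)
    list(proteome = proteome,
         truth = list(planted_shared_peptides = shared,
                      planted_met_peptides = met,
                      seed = seed))
  })
}

# Shuffle a peptide's interior, preserving both terminal residues (keeps the
# tryptic terminus; avoids the palindrome artifacts of simple reversal).
shuffle_peptide <- function(pep) {
  n <- nchar(pep)
  if (n <= 3) return(pep)
  chars <- strsplit(pep, "")[[1]]
  mid <- chars[2:(n - 1)]
  paste(c(chars[1], sample(mid), chars[n]), collapse = "")
}

#' Generate a target-decoy search result with ground truth
#'
#' True PSMs sample real tryptic peptides of the proteome (length 5--30)
#' with scores from the true-score distribution; false targets and an
#' equal number of decoys carry interior-shuffled peptides scored from a
#' shared null distribution (the equal-variance assumption under which the
#' decoy count estimates the false-target count).  Identity and homology
#' thresholds are constant.  Optionally attaches reporter intensities or
#' SILAC ratios with injected per-protein fold changes.
#'
#' @param proteome Proteome data frame (from [make_proteome()]).
#' @param n_true,n_false Numbers of true PSMs and false-target PSMs; decoy
#'   count equals `n_false`.
#' @param seed Integer seed.
#' @param score_true,score_null `c(mean, sd)` of the score distributions
#'   (defaults 60/10 and 30/10).
#' @param identity_threshold,homology_threshold Constant thresholds
#'   (defaults 40 and 30).
#' @param sample_id Sample label stamped on every PSM.
#' @param mz_ppm_sd Gaussian m/z measurement noise in ppm (default 3).
#' @param reporter_channels,reporter_fold_changes Optional: channel labels
#'   plus a named accession -> linear fold-change map applied to every
#'   non-reference channel (first channel is reference).
#' @param silac_fold_changes Optional named accession -> heavy/light ratio
#'   map; PSMs of those proteins get noisy `heavy_light_ratio` values.
#' @return List with `psms` (canonical PSM data frame) and `truth`
#'   (`true_psm_ids`, `false_psm_ids`, `decoy_psm_ids`, `seed`).
#' @export
make_search_result <- function(proteome, n_true = 500, n_false = 500,
                               seed = 1, score_true = c(60, 10),
                               score_null = c(30, 10),
                               identity_threshold = 40,
                               homology_threshold = 30,
                               sample_id = "sample_1", mz_ppm_sd = 3,
                               reporter_channels = NULL,
                               reporter_fold_changes = NULL,
                               silac_fold_changes = NULL) {
  with_seed(seed, {
    digests <- lapply(proteome$sequence, tryptic_digest)
    pool <- data.frame(
      peptide = unlist(digests),
      accession = rep(proteome$accession, lengths(digests)),
      stringsAsFactors = FALSE)
    pool <- pool[nchar(pool$peptide) >= 5 & nchar(pool$peptide) <= 30, ]
    # a peptide present in several proteins lists all of them
    acc_of <- tapply(pool$accession, pool$peptide,
                     function(a) paste(sort(unique(a)), collapse = ";"))
    pool <- pool[!duplicated(pool$peptide), ]
    pool$accessions <- unname(acc_of[pool$peptide])

    pick <- pool[sample(nrow(pool), n_true, replace = TRUE), ]
    true_df <- data.frame(peptide = pick$peptide,
                          accessions = pick$accessions,
                          score = stats::rnorm(n_true, score_true[1], score_true[2]),
                          is_decoy = FALSE, label = "true",
                          stringsAsFactors = FALSE)
    null_peps <- vapply(pool$peptide[sample(nrow(pool), 2 * n_false,
                                            replace = TRUE)],
                        shuffle_peptide, character(1), USE.NAMES = FALSE)
    false_df <- data.frame(
      peptide = null_peps[seq_len(n_false)],
      accessions = sample(proteome$accession, n_false, replace = TRUE),
      score = stats::rnorm(n_false, score_null[1], score_null[2]),
      is_decoy = FALSE, label = "false", stringsAsFactors = FALSE)
    decoy_df <- data.frame(
      peptide = null_peps[n_false + seq_len(n_false)],
      accessions = paste0("DECOY_",
                          sample(proteome$accession, n_false, replace = TRUE)),
      score = stats::rnorm(n_false, score_null[1], score_null[2]),
      is_decoy = TRUE, label = "decoy", stringsAsFactors = FALSE)
    all_df <- rbind(true_df, false_df, decoy_df)
    n <- nrow(all_df)
    charge <- sample(2:3, n, replace = TRUE)
    theo <- vapply(seq_len(n), function(i)
      peptide_mz(all_df$peptide[i], "", charge[i]), numeric(1))
    psms <- data.frame(
      sample_id = sample_id,
      spectrum_id = sprintf("%s_scan_%05d", sample_id, seq_len(n)),
      peptide_sequence = all_df$peptide,
      modifications = "",
      charge = charge,
      precursor_mz_observed = theo * (1 + stats::rnorm(n, 0, mz_ppm_sd) * 1e-6),
      retention_time_min = round(stats::runif(n, 10, 120), 3),
      score = round(all_df$score, 4),
      identity_threshold = identity_threshold,
      homology_threshold = homology_threshold,
      protein_accessions = all_df$accessions,
      is_decoy = all_df$is_decoy,
      stringsAsFactors = FALSE)
    if (!is.null(reporter_channels)) {
      ref <- reporter_channels[1]
      base <- stats::rlnorm(n, log(1000), 0.3)
      for (ch in reporter_channels) {
        fc <- if (ch == ref || is.null(reporter_fold_changes)) {
          rep(1, n)
        } else {
          first_acc <- vapply(strsplit(psms$protein_accessions, ";"),
                              `[`, character(1), 1L)
          f <- reporter_fold_changes[first_acc]
          ifelse(is.na(f), 1, f)
        }
        psms[[paste0("reporter_", ch)]] <-
          round(base * fc * stats::rlnorm(n, 0, 0.1), 2)
      }
    }
    if (!is.null(silac_fold_changes)) {
      first_acc <- vapply(strsplit(psms$protein_accessions, ";"),
                          `[`, character(1), 1L)
      r <- silac_fold_changes[first_acc]
      psms$heavy_light_ratio <-
        ifelse(is.na(r), NA, round(r * stats::rlnorm(n, 0, 0.1), 4))
    }
    list(psms = psms,
         truth = list(true_psm_ids = psms$spectrum_id[all_df$label == "true"],
                      false_psm_ids = psms$spectrum_id[all_df$label == "false"],
                      decoy_psm_ids = psms$spectrum_id[all_df$label == "decoy"],
                      seed = seed))
  })
}

#' Generate library spectra for PSMs
#'
#' One spectrum per PSM: the singly- and doubly-charged b/y ladder of the
#' peptide with log-normal intensities, plus `noise_peaks` unannotated
#' peaks placed at least 1 Th away from every ladder ion so annotation is
#' unambiguous.  The ground truth records each spectrum's ladder ions
#' sorted by descending intensity (the transition-selection oracle).
#'
#' @param psms PSM data frame.
#' @param seed Integer seed.
#' @param noise_peaks Number of noise peaks per spectrum (default 10).
#' @return List with `spectra` (list of `Spectrum`) and `truth`
#'   (`top_ions`: named list spectrum_id -> data frame of ladder ions
#'   sorted by intensity).
#' @export
make_spectra <- function(psms, seed = 1, noise_peaks = 10) {
  with_seed(seed, {
    spectra <- vector("list", nrow(psms))
    top_ions <- vector("list", nrow(psms))
    for (i in seq_len(nrow(psms))) {
      lad <- fragment_ladder(psms$peptide_sequence[i], psms$modifications[i])
      lad$intensity <- stats::rlnorm(nrow(lad), log(100), 1)
      noise <- matrix(numeric(0), ncol = 2)
      if (noise_peaks > 0) {
        got <- 0
        mzs <- numeric(0)
        while (got < noise_peaks) {
          cand <- stats::runif(noise_peaks, 120, 1500)
          ok <- vapply(cand, function(m) all(abs(lad$mz - m) > 1), logical(1))
          mzs <- c(mzs, cand[ok])
          got <- length(mzs)
        }
        mzs <- mzs[seq_len(noise_peaks)]
        noise <- cbind(mzs, stats::rlnorm(noise_peaks, log(20), 0.5))
      }
      peaks <- rbind(cbind(lad$mz, lad$intensity), noise)
      spectra[[i]] <- new_spectrum(
        psms$spectrum_id[i],
        psms$precursor_mz_observed[i],
        psms$charge[i],
        psms$retention_time_min[i],
        peaks)
      top_ions[[i]] <- lad[order(-lad$intensity, lad$mz), , drop = FALSE]
    }
    names(top_ions) <- psms$spectrum_id
    list(spectra = spectra, truth = list(top_ions = top_ions, seed = seed))
  })
}

#' Generate a label-free quantitation table with injected fold changes
#'
#' Each selected protein contributes `peptides_per_protein` peptides with
#' log-normal baseline abundances.  Changed proteins get the stated log2
#' fold change applied to the second condition; null proteins share
#' condition means.  Replicate noise is multiplicative log-normal at the
#' given coefficient of variation (mean 1).
#'
#' @param proteome Proteome data frame.
#' @param n_changed,n_null Numbers of changed and null proteins (drawn from
#'   the head of the proteome; requires enough proteins).
#' @param log2_fc Injected log2 fold change for changed proteins
#'   (default 2).
#' @param cv Coefficient of variation of the multiplicative noise
#'   (default 0.2).
#' @param conditions Condition labels (exactly 2, default A/B).
#' @param n_replicates Replicates per condition (default 3).
#' @param peptides_per_protein Peptides quantified per protein (default 3).
#' @param seed Integer seed.
#' @return List with `quant` (label-free CSV data frame) and `truth`
#'   (`injected_log2_fold_changes`: named accession -> log2 FC, 0 for null
#'   proteins; `seed`).
#' @export
make_quant_tables <- function(proteome, n_changed = 100, n_null = 200,
                              log2_fc = 2, cv = 0.2,
                              conditions = c("A", "B"), n_replicates = 3,
                              peptides_per_protein = 3, seed = 1) {
  stopifnot(length(conditions) == 2,
            nrow(proteome) >= n_changed + n_null)
  with_seed(seed, {
    accs <- proteome$accession[seq_len(n_changed + n_null)]
    fc <- c(rep(log2_fc, n_changed), rep(0, n_null))
    names(fc) <- accs
    sdlog <- sqrt(log(1 + cv^2))
    rows <- list()
    for (a in accs) {
      digest <- tryptic_digest(proteome$sequence[proteome$accession == a])
      digest <- digest[nchar(digest) >= 5 & nchar(digest) <= 30]
      peps <- utils::head(unique(digest), peptides_per_protein)
      base <- stats::rlnorm(length(peps), log(1e6), 0.8)
      for (k in seq_along(peps)) {
        for (cc in seq_along(conditions)) {
          level <- base[k] * if (cc == 2) 2^fc[[a]] else 1
          noise <- if (cv > 0) {
            stats::rlnorm(n_replicates, -sdlog^2 / 2, sdlog)
          } else rep(1, n_replicates)
          rows[[length(rows) + 1L]] <- data.frame(
            accession = a, peptide_sequence = peps[k],
            condition = conditions[cc], replicate = seq_len(n_replicates),
            abundance = level * noise,
            isotope_dot_product = round(stats::runif(n_replicates, 0.9, 1), 3),
            stringsAsFactors = FALSE)
        }
      }
    }
    quant <- do.call(rbind, rows)
    rownames(quant) <- NULL
    list(quant = quant,
         truth = list(injected_log2_fold_changes = fc, seed = seed))
  })
}

#' Write a simulation's ground truth as JSON
#' @param truth Truth list from any generator.
#' @param path Output path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
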