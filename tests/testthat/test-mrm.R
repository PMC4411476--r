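# Brute-force transition oracle: score every theoretical b/y ion against the
# peak list with a plain double loop, sort by intensity, take n.
oracle_transitions <- function(peptide, mods, peaks, n, tol = 0.5) {
  lad <- fragment_ladder(peptide, mods)
  best <- rep(NA_real_, nrow(lad))
  for (i in seq_len(nrow(lad))) {
    for (j in seq_len(nrow(peaks))) {
      if (abs(peaks[j, 1] - lad$mz[i]) <= tol) {
        best[i] <- max(best[i], peaks[j, 2], na.rm = TRUE)
      }
    }
  }
  lad$intensity <- best
  lad <- lad[!is.na(best), ]
  lad <- lad[order(-lad$intensity, lad$mz), ]
  head(lad, n)
}

entry_of <- function(peptide, score = 80, obs = 5, acc = "P1", charge = 2L,
                     mods = "") {
  data.frame(peptide_sequence = peptide, modifications = mods,
             charge = charge,
             precursor_mz = peptide_mz(peptide, mods, charge),
             retention_time_median = 42, best_score = score,
             identity_threshold = 40, homology_threshold = 30,
             observation_count = obs,
             best_spectrum_id = paste0("sp_", peptide),
             source_sample_ids = "s1", protein_accessions = acc,
             stringsAsFactors = FALSE)
}

test_that("fragment ladder satisfies b/y mass identities", {
  pep <- "SAMSPK"
  lad <- fragment_ladder(pep)
  z1 <- lad[lad$fragment_charge == 1, ]
  # complementary pair: b_i + y_(L-i) = precursor neutral mass + 2 protons
  M <- peptide_neutral_mass(pep)
  for (i in 1:5) {
    b <- z1$mz[z1$fragment_type == "b" & z1$fragment_index == i]
    y <- z1$mz[z1$fragment_type == "y" & z1$fragment_index == 6 - i]
    expect_equal(b + y, M + 2 * 1.007276, tolerance = 1e-9)
  }
  # y_L-1 ... full ladder size
  expect_equal(nrow(lad), 2 * 2 * (nchar(pep) - 1))
  # a phospho on residue 4 shifts b4, b5 and y3..y5, not b1..b3 / y1..y2
  lp <- fragment_ladder(pep, "4:79.966331")
  shift <- lp$mz[lp$fragment_charge == 1] - z1$mz
  expect_equal(shift[z1$fragment_type == "b"][1:3], rep(0, 3))
  expect_equal(shift[z1$fragment_type == "b"][4:5], rep(79.966331, 2),
               tolerance = 1e-9)
})

test_that("the five assay filtering criteria fire in order with recorded reasons", {
  proteome <- data.frame(
    accession = c("P1", "P2"),
    sequence = c(paste0("AAAGGSSKCCCDDEEKFFFGGHHKIIKLLNNQQK"),
                 paste0("SSSTTVVKWWYYAAEEKAAAGGSSK")),
    stringsAsFactors = FALSE)
  cands <- rbind(
    entry_of("AAAGGSSK", score = 90, obs = 9),   # shared with P2 -> not_unique
    entry_of("CCCDDEEK", score = 35, obs = 8),   # below identity (40)
    entry_of("FFFGGHHK", score = 80, obs = 7),
    entry_of("IIK", score = 80, obs = 6),        # unique in P1
    entry_of("SSSTTVVK", score = 80, obs = 4, acc = "P2"),
    entry_of("WWYYAAEEK", score = 80, obs = 3, acc = "P2"))
  res <- select_assay_peptides(cands, proteome)
  reason <- setNames(res$rejection_reason, res$peptide_sequence)
  expect_equal(unname(reason["CCCDDEEK"]), "below_identity")
  expect_equal(unname(reason["AAAGGSSK"]), "not_unique")
  # P2 retains only 2 candidates from the start -> too few peptides
  expect_equal(unname(reason["SSSTTVVK"]), "protein_too_few_peptides")
  expect_equal(unname(reason["WWYYAAEEK"]), "protein_too_few_peptides")
  # P1 passes the first three-peptide check (3 survivors after criterion 1)
  # but drops to 2 once the shared peptide is removed, so the re-check
  # rejects the remainder
  expect_equal(unname(reason["FFFGGHHK"]), "protein_too_few_peptides")
  expect_equal(unname(reason["IIK"]), "protein_too_few_peptides")
  expect_false(any(res$selected))
})

test_that("methionine exclusion and top-n ranking by observation count", {
  seqs <- c("AAAGGSSK", "CCCDDEEK", "FFFGGHHK", "IIVVWWK", "LLNNQQK",
            "SSTTVVYK", "AADDFFK", "AAMGGK")
  proteome <- data.frame(accession = "P1",
                         sequence = paste(seqs, collapse = ""),
                         stringsAsFactors = FALSE)
  cands <- do.call(rbind, c(
    lapply(seq_len(7), function(i) entry_of(seqs[i], obs = 10 - i)),
    list(entry_of("AAMGGK", obs = 20))))          # Met peptide, top count
  res <- select_assay_peptides(cands, proteome, top_n_peptides = 5)
  expect_equal(res$rejection_reason[res$peptide_sequence == "AAMGGK"],
               "contains_met")
  sel <- res[res$selected, ]
  expect_equal(nrow(sel), 5)
  # the five highest observation counts (9..5) survive; 4 and 3 are ranked out
  expect_setequal(sel$observation_count, 5:9)
  expect_equal(sort(res$rejection_reason[res$rejection_reason ==
                                           "not_top_ranked"]),
               rep("not_top_ranked", 2))
  # selected <=> no rejection reason
  expect_identical(res$selected, is.na(res$rejection_reason))
})

test_that("assay selection is invariant to candidate input order", {
  pr <- make_proteome(30, seed = 14, n_shared = 2, n_met = 2)
  sr <- make_search_result(pr$proteome, n_true = 200, n_false = 50, seed = 15)
  lib <- curate_library(sr$psms)
  a <- select_assay_peptides(lib, pr$proteome)
  set.seed(1)
  b <- select_assay_peptides(lib[sample(nrow(lib)), ], pr$proteome)
  key <- function(d) paste(d$peptide_sequence, d$charge)
  expect_setequal(key(a[a$selected, ]), key(b[b$selected, ]))
  ra <- setNames(a$rejection_reason, key(a))
  rb <- setNames(b$rejection_reason, key(b))
  expect_identical(ra[sort(names(ra))], rb[sort(names(rb))])
})

test_that("transition selection matches the brute-force oracle and documents ties", {
  pep <- entry_of("ELVISLIVESK")
  set.seed(16)
  lad <- fragment_ladder("ELVISLIVESK")
  peaks <- cbind(lad$mz, round(rlnorm(nrow(lad), log(100), 1), 3))
  spec <- pepflow:::new_spectrum("sp", pep$precursor_mz, 2, 42, peaks)
  tr <- select_transitions(pep, spec, n_transitions = 5)
  or <- oracle_transitions("ELVISLIVESK", "", peaks, 5)
  expect_equal(tr$product_mz, or$mz, tolerance = 1e-9)
  expect_equal(tr$fragment_type, or$fragment_type)
  expect_equal(tr$intensity_rank, 1:5)
  # tie in intensity -> lower product m/z first
  tied <- cbind(lad$mz[1:4], c(10, 10, 5, 1))
  spec2 <- pepflow:::new_spectrum("sp2", pep$precursor_mz, 2, 42, tied)
  tr2 <- select_transitions(pep, spec2, n_transitions = 2)
  expect_equal(tr2$product_mz, sort(tr2$product_mz))
  # n larger than available returns everything with a warning
  expect_warning(tr3 <- select_transitions(pep, spec2, n_transitions = 50),
                 "available")
  expect_equal(nrow(tr3), 4)
  # no annotatable peaks -> empty with warning
  far <- pepflow:::new_spectrum("sp3", pep$precursor_mz, 2, 42,
                                cbind(c(5000, 6000), c(1, 1)))
  expect_warning(tr4 <- select_transitions(pep, far), "no annotatable")
  expect_equal(nrow(tr4), 0)
})

test_that("build_method emits deterministic (accession, peptide, rank) order and round trips", {
  pr <- make_proteome(25, seed = 17)
  sr <- make_search_result(pr$proteome, n_true = 250, n_false = 60, seed = 18)
  keep <- sr$psms$spectrum_id %in% sr$truth$true_psm_ids
  sp <- make_spectra(sr$psms[keep, ], seed = 19)
  lib <- suppressWarnings(curate_library(sr$psms, spectra = sp$spectra))
  assay <- select_assay_peptides(lib, pr$proteome)
  path <- tempfile(fileext = ".tsv")
  method <- build_method(assay, sp$spectra, n_transitions = 3, path = path)
  expect_gt(nrow(method), 0)
  ord <- order(method$protein_accession, method$peptide_sequence,
               method$intensity_rank)
  expect_equal(ord, seq_len(nrow(method)))
  back <- read_transitions_tsv(path)
  expect_equal(nrow(back), nrow(method))
  expect_equal(back$product_mz, method$product_mz, tolerance = 1e-4)
  expect_equal(back$fragment_type, method$fragment_type)
  # per-precursor transition count contract
  expect_true(all(table(paste(method$peptide_sequence,
                              method$precursor_charge)) <= 3))
})
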