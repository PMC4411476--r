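# Minimal PSM table constructor used across test files.
make_psms <- function(score, is_decoy = rep(FALSE, length(score)),
                      peptide = NULL, accession = NULL,
                      modifications = "", sample_id = "s1",
                      identity_threshold = 40, homology_threshold = 30,
                      charge = 2L, rt = 30) {
  n <- length(score)
  if (is.null(peptide)) {
    peptide <- vapply(seq_len(n), function(i)
      paste0(paste(sample(c("A", "G", "S", "T", "V", "E", "D", "F"), 8,
                          replace = TRUE), collapse = ""), "K"),
      character(1))
  }
  if (is.null(accession)) {
    accession <- ifelse(is_decoy, "DECOY_P001", "P001")
  }
  data.frame(
    sample_id = rep_len(sample_id, n),
    spectrum_id = sprintf("spec_%03d", seq_len(n)),
    peptide_sequence = rep_len(peptide, n),
    modifications = rep_len(modifications, n),
    charge = rep_len(as.integer(charge), n),
    precursor_mz_observed = vapply(seq_len(n), function(i)
      pepflow::peptide_mz(rep_len(peptide, n)[i],
                          rep_len(modifications, n)[i],
                          rep_len(as.integer(charge), n)[i]),
      numeric(1)),
    retention_time_min = rep_len(rt, n),
    score = score,
    identity_threshold = rep_len(identity_threshold, n),
    homology_threshold = rep_len(homology_threshold, n),
    protein_accessions = rep_len(accession, n),
    is_decoy = is_decoy,
    stringsAsFactors = FALSE)
}
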