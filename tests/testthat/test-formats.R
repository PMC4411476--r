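test_that("read_fasta parses headers, tokens and multi-line sequences", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(
    ">sp|P001|TEST_HUMAN desc GN=TST OS=Homo sapiens",
    "MKA", "LYP",
    ">P002",
    "acdef"), fa)
  d <- read_fasta(fa)
  expect_equal(nrow(d), 2)
  expect_equal(d$accession[1], "sp|P001|TEST_HUMAN")
  expect_equal(d$gene_symbol[1], "TST")
  expect_equal(d$species[1], "Homo sapiens")
  expect_equal(d$sequence[1], "MKALYP")
  expect_equal(d$sequence[2], "ACDEF")   # uppercased
  expect_true(is.na(d$gene_symbol[2]))
})

test_that("read_fasta handles empty files and rejects duplicates", {
  fa <- tempfile(fileext = ".fasta")
  file.create(fa)
  expect_warning(d <- read_fasta(fa), "empty")
  expect_equal(nrow(d), 0)
  writeLines(c(">A x", "ACDE", ">A y", "GGG"), fa)
  expect_error(read_fasta(fa), "duplicate")
})

test_that("FASTA round trip preserves records and header tokens", {
  pr <- make_proteome(5, seed = 2)$proteome
  fa <- tempfile(fileext = ".fasta")
  write_fasta(pr, fa)
  back <- read_fasta(fa)
  expect_equal(back$accession, pr$accession)
  expect_equal(back$sequence, pr$sequence)
  expect_equal(back$gene_symbol, pr$gene_symbol)
  expect_equal(back$species, pr$species)
})

test_that("read_mgf parses blocks, converts RT to minutes and sorts peaks", {
  mgf <- tempfile(fileext = ".mgf")
  writeLines(c(
    "BEGIN IONS",
    "TITLE=spec1",
    "PEPMASS=523.7777 1000.0",
    "CHARGE=2+",
    "RTINSECONDS=120",
    "300.1 10", "200.2 20", "500.5 5", "100.0 7", "400.4 1",
    "END IONS",
    "BEGIN IONS",          # no PEPMASS: skipped
    "TITLE=bad",
    "100 1",
    "END IONS"), mgf)
  expect_warning(sp <- read_mgf(mgf), "PEPMASS")
  expect_length(sp, 1)
  expect_equal(nrow(sp[[1]]$peaks), 5)
  expect_equal(sp[[1]]$retention_time, 2.0)
  expect_equal(sp[[1]]$precursor_mz, 523.7777)
  expect_true(!is.unsorted(sp[[1]]$peaks[, "mz"]))
})

test_that("MGF round trip reproduces spectra", {
  pr <- make_proteome(5, seed = 2)
  sr <- make_search_result(pr$proteome, n_true = 10, n_false = 5, seed = 3)
  sp <- make_spectra(sr$psms[1:8, ], seed = 4, noise_peaks = 3)$spectra
  mgf <- tempfile(fileext = ".mgf")
  write_mgf(sp, mgf)
  back <- read_mgf(mgf)
  expect_length(back, 8)
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$spectrum_id, sp[[i]]$spectrum_id)
    expect_equal(back[[i]]$precursor_charge, sp[[i]]$precursor_charge)
    expect_equal(back[[i]]$retention_time, sp[[i]]$retention_time,
                 tolerance = 1e-4)
    expect_equal(back[[i]]$peaks, sp[[i]]$peaks, tolerance = 1e-3)
  }
})

test_that("canonical PSM CSV round trips and applies the decoy prefix rule", {
  psms <- make_psms(score = c(55, 44, 33), is_decoy = c(FALSE, FALSE, TRUE))
  psms$modifications[1] <- "3:79.966331"
  csv <- tempfile(fileext = ".csv")
  write_psm_csv(psms, csv)
  back <- read_identifications(csv, "csv")
  expect_equal(nrow(back), 3)
  expect_equal(back$peptide_sequence, psms$peptide_sequence)
  expect_equal(back$modifications, psms$modifications)
  expect_identical(back$is_decoy, psms$is_decoy)   # prefix agrees with flag
  # missing required column is named in the error
  broken <- psms
  broken$homology_threshold <- NULL
  write.csv(broken, csv, row.names = FALSE)
  expect_error(read_identifications(csv, "csv"), "homology_threshold")
  expect_error(read_identifications(csv, "nonsense"))
})

test_that("pepXML reader extracts scores, thresholds, decoy flags and mod deltas", {
  px <- tempfile(fileext = ".pep.xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<msms_pipeline_analysis>',
    ' <msms_run_summary>',
    '  <spectrum_query spectrum="run1.00042" precursor_neutral_mass="1049.5" assumed_charge="2" retention_time_sec="300">',
    '   <search_result>',
    '    <search_hit peptide="SAMSPK" protein="P001">',
    '     <alternative_protein protein="P002"/>',
    '     <modification_info>',
    '      <mod_aminoacid_mass position="4" mass="79.966331"/>',
    '     </modification_info>',
    '     <search_score name="ionscore" value="51.2"/>',
    '     <search_score name="identityscore" value="40.1"/>',
    '     <search_score name="homologyscore" value="28.7"/>',
    '    </search_hit>',
    '   </search_result>',
    '  </spectrum_query>',
    '  <spectrum_query spectrum="run1.00043" precursor_neutral_mass="900.4" assumed_charge="2">',
    '   <search_result>',
    '    <search_hit peptide="DECOYPEPK" protein="DECOY_P009">',
    '     <search_score name="ionscore" value="12.0"/>',
    '    </search_hit>',
    '   </search_result>',
    '  </spectrum_query>',
    ' </msms_run_summary>',
    '</msms_pipeline_analysis>'), px)
  d <- read_identifications(px, "pepxml")
  expect_equal(nrow(d), 2)
  expect_equal(d$score[1], 51.2)
  expect_equal(d$identity_threshold[1], 40.1)
  expect_equal(d$retention_time_min[1], 5)
  expect_equal(d$protein_accessions[1], "P001;P002")
  # the phospho delta is recognized within +-0.01 Da
  mods <- parse_modifications(d$modifications[1])
  expect_equal(mods$position, 4L)
  expect_equal(mods$name, "phospho")
  expect_true(abs(mods$mass_delta - 79.966331) <= 0.01)
  expect_identical(d$is_decoy, c(FALSE, TRUE))
  # observed m/z reconstructed from the neutral mass
  expect_equal(d$precursor_mz_observed[1], (1049.5 + 2 * 1.007276) / 2,
               tolerance = 1e-6)
})

test_that("protXML reader yields protein identifications with peptide evidence", {
  px <- tempfile(fileext = ".prot.xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<protein_summary>',
    ' <protein_group group_number="1" probability="0.99">',
    '  <protein protein_name="P001" probability="0.99" percent_coverage="41.5">',
    '   <annotation protein_description="widget kinase"/>',
    '   <peptide peptide_sequence="AAAGGK" charge="2"/>',
    '   <peptide peptide_sequence="SSSTTK" charge="2"/>',
    '   <peptide peptide_sequence="AAAGGK" charge="3"/>',
    '  </protein>',
    ' </protein_group>',
    '</protein_summary>'), px)
  d <- read_identifications(px, "protxml")
  expect_equal(d$accession, "P001")
  expect_equal(d$description, "widget kinase")
  expect_equal(d$coverage_fraction, 0.415)
  expect_equal(d$distinct_peptide_count, 2L)
})

test_that("spectral library write/read is a field-for-field round trip", {
  pr <- make_proteome(10, seed = 5)
  sr <- make_search_result(pr$proteome, n_true = 40, n_false = 20, seed = 6)
  sp <- make_spectra(sr$psms[sr$psms$spectrum_id %in%
                               sr$truth$true_psm_ids, ], seed = 7)
  lib <- suppressWarnings(curate_library(sr$psms, spectra = sp$spectra))
  lib <- annotate_uniqueness(lib, list(synthetica = pr$proteome))
  expect_gt(nrow(lib), 3)
  path <- tempfile(fileext = ".peplib")
  write_library(lib, path)
  back <- read_library(path)
  for (col in c("peptide_sequence", "modifications", "charge",
                "observation_count", "best_spectrum_id",
                "source_sample_ids", "protein_accessions")) {
    expect_identical(back[[col]], lib[[col]])
  }
  for (col in c("precursor_mz", "retention_time_median", "best_score")) {
    expect_equal(back[[col]], lib[[col]], tolerance = 1e-12)
  }
  for (i in seq_len(nrow(lib))) {
    expect_equal(back$peaks[[i]], lib$peaks[[i]], tolerance = 1e-12)
  }
  expect_equal(attr(back, "uniqueness")$is_unique,
               attr(lib, "uniqueness")$is_unique)
  # entry passthrough: observation count 7 survives the trip
  lib2 <- lib[1, , drop = FALSE]
  lib2$observation_count <- 7L
  write_library(lib2, path)
  expect_equal(read_library(path)$observation_count, 7L)
})

test_that("an empty library is written and read back as empty", {
  path <- tempfile()
  write_library(curate_library(make_psms(numeric(0))[0, ]), path)
  expect_equal(nrow(read_library(path)), 0)
})

test_that("transition TSV has header + rows, 4-decimal m/z, and round trips", {
  tr <- data.frame(
    protein_accession = "P001", peptide_sequence = "ELVISK",
    modified_sequence = "ELVISK", precursor_charge = 2L,
    precursor_mz = 523.77771, fragment_type = c("y", "y", "b", "y", "b"),
    fragment_index = c(4L, 3L, 2L, 2L, 3L), fragment_charge = 1L,
    product_mz = c(476.28221, 363.19815, 243.13393, 234.14483, 356.21799),
    intensity_rank = 1:5, retention_time_min = 42.5,
    stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  write_transitions_tsv(tr, path)
  lines <- readLines(path)
  expect_length(lines, 6)                     # header + 5 rows
  expect_true(grepl("\t523.7777\t", lines[2], fixed = TRUE))
  back <- read_transitions_tsv(path)
  expect_equal(back$product_mz, tr$product_mz, tolerance = 1e-4)
  expect_equal(back$fragment_type, tr$fragment_type)
  expect_equal(back$intensity_rank, tr$intensity_rank)
})
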