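#' Read a protein FASTA database
#'
#' Headers follow the common `accession description` convention; `GN=` and
#' `OS=` tokens are parsed into `gene_symbol` and `species` when present.
#' Sequences are uppercased and whitespace-stripped.
#'
#' @param path Path to a FASTA file.
#' @return Data frame with columns `accession`, `description`,
#'   `gene_symbol`, `species`, `sequence` (one row per entry).
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  empty <- data.frame(accession = character(), description = character(),
                      gene_symbol = character(), species = character(),
                      sequence = character(), stringsAsFactors = FALSE)
  if (file.size(path) == 0) {
    warning("empty FASTA file: ", path)
    return(empty)
  }
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) {
    warning("no FASTA records in: ", path)
    return(empty)
  }
  headers <- names(aa)
  accession <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  gene_symbol <- ifelse(grepl("\\bGN=(\\S+)", description),
                        sub(".*\\bGN=(\\S+).*", "\\1", description),
                        NA_character_)
  species <- ifelse(grepl("\\bOS=", description),
                    sub(".*\\bOS=(.*?)(\\s+[A-Z]{2}=.*)?$", "\\1", description),
                    NA_character_)
  sequence <- toupper(gsub("\\s", "", as.character(aa)))
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", sequence)
  if (any(bad)) {
    stop("non-standard residues in FASTA record(s): ",
         paste(utils::head(accession[bad], 3), collapse = ", "))
  }
  if (anyDuplicated(accession)) stop("duplicate accessions in FASTA: ", path)
  data.frame(accession = accession, description = description,
             gene_symbol = gene_symbol, species = species,
             sequence = sequence, stringsAsFactors = FALSE)
}

#' Write a protein table to FASTA
#' @param proteome Data frame as returned by [read_fasta()].
#' @param path Output path.
#' @export
write_fasta <- function(proteome, path) {
  hdr <- proteome$accession
  desc <- proteome$description
  extra <- character(nrow(proteome))
  if (!is.null(proteome$gene_symbol)) {
    gs <- proteome$gene_symbol
    extra <- ifelse(!is.na(gs) & nzchar(gs) & !grepl("GN=", desc),
                    paste0(" GN=", gs), "")
  }
  if (!is.null(proteome$species)) {
    sp <- proteome$species
    extra <- paste0(ifelse(!is.na(sp) & nzchar(sp) & !grepl("OS=", desc),
                           paste0(" OS=", sp), ""), extra)
  }
  hdr <- ifelse(nzchar(desc), paste(hdr, paste0(desc, extra)),
                ifelse(nzchar(extra), paste(hdr, sub("^ ", "", extra)), hdr))
  aa <- Biostrings::AAStringSet(proteome$sequence)
  names(aa) <- hdr
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

new_spectrum <- function(spectrum_id, precursor_mz, precursor_charge = 1L,
                         retention_time = NA_real_, peaks) {
  peaks <- peaks[order(peaks[, 1]), , drop = FALSE]
  colnames(peaks) <- c("mz", "intensity")
  structure(list(spectrum_id = spectrum_id,
                 precursor_mz = precursor_mz,
                 precursor_charge = as.integer(precursor_charge),
                 retention_time = retention_time,
                 peaks = peaks),
            class = "Spectrum")
}

#' @export
print.Spectrum <- function(x, ...) {
  cat(sprintf("<Spectrum %s> precursor %.4f Th (+%d), %d peaks\n",
              x$spectrum_id, x$precursor_mz, x$precursor_charge,
              nrow(x$peaks)))
  invisible(x)
}

#' Read an MGF peak list
#'
#' Parses `BEGIN IONS`/`END IONS` blocks with `PEPMASS`, optional `CHARGE`,
#' `RTINSECONDS` (converted to minutes) and `TITLE` headers.  Blocks without
#' a `PEPMASS` are skipped with a warning; peaks are returned sorted
#' ascending by m/z.
#'
#' @param path Path to an MGF file.
#' @return List of `Spectrum` objects (`spectrum_id`, `precursor_mz`,
#'   `precursor_charge`, `retention_time` in minutes, `peaks` matrix).
#' @export
read_mgf <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^BEGIN IONS\\s*$", lines)
  ends <- grep("^END IONS\\s*$", lines)
  stopifnot(length(starts) == length(ends))
  out <- vector("list", length(starts))
  kept <- 0L
  for (b in seq_along(starts)) {
    block <- lines[(starts[b] + 1L):(ends[b] - 1L)]
    is_kv <- grepl("=", block, fixed = TRUE)
    kv <- block[is_kv]
    keys <- sub("=.*$", "", kv)
    vals <- sub("^[^=]*=", "", kv)
    if (!"PEPMASS" %in% keys) {
      warning("MGF block ", b, " has no PEPMASS; skipped")
      next
    }
    pepmass <- as.numeric(strsplit(vals[match("PEPMASS", keys)], "\\s+")[[1]][1])
    charge <- if ("CHARGE" %in% keys) {
      as.integer(sub("\\+$", "", vals[match("CHARGE", keys)]))
    } else 1L
    rt <- if ("RTINSECONDS" %in% keys) {
      as.numeric(vals[match("RTINSECONDS", keys)]) / 60
    } else NA_real_
    title <- if ("TITLE" %in% keys) vals[match("TITLE", keys)] else
      sprintf("spectrum_%d", b)
    pk <- block[!is_kv & nzchar(trimws(block))]
    peaks <- if (length(pk)) {
      m <- do.call(rbind, lapply(strsplit(trimws(pk), "\\s+"),
                                 function(p) as.numeric(p[1:2])))
      m
    } else matrix(numeric(0), ncol = 2)
    kept <- kept + 1L
    out[[kept]] <- new_spectrum(title, pepmass, charge, rt, peaks)
  }
  out[seq_len(kept)]
}

#' Write spectra to MGF
#' @param spectra List of `Spectrum` objects.
#' @param path Output path.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", s$spectrum_id), con)
    writeLines(sprintf("PEPMASS=%.6f", s$precursor_mz), con)
    writeLines(sprintf("CHARGE=%d+", s$precursor_charge), con)
    if (!is.na(s$retention_time)) {
      writeLines(sprintf("RTINSECONDS=%.3f", s$retention_time * 60), con)
    }
    if (nrow(s$peaks)) {
      writeLines(sprintf("%.5f %.4f", s$peaks[, 1], s$peaks[, 2]), con)
    }
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Index spectra by spectrum_id
#' @param spectra List of `Spectrum` objects.
#' @return Named list keyed by `spectrum_id`.
#' @export
spectra_index <- function(spectra) {
  setNames(spectra, vapply(spectra, `[[`, character(1), "spectrum_id"))
}

PSM_REQUIRED_COLUMNS <- c(
  "sample_id", "spectrum_id", "peptide_sequence", "modifications", "charge",
  "precursor_mz_observed", "retention_time_min", "score",
  "identity_threshold", "homology_threshold", "protein_accessions",
  "is_decoy")

#' Read peptide/protein identifications
#'
#' Dispatches on `format_hint`:
#' \describe{
#'   \item{`csv`}{The canonical PSM CSV dialect (see Details); returns a PSM
#'     data frame.}
#'   \item{`pepxml`}{pepXML `spectrum_query`/`search_hit` records; returns a
#'     PSM data frame.  The `mod_aminoacid_mass` mass attribute is read as
#'     the modification mass delta and named via a small table of common
#'     modifications (phospho, oxidation, ...) at +-0.01 Da.}
#'   \item{`protxml`}{protXML protein groups; returns a protein data frame
#'     (`accession`, `description`, `probability`, `coverage_fraction`,
#'     `peptides` semicolon-joined).}
#' }
#'
#' @details The canonical CSV carries one PSM per row with required columns
#' `sample_id, spectrum_id, peptide_sequence, modifications ("pos:mass"
#' semicolon list), charge, precursor_mz_observed, retention_time_min,
#' score, identity_threshold, homology_threshold, protein_accessions
#' (semicolon list), is_decoy (0/1)` and optional `reporter_113` ...
#' `reporter_121`, `heavy_light_ratio`, `phospho_rs` ("pos:prob" list) and
#' `intensity` columns.
#'
#' @param path Input file.
#' @param format_hint One of `"csv"`, `"pepxml"`, `"protxml"`.
#' @param decoy_prefix Accession prefix marking decoy entries (also sets
#'   `is_decoy` for pepXML input).
#' @return A PSM data frame or (for protXML) a protein data frame.
#' @export
read_identifications <- function(path, format_hint = c("csv", "pepxml", "protxml"),
                                 decoy_prefix = "DECOY_") {
  format_hint <- match.arg(format_hint)
  switch(format_hint,
         csv = read_psm_csv(path, decoy_prefix),
         pepxml = read_pepxml(path, decoy_prefix),
         protxml = read_protxml(path))
}

read_psm_csv <- function(path, decoy_prefix = "DECOY_") {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(spectrum_id = "character"))
  missing_cols <- setdiff(PSM_REQUIRED_COLUMNS, names(d))
  if (length(missing_cols)) {
    stop("canonical PSM CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  d$is_decoy <- as.logical(as.integer(d$is_decoy))
  for (col in c("sample_id", "peptide_sequence", "modifications",
                "protein_accessions", "phospho_rs")) {
    if (col %in% names(d)) {
      d[[col]] <- as.character(d[[col]])
      d[[col]][is.na(d[[col]])] <- ""
    }
  }
  d$charge <- as.integer(d$charge)
  # prefix convention backs up the explicit flag
  pref <- startsWith(d$protein_accessions, decoy_prefix)
  d$is_decoy <- d$is_decoy | pref
  d
}

#' Write a PSM data frame as canonical CSV
#' @param psms PSM data frame.
#' @param path Output path.
#' @export
write_psm_csv <- function(psms, path) {
  out <- psms
  out$is_decoy <- as.integer(out$is_decoy)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_pepxml <- function(path, decoy_prefix = "DECOY_") {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_strip(doc)
  queries <- xml2::xml_find_all(doc, ".//spectrum_query")
  rows <- lapply(queries, function(q) {
    hit <- xml2::xml_find_first(q, ".//search_hit")
    if (is.na(hit)) return(NULL)
    score_of <- function(nm) {
      node <- xml2::xml_find_first(
        hit, sprintf(".//search_score[@name='%s']", nm))
      if (is.na(node)) NA_real_ else as.numeric(xml2::xml_attr(node, "value"))
    }
    mods <- xml2::xml_find_all(hit, ".//mod_aminoacid_mass")
    mod_str <- if (length(mods)) {
      paste(sprintf("%d:%.6f",
                    as.integer(xml2::xml_attr(mods, "position")),
                    as.numeric(xml2::xml_attr(mods, "mass"))),
            collapse = ";")
    } else ""
    accs <- c(xml2::xml_attr(hit, "protein"),
              xml2::xml_attr(xml2::xml_find_all(hit, ".//alternative_protein"),
                             "protein"))
    accs <- accs[!is.na(accs)]
    rt_sec <- as.numeric(xml2::xml_attr(q, "retention_time_sec"))
    z <- as.integer(xml2::xml_attr(q, "assumed_charge"))
    neutral <- as.numeric(xml2::xml_attr(q, "precursor_neutral_mass"))
    data.frame(
      sample_id = xml2::xml_attr(q, "spectrum"),
      spectrum_id = xml2::xml_attr(q, "spectrum"),
      peptide_sequence = xml2::xml_attr(hit, "peptide"),
      modifications = mod_str,
      charge = z,
      precursor_mz_observed = if (is.na(neutral)) NA_real_ else
        (neutral + z * PROTON_MASS) / z,
      retention_time_min = if (is.na(rt_sec)) NA_real_ else rt_sec / 60,
      score = score_of("ionscore"),
      identity_threshold = score_of("identityscore"),
      homology_threshold = score_of("homologyscore"),
      protein_accessions = paste(accs, collapse = ";"),
      is_decoy = all(startsWith(accs, decoy_prefix)),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

read_protxml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  prots <- xml2::xml_find_all(doc, ".//protein_group/protein")
  rows <- lapply(prots, function(p) {
    peps <- xml2::xml_attr(xml2::xml_find_all(p, ".//peptide"),
                           "peptide_sequence")
    desc_node <- xml2::xml_find_first(p, ".//annotation")
    cov <- as.numeric(xml2::xml_attr(p, "percent_coverage"))
    data.frame(
      accession = xml2::xml_attr(p, "protein_name"),
      description = if (is.na(desc_node)) "" else
        xml2::xml_attr(desc_node, "protein_description"),
      probability = as.numeric(xml2::xml_attr(p, "probability")),
      coverage_fraction = if (is.na(cov)) NA_real_ else cov / 100,
      distinct_peptide_count = length(unique(peps)),
      peptides = paste(unique(peps), collapse = ";"),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

LIB_ENTRY_COLUMNS <- c("entry_id", "peptide_sequence", "modifications",
                       "charge", "precursor_mz", "retention_time_median",
                       "best_score", "identity_threshold",
                       "homology_threshold", "observation_count",
                       "best_spectrum_id", "source_sample_ids",
                       "protein_accessions")

#' Write a curated spectral library
#'
#' Single-file relational text store with `[entries]`, `[peaks]` and
#' `[uniqueness]` tab-separated sections; one row per curated entry with its
#' modified-sequence key, charge, precursor m/z, median retention time,
#' observation (copy) count and the best replicate's peak array.
#' `read_library(write_library(x))` reproduces `x` field-for-field.
#'
#' @param entries Library entry data frame from [curate_library()] (may be
#'   empty); optional `peaks` list-column and `uniqueness` attribute are
#'   serialized when present.
#' @param path Output path.
#' @export
write_library <- function(entries, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# pepflow spectral library v1", con)
  writeLines("[entries]", con)
  writeLines(paste(LIB_ENTRY_COLUMNS, collapse = "\t"), con)
  n <- nrow(entries)
  if (n) {
    for (i in seq_len(n)) {
      e <- entries[i, ]
      writeLines(paste(
        i, e$peptide_sequence, e$modifications, e$charge,
        sprintf("%.17g", e$precursor_mz),
        sprintf("%.17g", e$retention_time_median),
        sprintf("%.17g", e$best_score),
        sprintf("%.17g", e$identity_threshold),
        sprintf("%.17g", e$homology_threshold),
        e$observation_count, e$best_spectrum_id,
        e$source_sample_ids, e$protein_accessions,
        sep = "\t"), con)
    }
  }
  writeLines("[peaks]", con)
  writeLines("entry_id\tmz\tintensity", con)
  if (n && !is.null(entries$peaks)) {
    for (i in seq_len(n)) {
      pk <- entries$peaks[[i]]
      if (is.null(pk) || !nrow(pk)) next
      writeLines(sprintf("%d\t%.17g\t%.17g", i, pk[, 1], pk[, 2]), con)
    }
  }
  writeLines("[uniqueness]", con)
  writeLines("entry_id\tspecies\tmatching_accessions\tis_unique", con)
  uq <- attr(entries, "uniqueness")
  if (!is.null(uq) && nrow(uq)) {
    writeLines(paste(uq$entry_id, uq$species, uq$matching_accessions,
                     as.integer(uq$is_unique), sep = "\t"), con)
  }
  invisible(path)
}

#' Read a spectral library written by [write_library()]
#' @param path Library file path.
#' @return Library entry data frame with `peaks` list-column and (when
#'   present) a `uniqueness` attribute.
#' @export
read_library <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sec <- function(name) {
    i <- match(paste0("[", name, "]"), lines)
    stopifnot(!is.na(i))
    j <- grep("^\\[", lines)
    j <- j[j > i]
    end <- if (length(j)) min(j) - 1L else length(lines)
    lines[(i + 1L):end]
  }
  parse_tsv <- function(txt) {
    utils::read.delim(text = paste(txt, collapse = "\n"),
                      stringsAsFactors = FALSE)
  }
  entries <- parse_tsv(sec("entries"))
  entries$modifications <- ifelse(is.na(entries$modifications), "",
                                  as.character(entries$modifications))
  peaks_df <- parse_tsv(sec("peaks"))
  uq <- parse_tsv(sec("uniqueness"))
  entries$peaks <- lapply(entries$entry_id, function(id) {
    p <- peaks_df[peaks_df$entry_id == id, c("mz", "intensity"), drop = FALSE]
    m <- as.matrix(p)
    dimnames(m) <- list(NULL, c("mz", "intensity"))
    m
  })
  entries$entry_id <- NULL
  if (nrow(uq)) {
    uq$is_unique <- as.logical(uq$is_unique)
    attr(entries, "uniqueness") <- uq
  }
  entries
}

TRANSITION_COLUMNS <- c("protein_accession", "peptide_sequence",
                        "modified_sequence", "precursor_charge",
                        "precursor_mz", "fragment_type", "fragment_index",
                        "fragment_charge", "product_mz", "intensity_rank",
                        "retention_time_min")

#' Write an MRM/SRM transition list as TSV
#'
#' Header row plus one row per transition; m/z values printed with 4 decimal
#' places (triple-quadrupole method precision).
#'
#' @param transitions Transition data frame from [build_method()] /
#'   [select_transitions()].
#' @param path Output path.
#' @export
write_transitions_tsv <- function(transitions, path) {
  stopifnot(nrow(transitions) >= 1)
  out <- transitions[, TRANSITION_COLUMNS]
  out$precursor_mz <- sprintf("%.4f", out$precursor_mz)
  out$product_mz <- sprintf("%.4f", out$product_mz)
  out$retention_time_min <- sprintf("%.3f", out$retention_time_min)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a transition TSV written by [write_transitions_tsv()]
#' @param path Input path.
#' @return Transition data frame.
#' @export
read_transitions_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  d$modified_sequence <- as.character(d$modified_sequence)
  d
}
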