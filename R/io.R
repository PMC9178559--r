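#' Construct a spectra table
#'
#' The package-wide container for peak lists is a tibble with one row per
#' scan and a `peaks` list column of `(mz, intensity)` tibbles, sorted
#' ascending by m/z. MS3 scans carry their parent MS2 scan id and the
#' selected precursor m/z from the trigger.
#'
#' @param scan_id Character scan identifiers.
#' @param ms_level Integer, 2 or 3.
#' @param precursor_mz Precursor m/z.
#' @param precursor_charge Integer precursor charge (0 = unknown).
#' @param peaks List of tibbles/data.frames with `mz` and `intensity`.
#' @param retention_time Optional retention time in seconds.
#' @param parent_scan_id Parent MS2 scan id (MS3 only).
#' @param selected_precursor_mz Doublet peak m/z selected for MS3.
#' @return A tibble of class `xl_spectra`.
#' @export
xl_spectra <- function(scan_id, ms_level = 2L, precursor_mz,
                       precursor_charge, peaks,
                       retention_time = NA_real_,
                       parent_scan_id = NA_character_,
                       selected_precursor_mz = NA_real_) {
  peaks <- lapply(peaks, function(p) {
    if (is.null(p) || NROW(p) == 0)
      return(tibble::tibble(mz = numeric(), intensity = numeric()))
    p <- tibble::as_tibble(as.data.frame(p)[, c("mz", "intensity")])
    if (nrow(p) > 0) {
      stopifnot(all(p$mz > 0), all(p$intensity >= 0))
      p <- p[order(p$mz), ]
    }
    p
  })
  out <- tibble::tibble(
    scan_id = as.character(scan_id),
    ms_level = as.integer(ms_level),
    precursor_mz = as.numeric(precursor_mz),
    precursor_charge = as.integer(precursor_charge),
    retention_time = as.numeric(retention_time),
    parent_scan_id = as.character(parent_scan_id),
    selected_precursor_mz = as.numeric(selected_precursor_mz),
    peaks = peaks
  )
  bad <- out$ms_level == 3L &
    (is.na(out$parent_scan_id) | is.na(out$selected_precursor_mz))
  if (any(bad))
    stop("MS3 scans need parent_scan_id and selected_precursor_mz: ",
         paste(out$scan_id[bad], collapse = ", "), call. = FALSE)
  class(out) <- c("xl_spectra", class(out))
  out
}

#' Read an MGF peak-list file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks. `PEPMASS` (first field) gives
#' the precursor m/z, `CHARGE` is parsed with its sign, `RTINSECONDS` the
#' retention time. Because standard MGF has no MS3 linkage fields, the
#' TITLE line carries `key=value` tokens: `scan=<id> mslevel=<n>`
#' and, for MS3 scans, `parent=<id> selected_mz=<x>`. Peak rows are
#' re-sorted ascending by m/z if needed.
#'
#' @param path Path to an MGF file.
#' @return An [xl_spectra()] tibble.
#' @export
parse_mgf <- function(path) {
  lines <- readLines(path)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins))
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS", call. = FALSE)
  if (length(begins) == 0) {
    return(xl_spectra(character(), integer(), numeric(), integer(), list()))
  }
  parse_block <- function(k) {
    block <- lines[(begins[k] + 1L):(ends[k] - 1L)]
    is_header <- grepl("^[A-Z]+=", block)
    headers <- block[is_header]
    key <- sub("=.*$", "", headers)
    val <- sub("^[A-Z]+=", "", headers)
    h <- stats::setNames(as.list(val), key)
    if (is.null(h$PEPMASS))
      stop("malformed MGF block ", k, ": missing PEPMASS", call. = FALSE)
    pepmass <- as.numeric(strsplit(trimws(h$PEPMASS), "\\s+")[[1]][1])
    charge <- 0L
    if (!is.null(h$CHARGE)) {
      ch <- trimws(h$CHARGE)
      sign <- if (grepl("-", ch)) -1L else 1L
      charge <- sign * as.integer(gsub("[^0-9]", "", ch))
    }
    rt <- if (!is.null(h$RTINSECONDS)) as.numeric(h$RTINSECONDS) else NA_real_
    tokens <- list()
    if (!is.null(h$TITLE)) {
      tk <- strsplit(trimws(h$TITLE), "\\s+")[[1]]
      tk <- tk[grepl("=", tk)]
      tokens <- stats::setNames(
        as.list(sub("^[^=]*=", "", tk)), sub("=.*$", "", tk))
    }
    peak_lines <- block[!is_header & nzchar(trimws(block))]
    if (length(peak_lines)) {
      fields <- strsplit(trimws(peak_lines), "\\s+")
      mzv <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 1)))
      iv <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2)))
      if (anyNA(mzv) || anyNA(iv)) {
        bad <- which(is.na(mzv) | is.na(iv))[1]
        stop("non-numeric peak line in MGF block ", k, " (line ",
             begins[k] + which(!is_header)[bad], ")", call. = FALSE)
      }
      pk <- tibble::tibble(mz = mzv, intensity = iv)
    } else {
      pk <- tibble::tibble(mz = numeric(), intensity = numeric())
    }
    list(
      scan_id = tokens$scan %||% as.character(k),
      ms_level = as.integer(tokens$mslevel %||% 2L),
      precursor_mz = pepmass,
      precursor_charge = charge,
      retention_time = rt,
      parent_scan_id = tokens$parent %||% NA_character_,
      selected_precursor_mz =
        if (!is.null(tokens$selected_mz)) as.numeric(tokens$selected_mz)
        else NA_real_,
      peaks = pk
    )
  }
  blocks <- lapply(seq_along(begins), parse_block)
  xl_spectra(
    scan_id = vapply(blocks, `[[`, "", "scan_id"),
    ms_level = vapply(blocks, `[[`, integer(1), "ms_level"),
    precursor_mz = vapply(blocks, `[[`, numeric(1), "precursor_mz"),
    precursor_charge = vapply(blocks, `[[`, integer(1), "precursor_charge"),
    retention_time = vapply(blocks, `[[`, numeric(1), "retention_time"),
    parent_scan_id = vapply(blocks, `[[`, "", "parent_scan_id"),
    selected_precursor_mz =
      vapply(blocks, `[[`, numeric(1), "selected_precursor_mz"),
    peaks = lapply(blocks, `[[`, "peaks")
  )
}

#' Write spectra to an MGF file
#'
#' Inverse of [parse_mgf()]: writes one `BEGIN IONS` block per scan with
#' TITLE tokens for scan id, MS level and (for MS3) parent linkage, so
#' that `parse_mgf(serialize_mgf(x))` is the identity on all typed fields.
#'
#' @param spectra An [xl_spectra()] tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
serialize_mgf <- function(spectra, path) {
  fmt <- function(x) sprintf("%.12g", x)
  blocks <- vapply(seq_len(nrow(spectra)), function(i) {
    s <- spectra[i, ]
    title <- paste0("scan=", s$scan_id, " mslevel=", s$ms_level)
    if (!is.na(s$parent_scan_id))
      title <- paste0(title, " parent=", s$parent_scan_id,
                      " selected_mz=", fmt(s$selected_precursor_mz))
    hdr <- c(
      "BEGIN IONS",
      paste0("TITLE=", title),
      paste0("PEPMASS=", fmt(s$precursor_mz)),
      paste0("CHARGE=", abs(s$precursor_charge),
             if (s$precursor_charge < 0) "-" else "+"),
      if (!is.na(s$retention_time))
        paste0("RTINSECONDS=", fmt(s$retention_time))
    )
    pk <- s$peaks[[1]]
    pk <- pk[order(pk$mz), ]
    paste(c(hdr, paste(fmt(pk$mz), fmt(pk$intensity)), "END IONS"),
          collapse = "\n")
  }, character(1))
  writeLines(blocks, path)
  invisible(path)
}

#' Read a protein FASTA database
#'
#' Wraps `Biostrings::readAAStringSet()`. Records whose sequence contains
#' a non-canonical letter are dropped with a warning naming the accession.
#' Accessions carrying `decoy_prefix` are marked as decoys.
#'
#' @param path FASTA file path.
#' @param decoy_prefix Accession prefix marking decoy records.
#' @return A tibble with `accession`, `sequence`, `is_decoy`.
#' @export
read_fasta <- function(path, decoy_prefix = "REV_") {
  ss <- Biostrings::readAAStringSet(path)
  acc <- sub("\\s.*$", "", names(ss))
  seqs <- as.character(ss)
  ok <- !grepl(paste0("[^", paste(names(AA_MONO_MASS), collapse = ""), "]"),
               seqs)
  if (any(!ok))
    warning("dropping records with non-canonical residues: ",
            paste(acc[!ok], collapse = ", "), call. = FALSE)
  tibble::tibble(
    accession = acc[ok],
    sequence = unname(seqs[ok]),
    is_decoy = startsWith(acc[ok], decoy_prefix)
  )
}

#' Write a protein table to FASTA
#'
#' @param proteins Tibble with `accession` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  ss <- Biostrings::AAStringSet(stats::setNames(proteins$sequence,
                                                proteins$accession))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Apply a global ppm recalibration to spectra
#'
#' Removes systematic mass error: every precursor m/z is multiplied by
#' `(1 - ms1_ppm_shift * 1e-6)` and every fragment m/z by
#' `(1 - ms2_ppm_shift * 1e-6)`; intensities are untouched. The shifts
#' are typically the median precursor/fragment mass errors of a first-pass
#' search, so that the median error after recalibration is ~0 ppm.
#'
#' @param spectra An [xl_spectra()] tibble.
#' @param ms1_ppm_shift,ms2_ppm_shift Systematic errors to remove (ppm).
#' @return The recalibrated spectra.
#' @export
recalibrate_spectra <- function(spectra, ms1_ppm_shift, ms2_ppm_shift) {
  stopifnot(is.finite(ms1_ppm_shift), is.finite(ms2_ppm_shift))
  f1 <- 1 - ms1_ppm_shift * 1e-6
  f2 <- 1 - ms2_ppm_shift * 1e-6
  spectra$precursor_mz <- spectra$precursor_mz * f1
  spectra$selected_precursor_mz <- spectra$selected_precursor_mz * f2
  spectra$peaks <- lapply(spectra$peaks, function(p) {
    p$mz <- p$mz * f2
    p
  })
  spectra
}

# mandatory columns of the CSM table interchange format
CSM_TABLE_COLUMNS <- c(
  "csm_id", "scan_id", "alpha_seq", "beta_seq", "alpha_mod", "beta_mod",
  "site_alpha", "site_beta", "charge", "score", "delta_score",
  "matched_frags_alpha", "matched_frags_beta",
  "alpha_is_decoy", "beta_is_decoy", "alpha_acc", "beta_acc",
  "self_link", "doublet_class", "coverage_alpha", "coverage_beta",
  "noncovalent_flag"
)

#' Read / write CSM tables
#'
#' Crosslink-spectrum-match tables are exchanged as TSV with a fixed
#' mandatory column set (peptide sequences and modifications, 1-based
#' link sites, precursor charge, score and delta score, per-peptide
#' matched fragment counts, target/decoy flags, protein accessions,
#' self/heteromeric flag, doublet class, per-peptide total coverage, and
#' the noncovalent flag). Extra columns round-trip unharmed.
#'
#' @param csms A CSM tibble.
#' @param path File path.
#' @return `read_csm_table()` returns the tibble; `write_csm_table()`
#'   returns `path` invisibly.
#' @export
write_csm_table <- function(csms, path) {
  missing <- setdiff(CSM_TABLE_COLUMNS, names(csms))
  if (length(missing))
    stop("CSM table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  keep <- vapply(csms, function(x) is.atomic(x) && !is.matrix(x), logical(1))
  readr::write_tsv(csms[, keep], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_csm_table
#' @export
read_csm_table <- function(path) {
  csms <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(CSM_TABLE_COLUMNS, names(csms))
  if (length(missing))
    stop("CSM table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  csms
}
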