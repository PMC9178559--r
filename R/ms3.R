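#' Classify an MS3 trigger against its parent annotation
#'
#' The selected MS3 precursor m/z is compared, within `ppm_tol`, with the
#' observed m/z of the matched intact-peptide (P-ion) stub fragments of
#' the parent MS2 CSM: a hit means the trigger correctly selected a
#' crosslinked-peptide stub peak (`correct_stub`). Otherwise the
#' precursor is compared with linear candidate peptides, unmodified
#' (`linear_peptide`) or carrying a hydrolyzed/amidated crosslinker
#' dead-end (`crosslinker_modified_linear`), at charges 1..3. Anything
#' else is `unmatched`.
#'
#' @param ms3 One row of an [xl_spectra()] tibble with `ms_level == 3`.
#' @param parent_matches Match tibble of the parent MS2 CSM.
#' @param linear_candidates Optional tibble of linear peptides (needs
#'   `sequence`) checked for false triggers.
#' @param crosslinker The [crosslinker()] in use.
#' @param ppm_tol Tolerance in ppm (default 20).
#' @return One-row tibble: `ms3_scan_id`, `outcome`, `matched_owner`,
#'   `matched_stub`, `ppm_error`.
#' @export
classify_ms3_trigger <- function(ms3, parent_matches,
                                 linear_candidates = NULL,
                                 crosslinker = xl_dsso(), ppm_tol = 20) {
  stopifnot(nrow(ms3) == 1, ms3$ms_level == 3L)
  if (is.na(ms3$parent_scan_id))
    stop("MS3 scan ", ms3$scan_id, " has no parent scan id", call. = FALSE)
  sel <- ms3$selected_precursor_mz
  res <- tibble::tibble(
    ms3_scan_id = ms3$scan_id, outcome = "unmatched",
    matched_owner = NA_character_, matched_stub = NA_character_,
    ppm_error = NA_real_
  )
  stubs <- dplyr::filter(parent_matches, .data$series == "P",
                         .data$loss == "none",
                         !.data$stub %in% c("none", "+P"))
  if (nrow(stubs) > 0) {
    ppm <- (sel - stubs$matched_mz) / stubs$matched_mz * 1e6
    j <- which.min(abs(ppm))
    if (abs(ppm[j]) <= ppm_tol) {
      res$outcome <- "correct_stub"
      res$matched_owner <- stubs$owner[j]
      res$matched_stub <- stubs$stub[j]
      res$ppm_error <- ppm[j]
      return(res)
    }
  }
  if (!is.null(linear_candidates) && nrow(linear_candidates) > 0) {
    M <- peptide_mass(linear_candidates$sequence)
    variants <- rbind(
      cbind(M, 0),                                   # unmodified
      cbind(M + crosslinker$hydrolyzed_mod, 1),
      cbind(M + crosslinker$amidated_mod, 1)
    )
    for (z in 1:3) {
      mzv <- mz_of(variants[, 1], z)
      ppm <- (sel - mzv) / mzv * 1e6
      j <- which.min(abs(ppm))
      if (abs(ppm[j]) <= ppm_tol) {
        res$outcome <- if (variants[j, 2] == 1)
          "crosslinker_modified_linear" else "linear_peptide"
        res$ppm_error <- ppm[j]
        return(res)
      }
    }
  }
  res
}

#' Summarise MS3 trigger correctness over CSMs
#'
#' @param classifications Tibble of per-MS3 classifications (from
#'   [classify_ms3_trigger()]) with an added `csm_id` column.
#' @param csm_ids All CSM ids considered (CSMs without MS3 scans count as
#'   zero correctly triggered peptides).
#' @return A list with `proportions` (tibble over 0/1/2 correctly
#'   triggered peptides; sums to 1) and `ms3_per_parent` (mean number of
#'   MS3 scans per parent, split by parent match type).
#' @export
trigger_summary <- function(classifications, csm_ids) {
  per_csm <- vapply(csm_ids, function(id) {
    cl <- classifications[classifications$csm_id == id &
                            classifications$outcome == "correct_stub", ]
    length(unique(cl$matched_owner))
  }, integer(1))
  proportions <- tibble::tibble(
    n_correct = 0:2,
    proportion = vapply(0:2, function(k) mean(per_csm == k), numeric(1))
  )
  counts <- vapply(csm_ids, function(id)
    sum(classifications$csm_id == id), integer(1))
  list(
    proportions = proportions,
    per_csm_correct = tibble::tibble(csm_id = csm_ids, n_correct = per_csm,
                                     n_ms3 = counts)
  )
}

#' Combined MS2 + MS3 sequence coverage
#'
#' Union of the matched (series, cleavage position) sets from the parent
#' MS2 annotation and all correctly triggered MS3 scans assigned to the
#' same peptide, over the same `2 * (L - 1)` denominator. MS3 scans whose
#' trigger classification is not `correct_stub` contribute nothing.
#'
#' @param ms2_matches Match tibble of the MS2 CSM.
#' @param ms3_matches List of match tibbles from annotating MS3 scans
#'   (against [linear_stub_fragments()] of the triggered peptide).
#' @param ms3_outcomes Character vector of trigger outcomes, parallel to
#'   `ms3_matches`.
#' @param peptide_length Length of the peptide under evaluation.
#' @param owner Which peptide of the pair.
#' @return One-row coverage tibble as from [sequence_coverage()].
#' @export
combined_coverage <- function(ms2_matches, ms3_matches = list(),
                              ms3_outcomes = character(),
                              peptide_length, owner = "alpha") {
  keep <- ms3_matches[ms3_outcomes == "correct_stub"]
  cols <- c("owner", "series", "index", "stub", "contains_link_site")
  all_m <- dplyr::bind_rows(
    c(list(ms2_matches[, intersect(cols, names(ms2_matches))]),
      lapply(keep, function(m) m[, intersect(cols, names(m))]))
  )
  sequence_coverage(all_m, peptide_length, owner = owner)
}
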