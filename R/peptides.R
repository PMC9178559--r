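#' In-silico tryptic digestion
#'
#' Cleaves protein sequences C-terminally of K/R, except before proline,
#' and enumerates all peptides with up to `max_missed` missed cleavage
#' sites. Positions are 1-based.
#'
#' @param proteins A tibble with columns `accession`, `sequence` and
#'   optionally `is_decoy` (as returned by [read_fasta()]), or a single
#'   character sequence.
#' @param max_missed Maximum number of missed cleavages (default 2).
#' @param length_range Numeric `c(min, max)` peptide length filter;
#'   `NULL` disables the filter.
#' @return A tibble with one row per peptide occurrence: `sequence`,
#'   `accession`, `start` (1-based position in the protein), `length`,
#'   `missed_cleavages`, `is_decoy`, `protein_nterm` (does the peptide
#'   start at the protein N-terminus).
#' @export
#' @examples
#' tryptic_digest("MKRA", max_missed = 2, length_range = NULL)
tryptic_digest <- function(proteins, max_missed = 2, length_range = c(6, 30)) {
  stopifnot(max_missed >= 0)
  if (is.character(proteins)) {
    proteins <- tibble::tibble(
      accession = paste0("seq", seq_along(proteins)),
      sequence = proteins, is_decoy = FALSE
    )
  }
  if (!"is_decoy" %in% names(proteins)) proteins$is_decoy <- FALSE

  digest_one <- function(accession, sequence, is_decoy) {
    res <- strsplit(sequence, "")[[1]]
    n <- length(res)
    # cleavage after position i if residue i is K/R and residue i+1 not P
    cut_after <- which(res[-n] %in% c("K", "R") & res[-1] != "P")
    bounds <- c(0L, cut_after, n)            # segment boundaries
    ns <- length(bounds) - 1L
    out <- vector("list", 0L)
    for (i in seq_len(ns)) {
      for (mc in 0:min(max_missed, ns - i)) {
        from <- bounds[i] + 1L
        to <- bounds[i + mc + 1L]
        out[[length(out) + 1L]] <- c(from, to, mc)
      }
    }
    m <- do.call(rbind, out)
    tibble::tibble(
      sequence = substring(sequence, m[, 1], m[, 2]),
      accession = accession,
      start = as.integer(m[, 1]),
      length = as.integer(m[, 2] - m[, 1] + 1L),
      missed_cleavages = as.integer(m[, 3]),
      is_decoy = is_decoy,
      protein_nterm = m[, 1] == 1L
    )
  }

  peps <- purrr::pmap(
    list(proteins$accession, proteins$sequence, proteins$is_decoy),
    digest_one
  )
  peps <- dplyr::bind_rows(peps)
  if (!is.null(length_range)) {
    peps <- dplyr::filter(peps,
                          .data$length >= length_range[1],
                          .data$length <= length_range[2])
  }
  peps
}

#' Monoisotopic peptide mass
#'
#' Neutral monoisotopic mass: sum of residue masses + H2O + fixed
#' modifications + any variable modification deltas.
#'
#' @param sequence Character vector of peptide sequences.
#' @param mod_mass Numeric vector (recycled) of total variable-modification
#'   mass to add per peptide (Da).
#' @param fixed_mods Named numeric vector of per-residue fixed
#'   modifications; default carbamidomethylated cysteine (+57.021464 Da).
#' @return Numeric vector of neutral masses (Da).
#' @export
#' @examples
#' peptide_mass("GG")
peptide_mass <- function(sequence, mod_mass = 0,
                         fixed_mods = c(C = CARBAMIDOMETHYL_MASS)) {
  masses <- AA_MONO_MASS
  if (length(fixed_mods))
    masses[names(fixed_mods)] <- masses[names(fixed_mods)] + fixed_mods
  vapply(seq_along(sequence), function(i) {
    res <- strsplit(sequence[i], "")[[1]]
    m <- masses[res]
    if (anyNA(m)) {
      bad <- unique(res[is.na(m)])
      stop("unknown residue(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    sum(m) + H2O_MASS + rep_len(mod_mass, length(sequence))[i]
  }, numeric(1))
}

#' Mass-to-charge ratio of an ion
#'
#' @param neutral_mass Neutral mass (Da).
#' @param charge Positive integer charge.
#' @return m/z in Da per elementary charge.
#' @export
mz_of <- function(neutral_mass, charge) {
  stopifnot(all(charge >= 1))
  (neutral_mass + charge * PROTON_MASS) / charge
}

#' Enumerate variable modification forms of peptides
#'
#' Returns, for each input peptide, the unmodified form plus every variant
#' carrying exactly one modification from the catalog at one compatible
#' site (at most one variable modification per peptide). Crosslinker
#' dead-end modifications are restricted to lysine side chains and the
#' protein N-terminus.
#'
#' @param peptides Tibble as from [tryptic_digest()] (needs `sequence`,
#'   `protein_nterm`).
#' @param mod_catalog Tibble with columns `label`, `residues`, `mass`,
#'   `nterm` (see [default_mod_catalog()]).
#' @return The input peptides replicated per modification form, with
#'   added columns `mod_label` (`""` if unmodified), `mod_position`
#'   (0 = N-terminus) and `mod_mass`.
#' @export
enumerate_variable_mods <- function(peptides, mod_catalog = default_mod_catalog()) {
  if (!"protein_nterm" %in% names(peptides)) peptides$protein_nterm <- FALSE
  one <- function(row) {
    res <- strsplit(row$sequence, "")[[1]]
    forms <- list(tibble::tibble(mod_label = "", mod_position = NA_integer_,
                                 mod_mass = 0))
    for (j in seq_len(nrow(mod_catalog))) {
      spec <- mod_catalog[j, ]
      sites <- which(res %in% strsplit(spec$residues, "")[[1]])
      if (spec$nterm && row$protein_nterm) sites <- c(0L, sites)
      if (length(sites)) {
        forms[[length(forms) + 1L]] <- tibble::tibble(
          mod_label = spec$label,
          mod_position = as.integer(sites),
          mod_mass = spec$mass
        )
      }
    }
    forms <- dplyr::bind_rows(forms)
    dplyr::bind_cols(row[rep(1, nrow(forms)), ], forms)
  }
  dplyr::bind_rows(lapply(seq_len(nrow(peptides)), function(i) one(peptides[i, ])))
}

#' Crosslink search-space size
#'
#' Number of candidate crosslinked peptide pairs that n linear peptides
#' generate: all unordered pairs including self-pairs, (n^2 + n) / 2.
#'
#' @param n Number of linear peptides in the database.
#' @return Number of candidate pairs.
#' @export
#' @examples
#' search_space_size(1000)
search_space_size <- function(n) {
  stopifnot(all(n >= 0))
  (n^2 + n) / 2
}
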