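#' Deisotope a peak list
#'
#' Greedy envelope clustering: peaks are visited as seeds in order of
#' decreasing intensity; for each unassigned seed and each charge
#' `z = 1..max_charge`, consecutive isotope positions
#' `seed + k * 1.0033548378 / z` (k = 1, 2, ...) are searched within
#' `ppm_tol`, requiring non-increasing member intensity. The charge that
#' recruits the most isotope peaks wins (ties favour the lower charge).
#' The seed is reported as the monoisotopic peak with the summed envelope
#' intensity; peaks recruiting no isotopes pass through as singletons with
#' charge 0 (undetermined).
#'
#' @param peaks A tibble/data.frame with columns `mz` (ascending) and
#'   `intensity`, or one row of an [xl_spectra()] tibble.
#' @param ppm_tol Isotope-position tolerance in ppm (default 10).
#' @param max_charge Highest envelope charge considered (default 4).
#' @param max_iso Maximum number of isotope peaks recruited per envelope.
#' @return A tibble of deisotoped peaks: `mono_mz`, `charge`, `intensity`
#'   (summed over the envelope), `n_peaks`, and `member_mz` (list column
#'   of the raw member m/z values, monoisotopic first), ranked by
#'   [assign_ranks()].
#' @export
deisotope <- function(peaks, ppm_tol = 10, max_charge = 4L, max_iso = 6L) {
  peaks <- as.data.frame(peaks)[, c("mz", "intensity")]
  n <- nrow(peaks)
  if (n == 0) {
    return(assign_ranks(tibble::tibble(
      mono_mz = numeric(), charge = integer(), intensity = numeric(),
      n_peaks = integer(), member_mz = list()
    )))
  }
  o <- order(peaks$mz)
  mz <- peaks$mz[o]; int <- peaks$intensity[o]
  assigned <- rep(FALSE, n)
  seeds <- order(int, decreasing = TRUE)
  clusters <- vector("list", 0L)

  find_near <- function(target, tol_abs) {
    # index of nearest unassigned peak within tol_abs of target, or 0
    i <- findInterval(target, mz)
    best <- 0L; bestd <- Inf
    for (j in c(i, i + 1L)) {
      if (j >= 1L && j <= n && !assigned[j]) {
        d <- abs(mz[j] - target)
        if (d <= tol_abs && d < bestd) { best <- j; bestd <- d }
      }
    }
    best
  }

  for (s in seeds) {
    if (assigned[s]) next
    best_members <- integer(0)
    best_z <- 0L
    for (z in seq_len(max_charge)) {
      members <- integer(0)
      prev_int <- int[s]
      for (k in seq_len(max_iso)) {
        target <- mz[s] + k * ISOTOPE_SPACING / z
        j <- find_near(target, ppm_tol * 1e-6 * target)
        if (j == 0L || int[j] > prev_int) break
        members <- c(members, j)
        prev_int <- int[j]
      }
      if (length(members) > length(best_members)) {
        best_members <- members
        best_z <- z
      }
    }
    idx <- c(s, best_members)
    assigned[idx] <- TRUE
    clusters[[length(clusters) + 1L]] <- list(
      mono_mz = mz[s],
      charge = if (length(best_members)) best_z else 0L,
      intensity = sum(int[idx]),
      n_peaks = length(idx),
      member_mz = mz[idx]
    )
  }
  out <- tibble::tibble(
    mono_mz = vapply(clusters, `[[`, numeric(1), "mono_mz"),
    charge = vapply(clusters, `[[`, integer(1), "charge"),
    intensity = vapply(clusters, `[[`, numeric(1), "intensity"),
    n_peaks = vapply(clusters, `[[`, integer(1), "n_peaks"),
    member_mz = lapply(clusters, `[[`, "member_mz")
  )
  out <- out[order(out$mono_mz), ]
  assign_ranks(out)
}

#' Assign deisotoped intensity ranks
#'
#' Rank 1 is the most intense deisotoped peak; ties are broken by
#' ascending m/z. Ranks are a permutation of `1..n`.
#'
#' @param peaks Deisotoped peak tibble with `intensity` and `mono_mz`.
#' @return The same tibble with a `rank` column (existing ranks replaced).
#' @export
assign_ranks <- function(peaks) {
  peaks$rank <- NULL
  ord <- order(-peaks$intensity, peaks$mono_mz)
  r <- integer(nrow(peaks))
  r[ord] <- seq_len(nrow(peaks))
  peaks$rank <- r
  peaks
}

#' Match theoretical fragments to deisotoped peaks
#'
#' Each fragment is matched to the nearest compatible peak within
#' `ppm_tol`. Compatibility at the monoisotopic position requires the
#' envelope charge to equal the fragment charge or be undetermined (0).
#' When `match_members = TRUE` (default), a fragment may also match a
#' non-monoisotopic envelope member peak, charge-agnostically: greedy
#' deisotoping can absorb a genuine distinct ion that coincides with an
#' isotope position, and member matching recovers such ions while keeping
#' deisotoped ranks and intensities. Ties (two in-tolerance peaks) are
#' resolved by smaller absolute ppm error, then higher envelope intensity.
#' A peak may satisfy several isobaric fragments; such matches are flagged
#' `ambiguous`.
#'
#' @param peaks Deisotoped, ranked peak tibble from [deisotope()].
#' @param fragments Fragment tibble from [theoretical_fragments()].
#' @param ppm_tol Match tolerance in ppm.
#' @param match_members Allow matching envelope member peaks (see above).
#' @return A tibble of matches: all fragment columns plus `peak_id` (row
#'   index into `peaks`), `matched_mz`, `ppm_error`, `peak_intensity`
#'   (envelope summed intensity), `peak_charge`, `rank`, `via_member`,
#'   `ambiguous`.
#' @export
match_fragments <- function(peaks, fragments, ppm_tol, match_members = TRUE) {
  stopifnot(ppm_tol > 0)
  empty <- dplyr::mutate(fragments[0, ],
    peak_id = integer(), matched_mz = numeric(), ppm_error = numeric(),
    peak_intensity = numeric(), peak_charge = integer(), rank = integer(),
    via_member = logical(), ambiguous = logical())
  if (nrow(peaks) == 0 || nrow(fragments) == 0) return(empty)

  if (match_members) {
    cand_mz <- unlist(peaks$member_mz)
    reps <- lengths(peaks$member_mz)
    cand_peak <- rep(seq_len(nrow(peaks)), reps)
    cand_mono <- unlist(lapply(reps, function(k) c(TRUE, rep(FALSE, k - 1L))))
  } else {
    cand_mz <- peaks$mono_mz
    cand_peak <- seq_len(nrow(peaks))
    cand_mono <- rep(TRUE, nrow(peaks))
  }
  o <- order(cand_mz)
  cand_mz <- cand_mz[o]; cand_peak <- cand_peak[o]; cand_mono <- cand_mono[o]
  nc <- length(cand_mz)

  fmz <- fragments$mz
  fz <- fragments$charge
  lo <- findInterval(fmz * (1 - ppm_tol * 1e-6), cand_mz) + 1L
  hi <- findInterval(fmz * (1 + ppm_tol * 1e-6), cand_mz)

  res_peak <- integer(length(fmz)); res_mz <- numeric(length(fmz))
  res_ppm <- numeric(length(fmz)); res_member <- logical(length(fmz))
  for (i in seq_along(fmz)) {
    if (lo[i] > hi[i]) next
    js <- lo[i]:hi[i]
    ok <- !cand_mono[js] |
      peaks$charge[cand_peak[js]] == fz[i] |
      peaks$charge[cand_peak[js]] == 0L
    # charge-compatible candidates take precedence; in-tolerance peaks
    # with a conflicting envelope charge call remain eligible because
    # greedy deisotoping occasionally mis-assigns the charge of a peak
    # that coincides with another envelope's isotope spacing
    if (any(ok)) js <- js[ok]
    if (!length(js)) next
    ppm <- (cand_mz[js] - fmz[i]) / fmz[i] * 1e6
    best <- order(abs(ppm), -peaks$intensity[cand_peak[js]])[1]
    res_peak[i] <- cand_peak[js[best]]
    res_mz[i] <- cand_mz[js[best]]
    res_ppm[i] <- ppm[best]
    res_member[i] <- !cand_mono[js[best]]
  }
  hit <- res_peak > 0L
  if (!any(hit)) return(empty)
  out <- fragments[hit, ]
  out$peak_id <- res_peak[hit]
  out$matched_mz <- res_mz[hit]
  out$ppm_error <- res_ppm[hit]
  out$peak_intensity <- peaks$intensity[out$peak_id]
  out$peak_charge <- peaks$charge[out$peak_id]
  out$rank <- peaks$rank[out$peak_id]
  out$via_member <- res_member[hit]
  dup <- out$peak_id %in% out$peak_id[duplicated(out$peak_id)]
  out$ambiguous <- dup
  out
}
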