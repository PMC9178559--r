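#' Score a crosslink spectrum match
#'
#' A deliberately simple, fully declared score in `[0, 2]`: the fraction
#' of total deisotoped intensity explained by matched peaks plus the mean
#' of the two peptides' total sequence coverage, weighted 1:1. It is
#' deterministic given the annotation and monotone in the matched set.
#'
#' @param matches Match tibble from [match_fragments()].
#' @param peaks Deisotoped peak tibble the matches refer to.
#' @param pair The [crosslinked_pair()] being scored.
#' @return A list with `score`, `explained_intensity`, `mean_coverage`,
#'   `matched_frags_alpha`, `matched_frags_beta`.
#' @export
score_csm <- function(matches, peaks, pair) {
  total_int <- sum(peaks$intensity)
  expl <- if (nrow(matches) == 0 || total_int == 0) 0 else
    sum(peaks$intensity[unique(matches$peak_id)]) / total_int
  cov_total <- function(owner, L) {
    sel <- matches$owner == owner & matches$series != "P"
    if (!any(sel)) return(0)
    length(unique(paste0(matches$series[sel], matches$index[sel]))) /
      (2 * (L - 1))
  }
  cov_a <- cov_total("alpha", pair$alpha$length)
  cov_b <- cov_total("beta", pair$beta$length)
  list(
    score = expl + (cov_a + cov_b) / 2,
    explained_intensity = expl,
    coverage_alpha = cov_a,
    coverage_beta = cov_b,
    matched_frags_alpha = sum(matches$owner == "alpha"),
    matched_frags_beta = sum(matches$owner == "beta")
  )
}

#' Target/decoy class of CSMs
#'
#' @param alpha_is_decoy,beta_is_decoy Logical vectors.
#' @return Character vector: `"TT"`, `"TD"` or `"DD"`.
#' @export
td_class <- function(alpha_is_decoy, beta_is_decoy) {
  n <- alpha_is_decoy + beta_is_decoy
  c("TT", "TD", "DD")[n + 1L]
}

#' Pre-FDR quality filters
#'
#' Keeps CSMs with at least `min_fragments` matched fragments for each
#' peptide, a delta score strictly greater than `min_delta_frac` of the
#' match score, both peptide lengths of at least `min_length`, no peptide
#' sequence shared by two or more proteins (when `alpha_prot_count` /
#' `beta_prot_count` columns are present), and no noncovalent flag. The
#' filter is a pure conjunction of per-record predicates and therefore
#' idempotent.
#'
#' @param csms CSM tibble.
#' @param min_fragments Minimum matched fragments per peptide (default 3).
#' @param min_length Minimum peptide length (default 6).
#' @param min_delta_frac Required delta score as a fraction of the score
#'   (default 0.15, strict inequality).
#' @return The filtered CSM tibble.
#' @export
prefilter_csms <- function(csms, min_fragments = 3, min_length = 6,
                           min_delta_frac = 0.15) {
  keep <- csms$matched_frags_alpha >= min_fragments &
    csms$matched_frags_beta >= min_fragments &
    csms$delta_score > min_delta_frac * csms$score &
    nchar(csms$alpha_seq) >= min_length &
    nchar(csms$beta_seq) >= min_length
  if ("noncovalent_flag" %in% names(csms))
    keep <- keep & !csms$noncovalent_flag
  if (all(c("alpha_prot_count", "beta_prot_count") %in% names(csms)))
    keep <- keep & csms$alpha_prot_count <= 1 & csms$beta_prot_count <= 1
  csms[keep, ]
}

# order-normalized unique-CSM key: peptide pair (with modifications and
# link sites) plus precursor charge
csm_unique_key <- function(csms) {
  a <- paste0(csms$alpha_seq, "[", csms$alpha_mod, "]@", csms$site_alpha)
  b <- paste0(csms$beta_seq, "[", csms$beta_mod, "]@", csms$site_beta)
  paste0(pmin(a, b), "--", pmax(a, b), "/", csms$charge)
}

#' Grouped target-decoy FDR estimation
#'
#' CSMs are reduced to unique CSMs (best score per peptide-pair /
#' link-site / charge key), split into self and heteromeric groups, and
#' within each group the score axis is scanned from high to low. At each
#' candidate threshold t the FDR is estimated as
#' `max(0, TD - DD) / TT` over records with score >= t, then monotonized
#' into a q-value (the minimum estimated FDR over all thresholds at or
#' below t), so the achieved FDR is non-increasing as the threshold
#' rises. The reported threshold is the lowest score whose q-value does
#' not exceed `level`.
#'
#' @param csms CSM tibble with `score`, `alpha_is_decoy`, `beta_is_decoy`,
#'   `self_link`, and key columns (see [write_csm_table()]).
#' @param level Requested FDR level (default 0.05).
#' @param unique_csms Reduce to unique CSMs first (default `TRUE`).
#' @return An object of class `xl_fdr`: list with `groups` (per-group
#'   threshold, TT/TD/DD counts above threshold and achieved FDR) and
#'   `csms` (unique CSMs with `group`, `q_value` and `pass` columns).
#' @export
estimate_fdr_grouped <- function(csms, level = 0.05, unique_csms = TRUE) {
  csms$td_class <- td_class(csms$alpha_is_decoy, csms$beta_is_decoy)
  csms$group <- ifelse(csms$self_link, "self", "heteromeric")
  if (unique_csms) {
    csms$.key <- csm_unique_key(csms)
    csms <- csms |>
      dplyr::group_by(.data$.key) |>
      dplyr::slice_max(.data$score, n = 1, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::select(-".key")
  }
  fdr_group <- function(g) {
    g <- g[order(-g$score), ]
    tt <- cumsum(g$td_class == "TT")
    td <- cumsum(g$td_class == "TD")
    dd <- cumsum(g$td_class == "DD")
    raw <- pmax(0, td - dd) / pmax(tt, 1)
    raw[tt == 0] <- Inf
    # ties: a threshold cannot split equal scores -- use the last index of
    # each tied block
    usable <- !duplicated(g$score, fromLast = TRUE)
    raw[!usable] <- Inf
    q <- rev(cummin(rev(raw)))
    g$q_value <- q
    g$pass <- q <= level
    idx <- which(g$pass)
    degenerate <- max(tt) == 0
    if (length(idx)) {
      i <- max(idx)
      summary <- tibble::tibble(
        group = g$group[1], threshold_score = g$score[i],
        tt = tt[i], td = td[i], dd = dd[i],
        achieved_fdr = q[i], level = level, degenerate = degenerate
      )
    } else {
      summary <- tibble::tibble(
        group = g$group[1], threshold_score = NA_real_,
        tt = 0L, td = 0L, dd = 0L,
        achieved_fdr = NA_real_, level = level, degenerate = degenerate
      )
    }
    list(summary = summary, csms = g)
  }
  parts <- lapply(split(csms, csms$group), fdr_group)
  structure(
    list(
      groups = dplyr::bind_rows(lapply(parts, `[[`, "summary")),
      csms = dplyr::bind_rows(lapply(parts, `[[`, "csms")),
      level = level
    ),
    class = "xl_fdr"
  )
}

#' @export
print.xl_fdr <- function(x, ...) {
  cat("<xl_fdr> grouped target-decoy FDR at level ", x$level, "\n", sep = "")
  print(as.data.frame(x$groups))
  invisible(x)
}

#' CSMs passing the FDR threshold
#'
#' @param fdr An `xl_fdr` object.
#' @param targets_only Keep only target-target matches (default `TRUE`).
#' @return Tibble of passing unique CSMs.
#' @export
passing_csms <- function(fdr, targets_only = TRUE) {
  out <- dplyr::filter(fdr$csms, .data$pass)
  if (targets_only) out <- dplyr::filter(out, .data$td_class == "TT")
  out
}

#' Doublet prefilter comparison
#'
#' Re-estimates grouped FDR after restricting the CSM set to records with
#' at least one detected peptide doublet (`doublet_class >= 1`) and
#' reports paired heteromeric yields, TT/TD score distributions and
#' FDR-vs-threshold curves for both conditions.
#'
#' @param csms CSM tibble with a `doublet_class` column.
#' @param level FDR level (default 0.05).
#' @return A list with `yields` (one row per condition), `scores`
#'   (long tibble of TT/TD scores by condition) and `fdr_curves`
#'   (q-value vs score threshold per condition, heteromeric group).
#' @export
doublet_filter_comparison <- function(csms, level = 0.05) {
  run <- function(x, condition) {
    f <- estimate_fdr_grouped(x, level = level)
    het <- dplyr::filter(f$csms, .data$group == "heteromeric")
    list(
      yield = tibble::tibble(
        condition = condition,
        heteromeric_pass = sum(het$pass & het$td_class == "TT"),
        threshold = f$groups$threshold_score[
          f$groups$group == "heteromeric"][1] %||% NA_real_
      ),
      scores = tibble::tibble(condition = condition,
                              td_class = het$td_class, score = het$score),
      curve = tibble::tibble(condition = condition,
                             score = het$score, q_value = het$q_value)
    )
  }
  unf <- run(csms, "unfiltered")
  fil <- run(dplyr::filter(csms, .data$doublet_class >= 1),
             "doublet_filtered")
  list(
    yields = dplyr::bind_rows(unf$yield, fil$yield),
    scores = dplyr::bind_rows(
      dplyr::filter(unf$scores, .data$td_class != "DD"),
      dplyr::filter(fil$scores, .data$td_class != "DD")
    ),
    fdr_curves = dplyr::bind_rows(unf$curve, fil$curve)
  )
}

#' Normalize scores to the FDR score cutoff
#'
#' Divides each CSM score by its group's score threshold at the given FDR
#' level, so a score of 1.0 sits exactly at the cutoff. Useful for
#' comparing score distributions across datasets or search modes.
#'
#' @param csms CSM tibble.
#' @param level FDR level defining the cutoff (default 0.10).
#' @return The unique-CSM tibble with an added `normalized_score` column.
#' @export
normalize_scores_to_fdr_cutoff <- function(csms, level = 0.10) {
  f <- estimate_fdr_grouped(csms, level = level)
  thr <- stats::setNames(f$groups$threshold_score, f$groups$group)
  if (any(is.na(thr)) || any(thr <= 0, na.rm = TRUE))
    stop("score threshold at level ", level,
         " is zero or undefined; cannot normalize", call. = FALSE)
  out <- f$csms
  out$normalized_score <- out$score / thr[out$group]
  out
}
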