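#' Detect signature stub doublets
#'
#' A doublet is called for a peptide (owner) at a given fragment charge
#' when both intact-peptide P-ion stub variants named by the
#' crosslinker's `doublet_pair` were matched at that charge. The rank of
#' the more intense of the two peaks (the smaller rank) is the rank of the
#' whole doublet. At most one call is emitted per (owner, charge); a
#' non-cleavable crosslinker yields no calls.
#'
#' @param matches Match tibble from [match_fragments()] (needs ranks).
#' @param crosslinker The [crosslinker()] used for annotation.
#' @return A tibble with `owner`, `charge`, `rank_light`, `rank_heavy`
#'   and `doublet_rank = min(rank_light, rank_heavy)`.
#' @export
detect_doublets <- function(matches, crosslinker) {
  empty <- tibble::tibble(owner = character(), charge = integer(),
                          rank_light = integer(), rank_heavy = integer(),
                          doublet_rank = integer())
  if (!crosslinker$cleavable) return(empty)
  pairlab <- crosslinker$doublet_pair
  p <- dplyr::filter(matches, .data$series == "P", .data$loss == "none",
                     .data$stub %in% pairlab)
  if (nrow(p) == 0) return(empty)
  p |>
    dplyr::group_by(.data$owner, .data$charge) |>
    dplyr::summarise(
      rank_light = min(.data$rank[.data$stub == pairlab[1]], Inf),
      rank_heavy = min(.data$rank[.data$stub == pairlab[2]], Inf),
      .groups = "drop"
    ) |>
    dplyr::filter(is.finite(.data$rank_light), is.finite(.data$rank_heavy)) |>
    dplyr::mutate(
      rank_light = as.integer(.data$rank_light),
      rank_heavy = as.integer(.data$rank_heavy),
      doublet_rank = pmin(.data$rank_light, .data$rank_heavy)
    )
}

#' Doublet class of a CSM
#'
#' Number of distinct peptides (0, 1 or 2) of a CSM with at least one
#' detected signature doublet.
#'
#' @param calls Doublet-call tibble from [detect_doublets()] for one CSM.
#' @return Integer 0, 1 or 2.
#' @export
csm_doublet_class <- function(calls) {
  length(unique(calls$owner))
}

#' Best (lowest) doublet rank of a CSM
#'
#' @param calls Doublet-call tibble for one CSM.
#' @return The smallest `doublet_rank`, or `NA` if no calls.
#' @export
best_doublet_rank <- function(calls) {
  if (nrow(calls) == 0) return(NA_integer_)
  min(calls$doublet_rank)
}

#' Cumulative doublet rank curve
#'
#' For each intensity-rank cutoff, the fraction of doublet-containing
#' CSMs whose best doublet rank passes the cutoff (an empirical CDF of
#' best doublet ranks).
#'
#' @param best_ranks Integer vector of per-CSM best doublet ranks
#'   (`NA` = no doublet; excluded).
#' @param cutoffs Integer rank cutoffs.
#' @return A tibble with `cutoff` and `fraction` (non-decreasing).
#' @export
#' @examples
#' doublet_rank_curve(c(1, 5, 30), cutoffs = c(1, 20))
doublet_rank_curve <- function(best_ranks, cutoffs = c(1, 5, 10, 20, 50)) {
  r <- best_ranks[!is.na(best_ranks)]
  if (length(r) == 0)
    return(tibble::tibble(cutoff = integer(), fraction = numeric()))
  tibble::tibble(
    cutoff = as.integer(cutoffs),
    fraction = vapply(cutoffs, function(k) mean(r <= k), numeric(1))
  )
}

#' Doublet prevalence over a CSM set
#'
#' Fractions of CSMs containing a doublet for at least one peptide and for
#' both peptides.
#'
#' @param doublet_class Integer vector of per-CSM doublet classes (0/1/2).
#' @return One-row tibble with `n`, `frac_ge1`, `frac_both`.
#' @export
doublet_prevalence_summary <- function(doublet_class) {
  tibble::tibble(
    n = length(doublet_class),
    frac_ge1 = if (length(doublet_class)) mean(doublet_class >= 1) else 0,
    frac_both = if (length(doublet_class)) mean(doublet_class == 2) else 0
  )
}

#' Conservative per-peptide sequence coverage
#'
#' Coverage is the fraction of the `2 * (L - 1)` possible sequence
#' fragments (one N-terminal and one C-terminal fragment per backbone
#' cleavage position) that are matched at least once, counting a cleavage
#' position once regardless of stub state, neutral loss, or charge
#' multiplicity. Sub-fractions use the same denominator but restrict the
#' matched set: `linear` to fragments without the link site, `link_site`
#' to fragments containing it, `stub_only` to cleaved-stub variants and
#' `plus_p` to +P variants.
#'
#' @param matches Match tibble from [match_fragments()] (or a fragment
#'   tibble; only `owner`, `series`, `index`, `stub` are used).
#' @param peptide_length Length L of the peptide (must be >= 2).
#' @param owner Which peptide of the pair to evaluate.
#' @return One-row tibble: `owner`, `total`, `linear`, `link_site`,
#'   `stub_only`, `plus_p`.
#' @export
sequence_coverage <- function(matches, peptide_length, owner = "alpha") {
  L <- peptide_length
  if (is.na(L) || L < 2) stop("coverage undefined for peptide length < 2",
                              call. = FALSE)
  denom <- 2 * (L - 1)
  m <- dplyr::filter(matches, .data$owner == !!owner,
                     .data$series %in% c("b", "y"))
  frac <- function(mm) {
    if (nrow(mm) == 0) return(0)
    nrow(dplyr::distinct(mm, .data$series, .data$index)) / denom
  }
  tibble::tibble(
    owner = owner,
    total = frac(m),
    linear = frac(dplyr::filter(m, !.data$contains_link_site)),
    link_site = frac(dplyr::filter(m, .data$contains_link_site)),
    stub_only = frac(dplyr::filter(m, !.data$stub %in% c("none", "+P"))),
    plus_p = frac(dplyr::filter(m, .data$stub == "+P"))
  )
}
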