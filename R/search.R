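#' Annotate one spectrum against a crosslinked pair
#'
#' Convenience wrapper: deisotope, rank, generate theoretical fragments,
#' match within tolerance and score.
#'
#' @param spectrum One row of an [xl_spectra()] tibble (or a deisotoped
#'   peak tibble).
#' @param pair An [crosslinked_pair()] object.
#' @param ppm_tol Fragment tolerance (ppm).
#' @param stub_aware Annotate cleaved-stub fragments (see
#'   [theoretical_fragments()]).
#' @param losses Emit neutral-loss fragment variants.
#' @param deiso_ppm,deiso_max_charge Deisotoping parameters.
#' @return A list with `peaks` (deisotoped, ranked), `matches`,
#'   `fragments` and the [score_csm()] fields.
#' @export
annotate_csm <- function(spectrum, pair, ppm_tol = 15, stub_aware = TRUE,
                         losses = FALSE, deiso_ppm = 10,
                         deiso_max_charge = 4L) {
  peaks <- if (!is.null(spectrum$peaks)) {
    deisotope(spectrum$peaks[[1]], ppm_tol = deiso_ppm,
              max_charge = deiso_max_charge)
  } else spectrum
  frags <- theoretical_fragments(pair, losses = losses,
                                 stub_aware = stub_aware)
  matches <- match_fragments(peaks, frags, ppm_tol = ppm_tol)
  c(list(peaks = peaks, matches = matches, fragments = frags),
    score_csm(matches, peaks, pair))
}

# draw a random peptide index from the pool, decoy with prob decoy_frac
draw_peptide <- function(pool_t, pool_d, decoy_frac) {
  if (stats::runif(1) < decoy_frac && nrow(pool_d) > 0)
    list(tab = pool_d, i = sample.int(nrow(pool_d), 1), decoy = TRUE)
  else
    list(tab = pool_t, i = sample.int(nrow(pool_t), 1), decoy = FALSE)
}

pep_from_pool <- function(drawn) {
  p <- drawn$tab[drawn$i, ]
  list(sequence = p$sequence, accession = p$accession,
       is_decoy = drawn$decoy, link_sites = p$link_sites[[1]])
}

random_site <- function(p) sample(rep(p$link_sites, 2), 1)

#' Search simulated spectra against candidate crosslinked pairs
#'
#' A compact search-engine emulation: for every MS2 scan a short list of
#' candidate pairs is scored with [annotate_csm()] and the best-scoring
#' candidate becomes the spectrum's CSM; the delta score is the gap to
#' the runner-up. For genuine crosslinked spectra the list holds the true
#' pair, `n_half_candidates` half-true pairs (one true peptide with a
#' random partner) and `n_random_candidates` fully random pairs. For
#' crosslink-free spectra the contaminant peptide takes the place of the
#' true peptides (a real engine would recover the best-matching linear
#' peptide). Random peptides are decoys with probability
#' `decoy_fraction_of_candidates`; with the default 0.5 the target-decoy
#' identity E\[TD - DD\] = E\[false TT\] holds for the FDR estimator.
#'
#' Doublets are detected on the winning annotation, coverage is computed
#' per peptide, and a CSM is flagged potentially noncovalent when the
#' annotation shows no link-site evidence at all (no link-site fragment
#' matched for either peptide and one peptide entirely unmatched), the
#' analogue of a zero-mass crosslinker flagging gas-phase-associated
#' peptide pairs.
#'
#' @param sim Result of [simulate_crosslinked_spectra()].
#' @param config The [sim_config()] in use.
#' @param stub_aware Annotate cleaved stubs (set `FALSE` for the
#'   noncleavable search mode).
#' @return A CSM tibble (one row per MS2 scan) with the columns of
#'   [write_csm_table()] plus `is_true_csm`, `true_pair_won`,
#'   `best_doublet_rank`, and list columns `matches` and `peaks`.
#' @export
run_search <- function(sim, config = sim$config, stub_aware = TRUE) {
  cfg <- config
  xl <- cfg$crosslinker
  pool <- linkable_peptides(sim$peptides, xl)
  pool_t <- pool
  decoys <- generate_decoy_db(sim$proteins)
  dpep <- tryptic_digest(decoys, max_missed = 2, length_range = c(6, 30))
  dpep <- dpep[!duplicated(dpep$sequence), ]
  pool_d <- linkable_peptides(dpep, xl)

  with_local_seed(cfg$seed + 3L, {
    rows <- vector("list", nrow(sim$spectra))
    for (si in seq_len(nrow(sim$spectra))) {
      spec <- sim$spectra[si, ]
      if (spec$ms_level != 2L) next
      tr <- sim$truth[sim$truth$scan_id == spec$scan_id, ]
      z <- spec$precursor_charge

      rand_pair <- function() {
        a <- pep_from_pool(draw_peptide(pool_t, pool_d,
                                        cfg$decoy_fraction_of_candidates))
        b <- pep_from_pool(draw_peptide(pool_t, pool_d,
                                        cfg$decoy_fraction_of_candidates))
        crosslinked_pair(a, b, random_site(a), random_site(b), xl,
                         charge = z, validate_sites = FALSE)
      }
      half_pair <- function(anchor, anchor_site) {
        b <- pep_from_pool(draw_peptide(pool_t, pool_d,
                                        cfg$decoy_fraction_of_candidates))
        crosslinked_pair(anchor, b, anchor_site, random_site(b), xl,
                         charge = z, validate_sites = FALSE)
      }

      cands <- list()
      if (tr$is_true_csm) {
        true_pair <- crosslinked_pair(
          list(sequence = tr$alpha_seq, accession = tr$alpha_acc),
          list(sequence = tr$beta_seq, accession = tr$beta_acc),
          tr$site_alpha, tr$site_beta, xl, charge = z,
          validate_sites = FALSE)
        cands[[1]] <- true_pair
        anchors <- list(
          list(pep = true_pair$alpha, site = tr$site_alpha),
          list(pep = true_pair$beta, site = tr$site_beta)
        )
        for (k in seq_len(cfg$n_half_candidates)) {
          an <- anchors[[(k - 1L) %% 2L + 1L]]
          cands[[length(cands) + 1L]] <- half_pair(an$pep, an$site)
        }
      } else {
        cont <- pool[pool$sequence == tr$contaminant_seq, ][1, ]
        anchor <- list(sequence = cont$sequence, accession = cont$accession,
                       is_decoy = FALSE, link_sites = cont$link_sites[[1]])
        for (k in seq_len(max(2L, cfg$n_half_candidates)))
          cands[[length(cands) + 1L]] <- half_pair(anchor,
                                                   random_site(anchor))
      }
      for (k in seq_len(cfg$n_random_candidates))
        cands[[length(cands) + 1L]] <- rand_pair()

      peaks <- deisotope(spec$peaks[[1]], ppm_tol = 10, max_charge = 4L)
      scored <- lapply(cands, function(p) {
        frags <- theoretical_fragments(p, stub_aware = stub_aware)
        m <- match_fragments(peaks, frags, ppm_tol = cfg$ms2_ppm_tol)
        c(list(pair = p, matches = m), score_csm(m, peaks, p))
      })
      sc <- vapply(scored, `[[`, numeric(1), "score")
      best <- scored[[which.max(sc)]]
      second <- if (length(sc) > 1) max(sc[-which.max(sc)]) else 0
      pair <- best$pair
      calls <- detect_doublets(best$matches, if (stub_aware) xl else
        xl_bs3())
      link_evidence <- sum(best$matches$contains_link_site)
      noncov <- link_evidence == 0 &&
        min(best$matched_frags_alpha, best$matched_frags_beta) == 0

      prot_count <- function(seq)
        length(unique(pool$accession[pool$sequence == seq]))
      rows[[si]] <- tibble::tibble(
        csm_id = tr$csm_id, scan_id = spec$scan_id,
        alpha_seq = pair$alpha$sequence, beta_seq = pair$beta$sequence,
        alpha_mod = pair$alpha$mod_label, beta_mod = pair$beta$mod_label,
        site_alpha = pair$site_alpha, site_beta = pair$site_beta,
        charge = z,
        score = best$score, delta_score = best$score - second,
        matched_frags_alpha = best$matched_frags_alpha,
        matched_frags_beta = best$matched_frags_beta,
        alpha_is_decoy = pair$alpha$is_decoy,
        beta_is_decoy = pair$beta$is_decoy,
        alpha_acc = pair$alpha$accession, beta_acc = pair$beta$accession,
        self_link = sub("^REV_", "", pair$alpha$accession) ==
          sub("^REV_", "", pair$beta$accession),
        doublet_class = csm_doublet_class(calls),
        best_doublet_rank = best_doublet_rank(calls),
        coverage_alpha = best$coverage_alpha,
        coverage_beta = best$coverage_beta,
        noncovalent_flag = noncov,
        alpha_prot_count = prot_count(pair$alpha$sequence),
        beta_prot_count = prot_count(pair$beta$sequence),
        is_true_csm = tr$is_true_csm,
        true_pair_won = tr$is_true_csm &&
          identical(pair$alpha$sequence, tr$alpha_seq) &&
          identical(pair$beta$sequence, tr$beta_seq),
        matches = list(best$matches), peaks = list(peaks)
      )
    }
    dplyr::bind_rows(rows)
  })
}
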