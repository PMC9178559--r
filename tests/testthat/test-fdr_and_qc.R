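test_that("the declared CSM score is bounded and monotone in matches", {
  pair <- crosslinked_pair("AKSAVLR", "TKFADER", 2, 2, xl_dsso(),
                           charge = 4, validate_sites = FALSE)
  fr <- theoretical_fragments(pair)
  peaks <- assign_ranks(tibble::tibble(
    mono_mz = sort(fr$mz[fr$charge == 1]), charge = 1L,
    intensity = rep(5, sum(fr$charge == 1)), n_peaks = 1L,
    member_mz = as.list(sort(fr$mz[fr$charge == 1]))))

  none <- score_csm(fr[0, ] |>
                      dplyr::mutate(peak_id = integer(0)), peaks, pair)
  expect_equal(none$score, 0)

  m <- match_fragments(peaks, fr, ppm_tol = 5)
  full <- score_csm(m, peaks, pair)
  expect_equal(full$score, 2.0, tolerance = 1e-9)  # everything explained
  half <- score_csm(m[m$owner == "alpha", ], peaks, pair)
  expect_lt(half$score, full$score)
  expect_gte(half$score, 0)
})

test_that("pre-FDR filters apply the declared conjunction of rules", {
  base <- tibble::tibble(
    alpha_seq = "ABCDEFG", beta_seq = "HIKLMNP",
    matched_frags_alpha = 5, matched_frags_beta = 5,
    score = 1, delta_score = 0.5, noncovalent_flag = FALSE,
    alpha_prot_count = 1, beta_prot_count = 1)

  expect_equal(nrow(prefilter_csms(base)), 1)
  expect_equal(nrow(prefilter_csms(
    dplyr::mutate(base, matched_frags_beta = 2))), 0)
  # boundary: delta exactly 15% of the score is removed (strict >)
  expect_equal(nrow(prefilter_csms(
    dplyr::mutate(base, delta_score = 0.15))), 0)
  expect_equal(nrow(prefilter_csms(
    dplyr::mutate(base, delta_score = 0.150001))), 1)
  expect_equal(nrow(prefilter_csms(
    dplyr::mutate(base, beta_seq = "HIKLM"))), 0)
  expect_equal(nrow(prefilter_csms(
    dplyr::mutate(base, noncovalent_flag = TRUE))), 0)
  expect_equal(nrow(prefilter_csms(
    dplyr::mutate(base, alpha_prot_count = 2))), 0)

  # oracle equivalence and idempotence on random records
  csms <- random_csm_scores(400, seed = 6)
  csms$alpha_prot_count <- sample(1:2, 400, TRUE, prob = c(0.9, 0.1))
  csms$beta_prot_count <- 1
  got <- prefilter_csms(csms)
  keep <- csms$matched_frags_alpha >= 3 & csms$matched_frags_beta >= 3 &
    csms$delta_score > 0.15 * csms$score &
    nchar(csms$alpha_seq) >= 6 & nchar(csms$beta_seq) >= 6 &
    !csms$noncovalent_flag & csms$alpha_prot_count <= 1
  expect_equal(got$csm_id, csms$csm_id[keep])
  expect_identical(prefilter_csms(got), got)
})

test_that("grouped FDR matches a brute-force threshold-scan oracle", {
  # worked example: above a threshold TT=190, TD=12, DD=2
  csms <- tibble::tibble(
      csm_id = 1:204, scan_id = as.character(1:204),
      alpha_seq = sprintf("PEPTIDEA%03d", 1:204),
      beta_seq = sprintf("PEPTIDEB%03d", 1:204),
      alpha_mod = "", beta_mod = "",
      site_alpha = 1L, site_beta = 1L, charge = 3L,
      score = seq(2, 1, length.out = 204),
      delta_score = 1,
      matched_frags_alpha = 5L, matched_frags_beta = 5L,
      alpha_is_decoy = c(rep(FALSE, 190), rep(TRUE, 2), rep(FALSE, 12)),
      beta_is_decoy = c(rep(FALSE, 190), rep(TRUE, 14)),
      alpha_acc = sprintf("A%03d", 1:204), beta_acc = sprintf("B%03d", 1:204),
      self_link = FALSE, doublet_class = 2L,
      coverage_alpha = 1, coverage_beta = 1, noncovalent_flag = FALSE)
  f <- estimate_fdr_grouped(csms, level = 0.06)
  g <- tidy(f)
  expect_equal(g$tt, 190L)
  expect_equal(g$td, 12L)
  expect_equal(g$dd, 2L)
  expect_equal(g$achieved_fdr, (12 - 2) / 190, tolerance = 1e-9)

  # no decoys at all: FDR 0, everything passes
  clean <- dplyr::mutate(csms, alpha_is_decoy = FALSE,
                         beta_is_decoy = FALSE)
  f0 <- estimate_fdr_grouped(clean, level = 0.05)
  expect_true(all(f0$csms$pass))
  expect_equal(tidy(f0)$achieved_fdr, 0)

  # randomized oracle equivalence on groups of <= 200 records
  withr::with_seed(19, {
    for (rep in 1:6) {
      n <- sample(50:200, 1)
      csms <- random_csm_scores(n, seed = rep + 100, p_decoy = 0.35)
      csms$self_link <- FALSE
      csms$score <- round(csms$score, 2)  # force score ties
      f <- estimate_fdr_grouped(csms, level = 0.05, unique_csms = FALSE)
      oracle <- oracle_fdr_threshold(
        csms$score, td_class(csms$alpha_is_decoy, csms$beta_is_decoy),
        level = 0.05)
      g <- tidy(f)
      expect_equal(g$threshold_score, oracle$threshold)
      expect_equal(sum(f$csms$pass), oracle$n_pass)
      # monotonized q-values never increase with the threshold
      ord <- order(-f$csms$score)
      expect_true(all(diff(f$csms$q_value[ord]) >= -1e-12))
    }
  })
})

test_that("unique-CSM reduction keeps the best score per pair key", {
  csms <- random_csm_scores(6, seed = 2)
  dup <- csms[c(1, 1, 2), ]
  dup$score <- c(0.5, 1.5, 1.0)
  dup$csm_id <- 1:3
  f <- estimate_fdr_grouped(dup, level = 1)
  expect_equal(nrow(f$csms), 2)
  expect_equal(max(f$csms$score), 1.5)
  # the pair key is order-invariant: swapped peptides collapse too
  swapped <- dup[1:2, ]
  swapped[2, c("alpha_seq", "beta_seq")] <- swapped[1, c("beta_seq", "alpha_seq")]
  swapped[2, c("site_alpha", "site_beta")] <- swapped[1, c("site_beta", "site_alpha")]
  f2 <- estimate_fdr_grouped(swapped, level = 1)
  expect_equal(nrow(f2$csms), 1)
})

test_that("doublet prefiltering interacts with FDR as expected", {
  csms <- random_csm_scores(300, seed = 23, p_decoy = 0.25)
  csms$self_link <- FALSE

  # filter on a set where every record has a doublet: exact no-op
  all_doublet <- dplyr::mutate(csms, doublet_class = 2L)
  cmp <- doublet_filter_comparison(all_doublet, level = 0.05)
  expect_equal(cmp$yields$heteromeric_pass[1],
               cmp$yields$heteromeric_pass[2])

  # if no TD/DD record has a doublet, filtering only removes decoys,
  # so the filtered threshold can only relax (not exceed the unfiltered)
  cls <- td_class(csms$alpha_is_decoy, csms$beta_is_decoy)
  sel <- dplyr::mutate(csms,
                       doublet_class = ifelse(cls == "TT", 2L, 0L))
  cmp2 <- doublet_filter_comparison(sel, level = 0.05)
  thr <- cmp2$yields$threshold
  expect_true(is.na(thr[2]) || is.na(thr[1]) || thr[2] <= thr[1])
  expect_gte(cmp2$yields$heteromeric_pass[2],
             cmp2$yields$heteromeric_pass[1])
})

test_that("score normalization maps the FDR cutoff to 1", {
  csms <- random_csm_scores(300, seed = 29, p_decoy = 0.2)
  norm <- normalize_scores_to_fdr_cutoff(csms, level = 0.10)
  f <- estimate_fdr_grouped(csms, level = 0.10)
  thr <- tidy(f)
  for (g in thr$group) {
    at <- which(norm$group == g &
                  abs(norm$score - thr$threshold_score[thr$group == g]) < 1e-12)
    expect_true(all(abs(norm$normalized_score[at] - 1) < 1e-9))
  }
  # normalization is monotone within each group
  for (g in unique(norm$group)) {
    sub <- norm[norm$group == g, ]
    expect_equal(order(sub$score), order(sub$normalized_score))
  }
})

test_that("tidy and glance summarise FDR objects", {
  csms <- random_csm_scores(100, seed = 40)
  f <- estimate_fdr_grouped(csms, level = 0.05)
  expect_s3_class(tidy(f), "tbl_df")
  g <- glance(f)
  expect_equal(g$level, 0.05)
  expect_lte(g$n_pass_tt_heteromeric, g$n_pass_tt)
  p <- autoplot(f)
  expect_s3_class(p, "ggplot")
})
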