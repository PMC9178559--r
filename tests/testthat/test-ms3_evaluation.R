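dsso <- xl_dsso()

make_ms3_row <- function(sel, parent = "p1") {
  xl_spectra("ms3a", 3L, sel, 1L,
             list(tibble::tibble(mz = numeric(), intensity = numeric())),
             parent_scan_id = parent, selected_precursor_mz = sel)
}

stub_match <- function(mz_obs, owner = "alpha", stub = "A") {
  tibble::tibble(owner = owner, series = "P", index = 0L, stub = stub,
                 loss = "none", charge = 1L, mz = mz_obs, neutral = 0,
                 contains_link_site = TRUE, peak_id = 1L,
                 matched_mz = mz_obs, ppm_error = 0, peak_intensity = 10,
                 peak_charge = 1L, rank = 1L, via_member = FALSE,
                 ambiguous = FALSE)
}

test_that("MS3 triggers are classified by ppm distance to stub peaks", {
  ann <- stub_match(500.004)
  cl <- classify_ms3_trigger(make_ms3_row(500.000), ann, crosslinker = dsso)
  expect_equal(cl$outcome, "correct_stub")
  expect_equal(cl$matched_owner, "alpha")
  expect_equal(cl$ppm_error, -8.0, tolerance = 1e-4)

  cl2 <- classify_ms3_trigger(make_ms3_row(500.015), stub_match(500.000),
                              crosslinker = dsso)
  expect_equal(cl2$outcome, "unmatched")  # 30 ppm exceeds the tolerance

  # falls through to linear candidates, with and without dead-end mods
  lin <- tibble::tibble(sequence = "AKGLER")
  mz_lin <- mz_of(peptide_mass("AKGLER"), 2)
  cl3 <- classify_ms3_trigger(make_ms3_row(mz_lin), stub_match(900),
                              linear_candidates = lin, crosslinker = dsso)
  expect_equal(cl3$outcome, "linear_peptide")
  mz_mod <- mz_of(peptide_mass("AKGLER") + dsso$hydrolyzed_mod, 2)
  cl4 <- classify_ms3_trigger(make_ms3_row(mz_mod), stub_match(900),
                              linear_candidates = lin, crosslinker = dsso)
  expect_equal(cl4$outcome, "crosslinker_modified_linear")

  bad <- xl_spectra("x", 2L, 500, 2L,
                    list(tibble::tibble(mz = 1, intensity = 1)))
  expect_error(classify_ms3_trigger(bad, ann), "ms_level")
})

test_that("simulated CID-MS3 triggers classify exactly as generated", {
  cfg <- sim_config(seed = 31, n_csms = 60, acquisition = "CID_MS2_MS3",
                    doublet_emission_prob = 0.85)
  sim <- simulate_crosslinked_spectra(cfg)
  ms3 <- simulate_cid_ms3_run(cfg, sim)
  tru <- ms3$trigger_truth
  expect_gt(nrow(tru), 0)
  expect_gt(sum(!tru$is_true_stub), 0)  # some false triggers exist

  for (i in seq_len(60)) {
    kids <- which(tru$parent_scan_id == sim$truth$scan_id[i])
    if (!length(kids)) next
    ann <- annotate_csm(sim$spectra[i, ], sim$pairs[[i]], ppm_tol = 15)
    for (k in kids) {
      row <- ms3$ms3_spectra[
        ms3$ms3_spectra$scan_id == tru$ms3_scan_id[k], ]
      cl <- classify_ms3_trigger(row, ann$matches, crosslinker = dsso)
      expect_equal(cl$outcome == "correct_stub", tru$is_true_stub[k])
      if (tru$is_true_stub[k])
        expect_equal(cl$matched_owner, tru$owner[k])
    }
  }
})

test_that("trigger summaries partition CSMs by correctly hit peptides", {
  cls <- tibble::tibble(
    csm_id = c(2, 3, 3),
    outcome = "correct_stub",
    matched_owner = c("alpha", "alpha", "beta"))
  s <- trigger_summary(cls, csm_ids = 1:3)
  expect_equal(s$proportions$proportion, c(1 / 3, 1 / 3, 1 / 3))
  expect_equal(sum(s$proportions$proportion), 1)
  s0 <- trigger_summary(cls[0, ], csm_ids = 1:3)
  expect_equal(s0$proportions$proportion, c(1, 0, 0))
})

test_that("combined MS2+MS3 coverage is a monotone union", {
  ms2 <- make_matches("alpha", "b", 2L, "none")
  ms3 <- make_matches("alpha", "y", 3L, "fixed")
  cov <- combined_coverage(ms2, list(ms3), "correct_stub",
                           peptide_length = 6)
  expect_equal(cov$total, 0.2)
  # wrongly triggered scans contribute nothing
  cov2 <- combined_coverage(ms2, list(ms3), "linear_peptide",
                            peptide_length = 6)
  expect_equal(cov2$total, 0.1)

  # union coverage >= each individual coverage on simulated CSMs
  cfg <- sim_config(seed = 77, n_csms = 25, acquisition = "CID_MS2_MS3")
  sim <- simulate_crosslinked_spectra(cfg)
  ms3 <- simulate_cid_ms3_run(cfg, sim)
  tru <- ms3$trigger_truth
  checked <- 0
  for (i in seq_len(25)) {
    kids <- which(tru$parent_scan_id == sim$truth$scan_id[i] &
                    tru$is_true_stub)
    if (!length(kids)) next
    ann <- annotate_csm(sim$spectra[i, ], sim$pairs[[i]], ppm_tol = 15)
    for (ow in c("alpha", "beta")) {
      kow <- kids[tru$owner[kids] == ow]
      pep <- sim$pairs[[i]][[ow]]
      site <- sim$pairs[[i]][[paste0("site_", ow)]]
      mlist <- lapply(kow, function(k) {
        row <- ms3$ms3_spectra[
          ms3$ms3_spectra$scan_id == tru$ms3_scan_id[k], ]
        frags <- linear_stub_fragments(
          pep$sequence, site, dsso$stub_masses[[tru$stub[k]]],
          owner = ow)
        match_fragments(deisotope(row$peaks[[1]]), frags, ppm_tol = 15)
      })
      cov_ms2 <- sequence_coverage(ann$matches, pep$length, ow)$total
      cov_all <- combined_coverage(ann$matches, mlist,
                                   rep("correct_stub", length(mlist)),
                                   pep$length, ow)$total
      expect_gte(cov_all, cov_ms2)
      for (m in mlist)
        expect_gte(cov_all, sequence_coverage(m, pep$length, ow)$total)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 10)
})
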