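test_that("deisotoping clusters envelopes and conserves intensity", {
  pk <- tibble::tibble(mz = c(500.000, 500.000 + 1.0033548378 / 2,
                              500.000 + 1.0033548378),
                       intensity = c(100, 60, 20))
  d <- deisotope(pk)
  expect_equal(nrow(d), 1)
  expect_equal(d$charge, 2L)
  expect_equal(d$intensity, 180)
  expect_equal(d$mono_mz, 500)

  # two isolated peaks stay singletons with undetermined charge
  d2 <- deisotope(tibble::tibble(mz = c(400, 403), intensity = c(5, 9)))
  expect_equal(nrow(d2), 2)
  expect_true(all(d2$charge == 0L))

  # total intensity is never created or destroyed
  withr::with_seed(9, {
    for (rep in 1:5) {
      pk <- tibble::tibble(mz = sort(runif(200, 100, 1500)),
                           intensity = rlnorm(200, 3, 1))
      d <- deisotope(pk)
      expect_equal(sum(d$intensity), sum(pk$intensity))
      expect_setequal(unlist(d$member_mz), pk$mz)
    }
  })
})

test_that("deisotoping recovers >= 95% of generated envelopes", {
  withr::with_seed(21, {
    n_env <- 40
    mono <- sort(sample(seq(300, 1500, by = 4), n_env)) + runif(n_env)
    z <- sample(1:3, n_env, replace = TRUE)
    base <- rlnorm(n_env, 5, 1)
    pk <- do.call(rbind, lapply(seq_len(n_env), function(i) {
      k <- 0:2
      data.frame(mz = mono[i] + k * 1.0033548378 / z[i],
                 intensity = base[i] * 0.55^k)
    }))
    d <- deisotope(pk[order(pk$mz), ])
    hits <- vapply(seq_len(n_env), function(i) {
      j <- which(abs(d$mono_mz - mono[i]) / mono[i] < 5e-6)
      length(j) == 1 && d$charge[j] == z[i] && d$n_peaks[j] == 3
    }, logical(1))
    expect_gte(mean(hits), 0.95)
  })
})

test_that("intensity ranks follow descending intensity with m/z ties", {
  pk <- tibble::tibble(mono_mz = c(100, 200, 300),
                       intensity = c(10, 100, 50))
  expect_equal(assign_ranks(pk)$rank, c(3L, 1L, 2L))
  tie <- tibble::tibble(mono_mz = c(400, 300), intensity = c(7, 7))
  expect_equal(assign_ranks(tie)$rank, c(2L, 1L))
  withr::with_seed(4, {
    pk <- tibble::tibble(mono_mz = runif(1000, 100, 2000),
                         intensity = sample(rlnorm(1000, 4, 2)))
    r <- assign_ranks(pk)$rank
    oracle <- order(order(-pk$intensity, pk$mono_mz))
    expect_identical(r, as.integer(oracle))
    expect_setequal(r, 1:1000)
  })
})

test_that("fragment matching respects ppm tolerance and nearest-peak rule", {
  peaks <- assign_ranks(tibble::tibble(
    mono_mz = 500.004, charge = 0L, intensity = 10, n_peaks = 1L,
    member_mz = list(500.004)))
  frag <- tibble::tibble(owner = "alpha", series = "b", index = 1L,
                         stub = "none", loss = "none", charge = 1L,
                         mz = 500.000, neutral = 498.99,
                         contains_link_site = FALSE)
  m <- match_fragments(peaks, frag, ppm_tol = 15)
  expect_equal(nrow(m), 1)
  expect_equal(m$ppm_error, 8.0, tolerance = 1e-6)
  expect_equal(nrow(match_fragments(peaks, frag, ppm_tol = 5)), 0)
})

test_that("matching agrees with a brute-force all-pairs oracle", {
  withr::with_seed(13, {
    for (rep in 1:4) {
      np <- 120; nf <- 80
      peaks <- assign_ranks(tibble::tibble(
        mono_mz = sort(runif(np, 100, 1500)),
        charge = sample(0:3, np, TRUE),
        intensity = rlnorm(np, 3, 1),
        n_peaks = 1L))
      peaks$member_mz <- as.list(peaks$mono_mz)
      frags <- tibble::tibble(
        owner = "alpha", series = "b", index = seq_len(nf), stub = "none",
        loss = "none", charge = sample(1:3, nf, TRUE),
        mz = sample(c(runif(nf / 2, 100, 1500),
                      sample(peaks$mono_mz, nf / 2) *
                        (1 + runif(nf / 2, -2e-5, 2e-5)))),
        neutral = 0, contains_link_site = FALSE)
      tol <- 15
      m <- match_fragments(peaks, frags, ppm_tol = tol)

      oracle <- 0L
      for (i in seq_len(nf)) {
        ppm <- (peaks$mono_mz - frags$mz[i]) / frags$mz[i] * 1e6
        inwin <- abs(ppm) <= tol
        compat <- inwin & (peaks$charge == frags$charge[i] |
                             peaks$charge == 0L)
        cand <- if (any(compat)) which(compat) else which(inwin)
        if (length(cand)) oracle <- oracle + 1L
      }
      expect_equal(nrow(m), oracle)
    }
  })
})

test_that("matching is stable under recalibrated global ppm shifts", {
  pair <- crosslinked_pair("AKSAVLR", "TKFADER", 2, 2, xl_dsso(),
                           charge = 4, validate_sites = FALSE)
  fr <- theoretical_fragments(pair)
  sp <- xl_spectra("s", 2L, mz_of(pair_mass(pair), 4), 4L,
                   list(tibble::tibble(mz = sort(fr$mz[fr$charge == 1]),
                                       intensity = rep(10, sum(fr$charge == 1)))))
  base <- match_fragments(deisotope(sp$peaks[[1]]), fr, ppm_tol = 15)
  shifted <- recalibrate_spectra(sp, 0, -6)   # inject +6 ppm
  back <- recalibrate_spectra(shifted, 0, 6)  # recalibrate away
  rematch <- match_fragments(deisotope(back$peaks[[1]]), fr, ppm_tol = 15)
  expect_equal(nrow(rematch), nrow(base))
})
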