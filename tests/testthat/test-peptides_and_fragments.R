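test_that("tryptic digestion applies K/R|P rules and missed cleavages", {
  expect_setequal(tryptic_digest("MKRA", 0, NULL)$sequence,
                  c("MK", "R", "A"))
  expect_setequal(tryptic_digest("MKRA", 2, NULL)$sequence,
                  c("MK", "R", "A", "MKR", "RA", "MKRA"))
  expect_equal(tryptic_digest("AAAA", 2, NULL)$sequence, "AAAA")
  # no cleavage before proline
  expect_setequal(tryptic_digest("AKPAKA", 0, NULL)$sequence,
                  c("AKPAK", "A"))

  # exhaustive enumeration oracle on random sequences: every substring
  # whose boundaries are valid cleavage points and whose internal missed
  # cleavages are within budget, and nothing else
  withr::with_seed(2, {
    for (rep in 1:5) {
      seqn <- paste(sample(c("A", "G", "K", "R", "P", "S"), 25, TRUE),
                    collapse = "")
      res <- strsplit(seqn, "")[[1]]
      n <- length(res)
      cuts <- c(0, which(res[-n] %in% c("K", "R") & res[-1] != "P"), n)
      expected <- character()
      for (a in seq_len(length(cuts) - 1)) {
        for (b in (a + 1):length(cuts)) {
          if (b - a - 1 > 2) next
          expected <- c(expected,
                        substr(seqn, cuts[a] + 1, cuts[b]))
        }
      }
      got <- tryptic_digest(seqn, 2, NULL)$sequence
      expect_setequal(got, unique(expected))
    }
  })

  # length filter and positions
  d <- tryptic_digest(
    tibble::tibble(accession = "P1", sequence = "MKRAAAK", is_decoy = FALSE),
    max_missed = 0, length_range = c(2, 10))
  expect_true(all(d$length >= 2))
  expect_equal(d$start[d$sequence == "AAAK"], 4L)
})

test_that("peptide masses follow the monoisotopic model", {
  expect_equal(peptide_mass("GG", fixed_mods = NULL), 132.05349,
               tolerance = 1e-4)
  # fixed carbamidomethyl on cysteine
  expect_equal(peptide_mass("C"),
               peptide_mass("C", fixed_mods = NULL) + 57.021464)
  # oxidation as a variable modification delta
  expect_equal(peptide_mass("AMA", mod_mass = 15.994915) -
                 peptide_mass("AMA"), 15.994915)
  expect_error(peptide_mass("AZB"), "Z")
})

test_that("variable modification forms enumerate single-site variants", {
  peps <- tibble::tibble(sequence = "AMA", protein_nterm = FALSE)
  cat <- default_mod_catalog()
  forms <- enumerate_variable_mods(peps, cat[cat$label == "ox", ])
  expect_equal(nrow(forms), 2)  # unmodified + M2

  dsso_cat <- default_mod_catalog(xl_dsso())
  forms <- enumerate_variable_mods(
    tibble::tibble(sequence = "AKA", protein_nterm = FALSE),
    dsso_cat[grepl("DSSO", dsso_cat$label), ])
  expect_equal(nrow(forms), 3)  # unmodified + K2 hydrolyzed + K2 amidated

  # at most one variable modification: MM gives none, M1, M2 - never both
  forms <- enumerate_variable_mods(
    tibble::tibble(sequence = "MM", protein_nterm = FALSE),
    cat[cat$label == "ox", ])
  expect_equal(nrow(forms), 3)
  expect_true(all(table(forms$mod_label) <= 2))
})

test_that("crosslink search space grows as (n^2 + n) / 2", {
  expect_equal(search_space_size(1), 1)
  expect_equal(search_space_size(3), 6)
  expect_equal(search_space_size(1000), 500500)
  # pair-enumeration cross-check
  n <- 40
  pairs <- expand.grid(i = 1:n, j = 1:n)
  expect_equal(search_space_size(n), sum(pairs$i <= pairs$j))
})

test_that("crosslinker chemistry identities hold for the presets", {
  dsso <- xl_dsso(); dsbu <- xl_dsbu(); bs3 <- xl_bs3()
  h2o <- 18.0105646863; nh3 <- 17.0265491015
  # dead-end mods are linker + water / ammonia
  expect_equal(dsso$hydrolyzed_mod, dsso$linker_mass + h2o, tolerance = 1e-4)
  expect_equal(dsso$amidated_mod, dsso$linker_mass + nh3, tolerance = 1e-4)
  expect_equal(dsbu$hydrolyzed_mod, dsbu$linker_mass + h2o, tolerance = 1e-4)
  expect_equal(dsbu$amidated_mod, dsbu$linker_mass + nh3, tolerance = 1e-4)
  # doublet deltas from the stub tables
  expect_equal(doublet_delta(dsso), 85.98264 - 54.01056)
  expect_equal(doublet_delta(dsbu), 111.032028 - 85.05276)
  expect_false(bs3$cleavable)
  expect_true(is.na(doublet_delta(bs3)))
  # config file loader reproduces a preset
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    name = "DSSO", linker_mass = dsso$linker_mass,
    stub_masses = as.list(dsso$stub_masses),
    doublet_pair = dsso$doublet_pair,
    hydrolyzed_mod = dsso$hydrolyzed_mod,
    amidated_mod = dsso$amidated_mod
  ), path, auto_unbox = TRUE, digits = NA)
  expect_equal(read_crosslinker_config(path)$doublet_delta,
               dsso$doublet_delta)
})

test_that("theoretical fragments carry stubs on link-site fragments only", {
  pair <- crosslinked_pair("AKAR", "KR", 2, 1, xl_dsso(), charge = 3)
  fr <- theoretical_fragments(pair)

  b1 <- fr[fr$owner == "alpha" & fr$series == "b" & fr$index == 1, ]
  expect_true(all(b1$stub == "none"))
  y3 <- fr[fr$owner == "alpha" & fr$series == "y" & fr$index == 3, ]
  expect_setequal(y3$stub, c("A", "S", "T", "+P"))

  # P-ion m/z: peptide mass + stub + proton at z = 1
  pa <- fr[fr$owner == "alpha" & fr$series == "P" & fr$stub == "A" &
             fr$charge == 1, ]
  expect_equal(pa$mz, peptide_mass("AKAR") + 54.01056 + 1.0072765,
               tolerance = 1e-5)

  # printed stub-mass differences: T - A and S - T (= water)
  for (ser in list(c("P", 0L), c("y", 3L))) {
    sel <- fr[fr$series == ser[1] & fr$index == as.integer(ser[2]) &
                fr$owner == "alpha" & fr$charge == 1, ]
    tA <- sel$neutral[sel$stub == "A"]; tT <- sel$neutral[sel$stub == "T"]
    tS <- sel$neutral[sel$stub == "S"]
    expect_equal(tT - tA, 31.97208, tolerance = 1e-5)
    expect_equal(tS - tT, 18.0105646863, tolerance = 1e-4)
  }

  expect_error(crosslinked_pair("AKAR", "KR", 9, 1, xl_dsso()), "range")
  expect_error(crosslinked_pair("AKAR", "KR", 3, 1, xl_dsso()), "reactive")
})

test_that("fragment complementarity and +P multiplicity hold", {
  withr::with_seed(5, {
    aa <- names(xlfrag:::AA_MONO_MASS)
    for (rep in 1:8) {
      sa <- paste(c(sample(aa, 7, TRUE), "K"), collapse = "")
      sb <- paste(c(sample(aa, 5, TRUE), "R"), collapse = "")
      site_a <- which(strsplit(sa, "")[[1]] %in% c("K", "S", "T", "Y"))[1]
      pair <- crosslinked_pair(sa, sb, site_a, 1, xl_dsso(), charge = 3,
                               validate_sites = FALSE)
      fr <- theoretical_fragments(pair)
      fr1 <- fr[fr$owner == "alpha" & fr$charge == 1 & fr$series != "P", ]
      L <- nchar(sa)
      Mp <- pair$alpha$mass
      for (i in seq_len(L - 1)) {
        bi <- fr1[fr1$series == "b" & fr1$index == i, ]
        yc <- fr1[fr1$series == "y" & fr1$index == L - i, ]
        # the link site sits on exactly one side of each cleavage, so sum
        # a plain fragment with its complement's stub/+P variants
        plain_b <- bi$neutral[bi$stub == "none"]
        plain_y <- yc$neutral[yc$stub == "none"]
        if (length(plain_b)) {
          ya <- yc$neutral[yc$stub == "A"]
          expect_equal(plain_b + ya, Mp + 54.01056, tolerance = 1e-6)
        } else {
          ba <- bi$neutral[bi$stub == "A"]
          expect_equal(ba + plain_y, Mp + 54.01056, tolerance = 1e-6)
        }
        # the cleavage's two fragments share one link side: one +P total
        expect_equal(sum(bi$stub == "+P") + sum(yc$stub == "+P"), 1)
        expect_equal(sum(bi$stub == "+P") * sum(bi$stub == "none"), 0)
      }
    }
  })
})

test_that("non-cleavable and stub-blind modes emit no stub fragments", {
  pair_bs3 <- crosslinked_pair("AKAR", "KR", 2, 1, xl_bs3(), charge = 3)
  fr <- theoretical_fragments(pair_bs3)
  expect_setequal(unique(fr$stub), c("none", "+P"))
  expect_false(any(fr$series == "P"))

  pair <- crosslinked_pair("AKAR", "KR", 2, 1, xl_dsso(), charge = 3)
  blind <- theoretical_fragments(pair, stub_aware = FALSE)
  expect_setequal(unique(blind$stub), c("none", "+P"))
  aware <- theoretical_fragments(pair, stub_aware = TRUE)
  expect_gt(nrow(aware), nrow(blind))
})

test_that("neutral-loss variants follow the site rules", {
  pair <- crosslinked_pair("AKAR", "KR", 2, 1, xl_dsso(), charge = 3)
  fr <- theoretical_fragments(pair, losses = TRUE)
  expect_setequal(unique(fr$loss), c("none", "H2O", "NH3", "CH3SOH"))
  # CH3SOH only on S/T-stub fragments (no oxidized Met here)
  ch3 <- fr[fr$loss == "CH3SOH", ]
  expect_true(all(ch3$stub %in% c("S", "T")))
  h2o <- fr[fr$loss == "H2O" & fr$series == "b" & fr$index == 1 &
              fr$owner == "alpha" & fr$charge == 1, ]
  none <- fr[fr$loss == "none" & fr$series == "b" & fr$index == 1 &
               fr$owner == "alpha" & fr$charge == 1, ]
  expect_equal(none$neutral - h2o$neutral, 18.0105646863)
})
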