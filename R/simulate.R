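# run expr with a locally seeded RNG, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Simulation configuration
#'
#' All knobs of the synthetic crosslinking-MS data generator. Every source
#' of randomness is driven by `seed`; a given configuration always
#' produces identical outputs.
#'
#' The acquisition mode sets the contrast the generator emulates: stepped
#' HCD (`"sHCD"`) records abundant backbone fragments and moderately
#' intense stub doublets in one MS2 scan, while low-energy CID
#' (`"CID_MS2"` / `"CID_MS2_MS3"`) preferentially cleaves the crosslinker,
#' yielding dominant stub doublets but sparse backbone fragmentation.
#' The mode-dependent defaults (`backbone_fragment_prob` 0.8 vs 0.45,
#' `stub_intensity_scale` 2 vs 8) encode that contrast.
#'
#' @param seed Integer seed (mandatory).
#' @param n_proteins,protein_length Size of the random target database.
#' @param crosslinker An [crosslinker()] object (default DSSO).
#' @param n_csms Number of genuine crosslinked spectra to simulate.
#' @param acquisition `"sHCD"`, `"CID_MS2"` or `"CID_MS2_MS3"`.
#' @param doublet_emission_prob Per-peptide probability that the P-ion
#'   stub doublet is emitted.
#' @param stub_intensity_scale Multiplier on the lognormal intensity
#'   scale of stub P ions relative to backbone fragments; `NULL` picks
#'   the acquisition-mode default.
#' @param backbone_fragment_prob Per-cleavage emission probability for
#'   b/y fragments; `NULL` picks the mode default.
#' @param plus_p_prob Probability that an emitted link-site backbone
#'   fragment is additionally emitted as a +P ion.
#' @param extra_stub_prob Probability of additionally emitting a
#'   non-doublet stub P ion (e.g. the DSSO S stub).
#' @param noise_peaks_per_spectrum Number of random noise peaks per
#'   genuine spectrum.
#' @param noise_meanlog,noise_sdlog Lognormal law of noise intensities.
#' @param signal_meanlog,signal_sdlog Lognormal law of backbone fragment
#'   intensities.
#' @param jitter_ppm_sd Gaussian m/z error (ppm) applied to every emitted
#'   ion and precursor.
#' @param n_isotopes Isotope peaks emitted per ion (envelope decays by
#'   `isotope_decay` per peak).
#' @param isotope_decay Intensity ratio of consecutive isotope peaks.
#' @param self_fraction Fraction of pairs drawn within one protein.
#' @param junk_fraction Additional spectra, as a fraction of `n_csms`,
#'   that contain no crosslink: a linear contaminant peptide's backbone
#'   fragments plus dense noise (these drive random matches in searches).
#' @param junk_noise_peaks Noise peaks per junk spectrum.
#' @param ms3_trigger_top_n Doublet peak pairs selected for MS3 per CID
#'   MS2 scan.
#' @param ms3_trigger_ppm Doublet mass-difference tolerance (ppm) of the
#'   emulated trigger logic.
#' @param ms3_backbone_prob Per-cleavage emission probability inside MS3
#'   scans.
#' @param decoy_fraction_of_candidates Fraction of randomly drawn
#'   candidate peptides that are decoys during [run_search()].
#' @param ms2_ppm_tol Fragment match tolerance (ppm) used downstream.
#' @param n_half_candidates,n_random_candidates Competing candidates
#'   evaluated per spectrum in [run_search()].
#' @return A list of class `xl_sim_config`.
#' @export
sim_config <- function(seed,
                       n_proteins = 20, protein_length = 400,
                       crosslinker = xl_dsso(),
                       n_csms = 200,
                       acquisition = c("sHCD", "CID_MS2", "CID_MS2_MS3"),
                       doublet_emission_prob = 0.9,
                       stub_intensity_scale = NULL,
                       backbone_fragment_prob = NULL,
                       plus_p_prob = 0.25,
                       extra_stub_prob = 0.3,
                       noise_peaks_per_spectrum = 60,
                       noise_meanlog = log(20), noise_sdlog = 1,
                       signal_meanlog = log(100), signal_sdlog = 1,
                       jitter_ppm_sd = 2,
                       n_isotopes = 3, isotope_decay = 0.5,
                       self_fraction = 0.1,
                       junk_fraction = 0,
                       junk_noise_peaks = 150,
                       ms3_trigger_top_n = 4,
                       ms3_trigger_ppm = 20,
                       ms3_backbone_prob = 0.8,
                       decoy_fraction_of_candidates = 0.5,
                       ms2_ppm_tol = 15,
                       n_half_candidates = 2,
                       n_random_candidates = 4) {
  acquisition <- match.arg(acquisition)
  cid <- acquisition != "sHCD"
  cfg <- list(
    seed = as.integer(seed),
    n_proteins = n_proteins, protein_length = protein_length,
    crosslinker = crosslinker, n_csms = n_csms, acquisition = acquisition,
    doublet_emission_prob = doublet_emission_prob,
    stub_intensity_scale = stub_intensity_scale %||% (if (cid) 8 else 2),
    backbone_fragment_prob = backbone_fragment_prob %||%
      (if (cid) 0.45 else 0.8),
    plus_p_prob = plus_p_prob, extra_stub_prob = extra_stub_prob,
    noise_peaks_per_spectrum = noise_peaks_per_spectrum,
    noise_meanlog = noise_meanlog, noise_sdlog = noise_sdlog,
    signal_meanlog = signal_meanlog, signal_sdlog = signal_sdlog,
    jitter_ppm_sd = jitter_ppm_sd,
    n_isotopes = n_isotopes, isotope_decay = isotope_decay,
    self_fraction = self_fraction,
    junk_fraction = junk_fraction, junk_noise_peaks = junk_noise_peaks,
    ms3_trigger_top_n = ms3_trigger_top_n,
    ms3_trigger_ppm = ms3_trigger_ppm,
    ms3_backbone_prob = ms3_backbone_prob,
    decoy_fraction_of_candidates = decoy_fraction_of_candidates,
    ms2_ppm_tol = ms2_ppm_tol,
    n_half_candidates = n_half_candidates,
    n_random_candidates = n_random_candidates
  )
  probs <- c(cfg$doublet_emission_prob, cfg$backbone_fragment_prob,
             cfg$plus_p_prob, cfg$extra_stub_prob, cfg$self_fraction,
             cfg$junk_fraction, cfg$ms3_backbone_prob,
             cfg$decoy_fraction_of_candidates)
  stopifnot(all(probs >= 0), all(probs <= 1))
  structure(cfg, class = "xl_sim_config")
}

# amino-acid sampling weights: roughly natural frequencies with K+R at
# ~9% so tryptic peptides average 6-30 residues
AA_SIM_WEIGHTS <- c(
  G = 7, A = 8, S = 7, P = 4, V = 6.5, T = 5.5, C = 1.5, L = 9, I = 5.5,
  N = 4, D = 5.5, Q = 4, K = 5.5, E = 6.5, M = 2, H = 2, F = 4, R = 3.5,
  Y = 3, W = 1
)

#' Generate a random target protein database
#'
#' Random amino-acid sequences drawn with near-natural residue
#' frequencies (K/R tuned so tryptic peptides mostly fall in the 6-30
#' residue range). Deterministic under the config seed.
#'
#' @param config An [sim_config()] object.
#' @return A protein tibble (`accession`, `sequence`, `is_decoy`).
#' @export
generate_protein_db <- function(config) {
  with_local_seed(config$seed, {
    aa <- names(AA_SIM_WEIGHTS)
    w <- AA_SIM_WEIGHTS / sum(AA_SIM_WEIGHTS)
    tibble::tibble(
      accession = sprintf("SYN%03d", seq_len(config$n_proteins)),
      sequence = vapply(seq_len(config$n_proteins), function(i)
        paste(sample(aa, config$protein_length, replace = TRUE, prob = w),
              collapse = ""), character(1)),
      is_decoy = FALSE
    )
  })
}

#' Generate reversed-sequence decoys
#'
#' One decoy per target: the sequence reversed, the accession prefixed.
#' Length distribution and amino-acid composition are preserved exactly.
#'
#' @param targets Protein tibble.
#' @param decoy_prefix Accession prefix (default `"REV_"`).
#' @return Decoy protein tibble.
#' @export
generate_decoy_db <- function(targets, decoy_prefix = "REV_") {
  tibble::tibble(
    accession = paste0(decoy_prefix, targets$accession),
    sequence = vapply(strsplit(targets$sequence, ""), function(x)
      paste(rev(x), collapse = ""), character(1)),
    is_decoy = TRUE
  )
}

# eligible linkable peptides: an internal reactive residue exists
linkable_peptides <- function(peptides, crosslinker) {
  sites <- lapply(strsplit(peptides$sequence, ""), function(res) {
    which(res[-length(res)] %in% crosslinker$reactive_sites)
  })
  keep <- lengths(sites) > 0
  peptides <- peptides[keep, ]
  peptides$link_sites <- sites[keep]
  peptides
}

# lognormal intensity draw
rint <- function(n, meanlog, sdlog) stats::rlnorm(n, meanlog, sdlog)

# emit one ion as an isotope envelope of raw peaks
emit_envelope <- function(mz0, z, intensity, cfg) {
  k <- 0:(cfg$n_isotopes - 1L)
  data.frame(mz = mz0 + k * ISOTOPE_SPACING / z,
             intensity = intensity * cfg$isotope_decay^k)
}

#' Simulate crosslinked-peptide fragmentation spectra with ground truth
#'
#' Draws `n_csms` crosslinked peptide pairs from the tryptic peptides of
#' the target database and emits one MS2 spectrum per pair:
#' intact-peptide stub doublets per peptide with probability
#' `doublet_emission_prob` (intensity scaled by `stub_intensity_scale`),
#' b/y backbone fragments per cleavage position with probability
#' `backbone_fragment_prob` (link-site fragments carry a cleaved stub
#' and/or the intact partner, +P), isotope envelopes, m/z jitter, and
#' random noise peaks. If `junk_fraction > 0`, additional crosslink-free
#' spectra containing a linear contaminant peptide are appended.
#'
#' The ground-truth table records each CSM's peptides, link sites,
#' doublet emissions and true per-peptide coverage; `stub_ions` is a list
#' column of the emitted stub P ions (owner, label, charge, observed m/z)
#' used to verify MS3 triggering.
#'
#' @param config An [sim_config()] object.
#' @param proteins Optional target protein tibble; generated from the
#'   config when omitted.
#' @return A list with `spectra` ([xl_spectra()]), `truth` (tibble),
#'   `pairs` (list of [crosslinked_pair()]), and `proteins`.
#' @export
simulate_crosslinked_spectra <- function(config, proteins = NULL) {
  cfg <- config
  xl <- cfg$crosslinker
  if (is.null(proteins)) proteins <- generate_protein_db(cfg)
  peptides <- tryptic_digest(proteins, max_missed = 2, length_range = c(6, 30))
  peptides <- peptides[!duplicated(peptides$sequence), ]
  pool <- linkable_peptides(peptides, xl)
  if (nrow(pool) < 2) stop("too few linkable peptides", call. = FALSE)

  with_local_seed(cfg$seed + 1L, {
    n_junk <- round(cfg$n_csms * cfg$junk_fraction)
    spectra_rows <- vector("list", cfg$n_csms + n_junk)
    truth_rows <- vector("list", cfg$n_csms + n_junk)
    pairs <- vector("list", cfg$n_csms)

    for (ci in seq_len(cfg$n_csms)) {
      self <- stats::runif(1) < cfg$self_fraction
      ia <- sample.int(nrow(pool), 1)
      same_prot <- which(pool$accession == pool$accession[ia])
      same_prot <- setdiff(same_prot, ia)
      ib <- if (self && length(same_prot)) sample(rep(same_prot, 2), 1) else
        sample(rep(setdiff(which(pool$accession != pool$accession[ia]), ia),
                   2), 1)
      pa <- pool[ia, ]; pb <- pool[ib, ]
      sa <- sample(rep(pa$link_sites[[1]], 2), 1)
      sb <- sample(rep(pb$link_sites[[1]], 2), 1)
      z <- sample(3:5, 1)
      pair <- crosslinked_pair(
        list(sequence = pa$sequence, accession = pa$accession),
        list(sequence = pb$sequence, accession = pb$accession),
        sa, sb, xl, charge = z, validate_sites = FALSE
      )
      pairs[[ci]] <- pair

      peaks <- list()
      stub_ion_rows <- list()
      truth_cov <- c(alpha = 0, beta = 0)
      doublet_emitted <- c(alpha = FALSE, beta = FALSE)
      for (owner in c("alpha", "beta")) {
        pep <- pair[[owner]]
        site <- pair[[paste0("site_", owner)]]
        rm <- pep_residue_masses(pep)
        cs <- cumsum(rm$masses)
        L <- pep$length
        # signature doublet (P ions with each doublet stub label)
        if (xl$cleavable && stats::runif(1) < cfg$doublet_emission_prob) {
          doublet_emitted[owner] <- TRUE
          zd <- sample.int(max(1L, min(2L, z - 1L)), 1)
          labs <- xl$doublet_pair
          if (length(xl$stub_masses) > length(labs) &&
              stats::runif(1) < cfg$extra_stub_prob)
            labs <- names(xl$stub_masses)
          for (lab in labs) {
            mz0 <- mz_of(pep$mass + xl$stub_masses[[lab]], zd)
            mz0 <- mz0 * (1 + stats::rnorm(1, 0, cfg$jitter_ppm_sd) * 1e-6)
            intens <- rint(1, cfg$signal_meanlog +
                             log(cfg$stub_intensity_scale), cfg$signal_sdlog)
            peaks[[length(peaks) + 1L]] <- emit_envelope(mz0, zd, intens, cfg)
            stub_ion_rows[[length(stub_ion_rows) + 1L]] <- data.frame(
              owner = owner, stub = lab, charge = zd, mz = mz0)
          }
        }
        # backbone fragments
        emitted_pos <- 0L
        for (series in c("b", "y")) {
          for (i in seq_len(L - 1L)) {
            if (stats::runif(1) >= cfg$backbone_fragment_prob) next
            emitted_pos <- emitted_pos + 1L
            neutral <- if (series == "b") rm$nterm_extra + cs[i] else
              cs[L] - cs[L - i] + H2O_MASS
            has_link <- if (series == "b") site <= i else site > L - i
            zf <- sample(c(1L, 2L), 1, prob = c(0.8, 0.2))
            zf <- min(zf, max(1L, z - 1L))
            emit_ion <- function(neutral_mass) {
              mz0 <- mz_of(neutral_mass, zf) *
                (1 + stats::rnorm(1, 0, cfg$jitter_ppm_sd) * 1e-6)
              peaks[[length(peaks) + 1L]] <<-
                emit_envelope(mz0, zf, rint(1, cfg$signal_meanlog,
                                            cfg$signal_sdlog), cfg)
            }
            if (!has_link) {
              emit_ion(neutral)
            } else if (xl$cleavable) {
              lab <- sample(names(xl$stub_masses), 1)
              emit_ion(neutral + xl$stub_masses[[lab]])
              if (stats::runif(1) < cfg$plus_p_prob) {
                other <- pair[[if (owner == "alpha") "beta" else "alpha"]]
                emit_ion(neutral + xl$linker_mass + other$mass)
              }
            } else {
              other <- pair[[if (owner == "alpha") "beta" else "alpha"]]
              emit_ion(neutral + xl$linker_mass + other$mass)
            }
          }
        }
        truth_cov[owner] <- emitted_pos / (2 * (L - 1))
      }
      if (cfg$noise_peaks_per_spectrum > 0) {
        nn <- cfg$noise_peaks_per_spectrum
        peaks[[length(peaks) + 1L]] <- data.frame(
          mz = stats::runif(nn, 150, 1800),
          intensity = rint(nn, cfg$noise_meanlog, cfg$noise_sdlog)
        )
      }
      pk <- do.call(rbind, peaks)
      prec_mz <- mz_of(pair_mass(pair), z) *
        (1 + stats::rnorm(1, 0, cfg$jitter_ppm_sd) * 1e-6)
      scan <- sprintf("MS2_%05d", ci)
      spectra_rows[[ci]] <- list(scan_id = scan, ms_level = 2L,
                                 precursor_mz = prec_mz,
                                 precursor_charge = z, peaks = pk)
      truth_rows[[ci]] <- tibble::tibble(
        csm_id = ci, scan_id = scan, is_true_csm = TRUE,
        alpha_seq = pair$alpha$sequence, beta_seq = pair$beta$sequence,
        alpha_acc = pair$alpha$accession, beta_acc = pair$beta$accession,
        site_alpha = sa, site_beta = sb, charge = z,
        self_link = pair$alpha$accession == pair$beta$accession,
        doublet_alpha = doublet_emitted[["alpha"]],
        doublet_beta = doublet_emitted[["beta"]],
        true_coverage_alpha = truth_cov[["alpha"]],
        true_coverage_beta = truth_cov[["beta"]],
        contaminant_seq = NA_character_,
        stub_ions = list(dplyr::bind_rows(stub_ion_rows))
      )
    }

    # crosslink-free "junk" spectra: a linear contaminant peptide plus
    # dense noise; these supply the random-match population for searches
    for (ji in seq_len(n_junk)) {
      idx <- cfg$n_csms + ji
      pc <- pool[sample.int(nrow(pool), 1), ]
      rm <- pep_residue_masses(list(sequence = pc$sequence, mod_mass = 0,
                                    mod_position = NA, mod_label = ""))
      cs <- cumsum(rm$masses)
      L <- nchar(pc$sequence)
      peaks <- list()
      for (series in c("b", "y")) {
        for (i in seq_len(L - 1L)) {
          if (stats::runif(1) >= 0.7) next
          neutral <- if (series == "b") cs[i] else cs[L] - cs[L - i] + H2O_MASS
          mz0 <- mz_of(neutral, 1L) *
            (1 + stats::rnorm(1, 0, cfg$jitter_ppm_sd) * 1e-6)
          peaks[[length(peaks) + 1L]] <-
            emit_envelope(mz0, 1L, rint(1, cfg$signal_meanlog,
                                        cfg$signal_sdlog), cfg)
        }
      }
      nn <- cfg$junk_noise_peaks
      peaks[[length(peaks) + 1L]] <- data.frame(
        mz = stats::runif(nn, 150, 1800),
        intensity = rint(nn, cfg$noise_meanlog, cfg$noise_sdlog)
      )
      pk <- do.call(rbind, peaks)
      z <- sample(3:5, 1)
      scan <- sprintf("MS2_%05d", idx)
      spectra_rows[[idx]] <- list(
        scan_id = scan, ms_level = 2L,
        precursor_mz = stats::runif(1, 400, 1200), precursor_charge = z,
        peaks = pk
      )
      truth_rows[[idx]] <- tibble::tibble(
        csm_id = idx, scan_id = scan, is_true_csm = FALSE,
        alpha_seq = NA_character_, beta_seq = NA_character_,
        alpha_acc = NA_character_, beta_acc = NA_character_,
        site_alpha = NA_integer_, site_beta = NA_integer_, charge = z,
        self_link = FALSE, doublet_alpha = FALSE, doublet_beta = FALSE,
        true_coverage_alpha = NA_real_, true_coverage_beta = NA_real_,
        contaminant_seq = pc$sequence,
        stub_ions = list(tibble::tibble())
      )
    }

    spectra <- xl_spectra(
      scan_id = vapply(spectra_rows, `[[`, "", "scan_id"),
      ms_level = vapply(spectra_rows, `[[`, integer(1), "ms_level"),
      precursor_mz = vapply(spectra_rows, `[[`, numeric(1), "precursor_mz"),
      precursor_charge =
        vapply(spectra_rows, `[[`, integer(1), "precursor_charge"),
      peaks = lapply(spectra_rows, `[[`, "peaks")
    )
    list(spectra = spectra, truth = dplyr::bind_rows(truth_rows),
         pairs = pairs, proteins = proteins, peptides = peptides,
         config = cfg)
  })
}

#' Emulate doublet-triggered MS3 acquisition on CID MS2 scans
#'
#' Mirrors the instrument's trigger logic on the observed peak list: the
#' MS2 peaks are scanned for peak pairs separated by the crosslinker's
#' doublet mass difference at charge 1 or 2 (within `ms3_trigger_ppm`);
#' up to `ms3_trigger_top_n` such doublet pairs, ranked by the intensity
#' of their more intense peak, each trigger an MS3 scan on the lighter
#' (A-stub) peak. Because the scan is over observed peaks, coincidental
#' mass-difference pairs (noise, linear-peptide fragments) produce
#' realistic false triggers. Correctly triggered MS3 scans contain
#' backbone fragments of the stub-bearing released peptide; false
#' triggers contain only noise.
#'
#' @param config The [sim_config()] used for the MS2 simulation.
#' @param sim Result of [simulate_crosslinked_spectra()].
#' @return A list with `ms3_spectra` ([xl_spectra()]) and
#'   `trigger_truth` (tibble: scan ids, parent CSM, whether the selected
#'   peak really was an emitted stub P ion, and for which peptide).
#' @export
simulate_cid_ms3_run <- function(config, sim) {
  cfg <- config
  xl <- cfg$crosslinker
  stopifnot(xl$cleavable)
  delta <- xl$doublet_delta
  with_local_seed(cfg$seed + 2L, {
    ms3_rows <- list()
    truth_rows <- list()
    counter <- 0L
    for (si in seq_len(nrow(sim$spectra))) {
      spec <- sim$spectra[si, ]
      tr <- sim$truth[sim$truth$scan_id == spec$scan_id, ]
      pk <- spec$peaks[[1]]
      if (nrow(pk) < 2 || cfg$ms3_trigger_top_n < 1) next
      mz <- pk$mz; int <- pk$intensity
      cand <- list()
      for (zd in 1:2) {
        target <- mz + delta / zd
        hi <- findInterval(target * (1 + cfg$ms3_trigger_ppm * 1e-6), mz)
        lo <- findInterval(target * (1 - cfg$ms3_trigger_ppm * 1e-6), mz) + 1L
        for (i in which(lo <= hi)) {
          js <- lo[i]:hi[i]
          j <- js[which.min(abs(mz[js] - target[i]))]
          cand[[length(cand) + 1L]] <-
            data.frame(light = i, heavy = j, zd = zd,
                       intensity = pmax(int[i], int[j]))
        }
      }
      if (!length(cand)) next
      cand <- do.call(rbind, cand)
      cand <- cand[!duplicated(cand$light), , drop = FALSE]
      cand <- cand[order(-cand$intensity), , drop = FALSE]
      # greedy selection with isotope exclusion: skip candidates whose
      # selected peak sits on an isotope position of an already selected
      # one (instruments exclude envelope members from re-triggering)
      sel <- integer(0)
      iso_offsets <- outer(-5:5, 1 / (1:2)) * ISOTOPE_SPACING
      for (r in seq_len(nrow(cand))) {
        m <- mz[cand$light[r]]
        if (length(sel)) {
          prev <- mz[cand$light[sel]]
          d <- abs(outer(m - prev, as.vector(iso_offsets), `-`))
          if (any(d < cfg$ms3_trigger_ppm * 1e-6 * m)) next
        }
        sel <- c(sel, r)
        if (length(sel) >= cfg$ms3_trigger_top_n) break
      }
      cand <- cand[sel, , drop = FALSE]

      stub_truth <- tr$stub_ions[[1]]
      for (k in seq_len(nrow(cand))) {
        counter <- counter + 1L
        sel_mz <- mz[cand$light[k]]
        owner <- NA_character_
        stub_lab <- NA_character_
        if (nrow(stub_truth) > 0) {
          # the trigger is correct if the selected peak is any emitted
          # stub P ion, whichever stub label it carries
          d <- abs(stub_truth$mz - sel_mz) / sel_mz * 1e6
          hit <- which(d < 0.5)
          if (length(hit)) {
            owner <- stub_truth$owner[hit[1]]
            stub_lab <- stub_truth$stub[hit[1]]
          }
        }
        is_true <- !is.na(owner)
        if (is_true) {
          pep <- if (owner == "alpha")
            list(sequence = tr$alpha_seq, site = tr$site_alpha) else
              list(sequence = tr$beta_seq, site = tr$site_beta)
          frags <- linear_stub_fragments(
            pep$sequence, pep$site,
            xl$stub_masses[[stub_lab]], max_charge = 1L)
          emit <- frags[stats::runif(nrow(frags)) < cfg$ms3_backbone_prob, ]
          sig <- if (nrow(emit)) data.frame(
            mz = emit$mz * (1 + stats::rnorm(nrow(emit), 0,
                                             cfg$jitter_ppm_sd) * 1e-6),
            intensity = rint(nrow(emit), cfg$signal_meanlog,
                             cfg$signal_sdlog)
          ) else NULL
        } else sig <- NULL
        noise <- data.frame(
          mz = stats::runif(25, 100, 1500),
          intensity = rint(25, cfg$noise_meanlog, cfg$noise_sdlog)
        )
        pk3 <- rbind(sig, noise)
        scan3 <- sprintf("MS3_%06d", counter)
        ms3_rows[[length(ms3_rows) + 1L]] <- list(
          scan_id = scan3, parent = spec$scan_id, selected = sel_mz,
          charge = cand$zd[k], peaks = pk3
        )
        truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
          ms3_scan_id = scan3, parent_scan_id = spec$scan_id,
          csm_id = tr$csm_id, parent_is_csm = tr$is_true_csm,
          selected_mz = sel_mz, is_true_stub = is_true,
          owner = owner, stub = stub_lab
        )
      }
    }
    ms3 <- if (length(ms3_rows)) xl_spectra(
      scan_id = vapply(ms3_rows, `[[`, "", "scan_id"),
      ms_level = 3L,
      precursor_mz = vapply(ms3_rows, `[[`, numeric(1), "selected"),
      precursor_charge = vapply(ms3_rows, `[[`, integer(1), "charge"),
      peaks = lapply(ms3_rows, `[[`, "peaks"),
      parent_scan_id = vapply(ms3_rows, `[[`, "", "parent"),
      selected_precursor_mz = vapply(ms3_rows, `[[`, numeric(1), "selected")
    ) else xl_spectra(character(), integer(), numeric(), integer(), list())
    list(ms3_spectra = ms3, trigger_truth = dplyr::bind_rows(truth_rows))
  })
}
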