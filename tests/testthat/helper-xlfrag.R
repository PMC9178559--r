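# shared fixture builders (all generated in code, nothing stored on disk)

# random spectra table for I/O round-trip tests
random_spectra <- function(n, seed = 42, with_ms3 = FALSE) {
  withr::with_seed(seed, {
    peaks <- lapply(seq_len(n), function(i) {
      k <- sample(0:40, 1)
      tibble::tibble(mz = sort(runif(k, 100, 2000)),
                     intensity = round(runif(k, 1, 1e5), 3))
    })
    ms_level <- rep(2L, n)
    parent <- rep(NA_character_, n)
    sel <- rep(NA_real_, n)
    if (with_ms3 && n >= 4) {
      idx <- seq(2, n, by = 3)
      ms_level[idx] <- 3L
      parent[idx] <- sprintf("S%03d", idx - 1L)
      sel[idx] <- round(runif(length(idx), 200, 900), 4)
    }
    xl_spectra(
      scan_id = sprintf("S%03d", seq_len(n)),
      ms_level = ms_level,
      precursor_mz = round(runif(n, 300, 1500), 4),
      precursor_charge = sample(2:5, n, replace = TRUE),
      peaks = peaks,
      retention_time = round(runif(n, 0, 3600), 2),
      parent_scan_id = parent,
      selected_precursor_mz = sel
    )
  })
}

# minimal match-table builder for doublet/coverage unit tests
make_matches <- function(owner, series, index, stub, charge = 1L,
                         rank = seq_along(owner), loss = "none") {
  tibble::tibble(
    owner = owner, series = series, index = as.integer(index),
    stub = stub, loss = loss, charge = as.integer(charge),
    contains_link_site = !stub %in% "none",
    rank = as.integer(rank)
  )
}

# random CSM score table for FDR unit tests
random_csm_scores <- function(n, seed = 1, p_decoy = 0.3) {
  withr::with_seed(seed, {
    tibble::tibble(
      csm_id = seq_len(n),
      scan_id = sprintf("S%05d", seq_len(n)),
      alpha_seq = replicate(n, paste(sample(LETTERS[1:20], 8, TRUE),
                                     collapse = "")),
      beta_seq = replicate(n, paste(sample(LETTERS[1:20], 8, TRUE),
                                    collapse = "")),
      alpha_mod = "", beta_mod = "",
      site_alpha = sample(1:5, n, TRUE), site_beta = sample(1:5, n, TRUE),
      charge = sample(3:5, n, TRUE),
      score = round(runif(n, 0, 2), 4),
      delta_score = runif(n, 0, 1),
      matched_frags_alpha = sample(0:20, n, TRUE),
      matched_frags_beta = sample(0:20, n, TRUE),
      alpha_is_decoy = runif(n) < p_decoy,
      beta_is_decoy = runif(n) < p_decoy,
      alpha_acc = sample(sprintf("P%02d", 1:10), n, TRUE),
      beta_acc = sample(sprintf("P%02d", 1:10), n, TRUE),
      self_link = runif(n) < 0.2,
      doublet_class = sample(0:2, n, TRUE),
      coverage_alpha = runif(n), coverage_beta = runif(n),
      noncovalent_flag = runif(n) < 0.05
    )
  })
}

# independent brute-force grouped-FDR oracle (threshold scan with loops)
oracle_fdr_threshold <- function(score, class, level) {
  ord <- order(-score)
  score <- score[ord]; class <- class[ord]
  n <- length(score)
  raw <- rep(Inf, n)
  for (i in seq_len(n)) {
    if (i < n && score[i + 1] == score[i]) next  # cannot cut inside a tie
    s <- score[seq_len(i)]
    tt <- sum(class[seq_len(i)] == "TT")
    td <- sum(class[seq_len(i)] == "TD")
    dd <- sum(class[seq_len(i)] == "DD")
    raw[i] <- if (tt == 0) Inf else max(0, td - dd) / tt
  }
  q <- raw
  for (i in rev(seq_len(n - 1))) q[i] <- min(q[i], q[i + 1])
  pass <- which(q <= level)
  if (!length(pass)) return(list(threshold = NA_real_, n_pass = 0L))
  list(threshold = score[max(pass)], n_pass = max(pass),
       achieved = q[max(pass)])
}
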