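#' Run the simulation/search/FDR pipeline and write stage outputs
#'
#' Executes the deterministic chain simulate -> search -> fdr -> report up
#' to the requested stage and writes each completed stage's outputs to
#' `out_dir`: the simulated MGF (MS2 and, for CID-MS2-MS3 acquisition,
#' MS3 scans), target+decoy FASTA, ground-truth TSV, CSM table, FDR
#' summaries and report tables, plus a `manifest.json` recording the
#' command, the configuration snapshot, the seed, the package version and
#' the output files. Rerunning with an identical configuration reproduces
#' identical data outputs.
#'
#' @param command One of `"simulate"`, `"search"`, `"fdr"`, `"report"`
#'   (each implies the stages before it).
#' @param config An [sim_config()] object.
#' @param out_dir Output directory (created if needed).
#' @param fdr_level FDR level for the fdr/report stages.
#' @return Invisibly, a list with the in-memory stage results
#'   (`sim`, `ms3`, `csms`, `fdr`, `report`).
#' @export
run_pipeline <- function(command = c("report", "simulate", "search", "fdr"),
                         config, out_dir, fdr_level = 0.05) {
  command <- match.arg(command)
  stages <- c("simulate", "search", "fdr", "report")
  upto <- match(command, stages)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  res <- list()

  res$sim <- simulate_crosslinked_spectra(config)
  spectra <- res$sim$spectra
  if (config$acquisition == "CID_MS2_MS3" && config$crosslinker$cleavable) {
    res$ms3 <- simulate_cid_ms3_run(config, res$sim)
    spectra <- dplyr::bind_rows(spectra, res$ms3$ms3_spectra)
    class(spectra) <- class(res$sim$spectra)
  }
  p <- file.path(out_dir, "spectra.mgf")
  serialize_mgf(spectra, p); outputs <- c(outputs, p)
  p <- file.path(out_dir, "database.fasta")
  write_fasta(dplyr::bind_rows(res$sim$proteins,
                               generate_decoy_db(res$sim$proteins)), p)
  outputs <- c(outputs, p)
  p <- file.path(out_dir, "truth.tsv")
  readr::write_tsv(dplyr::select(res$sim$truth, -"stub_ions"), p,
                   progress = FALSE)
  outputs <- c(outputs, p)

  if (upto >= 2) {
    res$csms <- run_search(res$sim, config)
    p <- file.path(out_dir, "csms.tsv")
    write_csm_table(res$csms, p); outputs <- c(outputs, p)
  }
  if (upto >= 3) {
    res$fdr <- estimate_fdr_grouped(prefilter_csms(res$csms),
                                    level = fdr_level)
    p <- file.path(out_dir, "fdr_groups.tsv")
    readr::write_tsv(tidy(res$fdr), p, progress = FALSE)
    outputs <- c(outputs, p)
    p <- file.path(out_dir, "csms_passing.tsv")
    readr::write_tsv(
      dplyr::select(passing_csms(res$fdr),
                    -dplyr::any_of(c("matches", "peaks"))), p,
      progress = FALSE)
    outputs <- c(outputs, p)
  }
  if (upto >= 4) {
    res$report <- report_tables(res, fdr_level = fdr_level)
    for (nm in names(res$report)) {
      p <- file.path(out_dir, paste0("report_", nm, ".tsv"))
      readr::write_tsv(res$report[[nm]], p, progress = FALSE)
      outputs <- c(outputs, p)
    }
  }

  manifest <- list(
    command = command,
    seed = config$seed,
    config = config[setdiff(names(config), "crosslinker")],
    crosslinker = config$crosslinker$name,
    fdr_level = fdr_level,
    outputs = basename(outputs),
    tool_version = as.character(utils::packageVersion("xlfrag")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}

#' Figure-panel-style summary tables
#'
#' Computes, from in-memory pipeline results, the summary tables that
#' mirror the standard QC panels of a cleavable-crosslinker analysis:
#' doublet prevalence of target-target CSMs, cumulative doublet rank
#' curves, doublet prevalence among heteromeric target-decoy matches,
#' doublet-prefilter yields, FDR group summaries and (when MS3 data are
#' present) MS3 trigger-correctness proportions.
#'
#' @param res Pipeline results list with at least `csms` (from
#'   [run_search()]); optionally `ms3` trigger truth.
#' @param fdr_level FDR level for yield tables.
#' @return A named list of tibbles.
#' @export
report_tables <- function(res, fdr_level = 0.05) {
  csms <- res$csms
  out <- list()
  tt <- dplyr::filter(csms, !.data$alpha_is_decoy, !.data$beta_is_decoy,
                      .data$is_true_csm)
  out$doublet_prevalence <- doublet_prevalence_summary(tt$doublet_class)
  out$doublet_rank_curve <- doublet_rank_curve(
    tt$best_doublet_rank, cutoffs = c(1, 2, 5, 10, 20, 50, 100))
  td <- dplyr::filter(csms, !.data$self_link,
                      td_class(.data$alpha_is_decoy,
                               .data$beta_is_decoy) == "TD")
  out$td_doublet_prevalence <- doublet_prevalence_summary(td$doublet_class)
  fdr <- estimate_fdr_grouped(csms, level = fdr_level)
  out$fdr_groups <- tidy(fdr)
  cmp <- doublet_filter_comparison(csms, level = fdr_level)
  out$doublet_filter_yields <- cmp$yields
  out$score_distributions <- cmp$scores
  out$fdr_curves <- cmp$fdr_curves
  if (!is.null(res$ms3)) {
    tru <- res$ms3$trigger_truth
    parents <- dplyr::filter(res$csms, .data$is_true_csm)
    per_csm <- vapply(parents$csm_id, function(id) {
      k <- tru[tru$csm_id == id & tru$is_true_stub, ]
      length(unique(k$owner))
    }, integer(1))
    out$ms3_trigger_proportions <- tibble::tibble(
      n_correct = 0:2,
      proportion = vapply(0:2, function(k) mean(per_csm == k), numeric(1))
    )
    out$ms3_per_parent <- tru |>
      dplyr::count(.data$parent_scan_id, .data$parent_is_csm,
                   name = "n_ms3") |>
      dplyr::group_by(.data$parent_is_csm) |>
      dplyr::summarise(mean_ms3_per_ms2 = mean(.data$n_ms3),
                       n_parents = dplyr::n(), .groups = "drop")
  }
  out
}

#' Intersect two CSM sets on the unique pair key
#'
#' Matches CSMs of two runs (e.g. two acquisition methods or two
#' crosslinker search modes) identified as the same peptide-pair species:
#' identical peptide sequences, modifications, link sites and precursor
#' charge.
#'
#' @param csms_x,csms_y CSM tibbles.
#' @param suffix Column suffixes for the joined table.
#' @return A joined tibble with one row per common unique CSM.
#' @export
compare_common_csms <- function(csms_x, csms_y, suffix = c("_x", "_y")) {
  kx <- dplyr::mutate(csms_x, .key = csm_unique_key(csms_x))
  ky <- dplyr::mutate(csms_y, .key = csm_unique_key(csms_y))
  kx <- kx[!duplicated(kx$.key), ]
  ky <- ky[!duplicated(ky$.key), ]
  keep <- c(".key", "scan_id", "score", "doublet_class",
            "coverage_alpha", "coverage_beta")
  dplyr::inner_join(
    dplyr::select(kx, dplyr::any_of(keep)),
    dplyr::select(ky, dplyr::any_of(keep)),
    by = ".key", suffix = suffix
  )
}

#' Paired coverage comparison between two conditions
#'
#' Two-sided Wilcoxon signed-rank test on paired per-CSM coverage values
#' (e.g. sHCD vs CID+MS3, or cleavable vs noncleavable annotation).
#'
#' @param x,y Paired numeric coverage vectors.
#' @return One-row tibble: n, medians, and the Wilcoxon p-value.
#' @export
paired_coverage_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  p <- if (sum(keep) >= 2 && any(x[keep] != y[keep]))
    stats::wilcox.test(x[keep], y[keep], paired = TRUE)$p.value
  else NA_real_
  tibble::tibble(n = sum(keep), median_x = stats::median(x[keep]),
                 median_y = stats::median(y[keep]), p_value = p)
}
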