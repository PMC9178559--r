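#' Tidy a grouped FDR result
#'
#' @param x An `xl_fdr` object.
#' @param ... Unused.
#' @return The per-group summary tibble (group, threshold score, TT/TD/DD
#'   counts above threshold, achieved FDR).
#' @method tidy xl_fdr
#' @export
tidy.xl_fdr <- function(x, ...) {
  x$groups
}

#' One-row summary of a grouped FDR result
#'
#' @param x An `xl_fdr` object.
#' @param ... Unused.
#' @return A one-row tibble: requested level, total unique CSMs, passing
#'   target-target CSMs overall and in the heteromeric group.
#' @method glance xl_fdr
#' @export
glance.xl_fdr <- function(x, ...) {
  pass <- x$csms[x$csms$pass & x$csms$td_class == "TT", ]
  tibble::tibble(
    level = x$level,
    n_unique_csms = nrow(x$csms),
    n_pass_tt = nrow(pass),
    n_pass_tt_heteromeric = sum(pass$group == "heteromeric"),
    n_groups_degenerate = sum(x$groups$degenerate)
  )
}
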