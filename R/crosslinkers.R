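#' Define a (possibly MS-cleavable) crosslinker
#'
#' A crosslinker is described by its reactive residues, the mass it adds
#' when intact (`linker_mass`), its hydrolyzed and amidated dead-end
#' modification masses, and -- for MS-cleavable reagents -- the masses of
#' the stub fragments left on each peptide after gas-phase cleavage
#' together with the pair of stub labels that forms the signature doublet.
#'
#' For a cleavable reagent the two complementary stubs (e.g. alkene and
#' sulfenic acid for DSSO) sum to `linker_mass`, and the doublet delta is
#' the mass difference of the two doublet labels (DSSO A/T: 31.97208 Da).
#'
#' @param name Short reagent name, e.g. `"DSSO"`.
#' @param linker_mass Mass (Da) added by the intact crosslinker.
#' @param stub_masses Named numeric vector of stub label -> mass (Da);
#'   empty for non-cleavable reagents.
#' @param doublet_pair Character vector of the two stub labels whose peak
#'   pair forms the signature doublet (light, heavy); `NULL` if
#'   non-cleavable.
#' @param hydrolyzed_mod,amidated_mod Dead-end modification masses (Da).
#' @param reactive_sites One-letter codes of linkable side chains.
#' @param cleavable Logical; does the reagent cleave in the mass
#'   spectrometer?
#' @return An object of class `xl_crosslinker`.
#' @seealso [xl_dsso()], [xl_dsbu()], [xl_bs3()], [read_crosslinker_config()]
#' @export
#' @examples
#' dsso <- xl_dsso()
#' doublet_delta(dsso)
crosslinker <- function(name, linker_mass, stub_masses = numeric(),
                        doublet_pair = NULL,
                        hydrolyzed_mod, amidated_mod,
                        reactive_sites = c("K", "S", "T", "Y"),
                        cleavable = length(stub_masses) > 0) {
  stopifnot(is.character(name), length(name) == 1,
            is.numeric(linker_mass), length(linker_mass) == 1)
  if (cleavable) {
    if (length(stub_masses) == 0 || is.null(names(stub_masses)))
      stop("a cleavable crosslinker needs named stub masses", call. = FALSE)
    if (is.null(doublet_pair) || length(doublet_pair) != 2 ||
        !all(doublet_pair %in% names(stub_masses)))
      stop("doublet_pair must name two stub labels", call. = FALSE)
    delta <- unname(stub_masses[doublet_pair[2]] - stub_masses[doublet_pair[1]])
    if (delta <= 0)
      stop("doublet_pair must be ordered (light, heavy)", call. = FALSE)
  } else {
    doublet_pair <- NULL
    delta <- NA_real_
  }
  structure(
    list(
      name = name,
      linker_mass = linker_mass,
      stub_masses = stub_masses,
      doublet_pair = doublet_pair,
      doublet_delta = delta,
      hydrolyzed_mod = hydrolyzed_mod,
      amidated_mod = amidated_mod,
      reactive_sites = reactive_sites,
      cleavable = cleavable
    ),
    class = "xl_crosslinker"
  )
}

#' @export
print.xl_crosslinker <- function(x, ...) {
  cat("<xl_crosslinker> ", x$name,
      if (x$cleavable) " (MS-cleavable)" else " (non-cleavable)", "\n", sep = "")
  cat("  linker mass: ", format(x$linker_mass, nsmall = 5), " Da\n", sep = "")
  if (x$cleavable) {
    cat("  stubs: ",
        paste(sprintf("%s=%.5f", names(x$stub_masses), x$stub_masses),
              collapse = ", "), "\n", sep = "")
    cat("  doublet: ", paste(x$doublet_pair, collapse = "-"),
        sprintf(" (delta %.5f Da)", x$doublet_delta), "\n", sep = "")
  }
  cat("  reactive sites: ", paste(x$reactive_sites, collapse = ", "),
      " + protein N-terminus\n", sep = "")
  invisible(x)
}

#' Signature doublet mass difference
#'
#' @param crosslinker An [crosslinker()] object.
#' @return The neutral mass difference (Da) between the heavy and light
#'   doublet stubs, or `NA` for a non-cleavable reagent.
#' @export
doublet_delta <- function(crosslinker) {
  stopifnot(inherits(crosslinker, "xl_crosslinker"))
  crosslinker$doublet_delta
}

#' Built-in crosslinker presets
#'
#' DSSO (disuccinimidyl sulfoxide) cleaves asymmetrically into an alkene
#' (A, 54.01056 Da) and a sulfenic-acid (S, 103.99320 Da) stub; the S stub
#' commonly loses water to the unsaturated thiol (T, 85.98264 Da), so the
#' A/T pair forms the signature doublet. DSBU (disuccinimidyl dibutyric
#' urea) leaves A (85.05276 Da) and B (111.032028 Da) stubs. BS3 is
#' non-cleavable: no stubs, link-site evidence only through fragments
#' carrying the intact partner peptide.
#'
#' @return An `xl_crosslinker` object.
#' @name crosslinker-presets
NULL

#' @rdname crosslinker-presets
#' @export
xl_dsso <- function() {
  crosslinker(
    name = "DSSO",
    linker_mass = 54.01056 + 103.99320,
    stub_masses = c(A = 54.01056, T = 85.98264, S = 103.99320),
    doublet_pair = c("A", "T"),
    hydrolyzed_mod = 176.01433,
    amidated_mod = 175.03031
  )
}

#' @rdname crosslinker-presets
#' @export
xl_dsbu <- function() {
  crosslinker(
    name = "DSBU",
    linker_mass = 85.05276 + 111.032028,
    stub_masses = c(A = 85.05276, B = 111.032028),
    doublet_pair = c("A", "B"),
    hydrolyzed_mod = 214.095357,
    amidated_mod = 213.11134
  )
}

#' @rdname crosslinker-presets
#' @export
xl_bs3 <- function() {
  crosslinker(
    name = "BS3",
    linker_mass = 138.06808,
    stub_masses = numeric(),
    hydrolyzed_mod = 156.07864,
    amidated_mod = 155.09463,
    cleavable = FALSE
  )
}

#' Load a crosslinker definition from a YAML/JSON-style config file
#'
#' The file is JSON with fields `name`, `linker_mass`, `stub_masses`
#' (object label -> Da), `doublet_pair`, `hydrolyzed_mod`, `amidated_mod`,
#' `reactive_sites` and `cleavable`.
#'
#' @param path Path to a JSON config file.
#' @return An `xl_crosslinker` object.
#' @export
read_crosslinker_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  crosslinker(
    name = cfg$name,
    linker_mass = cfg$linker_mass,
    stub_masses = unlist(cfg$stub_masses %||% list()),
    doublet_pair = cfg$doublet_pair,
    hydrolyzed_mod = cfg$hydrolyzed_mod,
    amidated_mod = cfg$amidated_mod,
    reactive_sites = cfg$reactive_sites %||% c("K", "S", "T", "Y"),
    cleavable = cfg$cleavable %||% (length(cfg$stub_masses) > 0)
  )
}
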