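#' Construct a crosslinked peptide pair
#'
#' Bundles two peptides, their 1-based link sites (0 for the protein
#' N-terminus), the crosslinker and the precursor charge. The neutral mass
#' of the pair is `mass(alpha) + mass(beta) + linker_mass`.
#'
#' @param alpha,beta Peptide descriptions: either a character sequence or a
#'   list/one-row tibble with `sequence` and optional `mod_mass`,
#'   `mod_position`, `mod_label`, `accession`, `is_decoy`.
#' @param site_alpha,site_beta Link-site positions (1-based; 0 = protein
#'   N-terminus). The linked residue must be one of the crosslinker's
#'   reactive sites.
#' @param crosslinker An [crosslinker()] object.
#' @param charge Precursor charge.
#' @param validate_sites Check that link sites fall on reactive residues.
#' @return An object of class `xl_pair`.
#' @export
#' @examples
#' p <- crosslinked_pair("AKAR", "KVER", 2, 1, xl_dsso(), charge = 3)
#' pair_mass(p)
crosslinked_pair <- function(alpha, beta, site_alpha, site_beta,
                             crosslinker, charge = 3L,
                             validate_sites = TRUE) {
  stopifnot(inherits(crosslinker, "xl_crosslinker"))
  norm <- function(p) {
    if (is.character(p)) p <- list(sequence = p)
    p <- as.list(p)
    p$sequence <- as.character(p$sequence)
    p$mod_mass <- as.numeric(p$mod_mass %||% 0)
    if (is.na(p$mod_mass)) p$mod_mass <- 0
    p$mod_position <- p$mod_position %||% NA_integer_
    p$mod_label <- as.character(p$mod_label %||% "")
    p$accession <- as.character(p$accession %||% NA_character_)
    p$is_decoy <- isTRUE(p$is_decoy)
    p$length <- nchar(p$sequence)
    p$mass <- peptide_mass(p$sequence, p$mod_mass)
    p
  }
  a <- norm(alpha); b <- norm(beta)
  check_site <- function(p, site, who) {
    if (site < 0 || site > p$length)
      stop("link site out of range for ", who, call. = FALSE)
    if (validate_sites && site >= 1) {
      res <- substr(p$sequence, site, site)
      if (!res %in% crosslinker$reactive_sites)
        stop("link site residue '", res, "' of ", who,
             " is not reactive for ", crosslinker$name, call. = FALSE)
    }
  }
  check_site(a, site_alpha, "alpha")
  check_site(b, site_beta, "beta")
  structure(
    list(alpha = a, beta = b,
         site_alpha = as.integer(site_alpha),
         site_beta = as.integer(site_beta),
         crosslinker = crosslinker,
         charge = as.integer(charge)),
    class = "xl_pair"
  )
}

#' @export
print.xl_pair <- function(x, ...) {
  cat(sprintf("<xl_pair> %s(%d) -- %s(%d), %s, z=%d, M=%.4f Da\n",
              x$alpha$sequence, x$site_alpha,
              x$beta$sequence, x$site_beta,
              x$crosslinker$name, x$charge, pair_mass(x)))
  invisible(x)
}

#' Neutral mass of a crosslinked pair
#' @param pair An [crosslinked_pair()] object.
#' @return Neutral monoisotopic mass (Da).
#' @export
pair_mass <- function(pair) {
  pair$alpha$mass + pair$beta$mass + pair$crosslinker$linker_mass
}

# residue-mass vector including fixed carbamidomethyl and the peptide's
# variable modification folded into its site (N-terminal mods are added
# separately to N-terminal fragments)
pep_residue_masses <- function(pep) {
  res <- strsplit(pep$sequence, "")[[1]]
  m <- AA_MONO_MASS[res]
  if (anyNA(m))
    stop("unknown residue(s): ",
         paste(unique(res[is.na(m)]), collapse = ", "), call. = FALSE)
  m <- unname(m)
  m[res == "C"] <- m[res == "C"] + CARBAMIDOMETHYL_MASS
  nterm_extra <- 0
  if (pep$mod_mass != 0) {
    pos <- pep$mod_position
    if (is.na(pos) || pos == 0) nterm_extra <- pep$mod_mass
    else m[pos] <- m[pos] + pep$mod_mass
  }
  list(masses = m, nterm_extra = nterm_extra)
}

#' Generate theoretical fragments for a crosslinked pair
#'
#' Emits, for each peptide of the pair, b- and y-series backbone fragments
#' and intact-peptide P ions. Fragments that do not contain the link site
#' get plain masses. Fragments containing the link site are emitted once
#' per cleaved-stub label (MS-cleavable reagents only) and once as a +P
#' ion that carries the intact linker plus the entire partner peptide.
#' P ions (the doublet-forming signature peaks) are emitted once per stub
#' label. Optionally, neutral-loss variants are produced: -H2O and -NH3
#' generally, -CH3SOH only for fragments carrying an S or T stub or an
#' oxidized methionine.
#'
#' @param pair An [crosslinked_pair()] object.
#' @param max_fragment_charge Highest fragment charge to emit; default
#'   `min(precursor charge - 1, 3)`, at least 1.
#' @param losses Emit neutral-loss variants (default `FALSE`).
#' @param stub_aware If `FALSE`, behave as if the crosslinker were
#'   non-cleavable: no stub variants and no stub P ions (used for the
#'   "noncleavable search" comparison).
#' @return A tibble with columns `owner` (`"alpha"`/`"beta"`), `series`
#'   (`"b"`, `"y"`, `"P"`), `index` (cleavage ordinal; 0 for P ions),
#'   `stub` (`"none"`, a stub label, or `"+P"`), `loss`, `charge`, `mz`
#'   and `contains_link_site`.
#' @export
#' @examples
#' pair <- crosslinked_pair("AKAR", "KR", 2, 1, xl_dsso(), charge = 3)
#' theoretical_fragments(pair)
theoretical_fragments <- function(pair, max_fragment_charge = NULL,
                                  losses = FALSE, stub_aware = TRUE) {
  stopifnot(inherits(pair, "xl_pair"))
  xl <- pair$crosslinker
  if (is.null(max_fragment_charge))
    max_fragment_charge <- max(1L, min(pair$charge - 1L, 3L))
  zs <- seq_len(max_fragment_charge)
  cleav <- xl$cleavable && stub_aware

  stub_labs <- if (cleav) names(xl$stub_masses) else character()
  n_link_var <- length(stub_labs) + 1L      # stub variants + "+P"

  frag_one <- function(owner) {
    pep <- pair[[owner]]
    other <- pair[[if (owner == "alpha") "beta" else "alpha"]]
    site <- pair[[paste0("site_", owner)]]
    rm <- pep_residue_masses(pep)
    L <- pep$length
    cs <- cumsum(rm$masses)
    ox_pos <- if (pep$mod_label == "ox") pep$mod_position else NA_integer_

    series <- character(0); index <- integer(0); stub <- character(0)
    neutral <- numeric(0); contains <- logical(0); ox_in <- logical(0)
    if (L >= 2) {
      i <- seq_len(L - 1L)
      base <- data.frame(
        series = rep(c("b", "y"), each = L - 1L),
        index = c(i, i),
        neutral = c(rm$nterm_extra + cs[i], cs[L] - cs[L - i] + H2O_MASS),
        # b_i holds residues 1..i (site 0, the N-terminus, is in every b);
        # y_i holds residues L-i+1..L
        has_link = c(site <= i, site > L - i),
        ox = c(!is.na(ox_pos) & ox_pos >= 1 & ox_pos <= i,
               !is.na(ox_pos) & ox_pos > L - i)
      )
      lin <- base[!base$has_link, ]
      lnk <- base[base$has_link, ]
      series <- c(lin$series, rep(lnk$series, each = n_link_var))
      index <- c(lin$index, rep(lnk$index, each = n_link_var))
      stub <- c(rep("none", nrow(lin)),
                rep(c(stub_labs, "+P"), nrow(lnk)))
      stub_add <- c(unname(xl$stub_masses)[seq_along(stub_labs)],
                    xl$linker_mass + other$mass)
      neutral <- c(lin$neutral, rep(lnk$neutral, each = n_link_var) +
                     rep(stub_add, nrow(lnk)))
      contains <- c(rep(FALSE, nrow(lin)),
                    rep(TRUE, nrow(lnk) * n_link_var))
      ox_in <- c(lin$ox, rep(lnk$ox, each = n_link_var))
    }
    # intact-peptide P ions with each stub label (signature doublet peaks)
    if (cleav) {
      series <- c(series, rep("P", length(stub_labs)))
      index <- c(index, rep(0L, length(stub_labs)))
      stub <- c(stub, stub_labs)
      neutral <- c(neutral, pep$mass + unname(xl$stub_masses))
      contains <- c(contains, rep(TRUE, length(stub_labs)))
      ox_in <- c(ox_in, rep(!is.na(ox_pos), length(stub_labs)))
    }
    df <- data.frame(series = series, index = index, stub = stub,
                     loss = "none", neutral = neutral,
                     contains_link_site = contains)
    if (losses && nrow(df) > 0) {
      general <- rbind(
        transform(df, loss = "H2O", neutral = neutral - H2O_MASS),
        transform(df, loss = "NH3", neutral = neutral - NH3_MASS)
      )
      sulf <- df[df$stub %in% c("S", "T") | ox_in, ]
      if (nrow(sulf))
        sulf <- transform(sulf, loss = "CH3SOH",
                          neutral = neutral - CH3SOH_MASS)
      df <- rbind(df, general, if (nrow(sulf)) sulf)
    }
    if (nrow(df) == 0) return(NULL)
    df <- df[rep(seq_len(nrow(df)), each = length(zs)), ]
    df$charge <- rep(zs, length.out = nrow(df))
    df$owner <- owner
    df
  }

  out <- rbind(frag_one("alpha"), frag_one("beta"))
  out$mz <- mz_of(out$neutral, out$charge)
  tibble::as_tibble(out[, c("owner", "series", "index", "stub", "loss",
                            "charge", "mz", "neutral",
                            "contains_link_site")])
}

#' Theoretical fragments of a stub-bearing linear peptide (MS3 target)
#'
#' After MS-cleavage and MS3 selection, each released peptide is a linear
#' peptide carrying a crosslinker stub as a fixed modification at its link
#' site. This generates its b/y fragments for annotating MS3 scans.
#'
#' @param pep Peptide description as in [crosslinked_pair()].
#' @param site Link-site position (1-based, 0 = N-terminus).
#' @param stub_mass Stub mass (Da) carried at the site.
#' @param max_charge Highest fragment charge (default 2).
#' @param owner Owner label to stamp on the fragments (default "alpha").
#' @return A fragment tibble in the format of [theoretical_fragments()];
#'   `stub` is `"fixed"` for fragments containing the stub-modified site.
#' @export
linear_stub_fragments <- function(pep, site, stub_mass, max_charge = 2L,
                                  owner = "alpha") {
  if (is.character(pep)) pep <- list(sequence = pep)
  pep <- as.list(pep)
  pep$mod_mass <- as.numeric(pep$mod_mass %||% 0)
  pep$mod_position <- pep$mod_position %||% NA_integer_
  pep$mod_label <- as.character(pep$mod_label %||% "")
  pep$length <- nchar(pep$sequence)
  rm <- pep_residue_masses(pep)
  L <- pep$length
  if (site >= 1) rm$masses[site] <- rm$masses[site] + stub_mass
  else rm$nterm_extra <- rm$nterm_extra + stub_mass
  cs <- cumsum(rm$masses)
  zs <- seq_len(max_charge)
  i <- seq_len(L - 1L)
  b <- data.frame(series = "b", index = i, neutral = rm$nterm_extra + cs[i],
                  contains = site <= i)
  y <- data.frame(series = "y", index = i,
                  neutral = cs[L] - cs[L - i] + H2O_MASS,
                  contains = site > L - i)
  df <- rbind(b, y)
  df <- df[rep(seq_len(nrow(df)), each = length(zs)), ]
  df$charge <- rep(zs, length.out = nrow(df))
  tibble::tibble(
    owner = owner, series = df$series, index = as.integer(df$index),
    stub = ifelse(df$contains, "fixed", "none"), loss = "none",
    charge = df$charge, mz = mz_of(df$neutral, df$charge),
    neutral = df$neutral, contains_link_site = df$contains
  )
}
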