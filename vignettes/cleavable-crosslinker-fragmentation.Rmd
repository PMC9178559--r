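---
title: "Analysing fragmentation spectra of MS-cleavable crosslinked peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing fragmentation spectra of MS-cleavable crosslinked peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xlfrag)
```

## The problem

Crosslinking mass spectrometry identifies residue–residue proximities by
covalently linking two peptides and fragmenting them together. A
crosslink spectrum match (CSM) must explain one MS2 spectrum with *two*
peptide sequences, so the candidate space grows as $(n^2+n)/2$ in the
number $n$ of linear peptides. MS-cleavable reagents such as DSSO and
DSBU attack this problem in the gas phase: the linker cleaves
preferentially, releasing each peptide with a small "stub" remnant.
DSSO cleaves asymmetrically into an alkene (A, 54.01056 Da) and a
sulfenic-acid (S, 103.99320 Da) stub; S commonly loses water to the
unsaturated thiol (T, 85.98264 Da). The intact-peptide ions carrying the
A and T stubs differ by a fixed Δm = 31.97208 Da and form a *signature
doublet* from which the individual peptide masses can be read off, and
on which MS3 acquisition can be triggered.

`xlfrag` implements the downstream analysis of such spectra as a tested,
reusable pipeline: theoretical fragment generation with stub and
intact-partner (+P) masses, ppm-tolerant annotation with deisotoped
intensity ranks, doublet detection and prevalence/rank statistics,
conservative sequence coverage split by fragment category, MS3
trigger-correctness evaluation, and grouped target–decoy FDR with an
optional doublet prefilter. Because public raw data are not required, a
first-class synthetic-data module generates ground-truthed spectra so
that every stage can be validated in a closed loop.

## The fragment model

For a crosslinked pair (α, β) with link sites $s_\alpha, s_\beta$,
each peptide of length $L$ contributes b- and y-series ions for the
$L-1$ backbone cleavage positions plus intact-peptide "P" ions:

* fragments **not** containing the link site have plain monoisotopic
  masses (residue masses, fixed carbamidomethyl-Cys, one optional
  variable modification, H₂O for y ions);
* fragments containing the link site are emitted once per stub label
  (cleavable reagents only) and once as a **+P** ion — the fragment plus
  the intact linker plus the entire partner peptide;
* P ions are emitted once per stub label; the A/T (DSSO) or A/B (DSBU)
  pair of these is the signature doublet. For the non-cleavable BS3
  there are no stubs, and link-site evidence exists only via +P ions.

Charges run from 1 to `max_fragment_charge` (default
`min(precursor charge − 1, 3)`; the literature does not prescribe stub-ion
charge ranges, so this is exposed as configuration). Optional neutral
losses are −H₂O and −NH₃ generally, and −CH₃SOH only for S/T-stub or
oxidised-Met fragments, a chemically motivated restriction since the
loss originates from the sulfoxide.

Internal identities, tested against the published stub masses: A + S
equals the intact DSSO linker mass; hydrolyzed and amidated dead-end
modifications equal linker + H₂O and linker + NH₃; S − T = H₂O;
b$_i$ + y$_{L-i}$ of one peptide reconstruct its mass up to the
link-dependent constant.

## Annotation, deisotoping and ranks

Observed peaks are deisotoped by greedy envelope clustering: seeds are
visited in order of decreasing intensity; isotope positions
(1.0033548378/z spacing, consecutive from k = 1, non-increasing
intensity) are collected for each charge and the charge recruiting the
most peaks wins. Intensity ranks — used for all doublet rank statistics —
are computed on deisotoped peaks (rank 1 = most intense, ties broken by
ascending m/z).

Fragments match the nearest peak within the ppm tolerance (5–15 ppm
is typical for Orbitrap data; 15 ppm is the package default), with ties
resolved by smaller |ppm| then higher intensity. Two deliberate
relaxations of the naive "match the monoisotopic peak with equal
charge" rule are made, because greedy deisotoping is fallible when two
ions coincide with an isotope spacing:

1. a fragment may match a *member* peak of an envelope
   (charge-agnostically), recovering genuine ions absorbed into a
   coincidental cluster;
2. peaks whose envelope charge conflicts with the fragment charge stay
   eligible when no charge-compatible peak exists in tolerance.

Without these, roughly 3% of noise-free simulated CSMs lose one
coverage position to isotope-spacing coincidences; with them, the
zero-noise closed loop is exact (see below). Both behaviours can be
disabled (`match_members = FALSE`).

## Doublets, coverage, MS3

A doublet call requires both P-ion stub variants of the crosslinker's
doublet pair matched *at the same fragment charge* — a mass-difference
signature is only meaningful within one charge state. Doublets are
defined on intact-peptide P ions, not on backbone stub pairs. The rank
of a doublet is the rank of its more intense peak; a CSM's doublet class
is the number of peptides (0/1/2) with at least one call.

Sequence coverage is deliberately conservative: the fraction of the
$2(L-1)$ possible (N-terminal, C-terminal) × cleavage-position fragments
matched at least once, counting each position once regardless of stub
state, charge or loss multiplicity. Sub-fractions restrict the matched
set to linear, link-site, stub-only and +P fragments over the same
denominator, which is what makes cleavable and non-cleavable reagents
comparable category by category.

An MS3 trigger is correct when the selected precursor m/z matches a
*matched* P-ion stub peak of the parent CSM within 20 ppm (the observed
peak position, as an instrument would have selected it). Failing that,
the precursor is compared against linear peptides with and without
hydrolyzed/amidated dead-end crosslinker at charges 1–3, classifying
the common false-trigger parents. Only P-ion stub matches count as
correct; counting backbone stub fragments as correct triggers is a
stricter/looser design fork we resolved to "P ions only" since the
doublet logic the instrument runs operates on peptide-level peaks.
Combined MS2+MS3 coverage is the union of matched position sets, with
wrongly triggered scans contributing nothing.

## Scoring and FDR

The search score is deliberately simple and fully declared (engine
scores are out of scope here): the fraction of total deisotoped
intensity explained by matched peaks plus the mean of the two peptides'
total coverage, range [0, 2], monotone in the matched set. The delta
score is the gap to the best competing candidate for the same spectrum.

Pre-FDR filters follow standard practice: ≥3 matched fragments per
peptide, delta score > 15% of the score (strict), peptide length ≥ 6,
no peptide shared by several proteins, no noncovalent flag. The
noncovalent flag marks spectra with no link-site evidence at all and one
peptide entirely unmatched — a lightweight analogue of searching a
zero-mass crosslinker to catch gas-phase-associated peptide pairs.

FDR is estimated on unique CSMs (best score per peptide-pair/link-site/
charge key, order-invariant) in two groups, self and heteromeric,
because random matches are much more frequent among heteromeric
candidates. Within a group, scanning thresholds from high to low,
$\widehat{FDR}(t) = \max(0, TD - DD)/TT$ over records with score ≥ t,
monotonized into a q-value (minimum over all thresholds at or below t,
so the estimate never increases as the threshold rises); the reported
threshold is the lowest score with q ≤ level. Tied scores cannot be
split by a threshold and are treated as a block. The TD − DD form is the
standard target–decoy estimator for crosslinks: a random match is TT,
TD, DD with probabilities ¼, ½, ¼ when each peptide is a decoy with
probability ½, so TD − DD is an unbiased count of random TT matches.

`doublet_filter_comparison()` re-estimates FDR after keeping only CSMs
with at least one detected doublet, and
`normalize_scores_to_fdr_cutoff()` rescales scores by the group
threshold (default 10% FDR) so distributions are comparable across
datasets or search modes. `theoretical_fragments(..., stub_aware =
FALSE)` reruns annotation as if the reagent were non-cleavable (linear
and +P ions only), the basis of the cleavable-vs-noncleavable
comparison.

## The synthetic-data generator

The generator emulates, with fully seeded randomness, the features of
real acquisitions that the pipeline consumes — not the physics that
produces them:

* random protein databases (near-natural residue frequencies, K/R tuned
  so tryptic peptides fall mostly in 6–30 residues), reversed-sequence
  decoys;
* per CSM: two tryptic peptides with reactive link sites (K/S/T/Y),
  precursor charge 3–5; P-ion stub doublets emitted per peptide with
  probability `doublet_emission_prob`; b/y fragments per cleavage with
  probability `backbone_fragment_prob`, link-site fragments as a stub
  variant and optionally +P; lognormal intensities with a
  mode-dependent stub scale (CID ≫ sHCD, capturing the rank
  phenomenology of doublets being top-ranked in CID); isotope envelopes
  (3 peaks, ratio 0.5); Gaussian m/z jitter (2 ppm); uniform-m/z
  lognormal noise peaks;
* acquisition modes: stepped HCD (backbone probability 0.8, stub scale
  2) versus low-energy CID (0.45, 8), the contrast between
  backbone-rich single-scan acquisition and crosslinker-cleavage-first
  acquisition;
* CID-MS3: the trigger logic runs on *observed* peaks — peak pairs at
  the doublet Δm (charges 1–2, 20 ppm), ranked by intensity, isotope
  positions of already-selected peaks excluded, up to `ms3_trigger_top_n`
  selections — so coincidental pairs produce realistic false triggers on
  noise and linear-peptide parents;
* optional crosslink-free "junk" spectra containing a linear
  contaminant peptide's fragments plus dense noise, which supply the
  random-match population for FDR studies.

`run_search()` emulates a search engine by scoring a short candidate
list per spectrum — the true pair, "half-true" pairs (one true peptide
with a random partner) and fully random pairs, partners drawn as decoys
with probability 0.5 — and keeping the best. This is a deliberate
simplification: it reproduces the statistical structure of a search
(competition, delta scores, target–decoy symmetry) without enumerating
$(n^2+n)/2$ candidates. What passing tests on these simulations show is
that the *pipeline's statistics are correct given their inputs*; they do
not show that real spectra fragment as the generator assumes (no
chimeric spectra, no intensity correlation between ion series, no
retention-time structure, no physical collision-energy model).

## Validation design

Four layers of checks, all in the test suite and recomputed by
`scripts/acceptance.R`:

1. **Analytic identities** of the mass model from the published stub
   and modification masses (sub-1e-4 Da).
2. **Closed-loop exactness**: with zero noise and unit emission
   probabilities (500 CSMs), every CSM shows both doublets, coverage is
   exactly 1.0 for both peptides, and every unique true CSM passes 5%
   grouped FDR. The closed-loop FDR check deliberately skips the
   pre-FDR ambiguity filters: the delta-score rule can legitimately
   remove a true CSM whose partner peptide has a near-homologous
   competitor in the database, which is filter correctness rather than
   an FDR failure.
3. **Parameter recovery**: with doublet emission probability p = 0.9
   (500 CSMs), the both-doublet fraction and the both-peptide MS3
   trigger-correctness fraction concentrate at p² within 3 binomial σ;
   with a mixed true/random population (2000 CSMs), the achieved FDR
   estimate sits at the requested 5% and agrees with the true
   false-discovery proportion computed from ground truth.
4. **Oracle equivalence and structure**: grouped FDR thresholds equal a
   brute-force threshold scan; coverage equals exhaustive position-set
   counting; b/y complementarity holds for generated peptides; BS3
   yields doublet class 0 always; stub-blind annotation never out-scores
   stub-aware annotation and passes at most as many CSMs.

Problem sizes (500 simulated CSMs for recovery studies, 2000 for FDR
calibration, 150 per arm for the search-mode comparison) were chosen so
binomial 3σ bands are a few percentage points wide — large enough to be
diagnostic, small enough to run routinely.

## Numerical choices and edge cases

* Monoisotopic constants: proton 1.00727646677 Da, H₂O 18.0105646863 Da,
  NH₃ 17.0265491015 Da, isotope spacing 1.0033548378 Da.
* Deisotoping tolerance 10 ppm, envelope charges up to 4, at most 6
  isotopes; clusters need at least one recruited isotope, otherwise the
  peak passes through with charge 0.
* Coverage is undefined for peptides of length < 2 (error, not 0).
* An FDR group with no targets is flagged degenerate; with no decoys the
  estimate is 0 and everything passes. A zero or undefined threshold
  makes score normalization an error rather than an Inf.
* MGF has no MS3 linkage fields, so TITLE carries
  `scan= mslevel= parent= selected_mz=` tokens; this keeps MS2 and MS3
  scans in one open, diff-able text format and round-trips exactly.
* 1-based residue positions everywhere; link site 0 denotes the protein
  N-terminus.

## Known limitations

The generator's intensity model is a declared stand-in (lognormal with a
stub scale), not a fragmentation model; absolute prevalence numbers from
simulations track the configured probabilities, not any instrument.
ETD c/z ions, a-ions, semi-tryptic digestion, isotope-labelled linkers,
looplinks beyond the −OH/−NH₂ dead-ends, and vendor raw/mzML parsing are
out of scope. The candidate-sampling search is not a database search
engine and should not be benchmarked as one.
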