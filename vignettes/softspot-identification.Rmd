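---
title: "Soft-spot identification for cyclic peptides with 2PCA derivatization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Soft-spot identification for cyclic peptides with 2PCA derivatization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(softspotter)
```

## The identification problem

The first metabolic event for a cyclic peptide is hydrolysis of one
backbone amide, which linearizes the ring and shifts the mass by exactly
one water (+18.0106 Da) *wherever* the cut occurs. All ring-opening
products are therefore isomers, and the precursor mass carries no
information about the soft spot. MS/MS could resolve it, but
collision-induced spectra of linearized macrocycles are rich in internal
fragments whose low-mass ions mimic terminal sequence ions and suggest
false start sites.

Derivatization with 2-pyridinecarboxaldehyde (2PCA) breaks the symmetry.
2PCA condenses selectively with the α-amine of the newly exposed
N-terminus (the lysine ε-amine gives no stable product) and cyclizes with
the first backbone amide nitrogen into an imidazolidinone, adding a
residual mass of C6H3N = 89.0265 Da. Collisional activation across the
imidazolidinone then yields:

* a pseudo **b1-type** ion, `residue + C6H3N + H⁺`, and a pseudo
  **a1-type** ion exactly CO (27.9949 Da) lower — a doublet that names the
  first residue and cannot be confused with any unmodified sequence ion,
  because no natural residue adds 89.0265 Da;
* a **marker ion**, C6H7N2 at m/z 107.0609, produced by any 2PCA
  conjugate regardless of sequence — an orthogonal "a derivatized peptide
  fragmented here" signal.

The package automates the complete interpretation chain around these ions.

## Model and procedure

### Mass bookkeeping

All masses are monoisotopic and derive from a single element table
(`element_masses()`), from which residue masses and the workflow constants
(`pca_constants()`) are computed at load time; nothing is hard-coded
twice. m/z is `(M + z·m_p)/z` with the physical proton mass and no
electron-mass correction. The printed m/z of the marker ion is the plain
atomic-mass sum of the ion formula C6H7N2 (which already contains the
charging hydrogen), and the package stores it that way.

Gas-phase chemistry of the imidazolidinone is incompletely understood and
±1 hydrogen-atom transfers are observed in the doublet region. The
canonical doublet is defined once (`residue + C6H3N + H⁺`) and
hydrogen-transfer variants are generated explicitly at configurable
offsets (`h_transfer_offsets`, default 0 and −1). A second bookkeeping
convention, `neutral_h` (`residue + C6H3N + H_ATOM`), is available in
`doublet_variants()` because calculated masses for the H-transfer species
are conventionally quoted that way (e.g. 178.0742 Da for serine with one
transferred hydrogen). Matching uses a ppm window (default 15 ppm) wide
enough to absorb the proton-vs-hydrogen distinction at low m/z; one
defined convention plus explicit variants beats silently mixed formulas.

### Candidate space

`enumerate_openings()` generates every ring-opening isomer. For a
head-to-tail *n*-mer these are the *n* rotations of the written sequence,
indexed by the residue that becomes the new N-terminus. For a
disulfide-bridged peptide only amides strictly between the bridged
cysteines open the ring; the opened species is branched (two chains joined
by the intact S–S bond), but its MS/MS is interpreted pseudo-linearly: the
candidate sequence runs from the new N-terminus to the written C-terminus
and the other chain (its residue sum plus water, minus the two hydrogens
lost to the bridge) rides as a fixed mass appendage on the anchoring Cys.
This reproduces the y-ion ladder annotation a practitioner writes on such
spectra without inventing branched-fragment chemistry; it encodes the
working assumption that the disulfide survives collisional activation,
which is plausible but not verified mechanism. Topology is a required
user input and never inferred from the sequence — a peptide with two
terminal cysteines could be either head-to-tail or disulfide-cyclized.

### Background subtraction

Stability matrices are proteolytically active and generate their own
2PCA-reactive peptides, so the marker ion alone cannot distinguish analyte
conjugates from matrix conjugates. The dynamic control-scan algorithm
removes the matrix: for each analyte scan at time *t*, control scans of
the same scan function within ±`time_window` (default 0.2 min) are pooled;
for each analyte ion, every control ion within ±`ppm_tol` (default
10 ppm) is located, and `scaling_factor` (default 2) times the highest
matched control intensity is subtracted. Peaks driven to zero or below are
removed by default (`drop_nonpositive`), since empty peaks only add noise
to downstream chromatograms; clamping to zero is available because the
original behaviour is not documented. Matching each analyte peak against
the maximum over the whole control window makes the subtraction
deliberately aggressive — a factor-2 overshoot against the worst-case
background — which is the point: surviving signal is analyte-specific.
The two runs are assumed time-aligned (same LC method); no retention-time
warping is attempted. When no matrix-only control exists, runs of samples
incubated with *other* cyclic peptides cover the same matrix and
`cross_peptide_controls()` assembles them into a control run.

### Scoring and ranking

No numeric score exists in manual interpretation, so the score is an
explicit, overridable encoding of the evidence channels:

```
score = 0.40 · doublet + 0.40 · y_coverage + 0.10 · b_coverage
      + 0.05 · marker + 0.05 · matched_intensity_fraction
```

The doublet and the y-ladder dominate because they are the two channels
that actually decide identifications: the doublet names the first residue,
and the y-series — identical for the derivatized and underivatized forms
of a sequence, since 2PCA sits on the N-terminus — separates candidates
that share it. The doublet is credited only when **both** members match at
one consistent hydrogen-transfer offset; its diagnostic power is the
27.9949 Da spacing, not either mass alone. Somatostatin is the canonical
duplicate-residue case: two threonines (T10, T12) give the same doublet at
191.08/163.08, and only the y-ladder of the true opening matches.

Isobaric internal fragments are generated (internal b-type/acylium only —
the observed species; internal a-type is opt-in) and any group of
internal ions within tolerance of one another that overlaps the matched
evidence is reported as an ambiguity flag, never silently counted: in
JB1, the prolines produce internal PLK at m/z 339.2391, isobaric with
internal LKP from elsewhere in the ring.

Ranking is total and deterministic: score, then doublet match, then
y-coverage, then opening site. A verdict is issued when the top candidate
leads the runner-up by `margin` (default 0.1 score units — not derivable
from first principles, chosen so that a single chance y-match in noise
cannot flip a verdict); otherwise the result is "ambiguous" with the tied
set visible. A best score below `min_evidence` (default 0.1) downgrades
the result to "no evidence", because chance matches in noise-only spectra
score slightly above zero. Marker peaks with no scoreable MS/MS in their
elution window are reported as unassigned 2PCA species — typically
secondary metabolites that underwent a further hydrolysis — with the
strongest co-eluting background-subtracted MS1 peak as observed precursor;
sequencing them de novo is out of scope.

## The synthetic-data generator

No public raw data exist for this workflow, so validation rests on
`simulate_runs()`, which emulates the acquisition's shape with known
ground truth: alternating full-MS and AIF scans plus unscheduled targeted
MS/MS on the derivatized-parent m/z, over a configurable gradient window.

What it emulates, and the defaults chosen as study-realistic:

* **Matrix background** — 50 species at random m/z (400–1200) and
  retention times, log-uniform MS1 intensities (10³–10⁵), each shedding a
  few AIF fragments; 20% carry 2PCA and emit the marker ion at 8% of
  their intensity (the marker is stated to stay below 5–10% of the base
  peak). Matrix peaks are *identical* in analyte and control runs —
  the perfectly reproducible chromatography limit of the same-LC-method
  assumption.
* **Analyte species** — each planted opening elutes as a Gaussian peak
  (σ = 0.05 min) at apex intensity 10⁶ (a 10 µM spike dominates a dilute
  matrix), contributing MS1 precursors (z = 1, 2), marker + y-ions in
  AIF, and targeted MS/MS containing the doublet at a configurable
  H-transfer offset, partial b/y ladders (defaults 50%/90%; y-ions
  boosted when an internal lysine sequesters charge), every internal
  fragment, and 20 uniform noise peaks.
* **Mass error** — every emitted peak is jittered with a Gaussian whose
  3σ envelope is `mz_jitter_ppm` (default 3 ppm, inside the 5 ppm marker
  window and small against the 10 ppm subtraction window).
* **Split-peak isomers** — optionally two Gaussians per species sharing
  one fragment set, modelling the two chromatographically resolvable
  imidazolidinone conjugation isomers whose tandem spectra are
  indistinguishable.

What it does **not** model: isotope envelopes, profile-mode peak shapes,
retention-time drift between runs, intensity-dependent mass error,
ion suppression, and real fragmentation propensities (intensities are
log-uniform draws). Passing the end-to-end tests therefore demonstrates
that the interpretation chain is correct under the stated acquisition
shape — not that the score weights are optimal for any particular
instrument's fragmentation behaviour.

```{r example}
jb1 <- cyclic_peptide("JB1", "CYAAPLKPAKSC", "head_to_tail")
sim <- simulate_runs(synth_config(
  jb1, true_opening_sites = data.frame(site = 11L, abundance = 1),
  seed = 7L))
identify_soft_spots(sim$analyte, sim$control, jb1)
```

## Numerical and design choices

* **Peak matching** is symmetric ppm on the target m/z everywhere
  (subtraction 10 ppm, marker XIC 5 ppm, fragment matching 15 ppm,
  precursor matching 10 ppm), mirroring the ± phrasing of the method's
  stated tolerances.
* **Chromatographic peak picking** is threshold-contiguity (runs of
  ≥ `min_points` points above `min_intensity`, apex = maximum, earliest
  wins ties). It is deliberately simple and deterministic; closely spaced
  peaks whose valley stays above threshold merge, which is acceptable for
  marker screening where the threshold sits far above the subtracted
  baseline.
* **Scan-function classification** from mzML metadata: MS1 ⇒ full; MS2
  with a ≥100 m/z isolation window or no selected precursor ⇒ AIF;
  otherwise targeted MS/MS. AIF fragments the entire transmitted range,
  so the absence of a narrow precursor is its defining signature.
* **Retention times are minutes** throughout; mzR's seconds are converted
  at the boundary.
* **Degenerate inputs**: a 1-mer macrocycle opens to its free amino acid;
  candidates shorter than two residues produce no ladders, only
  parent-level and diagnostic ions; an empty MS/MS spectrum scores zero
  rather than erroring; an empty control run warns and passes the analyte
  through unchanged.
* **RT gating** of MS/MS spectra by marker peaks is off by default —
  targeted scans fire throughout the run, including outside AIF marker
  peaks — but turning it on yields per-peak verdicts, the natural reading
  when several soft spots or secondary metabolites elute separately.
* Test and example simulations use a 3–7 min run at a 0.05 min cycle
  (roughly 40–140 cycles, ~560 spectra per full-scale run), which keeps a
  complete multi-seed validation fast while exercising every scan
  function.

## Known limitations

* Single disulfide bridges only; lactam or thioether cyclizations and
  multiply bridged scaffolds are not represented.
* Secondary metabolites are flagged from the marker chromatogram but not
  sequenced; multiply derivatized species (more than one 2PCA per
  molecule) are outside the target list by design.
* The H-transfer behaviour of the doublet is exposed as configuration,
  not predicted per residue — the underlying gas-phase mechanism is not
  settled.
* Scores compare candidates within one spectrum; they are not calibrated
  probabilities and should not be compared across instruments or
  collision energies without re-examining the weights.
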