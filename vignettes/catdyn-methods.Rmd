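---
title: "Methods: quantifying PARP-1 catalytic-domain subdomain dynamics"
author: "catdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying PARP-1 catalytic-domain subdomain dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catdyn)
```

# The scientific problem

The catalytic domain (CAT) of human PARP-1 comprises two subdomains: the
helical regulatory subdomain (HD), which sterically blocks the active site,
and the ADP-ribosyl-transferase subdomain (ART), which carries the catalytic
centre. Allosteric activation by DNA damage, and the differing behaviour of
clinical PARP inhibitors, both act through changes in the stability and
position of the HD relative to the ART. `catdyn` implements the four
quantitative comparisons that characterise those changes:

1. **Chemical-shift perturbation (CSP) mapping** — which residues sense a
   mutation or a bound inhibitor, and how strongly;
2. **¹⁵N relaxation analysis** — whether the two subdomains tumble as one
   rigid body (per-residue rotational correlation times, τc) and which
   residues move on the sub-nanosecond timescale (heteronuclear NOE);
3. **Amide solvent-exchange classification** — which amide protons are
   protected by stable hydrogen bonds, on a five-level scale from
   CLEANEX-visible "fast" to real-time "slow-dark";
4. **Two-atom-set superposition metrics** — how far the HD is displaced as
   a rigid body relative to the ART between two crystal structures.

A synthetic-data module generates inputs for every stage with recorded
ground truth, so the full pipeline is testable without downloading
depositions.

# Chemical-shift perturbations

For a residue assigned in both sample conditions,

$$\mathrm{CSP} = \sqrt{\Delta\delta(^1\mathrm{H})^2 +
  \left(\tfrac{\Delta\delta(^{15}\mathrm{N})}{5}\right)^2}\ \mathrm{(ppm)},$$

where the divisor 5 compensates the larger dispersion of ¹⁵N shifts. The
divisor is exposed (`nscale`) because other conventions exist, but 5 is the
default throughout. Three deliberate rules:

* Residues assigned in only one condition are carried with status
  `unassigned` and **no CSP value** — scoring them zero would fabricate
  agreement between conditions.
* Prolines (no amide NH) and the consistently invisible Ala823–Asn827 loop
  are distinct status categories so that plots can annotate them.
* For structure colouring, all profiles in a comparison share one global
  maximum: the colour ramp runs from 0 to $0.2\,\mathrm{CSP_{max}}$ and
  saturates above it. Without truncation the map is dominated by a handful
  of large, chemically uninformative perturbations at the binding site
  (ring-current effects of the bound aromatic inhibitor).

The synthetic generator (`makeShiftPair()`) plants a perturbation of known
magnitude $a\,e^{-|r-s|/\lambda}$ at site $s$, splitting it at a random
angle between the ¹H and (pre-scaled) ¹⁵N dimensions so the planted CSP is
exact by construction; recovery to 1e−12 ppm is asserted in the tests.

# ¹⁵N relaxation and rotational correlation times

Decays are fitted as $I(t) = I_0 e^{-t/T}$ by non-linear least squares
(`minpack.lm::nlsLM`; initialisation $I_0 = \max I$, $T = \mathrm{span}/3$,
robust for monotone decays). Parameter errors come from the fit covariance
scaled by residual variance. The study delay schedules (T1: 0–6800 ms; T1ρ:
0.15–100 ms) include duplicate delays; these are fitted as independent
observations and their intensity differences reported as a reproducibility
check. Monte-Carlo tests at 2% noise verify that the ±1.96σ intervals cover
the truth at 95% ± 4%.

Observed T1ρ values are corrected for resonance offset with the standard
tilted-rotating-frame relation: with spin-lock amplitude
$\omega_1 = 2\pi B_1$ ($B_1$ = 1.56 kHz) and offset $\Omega$ from the
117.074 ppm carrier, $\theta = \arctan(\omega_1/\Omega)$ and
$R_2^{\mathrm{eff}} = (R_{1\rho,\mathrm{obs}} - R_1\cos^2\theta)/\sin^2\theta$.
Residues with $\sin^2\theta < 10^{-6}$ get an undefined flag rather than a
wildly amplified number. Whether replicate T1ρ delays should be averaged
before correction is not settled usage; here duplicates enter the decay fit
and the correction acts on the fitted time.

The per-residue correlation time uses the T1/T1ρ ratio:

$$\tau_c \approx \frac{1}{4\pi\nu_N}\sqrt{6\,\frac{T_1}{T_{1\rho}} - 7},$$

with $\nu_N$ the ¹⁵N frequency in Hz (0.10137 × the ¹H frequency; 81.1 MHz
at 800 MHz). The estimate is undefined (flagged, not an error) when the
radicand is negative, as happens for flexible residues. No model-free
fitting is attempted — the approximate formula is the method. Subdomain
means over the HD (666–721, 730–743, 750–779) and ART (790–936, 939–1009)
ranges use a 10% trimmed mean, because per-residue τc estimates have heavy
tails from residual flexibility; the two subdomains are reported as
tumbling separately only when their means differ by more than the pooled
standard deviation. At the study condition (τc ≈ 25 ns for the ~40 kDa
domain) the synthetic pipeline reproduces equal means for both subdomains
— the "tumble as a single unit" outcome.

The steady-state heteronuclear NOE is the saturated/unsaturated intensity
ratio with two-spectrum error propagation; values near 0.8 indicate a rigid
amide at high field, and the ratio is undefined when the unsaturated
intensity is within 3σ of zero.

# Solvent-exchange classification

CLEANEX-PM intensities are normalised between samples by the factor
$\sum I^{CL}_i / \sum I^{TR}_i$ over reference residues 657, 660 and 661 —
unstructured N-terminal residues that exchange freely and are unaffected by
inhibitors or HD mutations. Real-time ²H₂O intensities at 3, 12 and 39 h
then classify the slow exchangers:

* light: $I(3) - I(12) > 0.5\,I(3)$;
* medium: not light and $I(12) - I(39) > 0.25\,I(12)$;
* dark: neither.

Equality at a boundary goes to the **slower** class: both defining
inequalities are strict, leaving the boundary open, and the slower call is
the conservative protection claim. Precedence in `classifyResidue()` is
CLEANEX-first (a CLEANEX signal means sub-second exchange regardless of the
real-time series), then the slow classes, then `unobserved` (white). The
detection threshold defaults to 3 × the spectrum RMS noise. Rates between
roughly 0.5 and 500 s⁻¹ fall in the blind window between the two
experiments — too slow for CLEANEX, too fast for real time — and surface as
`unobserved`; the classifier annotates rather than infers around this gap.
Cross-spectrum normalisation of the real-time series is a user-supplied
per-spectrum factor, since the residues used for it in practice vary by
dataset.

`makeExchangeProfile()` plants per-residue first-order rates, emits the
ideal observables (CLEANEX intensity present iff the rate is inside the
detectable window, default 0.5–100 s⁻¹), and stores analytically derived
classes using the same detection floor the classifier will apply — with a
noise floor of zero any positive intensity counts, so truth and
classification stay consistent by construction. Noiseless agreement is
exactly 100%; at 1% Gaussian noise agreement stays above 95% because only
residues sitting near a class boundary can flip.

# Superposition metrics

`kabschFit()` is an SVD (Kabsch) least-squares superposition returning a
proper rotation (a reflection, when it would fit better, is replaced by the
best proper rotation), with errors for fewer than three atoms or collinear
geometry. It is cross-checked in the tests against an independent
brute-force search over Euler angles with local refinement (agreement to
1e−3 Å on small instances) and against an applied-transform inverse
(recovery to 1e−9).

The headline metric is the **two-set rmsd**: superpose structure B onto
reference A using only the *fit* set (set 1), then measure the rmsd over a
*different* set (set 2) without moving anything. With fit = measure this is
the conventional rmsd and captures internal differences; with fit = ART and
measure = HD it isolates the rigid-body displacement of the HD relative to
the ART. Deposited models differ in which residues are modelled, so pairing
uses the intersection of present atoms and both paired counts are always
reported; reproduction tolerance on published superposition tables is
±0.05 Å for this reason. Conventions, chosen once:

* selections use backbone N, Cα, C′ of the CAT/HD/ART ranges above,
  author residue numbering, no renumbering;
* chains default to A with an override (one published comparator uses
  chain C);
* alternate locations: keep blank or 'A', otherwise highest occupancy,
  ties by label order; atoms are not occupancy-weighted in the fit (usage
  in published tables is unstated; unweighted is assumed);
* hydrogens and waters are excluded.

The glycosidic torsion of a bound adenosine-containing ligand uses the
O4′–C1′–N9–C4 purine convention (the source data do not state theirs) with
the IUPAC sign convention, and multi-chain averages are **circular** means
— an arithmetic mean is meaningless near the ±180° seam. The torsion is
invariant under rigid motion and under reversal of the atom order, and
flips sign under reflection; the tests assert exactly these properties.

# Synthetic geometry

Structural toys are ideal poly-alanine helices (rise 1.5 Å, 100°/residue,
N/Cα/C at fixed angular offsets) — chemically naive but sufficient for
superposition arithmetic, which only needs rigid, non-collinear point sets.
`makeTwoDomainPair()` joins a fixed and a mobile helix, rotates the mobile
one about a hinge residue by a known angle (optionally kinking one helix at
its midpoint, the analogue of a regulatory helix kinking at a buried
aspartate), and records the exact transform; the cross-set rmsd measured
downstream must equal the analytic displacement to 1e−9 Å. All generators
are pure functions of (parameters, seed) and restore the caller's RNG
state.

# What the synthetic data do and do not show

The generators emulate the *statistical and geometric structure* the
analysis assumes: localised shift perturbations, mono-exponential decays
with homoscedastic Gaussian noise at the study delay schedules, first-order
exchange, rigid-body subdomain displacement. They do not emulate spectral
overlap, baseline artefacts, peak-picking errors, heteroscedastic or
correlated noise, anisotropic tumbling, or crystal-packing distortion.
Passing tests therefore demonstrate the correctness of the arithmetic and
the robustness of the classification rules to first-order noise — not that
real spectra will be this clean. Checks against deposited crystal
structures and shift tables are wired into the acceptance suite and run
whenever the depositions are retrievable.

# Problem sizes and numerical choices

Test and acceptance runs use: 200 replicate decays for Monte-Carlo
calibration; 50 seeds × 60 rates for exchange-noise robustness; 354-residue
shift tables (the CAT construct length); 124 + 230 residue two-domain toys
(hinge at the HD/ART boundary of the real numbering). These sizes give
stable statistics in seconds on one core. Tolerances: 1e−6 relative for
noiseless decay recovery (limited by the optimiser's convergence
criterion), 1e−9 for transforms and algebraic round-trips, 1e−12 for the
planted-CSP identity, which is exact arithmetic. Degenerate inputs
(collinear atom sets, constant decays, all-zero CSP profiles, off-resonance
residues, non-positive rates) raise errors or flags rather than returning
numbers.

# Known limitations

* The τc formula assumes isotropic tumbling and dipolar/CSA-dominated
  relaxation; it is an estimator for comparing subdomains, not a
  hydrodynamic measurement.
* Exchange classes are coarse by design; no continuous rates or protection
  factors are fitted, and the 0.5–500 s⁻¹ blind window is annotated, not
  bridged.
* The mmCIF reader inherits bio3d's dialect coverage; unusual depositions
  may need conversion to PDB format.
* The NMR-STAR reader covers the chemical-shift loop of backbone-amide
  depositions only; it is not a general STAR parser.

# Running a study

```{r, eval = FALSE}
cfg <- readStudyConfig("study.yaml")
report <- runStudy(cfg)
report
```

The configuration is a flat YAML file (see `?readStudyConfig`); every
stage writes its TSV outputs plus a manifest and summary, failures in one
sample are flagged without aborting the others, and identical
configuration plus seed reproduces the report byte for byte.
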