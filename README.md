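# catdyn

Quantitative analysis of subdomain dynamics in the PARP-1 catalytic (CAT)
domain from solution NMR and crystal structures.

PARP-1 is the key early responder to DNA single-strand breaks; its
catalytic domain is autoinhibited by the helical regulatory subdomain (HD),
which packs against the ADP-ribosyl-transferase subdomain (ART) and blocks
the active site. Allosteric activation — and the clinically important
differences between PARP inhibitors — play out as changes in the stability
and rigid-body position of the HD. `catdyn` implements the four
measurements that quantify this, for structural biologists comparing
wild-type protein, point mutants and inhibitor complexes:

* **Chemical-shift perturbations** between two conditions,
  `CSP = sqrt(ΔδH² + (ΔδN/5)²)` (ppm), with global normalisation across
  samples and a colour ramp truncated at `0.2·CSP_max`;
* **¹⁵N relaxation**: mono-exponential T1/T1ρ decay fits at the study
  delay schedules, tilted-frame resonance-offset correction of T1ρ,
  heteronuclear NOE ratios with propagated errors, and per-residue
  rotational correlation times
  `τc ≈ (1/4πνN)·sqrt(6·T1/T1ρ − 7)` summarised over the HD and ART
  residue ranges;
* **Amide solvent-exchange classification** from CLEANEX-PM (normalised by
  the reference-residue factor `ΣI^CL/ΣI^TR` over residues 657/660/661) and
  real-time ²H₂O intensities at 3/12/39 h into fast / slow-light /
  slow-medium / slow-dark / unobserved;
* **Two-atom-set superposition**: Kabsch-fit one subdomain's backbone
  (N, Cα, C′), measure the rmsd over the other without moving anything —
  the displacement metric for the HD relative to the ART — plus Cα–Cα
  distances and glycosidic χ torsions with circular chain averaging.

Built-in atom selections follow the study's subdomain definitions
(CAT = 666–721, 730–743, 750–779, 790–936, 939–1009; HD and ART are the
respective halves). A synthetic-data module generates structure pairs with
a known hinge rotation, shift tables with planted perturbations,
noisy decay series and exchange profiles with recorded ground truth, so the
entire pipeline runs and is verified offline.

## Worked example

```r
library(catdyn)

# a two-subdomain toy with a known 10-degree hinge displacement
pair <- makeTwoDomainPair(124, 230, hingeAngle = 10, seed = 1)
twoSetRmsd(pair$reference, pair$displaced,
           fitSel = pair$fixedSelection, measureSel = pair$mobileSelection)
#> SuperpositionResult: rmsd_fit = 0.000 A over 372 atoms; rmsd_measure = 34.610 A over 690 atoms
```

The fit set (the fixed subdomain) superposes exactly — its internal
geometry is unchanged — while the cross-set rmsd of 34.6 Å over 690 atoms
is pure rigid-body displacement of the mobile subdomain, and equals the
value computed analytically from the generator's recorded transform.

```r
# planted chemical-shift perturbation, recovered and colour-mapped
sp <- makeShiftPair(354, site = 888, amplitude = 1.247, decayLength = 4,
                    seed = 1, firstRes = 656)
normaliseProfiles(computeCsp(sp$reference, sp$perturbed))[[1]]
#> CSPProfile 'synthetic-ref vs synthetic-perturbed': 354 residues, 354 with CSP, max 1.247 ppm (threshold 0.2494)

# relaxation: exact recovery at the study delay schedule, then tau_c
f <- fitDecay(relaxationSeries(700, "T1", delaySchedule("T1"),
                               exp(-delaySchedule("T1") / 1200)))
f$T                               # 1200 ms
estimateTauC(2000, 18.3)          # 25.0 ns at 800 MHz
foldChange(2.1e-9, 1.3e-10)       # fold 16.15, direction "tighter"
simulateClassFromRate(0.2, units = "h")  # "slow-light"
```

The CSP maximum of 1.247 ppm sets the truncation threshold at
0.2 × 1.247 = 0.2494 ppm: residues above it saturate the colour ramp. A
T1/T1ρ pair of 2000/18.3 ms at 800 MHz gives τc ≈ 25 ns, the tumbling time
of the intact ~40 kDa domain; the 16-fold KD ratio is the allosteric
tightening of DNA binding by an active-site ligand that destabilises the
HD. End-to-end orchestration over a sample manifest (CSP, relaxation,
exchange and superposition stages, with per-stage TSV outputs and a
summary) is `runStudy("study.yaml")`; see `?readStudyConfig` for the
format and the vignette in `vignettes/catdyn-methods.Rmd` for the methods.

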