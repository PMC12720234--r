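---
title: "Methods: normal-mode potential-energy-scan analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: normal-mode potential-energy-scan analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modescan)
```

## The model

A molecule with N atoms has 3N−6 vibrational normal modes (3N−5 if
linear), each a collective Cartesian displacement pattern `q` with a
harmonic frequency. `modescan` analyses one-dimensional cuts of the
ground- and excited-state potential energy surfaces along each mode:
the equilibrium geometry is displaced as

    x(i) = x_eq + i · q,   i = −0.10, −0.09, …, +0.10,

where `q` is normalized so the sum of squares of all 3N components is 1
and `i` is a unitless scaling factor. An external electronic-structure
engine supplies state energies at every displaced geometry; the package
never invokes one. Each state's scan is fitted with a quadratic
`y = a·i² + b·i + c` by ordinary least squares. Three derived per-mode
statistics carry the analysis:

* **Normalized anharmonicity.** The fit RMSD,
  `sqrt(mean(residual²))` over all 21 points, divided by the mean scan
  energy; for an excited state the mean is first reduced by the
  vertical excitation energy so the denominator measures the energy
  change the distortion produces, not the electronic gap. Because the
  mode vectors are unit-normalized, localized modes change the energy
  far more per unit `i` than delocalized ones; the ratio, and
  especially the S1 − S0 difference of the ratio, puts modes on a
  common footing.
* **Relaxation energy λ** = E_S1(i = 0) − min E_S1 along the mode. A
  displaced excited-state minimum (nonzero `b` relative to the ground
  state) gives λ > 0 and marks the mode as Franck–Condon active.
* **Crossing diagnostics.** An excited-state scan that kinks because a
  second state dips below it is detected as an interior local minimum
  of the adiabatic gap |E_S2 − E_S1| below a threshold; the two states
  are then relabeled diabatically past the crossing so each fitted
  curve is smooth.

Modes are flagged when a statistic exceeds the population mean plus
`k_sd` standard deviations (default 1), and the three flags (S0
anharmonic, S1 excess-anharmonic, FC active) place each mode in one of
eight cases; the flag triple maps to cases 1–8 in the conventional
order (TTT→1 … FFF→8).

## Assumptions and scope

The displacement coordinate is the raw Cartesian mode vector scaled by
`i` — no mass weighting, no conversion to dimensionless normal
coordinates, no Duschinsky rotation between the states' mode bases, and
no projection of translational/rotational contamination (vectors are
displaced as given). Fits are plain unweighted least squares with the
RMSD denominator `n` (all 21 points, no degrees-of-freedom correction).
Only 1D scans are analysed: mode–mode anharmonic coupling, 2D crossing
seams and minimum-energy crossing-point optimization are out of scope.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| grid | −0.10…+0.10 step 0.01 | 21-point scan; larger factors (±1) are accepted but warn, since such distortions are known to be too large for typical modes |
| `gap_threshold` | 0.15 eV | max interior gap minimum that counts as a crossing; generous enough to admit crossings whose grid-sampled gap is a few hundredths of an eV |
| `excitation_offset` | `"auto"` | vertical excitation energy subtracted in the excited-state ratio; `auto` uses the scan's own i = 0 gap so the formula generalizes to any molecule, a fixed value reproduces a published constant |
| `k_sd` | 1 | SD multiplier of the thresholds |
| `sd_convention` | sample (n−1) | population (n) selectable; with ~90 modes the difference is <1% |
| `dominance` | 60% | PED percentage a motion type needs to name the mode; below it the mode is MIX |
| `eps` (assign_cases) | 1e−9 | absolute guard above the threshold, so machine-epsilon residuals in an exactly-harmonic population cannot flag modes |

## Numerical choices

* **R² convention:** when the scan is constant (zero total variance),
  R² is reported as 1 if the residuals are also zero, otherwise it is
  an error; constant scans are fit exactly by a constant.
* **λ from the fit:** the minimum is the fitted parabola's value over
  the scanned interval — the vertex when `a > 0` and `−b/2a` lies
  inside the grid, otherwise the lower endpoint of the fitted curve;
  for concave fits (`a ≤ 0`) the minimum scanned data point is used and
  the fallback is recorded per mode. The FC-point energy is the
  observed value at i = 0. λ is clamped at 0.
* **Crossing-point energy:** read at the minimum-gap grid point as the
  mean of the two state energies, minus the lower state's grid minimum.
  Linear interpolation of the signed gap between the bracketing points
  is available (`interpolate = TRUE`) but off by default, since scans
  are reported at grid points.
* **Diabatization criterion:** without wavefunction data, "same
  electronic character" is operationalized as the branch swap, on the
  crossing's side of i = 0 only, that minimizes the summed quadratic-fit
  RMSD of the two curves; candidate swap starts are the minimum-gap
  point and its neighbor away from zero, and the swap is applied only
  when it strictly reduces the RMSD (hence a no-op on avoided crossings
  and already-diabatized scans, making the operation idempotent). When
  per-point character scalars (e.g. oscillator strengths) are supplied,
  continuity of the character traces decides instead.
* **Ties in PED categorization** at exactly the dominance threshold
  count as dominant.

## The PED projection is a simplification

The mode-character module projects each mode vector onto the unit
first-order displacement rows (numerical central-difference gradients,
step 1e−5) of a fixed redundant set of internal coordinates: bonds
(distance < 1.2 × covalent-radius sum), all bonded angles, all proper
torsions, and an out-of-plane distance at every three-coordinate
center. Squared projections, normalized to 100%, are summed by type
(stretch split by hydrogen participation). This reproduces the six
motion buckets, not any particular program's %PED values: dedicated
vibrational-distribution tools optimize a non-redundant coordinate set
before assigning percentages, which is deliberately not reimplemented.
Two consequences are worth knowing: redundant rows are not mutually
orthogonal, so a motion built naively from bond directions also carries
a genuine first-order angle change; and percentages are
projection-based, so they are invariant to mode-vector scaling but not
comparable to force-field-weighted PED values.

## What the synthetic generator emulates — and what it does not

`generate_two_state()` emits, per mode, a ground-state potential and
two excited-state diabats (harmonic `k/2·x²` or Morse `D(1−e^{−αx})²`,
each with a vertical offset and a minimum shift), diagonalized as a
2×2 diabatic matrix with constant coupling `w`; `w = 0` reproduces the
exact degeneracy signature of a conical intersection crossed along a 1D
scan, small `w > 0` gives avoided-crossing controls that must not be
relabeled. Independent Gaussian noise (default 0) stresses fit
robustness only — real QM energies carry systematic, geometry-correlated
error, not i.i.d. noise, so passing recovery tests demonstrates
correctness of the statistics, not robustness to method error. The
generator makes no attempt to mimic any real molecule's electronic
structure, state ordering or specific per-mode values.

Benchmark-suite conditions (chosen once as typical of ±0.1-factor scans
of a mid-sized chromophore): ground curvature `k0 ~ U(80, 140)` eV
(≈0.4–0.7 eV at the grid edge), excited curvature `k1 = k0·U(0.6, 0.9)`
(excited states are flatter), vertical offsets 3.0/3.5 eV,
Morse range parameter α = 5 with `D = k1/2α²` so anharmonic and
harmonic states share their curvature, and crossings placed at
`i_c ~ U(0.045, 0.07)` via an S2 diabat shifted by 0.08 with equal
curvature, which makes the gap exactly linear in `i` (one crossing,
gap minimum within half a grid step). FC-active scenarios target
λ ∈ [0.10, 0.13] eV, solving the displacement per potential shape;
the target is set so intended-active draws sit decisively above the
mixture's mean + 1 SD cutoff — a population-relative rule leaves the
"intended case" of a draw near the threshold undefined, which is a
property of the labels, not of the classifier. The default mixture is
50% harmonic, 10% each FC-shifted, Morse, Morse+FC, both-anharmonic,
and crossing.

Two subtleties surfaced by the generator's analytic truth are worth
recording. First, on a symmetric grid the cubic Taylor term of a Morse
potential cancels from the curvature estimate and the quartic term
*raises* the fitted `a` slightly above its i→0 value `Dα²`;
fitted curvatures of anharmonic states therefore mix in higher-order
shape and only harmonic states support the clean reading
`Δa < 0 ⇔ flatter excited state`. Second, λ defined with a grid-point
minimum differs from the fitted-vertex λ by up to `k·(Δi/2)²/2` when
the true minimum falls between grid points; recovery tests compare
against the continuous-interval truth (`lambda_interval`), while the
grid-restricted value (`lambda_true`) is also recorded.

## Problem sizes used in tests

The shipped tests and the acceptance script run the fit-oracle
comparison on 1000 random scans, diabatization properties on 100
zero-coupling crossing replicates, classification recovery on a
100-replicate mixed suite at noise SD 1e−3 eV, and λ recovery on 50
FC-shifted draws — sizes at which every stochastic margin observed is
wide (case recovery 100%, detection sensitivity 100% with 0 false
positives) while the whole suite stays desk-scale.

## Known limitations

* Diabatization handles one crossing per mode per side; multiply
  re-crossing states along one scan would need the character-scalar
  hook.
* The RMSD-based swap criterion can in principle prefer a swap on
  near-degenerate parallel states; the detection threshold and the
  strict-reduction rule guard the realistic cases but are not proofs.
* PED categories on heavily delocalized modes depend on the redundant
  coordinate set; MIX is the honest answer there.
* The excitation-offset `auto` policy uses the i = 0 gap of each mode's
  own scan; scans assembled from inconsistent references across modes
  would silently shift ratios (the assembly step re-references each
  mode, which assumes the table is per-mode consistent).
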