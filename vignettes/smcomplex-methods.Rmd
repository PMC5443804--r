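---
title: "Models and methods behind smcomplex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smcomplex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smcomplex)
```

`smcomplex` quantifies how an amyloid-β(14–23) hairpin mimic (H)
interacts with the linear monomer (M): how strongly the H-M and H-H
dimers resist force, how long they live, what the resulting aggregates
look like, and what a coarse-grained pulling simulation says about the
origin of the strength difference. This vignette records the models,
the parameter choices that matter, and the places where the design was
genuinely open.

## Force spectroscopy

### Model

A specific unbinding event in a retraction curve is the stretch of a
PEG tether followed by an abrupt drop of the force to baseline. The
tether elasticity is the worm-like chain interpolation formula,

$$F(x) = \frac{k_B T}{L_p}\left[\frac{1}{4}\left(1 -
\frac{x}{L_c}\right)^{-2} - \frac{1}{4} + \frac{x}{L_c}\right],$$

with persistence length $L_p$ and contour length $L_c$. $F$ is zero at
zero extension, strictly increasing, and diverges at $x = L_c$; the
package treats $x \ge L_c$ as a domain error rather than clamping.

### Detection and fitting choices

* **Baseline**: median of the final 20% of the trace — the
  far-from-surface region is event-free. The noise scale is the MAD of
  the same region.
* **Drop detection**: on a 5-point running median, a drop across a
  2-sample lag exceeding `max(6 sigma, 30 pN)` marks a candidate. Drops
  within 10 nm of contact are nonspecific adhesion and are ignored.
  When several drops qualify, the one at the largest distance wins
  (serial tether geometry: the last unbinding is the specific one).
* **Rupture position**: the drop is localised on the raw trace as the
  largest single-sample fall near the candidate, and the rupture
  distance is the midpoint of the two bracketing samples. The true
  rupture lies uniformly between them, so the midpoint is unbiased;
  anchoring it on the last ramp sample instead would bias the rupture
  force low by half a sample times the terminal WLC slope (tens of
  pN/nm near rupture).
* **WLC fit**: Levenberg–Marquardt least squares (via minpack.lm) on
  the ramp from 2 nm (contact artefacts excluded) to the drop. $L_p$ is
  a free parameter bounded in [0.1, 2] nm by default because the
  tether's persistence length is not known a priori; it can be fixed.
  Start values: $L_p = 0.38$ nm, $L_c = x_{max}/0.85$.
* **Rupture force**: the fitted model force at the rupture distance,
  not the raw last sample — robust to noise spikes at the drop.
* **Specificity filter**: $L_c$ inside 23–43 nm (the 33 ± 5 nm tether
  ± 2 SD) and $F_r$ above a 20 pN noise floor.
* **Histograms**: Freedman–Diaconis bin width by default; the Gaussian
  is fitted to bin counts by unweighted least squares. A bimodal
  sample is *flagged* by a large relative residual, but the fitted
  location then sits on one of the modes — a single Gaussian fitted by
  least squares prefers one mode over the midpoint.

### Synthetic curves

`sim_fd_curves()` renders specific events by numerically inverting the
force law (bisection; the model gives $F(x)$, curves need the
extension where the drawn rupture force is reached), on a distance
grid set by a 500 nm/s retraction sampled at 5 kHz (0.1 nm/sample).
Rupture forces and contour lengths are normal (truncated positive),
instrument noise is white Gaussian (10 pN default), nonspecific curves
carry a triangular adhesion peak within 10 nm of contact, and the rest
are noise-only. What the generator does *not* emulate: coloured
cantilever noise, multiple simultaneous tethers (sawtooth curves),
baseline drift, and hydrodynamic drag — so passing recovery tests
demonstrates correctness of the estimators under the stated noise
model, not robustness to every instrumental artefact.

## Dwell-time (lifetime) analysis

A bound complex appears as a one-step rise of fluorescence and a
one-step fall; the dwell is the complex lifetime. Traces are framed at
100 ms (the recording resolution), so dwells are integral frame
multiples.

* **Threshold**: per-trace median + 5 MAD. Runs above threshold are
  events; runs touching the first or last frame are censored (their
  duration is unknown), and events must be one-step: the coefficient
  of variation of the plateau must stay below 0.25, which rejects
  staircase (multi-complex) events.
* **Lognormal fit**: the dwell histogram (bin width a whole multiple
  of the frame, edges offset half a frame so quantized values sit
  mid-bin) is fitted with a scaled lognormal density by weighted least
  squares. Weights are Poisson ($1/\text{expected count}$),
  *iteratively reweighted* from the fitted counts: weighting by
  observed counts favours downward-fluctuating bins and biases the
  scale parameter low by a few percent, which matters when the
  tolerance is a few percent. Closed-form maximum likelihood is
  available as `method = "mle"`.
* **Reported lifetime**: the distribution mean $\exp(\mu + \sigma^2/2)$.
  Which location ("average lifetime") a lognormal fit should quote is a
  convention; the mean is the default here and the fitted
  $(\mu, \sigma)$ are returned so median or mode can be derived.
* **Replicates**: `aggregate_replicates()` pools independent
  experiments as mean ± SD of the per-replicate fitted means, the same
  protocol as the triplicated experiments; the acceptance script uses
  three replicates for the lifetime targets.

The generator draws true dwells from a lognormal parameterised by its
distribution mean $m$ and shape $\sigma$ ($\mu = \ln m - \sigma^2/2$),
because the reported tables list means. $\sigma = 0.8$ is the default
shape: it places roughly 90% of the H-M dwell mass below 2 s, matching
the presented histogram range. Dwells are quantized by rounding to
whole frames (minimum one frame; sub-frame dwells are emitted but
flagged), so quantized and true dwells differ by less than one frame.
Photophysics (blinking, bleaching) is deliberately not modelled.

## AFM morphology

Cross-sections interpolate the height map bilinearly along a segment;
the baseline is the median of the outer 10% of profile samples. Peak
height and FWHM are read off the baseline-corrected profile. On a
noise-free spherical cap the interpolated profile tracks the analytic
sphere to within curvature × pixel²/8 on the smooth interior; at the
rim the profile has a slope discontinuity, where any linear
interpolation errs by O(slope × pixel) — cross-section accuracy
statements therefore apply to the interior of a feature.

Particle statistics threshold the map at baseline + `min_height` and
label connected components (EBImage). Two choices deserve note:

* **Baseline** is a clipped median (median re-taken over pixels within
  3 MAD, twice): the plain image median is biased upward by the
  fraction of the surface the particles cover.
* **Per-particle height** is an *apex estimate*: the mean of region
  pixels within 2 background-SDs of the region maximum on a 3×3
  median-filtered map. A plain maximum is biased upward by
  extreme-value statistics of the roughness — for a flat-topped disk
  of several hundred pixels at 0.05 nm roughness the bias is of order
  0.15 nm, which would swamp the 0.85 ± 0.08 nm disk population.
  `method = "max"` is retained for comparison.

The generator composes spherical caps, flat disks and
half-elliptical fibril ridges by pointwise maximum (a tip reads the
tallest surface) plus white Gaussian roughness. Tip convolution is not
modelled; lateral sizes are therefore "as-imaged" widths, and the
fibril width parameter is treated as the tip-convolved apparent width,
independent of the apex height.

## Dihedral PCA and free-energy landscapes

Angles are mapped to $(\cos\theta, \sin\theta)$ to remove periodicity;
terminal-residue angles are excluded (floppy chain ends dominate
variance otherwise). PCA is the mean-centred covariance
eigendecomposition; each component's sign is fixed by making its
largest-magnitude loading positive, so projections are reproducible.

The landscape is $\Delta G = -\ln(P/P_{max})$ in units of $k_B T$ over
a 50 × 50 grid spanning the data range padded by 5%. Empty bins are
`NA` sentinels, not capped values, so minima search cannot walk
through unsampled territory.

Minima detection is a watershed/persistence pass with two
statistical guards, both consequences of finite counts:

* a basin merging into a deeper one at saddle height $s$ is a genuine
  minimum only if $s - \Delta G_{min}$ exceeds the depth threshold
  *plus* `sig_z` (default 3) standard errors of the log count ratio,
  $\sqrt{1/c_{seed} + 1/c_{saddle}}$ — otherwise one- and two-count
  fringe bins fake ln 2 ≈ 0.7 $k_B T$ of "persistence";
* basins that never meet another basin (states separated by unsampled
  territory, and the global basin) are kept only when the landscape
  has relief and they hold at least `min_population` frames. Relief is
  measured over interior bins: the 5% padding geometrically dilutes
  border bins, which is binning artefact, not occupancy structure, and
  a uniform distribution must report no minima.

`basin_free_energies()` integrates occupancy over each basin and
reports $-\ln(P_i/P_{max})$; for well-separated states this recovers
occupancy ratios with plain multinomial error, free of the bin-width
and peak-alignment noise of single-bin estimates.

The trajectory generator draws frames from a von Mises mixture with
known occupancies. The validation landscapes use broad states
(concentration κ = 10) so that each state spans many bins of the
default grid; with very tight states the per-bin peak estimate
degrades for the reasons above, which is exactly what
`basin_free_energies()` is for.

## Monte Carlo pulling

The energy is a Cα Gō model in $k_B T$ units: harmonic bonds (rest
lengths equal to the built geometry, stiffness 300 $k_B T$/nm²), 12-10
native-contact wells (depth 6 $k_B T$ per contact, the Lys–Asp salt
bridge at double depth), and a truncated soft-sphere repulsion
(diameter 0.5 nm) between non-bonded, non-contact pairs, clamped so
the energy stays finite for any overlap. At the built geometry the
energy is exactly minus the summed contact depths.

The two dimers are parameterised by the reported hydrogen-bond
counts — H-M: 5 inter-chain contacts + salt bridge (+3 intra-hairpin),
H-H: 4 inter-chain contacts (+3 intra per hairpin) — and arranged so
that the comparison is about those counts and nothing else: all plain
inter-chain contacts share one rest length (0.75 nm), and in both
geometries the pulled N-terminal Cys beads enter the contacting
strands at *opposite ends*. That makes pulling load the contact
ladder in shear (cooperatively). The alternative — pulled ends on the
same side — lets backbone compliance peel the rungs one by one, and
the rupture force then measures the single-contact strength instead
of the interaction count. The hairpin keeps its printed sequence
(Cys + HQKLVFFAED + YNGK + HQKLVFFAED = 25 beads; the monomer
CHQKLVFFAED = 11).

Dynamics are single-bead Gaussian displacements (SD 0.05 nm, roughly
half-accepted at 298 K) under Metropolis acceptance; sampling against
the exact Boltzmann distribution is verified on a two-bead toy
(χ² test of thinned spring-held bead positions against the analytic
Gaussian). Two virtual springs (25 pN/nm, within the experimental
cantilever range) connect the pulling groups to anchors that recede
along the pulling vector at `velocity` nm per sweep (default 0.002,
with 200 static equilibration sweeps first). The velocity is in MC
sweeps, not seconds: a Metropolis sweep has no physical time, so the
experimental 500 nm/s (or any internal unit of another engine) cannot
be mapped onto it; only orderings and trends are meaningful. Rupture
is declared when the fraction of formed inter-chain contacts
(distance < 1.5 rest lengths) falls below 0.25, and the rupture force
is the maximum spring force seen before that sweep; the rupture
criterion and the spring parameters are choices of this simulator, as
Monte Carlo pulling has no canonical definitions for them.
Consistent with dynamic force
spectroscopy, the mean rupture force does not decrease when the
velocity is doubled (checked by simulation). The model reproduces the
H-M > H-H rupture-force *ordering* over 50-seed batches; absolute
forces depend on the toy energy scale and are not comparable to the
all-atom values.

## Problem sizes and reproducibility

The validation suite and the acceptance script use the study's own
sample sizes where they are stated: 2000 force curves per system with
180 / 175 specific events, 297 / 274 dwell events, 100 particles per
morphology class, 50,000 frames for landscape calibration, 50 pulling
seeds per dimer. Every stochastic step is seeded, and fixed seeds give
bitwise-identical generator output.

## Limitations

* All recovery results are on synthetic data drawn from the same
  families the estimators assume; they validate the implementation,
  not the estimators' robustness to real-world model misfit.
* The dwell pipeline has no spot detection: traces, not movies, are
  the input unit.
* No Bell–Evans loading-rate analysis (single retraction speed), no
  multi-rupture deconvolution, no cantilever calibration.
* No tip-shape deconvolution in morphology; lateral sizes are
  apparent sizes.
* The pulling engine is a toy Gō model: no solvent, no sequence
  energetics beyond the contact map, no physical time base.
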