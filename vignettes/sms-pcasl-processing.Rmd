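---
title: "Processing multi-delay SMS PCASL: models, corrections and design choices"
author: "smsasl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing multi-delay SMS PCASL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smsasl)
```

## The problem

Pseudo-continuous arterial spin labelling (PCASL) measures cerebral perfusion
by magnetically labelling arterial blood water and subtracting label from
control images. Acquired at several post-labelling delays (PLDs), it yields
both cerebral blood flow (CBF, ml/100g/min) and arterial transit time (ATT,
s). A simultaneous multi-slice (SMS) 2D readout excites several slice bands
at once; combined with a strong pre-saturation pulse before labelling, this
produces a conspicuous *banding* artefact: slice-wise intensity steps, most
visible between the last slice of one band and the first slice of the next.

`smsasl` implements the computational core of a processing chain for such
data — banding simulation and correction, motion-aware label–control
subtraction, voxelwise kinetic inference, CSF reference-region calibration,
and partial-volume-corrected (PVEc) estimation — together with a synthetic
phantom that makes every stage testable against known ground truth.

The default acquisition (`asl_protocol()`) uses a 1.5 s label, PLDs of
0.2/0.7/1.2/1.7/2.2 s repeated 6/6/6/10/15 times (86 ASL volumes), 60 slices
in 6 bands of 10 with a 59 ms per-slice readout, a 19 ms echo time, and two
long-TR (8 s) proton-density calibration images.

## Two banding mechanisms and their corrections

**Saturation recovery.** Within a band, slice at position $p$ (0-based
acquisition order) is read out $p\,\delta t$ after the first, so its tissue
magnetisation has recovered for
$t_{sat}(s) = \tau + \mathrm{PLD} + p(s)\,\delta t$
seconds since pre-saturation. The signal model
$S(t_{sat}) = M_0\,(1 - e^{-t_{sat}/T_1})$
is fitted voxelwise to the control volumes (`fit_satrecov()`), yielding an
$M_0$ and $T_1$ map, and every volume is then multiplied by
$$C(s, \mathrm{PLD}) = \frac{1 - e^{-(\tau+\mathrm{PLD})/T_1}}
                            {1 - e^{-t_{sat}(s,\mathrm{PLD})/T_1}},$$
normalising each slice to the value it would have had if acquired at the
nominal PLD (`satrecov_correct()`). The correction is strongest at short
PLDs and fades as recovery saturates, so it cannot explain banding seen on
the fully relaxed calibration image.

**Residual (empirical) gradient.** The remaining banding is modelled as a
linear function of within-band position: a multiplicative factor
$1 + g\,(p - (B-1)/2)$ with $B$ the band size. `fit_empirical_banding()`
estimates $g$ by regressing masked slice-mean intensity on $p$ within each
band (ordinary least squares), normalising the slope by the band-mean
intensity, and averaging over bands and subjects. `empirical_correct()`
divides the factor out; by construction the factors average one per band, so
band-mean intensity is preserved. A single scalar $g$ (rather than per-band
slopes) is the default because it is identifiable from a single calibration
image; per-band behaviour can be explored by fitting bands separately.

The two mechanisms act in opposite directions at short PLDs when $g < 0$ —
the phantom default ($g = -0.02$) reproduces that near-cancellation at
PLD 0.2 s, while at late PLDs the gradient dominates. The
`band_discontinuity_index()` (BDI) quantifies banding as the ratio of
across-boundary to within-band slice-mean jumps (≈1 for band-free images);
it is scale-free, so even a small residual linear profile scores high, which
makes it a sensitive QC metric.

## Motion-aware subtraction

Because the slice-dependent corrections live in scanner coordinates while
anatomy moves, a voxel that crosses slices between volumes receives the
wrong factor if corrections are applied statically. `motion_resolved_factors()`
translates the scanner-frame correction fields (recovery ratio, gradient,
inverse bias) by each volume's rigid translation so corrections follow
anatomy; the voxelwise $T_1$ component deliberately stays attached to
anatomy. The pipeline removes the gradient and bias *before* the
saturation-recovery fit: under motion those factors differ between volumes
at a fixed voxel and would otherwise bias the fitted $T_1$ (they no longer
absorb into the voxel's $M_0$).

Subtraction itself is a per-voxel, per-PLD ordinary least squares fit with
two regressors — a static column of ones and a perfusion column coded
$+1/2$ (control) and $-1/2$ (label) — so the perfusion coefficient equals
control-minus-label (`build_design()`, `subtract_glm()`). With balanced,
fully valid volumes this reproduces the naive mean difference exactly;
voxels that leave the field of view in *any* volume are excluded outright.
Each voxel's effective PLD is the nominal PLD plus its slice-timing offset
in the reference geometry; the per-volume PLD jitter that motion induces is
ignored beyond the FOV exclusion (a documented approximation). The GLM
residuals (84 degrees of freedom per voxel) provide the noise variance used
to weight the kinetic likelihood.

## Kinetic inference

The difference signal is modelled as the standard PCASL tissue curve plus a
macrovascular component:

$$\Delta M(t) = \underbrace{2\alpha M_{0a} f\, T_1'\,
  e^{-\Delta t/T_{1b}}\bigl(1 - e^{-(t-\Delta t)/T_1'}\bigr)}_{\text{tissue, during bolus}}
  \;+\; 2\alpha M_{0a}\,\mathrm{aBV}\, e^{-t/T_{1b}}\,
  \mathbf{1}[\Delta t_a \le t < \Delta t_a + \tau],$$

with the trailing-edge form after $t \ge \Delta t + \tau$ and
$1/T_1' = 1/T_1 + f/\lambda$. Fixed constants default to consensus values
$T_{1b} = 1.65$ s, $\alpha = 0.85$, $\lambda = 0.9$ ml/g (configurable).
`fit_kinetic()` computes per-voxel MAP estimates of $(f, \Delta t,
\mathrm{aBV}, \Delta t_a)$ under a Gaussian ATT prior (mean 1.3 s, SD 0.5 s),
a Gaussian arterial-arrival prior (0.5 ± 0.3 s), a flat prior on $f$, and an
automatic relevance determination (ARD) prior on aBV. The prior SDs are
implementation defaults (weakly informative), not literature constants.

Implementation notes, in decreasing order of consequence:

* **Noise weighting.** The likelihood uses the GLM-derived per-voxel noise
  variance as a fixed weight. This makes the prior-reversion property hold
  mechanically — as data become uninformative the posterior mode moves to
  the prior means — and makes noiseless recovery exact.
* **ARD.** The aBV precision follows the evidence (MacKay) update
  $\phi \leftarrow \gamma/\mu^2$ with $\gamma = 1 - \phi\,\mathrm{var}$ and
  outright pruning when $\mu^2 \le \gamma\,\mathrm{var}$, iterated at most
  20 times to a $10^{-4}$ tolerance; estimates below $10^{-4}$ are set to
  exactly zero. The simpler update $\phi \leftarrow 1/(\mu^2+\mathrm{var})$
  was evaluated and rejected: it has a non-zero fixed point near half the
  maximum-likelihood aBV, so non-arterial voxels retain spurious small
  volumes under noise.
* **Multi-start for the arterial term.** At the conventional start
  (aBV = 0, arrival 0.5 s) the arterial component has an exactly flat
  gradient whenever no observation time falls inside the initial bolus
  window. A second start whose window covers the earliest observation, with
  aBV seeded from that observation's residual, is always tried and the
  better optimum kept per voxel.
* **Units and the flow term in $T_1'$.** The fit runs in the arbitrary
  units of the data, where both $f$ and aBV absorb $M_{0a}$; bounds and
  thresholds are scaled accordingly and aBV is reported as a fraction. The
  flow dependence of $T_1'$ needs $f$ in s$^{-1}$, so the first pass sets it
  to zero and, when the reference-region $M_{0a}$ is available (it does not
  depend on this fit), one refinement pass re-fits with
  $T_1'(f_{phys})$.
* **Optimiser.** All voxelwise fits share a bounded Levenberg–Marquardt
  routine vectorised across voxels (forward-difference Jacobians; damped
  normal equations solved by a Cholesky factorisation vectorised over
  voxels with Jacobi scaling, since likelihood weights and prior precisions
  can differ by many orders of magnitude). Tolerance $10^{-8}$, at most 50
  iterations; negative $f$ is allowed during optimisation to avoid boundary
  bias and only clipped in summaries.

## Calibration

`estimate_m0_blood()` converts the mean ventricular-CSF signal of the first
(corrected) calibration image to arterial blood magnetisation,
$M_{0a} = \bar S_{CSF}\, e^{TE/T2_{CSF}}\, e^{-TE/T2_{blood}} / \lambda_{CSF}$,
with 3T defaults $\lambda_{CSF} = 1.15$, $T2_{CSF} = 0.75$ s,
$T2_{blood} = 0.15$ s. The long TR (> 8 s) makes a saturation correction
unnecessary (< 1% error). `calibrate()` then applies
$\mathrm{CBF} = 6000 f_{au} / M_{0a}$ — a global positive scaling that
preserves voxel rank order exactly. Reference-region calibration is used
instead of voxelwise division so residual banding in the calibration image
cannot propagate into the perfusion maps.

## Partial volume correction

`fit_pvec()` fits, in every voxel with appreciable tissue, a two-tissue
mixture $PV_{GM}\,\Delta M(f_{GM}, \Delta t_{GM}; T_{1,GM}) +
PV_{WM}\,\Delta M(f_{WM}, \Delta t_{WM}; T_{1,WM})$ with ATT priors of
1.3 s (GM) and 1.6 s (WM) and a first-order spatial penalty — the sum of
squared 6-neighbour differences of $f_{GM}$ and $f_{WM}$, weighted by
`smoothness` times the median likelihood precision (default 0.1, chosen so
the penalty is comparable to the likelihood curvature at typical SNR; the
full spatial-Bayes machinery that would estimate this weight from the data
is out of scope). Block-coordinate sweeps alternate vectorised voxel
updates with refreshing neighbourhood means, stopping when the mean
relative parameter change falls below $10^{-4}$ (at most 50 sweeps; a few
ill-conditioned low-PV voxels must not stall the loop, hence the mean
rather than the max). The macrovascular component is omitted from the PVEc
model — two tissues only — with arterial signal handled by the non-PVEc
path. $T_1$ defaults are 1.3/1.1 s for GM/WM.

On mixed phantoms PVEc raises GM CBF relative to the PV-diluted voxelwise
estimate (the voxel fit averages GM and WM flow) while leaving ATT nearly
unchanged — the package asserts the direction, not a magnitude.

## The phantom: what it does and does not emulate

`make_phantom()` builds nested ellipsoids — a GM shell over a WM interior
with a central ventricular CSF compartment — with smooth partial-volume
transitions, plus a thin intra-cerebral "artery" carrying macrovascular
signal. Defaults (the package's study conditions, chosen once):

| quantity | default | note |
|---|---|---|
| f (GM/WM) | 60 / 20 ml/100g/min | cortical vs deep white matter |
| ATT (GM/WM) | 1.2 / 1.5 s | near, not equal to, the prior means |
| arterial arrival / aBV | 0.8 s / 0.01 | bolus visible at the first PLD for every slice |
| T1 (GM/WM/CSF) | 1.3 / 1.1 / 4.3 s | drives the recovery banding |
| M0 (GM = WM) | 100 a.u. | PD contrast is modest; equal keeps the gradient estimator identifiable |
| gradient g | −0.02 per position | opposes the recovery profile at short PLDs |
| bias amplitude | 0.1 | smooth off-centre bump |
| noise SD | 0.4 a.u. | per-volume contrast-to-noise ≈ 2 on peak GM ΔM |

The CSF proton density embeds the calibration constants
($\lambda_{CSF} M_{0,blood}\, e^{-TE/T2_{CSF}} e^{TE/T2_{blood}}$) so that
reference-region calibration is exact on noiseless data — unit bookkeeping
is testable end to end. The brain's axial semi-axis (0.58 × slab) makes
tissue reach the first and last slices, as in a real acquisition slab over
the cerebrum; with empty polar slices the gradient estimator would inherit
an anatomy-curvature bias larger than its round-trip tolerance.

The saturation-recovery banding is applied as a multiplicative slice
profile on the *whole* signal (static and perfusion-weighted), which makes
the normalisation correction exact in the ideal case; mechanisms are
applied in scanner coordinates after the per-volume translation of anatomy,
and Gaussian noise is added last. Label volumes subtract the forward
kinetic difference signal evaluated at each slice's effective time, so
corrected data match `buxton_tissue()`/`buxton_arterial()` to machine
precision and parameter recovery can be asserted tightly.

What the phantom does **not** emulate: susceptibility or gradient
distortion (corrections out of scope), background suppression (not used by
the acquisition modelled), Rician noise (additive Gaussian is adequate at
the SNRs simulated), realistic anatomy, cardiac/respiratory physiology, or
dispersion of the labelled bolus. Passing tests therefore demonstrate
correctness of the algorithms under the stated generative model, not
performance on real data; in particular, sub-voxel motion is
interpolation-limited (trilinear resampling in both simulator and
realignment smooths the static signal by a few percent near edges, which is
large relative to the ~1% perfusion signal), so motion properties are
demonstrated with integer-slice translations where realignment is exact.

## Degenerate inputs and tie-breaks

Constant-in-time control signal pins $T_1$ at the lower feasibility bound
(0.1 s) and the voxel is flagged invalid; invalid voxels are corrected with
the mask-median $T_1$ so no voxel is ever divided by an unfitted value.
Series objects carry provenance flags and refuse double correction. A
constant image has BDI 1 by definition (0/0). Bands with fewer than two
populated slices are skipped by the gradient estimator; if all are skipped
it is an error. Empty masks, missing conditions at a PLD, and all-voxel FOV
loss are errors with stage names attached by the pipeline.

## Problem sizes

The shipped tests and the acceptance script run on 24×24×60 grids for the
saturation-recovery round trip, 16×16×60 for gradient, kinetic, ARD and
PVEc checks (≥ 500 pure-GM voxels), 12×12×60 for prior reversion, and
10×10×60 with ten phantoms per cohort for the two-cohort contrast; these
sizes give stable statistics for every property while keeping a full run in
a few minutes.

## Known limitations

* Motion is translation-only; rotations would require a full rigid
  resampler and slice-timing geometry.
* The MAP point estimate stands in for the full variational posterior of
  the reference tools; posterior uncertainty is not propagated (ARD uses
  the Gaussian curvature approximation).
* The empirical gradient is a single scalar shared across subjects and
  bands; cohort- or subject-specific coefficient sets are intentionally
  not modelled.
* PVEc assumes the PV maps are exact inputs; errors in them propagate
  directly into tissue estimates.
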