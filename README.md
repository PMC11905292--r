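# smsasl

Processing tools for **simultaneous multi-slice (SMS) multi-delay PCASL**
perfusion MRI, for imaging scientists who need a tested, ground-truth-
validated implementation of the bespoke steps this kind of acquisition
requires: correction of the two slice-banding mechanisms, motion-aware
label–control subtraction, multi-delay kinetic inference, CSF
reference-region calibration, and partial-volume-corrected estimation —
plus a synthetic phantom that makes every stage verifiable by parameter
recovery, with no data download.

## What it computes

An SMS 2D readout after a pre-saturation pulse produces slice-wise
intensity *banding* from two mechanisms. The saturation-recovery component
follows $S(t_{sat}) = M_0 (1 - e^{-t_{sat}/T_1})$ with
$t_{sat} = \tau + \mathrm{PLD} + p\,\delta t$ for within-band position $p$;
it is fitted voxelwise to the control images and normalised out. The
residual component is a within-band linear gradient
$1 + g\,(p - (B-1)/2)$, estimated from calibration images and divided out.

Subtraction is a per-voxel, per-PLD GLM (static column + ±1/2
label/control contrast) with field-of-view exclusion under motion, and
corrections are evaluated at the slice each voxel occupied at acquisition.
Perfusion, arterial transit time and macrovascular blood volume come from
MAP inference on the Buxton PCASL model,

$$\Delta M(t) = 2\alpha M_{0a} f\,T_1'\,e^{-\Delta t/T_{1b}}
  \left(1 - e^{-(t-\Delta t)/T_1'}\right), \qquad
  \tfrac{1}{T_1'} = \tfrac{1}{T_1} + \tfrac{f}{\lambda},$$

with a $\mathcal N(1.3, 0.5^2)$ s prior on ATT and an automatic relevance
determination prior that removes the macrovascular component from
non-arterial voxels. CBF is converted to ml/100 g/min by reference-region
calibration against ventricular CSF
($M_{0a} = \bar S_{CSF} e^{TE/T2_{CSF}} e^{-TE/T2_{blood}} / \lambda_{CSF}$,
$\mathrm{CBF} = 6000 f / M_{0a}$). PVEc jointly fits GM and WM kinetics
weighted by partial-volume fractions, with ATT priors 1.3/1.6 s and a
6-neighbour spatial penalty on the tissue flows.

See the methods vignette (`vignettes/sms-pcasl-processing.Rmd`) for the
models, priors, numerical choices, and what the phantom does and does not
emulate.

## Worked example

```r
library(smsasl)
protocol <- asl_protocol()                       # 1.5 s label; PLDs 0.2..2.2 s
phantom  <- make_phantom(c(16, 16, 60), protocol, seed = 1)
dataset  <- simulate_dataset(phantom)            # 86 ASL volumes + 2 calibration
run      <- run_pipeline(pipeline_config(dataset = dataset, seed = 1))
print(run)
```

```
SMS PCASL pipeline run
  gradient g: -0.01962
  BDI raw -> corrected (per PLD): 3.51/5.21/6.04/6.52/6.82 -> 0.59/0.62/0.65/0.66/0.70
  M0a: 110 a.u.
ASL kinetic model fit (MAP, Buxton model + macrovascular ARD)
  voxels fitted : 6440 (6 non-converged)
  median CBF    : 44.93 ml/100g/min
  median ATT    : 1.279 s
  aBV > 0       : 772 voxels
```

The within-band gradient estimate (−0.0196) recovers the injected −0.02;
the band-discontinuity index (ratio of across-band to within-band
slice-intensity jumps; ≈1 means band-free) drops from 3.5–6.8 to below 0.7
once both corrections are applied; the CSF-calibrated blood magnetisation
matches the simulated 110 a.u. Whole-brain median CBF (44.9) mixes grey and
white matter; restricting to pure grey matter recovers the simulated
conditions:

```r
gm <- phantom$pv_gm >= 0.99
mean(run$fit$cbf[gm & run$fit$mask], na.rm = TRUE)   # 62.3  (truth 60)
mean(run$fit$att[gm & run$fit$mask], na.rm = TRUE)   # 1.24  (truth 1.2)
head(run$idps, 3)                                    # parcel-wise mean/std table
```

Command-line wrappers live in `inst/cli/`: `aslsim` writes a simulated
dataset (NIfTI + JSON sidecar + motion TSV) to a directory, and
`aslrun config.yaml` executes the pipeline from a YAML configuration
(see `?read_run_config`).

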