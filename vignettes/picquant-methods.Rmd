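---
title: "Methods: quantifying PIC J-aggregation as a crowding sensor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying PIC J-aggregation as a crowding sensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picquant)
```

## The measurement problem

Pseudoisocyanine chloride (PIC) is a cyanine dye that self-assembles into
fibrillar J-aggregates above a concentration/temperature threshold. The two
states are spectrally distinct: the monomer emits a weak, broad band from
roughly 520 to 650 nm peaking near 560 nm, while the J-aggregate shows an
intense, narrow band at ~575 nm. Because the assembly equilibrium responds
to macromolecular crowding, the dye's state reports on the physicochemical
environment of the compartment it sits in -- cytoplasm, nucleus, stress
granule or reconstituted protein droplet. `picquant` implements the
quantitative analyses such an assay needs, plus synthetic-data generators
that carry ground truth for every input so the whole chain is testable.

## Pixel classification

Confocal images are acquired in three detection bands: 500--520 nm
(FUS-GFP, marking stress granules), 565--585 nm (aggregate band) and
600--620 nm (monomer band), on a 12-bit scale (0--4095 counts). The
classifier is a pair of intensity rules on the aggregate band:

* **aggregate** -- intensity >= 400 counts (inclusive at the threshold);
* **monomer** -- intensity below the threshold but at or above a background
  floor (default one third of the 175-count monomer-window minimum, i.e.
  ~58 counts; the monomer window itself is 175--350 counts with a typical
  diffuse level of 250);
* **background** -- everything else, plus all excluded pixels.

Nucleoli accumulate bright monomer signal that would cross the 400-count
threshold and masquerade as aggregate, so they are excluded. Where the
original workflow cut them out by hand, `mask_nucleoli()` automates the
step with an Otsu threshold restricted to the nucleus mask, keeping
8-connected bright components of at least 4 px. A contrast guard (bright
class must exceed 1.5x the dim-class mean) prevents the Otsu split from
fabricating structure in a uniform nucleus.

### Spectral signature and threshold calibration

`classify_spectrum()` decides monomer vs aggregate for a single emission
spectrum with two criteria that must both hold: the 565--585 nm band mean
must exceed 1.5x the 600--620 nm band mean, and the 575 nm peak must be
locally *sharp*. Sharpness is the mean over 573--577 nm minus the mean of
the +/-5 nm shoulders (568--572 and 578--582 nm), and must exceed both 3x
the noise SD and 5% of the peak height. The relative floor is essential: a
broad band is concave near its flank, so its prominence over any chord is
strictly positive, and with noiseless data a noise-scaled floor alone
never rejects the monomer. A band tens of nanometres wide loses well under
5% of its height over +/-5 nm; the ~4 nm aggregate band loses over half.
This is the one place the package deviates from its own first-draft design
(noise-scaled floor only), for the reason just given.

`calibrate_threshold()` reproduces the iterative threshold search: scan
candidate intensity levels above the monomer window and return the lowest
level L such that *every* pixel at or above L carries the sharp-peak
signature. On synthetic pixels whose signature appears at 400 counts, the
calibration returns 400.

### Quantification

The headline quantity is the aggregate area fraction of the cytoplasm,
`100 * |aggregate AND cytoplasm| / |cytoplasm|`, reported per cell and as
mean +/- SD across cells; a pooled-pixel variant is also reported because
the original averaging weights are not documented. Stress-granule
colocalization reports, per granule, the class content fractions and the
granule/cytoplasm monomer-intensity ratio.

## Morphometrics

Objects (droplets, stress granules) are segmented as 8-connected
components at an intensity threshold -- matching wand-tool behaviour --
with a 4 px minimum size to suppress shot-noise specks, or by seeded flood
fill. Circularity is `4*pi*A/P^2`, capped at 1. The perimeter estimator is
the Kulpa-corrected chain code from Moore boundary tracing: raw chain
codes (1 per straight step, sqrt(2) per diagonal) overestimate smooth
contours by ~5.5%, and the pi*(1+sqrt(2))/8 factor removes that bias, so a
rasterized disc measures 1.00 +/- 0.05 and the value is scale-invariant to
better than 0.02. We deliberately do not chase bit-level parity with any
particular GUI's estimator; the disc tolerance documents ours.
Background correction subtracts the arithmetic mean of (conventionally 10)
background-spot means; spots overlapping a segmented object are excluded
with a warning. Group summaries use type-7 quantiles (Q1/median/Q3 boxes,
5--95% whiskers), Welch's two-tailed t-test and one-way ANOVA.

## FRAP

Recovery traces are normalized by the double-normalization-plus-full-scale
scheme: background-subtract, divide the bleached-ROI by the reference-ROI
trace (correcting acquisition photobleaching), rescale both by their
pre-bleach means, then map the first post-bleach point to 0 and the
pre-bleach plateau to 1. The cited protocol's exact formula is not printed
in the source material; this is its standard full-scale variant, and each
step is a separate, testable transformation. Note a structural consequence:
on the full-scale axis the first post-bleach point is 0 by construction,
so a trace that is already full-scale has amplitude a equal to its plateau
I0, and normalization is idempotent exactly on that family.

The post-bleach points are fitted with `I(t) = I0 - a*exp(-beta*t)` by
bounded nonlinear least squares (`nls`, port algorithm; bounds
0 <= I0 <= 1.2, a >= 0, beta > 0), with deterministic initialization: I0
from the last-decile mean, a from I0 minus the first post-bleach value,
beta from the time to half recovery. `nls` declines zero-residual data, so
noiseless traces fall back to a bounded quasi-Newton minimization of the
same objective; both routes recover noiseless parameters to < 1e-6
relative. Covariances come from the analytic Jacobian. A flat trace leaves
beta unidentifiable and is flagged rather than fitted. I0 is the mobile
fraction; group comparisons delegate to the morphometrics summary.

## Light scattering

The time-resolved SLS/DLS evaluation follows the standard 8-detector
geometry (30--86 degrees at 8-degree increments; with n = 1.332 and
lambda0 = 632.8 nm this spans q = 6.8e-3 to 1.8e-2 1/nm):

1. `q = 4*pi*n/lambda0 * sin(theta/2)`;
2. excess Rayleigh ratio `dR = RR_std * (r_sol - r_solv)/r_std` against
   the toluene standard; angles with non-positive excess are dropped, not
   fatal, because time-resolved series must keep running;
3. contrast factor `K = 4*pi^2*n0^2*(dn/dc)^2/(N_A*lambda^4)` in
   cm^2 mol/g^2 (lambda in cm, dn/dc in ml/g, concentrations converted
   from g/l to g/ml), so that `K*c/dR` is mol/g and fit intercepts are
   1/Mw directly;
4. Zimm fit (`K*c/dR` linear in q^2 and c) before droplet formation, with
   the 2*A2*c term dropped and flagged at a single concentration since it
   is then inseparable from the intercept; Guinier fit
   (`ln(K*c/dR)` linear in q^2) once droplets grow. One sign choice needs
   stating: with `dR = K*c*Mw*exp(-q^2*Rg^2/3)`, the reciprocal inside
   the log makes the slope of `ln(K*c/dR)` vs q^2 equal to +Rg^2/3 -- the
   form consistent with the Zimm expansion -- and that is what is
   implemented;
5. second-order cumulant fit of `ln g1(tau)` per angle over the window
   `g1 > 0.1*g1(0)` (later lags are noise-dominated), giving apparent D;
6. extrapolation of D to q^2 = 0 for Dz (the k_d*c concentration term is
   neglected, as is standard in time-resolved work); with fewer than 3
   valid angles the mean D is used and flagged;
7. Stokes--Einstein `Rh = kB*T/(6*pi*eta*Dz)` at T = 298.15 K,
   eta = 0.891 mPa s;
8. `rho = Rg/Rh`, ~0.775 for solid spheres (quoted as 0.78 in the
   literature -- 0.775 rounded up; the tests assert the exact sqrt(3/5)
   and proximity to 0.78 within one unit of the last printed digit).

The bath and solvent refractive indices appear in the source material as
"1496" and "1332"; they are read as 1.496 (toluene) and 1.332 (water),
the only physically plausible values. The absolute toluene Rayleigh ratio
is deliberately a required calibration input rather than a constant; the
synthetic fixtures use 1.35e-5 1/cm, a standard literature value at
632.8 nm.

**Induction time.** The reported induction period of droplet formation
comes without a printed detection rule, so the package defines one: the
first time at which Mw exceeds the baseline mean plus 3 baseline SDs for
3 consecutive frames, with baseline frames those at t <= 0 (pre-addition).
The persistence requirement suppresses single-frame noise; the 3-sigma
level ties the detector to the measured baseline noise rather than an
absolute scale. On the default synthetic growth model with 1% intensity
noise the detector fires 2 frame intervals (20 s) after the planted
nucleation time -- one frame because growth starts from zero radius, one
because the earliest droplets scatter below 3 sigma -- and this lag is
deterministic, so *differences* between conditions are recovered to within
frame resolution.

## Threshold temperature from UV--Vis ramps

Cooling ramps start at 25 degrees C and record 400--600 nm absorbance
spectra at 1 nm steps. "Appearance of a sharp peak at 573 nm" is
operationalized as: prominence of the 573 nm local maximum over a linear
baseline through 560 and 590 nm exceeding a floor (default 5x the
spectral noise SD, estimated from first differences over 400--500 nm of
the warmest spectrum), *and persisting at every lower measured
temperature* -- aggregation is reversible and monotone in temperature, so
a blip that vanishes on further cooling is noise. T_JA is the highest
temperature of the persistent run; a peak already present at the start is
start-censored (T_JA >= 25), a peak never seen is "not reached". Detected
onsets are resolution-limited: a planted threshold of 23 degrees C on a
0.5-degree grid is reported at 22.5, the first measured temperature below
the truth. Replicates are averaged per condition (two technical replicates
in the emulated design), and censored conditions are excluded from means
and flagged.

## Synthetic data: what it emulates, and what it does not

Every pipeline input has a generator emitting ground truth alongside the
data, and recovery tests compare against the emitted truth, never against
truth re-derived from the signal.

* **Cell scenes** place an elliptical cell, nucleus, bright nucleoli,
  optional stress granules and anti-aliased aggregate rods (length >>
  width, matching the fibrillar geometry) on a 12-bit raster. Diffuse
  monomer signal averages 250 counts in the aggregate band; rods default
  to 1200 counts, well above the 400-count threshold; granules carry 2x
  monomer enrichment. Rods are planted until the requested cytoplasm
  coverage is met, trimming the last rod to land within a fraction of a
  percent. Noise is Poisson shot noise plus Gaussian read noise
  (`monomer_spread`, default 15 counts; 0 switches all noise off). Pixel
  sizes and noise levels are free parameters chosen at typical confocal
  values (0.2 um/px), since the source material does not state them.
* **Emission spectra** are Gaussian band models (monomer: centre 560 nm,
  sigma 38 nm; aggregate: centre 575 nm, sigma 4 nm, 5x amplitude)
  blended by a mixture weight, with additive Gaussian noise.
* **FRAP traces** follow the single-exponential model exactly, with raw
  bleached/reference/background channels constructed so normalization has
  real work to do (reference photobleaching, additive background); a
  bypass mode emits already-normalized traces for fit-only tests.
* **Scattering series** realize a nucleation-and-growth model: spherical
  droplets appearing at a planted nucleation time, radius growing as
  `radius_max*(1 - exp(-(t - t_nuc)/tau_growth))` (defaults 150 nm,
  100 s -- growth fast enough that the detectable signal follows within
  ~1 frame of nucleation, as observed for liquid-liquid phase separation),
  lognormal polydispersity, and an effective droplet density of 0.4 g/ml
  (dilute protein condensate). SLS intensities are Guinier-consistent for
  the instantaneous size distribution; g1 is the intensity-weighted
  exponential mixture with Stokes-Einstein decay rates, emitted as the
  field correlation directly. Droplet mass is capped at 95% of total
  solute.
* **Absorbance ramps** add a narrow 573 nm band to a broad 525 nm monomer
  absorption exactly for temperatures strictly below the planted T_JA.

None of this emulates optical point-spread functions, photophysics beyond
the single-exponential bleach model, hydrodynamic interactions, multiple
scattering, or real cell-to-cell biological variability. A green recovery
test therefore establishes that the analysis chain is *correct* (it
recovers what was planted, under the stated noise), not that the
generators are faithful reproductions of microscope or goniometer data --
in particular, the reported in-cell percentages (41%, 0.2%, ...) enter
only as planted scenario parameters, and their recovery validates the
pipeline, not the biology.

## Numerical choices and degenerate inputs

* Intensity ties at the 400-count threshold classify as aggregate
  (inclusive reading of "established at an intensity level of 400").
* Quantiles are type 7 (linear interpolation), matching common defaults.
* Negative fitted Rg^2 (Zimm/Guinier) reports Rg = 0 with a flag;
  non-positive log arguments drop the angle; fewer than 3 usable angles
  is a fit error (SLS) or a flagged mean-D fallback (DLS).
* Single-pixel regions have circularity 1 by convention.
* A 1-group summary is allowed for descriptive statistics
  (`tests = FALSE`); requesting tests with one group is an error.
* All generators are bit-reproducible under a fixed seed, and the
  pipeline writers produce byte-identical output on re-runs.

## Known limitations

No CONTIN-style inverse-Laplace DLS inversion, no form-factor fitting
beyond Guinier/Zimm, no whole-cell segmentation from raw images (masks
are inputs or ground truth), no object tracking across frames, no 3-D
morphometrics, and no thermodynamic modelling of the aggregation
equilibrium. Images travel as plain CSV rasters with a JSON sidecar
rather than TIFF, since the deliverable is text-only and the target R
stack ships no TIFF codec.
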