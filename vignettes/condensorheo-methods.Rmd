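---
title: "Methods: models, generators and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, generators and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condensorheo)
```

This vignette is the package's own account of the science it
implements: the measurement models, what the synthetic-data generators
do and do not emulate, and the numerical decisions taken where more
than one defensible choice existed.

## 1. FCS: from photon counts to concentration

### Model

Fluorescence correlation spectroscopy infers the number and mobility of
fluorescent molecules from intensity fluctuations in a femtolitre-scale
observation volume.  The package assumes the standard 3D Gaussian
detection profile with lateral 1/e² waist $w_0$ and structural
parameter $k$ (axial/lateral ratio), under which the autocorrelation
$G(\tau) = \langle \delta I(t)\,\delta I(t+\tau)\rangle / \langle
I\rangle^2$ of a single freely diffusing species is

$$G(\tau) = \frac{1 + \frac{\theta_T}{1-\theta_T} e^{-\tau/\tau_T}}{N}
\left(1+\frac{\tau}{\tau_D}\right)^{-1}
\left(1+\frac{1}{k^2}\frac{\tau}{\tau_D}\right)^{-1/2},$$

with $N$ the mean particle number in the effective volume
$V = \pi^{3/2} w_0^3 k$, $\tau_D$ the diffusion time, and
$(\theta_T, \tau_T)$ the dark-state (triplet) fraction and lifetime
(`fit_triplet_diffusion()`).  Cellular fluorescent-protein data use the
anomalous-diffusion variant with exponent $\alpha$ and the
multiplicative blinking prefactor
$1-\theta_T+\theta_T e^{-\tau/\tau_T}$, whose zero-lag amplitude is
exactly $1/N$ (`fit_anomalous_blinking()`); a single diffusing
component is fitted by default because one component is what the
cellular model describes.  A reference dye of known diffusion
coefficient (default $D_\mathrm{dye} = 521.46\ \mu m^2/s$) calibrates
the volume through $w_0 = \sqrt{4 D_\mathrm{dye} \tau_D}$, and
concentration follows as $C = N/(V N_A)$.

### Correlator

`compute_autocorrelation()` is a multiple-tau correlator: lags
$1..m$ (default $m = 16$) at full resolution, then lags
$m/2{+}1..m$ on successively pairwise-binned copies of the trace.  Each
lag uses the *symmetrically normalized* estimator

$$\hat G(j) = \frac{\frac{1}{n-j}\sum_t I_t I_{t+j}}
{\bar I_{1..n-j}\; \bar I_{j+1..n}} - 1,$$

which removes the leading finite-length bias and makes the estimator
identical to the direct all-pairs correlator at uncoarsened lags — the
test suite asserts exact agreement against a brute-force oracle there,
and bounded agreement (the usual triangular-averaging bias) at
coarse-grained lags.  The trace is first rebinned to a user-chosen
**base frequency**, the rate that defines the smallest lag; defaults
follow common acquisition practice (10⁶ Hz for fast dyes, 10⁵ Hz for
cells).  We interpret base frequency as this rebinning rate; analysis
software differs in such details, and no equivalence to any particular
program is claimed.

### Background, bleaching, and averaging of repeated readings

`correct_trace()` subtracts the expected background per bin (the
background rate is measured in cells without fluorophore).  If the
requested background exceeds the observed mean, it is clipped to the
mean with a warning — individual fluctuation bins are deliberately
*not* clipped at zero, because truncating the fluctuation distribution
would bias $G$.  Optional bleaching detrending fits a two-component
exponential $f(t)$ to the coarsely binned rate (fallback: single
exponential, then constant) and rescales fluctuations as
$I'(t) = (I(t)-f(t))/\sqrt{f(t)/f(0)} + f(0)$, restoring a stationary
mean and variance.

Repeated acquisitions at one position (e.g. four 10-s readings) are
correlated separately and averaged pointwise with pair-count weights
(`average_correlations()`), which is robust to slow drift between
readings.  Averaging curves before fitting (rather than fitting each
reading) was chosen for the same robustness reason.

### Fitting

Fits are bounded weighted nonlinear least squares
(Levenberg–Marquardt via `minpack.lm`), weighted by per-lag pair counts
unless the user supplies variances; the data do not come with known
per-lag errors, and pair counts are the natural proxy.  Three
deterministic starts (the data-driven guess, and the guess with
timescales scaled by 0.2× and 5×) guard against local minima; the
lowest residual wins.  Deterministic jitter was preferred over random
restarts so that fitting never touches the R RNG stream.
Non-convergence returns a flagged result carrying the optimizer
diagnostics — never silently defaulted parameters.

## 2. The FCS trace generator

`simulate_fcs_trace()` places a Poisson-distributed number of emitters
(mean = density × box volume) in a periodic box of side
`box_multiplier`·$w_0$ laterally and `box_multiplier`·$k w_0$ axially,
propagates Brownian steps (one substep per bin), and Poisson-samples
photon counts from the summed 3D Gaussian detection efficiencies plus
background.  Blinking is a two-state telegraph process with stationary
dark fraction $\theta_T$ and relaxation time $\tau_T$; bleaching decays
the per-particle brightness exponentially.  The long-time mean rate has
the closed form $B\,N_\mathrm{eff}\,2^{-3/2} + bg$, which the test
suite checks against a numeric-integration oracle.

Deliberate simplifications: no detector afterpulsing or dead time, no
non-Gaussian (e.g. Airyscan) optics, one Brownian substep per bin
(adequate when the bin is ≲ $\tau_D/10$, which all shipped scenarios
respect).  Passing recovery tests therefore demonstrate correctness of
the estimator chain under the model's own assumptions, not robustness
to real-detector artifacts.

Two numerical sizes matter:

- **Bin width**: scenarios choose sampling so the bin is ~1/10 of
  $\tau_D$; coarser bins average out the fastest correlations and bias
  $\tau_D$ upward.
- **Box size**: the box is a finite reservoir, so the realized emitter
  density fluctuates with $\mathrm{sd} \propto 1/\sqrt{cV_\mathrm{box}}$
  around the target.  Validation scenarios at very low concentration
  (sub-5 expected particles in the volume) enlarge `box_multiplier`
  from 5 to 9 so the box holds ≥ ~100 emitters and this reservoir
  noise stays small against the 15% recovery tolerance being tested.

Default scenario conditions mirror the calibration experiment: 225 nm
waist, $k=5$ (hence $V = 0.317$ fL), dye $D = 521.46\ \mu m^2/s$,
concentration recovery at 5–500 nM from four 10-s readings, with
molecular brightness of 30 kcounts/s per molecule and a 500 counts/s
background — ordinary confocal-FCS magnitudes.

## 3. FCS-calibrated imaging

A calibration line is built from cells measured by both FCS and
imaging: `fit_calibration_line()` regresses mean image intensity
(6×6-voxel window at the FCS position, `sample_image_at_point()`)
on FCS concentration by ordinary least squares.  Choices made where
practice varies:

- **Free intercept.**  The regression includes an intercept to absorb
  camera offset; constraining it through zero is not assumed.
- **Even-window centering.**  A 6×6 window has no central voxel; the
  window covers $[c-3, c+2]$ per axis, fixed and documented.
- **Linear-range check.**  $r^2 < 0.9$ raises a warning flag, since the
  method presumes the detector's linear range.
- **Negative concentrations.**  Voxels mapping below zero (noise below
  the fitted offset) are clipped to zero and counted in the output,
  rather than silently truncated or left negative.

Molecules per voxel follow $N = N_A\,C\,\Delta p$ with the default
voxel $0.1 \times 0.1 \times 0.4\ \mu m$ ($\Delta p = 4\times10^{-18}$
L), so 862 nM corresponds to ~2.08 molecules per voxel; copy numbers
sum molecules over a structure mask and per-cell values average the
cell's structures.  Segmentation for synthetic tests is Otsu
thresholding plus 8-connected components (`segment_structures()`) —
the interactive pixel classification used for real images is out of
scope, and externally supplied masks are accepted.  Patch shape
statistics come from the second-moment equivalent ellipse with a
1/12-per-axis pixel-variance term so single pixels behave as unit
squares.

The calibration-cell generator plants a cytosolic plateau that is
exactly linear in concentration, circular foci of known local
concentration whose integrated molecule count is recorded (so
copy-number recovery is exact by construction), and elliptical
cytoplasmic patches only in cells above the condensate concentration
threshold (default 110 nM).  Real cell images are not linear ramps
with Gaussian noise; the generator validates the calibration
arithmetic, not biological image complexity.

## 4. Microrheology

Tracks come either from tables (TrackMate-dialect CSV) or from the
built-in detector/linker: Laplacian-of-Gaussian detection with
intensity-weighted subpixel refinement, and frame-to-frame one-to-one
greedy assignment (shortest displacement first, hard `max_disp` gate,
no gap closing).  This mirrors simple nearest-neighbour LAP linking at
the level needed for sparse beads (about one per cell); dense-scene
global optimization is out of scope.

`compute_msd()` is the time-averaged MSD over all overlapping pairs;
it is tested for exact equality against a brute-force double loop.
$D$ comes from a weighted straight-line fit (weights = pair counts) of
the first 25% of delays, $D = \mathrm{slope}/4$, with a **free
intercept** so the static localization-error offset $4\sigma^2$ does
not contaminate the slope; a negative slope reports $D = 0$ with a
flag.  $\alpha$ is the log–log slope over the same range.  Tracks
shorter than 60 frames are discarded (strictly: 60 is kept), matching
standard practice for 10-s-interval bead movies.

Choices at genuinely open points:

- **Directed-motion exclusion** was a manual judgement in practice; the
  package's automated rule (straightness index > 0.6 **and** fitted
  $\alpha$ > 1.5) is explicit, logged per rejection, switchable off,
  and calibrated so that ≥ 95% of genuinely Brownian tracks survive
  (asserted in the tests).
- **Drift correction** defaults: `ensemble` (per-frame mean
  displacement) when several concurrent tracks exist, otherwise
  `per_track_velocity` (subtract each track's linear trend) with a
  warning fallback.
- **Stokes–Einstein constants**: bead radius defaults to 87.5 nm (the
  nominal 175 nm polystyrene microspheres), temperature to 310.15 K
  (imaging at 37 °C); both configurable, and the water comparison uses
  21 °C tabulated viscosity.  $D$ at or below the tracking noise floor
  (default $1.5\times10^{-6}\ \mu m^2/s$, measurable from immobilized
  beads via `noise_floor_from_immobile()`) flags the viscosity as
  uninterpretable rather than refusing to compute it.

The track generator draws per-axis increments
$\mathcal N(v\,\Delta t, \sqrt{2D\Delta t})$ plus independent Gaussian
localization noise; it does not simulate motion blur, intermittent
detection, or depth-dependent localization error.

## 5. FRAP

`normalize_frap()` background-subtracts and maps the series minimum to
0% and maximum to 100%.  Normalization is per cell, then curves are
averaged (`mean_recovery()`); the alternative order (average, then
normalize) was rejected because per-cell normalization is what makes
cells of different brightness commensurable.  An optional unbleached
control curve can divide out acquisition bleaching before scaling; it
is off by default because acquisition bleaching is typically verified
to be minimal.

`recovery_halftime()` fits $y_0 + A(1-e^{-k t})$ to post-bleach data.
The offset $y_0$ exists because min–max scaling pins the *noisiest*
point of the series to exactly zero, so the true post-bleach level sits
slightly above 0 and a through-origin fit would bias $k$ upward.  For
the same reason the mobile fraction is reported as
$A/(\bar y_\mathrm{pre} - y_0)$ — amplitude over realized bleach
depth — which cancels the range inflation noisy extrema impose.  The
recommended estimator for a condition is the fit to the mean recovery
curve of its cells; per-curve fits of few noisy points leave $A$
poorly constrained.

## 6. Cohesion scoring

A cell is *split* when two marker foci are present and their centroid
distance **strictly** exceeds the threshold (default 1.6 μm; exactly
1.6 μm is not split).  Distances are computed in whatever
dimensionality the centroids carry (2D projections or 3D), and the
dimensionality travels with the output; both conventions exist in
practice and neither is privileged.  `classify_split()` is tested for
exact agreement with an explicit counting oracle, order invariance,
rigid-motion invariance and threshold monotonicity.
`compare_replicates()` wraps the paired/unpaired two-sided t test on
replicate-level percentages; a paired design with zero-variance
differences is reported as degenerate rather than raising.

## 7. Problem sizes and determinism

Validation runs use: 0.5 s of 10⁶ Hz dye trace (~24 μs diffusion
time); four 10-s readings at 5×10³ Hz per concentration in
{5, 50, 500} nM; 200 bead tracks of 60 frames at Δt = 10 s; 30 FRAP
curves of ~35 s; 1,000-cell cohesion populations; 12 calibration
cells of 64×64 voxels.  These sizes keep every recovery estimate
comfortably inside its stated tolerance while the full suite runs in a
couple of minutes on one CPU.  All stochastic outputs are bit-identical
under a fixed seed: simulators seed R's RNG once from their `seed`
parameter, and the compiled kernels draw exclusively from R's RNG.

## 8. Known limitations

- The FCS fit assumes the 3D Gaussian volume; aberrated or saturated
  volumes bias $N$ and $\tau_D$ in ways the generator cannot reveal.
- No photon-arrival-time correlation, cross-correlation, or >1-component
  models.
- The tracker has no gap closing or split/merge handling; blinking
  beads fragment into multiple tracks (which the ≥ 60-frame filter then
  removes).
- Viscosity assumes a purely viscous medium at the probed timescales;
  viscoelastic moduli are not computed.
- Synthetic images are far simpler than real cells; passing tests
  validates the arithmetic of calibration, segmentation and scoring,
  not performance on real microscopy data.
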