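---
title: "Speckle contrast processing for cerebral blood flow and volume"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speckle contrast processing for cerebral blood flow and volume}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scosflow)
```

## The measurement

Speckle contrast optical spectroscopy (SCOS) infers blood flow from how
fast laser speckle decorrelates. Coherent near-infrared light launched
into the scalp is multiply scattered; moving red blood cells impose a
field decorrelation time $\tau_c$ that shortens as flow increases. A
camera exposed for a time $T$ blurs the speckle in proportion to
$x = T/\tau_c$, so the spatial contrast of each frame,

$$K_\mathrm{raw}^2(t) = \frac{\sigma^2(I(t))}{\mu^2(I(t))},$$

carries the flow information: the faster the flow, the lower the
contrast. `scosflow` implements the whole chain from raw frames to
multi-channel correlation analysis, together with a physics-based
simulator that makes every stage verifiable against closed-form theory.

## Noise-corrected contrast and the flow index

The measured variance contains instrumental contributions that must be
removed before inverting the contrast into a flow index:

$$K_\mathrm{adj}^2 = K_\mathrm{raw}^2 - K_\mathrm{shot}^2
  - K_\mathrm{quant}^2 - K_\mathrm{cam}^2,$$

with the standard camera-calibration forms (all intensities in digital
numbers, DN): shot noise $1/(g\,\mu)$ for conversion gain $g$ (e$^-$/DN),
quantization $(1/12)/\mu^2$, and read+dark noise $\sigma_r^2/\mu^2$. The
cerebral blood flow index is the reciprocal

$$\mathrm{CBFI}(t) = \frac{1}{K_\mathrm{adj}^2(t)},$$

reported both raw and normalized by its mean over a baseline window
(default: the first 5 s; the normalization window is configurable and the
same window feeds the volume baseline). Frames whose noise terms meet or
exceed the measured contrast would produce a non-positive
$K_\mathrm{adj}^2$; these are flagged invalid and excluded rather than
clamped, because $1/K^2$ diverges for clamped values. Saturated pixels
(DN at the top of the range) are excluded from the spatial statistics by
default and their fraction is logged — saturation truncates the upper
intensity tail and visibly biases the variance when even $\sim 10^{-4}$
of pixels clip.

The contrast is computed over the whole frame (population variance, no
spatial windowing): whole-frame statistics match the single-K-per-frame
usage of fiber-less SCOS instruments, as opposed to the 7×7-kernel maps
of speckle contrast *imaging*, which are out of scope here.

## Blood volume indices

Transmitted mean intensity tracks absorption, hence blood volume. With
$I_0$ the mean of the per-frame spatial mean intensity over the baseline
window, the package computes both the linear index
$\mathrm{CBVI}(t) = 2 - \mu(I(t))/I_0$ (equal to 1 at baseline) and the
logarithmic index
$\Delta\mathrm{CBVI}(t) = \log_{10}(I_0/\mu(I(t)))$ (0 at baseline). Both
are first-class outputs: the linear form is the default for continuity
with prior compact-SCOS analyses, while the log form is exact under
Beer–Lambert attenuation and preferable for large excursions. Near
baseline they agree to second order,
$(\mathrm{CBVI}-1) \approx \ln(10)\,\Delta\mathrm{CBVI}$, a relation the
test suite checks at the 1 % level for 1 % intensity dips.

## Multi-channel correlation

For channels $i, j$ the two-channel correlation factor is the Pearson
coefficient of their CBFI time traces,

$$\rho(i,j) = \frac{\sum_t (\mathrm{CBFI}(i,t)-\overline{\mathrm{CBFI}}(i))
  (\mathrm{CBFI}(j,t)-\overline{\mathrm{CBFI}}(j))}
  {\sqrt{\sum_t (\mathrm{CBFI}(i,t)-\overline{\mathrm{CBFI}}(i))^2
         \sum_t (\mathrm{CBFI}(j,t)-\overline{\mathrm{CBFI}}(j))^2}},$$

giving $\binom{6}{2} = 15$ pairs for a six-channel montage. Design
choices, made where the analysis was genuinely open:

* correlation is computed on **normalized CBFI over the full recording,
  with no detrending or band-pass filtering** — none is prescribed for
  the instrument's analysis, and filtering would silently change the
  correlation floor;
* samples flagged invalid in either channel are dropped pairwise
  (complete-case), and the dropped count is logged;
* "two distinct groups" of channels is operationalized as the connected
  components of the graph whose edges join pairs with
  $\rho \ge$ threshold. The default threshold 0.6 sits between the
  reported healthy-montage floor (>0.75) and typical decorrelated-pair
  values, and just below the 0.62 within-pair correlation reported for
  an injured region — so an injured pair stays grouped while cross-group
  edges are cut.

The `two_channel_summary()` view (pair correlation vs pair mean
intensity) exists to separate physiology from photometrics: a dim but
physiologically coherent pair keeps a high $\rho$, whereas if low
intensity (high noise) drove the decorrelation, $\rho$ would fall with
intensity across all pairs.

## The simulator

No public raw data exist for this class of instrument, so the package
ships a forward model faithful enough that the processing chain can be
validated end to end.

**Temporal statistics.** The speckle field is a complex Gaussian process
with autocorrelation $g_1(\Delta t) = e^{-\Delta t/\tau}$ (single-
scattering Lorentzian form; intensity statistics follow by the Siegert
relation). Exposure integration uses the analytic Karhunen–Loève
expansion of this kernel on the exposure window: the exposure-averaged
intensity at a point is $\sum_m \lambda_m |z_m|^2$ with independent unit
complex Gaussians $z_m$ and eigenvalues
$\lambda_m = b/(v_m^2 + b^2)$, $b = x/2$, where $v_m$ solves
$v\tan v = b$ (even modes) or $\tan v = -v/b$ (odd modes). Each retained
mode contributes one independent spatial speckle pattern weighted by
$\lambda_m$. Modes are kept down to $2\,\%$ of the leading eigenvalue;
the truncated tail is replaced by one variance-matched extra mode plus a
deterministic constant, so the mean and the expected $K^2$ are exact by
construction ($\sum_m \lambda_m^2$ reproduces the closed-form visibility
curve to $<10^{-9}$ relative — the unit tests assert this). Flow enters
by scaling the decorrelation rate frame by frame
($\tau = \tau_c/\mathrm{relative\_flow}(t)$, held constant within one
exposure — cardiac flow variation is slow compared with a 6 ms
exposure). Consecutive frames are independent field realizations: at the
regimes of interest $\tau_c$ (ms) is far below the 25 ms frame period,
so frame-to-frame field correlation is negligible; the static sentinel
$\tau_c = \infty$ instead freezes one pattern for the whole recording.

**Spatial statistics.** Fields are generated by low-pass pupil filtering
of white complex noise in the Fourier plane. The pupil cutoff is
calibrated so the one-dimensional speckle-to-pixel length ratio equals
`sp_ratio`; for sub-pixel speckle (the default s/p = 0.5, i.e. about
four speckles per pixel) the field is synthesized on an upsampled grid
and intensity is integrated over each pixel's area. The resulting
contrast ceiling (≈ 0.27 at s/p = 0.5 for a single polarization) is not
imposed — it emerges from the pixel averaging, and analyses estimate it
empirically from the static configuration ($\hat\beta$), exactly as one
would calibrate a real instrument whose effective $\beta$ is unknown. An
optional coherence factor `beta` adds an incoherent background for
further ceiling reduction.

**Sensor stage**, in order: scale to electrons by the conversion gain →
Poisson shot noise → additive Gaussian read/dark noise → back to DN →
quantization by rounding to integer DN → clipping at saturation. The
three stages map one-to-one onto the three correction terms, so the
correction formulas are exact for this model. Rounding (rather than
truncation) keeps the quantizer mean-unbiased.

**Cardiac waveform.** Each beat is a baseline of 1 plus two asymmetric
Gaussian bumps — a systolic peak (amplitude 0.45 of baseline at 16 % of
the beat) and a dicrotic bump (0.14 at 46 %) — normalized so the mean
over whole beats is exactly 1. The template was chosen so the spectral
fundamental dominates its harmonics (≈ 6× in power), giving the
cross-channel correlation a realistic narrowband driver; amplitudes are
in the range of pulsatile CBF excursions. Blood volume couples to the
same waveform through a configurable modulation of the mean level
(default 0.15, i.e. a ±25 % flow swing moves transmitted intensity by
∓3.75 %); no physiological absorption model is claimed.

**What the simulator does and does not emulate.** It reproduces fully
developed dynamic speckle, controllable speckle-to-pixel sampling,
exposure integration, the complete sensor noise chain, shared and
independent flow dynamics across channels, and per-channel transmission
differences. It does **not** model photon transport in layered tissue
(no scalp-vs-brain partial volumes, no source–detector depth
sensitivity), rolling-shutter readout (frames are treated as globally
shuttered, matching the uncorrected processing of the real instrument),
motion artifacts, ambient light, or beat-to-beat physiological
variability. Passing tests therefore demonstrate the *processing chain*
is correct and noise-robust — not that the instrument separates brain
from scalp.

## Numerical choices and degenerate inputs

* Visibility curve: series expansion below $x = 10^{-3}$ to avoid
  cancellation in $(e^{-2x} - 1 + 2x)/2x^2$.
* KL eigenvalue roots: bracketed `uniroot` on sign-change intervals
  (tolerance $10^{-13}$); ratios below $10^{-10}$ take the static path.
* Degenerate frames (empty, all-zero, zero-mean mask) raise errors
  rather than returning NaN; invalid contrast samples propagate as
  flags, never as numbers.
* Ties/boundaries: a baseline window is inclusive at both ends; a
  single-frame window is legal.
* Recording durations beyond the 180 s acquisition cap are truncated
  with a warning, mirroring the instrument's GUI behavior.

## Problem sizes used in validation

The validation suite balances Monte-Carlo precision against runtime:
oracle-equivalence runs use 64 frames of 256×256 pixels (the
contrast-of-variance estimator then resolves ~0.3 % effects at 3
standard errors); the mean-level invariance and flow-ratio checks use 32
frames of 128×128; multi-channel scenes use six channels of 10 s at
40 FPS with 64×64 frames, where per-frame CBFI noise (~2–3 %) is small
against the cardiac signal. The noise-invariance comparison runs at
$x = 20$ so that the 150 DN intensity distribution stays fully inside
the 8-bit range — at $x = 10$ roughly $5\times10^{-4}$ of pixels clip
and the saturation mask truncates the variance by ~1 %, a real effect
that would confound the check.

## Known limitations

* The forward model is single-scattering Lorentzian ($g_1 = e^{-\tau/\tau_c}$);
  multiple-scattering $\sqrt{\tau}$ decays would change the visibility
  curve, though not the processing chain.
* CBFI is an index, not absolute perfusion; no calibration to
  mL/100 g/min is attempted, and exposure-time sweeps (multi-exposure
  speckle imaging) are out of scope.
* The correlation analysis assesses synchrony only; it makes no
  statistical claim across subjects and no diagnostic claim.

## A complete run

```{r, eval = FALSE}
cam <- camera_model(gain_e_per_dn = 2, read_noise_dn = 1.5, bit_depth = 8)
p <- speckle_params(tau_c = 3e-3, mean_level = 100, frame_shape = c(64, 64))
wf <- cardiac_waveform(heart_rate = 60, duration = 10, frame_rate = 40)
scene <- scene_spec(n_channels = 6, waveform = wf, seed = 1)
stacks <- simulate_scene(scene, p, cam)
set <- process_scene(stacks, baseline_window = c(0, 5))
res <- correlation_matrix(set)
res$pairs
group_channels(res, threshold = 0.6)
```

The same pipeline is available from a shell via the `scos` entry point
(`inst/scripts/scos`): `simulate`, `process`, `correlate` and
`check-safety` subcommands write TIFF stacks with JSON sidecars,
per-channel trace CSVs, the correlation matrix and pair summary CSVs,
a grouping JSON, and a provenance record; identical configuration and
seed reproduce byte-identical outputs.
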