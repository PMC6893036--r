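---
title: "Methods: respiration-modulated cerebral oxygenation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: respiration-modulated cerebral oxygenation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(respox)
```

## The scientific problem

During voluntary locomotion, cortical tissue oxygenation rises even in
regions where blood vessels constrict rather than dilate. respox implements
the analysis chain needed to dissect that observation in head-fixed mouse
experiments: locomotion must be detected from a treadmill encoder; neural
drive quantified from laminar electrophysiology (gamma-band LFP power,
multiunit spike rates split into fast-spiking and regular-spiking
populations); vascular and oxygen responses measured by intrinsic optical
imaging, polarographic tissue-oxygen electrodes and phosphorescence-lifetime
arterial oximetry; the couplings among respiration, neural activity and
oxygenation quantified with correlation, coherence and partial-coherence
statistics; and finally the competing drivers (vasodilation, oxygen
consumption, arterial oxygenation) weighed against each other in a physical
transport model of a cortical arteriole.

Every stage can be exercised on synthetic sessions with known ground truth
(`generate_session()`, `generate_decays()`), which is how the package's test
suite and `scripts/acceptance.R` validate the machinery end to end.

## Behavioral state

Treadmill velocity is low-passed (10 Hz, 5th-order Butterworth, zero phase)
and differentiated by central differences; a sample is locomotion when
$|a_t| \ge a_c$ with $a_c = 3\ \mathrm{cm\,s^{-2}}$ (inclusive threshold).
Evoked events require at least 3 s of stillness before onset and at least
5 s of locomotion (10 s for oxygen analyses); rest periods start 4 s after a
bout ends and must exceed 10 s (30 s for resting cross-correlations). Two
conventions are ours because no rule is standard: runs separated by gaps
shorter than 0.5 s are merged (without a merge rule, encoder jitter
fragments single bouts), and session boundaries count as rest boundaries.

## Zero-phase filtering

All filters run forward-backward so that filtered features keep their
timing relative to event onsets — essential for triggered averages and
kernel estimation. Butterworth designs are factored into cascaded
second-order sections rather than a single transfer-function polynomial: at
the normalized cutoffs this pipeline needs (a 1 Hz low-pass on a 1 kHz
oxygen channel is $10^{-3}$ of Nyquist) a 5th-order polynomial realization
is numerically unstable, while biquads are accurate. Band-passes cascade a
high-pass and a low-pass of the stated order. A digital Bessel low-pass
(analog Bessel prototype, prewarped bilinear transform) smooths spike-rate
series. Edge transients are controlled by reflective padding plus exact DC
handling, but a 0.1 Hz high-pass still needs tens of seconds of data to
settle — analyses should use records much longer than the slowest filter
time constant.

## Response-function estimation

The neurovascular relationship is treated as linear and time-invariant.
With $\delta(t)$ the binarized locomotion regressor, the design matrix has
an intercept column plus $k$ lagged copies of $\delta$ (zero-filled at the
record start), and the response function is the least-squares solution of
$V \approx L H$. We solve by QR factorization (or an SVD pseudoinverse) —
never by forming $(L^T L)^{-1}$ explicitly, which is algebraically
identical but numerically inferior. No regularization is applied by
default; a ridge flag exists for ill-conditioned real recordings. The
kernel length defaults to 15 s at 30 Hz (450 lags), long enough for the
slow tissue-oxygen responses; summary metrics report the signed peak
amplitude, its lag, and an onset time defined (as a reporting convention,
configurable) as the first lag reaching 10% of peak amplitude in the peak's
direction.

## Spectral analysis and spike classification

LFP spectrograms use Slepian multitapers on 1 s windows. Nine tapers imply
a time-bandwidth product of 5 (a ±5 Hz concentration band on a 1 s window);
both knobs are exposed. Gamma power integrates 40–100 Hz. Spike rates count
threshold crossings (3 robust SDs, median absolute deviation estimator to
resist contamination by the spikes themselves) in 1 ms bins, smoothed with
a 5 Hz Bessel low-pass.

Waveform classification extracts spikes at 4 SD crossings, upsamples them
10× with a cubic spline, normalizes to unit peak, and measures each spike's
peak-to-trough duration. The duration histogram (0.05 ms bins) is fitted
with a two-Gaussian mixture by EM (weighted, quantile-seeded with jittered
restarts); a bin is labelled FS or RS when its posterior membership reaches
0.95, with the boundary forced to a single duration threshold so labels are
monotone in duration. Two safeguards handle degenerate data: when the
fitted components are closer than 0.2 ms or one component's weight falls
below 0.08, the data are treated as a single duration regime, labelled FS
below 0.4 ms, RS above 0.6 ms, and left unclassified in between. This
implements the sensible limiting behaviors — a pure fast-spiking recording
is labelled FS wholesale, while two templates too close to resolve yield a
large unclassified fraction rather than arbitrary splits.

## Spectroscopy

Reflectance changes at two (or three) wavelengths are converted to
oxy-/deoxyhemoglobin concentration changes through the modified
Beer-Lambert law, $\Delta A(\lambda) = -\ln(R/R_0) =
X(\lambda)\,[\varepsilon_{HbO}(\lambda)\,\Delta HbO +
\varepsilon_{HbR}(\lambda)\,\Delta HbR]$, solved per sample by least
squares (exact for two wavelengths, overdetermined for the
oxygen-challenge three-wavelength configuration). The extinction and
pathlength table is configuration, not code: `pathlength_table()` ships
literature values for 470/530/660 nm, and any preparation-specific table of
the same shape may be passed instead. Natural logarithms are used
consistently in the forward and inverse maps. Total hemoglobin is not
constrained; the solution is plain least squares. The oxygenation index is
$\Delta HbO - \Delta HbR$.

## Coupling statistics

Cross-correlations low-pass both channels at 1 Hz, remove means, and
normalize by total energy; the correlation at lag $\ell$ is
$\mathrm{corr}(x(t), y(t+\ell))$, so a delayed copy of $x$ peaks at a
positive lag equal to its delay. Significance bands come from circular
time-shift surrogates, which preserve each channel's autocorrelation while
destroying alignment; the paper-standard 1000 surrogates give per-lag
2.5/97.5 percentile bands. (Circular shifting was chosen over sample
permutation deliberately: permutation destroys autocorrelation and
anti-conservatively narrows the null for slow signals.)

Coherence and partial coherence are estimated from multitaper spectra
averaged over at least ten non-overlapping segments; a single averaged
estimate would make coherence identically 1. Partial coherence uses the
closed form
$PC^2_{xy\cdot z} = |S_{xy}S_{zz} - S_{xz}S_{zy}|^2 /
[(S_{xx}S_{zz}-|S_{xz}|^2)(S_{yy}S_{zz}-|S_{yz}|^2)]$,
with frequencies masked where a denominator falls below $10^{-12}$ of its
maximum; where the numerator vanishes at higher order (total removal, e.g.
$x = z$) the residual coherence is reported as 0 rather than undefined.

The exact Wilcoxon signed-rank test enumerates all $2^n$ sign assignments
(as a dynamic-programming convolution over the rank values, which is the
same distribution computed without materializing $2^n$ cases); ties get
average ranks, zeros are dropped, and the two-sided p doubles the smaller
tail. Six all-positive pairs give $p = 2/64 = 0.03125$; nine give
$2/512 = 0.00390625$.

## Respiration-phase-resolved arterial oximetry

Expiratory peaks are negative-going zero crossings of the thermocouple
derivative, amplitude-gated so that derivative crossings in the flat
inter-breath baseline are ignored. Phase-resolved oximetry accepts only
epochs with regular breathing (SD ≤ 0.6 Hz, mean/SD > 4, ceiling 5 Hz).
Each phosphorescence decay is assigned the time since the last expiratory
peak (an absolute offset, not a normalized phase fraction, matching the
fixed 20 ms bin width); cycles longer than mean + 3 SD are excluded. Decays
pooled per bin are averaged and fitted with a three-parameter exponential
(amplitude, lifetime, background) by Levenberg–Marquardt least squares,
seeded by a weighted log-linear fit; the first 5.6 µs of every record are
discarded. A tail-background-only log-linear fit was tried first and
rejected: its background feedback inflates variance ~2.5× and biases short
records. Oxygen tension follows the Stern–Volmer relation
$1/\tau = 1/\tau_0 + k_q\,P$; the probe constants are required
configuration (`oximetry_calibration()`, defaults representative of
two-photon phosphorescent probes).

The profile is smoothed by five passes of the circular binomial kernel
[1,2,1]/4 (circular because the respiratory cycle is periodic; a sinusoid
over $n$ bins is attenuated by exactly $\cos^{10}(\pi/n)$ with no phase
shift), and $T_{min}$/$T_{max}$ are 40 ms (two-bin) windows at the smoothed
extrema, averaging the raw bin values for paired testing across recordings.

Respiration locking is tested by permutation: per-decay oxygen estimates
(fast vectorized log-linear fits — their common-mode bias cancels in the
test statistic) are binned by phase, the profile's power spectrum computed,
and the power at the respiratory frequency compared with the 95th
percentile over random permutations of the decay-to-phase assignment.
Permutation of the measurements (rather than phase randomization of the
binned profile) was chosen because it preserves the marginal oxygen
distribution exactly and makes the statistic exchangeable under the null,
so the test is calibrated by construction — the false-positive-rate study
in the acceptance suite confirms the nominal 5% level empirically.

## The arteriole oxygen-transport model

Geometry is a blood cylinder (radius $R_1 = 9$ µm) inside a tissue annulus
(outer radius $R_2 = 50$ µm), axial length $L_a = 100$ µm. Blood carries
total oxygen $c_T = \alpha P + 4 C_{Hb} S(P)$, with Hill saturation
$S(P) = P^n/(P^n + P_{50}^n)$; tissue carries free oxygen $\alpha P$ with a
uniform zero-order sink (CMRO2). Flow is quasi-static Poiseuille under a
fixed axial pressure difference calibrated to a 2 mm/s resting centerline
velocity, so dilation raises flow as radius$^4$. The inlet oxygen tension
is fixed; the outlet is advective-only; all open tissue boundaries are
no-flux.

The solver is a structured finite-volume discretization in $(r, z)$
(default 40 × 50 cells) with z-upwinded advection and Newton iteration on
the Hb-buffered nonlinear system (sparse Jacobian, damped steps, relative
residual < $10^{-8}$). Dilation moves the wall; blood nodes follow the
wall, tissue nodes follow a volume-preserving quadratic radial remap with
the outer boundary fixed, and the CMRO2 density is rescaled so its volume
integral tracks only the metabolic scenario — this reduces the tissue's
near-incompressible elastic response to its observable consequence for
oxygen transport (interface motion plus conserved consumption). The
mesh-velocity flux is neglected (dilations are ≤ 10% and slow); time
stepping is implicit Euler with per-step Newton solves.

Verification rests on three oracles: with advection off and a fixed wall
tension the tissue solution matches the closed-form annulus profile
$P(r) = P_w + \frac{M}{D\alpha}\left[\frac{r^2 - R_1^2}{4} -
\frac{R_2^2}{2}\ln\frac{r}{R_1}\right]$ to under 1%; global oxygen balance
(inlet minus outlet flux versus integrated consumption) closes to the
solver tolerance; and zero consumption returns a uniform field at the
inlet tension.

Printed transport constants: $D_{O_2} = 2800$ µm²/s, resting CMRO2
3 µmol cm⁻³ min⁻¹, inlet 35 mmHg. Constants not printed anywhere in the
main text are configuration with flagged literature defaults: solubility
$\alpha = 1.3$ µM/mmHg, hemoglobin 2300 µM (tetramer), $P_{50} = 40$ mmHg,
$n = 2.6$, viscosity 3 mPa s. Scenarios: locomotion in forelimb/hindlimb
cortex is +15% CMRO2 with 10% dilation; frontal cortex is +4% CMRO2 with 5%
constriction; neural blockade removes 82% of the 75% activity-dependent
consumption (3 → 1.2 µmol cm⁻³ min⁻¹) with dilation clamped to zero. The
time profiles of all drivers are smoothed trapezoids, since only their
plateau magnitudes are quantitative; the systemic arterial oxygenation rise
during locomotion defaults to +3 mmHg (~9%), chosen so the dilation and
oxygenation contributions to the forelimb/hindlimb response are of
comparable size and the frontal response is positive only when the
oxygenation rise is included — the qualitative structure the model is meant
to expose. `o2_decompose()` reruns a scenario with each driver alone and
reports the additivity defect, which stays below 10% only for genuinely
small perturbations; the default scenarios are visibly nonlinear.

```{r model-example, eval = FALSE}
par <- o2_params()
fl <- o2_simulate(par, scenario_flhl(), t_end = 30)
autoplot(fl)
autoplot(o2_decompose(par, scenario_flhl(), t_end = 30))
```

## The synthetic-data generator

`generate_session()` draws locomotion bouts as a Poisson process
(exponential gaps with an 8 s refractory floor, exponential durations with
a 2 s floor, defaults ~1 bout/45 s of mean length 8 s) and builds every
channel from them at the study's acquisition rates (1 kHz analog channels,
20 kHz multiunit, 30 Hz frames; the LFP channel defaults to 1 kHz because
its content is band-limited to 300 Hz). Velocity integrates alternating
±12 cm/s² stride accelerations inside bouts and a sub-threshold 1.5 cm/s²
relaxation outside, so the binarization recovers the bouts. The LFP is
1/f-colored noise whose 40–100 Hz component is scaled by
$\sqrt{\text{gain}}$ during bouts (so band power scales by the configured
gain exactly). The MUA channel superimposes biphasic spike templates
(peak-to-trough 0.3 ms FS / 0.7 ms RS, per-spike jitter 0.05 ms; the
template's time axis is rescaled so its measured peak-to-trough distance
equals the nominal value exactly) on Gaussian noise at state-dependent
Poisson rates. Tissue oxygen is baseline + kernel-convolved locomotion + a
small respiration-coupled oscillation + white noise. The thermocouple is a
raised-cosine pulse train whose instantaneous rate follows the behavioral
state (2.5 Hz rest, 5 Hz locomotion — the regular-breathing regime the
phase analysis targets). Reflectance frames are the exact Beer-Lambert
forward map of imposed HbO/HbR transients with multiplicative pixel noise.
Phosphorescence decays are Poisson photon counts around
$A e^{-t/\tau} + b$ with $\tau$ from the Stern–Volmer map of the
instantaneous arterial oxygen (baseline plus a sinusoidal
respiration-phase modulation, peak-to-trough equal to the configured
depth, maximum a quarter cycle after the expiratory peak).

What the generator does **not** emulate: electrode drift and response-time
lag, movement and photon-scatter artifacts in imaging, heart-rate
pulsation, sighs and apneas, spike waveform diversity beyond two
templates, or any nonlinearity in neurovascular coupling. Passing tests
therefore demonstrate that the estimators recover the structure they
assume, at realistic noise levels — not that real recordings satisfy those
assumptions.

## Problem sizes used in validation

The test suite and acceptance script choose deliberate problem sizes:
30 minutes at 30 Hz (matching the 30–40 min recordings the protocols
describe) with a 5 s / 150-lag kernel for the SNR-5 kernel-recovery study;
30 s oximetry runs at 1000 decays/s for the permutation-test calibration
(50 null + 50 modulated runs at 1000 surrogates each); and the default
40 × 50 transport grid with a doubled grid for conservation and
convergence checks. The kernel-recovery study drives the estimator with a
persistently exciting random locomotion regressor: a bout-structured
regressor offers only a handful of transitions per session, which leaves a
150-lag kernel unidentifiable at any noise level — a property of that
design, not of the estimator. The (noise-free) bout-structured round trip
is validated separately through the session generator. Determinism is
guaranteed by explicit seeds everywhere randomness enters.

## Known limitations

* The kernel estimator is unregularized by design; for real data with few
  bouts the lagged design can be ill-conditioned (use the ridge flag).
* Lifetime fitting assumes a single-exponential decay; multi-exponential
  probe kinetics are out of scope.
* The transport model is a single straight arteriole: no capillary
  network, no red-blood-cell granularity, no 3D geometry; its role is the
  relative weighing of drivers, not absolute tissue maps.
* Partial coherence removes only linear, stationary contributions of the
  conditioning channel.
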