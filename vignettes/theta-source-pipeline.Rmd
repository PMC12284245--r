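---
title: "Hippocampal theta from scalp EEG: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hippocampal theta from scalp EEG: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its science: the forward and
inverse models, the burst and connectivity estimators, the crossover
statistics, what the synthetic-data generator does and does not emulate,
and the numerical decisions taken where the design was genuinely open.
Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The estimation problem

A current dipole ensemble $\mathbf{j}$ in the head produces scalp
potentials $\mathbf{y}(t) = G\,\mathbf{j}(t) + \varepsilon(t)$ through a
leadfield matrix $G$. For a dense cortical source space the column span
of $G$ practically contains the topography of any deep (hippocampal)
source, so a minimum-norm inverse explains hippocampal activity with
nearby ventral cortex and deep sources are unidentifiable. The pipeline's
premise is that *sparsity restores identifiability*: if at most a few
cortical sources are active, their joint span is a thin subspace, and a
hippocampal topography that is not inside it can claim its own share of
the signal. The hierarchy therefore (1) finds a sparse cortical support
at a coarse patch scale, (2) refines it at a finer scale, and (3) re-runs
the sparse search with explicit hippocampal candidates added.

## Forward model

Heads are concentric spherical conductors (`head_model()`): by default a
single homogeneous sphere of radius 0.09 m and conductivity 0.33 S/m; a
brain/skull/scalp three-shell variant (0.08/0.085/0.09 m at
0.33/0.0042/0.33 S/m) is available. The surface potential of an internal
current dipole is evaluated from the Legendre series of the boundary
value problem with an insulating scalp; for multi-shell models the
per-degree transfer coefficient is obtained by solving the interface
conditions degree by degree, with the linear system scaled so all entries
are O(n) (the naive formulation is numerically singular beyond degree
~45). The series is truncated at 100 terms; for the deepest sources used
(relative eccentricity ≤ 0.75) the truncation error is below $10^{-10}$.
The implementation is validated in the tests against a constant-element
boundary-integral (collocation BEM) oracle on an icosahedral mesh, which
agrees to <1% relative error for radial and tangential dipoles.

Cortical geometry mirrors how surface-based pipelines treat hemispheres:
each hemisphere is a *closed* icosahedral surface (so a level-$L$
subdivision gives exactly $10\cdot4^L+2$ vertices per hemispheric
surface), scaled to 40% of the cortex-shell radius and raised slightly so
a ventral gap remains below it. Source orientations are the outward
surface normals (orientation-fixed, one leadfield column each). The
hippocampal surrogates are mirrored $20\times10\times10$ mm volumetric
grids at 5-mm spacing — 45 candidate points per structure — centred at
60% of the cortex-shell radius in an inferior-posterior-lateral direction
(the medial-temporal position), with free orientation (three columns per
point). The placement was chosen once, when the phantom was designed, so
that the two hippocampi and the ventral cortical surface are genuinely
distinct signal-space objects; a phantom whose "hippocampus" sits a few
millimetres under the cortical sheet would make the paper-level question
(can sparse support separate deep from superficial?) unanswerable by
construction. Electrodes are a Fibonacci spiral over a spherical cap
extending well below the equator (to $z = -0.55R$): inferior
temporal/mastoid-level coverage is what gives scalp EEG its leverage on
deep and left-right source distinctions, as in full-head montages.

## Synthetic data: what is and is not emulated

`simulation_config()` defaults are the study conditions: 62 EEG + 2 EOG
channels, 1000 Hz sampling, 6-minute resting blocks, theta bursts at 6
per minute. Bursts are 6 Hz cosines under a 500 ms Hanning envelope —
the stimulation band, and an envelope that gives unambiguous ground-truth
peak times. Burst counts are Poisson with the configured rate; placements
keep 1.2 s separation by re-drawing locations (the count itself is never
thinned, so realized counts stay exactly Poisson). Default generators:
one source each in superior-frontal and temporal cortex per hemisphere
(20 nA·m) and the central grid point of each hippocampus (20 nA·m). The
default generators carry distinct inter-regional phase lags (cortical
sources alternate 0 and 90° within a hemisphere, the right hemisphere
adds 45°, hippocampi lag their hemisphere's cortex by 120°): exactly
zero or 180° lags would leave the phase-lag index downstream undefined
(no imaginary cross-spectral mass), and fully coherent generators bias
any sparse localizer toward their common centroid. Background activity is $1/f$ noise carried by
100 random cortical dipoles — so neighbouring channels are realistically
correlated — plus spatially white sensor noise (10% of noise power), all
scaled so the sensor-space SNR over burst windows matches `snr_db`.
Blinks are Gaussian pulses through a fixed anterior topography; EOG
channels carry the scalp field at their own site (from the same forward
model) plus the ocular signal, which is what makes bipolar EOG
derivations cancel cerebral activity the way they do in practice.

Not emulated: realistic cortical folding (and hence the wide orientation
spectrum of real patches), skull inhomogeneities, heartbeat and muscle
artifacts, non-stationary background, inter-individual anatomy, and
stimulation artifacts (recordings represent pre/post blocks, not
stimulation periods). Passing tests therefore demonstrate correctness of
the estimators under a spherical, stationary phantom with known truth —
not field performance on clinical recordings.

The crossover table generator produces one row per participant and
condition with counterbalanced order (participant parity under the
seed), baseline and during-stimulation memory scores around 75% (between
participants SD 8), and an outcome built from configurable effects —
default condition effect 0.3, memory slope 0.02/%, condition-by-memory
interaction 0.06/% — plus a participant random intercept (SD 0.5) and
residual noise (SD 1). The defaults put the interaction at roughly half
a residual SD across the interquartile memory range: detectable in form,
not trivially significant at n = 20, matching a pilot-scale design.

## Preprocessing

Resampling is integer decimation after a Hamming-window anti-alias
lowpass (passband edge 80%, stopband edge 95% of the new Nyquist). The
band-pass design rule: transition bandwidths
$tb_{low} = \min(\max(0.25\,f_{low}, 2), f_{low})$ and
$tb_{high} = \min(\max(0.25\,f_{high}, 2), f_s/2 - f_{high})$ Hz; each
edge gets its own Hamming-window sinc kernel of the smallest odd length
$\ge 3.3/tb\cdot f_s$, normalized to exact unity DC gain, centred in the
overall filter (whose length the narrower transition sets), and the
band-pass is their difference — hence an exactly zero DC gain and, for
0.3–30 Hz at 200 Hz, 2201 taps (11.005 s, printing as 11.01 at two
decimals). Measured on its own frequency response, the design has
≈0.02 dB passband ripple and ≈52 dB stopband attenuation; the canonical
Hamming table figures (0.0194 dB, 53 dB) are the asymptotic values of
this window family. Filtering is applied in one pass, zero-phase, by
delay compensation with reflection padding.

Bad channels: a channel is flagged when its best absolute Pearson
correlation with neighbouring channels falls below 0.7. Neighbourhoods
are the k = 6 nearest sensors by great-circle distance — deterministic
and standard; a triangulation would serve equally but adds a geometry
dependency. Flagged channels are excluded, not interpolated:
interpolation would re-introduce them as linear combinations and alter
the rank assumptions of whitening and the inverse model.

Ocular rejection: FastICA (tanh contrast, symmetric decorrelation,
seeded random orthogonal initialization, tolerance $10^{-6}$, ≤200
iterations) on the retained EEG channels; components whose absolute
correlation with either bipolar EOG derivation reaches 0.3 are zeroed.
Both derivations subtract the EEG channel nearest to the EOG electrode:
with a distant (e.g. contralateral) reference the derivation retains a
lateralized cerebral residual that correlates above threshold with brain
components even on artifact-free data, defeating the rule's purpose.
Zero rejections on clean recordings is the expected outcome.

## Burst detection and epoching

The TFR uses complex Morlet wavelets, 4–8 Hz in 0.5 Hz steps, 3 cycles,
truncated at ±3 standard deviations of the Gaussian envelope (so a 4 Hz
kernel still fits inside a ±400 ms epoch) and normalized to unit energy.
Unit energy makes white noise excite all bins equally — the right
property for a detector that averages power across bins. The flip side
is spectral resolution: a 3-cycle wavelet has ≈2 Hz spectral SD, so a
pure 6 Hz tone's maximum can land on the 5.5 Hz bin by a sub-percent
margin; no normalization gives both bin-exact tone peaks and flat noise
response simultaneously.

Recordings are cut into $\lfloor duration/10\rfloor$ 10-s segments for
the TFR; each segment's transform is computed on a window extended by
one wavelet half-length into the neighbouring data, so only samples at
the recording boundaries are invalid (otherwise ~8% of the recording
would be undetectable dead zone). Power is averaged over the nine bins,
z-scored per channel along the whole recording's time axis (population
SD; a zero-variance channel contributes zeros), and averaged over
channels. Z-scoring over the whole recording rather than per segment
keeps quiet segments from amplifying their own noise floor. Peaks are
local maxima with topographic prominence ≥ 1.5 (standard definition:
height above the higher of the two flanking minima, bases bounded by the
nearest higher sample or the edge).

Epochs are cut ±400 ms around each peak after shifting the centre by
$\Delta t = \mathrm{wrap}(\varphi_{ref} - \varphi_{peak})/(2\pi f_0)$,
where $\varphi_{peak}$ is the circular mean over channels of the 6 Hz
phase at the peak and $\varphi_{ref} = 0$ (cosine peak; only relative
alignment matters). The phase is taken at the 6 Hz bin — the carrier
frequency — rather than averaged over 4–8 Hz; both are available. The
shift is realized as a nearest-sample displacement (max error 2.5 ms at
200 Hz), bounded by half a theta cycle (±83 ms) by construction.

## Hierarchical sparse localization

From the epochs: the noise covariance is the empirical sensor covariance
of the epochs with the sample mean — the across-epoch average, i.e. the
phase-locked response — subtracted, pooled over epochs and samples, with
diagonal loading $0.01\cdot\mathrm{tr}(C)/n$. Subtracting the mean
response matters: a covariance that keeps the evoked signal puts the
signal directions at the top of the noise spectrum, and whitening then
suppresses exactly what the inverse should explain. Whitening uses the
pseudo-inverse square root (average reference leaves a null direction).

Patch decomposition assigns every dense cortical source to its nearest
level-$L$ icosahedral seed on its hemisphere (42 per surface at ico1,
162 at ico2). Per patch, the whitened leadfield block is SVD-reduced to
the smallest number of components whose cumulative squared singular
values reach 90% — typically 2–3 — retained as left singular vectors
scaled by their singular values. The same reduction applied to each
hippocampal grid (135 free-orientation columns) also yields 2–3
components per structure.

The minimum-norm estimate is
$\hat{x} = G^{\top}(GG^{\top} + \lambda^2 C)^{-1}y$, computed via the
SVD of the whitened leadfield; $\lambda^2 = 1/9$ in whitened
coordinates (the conventional SNR = 3 assumption), and $\lambda^2 = 0$
degrades gracefully to the pseudo-inverse.

Subspace pursuit operates on *groups* (a cortical patch, or one
hippocampal structure): initialization fits all candidates by minimum
norm and greedily takes the top-$s$ groups under the constraint that no
selected pair's mutual coherence (maximum absolute normalized inner
product over the two groups' component columns — the conservative
reading for multi-component patches) exceeds $\mu = 0.5$; each iteration
correlates the residual with all unit-normalized columns, takes the
top-$s$ feasible groups, unions them with the current support, refits,
prunes back to $s$ by group strength, and accepts only if the residual
norm drops by more than $10^{-6}$ relative (≤30 iterations). Group
strength is measured as the norm of the group's *fitted contribution*
to the whitened data, not its coefficient norm: coefficients scale
inversely with column sensitivity, and after whitening that ordering
inverts (weakly seen deep or ventral groups would outrank the groups
that actually explain the measurement). Ties break toward the lower
group index. If fewer than $s$ mutually feasible groups exist the
largest feasible set is returned with a warning.

The hierarchy runs pursuit with $s_1 = 4$ on the ico1 reduction, then
$s_2 = 4$ on the ico2 patches that strictly overlap (share a dense
source with) the stage-1 winners — no bordering patches — and finally
$s_3 = 6$ on the stage-2 selections combined with the hippocampal
component groups. The stage-3 candidate set is small (six groups), but
the coherence ceiling is what does the work there: a ventral cortical
patch that only mimics a hippocampal field is incoherent-infeasible with
the explicit hippocampal candidate and loses the pruning on explained
signal. Per region (superior-frontal, middle-frontal, temporal,
hippocampus × hemisphere) the reported time course is the selected
component with the largest RMS; regions without a selected source are
flagged absent. Pre- and post-stimulation recordings are localized
independently, each with its own noise covariance.

## Connectivity

Theta power is the mean squared band-limited (4–8 Hz, one-sided FFT
mask) analytic amplitude divided by two, i.e. the band-limited variance:
a unit-amplitude sinusoid has power 0.5. wPLI uses the same Morlet
family as burst detection for cross-spectra, evaluated at each epoch's
centre sample; the expectation runs across epochs and the index is
averaged over the nine bins. A vanishing denominator (no imaginary
cross-spectral mass, e.g. exactly zero lag) returns 0 with an
`undefined` flag rather than 0/0. The debiased squared estimator is
available behind a flag; the default is the original weighted index. By
default the three reported left-hemisphere pairs
(hippocampus–superior-frontal, hippocampus–middle-frontal,
hippocampus–temporal) are emitted; all pairs via `all_pairs = TRUE`.

## Crossover statistics

The mixed model is `outcome ~ condition + memory + condition:memory +
baseline + order + visit + (1 | participant)` with condition and order
effect-coded ±0.5 (the condition coefficient is then the verum–sham
difference), memory and baseline centred at their grand means, and visit
centred. Priors: Normal(0, (10·sd(y))²) on fixed effects and
half-Cauchy(sd(y)) on both SDs, the latter through the inverse-gamma
scale-mixture representation so every conditional is conjugate and the
sampler is a plain Gibbs scheme. Defaults: 4 chains × 2000 kept draws
after 1000 warm-up, chain seeds derived deterministically from the user
seed; summaries report posterior means, 80% credible intervals (the
"80% confidence intervals" of pilot-style reporting, read as credible
intervals), split-half R̂ and an autocorrelation-based effective sample
size. Conditional stimulation effects at the 25th/75th memory
percentiles are computed draw-wise as
$\beta_{cond} + \beta_{int}(q_p - \bar m)$. Semi-partial R² is the
residual-sum-of-squares reduction for dropping a term, evaluated at
posterior-mean coefficients with random intercepts profiled out
(subtracted at their posterior means; the reduced model is refit by
least squares); a variance-partition variant is available
(`method = "vp"`). Spearman's rho uses midranks; its two-sided p-value
is exact by full enumeration of rank permutations for n ≤ 9 (9! =
362,880 — the practical enumeration bound in R) and the t approximation
above.

## Numerical choices and degenerate inputs

* FIR kernels are all odd-length and palindromic; zero-phase application
  uses reflection padding.
* Morlet kernels truncate at ±3σ; TFR samples within one kernel
  half-length of a data boundary are flagged invalid and never yield
  peaks.
* The Legendre forward series is truncated at 100 terms with scaled
  interface solves; zero moments yield exactly zero columns; sources on
  or outside the innermost shell are rejected.
* SVD reductions drop all-zero patches with a warning; `var = 1` retains
  the numerical rank.
* The whitener inverts only eigenvalues above $10^{-10}$ of the maximum.
* Pursuit with data orthogonal to every column returns an empty
  effective support (threshold $10^{-8}\lVert y\rVert$).
* Gibbs variance draws use inverse-gamma updates with the half-Cauchy
  auxiliary; a zero-variance outcome falls back to unit prior scales.
* Zero-variance channels: correlation treated as 0 (flagged bad);
  z-scores defined as all zeros.

## Problem sizes used by the tests

The suite exercises the study conditions at sizes chosen to keep a full
run in a few minutes of a single CPU: geometry at dense level ico3 (642
vertices per hemisphere), 62 channels at 200 Hz (recordings are
generated at the analysis rate; the resampling path is tested
separately at 1000 Hz), 2–6 minute blocks, 20-seed Monte-Carlo for
detection (SNR 0 dB) and hierarchical recovery (SNR 10 dB), 100
noiseless trials for pursuit-versus-exhaustive equivalence, 200
replicate studies for interval coverage, and full permutation
enumeration at n = 7 for the Spearman oracle.

## Known limitations

* The spherical phantom's cortical orientations are radial from each
  hemisphere ball; real folded cortex produces more diverse patch
  subspaces, which if anything *helps* coherence-based separation.
* Hippocampal left/right separability depends on inferior sensor
  coverage; montages confined to the upper head will not reproduce it.
* The s3 = 6 stage guarantees room for both hippocampi only when the
  cortical stages have not spent selections on ventral surrogates that
  remain coherence-feasible; single runs can report fewer than six
  groups.
* wPLI at the epoch centre uses one cross-spectral sample per epoch;
  pooling time points within epochs is supported but correlated samples
  do not add independent information.
* The Gibbs sampler assumes Gaussian outcomes; heavy-tailed outcome
  noise is not modelled.
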