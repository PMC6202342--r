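---
title: "Network-mediated activation: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-mediated activation: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stimnet)
```

## The question the package answers

Direct electrical stimulation through an intracranial electrode changes
spectral power not only near the stimulated contact but at distant
recording sites. The question is whether *where* those changes land is
predicted by the brain's resting functional network: if region B is
strongly coupled to the stimulated site A at rest, does stimulating A
change band power at B more than at weakly coupled regions, once the
trivial effect of physical proximity is removed?

`stimnet` operationalizes this as a per-site statistic, the
**network-mediated activation (NMA)**, and surrounds it with everything
needed to compute it from multichannel recordings — and, crucially, with a
synthetic-data generator that plants a known connectivity-to-power effect
so that every stage can be verified against ground truth without any
clinical data.

## The model

### Resting connectivity

Functional connectivity between channels $x$ and $y$ is multitaper
spectral coherence,

$$C_{xy}(f) \;=\; \frac{\left|\langle S_{xy}(f)\rangle\right|}
{\sqrt{\langle S_{xx}(f)\rangle\,\langle S_{yy}(f)\rangle}},$$

where $S_{xy}$ is the cross-spectral density averaged over Slepian tapers
(time–bandwidth product $NW = 4$, at most 8 tapers, tapers with spectral
concentration below 0.9 dropped) and over sequential 1-s windows cut from
10-s baseline periods. The low-frequency network averages $C_{xy}(f)$ over
all frequency bins from 5 to 13 Hz; per-frequency networks (4–50 Hz, 1 Hz
spacing, 47 networks) keep the bins separate. Note the denominator: the
normalization uses the *square root* of the averaged auto-spectra, the
standard estimator bounded in $[0,1]$. Whether the band value should
average coherence across bins or average cross-spectra before normalizing
is ambiguous in common usage; bin-averaged coherence is implemented
because it keeps each per-frequency network an honest coherence and makes
the 5–13 Hz band value exactly the mean of its per-frequency members (a
property the tests assert to $10^{-12}$).

An alternative network uses high-frequency broadband (HFB, 50–200 Hz)
amplitude co-fluctuation: the notch-filtered resting signal is band-passed
in fifteen 10 Hz sub-bands, each sub-band's analytic amplitude is divided
by its own mean (making the measure gain-invariant per channel), the
sub-bands are averaged, the result is low-pass filtered below 1 Hz, and
the slow envelopes are Pearson-correlated between channels and Fisher
z-transformed.

### Evoked power

Around each stimulation trial (500 ms trains, ≥3 s apart, ≥240 trials per
site) the pipeline takes a pre window −950 to −50 ms before onset and a
post window +50 to +950 ms after offset, computes multitaper band power in
each (theta 5–8, alpha/beta 10–25, gamma 30–50, HFB 50–200 Hz), and forms
for every electrode the paired t-statistic of the log-power difference
across trials,

$$t_e = \frac{\overline{d_e}}{s_{d_e}/\sqrt{n}},\qquad
d_e = \ln P^{\text{post}}_e - \ln P^{\text{pre}}_e .$$

No per-electrode p-values are attached to these: sequential trials are not
independent, so the $t_e$ serve only as a graded response measure for the
downstream regression. The log base is immaterial (t-statistics are
scale-free); natural log is used. For whole-brain summaries, electrodes
with $t > 10$ are additionally dropped as likely artifact survivors; this
cap deliberately does *not* apply to the NMA regression (configurable).

### The NMA statistic

For a stimulated site $s$, over all included electrodes $e$:

$$t_e \;=\; \beta_0 + \beta_{\text{dist}}\, e^{-d_{se}/d_{\max}}
 + \beta_{\text{conn}}\,\mathrm{logit}\!\left(C_{se}\right) + \varepsilon_e,$$

an OLS fit with intercept. Distance enters as $e^{-d/d_{\max}}$ (zero
separation maps to exactly 1.0); coherence is logit-transformed to
unbound it from $(0,1)$. The predictor rows are then jointly permuted
against the responses 1000 times, re-recording $\beta_{\text{conn}}$ each
time; the NMA is

$$z = \frac{\beta_{\text{conn}} - \overline{\beta^{\text{null}}}}
{\mathrm{sd}\left(\beta^{\text{null}}\right)},$$

with a two-tailed empirical p-value using add-one smoothing
($p \ge 1/(n_{\text{perm}}+1)$, never exactly zero). Before the fit,
electrodes in the seizure-onset zone or with inter-ictal spiking, channels
failing the artifact screen, virtual electrodes sharing a physical contact
with the stimulated pair, and the site itself are excluded; a site
retaining fewer than 10 electrodes is discarded outright.

### Artifact screening

Stimulation leaves a brief voltage deflection on some channels. Per
channel, the trialwise mean voltage in the 350 ms before onset is compared
with the 350 ms after offset by a paired t-test (mean shift) and a Levene
test (variance change); either test at $P < 0.01$ excludes the channel.
The Levene test is Brown–Forsythe (median-centered) by default for
robustness, toggleable to mean-centering. Under the null the union rule
excludes $1-(1-0.01)^2 \approx 2\%$ of channels, which the tests verify by
simulation. The 350 ms windows are taken to abut the stimulation interval
exactly, a choice the windowing arithmetic makes explicit.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| time-bandwidth $NW$ | 4 | — | variance/bandwidth trade-off of the taper family |
| max tapers | 8 | — | $2NW$; the 8th falls below the concentration cut |
| concentration cut | 0.9 | — | drops leaky tapers (in practice 7 retained) |
| connectivity window | 1.0 | s | 1 Hz resolution; ≥100 windows recommended |
| trial power window | 0.9 | s | −950…−50 / +50…+950 ms around stimulation |
| artifact window | 0.35 | s | abutting the stimulation interval |
| artifact threshold | 0.01 | p | union of paired-t and Levene screens |
| band network | 5–13 | Hz | low-frequency coherence band |
| `n_perm` | 1000 | — | below 100 the z-score is noticeably unstable |
| electrode floor | 10 | — | site-discard rule |
| responsiveness cut | $t > 2$ | — | strict inequality, theta-responsive subsets |
| whole-brain cap | $t \le 10$ | — | residual-artifact guard, whole-brain mean only |

## What the synthetic generator emulates — and what it does not

The generator's defaults are the study conditions the rest of the package
is tested under:

* **Layouts** — electrode midpoints uniform in a 60 × 60 × 40 mm box with
  rejection sampling enforcing 3.5 mm minimum spacing (the lower bound of
  depth-electrode contact spacing); distance-to-white-matter uniform on
  0–10 mm. Absolute geometry is irrelevant downstream because distance
  enters only as a covariate, so no cortical surface is modeled.
* **Baselines** — each channel is a weighted sum of independent narrowband
  latent sources (sinusoids with phase re-randomized per 10-s period) plus
  white noise, sampled at 1000 Hz by default (500 and 1600 Hz are equally
  supported). Channels sharing a source show elevated coherence at its
  frequency; with unit source weight and noise SD $\sigma$, the amplitude
  SNR is $1/\sigma$. Sources are placed in 5–13 Hz where the band network
  looks. This is the simplest model with analytically controllable
  coherence; it deliberately has no 1/f spectrum, no AR dynamics, no
  volume conduction.
* **Stimulation sessions** — the planted effect is defined *directly on
  mean log theta power*: per electrode, pre-trial log power is
  $N(\mu, \sigma_{\text{noise}}^2)$ and post-trial log power is shifted by
  $\delta_e = \beta_0 + \beta_{\text{conn}}\,\mathrm{logit}(C_{se}) +
  \beta_{\text{dist}}\,e^{-d}$ — exactly the regression the NMA assumes.
  When waveforms are requested, a fixed theta-band carrier is scaled so
  that the multitaper theta power of each 900 ms segment reproduces the
  drawn value to machine precision (band power is quadratically
  homogeneous, so the scaling is exact). Large Monte-Carlo runs use the
  power-level representation directly; a test verifies the two paths give
  identical powers through the multitaper measurement.
* **Artifacts** — a DC offset and/or variance scaling added to the
  post-stimulation 350 ms windows of chosen channels.

Passing tests on these data show the *inference machinery* is correct and
calibrated; they cannot show that real iEEG satisfies the model (linear
effect on log power, Gaussian trial noise, stationary baseline
coherence). Trial-to-trial dependence, 1/f background, line-noise
harmonics beyond the fundamental, and non-stationarity are all absent by
design.

The per-trial log-power noise SD defaults to 0.2: trial-level power
variance is rarely reported for this paradigm, so the value was chosen
once to give the test suite useful power, not for physiological realism,
and is documented as such.

## Numerical choices

* **Slepian tapers** are computed in-package from the symmetric
  tridiagonal eigenproblem, with concentrations evaluated as the quadratic
  form of the Dirichlet-kernel Toeplitz matrix; taper sets are cached per
  window length. The cross-spectral engine is verified against a literal
  taper-multiply-DFT-average oracle to $10^{-10}$ relative error.
* **Window arithmetic** uses 0-based, half-open sample intervals with
  `start = round(t * fs)` and fixed lengths `round(0.9 * fs)` /
  `round(0.35 * fs)`, making windows sample-exact at 500, 1000, and
  1600 Hz.
* **Zero-phase filtering** (notch, HFB sub-bands, envelope low-pass) uses
  forward–backward Butterworth filters. FIR designs were considered; a
  < 1 Hz FIR low-pass at 1 kHz needs thousands of taps, and
  forward–backward IIR achieves the required zero-phase property and
  stop-band attenuation at a small fraction of the cost. The notch's
  measured behavior (≥20 dB at the line frequency, <1% passband change at
  0.8× line) is asserted in tests.
* **Logit clipping** — estimated coherence can touch 0 or 1 on degenerate
  inputs; values are clipped to $[10^{-6}, 1-10^{-6}]$ with a warning
  before the logit.
* **Permutations** — independent uniform permutations, seeded; the
  identity permutation is not excluded; collisions are allowed. Jointly
  permuting both predictor rows leaves $X^\top X$ unchanged, so the null
  coefficients are computed as one projection matrix applied to permuted
  responses; a test asserts equality with the literal re-fit. Electrodes
  are processed in label order inside `compute_nma()`, so results are
  exactly invariant to storage order.
* **Degenerate inputs** — all-zero trial segments return power 0 with a
  flag (log undefined downstream); zero-variance trial differences flag
  the electrode rather than emit $\pm\infty$; identical values in every
  white-matter category give a trend-test statistic of 0 and $p \approx 1$;
  coincident distinct electrodes get linearized distance 1.0 with a
  warning.
* **Ties** — sites tied at the median white-matter distance go to "near";
  tercile remainders go to the middle bin (40 sites split 13/14/13).

## Open design points, and how they were resolved

* **"Permute the order of the predictors"** can mean shuffling both
  predictor columns jointly as rows or shuffling connectivity alone. Joint
  shuffling is the default (it matches the sentence read literally and
  preserves the conn–distance pairing, so the null also preserves their
  collinearity); connectivity-only shuffling is available via
  `perm_mode = "connectivity"`.
* **Distance normalization** — "normalized Euclidean distance" is divided
  by the layout's maximum pairwise distance before exponentiation, giving
  a dimensionless value in $(0,1]$ with $e^{-1}$ at the layout's diameter.
  Any strictly monotone normalization changes NMA only marginally since
  distance is a covariate; the choice is isolated in `distance_network()`.
* **White-matter split direction** — the category description admits two
  readings of which side of the median split is "near" white matter. The
  semantic reading (smaller distance-to-white-matter → "near") is the
  default; `direction = "near_is_far"` flips it. Expert in-white-matter
  labels always take precedence.
* **Pooling across stimulation parameters** — trials at different
  amplitudes/pulse frequencies are pooled unweighted into one session
  contrast.
* **Hub terciles** are computed within the in/near-white-matter site
  subset, matching the group sizes that subset implies.

## Problem sizes used by the test suite

The packaged tests run the study conditions at full per-site scale — 60
electrodes, 240 trials, 1000 permutations — and choose Monte-Carlo
replicate counts per question: 200 replicates for null calibration of the
NMA (rejection rate at $\alpha = 0.05$, mean and SD of z), 100 for power
and effect recovery, 1000 simulated channels for the artifact screen's
false-positive rate, and 100/200 runs for the white-matter trend test's
power and type-I error. The planted gradient for the trend-power check
uses 2 SD gaps at 12 sites split 5/4/3: a prospective power calculation
showed 1 SD gaps yield only ~65% power at that site count, so the planted
effect was fixed at 2 SD — comfortably inside the "at least 1 SD"
condition — before the test was written. Monte-Carlo loops use the
power-level session representation; waveform synthesis is exercised by
exactness tests at small size.

## Known limitations

* The generator's exactness trick ties ground truth to the theta band;
  planted effects in other bands would need their own carriers.
* Coherence targets are planted qualitatively (shared source ⇒ elevated
  coherence), not as exact numeric coherence values.
* The EDF reader is minimal: single sampling rate across signals, no
  EDF+ annotations, 16-bit quantization inherent to the format. The native
  container (float64 + JSON sidecar) is the bit-exact interchange format.
* No directed or phase-lag connectivity measures, no biophysical
  simulation, no anatomical mapping: white-matter distances and labels are
  inputs.
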