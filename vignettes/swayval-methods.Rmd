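---
title: "Validating head-mounted sway tracking against force-plate posturography: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating head-mounted sway tracking against force-plate posturography: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swayval)
```

## The problem

Static balance is routinely quantified by recording the center of pressure
(COP) under a standing subject with a laboratory force plate and summarizing
its excursion in the medial-lateral (ML) and anterior-posterior (AP)
directions. Force plates are accurate but expensive and immobile, which has
motivated validating consumer virtual-reality headsets — whose inertial
tracking reports head position at a modest rate — as a low-cost surrogate.
The validation questions are the classic instrument-validation pair:

1. **Reliability** — are the sway summaries computed from each device
   repeatable across trials (test-retest intraclass correlation)?
2. **Agreement** — does the headset-derived summary predict the
   plate-derived summary across subjects (regression R²)?

`swayval` implements this pipeline end to end for the standard design: 20
subjects, three 20-second quiet-standing trials per visual condition (eyes
open, EO; eyes closed, EC), COP sampled at 200 Hz, head position at 10 Hz,
and three summary measures per trace — normalized path length (NPL, cm/s),
root mean square (RMS, cm) and peak-to-peak (P2P, cm). Because raw
recordings from such studies are typically not released, the package ships
a synthetic cohort generator with the statistical structure the analysis
assumes; every stage is exercised and validated against that generator.

## The latent sway model

Each (subject, condition, trial, direction) channel is a stationary
Ornstein–Uhlenbeck (OU) process
$$\mathrm{d}x = -\theta x\,\mathrm{d}t + \sigma_{OU}\,\mathrm{d}W,$$
simulated by its exact discretization
$x_{t+\Delta} = x_t e^{-\theta\Delta} + s\,\varepsilon$ with
$s^2 = A^2(1 - e^{-2\theta\Delta})$ and a stationary start, so the
marginal SD equals the trial amplitude $A$ at every sample with no
integration error. The OU process is the simplest stationary surrogate
with COP-like autocorrelation; it does not claim biomechanical realism
(no inverted-pendulum dynamics, no intermittent control), only the
second-order structure the downstream estimators care about.

Per-trial amplitudes follow a log-normal random-effects model,
$$A_{ict} = \sigma_{\text{base}} \cdot m_c \cdot a_d \cdot
\exp(u_i + w_{ict}), \qquad u_i \sim N(0, \tau^2),\;
w_{ict} \sim N(0, \omega^2),$$
with $m_c$ the eyes-closed multiplier ($m_{EO} = 1$), $a_d$ the AP
anisotropy factor. The between/within decomposition makes
$\tau^2/(\tau^2+\omega^2)$ the target intraclass correlation of log sway
amplitude — the dial against which the reliability stage is validated.

### Default process parameters

| parameter | default | units | why |
|---|---|---|---|
| `theta` | 8 | 1/s | correlation time 0.125 s, short against a 20 s trial, so per-trial amplitude estimates are stable and reliability estimates are dominated by $\tau^2,\omega^2$ rather than path noise |
| `sigma_base` | 0.3 | cm | typical quiet-standing ML COP RMS |
| `ec_multiplier` | 1.4 | — | typical EO→EC amplitude inflation in healthy adults |
| `tau2`, `omega2` | 0.06, 0.04 | — | target amplitude ICC 0.6, the middle of the moderate band where published plate amplitude ICCs sit |
| `ap_anisotropy` | 1.2 | — | AP sway exceeds ML sway in quiet standing |
| `duration`, `fp_rate`, `vr_rate` | 20 s, 200 Hz, 10 Hz | | the study design |

Time grids include the $t = 0$ sample ($N = \text{duration}\cdot\text{rate} + 1$),
which makes 200 Hz → 10 Hz decimation an exact 20:1 subsample on aligned
grids.

## The headset observation model

The head rides above the center of gravity, so its excursion tracks the COP
path but is not the COP path. The generator composes four interpretable
channels:

$$\text{VR}(t) = g \cdot \mathcal{L}_{f_c}[\text{COP}](t_{10\,\mathrm{Hz}})
 + \text{drift}(t) + \text{tremor}(t),$$

* **gain** $g \ge 1$ (default 1.5): sway displaces the head more than the
  COP;
* **low-pass** $\mathcal{L}_{f_c}$: zero-phase order-2 Butterworth at
  `smooth_cutoff` (default 1 Hz) — the trunk and neck act as a mechanical
  low-pass filter — followed by decimation to 10 Hz;
* **drift**: a slow random walk scaled so its SD at trial end is
  `drift_sd` (default 0.1 cm) — headset slippage and inertial drift;
* **tremor jitter**: additive white noise at the headset rate with
  per-trial SD `jitter_sd` · $\exp(b_i + v_{it})$,
  $b_i \sim N(0, \texttt{jitter\_subj\_sd}^2)$,
  $v_{it} \sim N(0, \texttt{jitter\_trial\_sd}^2)$ (defaults 0.25 cm,
  0.25, 0.34).

The subject- and trial-varying tremor amplitude is the load-bearing design
choice. A *constant* jitter level would add a near-constant offset to the
headset's path length, which shifts NPL without decorrelating it from the
plate's NPL — amplitude-driven correlation would survive and headset NPL
agreement would look as strong as RMS agreement, contrary to what
head-mounted tracking shows in practice. Giving the head's own
micro-motion an amplitude that varies *independently* of sway across
wearers and trials reproduces the observed phenomenology with one
mechanism: NPL, which weights high-frequency content, is dominated by the
independent tremor channel (weak cross-device NPL agreement, and headset
NPL reliability governed by the tremor's own subject-to-trial variance
ratio, kept below the sway amplitude's), while RMS and P2P, which weight
low-frequency amplitude, remain coupled to the latent sway (strong
agreement, EC and AP cells strongest because larger sway raises the
signal-to-tremor ratio). The defaults were fixed by forward design to sit
in this regime and are not tuned per analysis.

Because the tremor channel enters the headset RMS in closed form given the
smoothed sway, drift and tremor realizations,
`calibrate_headset_jitter()` can solve for the nominal `jitter_sd` that
yields any requested population correlation between the two devices'
subject-level RMS values — used to validate that the agreement stage
recovers a known linkage strength.

## Sway metrics

For a trace $p_1,\dots,p_N$ over duration $t$:

* $\text{NPL} = \frac{1}{t}\sum_{j=1}^{N-1} |p_{j+1} - p_j|$;
* $\text{RMS} = \sqrt{\frac{1}{N}\sum_j (p_j - \bar p)^2}$ (divisor $N$;
  at $N = 201$ the $N$ vs $N-1$ choice moves RMS by under 0.3%, and at
  $N = 4001$ by under 0.02%);
* $\text{P2P} = \max_j p_j - \min_j p_j$.

Each trace is analyzed at its native rate — COP at 200 Hz, headset at
10 Hz — with no resampling, filtering or detrending beyond the mean
removal inside RMS. NPL is therefore *systematically* rate-dependent: the
same process observed at 200 Hz accumulates several times the path of its
10 Hz decimation, while RMS is rate-stable and P2P only mildly widened by
the extra extremes. This asymmetry is a property of the measures, is
demonstrated by a dedicated test, and is the mechanistic reason
path-length measures travel poorly across devices with different rates
and noise floors.

## Reliability: two-way mixed-effects ICC

Each (device, metric, condition, direction) cell yields an
$n \times k$ subjects-by-trials matrix. A two-way ANOVA (subjects random,
trials fixed) gives mean squares $MS_R$ (rows), $MS_C$ (columns, i.e.
trial main effects) and $MS_E$; the **single-measure consistency ICC**
(ICC(3,1) in the Shrout–Fleiss taxonomy) is
$$\hat\rho = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E},$$
with the 95% CI from the F pivot: $F = MS_R/MS_E$ on
$(n-1, (n-1)(k-1))$ df, $F_L = F / F_{0.975}$,
$F_U = F \cdot F'_{0.975}$ (df reversed), bounds
$(F_\cdot - 1)/(F_\cdot + k - 1)$.

Design choices, each of which was genuinely open:

* **Form.** "Two-way mixed-effects" does not pin down single vs average
  measures or consistency vs absolute agreement. Single-measure
  consistency is chosen because per-trial reliability of a single
  measurement is what a clinician reusing one trial needs, and because
  the conventional classification bands were developed for that family.
  Average-measure ICC(3,k) is available via `type = "average"` to
  bracket the assumption. Absolute-agreement and one-way forms are out
  of scope.
* **Truncation.** Reported lower bounds are floored at 0 (published
  reliability tables print intervals like "(0–0.771)"); the untruncated
  bound is kept in `ci_low_raw`, and coverage checks use it. Point
  estimates are *not* floored — negative ICCs print as computed and
  classify as poor.
* **Bands.** poor < 0.5, moderate [0.5, 0.75), good [0.75, 0.90],
  excellent > 0.90. The interior edges are read lower-inclusive; 0.90
  exactly is "good" because "excellent" is stated strictly as > 0.90.
* **Degeneracies.** $MS_E = 0$ with subject variance → ICC 1 with CI
  [1, 1]; an all-constant matrix → flagged not estimable. Subjects with
  incomplete trials are dropped listwise per cell, with a message.

The estimator and its CI are verified against an explicit sums-of-squares
oracle (10⁻¹⁰), against `aov()`'s decomposition, and against the
`pingouin` reference implementation (ICC(C,1), 10⁻⁸); CI coverage at true
ICC 0.6 is checked to be 93–97% over 1000 simulated 20 × 3 matrices.

## Agreement: COP regressed on headset output

Per (metric, condition, direction) cell and per aggregation (trial 1
only, or the mean of the three trials), ordinary least squares with the
plate value as response and the headset value as predictor:
$R^2 = 1 - SS_{res}/SS_{tot}$, equal to the squared Pearson correlation;
the p-value is the regression F test, $F = (n-2)R^2/(1-R^2)$ on
$(1, n-2)$ df, with printed tiers p < .001, p < .05, ns and no
multiple-testing correction (per-cell reporting is the field's
convention for these tables). The regression direction matters only for
slope and intercept — $R^2$ is symmetric — and is fixed as COP ~ VR so
the slope reads as "cm of COP per cm of headset excursion". Subjects are
the unit of analysis; trials are never pooled into one regression.
Degenerate cells (zero predictor variance) are flagged, not fit.

## What the generator does and does not emulate

Emulated: the paired dual-rate observation of a common latent sway path;
between- and within-subject amplitude variance with a controllable ICC;
condition and direction amplitude effects; amplitude-coupled but
path-length-decoupled headset observation; exact reproducibility (every
random stream is derived from the root seed per record, so adding
subjects never perturbs existing ones).

Not emulated: inverted-pendulum dynamics and intermittent postural
control, non-Gaussian sway, VR latency and dropped frames, device
synchronization error, ML/AP cross-correlation, learning or fatigue
across trials. Consequently, passing tests validate the *estimators and
pipeline* under the assumed structure; they do not certify any physical
headset, and real-data effect sizes (e.g. plate NPL reliability near
0.99, driven by stable individual sway-velocity signatures that an OU
amplitude model compresses) need not match the synthetic ones.

## Validation problem sizes

The shipped checks use: identity and oracle tests at trivial sizes; 50
random matrices for the ICC oracle; 1000 20 × 3 matrices for coverage;
50 replicate 200-subject single-condition cohorts per reliability dial
setting {0.3, 0.6, 0.9} (tolerance ±0.05 on the mean); one 500-subject
cohort per calibrated correlation {0.5, 0.8, 0.95} (tolerance ±0.05 on
R² — at n = 500 the sampling SD of R² near ρ = 0.5 is ≈ 0.03, so this
check deliberately runs close to its noise floor); and 50 regenerated
default 20-subject cohorts for the qualitative contrasts. These sizes
were chosen so each study estimates its quantity well inside the stated
tolerance while remaining a desk-scale computation.

## Known limitations

* The OU surrogate understates the between-subject spread of sway
  *velocity*; plate NPL reliability in synthetic cohorts sits near the
  amplitude ICC rather than near 1.
* With every headset noise channel off, first-trial amplitude agreement
  still tops out slightly below 1 because a 201-sample trace estimates
  its own amplitude with ~5% error — an irreducible consequence of the
  10 Hz rate, visible in the noise-free linkage tests.
* `read_trace()` tolerates ≤ 0.5% timing jitter and otherwise rejects;
  there is no gap-filling for dropped samples.
* Headset rates that do not divide the plate rate are handled by linear
  interpolation (with a message), which slightly attenuates
  high-frequency content relative to exact decimation.
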