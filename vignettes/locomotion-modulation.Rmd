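---
title: "Quantifying context-dependent locomotion modulation of cortical activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying context-dependent locomotion modulation of cortical activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locomod)
```

## The problem

Neurons in mouse primary visual cortex change their firing when the animal
runs, and the size — even the sign — of that change depends on the sensory
context: the same neuron can be strongly locomotion-driven during grating
stimulation and unmodulated in darkness. Quantifying this from two-photon
calcium imaging requires a chain of decisions: how to convert raw ROI
fluorescence into a relative change measure, how to decide which imaging
frames count as locomotion, how to summarize modulation per neuron, how to
attach uncertainty to that summary given strongly autocorrelated calcium
signals, and how to decide that a neuron's modulation genuinely differs
between contexts rather than fluctuating across bouts. `locomod` implements
that chain as a reusable, seeded pipeline, together with a synthetic-data
generator whose ground truth makes every stage testable.

## The measurement model

### From fluorescence to $\Delta F/F_0$

The raw ROI trace $F(t)$ (40 Hz, 60 s trials) is smoothed with a zero-phase
60th-order FIR low-pass at 1 Hz (windowed-sinc, Hamming window; the kernel is
symmetric, so a single centered pass with reflection padding is zero-phase
and has unit DC gain). The baseline $F_0$ is the 5th percentile of the
smoothed trace within each trial, averaged across *all* trials of a neuron —
dark and stimulation pooled — so a single baseline serves every context.
Then $\Delta F/F_0(t) = (F(t) - F_0)/F_0$.

Two conventions had to be fixed:

* **Scalar versus time-varying baseline.** A per-trial baseline would make
  $\Delta F/F_0$ incomparable across contexts whenever slow drift differs
  between trial types; the across-trial scalar average is the only choice
  that guarantees the shared-baseline property, so `compute_f0()` returns a
  scalar.
* **Percentile convention.** Linear interpolation between order statistics
  (R's type 7). Any fixed convention works; one must be named for the order
  statistic tests to be meaningful.

Neuropil contamination can be removed before baselining with
`nmf_demix()`: the ROI trace and the surrounding-neuropil trace form a
nonnegative matrix that is factorized (rank 2 by default: soma + neuropil)
by Lee–Seung multiplicative updates minimizing squared error, whose
objective is provably non-increasing — asserted per iteration in the tests.
The component most correlated with the ROI trace is taken as the somatic
signal; that mapping rule is this package's choice, since no standard exists
for picking "the" demixed component. Demixing is off by default: the
simulator emits contamination-free traces unless asked, which isolates
downstream statistics from the demixing step in tests.

### Behavioral segmentation

Treadmill speed (raw encoder samples, nominally 12 kHz) is linearly
interpolated onto the 40 Hz frame grid. A frame is **locomotion** when all
three criteria hold: instantaneous speed $\ge$ 0.1 cm/s, 0.25 Hz low-passed
speed $\ge$ 0.1 cm/s, and mean speed $\ge$ 0.1 cm/s over a 2 s window
centered on the frame (truncated at trace edges rather than discarding
them). Inter-locomotion gaps strictly shorter than 500 ms become locomotion.
Frames below threshold are **stationary** unless they lie within 3 s after
or 0.2 s before a locomotion period — those are **excluded**, as are frames
that pass the instantaneous criterion but fail a smoothed one (they fit
neither printed definition; discarding them is the conservative reading).
The order of operations matters and is fixed: criteria, then gap merging,
then exclusion windows — exclusion is defined relative to *final* locomotion
periods, so merging must come first. A frame-by-frame brute-force
implementation of the same rules lives in the test suite and must agree
exactly on random traces.

### The locomotion modulation index and its uncertainty

Per neuron and context (darkness; grey screen; gratings),

$$\mathrm{LMI} = \frac{R_L - R_S}{R_L + R_S}$$

with $R_L$, $R_S$ the mean $\Delta F/F_0$ over locomotion and stationary
frames. LMI 0 means no modulation; 0.5 means a three-fold increase; 0.2 —
the responsiveness threshold — corresponds to a 50% change. Because
$\Delta F/F_0$ can be negative, $R_L + R_S \le 0$ is possible; such indices
are unbounded and are flagged invalid rather than clipped, which would bias
population summaries. Neurons need at least 5 s of each state per context
(configurable; the source analysis prints no floor).

Uncertainty comes from a bootstrap over 1 s bins: every maximal period
homogeneous in state and stimulus contributes bins starting at its onset,
successive starts 2 s apart (the calcium autocorrelation takes ~2 s to halve,
so closer samples are redundant). Consecutive bins still correlate at
$R = 0.35$, so each of the 10000 bootstrap iterations draws only
$1 - R = 65\%$ of the bins per state, with replacement, and recomputes the
LMI from the resampled state means; the CI is the equal-tailed 95%
percentile interval. Two choices were open:

* **Stratification.** Resampling locomotion and stationary pools separately
  guarantees every iteration defines an LMI and preserves the state ratio;
  unstratified resampling can produce undefined iterations. The source
  analysis does not say which was used; stratified is the only one with a
  defined estimand every draw.
* **Conservatism.** Drawing 65% of genuinely independent samples widens the
  CI; measured null coverage is ~97% at a nominal 95%. That is the intended
  direction of the correction — it trades power for validity under
  autocorrelation.

A neuron is *locomotion responsive* when its CI excludes 0 **and**
$|\mathrm{LMI}| > 0.2$; the negative rule mirrors the printed positive one.

### Context dependence

For each neuron the bootstrap replicate distributions of the two contexts
are differenced per iteration; a 95% CI of
$\mathrm{LMI}_{stim} - \mathrm{LMI}_{dark}$ excluding 0 marks the neuron as
significantly context-modulated. Reliability is assessed by splitting each
context's locomotion and stationary epochs (maximal runs, numbered
independently in time order) into odd and even halves and recomputing the
LMI in each; the 5% most variable neurons per cell type and context — those
whose $|\mathrm{LMI}_{odd} - \mathrm{LMI}_{even}|$ strictly exceeds the 95th
percentile of their population — cannot be labelled context-dependent.
Labels:

* **CD** — significant difference and not high-variability in either
  context;
* **CI** — not CD, $|\Delta \mathrm{LMI}| < 0.2$, and responsive in at least
  one context (a config flag demands both);
* **OTHER** — everything else, including invalid indices.

The high-variability veto applies to the CD label only: an unreliable neuron
with a stable small context difference can still be CI. (An alternative
reading also bars flagged neurons from CI; with two per-context 5% tails
that would mechanically exclude ~10% of every population from both labels,
which the recovery experiments show is too aggressive.) The $\pm 0.2$ band
on the LMI difference is promoted from a descriptive figure convention to a
necessary CI condition — one of the genuinely open design points.

### Population statistics

All hypothesis tests consume **per-animal** summaries (median LMI, mean
$\Delta F/F_0$ per state), never per-neuron values — neurons within an
animal are not independent and using them as the sample would
pseudo-replicate. Paired per-animal comparisons (locomotion vs stationary;
dark vs stimulation) use two-tailed Wilcoxon signed-rank tests, LMI
distribution comparisons across contexts use Kruskal–Wallis, and layer
comparisons use Mann–Whitney U. No multiple-testing correction is applied
(none is applied in the source analysis); p-values are reported to 3
significant figures.

## The synthetic world

The generator states one fixed world rather than exposing dials to tune
tests against:

* **Sessions.** 60 s trials at 40 Hz, dark and stimulation trials randomly
  interleaved: 10 dark + 16 stimulation by default (midpoints of the 8–12
  and 12–20 ranges typical of such experiments). Stimulation trials start
  and end with grey screen and contain repeated presentations of one
  grating direction: 4–5 s static then 2 s drifting; directions are drawn
  without replacement per block of 8 stimulation trials.
* **Behavior.** An alternating bout/gap renewal process, implemented as its
  exact 40 Hz discretization (per-frame hazards $\Delta t/\bar\tau$), with
  mean bout duration 10 s and context-specific gap means derived from the
  target run fractions: 26% of time in darkness, 41% during stimulation.
  Within bouts speed is a 1 Hz-smoothed Gaussian around 5 cm/s (SD 1.5),
  floored at 0.5 cm/s so every within-bout frame clears the 0.1 cm/s
  criteria; outside bouts speed is exactly 0. No bout statistics beyond the
  run fractions are printed anywhere, so bout length and speed are free
  parameters chosen once for realism.
* **Neurons.** Inhomogeneous Poisson spiking with rate
  $\lambda(t) = r_0 \cdot \mathrm{tuning}(t) \cdot G(t)$: baseline 0.5 Hz
  for sparse excitatory-like cells (this puts stationary
  $\Delta F/F_0 \approx 0.07$, the scale such recordings report), a
  cosine-power direction-tuning bump during gratings, and a multiplicative
  locomotion gain $G$ per context — applied only when visual drive is
  present if the neuron is *gated*. The multiplicative form makes the
  ground truth analytic: a gain $g$ yields
  $\mathrm{LMI} = (g-1)/(g+1)$ under a linear readout, so parameter
  recovery is a sharp test. Spikes drive a GCaMP6f-like kernel
  (instantaneous rise, 0.7 s exponential decay, 20% $\Delta F/F_0$ per
  spike) on a positive offset, plus optional shared slow neuropil and
  Gaussian noise.

What the generator does **not** emulate: pixel-level movies, motion
artifacts, indicator nonlinearity and saturation, slow drift in $F_0$,
correlated noise across neurons, or realistic bout-speed dynamics
(acceleration, stereotyped starts). A green recovery test therefore
establishes that the analysis chain is correct *for data obeying its
assumptions* — not that those assumptions hold for any given recording.

### Numerical notes

* The 5th-percentile baseline slightly exceeds the true offset because
  baseline activity rarely reaches zero; at sparse firing rates the induced
  LMI inflation is below 0.01 and the gain-3 recovery criterion
  ($\pm 0.05$) absorbs it. At high baseline rates (several Hz) the bias
  grows — a real caveat shared with the original measure, not an artifact
  of this implementation.
* Equality comparisons in segmentation (`>=` thresholds, *strictly* shorter
  gap merging, *strictly* above percentile flags) follow the printed
  wording; ties behave identically in pipeline and oracle because both
  compare the same floating-point values.
* Every stochastic function takes an explicit seed and restores the
  caller's RNG state; stage and per-neuron seeds are derived from one root
  seed, so full pipeline runs are byte-identical.
* Recovery experiments use a common locomotion gain of 3 for gated and
  ungated populations, isolating gating as the only population difference.
  With paper-scale gated gains (stimulation LMI ≈ 0.33) the context
  difference is comparable to the bootstrap difference-CI half-width at
  session lengths this world states, and CD recovery drops to ~0.85 — a
  power limit of the design, documented rather than papered over.

## Worked example

```{r, eval = FALSE}
library(locomod)

out <- run_pipeline(default_pipeline_config(), seed = 1,
                    out_dir = "locomod_demo")
out$classes[, c("neuron_id", "lmi_dark", "lmi_stim", "label")]
out$summaries
```

See the README for the printed output of this exact call and a walk-through
of the single-neuron interface.

## Known limitations

* The orientation/direction selectivity formulas (preferred vs
  opposite/orthogonal ratio) are a stated convention; the source analysis
  names the indices without printing formulas.
* The empirical inter-sample correlation is not re-estimated from data; the
  configured $R = 0.35$ is used globally, matching the fixed-value design
  of the source analysis. A diagnostic re-estimate would be a natural
  extension.
* `flag_high_variability()` needs populations of ~20+ neurons per group for
  its percentile to mean anything; smaller groups are left unflagged with a
  warning.
* Real percentages of CD/CI neurons per cell type depend on data that was
  never deposited; the simulator can produce populations with similar
  structure for demonstration, but no claim of numerical reproduction is
  made.
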