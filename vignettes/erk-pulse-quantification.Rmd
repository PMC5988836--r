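---
title: "Quantifying single-cell ERK activity pulses: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying single-cell ERK activity pulses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erkpulse)
```

## The measurement problem

Cells expressing a FRET biosensor for ERK kinase activity (such as
EKAREV-NLS) report activity as the ratio of sensitized acceptor emission to
donor emission — the FRET/CFP ratio. In epithelial tissue this ratio is not
constant: individual cells show a sustained *basal* level punctuated by
transient, minutes-scale *pulses*, which can arise spontaneously in one cell
or propagate from a neighbour. Treatments can reshape these dynamics along
two distinct axes — suppressing the pulses (as EGFR inhibition does) or
lowering the basal component (as ErbB2 inhibition does) — so the analysis
must separate the two components cell by cell rather than average them away.

`erkpulse` implements the full quantification chain: ratio image processing,
per-cell trace extraction, trace smoothing, a parametric pulse model fitted
per cell, pulse⁺/pulse⁻ classification, pulse metrics, autocorrelation,
wave detection and the nonparametric statistics used to compare conditions.
A synthetic-data generator with complete ground truth closes the loop for
validation.

## The pulse model

A cell's smoothed ratio trace $y(t)$ is fitted to either a flat line or a
multi-peak function:

$$
y(t) \;=\;
\begin{cases}
\omega_0 & (N = 0)\\[2pt]
\max\{y_1(t), \dots, y_N(t)\} + \omega_0 & (N \ge 1)
\end{cases}
\qquad
y_i(t) = A_i\,\varphi_i(t - t_i),
$$

where $\omega_0$ is basal activity (ratio units), $A_i \ge 0$ and $t_i$ are
the amplitude and timing of the $i$-th pulse, and the basis is one period of
a raised cosine,

$$
\varphi_i(s) = \cos(\omega_i s) + 1 \quad \text{for } -\pi/\omega_i \le s \le
\pi/\omega_i, \qquad \varphi_i(s) = 0 \text{ otherwise,}
$$

so a pulse lasts $2\pi/\omega_i$ minutes and peaks $2A_i$ above basal.
Overlapping pulses combine through the pointwise **maximum**, not the sum:
two coincident unit pulses peak at $\omega_0 + 2$, never $\omega_0 + 4$.
Parameters are estimated by least squares.

```{r model}
fit <- list(basal = 1, pulses = pulse_params(amplitude = 0.2, center = 45,
                                             omega = 2 * pi / 20))
evaluate_model(fit, c(30, 45, 60))   # support edge, peak, support edge
```

Two consequences of the max-composition rule matter in practice:

* **Identifiability.** A pulse whose curve lies entirely under a larger
  pulse's envelope contributes nothing to $y(t)$; no fitting procedure can
  recover it. In pulse-dense traces the recoverable quantity is closer to
  the number of *visible excursions* than the number of generating events,
  and detected pulse counts in high-rate regimes should be read with that
  bias in mind (the suppression *ratio* between conditions tracks the
  ground-truth ratio well, as the test-suite shows end to end).
* **Piecewise smoothness.** The objective is differentiable almost
  everywhere; at each time point only the maximal pulse receives gradient.
  `fit_trace()` uses this subgradient with box-constrained `L-BFGS-B`.

## How the pulse count is chosen

The original description fixes the model but not the search over $N$, so
the procedure here is the package's own design:

1. Start from the flat fit ($\omega_0$ = trace mean).
2. Seed a new pulse at the largest positive local maxima of the residual
   (the trace ends count as one-sided maxima so edge-truncated pulses can
   be seeded; centres may lie up to half the maximum duration outside the
   recording). Each seed is multi-started over candidate durations
   (10, 20, 40 min by default) and all parameters are re-optimised jointly.
3. Repeat up to `max_pulses` (default 5), keeping the best fit for every
   $N$. A "continuity" start (previous optimum plus a vanishing pulse)
   guarantees the best $(N{+}1)$-pulse error never exceeds the best
   $N$-pulse error.
4. Report the $N$ minimising a BIC-type score
   $n_\mathrm{eff}\log(\mathrm{SSE}/n) + (1 + 3N)\log n_\mathrm{eff}$,
   with ties broken toward fewer pulses.

Growth deliberately does **not** stop at the first score worsening: when a
trace holds several pulses, the flat line sits high between them and the
first added pulse gains little — the score only collapses once most pulses
are modelled. Stopping early on the score was the single largest source of
missed pulses in development and is the reason the search is
grow-then-select.

$n_\mathrm{eff} = n/w$ is the effective sample size of a trace smoothed
with a $w$-frame moving average (floored at 8). A 6-min moving average at
1.5-min sampling ($w = 5$) leaves the noise strongly autocorrelated; an
unadjusted BIC treats the $n$ smoothed samples as independent and accepts
noise wiggles as sub-threshold pulses roughly once per trace, which
corrupts pulse-frequency comparisons even though classification (which
thresholds on amplitude) survives. Numerical guards: the SSE entering the
score is floored (`1e-16 * n`, and `1e-12` of the flat-fit SSE) so
noiseless fits do not produce $\log 0$, and growth stops when a new pulse
improves the SSE by less than `min_improvement` (default $10^{-6}$) of the
flat-fit SSE — on a noiseless trace an exact fit would otherwise keep
accepting vanishing pulses.

## Classification and the amplitude threshold

A cell is **ERK-pulse⁺** when at least one fitted amplitude exceeds a
threshold, **ERK-pulse⁻** otherwise ($N = 0$ included). No numeric
threshold value is published, so the default is a calibration choice,
flagged here explicitly: $3\hat\sigma$, where $\hat\sigma$ is a robust
estimate of the noise sd *of the trace being fitted*, from the median
absolute successive difference of the fit residual $r = y - \hat y$:

$$
\hat\sigma \;=\; \frac{\mathrm{median}\,|\Delta r|}{\Phi^{-1}(3/4)}
\sqrt{w/2}.
$$

The residual is used rather than the trace because successive differences
are only robust to pulses that occupy a minority of the recording; at the
default pulse rate and durations, pulses cover most of a control trace and
their slopes would inflate a trace-based estimate (and hence the threshold)
several-fold. The $\sqrt{w/2}$ factor matters too: for white noise of sd
$\sigma$, a $w$-frame moving average carries noise of sd $\sigma/\sqrt w$
while its successive differences have sd $\sqrt2\,\sigma/w$, so without the
correction the estimator would understate the smoothed trace's noise by
about $\sqrt{w/2}$ (2.2-fold at $w=5$) and the false-positive calibration
would not hold. With it, on simulated flat-plus-noise traces the default
threshold yields a false-positive rate well under 5%, while pulses whose
peak height reaches $6\sigma$ are detected essentially always (the
acceptance suite recomputes both rates).

Reported metrics: frequency $N/T$ in h⁻¹, per-pulse duration $2\pi/\omega_i$
in minutes, and *both* $A_i$ and the peak height $2A_i$ — published
summaries are ambiguous about which "amplitude" means, so the tables label
the two explicitly.

## Image processing

The imaging front end follows the standard ratiometric recipe:

* **Ratio stacks** — per pixel $(\mathrm{FRET}-b_F)/(\mathrm{CFP}-b_C)$,
  valid only where background-corrected CFP exceeds a floor; invalid pixels
  are `NA`-flagged, never silently zero. Backgrounds are user-supplied
  constants (the source protocol does not state its background handling).
* **Z-stacks** are reduced by maximum intensity projection *per channel
  before division*; projecting first avoids ratios of dim out-of-focus
  voxels. The projection order is unspecified in the source and is this
  package's choice.
* **5×5 median filter** on ratio frames, with the window shrinking at
  borders (no invented padding) and `NA` pixels excluded.
* **IMD rendering** — hue encodes ratio in 8 bins from HSV blue (240°) to
  red (0°), brightness encodes CFP in 32 grades. The endpoints and counts
  are fixed by convention; even hue spacing is this package's choice.
* **Traces** — mean ratio over each ROI label per frame, `NA` when a cell
  has no valid pixel in a frame.

Whether the median filter should precede or follow trace extraction is not
fixed by the source (it is described only as noise reduction for in vivo
data); both orders are possible here — `median_filter_stack()` before
`extract_cell_traces()`, or neither — and the smoothing that *is* fixed
(the 6-min moving average) is applied to traces. The default trace pipeline
is smooth-then-fit; baseline normalization (`normalize_to_baseline()`), when
used for treatment time courses, divides by the pre-treatment mean so the
baseline maps to 1. Missing frames are excluded from window means rather
than interpolated.

## Wave detection

Propagation between adjacent cells is described qualitatively in the source
(velocities "comparable" across preparations) with no stated algorithm, so
the detector here is a reconstruction validated only against synthetic
ground truth:

* A pulse's **onset** is the start of its support, $t_i - \pi/\omega_i$
  (a half-maximum-crossing definition is available as an option).
* Cells are **neighbours** within a centroid-distance threshold, default
  1.5× the median nearest-neighbour spacing.
* A **wave** is a maximal chain of neighbour cells whose onsets increase by
  $0 < \Delta \le$ `max_lag` per hop (default 3 min); chains are extracted
  longest-first from the directed onset graph, each pulse joining at most
  one wave. Velocity = total centroid path length / onset span.
* Only chains of at least `min_cells = 4` cells (three hops) are reported.
  This floor is set by the permutation null: among sporadic pulses,
  two- and three-cell coincidences with plausible hop delays occur often
  enough to swamp a shuffled-onset control, while four-cell ordered chains
  between neighbours are rare by chance. With the default, shuffling onsets
  across cells suppresses detected events more than tenfold in the
  acceptance simulations.

## The synthetic-data generator

The generator is first-class, tested code; it emulates the study's
recording conditions with full ground truth:

* **Recordings** default to 90 min at 1.5-min sampling, basal ratio 1.
* **Pulse timing** is homogeneous Poisson thinned by a hard refractory
  period (default 10 min). The observed pulses are sporadic — their
  autocorrelation shows no periodicity — which a Poisson process satisfies;
  the refractory default keeps simulated pulses mostly resolvable at the
  default rate, matching the visually distinct pulses in published traces.
* **Pulse shape** draws: rate 2 h⁻¹, amplitude $\mathcal N(0.15, 0.05^2)$
  truncated at 0 (ratio units), duration $\mathcal N(20, 5^2)$ min floored
  at a small positive value — pulse durations in the 10–40 min range at
  ratio amplitudes a few-fold above noise, the regime the published traces
  display.
* **Noise** is additive Gaussian on the ratio, default sd 0.02. No noise
  magnitude is measurable from published figures, so this is a free fixture
  parameter (chosen once; peak SNR ≈ 15 for a typical pulse), not an
  estimate of the instrument.
* **Condition effects** scale the pulse rate and/or basal level, encoding
  the two inhibition regimes (EGFR-inhibitor-like: rate ×0.2;
  ErbB2-inhibitor-like: basal ×0.8).
* **Wave scenes** place cells on a grid (default 20 µm spacing); a source
  fires and recruits 4-neighbours once each with a fixed per-hop onset lag
  (no re-triggering — single outward waves), giving ground-truth velocity
  `spacing / hop_lag`.
* **Movies** paint nuclei as disks, set FRET = CFP × ratio per pixel, add a
  uniform background and optional intensity noise; by construction, ratio
  imaging followed by extraction recovers the generating traces exactly in
  the noiseless, background-free case. Overlapping nuclei are rejected so
  ROI truth stays unambiguous.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: photon-limited (multiplicative) noise,
photobleaching and focus drift, cell movement and segmentation error,
irregular cell packing, 3-D nuclei, and any biology beyond the two-axis
condition model. Results on real recordings depend on segmentation quality
and background handling, which are the caller's responsibility here.

## Statistics

Two-group comparisons use the Mann–Whitney U test (exact for small
tie-free samples, tie-corrected normal approximation otherwise; the
degenerate all-tied case reports $p = 1$). Multi-group comparisons use the
Steel–Dwass all-pairs procedure — pairwise rank statistics referred to the
Studentized range over $k$ groups — implemented in the package because no
installed dependency provides it, with Bartlett's homoscedasticity check
reported alongside rather than enforced. Families of proportion tests use
Pearson's χ² (no continuity correction) with Benjamini–Hochberg adjustment.
Under a three-group null the Steel–Dwass family-wise error measures ≈ 4–5%
at nominal 5% in the acceptance simulations.

## Problem sizes and determinism

Every stochastic step takes a seed (or inherits the caller's RNG stream),
and the pipeline records its seed in a JSON manifest: identical config and
seed give bit-identical outputs. The validation suite uses 100 traces for
parameter recovery, 100 for count selection, 300 for classification
calibration, 50 cells per condition for the regime comparison, 50 scenes
for wave recovery and 1000 simulations for the Steel–Dwass null — sizes at
which the Monte-Carlo standard errors are comfortably inside the asserted
margins while a full run stays in the minutes range on one CPU.

## Known limitations

* Pulse counts in dense regimes are counts of visible excursions (see
  identifiability above); between-condition ratios are trustworthy,
  absolute rates in high-overlap regimes are lower bounds.
* The amplitude threshold is a calibration choice; no published value
  exists to compare against.
* The wave detector is validated against its own generative model only; on
  real tissue the neighbour radius and `max_lag` must be set from the
  observed geometry and hop lags.
* Fitting assumes a complete, uniformly sampled trace; frames lost to
  invalid pixels must be handled (dropped cells or interpolation) before
  `fit_trace()`.
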