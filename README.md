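# erkpulse

Quantification of pulsatile ERK kinase activity in single cells from
ratiometric FRET time-lapse imaging.

Epithelial cells expressing an ERK FRET biosensor (e.g. EKAREV-NLS) report
kinase activity as the FRET/CFP emission ratio. The ratio trace of each cell
decomposes into a sustained **basal** level and transient, minutes-scale
**pulses** that can fire spontaneously or propagate between neighbouring
cells — and treatments can act on the two components independently
(EGFR inhibition abolishes pulses; ErbB2 inhibition lowers basal activity).
`erkpulse` is for experimenters and image analysts who need to turn
two-channel movies or pre-extracted ratio traces into per-cell pulse
statistics and condition comparisons.

## The model

Each smoothed single-cell trace is fitted by least squares to a flat line or
a multi-peak function

```
y(t) = ω₀                                 (N = 0)
y(t) = max{y₁(t), …, y_N(t)} + ω₀         (N ≥ 1),     yᵢ(t) = Aᵢ φᵢ(t − tᵢ)
```

with a raised-cosine basis of compact support,
`φᵢ(s) = cos(ωᵢ s) + 1` for `−π/ωᵢ ≤ s ≤ π/ωᵢ` and 0 otherwise, so pulse *i*
has amplitude `Aᵢ` (peak height `2 Aᵢ` above basal), timing `tᵢ` and
duration `2π/ωᵢ`. Overlapping pulses combine through the pointwise
**maximum**, not the sum. The pulse count `N` is chosen by greedy growth
with a BIC-type criterion; a cell is **ERK-pulse⁺** if some fitted `Aᵢ`
exceeds a threshold (default: 3× a robust noise estimate from the fit
residual), **ERK-pulse⁻** otherwise. Downstream the package computes pulse
frequency/duration/amplitude summaries, temporal autocorrelation,
neighbour-to-neighbour pulse-propagation events with velocities, and the
group statistics used for condition comparisons (Mann–Whitney U,
Steel–Dwass, χ² with Benjamini–Hochberg adjustment).

The methods vignette (`vignettes/erk-pulse-quantification.Rmd`) documents
the model, every tunable parameter, the synthetic-data generator and the
design decisions in detail.

## Worked example

Simulate a control population and an EGFR-inhibitor-like condition
(pulse rate × 0.2), fit every cell and compare:

```r
library(erkpulse)

pop <- generate_population(
  20, pulse_train_spec(rate = 2), trace_spec(noise_sd = 0.02),
  effects = list(condition_effect("EGFRi", rate_multiplier = 0.2)),
  seed = 42)

fits <- fit_population(pop$traces, fit_config(), smooth_window_min = 6)
fits[["control_001"]]
#> Pulse-model fit: 3 pulse(s), pulse+
#>   basal activity: 0.9934   sse: 0.02051   threshold: 0.05757
#>  amplitude   center     omega duration
#>  0.1598020 25.81765 0.2696902 23.29779
#>  0.1550140 50.97445 0.1238061 50.75021
#>  0.2118232 74.90577 0.2131375 29.47949

print(summarize_population(fits), digits = 3)
#>   condition n_cells prop_pulse_pos mean_frequency_per_h median_frequency_per_h
#> 1   control      20           0.95                  1.5                  1.667
#> 2     EGFRi      20           0.60                  0.6                  0.667
#>   mean_basal
#> 1      0.999
#> 2      1.000

cells <- fits_to_df(fits)$cells
mann_whitney(cells$frequency_per_h[cells$condition == "EGFRi"],
             cells$frequency_per_h[cells$condition == "control"])$p
#> [1] 0.0001303643
```

Reading: `control_001` carries three supra-threshold pulses (ERK-pulse⁺)
on a basal ratio of ~0.99; across the population the inhibitor-like
condition drops the mean pulse frequency from 1.5 h⁻¹ to 0.6 h⁻¹ (the
generative suppression was 5-fold; overlapping pulses merge under the max
rule, see the vignette) while basal activity is untouched — and the
frequency difference is significant by Mann–Whitney.

Image-based workflows start from TIFF stacks instead:
`read_stack_tiff()` → `compute_ratio_stack()` (→ `median_filter_stack()`)
→ `extract_cell_traces()`, with `render_imd()` for intensity-modulated
ratio display and `detect_propagation()` for wave events.
`run_pipeline(run_config(...))` orchestrates the whole chain and writes
CSV tables plus a seed-recording manifest; `inst/scripts/erkpulse` exposes
the same steps as shell subcommands (`simulate`, `fit`, `stats`, `waves`,
`run`).

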