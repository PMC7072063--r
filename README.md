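# chromapop

Quantifying the dynamics of population heterogeneities in mammalian (CHO)
cell cultures whose sub-populations carry stably integrated
fluorescent-protein barcodes.

Even "monoclonal" production cultures drift: sub-populations with
different growth rates, lag behaviour and productivities arise and shift
over passaging. When cells are marked with lentivirally integrated
fluorescent proteins — stochastic red/green/blue combinations
(RGB-marking) or one distinct colour per seed culture — flow cytometry
measures the culture composition directly. `chromapop` provides the
analysis chain for such experiments, for bioprocess engineers and
cell-line developers:

* **Preprocessing** — debris/doublet scatter gating, sequential spillover
  compensation (e.g. Venus′ = Venus − 0.15·mCherry, Cerulean′ = Cerulean −
  0.039·Venus′), and bounded log normalization
  `I_norm = (log I − log I_lower)/(log I_upper − log I_lower)` onto the
  unit colour cube.
* **Gating** — octant classification of three-colour events into the 2³
  populations {none, R, G, B, RG, GB, BR, RGB} by strict positivity above
  per-channel thresholds; nearest-centroid classification of four singly
  marked populations in two-detector log space; population sizes (% of
  gated events) and marginal channel positives.
* **Population dynamics** — fraction/density time series; total change
  (percentage points) vs individual change (% of own baseline) between
  baseline and final windows; sum of absolute changes; broken-stick lag +
  exponential fits `log X(t) = a + μ·max(0, t − L)` with the breakpoint
  searched over sample times.
* **Kinetics** — cell-specific rates from two-point concentration
  differences normalized by the trapezoidal mean viable density,
  `q = ±Δc/Δt · 2/(X_v,i + X_v,i+1)`, with passage-spanning intervals
  excluded; delta and ratio percent-change conventions.
* **Synthetic data** — generators emulating both study designs (130-day
  repeated batch with clonal outgrowth; mixed growth-phase cultures with
  lags of 3/13/15/18 h and a common μ = 0.037 h⁻¹ sampled hourly), with
  Poisson copy-number transduction, replicator selection dynamics, and
  closed-form metabolite integration — every analysis stage is testable
  against known ground truth.

## Worked example

A synthetic hourly bioreactor run of four populations pooled from
different preculture growth phases, and its analysis:

```r
library(chromapop)
sim <- simulate_mixed_culture(afc_reference_populations(),
                              schedule_h = 0:48,
                              inoculum_density = 0.25e6,
                              noise_cv = 0.05, seed = 11)
fit_population_growth(sim$population_ts)
#>    population lag_h   mu_per_h        rss
#> 1 Cerulean-EX     3 0.03725215 0.08546936
#> 2 mOrange2-LE    14 0.03749620 0.10517784
#> 3  mTagBFP-TP    15 0.03606265 0.11888957
#> 4    Venus-SP    18 0.03769797 0.10188211
population_change(sim$population_ts, baseline_n = 3, final_n = 3)
#>    population baseline_pct final_pct total_change_pts individual_change_pct
#> 1 Cerulean-EX     24.02780  33.76125         9.733453             40.509131
#> 2 mOrange2-LE     25.19852  23.50308        -1.695437             -6.728319
#> 3  mTagBFP-TP     25.02442  22.05890        -2.965525            -11.850521
#> 4    Venus-SP     25.74926  20.67677        -5.072492            -19.699565
```

The fitted lags recover the configured preculture ages, the slopes are
equal within a few percent ("parallel lines"), and the
stationary-phase-derived population (Venus-SP) loses the most share
during the first day. The octant side works the same way:

```r
panel <- case1_panel()
s <- draw_cluster_events(case1_day0_composition(), 1e5, panel, seed = 42)
g <- gate_rgb_sample(s, panel)
g$populations          # eight octant fractions, e.g. RGB 22.86 %
g$marginals            # e.g. R (mCherry-positive) 49.4 %
```

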