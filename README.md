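# forestbats

Survey-design tools for passive acoustic bat inventories in forests.

Bats use forest space in three dimensions — open gaps, the cluttered ground
layer, the canopy — and different echolocation guilds prefer different
strata at different times of night. A detector therefore records a biased
sample of the community that depends on *where* it hangs and *when* it
listens. `forestbats` quantifies that dependence for inventory design: given
detection records (one row per identified echolocation call sequence), it
evaluates any of 21 candidate sampling schemes — the 7 nonempty subsets of
{forest ground, canopy, gap} crossed with 3 within-night recording patterns
(full 8-h night, first 4 h, or 2 h after dusk + 2 h before dawn) — and asks
how many detector-nights each scheme needs to capture a target share of the
species pool, and what that effort costs.

## The statistics at the core

**Activity index.** Nightly activity of a taxon or guild is the number of
distinct 5-minute intervals containing at least one of its sequences
(maximum 96 per 8-h night), which is robust to a single bat circling the
microphone for minutes on end.

**Accumulation and rarefaction.** For a sampling unit (a plot or cell under
a scheme), detections are reduced to a taxon × night incidence matrix;
nights are the effort unit, and a night with no detections still counts as
effort. The species accumulation curve is estimated by randomising night
order (1000 permutations by default) and averaging cumulative richness.
The package also provides the exact expectation over all orderings,

```
E[S(t)] = Σ_i [ 1 − C(T − n_i, t) / C(T, t) ]
```

(taxon *i* present on `n_i` of `T` nights; hypergeometric inclusion), used
as an independent oracle for the permutation estimator, together with the
exact ordering variance from pairwise joint-absence probabilities.

**Clench extrapolation.** Curves are extrapolated with the saturating model
`S(t) = a·t / (1 + b·t)` — initial accumulation rate `a`, shape `b`,
asymptotic richness `a/b` — fitted by nonlinear least squares. Per-scheme
summaries average the fitted parameters across units. The effort to reach a
fraction `q` of the asymptote has the closed form `t_q = q / ((1 − q)·b)`;
the conventional 90% target gives `t_0.9 = 9/b` nights.

**Cost model.** Total time is `T_t = T_f + T_a`, where field time `T_f` is
an input and analysis time `T_a = N_n · N_p · X_s · A` scales with nights,
plots, the mean sequences recorded per night and plot (`X_s`), and the
per-sequence identification time (`A`, default 20 s). Labor is costed at a
technician rate for fieldwork and an expert rate for acoustic analysis;
equipment cost is one detector per sampled microhabitat per plot.

A seeded simulator (`simulate_survey()`) generates surveys with the
structure these analyses assume — Poisson detection counts, a strongly
dominant species, guild-specific microhabitat affinities, bimodal nightly
activity — so the whole pipeline is testable without field data.

## Worked example

```r
library(forestbats)

## a survey with the default community and layout: 8 cells x 4 plots x
## 3 microhabitats, 6-12 nights per cell, ~87%-dominant species
recs <- collapse_taxa(simulate_survey(default_community(), survey_layout(), seed = 2026))
nrow(recs)                      # 146274 sequences, 16 taxa

## accumulation curve for one plot, all microhabitats, full-night recording
inc <- build_incidence(recs, sampling_scheme(c("GR", "CA", "GA"), "FULL_NIGHT"),
                       cell = "cell01", plot = "p1")
cur <- accumulation_permuted(inc, n_perm = 1000, seed = 1)
fit <- fit_clench(cur)
fit
#> Clench fit: a = 16.93, b = 1.155, asymptote a/b = 14.66 (converged)
effort_to_fraction(fit, q = 0.9)
#> $effort
#> [1] 7.794949
#> $nights
#> [1] 8
```

So at this plot, 14.0 of an estimated 14.7 taxa were seen in 10 nights, and
the fitted curve reaches 90% of its asymptote after 8 nights. The bundled
cost scenarios compare the two schemes worth implementing at the km² scale:

```r
tab <- scenario_table(cbind(scheme = rep(c("three_mh", "gap_ground"), each = 3),
                            example_cost_scenarios()))
tab$breakdown[, c("scheme", "n_plots", "analysis_hours", "labor_cost",
                  "detector_cost", "total_cost")]
#>      scheme n_plots analysis_hours labor_cost detector_cost total_cost
#>    three_mh       2          252.9      26030          9870      35900
#>    three_mh       3          206.9      21170         14805      35975
#>    three_mh       4          183.9      18735         19740      38475
#>  gap_ground       2          270.9      27850          6580      34430
#>  gap_ground       3          228.6      23295          9870      33165
#>  gap_ground       4          203.2      20680         13160      33840
tab$dispersion
#>      scheme n_scenarios mean_total_cost sd_total_cost
#>  gap_ground           3        33811.67      632.9758
#>    three_mh           3        36783.33     1465.5062
```

Reading: sampling all three microhabitats costs about 37,000 (± 1,466)
currency units regardless of plot count — more plots mean fewer nights and
less analysis, but more detectors — while the gap + ground compromise runs
about 34,000 (± 633). Analysis time, not fieldwork, dominates labor cost.

`run_pipeline()` drives the whole chain (ingest/simulate → filter →
accumulate → fit → effort → cost) and writes delimited tables plus a run
manifest; identical config and seed give identical outputs.

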