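---
title: "Evaluating acoustic sampling schemes: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating acoustic sampling schemes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestbats)
```

This vignette is the package's account of its science: what each stage
computes, which assumptions it rests on, which knobs matter, and where the
design was genuinely open and a choice had to be made.

## The problem

Passive acoustic detectors record bat echolocation sequences unattended,
but forests are three-dimensional and bat guilds partition that space:
long- and middle-range echolocators favour open gaps, gleaners hunt the
cluttered ground layer, and activity is typically bimodal within the night
(a post-dusk peak and a smaller pre-dawn peak). A sampling scheme — which
microhabitats of a plot carry detectors, and which part of the night they
record — therefore determines which community sample you get. The package
asks, for each of the 21 candidate schemes (7 nonempty microhabitat designs
× 3 temporal patterns), how many detector-nights are needed to reach a
target fraction of asymptotic species richness, and what that effort costs.

## Coordinate system and records

All timestamps are minutes from the start of the fixed 21:30–05:30
recording window, so a night is the half-open interval `[0, 480)`. A single
night-relative axis avoids date arithmetic entirely: the recording window
is fixed by protocol, not by sunset. All windows are half-open
(`[start, end)`), which assigns every instant to exactly one 5-minute bin
and one temporal window — no double counting at boundaries. The temporal
patterns are `FULL_NIGHT` `[0, 480)`, `FIRST_4H` `[0, 240)`, and
`SPLIT_2H_2H` `[0, 120) ∪ [360, 480)`.

Species whose calls cannot reliably be separated are collapsed to group
taxa (`Plecotus sp.`, `Nyctalus sp.`, `Eptesicus sp.`) before any richness
analysis; a group counts as one taxon. Sequences identifiable only to order
level cannot be assigned to an echolocation guild; they are excluded from
guild activity and from the guild-assignable denominator of identification
summaries, and flagged in output. Reported percentages round half-up — two
decimals in tables, one decimal in text-style summaries — matching the
conventions of published survey reports.

## Activity index

Nightly activity is the number of distinct occupied 5-minute bins
(`bin k = [5k, 5(k+1))`, `k = 0..95`), not the raw sequence count: one bat
foraging around a microphone for an hour should not look like sixty bats.
The index is an integer in `[0, 96]`, monotone under record union, and the
package deliberately stops at the per-night index table. Mixed-model
analysis of such indices (Poisson GLMMs with site and night random effects)
is routine with standard tools, and the package's contribution is the
statistic and the design comparison, not the model fit.

## Accumulation curves

For a sampling unit (one plot or cell under one scheme), records are
filtered by design and pattern and reduced to a binary taxon × night
incidence matrix, pooling the unit's sites. Two choices here were open:

* **Night is the resampling unit**, pooled over sites, because effort is
  counted in sampling nights; resampling site-nights instead would
  conflate spatial and temporal replication.
* **Nights with zero (or zero surviving) detections are retained** as
  all-zero columns: a deployed detector-night is effort whether or not a
  bat flew past. The night set is fixed *before* temporal filtering for
  the same reason.

The accumulation curve randomises night order (default 1000 permutations)
and averages cumulative richness; randomisation removes order-specific
bias (seasonal drift, weather runs) and smooths the curve. The exact
expectation over all orderings has the closed hypergeometric form
`E[S(t)] = Σ_i [1 − C(T − n_i, t)/C(T, t)]`, implemented alongside as an
oracle; its ordering variance follows from pairwise joint-absence
probabilities `C(T − |N_i ∪ N_j|, t)/C(T, t)`. The permutation estimator is
unbiased for the exact curve, and the suite asserts their agreement at
three Monte-Carlo standard errors under fixed seeds. (The test is seeded
deliberately: across the several hundred matrix × effort comparisons the
suite makes, unseeded 3-σ checks would fail by chance in most runs.) Note
one subtlety: adding an *empty* night to a unit legitimately lowers the
expected curve at fixed effort — extra effort, no return — so monotonicity
in nights holds only when added nights re-detect the known taxa.

## Clench extrapolation

Units differ in how many nights they were sampled, so observed richness is
not comparable across units directly. Curves are therefore extrapolated
with the Clench model `S(t) = a·t/(1 + b·t)` (initial rate `a` in taxa per
night, shape `b` per night, asymptote `a/b`), which is appropriate when the
chance of adding a new taxon falls as the inventory grows but rises with
continued effort. Numerical choices:

* **Fitting**: Levenberg–Marquardt nonlinear least squares on the
  permutation-mean curve, unweighted (weighting by inverse variance is
  available via the `weights` argument but is not the default, since the
  mean curve is already the smoothed target of inference). Start values
  `a₀ = S(1)` and `b₀ = a₀/S(T)` place the initial asymptote at the
  observed maximum. Tolerances are tight (`ftol = ptol = 1e-15`, ≤1000
  iterations) so noise-free curves are recovered to machine-level
  accuracy; parameters are bounded below at `1e-10` to keep `a, b > 0`.
* **Degenerate inputs**: an all-zero curve is an error; a constant curve
  (community exhausted on night one) has no finite-parameter optimum —
  the fitter either converges with `a/b` at the constant or flags
  non-convergence, and non-converged fits are never silently used.
* **Scheme summaries average the fitted parameters** (`mean a`, `mean b`)
  across units rather than refitting a pooled curve — the convention lets
  units with unequal night counts contribute symmetrically. Beware that
  `mean(a)/mean(b)` is not the mean of per-unit asymptotes: fits
  (a=2, b=0.2) and (a=3, b=0.6) average to asymptote 6.25, while their
  individual asymptotes average 7.5. The package follows the
  parameter-averaging convention throughout.
* **Effort targets**: `t_q = q/((1 − q)·b)` is exact, so `S(t_q) = q·a/b`
  to machine precision; the default completeness target is `q = 0.9`
  (demanding 100% in forests is quixotic — the curve's tail is dominated
  by vagrants). Effort is reported raw and rounded *up* to whole nights,
  since nights are indivisible effort units.

## The survey simulator

The generator exists so that every downstream stage has a testable ground
truth. It emulates the structure the analyses assume:

* detection counts per (site, night, species) are Poisson with mean
  `base_rate × abundance_weight × affinity(species, microhabitat)` — the
  same Poisson assumption that underlies activity modelling of such data;
* within-night timestamps follow a two-component truncated-Gaussian
  mixture per species (bimodal activity); the default profiles put the
  secondary peak after midnight, so part-night patterns demonstrably
  under-sample bimodal species;
* the default community (16 taxa, 3 guilds) copies the bundled reference
  survey's shape: abundance weights proportional to the observed sequence
  totals (the dominant species carries 87% of the weight), microhabitat
  affinities proportional to each taxon's observed distribution across
  gap/ground/canopy (zeros preserved as structural absences, rows scaled
  to mean 1), and `base_rate = 170` sequences per detector-night, the
  reference campaign's mean. Nightly rates per species are otherwise
  illustrative defaults, **not** estimates of any real system;
* the default layout is 8 cells × 4 plots × 3 microhabitats with 6–12
  nights per cell, drawn uniformly.

What the simulator does *not* model: weather (the field protocol already
excluded cold and rainy nights; a night-level rate-multiplier hook is
provided for users who want covariates), detection distance and acoustic
propagation, call structure, between-night correlation, and
season-dependent phenology. Passing tests therefore certify the
*estimators* — the accumulation, fitting and costing machinery — under the
stated stochastic model, not the field realism of that model.

## Cost model

Total time is `T_t = T_f + T_a`. Field time `T_f` (travel, deployment,
rotation, retrieval) is taken as an input — it depends on local logistics
that no package should pretend to know. Analysis time is
`T_a = N_n × N_p × X_s × A`, with `X_s` the mean sequences per night and
plot under the scheme, and `A` the per-sequence identification time. Two
conventions are load-bearing and were fixed by consistency with the
bundled reference scenarios:

* `A = 20` seconds per sequence (1/180 h). This is the unique constant
  for which `T_a = N_n·N_p·X_s·A` reproduces every analysis-hours cell of
  the bundled scenarios; it is the documented default and overridable per
  scenario.
* `T_a` is rounded half-up to 0.1 h *before* entering cost arithmetic —
  the only convention under which every labor-cost cell of the reference
  scenarios reproduces exactly (e.g. `6.9 × 50 + 183.9 × 100 = 18735`).

Labor is costed at a technician rate for fieldwork (default 50/h) and an
expert rate for analysis (default 100/h); equipment is one detector
(default 1645/unit) per sampled microhabitat per plot. Arithmetic is
currency-agnostic. Per-scheme dispersion across plot-count scenarios uses
the sample standard deviation (n − 1): the exact values for the bundled
scenarios are 1465.51 and 632.98, quoted as ±1465/±633 at integer
precision. Scenarios with a single row report dispersion as undefined
(`NA`), never as zero. Whether a scheme is *feasible* (can reach the
richness target at all with a given plot count) is decided upstream by the
Clench stage; the cost model prices schemes, it does not validate them.

## What is and is not reproducible at desk scale

The bundled reference scenarios and counts reproduce exactly (cost table
cells, dispersions, identification percentages). The reference campaign's
*fitted* effort values — e.g. 12 nights for three microhabitats, 33 for
gap + ground, 17/18/20 nights per single microhabitat — depend on the
original field detections and per-scheme fit parameters that are not
published, so they cannot be recomputed here and the package does not
assert them. The machinery that would produce them is instead validated
by self-consistency: exact-oracle agreement of the permutation curves,
machine-precision parameter recovery on noise-free curves, ~1% median
asymptote error on simulated saturating surveys, and the qualitative
ordering (full-night ≥ part-night richness; richer designs dominate their
sub-designs) that motivated the recommended schemes.

## Problem sizes

The test suite and acceptance script were sized for a desk machine: the
asymptote-recovery study uses 100 simulated 8-species surveys of one plot
× 30 nights with a moderately saturating community (rarest species at
~0.7 expected plot-sequences per night; `base_rate = 15`); the oracle
comparison uses 10-taxa × 8-night matrices at 1000 permutations; the
pipeline examples run 1–3 schemes at 50–200 permutations on 1–2 simulated
cells. The full default survey (~150,000 records) simulates in seconds;
evaluating all 21 schemes over all 32 plots at 1000 permutations is a
coffee-break job, not an overnight one.

## Known limitations

* Parameter averaging across units is a convention, not an estimator with
  known sampling properties; refit-on-pooled-curves is a reasonable
  alternative and gives different asymptotes (see above).
* The Clench asymptote is an extrapolation; with strongly unsaturated
  curves `b` is weakly identified and `a/b` unstable — the `converged`
  flag and residuals should be inspected before trusting `t_q`.
* Incidence pooling discards within-night abundance; schemes that differ
  only in how *much* activity they capture (not which taxa) look
  identical to the richness analysis by design.
* The cost model is linear and ignores equipment depreciation, travel
  economies of scale, and currency effects.
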