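---
title: "Modelling the excitability margin as a gating variable"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the excitability margin as a gating variable}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(excitmargin)
```

## The model

The excitability margin of a neuron is the distance from resting membrane
potential to spike threshold,

$$\Delta V_\mathrm{margin} = V_\mathrm{thr} - V_\mathrm{rest},$$

i.e. the minimal depolarization needed to fire. `excitmargin` treats this
single voltage as a gating variable: chronic stress, inflammatory load and
transient reactivation-related states are each translated into a
voltage-equivalent "hit" on the margin, and the residual *effective* margin
is compared against the amplitudes of ordinary subthreshold network events.
The model is phenomenological and static — it asks how far the reserve has
been compressed in the voltage domain, not how a conductance-based membrane
would behave dynamically.

Three kinds of hit (`modifier()`) are distinguished:

* **chronic shifts** (mV): sustained depolarizing shifts of the resting
  potential, subtracted from the baseline margin *before* compression. The
  reference value is a conservative stress-associated inflammatory shift of
  +2.0 mV (about one third of an acute-LPS-scale depolarization).
* **compression** (dimensionless, in (0, 1]): a phenomenological scaling of
  the remaining reserve. The reference value 0.56 is the ratio of stressed
  to control rheobase after chronic restraint stress
  (`gamma_from_rheobase()`); it is used strictly as a compression
  coefficient, never as a current-to-voltage conversion.
* **acute shifts** (mV): transient threshold-lowering effects, subtracted
  *after* compression. The reference value is a +3.2 mV CREB-dependent
  engram-reactivation "hot-spot" term.

`apply_scenario()` composes the hits in this fixed phase order regardless of
input order, so with one of each the result is the cumulative equation

$$\Delta V_\mathrm{eff} \;=\; \gamma_\mathrm{rh}\,
  (\Delta V_\mathrm{margin,0} - \Delta V_\mathrm{rest,infl}) -
  \Delta V_\mathrm{hot}.$$

```{r main}
res <- apply_scenario(18.4, list(
  modifier("stress", "compression", 0.56),
  modifier("inflammation", "chronic_shift", 2.0),
  modifier("hot_spot", "acute_shift", 3.2)))
res
```

The ventral CA1 baseline of 18.4 mV narrows to 5.984 mV (printed 6.0 mV), a
67.5 % loss of reserve.

### Phase semantics and composition rules

The published equation fixes the placement only of the three named terms:
the inflammatory shift sits inside the compression parenthesis, the
hot-spot term outside. We generalize this by requiring every modifier to
declare its phase (`chronic_shift` / `compression` / `acute_shift`); any
number of each is allowed, shifts add within their phase and compressions
multiply. Permuting the input order can therefore never change the result,
which a property test asserts on random modifier sets.

Two numerical edge rules matter:

* A set of chronic shifts summing to at least the baseline margin is a
  domain error — the pre-compression reserve would be non-positive and the
  equation is not defined there.
* A raw result below 0 mV (possible only in the acute phase) is floored at
  0 and flagged `clamped`, rather than erroring, so extreme grid points in a
  sensitivity sweep cannot abort a scan. The floor is applied stepwise
  within the acute phase, which keeps the decomposition chain exact (each
  step's "after" is the next step's "before") while yielding the same final
  value as flooring once.

All voltages are in mV throughout; there is no unit-conversion layer.
Printed comparisons use half-up rounding to one decimal
(`round_half_up()`); internal arithmetic is never rounded.

## The scenario library

`builtin_scenarios()` registers the combined-condition scenarios with their
published one-decimal values: `baseline` (18.4), `main` (6.0, −67.5 %) and
`strong_inflammation` (3.7, with the inflammatory shift at the full
acute-LPS scale, 3 × 2.0 mV). Two further variants are shipped with
magnitudes we had to *reconstruct*, because only their end results are
published: `chronic_proexcitatory` (an extra chronic shift of 3.0 mV gives
0.56 × (18.4 − 2.0 − 3.0) − 3.2 = 4.304 ≈ 4.3) and `caffeine_acute` (an
extra acute shift of 4.3 mV gives 5.984 − 4.3 = 1.684 ≈ 1.7). Both carry
`reconstructed = TRUE`, are excluded from expected-value matching, and are
footnote-flagged in reports — visible, but never overclaimed. `run_all()`
evaluates a scenario collection and reports computed-vs-expected mismatches
explicitly instead of silently passing them.

## Sensitivity analysis

`oat_sweep()` varies one parameter at a time around the nominal scenario
(the nominal value is inserted into any grid that omits it);
`combined_sweep()` enumerates the full Cartesian product exactly as
supplied, with a configurable size cap (default $10^6$) and lexicographic
tie-breaking for the extrema. The published alternative parameterizations
behind the quoted sensitivity spans are not available in detail, so the
package ships a generic engine plus one clearly labelled *illustrative*
default grid (`default_grids()`): compression {0.50, 0.56, 0.62},
inflammatory shift {0, 2, 6} mV, hot-spot shift {0, 3.2} mV — a local
neighbourhood of the nominal parameters whose one-at-a-time compression
span (5.0–7.0 mV at one decimal) is consistent with the published
low-millivolt regime. The exact published spans are treated as qualitative
context, not as machine-checked targets. Sweep correctness is tested
against brute-force enumeration through an independent closed-form oracle.

## Event catalog and exceedance

`builtin_events()` carries the six consolidated transient depolarizing
event classes: somatic NMDA-spike equivalents (gaussian 5.9 ± 1.5 mV),
NMDA spike/plateau amplitudes (range 3–23 mV), sharp wave–associated
depolarizations (gaussian 4.1 ± 2.3 mV), intracellular ripples (1–4 mV),
burst-associated depolarizations (10–25 mV) and place-field subthreshold
hills (5–20 mV). Classes reported only as a range are modelled uniform on
that range (the maximum-entropy choice); gaussian classes are truncated at
0 mV and renormalized, since depolarization amplitudes are positive.

`classify_crossing()` compares a residual margin to an event's amplitude
support: `exceeds` when even the smallest supported amplitude reaches the
margin, `cannot_cross` when even the largest falls short, else
`partially_within`. For gaussian classes the "support" is the mean ± 2 SD
interval clamped at 0 — an explicit artifact convention (flagged in the
output), under which `cannot_cross` implies an exceedance probability below
0.025. At the main-scenario margin this reproduces the qualitative picture:
ripples cannot cross alone, bursts exceed, and the NMDA plateau range is
partially within.

`exceedance_probability()` goes beyond the amplitude-scale comparison and
reports $P(\text{amplitude} \ge \text{margin})$ under each amplitude model
(analytic truncated-gaussian tail or uniform mass, with a seeded Monte
Carlo alternative that the tests hold to within three binomial standard
errors at $10^5$ draws). This probabilistic layer is package plumbing: it
operationalizes the comparison, but temporal structure, dendritic location,
conductance state, inhibition and synchrony are deliberately outside the
model, so these probabilities quantify amplitude overlap only — not
spike-triggering efficacy.

```{r events}
crossing_table(5.984)
```

## Synthetic populations and parameter recovery

No experimental recordings ship with the package; `generate_population()`
creates populations with the statistical structure the analysis assumes.
Margins are gaussian around 18.4 mV, truncated below at 1 mV by inverse
CDF (so `sd = 0` is exactly degenerate); control rheobase is lognormal with
a configurable coefficient of variation; stressed rheobase is
`gamma_true × control` with mean-one multiplicative lognormal noise at half
that CV, which keeps the mean of per-neuron ratios an unbiased estimator of
the compression coefficient. The dispersion defaults (`margin_sd = 2` mV,
`rheobase_cv = 0.2`) are artifact conventions chosen as plausible
order-of-magnitude cell-to-cell variability — they are not published
values, and they are config-overridable. Because only the margin is
published, the split into potentials is a convention too: threshold is
fixed at −50 mV (typical for CA1 first spikes) and the resting potential
derived from it.

What passing tests show, and what they do not: `recover_gamma()` retrieving
0.56 ± 0.02 from 500 synthetic neurons demonstrates that the estimator and
the generator are mutually consistent and that the pipeline is seeded and
deterministic; it says nothing about real electrophysiological variability,
which includes correlated parameters, non-gaussian tails and measurement
error that the generator deliberately does not emulate.

Problem sizes were chosen so every check is statistically meaningful at
desk scale: populations of 50–5000 neurons, $10^5$ Monte Carlo draws,
1000 bootstrap replicates.

## Reports and reproducibility

`run_report()` ties the stages into one bundle (scenarios, sensitivity,
event crossings, population summary, manifest) under a single seed, with
atomic write-then-rename per file so a failed run never leaves partial
output. CSVs carry full-precision columns plus `*_printed` one-decimal
columns for comparison against published values; in strict mode a
non-reconstructed scenario that misses its published value fails the run. A
thin command-line wrapper (`inst/cli/excitmargin.R`) exposes the verbs
`scenarios`, `sensitivity`, `events`, `population` and `all`. Configs are
YAML and round-trip exactly.

## Known limitations

* Static, voltage-domain only: no membrane dynamics, no inhibitory
  conductance term beyond voltage-equivalent shifts, no temporal or spatial
  structure of the triggering events.
* The compression coefficient is operational; multiplying several
  compressions is the simplest composition consistent with its ratio
  definition, not a biophysical claim.
* Two library scenarios rest on reconstructed magnitudes and are flagged as
  such.
* The uniform and truncated-gaussian amplitude models are conventions over
  sparse published summaries (a range, a mean ± SD), not fitted
  distributions.
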