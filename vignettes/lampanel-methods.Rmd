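---
title: "Methods: signal model, Tt calling, panel logic and LoD estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal model, Tt calling, panel logic and LoD estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lampanel)
```

## The measurement being modelled

lampanel implements the analysis chain of a multi-well isothermal
amplification (LAMP) diagnostic chip read out with quenching probes
(QProbes). A 25-well cartridge receives one purified nucleic-acid eluate;
each well carries primers and a probe for one diagnostic item, and in the
default respiratory panel each of four bacterial targets — *Bordetella
pertussis* (BP), *Mycoplasma pneumoniae* (MP), *Chlamydophila pneumoniae*
(CP), *Legionella pneumophila* (LP) — plus an internal control occupies
five wells. The reaction runs at a single temperature and an optical unit
reads fluorescence from all wells in real time. Because QProbe fluorescence
is *quenched* on hybridisation to amplified target, amplification shows as
a signal **drop**, not a rise.

Three quantities matter downstream:

* **Tt (amplification time)** — the time at the minimum of the
  differentiated, baseline-normalized fluorescence curve of one well.
* **Item status** — POSITIVE iff at least one of the item's wells has
  Tt within the sample-type cutoff (15 min swab, 20 min sputum).
* **LoD (limit of detection)** — derived from dilution-series replicate
  grids by a step-back rule over all-negative runs (below).

## Tt calling: normalized differential curve

For a trace $F(t_i)$, the caller:

1. **Normalizes** by the median of the readings in the first
   `baseline_window_min` minutes (default 2.0 min). The median resists
   early spikes; a non-positive baseline median signals corrupt input and
   is an error. Normalization is idempotent to numerical tolerance.
2. **Smooths** with a Savitzky–Golay local polynomial filter
   (`signal::sgolayfilt`), window 9 samples, order 2 by default. At the
   default 10-second sampling the window spans 1.5 min, narrow relative to
   the logistic transition (a few minutes) so the minimum is not displaced,
   wide enough to suppress instrument noise.
3. **Differentiates** by central differences on the time grid (one-sided
   at the endpoints), giving units of min$^{-1}$. The smoother and the
   differentiator are exact on polynomials up to the filter order, so a
   linear trace yields its slope everywhere.
4. **Locates the global minimum** of the derivative over the interior,
   excluding `edge_exclude = 3` samples at each end (one-sided differences
   and filter transients make the extreme ends unreliable). Ties break to
   the earliest time — the conservative, earlier-Tt choice.

The well is called amplified iff **both** the minimum-derivative magnitude
reaches `min_slope_mag` (default 0.05 min$^{-1}$) and the total normalized
drop $1 - \min_i \hat F_n(t_i)$ reaches `min_drop_frac` (default 0.10).
With the simulator's default kinetics a true quench has slope magnitude
$\approx q/4\tau = 0.25$ min$^{-1}$ and drop 0.40, while flat noise at the
default 0.5% relative noise level reaches neither threshold, so the two
gates sit comfortably between the signal and noise regimes rather than on
either shoulder. Both are configuration, not constants.

Tt is reported at the sample grid point of the minimum; there is no
sub-sample interpolation, so Tt resolution equals the sampling interval
(10 s by default). This is a documented limitation, acceptable because
cutoff decisions operate at whole-minute scales.

The quench sign convention is fixed: the caller looks for a *minimum* of
the derivative and never auto-detects signal direction. Traces from an
intercalating-dye instrument (rising signal) must be negated upstream.

## Panel aggregation and run validity

An item with $n$ member wells is **POSITIVE iff at least one well is
positive** — the multi-well design exists to catch the single well that
received template at near-LoD concentrations. Consequences verified as
properties: making any well positive never demotes an item; item results
are invariant to relabeling wells within an item; raising the cutoff can
only convert NEGATIVE to POSITIVE.

The **co-infection flag** is raised iff two or more non-control items are
simultaneously positive.

**Run validity** needed a decision the source material does not supply: an
internal control exists to prove the run worked, but no decision rule is
published. The package's default is *permissive*: a run is valid if the
control fired **or** any target fired, on the argument that target
amplification is itself evidence of a functioning reaction and reagents; a
dead control with a strong target signal more likely reflects control-well
delivery failure than a failed run. `strict_control = TRUE` switches to
the unconditional rule (control must fire) for laboratories that prefer
it. Invalid runs retain their item statuses but are flagged INVALID.

The default layout assigns one well column per item. The published chip
does not print its geometric well-to-item map, so this arrangement is an
arbitrary package convention; nothing downstream depends on geometry.

## The LoD step-back rule

Input is a replicate grid: for each dilution series, concentration
(copies/well, cps/well) and run, the count of positive wells out of
(usually) five. A run with zero positive wells is an **all-negative run**.
The rule:

* triggering concentration = the *highest* concentration with any
  all-negative run;
* LoD = the next concentration *above* it on the ladder (`EXACT_STEP`);
* no all-negative run anywhere → LoD `< min(ladder)` (`BELOW_RANGE`),
  represented explicitly as a bound, never as the bare number;
* an all-negative run at the top of the ladder → `ABOVE_RANGE`.

The step is taken on the **pooled ladder** — the union of all series'
concentrations — by default. This is the only reading consistent with the
packaged respiratory-panel table: BP's all-negative run at 1.25 cps/well
steps to 1.56 (its pooled neighbour, from a different series), not to the
within-series neighbour 2.50; likewise CP's 3.13 steps to 3.75, not 6.25.
A `mode = "within-series"` flag implements the alternative reading for
comparison; when several series contain a triggering run the smallest
within-series step is used, and a series-topping trigger falls back to the
pooled step. Only the highest triggering concentration matters: lower
all-negative runs are expected near and below the LoD and carry no extra
information under this rule.

The packaged fixture `table1_respiratory_panel.csv` is a transcription of
the published replicate table (3 series × 5 concentrations × 5 runs per
item, positive wells out of 5). Its published no-template-control row (0
cps/well, all zeros) is not part of the grid: the LoD ladder contains only
template-bearing concentrations. Structural integrity — record counts,
ranges, saturation of the top concentrations, anchor cells — is validated
on load.

### Detection-efficiency fit

As a descriptive companion, `fit_detection_efficiency()` fits
$p(\lambda) = 1 - e^{-e\lambda}$ to the binomial well counts by maximum
likelihood ($\lambda$ = nominal cps/well, $e$ = per-copy detection
efficiency), via a one-dimensional search on $\log e$ with the binomial
probability clamped away from 0/1 to keep the likelihood finite at the
search edges. `lod95` $= -\ln(0.05)/e$ is the concentration with 95%
per-well detection. This is intentionally the simplest dose–response
summary — no probit analysis, no inter-laboratory variance components —
and it presumes the exponential (single-hit Poisson) form; grids whose
hit rates are all 0 or all 1 are non-identifiable and error out.

## Poisson occupancy model

Near the LoD the few template copies in the eluate land unevenly across
wells. The model: copies per well $\sim$ Poisson($\lambda$), each copy
detected independently with probability $p_{det}$, a well positive iff it
holds $\ge 1$ detected copy. Then

$$p_{well} = 1 - e^{-\lambda p_{det}}, \qquad
  K \sim \mathrm{Binomial}(n, p_{well}), \qquad
  p_{item} = 1 - (1 - p_{well})^n .$$

$p_{det}$ defaults to 1 (single-copy detection), consistent with the
panel's measured LoDs of 4 copies/well or less; it is exposed for
sensitivity analyses. $\lambda$ is parameterized directly in cps/well to
match the dilution tables rather than derived from eluate and well
volumes, which are only approximate. A seeded Monte-Carlo mirror
(`simulate_occupancy()`) draws the same process explicitly and serves as
the numerical cross-check of the closed forms. The well-known caveat that
"well positive" is equated with "contains a detected copy" — collapsing
per-well amplification efficiency into $p_{det}$ — is inherited by
everything downstream.

## The trace simulator: what it emulates, and what it does not

`simulate_well_trace()` generates

$$F(t) = f_0\left[1 - \frac{q}{1 + e^{-(t - T_t)/\tau}}\right]
  + d\,t + \varepsilon_t,\qquad \varepsilon_t \sim N(0, \sigma_f^2),$$

on a uniform grid, with the true amplification time following a standard
amplification phenomenology — Tt decreases by a fixed amount per doubling
of template:

$$T_t = \max\!\big(1,\; t_0 - s \log_2(\text{detected copies})
  + N(0, \sigma_{Tt}^2)\big).$$

Defaults (all configuration, none instrument calibrations): baseline
$f_0 = 1000$ AU; quench amplitude $q = 0.40$; transition time constant
$\tau = 0.4$ min; intercept $t_0 = 10$ min at one copy; slope $s = 0.75$
min/doubling; Tt jitter $\sigma_{Tt} = 0.3$ min; additive noise
$\sigma_f = 5$ AU; drift 0.2 AU/min; sampling 10 s; duration 15 min (swab)
or 20 min (sputum). The kinetic values were chosen once so that simulated
Tt values fall in the 6–15 min band appropriate to 15/20-minute reaction
windows and a cutoff of 15/20 min; the noise level (0.5% relative) makes
calling easy but not trivial.

Chip runs draw Poisson copies per well at the item's concentration
(thinned by $p_{det}$), so the simulator and the occupancy model share one
partition process; the end-to-end test demands that simulated,
Tt-called hit rates match the closed-form occupancy curve. Copies are
**not** conserved across wells — each well draws independently — which
approximates aliquoting from a large eluate volume.

Reproducibility: every well derives its own RNG sub-seed from the master
seed and a string key (well address, or concentration/run/well triple)
through a 31-bit polynomial string hash modulo $2^{31}-1$. Adding wells or
concentrations to a design therefore never perturbs the draws of existing
ones, and identical seeds give byte-identical trace files.

What the simulator deliberately does **not** emulate: extraction yield and
pretreatment chemistry, sputum-viscosity Tt delays (reported only as a
qualitative trend, so excluded rather than guessed), cross-reactivity,
inhibition, multi-dye optics, melt behaviour, or channel-filling fluidics.
Passing tests therefore demonstrate the *analysis chain* — normalization,
differentiation, thresholding, aggregation, LoD arithmetic, occupancy
statistics — on signals with realistic shape, noise and partition
statistics; they say nothing about wet-lab performance on real specimens.

## Numerical and degenerate-input choices

* Baseline window must contain ≥ 3 samples; baseline median must be > 0.
* Traces must be ≥ 8 samples, strictly increasing in time, finite, and at
  least as long as the smoothing window.
* Derivative ties break to the earliest time.
* `estimate_lod` on an empty grid is an error; `BELOW_RANGE` carries the
  lowest tested concentration as an explicit upper bound.
* The efficiency MLE searches $\log e \in [\log 10^{-6}, \log 10^{4}]$;
  probabilities are clamped to $[10^{-12}, 1 - 10^{-12}]$ inside the
  likelihood.
* The sub-seed hash keeps all arithmetic below $2^{53}$, exact in doubles,
  and returns seeds in $[0, 2^{31}-2]$.

## Problem sizes used by the test suite

The suite exercises: the full packaged replicate table (4 items × 75
runs); a 61-point grid of noiseless logistic midpoints over 3–18 min at
10-second sampling; 100,000-replicate Monte-Carlo occupancy checks at five
ladder concentrations; an end-to-end simulated dilution experiment of 200
runs per concentration over the full 15-concentration ladder (15,000
wells, simulated and Tt-called individually); 1,000 flat-noise wells for
false-positive specificity; 500 noisy wells for Tt accuracy; and 200
randomized grids against a brute-force LoD oracle. These sizes keep the
statistical checks at 3-standard-error resolution while the whole suite
runs in well under a minute.
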