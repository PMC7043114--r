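---
title: "A deterministic portfolio model for vaccine development pipelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A deterministic portfolio model for vaccine development pipelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p2i)
```

## What the model does

`p2i` answers a portfolio-level funding question: given a set of vaccine
candidates at known development stages, what will it cost to push them all
through phase III, year by year, and how many launches should be expected?
The model is deliberately simple and fully deterministic — a risk-adjusted
cash-flow projection, not a simulation. Its unit of assumption is the
*archetype*: a product class (simple, complex, or unprecedented vaccine)
that shares per-phase cost, duration and probability-of-success values.
"Unprecedented" denotes HIV/TB/malaria-type candidates, for which no
platform has yet produced a licensed vaccine; they carry drastically lower
phase II/III success (0.05 and 0.40) than other complex vaccines.

The modelled pipeline runs from advanced preclinical work through phase III
only. Discovery, regulatory review, manufacturing scale-up and phase IV are
all outside scope, so every cost figure is a deliberate under-estimate of
full development cost. "Launch" means completing phase III.

## Mechanics and conventions

For a candidate with entry phase $e$ and archetype $a$, with per-phase
success $s_{a,p}$, cost $C_{a,p}$ and duration $L_{a,p}$:

* **Time.** The candidate starts phase $e$ at $t = 0$, January 1 of the
  start year, and traverses the remaining phases contiguously; phase $p$
  occupies the half-open interval $[\sum L_{<p}, \sum L_{\le p})$ in
  fractional years. No candidate-specific start dates exist in the inputs,
  so a common origin is the only defensible choice — and it reproduces the
  published early-year figures exactly (below).
* **Probabilities.** The probability of *reaching* phase $p$ is
  $\pi_p = \prod_{e \le q < p} s_{a,q}$ (an empty product is 1); the launch
  probability is $\lambda = \prod_{p \ge e} s_{a,p}$. Probabilities are
  stored as fractions; percent inputs are converted once on read, with no
  hidden extra precision.
* **Cost accrual.** Phase $p$'s risk-adjusted cost $\pi_p C_{a,p}$ accrues
  uniformly over its duration; a calendar year's accrual is the
  rate-weighted overlap of the year with each phase interval, and anything
  past December 31 of the end year is discarded. The risk adjustment applies
  to the whole phase including its first partial year — the only rule
  consistent with the published second-year figure, where the two simple
  vaccines switch from phase I to risk-weighted phase II at $t = 1.6$.
* **Launch dating.** A launch is counted in the calendar year containing
  the end of the phase III interval; an end time landing exactly on a year
  boundary belongs to the earlier year (intervals are half-open). This
  convention is what aligns the launch mass with the published 2025 / 2026 /
  2028 / 2031 steps.
* **Degenerate inputs.** A zero-length phase accrues its full risk-adjusted
  cost as a point mass at its start instant, assigned by the same
  earlier-year boundary rule — the limit of uniform accrual as duration
  goes to zero. Empty portfolios aggregate to all-zero results. Launch
  instants are snapped to $10^{-9}$ years before year-binning to absorb
  float noise in summed durations.
* **Units.** US$ millions and fractional years throughout; no discounting
  and no inflation adjustment (the source analysis applies none). Rendered
  tables round costs to 2 decimals and launch probabilities to 2 (3 below
  0.1); rounding is a pure view and never feeds back into computation.

## Parameters that matter

The packaged parameter set (`p2i_v2_params()`) drives everything. The launch
side of the model is most sensitive to success probabilities late in the
product's remaining path: a candidate with $k$ remaining phases scales as
$m^k$ when all probabilities are multiplied by $m$, which is why the ±10%
sensitivity run moves total launches by roughly ±30% (0.69 → 0.91 / 0.51).
Costs enter linearly: scaling all costs by $m$ scales every cost output by
exactly $m$ and leaves launches untouched.

Scenario runs (`apply_overrides()`) replace single parameter cells. The
canonical scenario (`evi_overrides()`) uses the only two EVI-internal
measurements backed by ten data points — phase I transition success 0.70
and phase I duration 1.45 years (17.4 months) for unprecedented vaccines.
The duration is entered as 1.45 exactly, as published. The rest of the
internal data (`evi_internal_data()`) rests on two or three observations
and is shipped as annotation only; its EUR cost figures are deliberately
not currency-converted. Perturbation multipliers clamp probabilities at 1,
although no packaged value exceeds 0.91 after ×1.1.

## What the synthetic generator does and does not emulate

`generate_portfolio()` draws candidates by seeded, independent weighted
sampling of archetype, entry phase and disease, with default weights equal
to the EVI portfolio's empirical mix (archetypes 15:2:1; phases 3:11:4:0).
It emulates portfolio *composition* only: it does not model correlation
between disease and archetype (in the real portfolio, all malaria-family
candidates are unprecedented), staggered entry dates, candidate dependency,
or re-run trial phases. Property tests passing on synthetic portfolios
therefore establish the engine's algebraic invariants (monotone cumulative
series, exact per-disease aggregation, the $m^k$ scaling law, closed-form
vs accrual equivalence) — not fidelity of any particular forecast to a real
pipeline. An optional `jitter_params` mode perturbs the parameter table
cell-wise within ±20% so invariants are exercised away from the single
published parameter set; it is not meant for substantive analysis.

## Numerical fidelity to the published analysis

With the shipped portfolio and parameters, the accrual rule reproduces the
published cumulative costs for 2019 (44.11794) and 2021 (145.5832) to every
printed digit and 2020 to within one unit in its last printed digit
(90.399872 computed vs 90.39988 printed). From 2022 onward the published
series drifts by up to ~0.1% from the exact rule (e.g. 199.9804 printed vs
199.8963 computed for 2022), and the published per-disease cost totals sit
0.04–0.13 US$M below the closed-form risk-adjusted sums (73.96 printed vs
74.0488 for a simple phase I candidate). The internal discretization of the
original spreadsheet implementation is not documented, so the package makes
no attempt to emulate the drift: costs are computed by the exact rule and
compared with a 0.5% band where the published figures are affected. Launch
probabilities have no such ambiguity — they are closed-form products and
match exactly at the published precision, as do the published sensitivity
swings (0.91 / 0.51) that pin down the "10% higher" perturbation as
multiplicative rather than additive.

The test suite and the analysis scripts run the full 18-candidate portfolio
everywhere (the model is closed-form, so even the 10,000-candidate sampling
check used for the generator's law-of-large-numbers test completes in
seconds); nothing is scaled down.

## Known limitations

The model ignores trial reiteration (real programmes often run several
phase I trials per antigen), cannot send candidates backwards in the
pipeline, uses archetype parameters pooled across diseases and settings,
and prices no post-phase-III activity. Cost forecasts should accordingly be
read as lower bounds on true development cost, and launch forecasts as
conditional on the archetype assumptions rather than disease-specific
evidence.
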