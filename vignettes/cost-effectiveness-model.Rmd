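---
title: "A short-term decision-tree model for GLP-1 receptor agonist cost-effectiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A short-term decision-tree model for GLP-1 receptor agonist cost-effectiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glp1ce)
```

## The decision problem

Adults with type 2 diabetes who remain hyperglycemic on metformin and
lifestyle modification are commonly offered a GLP-1 receptor agonist. Two
widely used options differ in schedule and price: once-daily liraglutide
1.8 mg and once-weekly exenatide 2 mg. Their HbA1c effectiveness is
similar, their costs are not, and the head-to-head trial evidence
(DURATION-6: liraglutide −1.48% vs exenatide −1.28% at 6 months) points in
a different direction than pooled network meta-analysis evidence (−1.18%
vs −1.15%). `glp1ce` quantifies what those alternative effectiveness
readings imply for short-term value from a payer perspective, with
effectiveness measured as the reduction in HbA1c in percentage points and
value as the incremental cost per 1% HbA1c reduction.

The time horizons are deliberately short — 6 and 12 months — matching how
US payers tend to evaluate glycemic-control endpoints; the model makes no
attempt to project microvascular complications or QALYs.

## Model structure

Each strategy's cohort moves through a single-shot decision tree:

1. **Early discontinuation** (before week 4), probability $p_e$: the
   patient accrues **1 month** of drug cost and, returning to baseline
   HbA1c, contributes no effect.
2. **Late discontinuation** (after week 4, conditional on remaining),
   probability $p_l$: **3 months** of drug cost, no effect.
3. **Completion**, probability $r = (1-p_e)(1-p_l)$: drug cost for the
   full horizon $h$ and the full-course HbA1c reduction $\Delta$.

An independent adverse-event branch applies to the whole cohort: a
gastrointestinal episode costs $c_{GI}$ and occurs with probability
$P(\text{TEAE}) \cdot P(\text{GI}\mid\text{TEAE})$. Discontinuation
itself carries no cost. The closed-form per-patient expectations are

$$E[\text{drug}] = p_e m + (1-p_e)p_l\,3m + r\,h\,m, \qquad
  E[\text{AE}] = P(\text{TEAE})\,P(\text{GI}\mid\text{TEAE})\,c_{GI},$$

$$E[\text{effect}] = r\,\Delta, \qquad
  \text{total} = \text{drug} + \text{AE} + \text{disc} \;(\text{disc} \equiv 0).$$

with $m$ the monthly acquisition cost — for liraglutide the pack price
plus the $9/month needle cost, since needles are consumed with each daily
dose. The incremental cost-effectiveness ratio divides the unrounded
incremental total cost by the unrounded incremental effect; net monetary
benefit at willingness to pay $\lambda$ is
$\lambda\,\Delta E - \Delta C$.

```{r base-case}
scn <- builtin_scenario("duration6")
base_case_table(scn)
base_case_table(scn, 12L)$total_cost[3] # 12-month incremental cost
```

### Conventions worth stating

Several modelling choices are genuinely open and were fixed once, as
follows:

* **Accrual calendar.** "28 days" of drug for early discontinuers is
  charged as exactly 1 monthly pack and "12 weeks" as exactly 3 packs;
  prices are monthly pack prices and no day-level price exists.
* **Adverse events apply to the whole cohort in both arms.** The trial
  reporting is ambiguous about whether liraglutide's TEAE rate refers to
  patients remaining after week 4; applying it cohort-wide is the only
  reading that reproduces the published exenatide adverse-event cost
  ($273) exactly, so it is used symmetrically in both arms.
* **Sequential discontinuation.** $p_l$ is conditional on surviving
  week 4 (immaterial for exenatide, where $p_e = 0$).
* **12-month horizon.** Discontinuation probabilities are applied once
  (no second wave), the adverse-event cost is incurred once, and the
  full-course HbA1c reduction is carried unchanged, so only completers
  accrue the extra 6 months of drug cost.
* **Sign convention.** HbA1c reductions are stored as positive
  magnitudes and rendered with a leading minus in reports.
* **Rounding.** All arithmetic is unrounded; presentation rounds costs
  and ICERs to whole dollars and effects to two decimals. In particular
  ICERs are always computed from unrounded deltas — dividing the rounded
  difference row reproduces neither this model's ratio nor published ones.

### Dominance handling

`icer_with_dominance()` classifies the incremental pair on the
cost-effectiveness plane. The ratio is reported only in the NE quadrant
(costlier, more effective) and — numerically but flagged — in SW, where a
*lower* ratio favours the intervention; SE is "dominant" and NW
"dominated" with the ICER undefined, including the boundary
$\Delta E = 0,\ \Delta C \neq 0$. A pair with both deltas zero is
"equivalent". This keeps probabilistic sweeps from silently averaging
ratios across quadrants; PSA summaries therefore use CEAC/NMB, never a
mean of per-draw ICERs.

## Parameter uncertainty

Every input is an `uncertain_input`: point estimate, low/high bounds, and
a distribution family (beta for probabilities and HbA1c reductions,
normal for costs, or fixed). For the probabilistic sensitivity analysis
the bounds are read as a central **95% interval**, so the implied standard
deviation is $(\text{high} - \text{low})/3.92$. This is the most common
convention for published low/high columns but it is an interpretation,
not a fact; the divisor is exposed as `interval_factor` everywhere
(default 3.92) rather than hard-coded, so the consequences of, say,
reading the bounds as $\pm 1$ sd (`interval_factor = 2`) can be examined
directly.

Beta parameters come from the method of moments:
$\alpha = m(m(1-m)/s^2 - 1)$, $\beta = (1-m)(m(1-m)/s^2-1)$ with $m$ the
point estimate. Edge rules: a point estimate of exactly 0 (the exenatide
early-discontinuation input is 0% with a 1% upper bound) leaves the
method undefined, so the mean moves to half the interval
($\text{high}/2$) with $s = \text{high}/3.92$, keeping the branch
stochastic; an infeasible variance ($s^2 \ge m(1-m)$) is clamped to
$0.9\,m(1-m)$ with a warning; a collapsed interval degrades the input to
fixed and it is never sampled. HbA1c reductions exceed 1 in percentage
points, so beta-family inputs with `high > 1` are fitted and sampled on
the divided-by-100 scale — the mean and the percentage-point spread are
preserved and draws stay positive. Normal cost draws are truncated at
zero by resampling (the truncation probability is negligible for every
bundled input, all of which sit more than 9 sds above zero).

Inputs are sampled independently — no correlation structure is imposed —
once per run, with the shared gastrointestinal episode cost drawn once
and used in both arms. The sampling order is fixed (intervention fields,
comparator fields, shared cost) and the RNG is seeded, so a PSA is
byte-reproducible from `(scenario, n_runs, seed, interval_factor)`;
`run_psa()` restores the caller's RNG state on exit.

```{r psa}
psa <- run_psa(scn, n_runs = 5000, seed = 1)
psa
ceac <- ceac_curve(psa, seq(0, 5000, by = 100))
ceac_crossover(ceac)
```

The default 5,000 runs make the Monte Carlo standard error of a CEAC
ordinate about 0.007. That matters for the crossover: the curve reaches
0.5 where the *median* net monetary benefit crosses zero, slightly below
the base-case ICER of ≈$4,810 because the NMB distribution is
right-skewed, and on a $100 grid the observed crossover can land one step
to either side of $4,800 at this simulation size. Under the meta-analysis
source the curve stays below 0.5 over the whole $0–$5,000 grid. The
default grid is a superset of the conventional $500–$5,000 evaluation
range so the curve's left tail is visible.

One-way sensitivity (`one_way_sweep()`) re-evaluates the full model with
each input at its low and then its high bound, everything else at point
estimates, and ranks inputs by the width of the induced range — the
tornado ordering. Degenerate inputs get width 0 and rank last; the
reporting layer keeps the top 10.

## The micro-simulation oracle and what the tests show

`simulate_patients()` realises the same tree patient-by-patient
(sequential discontinuation indicators, then an independent TEAE/GI
chain) and returns per-field means with standard errors. Because it
shares only the tree *structure* — not the closed-form algebra — with
`evaluate_strategy()`, agreement within 3 standard errors at
$n = 10^5$ patients across randomly generated scenarios is an
independent check of the cohort expectations. The random-scenario
generator (`random_scenario()`) draws probabilities from (0.01, 0.6),
full-course reductions from (0.2, 2.5) percentage points, monthly costs
from (50, 1500) USD and the episode cost from (200, 3000) USD, with
bounds at 0.8×/1.2× the point estimate clamped to each field's domain —
wide enough to exercise the model well outside the bundled inputs while
staying clinically plausible. The oracle deliberately mirrors the
cohort-wide adverse-event assumption, so the pair of implementations
tests the arithmetic, not that assumption.

Test problem sizes — 20 random scenarios at $10^5$ patients in the
acceptance suite, smaller sweeps elsewhere — keep the full suite around
ten seconds while holding the per-comparison false-alarm rate of the 3-SE
band low; with fixed seeds the suite is deterministic.

What passing does *not* show: the generator emulates parameter files, not
patients — real-world adherence, correlated parameters (e.g. price and
discontinuation), time-varying HbA1c trajectories, or adverse events
beyond the gastrointestinal category are all outside the model, so the
tests validate internal correctness and reproducibility, not external
validity.

## Known divergences from the published analysis

The bundled inputs reproduce the published exenatide adverse-event cost
exactly and the headline ICERs and incremental costs within a few
percent ($4,810 vs $4,773; $27,691 vs $27,179; $866 vs $891 at 6 months;
$1,599 vs $1,604 at 12 months). They do **not** reproduce the published
per-strategy totals ($3,509/$2,618), the per-strategy HbA1c reductions
(−1.54/−1.36, which *exceed* the trial-level inputs and cannot follow
from any retention-scaled rule), the liraglutide adverse-event cost
($432, where the stated three-way product gives $395 even though the
exenatide analogue matches exactly), or the published PSA
effect-positive fractions (81%/58%, which imply a wider effectiveness
spread than the 95%-interval reading; this model yields ≈99%/≈65%). The
exact accrual calendar and interval interpretation behind those numbers
are not recoverable from the published inputs; rather than tune hidden
constants, the model pins the conventions above and keeps
`interval_factor` as an explicit knob. A regression test asserts these
divergences stay in their documented bands so silent drift is caught.

## Limitations

Two strategies only; no QALYs, utilities or willingness-to-pay
calibration; no CPI adjustment (costs are 2014 USD as given); no
correlation structure or value-of-information analysis; wholesale
acquisition costs without rebates. The model is a single-shot tree — no
Markov cycling, half-cycle correction, or time-varying hazards — which is
adequate for the 6–12-month horizons it targets and wrong for anything
longer.
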