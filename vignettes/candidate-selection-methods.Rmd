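---
title: "Selecting variant-call verification candidates under a budget"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting variant-call verification candidates under a budget}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcselect)
```

## The problem

When several variant callers are run on the same sample, their error
profiles must usually be estimated by re-testing a subset of the predictions
on an orthogonal assay: verifying everything is too expensive, so a
*verification budget* of `n_targets` candidate calls is chosen and each
caller's precision, recall and F1 are inferred from the verified subset
alone. The estimate quality then depends entirely on *which* calls are
chosen. A uniform draw over the pooled calls is unbiased per call but can
leave a caller with a small call set entirely unsampled; quota schemes
guarantee coverage but change the composition of what is sampled. vcselect
implements six selection strategies spanning that trade-off, the subset
scoring that goes with them, and a simulation harness for benchmarking the
strategies when ground truth is known.

## Data model

A *call profile* is the union of predicted variants, each identified by
(chromosome, position) only and mapped to the set of callers that predicted
it. The size of that set is the variant's *overlap level*: level 1 calls are
unique to one caller, level N calls were made by all N callers. Alternate
alleles, genotypes and strand are deliberately outside the model — the
interchange formats carry coordinates and 0/1 membership flags, nothing
else — and chromosome labels are compared as opaque strings, with an opt-in
toggle to strip a leading `"chr"` when reconciling sources that disagree on
the dialect. Truth is a separate table mapping variants to a boolean
verified/not-verified label; looking up an unlabelled variant is an error
rather than a silent default, because a missing label is not evidence of a
false call.

## The six strategies

All strategies sample without replacement and obey one contract: the
selection contains exactly `min(n_targets, number of distinct calls)`
variants — the budget goes unfilled only when the calls run out.

* **random_rows** — uniform over the pooled calls.
* **equal_per_caller** — the budget is split equally among callers; each
  caller's not-yet-consumed calls are sampled up to its share (a call chosen
  for one caller is invalid for the rest).
* **equal_per_overlap / increasing_with_overlap / decreasing_with_overlap**
  — the budget is split across overlap levels 1..N with weights 1, k, and
  1/k respectively.
* **directed_sampling** — walks the call overlap-by-caller matrix (cell
  (k, j) = calls at level k made by caller j) from the full-agreement row
  down to the unique-call row, cells within a row in ascending size order;
  each cell's budget is the remaining budget divided by the number of
  unexamined cells that still hold selectable calls, so every caller and
  every overlap level is represented when the budget allows.

Three numerical choices are shared by the quota strategies and were left
open by the verbal description of the methods, so they are fixed here as
package policy:

* **Integerization.** Fractional shares are resolved by largest-remainder
  apportionment (`apportion()`): each unit receives the floor of its exact
  share and the leftover units go to the largest fractional remainders,
  ties broken by a seeded shuffle. Quotas always sum to the budget and no
  unit is systematically favoured.
* **Shortfall redistribution.** A unit that cannot spend its quota (too few
  available calls) returns the unspent budget to a pool that is
  re-apportioned — with the strategy's own weights — over the units that
  still have unconsumed calls, iterating until the budget is spent or no
  calls remain. A single redistribution round is not enough: the recipient
  units can themselves run dry, and only iteration preserves the budget
  contract above.
* **Order randomization.** Caller processing order (equal_per_caller) and
  equal-size cell ties (directed_sampling) are shuffled by the selection
  seed. Order matters whenever calls are shared — an early unit can consume
  a later unit's calls — and randomizing it spreads that advantage evenly
  across replicate runs.

For directed sampling, the divisor counts only unexamined cells that still
hold selectable calls. This guarantees the final such cell receives at
least `floor(remaining / 1) >= 1`, so every traversal makes progress and the
repeat-until-spent loop terminates; a guard pass granting one selection per
non-empty cell is retained for safety but is unreachable under this
divisor. Every selection is a pure function of (profile, budget, strategy,
seed), and the seed is recorded in the output.

## Scoring a verified subset

Counts are defined over the selected variants only. For caller j: TP are
selected true variants j called, FP selected false variants j called, and FN
selected *true* variants j did **not** call — i.e. true calls surfaced by
some other caller. Then

$$\mathrm{precision} = \frac{TP}{TP+FP}, \qquad
  \mathrm{recall} = \frac{TP}{TP+FN}, \qquad
  F_1 = 2\,\frac{\mathrm{precision}\cdot\mathrm{recall}}
                 {\mathrm{precision}+\mathrm{recall}}.$$

A score whose denominator is empty is undefined and reported as `NA` — this
is the characteristic failure of uniform sampling on skewed ensembles — and
`NA` propagates to F1 and is excluded from all aggregates as missing data.
When precision and recall are both defined and both zero, F1 is 0, not `NA`:
the estimate exists, it is simply the worst possible one.

**Weighted precision.** A strategy that skews sampling across overlap levels
also skews the *composition* of a caller's scored calls: if unique calls are
oversampled and unique calls are mostly errors, the default precision is
biased down regardless of the caller's real output. The weighted mode
removes this bias by scoring each overlap level separately and averaging the
group precisions with weights equal to the caller's *total* (verified plus
unverified) call count at that level. A caller with 100 unique calls and 50
shared calls therefore counts its unique-call precision twice as strongly as
its shared-call precision, whatever the selection sampled. Levels at which
the caller has calls but the selection took none contribute neither
numerator nor denominator — inventing a precision for an unsampled group
seemed worse than omitting it, and the omission is visible in
`overlap_group_weights()`. Recall has no analogous correction; the weighted
mode alters precision only, and F1 combines the weighted precision with the
unchanged recall.

**Full-set baselines.** Subset scores are judged against the caller's
full-prediction-set scores. Two baselines are available. `"union"` treats
the entire call union as selected; it is the limit the subset estimate
actually converges to as the budget grows, since no subset of the calls can
witness a mutation every caller missed, and it is therefore the default
reference inside the benchmarking harness, where convergence-to-zero of
ΔF1 = subset F1 − full F1 is the quantity of interest. `"all-mutations"`
additionally counts mutations missed by every caller as FN for each caller,
giving recall against the complete mutation set; it is the default for
`full_set_metrics()` itself, where the question is the caller's true error
profile rather than an estimator's convergence target.

## The synthetic generator

`simulation_config()` describes a caller ensemble by exactly the properties
the selection and scoring arithmetic responds to: a number of true mutations
on a synthetic chromosome, a per-caller detection probability applied
independently per mutation (sensitivity), a per-caller false-positive count,
and a *shared* false-positive pool from which a configurable fraction of
each caller's errors is drawn, giving recurrent errors overlap level ≥ 2.
True-mutation and false-positive coordinates are kept disjoint by
construction so every generated call has an unambiguous label. The axes of
difficulty of real tumour data — purity, sub-clonality, mutation rate,
sequence context — are intentionally collapsed into these knobs: the
generator makes no claim of sequence-level realism, and results on it
demonstrate estimator behaviour (coverage, bias, convergence), not caller
performance on real genomes.

Defaults model a three-caller somatic-SNV ensemble of ~10^4 calls:
sensitivities 0.9/0.8/0.7 (a realistic spread between a strong and a
mediocre caller), false positives ≈ 15% of each caller's output, a quarter
of them recurrent through a 400-position shared pool, over 3500 true
mutations. `skewed_ensemble()` instead produces the regime where uniform
sampling fails: one dominant caller of ~10^4 calls (sensitivity 1.0 plus
9900 private false positives over 100 true mutations) and three minor
callers of ~10 calls each — a 1000-fold size ratio. With ~10 calls among
~10^4, a budget-100 uniform draw misses a minor caller entirely with
probability `dhyper(0, 10, 10005, 100)` ≈ 0.9, which the test suite checks
against the observed N/A rate; the per-caller quota of equal_per_caller
makes that starvation impossible.

The fixed problem sizes used throughout the tests and the acceptance script
— a ~10^4-call ensemble, budgets 100–2500, 5–10 replicates, 200 seeds for
rate estimates — were chosen so that structural effects (bias, starvation
rates) dominate Monte-Carlo noise at desk scale.

## What the benchmarks do and do not show

`run_sweep()` crosses datasets × caller subsets × strategies × budgets ×
precision modes × replicates, derives every seed from the master seed and
the factor coordinates (any row is reproducible in isolation), and ranks
strategies by the median |ΔF1| across callers and replicates, ties broken
by the IQR of |ΔF1| and then by name. Undefined scores are excluded from
location and spread statistics but reported as an `na_rate` column, because
a strategy can otherwise *appear* accurate by failing to score exactly the
callers it estimates worst — on the skewed ensemble, uniform sampling posts
a low mean |ΔF1| while leaving minor callers unscored in ~90% of runs. Rank
and `na_rate` must be read together.

Two known limitations follow from the estimator itself, not the
implementation. First, caller-quota strategies inflate each caller's recall
estimate at small caller counts: a caller's own quota guarantees it appears
in roughly 1/N of the selected-true set, biasing
P(called | true, selected) upward by about (1/N)(1 − sensitivity). The
effect shrinks as 1/N and is negligible for ensembles of ~20 callers but
measurable at N = 3. Second, decreasing_with_overlap concentrates the
budget on unique calls, whose true variants are by definition the ones most
callers missed; its recall estimates sit systematically below the full-set
value, and its precision estimates are trustworthy only in weighted mode.

## Worked example

```{r example}
ens <- simulate_ensemble(simulation_config(seed = 7))
ens$profile

sel <- select_candidates(ens$profile, 500, "equal_per_caller", seed = 7)
evaluate_callers(ens$profile, sel, ens$truth, mode = "weighted")

full_set_metrics(ens$profile, ens$truth, baseline = "union")
```
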