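---
title: "The sink algorithm: stratified conditional-probability inference of the underlying cause-of-death"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The sink algorithm: stratified conditional-probability inference of the underlying cause-of-death}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(sinkcod)
```

## The problem

A death certificate carries an ordered *cause-of-death chain* of up to four
ICD-10-coded conditions — the direct cause `A` first, then the antecedent
conditions `B`, `C`, `D` running back toward the originating condition —
plus, sometimes, past-medical-history codes `E` that are not part of the
chain. Mortality statistics are tabulated by a single *underlying
cause-of-death*, which must be selected from `A`–`D` (usually) or `E`
(occasionally). Doing this by hand is slow and rater-dependent; `sinkcod`
automates it with a stratified conditional-probability model.

## The model

Two estimators are fitted from labeled records.

**RDCP** (regional death-cause proportion): for cause $i$ in region $j$,

$$\mathrm{rdcp}_{ij} = \frac{n_{ij}}{N_j},$$

where $n_{ij}$ counts labeled deaths in region $j$ with underlying cause $i$
and $N_j$ is the region's total. It describes the regional burden of each
cause and sums to one within every region; it is a descriptive quantity and
does not enter inference.

**CDCP** (conditional death-cause proportion): the probability that cause
$i$ is the underlying cause *given that it appears on the record*,
stratified by age group and gender:

$$\mathrm{cdcp}_i(a, g) =
  \frac{\mathrm{death}[i][a][g] + \alpha}{\mathrm{occur}[i][a][g] + 2\alpha},$$

with `occur` the number of decedents of stratum $(a, g)$ carrying cause $i$
anywhere on the record, `death` the number for whom it was the labeled
underlying cause, and $\alpha \ge 0$ an additive (Laplace-style) smoothing
constant that damps cells supported by very few decedents. The strata are
the two genders and three age groups (`young`: age $\le 18$; `middle`:
$18 <$ age $< 55$; `old`: age $\ge 55$; the boundary ages belong to the
outer groups). A `log` variant, $\log_2(10\,\mathrm{cdcp})$, is also
provided: it compresses the dynamic range between causes, is bounded above
by $\log_2 10 \approx 3.32$, and — being a strictly increasing transform —
induces exactly the same within-stratum ranking, hence identical
predictions. `raw` is the default because its values are directly
interpretable as probabilities and match the scale on which such tables are
usually printed; the equivalence of the two variants is asserted by a
property test.

**Inference (the sink rule).** A decedent is pictured as a boat sunk by the
stones loaded into it: each cause on the record is a stone whose weight is
its stratum-specific CDCP, and the underlying cause is the heaviest stone.
The candidate set is the chain plus (by default) the history; the
prediction is $\arg\max$ of CDCP over candidates. Two auxiliary rules:

* **External-cause short-circuit** (on by default): when the direct cause
  `A` is an ICD-10 Chapter XX external cause (codes V01–Y98), it is
  returned immediately — an external underlying cause coincides with the
  direct cause. Only position `A` triggers the rule: an injury code deeper
  in the chain is an intermediate mechanism, not a candidate short-circuit.
* **Unseen-candidate fallback**: a candidate absent from the fitted table
  is resolved through progressively pooled cells — pooled over gender
  (cause, age group), then over age (cause, gender), then globally
  (cause) — each recomputed from pooled *counts*, never by averaging CDCP
  values (which would weight strata incorrectly). If every candidate is
  still unresolved the direct cause is returned, flagged `fallback`.

**Tie-breaking.** Exact CDCP ties are broken deterministically: the
candidate latest in the chain wins (the chain is ordered from the direct
cause backwards, so later positions sit closer to the originating
condition, which the underlying cause is); chain candidates beat history
candidates; remaining history ties go to the lexicographically smallest
code. Ties are flagged `tie_broken` so their frequency can be audited.
There is no randomness anywhere in inference.

## Counting conventions

Counts are per decedent: a cause appearing both in the chain and the
history of one record increments `occur` once. The labeled underlying cause
is always counted as occurring on its own record, even when
`include_history = FALSE` removes the history from the candidate pool —
otherwise a history-labeled record would produce a cell with
`death > occur`, breaking the table invariant that every cell is a valid
binomial numerator/denominator pair. `include_history` defaults to `TRUE`
(the underlying cause may legitimately come from the history) and is
exposed for sensitivity analysis. CDCP carries no region index — region
enters only through RDCP — and $\alpha$ defaults to 0, the plain ratio.

## Evaluation design

`cross_validate()` runs k-fold cross-validation (default $k = 17$): records
are shuffled under a fixed seed and dealt round-robin, so fold sizes differ
by at most one; each fold is held out exactly once while the estimator is
fitted on the remaining $k-1$ folds only, so no test-fold counts leak into
training. Held-out predictions are pooled over all folds before computing
per-cause one-vs-rest precision, recall and F1 — pooling keeps metrics
defined for rare causes that would have empty cells within single folds;
per-fold averaging of the aggregates is available as an option. Because
every record receives exactly one prediction and one label, the
micro-averaged precision, recall and F1 all equal the overall accuracy;
macro averages weight causes equally, and `f1_distribution()` summarizes
how many causes clear a set of F1 thresholds.

Two reference baselines share the evaluation contract: a Bernoulli naive
Bayes over cause-presence features plus categorical age group and gender
(additively smoothed, restricted by default to the record's candidate set),
and a k-nearest-neighbour classifier under Hamming distance on the same
features (neighbour and label ties broken by distance, then label, then
record id, making it invariant to training-set order). These are
implemented as transparent reference code, not wrappers, so their decision
rules are exactly known in tests.

## The synthetic cohort generator

No death-registry data ships with the package; `generator_config()` and
`generate_cohort()` define a generative model with known structure instead:

* region, age group and gender are drawn from configurable marginals
  (defaults: 3 regions, deaths concentrated in the `old` stratum
  (5/20/75%), balanced genders);
* a chain of $L \in \{1,\dots,4\}$ *distinct* causes is drawn without
  replacement with region-specific prevalence weights (default chain-length
  distribution 5/15/30/50% — most certificates carry the full four items);
* with probability `external_fraction` (default 8%) the direct cause is
  replaced by an external-chapter code and the underlying label is set to
  it, mirroring the external-cause coding rule;
* otherwise the underlying label is sampled from chain ∪ history with
  probability proportional to a per-(cause, age group, gender) *lethality*
  parameter. This is deliberately the simplest mechanism under which
  "pick the maximal-CDCP candidate" is the Bayes decision rule, which makes
  the sink algorithm's optimality a testable property rather than an
  assumption;
* history codes (Poisson mean 0.5, truncated at 4 so records stay inside
  the fixed code universe) share the prevalence and lethality tables with
  chain codes.

Distinct-cause sampling uses the Gumbel-max trick (top-$L$ of
$\log p + $ Gumbel noise), which vectorizes weighted sampling without
replacement across the whole cohort. Unspecified prevalence/lethality
parameters are synthesized deterministically from the config seed, so a
config is a pure value and a cohort is a pure function of its config.

`induced_cdcp_oracle()` estimates, by brute-force simulation, the induced
conditional probability $P(i \text{ underlying} \mid i \text{ present},
\text{stratum})$ — the quantity CDCP actually estimates. It differs from
the raw lethality parameter because a cause's chance of being selected
marginalizes over whichever competitors co-occur with it.

**What the generator does *not* emulate**: real ICD-10 epidemiology
(disease frequencies, comorbidity correlations, chain ordering driven by
pathology), coding errors, or temporal structure. Passing tests therefore
demonstrate statistical correctness of the estimators and decision rule
under a well-specified model — not clinical performance on any real
registry.

## Numerical and design choices

* Record CSVs use a fixed comma-delimited header with `";"` separating
  history codes; string fields may not contain the delimiters. Strict mode
  aborts on the first invalid row (named, with reason); lenient mode skips
  and counts.
* Duplicate codes within a chain are rejected, not deduplicated: chain
  positions carry causal order.
* Code validation is syntactic only (letter + two digits + optional
  1–2-character suffix); dictionary membership is out of scope.
* Fitted tables serialize to versioned JSON with sorted
  `"CODE|age_group|gender"` cell keys and full-precision doubles, so
  serialize–deserialize–serialize is byte-stable.
* Cells with `occur = 0` do not exist in a fitted table (they are absent,
  not zero); zero-raw cells are dropped from `log` tables with a warning.
* Test problem sizes: the brute-force recount equivalence runs at 10,000
  records; parameter recovery fits 100,000 records against a 1,000,000-
  record Monte-Carlo oracle (RMSE ≤ 0.02 over cells with ≥ 500
  occurrences); the three-method cross-validation comparison uses 20,000
  records at $k = 17$. The Monte-Carlo self-consistency check accepts
  differences up to 0.05 on cells with ≥ 500 hits, the ~3-standard-
  deviation envelope of a binomial proportion difference at that support.

## Limitations

* The method assumes the training labels are correct; systematic coder
  bias propagates directly into the CDCP table.
* Causes unseen in training fall back to pooled estimates or the direct
  cause; performance on novel codes is necessarily heuristic.
* When no candidate on a record has pathological priority (the chain is
  causally incoherent), an argmax over marginal conditional probabilities
  cannot recover relations the data never encodes.
* The 17-fold default follows the evaluation protocol the method was
  designed under; nothing in the implementation depends on that particular
  $k$.

## A worked example

```{r}
tbl <- example_cdcp_table("male")
rec <- as_death_records(data.frame(
  record_id = "ex1", age = 77, sex = "male", region = "X",
  cause_a = "J18.9", cause_b = "I61.9", cause_c = "J98.4",
  cause_d = "A41.9"))
sink_infer(rec, tbl, external_rule = FALSE)
```

Intracerebral haemorrhage (I61.9) carries by far the largest male CDCP of
the four candidates, so it sinks the boat.
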