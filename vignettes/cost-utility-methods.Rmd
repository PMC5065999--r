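---
title: "Methods: a Markov cohort cost-utility model of adalimumab in ulcerative colitis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort cost-utility model of adalimumab in ulcerative colitis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uccea)
```

## The decision problem

Patients with moderate-to-severe ulcerative colitis (UC) who are
corticosteroid-dependent and have failed or cannot tolerate thiopurines face
three options: continue (largely ineffective) medical therapy in a
chronically unwell state, undergo proctocolectomy, or receive anti-TNF
biologic therapy. In practice many patients strongly prefer to avoid
colectomy, so where adalimumab is not available they remain chronically
unwell. `uccea` implements the decision-analytic comparison behind that
trade-off: a Markov cohort cost-utility model contrasting

* **no adalimumab** — the cohort starts 100% in *Unwell on steroids* and can
  progress only through disease-driven events (steroid complications,
  surgery, post-surgical pouchitis), versus
* **adalimumab available** — the cohort starts 100% in an induction state
  (160 mg / 80 mg, then 40 mg every other week) and responders follow a
  real-life maintenance-of-response curve,

over 3-month cycles at 5/10/15-year horizons, accumulating discounted costs
(CA$, health-system perspective: physician, hospital and outpatient drug
costs) and quality-adjusted life years, and reporting the incremental
cost-effectiveness ratio (ICER),
$\mathrm{ICER} = \Delta C / \Delta Q$.

All model inputs ship as two YAML fixtures (`uc_no_ada.yaml`,
`uc_ada.yaml`): 18 transient health states plus one absorbing death state,
per-cycle costs with ±25% uncertainty, annual utility scores with printed
±half-widths, transition rows in percent with a single complement (`#`)
entry each, and four retention curves (primary UC maintenance, two chronic
pouchitis curves, and a dose-escalated curve taken from Crohn's-disease
outpatient data). The arms share all state definitions and differ only in
the start state, the pouchitis response curve (previously-exposed patients
carry a 15% response discount, reproduced exactly by
`apply_retention_discount()` with half-up rounding to one decimal) and the
pouchitis complication row.

## Retention curves are per-cycle maintenance probabilities

The central structural decision in this reconstruction is how to read the
cycle-indexed retention tables. Two readings are possible:

1. **cumulative survival**: the value at cycle $k$ is $S(k)$, the fraction
   still responding, and the per-cycle transition is the conditional ratio
   $S(k{+}1)/S(k)$;
2. **direct per-cycle maintenance**: the value at cycle $k$ *is* the
   probability of maintaining response for one more cycle.

The shipped model uses reading 2, for three reasons. First, under reading 1
the pouchitis response rows are infeasible: the cycle-0 conditional ratio
(61.2/62.6 ≈ 0.978) plus the fixed 4.2% complication branch exceeds 1, so
the complement entry would be negative at the very first cycle. Second, the
induction row's printed response probability equals the curve's cycle-0
value, which is exactly what reading 2 implies when the curve is indexed by
time on treatment (the induction state consumes cycle 0, the response state
consumes cycle $k$ at model cycle $k$). Third, only reading 2 reproduces
the reported arm economics and the characteristic sensitivity of the ICER
to the utility elicitation; reading 1 overstates response-state occupancy
several-fold. Reading 1 remains available — `retention_to_conditional()`
implements the survival-to-probability conversion and any series entry can
be declared `mode: conditional` — and the engine supports both modes for
synthetic models.

Clock conventions follow from "rows consumed so far": the primary response
curve is indexed by model time (all patients start adalimumab at cycle 0);
the pouchitis response state is entered mid-simulation, so it is expanded
into 21 residence-indexed tunnel copies with offset 1 (its curve's cycle 0
was consumed by the entry transition from the chronic-pouchitis state); the
dose-escalated curve uses the model-time clock like the primary curve.
Rows resolve as: fixed entries keep their printed values, the series entry
contributes the curve value, and the complement takes the remainder
(clamped at zero only where a curve exceeds the available mass, which in
the shipped model can occur only at clock positions no patient occupies).
Beyond cycle 20 every curve plateaus at its cycle-20 value.

## Engine and economic conventions

`run_cohort()` propagates occupancy through per-cycle transition matrices
(rebuilt each cycle; only model-time series rows actually change), after
`expand_tunnels()` has rewritten residence-clock states. Conservation is
exact: every trace row sums to 1 within 1e-10 and death occupancy is
non-decreasing, both asserted across fixtures and random models.

Economics (`accumulate()`):

* state membership counts at cycle start; no half-cycle correction is
  applied (none is part of the original design as far as its outputs
  indicate; the convention is stated so it can be audited);
* per-cycle QALYs are `annual_utility × 0.25`;
* discounting is `(1.05)^(-k/4)` at cycle `k` — 5%/year applied
  continuously per cycle from cycle 0;
* death accrues nothing, but the transition *into* death is charged once
  with the predecessor state's per-cycle cost, at the transition cycle's
  discount factor;
* `compute_icer()` labels dominance cases instead of dividing, and reports
  dollar figures rounded to the nearest $1,000 and QALYs to three decimals,
  matching the original reporting convention.

## Dose escalation and de-escalation

Secondary loss of response is what drives dose escalation in practice, and
the scenario is modelled accordingly: at every cycle, half of the
response-state loss flow (`fraction_escalated = 0.50`) enters a
dose-escalated state instead of exiting to the unwell state. The escalated
state

* retains response per the Crohn's-disease escalation curve on the
  model-time clock, with no separate complication branch (the curve is
  real-life follow-up data in which complication-driven losses are already
  embedded);
* costs $8,884.32 per cycle — the printed response-state cost ($4,442)
  equals six 40 mg pens at $740.36, i.e. pure every-other-week drug cost,
  and escalation doubles the dosing frequency;
* carries utility 0.32 (±0.31), the value shared by every on-adalimumab
  state without an established durable response (induction, chronic
  pouchitis): escalated patients have just lost response and are being
  re-captured.

Nothing in the escalation policy sets a time: the observed mean time to
escalation emerges from the loss dynamics. The model-implied mean is ≈59.2
weeks (`analysis/02_scenarios.R` computes it), against the observed
59.3 (±70.5) weeks — a strong independent check of the loss-triggered
mechanism. De-escalation is attempted in 54% of escalated patients and
succeeds in 63% of attempts, so 34.02% return to standard-dose cost one
confirmed cycle after escalating, while keeping the escalated retention
curve. With `fraction_escalated = 0` the scenario collapses exactly to the
base case, and a 0% attempt rate collapses de-escalation to escalation
(both are tested identities).

The escalated-state cost and utility are the two genuinely free choices of
the reconstruction (no escalated cost is printed); both are plain policy
fields on `escalation_policy()` so they can be varied.

## Sensitivity analyses

**One-way (tornado).** Every state cost is varied ±25%, every utility over
its printed ±half-width clipped to [0, 1], and every fixed transition
probability over its printed 95% CI — or ±25% relative when no CI is
printed, clipped to the simplex (if a varied row's complement would go
negative, the other fixed entries are rescaled proportionally).
Arm-specific probabilities without a CI are varied by the same relative
amount around each arm's own printed value. Each bound re-runs the full
incremental analysis; entries are ranked by ICER spread. The response-state
utility has no printed half-width of its own; it uses ±0.21, the half-width
printed for the identical elicitation value of the steroid-response state.

**Probabilistic.** Only costs and utility scores are sampled (probabilities
stay at base, as in the original design): normal for costs with
`sd = 0.25·mean/1.96` truncated at 0; beta by moment matching for utilities
≥ 0.4; for utilities below 0.4 (0.16, 0.32, 0.37) the decrement `1 − u` is
gamma by moment matching, with samples clipped to [0, 1]. The 0.4 cut makes
the qualitative "close to zero" rule explicit. Printed half-widths are read
as 95% intervals. Because probabilities are fixed, the cohort trace is
draw-invariant and each draw just re-prices two per-state discounted
exposure vectors — exact, and fast enough for 10,000 draws in well under a
second (equality with literal re-runs is tested). Draws are sampled
**independently per arm**: with fully shared draws the acceptability curve
is far too steep (it would exceed 80% at $100k/QALY), whereas independent
per-arm sampling — the behaviour of per-strategy distribution objects in
common decision-tree software — reproduces the reported curve closely.
`share_draws = TRUE` exposes the alternative. The CEAC reports, for each
willingness-to-pay λ, the fraction of draws with positive net monetary
benefit λ·ΔQ − ΔC.

Default problem sizes: 10,000 PSA draws with a mandatory seed;
acceptability curves on a $0–200k grid in $5k steps.

## Synthetic models and the microsimulation oracle

`generate_model()` produces random, structurally valid cohort models
(arbitrary graphs, complement-resolved rows on the simplex, optional
residence-clock retention dynamics in either series mode, guaranteed death
reachability, deterministic per seed) with costs and utilities drawn from
the realistic ranges of the disease model ($0–37,159/cycle, 0.16–0.82).
`microsimulate()` is the independent estimator: it samples individual
patient trajectories from the same resolved per-cycle probabilities and
accrues discounted costs (including the one-time death charge) and QALYs
per patient. Cohort engine and microsimulation agree within 3 standard
errors on both fixture arms (100,000 patients) and on batches of random
models — this is the package's main defence against wiring errors, since
the two estimators share only the row-resolution code.

The generator emulates the *structure* of cohort models, not UC biology:
random graphs have no clinical pathway logic, and the disease model itself
omits background age/sex mortality (no life table is part of the design),
concomitant immunosuppressant therapy, and switching between anti-TNF
agents. Passing tests therefore certify the engine and accounting, not the
clinical realism of any particular input set.

## Numerical choices and limitations

* Probabilities are stored in percent exactly as printed and converted at
  resolution time; fixture diffs against the source tables are one-to-one.
* Rounding of the 15%-discounted pouchitis curve is half-up (38.25 → 38.3),
  which is what the printed curve uses; `round_half_up()` exists because
  base R rounds half to even.
* Conservation tolerance 1e-10 on trace rows; complement feasibility is an
  error, not a warning, for fixed-entry rows.
* The reconstruction reproduces reported base-case arm totals to within
  1–5%, all twelve base and scenario ICERs within their stated tolerances,
  and the acceptability probabilities within 1–2 points; residual
  differences trace to the undocumented wiring details discussed above
  (discount timing, the escalated-state economics, and the exact state
  graph, which is reconstructed from the transition tables rather than a
  printed diagram).

```{r example, eval = FALSE}
run_analysis(analysis_request(horizon_years = 10, response_utility = 0.79))
make_table1("base", with_ranges = FALSE)
```
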