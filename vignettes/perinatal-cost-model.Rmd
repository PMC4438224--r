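---
title: "Modeling the short-term costs of gestational diabetes, maternal overweight, and macrosomia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the short-term costs of gestational diabetes, maternal overweight, and macrosomia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perinatalcosts)
```

## The problem

Gestational diabetes mellitus (GDM) — hyperglycemia first diagnosed during
pregnancy — and pre-pregnancy maternal overweight both raise the risk of
fetal macrosomia (birth weight above 4,000 g) and of a cluster of
perinatal complications for mother and child: cesarean delivery, shoulder
dystocia, preeclampsia, neonatal hypoglycemia and hyperbilirubinemia, NICU
admission, and others. Each of these events carries a payer cost on top of
a routine pregnancy and vaginal delivery.

`perinatalcosts` implements a decision-analytic framework for the
short-term (pregnancy and delivery) healthcare costs of these conditions:
per-case expected costs by arm (normal, GDM, overweight), a national
budget-impact translation, and one-way deterministic sensitivity analysis.
Cost horizons beyond delivery are handled by a generic Markov cohort
engine. The perspective is the national payer's; utilities, QALYs and
long-term sequelae are out of scope.

## Model structure

### Decision tree with mother/child cost pairs

The computational object is a rooted tree of decision, chance, and
terminal nodes. Chance-node branches carry probabilities (summing to 1
within $10^{-9}$; one branch may be declared `"complement"` and is
resolved to the residual, since clinical tables print event probabilities
only, never the no-event branch). Costs accrue both on edges (where an
event happens) and on terminal payoffs, always as a mother/child pair, so
any aggregate can be reported in the mother / child / total layout.

The expected cost of an arm is the probability-weighted sum over all
root-to-leaf paths, computed by recursive rollback:

$$E[C] \;=\; \sum_{\text{paths } \pi} \Big(\prod_{e \in \pi} p_e\Big)
             \Big(\sum_{e \in \pi} c_e + c_{\text{leaf}}\Big).$$

Decision nodes are evaluated under an *explicit* arm selection — there is
no cost-minimizing auto-selection, because the comparisons the model
supports are descriptive, not optimizing.

Every rollback is cross-checkable against an independent oracle,
`enumerate_paths()`, which walks all paths exhaustively (refusing trees
beyond $10^6$ paths) and must agree with the rollback within $10^{-9}$.
The test suite enforces this on 200 seeded random trees from
`random_tree()`, along with path-probability conservation, linearity of
the expected value in costs, and invariance under zero-probability or
split branches.

### Arm construction: calibrated and mechanistic modes

The exact branch wiring behind the published per-case totals cannot be
reconstructed from the available description of the tree figure, so arms
are built in one of two modes:

* **Calibrated** (default when calibration rows are present): the arm is
  a single terminal carrying the configuration's printed per-case
  mother/child totals — Normal \$7,790 / \$0, GDM \$11,794 / \$3,799,
  overweight \$13,047 / \$5,243. All downstream results (incremental
  costs, budget impact, sensitivity) then reproduce the published base
  case exactly. This is the mode used for reproduction.
* **Mechanistic**: the arm is a transparent chain of binary chance nodes,
  one per complication, with the macrosomia split (macrosomic vs normal
  child) placed first; every path accrues the routine delivery cost plus
  the unit costs of the complications that occur. Because the
  complications enter as independent marginal events, the rollback value
  is exactly

  $$E[C] = c_{\text{routine}} + \sum_i p_i \, c_i ,$$

  which the suite verifies by the dual route (tree rollback vs direct
  $\sum p_i c_i$). Independence is the minimal assumption available: the
  sources report marginal probabilities only, never joint distributions,
  and any tree wiring with the same marginals has the same expectation.

The mechanistic GDM arm defaults to the *untreated* (control) mild-GDM
probability table — the conservative choice, and the one consistent with
the published framing — with the treated table selectable via
`gdm_source = "gdm_treated"`. The mechanistic GDM total (\$15,243 with the
shipped tables) lands close to, but not exactly on, the calibrated
\$15,593; the gap is expected since the published totals embed wiring
details and possibly conditional cost readings that the printed tables do
not pin down. The overweight arm does not nest a GDM sub-branch: the two
conditions are costed separately.

### Parameters

All parameters live in one validated `model_config` bundle, read from
YAML/JSON (`load_config()`) or from the packaged US 2011 fixture
(`builtin_paper_parameters()`):

* **Complication probabilities** per arm (`gdm_treated`, `gdm_untreated`,
  `obese`, `non_obese`, `normal`), keyed by the cost table's own item
  names. Percent notation (`"14.30%"`) is accepted and normalized to
  proportions at parse time. Statistical-significance flags (S/NS) are
  stored as metadata only; non-significant differences still enter as
  point estimates.
* **Unit costs** (USD, 2011): 28 items plus the routine normal
  pregnancy/vaginal delivery cost of \$7,790. Zero-cost items (maternal
  anemia, stillbirth, weight gain, hydramnion, body mass) are deliberate.
* **Odds ratios** for the macrosomia treatment effect are shipped but
  *not* applied in the base case — the probability tables already
  distinguish treated from untreated, and applying the OR on top would
  double-count the treatment effect. `or_to_probability()` exposes the
  opt-in conversion $p = \mathrm{OR}\,b \,/\, (1 - b + \mathrm{OR}\,b)$.
* **Delivery-strategy probabilities** (elective induction, elective
  cesarean, expectant management, for an estimated fetal weight of
  4,500 g) are stored for strategy-level analyses.
* **Population**: US population 313,847,500, pregnancy rate 13.68 per
  1,000, GDM incidence 5.5% (a deliberately conservative incidence pick
  at the bottom of the 4–7% Caucasian range).

Two naming choices deserve a note. First, outcome names from the source
cohorts map onto cost-item keys via a documented alias table; for the
obese-mother outcomes without an exact key we map insulin-treated diabetes
to `Mother_gdm`, other (diet-treated) diabetes to `Mother_gest`, chronic
hypertension to `Mother_hypertension`, and eclampsia to `Mother_PIH` —
treatment-similarity readings, each worth revisiting with country-specific
costing. Second, the combined "preeclampsia or gestational hypertension"
column is kept as metadata only, since costing it alongside plain
preeclampsia would double-count. The much higher shoulder-dystocia
probability reported for macrosomic deliveries (14.5%) ships as an
override flagged off by default; whether it should replace the untreated
arm's 4.0% is genuinely ambiguous in the sources. Perinatal mortality
attributable to GDM management has no published point value in the cost
sources, so it defaults to zero rather than inventing a number; stillbirth
and intrauterine demise enter as cost events only (no life-years).

### Markov follow-up engine

Post-delivery follow-up is a discrete-time Markov cohort model:
`occupancy[t] = initial × P^t`, with discounted cost
$\sum_t \mathbf{o}_t \cdot \mathbf{c} \,/\, (1+r)^t$ accumulated over the
cycles lived (state membership costed at the start of each cycle; an
optional half-cycle correction weights the first and last time points by
one half and is off by default). Because no long-term results are being
reproduced, the engine is deliberately generic: states, transitions, and
costs are caller-supplied, with defaults of 1-year cycles, a 20-cycle
horizon, and a 0% discount rate. The test suite pins it to the
closed form $(1-p)^n$ for two-state absorbing chains within $10^{-12}$
and checks occupancy conservation on random chains; the illustrative
chain (4%/year conversion to diabetes leaving $0.96^{17} \approx 0.50$ of
a GDM cohort diabetes-free after 17 years) is a plausibility fixture,
not a reproduction target.

### Budget impact

The national annual burden chains

$$\text{pregnancies} = \frac{\text{population} \times \text{rate}}{1000},
\qquad \text{cases} = \text{pregnancies} \times \text{incidence},
\qquad \text{BIA} = \text{cases} \times \Delta C,$$

with $\Delta C$ the per-case incremental cost of the condition arm versus
the normal arm. With the shipped configuration: 4,293,433.8 pregnancies,
236,138.859 cases (displayed 236,139), $\Delta C = \$15{,}593 - \$7{,}790
= \$7{,}803$, giving \$1,842,591,517 — the "more than \$1.8 billion"
headline. Case counts stay unrounded internally; rounding
(half-away-from-zero, matching the printed whole-dollar style) happens
only in display fields, because the published sensitivity cells are only
consistent with unrounded intermediates.

One discrepancy is documented rather than chased: the published
sensitivity table's base cell (\$1,842,525,634) implies an unrounded
per-case incremental of about \$7,802.72 that is not recoverable from the
printed components; the value computed here differs by $3.6\times10^{-5}$
relative and satisfies the headline claim either way.

### One-way sensitivity analysis

Five parameters are varied one at a time by a relative delta (default
±20%, the published variation chosen for lack of statistical
distributions):

| parameter | semantics |
|---|---|
| `incidence` | scales the condition incidence; per-case cost untouched |
| `condition_total_cost` | scales the condition arm's total; reference fixed |
| `normal_pregnancy_cost` | scales the reference (routine) cost only |
| `child_complication_cost` | scales the child component of the condition arm |
| `mother_complication_cost` | scales the mother component of the condition arm |

These semantics were chosen to match the internally consistent published
cells: incidence ±20% leaves the per-case cost at \$7,803 and scales the
BIA by exactly 0.8/1.2, and condition-cost −20% gives
$0.8 \times 15{,}593 - 7{,}790 = 4{,}684.4$, printing \$4,684. At +20%
the computation from rounded printed inputs gives \$10,922 against a
printed \$10,921 — again a sign of unrounded internals upstream, flagged
and not chased. Several remaining published rows appear misaligned as
printed (the "normal pregnancy" block shows ±20% of the *incremental*
cost, and the "baby" and "mother" blocks match the mother and child
components respectively, i.e. apparently swapped, with BIA-column cells
holding per-case values); the package implements the consistent semantics
above and leaves those cells out of its exact assertions.
`tornado_order()` ranks parameters by the spread
$|{\rm BIA}(+\delta) - {\rm BIA}(-\delta)|$, ties alphabetical; the
condition arm's total cost dominates incidence by construction, since
$0.4\,C_{\rm total} N > 0.4\,(C_{\rm total}-C_{\rm normal})\,N$.

## Numerical choices and degenerate inputs

* Probabilities are proportions in $[0,1]$ internally; chance-node sums
  are validated to $10^{-9}$; transition-matrix rows likewise.
* All arithmetic is double precision throughout; dollar rounding
  (half-away-from-zero) is applied only when printing.
* Validation is collecting, not fail-fast: `validate_tree()` reports
  every violation (bad sums, negative costs, childless chance nodes,
  duplicate ids), and `expected_value()` refuses unvalidated-invalid
  trees. Structural malformations (a child that is not a node) raise
  immediately with the offending id.
* `random_tree()` draws branch probabilities uniformly and normalizes,
  so generated trees are always valid; it generates chance/terminal
  nodes only, keeping every generated tree evaluable without a decision
  selection, and restores the caller's RNG state.
* Degenerate inputs behave linearly: zero incidence gives a zero budget
  impact, an empty probability table costs the routine delivery only, a
  zero-cycle Markov run costs nothing, and an all-zero sensitivity table
  falls back to alphabetical tornado order.
* Scenario deltas must exceed −1; a scenario that would push incidence
  above 1 is refused.

## What the synthetic generator does and does not emulate

`random_tree()` exercises the engine's *arithmetic* — arbitrary depths,
branching factors, probability profiles and cost magnitudes — under a
fixed seed, which is exactly what the rollback/enumeration equivalence
needs. It does not emulate the *clinical structure* of real pregnancy
arms (no correlation between events, no macrosomia-conditional
complication rates, no cost pairing between mother and child sides), so
passing the property suite demonstrates numerical correctness of the
engine, not epidemiological fidelity of any particular tree. Fidelity to
the published base case rests on the fixture tables and the calibrated
arms instead.

## Problem sizes

All computations are desk-scale. The test suite's heaviest pieces are the
200-tree oracle sweep (depth ≤ 5, branching ≤ 4, ~1,000 paths each,
run twice), the mechanistic GDM arm (13 complication events, $2^{13}$
paths), and 100 random Markov chains over 25 cycles — seconds each on one
CPU; the whole suite runs in a few minutes and the acceptance script in
under ten seconds.

## Known limitations

* Short-term only: no long-term maternal diabetes or child obesity
  costs, no QALYs, no discounted life-years — the Markov engine is
  scaffolding for such extensions, not a calibrated model.
* US 2011 costing only; results do not transfer across countries, and no
  currency/inflation adjustment is provided.
* The mechanistic mode treats complications as independent; real joint
  distributions (e.g. cesarean given macrosomia) are not represented
  because no joint data are shipped.
* Whether the published GDM child cost is conditional on macrosomia or
  averaged over all GDM births is ambiguous; calibrated mode sidesteps
  the question and mechanistic mode documents the averaged reading.
* A single-condition budget impact; summing the GDM and overweight
  burdens would double-count the overlap between the two populations.
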