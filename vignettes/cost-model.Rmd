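---
title: "An expected-cost decision model for OSA diagnostic pathways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An expected-cost decision model for OSA diagnostic pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apneacost)
```

## The problem

A symptomatic patient is referred for suspected obstructive sleep apnea
(OSA) with pretest probability $P$ of disease. The clinic can diagnose
with attended in-laboratory polysomnography (PSG, Level I), with an
unattended full polysomnogram at home (Level II, "LII"), or with a
limited-channel home study (Level III, "LIII"), and may chain these.
`apneacost` compares four fixed strategies on a single outcome measure,
the **expected cost per patient evaluated**:

1. **PSG first** — everyone gets a PSG.
2. **LII first** — everyone gets an LII; a technical failure is followed
   by a PSG.
3. **LIII then PSG** — everyone gets an LIII; negatives, positive CPAP
   nonresponders, and technical failures are worked up with PSG.
4. **LIII then LII** — as above, but the first follow-up study is an LII
   (falling back to PSG if the LII fails).

Each strategy is a pure chance tree: there are no decision nodes inside a
strategy, because the comparison is between fixed policies. The expected
cost is
$$ \mathbb{E}[\text{cost}] \;=\; \sum_{\text{terminal states } s} \Pr(s)\, c_s , $$
with $\Pr(s)$ the product of branch probabilities from root to leaf and
$c_s$ the accumulated study and CPAP-trial costs on that path. Every
branch probability is linear in $P$ and no path crosses two
$P$-dependent branches, so each strategy's expected cost is **affine in
$P$** — the property the crossover and break-even solvers rely on, and
one the test suite verifies directly.

## Model assumptions

* PSG is the gold standard: 100% sensitive and specific, never fails
  technically.
* An LII is as accurate as PSG but is nondiagnostic with probability
  $J$; after a failed LII the patient gets a PSG (failures do not
  recur).
* An LIII has sensitivity $F$, specificity $G$, and fails technically
  with probability $E$; on failure the patient enters the strategy's
  fallback modality as a complete sub-algorithm (the PSG-first pathway
  in strategy 3, the LII-first pathway in strategy 4), having sunk the
  LIII cost $I$.
* Patients diagnosed with OSA start CPAP (trial cost $D$, charged
  exactly once per path on which CPAP is started). A fraction $A$ do
  not tolerate or improve.
* Because the model targets **symptomatic** patients, every
  LIII-negative patient receives a confirmatory study — a false
  negative must not be missed. False negatives then start CPAP; true
  negatives exit after the confirmatory study. False positives fail
  their CPAP trial, receive one confirmatory study, and exit; they
  never loop.
* Nonresponder follow-up: after a diagnosis made by PSG or LII
  (including LIII false negatives confirmed by the follow-up study), a
  fraction $B$ of nonresponders need one repeat titration PSG. After a
  diagnosis made directly by a positive LIII, a fraction $H$ need a
  single follow-up study and $1-H$ need two (diagnostic + titration).
  At the default values $B = 1 - H = 0.4$, so the two conventions
  coincide numerically; we fix the reading above because it matches the
  wording of the parameter definitions, and note that data
  distinguishing the two would be needed to tell them apart.

## Parameters

All eleven parameters (letters are the conventional aliases accepted
everywhere in the package) with their British Columbia base-case
defaults; costs are 2020 fee-schedule values in Canadian dollars, but
the engine treats currency as unitless:

```{r}
default_parameters()
```

Proportions may sit at 0 or 1 exactly — the trees degenerate but remain
well defined, which the limit-case tests exploit (a free, perfect,
never-failing LIII; an LII priced like PSG with $J=0$).

## Worked base case

```{r}
cmd_evaluate(0.5)
```

The least-cost frontier over $P$ switches exactly once, from LII-first
to LIII-then-LII:

```{r}
sw <- sweep_costs(default_parameters(), seq(0, 1, by = 0.01))
range(sw$pretest_prob[sw$cheapest == "l2_first"])
crossover_probability("l2_first", "l3_then_l2")
crossover_probability("psg_first", "l3_then_psg")
```

PSG-first and LII-first never cross: both curves have slope
$C\,A\,B$ in $P$, separated by the constant $K + JC - C$, so the solver
reports the crossover as absent rather than erroring.

Break-even analysis solves for the parameter value equating two
strategies at fixed $P$:

```{r}
breakeven_parameter("l2_cost", "psg_first", "l2_first",
                    scenario(pretest_prob = 0.5), c(0, 1000))
```

Break-even money values are reported both exact and to the nearest $10,
the resolution at which such fee thresholds are typically quoted.

## Numerical choices

* **Exact evaluation.** Expected costs come from full terminal-state
  enumeration (depth-first, declared branch order), not simulation.
  Each chance node's branch probabilities must sum to 1 within an
  absolute tolerance of 1e-9; a violation is an error, never a warning,
  because it always indicates a malformed tree rather than noise.
* **Root-finding.** Crossovers and break-evens use bracketed Brent
  iteration (`stats::uniroot`) to an absolute tolerance of 1e-6 in the
  unknown. The cost curves are affine (in $P$) or affine/piecewise
  monotone (in cost parameters), so bracketing is robust and no
  derivatives are assumed. A bracket without a sign change yields an
  explicit "absent" result.
* **Ties.** The least-cost strategy at a sweep point is the first
  minimizer in the fixed order `psg_first`, `l2_first`, `l3_then_psg`,
  `l3_then_l2`.
* **Display rounding.** Dollars round half-away-from-zero to the
  nearest dollar; probabilities display at 3 decimals; break-even money
  additionally to the nearest $10. Unrounded values are always carried
  alongside.
* **Cohort savings.** The headline "savings per 1000 patients" figure
  uses per-patient costs rounded to the nearest dollar *before*
  differencing (policy `"per-patient-nearest-dollar"`); the `"exact"`
  policy is available and differs (171,750 vs 171,000 at the base
  case).

## The Monte Carlo simulator as an oracle

`simulate_cohort()` is not the engine — it is a deliberately separate
implementation used to verify the engine. Each patient is pushed through
the pathway **event by event**: disease status $\sim$ Bernoulli($P$),
initial-test technical failure, LIII result given disease status, CPAP
response, follow-up need, follow-up LII failure. Every patient owns one
uniform draw per event slot in a fixed order, so results are independent
of patient processing order; per-patient cost is the exact sum of the
event costs, with no variance-reduction tricks. The simulator shares
only outcome-label strings with the tree builders, so agreement of its
mean with `expected_cost()` (the suite demands agreement within
3.29 standard errors at $n = 200{,}000$, a 99.9% band, at
$P \in \{0.2, 0.5, 0.8\}$ for all four strategies) and of its
terminal-state frequencies with the analytic path probabilities (within
$4/\sqrt{n}$ in sup-norm at $n = 100{,}000$) is a genuine structural
cross-check of both codes.

What the simulator emulates is exactly the model: independent patients,
Bernoulli events with the stated rates, costs attached to events. It
does not emulate features of real cohorts — correlated comorbidity,
capacity constraints, waiting times, repeat technical failures, CPAP
adherence drift — so passing these tests shows the two implementations
agree on the model, not that the model matches any clinic.

Problem sizes in the shipped test suite (100 random parameter draws for
normalization, 50 for the closed-form identity, cohorts of 1e3–2e5 for
the stochastic checks) were chosen so the whole suite exercises every
property at tight tolerances while remaining quick to run routinely.

## Design decisions that were genuinely open

* **Failure routing.** An LIII technical failure enters the fallback
  modality as a *complete* sub-algorithm (including its own failure
  handling in strategy 4), rather than a single rescue study. This is
  the reading consistent with the strategies' definitions and with all
  the base-case results.
* **Confirmatory studies for all negatives.** In a rule-in population,
  true negatives cannot be distinguished from false negatives without a
  confirmatory study, so both pay for one. Dropping confirmation for
  true negatives would change the LIII strategies' intercepts
  substantially.
* **First-follow-up substitution in strategy 4.** Only the *first*
  follow-up study becomes an LII; any additional titration study
  remains an in-laboratory PSG, matching the parameter definitions
  ("require an additional PSG").
* **Functions, not numbers, in the trees.** Branch probabilities are
  functions of the scenario and terminal costs functions of the
  parameters, so one built tree serves every parameter value — this is
  what lets the break-even solver vary any field without rebuilding
  logic.

## Known limitations

The model is a cost comparison only: no utilities or QALYs, no
discounting, no Markov cycling, no physician follow-up or travel costs,
no modelling of adherence over time, and no currency conversion. One-way
sensitivity is deterministic; there is no probabilistic sensitivity
analysis over parameter uncertainty. These are boundaries of the model,
not of the implementation.
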