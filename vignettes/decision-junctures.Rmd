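---
title: "Multilevel decision junctures: model, identification and Monte Carlo design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel decision junctures: model, identification and Monte Carlo design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(junctures)
```

## The problem this package addresses

Whether an evidence-based intervention such as cognitive behavioural
therapy (CBT) helps patients depends not only on the intervention itself
but on a chain of decisions made on the way to the patient: a health
organization decides whether to adopt the programme at all, then which
implementation strategy to fund; practitioners form perceptions of the
programme's feasibility and appropriateness and decide, patient by
patient, whether to assign the treatment. Routine (non-experimental) data
collected from such a system are shot through with self-selection at every
one of these *decision junctures*: organizations that adopt differ
systematically from those that do not, practitioners who assign treatment
differ from those who do not, and naive comparisons of treated and
untreated patients confound implementation effects with case mix.

`junctures` models such a system explicitly as a structural causal model
(SCM) on a directed acyclic graph, uses graphical identification theory
(d-separation and the back-door criterion) to derive which covariate sets
suffice to estimate each effect of interest, simulates the full
multilevel system, and verifies by Monte Carlo that the resulting
regression estimators recover the true effects.

## The decision-juncture model

Each decision is a binary latent-utility threshold: a decision maker
facing observed inputs $x$ and unobserved inputs $\varepsilon$ chooses

$$ d = \mathbf{1}\left[\alpha + \beta' x + \varepsilon > 0\right],
   \qquad \varepsilon \sim N(0, 1). $$

The standard-normal error makes probit regression the correctly specified
estimator of the decision index — the scale of $\varepsilon$ is not
separately identified in threshold models, so fixing it to 1 is the usual
probit normalisation. Continuous variables follow linear structural
equations $y = \alpha + \beta' x + \varepsilon$, $\varepsilon \sim
N(0,\sigma)$; deterministic aggregates (the total anticipated cost
$W = W_1 + W_2$) are computed exactly.

### The canonical CBT system

`canonical_cbt_model()` encodes a hypothetical CBT implementation system
with 20 variables on three hierarchy levels (40 organizations × 5
practitioners × 30 patients = 6000 patients):

| symbol | level | meaning |
|---|---|---|
| Z1, Z2, Z3 | organization | networks, management style, structure |
| B1 | organization | perceived evidence of effectiveness |
| W1, W2, W | intervention | anticipated strategy costs and their sum |
| D1 | organization | adopt CBT at all (the *selection* juncture) |
| D2 | organization | enhanced vs. standard implementation strategy |
| X1, X2, X3 | practitioner | age, perceived leadership, tenure |
| X4, X5 | practitioner | perceived feasibility / appropriateness |
| T1 | patient | practitioner assigns treatment |
| V1, V2, V3 | patient | age, gender, socio-economic status |
| Y1, Y2 | patient | baseline and follow-up outcome score |

Arrows run Z/B/W → D1, D2; D2 → X4, X5; X4, X5 (with Z1, X2, X3 and case
mix V1, V2, Y1) → T1; and T1, V1, V2, V3, Y1 → Y2. Management style and
perceived leadership share unobserved correlated errors (Z2 ↔ X2,
correlation 0.5), the one bidirected edge of the system.

Several encoding choices were genuinely open and are fixed here as
package design decisions:

* **Edge list.** The variable list and several parent statements are
  given for the system (e.g. Z1 and W1 are parents of D2; Z1 and X2
  identify the strategy effects; Z1, X2, X5 identify the feasibility
  effect; V1, V2, Y1 are needed for the treatment effect while X3, V1,
  V2, Y1 are precision-only for X4 → T1), but not a complete edge
  enumeration. The canonical edge list is the minimal structure
  satisfying *all* of those statements simultaneously; `validate_claims()`
  re-certifies every one of them against the encoded DAG, so the encoding
  is checked rather than assumed. X2's confounding of the D2 effects
  travels through the correlated error Z2 ↔ X2 into D2's parent Z2 —
  the minimal mechanism that makes perceived leadership a genuine
  confounder. X1 (practitioner age) has no documented identification
  role; it enters X4 and X5 only.
* **Coefficients.** Structural coefficients are not published with the
  system description; defaults are moderate effects (decision-index
  coefficients 0.3–0.5, strategy effects D2 → X4 = D2 → X5 = 0.5,
  feasibility/appropriateness index effects 0.4 / 0.3, treatment effect
  T1 → Y2 = 1.0, baseline-score carry-over 0.5, all confounder paths
  0.3), chosen once so that omitted-confounder negative controls show
  clearly visible bias while every decision probability stays interior
  (≈ 0.5 on average, so both branches of every juncture are populated).
  Cost terms carry economic signs: the aggregate cost W discourages
  adoption (−0.3 in D1), and the enhanced strategy's own cost W2
  discourages choosing it (−0.3 in D2) while the alternative's cost W1
  encourages it (+0.3).
* **Hierarchy.** 40 × 5 × 30 reaches exactly 6000 patients while keeping
  a realistic, deliberately small organizational sample — the strategy
  effects D2 → X4/X5 vary at organization level only, and their larger
  Monte Carlo variability is a feature of the design, not an accident.
* **Selection.** Organizations with D1 = 0 do not participate in any
  later juncture. The simulator encodes this as missing-by-selection
  (`NA`) rather than dropping rows, so negative-control analyses on the
  full table remain possible; every identification query conditions on
  D1 implicitly, because post-selection data exist only where D1 = 1.

## Identification machinery

`d_separated()` implements d-separation by the ancestral-moralization
reduction; bidirected edges are expanded internally into fresh latent
parents (which are never eligible for adjustment), reducing their
semantics to ordinary d-separation. `is_valid_backdoor()` checks the
back-door criterion — no conditioning variable descends from the
treatment, and the set blocks every path into the treatment once its
outgoing arrows are removed — always adding the selection node to the
conditioning set. `minimal_adjustment_sets()` enumerates *all*
inclusion-minimal valid sets: because candidates can be restricted to
ancestors of treatment, outcome or selection node, validity reduces to
monotone vertex separation in a single moralized graph, where necessary
members can be detected by single-node removal and the remaining subsets
enumerated smallest-first with superset pruning. Output ordering is
deterministic (lexicographic) so results are stable across runs.

On the canonical system the enumeration finds, conditioning on D1:

* D2 → X4 (and X5): `{X2, Z1}` and `{Z1, Z2}` — the documented set
  `{Z1, X2}` is minimal, and management style can substitute for
  perceived leadership because the confounding travels through their
  shared error;
* X4 → T1: `{X2, X5, Z1}` and `{D2, X1, X2, Z1}` — the documented set is
  again minimal; X3, V1, V2, Y1 appear in no minimal set (they are pure
  precision covariates);
* T1 → Y2: `{V1, V2, Y1}`, uniquely.

## Simulation and sample-specific truth

`draw_population()` samples in topological order with one RNG stream per
draw (`population_config(seed = )` fixes everything). The correlated pair
is drawn jointly: practitioner-level X2 inherits its organization's Z2
value scaled by the error correlation plus idiosyncratic noise, giving
exactly the configured correlation while retaining within-organization
variance; organization-level context otherwise reaches practitioners and
patients through the structural equations themselves.

True effects are *sample-specific*: `true_sample_effects()` replays the
structural equations under interventions with every error draw held fixed
(abduction–action–prediction), over the eligible (D1 = 1) population. For
linear children the replayed average treatment effect equals the
structural coefficient exactly; for the treatment-assignment probability
the average marginal effect is the derivative of the threshold-crossing
probability at the observed covariates, `mean(dnorm(index)) * coefficient`
(a finite-difference oracle reproduces it to 10⁻⁶ in the tests).

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: non-normal errors, measurement error,
time-varying covariates, repeated implementation cycles or
quality-improvement feedback, patient non-compliance, and interference
between patients. Correlated errors are supported for exogenous variable
pairs, which covers the canonical system's single bidirected edge.

## Estimation

`build_specification()` produces the two regression specifications
compared throughout: *short* adjusts only for a back-door-minimal set
(the documented set when valid on the encoded DAG, else the
lexicographically first minimal set — a deterministic tie-break), *full*
adds all remaining parents of the outcome. Estimation uses eligible
(D1 = 1, complete-case) rows only, mirroring observability.

Continuous outcomes are fitted by least squares (QR, with aliased-column
detection); binary outcomes by probit maximum likelihood (IRLS, then
Fisher-scoring refinement until the score norm is below 10⁻⁸, at most
200 iterations, with perfect-separation detection). The reported effect
for a binary outcome is the average marginal effect, matching the
probability-scale definition of the replayed truth; its standard error
composes the AME gradient with the coefficient covariance by the delta
method. When the treatment varies at organization level the coefficient
covariance is a cluster sandwich with the small-sample factor G/(G−1)
(40 clusters is moderate; heavier corrections are not attempted);
otherwise the linear fits use an HC1 heteroskedasticity-robust sandwich
and the probit fits the inverse observed information.

## Monte Carlo design

`run_mc()` repeats draw → truth → fit over the eight
estimand × specification pairs. Per-repetition seeds are derived once
from the master seed and stored, so repetitions are order-independent and
individually reproducible. Degenerate repetitions (e.g. a constant
treatment among the ~20 implementing organizations, probability ≈ 10⁻⁶
per repetition at the defaults) are recorded and excluded, never
resampled; more than 1% of failures aborts the run. `summary()` reports,
per pair, the mean of per-repetition relative biases
$(\hat\theta_r - \theta_r)/\theta_r$, their empirical standard error, and
the 95% interval mean ± 1.96 · SE/√R; the ratio-of-means alternative
(mean estimate over mean truth, minus one) is reported as a secondary
column since either aggregation is defensible.

The package default is R = 1000 repetitions (used by the test suite and
the acceptance script; roughly 2–4 minutes of desk-scale computation),
with larger R available via the `reps` argument or the CLI `--reps` flag.
One consequence worth stating plainly: the organization-level estimands
have per-repetition relative-bias standard deviations around 0.46 (their
effective sample is ~20 implementing organizations), so at R = 1000 the
Monte Carlo noise floor on their *mean* relative bias is about 1.45
percentage points. A measured mean within ±1% for those two estimands is
therefore expected but not guaranteed at this R even for an exactly
unbiased estimator; at R = 10000 the floor drops to ≈ 0.46 points. The
patient-level estimands sit far below the floor either way.

## Numerical choices and degenerate inputs

* Probit convergence: score-norm tolerance 10⁻⁸, ≤ 200 iterations;
  non-convergence and separation raise classed errors rather than
  returning garbage.
* Exact collinearity raises an error naming the offending columns; a
  treatment constant in the eligible sample is caught the same way.
* A repetition with any zero true effect makes relative bias undefined;
  `summarize_mc()` refuses with an instruction to change coefficients
  (the defaults keep all truths ≥ 0.08 in magnitude).
* Zero implementing organizations is a *valid* draw (fully masked
  downstream tables) for simulation and serialization, but no
  post-selection estimand is then defined.
* Dataset bundles store retained error draws and pre-masking values of
  gated nodes, so potential-outcome replay survives a round trip;
  values round-trip to at least 12 significant digits.

## Known limitations

Identification support covers back-door adjustment (with selection
conditioning) only — no front-door or instrumental-variable
identification, and no cyclic/feedback structures. The estimand roster is
the canonical system's five effects; other systems can be simulated and
fitted through the same surface, but `true_sample_effects()` expects the
canonical estimands to exist. Minimal-set enumeration is exhaustive over
an ancestrally restricted pool, entirely adequate at 20 nodes but not
intended for graphs with hundreds of vertices.
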