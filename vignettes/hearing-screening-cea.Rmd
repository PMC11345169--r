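---
title: "Methods: decision-tree cost-effectiveness analysis of newborn hearing screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decision-tree cost-effectiveness analysis of newborn hearing screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hearcea)
```

## The decision problem

Universal neonatal hearing screening programs must choose a first-line test.
Otoacoustic emission (OAE) is fast and cheap but measures only cochlear
function and refers many healthy newborns; a portable automated auditory
brainstem response device (P-AABR) measures the neural pathway directly,
costs more per screen, and refers far fewer false positives. Every referral
triggers a long, expensive confirmatory brainstem evoked response audiometry
(BERA) assessment, and every missed case carries a lifetime of reduced
quality of life. `hearcea` quantifies this trade-off as a decision-tree
cost-effectiveness analysis over a one-year screening horizon with lifetime
QALY consequences.

## Model structure and assumptions

Each strategy propagates a cohort of `N` newborns with hearing-loss
prevalence `p` through four branches — screen true positive (A), screen false
negative (B), screen false positive (C), screen true negative (D) — with
referral of branches A and C to BERA. The structural assumptions are:

- **Terminal screen-negatives.** A newborn who passes the screen receives no
  further testing, cost, or chance of detection within the model.
- **Conditional independence.** Screen and confirmation outcomes are
  independent given true hearing status; this is the decision tree's implicit
  factorization and the Monte-Carlo simulator draws from exactly this model.
- **Single-visit cascade.** One screening visit per newborn and one
  confirmation visit per referral; repeat-screen protocols (e.g. two-stage
  TEOAE at three weeks) are out of scope.
- **Perfect gold standard by default.** BERA defaults to sensitivity =
  specificity = 1; both are configurable.
- **Expectations, not integers.** Branch counts are kept as real-valued
  expectations so conservation identities (`A+B+C+D = N`, `A+B = Np`) hold
  exactly; rounding (half-up) happens only in reporting views.

### Two cascade parameterizations

The textbook tree (`sens_spec` mode) derives all counts from sensitivity and
specificity. Field programs, however, often report detection counts that are
*not* reproducible from their own quoted accuracy: in the bundled reference
scenario, a specificity of 97% implies ~2,985 false referrals while the
observed program data report 238. Forcing either view onto the other would
misstate one of them, so both are first-class: `observed` mode carries the
referral and confirmed-case counts directly, back-fills what the arithmetic
allows (`false_referrals = referred − confirmed`,
`confirmation_false_negative = diseased − confirmed − under_detected`), and
raises an error — rather than silently clamping — when observed inputs are
mutually inconsistent. Every report labels its mode. When the cascade cannot
say how many diseased newborns the screen itself missed, `under_detected`
defaults to `max(diseased − referred, 0)`; the reference scenario supplies
the observed values (0 for P-AABR, 3 for OAE). The reference also fixes
OAE's confirmed cases at 26, the value used consistently in its downstream
arithmetic; an alternative observed figure of 38 circulates in the same
source and can be run as a scenario by passing
`cascade_mode("observed", referred = 344, confirmed = 38)`.

## Costing conventions

Costs are micro-costed in INR at 2019–20 prices, one year of operation,
no discounting, inflation or currency conversion.

| Parameter | Default | Rationale |
|---|---|---|
| Effective screening hours/day | 6 h | chosen so that the stated test durations (15/10/90 min) reproduce the reference daily throughputs of 24/36/4; a gross 8-hour day overstates realistic device utilization |
| Test durations | minutes (15, 10, 90) | stored in minutes because rounded decimal hours (0.17 h) do not reproduce the observed 36 screens/day |
| Working days/year | 260 | five-day weeks |
| Equipment lifespan | 6 years | straight-line annualization, no discounting or salvage, matching the single-year horizon |
| Staff months/year | 12 | apportioning statistic = screening hours / overall monthly hours (176) |
| Training | full in-year amortization | a 25,000 INR post-service training line is treated as human-resource cost of the analysis year |

Reported INR values round half away from zero (`round_half_up()`); all
internal arithmetic — in particular program cost accumulation — uses
unrounded unit costs, so `unit_cost × volume` equals the annual total to
machine precision.

## Health economics

**QALYs are undiscounted.** The reference totals are consistent only with
`N × utility × life expectancy` (100,000 × 0.95 × 69.2 = 6,574,000 exactly);
a discount-rate argument exists on `strategy_qalys()` and defaults to 0.
Detected cases are assumed treated to the normal-hearing utility (0.95);
missed cases accrue the pooled untreated hearing-loss utility (0.77) over
the 69.2-year life expectancy. Laterality-specific weights (0.85/0.69) are
housed but unused by default, mirroring the pooled analysis.

**Stated vs model-derived QALY differences.** The reference analysis states
a QALY difference of 33.67 that cannot be reconstructed from its own
utilities, counts and life expectancy (3 missed cases × 0.18 × 69.2 = 37.37).
The configuration therefore accepts `delta_qaly_override`; every summary
reports the stated and the model-derived difference side by side, and the
discrepancy log records the gap.

**Derived treatment costs.** Lifetime cochlear-implant and hearing-aid costs
per treated child are never itemized in the reference source; the defaults
(1,229,552.89 and 699,745.55 INR) are back-calculated as
`(scenario total − screening total) / cases detected` from its
intervention-arm totals. The comparator arm back-calculates to slightly
different values — one more internal inconsistency — so these defaults are
flagged derived, not authoritative, and are ordinary config inputs.

**OOPE is approximate by construction.** The societal increments in the
reference (~80.5M INR per strategy) imply roughly 802 INR per visit but are
not decomposable from the published per-visit transport means (440/300/207/99
INR by facility level). The default profile — equal facility mix (mean
transport 261.5 INR) plus wage loss of 540.5 INR per visit, one screening
visit per newborn and one extra per referral — reproduces the societal totals
to about 0.2% and is labeled approximate; mix, visits and wage loss are free
parameters.

## The synthetic cohort generator

`simulate_cohort()` draws exactly the model the tree assumes: Bernoulli
disease status at the configured prevalence, referral with probability
`Se` (diseased) or `1 − Sp` (healthy), confirmation only for referrals,
facility levels from the configured mix. Seeding goes through
`withr::with_seed()`, so a fixed seed yields bitwise-identical cohorts while
the caller's random state is untouched.

The generator validates the deterministic model (`validate_cascade()`
reports deviations in binomial standard-error units; the suite asserts
|z| ≤ 3) and recovers its own generating accuracy across replicates. It does
**not** emulate loss to follow-up, repeat screens, age-dependent accuracy,
unilateral/bilateral subtypes, or cost dispersion between families (OOPE is
deterministic per facility level unless the user varies the profile). A green
simulation suite therefore shows internal consistency of the tree and its
sampler — not that real screening programs behave this way.

## Numerical and design choices

- Half-up rounding uses a `1e-9` epsilon to absorb binary representation of
  exact halves; ratios are reported at 2 decimals.
- Division guards: zero throughput, zero referrals, zero detected cases and
  zero QALY differences raise informative errors or dominance/equivalence
  flags rather than producing `Inf`/`NaN`.
- Observed-mode back-fills that would go negative raise validation errors.
- One-way sweeps re-run the full deterministic pipeline per grid point;
  sweeps over prevalence, cohort size or accuracy switch strategies to
  `sens_spec` mode, since observed field counts cannot respond to those
  inputs, and compare strategies on the model-derived QALY difference.
- The discrepancy log compares every computed quantity against the published
  values carried in the configuration and is deliberately nonempty on the
  reference scenario — a regression guard against "fixing" published numbers.
- Test problem sizes: cohorts of 100,000 for Monte-Carlo validation (the
  reference cohort size), 50 replicates for parameter recovery, 20–25 random
  draws for property loops; these run in seconds while keeping 3-SE
  assertions meaningful.

## Known limitations

The model has no probabilistic sensitivity analysis, willingness-to-pay
threshold, multi-year budget impact, or rescreening pathways; the societal
perspective inherits the approximate OOPE calibration; and the derived
treatment costs tie the absolute scenario totals (though not the
screening-only comparison) to the reference source's internal arithmetic.
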