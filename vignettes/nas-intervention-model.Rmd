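---
title: "A probability-tree microsimulation of NAS system interventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A probability-tree microsimulation of NAS system interventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nassim)
```

## The model and its assumptions

`nassim` simulates a one-year cohort of Medicaid-enrolled women with opioid
use disorder (OUD). Each woman takes a single pass through a rooted,
acyclic probability tree: she is or is not pregnant this year; a pregnant
woman does or does not seek treatment; a seeker does or does not receive a
slot; an entrant is assigned a modality (methadone, buprenorphine,
detoxification, or psychological support) and completes or drops out; every
pregnancy ends in a birth with or without neonatal abstinence syndrome
(NAS), except for the small fraction of untreated women lost to overdose.
Non-pregnant women either die of overdose or live with OUD for the year.

The core assumptions are:

* **Single pass, one-year horizon.** No state is re-entered: a woman who
  relapses after dropping out is simply "living with OUD" at year's end, and
  no relapse-then-retreat cycle is modelled inside the year. Because
  topology is data (see below), a user who wants an unrolled
  relapse-retreatment stage can add states to the parameter file without
  code changes; cyclic (Markov-cycle) structure is out of scope.
* **Independence.** Women are independent; there is no capacity coupling
  between them. Capacity expansion is modelled as a higher slot-availability
  probability, not a queue.
* **Undiscounted in-year costs.** The horizon is one year, so in-year costs
  are not discounted. The only discounting anywhere is inside the
  productivity-loss valuation of an overdose death, which spans future
  years.
* **Flags are state sets.** Every outcome (pregnant, started treatment,
  completed treatment, NAS case, overdose death, living with OUD) is defined
  in the parameter file as a set of state ids; a path carries a flag iff it
  visits one of them. "Living with OUD" applies to any woman alive and
  untreated-or-dropped-out at her terminal state, including
  treated-but-relapsed women: treatment completion is the only exit from
  that cost within the year.

## Topology as data, interventions as modifiers

The five scenario trees (community baseline plus four interventions) are not
five hard-coded graphs: there is one baseline topology, and each
intervention is a per-woman cost plus a list of transition modifiers. A
modifier rewrites one transition's probability (`set`, `multiply_prob`, or
`multiply_odds`) and proportionally renormalizes the untouched siblings.
Scenario composition applies modifiers in a fixed canonical order
(mandatory testing, navigators, capacity, coaches). This was a genuinely
open design choice: the source material for such models typically says that
combined interventions interact without saying how. Sequential application
with renormalization is explicit, keeps every single-intervention tree
exactly equal to its definition, and produces interaction (not addition) in
combinations automatically, because a second modifier on the same sibling
group acts on the already-modified probabilities.

Odds-scale modifiers exist because a multiplicative effect on a probability
can exceed 1; an odds multiplier cannot, so effect sizes ported across
baselines stay valid. A modifier that drives a sibling group's touched mass
above one is an error, never a silent clamp.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `n_women` | 200,000 | women/replication | cohort size of the stated study conditions |
| `n_replications` | 500 | — | stabilizes means; SE = SD/√500 |
| `reference_population` | 239,200 | births | denominator for NAS per 1000 and effect-size scaling |
| pregnancy probability | 0.039627 | — | calibrated: 7925.4 expected pregnancies per 200,000 |
| slot availability | 0.84 | — | baseline capacity constraint; capacity expansion multiplies it by 1.19 |
| `nas_treatment_days` | 17 | days | expected NAS length of stay (fixed-days form; a discrete distribution can be substituted upstream by editing the YAML) |
| `daily_hospital_cost` + `daily_nas_treatment_cost` | 1500 + 500 | USD/day | NAS treatment cost per day |
| `annual_oud_incremental_cost` | 15,000 | USD/yr | incremental healthcare cost of living with OUD |
| `special_education_cost` | 6,000 | USD/child | NAS long-term education cost |
| `productivity_discount_rate` | 0.03 | 1/yr | standard health-economics practice for future earnings |
| `retirement_age` | 65 | yr | end of the earnings stream |
| age distribution | uniform 18–44 | yr | explicit, overridable assumption; no published distribution to copy |

Monetary values are plain dollar amounts. The `money_scale: as_printed`
metadata field records that no rescaling is ever applied: reference tables
are compared as printed, without taking a position on their implied
per-woman unit scale.

## Calibration of the shipped defaults

The transition probabilities and cost schedule behind the reference results
are not among this package's public inputs, so the
shipped default configuration is a synthetic stand-in calibrated once, at
build time, to the headline baseline marginals: expected pregnancies 7925.4,
treatment starts 570.7, completions 418.34, and NAS births 3697.32 per
200,000 women (15.4 per 1000 births against the 239,200-birth reference
population). These are enumeration-exact expectations of the default tree,
not tuned simulation outputs. Single-intervention modifier values are
likewise calibrated to the single-intervention effect sizes (testing ≈
×3.19 on treatment entry, navigators ≈ ×1.95, capacity ×1.19 on slot
availability, coaches ≈ +13% on completions). Everything downstream —
combination scenarios, cost magnitudes, overdose-death responses — is a
*prediction* of this calibrated structure, and residuals against the
reference tables are computed and reported cell by cell by
`compare_to_reference()` rather than asserted. In particular the shipped
structure yields a smaller NAS reduction for the triple combination (−21%)
than the reference (−32%): with only entry- and completion-odds modifiers,
combinations saturate rather than synergize. That residual is surfaced, not
hidden.

What passing tests therefore show: the engine's arithmetic and statistics
are right (sampling converges to enumeration, identities hold exactly,
reported percent cells reproduce). What they do not show: that the shipped
probabilities equal the original study inputs.

## Random numbers and reproducibility

One root seed governs an experiment. Each replication re-seeds the generator
with a child seed derived by multiplicative mixing modulo 2³¹ − 1
(`substream_seeds()`), so any replication can be reproduced alone.
Categorical draws use the transition-file branch order, making runs
bit-stable.

A replication draws one uniform per woman and classifies it against the
cumulative enumerated-path probabilities (inverse CDF). This is
distributionally identical to stage-by-stage categorical draws — each woman
is still one independent draw from the path distribution — but it makes
common random numbers (CRN) effective: two scenarios sharing a substream
classify the *same* uniforms against slightly different cutpoints, so
paired differences isolate the intervention effect. CRN is the default;
independent substreams are available (`crn = FALSE`), and results record
which mode produced the intervals. With CRN and a no-op intervention,
scenario totals equal baseline exactly; with a costed but effect-less
intervention, the Medicaid total shifts by exactly eligible-count × cost.

Ages enter the model only through the productivity-loss valuation of
overdose deaths and are independent of the path, so the engine samples ages
for the women who die; the per-woman API (`sample_paths()` +
`cost_outcomes()`) carries ages for everyone and gives the same
distributions.

## Numerical choices

* Sibling probabilities must sum to 1 within 1e-9. Loaded files off by more
  than that but within [0.99, 1.01] are renormalized with a warning
  (published tables are rounded); anything worse is a validation error
  naming the state.
* Percent differences from baseline round half away from zero to integers —
  the convention under which every reference percent cell (including −0.54%
  → −1%) reproduces exactly.
* NAS rates per 1000 births truncate (not round) to one decimal:
  3697/239,200 must print 15.4, not 15.5.
* Confidence intervals are mean ± 1.96·SE across replications (normal
  approximation; 500 replications make this innocuous). Significance
  against baseline is a Welch two-sample t-test at α = 0.05 per output;
  under CRN this is conservative (the pairing is ignored), which only makes
  "significant" labels harder to earn.
* The productivity loss of a death at age *a* is
  `Σ_{t=0}^{R−a−1} earnings(a+t)/(1+r)^t` — an annuity-due (year of death
  counts as a lost earnings year), computed from the current age with the
  full remaining career; death timing within the year is not modelled.
* Degenerate inputs: terminal states with outgoing edges, cycles, orphan
  flag states, negative money and malformed age distributions are all
  validation messages, returned rather than thrown, so validation is total.

## The synthetic generators

`generate_parameter_set()` resamples each sibling group from a Dirichlet
distribution centred on the base probabilities (concentration parameter
`c`: component SD ≈ √(p(1−p)/c)) and jitters costs multiplicatively. It
emulates parameter uncertainty around a literature-sourced table — not new
structure: topology and flags are preserved, and outputs always validate.

`generate_claims()` emulates the claims extract used for baseline
validation: members deliver at a configured rate, carry OUD diagnosis codes
(ICD-10 F11.*) and treatment codes at configured conditional rates, with
true-positive codes placed strictly inside the inclusive 365-day lookback
window from the first delivery of the year and decoy codes (irrelevant
diagnoses in-window; real codes strictly out-of-window) injected to
exercise the matching rules. Truth labels go to a sidecar table, never into
the records, so the extractor cannot cheat; the closed loop
`extract_cohort(generate_claims(cfg))` recovers truth counts exactly by
construction. What the synthetic claims do *not* emulate: under-recognition
of OUD in real claims (which biases claims ratios relative to simulation
truth — both numbers are reported without correction), realistic code
ontologies, or enrollment spans. The shipped code lists are placeholders.

The claims ratio is reported under both conventions — treated/identified
and treated/untreated — because source descriptions alternate between them;
validation applies its tolerance (default 4.8% relative on the ratio, 0.5
per 1000 absolute on the NAS rate) to the configured one, by default
treated/identified. Mandatory-testing eligibility defaults to all pregnant
women (the denominator is configurable; prenatal-care-only restriction
would be a flag-set edit in the YAML).

## Problem sizes

The shipped experiment size (500 × 200,000 per scenario) runs in under a
minute for all 13 scenarios thanks to the enumeration + inverse-CDF engine.
The test suite uses that full size where the check is about the calibrated
means, and smaller cohorts (2,000–200,000 women, 1–50 replications) for
property checks, where binomial error bounds — 4 standard errors around
enumeration expectations — make the assertions size-aware rather than
size-dependent.

## Known limitations

* Costs of miscarriage and of non-special-education child morbidity are not
  modelled, matching the scope of the incremental-cost framing.
* No QALYs and no cost-effectiveness ratios: outputs are counts and costs.
* The combination-scenario interaction is whatever sequential
  modifier-with-renormalization produces; no interaction terms are fitted.
* The single-pass tree cannot express within-year relapse/readmission.
* Claims validation covers the baseline scenario only, and inherits the
  recognition bias described above.
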