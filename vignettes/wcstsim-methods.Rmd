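---
title: "Methods: a cycle-budgeted executive-function model of the WCST"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a cycle-budgeted executive-function model of the WCST}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wcstsim)
```

## Scope

`wcstsim` implements a complete computational experiment around the
128-card Wisconsin Card Sorting Task: stimulus materials and administration
rules, a cycle-limited cognitive agent with parameterised executive
functions, a factorial grid of virtual participants, the statistical
pipeline run on the resulting perseveration-error (PE) counts, and a
boundary classifier that compares model means against published
cancer-survivor comparison data. This vignette documents the model, its
assumptions, the tunable constants, and the design decisions that were
genuinely open.

## Task and scoring

The administration follows the standard Heaton conventions as implemented
in `administration_config()`:

* a 128-card deck (two complete 64-card sets; each set holds every
  colour × shape × number combination exactly once);
* the required dimension starts at colour and cycles colour → shape →
  number, advancing covertly after 10 *consecutive* correct sorts
  (an error resets the run);
* the session ends after six completed categories or when the deck is
  exhausted.

Scoring uses the agent's covert chosen dimension, not the response pile.
A sort is correct iff the chosen dimension equals the current rule; an
incorrect sort is a PE iff the chosen dimension equals the immediately
preceding rule, otherwise an NPE. The feedback delivered on an error trial
counts as "being informed", so the first post-shift old-rule error is
already perseverative; before the first rule change nothing can be. Two
assumptions here are interpretations rather than published facts: the
starting dimension (colour) and the fixed cyclic rule order are
conventional choices, and deck order is a seeded uniform shuffle of each
64-card set because the published fixed orderings are proprietary. Under
covert-strategy scoring the card identities never influence outcomes, so
deck order is cosmetic; it is still recorded for reproducibility.

## The agent

State per sorting dimension `d ∈ {colour, shape, number}`:

* `e_d ∈ [0, 1]` — working-memory *evidence* that `d` is the required
  dimension (initially 1/3 each);
* `a_d ∈ [0, 1]` — response *activation* (initially 0);
* a *prepotent* marker (the last positively reinforced dimension) and a
  per-dimension *disconfirmed* flag.

`deliberate()` runs exactly `C` cycles (the cycle budget) and sorts by the
final activation argmax. Per cycle, in order:

1. **Monitoring (updating):** every non-disconfirmed dimension moves
   toward its evidence, `a_d ← a_d + u (e_d − a_d)`. A disconfirmed
   dimension receives no working-memory support: once feedback has
   contradicted a strategy, memory maintenance no longer props it up. This
   exclusion is load-bearing — if monitoring kept refreshing the old
   strategy, the activation field would reach a budget-independent
   equilibrium within any realistic number of cycles and the cycle budget
   would stop mattering, removing the phenomenon the model exists to
   express.
2. **Strategy evaluation (shifting):** the highest-evidence candidate
   (ties in canonical colour/shape/number order) gains `κ_s · s⁺`; every
   other dimension gains `κ_s · s⁻` (`s⁻ ≤ 0`).
3. **Inhibition:** each disconfirmed dimension loses `i · κ_i`.
4. **Automatic activation:** the prepotent dimension, while not
   disconfirmed, gains `κ_p` — the contention-scheduling idea that the
   recently rewarded action schema activates itself. This is what makes
   10-sort runs stable enough that essentially every session completes all
   six categories.
5. Additive Gaussian noise (`sd = noise_sd`) and clipping to `[0, 1]`.

`process_feedback()` then updates working memory: positive feedback moves
`e_chosen` toward 1 with gain `u`, makes the chosen dimension prepotent and
clears all disconfirmed flags; negative feedback moves `e_chosen` toward 0
with gain `u` and flags the chosen dimension disconfirmed. Flagging the
*chosen* dimension (not only the prepotent one) is deliberate: it removes a
just-contradicted alternative from strategy-evaluation candidacy, without
which an agent whose remaining candidates are tied at zero evidence can
lock onto a wrong dimension indefinitely. Between trials activations decay
multiplicatively by `decay`.

Agents whose shifting is active (`s⁻ < 0`) also *anticipate* the covert
rule change: after the criterion run length of consecutive positive
feedback (task-structure knowledge, default 10), the current strategy's
evidence is demoted by `min(1, anticipation · |s⁻|)` of itself and the
strategy is flagged. Anticipation is what lets the unimpaired expert agent
finish a session with zero PEs while the first post-shift old-rule error
still scores as a PE for everyone else; agents with inactive shifting
(`(0, 0)`) cannot anticipate and therefore floor at roughly one PE per
rule change.

The executive-function levels are fixed data (`ef_levels()`): updating
0.07 / 0.12 / 0.24 / 0.37 (very poor → high), shifting (0, 0) / (1, −1) /
(2, −2) (poor → high; whole-number strategy ranking permits only three
levels), inhibition 0.10 / 0.22 / 0.44 / 0.65. "High" represents 99% of
expert functioning, so the expert profile divides the high values by 0.99.

### Why the mechanism trades time against inhibition

After a rule change the old strategy starts near ceiling activation.
Monitoring no longer supports it (it is disconfirmed), so its per-trial
loss is approximately `(1 − decay) · a + C · i · κ_i`: a small passive
leak plus an inhibitory term proportional to the cycle budget. With
`decay = 0.98` the leak is minor and suppression time is governed by
`C · i`. A 20-cycle agent with inhibition 0.10 needs several trials —
several PEs — to push the old strategy below the alternatives; the same
agent given 60 cycles needs one or two. Strong inhibition (0.65) crushes
the old strategy within a single deliberation at any budget, which is why
processing time compensates most visibly for *inhibition* impairments.

## Constants: values and rationale

The level values above are data; everything else is configuration
(`agent_constants()`), calibrated once so that the qualitative behaviour
of the default grid holds, then frozen:

| constant | default | role |
|---|---|---|
| `noise_sd` | 0.015 | per-cycle activation noise (unitless activation); source of between-participant variance. Larger values break criterion runs so often that sessions stop completing; 0 disables noise for deterministic checks |
| `decay` | 0.98 | between-trial activation carry-over; close to 1 so that post-shift suppression is dominated by the cycle-scaled inhibition term rather than passive forgetting |
| `kappa_shift` | 0.01 | per-cycle scale of the shifting biases; small enough that even strong shifting guides rather than dictates the choice within one deliberation |
| `kappa_inhib` | 0.045 | per-cycle scale of inhibition. The pivotal constant: it must be weak enough that poor inhibition cannot finish suppression in 20 cycles (perseveration under time pressure) yet strong enough that 40–60 cycles do finish it, and that the 40-vs-60 contrast remains detectable |
| `kappa_prepotent` | 0.05 | per-cycle automatic activation of the reinforced strategy; saturates the current strategy within a run so runs survive noise |
| `anticipation` | 0.5 | fraction of `|s⁻|` by which evidence is demoted at an anticipated shift (capped at a full reset; medium shifting halves the evidence, high shifting clears it) |
| `expected_run_length` | 10 | the criterion run length the agent treats as task knowledge |

These are claims about the implementation, not about people; the
level values carry the psychological content.

## The factorial experiment

`enumerate_variants()` orders the 48 profiles with updating varying
slowest, then shifting, then inhibition (each from worst to best). The
packaged reference table of published per-model means uses its own printed
numbering, shipped verbatim in the fixture. `run_grid()` crosses the
variants with the cycle budgets (20/40/60), runs `n_participants`
(default 20) independent sessions per model, and derives one child seed
per session from the master seed arithmetically, recording it in the
results table; sessions share no state, so execution order is irrelevant
to the output.

## Statistics

`pe_descriptives()` reports n, mean, sample SD (n − 1), SE = SD/√n, a
normal-approximation 95% CI (±1.96 SE — matching how the comparison
descriptive tables were computed), min and max. `one_way_anova()` is the
classical fixed-effects decomposition with η² = SS_between/SS_total.
`ancova()` fits `outcome ~ factor + covariates` with covariates entered
simultaneously and tests the factor by full-vs-reduced model comparison (a
type-III-style partial F; with only one factor, type II and III coincide);
marginal means are predictions at covariate grand means. Zero-variance
covariates are dropped with a warning; a covariate collinear with the
factor is an error, as the partial test would be meaningless.
`pairwise_comparisons()` uses the pooled within-group mean square for the
contrast SE, Bonferroni-adjusts both the p values (`min(1, m·p)`) and the
simultaneous confidence intervals, and reports Cohen's d with the
two-group pooled SD `√((s_a² + s_b²)/2)` — the convention that reproduces
the published effect sizes from the published group summaries. P values
are kept at machine precision; "< 0.001" is presentation, not storage.

## Classification against comparison groups

The two cancer-survivor groups (chemotherapy n = 27, PE 12.5 (6.9), SE
1.33; local therapy n = 30, PE 12.8 (9.3), SE 1.70) are packaged with
their simulation boundary intervals carried *verbatim* (LT 12.50–15.90,
CT 13.27–15.93). The printed boundaries are not `mean ± SE` of the printed
PE summaries — recomputing them would give [11.17, 13.83] and
[11.10, 14.50] — but the published per-model classifications are
consistent with the printed boundaries, so the boundaries are treated as
data and never derived. Interval endpoints are inclusive; printed means
are classified as printed, without re-rounding. The label vocabulary
partitions the line: below both intervals (`LT-`), inside LT only,
inside both (`LT, CT`), inside CT only, above both (`CT+`). The two
sliver regions ([12.50, 13.27) and (15.90, 15.93]) get the single-group
labels even though no packaged mean falls in them.

## Synthetic data

`generate_synthetic_results()` exists so the statistics and classification
stages can be tested without the simulator: per group it draws PE counts
from a zero-censored normal rounded to integers, with the *latent*
location solved by root finding so the censored distribution has exactly
the stated group mean (plain censoring at zero would inflate a stated mean
of 5.3 with SD 6 by about 0.6 — more than the recovery tolerance any
sensible test would use). The stated SD is the latent scale, so realised
SDs shrink slightly under censoring; rounding adds a negligible bias.
Covariates are deliberately simple — categories constant at the ceiling,
NPE an independent censored normal — so synthetic tables exercise the
ANCOVA code paths but do not emulate the joint (PE, NPE, categories)
distribution of simulated or human data. Passing statistics tests on
synthetic tables therefore validates the arithmetic, not the simulator.

## Numerical and degenerate-case conventions

* Activation ties at the argmax are broken uniformly at random from the
  session RNG stream; evidence ties in target selection use the canonical
  dimension order (deterministic).
* All randomness in a session (deck shuffle when none is supplied,
  per-cycle noise, tie breaks) derives from the single session seed, so
  sessions are exactly reproducible; grid runs are reproducible from the
  master seed alone.
* Single-observation groups report SD 0 by convention; empty tables raise
  a typed no-data error rather than producing NaNs.
* The uniroot moment match in the synthetic generator uses a 1e-10
  tolerance on an interval wide enough to bracket any positive target.
* Test oracles for ANOVA/ANCOVA are brute-force sums of squares and
  normal equations (`solve()`), independent of the `lm` route used by the
  package, and agree to 1e-8 on small instances.

## Problem sizes used by the tests

The full default grid (2,880 sessions) is simulated once inside the
acceptance-style tests; unit tests use 1–3 participants per model or
single sessions so the suite stays fast. The package-level checks assert
pattern-level behaviour of the simulator (monotone cycle effect with
diminishing drops, the inhibition-by-cycles interaction, near-universal
completion, the zero-PE expert) rather than numeric equality with any
published per-model table, which a reimplementation of the agent dynamics
cannot and should not promise.

## Known limitations

* The agent is a functional reconstruction: published level values and
  process roles are respected, but the update equations are this
  package's own, so per-model PE means and SDs are comparable in pattern,
  not in value, to the published reference table.
* The locus and magnitude of between-participant variance in the original
  models is unknown; here it is a single per-cycle noise term.
* Cycles are not mapped to physical time units.
* Only the four standard outcome metrics are scored; the extended
  clinical battery (failure to maintain set, conceptual-level responses,
  learning-to-learn) is out of scope.
* With covert-strategy scoring, ambiguous cards (which match the same key
  on two dimensions) need no special handling; response-pile scoring
  would require it.
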