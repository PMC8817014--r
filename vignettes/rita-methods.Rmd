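---
title: "Recurrent individual treatment assignment: model, simulation design, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recurrent individual treatment assignment: model, simulation design, and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rita)
```

## The problem

A longitudinal two-arm trial assigns each of `obs` individuals to one of two
interventions, A or B, in every period `t = 1, ..., T`, and observes a
per-period *treatment response* — the outcome change
$\Delta y_{ti} = y_{ti} - y_{t-1,i}$. When individual treatment effects are
heterogeneous, the population average treatment effect (ATE) that a
conventional randomized controlled trial estimates can be uninformative, or
even misleading, about which arm is better *for a given individual*: an
unbiased ATE is a biased estimate of an individual effect. If the
heterogeneity loads on unobserved characteristics, conditioning on
covariates cannot recover it either.

Recurrent Individual Treatment Assignment (RITA) sidesteps individual-effect
estimation entirely. It treats each period as a randomized assignment,
scores every individual by the *rank* of their response in the pooled
population, and pushes each individual's assignment probability towards the
arm under which they rank higher — while a pair of exploration bounds keeps
assignment forever probabilistic. Because response variation encompasses all
heterogeneity, observed or not, the policy can personalize without modeling
the heterogeneity.

## The RITA update

Per individual $i$ the policy carries an assignment probability
$\tau_{Ati}$ (with $\tau_{Bti} = 1 - \tau_{Ati}$), one *individual mean
rank* per arm ($\mathrm{IMR}_{A}$, $\mathrm{IMR}_{B}$), and per-arm
assignment counts. Each period:

1. assign A with probability $\tau_{Ati}$, else B;
2. observe the response $\Delta y_{ti}$;
3. rank all `obs` responses pooled over both arms — rank 1 for the smallest
   change, `obs` for the largest;
4. add the rank to the assigned arm's running mean
   ($\mathrm{IMR}_Z = \sum \mathrm{rank}_Z / \sum c_Z$); the other arm's IMR
   is untouched;
5. update the probability. For an individual assigned to A:
   $$\tau_{A,t+1,i} =
     \underbrace{\frac{\mathrm{rank}_{ti}}{obs}}_{\text{individual rank}}
     \cdot
     \underbrace{\left(\frac{\mathrm{rank}_{ti}}{\mathrm{IMR}_{Bti}}\right)
       ^{\textstyle\sum c_{Ati} - 1}}_{\text{relative rank}^{\text{learning parameter}}}$$
   and for an individual assigned to B the mirrored form
   $\tau_{B,t+1,i} = (\mathrm{rank}/obs) \cdot
   (\mathrm{rank}/\mathrm{IMR}_{A})^{\sum c_{B}-1}$ with
   $\tau_A = 1 - \tau_B$;
6. clamp both arms' probabilities into $[\lambda_l, \lambda_u]$.

Before any evidence, $\tau_{A1i} = 1/2$ and both IMRs start at the mid-rank
`obs/2`, so the first update's exponent is zero and the probability moves
with the individual rank alone. As the count grows, the relative-rank factor
dominates exponentially: a run of above-IMR ranks drives the probability to
the upper clamp within a few periods, and the same drift lets the policy
re-polarize quickly if relative effectiveness ever changes.

```{r dina}
# one individual assigned A and ranked 600 of 1000, twice in a row
st <- init_states(1000)
arms <- c("A", rep("B", 999)); ranks <- c(600L, setdiff(1:1000, 600L))
st <- update_imr(st, arms, ranks)
update_probability(st, arms, ranks)[1]          # 0.6 * (600/500)^0
st <- update_imr(st, arms, ranks)
update_probability(st, arms, ranks)[1]          # 0.6 * (600/500)^1
```

### The mirrored B branch

The two branches of the probability update must be structurally symmetric:
whichever arm was assigned, a high rank should reinforce *that* arm. Writing
the B branch instead as
$1-\tau_{A} = (1 - \mathrm{rank}/obs)\cdot(\mathrm{IMR}_A/\mathrm{rank})^{\sum c_B - 1}$
moves probability mass away from B precisely when B performs well, the
opposite of the policy's intent; after a first-ever B assignment it leaves
$\tau_A = \mathrm{rank}/obs$, i.e. it *keeps* a poorly-responding individual
on B. The package therefore defaults to the symmetric mirror and exposes the
alternative form behind `rita_config(eq10_literal = TRUE)` for comparison
only.

### Tunables

* `lambda_l`, `lambda_u` (probabilities, defaults 0.05 / 0.95): the
  exploration bounds. Assignment never becomes deterministic, so the policy
  keeps paying an exploration tax of at least `lambda_l` misassignment
  probability per period in exchange for the ability to detect drifting
  individual effects. With symmetric bounds, clamping $\tau_A$ alone would
  suffice; the implementation clamps both sides so asymmetric bounds also
  behave.
* `tie_rule` (`"random"`, default): pooled ranks must be an exact
  permutation of `1..obs` because the update rescales them by `obs`. Tied
  responses are broken at random under the period's seeded sub-stream;
  `"average"` computes midranks first and re-indexes them to a permutation
  in id order. Under continuous outcome noise ties have probability zero,
  so the choice is immaterial in the benchmark worlds.

## The baseline policies

The RCT baseline randomizes period 1 (probability 1/2 per arm), estimates
the ATE once by ordinary least squares of the period-1 response on an
intercept and the arm indicator, and then assigns every individual the
coefficient-wise better arm with certainty for all remaining periods. The
sign of the coefficient decides even when it is insignificant: when the two
arms truly tie on average, either choice is equally defensible, but a
deployment rule must commit. The recorded two-sided t-test and its 0.05
threshold are reporting-only. The baseline never re-estimates: after period
1 its assignment is deterministic, so later periods carry no assignment
variation to re-estimate from (a `re_estimate` switch exists for
experimentation).

The moderator baseline adds an arm-by-group interaction,
$y = (\alpha_1 + \alpha_2 X_1)\, I_A + X'\beta + \varepsilon$, and assigns A
to an individual iff $\alpha_1 + \alpha_2 X_{1i} > 0$. It captures all
heterogeneity that loads on the observed group and none of the latent part,
which brackets RITA from the other side.

## The simulation worlds

Individual effects are generated as $e_L \cdot (1 + \text{ind}_G/s)$: a
latent normal draw per arm, optionally scaled up by an observed binary
group interaction (indicator $G$ for arm A, $1-G$ for arm B; divisor $s$).
The four presets:

| world | arm A | arm B | heterogeneity |
|---|---|---|---|
| 1 | constant 0.8 | constant 0.6 | none |
| 2 | $N(0.8, 0.4)$ | $N(0.6, 0.3)$ | latent only |
| 3 | $N(0.7, 0.35) \times (1+G/3.5)$ | $N(0.5, 0.25)\times(1+(1-G)/2.5)$ | latent + observed |
| 4 | $N(0.7, 0.35) \times (1+G/3.5)$ | $N(0.7, 0.35)\times(1+(1-G)/3.5)$ | latent + observed, equal ATEs |

The latent standard deviations are half the means (coefficient of variation
0.5). In world 3 the closed-form subgroup means are 0.9/0.7 for A and
0.5/0.7 for B, so the overall ATEs remain 0.8 and 0.6; in world 4 both arms
average 0.8 overall but favor opposite groups, so the ATE carries no
assignment information at all. Worlds 1 and 4 are each other's counterparts:
one is the best case for the one-shot ATE rule, the other its worst.

Remaining generative conditions: baseline outcome $y_0 \sim N(10, 1)$;
outcome noise $\epsilon_{ti} \sim N(0, 0.1)$ per period; `obs = 1000`
individuals; `T = 60` periods; $G$ balanced. These are the benchmark
defaults throughout the package.

Generator choices that the published parameter tables leave open:

* Latent normals are **not truncated**; a small fraction of individuals can
  have negative per-period effects. Truncation would silently change the
  population means that the closed-form `world_ate()` arithmetic relies on.
* $G$ is an **exact half split** (shuffled by seed) so "equally distributed"
  holds exactly; iid Bernoulli assignment is available via
  `group_assign = "bernoulli"`.
* Heterogeneity is purely multiplicative, $h = u\,(1 + o)$; there is no
  additive observed-only term. This is the constrained form the benchmark
  imposes and what makes the subgroup means exactly
  $\bar e_L (1 + \text{ind}/s)$.

What the generator deliberately does not emulate: time-varying individual
effects (effects are frozen per individual — so the exploration bounds are
pure cost here, and the simulations measure that cost rather than the
benefit exploration buys under drift), dropout or missingness, interference
between individuals, more than two arms, and real-data covariate structure.
Passing tests on these worlds show that the machinery reproduces its
intended dynamics, not that RITA will outperform on any particular real
population.

## Engine and reproducibility

One master seed drives named sub-streams (`"population"`, `"noise"`,
`"policy/<name>/<period>"`), derived by a deterministic string hash
(`substream_seed()`). Consequences: the same seed reproduces a run
bit-for-bit; all policies in a comparison face the identical population;
the outcome-noise stream is shared per (individual, period) across policies
(common random numbers), so per-individual gain differences isolate the
assignment decisions — which is what makes statements like "this individual
was assigned the wrong arm five times" meaningful on paired runs. Policy
list order is irrelevant, and an `independent_noise` switch reproduces fully
independent runs. Period 1 is randomized 50/50 for *every* policy, the
baseline included; its deterministic rule starts at period 2.

Comparisons report cumulative *gains* $y_t - y_0$ rather than levels:
$y_0$ is policy-independent noise, and paired differences are invariant to
the choice.

## Evaluation conventions

* Subgroup medians split the paired differences by each individual's
  ground-truth optimal arm (`optimal_arm()`, exact ties to A) — information
  the policies never see.
* Medians use the standard midpoint convention for even counts.
* In world 4 the design is exactly label-symmetric (swap A/B and
  $G/1{-}G$), so the baseline's period-1 coefficient sign is a fair coin
  and the *identity* of the small-loss subgroup flips between replications:
  it is always the subgroup whose optimal arm matches the baseline's
  realized choice. Replication summaries therefore also report the medians
  re-keyed to the realized baseline arm (`median_fav`, `median_other`),
  which are stable across seeds where the raw A-/B-optimal medians are
  bimodal. A single-run report that conditions on its own realized
  configuration corresponds to the re-keyed statistic.
* The "RITA rank" ordering used for individual-level displays sorts by
  final cumulative outcome under RITA, ties by id; binning in the ranked
  plot (default 10 individuals) is cosmetic only.

## Numerical choices and degenerate inputs

* Within a period the IMR update precedes the probability update, so the
  learning exponent is (current count − 1): zero on an arm's first
  assignment, exactly as the first-period behavior requires.
* The relative-rank power can overflow for extreme rank/IMR ratios at high
  counts; overflow is treated as full certainty and resolved by the clamp.
  The unclamped value is retained per individual (`tau_A_unclamped`) for
  diagnostics.
* Non-finite responses are refused by the ranking step rather than silently
  ranked.
* `update_probability()` errors if the assigned arm's count is still zero,
  catching a mis-ordered update sequence.
* Nothing is hard-coded to 1000 individuals; all formulas use the actual
  `obs`, including the `obs/2` IMR initialization.

## Known limitations

* **Sensitivity of the high-count regime.** Because the learning exponent
  is the cumulative assignment count, the relative-rank factor at, say,
  count 40 raises a single period's ratio to the 39th power: one draw below
  the opposite arm's IMR collapses the assignment probability from the
  upper clamp to the lower one in one step. Individuals whose opposite-arm
  IMR rests on a few early, mediocre ranks are particularly exposed. The
  realized steady-state misassignment rate therefore sits above the
  `lambda_l` floor, and the long-run assignment proportion in a
  homogeneous world plateaus below the upper clamp. This is inherent to
  the published update; a caliper on switching (hysteresis) is a natural
  mitigation and is left as a configuration hook, not implemented logic.
* Oscillating assignments between near-tied arms are not damped (same
  caliper remark).
* Exactly two arms; no covariate-conditional RITA variant.
* The repeated-measures (SUR/SEM) formulation of the longitudinal ATE is
  out of scope; the baseline needs only the period-1 cross-sectional
  estimate.

## Problem sizes used in the shipped checks

The package's own test suite verifies the generator moments at $10^5$
draws, the full state-trajectory equivalence against an independently coded
brute-force oracle on panels of up to 6 individuals and 3 periods, and the
headline paired-comparison statistics at the full benchmark size
(`obs = 1000`, `T = 60`) over 30 master seeds — sizes at which the
across-seed replication intervals of the headline metrics are a fraction of
an outcome unit wide. The same 30-replication design backs
`replication_report()` and the acceptance script.
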