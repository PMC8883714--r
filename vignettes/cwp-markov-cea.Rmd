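---
title: "A Markov cohort model for the cost-effectiveness of coal-dust interventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model for the cost-effectiveness of coal-dust interventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cwpcea)
```

## The model

Coal workers' pneumoconiosis (CWP) is an irreversible occupational lung
disease caused by inhaled coal-mine dust. `cwpcea` models its prevention
with a discrete-time Markov cohort model over three states — `health`,
`cwp`, `death` — with annual cycles. A cohort of healthy miners enters
at age 20 and is followed for 43 cycles (through age 62, spanning a full
underground working life plus retirement into the ages where CWP
mortality concentrates). Permitted transitions are health→CWP,
health→death, CWP→death, and the self-loops; CWP→health is structurally
zero (the disease does not regress) and death is absorbing. The model is
*time-dependent*: all three hazards vary by cycle, through age
(background and CWP mortality) and exposure duration (incidence).

Per cycle `t` the transition matrix is

$$
P_t = \begin{pmatrix}
1-\lambda_t-q^h_t & \lambda_t & q^h_t \\
0 & 1-q^c_t & q^c_t \\
0 & 0 & 1
\end{pmatrix}
$$

with row-stochasticity enforced in one place: matrices are always
derived from the schedule by `to_matrix()`, never stored, and
`1-\lambda-q^h \ge 0` is a validated invariant of every schedule.

### Counterfactual arms by back-adjustment

Observed incidence reflects whatever interventions were in force while
the data accrued. The generalised cost-effectiveness analysis (GCEA)
framework reconstructs a counterfactual *null* scenario by removing
them: an intervention with coverage $c$ and efficiency $e$ scales
incidence by $(1-ce)$, so

$$\lambda_N = \frac{\lambda_C}{\prod_i (1 - c_i e_i)},$$

and any arm's incidence is $\lambda_N \prod (1-ce)$ over the
interventions it deploys. The two operations are exact inverses
(`back_adjust_to_null()` / `apply_interventions()`), which the test
suite asserts to 1e-12 over random parameter draws. The adjustment is
assumed to touch *only* the health→CWP probability: dust interventions
are purely preventive, so both mortality columns are carried over
unchanged into every derived arm — stated explicitly so that nobody
"improves" the null arm's mortality.

Back-adjustment can push a probability above 1 when the input incidence
is large relative to the retention factor. Because realistic per-cycle
CWP incidence is small (order 1e-3), an overflow almost always signals
bad input; the default policy is therefore a hard error, with an
explicit `overflow = "clamp"` opt-in for exploratory use.

## Parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| entry age / horizon | 20 / 43 | years / cycles | working-life cohort |
| discount rate | 0.05 | per year | standard for the setting |
| utility, health | 1.0 | — | scale anchor (1 = perfect health) |
| utility, CWP | 0.666 | — | EQ-5D survey of Chinese pneumoconiosis cases |
| coverage = efficiency, engineering | 0.95 | proportion | regulated dust-proofing of the underground roadway |
| coverage = efficiency, individual | 0.70 | proportion | real-world mask fit/usage well below filter ratings |
| annual cost, management | 2,477.76 | RMB/person/yr | six-mine cost survey means |
| annual cost, engineering | 1,582.80 | RMB/person/yr | ditto |
| annual cost, individual | 2,486.25 | RMB/person/yr | ditto |
| per-capita GDP | 72,447 | RMB | 2020 value; thresholds at 1x and 3x |

Arm costs compose additively from the survey categories: every arm pays
management; each dust intervention adds its own category; the
comprehensive arm pays the surveyed total (6,546.81 RMB). This mapping
is a genuine design choice — the source tables do not pin it down — and
is therefore fully config-driven rather than hard-coded: `annual_cost`
is free per arm in the scenario file.

## Accrual conventions

Several conventions are unstated in the literature this model follows;
each is a flag so alternatives can be explored, with these defaults:

- **Half-cycle correction applies to QALYs only.** QALYs are summed
  trapezoidally over the `T + 1` cycle-start occupancies
  ($v_0/2 + v_1 + \dots + v_{T-1} + v_T/2$), acknowledging that
  transitions occur mid-cycle on average. Costs are summed at cycle
  starts over cycles $0..T-1$ without the correction;
  `cost_half_cycle = TRUE` restores the convention of decision-tree
  packages that correct both.
- **Cost accrual base.** Prevention cost accrues to everyone alive
  (health + CWP occupancy): dividing published arm costs by annual
  costs approximates discounted alive-years, which supports this base.
  `cost_states = "health"` restricts accrual to working (healthy)
  miners.
- **Discount timing.** Cycle $t$ is discounted by $(1+r)^{-t}$ with
  $t = 0$ undiscounted — the standard cohort-model convention.

## Incremental analysis

`cea_table()` reports each arm against the null scenario by default
(matching the usual base-case table layout); `mode = "sequential"`
compares along the frontier instead. `cea_frontier()` sorts by cost
(ties: higher QALY first, then stable input order), flags strict
dominance, and removes extended dominance iteratively wherever
sequential ICERs fail to increase; frontier ICERs are strictly
increasing by construction afterwards.

Numerical conventions worth stating:

- A zero QALY difference yields an undefined ICER, signalled as `NaN`
  (zero cost difference too) or signed `Inf` — never an error.
- Negative ICERs keep their sign and are *additionally* flagged
  dominant/dominated via the QALY difference; ranking negative ICERs
  numerically is a classic CEA error the API refuses to invite.
- Threshold boundaries: an ICER exactly at 1x GDP is `cost_effective`
  (not highly — the rule is "less than"), exactly at 3x GDP also
  `cost_effective` (the rule is "exceeds").
- Computation is full-precision throughout; `round_half_up()` exists
  only for report formatting (base `round()` rounds half to even, which
  published tables do not).

## Sensitivity analysis

**One-way (tornado).** Each of `utility_cwp` and the per-arm annual
costs is scaled to $(1 \pm 0.4)$ of its base value, the whole model is
re-run, and vs-null ICERs are reported for every non-null arm. A
perturbed utility above 1 is clamped to 1 with a warning so the
parameter stays in its legal domain (with the default 0.666 the +40%
value, 0.9324, does not clamp).

**Probabilistic (PSA).** Costs draw from gamma and the CWP utility from
beta distributions, parameterised by method of moments around the base
values. The source analysis states the distribution families but no
variances; the default coefficient of variation, **0.204**, treats the
±40% one-way range as an approximate 95% interval (0.4/1.96). It is a
documented assumption and fully configurable. Only the five cost
parameters and the utility are sampled — transition probabilities are
held fixed, as no distributional information exists for them; since the
dynamics are then iteration-invariant, each arm's trace is propagated
once and costs/QALYs re-accrued per draw, which is the exact model
evaluation. Method-of-moments beta validity (variance < mean(1−mean))
is checked up front and errors early.

All PSA randomness flows through one seed; the caller's RNG state is
saved and restored, and identical spec + seed gives bit-identical
results. Tie handling: pairwise cost-effectiveness probabilities count
strict NMB wins, crediting ties to the comparator; the multi-arm
acceptability curve credits ties to the earliest arm in configuration
order. Ties have probability zero for continuous draws, so these rules
only matter in degenerate (zero-variance) settings — and no single
argument-symmetric rule can make pairwise probabilities sum exactly to
1 under ties, which is why the complementarity property is stated for
continuous draws. The default WTP grid, 0–300,000 RMB in 5,000 steps,
covers both GDP thresholds and the region where the optimal arm
switches.

## Synthetic inputs

The per-cycle transition schedules behind the original analysis live in
unpublished supplementary material, so `generate_schedule()` produces a
synthetic stand-in with the same structure:

- **Incidence** under comprehensive dust control follows a Weibull
  hazard in exposure duration (shape 2.2, rising with exposure). The
  scale — a single scalar — is calibrated by root-finding so the
  cohort's lifetime CWP risk matches the source cohort's crude
  proportion 2,873/87,904 ≈ 3.27% (tolerance 1e-4), keeping every
  derived arm in a realistic regime.
- **Background mortality** is Gompertz,
  $q(a) = 1 - \exp(-A e^{Ba})$ with $A = 2.85 \times 10^{-4}$,
  $B = 0.0576$ — about 0.9 per 1,000 at age 20 rising tenfold by 60,
  plausible for Chinese adult men — rather than an embedded census
  table, keeping the package download-free. It is synthetic and
  labelled as such.
- **CWP mortality** is specified as 5-year-band probabilities
  (defaults rising from 0.035 to 0.20 across ages 20–64), converted to
  annual values by the constant-hazard transform
  $1-(1-P)^{1/5}$ and held constant within each band; the youngest
  band copies the 25–29 band, mirroring the age range the source
  mortality study covers. A small seeded log-normal jitter (SD 0.05)
  emulates the sampling roughness of an empirical study; the 20–24
  copy is applied after jittering so the convention survives.

What the generator does *not* emulate: cohort heterogeneity (dust-level
strata, smoking), CWP stage progression (I/II/III), calendar-period
effects, and the exact supplementary values. Passing tests therefore
demonstrate that the *machinery* — back-adjustment, propagation,
accrual, dominance, PSA — is correct and that qualitative conclusions
(arm ordering, dominance of individual protection, engineering controls
optimal at 3x GDP) are reproduced under realistic inputs; they do not
certify the published absolute costs and QALYs, which are not
desk-reproducible without the original schedules.

`generate_life_table_cohort()` supports estimator testing: onset and
withdrawal are competing exponential processes whose annual event
probabilities equal the spec's values, so a same-year withdrawal only
censors a case when it occurs first. This matches the actuarial
assumption behind $\hat P = I/(N_0' - W/2)$ (withdrawals at risk half
the interval on average) and makes the estimator unbiased to
$O(p^2)$ — the 20-seed parameter-recovery test verifies mean bias
within three pooled binomial standard errors.

## Problem sizes

The test suite verifies the cohort engine against a seeded 100,000-miner
individual-level microsimulation at every cycle (three Monte-Carlo
standard errors), runs the PSA determinism and limit checks at 10,000
iterations, and the estimator recovery at 20 seeds x 50,000 miners.
These sizes give Monte-Carlo error well below every tolerance asserted
while keeping a full test run around fifteen seconds.

## Known limitations

- The enterprise perspective excludes post-diagnosis treatment and
  compensation costs; an arm's "cost" is prevention investment only.
- Whether prevention cost keeps accruing for miners already in the CWP
  state is unknowable from the sources; the default says yes
  (`cost_states` toggles it).
- Transition probabilities carry no uncertainty in the PSA.
- No CWP staging, smoking covariates, or individual-level production
  mode (the microsimulation exists only as a test oracle).
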