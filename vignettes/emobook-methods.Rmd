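---
title: "Emotional bookkeeping in a simulated macaque group: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emotional bookkeeping in a simulated macaque group: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emobook)
```

## The question

Primates maintain differentiated affiliative relationships, yet it is
debated what cognitive machinery this requires.  *Emotional bookkeeping*
is a low-cognition candidate: an individual accumulates the emotional
effect of past affiliative interactions with each partner into a
partner-specific attitude, without remembering who did what and when.
`emobook` implements an agent-based model of a small macaque-like group
in which such attitudes (called **LIKE**) emerge from received grooming,
decay over a configurable timescale, and optionally feed back on partner
choice.  The package exists to ask: over which memory timescales, and at
which degrees of partner selectivity, does this bookkeeping produce
stable, reciprocated grooming partner preferences?

## The model

Twenty agents live on a 300 m square torus.  Each has a fixed dominance
strength `myDOM` (by default evenly spaced on 0.05–1.00), a position,
heading and 120° view angle, and a three-dimensional emotional state —
*arousal* (readiness to act), *anxiety* (aversive activation) and
*satisfaction* (contentedness), each in [0, 1].  Toward every group
member it holds two directed attitudes:

* **FEAR(i,j) = myDOM(j) − myDOM(i)** — fixed, governing
  aggression/submission tendencies;
* **LIKE(i,j) ∈ [0, 1]** — dynamic, driven by grooming received from j.

Time is continuous, in simulated minutes (a day is 12 h, a year 50
weeks of 7 days, a month 1/12 year = 21 000 min).  The simulation is
event-driven: the agent with the lowest scheduled time activates; all
time-dependent state is brought up to date lazily; the agent executes a
pending movement step, or — if fewer than 3 others are within 20 m or
anyone is beyond 100 m — performs grouping, or otherwise selects an
action.  Resting and grooming bouts are re-examined after
Normal(7.5, 0.375) min; movement proceeds in 3-s steps at 0.6 m/s;
reactions to signals and observed fights occur 0.1 ± 0.005 s later;
discrete acts are followed up after Normal(1, 0.05) min (all delays are
truncated positive).

### Emotion dynamics

All continuous dynamics are *linear, rate-limited, clipped* approaches to
context-dependent limits — the description of the system is phrased
entirely in per-minute rates, so no exponential smoothing is involved:

* arousal moves at 0.02/min toward a context limit (default 0.09;
  being groomed 0.0; grooming 0.04; dominant within 5 m 0.3);
* anxiety decays to 0 at 0.002/min (0.01 while grooming, 0.02 while
  being groomed) and jumps instantaneously on events: receiving an
  attack (+0.3) more than giving one (+0.15); winning a fight, receiving
  submission or an affiliative signal lower it (−0.1);
* satisfaction rises at 0.1/min while receiving grooming and 0.05/min
  while giving, else decays at 0.02/min;
* the partner-specific satisfaction `PARTNER_SAT(i,j)` rises at 0.1/min
  only while j grooms i, else decays at 0.02/min.

The central update couples this to memory.  Whenever LIKE(i,j) is
brought up to date after an interval `dt`,

$$\mathrm{LIKE}_{t} \;=\; \max\!\left\{
  \frac{LHW \cdot \mathrm{LIKE}_{t-dt} + dt \cdot \mathrm{PSAT}_{t}}
       {LHW + dt},\; \mathrm{PSAT}_{t}\right\}$$

`LHW`, the LIKE-history weight (minutes), is the half-life of LIKE over
a single spanning update: `update_like(1, 0, L, L) == 0.5` for every
`L > 0`.  At `LHW = 0` LIKE collapses to the instantaneous partner
satisfaction.  The swept grid is LHW ∈ {0, 180, 720, 5400, 21600} min
(no memory up to a one-month half-life) × LPS ∈ {0, 0.5, 0.9, 0.95,
0.99}.

**Update policy.**  The update equation is not composition-invariant:
splitting an interval into sub-updates decays faster than one spanning
update (this is a tested property).  The engine therefore supports two
policies.  The default, `like_policy = "lazy"`, re-bases a dyad's LIKE
only at *LIKE-relevant* moments — the start and end of a received
grooming bout (and continuously during it, which keeps the running-max
floor) — and otherwise evaluates it read-only from the last base point.
This preserves the printed half-life semantics exactly.  The
alternative, `"per_activation"`, re-bases every row at each activation
of its owner, which makes effective decay faster than nominal; it is
retained as a switch because an implementation following the activation
schedule literally would behave this way.

### Action selection

Candidates are the ≤ 10 nearest individuals within 50 m and the current
view angle (anyone within 1 m is always perceived).  The distribution
over behavior–partner pairs is built from base weights per behavior
class multiplied by:

* an activity factor `0.1 + 0.9·arousal` for every active behavior, with
  the rest weight scaled by `1 − 0.9·arousal` — the probability of being
  active increases with arousal;
* an affiliation motivation `(1 + anxiety)·(1 − 0.5·satisfaction)` —
  anxiety promotes affiliation more strongly than satisfaction dampens
  it, a deliberately conservative choice that avoids a direct positive
  loop from satisfaction into LIKE;
* a *relative* selectivity factor on grooming, affiliative signalling
  and approaching: with the mixture `mix(j) = (1 − LPS) + LPS·LIKE(i,j)`,
  partner j's affiliative weight is scaled by
  `(mix(j) / mix(best))^γ`, where `mix(best)` uses the highest LIKE ego
  currently holds toward anyone.  At LPS = 0 the factor is identically 1
  and the code never reads a LIKE value (an instrumented counter in the
  engine verifies this);
* a near-distance bias `(1 − d/50)^6` on approaches, keeping partner
  choice local and producing persistent spatial neighborhoods;
* `plogis(−4·FEAR)·(1 − anxiety)` on attack/aggressive signalling and
  `plogis(4·FEAR)·(1 + anxiety)` on leave/submissive signalling/avoid.

Distance gates: groom/attack/leave within 1 m; signals and avoidance
within 5 m; approaches up to 50 m.  Attacked individuals respond
immediately: they counter-attack with probability
`plogis(4·(myDOM_victim − myDOM_attacker))` (0.5 at equal rank, higher
against lower-ranking attackers), which escalates into a fight whose
winner is drawn from `w_ij = 1/(1 + exp(−η(myDOM_i − myDOM_j)))` with
η = 4; the loser flees, and bystanders within 5 m receive an
observe-fight event and a fast reaction activation.  Scanning (view
widened to 360°) occurs only at rest, with probability increasing in
arousal.

Two design choices in the affiliation weights deserve justification,
because the exact published probability functions are not available and
the constraints they must satisfy leave a family of candidates.

First, the selectivity factor is *relative* rather than absolute.  An
absolute factor `mix(j)^γ` multiplying every affiliative weight fails
at high selectivity: at LPS = 0.99 all LIKE attitudes start at 0, the
factor is `0.01^γ` for everyone, grooming never starts, and therefore
LIKE can never grow — the behavior collapses to zero grooming instead
of the documented moderate decrease.  Normalizing by the best available
mixture preserves the intended property (the *choice between partners*
becomes steeply dependent on LIKE differences as LPS rises) while
leaving the overall affiliative propensity finite: an agent with no
differentiated attitudes chooses partners uniformly, and an agent with
a strongly LIKEd partner suppresses affiliation toward everyone else —
which is what makes total grooming fall as selectivity rises.  The
sharpening exponent γ (default 3) steepens this contrast: at LPS =
0.99, LIKE 0.9 vs 0.1 gives relative odds ≈ 550 : 1 instead of the too
flat 8.2 : 1 of the linear mixture.

Second, approaches carry a near-distance bias `(1 − d/50)^6`.  Without
it, partner choice is spatially uniform over the whole 50 m perception
range, the group mixes completely within days, monthly grooming spreads
thinly over nearly all partners, and *no* partner ever exceeds the 10 %
preference threshold — even the null model then has no preferred
partners, contradicting the documented month-scale preference bouts at
LPS = 0.  A strong near bias creates persistent spatial neighborhoods,
the proximity-driven concentration that the null model's preferences
rest on.  Both the exponent and the bias power are configurable.

### Numerical and degenerate-case choices

* Scheduling ties are broken by the lowest agent id; together with a
  single seeded RNG stream consumed in a fixed order this makes runs
  bit-identical under a fixed seed.
* All scheduling noise uses truncated normals (resampled while ≤ 0).
* Directed movement bouts carry a travel-time budget: the straight-line
  travel time to the target plus two minutes, and fleeing lasts at most
  one minute.  Without a budget, two agents moving at the same constant
  speed can lock into a pursuit whose distance never changes (e.g. a
  loser fleeing its pursuer), freezing the whole group in permanent
  grouping movement.  The budget is a modelling addition required to
  make the constant-speed movement submodel well-posed.
* An approach stops once within 1 m (aiming at half the interaction
  distance to avoid overshoot); avoidance/leaving/fleeing stop beyond
  5 m; after any movement bout a proximity update refreshes the arousal
  limits of the mover and of lower-ranked neighbors within 5 m.
* A dyad's LIKE floor (the max with current partner satisfaction) means
  LIKE never decays below the satisfaction still attributable to an
  ongoing bout.
* Rows without variance are skipped in both matrix correlations; if all
  rows are degenerate the statistic is `NA` with a warning.  Row-wise
  Kendall reciprocity uses tau-b (tie-corrected), computed from the
  definition by exhaustive pair counting; preference-duration matrices
  are heavily tied, so tie correction matters.
* The preferred-partner rule uses a strict `> 10%` share of the actor's
  monthly grooming; an actor that groomed nobody that month has no
  preferred partners.  Dyads with no preference bout contribute 0 to
  group-mean bout durations (exclusion is available via
  `zero_for_no_bouts = FALSE`).

### Calibrated defaults

Event-increment magnitudes, context arousal limits and the behavioral
base weights are not published constants; they are package defaults
chosen once to satisfy every stated ordering/sign constraint and then
calibrated so that a default-parameter run (LHW = 720, LPS = 0.5)
yields a mean grooming-bout duration inside the established 5.7–6.3 min
band.  The dominant lever is the rate of interruptions — signals
received by a groomer, observed fights, and the groomed partner moving
off — relative to the Normal(7.5, 0.375) min bout re-examination
schedule.  The shipped weights give ≈ 6.0 min at the desk tier across
seeds.  All of these live in `emo_params()` and can be overridden from
a YAML config.

## What the generator emulates — and what it does not

The simulator *is* the study system: there is no empirical input.  Its
defaults encode the study conditions — 20 individuals, fixed despotic
rank order, two recorded years after an LHW-dependent stabilization of
`max(6000, 10·LHW)` min, LIKE sampled every 3.5 days, grooming
accumulated per 3.5-day interval and per month, and the 5 × 5 LHW × LPS
grid with 10 replicates.  It does not model kinship, coalitions,
reconciliation, ecology, demography, or dominance change, and the
emotional processes are stylized (linear rates, a single groomer per
receiver at a time).  Passing tests therefore show internal consistency
of the mechanism and its analysis layer, not fidelity to any particular
macaque population.

## Problem sizes used in tests

The packaged checks run scaled tiers chosen as the package's own
defaults for interactive verification: a **smoke** tier (one recorded
week, one-day burn-in) for distributional and invariance checks, and a
**desk** tier (two recorded months, 100-hour burn-in) for bout-duration
and direction-of-effect checks.  Full-scale results (two recorded
years, 250 runs) use the same code path via `preset_params("full")`
and `run_sweep()`; a single full run takes on the order of an hour, the
complete grid an overnight batch.  Quantities that need the full
horizon — e.g. mean preference-bout durations around 2.25 months at
LHW = 720, LPS = 0.99, or reciprocity above 0.875 — are only checked
directionally at the desk tier (higher selectivity must increase
preference stability, reciprocity and the grooming–LIKE match).

## Known limitations

* The two-month desk tier yields only two monthly blocks, so
  preference-bout statistics there are coarse (values 0, 1 or 2
  months); they are used for directional comparisons only.
* Event-increment magnitudes and behavioral base weights are
  constrained calibrations, not published values; conclusions that
  depend on their exact magnitudes (rather than their orderings) should
  be re-examined under the YAML config interface.
* The lazy LIKE policy evaluates decay from the last grooming episode,
  which is exact for the half-life semantics but means two successive
  read-only evaluations see a slightly different trajectory than an
  implementation committing at every activation (`"per_activation"`);
  both are available, and the difference vanishes as LHW → 0.
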