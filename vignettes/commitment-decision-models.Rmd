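---
title: "Commitment motion models and pass decision valuation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Commitment motion models and pass decision valuation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(commitval)
```

This vignette is the package's own account of its models: what is being
estimated, which choices were forced by the problem, which were genuinely
open and how they were settled, and what the synthetic-data tests do and do
not establish. No empirical number is quoted here that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The problem

In Australian Rules football the ball is not tracked; only players are
(10 Hz positional streams), alongside manually coded match events at whole
seconds. Two coupled questions are addressed:

1. **Where will a player go when the ball drops into a contest?**
   Classical motion models answer with kinematic reachability (Voronoi
   regions, arrival-time discs). Here the answer is *behavioural*: a
   probability learned from what players actually did at thousands of real
   contests.
2. **How good was a pass, relative to the kicker's best option?** Every
   location in kicking range is scored by risk (can we mark it? will we
   own the space?) and reward (what is possession there worth?), and the
   executed pass is compared with the best teammate option available at
   the moment of the kick.

## 2. Commitment modelling

### Definitions

* A **contest** is a spoil or contested mark following a pass, at a
  location inferable from the event stream. Both moments matter: the kick
  at `t_p` and the contest at `t_c`.
* A player **committed** iff their distance to the contest location at
  `t_c` is ≤ 2 m. The boundary is inclusive: the source material is
  ambiguous between "< 2 m" and "≤ 2 m" and the procedural form (≤) was
  adopted; the radius is a parameter of `build_observations()` so the
  other reading is one argument away.
* Training rows are only recorded for players within **35 m** of the
  contest at `t_p` (options are confined to a 60 m kicking radius, so the
  ball arrives within ~4 s and players cannot usefully relocate from
  further than ~30 m; the cap bounds compute). The 35 m reference point is
  the player's position at `t_p`.

### The estimator

The committed and non-committed rows are 4-D points
`(velocity, time_to_point, rel_x, rel_y)`. Each class gets a Gaussian
product-kernel density estimate with a **single bandwidth of 1.5 applied
to all four dimensions without standardisation** — deliberately a literal
implementation: the four coordinates have mixed units (m/s, s, m, m) and
one could argue for per-dimension scaling, but the fitted surfaces are
used through the *ratio*

`Pr = w f1 / (w f1 + (1 − w) f0)`, `w = n1/(n1 + n0)`,

and the shared kernel constant cancels there. A per-dimension bandwidth
vector is accepted for experimentation but is not the default.

Numerical choices:

* **Underflow far from data.** Where both class densities underflow, the
  posterior is defined as 0 ("no influence") and flagged; this prevents
  0/0 and matches the intuition that a player exerts no influence 100 m
  away. In the compiled kernel sums, exponents below −60 are skipped
  (contributions < 1e−26 of a unit kernel).
* **Evidence floor for peaks.** A ratio of two density estimates is
  untrustworthy where *both* are near zero: one isolated training row in
  an otherwise empty region can push the posterior to ~1. When a motion
  grid reports its argmax, cells carrying less kernel mass than
  `min_evidence = 5` training rows are excluded from the *search* (the
  returned surface itself is never masked). Without this, grid peaks on
  moderate corpora occasionally jump to unsupported cells many metres
  behind the player.
* **Grids.** Surfaces are sampled at integer-metre cell centres, `rel_y`
  positive ahead of the player. At a fixed (velocity, time) slice the
  product kernel separates, so a full 71×71 grid is two small matrix
  crossproducts per class rather than a per-cell kernel sum; the
  element-wise compiled path remains the reference implementation and the
  two are cross-checked in the tests to 1e−6.
* **Players with undefined kinematics** (no frame 1 s earlier, or
  sub-epsilon displacement with no carried heading) are excluded from
  training but treated as stationary with an arbitrary heading at
  inference — with velocity 0 the fitted densities are nearly isotropic,
  so the arbitrary frame has little leverage.

## 3. Control, outcomes, expected value

Team influence is the plain sum of the 18 players' commitment
probabilities; no clipping is applied even though the sum can exceed 1,
because the downstream products (`DOM × INF`) are what carry meaning and
the literal form reproduces the expected scale of risk values (~0.2).
Dominance at a cell with no influence from either team is defined as 0.5
(neutral). The four outcome probabilities `p_A = DOM_a INF_a`,
`p_B = DOM_a`, `p_C = DOM_o INF_o`, `p_D = DOM_o` are used exactly as
defined — they do not sum to 1; an optional normalised mode exists but is
off by default, matching the source formulation.

`EO = (p_A + p_B) e_a − (p_C + p_D) e_o` is computed cellwise on a
rectangular grid clipped to the field's bounding box; grid corners fall
outside the oval and the equity surrogate simply extrapolates smoothly
there (`strict = FALSE`), which cannot affect results because passes and
teammates are always inside the boundary.

**Kicking-variance smoothing.** The likely landing point of a kick to `x`
is modelled as an isotropic 2-D Gaussian centred at `x`. "Covariance equal
to 5% of the kicking distance" is read as a standard deviation of
`0.05 × distance` metres, and the support `S` is the set of integer cells
within that same radius. Two deliberate deviations from the rawest
reading:

* the truncated Gaussian weights are **renormalised to sum to 1** over
  `S`, so a constant EO field is a fixed point of smoothing (the raw-PDF
  reading would shrink every value and make the smoother change fields it
  has no information to change);
* when the radius is under one cell (kicks below 20 m) the raw value is
  kept unchanged rather than degenerating to an empty neighbourhood.

**Decision value.** `DV = EO / EO_opt`, clamped below at −1. When
`EO_opt ≤ 0` the ratio flips sign and is meaningless, so DV is undefined
(`NA`, flagged) and the event is excluded from DV summaries. The
alternative search evaluates the *smoothed* EO at each teammate's current
position within 60 m of the kicker (smoothing precedes the comparison in
the pipeline, and evaluating options at player positions — not at motion
model peaks — matches the framing of a pass *to a teammate*); ties break
to the lowest player id for determinism. Decision metrics are read at the
receiver's mark location using the formation frozen at `t_p`: the
comparison is between options as they stood when the kick was taken.

## 4. Field equity: a surrogate, by necessity

The decision model needs `e_a(x)`, `e_o(x)` — the expected scoring value
of possession at `x` for either team. Published AFL equity models are
built from proprietary historical data and are not reproducible from their
descriptions, so the package treats equity as a **pluggable provider**:

* the default surrogate is
  `e(x) = V · [g(d_att, θ_att) − g(d_def, θ_def)]` with
  `g(d, θ) = exp(−d/L) · cos(θ/2)`, `V = 6` points (the value of a goal),
  `L = 35` m; `d` and `θ` are the distance and off-axis angle to each
  goal. It is monotone towards the attacking goal, decays off-axis,
  is exactly antisymmetric under team exchange (so deep-defensive
  positions have negative equity, which the decision model requires), and
  is zero at the centre. The ±6 scaling is a convention, not a claim about
  the real metric's units.
* `equity_lookup()` / `load_equity_table()` accept any gridded equity
  table (`x,y,equity_attacking_right`), with the attacking-left value
  defined as the mirrored lookup.

All decision code touches equity only through `equity_value()`, so
substituting a real equity surface changes no other component. Note that
EO is linear in the equity scale and DV is a ratio of EOs, so **DV is
invariant to the surrogate's overall scale** — one reason the surrogate
is adequate for decision-value analysis even though its absolute EO
numbers are conventional.

## 5. The synthetic world

The generator exists because the real feeds are proprietary. It emulates
exactly the structures the pipeline consumes and nothing more: no rucks,
stoppages, scoring, or tactics.

* **Trajectories.** Each player pursues a per-passage anchor at an
  individual preferred ("cruise") speed with Gaussian velocity noise and a
  hard cap — a mean-reverting process producing smooth tracks and a broad,
  right-skewed speed distribution. Cruise speeds are drawn from
  0.3–10 m/s (elite sprint maxima reach ~10 m/s); covering the queried
  velocity range matters because a KDE queried at the edge of its support
  is pulled towards the data interior.
* **Passages.** Mark → 2 s hold → kick → ball flight at 18.5 m/s →
  either a clean receiving mark or a planted contest (spoil/contested
  mark) at the pass destination. Transactions are whole-second; pass
  distances span 10–65 m so integer ball times-to-point cover 1–4 s.
* **Contests draw packs.** The contest destination is chosen near an
  intended receiver (preferring one with an opponent within reach), and a
  handful of nearby players from both teams re-anchor towards the drop
  zone during the hold — contests happen where players converge, which is
  also what gives the corpus a realistic committed fraction (~7–8% of
  within-35 m observations).
* **Ground truth.** At the kick instant every player within 35 m draws
  commitment from a logistic rule in (distance, velocity, time-to-point,
  reorientation angle): a bump centred at the player's velocity-scaled
  arrival distance `μ = 1.25 v` (momentum carries a runner to a braking
  point ahead, and `μ` must separate the queried velocity slices by more
  than the grid step plus smoothing blur for the peak ordering to be
  resolvable at desk-scale corpora), an `exp(−0.5 (t − 1))` decay strong
  enough to remain visible through the fixed bandwidth-1.5 smoothing of a
  1–4 s time axis, and a forward bias `exp(−(1 + 0.3 v)(θ/π)²)` present
  even at low speed (players face the play) and strengthening with
  velocity. The rule's family (logistic) is deliberately not the fitted
  model's family (KDE posterior), so recovery tests are non-circular.
* **Exactness.** Committed players are steered to within 1.5 m of the
  contest by `t_c`; non-committed eligible players that drift inside
  2.3 m are nudged back out. Positions are generated at the documented
  interchange precision (1e−6 m), so the in-memory stream, the CSV
  round-trip, and the ledger agree and the pipeline's extracted labels
  equal the ledger's Bernoulli draws *exactly*, with no stochastic slack.

What a green recovery test establishes: the full pipeline (consolidation,
contest extraction, feature construction, two-class KDE, posterior
evaluation) recovers the planted ordinal structure — peak position
increasing with speed, peak probability decreasing with time-to-point —
from data it has never seen in labelled form. What it does **not**
establish: anything about real match data, real commitment ranges, or the
real magnitudes of those trends; the generator's world is simpler than
football (no packs of >6, no tactical structure, isotropic noise), and
all numeric levels (peak heights, commit fraction) are properties of the
chosen rule parameters, not findings.

## 6. Statistics

Decision/alternative comparisons use the Mann–Whitney U test with average
ranks, the tie-corrected normal approximation and a continuity
correction; an identical-samples edge case returns `p = 1` by convention.
The implementation is in-package and is validated in the tests against a
complete enumeration of group assignments at small n. Spearman's ρ is
Pearson on average ranks (validated against `stats::cor`). 1-D density
profiles for distribution shape use `stats::density` with a plug-in
bandwidth by default — the 1.5 bandwidth is specific to the 4-D
commitment model and there is no stated value for profiling, so the
standard `bw.nrd0` rule is used and exposed as a parameter. Raw p-values
are reported without multiple-testing correction, and the report says so.

## 7. Known limitations

* Ball position exists only at transaction instants; nothing is
  interpolated between possessions.
* The surrogate equity is a stand-in: absolute EO values are conventional
  (DV is scale-invariant, see §4).
* One pooled motion model for all players; no individualisation and no
  teammate-aware commitment (a committed teammate presumably lowers a
  neighbour's need to commit).
* Constant straight-line ball flight at 18.5 m/s; no trajectory model,
  and kicking error is a one-parameter isotropic Gaussian.
* Handballs, shots on goal, and decisions not preceded by a mark are out
  of scope; only mark → kick → mark chains are valued.
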