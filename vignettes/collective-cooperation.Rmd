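---
title: "Modelling collective cooperation in dense crowds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling collective cooperation in dense crowds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdcoop)
```

## The problem

A pedestrian who must get through a dense, stationary crowd — a first-aid
attendant, a passenger leaving a packed platform — cannot do it by collision
avoidance alone. At a crossing density of 5.30 ped m⁻² the gaps between
bodies are narrower than a body, so a purely repulsive microscopic model has
no admissible path: the walker either overlaps the crowd (unphysical) or
deadlocks in front of it. Real people cross anyway, because the crowd
*cooperates*: people notice they are stuck, accept a brief change of role,
and trade places with a neighbour.

`crowdcoop` models this with two layers. A **locomotion layer** moves each
agent kinematically; a **psychology layer** — perception, cognition,
behaviour selection, run in that order every step — decides *what* the agent
is trying to do. The crossing then emerges from the interaction of the two,
not from any special-cased path-finding.

## The model

### Locomotion: utility maximisation on a step disc

Each step interval `dt`, a target-oriented agent evaluates candidate
footholds on a disc of radius `v_free · dt` (16 directions × 4 radii, plus
staying put) and takes the admissible candidate maximising

$$u(p) = -w_t\,d_\mathrm{target}(p)
        \;-\; w_a \sum_i e^{-g_i(p)/\rho_a}
        \;-\; w_o \sum_k e^{-g_k(p)/\rho_o},$$

where $d_\mathrm{target}$ is the Euclidean distance to the nearest point of
the target region (the corridor is convex, so this equals the geodesic
distance), and $g_i$, $g_k$ are surface-to-surface gaps to neighbours and
obstacles. Admissibility is a *hard* constraint, separate from utility: the
whole swept segment of the step must keep centre distance ≥ 2 · body radius
from every neighbour and body-radius clearance from every obstacle and the
domain boundary. Checking the swept segment, not just the endpoint, matters:
at stride-scale steps (≈0.8 m) an endpoint-only check lets an agent tunnel
through a rank of the crowd between two frames.

Two further rules make the chooser well behaved in crowds. The agent moves
only on a *strict* utility improvement over staying put, so a blocked agent
stands still (recorded speed 0) instead of dithering; and ties are broken
deterministically (smallest angle to the target, then smallest radius), so
runs are reproducible.

The repulsion weights (`w_a = 0.08`, `ρ_a = 0.3` m; `w_o = 0.3`,
`ρ_o = 0.3` m against `w_t = 1`) are deliberately weak: repulsion shapes the
path, while blocking is entirely the hard constraint's job. This was a
genuine design decision with a wrong answer we rejected: with strong agent
repulsion (e.g. `w_a = 0.25`, `ρ_a = 0.5`), the *summed* exponential terms
of 13 agents form a potential wall comparable to a whole step's target gain,
and the utility maximiser prefers skirting the crowd sideways indefinitely —
the agent never presses against the crowd face, so the cooperation trigger
below never fires. Weak repulsion also guarantees that retreating from the
crowd face never pays: the marginal repulsion relief of a backward step
(bounded by `2 w_a/ρ_a` per metre near contact) is below the target-distance
cost.

A social-force baseline (`social_force_step`: velocity relaxation toward the
target at time constant τ = 0.5 s plus exponential repulsion, Euler substeps
of ≤ 0.05 s, speed capped at free-flow, the same hard non-overlap) is
included because it exhibits the classic failure: against the 13-agent
crowd it equilibrates at a standoff in front of the first rank and makes
less than 0.2 m of progress in 60 s.

### Psychology: perception, cognition, cooperative swapping

* **Perception** (`perceive`): the neighbours within search radius `r`
  (default 1.0 m), a closed ball, sorted by distance then id. The shipped
  perception model carries no external stimuli — there were none in the
  study situation being re-enacted — but the sub-layer is a separate,
  single-purpose function so richer percepts can be slotted in.
* **Cognition** (`update_cognition`): keyed on the agent's own recent
  kinematics only, matching the layering contract (each sub-layer consumes
  only what the layer above produced plus the agent's own state). If each of
  the last `n_history = 3` step speeds is below `v_threshold`, the agent has
  effectively stopped: it becomes COOPERATIVE. If the mean of the last 3
  speeds is at or above the threshold, it reverts to its role's default
  (TARGET_ORIENTED for the walker, WAIT for a waiter). In between, the
  category is unchanged. With fewer than 3 recorded speeds no transition
  occurs, which is why a freshly started simulation shows the waiting crowd
  turning cooperative at step 4 — the earliest step with a full history.
* **Behaviour**: a cooperative agent looks for a swap partner among
  perceived cooperative neighbours strictly closer to its target, choosing
  the one closest to the target (ties to the smaller id), and exchanges
  positions with it exactly, within one step. Both partners carry a one-step
  swap cooldown, so an exchange cannot immediately un-do itself. Waiters
  have no target, so they never initiate swaps; they are passive partners.
  A cooperative agent with no partner available simply attempts a normal
  locomotion step (for a waiter: stands).

Two parameter choices here deserve their rationale:

* `v_threshold = 0.2` m s⁻¹. The threshold must sit far below purposeful
  walking (≈1.3 m s⁻¹) so an unobstructed walker never turns cooperative,
  but *above* the residual shuffling speed of an agent pressed against the
  crowd face: the discrete chooser occasionally finds centimetre-scale
  admissible adjustments whose instantaneous speeds reach ~0.3 m s⁻¹ at
  stride-scale `dt`. A threshold of 0.05 m s⁻¹ — the other natural choice —
  can starve the trigger entirely and reinstate the deadlock *with* the
  psychology layer on.
* `swap_reach = 0.8` m (< `r`). A position swap is a physical manoeuvre with
  an adjacent person. If eligibility extended to the whole percept
  (radius 1 m), the walker would regularly "swap" with an agent two ranks
  ahead, teleporting through the intervening body. The reach admits nearest
  and diagonal neighbours of the crowd grid (0.39–0.55 m apart) and excludes
  the next-but-one rank (≥ 1.0 m).

### The simulation loop

Each step, agents act in a seeded random order (sequential updating avoids
simultaneous-swap conflicts; the first swap wins and the loser retries next
step). Every agent runs perceive → cognition → behaviour; realised
displacements feed the speed histories; all positions are recorded each
frame. The run ends when the walker reaches the target region or the 60 s
horizon expires, which is reported as `crossed = FALSE`, not an error.
Everything is bit-reproducible per seed.

## The re-enactment scenario

`build_reenactment_scenario()` reconstructs the crossing study from its
printed dimensions: a 1.55 m × 1.70 m waiting area (2.635 m², printed
rounded as 2.64 m²) holding 13 waiting agents, one walker starting below it,
a target area above it, and table strips flanking the area so the only route
leads through the crowd — 14 agents over 2.635 m² is the printed crossing
density of 5.30 ped m⁻². Coordinates are metres, origin at the domain's
bottom-left, walking direction +y.

The waiting crowd's real standing positions were never published (any layout
matching n and the density is admissible), so placement is a deterministic
centred grid: 4 ranks of 4/3/3/3 agents, inset half a body radius from the
area edges, short ranks centred at the full ranks' spacing so the ranks are
staggered like a packed crowd. Determinism keeps the crowd identical across
all batch runs; the real experiment's crowd-shuffling between runs was a
measure against human training effects, which simulated agents do not have.
The walker starts centred in x (jittered ±0.3 m across a batch, the
"slightly varying initial position") with free-flow speed drawn per run from
a truncated normal (mean 1.34 m s⁻¹, s.d. 0.26, bounds [0.5, 2.2] — the
canonical empirical free-flow distribution).

Key defaults and why:

| parameter | default | role |
|---|---|---|
| `dt` | 0.6 s | step interval ≈ stride duration; calibrated, see below |
| `r` | 1.0 m | perception radius: the immediate vicinity people attend to |
| `n_history` | 3 steps | immobility evidence window (≈2 s) |
| `v_threshold` | 0.2 m s⁻¹ | "cannot move anymore" boundary (see above) |
| `body_radius` | 0.195 m | torso radius; makes 5.30 ped m⁻² feasible |
| `swap_reach` | 0.8 m | adjacent-partner limit for swaps (see above) |
| `t_max` | 60 s | horizon; a blocked run fails rather than hangs |

**Calibration of `dt`.** A stepped optimal-steps model advances roughly one
stride per update, suggesting `dt` in the 0.4–0.7 s range. Within that
range, `dt` sets the pace of the swap cycle (one swap per `n_history + 1`-ish
steps) and hence the in-area crossing time, so we calibrated it against the
reported mean in-area duration of the original re-enactment batch
(9.90 ± 2.24 s): over `dt ∈ {0.4, 0.5, 0.6, 0.7}` the 100-run batch mean
in-area duration is 7.10, 8.58, 10.06 and 11.42 s, with the crossing rate
(100/100) and the mean outside speed (1.347 m s⁻¹) unchanged. `dt = 0.6 s`
is the closest match and is the default. This is the one parameter fitted to
a batch-level outcome; the model itself acknowledges needing this kind of
calibration, and no other parameter was revisited afterwards.

## Analysis toolkit

The same code measures simulated and experiment-style trajectories:

* `instantaneous_speeds`: $v(t) = \sqrt{\Delta x^2 + \Delta y^2}/\Delta T$
  per frame transition (ΔT = 0.04 s for 25 fps video; `dt` for simulation
  output). Non-uniform frame spacing is an explicit error.
* `mean_speed` / `region_stats`: arithmetic mean over masked frames; a speed
  is attributed to the frame its transition lands on; an empty mask errors
  rather than returning NaN.
* `split_inside_outside`: the inside mask is the closed waiting-area
  rectangle; the free-flow ("outside") mask is a same-width window 1.5 m
  long ending 0.6 m *before* the entrance edge. The setback is deliberate:
  the walker queues at the crowd face ~0.3–0.4 m before the first rank, and
  a window adjacent to the entrance would average standing frames into the
  "free-flow" estimate. The real measurement region was likewise clear of
  the crowd.
* `duration_in_area`: inside-frame count × ΔT.
* `displacement_stats`: end and maximum Euclidean distance from the initial
  position (max ≥ end by construction).
* `paired_onesided_ttest`: $T = \sqrt{N}\,\overline{\Delta v}/s_{\Delta v}$
  with the sample (N−1) standard deviation, tested against the lower 5%
  t quantile (−1.70 at N = 30); zero variance is a precondition error.
* `ks_fit_survey`: maximum-likelihood fits (via `fitdistrplus`) over a
  configurable candidate list (default: normal, log-normal, gamma, Weibull,
  exponential), one-sample KS p-values, strict `p > 0.90` retention.
  Caveat, stated rather than hidden: the p-values use the asymptotic KS
  distribution without a fitted-parameter correction, so they are biased
  upward for fitted families; that matches how such surveys are commonly
  run, and the retention rule is a screen, not an inference.

## What the synthetic data does and does not show

The fixture generator (`generate_fixture`) produces trajectories with known
kinematics — constant velocity, out-and-back, seeded random walks, a
blocked-then-crossing profile — so every analysis statistic can be tested
against closed-form or brute-force oracles (constant-speed recovery is exact
to 1e-12; displacement metrics match an explicit loop). These fixtures stand
in for extracted video trajectories, which are not available. They emulate
clean, uniformly sampled head-point tracks; they do not emulate tracking
noise, optical-distortion residues, body sway, or the contact-zone
negotiation of real crowds. Passing tests therefore demonstrate that the
*measurement code* is correct and that the *model* reproduces the
re-enactment's batch-level behaviour — not that the model's inside-crowd
micro-dynamics match real humans. Indeed the known gap carries over from
the original model: simulated inside-crowd speeds (≈0.27 m s⁻¹ mean) sit
well below the empirical ≈0.70 m s⁻¹, because a simulated walker's speed is
exactly zero while it waits to turn cooperative, whereas a real person keeps
inching forward. We check the inside speed only qualitatively
(inside ≪ outside).

## Numerical choices and degenerate inputs

* Boundary conventions are closed sets everywhere (a frame on the area edge
  is inside; a neighbour at exactly `r` is perceived), stated once and
  tested.
* Strict-improvement stepping with a 1e-12 margin plus deterministic
  tie-breaking makes the chooser's argmax stable under floating-point ties.
* Non-overlap uses a 1e-9 slack on the 0.39 m contact distance so that
  agents standing exactly at contact (e.g. right after a swap) are not
  spuriously rejected.
* Degenerate inputs error loudly and specifically: infeasible crowd packing
  (capacity error), empty analysis masks, zero-variance t-tests,
  non-uniform frame spacing, malformed trajectory files (with line numbers).
* `place_waiting_crowd` with n = 0 returns an empty layout; n = 1 sits at
  the centroid; the scenario builder accepts `n_waiters = 0`, giving the
  free-crossing control in which traversal time equals distance over
  free-flow speed to within one `dt`.

## Known limitations

* Waiters in WAIT do not move at all, so waiting-crowd displacement
  statistics are identically zero in simulation; the displacement metrics
  exist for experiment-style input. The observed tendency of real waiters to
  return near their initial positions (mean end displacement 0.14 m vs max
  0.25 m) is not modelled.
* Only pairwise swaps: no chains, no verbal negotiation, no shoving, no
  external stimuli (the architecture has the slots; the behaviours are out
  of scope).
* The stepped clock is declared, not inferred: the original implementation's
  internal update scheme was not published, and second-order timing
  quantities (notably the inside-crowd mean speed) depend on it; that is
  exactly why the inside speed is held to a qualitative check only.
* One walker per scenario is the studied condition; the engine runs any
  roster, but multi-walker cooperation has no empirical anchor here.

## Problem sizes

The test suite and the acceptance script use the study-scale problem
throughout: 14 agents, ≤100 steps per run, and 100-run batches (~30 s on one
CPU). Statistical checks on the sampler use 10 000 draws; the KS survey
examples use 2 000–5 000.
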