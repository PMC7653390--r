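# crowdcoop

Agent-based simulation of **collective cooperation in dense crowds**: a
single walker forging a path through a dense, stationary waiting crowd,
together with the trajectory statistics used to quantify the phenomenon.

Classic microscopic locomotion models fail at this task. Purely repulsive
agents either walk over the crowd or deadlock against it: at a crossing
density of ρ = 5.30 ped m⁻² there is simply no collision-free path, so no
amount of collision avoidance gets the walker through. Real people get
through anyway — by cooperating. `crowdcoop` operationalises that as a
*psychology layer* of three sequential sub-layers executed every simulation
step, on top of an optimal-steps-style locomotion layer:

1. **Perception** — each agent perceives the neighbours within a search
   radius *r* (closed ball, default 1 m).
2. **Cognition** — an agent that "cannot move anymore" (each of its last *n*
   step speeds below a threshold v⁎) switches its self-category from
   target-oriented (or waiting) to **cooperative**; when its mean recent
   speed recovers above v⁎ it switches back.
3. **Behaviour** — a cooperative agent swaps positions with an adjacent
   cooperative neighbour that is closer to its target (ties to the smaller
   id), completing the exchange within one step.

The walker's ability to cross the crowd *emerges* from these rules: with the
layer disabled the optimal-steps walker deadlocks at the crowd face for the
whole 60 s horizon; with it enabled, every run of the 100-run re-enactment
batch crosses.

The locomotion layer picks each agent's next foothold on a disc of radius
`v_free · dt` by maximising

```
u(p) = −w_t · d_target(p) − w_a · Σ_i exp(−gap_i / ρ_a) − w_o · Σ_k exp(−gap_k / ρ_o)
```

subject to hard non-overlap (centre distance ≥ 2 · body radius along the
whole swept step) and obstacle clearance. A social-force baseline
(driving force plus exponential repulsion) is included for the deadlock
demonstration.

The analysis toolkit implements the statistics used on the real experiment's
video trajectories, so simulated and experiment-style trajectories are
measured with identical code: instantaneous speeds v(t) = ‖Δp‖/ΔT,
region-averaged means (Eq.-style v̄ = (1/N) Σ v(t)), in-area duration,
end/max displacement metrics, the slow-down factor v̄_out/v̄_in, a paired
one-sided t-test T = √N · mean(Δv)/sd(Δv), and a Kolmogorov–Smirnov
distribution-fitting survey with strict p > 0.90 retention.

## Worked example

```r
library(crowdcoop)

scn <- build_reenactment_scenario()
scn
#> <crowdcoop scenario>
#>   waiting area: 2.635 m^2, 14 agents (13 waiters + 1 walker)
#>   crossing density: 5.31 ped/m^2
#>   dt = 0.60 s, r = 1.00 m, n_history = 3, v_threshold = 0.20 m/s

res <- run_simulation(scn, seed = 5, jitter_x = 0.3)
res$summary
#>   crossed duration_in_area mean_speed_inside mean_speed_outside n_swaps seed
#> 1    TRUE             10.2         0.2682698           1.465438       4    5

run_simulation(scn, seed = 5, psychology = FALSE, jitter_x = 0.3)$summary$crossed
#> [1] FALSE
```

The walker (free-flow draw 1.47 m s⁻¹ this run) walks the approach corridor
unhindered, stalls at the crowd face, turns cooperative, and works through
the four ranks of the crowd with 4 position swaps, spending 10.2 s inside
the 1.55 m × 1.70 m waiting area — far more than the 1.70/1.47 ≈ 1.2 s a
free crossing would take, and its mean speed inside (0.27 m s⁻¹) is far
below its free-flow speed outside. With the psychology layer off the same
seed never crosses.

A batch, and the analysis side:

```r
batch <- run_batch(scn, n_runs = 100, base_seed = 1000, jitter_x = 0.3)
c(crossed = sum(batch$crossed),
  outside = mean(batch$mean_speed_outside),
  duration = mean(batch$duration_in_area))
#>   crossed    outside   duration
#> 100.00000    1.34676   10.05600
```

A command-line interface wrapping the same functions ships at
`inst/cli/crowdcoop.R` (subcommands `run`, `batch`, `analyze`, `fixtures`);
an example scenario config and a small synthetic trajectory file live in
`inst/extdata/`.

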