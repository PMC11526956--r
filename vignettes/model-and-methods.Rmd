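---
title: "An evolutionary model of negative feedback in immune signaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An evolutionary model of negative feedback in immune signaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nflevo)
```

## The question

Signaling pathways attenuate their own activity with negative feedback loops
(NFLs): proteins induced by signaling that downregulate the response, either
upstream (reducing input, e.g. at the receptor) or downstream (reducing
output, e.g. at the transcription-factor level). `nflevo` implements a
minimal evolutionary model of immune signaling that asks under which
conditions upstream and downstream NFLs evolve, and with what evolutionary
rates.

## The model

### Genotypes and interactions

A host carries five proteins — receptor `R`, central activator `A`, immune
effector `I`, upstream regulator `U` and downstream regulator `D` — and the
pathogen is a single protein `P`. Every protein is encoded by three bit
domains of `L = 10` sites: a *receiver*, a *sender*, and a *neutral* domain
that never participates in interactions and serves as the within-genome
benchmark for the neutral evolutionary rate.

Eight directed interactions can form (`signaling_topology()`): P→R, R→A,
A→I, A→U, A→D, U→R, D→I and I→P. The strength and sign of each is set by the
Hamming distance `H` between the acting protein's sender domain and the
target's receiver domain:

$$\mu_{i,j} = 1 - \frac{2 H_{i,j}}{L} \in [-1, 1].$$

More than half the sites matching gives activation, fewer gives inhibition,
and exactly half gives no interaction. Interactions are not wired in — they
*evolve*, as mutation, recombination and selection reshape the domains.

### Within-host dynamics

During one host lifetime (`T = 1000` time units) concentrations
`y ∈ [0, 1]` of the six species follow

$$\frac{dy_P}{dt} = -|\mu_{P,I}|\, y_I\, y_P + \pi\, y_P (1 - y_P),$$

$$\frac{dy_i}{dt} = -\phi_i y_i + \sum_{j \to i} \mu_{i,j}\, y_j \times
\begin{cases} (1 - y_i) & \mu_{i,j} > 0 \\ y_i & \mu_{i,j} < 0,\end{cases}$$

with `y(0) = (P0, 0, 0, 0, 0, 0)` for an infected host and the identically
zero trajectory for an uninfected one (no constitutive immunity). The
saturating interaction terms keep concentrations in `[0, 1]`; host proteins
degrade at rate `phi` while the pathogen only declines through clearance by
immunity and regrows logistically at rate `pi`.

Two points deserve emphasis:

* **The interaction term includes the acting concentration `y_j`.** The
  compact printed form of the host equation shows only the saturation
  factor; the definition in the accompanying text makes the acting protein's
  concentration multiply it, which is also the only form for which "no
  acting protein" implies "no effect". Targets with two regulators (R from
  {P, U}; I from {A, D}) sum one such term per incoming edge.
* **Clearance is constrained inhibitory** (`force_inhibitory_IP = TRUE`, the
  default): the evolved matching between I's sender and P's receiver sets
  only the *strength* `|mu[P,I]|` of clearance. This is not cosmetic. Under
  the signed alternative (`FALSE`) the pathogen — which mutates twice as
  fast and controls one of the two domains — can hold the coefficient at
  zero or push it negative, making immunity pure cost, so selection acts
  *against* the R→A→I pathway and no functional network can establish. The
  constrained form
  leaves the pathogen an evasion strategy (minimising `|mu|`) while keeping
  immunity selectable, and reproduces the persistent receptor/immunity
  oscillations that characterise host–pathogen coevolution in this model.

### Fitness and the generational loop

Each generation: every host meets one random pathogen and is infected with
probability `theta`. Infected hosts integrate their lifetime dynamics;
fitness is

$$F_H = e^{-(\alpha \bar P + \beta \bar I)}, \qquad F_P = \bar P,$$

where $\bar X$ is the lifetime average of $X$ over the stored integration
grid (including `t = 0`) divided by `T`. `alpha` prices infection,
`beta` prices the immune response (energetic cost and immunopathology).
Uninfected hosts have fitness exactly 1; pathogens that failed to infect
have fitness 0. Hosts reproduce sexually — each offspring draws two
distinct fitness-proportional parents, and each protein independently
undergoes one crossover (a uniformly chosen domain is cut at a uniform site
`k ∈ 1..L-1`, sites left of the cut from one parent, the rest from the
other; the two other domains are each inherited whole from a random parent).
Pathogens reproduce asexually from fitness-proportional draws. Offspring
mutate with probability `MH` (hosts; one uniformly chosen bit flips) or
`MP = 2 MH` (pathogens). Population sizes are constant.

When `theta = 0` no pathogen infects, every pathogen fitness is 0, and the
engine draws pathogen parents uniformly — the population drifts neutrally
instead of erroring, which is the behaviour needed for neutral-expectation
experiments (and the only sensible continuation of the model).

### The rate-of-evolution estimator

Every `sample_interval = 5` generations the per-site consensus (frequency of
1s) of every host protein domain is recorded. For focal consensus `FO` (the
consensus when the current epoch started) and temporal consensus `TE` (now),
divergence is

$$k = \frac{1}{L}\sum_{l=1}^{L} \big[FO_l (1 - TE_l) + TE_l (1 - FO_l)\big],$$

the expected per-site proportion of 1→0 plus 0→1 changes. Applied to the
neutral domain this is `ks`; to sender/receiver domains, `ka`; and
`omega = ka / ks` measures selection (≈1 neutral, <1 purifying, >1
positive). When the neutral domain saturates (`ks > 0.5`) the focal
consensus of *all three domains of that protein* is reset together, so `ka`
and `ks` always share an epoch. The sum is normalised by `L` so the 0.5
saturation threshold is a per-site quantity, comparable across `L`.
When `ks = 0` the ratio is undefined and recorded as missing — never as
infinity, which would fabricate selection signal out of an invariant window.
Note that `k(x, x) = 2\,\overline{x(1-x)}` is the consensus heterozygosity,
zero only for a fixed population: a maximally polymorphic, unchanged
consensus scores `k = 0.5` by construction.

### Architecture classification

The by-eye judgement "this interaction evolved as activation /
inhibition / did not evolve" is made deterministic in `call_edge()`: the
mean of the final 10% of a coefficient trajectory is compared against
±0.25. `classify_run()` derives the architecture flags — functional pathway
(R→A and A→I activatory), downstream NFL via D (A→D activatory, D→I
inhibitory; three steps to downregulation), downstream NFL via A (D→I
activatory, A→I inhibitory; two steps), upstream NFL (A→U activatory, U→R
inhibitory). It also reports the model's defining single-edge criteria,
`downstream_inhibition` (D→I inhibitory) and `upstream_inhibition` (U→R
inhibitory): an evolved NFL is *defined* by its inhibitory edge. The
two-edge flags additionally require the loop's activation leg to clear the
threshold, but at `L = 10` that leg frequently fixes at the lattice value
0.2 — once a non-degrading (or slowly degrading) regulator receives any
positive drive it saturates, so selection for stronger drive is weak — and
0.2 sits below the 0.25 call threshold. The single-edge criteria are
therefore the faithful count of evolved feedback, and they are what the
package's replicate-count checks use. The two pathogen-facing edges oscillate under coevolution
rather than stabilising; they are reported with window mean *and* amplitude
and labelled `coevolving` when the amplitude is large, rather than
`not_evolved`. Both the window fraction and the threshold are exposed;
near-threshold trajectories can be called differently than a human eye
would, which is why replicate counts, not individual calls, are the unit of
comparison.

## Parameters and defaults

| parameter | meaning | default |
|---|---|---|
| `L` | sites per domain | 10 |
| `n` | hosts = pathogens per generation | 2000 |
| `generations` | non-overlapping generations | 20000 |
| `theta` | infection probability | 1 |
| `alpha`, `beta` | infection / response cost | regime-specific (2, 1–2) |
| `phi` | host protein degradation | 0 or 0.15 per regime |
| `pi` | pathogen replication rate | **none — must be chosen** |
| `P0` | initial pathogen load | 1 |
| `T`, `dt` | lifetime, Euler step | 1000, 1 |
| `MH`, `MP` | mutation probabilities | 0.001, `2*MH` |

`pi` is deliberately left without a default: no single value is canonical,
and it shapes outcomes strongly, so every run must own its choice.
Everything in this package that needs a value uses `pi = 0.2` — a moderate
regrowth rate (recovery timescale `1/pi = 5`, short against `T = 1000`,
slow against the maximal clearance rate 1) — chosen once and used
consistently. The trade-off: the within-host clearance rate is
`|mu[P,I]| * yI <= 1`, and coevolution keeps the realised `|mu[P,I]|` well
below 1, so a `pi` approaching that scale keeps the pathogen pinned near
carrying capacity whatever the host does, flattening the fitness landscape
over the signaling edges; a very small `pi` instead lets one immune episode
suppress the pathogen for the rest of the lifetime, removing the sustained
pressure that maintains immunity.

The named regimes are available as `scenario_preset("no_degradation")` …
`scenario_preset("stable_receptor_high_cost")`; see that function's help for the exact parameter
bundles.

## Numerical choices

* **Integrator.** Forward Euler with `dt = 1` and post-step clamping to
  `[0, 1]`. The model's saturating terms bound growth intrinsically, but
  Euler can overshoot by `O(dt)`; clamping removes this at negligible cost
  and matches the discrete lifetime sum used by the fitness averages. `dt`
  is configurable, and the lifetime average generalises as
  `dt * (grid sum) / T`.
* **Determinism.** All randomness — R level and compiled level — flows
  through R's RNG; a run is a pure function of `(config, seed)`. Replicate
  `r` of `run_replicates()` uses seed `master_seed + 7919 r`.
* **Two engines.** Every step of the generational pipeline exists twice:
  as documented R functions (`pair_and_infect()`, `select_parents()`,
  `recombine_host()`, …, composed by `step_generation()`) and as one
  compiled loop (`run_simulation(engine = "cpp")`). The compiled batch
  integrator is required to match the scalar R integrator to 1e-12 per
  state per step; the engines consume the RNG stream in different orders
  and so are individually, not mutually, reproducible.

## What the simulator does and does not emulate

The generator produces the study conditions themselves — random
Bernoulli(0.5) initial bit pools, the fixed network scaffold, logistic
pathogen growth — so "passing" means the *model* behaves as described, not
that any real immune pathway does. Real signaling proteins have continuous
binding affinities, structured mutation, overlapping generations and
population structure, none of which are represented. The bit-string genotype
gives `mu` a discrete lattice (`2/L` steps), so evolved coefficients sit on
multiples of 0.2 and an interior optimum (say 0.1) is approximated by its
nearest lattice points.

## Scale of the bundled experiments

Full-scale runs (n = 2000, 20000 generations, 10 replicates) take hours on
one core. The package's own tests and the acceptance script therefore run
the qualitative architecture checks at a reduced scale — n = 500 with
3000–5000 generations and 5–10 replicates — which preserves the regime
structure while completing in minutes; the problem size used is stated next
to every such check. Replicate counts at reduced scale are noisier than the
full-scale counts: majority outcomes, not exact tallies, are the meaningful
desk-scale observable.

## Known limitations

* Mutation is a single-bit event per offspring (probability `MH`).
  Mutational input therefore scales with `n`; at reduced population sizes
  adaptation is mutation-limited sooner than at full scale.
* The architecture caller uses a fixed threshold; trajectories that end
  near ±0.25 are called discontinuously.
* `omega` is a ratio of noisy divergences; it is reported per domain and
  protein and should be averaged across replicates (`summarize_omega()`)
  before interpretation.
* Hosts and pathogens share one population size `n`; the model has no
  notion of differing census sizes.
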