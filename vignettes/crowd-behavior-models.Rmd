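---
title: "Modeling mass behaviors: panic cascades, conformity, and belief contagion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling mass behaviors: panic cascades, conformity, and belief contagion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdsim)
```

crowdsim implements three small, seeded agent-based models of crowd
phenomena observed during large societal shocks: an outbreak of panic
buying, the drift of a population's behavior under social conformity, and
the spread of a conspiracy belief. Each model isolates one behavioral
mechanism; none is fitted to data. This vignette explains each model, its
assumptions, the tunable parameters and their defaults, the numerical
choices made, and what the simulations can and cannot show.

## 1. Panic buying as a threshold cascade

### Model

Each of $n$ consumers holds a panic threshold expressed in *panic-fraction
units*: consumer $i$ starts panic buying once the fraction of the
population already panic buying reaches $\tau_i$. Base thresholds are
drawn from a normal distribution,
$z_i \sim \mathcal{N}(\mu, \sigma^2)$, and scaled by the product's
visibility $v > 0$:

$$\tau_i = z_i / v.$$

Conspicuous products (toilet paper, say, rather than pharmaceuticals) have
large $v$, which shrinks every threshold and makes cascades easier to
ignite. Consumers with $\tau_i \le 0$ panic from the outset; because
dividing by a positive $v$ preserves signs, this initial trigger share is
independent of visibility. Updates are synchronous and panic is absorbing:
in each round every consumer whose threshold is at or below the current
panicking fraction joins, and the process stops when a round adds nobody.
Each joining round adds at least one consumer, so equilibrium is reached
in at most $n$ rounds.

### Calibration

The base distribution is calibrated so that the sub-zero mass is exactly
10%: $\mu = 0.35$ and $\sigma = \mu / \Phi^{-1}(0.9) \approx 0.2731$, so
$\Phi(-\mu/\sigma) = 0.10$. The 10% trigger is the model's one anchored
quantity; $\mu$ itself only sets where on the $v$ axis the transition from
contained to near-total cascades falls. Both parameters are exposed in
`panic_config()`.

### Analytic oracle

In the large-$n$ limit the equilibrium fraction $f$ solves

$$f = \Phi\!\left(\frac{v f - \mu}{\sigma}\right),$$

and the cascade converges to the smallest fixed point at or above the
trigger share $f_0 = \Phi(-\mu/\sigma)$. `analytic_fixed_point()` iterates
this map from $f_0$; the map is increasing in $f$, so the iteration is
monotone nondecreasing and bounded by 1, and it stops when successive
iterates differ by less than $10^{-10}$. The oracle is independent of the
simulator (it never draws thresholds) and the test suite checks that
simulated equilibria at $n = 10^5$ agree with it within three Monte-Carlo
standard errors across low, transitional and high visibilities.

```{r oracle}
vapply(c(0.2, 0.5, 1, 1.5, 2), analytic_fixed_point, numeric(1))
```

Low-visibility products stay near the 10% trigger; high-visibility
products cascade to (essentially) everyone. `sweep_visibility()` traces
the whole curve over the canonical grid $v = 0.01, 0.02, \dots, 2$.

## 2. Conformity on a small-world network

### Substrate

Agents occupy the nodes of a Watts-Strogatz small-world network: a ring
lattice with $N$ nodes and $k$ links per node ($k/2$ nearest neighbors on
each side), each link independently rewired with probability $p$ by
detaching its clockwise endpoint and reattaching it to a uniformly random
node. Self-loops and duplicate links are rejected and redrawn, so the edge
count $Nk/2$ is exact. Node indices are 0-based throughout, including the
plain-text edge-list format; under the canonical $N = 500$, $k = 10$
lattice, node 100 is linked to nodes 95–99 and 101–105. Rewiring may
disconnect the graph; isolated agents simply skip their learning turns.

Each agent starts with a score $x_i$ — its propensity to do a behavior —
and does the behavior exactly when $x_i > 0$. Because real social ties
connect similar people, neighboring agents get correlated initial scores:
Gaussian white noise is smoothed with a circular moving average of window
$w$ (`smoothness`), scaled by an amplitude $a$, and shifted by a mean
level $\ell$,

$$x_i = a \cdot \mathrm{MA}_w(\varepsilon)_i + \ell, \qquad
  \varepsilon_j \sim \mathcal{N}(0, 1).$$

The smoothed noise has marginal standard deviation $a/\sqrt{w}$ and
adjacent-node correlation $(w-1)/w$, so by default $\ell$ is derived from
the intended minority share $q$ of anti-behavior agents as
$\ell = a\,\Phi^{-1}(1-q)/\sqrt{w}$, making the expected share of negative
scores exactly $q$.

### Learning

Agents are heterogeneous in conformism: each gets a half-range
$r_i \sim \mathrm{Uniform}(r_{\min}, r_{\max})$ and a permissible score
interval $[x_i - r_i,\, x_i + r_i]$ centered at its initial score. Wide
ranges mean conformist agents. In each period one uniformly random agent
observes one uniformly random contact and moves its score by $\theta$
toward the contact's behavior (up if the contact does it, down
otherwise) — but only if the move stays inside its permissible range;
out-of-range proposals are rejected outright (a clamp-to-boundary variant
is available but off by default, since the rejection rule is the literal
reading of "as long as the update keeps the score within the range").
Behavior is recomputed after every update; crossing zero flips it.

### Defaults and why

* $N = 500$, $k = 10$, $p \in \{0.1, 0.2, 0.3\}$: the canonical
  experiment triple. At $p = 0.1$ each agent has on average one rewired
  link.
* $\theta = 0.01\,a$: the step must be small relative to the ranges so
  that conformity acts through many repeated observations; an agent needs
  on the order of a hundred consistent observations to traverse its range.
* half-ranges on $[0.25, 1.5]\,a$: spans clearly non-conformist to
  clearly conformist agents relative to the score spread.
* `n_periods` $= 500N$ (about 500 updates per agent), with early stop
  once no behavior flip has occurred for $50N$ consecutive periods.
* score field: $w = 10$ (one neighborhood width, so initial like-minded
  clusters are commensurate with what an agent sees) and $q = 0.20$ — a
  moderate, spatially clustered anti-behavior minority. These two values
  were chosen, once, so that the model reproduces the three canonical
  outcomes: entrenched polarization with a visible strongly-anti group at
  $p = 0.1$, a smaller anti group at $p = 0.2$, and near-consensus (over
  90% pro) at $p = 0.3$. With much longer correlation (e.g. $w = 25$) the
  anti clusters are wider than any agent's neighborhood and survive even
  heavy rewiring, which contradicts the consensus outcome the model is
  meant to exhibit.

```{r conformity, eval = FALSE}
res <- lapply(c(0.1, 0.2, 0.3), function(p)
  run_learning(conformity_config(rewiring_prob = p, seed = 1)))
vapply(res, function(r) r$polarization$fraction_anti_final, numeric(1))
```

### What the runs show

Polarization here is mechanical: inside a like-minded cluster, agents
mostly observe their own camp and drift to their range boundaries, where
they are immune to further influence. Rewiring injects cross-cutting ties
that pull minority agents toward the majority. The summary statistics
(`polarization_metrics()`) operationalize the visual comparison of
initial and final score curves: the final anti share, the final/initial
variance ratio (variance growth = polarization), and the shares of agents
within 10% of their range boundaries ("strongly" pro/anti).

## 3. Conspiracy belief as a modified SIR contagion

### Model

A well-mixed population of $N$ individuals in four compartments:
unsusceptible (will never believe), susceptible, infected (believes) and
recovered (abandoned the belief). Transitions are one-directional,
S $\to$ I $\to$ R; the unsusceptible never change. Per period one
individual $i$ is drawn uniformly; if $i$ is infected, with probability
$m$ its partner is drawn uniformly from the *other believers*
(echo-chambering), otherwise — and always when $i$ is uninfected — the
partner is uniform over everyone else. Exactly one rule then fires:

1. susceptible × infected — the susceptible becomes infected, with
   recovery probability reset to $p_0$;
2. infected × non-susceptible (incl. recovered) — the believer's views
   are challenged: it recovers with its current probability $p_{it}$.
   Under *cumulative influence*, a failed challenge multiplies $p_{it}$
   by 1.1 (capped at 1), so repeated challenges wear the belief down —
   from 5% to 5.5% after one failed challenge, and so on;
3. infected × infected — mutual reinforcement: both probabilities are
   multiplied by 0.9 (skipped under *constant recovery*).

The time axis reported in trajectories is mean interactions per
individual, $2t/N$, sampled every $N/2$ periods.

### Defaults and why

Baseline: $N = 1000$, 100 susceptible of whom 10 start infected,
$m = 0.5$, $p_0 = 0.05$. The scenario presets alter exactly one element
each: `sim2` lowers $m$ to 0.2, `sim3` holds recovery probabilities
constant, `sim4` switches on cumulative influence.

The horizon defaults to $250N$ periods (500 mean interactions per
individual). This is long enough that (i) the baseline visibly plateaus —
every susceptible is reached and the surviving believer core is frozen,
its recovery probabilities having decayed geometrically so far that the
remaining recovery hazard is negligible — and (ii) the two burnout
scenarios actually reach extinction rather than being cut off with a few
straggler believers. At half this horizon roughly a fifth of baseline
runs still leave one susceptible untouched and the burnout scenarios
retain one to three believers, which misrepresents the models' long-run
behavior. "Equilibrium" is operationalized as: no believers remain, or
every remaining believer's recovery probability is below $10^{-9}$ with
no compartment change for $50N$ periods.

Degenerate cases are handled explicitly: a believer drawn as $i$ when it
is the sole believer falls back to uniform matching; a newly infected
individual's recovery probability always restarts at $p_0$; recovery
probabilities are capped at 1 under repeated amplification.

```{r contagion, eval = FALSE}
print(run_contagion(contagion_config(seed = 1)))
sweep_assortativity(c(0.2, 0.5), replicates = 30, contagion_config(seed = 1))
```

In the baseline, all susceptibles are eventually infected and roughly
half the believers persist forever — believers who met each other early
and drove their recovery probabilities toward zero. Lowering $m$ thins
this persistent core; removing reinforcement or adding cumulative
influence extinguishes the belief entirely, faster under cumulative
influence.

## Reproducibility machinery

All randomness flows through R's global RNG: every config carries a
`seed`, and the compiled inner loops (used by `run_learning()` and
`run_contagion()` for speed) consume `unif_rand()` in exactly the same
order as the exported pure-R single-step functions `learning_step()`,
`match_pair()` and `interact()`. The test suite asserts bit-for-bit
equality between the compiled loops and R-level step drivers, so the fast
path and the documented semantics cannot drift apart.

Replicate orchestration (`run_scenario()`, `sweep_visibility()`,
`sweep_assortativity()`) derives per-replicate seeds from a master seed
with a counter scheme, `child_seed(master, index)`; sweeps pair
replicates across grid values by reusing the same child seed. CSV output
is formatted at 9 significant digits, making repeated runs byte-identical;
each scenario writes a manifest from which the run can be re-executed
exactly.

## Scope and limitations

* The synthetic populations emulate the *stated mechanisms only*:
  normally distributed thresholds, uniformly random mixing (contagion),
  uniform conformism ranges. Passing tests show the mechanisms produce
  the claimed aggregate patterns; they say nothing about how real
  populations are parameterized, and nothing here is fitted to data.
* The panic model has no prices, inventories or multiple products; the
  conformity model has a single binary behavior on a fixed network; the
  contagion model is well-mixed (no network) with one belief and no
  demographic turnover.
* The exact initial score curve and base threshold parameters behind the
  original figures are not recoverable; the defaults reproduce the
  anchored 10% trigger and the qualitative regimes, not necessarily the
  precise transition locations.
* Problem sizes used in the test suite follow the canonical experiments
  ($n = 1000$ consumers with $n = 10^5$ for oracle agreement; $N = 500$
  agents over $2.5\times10^5$ periods; $N = 1000$ individuals over
  $2.5\times10^5$ periods), with 20–30 replicates where distributional
  claims are tested.
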