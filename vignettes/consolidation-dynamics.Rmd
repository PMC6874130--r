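---
title: "Methods: bistable consolidation dynamics and protocol optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bistable consolidation dynamics and protocol optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model and its assumptions

The package studies a deliberately minimal description of synaptic
consolidation: two coupled scalar variables, a fast synaptic weight $w$
(what an experimenter measures, e.g. EPSP amplitude) and a slow hidden
consolidation variable $z$ summarizing the biochemical state of the
synapse,

$$\tau_w \dot w = -K_w (w - w_0)(w + w_0)\,w + C_w\!\left(z - \tfrac{z_0}{w_0} w\right) + I(t),\qquad
\tau_z \dot z = -K_z (z - z_0)(z + z_0)\,z + C_z\!\left(w - \tfrac{w_0}{z_0} z\right).$$

The assumptions baked into this form:

- **Bistability of each variable.** Cubic self-dynamics are the lowest
  polynomial order admitting two stable states; each uncoupled equation is
  an overdamped particle in a double well.
- **Linear cross-coupling**, shaped so that $\pm(w_0, z_0)$ are equilibria
  at $I = 0$ for *every* coupling strength. This puts the experimentally
  accessible quantity — the stable weight — directly into the parameters.
  The coupling terms read $C_w(z - (z_0/w_0)w)$ and $C_z(w - (w_0/z_0)z)$;
  this is the unique reading under which $\pm(w_0,z_0)$ are coupling-independent
  equilibria, and the package's tests verify it by direct substitution for
  random parameters.
- **Signed coordinates.** Weights may be negative; an affine shift maps
  the system onto positive weights without changing the dynamics, so no
  range restriction is imposed on states.
- **The stimulus is a rectangle.** An episode of extracellular
  high-frequency pulses is compressed into a single rectangular drive
  $I(t)$ entering the $w$ equation only; pulse frequency maps
  (monotonically, but not explicitly) onto amplitude. No mapping from
  stimulation current to $I$ is attempted, and global phenomena
  (cross-tagging, shared protein synthesis) are out of scope.

## Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| $C_w, C_z$ | coupling strengths (dimensionless) | 1 | symmetric case $C_w = C_z = C$ |
| $K_w, K_z$ | cubic coefficients (dimensionless) | 1 | 0 makes an equation linear; any $K \ge 0$ accepted |
| $w_0, z_0$ | equilibrium magnitudes | 1 | $> 0$ |
| $\tau_w$ | weight time constant | 1 | the time unit of the whole package |
| $\tau_z$ | consolidation time constant | 1 | $\tau_z = 7$ is the strong-separation regime |

All times (`t_on`, `t_off`, `dt`, `t_max`) are in units of $\tau_w$. The
defaults reproduce the baseline regime: two stable equilibria at
$\pm(1,1)$, a saddle at the origin, basins split by the anti-diagonal
$z = -w$.

For symmetric coupling the flow is a gradient system,
$\tau_w \dot w = -\partial V/\partial w$, $\tau_z \dot z = -\partial V/\partial z$, with

$$V(w,z) = \tfrac{K_w}{4}w^4 + \tfrac{K_z}{4}z^4
 - \tfrac{K_w w_0^3 - z_0 C}{2w_0}w^2
 - \tfrac{K_z z_0^3 - w_0 C}{2z_0}z^2 - C\,w z - I\,w.$$

The drive appears as the tilt $-I\,w$: that is the only form whose
negative $w$-derivative reproduces the additive drive $+I$ in the $w$
equation, and the implementation uses it (a `+I` constant term, which one
sometimes sees written, would not be gradient-consistent; a constant shift
of $V$ is immaterial anyway, a $w$-independent drive term is not). The
gradient identity and the Lyapunov descent $\dot V \le 0$ are enforced by
property tests with central differences.

## Phase-plane machinery

**Equilibria.** Substituting the $w$-nullcline $z = P_3(w)$ into the
$z$-nullcline $w = Q_3(z)$ gives a univariate polynomial of degree
$n\cdot m \le 9$; its real roots (via `polyroot`) are candidate equilibria.
Every candidate is polished by a damped Newton iteration on the full 2-D
vector field (tolerance $10^{-12}$ on the drift max-norm, at most 100
iterations) and deduplicated at $10^{-8}$ in the max-norm — near
bifurcation parameters a degree-9 polynomial in double precision needs the
polish. When a coupling vanishes the system decouples and the cubics are
solved separately. Stability comes from the analytic Jacobian; eigenvalue
real parts within $10^{-9}$ of zero are classified `marginal` rather than
guessed, which is what one gets exactly at a bifurcation.

**Bifurcations** are detected as changes of the integer root count along a
parameter sweep (coarse step 0.01, bisection refinement to $10^{-6}$),
not by eigenvalue tracking: the pitchforks here create root *pairs*, so
counting is robust. Count changes closer than $10^{-4}$ are merged and
reported as one critical value — this is how the degenerate double
pitchfork at $C = 1/3$ is reported. Eigenvalue crossings ($1 - 2C$ at the
origin, the closed-form DC fold $I_c = 9^{-1/8} - 9^{-9/8}$) are used as
independent cross-checks in the tests.

**Basins** follow the mesh-grid method: each point of a $100 \times 100$
grid on $[-1.5, 1.5]^2$ is integrated (RK4, $dt = 0.01$) until within
$10^{-3}$ of a stable fixed point, with a cap of
$t_{\max} = 200\max(\tau_w,\tau_z)$. The convergence radius and the cap
are this package's choices: the slowest relevant eigenvalue sets the
approach rate, and $200\tau$ leaves orders of magnitude of slack except
for initial conditions *exactly* on a separatrix, whose trajectories run
into the saddle and are reported as non-convergent. On a symmetric grid
the anti-diagonal lattice points do exactly that; the separatrix extractor
therefore bridges narrow runs of non-convergent cells when marching the
label boundaries (mid-edge interpolation, greedy chaining into ordered
polylines).

**Fast basin membership.** Protocol simulation needs a per-step membership
test. The reference semantics — relax with $I = 0$ and see which attractor
wins — is exact but slow, so the package tabulates the separatrix as a
graph $z = s(w)$ by *bisecting in $z$ with the relaxation oracle itself*
(tolerance $10^{-8}$), then tests $z > s(w)$ by linear interpolation. This
inherits reference accuracy at the tabulation nodes; between nodes the
piecewise-linear error is what limits agreement, so tests compare lookup
and relaxation labels away from a $10^{-6}$ band around the curve. The
construction assumes the drive-free portrait is bistable with a
separatrix that is a graph over $w$ — true in the operating regime
$C_w + C_z > 1$ used for all protocol work; for weak coupling (four
attractors) only the reference semantics applies.

## Integration and potentiation detection

The integrator is classical fixed-step RK4 with $dt = 0.01\,\tau_w$,
compiled, with the drive sampled at the stage times $t$, $t + dt/2$,
$t + dt/2$, $t + dt$. Episode windows are half-open $[{\rm onset},\,
{\rm onset} + t_{\rm on})$ and **episode durations must be integer
multiples of $dt$** — configurations violating this are rejected at setup,
because a rectangle edge inside a step would make the stage sampling
inconsistent. Note the consequence for the shortest episodes
($t_{\rm on} = dt$): the final stage of the on-step already samples the
off phase, so the effective impulse of one episode is $\tfrac{5}{6}$ of
$A\,dt$. This is a property of *any* fixed-stage RK4 with grid-aligned
rectangles; it matters only near potentiation thresholds (below).

A potentiation run starts at $(-w_0, -z_0)$ and tests membership of the
potentiated basin after every step; the episode count on success includes
the episode during which the crossing happened (onsets at times
$kT < t_{\rm cross}$). Non-potentiating protocols are cut short early once
the state at successive episode onsets has settled to $10^{-12}$ — the
period map has converged on the unpotentiated side, so no later crossing
is possible — and otherwise a drive-free relaxation decides the outcome
when the episode budget (default 500) runs out. `t_off = 0` with unbounded
episodes is the DC limit and is integrated as one sustained drive.

## Protocol sweeps and the area optimum

Sweeps are exhaustive grid runs (no randomness anywhere; repeated runs are
bit-identical). The stimulus area of $k$ episodes is
$k \times |A| \times t_{\rm on}$. In the area-parameterized single-episode
map, $t_{\rm on} = {\rm area}/A$ is snapped to the step grid; cells whose
snapped duration changes the delivered area by more than 1% are flagged,
and durations below one step are unevaluable. The minimal-area search uses
amplitude 5–30 (step 0.25), $t_{\rm off}$ 0.01–1 (step 0.01),
$t_{\rm on} = 0.01$, $\tau_z = 7$: 10,100 protocol simulations, a few
seconds of compute with the compiled core. Ties break toward smaller
amplitude, then smaller $t_{\rm off}$.

Two properties of the computed optimum deserve emphasis, because they are
findings about the *method*, not bugs:

- **The valley is flat.** The minimal area ($\approx 8.5$ under the
  defaults) is attained along a ridge $t_{\rm off} \approx 0.0064 A$
  on which the area varies by well under 1%. The *minimum value* is robust
  (halving both grid steps moves it by far less than 2%), but the *argmin
  cell* is ill-conditioned: any sub-percent change in the dynamics — a
  different stage sampling of the rectangle, a separatrix tabulated a few
  $10^{-3}$ lower — slides the winning tie along the valley.
- **Episode counts are threshold-sensitive.** Near the optimum each
  additional episode adds only $\sim 10^{-2}$ to the consolidation
  variable, while a basin-membership test biased low by a grid
  interpolation error of similar size fires one or two episodes earlier.
  Exact pulse counts at a specific near-threshold cell therefore carry a
  $\pm 2$-episode halo across defensible numerical conventions; the
  package resolves every such choice toward reference semantics (exact
  separatrix, stage-sampled drive, onset counting) and documents the
  convention rather than tuning it.

## What the default conditions emulate — and what they do not

The default parameter set (all constants 1, $dt = 0.01$, $\tau_z = 7$ for
protocol optimization) represents a synapse whose consolidation machinery
is an order of magnitude slower than its expression machinery, probed by
idealized rectangular episodes. Passing tests show that the *model*
behaves as analyzed — cascade of pitchforks, DC fold, timescale-dependent
optimal protocols. They do not show that real synapses do: the model has a
single contact point, no noise, no receptor-level detail, no
cross-synaptic interactions, and the stimulus-to-amplitude mapping is left
abstract. Depression protocols are covered only through the odd symmetry
of the flow (negative drive mirrors positive).

## Known limitations

- Fixed-step integration only; no adaptive control or sub-step event
  location (grid-aligned rectangles make the crossing grid-aligned too).
- The fast membership test requires a separatrix that is a graph over $w$;
  multi-attractor regimes fall back to relaxation.
- Root certification is floating-point (polish + dedup), not rigorous
  interval arithmetic.
- The bifurcation boundary in the coupling plane is resolved by
  root-count bisection at the scan resolution; normal-form classification
  of the pitchforks is not attempted.

## Problem sizes used by the test suite

Unit and property tests run on reduced grids (basins at 50–60², sweeps
with a handful of amplitudes) chosen to exercise every code path; the
end-to-end checks use the full reference setup — 100 × 100 basins, the
complete 101 × 100 protocol sweep, and 10×10 coupling lattices against a
400 × 400 brute-force oracle. The whole suite completes in about a minute.
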