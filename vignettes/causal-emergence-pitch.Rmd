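---
title: "Measuring causal emergence in football team dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring causal emergence in football team dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emergentpitch)
```

## The question and the statistic

A football team is a textbook case of collective behaviour: ten outfield
players produce team-level structure — a drifting block, compact defensive
shapes, synchronised pressing waves — that no single player's trajectory
explains. `emergentpitch` asks a quantitative version of that observation:
does a *macroscopic* team feature $V_t$ predict its own future better than
the sum of what the individual players predict about it?

The package measures this with the practical causal-emergence criterion

$$
\Psi_{t,t'}(V) \;=\; I(V_t; V_{t'}) \;-\; \sum_{i=1}^{N} I(X^i_t; V_{t'}),
\qquad t' = t + \text{lag},
$$

where $X^i_t$ is the microscopic state of player $i$ and $I(\cdot;\cdot)$ is
mutual information. $\Psi > 0$ means the macro state carries *synergistic*
predictive information not available to any single player; $\Psi < 0$ means
the players are largely *redundant* copies of the macro signal, so the sum
over-counts. Both signs are informative: redundancy is how a team maintains
a stable shape, synergy is how structure emerges beyond individual
behaviour. The analysis is restricted to order 1 — micro variables enter one
player at a time; subsets of two or more players are out of scope.

All mutual informations use the Gaussian estimator: with maximum-likelihood
(1/n) covariances,
$I(X;Y) = \tfrac12 \log\big(\det\Sigma_{XX}\,\det\Sigma_{YY} /
\det\Sigma_{[X,Y]}\big)$, reported in nats by default. The estimator is
exact for jointly Gaussian data and, on a window of $n$ pairs, has an upward
bias of order $pq/2n$ per term; because $\Psi$ subtracts $N$ micro terms
from one macro term, the windowed $\Psi$ is biased slightly *downward*
(about $-0.3$ nats at the default 60-s window for the 2-D centre-of-mass
feature). This bias is common to every condition being compared, so
differences, trends and correlations are unaffected.

## Macroscopic features and their micro variables

Four macro features are implemented, each supervening on per-player micro
variables (grouped per player):

| feature | macro $V_t$ | micro $X^i_t$ |
|---|---|---|
| `com` | 2-D centre of mass (mean player position) | 2-D position |
| `relative_distance` | distance of the CoM to the field centre | player's distance to the field centre |
| `clust_vel` | team-average weighted clustering coefficient, velocity-similarity graph | 2-D velocity |
| `clust_dist` | same, inverse-distance graph | 2-D position |

Coordinates are pitch-centred (origin at the centre spot, $x$ along the long
axis), so "distance to the field centre" is a plain Euclidean norm. The
graphs are complete weighted graphs over the ten players, rebuilt every
second: the velocity edge weight is $S_u S_v(\cos\Delta\theta + 1)$ (large
for fast, co-directed pairs; zero for anti-parallel movement or a stationary
player) and the proximity edge weight is the inverse Euclidean distance,
floored at `eps = 0.1` m to cap coincident players. The node clustering
coefficient averages the half-sum of incident edge weights over ordered
pairs of connected neighbours,
$C_i = \frac{1}{k_i(k_i-1)}\sum_{j,k\neq i}\frac{w_{ij}+w_{ik}}{2}a_{jk}$,
and the team value is the player average. Under the complete-graph
convention ($a_{jk} \equiv 1$, $k_i = N-1$) this reduces to the mean
incident weight; an optional weight threshold turns edges off, in which case
the general formula is used. Weights are deliberately *not* normalised — no
normalisation is part of the definition.

`relative_distance` has two published wordings that disagree: the CoM's
distance to the centre, and the mean of the players' distances. Both are
implemented (`variant = "com_to_center"`, the default, and
`"mean_distance"`); they satisfy `mean_distance >= com_to_center` pointwise
and give similar dynamics, but they are different statistics and the package
does not claim either is canonical.

## The sliding-window estimator

`sliding_window_psi()` anchors each window at its **end** time: the value at
time $e$ summarises the `window_s` seconds up to and including $e$, so
event-locked curves read "the $\Psi$ of the 60 s before this moment". A
window contributes the sample pairs $t \in [e-\mathrm{window}+1,\,
e-\mathrm{lag}]$, each paired with $t' = t+\mathrm{lag}$, all inside the
window: `window_s - lag_s` pairs (59 at the defaults; a 120-s series yields
61 windows). The lag defaults to 1 s — the minimal step at the 1 Hz sampling
rate — and is configurable.

Numerical choices, all visible in `emergence_config()`:

* **Ridge.** `1e-10` is added to the diagonal of the joint covariance before
  any determinant; block determinants are taken from the ridged joint, so
  the three log-determinants are mutually consistent. The perturbation is
  ~9 orders of magnitude below the data scale and only matters for
  near-singular windows.
* **Clamping.** Each MI estimate is clamped at 0 before the subtraction
  (slightly negative values are possible only through the ridge).
* **Flags.** Windows containing masked frames (the first frame of a half
  has no velocity) are flagged `masked`; windows whose macro variance falls
  below $10^{-12}$ are `degenerate`; numerically singular covariances are
  `singular`. Flagged windows carry `NA` and are excluded from averages.
* **Units.** Nats by default; bits are a config switch. No published value
  pins the unit, so it is documented rather than asserted.
* Windows never cross a half boundary: each half is processed separately
  and the series are concatenated on the match clock.

Internally the window moments are assembled from cumulative sums of the
(globally centred) feature columns and their pairwise products, with
closed-form determinants for the small (≤ 4×4) blocks, so a full match
costs seconds rather than minutes; the engine is verified against the
direct per-window `psi_statistic()` computation in the test suite.

## The synthetic match generator

Real tracking data of the kind this analysis was designed for are
proprietary, so the package ships a generator whose *statistical* structure
matches what the pipeline assumes, with explicit dials for every mechanism
the analyses measure. It makes no attempt at football physics: no ball, no
opponent-aware tactics, no pitch confinement.

Per team, the latent centre $V_t$ is a mean-reverting AR(1) around a
possession-dependent attractor $c_t$:
$V_{t+1} = c_{t+1} + \phi_{t+1}(V_t - c_{t+1}) + \eta_t$, with persistence
`phi_p` in possession and `phi_n` out of it, and innovations scaled by
$\sqrt{1-\phi^2}$ so the *stationary spread* of the centre is `sigma_macro`
metres regardless of $\phi$. Player $i$ sits at
$X^i_t = V_t + F_i + D^i_t$: a fixed formation offset plus AR(1) jitter
with persistence `rho_idio` and stationary SD `sigma_idio`, mean-centred
across the team at every second (`center_idio = TRUE`). Possession follows
a symmetric two-state chain (`p_stay`), shots are drawn with a per-second
hazard for the possessing team, and in the 60 s before each shot the
shooting team's jitter SD is multiplied per second by `gamma_attack` > 1
and the conceding team's by `gamma_defend` < 1 (overlapping ramps combine
by the most advanced ramp position rather than stacking).

Three of these choices were genuinely open and deserve their reasoning:

**Formation-preserving jitter.** With independent per-player jitter the
centre of mass is $V_t + \bar D_t$, and $\bar D_t$ has variance
$\sigma^2_{\text{idio}}/N$: as the jitter grows it *swamps* the centre of
mass, the macro's own mutual information collapses, and no synergy-dominated
regime exists for the CoM feature — the micro noise cannot hide information
from the players without also destroying the macro signal. Centring the
jitter across the team (players exchange space; the block stays put) makes
the CoM equal $V_t$ exactly, giving the clean limits

$$
\Psi \xrightarrow{\sigma_{\text{idio}}\to\infty} -\ln(1-\phi^2),
\qquad
\Psi \xrightarrow{\sigma_{\text{idio}}\to 0} (1-N)\,\big(-\ln(1-\phi^2)\big),
$$

(`theoretical_psi_limit()`), and in between the exact stationary value

$$
\Psi = -\ln(1-\phi^2) + N \ln\!\Big(1 - \frac{\phi^2 v}{v + d}\Big),
\qquad v = \sigma_{\text{macro}}^2,\;
d = \sigma_{\text{idio}}^2\big(1 - \tfrac1N\big),
$$

implemented as `stationary_psi_com()` (the jitter's own persistence drops
out at order 1). $\Psi$ is monotonically increasing in
$\sigma_{\text{idio}}$, which is what makes the jitter SD the package's
synergy/redundancy dial.

**Stationary-SD parametrisation.** The match-level analysis couples
possession to the centre's persistence ($\phi_p > \phi_n$). Had
`sigma_macro` been an *innovation* SD, higher persistence would also inflate
the centre's variance as $1/(1-\phi^2)$, making every player *more*
informative about the future macro state in possession and pushing $\Psi$
the wrong way. Fixing the stationary spread keeps
the excursion a physical quantity (metres of wander) and makes the
possession–$\Psi$ coupling well defined: with fixed spread, differentiating
the closed form above shows $\Psi$ increases with $\phi$ at every $\phi$
precisely when $N v/(v+d) < 1$. That inequality is why the default jitter
SD (10 m) is large relative to the centre spread (2 m): the direction of
the coupling requires the micro-weak regime.

**Small attractor offsets.** The attractor shifts a few metres towards the
opponent goal in possession (±4 m). Large shifts put a shared step change
into every player's series at each possession change; within a 60-s window
this mimics perfect redundancy and injects deep negative $\Psi$ spikes that
drown the half-level means in noise. The offsets are therefore kept small
relative to the formation extent.

Default parameters (one team, 1 Hz):

| parameter | default | unit | meaning |
|---|---|---|---|
| `half_length_s` | 2700 | s | frames per half (two halves per match) |
| `phi_p`, `phi_n` | 0.88, 0.45 | — | centre persistence in/out of possession |
| `sigma_macro` | 2 | m | stationary SD of the centre about its attractor |
| `sigma_idio`, `rho_idio` | 10, 0.5 | m, — | stationary SD / persistence of player jitter |
| `attack_x`, `defend_x` | +4, −4 | m | attractor shift along the attacking axis |
| `p_stay` | 0.985 | — | possession retention per second (mean bout ≈ 67 s) |
| `shot_hazard` | 0.003 | s⁻¹ | shot probability per possessed second (~16 shots/match) |
| `gamma_attack`, `gamma_defend` | 1.02, 0.98 | — | per-second pre-shot jitter scaling |

With these defaults the in-possession stationary $\Psi$ is mildly positive
and the out-of-possession value mildly negative, windows spanning
possession turnovers dip strongly negative, and the pre-shot ramps move the
attacker towards synergy (jitter tripled by the shot) and the defender
towards redundancy (jitter cut to a third).

**What passing tests do and do not show.** The generator produces exactly
the covariance structure the estimator assumes, so the suite demonstrates
that the pipeline recovers *known* emergence structure: the analytic limits,
monotonicity in the jitter dial, the possession–$\Psi$ direction, and the
attack/defence sign pattern before shots. It does not show that real
football exhibits these effects; real data have bounded pitches, non-Gaussian
accelerations, role asymmetries and ball-driven dynamics that the generator
deliberately omits. Players can also wander far off a real pitch here —
loading synthetic files back in uses a generous out-of-bounds margin for
this reason.

**The null condition.** The check that the event-locked machinery produces
*no* spurious Bonferroni-significant timepoints uses a generator with both
shot-related mechanisms off: ramps disabled **and** `phi_p = phi_n`.
Disabling only the ramps is not a null world: shots are taken by the team
in possession, and with possession-coupled persistence the attacker's
dynamics genuinely differ from the defender's in the minute before a shot.

## Preprocessing contract

Raw tracking at a higher rate is decimated (every $k$-th frame, phase reset
at each half's first frame), not averaged — velocities are then defined
between consecutive retained seconds as position differences. The first
frame of each half gets velocity (0, 0) and a validity flag that masks it
out of velocity-based features; differencing never crosses the inter-half
gap. Frames from a red card to the end of that half are excluded, keeping
ten outfield players per team throughout (goalkeepers are excluded
entirely; substitutions are slot changes and do not alter the player
count). Velocities are differentiated within halves after segmentation.

## Analysis conventions

* **Match level**: one scatter point per (match, half) — the home-minus-away
  difference in half-mean $\Psi$ (over unflagged windows) against the
  home-minus-away possession-rate difference, with Pearson's $R$.
* **Shot-locked**: curves are the $\Psi$ values whose windows end in the
  60 s before each shot; the shooting team is labelled attacker for the
  whole interval even if possession changes inside it. One random baseline
  interval per retained shot is drawn uniformly from the same half (from
  the shooting team's series, overlap with shot windows permitted). Per
  timepoint, groups are compared with Welch's $t$ test at
  $\alpha/60$ (Bonferroni); the named test is a package choice, as is
  fitting the trend regression to the across-event *mean* curve (per-event
  curves are far too noisy for meaningful $R^2$).
* Shots closer than 120 s to the start of a half are dropped (their curves
  cannot be fully covered by 60-s windows) and reported as such.

## Problem sizes

The test suite and the acceptance script use: windows of 2000 s on a
6000-s constant-possession segment for the synergy limit; 10 (tests) or 5
(script) seeds over the jitter grid {0, 0.5, 2, 8, 32} m at a 600-s window
for monotonicity; 30 matches for the match-level correlation; and ~13
matches pooling ≥ 200 shots for the shot-locked trends. These sizes give
Monte-Carlo error comfortably inside the assertion bands while keeping a
full run in minutes on one core.

## Known limitations

* Order-1 only: synergy among player subsets is invisible to $\Psi$ as
  computed here.
* The Gaussian estimator is exact only for jointly Gaussian data; the
  clustering-coefficient features are nonlinear functionals of Gaussians,
  so their MI values are approximations.
* $\Psi$ compares, it does not calibrate: values are comparable across
  conditions within a feature, not across features or datasets.
* The 60-s window trades variance for nonstationarity; windows spanning
  possession turnovers mix regimes, which shows up as strong negative
  excursions.
* The generator's Gaussian tails place occasional positions far outside a
  real pitch; it emulates second-order statistics, not geometry.
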