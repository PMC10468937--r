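---
title: "Amyloid-beta and tau dynamics on brain connectomes: model and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amyloid-beta and tau dynamics on brain connectomes: model and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`adsim` simulates a macroscopic model of Alzheimer's disease progression on
a brain parcellation.  The cerebral parenchyma is represented as two
superposed weighted graphs over the same parcels: a *proximity graph*
$\Gamma$ whose edges link spatially neighbouring parcels with
distance-derived weights $w^F_{ij}$, and a *connectivity graph* $G$ whose
weights $w^E_{ij}$ measure white-matter fibre connection strength.
Extracellular amyloid-beta (A$\beta$) moves by proximity on $\Gamma$;
intraneuronal misfolded tau spreads along neural connections on $G$.  Both
graphs use the row-normalised weighted Laplacian

$$\Delta g(x_m) = \frac{1}{\pi_m}\sum_j \big(g(x_m) - g(x_j)\big) w_{mj},
\qquad \pi_m = \sum_j w_{mj} > 0,$$

which is positive semidefinite, so diffusion terms carry a leading minus
sign.  Every parcel must have $\pi_m > 0$; isolated parcels are rejected at
construction.

### Protein compartments

Each protein is tracked in five compartments per parcel: monomers, dimers,
short proto-oligomers, long oligomers, and the insoluble end state (senile
plaques for A$\beta$, neurofibrillary tangles for tau).  Aggregation
follows discrete Smoluchowski coagulation restricted to these compartments:
binary coalescence $P_j + P_k \to P_{j+k}$ at rate $\alpha$ (A$\beta$) or
$\gamma$ (tau), with every merger of soluble species reaching total length
$\ge 5$ deposited in the insoluble pool.  Fragmentation and nucleation are
not modelled.  The insoluble pool neither diffuses nor clears — its
coefficients are structurally absent from the parameter container, not
merely zero.

The A$\beta$ subsystem on $\Gamma$ (concentrations $u_i(x_m,t)$) is

$$\varepsilon\,\partial_t u_1 = -d_1 \Delta_\Gamma u_1
  - \alpha u_1 \textstyle\sum_{j=1}^5 u_j - \sigma_1 u_1 + \mathcal F(f),$$
$$\varepsilon\,\partial_t u_i = -d_i \Delta_\Gamma u_i
  + \tfrac{\alpha}{2}\textstyle\sum_{j=1}^{i-1} u_j u_{i-j}
  - \alpha u_i \textstyle\sum_{j=1}^5 u_j - \sigma_i u_i, \quad i = 2,3,4,$$
$$\varepsilon\,\partial_t u_5 =
  \tfrac{\alpha}{2}\textstyle\sum_{j+k \ge 5;\; j,k<5} u_j u_k,$$

where $\varepsilon$ is the ratio between the fast physical time scale
(aggregation, clearance, production) and the slow disease time scale.  The
division by $\varepsilon$ happens inside `abeta_rhs()`, so the integrator
sees plain derivatives.  Note one deliberate bookkeeping property taken
as printed from the model equations: the loss sums $\sum_{j=1}^5$ include
the insoluble pool (plaques and tangles keep scavenging soluble polymers),
while the insoluble equations credit only mergers of soluble pairs, so
monomer mass is *not* conserved.  The consequences are discussed under
*Known limitations* below.

The tau subsystem on $G$ (concentrations $\tau_i$) has the same
coagulation structure with rate $\gamma$, no clearance term, no
$\varepsilon$ factor, and two monomer sources: a Gamma-shaped seeding pulse
$c\, s_\tau(t)$ with $s_\tau(t) = (t/\lambda)e^{-t/\lambda}$ confined to
the entorhinal seed vertices (Braak staging), and production induced by
toxic A$\beta$ oligomers, $C_\tau (u_2 + u_3 + u_4 - \bar U)^+$.

### Neuronal health

Each parcel carries a probability density $f(x_m, a, t)$ of the degree of
malfunctioning $a \in [0,1]$ ($a=0$ healthy, $a=1$ dead), advected by

$$\partial_t f + \partial_a (v f) = 0, \qquad f(x_m, 1, t) = 0,$$

with nonnegative deterioration rate

$$v = C_{\mathcal G}\!\int_0^1 (b-a)^+ f(x_m,b,t)\,db
  + C_S (1-a)\big(\textstyle\sum_{i=2}^4 u_i - \bar U_{A\beta}\big)^+
  + C_T (1-a)\big(\textstyle\sum_{i=1}^5 \tau_i - \bar U_\tau\big)^+ .$$

The first term is a prion-like influence of already-malfunctioning
neighbours within the parcel; the other two are threshold-gated toxicity of
soluble A$\beta$ oligomers (compartments 2–4 only) and of total misfolded
tau (all five compartments, monomers and tangles included — the asymmetry
is kept exactly as the model prints it).  The health state feeds back into
A$\beta$ production through

$$\mathcal F(f) = C_{\mathcal F}\!\int_0^1 (\mu_0 + a)(1-a) f\,da :$$

a healthy parcel produces at baseline $C_{\mathcal F}\mu_0$, moderately
damaged neurons overproduce, dead neurons produce nothing.

## Parameters

Fixed values (`default_params()`): $d_i = \tilde d_i = \sigma_i = 1/i$,
$\varepsilon = 0.1$, $\gamma = 4$, $\lambda = 10$, $\bar U = 0.001$,
$C_{\mathcal G} = 0.1$, $C_S = C_T = 0.01$,
$\bar U_{A\beta} = \bar U_\tau = 0.001$, $C_{\mathcal F} = 10$,
$\mu_0 = 0.01$.  All quantities are dimensionless.  The three scenario
constants are deliberately unset until a case is named
(`scenario_params()`):

| case | $\alpha$ | $C_\tau$ | $c$ | reading |
|------|------|------|------|---------|
| A | 10 | 0 | 0 | no tau sources — simplified amyloid cascade |
| B | 10 | 0 | 0.05 | entorhinal seeding only |
| C | 10 | 10 | 0.05 | full amyloid–tau synergy |
| D | 10 | 10 | 0 | amyloid-driven tau without seeding |
| E | 0 | 10 | 0.05 | amyloid aggregation inhibited (drug-like) |

Two quantities the model itself does not pin down are configuration values
with logged defaults: the time horizon (`t_end = 50` dimensionless units)
and the uniform initial monomer level (`u01 = 0.01`, satisfying
$u_{0,1} \ll 1$).  The initial health density is a normalized triangular
bump of half-width $0.03$ (three cells at the default grid) centred at
$a_0 = 0.01$ — a resolvable approximation of a Dirac delta near the
healthy state.  The width is fixed in physical units so that refining the
grid solves the same continuous problem.

## The synthetic connectome generator

`synthesize_connectome()` emulates the *structure* of a
tractography-derived connectome without claiming anatomical realism:
parcels scattered in 3D around region centres on a sphere; two mirrored
"entorhinal" regions flagged as the tau seed set; a proximity graph linking
each parcel to its `k = 4` nearest neighbours with $1/d$ weights
symmetrised by max; and a connectivity graph with heavy-tailed (log-normal)
weights, denser intra-region wiring, distance-decaying inter-region wiring,
and stronger seed-incident edges.  The entorhinal regions receive half the
per-region node budget (minimum two parcels) because the entorhinal cortex
is an anatomically small structure.  Both graphs are guaranteed connected;
generation is deterministic given `rng_seed` and leaves the global RNG
stream untouched.

What the generator does **not** emulate: measured fibre-count
distributions, hemispheric lateralisation beyond the mirrored seed pair,
distance-dependent tract probability calibrated to dMRI, or named
anatomical parcels.  Simulation studies that pass on synthetic connectomes
therefore demonstrate correctness of the dynamics and the qualitative
seeding geometry, not quantitative agreement with any measured brain.
Real connectomes enter through `load_graph()` (edge-list CSV or GraphML)
plus a parcel table naming regions and seed membership.

## Numerics

* **Health grid.** $a \in [0,1]$ uses `M = 101` uniform cells by default;
  $f$ is stored as cell averages.  All $a$-integrals (production, prion
  influence, mean malfunction) share one midpoint-quadrature convention on
  this grid.
* **Transport.** Conservative upwind exploiting $v \ge 0$ with
  slope-limited (monotonized-central) second-order face reconstruction,
  $F_{k+1/2} = v_{k+1/2}\big(f_k + \tfrac{1-\nu}{2}s_k\big)$ where $s_k$
  is the MC-limited slope and $\nu$ the local Courant number (at $\nu = 1$
  this degenerates to plain first-order upwind).  The limiter keeps the
  update total-variation-diminishing, hence positivity-preserving, under
  the CFL condition $\,dt \max v / \Delta a \le 1$, while cutting the
  numerical diffusion that a plain first-order flux inflicts on the
  near-delta health densities this model transports — with the plain flux
  the final global damage still moved by several percent between
  $M = 101$ and $M = 202$, far from grid-converged.  The boundary
  condition at $a = 1$ is enforced through the analytically zero flux
  ($v(1) = 0$ term by term), not by zeroing the last cell, so per-parcel
  probability mass is conserved to round-off.
* **Operator splitting.** Each step freezes $f$, evaluates $\mathcal F(f)$
  and $v$, advances both protein systems by one classical fourth-order
  Runge–Kutta step, then advances $f$ by one upwind step with the frozen
  $v$.  The splitting is first-order; the engine test suite verifies the
  coupled error against an independent monolithic method-of-lines
  integration and that it shrinks when the step is halved.
* **Step control.** $dt$ is capped by the protein stiffness scale
  $\varepsilon / [10(\alpha S_u + \max\sigma_i + \max d_i)]$ (with the
  analogous tau-side cap $1/[10(\gamma S_\tau + \max\tilde d_i)]$, which
  carries no $\varepsilon$), by the transport CFL bound
  $0.9\,\Delta a/\max v$, and by the next sampling time.  A step producing
  a CFL violation, concentrations below $-10^{-12}$, or non-finite values
  is rejected and retried at $dt/2$; negativity within $-10^{-12}$ is
  clamped to zero as a round-off guard.  Positivity is treated as a model
  invariant, not a numerical suggestion.
* **Determinism.** The only randomness is the synthetic generator's seed;
  identical configurations produce bitwise-identical exported CSVs.

### Problem sizes used by the test suite

The campaign checks run the five cases on one 64-node, 8-region synthetic
connectome with $M = 101$ cells to $T = 50$, plus one refined run
($M = 202$, halved step cap) for a convergence check; engine-versus-oracle
comparisons use a hand-built 3-node connectome with $M = 21$ cells.  These
sizes were chosen as the smallest at which the regional phenomena of
interest (seed-region dominance, case ordering) are cleanly expressed.

## Design choices on genuinely open points

* **Laplacian normalisation.** Only the row-normalised ($1/\pi_m$) form is
  exposed; no symmetric-normalised or unnormalised variant, for
  reproducibility of the published operator.
* **Edge-list dialect.** 1-based ids in files, 0-based storage internally;
  undirected edges stored once; duplicate entries must agree
  (`dialect = "strict"`, default) or are summed (`"sum"`).
* **Scenario constants have no silent defaults** because the model's
  conclusions hinge on $(\alpha, C_\tau, c)$.
* **Equal parcel volumes** are hard-assumed in all burden and damage
  averages; a volume-weighted variant is out of scope.
* **Horizon.** `t_end = 50` is the logged default.  On the default
  synthetic connectome the global damage, tangle and plaque curves and the
  regional orderings are all well developed by then, while the amyloid
  monomer burden is still on its damage-amplified rise (see below).

## Known limitations

* The as-printed loss bookkeeping — soluble species scavenged by the
  insoluble pool with no reciprocal gain — has a visible dynamical
  consequence: as plaques accumulate, the quadratic loss term suppresses
  oligomers, so the soluble A$\beta$ oligomer curves peak during the early
  fast-time-scale transient, while the monomer burden keeps rising on the
  slow time scale as neuronal damage amplifies production
  ($\mathcal F$ grows with $(\mu_0 + a)(1-a)$ until mean malfunction
  reaches $\approx 0.5$).  Under the fixed parameter set the global
  monomer curve therefore peaks much later than the oligomer curves, and
  the test suite's curve-staging check documents exactly this tension: the
  classical staging (monomers peak first, oligomers in increasing length,
  tau lagging amyloid) is *not* reproduced at these conditions, whereas a
  variant whose loss total runs over soluble compartments only produces
  near-simultaneous late peaks.  The equations are implemented exactly as
  printed; no variant is exposed.
* Tau has no clearance anywhere, also as printed, so total tau grows
  without bound while sources persist.
* The health density genuinely concentrates: the deterioration rate
  decreases across the bump (both the prion integral and the
  $(1-a)$-damped toxicity terms fall with $a$), so the continuous
  solution sharpens toward a moving Dirac mass.  On a fixed grid the
  spike's width is floored at a few cells, and the prion term's
  self-interaction over that numerical width adds a spurious drift
  proportional to $\Delta a$.  Global damage therefore converges at first
  order in $\Delta a$ whatever the limiter; the test suite's
  grid-refinement check measures this sensitivity at the default sizes
  (a few percent of $A(T)$ in relative terms, well under one percentage
  point of the damage scale, when doubling $M$ from 101).  Users needing
  grid-insensitive damage values should raise `a_cells`.
* First-order operator splitting (frozen deterioration rate during the
  protein substep) contributes negligibly next to the spatial error: the
  engine tests verify the split trajectory against a monolithic
  method-of-lines integration and that the discrepancy shrinks with the
  step.
* The measure-theoretic formulation of the health density, oligomers of
  arbitrary length, fragmentation, nucleation, and extracellular tau
  release/uptake are out of scope, as is any fit to patient data: the
  model is descriptive, not predictive.
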