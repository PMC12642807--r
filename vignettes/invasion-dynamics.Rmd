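---
title: "Modelling microbially-mediated invasion with symbiovade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling microbially-mediated invasion with symbiovade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symbiovade)
```

## The model

`symbiovade` simulates the coupled dynamics of two host populations —
native ($p_n$) and invasive ($p_i$), e.g. plant species — and their
associated microbial symbiont communities ($m_n$, $m_i$, e.g.
mycorrhizal fungi), all tracked as biomass densities. Hosts are
facultative partners with intrinsic growth rates $r_{p}$; symbionts are
obligate and grow only through resource exchange with hosts.

The defining feature is a consumer–resource formulation of symbiosis:
instead of fixed per-capita interaction coefficients, benefits and
costs arise from explicit resource fluxes,

$$
\frac{dp_n}{dt} = r_{p_n} p_n + F_{p_n} - c_{p_{in}} p_n p_i - \mu_{p_n} p_n^2,
\qquad
\frac{dm_n}{dt} = F_{m_n} - c_{m_{in}} m_n m_i - \mu_{m_n} m_n^2,
$$

and symmetrically for the invasive compartments. The net flux into the
native host is

$$
F_{p_n} = q_{hp_n} p_n
  \frac{\alpha_{nn} m_n + \alpha_{in} m_i}{p_n/d + p_i/d + m_n + m_i}
  - q_{cp_n} p_n
  \frac{\beta_{nn} m_n + \beta_{ni} m_i}{p_n + p_i + d m_n + d m_i},
$$

with analogous expressions for the other three compartments. The
$\alpha_{jk}$ coefficients quantify symbiont-to-host supply and the
$\beta_{jk}$ coefficients host-to-symbiont supply, first subscript the
supplier, second the receiver. The shared saturating denominators make
each transfer limited by the partner with the lower biomass (adjusted
by the factor $d$): this is what lets the same association be
beneficial at one biomass ratio and exploitative at another, and it is
the reason classical Lotka–Volterra intuition does not carry over
directly. The $q$ coefficients convert received ($h$) and supplied
($c$) resources into biomass, $c_{\cdot}$ are interspecific competition
rates within the host and symbiont guilds, and $\mu_\cdot$ are
self-limitation (maintenance) rates.

Every flux ratio is defined as $0$ when its denominator vanishes, which
happens only at the all-zero state: total extinction must be an exact
equilibrium, and this convention makes it one.

## The mutualism–parasitism continuum

A single host–symbiont pair follows the reduced system

$$
\frac{dp}{dt} = r_p p + \frac{pm}{p/d + m} Q_p - \mu_p p^2,
\qquad
\frac{dm}{dt} = \frac{pm}{p/d + m} Q_m - \mu_m m^2,
$$

with the signed net-interaction coefficients

$$
Q_p = q_{hp}\frac{\alpha}{d} - q_{cp}\beta,
\qquad
Q_m = q_{cm}\beta - q_{hm}\frac{\alpha}{d}.
$$

Their signs classify the association: mutualistic ($Q_p, Q_m > 0$),
parasitic for the host ($Q_p < 0 < Q_m$), parasitic for the symbionts
($Q_m < 0 < Q_p$), with commensal boundary cases at exact zeros. In the
$(\alpha, \beta)$ plane the regimes are separated by two straight
break-even lines through the origin, $\beta = \alpha\, q_{hp}/(q_{cp}
d)$ and $\beta = \alpha\, q_{hm}/(q_{cm} d)$, and the mutualism wedge
lies between them:

```{r}
rm <- regime_region_map(model_params(), edge = "pn_mi", grid = 41)
rm
```

One subtlety worth stating plainly: the reduced parameterization above
attaches the biomass-adjustment factor $d$ to the aggregated saturating
term, whereas restricting the full four-compartment equations to a
single pair distributes $1/d$ over the host-to-symbiont stream. The two
forms — and hence the $(Q_p, Q_m)$ break-even lines and the full
model's pairwise dynamics — coincide exactly at $d = 1$, which is the
package default used everywhere a reduced-system quantity is compared
against the full system. For $d \neq 1$ the reduced system and its
regime algebra remain self-consistent (and all reduced-system tests
hold at any $d$), but they are then an approximation to, not a
restriction of, the full model.

A pattern with $Q_p \le 0$ and $Q_m \le 0$ (not both zero) has no place
on the continuum — with positive conversion efficiencies it cannot
arise unless both benefit streams vanish — so `classify_regime()`
reports it explicitly as `invalid_exchange` rather than forcing it into
a named regime.

## Invasion scenarios

Cross-community exchange is controlled by four coefficients:
$\alpha_{in}, \beta_{ni}$ (native host with invasive symbionts, the
`pn_mi` edge) and $\alpha_{ni}, \beta_{in}$ (invasive host with native
symbionts, `pi_mn`). With both resident pairs mutualistic, the regime
of each cross edge defines the scenario taxonomy returned by
`scenario_id()`: no shared partners (`"1"`), a mutualistic cross edge
(`"2"`, `"3"`), symbionts exploiting the novel host (`"4"`, `"6"`), or
hosts exploiting the novel symbionts (`"5"`, `"7"`); simultaneous cross
edges give combined labels such as `"2+6"`.

`invasion_experiment()` implements the standard protocol: the native
pair is brought to its equilibrium, a small invader propagule is added,
and the system is integrated until it settles. The endpoint's
persistence pattern is thresholded and named (`co_invasion`,
`native_resistance`, `full_coexistence`, novel-association endpoints,
and explicit collapse patterns), and `pathway_trace()` records which
compartments were excluded first — the exclusion order, not just the
endpoint, distinguishes mechanistically different invasions.

```{r}
inv <- invasion_experiment(model_params(alpha_in = 0.01, beta_ni = 2))
inv
```

## Default parameters and what they mean

The package defaults describe two mirror-image mutualistic resident
communities that share nothing: conversion efficiencies 2 on the
benefit stream and 1 on the cost stream for both guilds (so $Q_p = Q_m
= 1$ on resident edges with $\alpha = \beta = 1$), $r_p = 0.5$,
$\mu = 1$, competition $0.5$, $d = 1$, cross coefficients $0$. These
are repository choices of a generic, dimensionless mutualistic
community — biomass and time units are arbitrary — selected once so
that every interaction regime is reachable by moving a single cross
coefficient; none of them is fitted to an empirical system. The
scenario regression tests use documented one-knob variants: strong
competition ($c = 2$) for the shared-nothing bistability runs,
$(\alpha_{in}, \beta_{ni}) = (0.01, 2)$ for strongly exploitative
invasive symbionts, its mirror for exploitative native symbionts, and
$\beta_{in} = \beta_{ii} = 0.6$ (against native $\beta_{nn} = 1$) for a
low-quality-mutualist invading host.

## Numerical choices

* **Integration.** Adaptive stiff-capable lsoda/lsodar (compiled
  right-hand side) at `rtol = 1e-9`, `atol = 1e-12`. The tolerances are
  deliberately far below the extinction threshold so that outcome
  classification is solver-noise-free and byte-reproducible.
  Trajectory components in $[-10^{-9}, 0)$ are clipped to zero on
  output.
* **Settling.** `run_to_convergence()` integrates in windows of 1000
  time units up to a hard cap of $10^5$, declaring convergence when
  $\lVert \dot{x} \rVert_\infty < 10^{-10}$. If the cap is reached and
  the last window still shows biomass range above $10^{-6}$, the run is
  flagged as a limit cycle and the window time-average is reported —
  always with the flag, since cycle endpoints are not point attractors
  and outcome labels on them should be read with care.
* **Extinction threshold.** $\varepsilon = 10^{-6}$ relative to the
  resident community's total biomass: dimensionless, hence robust to
  rescaling the (arbitrary) biomass units.
* **Propagule.** Default $10^{-3}$ of resident biomass, split equally
  over the introduced compartments — small enough for linearized
  invasion criteria to apply, three orders of magnitude above
  $\varepsilon$.
* **Equilibria.** Damped Newton iteration with the analytic Jacobian
  (the fluxes are rational, so exact partials are available; one-sided
  finite differences are used on the nonnegativity boundary), projected
  to the nonnegative orthant; residuals below $10^{-10}$; stability
  from Jacobian eigenvalues with a $10^{-10}$ dead band for the
  marginal label. `resident_equilibrium()` polishes against the full
  system restricted to the resident compartments, so its residual is a
  full-model residual.
* **Regime boundaries.** $|Q| < 10^{-12}$ counts as zero: the
  commensal lines are measure-zero and float noise must not flip a
  boundary cell.
* **Sampling.** `sample_params()` draws free coefficients log-uniformly
  over $[10^{-2}, 10^1]$ — spanning flux-limited regimes on both sides
  of $d$ — and rejection-samples until the requested edge regimes hold.

## What the checks do and do not show

The test suite and `scripts/acceptance.R` verify structural identities
(per-pair flux conservation between supplier cost and receiver gain,
restriction of the full system to one pair at $d = 1$, native/invasive
relabelling symmetry), closed-form limits (logistic host growth without
exchange), agreement between the adaptive solver and an independent
fixed-step fourth-order integrator (100 mutualistic draws, horizon 100,
step $10^{-4}$), the regime algebra against brute-force inequality
evaluation ($10^4$ draws; boundary placement within one cell on a
$101\times101$ map), the rare-symbiont establishment criterion
($\mathrm{sign}$ of growth from $10^{-8} p^\ast$ matching
$\mathrm{sign}(Q_m)$ on 500 draws — draws with $|d\,Q_m| < 10^{-3}$
are redrawn, because below that the self-limitation term
$\mu_m m_0 \approx 10^{-8}\mu_m p^\ast$ competes with the linearized
rate and the sign criterion is mathematically uninformative), and the
scenario endpoint regressions described above. These sizes are the
package's standing choices; they complete in well under a minute.

All of this validates the simulator against its own mathematical
structure, on synthetic parameter sets. It says nothing about whether
a particular empirical host–symbiont system is well described by
saturating biomass-ratio exchange, a single averaged symbiont
compartment per community, or deterministic dynamics.

## Known limitations

* Communities are single averaged pools: no multi-strain structure,
  no preferential allocation among strains.
* Deterministic ODEs: no demographic or environmental stochasticity,
  which matters most exactly where invasions are decided — at low
  invader biomass.
* One-off introductions only; no repeated propagule input.
* No spatial structure or range expansion.
* Limit cycles are flagged and time-averaged, not characterised.
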