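---
title: "Evolution of biparental care under transgenerational quality effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolution of biparental care under transgenerational quality effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carevol)
```

## The model

`carevol` analyses the joint evolution of biparental care in a large,
continuously breeding population in which parental *quality* is itself a
consequence of the care an individual received while developing — a
transgenerational parental effect. Adults are either good (G) or poor
(P) parents; by definition a good parent pays a lower mortality cost for
any given amount of care. Breeding pairs form at random (the first
female and the first male to reach a breeding resource), care jointly
for one brood, then separate. Care is a sealed bid: an individual's
care level depends on its own quality and its partner's quality, but not
plastically on the partner's behaviour within a bout, giving a
four-component strategy

$$c = (c_{GG},\, c_{GP},\, c_{PG},\, c_{PP}),$$

where $c_{AB}$ is the care of an $A$-quality parent paired with a
$B$-quality partner. There are no sex differences.

Three life-history functions drive everything:

* **mortality** $m_A(c)$: the probability that a parent of quality $A$
  dies between breeding bouts after providing care $c$ — convex and
  increasing, with $m_G(c) < m_P(c)$ at every care level;
* **brood productivity** $b(C)$: expected offspring surviving from a
  brood that received total care $C = c_{AB} + c_{BA}$ — concave,
  increasing;
* **competitiveness** $f(C)$: the relative competitiveness of those
  offspring in the race to develop into good parents — concave,
  increasing; its gain scales with $\alpha_F$, the strength of the
  parental effect.

Opportunities to become a good parent are limited at the population
level: the proportion of recruits that develop into good parents is
fixed at $g_1$, whatever the average care level (a density-dependent
quota). An offspring whose brood received total care $C$ wins a slot
with probability $g_{AB} = 1 - e^{-\kappa f(C)}$; the calibration
$\kappa$ (the product of race intensity and competition time — only the
product matters) is pinned down by mass balance,
$g_{GG}q_{GG} + g_{GP}q_{GP} + g_{PP}q_{PP} = g_1$, where the $q_{AB}$
are the proportions of recruits raised by each pairing type. Because
only *relative* competitiveness matters, care raises a brood's chances
only insofar as it outpaces the population average — an arms-race
structure that matters for the comparative statics below.

### Resident equilibrium

For a monomorphic strategy the package solves, in order: the
demographic fixed point ($g_2$, the good-parent share of the mating
pool, by bracketed one-dimensional root-finding on $[0,1]$); raw and
normalized brood productivities (mean lifetime reproductive success is
normalized to one); the recruit-origin proportions $q_{AB}$; the
quality-transition calibration $\kappa$ (again a bracketed
one-dimensional root-find — the mass-balance residual is strictly
increasing in $\kappa$); and finally class reproductive values
$(v_G, v_P)$ as the right eigenvector of a $2 \times 2$ projection
matrix $M$ for the eigenvalue 1, normalized so
$g_1 v_G + (1 - g_1) v_P = 1$.

One scale convention deserves a note. If each parent is credited with
its full broods, every brood is counted twice (once per parent), so
with lifetime reproductive success normalized to one and the factor
$\tfrac12$ for parent–offspring relatedness, the projection matrix
would have Perron eigenvalue exactly $\tfrac12$. `carevol` therefore
uses the *genetic* normalization — the offspring term carries
$\tfrac12 \times 2$ — so that the resident matrix has eigenvalue
exactly 1, as a stationary one-generation map should. Eigenvectors,
selection gradients' zero sets, and all equilibria are invariant to
this uniform scale; only the eigenvalue's value depends on it.

### Invasion fitness and the ESS

A rare mutant with strategy $\hat c$ experiences the resident
background ($g_2$, $\bar b$, $\kappa$ are resident quantities). Its
projection matrix $\hat M$ substitutes the mutant's own care into its
mortality, its broods' productivity and its broods' quality transition.
Invasion fitness is the dominant eigenvalue of $\hat M$; it equals 1
when $\hat c = c$. Mutant reproductive values are computed by the
one-generation valuation $\hat v = \hat M v$, whose gradient in
$\hat c$ vanishes exactly where the eigenvalue gradient does. The
selection gradient takes partial derivatives of the quality-specific
mutant value ($\hat v_G$ for $c_{GG}, c_{GP}$; $\hat v_P$ for
$c_{PG}, c_{PP}$) by central finite differences (step
$10^{-6}\max(1, c)$, one-sided at the box boundaries), and the ESS is
located by gradient ascent $c_{t+1} = c_t + \Delta S(c_t)$ with
$\Delta = 0.01$, iterates projected onto $[0, c_{\max}]^4$,
convergence declared when the projected gradient norm falls below
$10^{-8}$.

**Removing sexual conflict.** In the `no_conflict` mode coparents are
genetically identical, so the mutant's partner expresses the mutant
allele too: every pairing total becomes $\hat c_{AB} + \hat c_{BA}$.
Because one allele then affects both class values, the gradient
component is the class-weighted total derivative
$\mathrm{d}[g_1\hat v_G + (1-g_1)\hat v_P]/\mathrm{d}\hat c_{AB}$
(the unweighted quality-specific form would drop the cross-class term).
At $g_1 = 0.5$ the weighting is immaterial to the location of the
equilibrium. The relatedness factor on the offspring term is kept at
$\tfrac12$ by default; the `offspring_factor` argument exposes the
$r = 1$ variant, which rescales $\hat M$ uniformly and therefore —
demonstrably, and tested — does not move the equilibrium.

## The default life-history family

Only the shape properties of $m_A$, $b$ and $f$ are fixed by the model;
their concrete forms are this package's design, chosen so that the
default parameterization reproduces the full set of qualitative
equilibrium predictions. The defaults are

$$m_G(c) = m_{\min} + (1 - m_{\min})\Big(\frac{c}{\eta_G \beta_G}\Big)^4,
\qquad
m_P(c) = \rho_0 m_{\min} + (1 - \rho_0 m_{\min})
         \Big(\frac{\rho c}{\beta_P}\Big)^2,$$

$$b(C) = b_{\min} + \alpha_B\big(1 - e^{-C/\sigma_B}\big), \qquad
f(C) = f_{\min} + \alpha_F\big(1 - e^{-C/\sigma_F}\big),$$

with $\eta_G = 0.36$, $\rho = 4.5$, $\rho_0 = 1.01$, $\sigma_B = 4$,
$\sigma_F = 10$, and headline values $g_1 = 0.5$, $m_{\min} = 0.25$,
$\beta_G = \beta_P = 5$, $b_{\min} = f_{\min} = 1$, $\alpha_B = 5$.
The care box is $c_{\max} = 0.95\min(\eta_G\beta_G,\, \beta_P/\rho)$,
just inside the care level at which mortality reaches certainty, so the
numerical clamp on mortality (at $1 - 10^{-6}$) is never active inside
the box and care beyond the box is never favoured.

The rationale, in terms of what each choice does to the equilibrium:

* **Why the asymmetry sits in the cost *rate*, not the baseline.** What
  determines how much a parent invests is the *relative marginal*
  mortality cost $m'(c)/m(c)$ at its optimum. In any family where the
  quality gap is a baseline shift (poor parents start at higher
  mortality but accrue cost at a comparable rate), the higher baseline
  mechanically *lowers* $m'/m$, making poor parents the cheaper carers
  — and the model then predicts poor parents caring more than good
  ones, the opposite of the quality structure of interest. The default
  family instead gives poor parents a steep quadratic cost from the
  first unit of care ($\rho$), and good parents a flat-then-steep
  quartic cost: good parents care substantially more, and their larger
  care investment leaves them with *higher* realized mortality at the
  ESS ($m_G > m_P$) even though $m_G(c) < m_P(c)$ pointwise. The small
  baseline multiplier $\rho_0$ exists only to keep the pointwise
  ordering strict at $c = 0$.
* **Why the benefits are near-linear over the box.** The response of
  the equilibrium to a parameter is (incentive)/(stiffness). Removing
  conflict doubles the incentive of every care component (the partner's
  share of the brood benefit is internalized) but also quadruples the
  stiffness contributed by *benefit* curvature (totals move twice as
  fast in a joint deviation). If benefit curvature dominates, removing
  conflict therefore *damps* the response to $\alpha_F$. With
  $\sigma_B$ and $\sigma_F$ large relative to equilibrium care totals,
  stiffness is dominated by the *own-mortality* curvature (which a
  joint deviation does not double), and the no-conflict population both
  cares more and responds more steeply to the strength of parental
  effects — the comparative statics the model is built to exhibit.

The family is pluggable (`mortality_fn`, `productivity_fn`,
`competitiveness_fn`); any replacement is validated at construction
against the model's shape assumptions over a dense grid (convex
increasing mortality with strict pointwise ordering, concave increasing
benefits). Exchangeable-quality analyses (identical mortality for both
classes) are possible through this interface with
`allow_equal_mortality = TRUE`.

## Numerical choices

* Root-finds (demographic fixed point; $\kappa$) are bracketed and run
  to near machine precision ($10^{-14}$ on the variable); residuals are
  re-checked below $10^{-10}$.
* When all pairings have equal competitiveness (for instance
  $\alpha_F = 0$), the quality transition is set to $g_{AB} = g_1$
  exactly rather than solved, avoiding needless round-off in the limit
  the model treats as special.
* Degenerate $g_1 \in \{0, 1\}$ collapses to a single quality class:
  the demographic and brood quantities reduce analytically, the absent
  class is reported as `NA`, and the ESS solver (which needs both
  classes) refuses such inputs.
* The eigenvalue-1 eigenvector is taken from `eigen()`; property tests
  cross-check it against plain power iteration.
* Convergence of the ESS iteration is declared on the KKT-projected
  gradient (components pinned at a boundary with the gradient pointing
  outward are discounted), not on the care step alone, so a small
  $\Delta$ cannot fake convergence.

## The individual-based simulator

`simulate_resident()` and `simulate_evolution()` implement the same
life cycle as an event-driven Monte Carlo simulation sharing no code
with the analytic solvers: a fixed pool of `pool_size` adults; random
pairing; Poisson brood sizes with mean $b(C)$; death with probability
$m_A(c)$; dead adults replaced in small recruitment epochs by offspring
sampled from the epoch's cohort in proportion to brood size. The
good-parent quota is enforced per epoch: recruits draw exponential
arrival times with rate equal to their competitiveness and the fastest
$g_1$ fraction become good parents — which gives each recruit success
probability $1 - e^{-f\tau}$ with a common threshold $\tau$, exactly
the analytic transition with a self-calibrated $\kappa$. In evolution
mode each adult carries four haploid care alleles (one per pairing
context); recruits inherit each allele from a random parent (free
recombination) with Gaussian mutation (`mutation_sd`), reflected into
the care box.

What the simulator emulates — and what it does not:

* It validates the analytic bookkeeping (demographic fixed point,
  recruit-origin proportions, quality transition, pairing-frequency
  care averages) to Monte Carlo precision; agreement within three block
  standard errors at $10^5$ events is part of the test suite.
* Its deliberate approximations: deaths are applied at epoch ends (the
  default 50-event epochs make this negligible against a pool of
  $10^4$); the pool composition relaxes over roughly
  `pool_size`/(2·mortality) events, so cross-checks seed the pool at
  the analytic $g_2$ — starting elsewhere leaves a transient that
  burn-in must cover.
* Two scheme details matter for unbiasedness and honest error bars.
  Recruits are drawn from the *previous* epoch's larval cohort: with
  same-epoch recruitment, epochs with many deaths (which skew toward
  poor-heavy pairings, and toward broods whose own parents died) also
  recruit more, coupling recruitment intensity to cohort composition
  and granting a spurious transmission advantage to high-mortality
  carers; the one-epoch lag removes both couplings. And because the
  pool composition mixes over `pool_size`/(2·mortality) events, error
  bars for cross-checks are computed across independent replicate runs
  (each started at the analytic composition, hence unbiased), not from
  within-run blocks whose autocorrelation is hard to estimate.
* Finite-population caveats for evolution mode. The good-parent care
  components sit on a wide near-neutral plateau *below* the ESS: the
  quartic cost is flat there, so fitness differences over a
  $\sim 0.1$-wide band fall beneath what drift can resolve at any
  affordable pool size. Two-morph competition experiments confirm the
  analytic equilibrium — a morph with higher $c_{GG}$ than the ESS is
  eliminated decisively, while a morph $0.1$ *below* drifts neutrally.
  Consequently the time-averaged allele means of an evolving population
  land $\sim 0.05$–$0.1$ below the analytic ESS on the good components
  (and within $\sim 0.01$ on the poor components, whose cost curvature
  is strong), independent of pool size, mutation scale and epoch
  length. Tests that demand sub-0.05 agreement on every component
  document this property of finite populations on neutral plateaus
  rather than a solver defect; the qualitative ESS structure (good
  care much more than poor; the partner-quality ordering) is recovered
  reliably. Passing resident-mode tests say nothing about biological
  realism beyond the model: no spatial structure, no sex differences,
  no carcass-size variation, no explicit time.

## Problem sizes

The test-suite and reproduction scripts use: 100 random draws for the
resident consistency properties; $10^5$ breeding events (pool $10^4$)
for resident-mode cross-checks; five grid points ($\alpha_F \in
\{0, 2.5, 5, 7.5, 10\}$) for the sweep; ten starting vectors (box
corners, centre, and near-zero) for the uniqueness check; and the
evolution-mode conditions above. These sizes give Monte Carlo standard
errors a decade below the effects being demonstrated.

## A worked example

```{r example, eval = FALSE}
p <- care_params(alpha_F = 5)
fit <- ess_solve(p, mode = "conflict")
summary(fit)
sw <- sweep_alpha_f(c(0, 2.5, 5, 7.5, 10), p)
plot(sw)
sim <- simulate(fit, nsim = 1e5, seed = 1)   # stochastic cross-check
sim
```

## Known limitations

* The qualitative predictions are properties of the *default* family at
  the headline parameters; other shape choices satisfying the same
  convexity/concavity assumptions can invert them (notably the
  good/poor care ordering), which is why the family is explicit,
  documented and validated rather than hidden.
* Second-order (evolutionary stability vs branching) conditions are not
  checked beyond multi-start convergence.
* The conflict comparison is between unrelated coparents ($r = 0$) and
  clones ($r = 1$); intermediate relatedness is not modelled, though
  the finite-pool simulator effectively realizes small positive
  relatedness, visible in its slight upward care bias.
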