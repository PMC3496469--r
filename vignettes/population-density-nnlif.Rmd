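---
title: "Population-density analysis of NNLIF networks: model, schemes and design choices"
author: "nnlifpd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-density analysis of NNLIF networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(nnlifpd)
```

## The model

`nnlifpd` works with the Fokker-Planck (population-density) description of a
large, fully coupled network of noisy leaky integrate-and-fire neurons.  After
the usual change of variables that absorbs the biophysical constants, the
membrane-voltage density $p(v,t)$ on $(-\infty, V_F]$ obeys

$$\partial_t p \;=\; -\partial_v\!\big[(bN(t) - v)\,p\big]
  \;+\; a(N)\,\partial_{vv} p \;+\; N(t)\,\delta(v - V_R),$$

with the absorbing condition $p(V_F,t)=0$ at the firing threshold, decay at
$-\infty$, and the mean firing rate defined *implicitly* by the probability
flux through the threshold,

$$N(t) \;=\; -\,a(N)\,\partial_v p(V_F,t), \qquad
  a(N) = a_0 + a_1 N, \qquad h(v,N) = bN - v.$$

Neurons that cross $V_F$ fire and restart at the reset voltage $V_R < V_F$,
which is the point source above.  The single connectivity parameter $b$
(excitatory if positive, inhibitory if negative) closes the mean-field loop:
the population's own activity feeds back into every neuron's drift (and,
if $a_1>0$, noise).  All quantities are in the dimensionless voltage/time
units of this reduced form; the defaults $V_R=1$, $V_F=2$, $a_0=1$, $a_1=0$
are the values used throughout the published experiments the presets
reproduce.

Despite its linear-looking coefficients the model is genuinely nonlinear, and
three behaviours coexist in the parameter space:

* **Stationary (asynchronous) states.**  A steady state has constant rate
  $N$ solving $N\,I(N)=1$, where $I(N)$ is a Gaussian-weighted integral of
  the scaled reset-to-threshold distance (`steady_state_integral()`).  For
  $b\le 0$ the root is unique; for moderate $b>0$ one or two roots exist; for
  large $b$ none does (`find_steady_states()`, `classify_regime()`).
* **Finite-time blow-up.**  For any $b>0$, initial densities concentrated
  enough near $V_F$ admit no global-in-time solution: the exponential moment
  $M_\mu=\int e^{\mu v}p\,dv$ satisfies a Gronwall inequality that forces it
  past the bound $e^{\mu V_F}$ valid for probability densities
  (`blowup_certificate()`).  Numerically this appears as divergence of
  $N(t)$, read as (partial) synchronization of the network.
* **Relaxation to equilibrium.**  In the uncoupled case $b=0$, $a_1=0$ the
  equation is linear, the equilibrium is the Dawson-type profile
  $p_\infty$, and every relative entropy
  $\int p_\infty G(p/p_\infty)\,dv$ with convex $G$ decreases; with
  $G(x)=(x-1)^2$ the decay is exponential (`relative_entropy_trace()`).

## Evaluating $I(N)$ and finding the steady states

The package evaluates the single-integral form

$$I(N) = \int_0^\infty \frac{e^{-s^2/2}}{s}
   \big(e^{s w_F} - e^{s w_R}\big)\, ds,
   \qquad w_{F,R} = \frac{V_{F,R} - bN}{\sqrt{a(N)}},$$

by adaptive quadrature.  Three numerical points matter:

* the integrand's singularity at $s=0$ is removable; values below
  $s = 10^{-12}$ are replaced by the limit $w_F - w_R$;
* the exponentials are fused ($e^{-s^2/2 + s w}$) and, when $w_F > 0$, the
  log-peak $w_F^2/2$ is factored out, so the quadrature always works on an
  $O(1)$ integrand; `steady_state_integral(..., log = TRUE)` returns
  $\log I$ and never overflows (for $b<0$, $I(N)$ itself exceeds double
  precision long before the scan bound is reached);
* the upper limit is truncated at $\max(w_F,0)+15$, where the integrand is
  $e^{-112}$ of its peak.

Root finding works on $F(N) = N\,I(N) - 1$, computed as
$\mathrm{expm1}(\log N + \log I)$: a 400-point log-spaced scan on
$(10^{-4}, N_{\max}]$, sign-change bracketing, and bisection to
$|F| < 10^{-9}$.  The default scan bound is
$N_{\max} = \max(50,\, 20(V_F-V_R)/b)$ for $b>0$ (where
$N I(N) \to (V_F-V_R)/b$ from below) and $50$ otherwise; the object warns
when the scan bound stops short of that limit by more than 5%.  Because the
uniqueness of the maximum of $N I(N)$ is an open question, near-tangent
brackets — a local maximum of $F$ within $10^{-6}$ of zero without a sign
change — are reported as flagged roots rather than silently dropped.

With the default parameters the two $b=1.5$ roots are
$N = 0.1923640$ and $N = 2.2891257$.  The second differs by about $1.3\%$
from the value $2.31901$ quoted alongside the original bistability
experiment; evaluating $N I(N)$ at $2.31901$ gives $0.9957$, so the quoted
figure appears to be a solver output rather than a root to all printed
digits.  The package reports its own refined root and uses $2.31901$ only
as the *initial condition* of the corresponding preset, where it is an
input.  The `fig4_bl` trajectory is insensitive to the difference: both
values sit near the unstable high-rate state and drift to the low one.

The sufficient conditions reported by `classify_regime()` are evaluated
literally, with one repair: the non-existence condition for high
connectivity is implemented as $b > \max\big(2(V_F-V_R),\, 2V_F\,I(0)\big)$.
The companion statement for rate-modulated diffusion prints the factor as
$2V_F I(0)$, and the proof's first step (no crossing below $N = 2V_F/b$
requires $I(0) < b/2V_F$) needs the product too, while the constant-diffusion
statement is typeset with a quotient — with the quotient the condition would
contradict the diffusion-bound existence condition for small $a_0$.
Similarly, the refined diffusion-bound condition is implemented as
$2a_0 b < V_R (V_F - V_R)\big(\sqrt{2\pi a_0} + V_F - V_R\big)$, following
the derivation line in which the $\sqrt{2\pi a_0}$ arises from
$\int_0^\infty e^{-s^2/2} ds$.  These conditions are *sufficient only*:
`classify_regime()` may return `"inconclusive"` for parameters whose root
scan nevertheless finds steady states (e.g. $b=3$ is inconclusive by the
conditions, while the scan proves no roots up to its bound).

## The solver

`run_simulation()` advances the density with explicit SSP (TVD) Runge-Kutta
time stepping (orders 2 and 3) over one of three spatial discretisations of
the flux form $\partial_t p = -\partial_v \Phi + N\delta_{V_R}$,
$\Phi = h\,p - a\,\partial_v p$:

* `upwind1` — first-order upwinding of $h\,p$ by the sign of the interface
  drift; robust, positivity-preserving, the default;
* `weno5` — fifth-order WENO reconstruction of the advective flux with
  local (Rusanov) splitting; past the threshold the stencil sees the density
  continued with its boundary slope, so the absorbing boundary does not act
  as a spurious kink;
* `chang_cooper` — exponential-fitting interface weights
  $\delta(w) = 1/w - 1/(e^w-1)$, $w = \Delta v\,A/a$, which make the flux
  vanish identically on densities proportional to the local Maxwellian
  $e^{-(v-bN)^2/2a}$; second-order and positivity-preserving.  (As in the
  original experiments, this discretisation is the wrong tool when $a$ is
  constant and $N$ is very large — the Maxwellian drift then almost
  vanishes on the domain — which is exactly the blow-up regime; the
  mesh-resolution guard below ends such runs first.)

Diffusion is always second-order centred.  The grid is uniform on
$[V_{\min}, V_F]$ with both $V_R$ and $V_F$ exactly on nodes
(`nnlif_grid()` adjusts the spacing to $(V_F-V_R)/k$ and extends the lower
end by less than one cell if needed); the density is node-centred and all
integrals are trapezoidal, so the Dirichlet value $p(V_F)=0$ is exact.

**Conservative reset.**  The discrete outflux through the last interface is
re-deposited in full on the reset node each stage.  The update then
telescopes: total mass is conserved to rounding ($\sim 10^{-14}$ over whole
runs), rather than to truncation order, and the stationary profile's
derivative jump $N/a$ at $V_R$ is reproduced by the single-node source.  The
*reported* rate $N(t)$ is read off the second-order one-sided stencil
$q = (4p_{J-1} - p_{J-2})/(2\Delta v)$ and the closed form
$N = a_0 q/(1 - a_1 q)$ of the implicit flux relation; deposit and read-off
agree to truncation order at stationarity.

**Time step and termination.**  Every step uses
$\Delta t = \mathrm{cfl}\cdot\min(\Delta v/\max|h|,\ \Delta v^2/2a)$ with
$\mathrm{cfl}=0.5$, which keeps forward-Euler stages (hence their SSP convex
combinations) positive for the upwind and Chang-Cooper fluxes.  A run ends
with one of five statuses: `reached_t_end`; `steady` when the $L^1$ change
per unit time stays below `steady_tol` ($10^{-5}$ by default) for half a
time unit — the persistence window exists so that a single small step cannot
declare convergence; `blowup` when $N \ge 10^3$, when $\Delta t$ collapses
below $10^{-12}\,t_{\mathrm{end}}$, or when $N b\,\Delta v \ge a(N)/2$;
`cc_breakdown` when $a_1 q \ge 1$ (the implicit rate relation loses its
solution — the blow-up mechanism of the $a_1>0$ model) or when the
Chang-Cooper flux loses positivity; `vmin_leak` when the density next to the
lower cutoff exceeds $10^{-6}$.

The third blow-up trigger deserves its own paragraph.  The absorbing
boundary creates an exit layer of width $a/(bN)$ in which the density bends
to zero.  Once $N \gtrsim a/(b\,\Delta v)$ this layer is thinner than a
cell, and the discrete system — which cannot steepen further — settles on a
spurious, mesh-dependent plateau ($N \approx 104$ for $b=3$ at
$\Delta v = 0.01$, where the continuous model has *no* steady state at any
rate).  A firing rate at half that scale is therefore declared numerically
divergent.  The guard sits orders of magnitude above every genuine
stationary rate of the presets (those are $O(0.1$–$2)$), and it is what
lets certified blow-up data be recognised as such instead of being quietly
re-absorbed after an unresolvable spike.

**Lower cutoff.**  The model lives on $(-\infty,V_F]$; the solver truncates
at $V_{\min}$ and pins $p(V_{\min})=0$.  The default
$V_{\min} = \min\big(v_0 - 6\sqrt{\sigma_0^2},\ V_R - 8\sqrt{a_0}\big)$ uses
eight noise standard deviations below the *reset*: equilibria are centred
near $bN$, usually well below $V_R$, and six deviations (a tempting default)
leaves an equilibrium tail of $\sim 2\cdot10^{-6}$ at the cutoff for the
single-steady-state preset — above the leak guard.  The guard itself stays:
a run that outgrows its box fails loudly rather than losing mass.

## Diagnostics

**Blow-up certificates.**  `blowup_certificate()` evaluates the sufficient
condition with $a_m = a_0$ (the infimum of $a(N)$ over $N\ge0$): an
exponent $\mu > \max(V_F/a_m,\ 1/b)$ with
$M_\mu(0) \ge \lambda = (e^{\mu V_F} - e^{\mu V_R})/(b\mu)$.  The automatic
scan tries 64 log-spaced exponents up to $50/(V_F-V_R)$ — beyond that,
$e^{\mu V_F}$-scale quantities exceed what the trapezoidal moment of a
gridded density can resolve — and both sides are compared in log space, so
nothing overflows.  The certificate is one-sided: the spread-out Gaussian of
the single-steady-state preset is *not* certified and indeed relaxes, while
both concentrated presets are certified and blow up; uncertified data may
still diverge.

**Moment bounds.**  `moment_bounds_report()` re-checks, along the recorded
traces, the a-priori estimates that global solutions satisfy (upper/lower
bounds on $\int(V_F - v)p\,dv$ depending on the size of $b$ relative to
$V_F-V_R$, and linear-in-time growth of $\int_0^T N\,dt$ and of the second
moment), reporting the observed constants and worst margins.

**Relative entropy.**  For $b=0$ runs, `run_simulation(...,
track_entropy = TRUE)` records $H(t)=\int p_\infty (p/p_\infty - 1)^2 dv$
at every step against the quadrature-built equilibrium.  Nodes where
$p_\infty < 10^{-30}$ are excluded (the quotient is ill-conditioned there
while the region carries under $10^{-20}$ of the integral), and the
boundary node contributes zero — the integrand's value there is the flux
ratio limit $N(t)/N_\infty$ squared times $p_\infty(V_F) = 0$.  Because the
discrete equilibrium differs from the exact one by truncation error, $H$
saturates at a positive floor; `relative_entropy_trace()` fits
$\log H$ only on the window $[\max(10^{-8}, 4H_{\min}),\ 10^{-2}]$.  The
decay *rate* is reported as an empirical fit only — the underlying
Poincaré-type constant is known to exist but no value for it is computed
anywhere in the package.  With the Chang-Cooper flux at
$\Delta v \in \{0.02, 0.01\}$ the fitted rate is $2.397$ and is stable to
$10^{-3}$ between the two grids; the first-order upwind flux reaches its
entropy floor much earlier (its equilibrium error is $O(\Delta v)$), which
is why the entropy acceptance checks run Chang-Cooper.

## Presets and problem sizes

The nine presets (`nnlif_presets()`) reproduce the published experiment
set-ups from their printed values: Gaussian initial profiles
$(v_0, \sigma_0^2)$ or stationary profiles at a given rate, $a\equiv1$,
$V_R=1$, $V_F=2$.  The package runs them at $\Delta v = 0.01$ by default —
fine enough that the terminal rate of the relaxing presets lands within 1%
of the corresponding root with the default scheme (within $10^{-4}$ with
Chang-Cooper), coarse enough that every preset finishes in seconds.  Final
times are chosen so the steady detector, not the horizon, ends the relaxing
runs (t = 20; the relaxation itself completes around $t\approx9$ at
`steady_tol` $=10^{-5}$, and the quoted "$3.5$ time units" of the original
experiments corresponds to a looser tolerance), and $t=25$ for the
bistable-drift runs, which spend several time units near the unstable
high-rate state before drifting to the stable root.  The blow-up presets
terminate on their own within $t\lesssim4$.

What the presets do *not* emulate: finite-size fluctuations (the density
equation is the mean-field limit), refractoriness, transmission delays, and
any structure beyond all-to-all mean coupling.  Passing the preset checks
therefore says the solver reproduces the mean-field model's phenomenology —
bistability, certified synchronization blow-up, asynchronous relaxation —
not that those phenomena survive in finite or structured networks.

## Known limitations

* Explicit diffusion forces $\Delta t \propto \Delta v^2$; the solver is
  meant for the 1-D desk-scale experiments it ships with, not for
  production-scale parameter sweeps.
* Solutions are not continued past blow-up; what the model does after the
  singularity (and whether periodic firing emerges) is an open question the
  package does not touch.
* The high-connectivity non-existence threshold $2V_F I(0)$ grows
  super-exponentially as $a_0 \to 0$, so for weak noise the classifier is
  almost always inconclusive even where the scan finds no roots.
* Near-tangent root pairs closer than the scan spacing may be reported as a
  single flagged root.
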