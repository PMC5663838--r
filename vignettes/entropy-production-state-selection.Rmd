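---
title: "Entropy production and state selection in the bistable Schloegl model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy production and state selection in the bistable Schloegl model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maxepp)
```

## The question

When a driven chemical system admits several coexisting nonequilibrium steady
states, which one does it occupy?  Two classical extremal principles give
opposite answers: minimum entropy production (MinEPP), rigorous only near
equilibrium, and maximum entropy production (MaxEPP), repeatedly conjectured
and repeatedly "disproved".  This package implements the complete
computational machinery needed to pose the question sharply in the simplest
nontrivial setting — the Schloegl model — and to answer it: *among coexisting
states, the one carrying the larger probability weight is the one with the
larger extensive entropy production rate*.

The Schloegl network couples a single intermediate species X to two chemical
reservoirs,

$$A \rightleftharpoons X \qquad (k_{+1},\, k_{-1}), \qquad\qquad
  3X \rightleftharpoons 2X + B \qquad (k_{+2},\, k_{-2}),$$

with the reservoir concentrations $a$ and $b$ held fixed.  Whenever
$b \neq b_0 = k_{+2}k_{+1}a/(k_{-1}k_{-2})$ the cycle
$A \to X \to B$ (or its reverse) carries a sustained flux and produces
entropy.  Throughout, entropy is in units of $k_B$, concentrations are
molecule numbers per reaction volume $\Omega$, and time is in units of the
autocatalytic rate constant ($k_{+2} = 1$).  The package defaults are the
standard benchmark constants $k_{+1}a = 0.5$, $k_{-1} = 3$,
$k_{+2} = k_{-2} = 1$, for which $b_0 = x_0 = 1/6$ and the deterministic
model is bistable for $b$ between about 3.3 and 4.5.

## Four routes to the same system

The same physical model is treated at four levels, each a module of the
package, and the tests cross-validate every pair where a comparison is
meaningful.

**Macroscopic rate equation** (`schloegl()`, `fixed_points()`,
`macroscopic_ep()`).  The concentration obeys
$\dot x = w_{+1} - w_{-1} + w_{-2} - w_{+2} = -\Phi'_{ODE}(x)$ with
mass-action rates $w_{+1} = k_{+1}a$, $w_{-1} = k_{-1}x$,
$w_{+2} = k_{+2}x^3$, $w_{-2} = k_{-2}bx^2$.  Roots of the cubic drift are
found from the polynomial directly (`polyroot`); roots with imaginary part
above $10^{-9}\max(1, |\mathrm{Re}|)$ are discarded, real parts are clamped
to zero, and a numerically double root (saddle-node) is classified
`marginal` and excluded from the bistable window.  The entropy production
rate per volume is Schnakenberg's
$ds_i/dt = \sum_r (w_{+r} - w_{-r})\ln(w_{+r}/w_{-r}) \ge 0$; a channel with
one vanishing rate has infinite affinity and is reported as `Inf` with a
flag rather than an error, so sweeps through $x = 0$ or $b = 0$ proceed.
Near $b_0$ the rate grows quadratically in the distance from equilibrium —
the MinEPP statement — which `minepp_report()` verifies as a log–log slope
of 2 over relative excursions $\delta \in [10^{-4}, 10^{-2}]$ (measured
slope 1.999; at $b = 2b_0$ the quadratic extrapolation is already off by
about 40%, which the report also documents).

**Chemical master equation** (`stationary_distribution()`,
`evolve_distribution()`, `entropy_rates()`, `partition_states()`,
`critical_b()`, `exact_mfpt()`).  The microscopic state is the molecule
number $X$ with the standard combinatorial propensities
$W_{+1} = k_{+1}a\Omega$, $W_{-1} = k_{-1}X$,
$W_{+2} = k_{+2}X(X-1)(X-2)/\Omega^2$, $W_{-2} = k_{-2}bX(X-1)/\Omega$,
chosen so that $W_{\pm r}/\Omega$ converges to the macroscopic rates (an
often-reproduced variant of the trimolecular birth propensity that omits one
power of $\Omega$ makes the chain monostable-high at every driving and
reproduces none of the reference behavior; the tests pin the scaling via the
macroscopic limit).  Because the chain is one-dimensional birth–death, the
stationary law follows from the zero-flux recursion solved in log space; the
truncation starts at $8\Omega x_{high}$ and grows geometrically until the
step ratio falls below 1/2 and the geometric tail bound is below $10^{-10}$.
Time-dependent solutions use `deSolve::lsoda` with the analytic tridiagonal
Jacobian (tolerances $10^{-9}$).  Entropy production and flow rates sum
$(f - g)\ln(f/g)$ and $-(f - g)\ln(W_\uparrow/W_\downarrow)$ over every
bond–channel pair; at stationarity they cancel to machine precision, and
along transients the balance $dS/dt = dS_i/dt + dS_e/dt$ holds to better
than $10^{-6}$ against finite differences of the Shannon entropy.

The **separatrix** is the interior minimum of the stationary pmf between the
two modes.  State weights, mean concentrations and extensive entropy
production rates are summed on each side; the separatrix bin and the two
bond terms touching it are split half-and-half so that the per-state pieces
add up to the totals exactly.  Peak detection uses a three-point moving
maximum with adjacent candidates merged, which suppresses single-bin
oscillations at small volumes; peaks are kept however exponentially
suppressed (down to $10^{-200}$ of the mode) so that metastable states
remain visible deep in the coexistence region.  At $\Omega = 100$ the weight
ordering transfers from the low to the high state at $b_c \approx 3.60$
(bisection on the weight difference), the per-state entropy production
ordering crosses at $\approx 3.53$, and the separatrix at $b = 3.65$ sits at
$x_{\min} = 0.94$.  The two crossings are close but not equal — the residual
is the curvature dependence of the weights — and outside that narrow window
the ordering of the weights matches the ordering of the extensive entropy
production rates everywhere: the MaxEPP state-selection statement.

**Large-volume (WKB) asymptotics** (`wkb_potential()`, `wkb_density()`,
`gaussian_peaks()`, `escape_rate_ratio()`).  For large $\Omega$ the
stationary law takes the form $p(x) = N(x)e^{-\Omega\Phi(x)}$ with
$\Phi'(x) = \ln[(w_{-1} + w_{+2})/(w_{+1} + w_{-2})]$, the continuum limit
of the exact recursion; it vanishes exactly at the deterministic fixed
points and reduces to the detailed-balance potential at $b_0$.  (A
frequently quoted variant takes the log of the *net* over the *total* rate;
that expression is zero at the fixed points inside the logarithm and
negative on half the domain, so it cannot serve as a potential derivative
and is not used.)  $\Phi$ is accumulated by adaptive quadrature (absolute
tolerance $10^{-10}$) anchored at the low stable root, and $\Phi''$ is
analytic.  The prefactor has two modes: the standard birth–death form
$N(x) \propto [(w_{+1}+w_{-2})(w_{-1}+w_{+2})]^{-1/2}$ (default) and a
constant mode retaining only the exponential.  Escape-rate asymptotics
$r_{1\to2}/r_{2\to1} = \frac{N(x_2)}{N(x_1)}
\sqrt{\Phi''(x_1)/\Phi''(x_2)}\,e^{\Omega[\Phi(x_1)-\Phi(x_2)]}$ are
validated against exact mean first-passage times: the orientation of the
exponent is fixed empirically by the growth of the exact rate ratio with
volume, and with the $N(x)$ ratio included the asymptotics agree with the
exact ratio to a few percent already at $\Omega = 30$ (curvature-only mode
is exposed for comparison; it is off by a volume-independent factor).

**Trajectories** (`gillespie()`, `ensemble_ep_rate()`,
`integral_ft_check()`; `simulate_langevin()`, `path_action()`,
`path_entropy_production()`, `weight_terms()`).  The Gillespie simulator is
exact and doubles as the package's synthetic-data generator; each jump
carries its medium-entropy increment $\ln[W_r(X\to X')/W_{-r}(X'\to X)]$, so
cumulative entropy and time-weighted occupancy stream in bounded memory for
runs of $10^8$ events (the jump loop is compiled).  The time-averaged
medium entropy of a stationary ensemble reproduces the master-equation
entropy production rate within Monte-Carlo error, and the occupancy
histogram reproduces the stationary pmf (total variation < 0.02 after
$t = 10^5$ at $\Omega = 10$, $b = 4$).

## The flux-constrained Langevin system and its action

With the reservoirs held at fixed concentrations the macroscopic equation is
indistinguishable from an equilibrium gradient flow.  The distinction
appears when the constraint is moved from concentrations to fluxes: $a$ and
$b$ become dynamic and a constant imposed flux $F$ — pinned to the target
state's steady value $w_{+1}(x^*) - w_{-1}(x^*)$ — maintains the driving:

$$\dot x = -\Phi'_{ODE}(x) + \eta_x, \qquad
  \dot a = -\Phi'_{ODE}(a) + F + \eta_a, \qquad
  \dot b = -\Phi'_{ODE}(b) - F + \eta_b.$$

The reservoir noises are independent with variance $\varepsilon g^*_q$ per
unit time, where $g^*_a = w_{+1} + w_{-1}$ and $g^*_b = w_{+2} + w_{-2}$ are
effective temperatures frozen at the target state and
$\varepsilon = 1/\Omega$; the noise on $x$ is their mirror,
$\eta_x = -(\eta_a + \eta_b)$, so that noise is not double counted and the
variances add, $g^*_x = g^*_a + g^*_b$.  This variance scaling is the
chemical-Langevin (fluctuation–dissipation) convention, and it is forced by
internal consistency: with amplitude proportional to $g$ itself (variance
$\varepsilon g^2$) a linearized Lyapunov computation gives a strictly
positive stationary entropy-production reading at the detailed-balance point
($\approx 2.5\,k_B$ per time unit at $\Omega = 100$) because the two
reservoirs would then sit at effective temperatures differing by two orders
of magnitude, and the additivity $g_x = g_a + g_b$ would be false.  With
variance $\varepsilon g$ the same computation yields exactly zero, as
equilibrium demands.

Three exact structural properties follow and are tested as identities:
$x + a + b$ is conserved (drift and noise both sum to zero, so the dynamics
live on a 2D shell); the sampled covariance of $\eta_x$ with
$\eta_a + \eta_b$ is $-\varepsilon(g^*_a + g^*_b)\,dt$ per step; and the
Onsager–Machlup action of a path,

$$A_\Gamma = \int_0^t \Big\{ \frac{\Omega}{2} \sum_{q}
  \frac{[\dot q + \Phi'_{ODE}(q) - F\sigma_q]^2}{g^*_q}
  - \frac{1}{2}\sum_q \Phi''_{ODE}(q) \Big\}\,dt,
  \qquad \sigma_a = 1,\ \sigma_b = -1,\ \sigma_x = 0,$$

decomposes exactly into a kinetic-minus-potential term, an
entropy-production cross term $\Omega\sum_q \dot q\,\Phi'(q)/g^*_q$, a
curvature (noise) term, and an $F\dot q$ term that time-averages to zero.
Under time reversal the quadratic and curvature terms are invariant and the
cross terms flip sign, so the trajectory entropy production is

$$\Delta S_\Gamma = A_{-\Gamma} - A_\Gamma
  = -2\Omega t\Big[\frac{\overline{\dot a\,\Phi'_{ODE}(a)}}{g^*_a}
  + \frac{\overline{\dot b\,\Phi'_{ODE}(b)}}{g^*_b}\Big],$$

with all products evaluated at midpoints (Stratonovich), because the
noise–gradient correlation carries its Stratonovich value.  Since $A_\Gamma$
is minimized by the realized dynamics while $\Delta S_\Gamma$ enters the
trajectory weight with a negative sign through $A_{-\Gamma}$, likely
trajectories are those that *maximize* the entropy production term — the
trajectory-level MaxEPP.  Per-basin evaluation of the steady-state weight
terms (`weight_terms()`) shows the high state carrying the larger
Schnakenberg term, matching the macroscopic rate at the stable state to a
few percent at $\varepsilon = 0.01$.

Simulation choices: Euler–Maruyama with $dt = 10^{-3}$ (well below the
stability limit $1/\Phi''$ of the stiffest mode at the default constants);
negative excursions reflected at zero and counted, with a warning beyond
0.1% of steps; midpoint evaluation for every functional.  Burn-in defaults
to five linearized relaxation times of the slowest mode of the 2D reduced
Jacobian — ensembles start exactly at the fixed point, so only the
stationary covariance needs to build up and the residual after $5\tau$ is
$e^{-10}$.  One structural feature deserves emphasis: under flux
constraints the low state is a *saddle* of the three-variable dynamics for
every $b > b_0$ (the unstable eigenvalue grows from $0.07$ at $b = 2$ to
$0.31$ at $b = 4$) while the high state is always stable — the Langevin
route, left to itself, selects the high state.  Low-basin ensembles are
therefore quasi-stationary: `weight_terms()` accumulates over a window
$\min(30, 0.7/\lambda_{unstable})$ before the unstable mode grows, and
rejects mixed-basin ensembles detected by per-path mean concentrations
straddling the unstable root.  Quantitative equality between the ensemble
mean of $\Delta S_\Gamma$ and $\Omega t$ times the macroscopic rate is *not*
asserted anywhere — the chain of approximations connecting them is
heuristic — only the sign, the linear growth in $t$, and the state ordering.

## What the simulations emulate, and what they do not

The Gillespie module *is* the exact microscopic model; agreement between its
histograms and the master equation tests sampling, not physics.  The
Langevin module is an approximation by construction: additive noise frozen
at the target state, reservoirs of the same size as the system, and no
reactions beyond the Schloegl pair.  Conclusions drawn from it transfer to
real biochemical networks only insofar as those are well described by
small-noise diffusion around a steady state; the per-basin saddle structure
above is a property of the three-variable idealization, not of chemistry in
general.  Passing tests therefore demonstrate internal consistency of the
four routes and the state-selection statement for this model class, not a
universal principle.

## Numerical and statistical choices

* **Problem sizes.**  Stationary solves use chains of roughly $25\Omega$
  states ($\approx 2500$ at $\Omega = 100$) — exact, fast, and deterministic.
  Stochastic checks use $t = 10^5$ (occupancy), $n = 200$, $t = 10^3$
  (entropy rate), $n = 10^4$, $t = 1$ (fluctuation theorem) and Langevin
  ensembles of 100–200 paths; all statistical assertions are at three
  standard errors of the estimator in question.
* **Equilibrium Langevin checks run at $\Omega = 400$.**  At $b_0 = 1/6$ the
  fixed point sits four standard deviations from the $x, b \ge 0$ boundary
  when $\Omega = 100$, and boundary reflections bias the entropy functional;
  at $\Omega = 400$ no reflections occur and the additive-noise model is
  clean.  The driven-state checks stay at $\Omega = 100$.
* **Fluctuation-theorem sampling.**  $\langle e^{-\Delta S}\rangle = 1$ is
  exact but its Monte-Carlo estimator fails when $\langle\Delta S\rangle$
  exceeds a few $k_B$, since the mean is carried by exponentially rare
  trajectories.  At $b = 4$, $\Omega = 10$ the stationary rate is
  $\approx 129\,k_B$ per time unit, so the identity is verifiable at
  $t \lesssim 0.02$ there, or at $t = 1$ under mild driving ($b = 0.5$,
  confidence interval $[0.992, 1.017]$); at the detailed-balance point every
  trajectory gives $\Delta S = 0$ exactly, which pins the bookkeeping to
  machine precision.
* **Degenerate inputs.**  Zero backward rate constants give infinite
  affinities (flagged `Inf`); $k_{+2} = 0$ reduces to a linear birth–death
  chain whose stationary law is Poisson (tested against `dpois`);
  saddle-node parameters classify as `marginal`; unimodal distributions
  partition into a single state of weight one.
* **Reproducibility.**  All randomness flows through R's RNG; every
  stochastic function takes a `seed`.  Sweeps and reports are deterministic
  and carry a provenance hash of their configuration.

## Known limitations

The master-equation machinery is written for the one-dimensional birth–death
topology only (general one-species chains would need multi-step jumps).  The
WKB prefactor is the standard birth–death form, not a derived closed form,
so WKB densities are accurate to $O(1/\Omega)$ in the log — visible as the
per-volume log discrepancy halving from 0.018 to 0.004 between
$\Omega = 50$ and $200$.  The classical-action term reported by
`weight_terms()` contains $\langle\dot q^2\rangle$ of a diffusion, which
diverges as $1/dt$ under refinement; it is reported at the requested $dt$
for term-by-term comparison between states at equal discretization, and only
the entropy-production term — which has a proper $dt \to 0$ limit — carries
scientific weight.  Langevin low-basin statistics are quasi-stationary
estimates with a drift bias of order 10–20% at strong driving; the stable
high state shows no such bias.
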