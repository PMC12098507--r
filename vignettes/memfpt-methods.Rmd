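---
title: "Non-Markovian barrier crossing in asymmetric double wells: models, methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-Markovian barrier crossing in asymmetric double wells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memfpt)
```

## The model

`memfpt` simulates and predicts barrier-crossing kinetics of a
one-dimensional reaction coordinate $x(t)$ — think of the fraction of
native contacts of a two-state folding protein — governed by the
generalized Langevin equation (GLE)

$$ m\ddot x(t) = -\int_0^t \Gamma(t-t')\,\dot x(t')\,dt' - U'(x(t)) + F_R(t), $$

with a (multi-)exponential friction memory kernel
$\Gamma(t) = \sum_i (\gamma_i/\tau_i)e^{-|t|/\tau_i}$ and, in equilibrium, a
random force obeying the fluctuation–dissipation relation
$\langle F_R(t)F_R(t')\rangle = \Gamma(t-t')/\beta$ component-wise.  The
potential is the piecewise-quartic asymmetric double well

$$ U(x) = \begin{cases}
  U_L\left[(x/L_L)^2-1\right]^2 & x \le 0\\
  U_R\left[(x/L_R)^2-1\right]^2 + (U_L-U_R) & x > 0,
\end{cases} $$

continuous with continuous first derivative at the barrier top $x=0$; the
second derivative jumps there for asymmetric parameters, which does not
perturb the dynamics.  Two derived scales non-dimensionalise everything:
the inertial time $\tau_m = m/\gamma$ and the diffusion time
$\tau_D = \beta L_L^2\gamma$.  All experiments in this package work in the
frame $\beta = \gamma = L_L = 1$ ($\tau_D = 1$), so a physical setting is
specified by $(\beta U_L, \beta U_R, L_R/L_L, \tau_m/\tau_D, \tau/\tau_D)$.

The package's central quantitative objects are mean first-passage times
(MFPTs) in the *mean all-to-first-passage* convention: every crossing of
the start level opens a passage and the next arrival at the target level
closes all open passages.  `well_to_well_mfpt()` uses the two minima as
start/target; `well_to_barrier_mfpt()` targets the barrier top, giving
$\tau^L_{MFP}$ and $\tau^R_{MFP}$.

## Closed-form predictions

The closed-form well-to-well MFPT for a symmetric well combines the
low-friction (energy-diffusion), high-friction (overdamped) and turnover
contributions:

$$ \tau_{MFP} = e^{\beta U_0}\left[\frac{1}{\beta U_0}\frac{3\pi}{8\sqrt 2}
  \left(\frac m\gamma + \frac{2K\tau^2}{3\gamma}\right)
  + \frac{2\sqrt2\pi\gamma/K}{1 + K\beta U_0\tau/(4\gamma)}
  + 4\sqrt{2m/K}\right], \qquad K = 8U_0/L^2 .$$

The well-to-barrier-top variant (`mfpt_well_to_top()`) halves the
overdamped prefactor, keeps the other terms, and uses only the chosen
side's $U_{L,R}$ and $K_{L,R} = 8U_{L,R}/L^2_{L,R}$ — the two wells
decouple, which is what makes the asymmetric problem tractable side by
side.  Multi-exponential kernels combine per-component overdamped
contributions in series and energy-diffusion contributions as parallel
rates (`multi_exponential_mfpt()`); for the non-equilibrium kernel pair the
equilibrium formula is reused with $\beta \to \beta_{NEQ} =
\beta\tau_R^2/\tau_V^2$ and $\tau \to \tau_V$ (`neq_mfpt_well_to_top()`).

An independent oracle, `mfpt_quadrature()`, evaluates the exact
overdamped-Markovian double integral
$\beta\gamma\int_{x_0}^{x_1}dy\,e^{\beta U(y)}\int_{-\infty}^y dz\,
e^{-\beta U(z)}$ by adaptive quadrature (inner limit truncated where the
Boltzmann weight drops below $10^{-12}$ of its maximum).  It shares no code
with the closed forms and anchors their asymptotics: the relative deviation
of the overdamped term falls monotonically with barrier height (20% at
$\beta U_0 = 2$, under 10% at $\beta U_0 = 5$ in our tests).

## The integrator

The paper-style model does not prescribe an integration scheme, so the
package makes its own, documented choice: each exponential kernel component
is embedded exactly as an auxiliary variable $z_i$ with
$$ z_i(t) = -\int_0^t (\gamma_i/\tau_i)e^{-(t-s)/\tau_i} v(s)\,ds
   + \text{(stationary OU noise)}, $$
updated over each step by its exact exponential decay plus the exactly
integrated Gaussian increment while the velocity is held at its mid-step
value, inside a velocity-Verlet splitting.  Consequences worth knowing:

* the timestep is set by the potential and inertial scales, not by the
  smallest memory time (the stiff $z_i$ update is exact);
* with the noise switched off and $\gamma \to 0$ the scheme is plain
  velocity Verlet and conserves energy to $O(dt^2)$;
* initial $v$ and $z_i$ are drawn from their stationary laws, which
  removes the startup transient of the memory integral's lower limit;
  a burn-in of $10\,\tau_D$ is discarded on top.

The default timestep is $0.01\cdot\min(\tau_m, \min_i\tau_i,
\sqrt{m/K_{max}}, \tau_D)$; an explicit override is accepted up to the
stability contract $0.1\cdot\min(\tau_m, \min_i\tau_i, \sqrt{m/K_{max}})$.
The long sweeps in the test suite use coarser overrides ($2$–$4\times
10^{-4}\,\tau_D$) after a halving check showed the MFPT shift stays below
one standard error.  The integrator was validated against closed-form
statistics that do not involve the MFPT formulas at all: the exact
stationary covariance and position autocorrelation of the harmonic-well
embedded linear system (matched to under 1% out to lags of ten diffusion
times, including the slow energy-relaxation envelope at $\tau/\tau_D = 1$),
equipartition, Boltzmann stationarity in the double well, the Einstein
relation for free diffusion, and agreement with an independent memoryless
BAOAB Langevin integrator in the $\tau \to 0$ limit.

The non-equilibrium engine carries friction in a deterministic auxiliary
variable with decay $\tau_V$ and the random force as an independent
stationary Ornstein–Uhlenbeck process with decay $\tau_R$ and amplitude
$\gamma/(\beta\tau_R)$; $\tau_V = \tau_R$ reproduces the equilibrium
engine's statistics exactly in distribution.

RNG: a counter-seeded xoshiro256++ generator with ziggurat normal sampling
lives inside the compiled core, so trajectories replay bit-identically for
a given seed on any platform; R's own RNG is used only for initial-state
draws and bootstrap resampling, and is seeded independently.

## Passage-time extraction and error bars

Crossings are detected as sign changes of $x - \text{level}$ between
consecutive samples and refined by linear interpolation; a sample exactly
on the level inherits the preceding sign, so touches do not double-count
(the convention is applied identically in the compiled online accumulator
and in the R reference path, and both are checked against an $O(n^2)$
brute-force scan).  When passage pairs are requested from the simulator,
statistics are accumulated online at full step resolution, so output
decimation never misses crossings; only per-arrival sufficient statistics
(count, duration sum) cross the C++/R boundary, which keeps arbitrarily
long runs in small memory.  Open passages are carried across internal run
chunks — truncating them would bias long-memory MFPTs low.

Passages that share a target arrival are strongly correlated, and at long
memory times *consecutive arrival groups* are correlated too (recrossing
bursts).  The SEM therefore comes from a seeded block bootstrap over
contiguous blocks of arrival groups (default 40 blocks, 200 resamples)
rather than over individual groups.  Estimates with fewer than 100
arrivals are flagged unreliable.  A practical warning encoded in
`run_memory_sweep()`: raw arrival counts overcount independent events
during bursts, so sweep runs are additionally sized by the predicted mean
(simulated time $\ge$ `events_target` $\times$ the largest predicted MFPT).

## The synthetic world, and what a green test establishes

No external data are used.  The `alpha3d_fixture()` profile is built from
the published fast-folder fit parameters ($\beta U_f = 3.2$,
$\beta U_u = 1.7$, $L_f = 0.08$, $L_u = 0.15$) and exists for fit
round-trips, not as a stand-in for molecular-dynamics data.  Sweep
experiments use the published figure parameter sets at reduced statistics:
event targets of 300 per point where a point costs $\lesssim 10^9$ steps,
and 25–60 events at the most expensive long-memory points, with the
achieved SEMs recorded in every sweep row.  A green sweep test therefore
establishes agreement *at the recorded error bars*, not at the (unreported)
statistics of the original figures.  Conversely, the simulations expose the
closed forms' own accuracy envelope: within a few percent for
$\tau/\tau_D \lesssim 0.1$, roughly $-20\%$ to $+10\%$ around the
energy-diffusion/overdamped crossover at moderate barriers
($\beta U \approx 3$–$4$), and wide-error agreement at $\tau/\tau_D = 10$.

## Choice of $\tau_V$ in the non-equilibrium experiment

The effective-temperature replacement $\beta_{NEQ} = \beta\tau_R^2/\tau_V^2$
is the high-frequency limit of the per-mode effective temperature of the
linear (harmonic) non-equilibrium GLE,
$$ \frac{T_{eff}(\omega)}{T} = \frac{1+\omega^2\tau_V^2}{1+\omega^2\tau_R^2}
 \;\xrightarrow{\;\omega\tau\gg1\;}\; \frac{\tau_V^2}{\tau_R^2}, $$
so it requires $\omega_0\tau_{V,R} \gg 1$ at the well frequency
$\omega_0 = \sqrt{K/m}$.  Solving the exact stationary covariance of the
embedded linear system shows the harmonic-well variance deviating from
$1/(\beta_{NEQ}K)$ by up to 46% at $\tau_V/\tau_D = 0.1$ with
$\tau_m/\tau_D = 0.1$ ($\omega_0\tau_V \approx 1.7$) but by only 1–3% at
$\tau_V/\tau_D = 1$ ($\omega_0\tau_V \approx 17$).  Because in-well
variance errors exponentiate into the MFPT, `run_neq_sweep()` defaults to
$\tau_V/\tau_D = 1$; the value remains a parameter.  Even inside the
validity regime, the non-equilibrium prediction inherits the crossover
accuracy of the underlying equilibrium formula at $\tau/\tau_D \sim 1$, so
deviations of order 15–25% at $\tau_R/\tau_V = 0.8$ and $1.25$ are expected
and observed while the monotone increase with $\tau_R/\tau_V$ is robust.

## Degenerate inputs, tie-breaks, tolerances

* `fit_double_well()` requires a two-minima/one-maximum topology (located
  on a lightly smoothed copy for noisy profiles) and refines six
  parameters — the four well constants plus the reported horizontal and
  vertical shifts — by bound-constrained least squares; profiles without
  that topology raise a shape error.  The exact weighting of the original
  fitting protocol is unknown; unweighted least squares is this package's
  choice.
* The theory functions accept $m = 0$ and $\tau = 0$ (finite limits); the
  simulator rejects $m = 0$ — only finite $\tau_m/\tau_D$ is ever
  simulated.
* `multi_exponential_mfpt()` special-cases $N = 1$ through the
  single-kernel code path so the documented algebraic reduction is
  bit-exact rather than subject to $1/(1/x)$ double rounding.
* The quadrature oracle reports non-convergence instead of returning a
  value; its truncation threshold ($10^{-12}$ of the maximal Boltzmann
  weight) is far below every tolerance used against it.

## Known limitations

Position-dependent mass, nonlinear friction, non-exponential kernels and
kernel extraction from data are out of scope.  The closed forms are
asymptotic interpolants with fitted constants, not exact results: their
accuracy is worst near the energy-diffusion/overdamped crossover, and the
all-to-first-passage estimator at long memory has heavy-tailed errors that
make tight testing there expensive.  Trajectory output is delimited text
only — no binary container support is built in.
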