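---
title: "Free-energy and friction profiles from constrained pulling, and temperature-boosted Langevin kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-energy and friction profiles from constrained pulling, and temperature-boosted Langevin kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dctmdr)
```

## The model

The package treats a molecular dissociation/association process as
one-dimensional diffusive motion of a reaction coordinate $x$ (typically an
inter-atomic or protein–ligand distance, in nm) governed by a memory-free
Langevin equation

$$ m\,\ddot x = -\frac{\mathrm{d}G}{\mathrm{d}x}
   - \Gamma(x)\,\dot x + \sqrt{2\,k_B T\,\Gamma(x)}\,\xi(t), $$

with free-energy profile $\Delta G(x)$ (kJ/mol), position-dependent
Markovian friction $\Gamma(x)$ (kJ ps mol$^{-1}$ nm$^{-2}$), mass $m$ (amu)
and Gaussian white noise $\xi$. All internal units are MD units (nm, ps,
kJ/mol, amu, K; $k_B$ = 0.0083144621 kJ mol$^{-1}$ K$^{-1}$), in which
amu nm$^2$/ps$^2$ = kJ/mol, so the equation needs no conversion factors.

Both fields are estimated from ensembles of *constrained constant-velocity
pulling* simulations, in which an external constraint force $f_c(t)$
enforces $x(t) = x_0 + v_c t$. Averaging the Langevin equation over the
ensemble gives the dissipation-corrected work theorem

$$ \Delta G(x) = \langle W(x)\rangle - v_c\!\int_{x_0}^{x}\Gamma(x')\,
   \mathrm{d}x', \qquad
   W(x)=\int_{x_0}^{x} f_c\,\mathrm{d}x', $$

and, invoking the Jarzynski identity truncated at second cumulant order
(exact for Gaussian work distributions),

$$ W_\mathrm{diss}(x) = \frac{\operatorname{var} W(x)}{2\,k_B T},
 \qquad
 \Gamma(x) = \frac{1}{k_B T}\int_{t_0}^{t(x)}
   \langle\delta f_c(t)\,\delta f_c(t')\rangle\,\mathrm{d}t'. $$

A note on the factor 2: part of the dcTMD literature prints
$W_\mathrm{diss} = \langle\delta W^2\rangle/k_BT$. Only the halved form
makes the work-variance route and the force-autocorrelation route for
$\Gamma$ mutually consistent (differentiating
$\operatorname{var}W/2k_BT$ along the pull recovers $v_c\Gamma$ exactly in
expectation), and it is the standard second-order cumulant of the Jarzynski
average. The package therefore uses the halved form;
`estimate_free_energy(..., halved = FALSE)` reproduces the other
convention for comparison.

### Assumptions and their diagnostics

* **Gaussian work.** The cumulant truncation is exact only for Gaussian
  work distributions; multiple unbinding pathways typically break it.
  `check_work_normality()` runs a D'Agostino–Pearson-style omnibus test
  (skewness + kurtosis) across traces at every grid point and fails the
  global flag when more than 10% of points reject at $\alpha$ = 0.01. On
  failure the correct remedy is pathway separation *before* dcTMD analysis,
  which is outside this package's scope. Because work curves at nearby
  grid points are strongly correlated, one tail fluctuation can carry a
  contiguous stretch of points past the threshold even for Gaussian
  ensembles — inspect the per-point table before acting on a failed flag.
* **Timescale separation.** The pull must be slow against the bath
  fluctuations so that nonequilibrium estimates coincide with their
  equilibrium counterparts. This is a property of the input data; the
  package cannot detect its violation.
* **Markovian friction.** $\Gamma(x)$ carries all solvent/orthogonal
  degrees of freedom; no memory kernels.

## Estimators and numerical choices

* **Work integration** is trapezoidal on the uniform position grid
  $x_i = x_0 + v_c\,i\,\Delta t$ (computed multiplicatively, so no
  accumulated drift). Variances are unbiased ($N-1$).
* **Friction (autocorrelation route)** integrates the running
  force-fluctuation autocorrelation from the start of the pull with the
  trapezoidal rule and *no truncation window* — windowing is an unstated
  choice in the source analyses; instead the noise is handled downstream by
  Gaussian smoothing of $\Gamma$. The running integral accumulates a
  random-walk error whose standard deviation grows with pulled distance
  (visible in any single realization); this is a real property of the
  estimator, so friction values far along the pull need either large
  ensembles or spatial averaging.
* **Smoothing.** $\Gamma$ is smoothed with a Gaussian kernel,
  $\sigma$ = 0.02 nm by default — small enough to resolve the ~0.1 nm
  features that barrier/hydration structure produces, large enough to tame
  the pointwise noise. Boundaries are handled by reflection, so constants
  are preserved exactly. After smoothing, $\Gamma$ is floored at
  $10^{-3}\times$ the median positive raw value: the Langevin noise term
  requires $\Gamma > 0$, and negative excursions of the raw estimate are
  statistical noise.
* **Errors** are leave-one-out jackknife over traces (closed-form
  downdates for the free energy; explicit re-estimation for the friction).
* **Friction cross-check.** $\Gamma = (1/v_c)\,\mathrm{d}W_\mathrm{diss}/
  \mathrm{d}x$ (central differences) is computed as a second route; the two
  routes agreeing within their jackknife errors is a convergence
  diagnostic, not an independent measurement.

## The Langevin propagator

`propagate()` integrates the equation above with the Bussi–Parrinello
splitting: an Ornstein–Uhlenbeck thermostat half-step, a velocity-Verlet
drift/kick, and a second OU half-step. The friction coefficient
$\Gamma(x)/m$ is frozen at the pre-step position within each step; because
the scheme is inertial (the $m\ddot x$ term is retained), no spurious-drift
correction is needed for position-dependent friction — a first-order
overdamped scheme would require one, which is why that design was avoided.
Fields are tabulated on a uniform grid with piecewise-linear interpolation
(exact at the nodes); the force is the central difference of $\Delta G$.

* **Stability.** A step is warned about (not rejected) when
  $\Delta t > 0.25\,\min(m/\Gamma_\mathrm{max},
  \sqrt{m/|G''|_\mathrm{max}})$. Because tabulated forces are bounded,
  instability shows up as absurd velocities rather than overflow; the
  integrator aborts when $|v|$ exceeds $10^4$ thermal velocities.
* **Boundaries.** Reflecting walls at the grid ends, implemented as an
  exact periodic fold (position mirrored, velocity negated). The walls make
  association observable in finite time, mimicking a finite simulation box.
* **Transition counting** uses a two-core scheme: the system is *bound*
  after visiting $x \le x_b$ and *unbound* after visiting $x \ge x_u$;
  events are first passages between core entries, so recrossings of a
  single threshold are never counted. Default cores: $x_b$ a quarter of the
  way from the bound minimum to the barrier top, $x_u$ the first point past
  the barrier where $\Delta G$ flattens to within 0.5 kJ/mol of its value
  at the far end. These defaults are package choices (the source analyses
  do not state numeric dividing surfaces) and are recorded in all outputs.
* **Rates.** $k_D = 1/\overline{\tau}_D$ (arithmetic mean of waiting
  times, not an exponential fit), $k_A = 1/(\overline{\tau}_A C_\mathrm{sim})$
  with the reference concentration $C_\mathrm{sim}$ defaulting to 1 M — the
  concentration implied by the outer wall is a user responsibility, and
  $k_A$ values carry $C_\mathrm{sim}$ in their metadata. Relative standard
  errors are $n^{-1/2}$ under the exponential-waiting assumption. A channel
  with zero events is reported absent, with $1/T_\mathrm{sim}$ as an upper
  bound on its rate.
* **MFPT oracle.** `reference_mfpt()` evaluates the overdamped
  double-quadrature mean first-passage time on a refined grid and serves as
  an independent check on the propagator in the overdamped regime.

## Temperature boosting

Temperature enters the Langevin equation only through the noise term, so on
*fixed* fields the rates at two temperatures obey
$k_2 = k_1 e^{-\Delta G^{\neq}(\beta_2-\beta_1)}$ with $\beta = 1/k_BT$ and
$\Delta G^{\neq}$ the transition-state energy. `run_ladder()` simulates the
same fields at several elevated temperatures (practical guidance: 25–50 K
increments, starting at the smallest temperature that yields on the order
of 100 transitions); `fit_boost()` fits $\ln k$ against $\beta$ by weighted
least squares with event counts as weights (Poisson counting gives
$\operatorname{var}\ln k \approx 1/n$; whether the original analyses
weighted their fits is unstated, so the statistically motivated choice is
made here). Both channels are fitted independently, with no shared
intercept. The extrapolated rate and its confidence interval follow from
the fit covariance by the delta method:
$\operatorname{var}(\ln k_1) = \operatorname{var}(a) + \beta_1^2
\operatorname{var}(b) + 2\beta_1 \operatorname{cov}(a,b)$. An analytic
error formula from the source's supplementary material is not available;
the delta-method estimator is used instead and is validated by Monte-Carlo
in the test suite (the reported error must track the empirical scatter of
the extrapolated rate within a factor 1.5).

**Mass enhancement.** In the overdamped regime the dynamics is
mass-independent, so `propagate_overdamped_boosted()` scales $m$ by
`mass_scale` and the time step by $\sqrt{\texttt{mass\_scale}}$ (keeping
the simulated physical time), e.g. a hundredfold mass gives a tenfold step.
The regime is checked post-hoc via the ratio $\Gamma^2/(m_\mathrm{eff}
|G''|_\mathrm{max})$, which must comfortably exceed 1 (threshold 10);
outside that regime the function warns that rates may be biased.

## The synthetic generator

`generate_pulling_ensemble()` inverts the constrained Langevin equation:
with $\dot x = v_c$ imposed, the total force vanishes and the constraint
force must be

$$ f_c(t) = \frac{\mathrm{d}G}{\mathrm{d}x} + \Gamma(x)\,v_c
   - \sqrt{2 k_B T \Gamma(x)/\Delta t}\; g_t, \quad g_t \sim
   \mathcal{N}(0,1)\ \text{i.i.d.}, $$

so that, by construction, $\langle W\rangle = \Delta G + v_c\!\int\!\Gamma$
and $\operatorname{var} W = 2k_BT\,v_c\!\int\!\Gamma$ — exactly the moments
the estimators must invert. The $\Delta t^{-1/2}$ noise scaling (Itô
discretization) makes integrated work statistics independent of the
sampling step. The generator's defaults mirror the study conditions of the
benchmark analyses: pull velocity $v_c$ = 1 m/s = $10^{-3}$ nm/ps,
ensembles of 500 runs, 300 K (293 K for the ion-pair setting).

Two field templates are provided. `nacl_template()` has a bound well, a
main barrier near 0.4 nm, a smaller barrier near 0.6 nm, and a friction
peak between them — the shape of a monovalent ion pair rebuilding its
shared hydration shell. Its numeric constants are package-defined,
*inspired by* the published figures, never digitized from them.
`single_barrier_template()` joins parabolas of curvature $\kappa$ so that
the curvature at the bound minimum and barrier top are exactly $\pm\kappa$,
making Kramers-rate oracles exact design targets; a flat plateau follows
the unbound basin.

What the generator deliberately does **not** emulate: multiple pathways
and conformational heterogeneity (work stays Gaussian by construction),
memory friction, pulling-speed dependence of the fields, and anharmonic
barrier shapes beyond the templates. Passing the recovery suites therefore
demonstrates correctness of the estimators *given the model*, not validity
of the model for any particular molecular system.

## Problem sizes and reproducibility

The test and validation suites size their simulations to run on a single
CPU in a few minutes: recovery tests use 100–500 traces on 200–1000-point
grids; propagator physics uses $2\times10^6$–$10^7$ steps; first-passage
and boosting benchmarks use the 10 kJ/mol double well with friction 100
(about $10^8$ steps for a few hundred events per condition), a
375–575 K ladder with $1.2\times10^5$ ps per temperature, and a 50-seed
Monte-Carlo on a faster 6 kJ/mol well. Every stochastic run takes an
explicit seed, and trajectories are bit-reproducible given
(fields, config, seed).

## Known limitations

* Friction estimates from constrained pulls are systematically on the high
  side of unbiased-MD estimates (constraints stiffen the apparent bath
  coupling); predicted rates inherit this bias even when $K_D$, a purely
  thermodynamic ratio, does not.
* The running autocorrelation integral is noisy at large pulled distance;
  far-plateau friction values should be read after smoothing and, ideally,
  averaged over the plateau.
* Waiting times are measured from core entry, which carries a small
  entry-conditioning bias relative to the equilibrium-start mean
  first-passage time (a few percent on the benchmark well).
* One reaction coordinate, one ligand: no multi-dimensional coordinates,
  no competing pathways, no memory kernels, no biased propagation.
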