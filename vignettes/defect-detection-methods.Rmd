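---
title: "Detecting arterial wall defects from velocity data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting arterial wall defects from velocity data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemodetect)
```

hemodetect answers a diagnostic question: given noisy measurements of blood
flow velocity at a few fixed points in a branching arterial network, where is
a structural defect — an aneurysm or a stenosis — and how severe is it? The
package combines three ingredients: a nonlinear one-dimensional pulse-wave
simulator (the forward model), a Gaussian prediction-error likelihood, and a
transitional MCMC (TMCMC) sampler that yields both posterior parameter
samples and the model evidence, so that candidate defect locations can be
ranked by Bayes factors.

## The flow model

Each artery is a distensible axisymmetric tube of length $\ell$ carrying an
incompressible flow with cross-sectional area $A(x,t)$, mean velocity
$u(x,t)$ and internal pressure $p(x,t)$. Conservation of mass and momentum
gives the hyperbolic system

$$
\partial_t A + \partial_x (Au) = 0, \qquad
\partial_t u + \partial_x\!\left(\tfrac{u^2}{2} + \tfrac{p}{\rho}\right)
  = \frac{K_r u}{\rho A},
$$

with blood density $\rho$ and a friction coefficient $K_r = -22\mu\pi$
derived from the blood viscosity $\mu$ and the assumed velocity profile. The
system is closed by the elastic (Laplace) tube law

$$
p = p_{ext} + B\left(\sqrt{A} - \sqrt{A_0}\right),
$$

where $A_0$ is the relaxed area and the stiffness coefficient
$B = \sqrt{\pi} E h / ((1-\nu^2) A_0)$ collects the wall's Young modulus,
thickness and Poisson ratio ($\nu = 1/2$). The wall is treated as purely
elastic; the momentum flux keeps a hook for a viscoelastic pressure
component, which is identically zero in this release. The associated wave
speed is $c = \sqrt{B/(2\rho)}\, A^{1/4}$, and the Riemann invariants
$W_{1,2} = u \pm 4c$ carry information forward and backward along each
vessel.

A defect is parametrized per artery by the scaled stiffness
$\beta = B/B^*$ and scaled area $\alpha = A_0/A_0^*$ relative to healthy
reference values; $\beta = \alpha = 1$ means no defect. An aneurysm is
typically $\alpha > 1$ (or a softened wall, $\beta < 1$), a stenosis
$\alpha < 1$.

## Discretization

The solver is a discontinuous Galerkin method: each artery is split into $N$
uniform elements, and $(A, u)$ are expanded in orthonormal Legendre
polynomials of degree $p$ per element. Interior interfaces use an upwind
flux constructed from the characteristic variables ($W_1$ from the left
state, $W_2$ from the right, inverted through the tube law). Time stepping
is second-order Adams–Bashforth, bootstrapped by a single forward-Euler
step.

Boundary treatment:

* **Inlet**: the velocity is prescribed from the inflow waveform; the area
  comes from the outgoing characteristic, so the inlet is reflection-free.
* **Terminal outlets**: fully absorbing — the incoming characteristic is
  held at its rest value (reflection coefficient zero), so pulses exit the
  tree without artificial reflections.
* **Y-bifurcations**: a 6-unknown Newton solve enforces conservation of mass
  flux $A_1u_1 = A_2u_2 + A_3u_3$ and continuity of total pressure
  $p + \rho u^2/2$ across the junction, together with the three outgoing
  characteristics. The iteration is warm-started from the previous time
  step and converges to near machine precision (the test suite requires the
  mass residual to stay below $10^{-10}\,\mathrm{m^3/s}$; in practice it
  sits at roundoff, $\sim 10^{-19}$).

Numerical choices worth knowing:

* The time step is chosen from a CFL-type bound
  $\Delta t = \mathrm{CFL}\, h_{\min} / ((2p+1)\, s_{\max})$ with
  $\mathrm{CFL} \le 0.5$, then rounded down so the sensor sampling period is
  an exact multiple of $\Delta t$. The signal-speed estimate $s_{\max}$
  includes a configurable headroom factor (default 2.0) on the resting wave
  speeds so that the same fixed discretization stays stable across the whole
  prior range of stiffness/area factors explored during inference — the
  forward map must be a deterministic function of the parameters alone, so
  the grid is resolved once against the reference network
  (`resolve_solver()`) and shared by data generation and every likelihood
  evaluation. The bound is re-audited periodically during each run.
* Quadrature is Gauss–Legendre with $p+1$ points per element.
* The initial condition is rest: $u = 0$, $A = A_0$. Rest is an exact fixed
  point of the discrete operator (verified to $10^{-12}$).
* A reconstructed area that is non-positive or non-finite anywhere aborts
  the run with an error naming the artery, element and time. During
  inference such failures simply score $-\infty$ log-likelihood, so the
  sampler rejects the offending parameters; extreme corners of the prior
  (e.g. a tube narrowed to a few percent of its area) are handled this way
  by design.

The inflow waveform is a truncated Fourier series (default: 10 harmonics
fitted to a half-sine systolic pulse, period 1.1 s, peak 0.5 m/s, systole
fraction 0.3) — a standard idealization of an aortic velocity pulse.
The defect-identification experiments this package replicates were
originally carried out on a 19-artery tree and a three-cycle inflow pulse
whose exact per-artery dimensions and Fourier coefficients are not
available; both are therefore represented here by self-describing, seeded
stand-ins: the waveform coefficients live in the configuration, and
`build_fixture_network()` generates trees constrained to the documented
ranges (lengths 0.026–0.17 m, areas $10^{-6}$–$10^{-5}\,\mathrm{m^2}$),
with stiffness set so resting wave speeds are physiological (4–6 m/s).
Replications on these fixtures reproduce the *method's* behaviour, not any
particular network's numbers.

## Synthetic observations

Velocity sensors sit at fixed positions (artery + location) and sample every
$\Delta t_2 = 0.064$ s; three cardiac cycles (final time 3.328 s) give 52
samples per sensor. Observations are corrupted as

$$
D_k = v_k + \sigma\,\epsilon_k, \qquad \sigma = f\,\eta,
$$

with i.i.d. standard-normal $\epsilon_k$, a noise fraction $f$ (0.01 or
0.05 in the replications) and $\eta$ the *pooled* standard deviation of all
clean velocities of the experiment (population convention, $n$ denominator,
so the injected $\sigma$ is exactly reproducible). Pooling is per experiment
rather than per sensor because the noise scale is a property of the whole
dataset; experiments with different sensor layouts naturally get different
$\sigma$.

Systemic misspecification is modelled by corrupting every artery's relaxed
area, $\alpha_k = \alpha_k^\ast (1 + \sigma_\alpha \epsilon_k)$, while the
inference model keeps using the uncorrupted reference values — so no
parameter setting can reproduce the data exactly. The perturbation is drawn
once per dataset. Observation noise and parameter noise use separate RNG
streams derived from the master seed by fixed offsets.

## Likelihood, sampler and model selection

The prediction-error model $D = g(\theta) + e$, $e \sim N(0, \sigma^2 I)$,
gives the log-likelihood

$$
\log p(D \mid \theta, M) = -\tfrac{m}{2}\log(2\pi\sigma^2)
  - \tfrac{1}{2\sigma^2}\lVert D - g(\theta)\rVert^2 ,
$$

with $m$ the total number of velocity samples. The noise SD $\sigma$ is by
default an additional free parameter with uniform prior $[0, 1]$ m/s (it can
be fixed, which is useful for noise-free self-consistency checks where the
free-$\sigma$ posterior is singular). All priors are uniform boxes; defect
factors default to $[0, 3]$.

TMCMC tempers from the prior to the posterior through
$f_j \propto p(D\mid\theta)^{q_j}\,\pi(\theta)$,
$0 = q_0 < \dots < q_\lambda = 1$:

1. At stage $j$, plausibility weights
   $w_k = p(D\mid\theta_k)^{q_{j+1}-q_j}$ are computed in log space with
   max-subtraction. The increment is chosen by bisection so the population
   coefficient of variation of the weights equals 1.0; if even the full
   jump to $q = 1$ stays below the target (including the degenerate case of
   identical likelihoods), the exponent is capped at exactly 1, so the final
   stage targets the true posterior.
2. The stage covariance is $\Sigma_j = b^2 \sum_k \bar{w}_k
   (\theta_k - \mu_j)(\theta_k - \mu_j)^T$ with $b = 0.2$.
3. Multinomial resampling by $\bar w$ selects chain seeds; a sample chosen
   $n_k$ times starts a Metropolis chain of length $n_k$ with Gaussian
   proposals $N(\cdot, \Sigma_j)$ targeting $f_{j+1}$, recording the state
   after every proposal. Proposals outside the prior box are rejected.
   Each chain runs on its own seeded RNG substream, so results are
   identical regardless of the worker count.
4. The log-evidence accumulates as $\sum_j \log S_j$, $S_j$ the stage mean
   of the plausibility weights — the standard TMCMC estimator.

Conventions chosen where the method description leaves room: population
(n-denominator) SD for both the weight CoV and the reported posterior CoV
$u = \mathrm{SD}/\mathrm{mean}$; constant population size across stages;
chains started *at* the resampled particle with the start counted only
through acceptance of its first proposal.

For localization, each candidate model $M_i$ frees the stiffness (or area)
factor of artery $i$ (pair models $M_{i:j}$ free two). Evidences are
normalized into $\Pr(M_i \mid D) \propto \rho(D \mid M_i)\Pr(M_i)$ with a
uniform model prior by default, computed with max-subtraction; probabilities
below $10^{-8}$ print as "~0" but are stored at full precision. The model
class is user-declared (a handful of candidate arteries), matching how the
approach is used in practice: the joint problem over all arteries is not
tractable, but a small class of single-defect models is, and
over-parametrized pair models are automatically penalized by the Occam
factor in the evidence.

## Problem sizes and what the tests demonstrate

The package ships two working scales:

* **Standard profile** (package defaults): 19-artery fixture, 4 elements per
  artery, $p = 2$, three cardiac cycles, 500 TMCMC samples — the
  configuration appropriate for a multi-core machine or cluster.
* **Desk profile** (used by the test suite and the acceptance script):
  5–7-artery fixtures, 1 element per artery, $p = 1$–2, one cardiac cycle
  (final time 1.152 s, 18 samples per sensor), 128 TMCMC samples,
  CFL number 0.3. These sizes were chosen once so that a full localization
  replication study (10 seeded datasets × 4 candidate models) completes in
  minutes on one core. At this scale the posterior is still decisive: the
  correct-model probability is typically indistinguishable from 1 and the
  defect magnitude is recovered to a few percent.

Because the synthetic datasets are generated by the same discretized forward
model used for inference (deliberately, as in the study design this package
replicates), passing tests demonstrate correct inversion, evidence
arithmetic, and robustness to observation and parameter noise — they do not
demonstrate discretization convergence to the continuum (checked separately
by the self-convergence test) nor robustness to *structural* model error
beyond the area-misspecification mechanism.

Known limitations: binary trees only (no trifurcations, loops, tapering or
curvature); terminal boundaries are perfectly absorbing (no Windkessel
models); the error model is homoscedastic and uncorrelated; only uniform
priors ship; and the elastic wall assumption means wave damping comes solely
from fluid friction.

## A worked example

```{r example, eval = FALSE}
net <- build_fixture_network(7, seed = 42)
wf <- inflow_waveform(n_cycles = 1)
cfg <- resolve_solver(solver_config(elements = 1, degree = 1, cfl = 0.3),
                      net, wf)
sens <- sensor_config(c(1, 7), "end")

# synthetic patient: artery 6 stiffness halved, 1% observation noise
obs <- generate_dataset(net, defect_spec(6, "stiffness", 0.5), wf, cfg,
                        sens, fraction = 0.01, seed = 7)

models <- list(defect_model(2), defect_model(5), defect_model(6),
               defect_model(7), defect_model(c(6, 7)))
sel <- run_selection(models, obs, net, wf, cfg,
                     tmcmc = tmcmc_config(n_samples = 128), seed = 11)
print(sel)
```

The chunk is not executed while building the vignette (a full selection run
takes a couple of minutes); the README shows the output of this exact code.
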