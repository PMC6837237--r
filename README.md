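# hemodetect

Bayesian localization of arterial wall defects from pulse-wave velocity
data.

Aneurysms and stenoses change the stiffness and cross-section of an artery,
and with them the way pressure pulses propagate through the arterial tree.
`hemodetect` asks the inverse question: given noisy velocity measurements at
a handful of fixed sensors, *where* is the defect and *how severe* is it?
It is aimed at researchers in computational haemodynamics and uncertainty
quantification who want a self-contained, reproducible testbed for
evidence-based defect identification — the same machinery accepts real
velocity recordings through a plain CSV interface.

The package combines:

* **a nonlinear 1D pulse-wave simulator** — mass/momentum conservation on a
  branching network of elastic vessels,
  `∂A/∂t + ∂(Au)/∂x = 0`, `∂u/∂t + ∂(u²/2 + p/ρ)/∂x = K_r u/(ρA)`,
  closed by the tube law `p = p_ext + B(√A − √A0)`. Discretization is a
  discontinuous Galerkin method (Legendre modal bases, upwind fluxes from
  the Riemann invariants `u ± 4c`, Newton-coupled Y-bifurcations,
  Adams–Bashforth time stepping), with the time-critical core in C++;
* **a synthetic-observation module** — additive Gaussian velocity noise
  scaled to the pooled signal SD (`σ = f·η`), plus optional multiplicative
  misspecification of the "known" healthy areas;
* **a transitional MCMC (TMCMC) sampler** — tempers from prior to
  posterior with adaptive exponents (weight-CoV target 1.0), scaled
  proposal covariance (`b = 0.2`), multinomial resampling and Metropolis
  chains, and returns the model log-evidence as a by-product;
* **Bayesian model selection** — candidate models `M_i` free one artery's
  scaled stiffness `β = B/B*` or area `α = A0/A0*` (pairs `M_{i:j}` free
  two); `Pr(M_i | D) ∝ ρ(D | M_i) Pr(M_i)` ranks the candidate defect
  locations.

## Worked example

Build a seeded 7-artery fixture tree, plant a defect (artery 6 stiffness
halved), generate 1%-noise observations at two sensors, and rank five
candidate defect models:

```r
library(hemodetect)

net <- build_fixture_network(7, seed = 42)
wf  <- inflow_waveform(n_cycles = 1)
cfg <- resolve_solver(solver_config(elements = 1, degree = 1, cfl = 0.3),
                      net, wf)
sens <- sensor_config(c(1, 7), "end")

obs <- generate_dataset(net, defect_spec(6, "stiffness", 0.5), wf, cfg,
                        sens, fraction = 0.01, seed = 7)

models <- list(defect_model(2), defect_model(5), defect_model(6),
               defect_model(7), defect_model(c(6, 7)))
sel <- run_selection(models, obs, net, wf, cfg,
                     tmcmc = tmcmc_config(n_samples = 128), seed = 11)
print(sel)
```

Output (about 3.5 minutes on one core):

```
defect_selection (winner: M6)
 model       estimate      u_pct    sigma_hat u_sigma_pct log_evidence probability
    M2          0.745       5.69 0.0063297312    9.488152        116.6          ~0
    M5          0.314       6.16 0.0035200943   17.148225        140.7          ~0
    M6         0.5033       1.03 0.0007675192   15.469503        189.4     1.00000
    M7          1.772       10.3 0.0050776656   14.354349        129.8          ~0
  M6:7 0.5145, 0.9492 2.99, 2.96 0.0019327624    8.170394        171.0          ~0
```

Reading the table: the true model `M6` wins with posterior probability
indistinguishable from 1; its stiffness estimate `β̂₆ = 0.5033` (posterior
CoV `u = 1.03%`) recovers the planted `β₆ = 0.5`, and `σ̂ = 0.00077` m/s
matches the injected noise level (`0.01·η = 0.00094`). The two-defect model
`M6:7` also finds `β̂₆ ≈ 0.51` and leaves artery 7 nearly unchanged
(`β̂₇ ≈ 0.95`), but its extra parameter costs it ~18 log-evidence units —
the Occam penalty that makes the parsimonious model win. Badly-placed
models (`M2`, `M5`, `M7`) can only explain the data by inflating `σ̂`, and
their evidence collapses.

A command-line front end over the same functions lives at
`inst/cli/hemodetect.R` (subcommands `network`, `simulate`, `observe`,
`infer`, `select`).

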