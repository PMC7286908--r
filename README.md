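# dctmdr

Ligand unbinding and binding happen on milliseconds to minutes — far beyond
what unbiased atomistic molecular dynamics can sample. `dctmdr` implements
the two-stage coarse-graining strategy known as dissipation-corrected
targeted MD (dcTMD) plus temperature-boosted Langevin simulation:

1. **Profile estimation.** From an ensemble of constrained constant-velocity
   pulling simulations (constraint force `f_c(t)` along
   `x = x0 + v_c t`), the free-energy profile is recovered by the
   second-order cumulant expansion of the Jarzynski equality,

       dG(x) = <W(x)> − var W(x) / (2 kB T),

   and the position-dependent friction from the running constraint-force
   autocorrelation integral,

       Gamma(x) = (1/kB T) ∫ <δf_c(t) δf_c(t')> dt',

   with Gaussian smoothing, positivity flooring, jackknife errors and a
   work-normality diagnostic (the cumulant truncation assumes Gaussian
   work — its failure signals multiple unbinding pathways).

2. **Kinetics.** The fields drive an unbiased 1D Langevin equation
   `m x" = −dG/dx − Gamma(x) x' + sqrt(2 kB T Gamma(x)) ξ(t)` integrated
   with the Bussi–Parrinello scheme. Waiting times between bound/unbound
   core visits give `k_off` and `k_on` (and `K_D = k_off/k_on`). Because
   temperature enters only through the noise, rates on fixed fields obey
   `k2 = k1 exp(−ΔG‡ (β2 − β1))`: simulating a ladder of elevated
   temperatures and extrapolating `ln k` vs `β = 1/kB T` back to the target
   temperature (*T-boosting*) reaches multisecond kinetics at negligible
   cost, with a delta-method error budget. In the overdamped regime the
   mass can be enhanced to enlarge the time step
   (`propagate_overdamped_boosted()`).

A synthetic trace generator with analytically known ground-truth fields
(`nacl_template()`, `single_barrier_template()`,
`generate_pulling_ensemble()`) makes every estimator testable without any
MD data.

## Worked example

Ion-pair-like dissociation on the two-barrier template (all data
synthetic):

```r
library(dctmdr)

fields <- nacl_template()
ens <- generate_pulling_ensemble(fields, N = 500, v_c = 1e-3,
                                 n_samples = 501, temperature = 293,
                                 seed = 1)
fit <- dctmd(ens, friction = "both")
fit
#> Dissipation-corrected targeted MD fit
#>   ensemble: N = 500 traces, v_c = 0.001 nm/ps, T = 293 K
#>   barrier:  dG = 10.7 kJ/mol at x = 0.41 nm
#>   endpoint: dG = 7.98 kJ/mol, W_diss = 0.0862 kJ/mol
#>   friction: max 170.8 kJ ps/mol/nm^2 at x = 0.562 nm
#>   Gaussian-work check: pass (0.0% points reject)
```

The fit recovers the template's main barrier (10.7 kJ/mol above the bound
minimum, at 0.41 nm) and the friction peak that sits *after* the barrier
(0.56 nm), where the hydration shell of a dissociating pair is rebuilt.
`plot(fit)` draws both profiles; `as_field_table(fit)` +
`write_field_table()` export them.

Langevin kinetics on the fitted fields (0.1 µs at 293 K, reduced mass of a
Na+/Cl− pair):

```r
lf <- langevin_fields(fit, mass = 13.9, temperature = 293)
cfg <- sim_config(dt = 0.002, n_steps = 5e7, seed = 1,
                  record_trajectory = FALSE)
tr <- propagate(lf, cfg)
estimate_rates(tr$events, C_sim = 1)
#> <rate_estimate>
#>   k_D = 1.92e+10 +/- 5.5e+08 s^-1 (n = 1212)
#>   k_A = 3.29e+10 +/- 9.5e+08 s^-1 M^-1 (n = 1212, C_sim = 1 M)
#>   K_D = 0.585 +/- 0.024 M
```

1212 dissociation events (mean waiting time 52 ps) give
`k_D = 1.9e10 s^-1`; `k_A` is reported per molar of the reference
concentration `C_sim` implied by the outer reflecting wall. For slow
processes, replace the direct run by a temperature ladder:

```r
pts <- run_ladder(lf, cfg, temperatures = seq(375, 575, 50),
                  time_per_T = 1e5)
fit_D <- fit_boost(pts, T1 = 293, channel = "D")
extrapolation_error(fit_D)   # delta-method error budget, target < 10%
```

`coef(fit_D)` gives the Arrhenius intercept/slope (the slope is −ΔG‡),
`predict(fit_D, 420)` evaluates the fitted line elsewhere, and
`confint(fit_D)` the 95% interval of the extrapolated rate.

A thin command-line front end with the same functionality ships in
`inst/cli/dctmdr` (subcommands `synth`, `estimate`, `rates`, `boost`).

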