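# Shared fixtures, all generated in code.

# ensemble of identical-grid traces from explicit force rows
make_ensemble <- function(force_rows, dt = 0.1, v_c = 1e-3, x0 = 0,
                          temperature = 300) {
  traces <- lapply(seq_len(nrow(force_rows)), function(i)
    pulling_trace(force_rows[i, ], dt = dt, v_c = v_c, x0 = x0,
                  temperature = temperature, run_id = paste0("run", i)))
  suppressWarnings(assemble_ensemble(traces))
}

# ensemble whose force fluctuations are an Ornstein-Uhlenbeck process:
# stationary variance sigma2, correlation time tau_c [ps]
make_ou_ensemble <- function(N, n, dt, sigma2 = 100, tau_c = 1,
                             mean_force = 0, v_c = 1e-3,
                             temperature = 300, seed = 1) {
  set.seed(seed)
  phi <- exp(-dt / tau_c)
  sdv <- sqrt(sigma2)
  f <- matrix(stats::rnorm(N * n), N, n)
  f[, 1] <- f[, 1] * sdv
  for (j in 2:n) f[, j] <- phi * f[, j - 1] + f[, j] * sdv * sqrt(1 - phi^2)
  make_ensemble(f + mean_force, dt = dt, v_c = v_c,
                temperature = temperature)
}

# standard benchmark: 10 kJ/mol double well, curvature 100, Gamma = 100,
# bistable (bound well <-> unbound basin with plateau)
benchmark_well <- function(height = 10, gamma = 100, kappa = 100,
                           n = 2001, mass = 1, temperature = 300) {
  flds <- single_barrier_template(height = height, x_b = 0.5,
                                  kappa = kappa, gamma = gamma)
  langevin_fields(fields_to_table(flds, n = n), mass = mass,
                  temperature = temperature)
}

# cheap fast-kinetics well for ladder/Monte-Carlo work: low barrier and
# low friction so events are plentiful at modest step counts
fast_well <- function(temperature = 300) {
  flds <- single_barrier_template(height = 6, x_b = 0.5, kappa = 100,
                                  gamma = 30)
  langevin_fields(fields_to_table(flds, n = 1001), mass = 0.1,
                  temperature = temperature)
}
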