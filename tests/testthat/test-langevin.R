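test_that("harmonic well sampling satisfies equipartition (position and velocity)", {
  kap <- 100
  x <- seq(-1, 1, length.out = 2001)
  tab <- field_table(x, 0.5 * kap * x^2 - 0.5 * kap, rep(50, 2001))
  flds <- langevin_fields(tab, mass = 10, temperature = 300)
  cfg <- sim_config(dt = 0.01, n_steps = 4e6, seed = 3, x_init = 0,
                    stride = 5)
  tr <- propagate(flds, cfg)
  expect_equal(var(tr$x), kB() * 300 / kap, tolerance = 0.03)
  expect_equal(var(tr$v), kB() * 300 / 10, tolerance = 0.03)
})

test_that("free diffusion obeys the Einstein relation", {
  x <- seq(0, 40, length.out = 2001)
  tab <- field_table(x, rep(0, 2001), rep(100, 2001))
  flds <- langevin_fields(tab, mass = 1, temperature = 300)
  cfg <- sim_config(dt = 0.0025, n_steps = 2e6, seed = 5, x_init = 20,
                    stride = 400)  # 1 ps between frames
  tr <- propagate(flds, cfg)
  D_emp <- var(diff(tr$x)) / 2
  expect_equal(D_emp, kB() * 300 / 100, tolerance = 0.05)
})

test_that("long trajectories reproduce the Boltzmann density (chi-square)", {
  flds <- single_barrier_template(height = 4, x_b = 0.5, kappa = 100,
                                  gamma = 50, plateau_nm = 0.15)
  lf <- langevin_fields(fields_to_table(flds, n = 1001), mass = 1,
                        temperature = 300)
  cfg <- sim_config(dt = 0.005, n_steps = 8e6, seed = 21, x_init = 0.5,
                    stride = 4000)   # ~20 ps between samples: decorrelated
  tr <- propagate(lf, cfg)
  xs <- tr$x[-1]
  brk <- seq(lf$x[1], lf$x[length(lf$x)], length.out = 16)
  obs <- as.integer(table(cut(xs, brk)))
  mid <- (head(brk, -1) + tail(brk, -1)) / 2
  p <- exp(-approx(lf$x, lf$dG, mid)$y / (kB() * 300))
  p <- p / sum(p)
  ct <- suppressWarnings(chisq.test(obs, p = p))
  expect_gt(ct$p.value, 0.01)
})

test_that("trajectories are bit-reproducible from the seed", {
  lf <- fast_well()
  cfg <- sim_config(dt = 8e-4, n_steps = 2e5, seed = 77, stride = 100)
  t1 <- propagate(lf, cfg)
  t2 <- propagate(lf, cfg)
  expect_identical(t1$x, t2$x)
  expect_identical(t1$events$events, t2$events$events)
  t3 <- propagate(lf, sim_config(dt = 8e-4, n_steps = 2e5, seed = 78,
                                 stride = 100))
  expect_false(identical(t1$x, t3$x))
})

test_that("unstable time steps are warned about and instabilities raised", {
  lf <- benchmark_well()
  expect_warning(
    propagate(lf, sim_config(dt = 0.5, n_steps = 10, seed = 1)),
    "stability")
  kap <- 1e8   # absurd stiffness to force overflow
  x <- seq(-1, 1, length.out = 101)
  tab <- field_table(x, 0.5 * kap * x^2 - 0.5 * kap, rep(1e-6, 101))
  flds <- langevin_fields(tab, mass = 1e-3, temperature = 300)
  expect_error(
    suppressWarnings(propagate(
      flds, sim_config(dt = 10, n_steps = 1000, seed = 1, x_init = 0.9))),
    "instability")
})

test_that("two-core transition detection is immune to recrossings", {
  # crafted path: bound start, two excursions to unbound, one return
  xx <- c(0.0, 0.8, 0.2, 0.8)
  rec <- detect_transitions(xx, x_b = 0.3, x_u = 0.7, time = 0:3)
  expect_equal(rec$n_D, 2L)
  expect_equal(rec$n_A, 1L)
  expect_equal(rec$events$type, c("dissociation", "association",
                                  "dissociation"))
  expect_equal(rec$events$waiting_time, c(1, 1, 1))
  # oscillation strictly between the cores -> no events
  osc <- 0.5 + 0.15 * sin(seq(0, 20, by = 0.1))
  expect_warning(rec0 <- detect_transitions(osc, x_b = 0.3, x_u = 0.7),
                 "no state change")
  expect_equal(nrow(rec0$events), 0L)
  # event types strictly alternate on a long random-ish path
  set.seed(2)
  path <- cumsum(rnorm(5000, 0, 0.05))
  rec2 <- suppressWarnings(detect_transitions(path, x_b = -0.5, x_u = 0.5))
  if (nrow(rec2$events) > 1)
    expect_true(all(diff(match(rec2$events$type,
                               c("dissociation", "association"))) != 0))
  expect_lte(abs(rec2$n_D - rec2$n_A), 1L)
})

test_that("telegraph trajectories recover their dwell time", {
  # two-state telegraph: dwell 100 ps in each core, sampled at 1 ps
  dwell <- 100
  xx <- rep(rep(c(0.1, 0.9), 25), each = dwell)
  rec <- detect_transitions(xx, x_b = 0.3, x_u = 0.7,
                            time = seq_along(xx) - 1)
  expect_equal(mean(rec$events$waiting_time), dwell, tolerance = 0.02)
})

test_that("rates and K_D follow from waiting times with correct units", {
  # tau_D = 420 ps -> k_D = 2.38e9 s^-1
  rec <- dctmdr:::new_transition_record(
    time = cumsum(rep(c(420, 625), 10)),
    type = rep(c(1, 2), 10),
    wait = rep(c(420, 625), 10), total_time = 11000)
  r <- estimate_rates(rec, C_sim = 1)
  expect_equal(r$k_D, 1e12 / 420, tolerance = 1e-12)
  # mean tau_A = 1000 ps at C_sim = 1 M -> k_A = 1e9 s^-1 M^-1
  rec2 <- dctmdr:::new_transition_record(
    time = cumsum(rep(c(500, 1000), 5)),
    type = rep(c(1, 2), 5),
    wait = rep(c(500, 1000), 5), total_time = 8000)
  r2 <- estimate_rates(rec2, C_sim = 1)
  expect_equal(r2$k_A, 1e9)
  expect_equal(r2$K_D, r2$k_D / r2$k_A)
  expect_equal(r2$se_k_D, r2$k_D / sqrt(5))
  # zero-event channel reported absent with an upper bound
  rec3 <- dctmdr:::new_transition_record(
    time = 100, type = 1, wait = 100, total_time = 1e4)
  r3 <- estimate_rates(rec3)
  expect_true(is.na(r3$k_A))
  expect_equal(r3$k_A_upper, 1e12 / 1e4)
})

test_that("mean first-passage quadrature matches closed forms", {
  # flat G, constant Gamma, wall at 0: tau = Gamma L^2 / (2 kBT)
  xg <- seq(0, 1, length.out = 501)
  ff <- langevin_fields(field_table(xg, rep(0, 501), rep(100, 501)),
                        mass = 1, temperature = 300)
  expect_equal(reference_mfpt(ff, 0, 1), 100 / (2 * kB() * 300),
               tolerance = 1e-6)
  # Kramers high-barrier estimate on the 10 kJ/mol double well
  lf <- benchmark_well()
  cores <- default_cores(lf)
  x_min <- lf$x[which.min(lf$dG[seq_len(which.max(lf$dG))])]
  tau <- reference_mfpt(lf, x_min, cores$x_u)
  k_kramers <- sqrt(100 * 100) / (2 * pi * 100) * exp(-10 / (kB() * 300))
  expect_equal(k_kramers, 2.89e-3, tolerance = 0.01)  # oracle sanity
  expect_equal(tau, 1 / k_kramers, tolerance = 0.25)
  expect_error(reference_mfpt(lf, 0.2, 0.2), "differ")
})

test_that("default cores sit between the bound minimum and the plateau", {
  lf <- benchmark_well()
  cores <- default_cores(lf)
  ib <- which.max(lf$dG)
  x_min <- lf$x[which.min(lf$dG[seq_len(ib)])]
  expect_equal(cores$x_b, x_min + 0.25 * (lf$x[ib] - x_min))
  expect_gt(cores$x_u, lf$x[ib])
  tail_dG <- lf$dG[length(lf$dG)]
  expect_lte(abs(approx(lf$x, lf$dG, cores$x_u)$y - tail_dG), 0.5)
})

test_that("mass boosting reduces to plain propagation at scale 1 and flags underdamped wells", {
  lf <- fast_well()
  cfg <- sim_config(dt = 8e-4, n_steps = 1e5, seed = 31, stride = 50,
                    mass_scale = 1)
  t1 <- propagate(lf, cfg)
  t2 <- propagate_overdamped_boosted(lf, cfg)
  expect_identical(t1$x, t2$x)
  expect_true(t2$regime$overdamped)
  # underdamped: tiny friction, heavy mass
  x <- seq(-1, 1, length.out = 201)
  tab <- field_table(x, 50 * x^2 - 50, rep(0.5, 201))
  lfu <- langevin_fields(tab, mass = 50, temperature = 300)
  cfgu <- sim_config(dt = 0.01, n_steps = 1e3, seed = 1, x_init = 0,
                     mass_scale = 4)
  expect_warning(tu <- propagate_overdamped_boosted(lfu, cfgu),
                 "not safely overdamped")
  expect_false(tu$regime$overdamped)
})

test_that("simulate() draws independent seeded trajectories", {
  lf <- fast_well()
  cfg <- sim_config(dt = 8e-4, n_steps = 1e4, seed = 1, stride = 100)
  trs <- simulate(lf, nsim = 2, seed = 500, config = cfg)
  expect_length(trs, 2)
  expect_false(identical(trs[[1]]$x, trs[[2]]$x))
  tr1 <- propagate(lf, sim_config(dt = 8e-4, n_steps = 1e4, seed = 500,
                                  stride = 100))
  expect_identical(trs[[1]]$x, tr1$x)
})
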