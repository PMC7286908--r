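test_that("work integration matches closed-form integrals", {
  # constant f = 2 kJ/mol/nm over 0.5 nm -> W = 1 kJ/mol
  n <- 501
  ens <- make_ensemble(rbind(rep(2, n), rep(2, n)), dt = 1, v_c = 1e-3)
  ws <- integrate_work(ens)
  expect_equal(ws$mean_W[n], 2 * 0.5)
  # f == 0 -> W == 0, var == 0
  ens0 <- make_ensemble(matrix(0, 2, 11), dt = 1, v_c = 1e-3)
  ws0 <- integrate_work(ens0)
  expect_true(all(ws0$mean_W == 0) && all(ws0$var_W == 0))
  # linear ramp f = x on [0, 1] -> W(1) = 0.5 (trapezoid is exact here)
  n <- 2001
  x <- seq(0, 1, length.out = n)
  ensr <- make_ensemble(rbind(x, x), dt = 1 / (1e-3 * (n - 1)), v_c = 1e-3)
  expect_equal(integrate_work(ensr)$mean_W[n], 0.5, tolerance = 1e-6)
})

test_that("zero-variance ensembles give dG = <W> and the pointwise identity holds", {
  ws <- generate_gaussian_workset(mu = seq(0, 12, length.out = 40),
                                  sigma2 = rep(0, 40), N = 5, seed = 1)
  fe <- estimate_free_energy(ws, temperature = 300)
  expect_equal(fe$dG, ws$mean_W)
  expect_true(all(fe$W_diss == 0))
  ws2 <- generate_gaussian_workset(mu = seq(0, 12, length.out = 40),
                                   sigma2 = seq(0, 30, length.out = 40),
                                   N = 200, seed = 2)
  fe2 <- estimate_free_energy(ws2, temperature = 300)
  expect_equal(fe2$dG + fe2$W_diss, ws2$mean_W)  # machine-precision identity
  expect_error(estimate_free_energy(ws2, temperature = -10), "temperature")
})

test_that("cumulant estimator agrees with the Gaussian Jarzynski closed form and the exponential average", {
  # mu = 10, sigma^2 = 20 at the endpoint, T = 300 K -> dG = 5.99 kJ/mol
  ws <- generate_gaussian_workset(mu = rep(10, 30),
                                  sigma2 = seq(0, 20, length.out = 30),
                                  N = 2e5, seed = 3)
  fe <- estimate_free_energy(ws, temperature = 300, errors = "none")
  kT <- kB() * 300
  expect_equal(fe$dG[30], 10 - 20 / (2 * kT), tolerance = 0.03 / 5.99)
  # oracle: direct exponential average on the same samples
  dG_exp <- -kT * log(mean(exp(-(ws$W[, 30] - 10) / kT))) + 10
  expect_lt(abs(fe$dG[30] - dG_exp), 0.05)
  # the unhalved literature variant differs by exactly var/(2 kT)
  fe1 <- estimate_free_energy(ws, temperature = 300, halved = FALSE,
                              errors = "none")
  expect_equal(fe$dG - fe1$dG, ws$var_W / (2 * kT))
})

test_that("free-energy recovery from force-level synthetic ensembles improves with N", {
  flds <- nacl_template()
  truth <- fields_to_table(flds, n = 501)
  kT <- kB() * 300
  rmse <- sapply(c(100, 500), function(N) {
    ens <- suppressWarnings(
      generate_pulling_ensemble(flds, N = N, n_samples = 501,
                                temperature = 300, seed = 17))
    fit <- estimate_free_energy(integrate_work(ens), errors = "none")
    sqrt(mean((fit$dG - truth$dG)^2)) / kT
  })
  expect_lt(rmse[2], 1)          # <= 1 kBT at N = 500
  expect_lt(rmse[2], rmse[1])    # error shrinks with ensemble size
})

test_that("identical traces give zero friction; friction ignores constant force offsets", {
  ens <- make_ensemble(rbind(1:50, 1:50) + 0, dt = 0.1)
  fr <- estimate_friction_autocorr(ens, sigma = 0)
  expect_true(all(abs(fr$gamma_raw) < 1e-12))
  # offset invariance: add a constant to every force at fixed time
  ens1 <- make_ou_ensemble(N = 40, n = 60, dt = 0.2, seed = 8)
  ens2 <- ens1
  ens2$f <- ens1$f + 7.5
  fr1 <- estimate_friction_autocorr(ens1, sigma = 0)
  fr2 <- estimate_friction_autocorr(ens2, sigma = 0)
  expect_equal(fr1$gamma_raw, fr2$gamma_raw)
})

test_that("friction recovers the analytic Ornstein-Uhlenbeck plateau", {
  # sigma_f^2 = 100, tau_c = 1 ps, T = 300 K ->
  # Gamma_plateau = sigma_f^2 tau_c / kBT = 40.1 kJ ps/mol/nm^2
  ens <- make_ou_ensemble(N = 5000, n = 200, dt = 0.25, sigma2 = 100,
                          tau_c = 1, seed = 1)
  fr <- estimate_friction_autocorr(ens, sigma = 0)
  plateau <- mean(fr$gamma_raw[21:61])   # 5-15 correlation times
  expect_equal(plateau, 100 * 1 / (kB() * 300), tolerance = 0.05)
})

test_that("friction recovers a white-noise ground truth", {
  # force noise variance 2 kBT Gamma0 / dt with Gamma0 = 50
  set.seed(12)
  N <- 2000; n <- 150; dt <- 0.5
  sd_f <- sqrt(2 * kB() * 300 * 50 / dt)
  ens <- make_ensemble(matrix(rnorm(N * n, sd = sd_f), N, n), dt = dt)
  fr <- estimate_friction_autocorr(ens, sigma = 0)
  expect_equal(mean(fr$gamma_raw[10:60]), 50, tolerance = 0.10)
})

test_that("dissipation-gradient route matches its closed forms", {
  # W_diss linear with slope s -> Gamma = s / v_c, constant
  x <- seq(0, 1, length.out = 101)
  fe <- structure(list(x = x, W_diss = 0.4 * x, dG = 0 * x,
                       temperature = 300),
                  class = "free_energy_profile")
  fr <- estimate_friction_from_dissipation(fe, v_c = 1e-3, sigma = 0)
  expect_equal(fr$gamma_raw, rep(400, 101))
  fe$W_diss <- 0 * x
  fr0 <- estimate_friction_from_dissipation(fe, v_c = 1e-3, sigma = 0)
  expect_true(all(fr0$gamma_raw == 0))
  fe$x <- fe$x[1:2]; fe$W_diss <- fe$W_diss[1:2]
  expect_error(estimate_friction_from_dissipation(fe, v_c = 1e-3),
               "3 grid points")
})

test_that("autocorrelation and dissipation routes agree within combined jackknife errors", {
  flds <- single_barrier_template(height = 6, x_b = 0.5, kappa = 100,
                                  gamma = 60)
  ens <- suppressWarnings(
    generate_pulling_ensemble(flds, N = 60, n_samples = 151,
                              temperature = 300, seed = 21))
  fit <- dctmd(ens, friction = "both", sigma = 0.05, normality = FALSE)
  se_auto <- jackknife_errors(ens, "friction", sigma = 0.05)
  a <- fit$friction$gamma_smooth
  b <- fit$friction_dissipation$gamma_smooth
  # dissipation route is noisier; allow its scale via the same jackknife
  agree <- abs(a - b) <= 2 * (se_auto + 1e-8) + 0.25 * pmax(a, b)
  expect_gte(mean(agree[-(1:5)]), 0.9)
})

test_that("route consistency: v_c * int Gamma dx equals var W / (2 kBT)", {
  flds <- single_barrier_template(height = 8, x_b = 0.5, kappa = 100,
                                  gamma = 90)
  ens <- generate_pulling_ensemble(flds, N = 400, n_samples = 401,
                                   temperature = 300, seed = 9)
  ws <- integrate_work(ens)
  fr <- estimate_friction_autocorr(ens, sigma = 0)
  dx <- diff(ws$x)
  int_gamma <- c(0, cumsum(dx * (head(fr$gamma_raw, -1) +
                                   tail(fr$gamma_raw, -1)) / 2))
  lhs <- ens$v_c * int_gamma
  rhs <- ws$var_W / (2 * kB() * 300)
  n <- length(lhs)
  expect_equal(lhs[n], rhs[n], tolerance = 1e-3)
  expect_lt(max(abs(lhs - rhs)), 0.02 * max(rhs))
})

test_that("gaussian smoothing preserves constants and mass, flooring enforces positivity", {
  x <- seq(0, 1, length.out = 201)
  const <- structure(list(x = x, gamma_raw = rep(42, 201),
                          gamma_smooth = NULL, smoothing_sigma = NA,
                          floor = NA, temperature = 300, route = "test"),
                     class = "friction_profile")
  sm <- smooth_profile(const, sigma = 0.07)
  expect_equal(sm$gamma_smooth, rep(42, 201), tolerance = 1e-12)
  # sigma = 0: output equals floored input
  spiky <- const
  spiky$gamma_raw <- rep(10, 201); spiky$gamma_raw[77] <- -5
  s0 <- smooth_profile(spiky, sigma = 0)
  expect_equal(s0$gamma_smooth[-77], spiky$gamma_raw[-77])
  expect_equal(s0$gamma_smooth[77], s0$floor)
  expect_true(all(s0$gamma_smooth >= s0$floor) && s0$floor > 0)
  # delta spike of area A on a baseline spreads mass-conservingly
  dx <- x[2] - x[1]
  spike <- const
  spike$gamma_raw <- rep(5, 201)
  spike$gamma_raw[100] <- 5 + 3 / dx   # area A = 3 above baseline
  ssm <- smooth_profile(spike, sigma = 0.03)
  expect_equal(sum(ssm$gamma_smooth - 5) * dx, 3, tolerance = 1e-6)
  expect_error(smooth_profile(const, sigma = -0.1), "sigma")
})

test_that("jackknife errors are calibrated and shrink as N^(-1/2)", {
  # identical traces -> zero error
  ens_id <- make_ensemble(rbind(1:30, 1:30, 1:30) + 0, dt = 0.1)
  expect_lt(max(jackknife_errors(ens_id, "free_energy")), 1e-6)
  expect_error(jackknife_errors(make_ensemble(rbind(1:3, 1:3) + 0)),
               "at least 3")
  # calibration against the Gaussian closed form, averaged over replicates
  kT <- kB() * 300
  se_cf <- sqrt(20 / 100 + 2 * 20^2 / (4 * kT^2 * 99))
  jk <- sapply(1:30, function(s) {
    ws <- generate_gaussian_workset(mu = rep(10, 3), sigma2 = rep(20, 3),
                                    N = 100, seed = s)
    estimate_free_energy(ws, temperature = 300)$stderr_dG[3]
  })
  expect_equal(mean(jk), se_cf, tolerance = 0.15)
  # N^(-1/2) scaling on a synthetic ensemble
  flds <- single_barrier_template(height = 5, gamma = 50)
  se_at <- sapply(c(100, 400), function(N) {
    ens <- suppressWarnings(
      generate_pulling_ensemble(flds, N = N, n_samples = 101,
                                temperature = 300, seed = 30))
    median(jackknife_errors(ens, "free_energy"))
  })
  expect_equal(se_at[1] / se_at[2], 2, tolerance = 0.25)
})

test_that("work-normality diagnostic passes Gaussian and flags bimodal ensembles", {
  ws_g <- generate_gaussian_workset(mu = seq(0, 10, length.out = 25),
                                    sigma2 = seq(0, 4, length.out = 25),
                                    N = 300, seed = 14)
  rep_g <- check_work_normality(ws_g)
  expect_true(rep_g$passed)
  # 50:50 mixture of Gaussians 10 kJ/mol apart, sd = 1
  set.seed(15)
  n <- 25; N <- 300
  shift <- rep(c(0, 10), each = N / 2)
  W <- outer(shift, seq(0, 1, length.out = n)) +
    matrix(rnorm(N * n, sd = 1), N, n) *
    matrix(seq(0, 1, length.out = n), N, n, byrow = TRUE)
  ws_b <- generate_gaussian_workset(mu = rep(0, n), sigma2 = rep(0, n),
                                    N = N, seed = 1)
  ws_b$W <- W
  ws_b$mean_W <- colMeans(W)
  ws_b$var_W <- apply(W, 2, var)
  rep_b <- check_work_normality(ws_b)
  expect_false(rep_b$passed)
  # N boundary
  ws8 <- generate_gaussian_workset(mu = rep(1, 5), sigma2 = rep(1, 5),
                                   N = 8, seed = 2)
  expect_s3_class(check_work_normality(ws8), "normality_report")
  ws7 <- generate_gaussian_workset(mu = rep(1, 5), sigma2 = rep(1, 5),
                                   N = 7, seed = 2)
  expect_error(check_work_normality(ws7), "at least N = 8")
})

test_that("dctmd() bundles estimates coherently and exports field tables", {
  flds <- single_barrier_template(height = 8, x_b = 0.5, kappa = 100,
                                  gamma = 70)
  ens <- generate_pulling_ensemble(flds, N = 120, n_samples = 201,
                                   temperature = 300, seed = 4)
  fit <- dctmd(ens, friction = "both")
  expect_s3_class(fit, "dctmd")
  cf <- coef(fit)
  expect_equal(unname(cf["dG_barrier"]), 8, tolerance = 0.15)
  expect_equal(unname(cf["x_barrier"]), 0.5, tolerance = 0.05)
  expect_true(fit$normality$passed)
  tab <- as_field_table(fit)
  expect_s3_class(tab, "field_table")
  expect_true(all(tab$gamma > 0))
  expect_equal(tab$dG[1], 0)
  expect_output(print(fit), "barrier")
  expect_output(print(summary(fit)), "jackknife")
})
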