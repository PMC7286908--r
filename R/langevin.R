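# Coarse-grained Langevin dynamics on tabulated free-energy/friction fields,
# transition detection, rate estimation and a mean-first-passage-time
# quadrature oracle.

#' Prepare fields for Langevin propagation
#'
#' Builds the internal uniform-grid representation of dG(x) and Gamma(x)
#' used by the propagator: the deterministic force -dG/dx from central
#' differences, piecewise-linear interpolation between nodes (exact at the
#' nodes), mass and temperature.
#'
#' @param table a [field_table()], a `dctmd` fit (converted via
#'   [as_field_table()]), or a [model_fields()] (tabulated on `n_grid`
#'   points).
#' @param mass particle (reduced) mass [amu]; e.g. 13.9 amu for a Na+/Cl-
#'   pair. Mass only influences dynamics outside the overdamped regime.
#' @param temperature temperature [K].
#' @param n_grid grid size when resampling is needed.
#' @return an object of class `langevin_fields`.
#' @export
langevin_fields <- function(table, mass, temperature = 300,
                            n_grid = 1001L) {
  if (inherits(table, "dctmd")) table <- as_field_table(table)
  if (inherits(table, "model_fields"))
    table <- fields_to_table(table, n = n_grid)
  stopifnot(inherits(table, "field_table"))
  if (!is.finite(mass) || mass <= 0) stop("mass must be positive", call. = FALSE)
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be positive", call. = FALSE)
  x <- table$x
  n <- length(x)
  dx <- diff(x)
  if (max(dx) - min(dx) > 1e-9 * mean(dx)) {
    # resample to a uniform grid (linear interpolation)
    xu <- seq(x[1L], x[n], length.out = max(n, n_grid))
    dG <- stats::approx(x, table$dG, xout = xu)$y
    gamma <- stats::approx(x, table$gamma, xout = xu)$y
    x <- xu; n <- length(x)
  } else {
    dG <- table$dG
    gamma <- table$gamma
  }
  if (any(gamma <= 0))
    stop("friction must be strictly positive on the grid (apply ",
         "smooth_profile() flooring first)", call. = FALSE)
  h <- (x[n] - x[1L]) / (n - 1L)
  force <- numeric(n)
  force[2:(n - 1)] <- -(dG[3:n] - dG[1:(n - 2)]) / (2 * h)
  force[1L] <- -(dG[2L] - dG[1L]) / h
  force[n] <- -(dG[n] - dG[n - 1L]) / h
  curv <- numeric(n)
  curv[2:(n - 1)] <- (dG[3:n] - 2 * dG[2:(n - 1)] + dG[1:(n - 2)]) / h^2
  structure(list(x = x, dG = dG, gamma = gamma, force = force,
                 mass = mass, temperature = temperature, dx = h,
                 max_curv = max(abs(curv)), max_gamma = max(gamma)),
            class = "langevin_fields")
}

#' @export
print.langevin_fields <- function(x, ...) {
  cat(sprintf(
    paste0("<langevin_fields: %d-point grid on [%.4g, %.4g] nm, m = %g amu,",
           " T = %g K,\n  barrier %.3g kJ/mol, Gamma in [%.3g, %.3g]",
           " kJ ps/mol/nm^2>\n"),
    length(x$x), x$x[1L], x$x[length(x$x)], x$mass, x$temperature,
    max(x$dG) - min(x$dG), min(x$gamma), x$max_gamma))
  invisible(x)
}

#' Simulation configuration for Langevin propagation
#'
#' @param dt integration time step [ps].
#' @param n_steps number of steps (may exceed 2^31; stored as double).
#' @param seed explicit RNG seed.
#' @param x_min,x_max reflecting-wall positions [nm]; default the grid ends.
#' @param x_b,x_u bound / unbound core boundaries [nm]; defaults are derived
#'   from the free-energy profile (see [default_cores()]).
#' @param x_init initial position [nm]; default the bound minimum.
#' @param v_init initial velocity [nm/ps]; default a Maxwell-Boltzmann draw.
#' @param mass_scale mass-enhancement factor for overdamped boosting.
#' @param stride record every `stride`-th step (positions and velocities).
#' @param record_trajectory set `FALSE` to keep only events and final state
#'   (long rate runs).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(dt, n_steps, seed, x_min = NULL, x_max = NULL,
                       x_b = NULL, x_u = NULL, x_init = NULL, v_init = NULL,
                       mass_scale = 1, stride = 1L,
                       record_trajectory = TRUE) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (n_steps < 1) stop("n_steps must be >= 1", call. = FALSE)
  if (missing(seed) || is.null(seed))
    stop("an explicit seed is required", call. = FALSE)
  if (mass_scale < 1) stop("mass_scale must be >= 1", call. = FALSE)
  structure(list(dt = dt, n_steps = as.double(n_steps),
                 seed = as.integer(seed), x_min = x_min, x_max = x_max,
                 x_b = x_b, x_u = x_u, x_init = x_init, v_init = v_init,
                 mass_scale = mass_scale, stride = as.integer(stride),
                 record_trajectory = isTRUE(record_trajectory)),
            class = "sim_config")
}

#' Default bound/unbound core boundaries from a free-energy profile
#'
#' The bound core ends a quarter of the way from the bound minimum to the
#' main barrier top; the unbound core starts at the first grid point beyond
#' the barrier where dG has flattened to within `plateau_tol` of its value
#' at the far end of the grid.
#'
#' @param fields a `langevin_fields`.
#' @param plateau_tol flatness tolerance [kJ/mol] (default 0.5).
#' @return list with `x_b` and `x_u` [nm].
#' @export
default_cores <- function(fields, plateau_tol = 0.5) {
  stopifnot(inherits(fields, "langevin_fields"))
  x <- fields$x; dG <- fields$dG
  ib <- which.max(dG)
  im <- which.min(dG[seq_len(ib)])
  x_b <- x[im] + 0.25 * (x[ib] - x[im])
  tail_val <- dG[length(dG)]
  after <- seq.int(ib, length(x))
  iu <- after[which(abs(dG[after] - tail_val) <= plateau_tol)[1L]]
  if (is.na(iu)) iu <- length(x)
  list(x_b = x_b, x_u = x[iu])
}

.resolve_config <- function(fields, config) {
  cfg <- config
  if (is.null(cfg$x_min)) cfg$x_min <- fields$x[1L]
  if (is.null(cfg$x_max)) cfg$x_max <- fields$x[length(fields$x)]
  if (is.null(cfg$x_b) || is.null(cfg$x_u)) {
    cores <- default_cores(fields)
    if (is.null(cfg$x_b)) cfg$x_b <- cores$x_b
    if (is.null(cfg$x_u)) cfg$x_u <- cores$x_u
  }
  if (!(cfg$x_min < cfg$x_b && cfg$x_b < cfg$x_u && cfg$x_u < cfg$x_max)) {
    if (is.null(config$x_b) && is.null(config$x_u)) {
      # profile has no usable barrier structure (e.g. single well):
      # fall back to domain terciles; events are then merely descriptive
      span <- cfg$x_max - cfg$x_min
      cfg$x_b <- cfg$x_min + span / 3
      cfg$x_u <- cfg$x_min + 2 * span / 3
    } else {
      stop("need x_min < x_b < x_u < x_max", call. = FALSE)
    }
  }
  if (is.null(cfg$x_init)) {
    ib <- which.max(fields$dG)
    cfg$x_init <- fields$x[which.min(fields$dG[seq_len(ib)])]
  }
  cfg
}

#' Propagate the unbiased Langevin equation
#'
#' Integrates `m x" = -dG/dx - Gamma(x) x' + sqrt(2 kB T Gamma(x)) xi(t)`
#' with the Bussi-Parrinello splitting (Ornstein-Uhlenbeck thermostat
#' half-steps around a velocity-Verlet core); the friction coefficient
#' `Gamma(x)/m` is frozen at the pre-step position within each step.
#' Reflecting walls bound the coordinate. Dissociation/association events
#' are recorded online at full step resolution with the two-core scheme of
#' [detect_transitions()]. Deterministic given the seed.
#'
#' A warning is issued when `dt` exceeds the stability guideline
#' `0.25 * min(m/Gamma_max, sqrt(m/|G''|_max))`.
#'
#' @param fields a [langevin_fields()].
#' @param config a [sim_config()].
#' @param temperature optional override of the simulation temperature [K]
#'   (used by temperature boosting; the fields stay as computed).
#' @return an object of class `langevin_trajectory`: strided `time`, `x`,
#'   `v`, a `transition_record` in `$events`, the resolved config and final
#'   state.
#' @export
propagate <- function(fields, config, temperature = NULL) {
  stopifnot(inherits(fields, "langevin_fields"),
            inherits(config, "sim_config"))
  cfg <- .resolve_config(fields, config)
  if (is.null(temperature)) temperature <- fields$temperature
  m <- fields$mass * cfg$mass_scale
  kT <- kB() * temperature
  dt_max <- 0.25 * min(m / fields$max_gamma,
                       if (fields$max_curv > 0) sqrt(m / fields$max_curv)
                       else Inf)
  if (cfg$dt > dt_max)
    warning(sprintf(
      "dt = %g ps exceeds the stability guideline %.3g ps; expect inaccurate or unstable integration",
      cfg$dt, dt_max), call. = FALSE)
  set.seed(cfg$seed)
  if (is.null(cfg$v_init)) cfg$v_init <- stats::rnorm(1L, 0, sqrt(kT / m))
  res <- propagate_core(fields$force, fields$gamma, fields$x[1L],
                        fields$dx, m, kT, cfg$dt, cfg$n_steps,
                        cfg$x_init, cfg$v_init, cfg$x_min, cfg$x_max,
                        cfg$stride, cfg$x_b, cfg$x_u,
                        cfg$record_trajectory)
  events <- new_transition_record(
    time = res$event_time, type = res$event_type, wait = res$event_wait,
    total_time = res$t_final, warn_empty = FALSE)
  tt <- if (cfg$record_trajectory)
    seq.int(0L, length(res$x) - 1L) * (cfg$dt * cfg$stride) else numeric(0)
  structure(list(time = tt, x = res$x, v = res$v, events = events,
                 config = cfg, temperature = temperature,
                 mass = m, x_final = res$x_final, v_final = res$v_final,
                 t_final = res$t_final),
            class = "langevin_trajectory")
}

#' @export
print.langevin_trajectory <- function(x, ...) {
  cat(sprintf(
    paste0("<langevin_trajectory: %.4g ps at dt = %g ps (T = %g K, m = %g ",
           "amu),\n  %d recorded frames, %d dissociations, %d ",
           "associations>\n"),
    x$t_final, x$config$dt, x$temperature, x$mass, length(x$x),
    x$events$n_D, x$events$n_A))
  invisible(x)
}

#' Mass-enhanced overdamped propagation
#'
#' In the overdamped regime the dynamics (and hence the rates) are
#' independent of the mass, so the mass may be enhanced artificially to
#' admit a larger integration step: with `m -> mass_scale * m` the step is
#' scaled as `dt -> sqrt(mass_scale) * dt` and the step count reduced to
#' keep the simulated time unchanged. A regime diagnostic compares the
#' inertial relaxation time `m_eff/Gamma` against the positional relaxation
#' time `Gamma/|G''|`: overdamped requires `Gamma^2 >> m_eff * |G''|`.
#'
#' With `mass_scale = 1` this reduces exactly to [propagate()].
#'
#' @param fields a [langevin_fields()].
#' @param config a [sim_config()]; its `mass_scale` is applied here.
#' @param temperature optional temperature override [K].
#' @return a `langevin_trajectory` with an added `$regime` diagnostic
#'   (`overdamped` flag and the timescale ratio).
#' @export
propagate_overdamped_boosted <- function(fields, config,
                                         temperature = NULL) {
  stopifnot(inherits(config, "sim_config"))
  s <- config$mass_scale
  cfg <- config
  cfg$dt <- config$dt * sqrt(s)
  cfg$n_steps <- max(1, round(config$n_steps / sqrt(s)))
  m_eff <- fields$mass * s
  ratio <- min(fields$gamma)^2 / (m_eff * max(fields$max_curv, 1e-12))
  traj <- propagate(fields, cfg, temperature = temperature)
  traj$regime <- list(
    overdamped = ratio > 10,
    gamma2_over_mK = ratio,
    inertial_time_ps = m_eff / min(fields$gamma))
  if (!traj$regime$overdamped)
    warning(sprintf(
      "dynamics not safely overdamped (Gamma^2/(m*K) = %.3g <= 10); mass-enhanced rates may be biased",
      ratio), call. = FALSE)
  traj
}

new_transition_record <- function(time, type, wait, total_time,
                                  warn_empty = TRUE) {
  type <- as.integer(type)
  lab <- c("dissociation", "association")[type]
  events <- data.frame(time = as.numeric(time), type = lab,
                       waiting_time = as.numeric(wait))
  tau_D <- events$waiting_time[type == 1L]
  tau_A <- events$waiting_time[type == 2L]
  if (nrow(events) == 0L && warn_empty)
    warning("no state change detected in trajectory; empty record",
            call. = FALSE)
  structure(list(events = events, tau_D = tau_D, tau_A = tau_A,
                 n_D = length(tau_D), n_A = length(tau_A),
                 total_time = total_time),
            class = "transition_record")
}

#' @export
print.transition_record <- function(x, ...) {
  cat(sprintf(
    "<transition_record: %d dissociations (mean tau_D = %.4g ps), %d associations (mean tau_A = %.4g ps) in %.4g ps>\n",
    x$n_D, if (x$n_D) mean(x$tau_D) else NA, x$n_A,
    if (x$n_A) mean(x$tau_A) else NA, x$total_time))
  invisible(x)
}

#' Detect binding/unbinding transitions in a trajectory
#'
#' Two-threshold (core-set) scheme: the system becomes "bound" on visiting
#' `x <= x_b` and "unbound" on visiting `x >= x_u`. A dissociation event is
#' the first passage from bound-core entry to the unbound core; association
#' is the reverse. Recrossings of either threshold without reaching the
#' opposite core create no events, and event types strictly alternate.
#' Waiting times are measured from core entry to the opposite-core arrival.
#'
#' @param trajectory a `langevin_trajectory`, or a numeric vector of
#'   positions (then `time` gives the matching times).
#' @param x_b,x_u core boundaries [nm] (`x_b < x_u`); default from the
#'   trajectory's config.
#' @param time sample times [ps] when `trajectory` is a plain vector.
#' @return a `transition_record` with the ordered event list and waiting
#'   time samples.
#' @export
detect_transitions <- function(trajectory, x_b = NULL, x_u = NULL,
                               time = NULL) {
  if (inherits(trajectory, "langevin_trajectory")) {
    if (is.null(x_b)) x_b <- trajectory$config$x_b
    if (is.null(x_u)) x_u <- trajectory$config$x_u
    xx <- trajectory$x
    tt <- trajectory$time
    total <- trajectory$t_final
  } else {
    xx <- as.numeric(trajectory)
    tt <- if (is.null(time)) seq_along(xx) - 1 else as.numeric(time)
    total <- tt[length(tt)]
  }
  if (is.null(x_b) || is.null(x_u) || !(x_b < x_u))
    stop("core boundaries must satisfy x_b < x_u", call. = FALSE)
  s <- integer(length(xx))
  s[xx <= x_b] <- 1L
  s[xx >= x_u] <- 2L
  keep <- s > 0L
  ss <- s[keep]; ts <- tt[keep]
  if (length(ss) == 0L)
    return(new_transition_record(numeric(0), integer(0), numeric(0), total))
  sw <- which(diff(ss) != 0L) + 1L
  if (length(sw) == 0L)
    return(new_transition_record(numeric(0), integer(0), numeric(0), total))
  entries <- c(1L, sw)
  ev_time <- ts[sw]
  ev_wait <- ts[sw] - ts[entries[-length(entries)]]
  ev_type <- ifelse(ss[sw] == 2L, 1L, 2L)  # arriving unbound = dissociation
  new_transition_record(ev_time, ev_type, ev_wait, total)
}

#' Convert waiting times into rate constants
#'
#' Dissociation: `k_D = 1/mean(tau_D)`, converted from ps^-1 to s^-1.
#' Association is bimolecular: `k_A = 1/(mean(tau_A) * C_sim)` [s^-1 M^-1],
#' where `C_sim` is the reference concentration implied by the finite
#' simulation volume (outer reflecting wall). The dissociation constant is
#' `K_D = k_D/k_A` [M]. Standard errors assume exponentially distributed
#' waiting times, so the relative error of each rate is `n^(-1/2)`.
#'
#' A channel with zero events is reported as `NA` with an upper bound
#' `1/total simulated time` on its rate.
#'
#' @param record a `transition_record`.
#' @param C_sim reference concentration [M] (default 1).
#' @return an object of class `rate_estimate`: `k_D`, `se_k_D`, `k_A`,
#'   `se_k_A`, `K_D`, `se_K_D`, upper bounds where applicable, event
#'   counts, `C_sim`.
#' @export
estimate_rates <- function(record, C_sim = 1) {
  stopifnot(inherits(record, "transition_record"))
  if (!is.finite(C_sim) || C_sim <= 0)
    stop("C_sim must be a positive concentration [M]", call. = FALSE)
  if (record$n_D < 1L && record$n_A < 1L)
    stop("no events in record; cannot estimate any rate", call. = FALSE)
  ub <- if (is.finite(record$total_time) && record$total_time > 0)
    .PS_TO_S / record$total_time else NA_real_
  k_D <- se_k_D <- k_D_upper <- NA_real_
  if (record$n_D >= 1L) {
    k_D <- .PS_TO_S / mean(record$tau_D)
    se_k_D <- k_D / sqrt(record$n_D)
  } else k_D_upper <- ub
  k_A <- se_k_A <- k_A_upper <- NA_real_
  if (record$n_A >= 1L) {
    k_A <- .PS_TO_S / (mean(record$tau_A) * C_sim)
    se_k_A <- k_A / sqrt(record$n_A)
  } else k_A_upper <- ub / C_sim
  K_D <- se_K_D <- NA_real_
  if (is.finite(k_D) && is.finite(k_A)) {
    K_D <- k_D / k_A
    se_K_D <- K_D * sqrt(1 / record$n_D + 1 / record$n_A)
  }
  structure(list(k_D = k_D, se_k_D = se_k_D, k_D_upper = k_D_upper,
                 k_A = k_A, se_k_A = se_k_A, k_A_upper = k_A_upper,
                 K_D = K_D, se_K_D = se_K_D,
                 n_D = record$n_D, n_A = record$n_A, C_sim = C_sim),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  fmt <- function(v, se, up, unit)
    if (is.finite(v)) sprintf("%.3g +/- %.2g %s", v, se, unit)
    else sprintf("absent (< %.3g %s)", up, unit)
  cat("<rate_estimate>\n")
  cat("  k_D =", fmt(x$k_D, x$se_k_D, x$k_D_upper, "s^-1"),
      sprintf("(n = %d)\n", x$n_D))
  cat("  k_A =", fmt(x$k_A, x$se_k_A, x$k_A_upper, "s^-1 M^-1"),
      sprintf("(n = %d, C_sim = %g M)\n", x$n_A, x$C_sim))
  if (is.finite(x$K_D))
    cat(sprintf("  K_D = %.3g +/- %.2g M\n", x$K_D, x$se_K_D))
  invisible(x)
}

#' Mean first-passage time by double quadrature (overdamped oracle)
#'
#' For overdamped one-dimensional diffusion on dG(x) with position-dependent
#' friction and a reflecting wall on the far side of the start, the mean
#' first-passage time to `x_target` is
#' `tau = (1/kB T) int_start^target dy Gamma(y) exp(dG(y)/kB T)
#' int_wall^y dz exp(-dG(z)/kB T)`, evaluated with nested trapezoids on a
#' refined grid. Serves as an independent check on the propagator.
#'
#' @param fields a [langevin_fields()].
#' @param x_start,x_target start and absorbing target [nm]; the reflecting
#'   wall is the grid end on the opposite side of the target.
#' @param refine grid-refinement factor for the quadrature.
#' @return mean first-passage time [ps].
#' @export
reference_mfpt <- function(fields, x_start, x_target, refine = 8L) {
  stopifnot(inherits(fields, "langevin_fields"))
  if (x_target == x_start)
    stop("x_target must differ from x_start", call. = FALSE)
  x <- fields$x
  flip <- x_target < x_start
  if (flip) {
    # mirror so that the target lies to the right
    x_ <- rev(-x); dG_ <- rev(fields$dG); ga_ <- rev(fields$gamma)
    xs <- -x_start; xt <- -x_target
  } else {
    x_ <- x; dG_ <- fields$dG; ga_ <- fields$gamma
    xs <- x_start; xt <- x_target
  }
  if (!(x_[1L] <= xs && xs < xt && xt <= x_[length(x_)]))
    stop("start/target must lie inside the grid with target beyond start",
         call. = FALSE)
  n <- (length(x_) - 1L) * refine + 1L
  xg <- seq(x_[1L], x_[length(x_)], length.out = n)
  dG <- stats::approx(x_, dG_, xout = xg)$y
  ga <- stats::approx(x_, ga_, xout = xg)$y
  kT <- kB() * fields$temperature
  h <- xg[2L] - xg[1L]
  inner <- exp(-dG / kT)
  Icum <- c(0, cumsum((inner[-1L] + inner[-n]) / 2 * h))  # from wall at left end
  outer_ <- ga * exp(dG / kT) * Icum / kT
  sel <- xg >= xs & xg <= xt
  yo <- outer_[sel]
  sum((yo[-1L] + yo[-length(yo)]) / 2 * h)
}

#' Simulate from Langevin fields
#'
#' `simulate()` method dispatching to [propagate()]: draws `nsim`
#' independent trajectories with seeds `seed, seed + 1, ...`.
#'
#' @param object a `langevin_fields`.
#' @param nsim number of trajectories.
#' @param seed base RNG seed.
#' @param config a [sim_config()] template (its seed is overridden).
#' @param ... passed to [propagate()].
#' @return a list of `langevin_trajectory` (length-1 lists are unwrapped).
#' @export
simulate.langevin_fields <- function(object, nsim = 1, seed = 1L,
                                     config, ...) {
  out <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    cfg <- config
    cfg$seed <- as.integer(seed + i - 1L)
    out[[i]] <- propagate(object, cfg, ...)
  }
  if (nsim == 1L) out[[1L]] else out
}
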