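# Synthetic pulling ensembles and benchmark fields with known ground truth.
#
# The generator solves the constrained Langevin equation for the constraint
# force: with the coordinate forced along x(t) = x0 + v_c t the total force
# vanishes, so
#   f_c(t) = dG/dx + Gamma(x) v_c - sqrt(2 kB T Gamma(x) / dt) g_t,
# g_t i.i.d. standard normal. By construction <W(x)> = dG(x) + v_c int Gamma
# and var W(x) = 2 kB T v_c int Gamma, which is what the dissipation
# correction must remove. The white-noise term carries the 1/sqrt(dt) Ito
# scaling so that integrated work statistics are independent of dt.

#' Construct parametric model fields
#'
#' Bundles analytic free-energy and friction profiles used as ground truth
#' by the synthetic trace generator and the Langevin benchmarks.
#'
#' @param dG function of x returning free energy [kJ/mol].
#' @param dGdx function of x returning its derivative [kJ mol^-1 nm^-1].
#' @param gamma function of x returning friction [kJ ps mol^-1 nm^-2],
#'   strictly positive on the range.
#' @param x_range length-2 numeric, the coordinate range [nm].
#' @param name template label.
#' @param params named list of the numeric parameters (for provenance).
#' @return an object of class `model_fields`.
#' @export
model_fields <- function(dG, dGdx, gamma, x_range, name = "custom",
                         params = list()) {
  stopifnot(is.function(dG), is.function(dGdx), is.function(gamma),
            length(x_range) == 2L, x_range[1] < x_range[2])
  probe <- seq(x_range[1], x_range[2], length.out = 257L)
  if (any(!is.finite(dG(probe))) || any(!is.finite(gamma(probe))))
    stop("model fields must be finite on the coordinate range", call. = FALSE)
  if (any(gamma(probe) <= 0))
    stop("friction must be strictly positive everywhere", call. = FALSE)
  structure(list(dG = dG, dGdx = dGdx, gamma = gamma,
                 x_range = as.numeric(x_range), name = name, params = params),
            class = "model_fields")
}

#' @export
print.model_fields <- function(x, ...) {
  cat(sprintf("<model_fields '%s' on [%g, %g] nm>\n",
              x$name, x$x_range[1], x$x_range[2]))
  invisible(x)
}

# sum-of-Gaussians free energy and its derivative
.gauss_sum <- function(A, c, w) {
  list(
    f = function(x) {
      out <- 0
      for (k in seq_along(A))
        out <- out + A[k] * exp(-(x - c[k])^2 / (2 * w[k]^2))
      out
    },
    df = function(x) {
      out <- 0
      for (k in seq_along(A))
        out <- out - A[k] * (x - c[k]) / w[k]^2 *
          exp(-(x - c[k])^2 / (2 * w[k]^2))
      out
    })
}

#' Two-barrier ion-pair dissociation template
#'
#' A free-energy profile with a bound well, a main dissociation barrier near
#' x = 0.4 nm and a second, smaller barrier near x = 0.6 nm, together with a
#' friction profile that is flat far from the contact pair and elevated in
#' the region between the two barriers where the shared hydration shell is
#' rebuilt. The shape emulates the dissociation of a solvated monovalent ion
#' pair (NaCl-like); the numeric values are package-defined benchmark
#' constants, not measured data.
#'
#' @param gamma0 baseline friction [kJ ps mol^-1 nm^-2].
#' @param gamma_peak extra friction at the hydration-shell peak.
#' @return a [model_fields()] on [0.25, 1.25] nm.
#' @export
nacl_template <- function(gamma0 = 60, gamma_peak = 120) {
  if (gamma0 <= 0) stop("gamma0 must be positive", call. = FALSE)
  g <- .gauss_sum(A = c(-8, 3, 1.5), c = c(0.25, 0.40, 0.60),
                  w = c(0.06, 0.05, 0.05))
  off <- g$f(0.25)
  gam <- function(x) gamma0 + gamma_peak * exp(-(x - 0.52)^2 / (2 * 0.07^2))
  model_fields(
    dG = function(x) g$f(x) - off,
    dGdx = g$df,
    gamma = gam,
    x_range = c(0.25, 1.25),
    name = "nacl_template",
    params = list(wells = c(-8, 3, 1.5), centers = c(0.25, 0.40, 0.60),
                  widths = c(0.06, 0.05, 0.05), gamma0 = gamma0,
                  gamma_peak = gamma_peak, gamma_center = 0.52,
                  gamma_width = 0.07))
}

#' Single-barrier unbinding template
#'
#' Piecewise-harmonic profile: a bound well of curvature `kappa`, a barrier
#' of height `height` (curvature `-kappa`) at `x_b`, a descent into an
#' unbound basin at level `dG_unbound`, then a flat plateau. Well, barrier
#' and basin are joined with continuous value and slope, so the curvature at
#' the bound minimum and at the barrier top are exactly `kappa` and
#' `-kappa` — convenient for Kramers-rate benchmarks. Friction is constant
#' unless a `gamma_fun` is supplied.
#'
#' @param height barrier height above the bound minimum [kJ/mol].
#' @param x_b barrier position [nm].
#' @param kappa curvature magnitude at minimum and barrier
#'   [kJ mol^-1 nm^-2].
#' @param gamma constant friction [kJ ps mol^-1 nm^-2] (ignored when
#'   `gamma_fun` is given).
#' @param dG_unbound free energy of the unbound plateau relative to the
#'   bound minimum [kJ/mol]; must be below `height`.
#' @param plateau_nm length of flat profile appended beyond the unbound
#'   minimum [nm].
#' @param gamma_fun optional function of x for a position-dependent friction.
#' @return a [model_fields()].
#' @export
single_barrier_template <- function(height = 10, x_b = 0.5, kappa = 100,
                                    gamma = 100, dG_unbound = 0,
                                    plateau_nm = 0.4, gamma_fun = NULL) {
  if (kappa <= 0) stop("curvature kappa must be positive", call. = FALSE)
  if (height <= 0) stop("barrier height must be positive", call. = FALSE)
  if (dG_unbound >= height)
    stop("dG_unbound must lie below the barrier height", call. = FALSE)
  if (is.null(gamma_fun)) {
    if (gamma <= 0) stop("friction must be positive", call. = FALSE)
    gamma_fun <- local({g0 <- gamma; function(x) rep.int(g0, length(x))})
  }
  # join points: half-distance where the two parabolas meet with equal slope
  d1 <- 2 * sqrt(height / kappa)          # well-to-barrier distance
  d2 <- 2 * sqrt((height - dG_unbound) / kappa)
  x1 <- x_b - d1                          # bound minimum
  x2 <- x_b + d2                          # unbound minimum
  m1 <- (x1 + x_b) / 2
  m2 <- (x_b + x2) / 2
  dG <- function(x) {
    ifelse(x <= m1, 0.5 * kappa * (x - x1)^2,
    ifelse(x <= m2, height - 0.5 * kappa * (x - x_b)^2,
    ifelse(x <= x2, dG_unbound + 0.5 * kappa * (x - x2)^2, dG_unbound)))
  }
  dGdx <- function(x) {
    ifelse(x <= m1, kappa * (x - x1),
    ifelse(x <= m2, -kappa * (x - x_b),
    ifelse(x <= x2, kappa * (x - x2), 0)))
  }
  model_fields(
    dG = dG, dGdx = dGdx, gamma = gamma_fun,
    x_range = c(x1 - 0.5 * d1, x2 + plateau_nm),
    name = "single_barrier_template",
    params = list(height = height, x_b = x_b, kappa = kappa,
                  x_min = x1, x_unbound = x2, dG_unbound = dG_unbound))
}

#' Tabulate model fields on a uniform grid
#'
#' @param fields a [model_fields()].
#' @param n number of grid points.
#' @param x_range optional range override.
#' @return a [field_table()] with dG anchored to 0 at the first point.
#' @export
fields_to_table <- function(fields, n = 1001L, x_range = NULL) {
  stopifnot(inherits(fields, "model_fields"))
  if (is.null(x_range)) x_range <- fields$x_range
  x <- seq(x_range[1], x_range[2], length.out = n)
  dG <- fields$dG(x)
  field_table(x, dG - dG[1L], fields$gamma(x))
}

#' Generate a synthetic constrained-pulling ensemble
#'
#' Draws `N` constraint-force traces from known model fields under the
#' constrained Langevin force balance (see the package vignette). Work
#' curves integrated from the output satisfy, in expectation,
#' `<W(x)> = dG(x) + v_c * int Gamma dx'` and
#' `var W(x) = 2 kB T v_c * int Gamma dx'`.
#'
#' @param fields a [model_fields()] ground truth.
#' @param N number of traces (>= 2).
#' @param v_c pull velocity [nm/ps].
#' @param n_samples samples per trace; the pull covers the fields' range, so
#'   dt = (range width) / (v_c * (n_samples - 1)).
#' @param temperature temperature [K].
#' @param seed RNG seed (explicit by design).
#' @param x0 start position; defaults to the lower end of the fields' range.
#' @param length_nm pulled distance; defaults to the full range width.
#' @return a `pulling_ensemble`.
#' @export
generate_pulling_ensemble <- function(fields, N = 500L, v_c = 1e-3,
                                      n_samples = 1001L, temperature = 300,
                                      seed = 1L, x0 = NULL,
                                      length_nm = NULL) {
  stopifnot(inherits(fields, "model_fields"))
  if (N < 2L) stop("N must be at least 2", call. = FALSE)
  if (v_c <= 0) stop("v_c must be positive", call. = FALSE)
  if (is.null(x0)) x0 <- fields$x_range[1]
  if (is.null(length_nm)) length_nm <- fields$x_range[2] - x0
  if (length_nm <= 0) stop("length_nm must be positive", call. = FALSE)
  dt <- length_nm / (v_c * (n_samples - 1L))
  x <- x0 + v_c * dt * (seq_len(n_samples) - 1L)
  gam <- fields$gamma(x)
  if (any(gam <= 0))
    stop("friction must be positive over the pulled range", call. = FALSE)
  det_force <- fields$dGdx(x) + gam * v_c
  noise_sd <- sqrt(2 * kB() * temperature * gam / dt)
  set.seed(seed)
  f <- matrix(stats::rnorm(as.double(N) * n_samples), nrow = N)
  f <- sweep(f, 2L, -noise_sd, `*`)          # minus sign: f_c balances +noise
  f <- sweep(f, 2L, det_force, `+`)
  rownames(f) <- sprintf("synth%04d", seq_len(N))
  if (N < 100L)
    warning("ensemble has only N = ", N, " runs; at least 500 recommended",
            call. = FALSE)
  structure(
    list(f = f, N = as.integer(N), n_samples = as.integer(n_samples),
         dt = dt, v_c = v_c, x0 = x0, temperature = temperature),
    class = "pulling_ensemble")
}

#' Generate Gaussian work curves directly
#'
#' Bypasses force-level generation: each trace's work curve is
#' `W_i(x) = mu(x) + sqrt(sigma2(x)) * z_i` with one standard-normal draw
#' per trace, so the pointwise ensemble mean and variance are exactly
#' `mu(x)` and `sigma2(x)`. Intended for estimator unit tests where the
#' Gaussian-work regime must hold by construction.
#'
#' @param mu numeric vector (or function of x) of mean work [kJ/mol].
#' @param sigma2 numeric vector (or function of x) of work variance
#'   [(kJ/mol)^2], all >= 0.
#' @param N number of traces.
#' @param seed RNG seed.
#' @param x position grid [nm]; default `seq(0, 1, length.out = length(mu))`.
#' @param temperature temperature attached to the work set [K].
#' @return a `work_set` (see [integrate_work()]).
#' @export
generate_gaussian_workset <- function(mu, sigma2, N, seed = 1L, x = NULL,
                                      temperature = 300) {
  if (is.function(mu) || is.function(sigma2)) {
    if (is.null(x)) stop("x grid required when mu/sigma2 are functions",
                         call. = FALSE)
    if (is.function(mu)) mu <- mu(x)
    if (is.function(sigma2)) sigma2 <- sigma2(x)
  }
  mu <- as.numeric(mu); sigma2 <- as.numeric(sigma2)
  if (length(sigma2) == 1L) sigma2 <- rep(sigma2, length(mu))
  stopifnot(length(mu) == length(sigma2))
  if (any(sigma2 < 0)) stop("sigma2 must be non-negative", call. = FALSE)
  if (is.null(x)) x <- seq(0, 1, length.out = length(mu))
  set.seed(seed)
  z <- stats::rnorm(N)
  W <- outer(z, sqrt(sigma2)) + matrix(mu, nrow = N, ncol = length(mu),
                                       byrow = TRUE)
  new_work_set(x = x, W = W, temperature = temperature,
               v_c = NA_real_, dt = NA_real_)
}
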