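# Dissipation-corrected estimation of free-energy and friction profiles
# from constrained pulling ensembles.
#
# Working relations (Gaussian-work / second-order cumulant regime):
#   dG(x)     = <W(x)> - W_diss(x),        W_diss(x) = var W(x) / (2 kB T)
#   Gamma(x)  = (1/kB T) int_{t0}^{t(x)} <df_c(t) df_c(t')> dt'
# The running force-fluctuation autocorrelation integral and the derivative
# of W_diss are two routes to the same friction; their agreement is a
# convergence diagnostic.

#' Estimate the dissipation-corrected free-energy profile
#'
#' Applies the second-order cumulant expansion of the Jarzynski equality to
#' a set of work curves: `dG(x) = <W(x)> - var W(x) / (2 kB T)`. The
#' variance term is the dissipated work `W_diss(x)`. Pointwise standard
#' errors of dG are obtained by leave-one-out jackknife over traces
#' (for N >= 3).
#'
#' @param work a `work_set` from [integrate_work()] or
#'   [generate_gaussian_workset()].
#' @param temperature temperature [K]; defaults to the work set's.
#' @param halved logical; `TRUE` (default) uses the cumulant factor
#'   `var/(2 kB T)`. `FALSE` reproduces the alternative convention
#'   `var/(kB T)` that appears in parts of the dcTMD literature; only the
#'   halved form is consistent with the force-autocorrelation friction.
#' @param errors `"jackknife"` (default) or `"none"`.
#' @return an object of class `free_energy_profile`: `x`, `dG`, `W_diss`,
#'   `stderr_dG`, `mean_W`, `temperature`.
#' @export
estimate_free_energy <- function(work, temperature = NULL, halved = TRUE,
                                 errors = c("jackknife", "none")) {
  stopifnot(inherits(work, "work_set"))
  errors <- match.arg(errors)
  if (is.null(temperature)) temperature <- work$temperature
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be positive", call. = FALSE)
  if (work$N < 2L) stop("need at least 2 work curves", call. = FALSE)
  fac <- if (halved) 2 else 1
  kT <- kB() * temperature
  W_diss <- work$var_W / (fac * kT)
  dG <- work$mean_W - W_diss
  stderr_dG <- rep(NA_real_, length(dG))
  if (errors == "jackknife" && work$N >= 3L)
    stderr_dG <- .jackknife_se_dG(work$W, kT, fac)
  structure(list(x = work$x, dG = dG, W_diss = W_diss,
                 stderr_dG = stderr_dG, mean_W = work$mean_W,
                 temperature = temperature, N = work$N, halved = halved),
            class = "free_energy_profile")
}

#' @export
print.free_energy_profile <- function(x, ...) {
  i <- which.max(x$dG)
  cat(sprintf(
    paste0("<free_energy_profile: %d points, barrier %.3g kJ/mol at ",
           "x = %.3g nm,\n  dG(end) = %.3g kJ/mol, W_diss(end) = %.3g ",
           "kJ/mol, T = %g K>\n"),
    length(x$x), x$dG[i], x$x[i], x$dG[length(x$dG)],
    x$W_diss[length(x$W_diss)], x$temperature))
  invisible(x)
}

# exact leave-one-out jackknife SE of dG = mean - var/(fac kT), via
# closed-form downdates of the column sums
.jackknife_se_dG <- function(W, kT, fac = 2) {
  N <- nrow(W)
  S <- colSums(W)
  Q <- colSums(W * W)
  th_sum <- 0
  th_sq <- 0
  for (i in seq_len(N)) {
    mi <- (S - W[i, ]) / (N - 1)
    vi <- (Q - W[i, ]^2 - (N - 1) * mi^2) / (N - 2)
    vi[vi < 0] <- 0
    th <- mi - vi / (fac * kT)
    th_sum <- th_sum + th
    th_sq <- th_sq + th^2
  }
  mbar <- th_sum / N
  sqrt(pmax(0, (N - 1) / N * (th_sq - N * mbar^2)))
}

#' Estimate the friction profile from constraint-force fluctuations
#'
#' Evaluates the running autocorrelation integral
#' `Gamma(x(t)) = (1/kB T) int_{t0}^{t} <df_c(t) df_c(t')> dt'` with the
#' trapezoidal rule from the start of the pull (no truncation window); the
#' raw estimate may be noisy and locally negative, which is handled by the
#' separate Gaussian smoothing and flooring step ([smooth_profile()]).
#'
#' @param ensemble a `pulling_ensemble`.
#' @param temperature temperature [K]; defaults to the ensemble's.
#' @param sigma Gaussian smoothing width [nm] applied to the raw estimate
#'   (default 0.02 nm); set 0 to skip smoothing (flooring still applies).
#' @return an object of class `friction_profile`: `x`, `gamma_raw`,
#'   `gamma_smooth`, `smoothing_sigma`, `floor`, `temperature`.
#' @export
estimate_friction_autocorr <- function(ensemble, temperature = NULL,
                                       sigma = 0.02) {
  stopifnot(inherits(ensemble, "pulling_ensemble"))
  if (is.null(temperature)) temperature <- ensemble$temperature
  if (ensemble$N < 2L)
    stop("friction estimation needs N >= 2 traces (variance undefined)",
         call. = FALSE)
  kT <- kB() * temperature
  D <- sweep(ensemble$f, 2L, colMeans(ensemble$f))
  # sum_{j'<=j} C[j,j'] = (1/(N-1)) colSums(D * rowcumsum(D)) -- O(N T)
  CS <- t(apply(D, 1L, cumsum))
  run <- colSums(D * CS)
  first <- colSums(D * D[, 1L])
  diag_ <- colSums(D * D)
  gamma_raw <- (ensemble$dt / (kT * (ensemble$N - 1))) *
    (run - 0.5 * first - 0.5 * diag_)
  gamma_raw[1L] <- 0
  prof <- structure(
    list(x = positions(ensemble), gamma_raw = gamma_raw,
         gamma_smooth = NULL, smoothing_sigma = NA_real_,
         floor = NA_real_, temperature = temperature,
         route = "autocorrelation"),
    class = "friction_profile")
  smooth_profile(prof, sigma = sigma)
}

#' Estimate friction from the dissipated-work gradient
#'
#' Cross-check route: along the constrained pull, `W_diss(x) = v_c int
#' Gamma dx'`, so `Gamma(x) = (1/v_c) dW_diss/dx`, evaluated by central
#' differences (one-sided at the ends).
#'
#' @param object a `free_energy_profile` (carries `W_diss`), or a `work_set`
#'   (then `temperature` is needed to form `W_diss = var W / (2 kB T)`).
#' @param v_c pull velocity [nm/ps]; defaults to the work set's, when given
#'   a work set.
#' @param temperature temperature [K], only used for a `work_set` input.
#' @param sigma Gaussian smoothing width [nm] (default 0.02).
#' @return a `friction_profile` (route `"dissipation"`).
#' @export
estimate_friction_from_dissipation <- function(object, v_c = NULL,
                                               temperature = NULL,
                                               sigma = 0.02) {
  if (inherits(object, "work_set")) {
    if (is.null(temperature)) temperature <- object$temperature
    if (is.null(v_c)) v_c <- object$v_c
    W_diss <- object$var_W / (2 * kB() * temperature)
    x <- object$x
  } else if (inherits(object, "free_energy_profile")) {
    W_diss <- object$W_diss
    x <- object$x
    if (is.null(temperature)) temperature <- object$temperature
  } else stop("object must be a work_set or free_energy_profile",
              call. = FALSE)
  if (is.null(v_c) || !is.finite(v_c) || v_c <= 0)
    stop("a positive pull velocity v_c is required", call. = FALSE)
  n <- length(x)
  if (n < 3L)
    stop("need at least 3 grid points for the derivative", call. = FALSE)
  d <- numeric(n)
  d[2:(n - 1)] <- (W_diss[3:n] - W_diss[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  d[1L] <- (W_diss[2L] - W_diss[1L]) / (x[2L] - x[1L])
  d[n] <- (W_diss[n] - W_diss[n - 1L]) / (x[n] - x[n - 1L])
  prof <- structure(
    list(x = x, gamma_raw = d / v_c, gamma_smooth = NULL,
         smoothing_sigma = NA_real_, floor = NA_real_,
         temperature = temperature, route = "dissipation"),
    class = "friction_profile")
  smooth_profile(prof, sigma = sigma)
}

#' @export
print.friction_profile <- function(x, ...) {
  g <- x$gamma_smooth
  i <- which.max(g)
  cat(sprintf(
    paste0("<friction_profile (%s): %d points, max %.4g kJ ps/mol/nm^2 at ",
           "x = %.3g nm,\n  smoothing sigma = %g nm, floor = %.3g>\n"),
    x$route, length(x$x), g[i], x$x[i], x$smoothing_sigma, x$floor))
  invisible(x)
}

#' Gaussian-smooth and floor a friction profile
#'
#' Convolves the raw friction with a Gaussian kernel of width `sigma`
#' (reflected boundary handling, so a constant profile is exactly
#' preserved), then floors the result at `1e-3 * median(positive raw
#' values)`: the Langevin noise term requires Gamma > 0 everywhere, and
#' negative raw excursions are statistical noise.
#'
#' @param profile a `friction_profile`.
#' @param sigma kernel standard deviation [nm]; 0 skips smoothing.
#' @return the profile with `gamma_smooth`, `smoothing_sigma` and `floor`
#'   filled in.
#' @export
smooth_profile <- function(profile, sigma = 0.02) {
  stopifnot(inherits(profile, "friction_profile"))
  if (!is.finite(sigma) || sigma < 0)
    stop("smoothing sigma must be >= 0", call. = FALSE)
  g <- profile$gamma_raw
  sm <- if (sigma > 0) .gauss_smooth_reflect(g, profile$x, sigma) else g
  pos <- profile$gamma_raw[profile$gamma_raw > 0]
  floor_val <- if (length(pos)) 1e-3 * stats::median(pos) else 1e-12
  profile$gamma_smooth <- pmax(sm, floor_val)
  profile$smoothing_sigma <- sigma
  profile$floor <- floor_val
  profile
}

.gauss_smooth_reflect <- function(y, x, sigma) {
  n <- length(y)
  dx <- (x[n] - x[1L]) / (n - 1L)
  h <- min(n - 1L, max(1L, ceiling(4 * sigma / dx)))
  k <- stats::dnorm(seq(-h, h) * dx, sd = sigma)
  k <- k / sum(k)
  ypad <- c(y[(h + 1L):2L], y, y[(n - 1L):(n - h)])
  out <- stats::filter(ypad, k, method = "convolution", sides = 2L)
  as.numeric(out[(h + 1L):(h + n)])
}

#' Jackknife standard errors of the profile estimators
#'
#' Leave-one-out recomputation over traces of either the free-energy
#' profile or the (raw, route-specific) friction profile, returning the
#' jackknife standard error at every grid point.
#'
#' @param ensemble a `pulling_ensemble` with N >= 3 traces.
#' @param estimator `"free_energy"` or `"friction"`.
#' @param temperature temperature [K]; defaults to the ensemble's.
#' @param sigma smoothing width for the friction estimator [nm].
#' @return numeric vector of per-grid-point standard errors.
#' @export
jackknife_errors <- function(ensemble,
                             estimator = c("free_energy", "friction"),
                             temperature = NULL, sigma = 0.02) {
  stopifnot(inherits(ensemble, "pulling_ensemble"))
  estimator <- match.arg(estimator)
  if (ensemble$N < 3L)
    stop("jackknife needs at least 3 traces", call. = FALSE)
  if (is.null(temperature)) temperature <- ensemble$temperature
  if (estimator == "free_energy") {
    work <- integrate_work(ensemble)
    return(.jackknife_se_dG(work$W, kB() * temperature, 2))
  }
  N <- ensemble$N
  th_sum <- 0; th_sq <- 0
  for (i in seq_len(N)) {
    sub <- ensemble
    sub$f <- ensemble$f[-i, , drop = FALSE]
    sub$N <- N - 1L
    p <- estimate_friction_autocorr(sub, temperature = temperature,
                                    sigma = sigma)
    th <- p$gamma_smooth
    th_sum <- th_sum + th
    th_sq <- th_sq + th^2
  }
  mbar <- th_sum / N
  sqrt(pmax(0, (N - 1) / N * (th_sq - N * mbar^2)))
}

#' Test the Gaussian-work assumption
#'
#' The cumulant truncation behind the dissipation correction is exact only
#' for Gaussian work distributions. This computes, at every grid point with
#' non-degenerate work variance, the sample skewness, excess kurtosis and a
#' D'Agostino-Pearson-style omnibus normality test of the work values
#' across traces. The global flag fails when more than `max_reject` of the
#' tested points reject at level `alpha`; failure typically indicates
#' multiple unbinding pathways, and the ensemble should be separated by
#' pathway before dcTMD analysis (such separation is outside this package).
#'
#' Work curves at neighbouring grid points are strongly correlated, so a
#' single tail fluctuation can push a contiguous stretch of points past
#' `alpha` even for perfectly Gaussian ensembles; a failed flag on an
#' otherwise unimodal-looking work histogram deserves inspection of
#' `$table` before drastic conclusions.
#'
#' @param work a `work_set` with N >= 8.
#' @param alpha per-point significance level (default 0.01).
#' @param max_reject maximum tolerated rejection fraction (default 0.10).
#' @return an object of class `normality_report`: data.frame `table`
#'   (x, skewness, ex_kurtosis, statistic, p_value), `frac_reject`,
#'   `passed`, `alpha`.
#' @export
check_work_normality <- function(work, alpha = 0.01, max_reject = 0.10) {
  stopifnot(inherits(work, "work_set"))
  N <- work$N
  if (N < 8L)
    stop("normality check needs at least N = 8 traces", call. = FALSE)
  use <- work$var_W > 1e-12 * max(work$var_W)
  W <- work$W[, use, drop = FALSE]
  res <- apply(W, 2L, .dagostino_k2)
  tab <- data.frame(x = work$x[use],
                    skewness = res["skew", ],
                    ex_kurtosis = res["exkurt", ],
                    statistic = res["K2", ],
                    p_value = res["p", ])
  frac <- mean(tab$p_value < alpha)
  structure(list(table = tab, frac_reject = frac,
                 passed = frac <= max_reject, alpha = alpha,
                 max_reject = max_reject, N = N),
            class = "normality_report")
}

#' @export
print.normality_report <- function(x, ...) {
  cat(sprintf(
    paste0("<normality_report: %.1f%% of %d grid points reject Gaussian ",
           "work at alpha = %g -> %s>\n"),
    100 * x$frac_reject, nrow(x$table), x$alpha,
    if (x$passed) "PASS" else "FAIL (consider pathway separation)"))
  invisible(x)
}

# D'Agostino-Pearson omnibus K^2 on one sample (n >= 8):
# Z1 from the skewness transform (D'Agostino 1970), Z2 from the kurtosis
# transform (Anscombe-Glynn 1983); K2 = Z1^2 + Z2^2 ~ chi^2(2).
.dagostino_k2 <- function(v) {
  n <- length(v)
  m <- mean(v)
  m2 <- mean((v - m)^2)
  g1 <- mean((v - m)^3) / m2^1.5
  b2 <- mean((v - m)^4) / m2^2
  # skewness
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(W2))
  a <- sqrt(2 / (W2 - 1))
  Z1 <- delta * asinh(Y / a)
  # kurtosis
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xs <- (b2 - Eb2) / sqrt(Vb2)
  sb <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sb * (2 / sb + sqrt(1 + 4 / sb^2))
  denom <- 1 + xs * sqrt(2 / (A - 4))
  # signed cube root: denom can be negative for strongly platykurtic samples
  term2 <- sign(denom) * abs((1 - 2 / A) / denom)^(1/3)
  Z2 <- ((1 - 2 / (9 * A)) - term2) / sqrt(2 / (9 * A))
  K2 <- Z1^2 + Z2^2
  c(skew = g1, exkurt = b2 - 3, K2 = K2,
    p = stats::pchisq(K2, df = 2, lower.tail = FALSE))
}

#' Fit dissipation-corrected free-energy and friction profiles
#'
#' The central fitting function of the package: from a validated ensemble
#' of constraint-force pulling traces it integrates the per-trace work,
#' applies the second-order-cumulant dissipation correction to obtain the
#' free-energy profile, estimates the friction profile from the running
#' force-fluctuation autocorrelation integral (with Gaussian smoothing and
#' positivity flooring), optionally cross-checks it against the
#' dissipated-work gradient, attaches leave-one-out jackknife errors, and
#' tests the Gaussian-work assumption underlying the whole analysis.
#'
#' @param ensemble a `pulling_ensemble` (see [assemble_ensemble()],
#'   [generate_pulling_ensemble()]).
#' @param temperature temperature [K]; defaults to the ensemble's.
#' @param sigma Gaussian smoothing width for the friction profile [nm].
#' @param friction which friction route(s) to compute: `"autocorr"`
#'   (default), `"both"` (adds the dissipated-work-gradient cross-check),
#'   or `"none"`.
#' @param errors `"jackknife"` (default) or `"none"`; friction jackknife is
#'   only computed with `friction_errors = TRUE` (it is N times as
#'   expensive as a single fit).
#' @param friction_errors logical, jackknife the friction too.
#' @param normality logical, run [check_work_normality()] (needs N >= 8).
#' @return an object of class `dctmd` with components `work`
#'   (`work_set`), `free_energy` (`free_energy_profile`), `friction`
#'   (`friction_profile` or NULL), `friction_dissipation` (cross-check
#'   route or NULL), `normality` (`normality_report` or NULL), and the
#'   ensemble metadata. Methods: `print`, `summary`, `coef`, `plot`,
#'   [as_field_table()].
#' @examples
#' flds <- single_barrier_template(height = 8, gamma = 50)
#' ens <- generate_pulling_ensemble(flds, N = 120, n_samples = 201, seed = 7)
#' fit <- dctmd(ens)
#' coef(fit)
#' @export
dctmd <- function(ensemble, temperature = NULL, sigma = 0.02,
                  friction = c("autocorr", "both", "none"),
                  errors = c("jackknife", "none"),
                  friction_errors = FALSE, normality = TRUE) {
  stopifnot(inherits(ensemble, "pulling_ensemble"))
  friction <- match.arg(friction)
  errors <- match.arg(errors)
  if (is.null(temperature)) temperature <- ensemble$temperature
  work <- integrate_work(ensemble)
  fe <- estimate_free_energy(work, temperature = temperature,
                             errors = errors)
  fr <- NULL; fr_diss <- NULL; fr_se <- NULL
  if (friction %in% c("autocorr", "both")) {
    fr <- estimate_friction_autocorr(ensemble, temperature = temperature,
                                     sigma = sigma)
    if (friction_errors && ensemble$N >= 3L)
      fr_se <- jackknife_errors(ensemble, "friction",
                                temperature = temperature, sigma = sigma)
  }
  if (friction == "both")
    fr_diss <- estimate_friction_from_dissipation(fe, v_c = ensemble$v_c,
                                                  sigma = sigma)
  nr <- NULL
  if (normality && ensemble$N >= 8L) nr <- check_work_normality(work)
  structure(list(work = work, free_energy = fe, friction = fr,
                 friction_dissipation = fr_diss, friction_stderr = fr_se,
                 normality = nr, N = ensemble$N, v_c = ensemble$v_c,
                 dt = ensemble$dt, temperature = temperature,
                 sigma = sigma, call = match.call()),
            class = "dctmd")
}

#' @export
print.dctmd <- function(x, ...) {
  cat("Dissipation-corrected targeted MD fit\n")
  cat(sprintf("  ensemble: N = %d traces, v_c = %g nm/ps, T = %g K\n",
              x$N, x$v_c, x$temperature))
  cf <- coef(x)
  cat(sprintf("  barrier:  dG = %.3g kJ/mol at x = %.3g nm\n",
              cf["dG_barrier"], cf["x_barrier"]))
  cat(sprintf("  endpoint: dG = %.3g kJ/mol, W_diss = %.3g kJ/mol\n",
              cf["dG_end"], cf["W_diss_end"]))
  if (!is.null(x$friction))
    cat(sprintf("  friction: max %.4g kJ ps/mol/nm^2 at x = %.3g nm\n",
                cf["gamma_max"], cf["x_gamma_max"]))
  if (!is.null(x$normality))
    cat(sprintf("  Gaussian-work check: %s (%.1f%% points reject)\n",
                if (x$normality$passed) "pass" else "FAIL",
                100 * x$normality$frac_reject))
  invisible(x)
}

#' Headline numbers of a dcTMD fit
#'
#' @param object a `dctmd` fit.
#' @param ... unused.
#' @return named vector: `dG_barrier` (main barrier height relative to the
#'   bound minimum, kJ/mol), `x_barrier` (nm), `dG_end` (free energy at the
#'   end of the pull relative to its start), `W_diss_end`, and, when a
#'   friction route was computed, `gamma_max` and `x_gamma_max`.
#' @export
coef.dctmd <- function(object, ...) {
  fe <- object$free_energy
  i <- which.max(fe$dG)
  n <- length(fe$x)
  out <- c(dG_barrier = fe$dG[i] - min(fe$dG[seq_len(i)]),
           x_barrier = fe$x[i],
           dG_end = fe$dG[n], W_diss_end = fe$W_diss[n])
  if (!is.null(object$friction)) {
    g <- object$friction$gamma_smooth
    j <- which.max(g)
    out <- c(out, gamma_max = g[j], x_gamma_max = fe$x[j])
  }
  out
}

#' @export
summary.dctmd <- function(object, ...) {
  structure(list(fit = object), class = "summary.dctmd")
}

#' @export
print.summary.dctmd <- function(x, ...) {
  print(x$fit)
  fe <- x$fit$free_energy
  if (!all(is.na(fe$stderr_dG)))
    cat(sprintf("  jackknife stderr of dG: median %.3g, max %.3g kJ/mol\n",
                stats::median(fe$stderr_dG, na.rm = TRUE),
                max(fe$stderr_dG, na.rm = TRUE)))
  if (!is.null(x$fit$friction_dissipation)) {
    a <- x$fit$friction$gamma_smooth
    b <- x$fit$friction_dissipation$gamma_smooth
    cat(sprintf(
      "  friction routes (autocorr vs dissipation): median |diff| = %.3g kJ ps/mol/nm^2\n",
      stats::median(abs(a - b))))
  }
  invisible(x)
}

#' @export
plot.dctmd <- function(x, ...) {
  fe <- x$free_energy
  op <- graphics::par(mfrow = c(if (is.null(x$friction)) 1 else 2, 1),
                      mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::plot(fe$x, fe$mean_W, type = "l", lty = 2,
                 xlab = "x [nm]", ylab = "energy [kJ/mol]",
                 main = "dcTMD profiles", ...)
  graphics::lines(fe$x, fe$dG, col = "blue", lwd = 2)
  if (!all(is.na(fe$stderr_dG))) {
    graphics::lines(fe$x, fe$dG + fe$stderr_dG, col = "lightblue")
    graphics::lines(fe$x, fe$dG - fe$stderr_dG, col = "lightblue")
  }
  graphics::legend("topleft", c("<W>", "dG"), lty = c(2, 1),
                   col = c("black", "blue"), bty = "n")
  if (!is.null(x$friction)) {
    graphics::plot(x$friction$x, x$friction$gamma_raw, type = "l",
                   col = "grey", xlab = "x [nm]",
                   ylab = "Gamma [kJ ps/mol/nm^2]")
    graphics::lines(x$friction$x, x$friction$gamma_smooth, col = "red",
                    lwd = 2)
    graphics::legend("topright", c("raw", "smoothed"), lty = 1,
                     col = c("grey", "red"), bty = "n")
  }
  invisible(x)
}

#' Export a dcTMD fit as a tabulated field profile
#'
#' @param fit a `dctmd` object (fitted with a friction route).
#' @return a [field_table()] carrying dG, smoothed gamma and available
#'   standard errors, ready for [write_field_table()] or
#'   [langevin_fields()].
#' @export
as_field_table <- function(fit) {
  stopifnot(inherits(fit, "dctmd"))
  if (is.null(fit$friction))
    stop("fit was computed with friction = \"none\"", call. = FALSE)
  fe <- fit$free_energy
  field_table(fe$x, fe$dG - fe$dG[1L], fit$friction$gamma_smooth,
              err_dG = if (!all(is.na(fe$stderr_dG))) fe$stderr_dG,
              err_gamma = fit$friction_stderr)
}
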