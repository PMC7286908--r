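# Temperature boosting: ladders of high-temperature Langevin runs on fields
# computed at the target temperature, Arrhenius-type fits in (beta, ln k)
# space, and extrapolation back to the target temperature.
#
# Because temperature enters the Langevin equation only through the noise
# term, rates at two temperatures on the *same* fields obey the
# Kramers-type relation k2 = k1 * exp(-dG_dagger * (beta2 - beta1)), with
# dG_dagger the transition-state energy. Simulating where events are
# frequent and extrapolating down in beta reaches rates that are
# inaccessible by direct simulation.

#' Run a temperature ladder of Langevin simulations
#'
#' Propagates the same fields at each ladder temperature with independent
#' seeds and collects per-channel rate points. Temperatures that produce no
#' events in a channel are dropped from that channel with a warning.
#'
#' @param fields a [langevin_fields()] computed at the target temperature.
#' @param config a [sim_config()] template; `n_steps` is derived from
#'   `time_per_T` and the (possibly mass-boosted) step. Runs use seeds
#'   `config$seed + 1, + 2, ...`.
#' @param temperatures ladder temperatures [K] (>= 3). Practical guidance:
#'   increments of 25-50 K, choosing the smallest ladder such that >~ 100
#'   transitions occur per temperature.
#' @param time_per_T simulated time per temperature [ps].
#' @param C_sim reference concentration [M] for association rates.
#' @param boosted use [propagate_overdamped_boosted()] (honours
#'   `config$mass_scale`) instead of [propagate()].
#' @return an object of class `boost_points`: a data.frame with columns
#'   `temperature`, `beta` [mol/kJ], `channel` ("D"/"A"), `k` [s^-1 or
#'   s^-1 M^-1], `n_events`, `se_lnk`.
#' @export
run_ladder <- function(fields, config, temperatures, time_per_T,
                       C_sim = 1, boosted = FALSE) {
  stopifnot(inherits(fields, "langevin_fields"),
            inherits(config, "sim_config"))
  temperatures <- sort(as.numeric(temperatures))
  if (length(temperatures) < 3L)
    stop("a temperature ladder needs at least 3 temperatures", call. = FALSE)
  rows <- list()
  for (i in seq_along(temperatures)) {
    T2 <- temperatures[i]
    cfg <- config
    cfg$seed <- as.integer(config$seed + i)
    cfg$n_steps <- max(1, round(time_per_T / cfg$dt))
    cfg$record_trajectory <- FALSE
    traj <- if (boosted)
      propagate_overdamped_boosted(fields, cfg, temperature = T2)
    else propagate(fields, cfg, temperature = T2)
    rec <- traj$events
    for (ch in c("D", "A")) {
      n <- if (ch == "D") rec$n_D else rec$n_A
      tau <- if (ch == "D") rec$tau_D else rec$tau_A
      if (n < 1L) {
        warning(sprintf("no %s events at T2 = %g K; point dropped",
                        c(D = "dissociation", A = "association")[ch], T2),
                call. = FALSE)
        next
      }
      k <- .PS_TO_S / mean(tau)
      if (ch == "A") k <- k / C_sim
      rows[[length(rows) + 1L]] <- data.frame(
        temperature = T2, beta = 1 / (kB() * T2), channel = ch,
        k = k, n_events = n, se_lnk = 1 / sqrt(n))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "C_sim") <- C_sim
  attr(out, "fields_temperature") <- fields$temperature
  class(out) <- c("boost_points", "data.frame")
  out
}

#' Fit the temperature-boosting relation and extrapolate
#'
#' Weighted least squares of `ln k` on inverse temperature
#' `beta = 1/(kB T)`, with weights equal to the event counts (Poisson
#' counting gives `var(ln k) ~ 1/n`). The slope is `-dG_dagger`
#' (transition-state energy, kJ/mol); the extrapolated rate at the target
#' temperature is `k1 = exp(intercept - dG_dagger * beta1)`, with its
#' confidence interval from the fit covariance by the delta method.
#'
#' @param points a `boost_points` data.frame (or any data.frame with
#'   columns `temperature`, `k`, `n_events`).
#' @param T1 target temperature [K].
#' @param channel which channel to fit ("D" or "A"); ignored when `points`
#'   has no `channel` column.
#' @return an object of class `boost_fit`: `coefficients` (intercept,
#'   slope), `dG_dagger`, `k1`, `se_lnk1`, `ci95_k1`, `r_squared`, `cov`,
#'   `T1`, `beta1`, `points`, `channel`. Methods: `print`, `coef`,
#'   `predict`, `confint`.
#' @export
fit_boost <- function(points, T1, channel = c("D", "A")) {
  channel <- match.arg(channel)
  pts <- as.data.frame(points)
  if ("channel" %in% names(pts)) pts <- pts[pts$channel == channel, ]
  need <- c("temperature", "k", "n_events")
  if (!all(need %in% names(pts)))
    stop("points must have columns temperature, k, n_events", call. = FALSE)
  pts <- pts[is.finite(pts$k) & pts$k > 0 & pts$n_events >= 1, ]
  if (nrow(pts) < 3L)
    stop("ladder too sparse: need at least 3 usable rate points",
         call. = FALSE)
  if (anyDuplicated(pts$temperature))
    stop("duplicate ladder temperatures give a rank-deficient fit",
         call. = FALSE)
  if (!is.finite(T1) || T1 <= 0) stop("T1 must be positive", call. = FALSE)
  beta <- 1 / (kB() * pts$temperature)
  y <- log(pts$k)
  w <- pts$n_events
  X <- cbind(intercept = 1, beta = beta)
  XtWX <- crossprod(X, w * X)
  if (rcond(XtWX) < 1e-12)
    stop("ladder temperatures are collinear; cannot fit", call. = FALSE)
  cov <- solve(XtWX)              # var(ln k) = 1/n assumed known
  cf <- drop(cov %*% crossprod(X, w * y))
  names(cf) <- c("intercept", "slope")
  fitted <- drop(X %*% cf)
  ybar <- sum(w * y) / sum(w)
  r2 <- 1 - sum(w * (y - fitted)^2) / sum(w * (y - ybar)^2)
  beta1 <- 1 / (kB() * T1)
  lnk1 <- cf["intercept"] + cf["slope"] * beta1
  v <- c(1, beta1)
  se_lnk1 <- sqrt(drop(t(v) %*% cov %*% v))
  structure(list(coefficients = cf, dG_dagger = -cf[["slope"]],
                 k1 = exp(unname(lnk1)), se_lnk1 = se_lnk1,
                 ci95_k1 = exp(unname(lnk1) + c(-1, 1) * 1.96 * se_lnk1),
                 r_squared = r2, cov = cov, T1 = T1, beta1 = beta1,
                 points = pts, channel = channel,
                 C_sim = attr(points, "C_sim")),
            class = "boost_fit")
}

#' @export
print.boost_fit <- function(x, ...) {
  unit <- if (x$channel == "A") "s^-1 M^-1" else "s^-1"
  cat(sprintf("Temperature-boosting fit (channel %s, %d ladder points)\n",
              x$channel, nrow(x$points)))
  cat(sprintf("  dG_dagger = %.4g kJ/mol, R^2 = %.4f\n",
              x$dG_dagger, x$r_squared))
  cat(sprintf("  k(T1 = %g K) = %.4g %s  (95%% CI %.3g - %.3g)\n",
              x$T1, x$k1, unit, x$ci95_k1[1], x$ci95_k1[2]))
  invisible(x)
}

#' @export
coef.boost_fit <- function(object, ...) object$coefficients

#' @export
confint.boost_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  exp(log(object$k1) + c(-1, 1) * z * object$se_lnk1)
}

#' Predict boosted rates at new temperatures
#'
#' @param object a `boost_fit`.
#' @param temperature temperatures [K] at which to evaluate the fitted
#'   Arrhenius line; default the target temperature `T1`.
#' @param ... unused.
#' @return named numeric vector of rates (same units as the fitted points).
#' @export
predict.boost_fit <- function(object, temperature = object$T1, ...) {
  beta <- 1 / (kB() * temperature)
  k <- exp(object$coefficients[["intercept"]] +
             object$coefficients[["slope"]] * beta)
  stats::setNames(k, as.character(temperature))
}

#' Extrapolation-error budget of a boosting fit
#'
#' Relative standard error of the extrapolated rate `k1` by the delta
#' method: `var(ln k1) = var(a) + beta1^2 var(b) + 2 beta1 cov(a, b)` from
#' the fit covariance. Also reports how many events per ladder temperature
#' would bring the error below `target` (error scales as n^(-1/2)).
#'
#' @param fit a `boost_fit`.
#' @param target desired relative error (default 0.10).
#' @return list: `rel_error`, `target`, `n_per_T_current` (mean),
#'   `n_per_T_needed`, `meets_target`.
#' @export
extrapolation_error <- function(fit, target = 0.10) {
  stopifnot(inherits(fit, "boost_fit"))
  rel <- fit$se_lnk1        # se of ln k ~ relative se of k for small errors
  n_cur <- mean(fit$points$n_events)
  n_need <- if (rel > target) ceiling(n_cur * (rel / target)^2) else n_cur
  list(rel_error = unname(rel), target = target,
       n_per_T_current = n_cur, n_per_T_needed = n_need,
       meets_target = rel < target)
}

#' Express a rate ratio as a free-energy difference
#'
#' A factor `r` between two rates corresponds to a free-energy difference
#' of `ln(r)` in thermal units (kB T); e.g. a factor 20 is about 3 kB T.
#'
#' @param rate_ratio positive ratio of two rates.
#' @return free-energy difference in units of kB T.
#' @export
ratio_in_kT <- function(rate_ratio) {
  if (any(!is.finite(rate_ratio)) || any(rate_ratio <= 0))
    stop("rate ratio must be positive", call. = FALSE)
  log(rate_ratio)
}
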