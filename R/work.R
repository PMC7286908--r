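# Work integration along the pulled coordinate.

new_work_set <- function(x, W, temperature, v_c, dt) {
  N <- nrow(W)
  mean_W <- colMeans(W)
  var_W <- (colSums(W * W) - N * mean_W^2) / (N - 1)
  var_W[var_W < 0] <- 0   # numerical round-off at the anchored origin
  structure(list(x = x, W = W, mean_W = mean_W, var_W = var_W,
                 N = N, temperature = temperature, v_c = v_c, dt = dt),
            class = "work_set")
}

#' @export
print.work_set <- function(x, ...) {
  cat(sprintf(
    "<work_set: N = %d work curves on %d grid points, <W>(end) = %.4g kJ/mol, var W(end) = %.4g (kJ/mol)^2>\n",
    x$N, length(x$x), x$mean_W[length(x$mean_W)], x$var_W[length(x$var_W)]))
  invisible(x)
}

#' Integrate per-trace pulling work
#'
#' Computes the external work `W_i(x) = int_{x0}^{x} f_c,i dx'` for every
#' trace by the trapezoidal rule on the uniform position grid, together with
#' the ensemble mean and unbiased (N - 1) variance at each grid point. All
#' work curves are zero at the start position.
#'
#' @param ensemble a `pulling_ensemble` (see [assemble_ensemble()]).
#' @return an object of class `work_set` with elements `x`, `W`
#'   (N x n matrix), `mean_W`, `var_W`, `N`, `temperature`, `v_c`, `dt`.
#' @export
integrate_work <- function(ensemble) {
  stopifnot(inherits(ensemble, "pulling_ensemble"))
  f <- ensemble$f
  dx <- ensemble$v_c * ensemble$dt
  cs <- t(apply(f, 1L, cumsum))
  W <- dx * (cs - 0.5 * f - 0.5 * f[, 1L])
  W[, 1L] <- 0
  new_work_set(x = positions(ensemble), W = W,
               temperature = ensemble$temperature,
               v_c = ensemble$v_c, dt = ensemble$dt)
}
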