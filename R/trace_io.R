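# Reading/writing constraint-force traces and tabulated field profiles,
# and assembly of validated pulling ensembles.

#' Construct a pulling trace
#'
#' A pulling trace holds the constraint force f_c sampled uniformly in time
#' during a constant-velocity constrained pull x(t) = x0 + v_c * t. The
#' implied position grid is x_i = x0 + v_c * (i - 1) * dt, computed
#' multiplicatively so it carries no accumulated drift.
#'
#' Sign convention: f_c is the force exerted on the system along +x, so the
#' external work W = integral of f_c dx is positive for uphill pulling.
#'
#' @param f numeric vector of constraint-force samples [kJ mol^-1 nm^-1].
#' @param dt sampling interval [ps].
#' @param v_c pull velocity [nm/ps].
#' @param x0 start position [nm].
#' @param temperature simulation temperature [K].
#' @param run_id text label identifying the run.
#' @return an object of class `pulling_trace`.
#' @export
pulling_trace <- function(f, dt, v_c, x0 = 0, temperature = 300,
                          run_id = "run") {
  f <- as.numeric(f)
  if (length(f) < 2L)
    stop("pulling trace needs at least 2 force samples", call. = FALSE)
  if (!all(is.finite(f)))
    stop("non-finite force samples in trace '", run_id, "'", call. = FALSE)
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (!is.finite(v_c) || v_c <= 0) stop("v_c must be > 0", call. = FALSE)
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be > 0", call. = FALSE)
  structure(
    list(run_id = as.character(run_id), f = f, dt = dt, v_c = v_c,
         x0 = x0, temperature = temperature),
    class = "pulling_trace")
}

#' @export
print.pulling_trace <- function(x, ...) {
  cat(sprintf(
    "<pulling_trace '%s': %d samples, dt = %g ps, v_c = %g nm/ps, x0 = %g nm, T = %g K>\n",
    x$run_id, length(x$f), x$dt, x$v_c, x$x0, x$temperature))
  invisible(x)
}

#' Position grid of a pulling trace or ensemble
#'
#' @param object a `pulling_trace` or `pulling_ensemble`.
#' @return numeric vector x_i = x0 + v_c * (i - 1) * dt [nm].
#' @export
positions <- function(object) UseMethod("positions")

#' @export
positions.pulling_trace <- function(object) {
  object$x0 + object$v_c * object$dt * (seq_along(object$f) - 1L)
}

#' @export
positions.pulling_ensemble <- function(object) {
  object$x0 + object$v_c * object$dt * (seq_len(object$n_samples) - 1L)
}

#' Read a constraint-force trace from an XVG-like text file
#'
#' The file must contain whitespace-separated columns; lines starting with
#' `#` or `@` are treated as comments (the XVG dialect). With two or more
#' columns the first is time [ps] and the second the constraint force; the
#' time column must match the stated `dt` to within 1e-6 ps. A one-column
#' file is read as forces only.
#'
#' @param path file to read.
#' @param dt sampling interval [ps].
#' @param v_c pull velocity [nm/ps].
#' @param x0 start position [nm].
#' @param temperature temperature [K].
#' @param run_id label; defaults to the file name.
#' @param skip_initial_ps drop samples with t < `skip_initial_ps` (the
#'   pre-equilibration stretch at x0, if any); the origin x0 is shifted
#'   accordingly. Default 0.
#' @return a [pulling_trace()].
#' @export
read_trace <- function(path, dt, v_c, x0 = 0, temperature = 300,
                       run_id = NULL, skip_initial_ps = 0) {
  if (is.null(run_id)) run_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*[#@]", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop("empty trace file: ", path, call. = FALSE)
  con <- textConnection(lines)
  on.exit(close(con))
  tab <- tryCatch(
    utils::read.table(con, header = FALSE, colClasses = "numeric"),
    error = function(e)
      stop("non-numeric payload in trace file ", path, ": ",
           conditionMessage(e), call. = FALSE))
  if (ncol(tab) >= 2L) {
    t_col <- tab[[1L]]
    f <- tab[[2L]]
    n <- length(t_col)
    expected <- t_col[1L] + dt * (seq_len(n) - 1L)
    if (n >= 2L && max(abs(t_col - expected)) > 1e-6)
      stop("non-uniform time grid in ", path,
           " (does not match dt = ", dt, " ps within 1e-6 ps)",
           call. = FALSE)
  } else {
    f <- tab[[1L]]
  }
  if (skip_initial_ps > 0) {
    n_skip <- floor(skip_initial_ps / dt + 1e-9)
    if (n_skip >= length(f) - 1L)
      stop("skip_initial_ps removes the whole trace", call. = FALSE)
    f <- f[-seq_len(n_skip)]
    x0 <- x0 + v_c * dt * n_skip
  }
  pulling_trace(f, dt = dt, v_c = v_c, x0 = x0,
                temperature = temperature, run_id = run_id)
}

#' Write a pulling trace to an XVG-like text file
#'
#' @param trace a [pulling_trace()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "pulling_trace"))
  hdr <- c(
    "# constraint-force pulling trace",
    sprintf("# run_id: %s", trace$run_id),
    sprintf("# dt_ps: %.12g  v_c_nm_per_ps: %.12g  x0_nm: %.12g  temperature_K: %.12g",
            trace$dt, trace$v_c, trace$x0, trace$temperature),
    "# sign convention: f_c acts on the system along +x; W = int f_c dx",
    "# columns: time[ps] force[kJ/mol/nm]")
  tt <- trace$dt * (seq_along(trace$f) - 1L)
  body <- sprintf("%.12g %.12g", tt, trace$f)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Assemble pulling traces into a validated ensemble
#'
#' All traces must share dt, v_c, x0, temperature and length: the ensemble
#' average of the dissipation-corrected work analysis is taken over runs on
#' a common time/position grid. Fewer than ~100 runs gives poorly converged
#' friction estimates; reliable field estimates (errors below about 1 kBT)
#' typically need at least 500 runs, so a warning is emitted for N < 100.
#'
#' @param traces a list of [pulling_trace()] objects (at least 2).
#' @return an object of class `pulling_ensemble` with the force matrix `f`
#'   (N runs x n_samples) and the shared grid metadata.
#' @export
assemble_ensemble <- function(traces) {
  if (inherits(traces, "pulling_trace")) traces <- list(traces)
  if (length(traces) < 2L)
    stop("an ensemble needs at least 2 traces (variance undefined otherwise)",
         call. = FALSE)
  ok <- vapply(traces, inherits, logical(1), "pulling_trace")
  if (!all(ok)) stop("all elements must be pulling_trace objects", call. = FALSE)
  ref <- traces[[1L]]
  for (tr in traces[-1L]) {
    for (fld in c("dt", "v_c", "x0", "temperature")) {
      if (!isTRUE(all.equal(tr[[fld]], ref[[fld]], tolerance = 1e-12)))
        stop("trace '", tr$run_id, "' has incompatible ", fld,
             " (", tr[[fld]], " vs ", ref[[fld]], ")", call. = FALSE)
    }
    if (length(tr$f) != length(ref$f))
      stop("trace '", tr$run_id, "' has incompatible length (",
           length(tr$f), " vs ", length(ref$f), ")", call. = FALSE)
  }
  n <- length(traces)
  if (n < 100L)
    warning("ensemble has only N = ", n, " runs; friction and free-energy ",
            "estimates converge slowly (at least 500 runs recommended for ",
            "errors below ~1 kBT)", call. = FALSE)
  f <- do.call(rbind, lapply(traces, `[[`, "f"))
  rownames(f) <- vapply(traces, `[[`, character(1), "run_id")
  structure(
    list(f = f, N = n, n_samples = ncol(f), dt = ref$dt, v_c = ref$v_c,
         x0 = ref$x0, temperature = ref$temperature),
    class = "pulling_ensemble")
}

#' @export
print.pulling_ensemble <- function(x, ...) {
  xg <- positions(x)
  cat(sprintf(
    paste0("<pulling_ensemble: N = %d runs, %d samples each, dt = %g ps,\n",
           "  v_c = %g nm/ps, x in [%.4g, %.4g] nm, T = %g K>\n"),
    x$N, x$n_samples, x$dt, x$v_c, min(xg), max(xg), x$temperature))
  invisible(x)
}

#' Construct a tabulated field profile
#'
#' A field table carries the free-energy profile dG(x) and friction profile
#' gamma(x) on a common strictly increasing position grid, plus optional
#' per-point standard errors. The free energy is anchored at dG(x[1]) = 0.
#'
#' @param x strictly increasing position grid [nm].
#' @param dG free energy [kJ/mol]; `dG[1]` must be 0 (it is re-anchored with
#'   a warning otherwise).
#' @param gamma friction [kJ ps mol^-1 nm^-2].
#' @param err_dG,err_gamma optional standard errors.
#' @return an object of class `field_table` (a data.frame).
#' @export
field_table <- function(x, dG, gamma, err_dG = NULL, err_gamma = NULL) {
  x <- as.numeric(x); dG <- as.numeric(dG); gamma <- as.numeric(gamma)
  n <- length(x)
  if (length(dG) != n || length(gamma) != n)
    stop("x, dG, gamma must have equal length", call. = FALSE)
  if (n < 2L) stop("field table needs at least 2 grid points", call. = FALSE)
  if (any(diff(x) <= 0))
    stop("position grid x must be strictly increasing", call. = FALSE)
  if (abs(dG[1L]) > 1e-9) {
    warning("dG not anchored at 0 at the first grid point; re-anchoring",
            call. = FALSE)
    dG <- dG - dG[1L]
  }
  out <- data.frame(x = x, dG = dG, gamma = gamma)
  if (!is.null(err_dG)) {
    stopifnot(length(err_dG) == n)
    out$err_dG <- as.numeric(err_dG)
  }
  if (!is.null(err_gamma)) {
    stopifnot(length(err_gamma) == n)
    out$err_gamma <- as.numeric(err_gamma)
  }
  class(out) <- c("field_table", "data.frame")
  out
}

#' Write a field table to a plain-text file
#'
#' Columns are x, dG, gamma and, when present, err_dG and err_gamma,
#' whitespace-separated, preceded by '#'-prefixed header lines recording
#' units and provenance. Round-trip through [read_field_table()] is lossless
#' to 12 significant digits.
#'
#' @param table a [field_table()].
#' @param path output file.
#' @param provenance optional character lines added to the header.
#' @return `path`, invisibly.
#' @export
write_field_table <- function(table, path, provenance = NULL) {
  stopifnot(inherits(table, "field_table"))
  cols <- intersect(c("x", "dG", "gamma", "err_dG", "err_gamma"),
                    names(table))
  hdr <- c("# free-energy and friction profile",
           "# units: nm kJ/mol kJ*ps/mol/nm^2",
           sprintf("# columns: %s", paste(cols, collapse = " ")))
  if (!is.null(provenance)) hdr <- c(hdr, paste("#", provenance))
  body <- do.call(sprintf, c(
    list(paste(rep("%.12g", length(cols)), collapse = " ")),
    lapply(cols, function(cc) table[[cc]])))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a field table written by [write_field_table()]
#'
#' @param path file to read.
#' @return a [field_table()].
#' @export
read_field_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[grepl("^\\s*#", lines)]
  cols <- c("x", "dG", "gamma")
  cl <- grep("^#\\s*columns:", hdr, value = TRUE)
  if (length(cl))
    cols <- strsplit(trimws(sub("^#\\s*columns:", "", cl[1L])), "\\s+")[[1L]]
  lines <- lines[!grepl("^\\s*[#@]", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty field-table file: ", path, call. = FALSE)
  con <- textConnection(lines)
  on.exit(close(con))
  tab <- utils::read.table(con, header = FALSE, colClasses = "numeric")
  if (ncol(tab) < 3L)
    stop("field table needs at least 3 columns (x dG gamma)", call. = FALSE)
  names(tab)[seq_along(cols)] <- cols[seq_len(min(length(cols), ncol(tab)))]
  if (any(diff(tab$x) <= 0))
    stop("non-monotone position grid in ", path, call. = FALSE)
  field_table(tab$x, tab$dG, tab$gamma,
              err_dG = if ("err_dG" %in% names(tab)) tab$err_dG,
              err_gamma = if ("err_gamma" %in% names(tab)) tab$err_gamma)
}
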