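#' Integrate a tumour-therapy system over a treatment course
#'
#' Solves the coupled compartment-plus-drug system with a stiff-capable
#' adaptive integrator. Integration is segmented at every dosing switch time
#' (`t_start + j * T/2` and the course end), restarting the solver at each
#' boundary so the discontinuous infusion input never crosses an adaptive
#' step. Reported abundances are clamped at zero (tiny negative undershoots
#' within tolerance are a solver artefact, the solver state itself is left
#' untouched).
#'
#' @param model `"ihom"` or `"ihem"`.
#' @param mode Therapy mode; must match `protocol$mode`.
#' @param init Named initial state. Compartments of the model (missing ones
#'   default to 0) and optionally `M`, `B`.
#' @param params A [model_params()] set with `d` set.
#' @param protocol A [therapy_protocol()].
#' @param horizon Final time in days (> 0).
#' @param sample_dt Spacing of the uniform output grid in days; switch times
#'   are always included as extra samples.
#' @param rtol,atol Relative/absolute solver tolerances. Populations span
#'   1 to 1e8 under the default competition rate, hence the tight defaults.
#' @param method A [deSolve::ode()] method name.
#' @param stop_at_cure If `TRUE`, stop (via root finding) once the total
#'   population first drops below `cure_threshold`.
#' @param cure_threshold Total population treated as extinction (default 1
#'   cell; sub-unity abundance is non-physical).
#' @return A `chemoicb_trajectory`: a data frame with columns `time`, the
#'   compartments, `M`, `B`, `total`, carrying `model`, `mode`, `params`,
#'   `protocol` as attributes.
#' @examples
#' p <- model_params(d = 1)
#' tr <- integrate_protocol("ihom", "none", c(N = 1), p,
#'                          therapy_protocol("none"), horizon = 10)
#' tail(tr, 2)
#' @export
integrate_protocol <- function(model = c("ihom", "ihem"),
                               mode = c("none", "icb", "chemo",
                                        "combo_concurrent", "combo_alternating"),
                               init, params, protocol, horizon,
                               sample_dt = 0.5, rtol = 1e-8, atol = 1e-10,
                               method = "lsoda", stop_at_cure = FALSE,
                               cure_threshold = 1) {
  model <- match.arg(model)
  mode <- match.arg(mode)
  p <- as_params(params)
  if (is.na(p$d)) stop("parameter 'd' must be set for dynamics")
  protocol <- as_protocol(protocol)
  if (protocol$mode != mode)
    stop("protocol mode '", protocol$mode, "' does not match 'mode'")
  if (!is.finite(horizon) || horizon <= 0) stop("'horizon' must be > 0")

  comp <- if (model == "ihom") c("N", "I", "E") else c("N", "A", "I", "E")
  vars <- c(comp, "M", "B")
  y0 <- stats::setNames(numeric(length(vars)), vars)
  if (is.null(names(init)) && length(init) > 0)
    stop("'init' must be a named vector")
  bad <- setdiff(names(init), vars)
  if (length(bad) > 0) stop("unknown state component(s): ",
                            paste(bad, collapse = ", "))
  y0[names(init)] <- init
  if (any(y0 < 0)) stop("initial state must be non-negative")

  ncomp <- length(comp)
  func <- function(t, y, parms) list(treated_core(model, mode, y, t, p, protocol))
  root <- if (stop_at_cure)
    function(t, y, parms) sum(y[seq_len(ncomp)]) - cure_threshold
  else NULL

  sw <- switch_times(protocol, horizon)
  bounds <- sort(unique(c(0, sw[sw > 0 & sw < horizon], horizon)))
  grid <- seq(0, horizon, by = sample_dt)

  rows <- vector("list", length(bounds) - 1L)
  y <- y0
  stopped <- FALSE
  for (i in seq_len(length(bounds) - 1L)) {
    t0 <- bounds[i]; t1 <- bounds[i + 1L]
    times <- sort(unique(c(t0, grid[grid > t0 & grid < t1], t1)))
    sol <- tryCatch(
      if (is.null(root))
        deSolve::ode(y, times, func, parms = NULL, method = method,
                     rtol = rtol, atol = atol)
      else
        deSolve::lsodar(y, times, func, parms = NULL,
                        rtol = rtol, atol = atol, rootfunc = root),
      warning = function(w) stop("integrator failed near t = ", t0, ": ",
                                 conditionMessage(w), call. = FALSE))
    m <- unclass(sol)
    rows[[i]] <- m[if (i == 1L) TRUE else -1L, , drop = FALSE]
    y <- m[nrow(m), -1L]
    if (!is.null(root) && !is.null(attr(sol, "troot"))) {
      stopped <- TRUE
      break
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  traj <- as.data.frame(out)
  names(traj) <- c("time", vars)
  for (v in comp) traj[[v]] <- pmax(traj[[v]], 0)
  traj$total <- rowSums(traj[, comp, drop = FALSE])
  structure(traj, model = model, mode = mode, params = p,
            protocol = protocol, cured = stopped,
            class = c("chemoicb_trajectory", "data.frame"))
}

#' Grow an untreated tumour until it crosses a detection threshold
#'
#' Integrates the untreated model from a small seed until the total
#' population first reaches `threshold` (root finding), mimicking clinical
#' detection before therapy begins.
#'
#' @inheritParams integrate_protocol
#' @param threshold Detection size in cells; default half of the escaped
#'   carrying capacity `r2 / c`.
#' @param t_max Hard cap on the growth phase in days.
#' @return A list with `time` (detection time), `state` (named compartment
#'   vector at detection) and `trajectory` (the growth curve).
#' @export
grow_to_detection <- function(model, params, init = c(N = 1),
                              threshold = NULL, t_max = 2000,
                              sample_dt = 0.5, rtol = 1e-8, atol = 1e-10) {
  model <- match_model(model)
  p <- as_params(params)
  if (is.null(threshold)) threshold <- 0.5 * p$r2 / p$c
  comp <- if (model == "ihom") c("N", "I", "E") else c("N", "A", "I", "E")
  vars <- c(comp, "M", "B")
  y0 <- stats::setNames(numeric(length(vars)), vars)
  y0[names(init)] <- init
  none <- therapy_protocol("none")
  ncomp <- length(comp)
  func <- function(t, y, parms) list(treated_core(model, "none", y, t, p, none))
  root <- function(t, y, parms) sum(y[seq_len(ncomp)]) - threshold
  times <- seq(0, t_max, by = sample_dt)
  sol <- deSolve::lsodar(y0, times, func, parms = NULL, rtol = rtol,
                         atol = atol, rootfunc = root)
  troot <- attr(sol, "troot")
  if (is.null(troot) || length(troot) == 0)
    stop("tumour did not reach the detection threshold ", threshold,
         " within ", t_max, " days")
  m <- unclass(sol)
  traj <- as.data.frame(m)
  names(traj) <- c("time", vars)
  traj$total <- rowSums(traj[, comp, drop = FALSE])
  list(time = as.numeric(troot),
       state = stats::setNames(as.numeric(m[nrow(m), -1L]), vars)[comp],
       trajectory = traj)
}

#' Quasi-equilibrium compartment fractions across immune-killing strengths
#'
#' For each immune death rate `d`, integrates the heterogeneity model (with
#' immune escape switched off, the growth-study setting) to quasi-equilibrium
#' and reports the antigenic and immunogenic fractions of the population.
#' Quasi-equilibrium is declared when the relative change of every compartment
#' falls below `tol` per day; runs hitting the horizon cap first are flagged.
#'
#' @param params A [model_params()] set (its `d` and `pe` are overridden).
#' @param d_values Numeric vector of immune death rates to scan.
#' @param pe Escape rate used for the scan; 0 by default (equilibria of the
#'   pre-escape tumour).
#' @param tol Per-day relative-change threshold declaring equilibrium.
#' @param t_cap Hard horizon cap in days.
#' @param chunk Days integrated between convergence checks.
#' @param init Initial state (default a single neutral cell).
#' @param ... Passed to [integrate_protocol()] (tolerances, method).
#' @return A data frame with columns `d`, `fraction_AC`, `fraction_IC`,
#'   `total`, `t_eq`, `converged`.
#' @export
equilibrium_fractions <- function(params, d_values, pe = 0, tol = 1e-8,
                                  t_cap = 3000, chunk = 100,
                                  init = c(N = 1), ...) {
  p0 <- as_params(params)
  res <- lapply(d_values, function(dv) {
    p <- update_params(p0, d = dv, pe = pe)
    none <- therapy_protocol("none")
    y <- c(N = 0, A = 0, I = 0, E = 0, M = 0, B = 0)
    y[names(init)] <- init
    t_now <- 0
    converged <- FALSE
    while (t_now < t_cap) {
      tr <- integrate_protocol("ihem", "none",
                               init = y, params = p, protocol = none,
                               horizon = chunk, sample_dt = chunk, ...)
      y_new <- unlist(tr[nrow(tr), c("N", "A", "I", "E", "M", "B")])
      names(y_new) <- c("N", "A", "I", "E", "M", "B")
      rel <- abs(y_new[1:4] - y[1:4]) / pmax(abs(y[1:4]), 1)
      t_now <- t_now + chunk
      y <- y_new
      if (max(rel) / chunk < tol) {
        converged <- TRUE
        break
      }
    }
    tot <- sum(y[c("N", "A", "I", "E")])
    data.frame(d = dv,
               fraction_AC = if (tot > 0) y[["A"]] / tot else 0,
               fraction_IC = if (tot > 0) y[["I"]] / tot else 0,
               total = tot, t_eq = t_now, converged = converged)
  })
  do.call(rbind, res)
}

#' @export
print.chemoicb_trajectory <- function(x, ...) {
  cat("<chemoicb_trajectory> model=", attr(x, "model"),
      " mode=", attr(x, "mode"),
      " t=[", min(x$time), ", ", max(x$time), "]d",
      " n=", nrow(x), "\n", sep = "")
  NextMethod()
}

## total population at time t (linear interpolation on the sample grid)
total_at <- function(traj, t) {
  stats::approx(traj$time, traj$total, xout = t, rule = 2)$y
}
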