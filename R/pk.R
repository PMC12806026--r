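#' Treatment cycle length
#'
#' The cycle period implied by a treatment frequency coefficient,
#' \eqn{T = 2\pi / f}.
#'
#' @param f Frequency coefficient in radians per day; must be positive.
#' @return Cycle length in days.
#' @examples
#' cycle_period(2 * pi / 21)  # 21-day standard cycle
#' @export
cycle_period <- function(f) {
  if (any(!is.finite(f)) || any(f <= 0)) stop("'f' must be > 0")
  2 * pi / f
}

#' Instantaneous drug infusion rates
#'
#' Evaluates the square-wave infusion schedule of a protocol at time `t`.
#' Infusion is on while \eqn{\sin(f (t - t_{start})) > 0} (the first
#' half-cycle); the positive-part sign function is zero at zero, so the exact
#' switch instants deliver nothing. In the alternating mode the ICB infusion
#' instead occupies the second half-cycle
#' (\eqn{\sin(f (t - t_{start})) < 0}). Outside the treatment course (before
#' `t_start` or after `n_cycles` full cycles) both rates are zero, and
#' single-drug modes force the other drug's rate to zero.
#'
#' @param t Time(s) in days; vectorised.
#' @param protocol A [therapy_protocol()].
#' @return A two-column matrix `cbind(vm = ..., vb = ...)` of infusion rates.
#' @export
dose_rate <- function(t, protocol) {
  protocol <- as_protocol(protocol)
  if (any(t < 0)) stop("'t' must be >= 0")
  vm_t <- numeric(length(t))
  vb_t <- numeric(length(t))
  if (protocol$mode != "none" && protocol$n_cycles > 0) {
    tt <- t - protocol$t_start
    active <- tt >= 0 & tt < protocol$n_cycles * protocol$period_days
    s <- sin(protocol$f * tt)
    first_half <- active & s > 0
    second_half <- active & s < 0
    switch(protocol$mode,
      icb = {
        vb_t[first_half] <- protocol$vb
      },
      chemo = {
        vm_t[first_half] <- protocol$vm
      },
      combo_concurrent = {
        vm_t[first_half] <- protocol$vm
        vb_t[first_half] <- protocol$vb
      },
      combo_alternating = {
        vm_t[first_half] <- protocol$vm
        vb_t[second_half] <- protocol$vb
      }
    )
  }
  cbind(vm = vm_t, vb = vb_t)
}

#' Blood-concentration derivatives
#'
#' First-order elimination with pulsed infusion:
#' \eqn{dM/dt = -\gamma M + v_m(t)}, \eqn{dB/dt = -\gamma B + v_b(t)}.
#'
#' @param M,B Current chemotherapy and ICB blood concentrations.
#' @param t Time in days.
#' @param protocol A [therapy_protocol()].
#' @param gamma Drug decay rate per day.
#' @return Named numeric vector `c(dM = ..., dB = ...)`.
#' @export
drug_rhs <- function(M, B, t, protocol, gamma) {
  v <- dose_rate(t, protocol)
  c(dM = -gamma * M + v[, "vm"], dB = -gamma * B + v[, "vb"])
}

#' Closed-form blood concentrations under a square-wave schedule
#'
#' Piecewise-constant infusion admits an exact solution on each half-cycle
#' segment: from level \eqn{L_0} with constant infusion rate \eqn{v},
#' \eqn{L(s) = v/\gamma + (L_0 - v/\gamma) e^{-\gamma s}} (pure decay when
#' \eqn{v = 0}). Segments are composed across every switch boundary, so the
#' value is exact for all `t`. Used both as the integrator's drug oracle and
#' as the drug input of the stochastic simulator.
#'
#' @param t Time(s) in days, vectorised; each must be `>= 0`.
#' @param protocol A [therapy_protocol()].
#' @param gamma Drug decay rate per day.
#' @param M0,B0 Concentrations at time zero.
#' @return A two-column matrix `cbind(M = ..., B = ...)`.
#' @examples
#' p <- therapy_protocol("chemo", vm = 5)
#' drug_closed_form(10.5, p, gamma = 0.9)  # end of first on-phase
#' @export
drug_closed_form <- function(t, protocol, gamma, M0 = 0, B0 = 0) {
  protocol <- as_protocol(protocol)
  if (any(!is.finite(t)) || any(t < 0)) stop("'t' must be finite and >= 0")
  if (!is.finite(gamma) || gamma < 0) stop("'gamma' must be >= 0")
  bounds <- switch_times(protocol, max(t))
  ## segment starts: 0, then each switch boundary
  starts <- unique(c(0, bounds[bounds > 0 & bounds < max(t) + 1e-12]))
  starts <- sort(starts)
  ## infusion rate is constant strictly inside each segment; probe just after
  ## each start (segments are half-open [start, next))
  widths <- diff(c(starts, max(t)))
  probe <- starts + pmax(widths, 1e-9) / 2
  v <- dose_rate(pmin(probe, max(probe)), protocol)
  evolve <- function(L0, rate, s) {
    if (gamma == 0) return(L0 + rate * s)
    rate / gamma + (L0 - rate / gamma) * exp(-gamma * s)
  }
  ## propagate levels to each segment start
  nseg <- length(starts)
  Mlev <- Blev <- numeric(nseg)
  Mlev[1] <- M0
  Blev[1] <- B0
  if (nseg > 1) {
    for (i in seq_len(nseg - 1)) {
      s <- starts[i + 1] - starts[i]
      Mlev[i + 1] <- evolve(Mlev[i], v[i, "vm"], s)
      Blev[i + 1] <- evolve(Blev[i], v[i, "vb"], s)
    }
  }
  seg <- findInterval(t, starts)
  seg[seg < 1L] <- 1L
  s <- t - starts[seg]
  M <- rate_apply(Mlev[seg], v[seg, "vm"], s, gamma)
  B <- rate_apply(Blev[seg], v[seg, "vb"], s, gamma)
  cbind(M = M, B = B)
}

## vectorised segment solution
rate_apply <- function(L0, rate, s, gamma) {
  if (gamma == 0) return(L0 + rate * s)
  rate / gamma + (L0 - rate / gamma) * exp(-gamma * s)
}

## All dosing switch times of a protocol up to (and including) t_max:
## course start, every half-cycle boundary, course end.
switch_times <- function(protocol, t_max) {
  if (protocol$mode == "none" || protocol$n_cycles <= 0) return(numeric(0))
  half <- protocol$period_days / 2
  t_end <- protocol$t_start + protocol$n_cycles * protocol$period_days
  ts <- seq(protocol$t_start, min(t_end, t_max), by = half)
  ts[ts <= t_max]
}
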