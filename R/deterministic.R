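#' Frequency-dependent selection terms
#'
#' The negative frequency-dependent transition rates of the heterogeneity
#' model are driven by two population frequencies: `f1`, the share of
#' antigenic cells among the immune-invisible pool (\eqn{A / (N + A)}), and
#' `f2`, the share of immunogenic cells among all cells not yet escaped
#' (\eqn{I / (N + A + I)}). Both are defined as 0 when their denominator is 0.
#'
#' @param N,A,I Abundances of neutral, antigenic and immunogenic cells
#'   (non-negative).
#' @return Named numeric vector `c(f1 = ..., f2 = ...)`, each in \eqn{[0, 1]}.
#' @examples
#' frequency_terms(10, 10, 0)
#' @export
frequency_terms <- function(N, A, I) {
  if (any(!is.finite(c(N, A, I))) || any(c(N, A, I) < 0))
    stop("'N', 'A', 'I' must be finite and >= 0")
  c(f1 = if (N + A > 0) A / (N + A) else 0,
    f2 = if (N + A + I > 0) I / (N + A + I) else 0)
}

## ---------------------------------------------------------------------------
## Internal unvalidated cores. `p` is a plain list of rates; callers validate
## once. The integrator may probe slightly negative states near extinction, so
## the frequency denominators are guarded but the dynamics are left as written.

freq_raw <- function(N, A, I) {
  nA <- N + A
  nAI <- nA + I
  c(if (nA > 0) A / nA else 0, if (nAI > 0) I / nAI else 0)
}

ihom_core <- function(y, p, d_eff) {
  N <- y[[1L]]; I <- y[[2L]]; E <- y[[3L]]
  tot <- N + I + E
  c(p$r1 * (1 - p$mu1) * N - p$r1 * p$mu1 * N - p$c * N * tot,
    (p$r2 - p$r2 * p$pe) * I + p$r1 * p$mu1 * N - p$r2 * p$pe * I -
      d_eff * I - p$c * I * tot,
    p$r2 * E + p$r2 * p$pe * I - p$c * E * tot)
}

ihem_core <- function(y, p, d_eff) {
  N <- y[[1L]]; A <- y[[2L]]; I <- y[[3L]]; E <- y[[4L]]
  fr <- freq_raw(max(N, 0), max(A, 0), max(I, 0))
  tot <- N + A + I + E
  c(p$r1 * (1 - p$mu1) * N - p$r1 * p$mu1 * N - p$c * N * tot,
    p$r1 * A + p$r1 * p$mu1 * N - p$mu2 * fr[1L] * A + p$mu3 * fr[2L] * I -
      p$c * A * tot,
    (p$r2 - d_eff) * I - p$mu3 * fr[2L] * I + p$mu2 * fr[1L] * A -
      2 * p$r2 * p$pe * I - p$c * I * tot,
    p$r2 * E + p$r2 * p$pe * I - p$c * E * tot)
}

## Composition of the untreated core with chemotherapy kill terms,
## immunotoxicity and ICB conversion; `y` is c(compartments, M, B).
treated_core <- function(model, mode, y, t, p, protocol) {
  ncomp <- if (model == "ihom") 3L else 4L
  M <- y[[ncomp + 1L]]
  B <- y[[ncomp + 2L]]
  chemo_on <- mode == "chemo" || mode == "combo_concurrent" ||
    mode == "combo_alternating"
  icb_on <- mode == "icb" || mode == "combo_concurrent" ||
    mode == "combo_alternating"
  kill <- if (chemo_on) 1 - exp(-M) else 0
  heal <- if (mode == "combo_alternating") p$h else 1
  d_eff <- p$d * (1 - heal * p$Kd * kill)
  yc <- y[seq_len(ncomp)]
  dx <- if (model == "ihom") ihom_core(yc, p, d_eff) else ihem_core(yc, p, d_eff)
  if (chemo_on) {
    kt <- if (model == "ihom") c(p$KN, p$KI, p$KE)
          else c(p$KN, p$KA, p$KI, p$KE)
    dx <- dx - kt * kill * yc
  }
  if (icb_on) {
    conv <- p$k * B * yc[[ncomp]]
    dx[[ncomp - 1L]] <- dx[[ncomp - 1L]] + conv   # I gains
    dx[[ncomp]] <- dx[[ncomp]] - conv             # E loses
  }
  v <- dose_rate(t, protocol)
  c(dx, -p$gamma * M + v[1L, 1L], -p$gamma * B + v[1L, 2L])
}

## ---------------------------------------------------------------------------

#' Untreated homogeneity-model right-hand side
#'
#' Derivatives of the antigenically homogeneous model: neutral cells (N)
#' divide at `r1` and transform into immunogenic cells (I) at the antigenic
#' mutation rate; ICs divide at `r2`, die from immune predation at `d`, and
#' escape to the immune-escaped compartment (E) in a fraction `pe` of
#' divisions; every pair of cells competes at rate `c`, one of the two dying.
#'
#' @param state Named numeric vector with components `N`, `I`, `E`.
#' @param params A [model_params()] set with `d` set.
#' @return Named derivative vector `c(N = ..., I = ..., E = ...)` (per day).
#' @export
ihom_rhs <- function(state, params) {
  p <- as_params(params)
  if (is.na(p$d)) stop("parameter 'd' must be set for dynamics")
  out <- ihom_core(as.numeric(state[c("N", "I", "E")]), p, p$d)
  names(out) <- c("N", "I", "E")
  out
}

#' Untreated heterogeneity-model right-hand side
#'
#' Derivatives of the antigenically heterogeneous model. Antigenic cells (A)
#' proliferate at `r1` but stay invisible to the immune system while rare:
#' they convert to immunogenic cells at rate \eqn{\mu_2 f_1} and immunogenic
#' cells revert at \eqn{\mu_3 f_2}, with `f1`, `f2` from
#' [frequency_terms()]. All other processes follow [ihom_rhs()].
#'
#' @param state Named numeric vector with components `N`, `A`, `I`, `E`.
#' @inheritParams ihom_rhs
#' @return Named derivative vector over `N`, `A`, `I`, `E` (per day).
#' @export
ihem_rhs <- function(state, params) {
  p <- as_params(params)
  if (is.na(p$d)) stop("parameter 'd' must be set for dynamics")
  out <- ihem_core(as.numeric(state[c("N", "A", "I", "E")]), p, p$d)
  names(out) <- c("N", "A", "I", "E")
  out
}

#' Extended homogeneity model with explicit division channels
#'
#' The compact homogeneous model folds asymmetric (NC -> NC + IC) and
#' symmetric (NC -> IC + IC) antigenic divisions into a single transformation
#' process, and likewise for escape. This right-hand side keeps the channels
#' explicit: `mu11`/`mu12` split the antigenic mutation probability and
#' `pe1`/`pe2` the escape probability. With `mu12 = pe2 = 0` the N equation
#' loses nothing to symmetric division and the asymmetric channel alone feeds
#' the immunogenic pool.
#'
#' @inheritParams ihom_rhs
#' @param full A [full_model_params()] object; `mu11 + mu12` must equal
#'   `params$mu1` and `pe1 + pe2` must equal `params$pe`.
#' @return Named derivative vector `c(N = ..., I = ..., E = ...)`.
#' @export
ihom_full_rhs <- function(state, params, full) {
  p <- as_params(params)
  if (!inherits(full, "chemoicb_full_params"))
    stop("'full' must be built with full_model_params()")
  if (abs(full$mu11 + full$mu12 - p$mu1) > 1e-12)
    stop("mu11 + mu12 must equal params$mu1")
  if (abs(full$pe1 + full$pe2 - p$pe) > 1e-12)
    stop("pe1 + pe2 must equal params$pe")
  if (is.na(p$d)) stop("parameter 'd' must be set for dynamics")
  N <- state[["N"]]; I <- state[["I"]]; E <- state[["E"]]
  tot <- N + I + E
  c(N = p$r1 * (1 - p$mu1) * N - p$r1 * full$mu12 * N - p$c * N * tot,
    I = (p$r2 - p$r2 * p$pe) * I +
      (p$r1 * full$mu11 + 2 * p$r1 * full$mu12) * N -
      p$r2 * full$pe2 * I - p$d * I - p$c * I * tot,
    E = p$r2 * E + (p$r2 * full$pe1 + 2 * p$r2 * full$pe2) * I -
      p$c * E * tot)
}

#' Treated right-hand side for any model/therapy combination
#'
#' Composes the untreated dynamics with the three therapy effects:
#' \itemize{
#' \item chemotherapy kills cells of each type at the rate
#'   \eqn{K_{type} (1 - e^{-M})} -- the saturating kill law, nearly
#'   linear at low blood concentration `M` and plateauing at high `M`, with
#'   the per-type sensitivity coefficient \eqn{K_{type}} reflecting that
#'   fast-cycling neutral/antigenic cells are hit hardest and
#'   checkpoint-overexpressing escaped cells least;
#' \item chemotherapy immunotoxicity attenuates immune killing,
#'   \eqn{d \to d (1 - K_d (1 - e^{-M}))}, softened to
#'   \eqn{d (1 - h K_d (1 - e^{-M}))} under the alternating protocol whose
#'   recovery half-cycle lets the immune system heal;
#' \item ICB converts escaped cells back to immunogenic cells at rate
#'   \eqn{k B}.
#' }
#' With `M = B = 0` the result equals the untreated right-hand side exactly.
#'
#' @param model `"ihom"` or `"ihem"`.
#' @param mode Therapy mode: `"none"`, `"icb"`, `"chemo"`,
#'   `"combo_concurrent"` or `"combo_alternating"`.
#' @param state Named numeric vector with the compartments of `model` plus
#'   drug concentrations `M` and `B`.
#' @param t Time in days (enters through the infusion schedule for the drug
#'   derivatives; the compartment derivatives depend on time only via `M`, `B`).
#' @param params A [model_params()] set with `d` set.
#' @param protocol A [therapy_protocol()]; its mode must agree with `mode`.
#' @return Named derivative vector over the compartments of `model` plus
#'   `M`, `B`.
#' @export
treated_rhs <- function(model = c("ihom", "ihem"),
                        mode = c("none", "icb", "chemo",
                                 "combo_concurrent", "combo_alternating"),
                        state, t, params, protocol) {
  model <- match.arg(model)
  mode <- match.arg(mode)
  p <- as_params(params)
  if (is.na(p$d)) stop("parameter 'd' must be set for dynamics")
  protocol <- as_protocol(protocol)
  if (protocol$mode != mode)
    stop("protocol mode '", protocol$mode, "' does not match 'mode' = '",
         mode, "'")
  comp <- if (model == "ihom") c("N", "I", "E") else c("N", "A", "I", "E")
  y <- as.numeric(state[c(comp, "M", "B")])
  out <- treated_core(model, mode, y, t, p, protocol)
  names(out) <- c(comp, "M", "B")
  out
}
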