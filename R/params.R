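#' Model parameters for the tumour-immune compartment models
#'
#' Builds the full rate-constant set shared by the deterministic compartment
#' models and the per-cell stochastic simulator. Defaults are the estimated
#' values used throughout the package's reference experiments; `d` (the
#' immune-mediated death rate of immunogenic cells) has no single default and
#' must be chosen per experiment from its plausible range \eqn{[0, 1]}.
#'
#' @param r1 Proliferation rate of neutral (NC) and antigenic (AC) cells, per day.
#' @param r2 Proliferation rate of immunogenic (IC) and escaped (EC) cells, per day.
#' @param mu1 Antigenic mutation probability per division, in \eqn{[0, 1)}.
#' @param mu2 Immune recognition coefficient (AC to IC transition scale), per day.
#' @param mu3 Heterogeneity-shielding coefficient (IC back to AC), per day.
#' @param d Immune-mediated death rate of ICs, per day. `NA` until an
#'   experiment supplies it.
#' @param c Cell-competition death rate, per cell per day. Sets the carrying
#'   scale of the model (equilibria are of order `rate / c`).
#' @param pe Immune-escape fraction of IC divisions, in \eqn{[0, 1]}.
#' @param gamma Blood drug decay rate, per day (shared by both drugs).
#' @param KN,KA,KI,KE Chemotherapy sensitivity of each cell type
#'   (dimensionless, in \eqn{[0, 1]}). Escaped cells are the least sensitive
#'   and `KE` is kept equal to `Kd`.
#' @param Kd Chemotherapy immunotoxicity coefficient: immune killing is
#'   attenuated to \eqn{d (1 - Kd (1 - e^{-M}))} at chemo concentration `M`.
#' @param k ICB drug efficacy: ECs convert back to ICs at rate \eqn{k B}.
#' @param lam Antigenicity-distribution parameter of newly drawn neoantigens
#'   (exponential rate by default; see [sim_config()]).
#' @param h Healing factor of the alternating chemo-then-ICB protocol, in
#'   \eqn{[0, 1]}: immunotoxicity becomes \eqn{d (1 - h Kd (1 - e^{-M}))}.
#'
#' @return An object of class `chemoicb_params`: a validated named list.
#' @seealso [default_params()], [validate_params()], [therapy_protocol()]
#' @examples
#' p <- model_params(d = 0.5)
#' p$mu2
#' @export
model_params <- function(r1 = 1, r2 = 0.5, mu1 = 0.5, mu2 = 0.6, mu3 = 0.05,
                         d = NA_real_, c = 1e-8, pe = 1e-5, gamma = 0.9,
                         KN = 0.9, KA = 0.9, KI = 0.9, KE = 0.6, Kd = 0.6,
                         k = 1, lam = 0.2, h = 0.5) {
  p <- list(r1 = r1, r2 = r2, mu1 = mu1, mu2 = mu2, mu3 = mu3, d = d,
            c = c, pe = pe, gamma = gamma, KN = KN, KA = KA, KI = KI,
            KE = KE, Kd = Kd, k = k, lam = lam, h = h)
  p <- lapply(p, as.numeric)
  class(p) <- "chemoicb_params"
  validate_params(p)
}

#' Default parameter set
#'
#' The default rate constants of the models. `d` is left unset (`NA`) because
#' it is experiment-specific within \eqn{[0, 1]}; dose strengths `vm`, `vb`
#' live on the [therapy_protocol()], not here.
#'
#' @return A `chemoicb_params` object.
#' @examples
#' default_params()$c
#' @export
default_params <- function() model_params()

#' Validate a parameter set
#'
#' Checks every rate-constant invariant and returns the object unchanged if
#' all hold. Validation is idempotent.
#'
#' @param params A `chemoicb_params` object (or a bare named list with the
#'   same fields).
#' @return `params`, invisibly unchanged, if valid; otherwise an error naming
#'   the offending field.
#' @export
validate_params <- function(params) {
  fields <- c("r1", "r2", "mu1", "mu2", "mu3", "d", "c", "pe", "gamma",
              "KN", "KA", "KI", "KE", "Kd", "k", "lam", "h")
  missing <- setdiff(fields, names(params))
  if (length(missing) > 0L)
    stop("parameter set is missing field(s): ", paste(missing, collapse = ", "))
  chk <- function(name, ok, what) {
    x <- params[[name]]
    if (length(x) != 1L || !is.numeric(x))
      stop("parameter '", name, "' must be a numeric scalar")
    if (name != "d" && is.na(x))
      stop("parameter '", name, "' is NA")
    if (!is.na(x) && !ok(x))
      stop("parameter '", name, "' = ", x, " violates ", what)
  }
  nonneg <- function(x) is.finite(x) && x >= 0
  unit <- function(x) is.finite(x) && x >= 0 && x <= 1
  for (nm in c("r1", "r2", "mu2", "mu3", "c", "gamma", "k", "d"))
    chk(nm, nonneg, "rate >= 0")
  chk("lam", function(x) is.finite(x) && x > 0, "lam > 0")
  chk("mu1", function(x) is.finite(x) && x >= 0 && x < 1, "mu1 in [0, 1)")
  chk("pe", unit, "pe in [0, 1]")
  for (nm in c("KN", "KA", "KI", "KE", "Kd", "h"))
    chk(nm, unit, paste0(nm, " in [0, 1]"))
  if (params$KE != params$Kd)
    stop("parameter 'KE' must equal 'Kd' (escaped cells share the immune-cell ",
         "chemosensitivity)")
  invisible(params)
}

#' @export
print.chemoicb_params <- function(x, ...) {
  cat("<chemoicb_params>\n")
  vals <- vapply(x, function(v) format(v, digits = 6), character(1))
  cat(paste0("  ", format(names(x), width = 6), " = ", vals, collapse = "\n"), "\n")
  invisible(x)
}

#' Asymmetric/symmetric division split of mutation and escape probabilities
#'
#' The compact models fold the two ways a division can change cell type --
#' asymmetric (one daughter transformed) and symmetric (both transformed) --
#' into single transformation processes. This object carries the split
#' probabilities for the extended homogeneous model: `mu11 + mu12` must equal
#' the parent set's `mu1`, and `pe1 + pe2` its `pe`.
#'
#' @param mu11 Probability of an asymmetric antigenic division (NC -> NC + IC).
#' @param mu12 Probability of a symmetric antigenic division (NC -> IC + IC).
#' @param pe1 Probability of an asymmetric escape division (IC -> IC + EC).
#' @param pe2 Probability of a symmetric escape division (IC -> EC + EC).
#' @return An object of class `chemoicb_full_params`.
#' @seealso [ihom_full_rhs()]
#' @export
full_model_params <- function(mu11, mu12, pe1, pe2) {
  x <- list(mu11 = as.numeric(mu11), mu12 = as.numeric(mu12),
            pe1 = as.numeric(pe1), pe2 = as.numeric(pe2))
  for (nm in names(x)) {
    v <- x[[nm]]
    if (length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
      stop("'", nm, "' must be a scalar in [0, 1]")
  }
  class(x) <- "chemoicb_full_params"
  x
}

#' Therapy protocol definition
#'
#' A dosing schedule for pulsed drug delivery. Infusion follows a half-cycle
#' square wave: drugs infuse at constant rate during the first half of each
#' cycle of length \eqn{T = 2\pi/f} and are off during the second half
#' (patient recovery). In the alternating mode the chemotherapy infusion keeps
#' the first half-cycle and the ICB infusion moves to the second half-cycle.
#'
#' @param mode One of `"none"`, `"icb"`, `"chemo"`, `"combo_concurrent"`,
#'   `"combo_alternating"`.
#' @param vm Chemotherapy infusion dose rate during the on-phase (concentration
#'   units per day).
#' @param vb ICB infusion dose rate during the on-phase.
#' @param f Treatment frequency coefficient, radians per day. The default
#'   gives the standard 21-day cycle.
#' @param t_start Therapy start time in days; the wave argument is
#'   \eqn{f (t - t_{start})} so every course begins at the start of an
#'   on-phase.
#' @param n_cycles Number of treatment cycles; both infusions are zero after
#'   `t_start + n_cycles * period_days`.
#' @return An object of class `chemoicb_protocol` with the derived field
#'   `period_days`.
#' @examples
#' therapy_protocol("combo_concurrent", vm = 5, vb = 0.9)$period_days
#' @export
therapy_protocol <- function(mode = c("none", "icb", "chemo",
                                      "combo_concurrent", "combo_alternating"),
                             vm = 0, vb = 0, f = 2 * pi / 21,
                             t_start = 0, n_cycles = 12) {
  mode <- match.arg(mode)
  if (!is.finite(f) || f <= 0) stop("'f' must be > 0")
  if (!is.finite(vm) || vm < 0) stop("'vm' must be >= 0")
  if (!is.finite(vb) || vb < 0) stop("'vb' must be >= 0")
  if (!is.finite(t_start) || t_start < 0) stop("'t_start' must be >= 0")
  if (!is.finite(n_cycles) || n_cycles < 0) stop("'n_cycles' must be >= 0")
  structure(list(mode = mode, vm = as.numeric(vm), vb = as.numeric(vb),
                 f = as.numeric(f), period_days = 2 * pi / f,
                 t_start = as.numeric(t_start),
                 n_cycles = as.numeric(n_cycles)),
            class = "chemoicb_protocol")
}

#' @export
print.chemoicb_protocol <- function(x, ...) {
  cat("<chemoicb_protocol> mode=", x$mode,
      " vm=", x$vm, " vb=", x$vb,
      " T=", format(x$period_days, digits = 6), "d",
      " start=", x$t_start, "d",
      " cycles=", x$n_cycles, "\n", sep = "")
  invisible(x)
}

## Internal: coerce/verify objects at module boundaries -----------------------

as_params <- function(params) {
  if (!inherits(params, "chemoicb_params")) {
    if (!is.list(params)) stop("'params' must be a chemoicb_params object")
    class(params) <- "chemoicb_params"
  }
  validate_params(params)
  params
}

as_protocol <- function(protocol) {
  if (!inherits(protocol, "chemoicb_protocol"))
    stop("'protocol' must be built with therapy_protocol()")
  protocol
}

match_model <- function(model) match.arg(model, c("ihom", "ihem"))

#' Replace fields of a parameter set
#'
#' Convenience for experiment sweeps: returns a new validated parameter set
#' with the named fields replaced.
#'
#' @param params A `chemoicb_params` object.
#' @param ... Named scalar replacements, e.g. `d = 1`.
#' @return A validated `chemoicb_params` object.
#' @export
update_params <- function(params, ...) {
  params <- as_params(params)
  repl <- list(...)
  if (length(repl) == 0L) return(params)
  if (is.null(names(repl)) || any(names(repl) == ""))
    stop("replacements must be named")
  unknown <- setdiff(names(repl), names(params))
  if (length(unknown) > 0L)
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "))
  for (nm in names(repl)) params[[nm]] <- as.numeric(repl[[nm]])
  validate_params(params)
  params
}
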