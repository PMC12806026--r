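#' Poisson mutation rate matching a per-division mutation probability
#'
#' The per-cell simulator draws the number of new neoantigens at a division
#' from Poisson(\eqn{\mu}). To keep the simulator consistent with the
#' compartment models, \eqn{\mu} is calibrated so that the probability of at
#' least one mutation equals the model's antigenic mutation probability:
#' \eqn{1 - e^{-\mu} = \mu_1}, i.e. \eqn{\mu = -\ln(1 - \mu_1)}.
#'
#' @param mu1 Per-division mutation probability in \eqn{[0, 1)}.
#' @return The Poisson rate \eqn{\mu \ge 0}.
#' @examples
#' mutation_rate_from_prob(0.5)  # log(2)
#' @export
mutation_rate_from_prob <- function(mu1) {
  if (any(!is.finite(mu1)) || any(mu1 < 0) || any(mu1 >= 1))
    stop("'mu1' must be in [0, 1) (the Poisson calibration -log(1 - mu1) ",
         "diverges at 1)")
  -log1p(-mu1)
}

#' Neoantigen registry
#'
#' A per-run store of neoantigen identities. Ids are consecutive integers,
#' never reused within a run; each id owns a positive antigenicity drawn at
#' creation.
#'
#' @param convention `"rate"` (antigenicities ~ Exponential with rate `lam`,
#'   mean `1/lam`) or `"scale"` (mean `lam`).
#' @return An environment with fields `antigenicity` (numeric vector indexed
#'   by id) and `n` (ids issued so far).
#' @keywords internal
antigen_registry <- function(convention = c("rate", "scale")) {
  convention <- match.arg(convention)
  reg <- new.env(parent = emptyenv())
  reg$antigenicity <- numeric(256)
  reg$n <- 0L
  reg$convention <- convention
  reg
}

#' Draw new neoantigens for one division
#'
#' Samples the number of new mutations `m` from Poisson(`mu`) and gives each
#' a fresh id and an antigenicity drawn from an exponential distribution with
#' parameter `lam` (rate convention by default, so the mean antigenicity is
#' `1/lam`).
#'
#' @param mu Poisson mutation rate (see [mutation_rate_from_prob()]).
#' @param lam Exponential antigenicity parameter (> 0).
#' @param registry An [antigen_registry()]; mutated in place.
#' @return Integer vector of new antigen ids (possibly empty).
#' @export
draw_mutations <- function(mu, lam, registry) {
  if (mu < 0) stop("'mu' must be >= 0")
  if (lam <= 0) stop("'lam' must be > 0")
  m <- stats::rpois(1L, mu)
  if (m == 0L) return(integer(0))
  rate <- if (registry$convention == "rate") lam else 1 / lam
  a <- stats::rexp(m, rate = rate)
  ids <- registry$n + seq_len(m)
  need <- ids[m]
  if (need > length(registry$antigenicity))
    registry$antigenicity <- c(registry$antigenicity,
                               numeric(max(length(registry$antigenicity), need)))
  registry$antigenicity[ids] <- a
  registry$n <- registry$n + m
  as.integer(ids)
}

#' Stochastic simulation configuration
#'
#' @param dt Time step in days. Events fire per cell with probability
#'   `rate * dt`; `dt` must keep the largest per-cell total event probability
#'   per step at or below 0.1 (checked at run time).
#' @param seed RNG seed (integer).
#' @param c_sim Competition rate used in simulation (per cell per day). The
#'   default 1e-3 puts equilibria at a few hundred cells, a scale at which
#'   replicate ensembles are cheap while demographic noise is still visible.
#' @param snapshot_times Times (days) at which the full per-cell population
#'   is captured for diversity metrics.
#' @param max_cells Safety cap on the population size.
#' @param track_antigens If `FALSE`, antigen bookkeeping is skipped (type
#'   dynamics are unchanged); ensemble runs that only need compartment counts
#'   are much faster.
#' @param lam_convention `"rate"` or `"scale"` reading of the antigenicity
#'   parameter `lam` (see [draw_mutations()]).
#' @return A `chemoicb_sim_config` list.
#' @export
sim_config <- function(dt = 0.02, seed = 1L, c_sim = 1e-3,
                       snapshot_times = numeric(0), max_cells = 2e5,
                       track_antigens = TRUE,
                       lam_convention = c("rate", "scale")) {
  if (!is.finite(dt) || dt <= 0) stop("'dt' must be > 0")
  if (!is.finite(c_sim) || c_sim < 0) stop("'c_sim' must be >= 0")
  structure(list(dt = dt, seed = as.integer(seed), c_sim = c_sim,
                 snapshot_times = sort(snapshot_times),
                 max_cells = max_cells,
                 track_antigens = isTRUE(track_antigens),
                 lam_convention = match.arg(lam_convention)),
            class = "chemoicb_sim_config")
}

## cell type codes
.NC <- 1L; .AC <- 2L; .IC <- 3L; .EC <- 4L

#' Create a starting population
#'
#' Founder cells are antigen-free; non-neutral founders (useful to start a
#' run from a macroscopic mixed state) carry empty antigen sets too, which
#' only matters to the diversity metrics, not to the dynamics.
#'
#' @param n_nc,n_ac,n_ic,n_ec Number of founder cells of each type.
#' @return A population list with fields `type` (integer codes NC=1, AC=2,
#'   IC=3, EC=4) and `ant` (list of integer antigen-id vectors).
#' @export
new_population <- function(n_nc = 1L, n_ac = 0L, n_ic = 0L, n_ec = 0L) {
  type <- rep(c(.NC, .AC, .IC, .EC), c(n_nc, n_ac, n_ic, n_ec))
  list(type = type, ant = rep(list(integer(0)), length(type)))
}

population_counts <- function(pop) {
  n <- tabulate(pop$type, 4L)
  c(NC = n[1], AC = n[2], IC = n[3], EC = n[4])
}

#' Advance a population by one time step
#'
#' Per cell, at most one event fires per step, chosen by a single uniform
#' draw against the cumulative per-event probabilities `rate * dt`:
#' division (with its mutation/transformation and escape sub-draws),
#' immune death, frequency-dependent type transitions, chemotherapy kill,
#' ICB conversion and pairwise competition (each cell dies at
#' `c_sim * (n_total - 1)`, the per-capita mean-field competition term).
#' A neutral cell's division draws one Poisson(\eqn{\mu}) mutation count for
#' the pair of daughters; at least one new mutation realises the
#' transformation into an antigenic cell (heterogeneity model) or an
#' immunogenic cell (homogeneity model) founded with those antigens --
#' the compact transformation process of the compartment models, with
#' \eqn{P(m \ge 1) = \mu_1} by the [mutation_rate_from_prob()] calibration.
#' Daughters of non-neutral divisions inherit their parent's antigen set
#' unchanged, so every antigen-bearing lineage carries its founding
#' neoantigens (antigen sets only ever grow along a lineage).
#'
#' @param pop A population (see [new_population()]).
#' @param dt Time step in days.
#' @param params A [model_params()] set with `d` set.
#' @param drugs Named numeric `c(M = , B = )` blood concentrations during the
#'   step.
#' @param model `"ihom"` or `"ihem"`.
#' @param config A [sim_config()].
#' @param registry An [antigen_registry()] (required when
#'   `config$track_antigens`).
#' @param healing Healing factor applied to immunotoxicity (1 = none; the
#'   alternating protocol passes `params$h`).
#' @return The advanced population.
#' @export
sim_step <- function(pop, dt, params, drugs = c(M = 0, B = 0), model = "ihem",
                     config = sim_config(), registry = NULL, healing = 1) {
  n <- length(pop$type)
  if (n == 0L) return(pop)
  p <- params
  track <- config$track_antigens
  if (track && is.null(registry)) stop("antigen tracking requires a registry")
  M <- drugs[["M"]]; B <- drugs[["B"]]
  kill <- 1 - exp(-M)
  cnt <- tabulate(pop$type, 4L)
  fr <- freq_raw(cnt[1], cnt[2], cnt[3])
  pcomp <- config$c_sim * (n - 1) * dt
  d_eff <- p$d * (1 - healing * p$Kd * kill)

  ## per-type event probability vectors (order matters; "no event" is the
  ## remaining mass)
  ev <- list(
    c(div = p$r1 * dt,                      # NC
      chemo = p$KN * kill * dt,
      comp = pcomp),
    c(div = p$r1 * dt,                      # AC
      to_ic = p$mu2 * fr[1] * dt,
      chemo = p$KA * kill * dt,
      comp = pcomp),
    c(div = p$r2 * dt,                      # IC
      death = d_eff * dt,
      to_ac = if (model == "ihem") p$mu3 * fr[2] * dt else 0,
      chemo = p$KI * kill * dt,
      comp = pcomp),
    c(div = p$r2 * dt,                      # EC
      to_ic = p$k * B * dt,
      chemo = p$KE * kill * dt,
      comp = pcomp)
  )
  worst <- max(vapply(ev, sum, numeric(1)))
  if (worst > 0.1)
    stop("time step too large: per-cell event probability ", signif(worst, 3),
         " exceeds 0.1; reduce dt")

  u <- stats::runif(n)
  event <- integer(n)     # 0 = nothing, else index into the type's event list
  for (tt in 1:4) {
    idx <- which(pop$type == tt)
    if (length(idx) == 0L) next
    cp <- cumsum(ev[[tt]])
    e <- findInterval(u[idx], cp) + 1L
    e[e > length(cp)] <- 0L
    event[idx] <- e
  }

  mu <- if (is.null(attr(pop, "mu"))) mutation_rate_from_prob(p$mu1)
        else attr(pop, "mu")
  lam <- p$lam
  killmask <- logical(n)
  new_type <- integer(0)
  new_ant <- list()

  for (i in which(event > 0L)) {
    tt <- pop$type[i]
    enm <- names(ev[[tt]])[event[i]]
    if (enm %in% c("chemo", "comp", "death")) {
      killmask[i] <- TRUE
    } else if (enm == "to_ic") {
      pop$type[i] <- .IC
    } else if (enm == "to_ac") {
      pop$type[i] <- .AC
    } else if (enm == "div") {
      if (tt == .NC) {
        ## a neutral division accumulates mutations at overall rate mu;
        ## any new antigen realises the transformation process
        newids <- if (track) draw_mutations(mu, lam, registry) else integer(0)
        mutated <- if (track) length(newids) > 0L
                   else stats::runif(1L) < p$mu1
        if (mutated) {
          ## transformation division: the mutated offspring replaces the NC
          pop$type[i] <- if (model == "ihem") .AC else .IC
          if (track) pop$ant[[i]] <- newids
        } else {
          new_type <- c(new_type, .NC)
          if (track) new_ant[[length(new_type)]] <- integer(0)
        }
      } else if (tt == .IC && stats::runif(1L) < p$pe) {
        ## escape division: the escaped offspring replaces the IC
        pop$type[i] <- .EC
      } else {
        ## ordinary division: daughters inherit the parent's antigen set
        new_type <- c(new_type, tt)
        if (track) new_ant[[length(new_type)]] <- pop$ant[[i]]
      }
    }
  }

  keep <- !killmask
  out <- list(type = c(pop$type[keep], new_type),
              ant = if (track) c(pop$ant[keep], new_ant) else NULL)
  attr(out, "mu") <- mu
  out
}

#' Run the per-cell branching simulation
#'
#' Simulates tumour growth (and optionally therapy) cell by cell with a
#' fixed-step scheme. Drug concentrations follow the exact square-wave
#' pharmacokinetics ([drug_closed_form()]) evaluated at each step. The run is
#' fully reproducible from `(config$seed, config, params, protocol)`.
#'
#' @param config A [sim_config()].
#' @param params A [model_params()] set with `d` set. The deterministic
#'   competition rate `params$c` is ignored in favour of `config$c_sim`.
#' @param protocol A [therapy_protocol()].
#' @param model `"ihom"` or `"ihem"`.
#' @param horizon Final simulated time in days (absolute; the run covers
#'   `[t_offset, horizon]`).
#' @param init Founder population (default one neutral cell); pass a
#'   previous run's `final` population to continue it.
#' @param record_dt Spacing of the recorded count series, days.
#' @param t_offset Start time of the run in days; drug schedules and
#'   snapshot times are interpreted on this absolute clock.
#' @param registry Continue an existing [antigen_registry()] (for runs that
#'   resume a population) instead of starting a fresh one.
#' @param stop_at_size Stop the run once the total population reaches this
#'   size; the stop time is returned as attribute `stopped_at` (an in-silico
#'   detection event).
#' @return A list of class `chemoicb_sim` with `trajectory` (data frame
#'   `time, NC, AC, IC, EC, M, B, total`), `snapshots` (list of
#'   `chemoicb_snapshot`, one per requested snapshot time), `final` (the end
#'   population), and `config`, `params`, `protocol`, `model`.
#' @export
simulate_tumor <- function(config, params, protocol = therapy_protocol("none"),
                           model = c("ihem", "ihom"), horizon = 30,
                           init = new_population(1L), record_dt = 0.5,
                           t_offset = 0, registry = NULL,
                           stop_at_size = Inf) {
  model <- match.arg(model)
  p <- as_params(params)
  if (is.na(p$d)) stop("parameter 'd' must be set for dynamics")
  protocol <- as_protocol(protocol)
  if (!inherits(config, "chemoicb_sim_config"))
    stop("'config' must be built with sim_config()")
  if (horizon <= t_offset) stop("'horizon' must exceed 't_offset'")
  set.seed(config$seed)
  if (config$track_antigens && is.null(registry))
    registry <- antigen_registry(config$lam_convention)
  healing <- if (protocol$mode == "combo_alternating") p$h else 1

  nstep <- ceiling((horizon - t_offset) / config$dt)
  step_times <- t_offset + (0:nstep) * config$dt
  drug <- drug_closed_form(step_times, protocol, p$gamma)

  rec_times <- seq(t_offset, horizon, by = record_dt)
  rec_idx <- pmin(round((rec_times - t_offset) / config$dt), nstep) + 1L
  rec <- matrix(NA_real_, nrow = length(rec_times), ncol = 4L)
  snaps <- list()
  snap_pending <- config$snapshot_times
  snap_pending <- snap_pending[snap_pending >= t_offset - 1e-9]

  pop <- init
  stopped_at <- NA_real_
  last_step <- nstep
  for (s in 0:nstep) {
    tnow <- step_times[s + 1L]
    while (length(snap_pending) > 0L && tnow >= snap_pending[1L] - 1e-9) {
      snaps[[length(snaps) + 1L]] <-
        make_snapshot(pop, registry, time = tnow)
      snap_pending <- snap_pending[-1L]
    }
    hit <- which(rec_idx == s + 1L)
    if (length(hit) > 0L)
      rec[hit, ] <- matrix(population_counts(pop), nrow = length(hit),
                           ncol = 4L, byrow = TRUE)
    if (length(pop$type) >= stop_at_size) {
      stopped_at <- tnow
      last_step <- s
      break
    }
    if (s == nstep) break
    if (length(pop$type) > config$max_cells)
      stop("population exceeded max_cells (", config$max_cells, ") at t = ",
           tnow, "; raise the cap or increase c_sim")
    pop <- sim_step(pop, config$dt, p,
                    drugs = c(M = drug[[s + 1L, 1L]], B = drug[[s + 1L, 2L]]),
                    model = model, config = config, registry = registry,
                    healing = healing)
  }

  keep_rec <- rec_idx <= last_step + 1L & !is.na(rec[, 1])
  traj <- data.frame(time = rec_times[keep_rec],
                     NC = rec[keep_rec, 1], AC = rec[keep_rec, 2],
                     IC = rec[keep_rec, 3], EC = rec[keep_rec, 4],
                     M = drug[rec_idx[keep_rec], "M"],
                     B = drug[rec_idx[keep_rec], "B"])
  traj$total <- traj$NC + traj$AC + traj$IC + traj$EC
  structure(list(trajectory = traj, snapshots = snaps, final = pop,
                 registry = registry, config = config, params = p,
                 protocol = protocol, model = model),
            class = "chemoicb_sim", stopped_at = stopped_at)
}

#' Capture a per-cell snapshot
#'
#' @param pop A population.
#' @param registry The run's [antigen_registry()] (or `NULL` when antigens
#'   are untracked).
#' @param time Snapshot time label.
#' @return A `chemoicb_snapshot`: list with `time`, `cells` (data frame
#'   `cell_id, type, antigen_count, cell_antigenicity`) and `incidence`
#'   (data frame `antigen_id, antigenicity, carrier_count`).
#' @export
make_snapshot <- function(pop, registry, time = NA_real_) {
  n <- length(pop$type)
  type_lab <- c("NC", "AC", "IC", "EC")[pop$type]
  if (is.null(registry) || is.null(pop$ant)) {
    cells <- data.frame(cell_id = seq_len(n), type = type_lab,
                        antigen_count = NA_integer_,
                        cell_antigenicity = NA_real_)
    incidence <- data.frame(antigen_id = integer(0), antigenicity = numeric(0),
                            carrier_count = integer(0))
  } else {
    counts <- lengths(pop$ant)
    antig <- vapply(pop$ant, function(ids)
      sum(registry$antigenicity[ids]), numeric(1))
    cells <- data.frame(cell_id = seq_len(n), type = type_lab,
                        antigen_count = counts, cell_antigenicity = antig)
    allids <- unlist(pop$ant, use.names = FALSE)
    if (length(allids) > 0L) {
      tab <- table(allids)
      ids <- as.integer(names(tab))
      incidence <- data.frame(antigen_id = ids,
                              antigenicity = registry$antigenicity[ids],
                              carrier_count = as.integer(tab))
    } else {
      incidence <- data.frame(antigen_id = integer(0),
                              antigenicity = numeric(0),
                              carrier_count = integer(0))
    }
  }
  structure(list(time = time, cells = cells, incidence = incidence,
                 sets = if (!is.null(pop$ant)) pop$ant else NULL),
            class = "chemoicb_snapshot")
}

#' @export
print.chemoicb_snapshot <- function(x, ...) {
  cat("<chemoicb_snapshot> t=", x$time, "d cells=", nrow(x$cells),
      " antigens=", nrow(x$incidence), "\n", sep = "")
  invisible(x)
}

#' Run replicate simulations with derived seeds
#'
#' Replicate `r` runs with seed `(base_seed + 99991 * r) mod (2^31 - 1)`;
#' everything else is shared.
#'
#' @param n_reps Number of replicates.
#' @param base_seed Base RNG seed.
#' @param config A [sim_config()] (its seed is overridden per replicate).
#' @param ... Passed to [simulate_tumor()].
#' @return List of `chemoicb_sim` results.
#' @export
simulate_replicates <- function(n_reps, base_seed, config, ...) {
  lapply(seq_len(n_reps), function(r) {
    cfg <- config
    cfg$seed <- as.integer((base_seed + 99991 * r) %% 2147483647)
    simulate_tumor(cfg, ...)
  })
}
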