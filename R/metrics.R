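#' Total antigenicity of a cell
#'
#' A cell's antigenicity is the sum of the antigenicities of all neoantigens
#' it carries; antigen-free (neutral) cells score 0.
#'
#' @param antigen_ids Integer vector of the cell's antigen ids.
#' @param antigen_table Lookup with columns `antigen_id` and `antigenicity`
#'   (e.g. a snapshot's `incidence` table), or an [antigen_registry()].
#' @return Non-negative scalar.
#' @examples
#' tab <- data.frame(antigen_id = 1:2, antigenicity = c(0.3, 0.7))
#' cell_antigenicity(1:2, tab)
#' @export
cell_antigenicity <- function(antigen_ids, antigen_table) {
  if (length(antigen_ids) == 0L) return(0)
  if (is.environment(antigen_table))
    return(sum(antigen_table$antigenicity[antigen_ids]))
  idx <- match(antigen_ids, antigen_table$antigen_id)
  if (anyNA(idx)) stop("unknown antigen id(s)")
  sum(antigen_table$antigenicity[idx])
}

#' Shannon diversity of the neoantigen landscape
#'
#' Diversity over antigen incidence: with \eqn{q_j} the share of antigen
#' \eqn{j}'s carrier count among all carrier counts,
#' \eqn{H = -\sum_j q_j \ln q_j} (natural log). Zero when at most one
#' distinct antigen is present (including the empty population).
#'
#' @param snapshot A `chemoicb_snapshot` (or any list with an `incidence`
#'   data frame carrying `carrier_count`).
#' @param level `"antigen"` (default; carrier counts of each distinct
#'   neoantigen) or `"clone"` (counts of cells per distinct antigen set).
#' @param base Logarithm base; `exp(1)` for nats (default), 2 for bits.
#' @return Non-negative scalar, at most `log(number of distinct antigens)`.
#' @examples
#' s <- list(incidence = data.frame(carrier_count = c(3, 1)))
#' shannon_diversity(s)
#' @export
shannon_diversity <- function(snapshot, level = c("antigen", "clone"),
                              base = exp(1)) {
  level <- match.arg(level)
  counts <- if (level == "antigen") {
    snapshot$incidence$carrier_count
  } else {
    if (is.null(snapshot$sets)) stop("clone-level diversity needs antigen sets")
    key <- vapply(snapshot$sets, function(s)
      paste(sort(s), collapse = ","), character(1))
    as.integer(table(key))
  }
  counts <- counts[counts > 0]
  if (length(counts) <= 1L) return(0)
  q <- counts / sum(counts)
  -sum(q * log(q, base = base))
}

#' Spread of cell antigenicity across a population
#'
#' Population variance (denominator n) and standard deviation of per-cell
#' antigenicity over all tumour cells, neutral cells included at 0.
#'
#' @param snapshot A `chemoicb_snapshot`.
#' @return Named numeric `c(variance = , sd = )`.
#' @export
antigenicity_variation <- function(snapshot) {
  x <- snapshot$cells$cell_antigenicity
  if (length(x) == 0L) stop("empty population")
  if (anyNA(x)) stop("snapshot lacks antigenicity (antigens untracked?)")
  v <- mean((x - mean(x))^2)
  c(variance = v, sd = sqrt(v))
}

#' Relative tumour size across a therapy course
#'
#' Post-therapy total population divided by pre-therapy total, the standard
#' response measure for the dose-grid experiments. Totals are interpolated
#' on the trajectory's sample grid.
#'
#' @param traj A `chemoicb_trajectory`.
#' @param t_pre Pre-therapy reference time; defaults to the protocol's
#'   `t_start`.
#' @param t_post Evaluation time; defaults to the end of the last cycle plus
#'   one drug half-life (\eqn{\ln 2 / \gamma}).
#' @return Non-negative scalar (1 means no net change).
#' @export
relative_tumor_size <- function(traj, t_pre = NULL, t_post = NULL) {
  prot <- attr(traj, "protocol")
  par <- attr(traj, "params")
  if (is.null(t_pre)) {
    if (is.null(prot)) stop("'t_pre' required for a bare trajectory")
    t_pre <- prot$t_start
  }
  if (is.null(t_post)) {
    if (is.null(prot) || is.null(par))
      stop("'t_post' required for a bare trajectory")
    t_post <- prot$t_start + prot$n_cycles * prot$period_days +
      log(2) / par$gamma
    t_post <- min(t_post, max(traj$time))
  }
  if (t_pre >= t_post) stop("'t_pre' must be earlier than 't_post'")
  if (t_pre < min(traj$time) || t_post > max(traj$time))
    stop("requested times fall outside the trajectory")
  pre <- total_at(traj, t_pre)
  if (pre <= 0) stop("pre-therapy population is zero")
  total_at(traj, t_post) / pre
}
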