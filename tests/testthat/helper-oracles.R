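## Independent oracles used across test files.
##
## literal_rhs() is a second, hand-written transcription of every printed
## equation system (untreated, ICB, chemotherapy, combination for each
## model), coded as flat formulas with no shared helpers, so that the
## package's composed right-hand side can be checked against it term for
## term.

literal_rhs <- function(model, mode, y, p) {
  ## y: named c(N, [A,] I, E, M, B)
  N <- y[["N"]]; I <- y[["I"]]; E <- y[["E"]]
  M <- y[["M"]]; B <- y[["B"]]
  A <- if (model == "ihem") y[["A"]] else 0
  q <- if (mode %in% c("chemo", "combo_concurrent", "combo_alternating"))
    1 - exp(-M) else 0
  hh <- if (mode == "combo_alternating") p$h else 1
  kB <- if (mode %in% c("icb", "combo_concurrent", "combo_alternating"))
    p$k * B else 0
  if (model == "ihom") {
    tot <- N + I + E
    f1 <- 0; f2 <- 0
    dN <- p$r1 * (1 - 2 * p$mu1) * N - p$c * (N^2 + I * N + E * N) -
      p$KN * q * N
    dI <- (p$r2 - 2 * p$r2 * p$pe) * I + p$r1 * p$mu1 * N -
      p$d * (1 - hh * p$Kd * q) * I - p$KI * q * I + kB * E -
      p$c * (I^2 + N * I + E * I)
    dE <- p$r2 * E + p$r2 * p$pe * I - p$KE * q * E - kB * E -
      p$c * (E^2 + N * E + I * E)
    out <- c(N = dN, I = dI, E = dE)
  } else {
    f1 <- if (N + A > 0) A / (N + A) else 0
    f2 <- if (N + A + I > 0) I / (N + A + I) else 0
    dN <- p$r1 * (1 - 2 * p$mu1) * N -
      p$c * (N^2 + A * N + I * N + E * N) - p$KN * q * N
    dA <- p$r1 * A + p$r1 * p$mu1 * N - p$mu2 * f1 * A + p$mu3 * f2 * I -
      p$c * (A^2 + N * A + I * A + E * A) - p$KA * q * A
    dI <- (p$r2 - p$d * (1 - hh * p$Kd * q)) * I - p$mu3 * f2 * I +
      p$mu2 * f1 * A - 2 * p$r2 * p$pe * I - p$KI * q * I + kB * E -
      p$c * (I^2 + N * I + A * I + E * I)
    dE <- p$r2 * E + p$r2 * p$pe * I - p$KE * q * E - kB * E -
      p$c * (E^2 + N * E + A * E + I * E)
    out <- c(N = dN, A = dA, I = dI, E = dE)
  }
  c(out, M = NA_real_, B = NA_real_)  # drug rows checked separately
}

## Compare two right-hand sides at machine precision *relative to the
## magnitude of the summed terms*: the two transcriptions associate the
## floating-point sums differently, so the admissible gap is eps times the
## term scale (states reach 1e7, competition terms 1e6), not eps times the
## possibly cancelling result.
expect_rhs_match <- function(got, want, y, p) {
  comp <- setdiff(names(want), c("M", "B"))
  S <- sum(abs(y[comp]))
  scale <- 4 * S + p$c * S^2 + sum(abs(want[comp]))
  ok <- all(abs(got[comp] - want[comp]) <= 1e-13 * scale)
  if (!ok) expect_equal(got[comp], want[comp], tolerance = 1e-13)
  ok
}

## a random strictly positive state for a model, spanning several orders of
## magnitude
random_state <- function(model) {
  comp <- if (model == "ihom") c("N", "I", "E") else c("N", "A", "I", "E")
  x <- stats::setNames(10^stats::runif(length(comp), -1, 7), comp)
  c(x, M = stats::runif(1, 0, 6), B = stats::runif(1, 0, 1.2))
}

fig_params <- function(d = 0.5) model_params(d = d)

## a minimal trajectory object for metric tests
toy_trajectory <- function(times, totals, E = NULL,
                           protocol = NULL, params = NULL) {
  df <- data.frame(time = times, total = totals)
  df$E <- if (is.null(E)) 0 else E
  structure(df, protocol = protocol, params = params,
            class = c("chemoicb_trajectory", "data.frame"))
}
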