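test_that("frequency terms are guarded ratios on the non-escaped pool", {
  expect_equal(frequency_terms(10, 10, 0), c(f1 = 0.5, f2 = 0))
  expect_equal(frequency_terms(5, 0, 3), c(f1 = 0, f2 = 3 / 8))
  expect_equal(frequency_terms(0, 0, 0), c(f1 = 0, f2 = 0))
  expect_error(frequency_terms(-1, 0, 0), ">= 0")
  f <- frequency_terms(2, 7, 4)
  expect_true(all(f >= 0 & f <= 1))
})

test_that("untreated derivatives match an independent transcription", {
  p <- model_params(d = 1)
  st <- c(N = 100, I = 10, E = 1)
  lit <- literal_rhs("ihom", "none", c(st, M = 0, B = 0), p)
  expect_equal(ihom_rhs(st, p), lit[c("N", "I", "E")], tolerance = 1e-13)
  st4 <- c(N = 50, A = 30, I = 20, E = 0)
  lit4 <- literal_rhs("ihem", "none", c(st4, M = 0, B = 0), p)
  expect_equal(ihem_rhs(st4, p), lit4[c("N", "A", "I", "E")],
               tolerance = 1e-13)
  # zero state is a fixed point
  expect_equal(unname(ihom_rhs(c(N = 0, I = 0, E = 0), p)), rep(0, 3))
  expect_equal(unname(ihem_rhs(c(N = 0, A = 0, I = 0, E = 0), p)), rep(0, 4))
})

test_that("the logistic fixed point survives when mutation is off", {
  p <- model_params(d = 1, mu1 = 0)
  st <- c(N = p$r1 / p$c, I = 0, E = 0)
  expect_equal(unname(ihom_rhs(st, p)), rep(0, 3), tolerance = 1e-12)
})

test_that("explicit division channels reduce to the compact model", {
  p <- model_params(d = 1)
  st <- c(N = 120, I = 30, E = 5)
  tot <- sum(st)
  # purely asymmetric: N loses nothing to symmetric division
  asym <- full_model_params(mu11 = p$mu1, mu12 = 0, pe1 = p$pe, pe2 = 0)
  dx <- ihom_full_rhs(st, p, asym)
  expect_equal(dx[["N"]], p$r1 * (1 - p$mu1) * st[["N"]] -
                 p$c * st[["N"]] * tot, tolerance = 1e-13)
  # even split: symmetric channel doubles the per-event yield
  ev <- full_model_params(p$mu1 / 2, p$mu1 / 2, p$pe / 2, p$pe / 2)
  dx2 <- ihom_full_rhs(st, p, ev)
  expect_equal(dx2[["I"]],
               (p$r2 - p$r2 * p$pe) * st[["I"]] +
                 (p$r1 * p$mu1 / 2 + 2 * p$r1 * p$mu1 / 2) * st[["N"]] -
                 p$r2 * (p$pe / 2) * st[["I"]] - p$d * st[["I"]] -
                 p$c * st[["I"]] * tot,
               tolerance = 1e-13)
  expect_equal(unname(ihom_full_rhs(c(N = 0, I = 0, E = 0), p, ev)),
               rep(0, 3))
})

test_that("therapy composition reproduces every printed system", {
  set.seed(401)
  p <- fig_params()
  combos <- expand.grid(
    model = c("ihom", "ihem"),
    mode = c("none", "icb", "chemo", "combo_concurrent", "combo_alternating"),
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    m <- combos$model[i]; md <- combos$mode[i]
    prot <- therapy_protocol(md, vm = 5, vb = 0.9)
    ok <- TRUE
    for (rep in 1:50) {
      y <- random_state(m)
      got <- treated_rhs(m, md, y, t = 3, params = p, protocol = prot)
      want <- literal_rhs(m, md, y, p)
      ok <- ok && expect_rhs_match(got, want, y, p)
    }
    expect_true(ok)
  }
})

test_that("without drugs on board the treated system is the untreated one", {
  p <- fig_params()
  prot <- therapy_protocol("combo_concurrent", vm = 5, vb = 0.9)
  y <- c(N = 1e5, A = 2e4, I = 3e4, E = 10, M = 0, B = 0)
  got <- treated_rhs("ihem", "combo_concurrent", y, t = 15.75, p, prot)
  base <- ihem_rhs(y[c("N", "A", "I", "E")], p)
  expect_equal(got[c("N", "A", "I", "E")], base, tolerance = 1e-13)
})

test_that("checkpoint blockade moves escaped cells back, one for one", {
  p <- fig_params()
  prot <- therapy_protocol("icb", vb = 0.9)
  y <- c(N = 10, I = 20, E = 1000, M = 0, B = 0.8)
  got <- treated_rhs("ihom", "icb", y, t = 3, p, prot)
  base <- ihom_rhs(y[c("N", "I", "E")], p)
  conv <- p$k * y[["B"]] * y[["E"]]
  expect_equal(got[["I"]] - base[["I"]], conv)
  expect_equal(got[["E"]] - base[["E"]], -conv)
})

test_that("integration respects trivial invariants", {
  p <- model_params(d = 1)
  none <- therapy_protocol("none")
  z <- integrate_protocol("ihem", "none", c(N = 0), p, none, horizon = 5)
  expect_true(all(z$total == 0))
  # escape closure: pe = 0 and E(0) = 0 keeps E identically zero
  p0 <- update_params(p, pe = 0)
  tr <- integrate_protocol("ihem", "none", c(N = 1), p0, none, horizon = 60)
  expect_true(all(tr$E == 0))
  expect_true(all(diff(tr$time) > 0))
  expect_true(all(tr[, c("N", "A", "I", "E")] >= 0))
})

test_that("untreated growth follows the logistic closed form", {
  p <- model_params(d = 1, mu1 = 0, pe = 0)
  tr <- integrate_protocol("ihom", "none", c(N = 1), p,
                           therapy_protocol("none"), horizon = 30,
                           sample_dt = 1)
  K <- p$r1 / p$c
  ref <- K / (1 + (K - 1) * exp(-p$r1 * tr$time))
  expect_lt(max(abs(tr$N - ref) / ref), 1e-6)
})

test_that("equilibrium fractions vanish without antigenic mutation and shift with d", {
  p0 <- update_params(default_params(), d = 1, mu1 = 0)
  f0 <- equilibrium_fractions(p0, d_values = 1, t_cap = 600)
  expect_equal(f0$fraction_AC, 0)
  expect_equal(f0$fraction_IC, 0)

  p <- update_params(default_params(), d = 1)
  fr <- equilibrium_fractions(p, d_values = c(0.25, 1), t_cap = 1500)
  expect_true(all(fr$converged))
  # stronger immune killing: fewer immunogenic, more antigenic cells
  expect_lt(fr$fraction_IC[2], fr$fraction_IC[1])
  expect_gt(fr$fraction_AC[2], fr$fraction_AC[1])
  # cross-integrator agreement at d = 1
  f_bdf <- equilibrium_fractions(p, d_values = 1, t_cap = 1500,
                                 method = "bdf", rtol = 1e-10, atol = 1e-12)
  expect_equal(fr$fraction_AC[2], f_bdf$fraction_AC, tolerance = 1e-4)
  expect_equal(fr$fraction_IC[2], f_bdf$fraction_IC, tolerance = 1e-4)
})
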