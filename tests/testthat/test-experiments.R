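test_that("growth studies with escape off never produce escaped cells", {
  gs <- run_growth_study(d_values = c(0.25, 1), d = 1, pe = 0,
                         models = "ihem", horizon = 80)
  expect_true(all(gs$trajectories$ihem$E == 0))
  expect_true(is.na(gs$escape_times[["ihem"]]))
  expect_lt(gs$fractions$fraction_IC[2], gs$fractions$fraction_IC[1])
  expect_gt(gs$fractions$fraction_AC[2], gs$fractions$fraction_AC[1])
})

test_that("with escape on, both models end escaped and the homogeneous one first", {
  gs <- run_growth_study(d_values = numeric(0), d = 1, pe = 1e-5,
                         horizon = 400)
  et <- gs$escape_times
  expect_false(any(is.na(et)))
  expect_lt(et[["ihom"]], et[["ihem"]])
})

test_that("therapy verdicts classify cure, nadir and relapse", {
  # synthetic course: drop from 100 to 10, regrow to 120 (escaped-dominated)
  tot <- c(100, 50, 10, 15, 25, 60, 120, 120)
  tr <- toy_trajectory(0:7, tot, E = c(0, 0, 1, 5, 20, 55, 115, 118))
  v <- chemoICB:::therapy_verdict(tr, t_start = 0)
  expect_false(v$cure)
  expect_equal(v$nadir, 10)
  expect_true(v$relapse)
  expect_equal(v$t_relapse, 4)  # first time total >= 2 x nadir
  # EC share read on the re-established tumour (>= half the starting size)
  expect_equal(v$ec_share_at_relapse, 55 / 60)
  expect_true(v$ec_dominated_relapse)
  cured <- toy_trajectory(0:3, c(100, 10, 0.5, 30))
  vc <- chemoICB:::therapy_verdict(cured, t_start = 0)
  expect_true(vc$cure)
  expect_equal(vc$t_cure, 2)
  expect_false(vc$relapse)  # post-cure regrowth is not scored
})

test_that("zero doses leave the dose-grid response at or above one", {
  p <- model_params(d = 0.5)
  dg <- dose_grid(vm_values = c(0, 5), vb_values = c(0, 0.9), params = p,
                  n_cycles = 4)
  base <- dg$relative_size[dg$vm == 0 & dg$vb == 0]
  expect_gte(base, 1)
  # the treated corner does strictly better than no treatment
  expect_lt(dg$relative_size[dg$vm == 5 & dg$vb == 0.9], base)
  # more checkpoint blockade never hurts at fixed chemotherapy
  for (v in unique(dg$vm))
    expect_true(all(diff(dg$relative_size[dg$vm == v][order(dg$vb[dg$vm == v])])
                    <= 1e-8))
})

test_that("an unperturbed sensitivity row has zero delta, twice", {
  p <- model_params(d = 0.5)
  a <- sensitivity_analysis(p, perturbation = 0, fields = "r2", n_cycles = 4)
  expect_equal(a$delta_relative_size, rep(0, 3))
  b <- sensitivity_analysis(p, perturbation = 0, fields = "r2", n_cycles = 4)
  expect_identical(a, b)
})

test_that("undosed protocols coincide with untreated growth", {
  p <- model_params(d = 0.5)
  pc <- protocol_comparison(h = 0.5, params = p, vm = 0, vb = 0, n_cycles = 2)
  conc <- pc$trajectories$concurrent
  alt <- pc$trajectories$alternating
  expect_equal(conc$total, alt$total, tolerance = 1e-10)
  none <- integrate_protocol("ihem", "none",
                             init = c(N = 0, A = 0, I = 0, E = 0) +
                               unlist(conc[1, c("N", "A", "I", "E")]),
                             params = update_params(p, h = 0.5),
                             protocol = therapy_protocol("none"),
                             horizon = max(conc$time), sample_dt = 0.5)
  expect_equal(conc$total, none$total, tolerance = 1e-8)
})

test_that("diversity replicates are reproducible and sham chemo is null", {
  a <- chemo_diversity_experiment(n_reps = 2, base_seed = 42, c_sim = 5e-4,
                                  init_cells = 50)
  b <- chemo_diversity_experiment(n_reps = 2, base_seed = 42, c_sim = 5e-4,
                                  init_cells = 50)
  expect_identical(a, b)
  sham <- chemo_diversity_experiment(n_reps = 4, base_seed = 7, vm = 0,
                                     c_sim = 5e-4, init_cells = 50)
  # without drug the landscape keeps drifting but does not collapse:
  # paired log-ratios straddle zero rather than sitting far below it
  expect_gt(median(sham$h_post), 0.5 * median(sham$h_pre))
  expect_false(any(sham$extinct))
})
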