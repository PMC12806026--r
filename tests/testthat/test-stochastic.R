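test_that("the Poisson rate calibration inverts the per-division probability", {
  expect_equal(mutation_rate_from_prob(0), 0)
  expect_equal(mutation_rate_from_prob(0.5), log(2))
  expect_error(mutation_rate_from_prob(1), "mu1")
  expect_error(mutation_rate_from_prob(-0.1), "mu1")
  # Monte-Carlo: P(m >= 1) recovers mu1
  set.seed(11)
  mu1 <- 0.5
  m <- stats::rpois(1e5, mutation_rate_from_prob(mu1))
  phat <- mean(m >= 1)
  expect_lt(abs(phat - mu1), 3 * sqrt(mu1 * (1 - mu1) / 1e5))
})

test_that("new neoantigens have Poisson counts and exponential strengths", {
  set.seed(21)
  reg <- chemoICB:::antigen_registry("rate")
  expect_identical(draw_mutations(0, 0.2, reg), integer(0))
  counts <- replicate(2e4, length(draw_mutations(log(2), 0.2, reg)))
  expect_lt(abs(mean(counts) - log(2)),
            3 * sqrt(log(2) / 2e4))
  a <- reg$antigenicity[seq_len(reg$n)]
  expect_true(all(a > 0))
  # rate convention: mean antigenicity 1/lam
  expect_lt(abs(mean(a) - 5), 3 * 5 / sqrt(length(a)))
  # ids are consecutive and never reused
  expect_identical(reg$n, as.integer(sum(counts)))
  reg2 <- chemoICB:::antigen_registry("scale")
  set.seed(22)
  ids2 <- unlist(replicate(5e3, draw_mutations(2, 0.2, reg2)))
  a2 <- reg2$antigenicity[ids2]
  expect_lt(abs(mean(a2) - 0.2), 3 * 0.2 / sqrt(length(a2)))
})

test_that("a step with all rates zero changes nothing", {
  p <- model_params(r1 = 0, r2 = 0, mu2 = 0, mu3 = 0, d = 0, pe = 0, k = 0)
  pop <- new_population(5, 3, 2, 1)
  cfg <- sim_config(dt = 0.05, c_sim = 0, track_antigens = FALSE)
  set.seed(1)
  out <- sim_step(pop, 0.05, p, model = "ihem", config = cfg)
  expect_identical(out$type, pop$type)
})

test_that("overly coarse steps are refused", {
  p <- model_params(d = 1)
  cfg <- sim_config(dt = 0.2, c_sim = 0, track_antigens = FALSE)
  set.seed(1)
  expect_error(
    sim_step(new_population(10), 0.2, p, model = "ihem", config = cfg),
    "event probability")
})

test_that("pure birth reproduces the Yule mean growth", {
  p <- model_params(d = 0, mu1 = 0, pe = 0)
  cfg <- sim_config(dt = 0.005, c_sim = 0, track_antigens = FALSE)
  sizes <- vapply(1:400, function(r) {
    cfg$seed <- 5000 + r
    s <- simulate_tumor(cfg, p, model = "ihom", horizon = 3, record_dt = 3)
    utils::tail(s$trajectory$total, 1)
  }, numeric(1))
  sem <- stats::sd(sizes) / sqrt(length(sizes))
  expect_lt(abs(mean(sizes) - exp(3)), 3 * sem)
})

test_that("runs are bit-reproducible from their seed", {
  p <- model_params(d = 1)
  prot <- therapy_protocol("chemo", vm = 5, t_start = 5, n_cycles = 1)
  cfg <- sim_config(dt = 0.02, seed = 77L, c_sim = 1e-2,
                    snapshot_times = c(5, 10))
  a <- simulate_tumor(cfg, p, prot, model = "ihem", horizon = 15)
  b <- simulate_tumor(cfg, p, prot, model = "ihem", horizon = 15)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$final, b$final)
  expect_identical(a$snapshots[[2]]$incidence, b$snapshots[[2]]$incidence)
})

test_that("type and antigen invariants hold along a tracked run", {
  p <- model_params(d = 1)
  cfg <- sim_config(dt = 0.02, seed = 3L, c_sim = 1e-2,
                    snapshot_times = 12, track_antigens = TRUE)
  s <- simulate_tumor(cfg, p, model = "ihem", horizon = 12,
                      init = new_population(20))
  snap <- s$snapshots[[1]]
  nc <- snap$cells$type == "NC"
  expect_true(all(snap$cells$antigen_count[nc] == 0))
  expect_true(all(snap$cells$antigen_count[!nc] >= 1))
  expect_true(all(snap$incidence$antigenicity > 0))
  expect_identical(anyDuplicated(snap$incidence$antigen_id), 0L)
  # escape off: no escaped cells ever
  p0 <- update_params(p, pe = 0)
  cfg$seed <- 4L
  s0 <- simulate_tumor(cfg, p0, model = "ihem", horizon = 12,
                       init = new_population(20))
  expect_true(all(s0$trajectory$EC == 0))
  # homogeneous model never uses the antigenic type
  cfg$seed <- 5L
  sh <- simulate_tumor(cfg, p, model = "ihom", horizon = 12,
                       init = new_population(20))
  expect_true(all(sh$trajectory$AC == 0))
})

test_that("halving the step leaves ensemble means within Monte-Carlo error", {
  p <- model_params(d = 1, pe = 0)
  run_mean <- function(dt) {
    sizes <- vapply(1:60, function(r) {
      cfg <- sim_config(dt = dt, seed = 900 + r, c_sim = 1e-3,
                        track_antigens = FALSE)
      s <- simulate_tumor(cfg, p, model = "ihem", horizon = 6, record_dt = 6,
                          init = new_population(100))
      utils::tail(s$trajectory$total, 1)
    }, numeric(1))
    c(mean(sizes), stats::sd(sizes) / sqrt(length(sizes)))
  }
  a <- run_mean(0.02)
  b <- run_mean(0.01)
  expect_lt(abs(a[1] - b[1]), 3 * sqrt(a[2]^2 + b[2]^2))
})

test_that("stop-at-size reports the detection time and resumes cleanly", {
  p <- model_params(d = 1)
  cfg <- sim_config(dt = 0.02, seed = 8L, c_sim = 1e-3,
                    track_antigens = TRUE)
  g <- simulate_tumor(cfg, p, model = "ihem", horizon = 200,
                      init = new_population(50), stop_at_size = 150)
  t0 <- attr(g, "stopped_at")
  expect_false(is.na(t0))
  expect_gte(length(g$final$type), 150)
  prot <- therapy_protocol("chemo", vm = 5, t_start = t0, n_cycles = 1)
  cfg2 <- sim_config(dt = 0.02, seed = 9L, c_sim = 1e-3,
                     track_antigens = TRUE)
  s <- simulate_tumor(cfg2, p, prot, model = "ihem", horizon = t0 + 21,
                      init = g$final, t_offset = t0, registry = g$registry)
  expect_equal(s$trajectory$time[1], t0)
  # drug concentrations follow the protocol clock, not the run clock
  cf <- drug_closed_form(s$trajectory$time, prot, p$gamma)
  expect_equal(s$trajectory$M, unname(cf[, "M"]), tolerance = 1e-12)
})
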