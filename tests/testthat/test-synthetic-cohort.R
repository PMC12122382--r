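test_that("sampled parameters respect the fitting bounds", {
  set.seed(5)
  s <- generator_settings(load_config())
  for (i in 1:300) {
    d <- sample_patient_parameters(runif(1, 168, 224), s)
    expect_gte(d$params$A, 0); expect_lte(d$params$A, 200)
    expect_gte(d$params$B, 0); expect_lte(d$params$B, 1.5)
    expect_gte(d$params$C, 0)
    expect_gt(d$noise_sd, 0)
  }
})

test_that("degenerate mixture weight pins C at zero", {
  set.seed(6)
  s <- generator_settings(load_config(), c_zero_fraction = 1)
  cs <- replicate(50, sample_patient_parameters(196, s)$params$C)
  expect_true(all(cs == 0))
})

test_that("amplitude and asymptote distributions match their configured truth", {
  # truncated-normal mean of A by numerical integration (independent oracle)
  mu <- 120.9; sig <- 27.54
  z <- integrate(function(x) x * dnorm(x, mu, sig), 0, 200)$value /
    (pnorm(200, mu, sig) - pnorm(0, mu, sig))
  set.seed(7)
  s <- generator_settings(load_config())
  draws <- replicate(10000, {
    d <- sample_patient_parameters(196, s)
    c(d$params$A, d$params$C)
  })
  a <- draws[1, ]; cc <- draws[2, ]
  expect_lt(abs(mean(a) - z), 3 * sd(a) / sqrt(length(a)))
  p0 <- mean(cc == 0)
  expect_lt(abs(p0 - 0.75), 3 * sqrt(0.75 * 0.25 / length(cc)))
})

test_that("schedules satisfy the cohort sampling constraints", {
  set.seed(8)
  s <- generator_settings(load_config())
  ns <- integer(500)
  for (i in seq_along(ns)) {
    sch <- generate_schedule(s)
    ns[i] <- length(sch)
    expect_true(all(diff(sch) > 0))
    expect_true(all(diff(sch) <= s$schedule_max_gap_days + 1e-12))
    expect_gte(sch[1], 3.0)
  }
  expect_true(all(ns >= 4 & ns <= 20))
  expect_true(median(ns) %in% 4:6)
})

test_that("degenerate schedule settings give an arithmetic grid", {
  s <- generator_settings(load_config(), n_fixed = 4L, first_pna_fixed = 4.0,
                          gap_fixed = 2.0)
  expect_equal(generate_schedule(s), c(4, 6, 8, 10))
  expect_error(
    generate_schedule(generator_settings(load_config(), gap_min_days = 20)),
    "infeasible")
})

test_that("zero-noise trajectories lie exactly on the model curve", {
  pars <- decay_parameters(A = 130, B = 0.12, C = 15, Tc = -190,
                           ga_days = 200)
  sch <- c(4, 7, 10, 14, 20)
  traj <- simulate_trajectory(pars, sch, noise_sd = 0)
  expect_equal(traj$tsb_umol_l, eval_patient_specific(pars, sch))
  # additive event bump of amplitude 80 at a sampled centre
  traj2 <- simulate_trajectory(pars, sch, noise_sd = 0,
                               event = list(amplitude = 80, center = 10,
                                            width = 2))
  expect_equal(traj2$tsb_umol_l[sch == 10],
               eval_patient_specific(pars, 10) + 80)
  # determinism under a fixed seed
  set.seed(9); t1 <- simulate_trajectory(pars, sch, noise_sd = 5)
  set.seed(9); t2 <- simulate_trajectory(pars, sch, noise_sd = 5)
  expect_identical(t1, t2)
})

test_that("negative simulated TSB is clipped at zero and counted", {
  pars <- decay_parameters(A = 1, B = 1.4, C = 0, Tc = -196, ga_days = 196)
  set.seed(10)
  traj <- simulate_trajectory(pars, c(5, 10, 20, 30), noise_sd = 50)
  expect_true(all(traj$tsb_umol_l >= 0))
  expect_gte(attr(traj, "n_clipped"), 1)
})

test_that("event injection adds the bump and an elevated CRP near the centre", {
  meas <- data.frame(pna_days = c(4, 8, 12, 16), tsb_umol_l = rep(100, 4))
  ev <- list(amplitude = 80, center = 12, width = 2, crp_value = 150,
             crp_offset = 1)
  inj <- inject_event(meas, ev)
  expect_equal(inj$measurements$tsb_umol_l[3], 180)
  expect_equal(inj$crp$crp_mg_l, 150)
  expect_lte(abs(inj$crp$pna_days - 12), 2)
  # amplitude 0 leaves the trajectory untouched
  inj0 <- inject_event(meas, modifyList(ev, list(amplitude = 0)))
  expect_equal(inj0$measurements$tsb_umol_l, meas$tsb_umol_l)
  # centre outside the sampled span is shifted in, with a warning
  expect_warning(
    inj2 <- inject_event(meas, modifyList(ev, list(center = 30))),
    "shifted")
  expect_equal(inj2$event$center, 16)
})

test_that("cohort generation is reproducible and size-stable", {
  g1 <- gen_quiet(n_patients = 8L, seed = 33L)
  g2 <- gen_quiet(n_patients = 8L, seed = 33L)
  expect_identical(g1$truth, g2$truth)
  expect_identical(g1$cohort$measurements, g2$cohort$measurements)
  # enlarging the cohort never reshuffles earlier patients
  g3 <- gen_quiet(n_patients = 12L, seed = 33L)
  expect_identical(g3$truth[1:8, ], g1$truth)
  # event_fraction = 0 leaves no injected events
  g4 <- gen_quiet(n_patients = 8L, seed = 33L, event_fraction = 0)
  expect_false(any(g4$truth$event_injected))
  # GA stays in the study range
  expect_true(all(g1$truth$ga_days >= 168 & g1$truth$ga_days < 224))
})
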