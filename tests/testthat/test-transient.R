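test_that("tau_analytic matches direct substitution and is additive", {
  # one downstream step: KM 100 uM, V 0.1 uM/s, v0 = 0.05 uM/s -> tau 2000 s
  spec <- two_step_spec(kcat1 = 1, km1 = 1, kcat2 = 1, km2 = 100)
  res <- tau_analytic(spec, c(E1 = 0.05, E2 = 0.1), substrate_conc = 1e6)
  expect_equal(res$v0, 0.05, tolerance = 1e-5)
  expect_equal(res$tau, 2000, tolerance = 1e-3)

  # two identical downstream steps double the transient
  e1 <- toy_enzyme("E1", 1, 1); e2 <- toy_enzyme("E2", 1, 100)
  e3 <- toy_enzyme("E3", 1, 100)
  spec3 <- cascade_spec(list(
    reaction_step(e1, c(A = 1), c(B = 1), "A"),
    reaction_step(e2, c(B = 1), c(C = 1), "B"),
    reaction_step(e3, c(C = 1), c(D = 1), "C")),
    monitored = "D")
  res3 <- tau_analytic(spec3, c(E1 = 0.05, E2 = 0.1, E3 = 0.1), 1e6)
  expect_equal(res3$tau, 2 * res$tau, tolerance = 1e-6)
})

test_that("tau_analytic scaling and limiting behaviour", {
  spec <- two_step_spec(1, 1, 1, 100)
  base <- tau_analytic(spec, c(E1 = 0.05, E2 = 0.1), 1e6)
  for (f in c(0.5, 2, 10)) {
    scaled <- tau_analytic(spec, c(E1 = 0.05 * f, E2 = 0.1 * f), 1e6)
    expect_equal(scaled$tau, base$tau / f, tolerance = 1e-6)
  }
  # strong channeling limit: V_j -> inf drives tau to zero
  fast <- tau_analytic(spec, c(E1 = 0.05, E2 = 1e9), 1e6)
  expect_lt(fast$tau, 1e-6)
  # a step slower than the input flux has no steady state
  slow <- tau_analytic(spec, c(E1 = 0.05, E2 = 0.04), 1e6)
  expect_identical(slow$tau, Inf)
  expect_false(slow$per_step$steady_state[1])
})

test_that("detect_linear_region finds exact lines and late lag asymptotes", {
  t <- seq(0, 6000, by = 60)
  w <- detect_linear_region(progress_curve(t, 0.01 * t, "concentration"))
  expect_equal(w$start, 0)
  expect_equal(w$end, 6000)
  expect_equal(w$slope, 0.01)

  flat <- detect_linear_region(progress_curve(t, rep(1, length(t)),
                                              "concentration"))
  expect_equal(flat$slope, 0)

  tau <- 800
  lag <- gen_lag_curve(v_ss = 0.02, tau = tau, t_end = 10 * tau)
  wl <- detect_linear_region(lag)
  expect_gt(wl$start, 3 * tau)    # asymptote dominates after ~3 tau
})

test_that("strong curvature everywhere raises the no-linear-region condition", {
  t <- seq(0, 6000, by = 60)
  y <- exp(10 * t / 6000)
  expect_error(detect_linear_region(progress_curve(t, y, "concentration")),
               class = "nanocascade_no_linear_region")
  expect_error(tau_empirical(progress_curve(t, y, "concentration")),
               class = "nanocascade_no_linear_region")
})

test_that("tau_empirical recovers closed-form transients within 1% noiseless", {
  for (tau in c(500, 2520, 6724)) {
    lag <- gen_lag_curve(v_ss = 0.02, tau = tau, t_end = 10 * tau)
    est <- tau_empirical(lag)
    expect_equal(est$tau, tau, tolerance = 0.01)
  }
  # tau = 0 collapses to a pure line through the origin
  line <- gen_lag_curve(v_ss = 0.02, tau = 0, t_end = 5000)
  est0 <- tau_empirical(line)
  expect_equal(est0$tau, 0, tolerance = 1e-8)
  expect_equal(est0$v_ss, 0.02)
})

test_that("tau_empirical shifts affinely and rejects wrong-signed slopes", {
  lag <- gen_lag_curve(v_ss = 0.02, tau = 1000, t_end = 10000)
  est <- tau_empirical(lag)
  shifted <- progress_curve(lag$time, lag$value + 5, "concentration")
  est2 <- tau_empirical(shifted)
  expect_equal(est2$tau, est$tau - 5 / est$v_ss, tolerance = 1e-8)

  t <- seq(0, 3000, by = 60)
  falling <- progress_curve(t, 100 - 0.01 * t, "concentration")
  expect_error(tau_empirical(falling, sign = 1L), class = "nanocascade_bad_fit")
  expect_equal(tau_empirical(falling, sign = -1L)$v_ss, -0.01)
})

test_that("empirical and analytic transients agree for a 2-step MM cascade", {
  # first enzyme saturated (S0 >> KM1) so v0 is constant; V2 = 3 v0
  spec <- two_step_spec(kcat1 = 1, km1 = 10, kcat2 = 1, km2 = 60)
  concs <- c(E1 = 0.02, E2 = 0.06)
  ana <- tau_analytic(spec, concs, substrate_conc = 1e4)
  expect_equal(ana$tau, 60 / (0.06 - 0.02), tolerance = 1e-2)
  sim <- simulate_cascade(spec, toy_conditions(c(A = 1e4), 15000, dt = 30),
                          concs)
  est <- tau_empirical(sim_progress_curve(sim))
  expect_equal(est$tau, ana$tau, tolerance = 0.15)
})

test_that("faster steady-state slope implies smaller estimated transient", {
  # four scaffold contexts ranked as in the reported comparison
  taus <- c(NPL = 2520, QD520 = 3314, QD600 = 5331, QD660 = 6724)
  slopes <- c(NPL = 0.030, QD520 = 0.020, QD600 = 0.012, QD660 = 0.008)
  est <- mapply(function(v, tau) {
    tau_empirical(gen_lag_curve(v, tau, t_end = 60000))$tau
  }, slopes, taus)
  expect_identical(order(est), order(-slopes), ignore_attr = TRUE)
})

test_that("channeling_regime is symmetric, linear in D, and crosses over once", {
  a <- channeling_regime(0.002, 0.002, 5e8, kcat = 100)
  b <- channeling_regime(0.002, 0.002, 5e8, kcat = 100)
  expect_equal(a$encounter_scale, b$encounter_scale)

  d2 <- channeling_regime(0.002, 0.002, 1e9, kcat = 100)
  expect_equal(d2$encounter_scale, 2 * a$encounter_scale)

  # sweeping enzyme concentration upward leaves the diffusion-limited regime
  E <- 10^seq(-5, 1, length.out = 30)
  flags <- vapply(E, function(e)
    channeling_regime(e, 1000, 5e8, kcat = 100)$channeling_potential,
    logical(1))
  expect_true(flags[1])
  expect_false(flags[length(flags)])
  expect_identical(sum(diff(flags) != 0), 1L)   # exactly one crossover

  expect_error(channeling_regime(1, 1, -1, 10), class = "nanocascade_bad_params")
})
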