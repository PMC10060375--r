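test_that("Beer-Lambert conversion is exact and invertible", {
  cu <- progress_curve(c(0, 60, 120), c(0, 0.0311, 0.0622),
                       value_kind = "absorbance")
  conc <- absorbance_to_concentration(cu, epsilon = 6220, path_length_cm = 1)
  expect_equal(conc$value, c(0, 5, 10))      # 0.0622 AU -> 10 uM
  back <- concentration_to_absorbance(conc, epsilon = 6220, path_length_cm = 1)
  expect_equal(back$value, cu$value)
  expect_error(absorbance_to_concentration(conc, 6220, 1),
               class = "nanocascade_bad_curve")
  expect_error(absorbance_to_concentration(cu, 6220, -1),
               class = "nanocascade_bad_params")
})

test_that("progress curves validate their invariants", {
  expect_error(progress_curve(c(0, 60), c(1, 2)), class = "nanocascade_bad_curve")
  expect_error(progress_curve(c(0, 60, 60), c(1, 2, 3)),
               class = "nanocascade_bad_curve")
})

test_that("initial_rate recovers exact slopes and the flat-curve edge case", {
  t <- seq(0, 600, by = 30)
  ir <- initial_rate(progress_curve(t, 0.01 * t, "concentration"))
  expect_equal(ir$rate, 0.01)
  expect_equal(ir$stderr, 0)

  flat <- initial_rate(progress_curve(t, rep(2, length(t)), "concentration"))
  expect_equal(flat$rate, 0)
  expect_equal(flat$stderr, 0)
})

test_that("initial_rate is shift-invariant and scales linearly", {
  t <- seq(0, 600, by = 20)
  y <- 0.02 * t + 1e-4 * sqrt(t + 1)
  r0 <- initial_rate(progress_curve(t, y, "concentration"))$rate
  r_shift <- initial_rate(progress_curve(t + 500, y, "concentration"))$rate
  r_scale <- initial_rate(progress_curve(t, 3 * y, "concentration"))$rate
  expect_equal(r_shift, r0)
  expect_equal(r_scale, 3 * r0)
})

test_that("initial_rate on a simulated MM step matches the true rate within 2%", {
  km <- 200; kcat <- 5; E <- 0.02; S0 <- 5 * km
  spec <- one_step_spec(kcat, km)
  sim <- simulate_cascade(spec, toy_conditions(c(A = S0), 20000, dt = 50),
                          c(E1 = E))
  curve <- sim_progress_curve(sim)
  ir <- initial_rate(curve, max_depletion = 0.05, s0 = S0)
  expect_equal(ir$rate, mm_rate(mm_params(kcat, km), E, S0), tolerance = 0.02)
})

test_that("fit_mm recovers known parameters exactly from noiseless titrations", {
  amy <- default_enzymes()$Amy$params_free    # kcat 25 /s, KM 213 uM
  ds <- gen_mm_dataset(amy, enzyme_conc = 0.002)
  fit <- fit_mm(ds, enzyme_conc = 0.002)
  expect_equal(fit$params$kcat, amy$kcat, tolerance = 1e-4)
  expect_equal(fit$params$km, amy$km, tolerance = 1e-4)
  expect_equal(fit$efficiency_mM_s, amy$kcat / (amy$km / 1000), tolerance = 1e-4)
})

test_that("fit_mm noiseless recovery holds across random parameter draws", {
  set.seed(41)
  for (i in 1:8) {
    kcat <- 10^runif(1, log10(0.07), log10(2481))
    km <- runif(1, 36, 3584)
    ds <- gen_mm_dataset(mm_params(kcat, km), enzyme_conc = 0.01)
    fit <- fit_mm(ds, enzyme_conc = 0.01)
    expect_equal(fit$params$kcat, kcat, tolerance = 1e-4)
    expect_equal(fit$params$km, km, tolerance = 1e-4)
  }
})

test_that("fit_mm rejects degenerate input and warns on poor designs", {
  expect_error(fit_mm(rate_dataset(c(10, 20, 40, 80), rep(0, 4)), 0.01),
               class = "nanocascade_bad_dataset")
  p <- mm_params(10, 500)
  ds3 <- gen_mm_dataset(p, 0.01, substrate_levels = c(100, 300, 900, 900),
                        reps = 1)
  expect_warning(fit_mm(ds3, 0.01), "fewer than 4")
})

test_that("substrate levels far below KM inflate the KM uncertainty", {
  p <- mm_params(10, 5000)
  good <- gen_mm_dataset(p, 0.01, noise_frac = 0.02, seed = 7)
  low <- gen_mm_dataset(p, 0.01, substrate_levels = p$km * c(0.002, 0.005, 0.01, 0.02),
                        noise_frac = 0.02, seed = 7)
  f_good <- fit_mm(good, 0.01)
  f_low <- suppressWarnings(fit_mm(low, 0.01))
  expect_gt(f_low$km_se / f_low$params$km, 5 * f_good$km_se / f_good$params$km)
})

test_that("enhancement_table reports fold changes with significance flags", {
  enz <- default_enzymes()
  free <- list(Mlt = enz$Mlt$params_free, Glk = enz$Glk$params_free)
  bound <- list(Mlt = enz$Mlt$params_bound, Glk = enz$Glk$params_bound)
  tab <- enhancement_table(free, bound)
  mlt <- tab[tab$enzyme == "Mlt", ]
  expect_equal(mlt$fold_kcat, 15.3 / 0.40, tolerance = 1e-6)   # ~38x
  expect_false(mlt$ns_kcat)
  glk <- tab[tab$enzyme == "Glk", ]
  expect_equal(glk$fold_kcat, 30.7 / 2.6, tolerance = 1e-6)    # ~11.8x
  expect_false(glk$ns_kcat)

  same <- enhancement_table(free, free)
  expect_true(all(same$fold_kcat == 1 & same$fold_km == 1 &
                    same$fold_efficiency == 1))
  expect_true(all(same$ns_kcat & same$ns_km & same$ns_efficiency))

  expect_error(enhancement_table(free, bound["Mlt"]),
               class = "nanocascade_bad_dataset")
})

test_that("progress CSV round-trips in tidy and wide dialects", {
  f <- withr::local_tempfile(fileext = ".csv")
  curves <- list(a = gen_lag_curve(0.02, 500, 5000, label = "a"),
                 b = gen_lag_curve(0.01, 100, 5000, label = "b"))
  write_progress_csv(curves, f)
  back <- read_progress_csv(f)
  expect_setequal(names(back), c("a", "b"))
  expect_equal(back$a$value, curves$a$value)
  expect_identical(back$a$value_kind, "concentration")

  wide <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(time_s = c(0, 60, 120), W1 = c(0, 0.01, 0.02),
                       W2 = c(0, 0.02, 0.04)), wide, row.names = FALSE)
  wb <- read_progress_csv(wide)
  expect_setequal(names(wb), c("W1", "W2"))
  expect_identical(wb$W1$value_kind, "absorbance")
})
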