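test_that("cascade presets have the expected steps, monitoring and errors", {
  s7 <- build_cascade("7E")
  expect_length(s7$steps, 7)
  expect_identical(cascade_enzymes(s7),
                   c("Glk", "PGI", "PFK", "FBA", "TPI", "GPD", "PGK"))
  expect_identical(s7$monitored, "NADH")
  expect_identical(s7$sign, 1L)

  s4 <- build_cascade("4E")
  expect_identical(cascade_enzymes(s4), c("PGM", "Eno", "PykA", "LDH"))
  expect_identical(s4$sign, -1L)

  expect_length(build_cascade("8E")$steps, 8)
  expect_length(build_cascade("9E")$steps, 9)
  expect_length(build_cascade("10E")$steps, 10)

  expect_error(build_cascade("11E"), class = "nanocascade_unknown_preset")
  expect_error(build_cascade("7E", enzymes = list()),
               class = "nanocascade_missing_enzyme")
})

test_that("mm_rate matches the hyperbolic law and its limits", {
  glk <- default_enzymes()$Glk$params_free
  expect_identical(mm_rate(glk, 1e-3, 0), 0)
  # half saturation: kcat * E / 2 = 2.6 * 1 nM / 2 = 1.3 nM/s
  expect_equal(mm_rate(glk, 1e-3, glk$km), 1.3e-3)
  # saturation: within 0.1% of kcat * E at S = 1000 KM
  expect_equal(mm_rate(glk, 1e-3, 1000 * glk$km), 2.6e-3, tolerance = 1e-3)
  expect_error(mm_rate(glk, -1, 10), class = "nanocascade_bad_params")
})

test_that("zero enzyme gives null dynamics", {
  spec <- build_cascade("7E")
  cond <- default_conditions("7E", t_end = 1200)
  sim <- simulate_cascade(spec, cond,
                          setNames(rep(0, 7), cascade_enzymes(spec)))
  for (sp in colnames(sim$conc))
    expect_equal(sim$conc[, sp], rep(sim$conc[1, sp], length(sim$time)),
                 ignore_attr = TRUE)
})

test_that("a single MM step matches the closed-form quadrature to 0.1%", {
  km <- 120; kcat <- 10; E <- 0.01; S0 <- 500
  spec <- one_step_spec(kcat, km)
  cond <- toy_conditions(c(A = S0), t_end = 8000, dt = 80)
  sim <- simulate_cascade(spec, cond, c(E1 = E))
  ref <- mm_S_of_time(sim$time, S0, kcat * E, km)
  expect_lt(max(abs(sim$conc[, "A"] - ref)) / S0, 1e-3)
  # product mirrors substrate exactly (mass balance)
  expect_equal(sim$conc[, "P"], S0 - sim$conc[, "A"], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("7E run to completion yields 2 NADH per glucose", {
  spec <- build_cascade("7E")
  cond <- assay_conditions(
    initial = c(GLC = 10, ATP = 7500, ADP = 7500, NAD = 5000, Pi = 4000),
    t_end = 30000, sample_dt = 60, path_length_cm = 1)
  concs <- setNames(rep(0.1, 7), cascade_enzymes(spec))
  sim <- simulate_cascade(spec, cond, concs, context = "bound")
  nadh_final <- unname(sim$conc[nrow(sim$conc), "NADH"])
  expect_equal(nadh_final, 20, tolerance = 0.01)
  # carbon bookkeeping: glucose consumed x2 = trioses in transit + downstream
  glc_used <- 10 - unname(sim$conc[nrow(sim$conc), "GLC"])
  triose_pool <- sum(sim$conc[nrow(sim$conc),
                              c("DHAP", "G3P", "BPG", "PG3")]) +
    2 * sum(sim$conc[nrow(sim$conc), c("G6P", "F6P", "FBP")])
  expect_equal(2 * glc_used, triose_pool, tolerance = 1e-4)
})

test_that("cofactor couples are conserved and the monitored species is monotone", {
  for (preset in c("7E", "4E")) {
    spec <- build_cascade(preset)
    cond <- default_conditions(preset, t_end = 6000)
    concs <- preset_enzyme_concs(preset)
    sim <- simulate_cascade(spec, cond, concs)
    expect_lt(max(couple_drift(sim)), 1e-5)     # 10x integrator atol
    mon <- spec$sign * sim$conc[, spec$monitored]
    expect_true(all(diff(mon) > -1e-9))
    expect_true(all(sim$conc >= 0))
  }
})

test_that("NADH plateau never exceeds the NAD+ pool", {
  spec <- build_cascade("7E")
  cond <- default_conditions("7E", t_end = 64800)
  sim <- simulate_cascade(spec, cond, preset_enzyme_concs("7E") * 20)
  expect_lte(max(sim$conc[, "NADH"]), 1130 + 1e-5)
})

test_that("a competing branch sink lowers yield monotonically", {
  spec <- build_cascade("7E")
  gox <- toy_enzyme("GOx", kcat = 600, km = 33000)
  branch <- reaction_step(gox, substrates = c(GLC = 1),
                          products = c(GL = 1), limiting = "GLC")
  cond <- default_conditions("7E", t_end = 6000)
  base <- preset_enzyme_concs("7E")
  y_at <- function(gox_conc) {
    sp <- add_competitor(spec, branch)
    sim <- simulate_cascade(sp, cond, c(base, GOx = gox_conc))
    unname(sim$conc[nrow(sim$conc), "NADH"])
  }
  ref <- simulate_cascade(spec, cond, base)$conc[, "NADH"]
  expect_equal(y_at(0), ref[length(ref)], tolerance = 1e-8)
  yields <- vapply(c(0, 0.001, 0.005, 0.02, 0.1), y_at, numeric(1))
  expect_true(all(diff(yields) < 0))

  orphan <- reaction_step(gox, substrates = c(XYZ = 1),
                          products = c(GL = 1), limiting = "XYZ")
  expect_error(add_competitor(spec, orphan), class = "nanocascade_bad_step")
})

test_that("thermo profile flags the endergonic high-KM step and sums energies", {
  tp <- thermo_profile(build_cascade("7E"))
  gpd <- tp[tp$enzyme == "GPD", ]
  expect_equal(gpd$delta_g, 15.9)
  expect_true(gpd$bottleneck)            # +15.9 kJ/mol and KM 3494 uM > 1 mM
  pgk <- tp[tp$enzyme == "PGK", ]
  expect_equal(pgk$delta_g, -20.2)
  expect_false(pgk$bottleneck)
  expect_equal(pgk$cumulative, 15.9 - 20.2)   # -4.3 kJ/mol over the known pair
  expect_false(any(tp$dg_known[1:5]))    # unreported energies stay unknown
  empty <- thermo_profile(NULL)
  expect_identical(nrow(empty), 0L)
})

test_that("simulations export tidy CSV", {
  spec <- two_step_spec(1, 50, 2, 80)
  sim <- simulate_cascade(spec, toy_conditions(c(A = 100), 1000),
                          c(E1 = 0.1, E2 = 0.1))
  f <- withr::local_tempfile(fileext = ".csv")
  write_sim_csv(sim, f)
  df <- read.csv(f)
  expect_identical(names(df), c("time_s", "species", "concentration_uM"))
  expect_equal(nrow(df), length(sim$time) * ncol(sim$conc))
})
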