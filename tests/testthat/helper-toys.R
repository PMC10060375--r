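# Small synthetic enzymes and cascades used across the suite.

toy_enzyme <- function(abbrev, kcat, km, subunits = 1, monomer_kda = 40,
                       bound = NULL, delta_g = NA_real_, capacity = list()) {
  enzyme_def(name = abbrev, abbrev = abbrev, subunits = subunits,
             monomer_kda = monomer_kda,
             params_free = mm_params(kcat, km),
             params_bound = bound, capacity = capacity, delta_g = delta_g)
}

# A -> B -> C chain; C is monitored (production).
two_step_spec <- function(kcat1, km1, kcat2, km2) {
  e1 <- toy_enzyme("E1", kcat1, km1)
  e2 <- toy_enzyme("E2", kcat2, km2)
  cascade_spec(list(
    reaction_step(e1, substrates = c(A = 1), products = c(B = 1), limiting = "A"),
    reaction_step(e2, substrates = c(B = 1), products = c(C = 1), limiting = "B")),
    monitored = "C", sign = 1L)
}

one_step_spec <- function(kcat, km) {
  e <- toy_enzyme("E1", kcat, km)
  cascade_spec(list(
    reaction_step(e, substrates = c(A = 1), products = c(P = 1), limiting = "A")),
    monitored = "P", sign = 1L)
}

toy_conditions <- function(initial, t_end, dt = t_end / 100) {
  assay_conditions(initial = initial, t_end = t_end, sample_dt = dt,
                   path_length_cm = 1)
}

# Closed-form implicit time of a single irreversible MM step
# dS/dt = -Vmax S/(KM+S):  t(S) = (S0-S)/Vmax + (KM/Vmax) log(S0/S).
mm_time_of_S <- function(S, S0, vmax, km) (S0 - S) / vmax + km / vmax * log(S0 / S)
mm_S_of_time <- function(t, S0, vmax, km) {
  vapply(t, function(ti) {
    if (ti <= 0) return(S0)
    stats::uniroot(function(S) mm_time_of_S(S, S0, vmax, km) - ti,
                   lower = S0 * 1e-12, upper = S0, tol = 1e-12 * S0)$root
  }, numeric(1))
}

default_7e_linkers <- function(scale = 1) {
  concs <- c(Glk = 5.5, PGI = 1, PFK = 9, FBA = 12, TPI = 1, GPD = 27,
             PGK = 7.5) * scale
  mapply(function(ab, cc) linker_spec(ab, cc), names(concs), concs,
         SIMPLIFY = FALSE)
}
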