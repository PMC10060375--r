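#' Assay conditions
#'
#' Initial concentrations, time grid and optical constants for a simulated
#' plate-reader cascade assay.
#'
#' @param initial Named numeric vector of initial concentrations, uM.
#'   Species absent from the vector start at 0.
#' @param t_end End of the simulated assay, s.
#' @param sample_dt Sampling interval, s (plate readers here read once per
#'   minute; default 60).
#' @param epsilon_nadh NADH extinction coefficient at 340 nm, 1/(M cm).
#' @param path_length_cm Optical path length through the well, cm. Depends
#'   on fill volume and plate geometry, so it must be given explicitly
#'   whenever absorbance is converted.
#' @param k_cof Half-saturation of the smooth cofactor-availability factor,
#'   uM (see Details).
#'
#' @details Co-substrates such as ATP or NAD+ are held in large excess in
#' the assays, but a finite pool must still deplete smoothly; each consumed
#' co-substrate multiplies its step rate by `C/(C + k_cof)`. With the
#' default `k_cof = 10` uM the factor is >0.99 at assay concentrations and
#' only rounds off the final approach to exhaustion, avoiding the ODE
#' discontinuity of a hard clamp.
#'
#' @return An object of class `assay_conditions`.
#' @export
assay_conditions <- function(initial, t_end, sample_dt = 60,
                             epsilon_nadh = 6220, path_length_cm = NULL,
                             k_cof = 10) {
  if (is.null(names(initial)) || any(initial < 0))
    .abort("`initial` must be a named vector of non-negative concentrations (uM)",
           "nanocascade_bad_conditions")
  if (t_end <= 0 || sample_dt <= 0 || sample_dt > t_end)
    .abort("need 0 < sample_dt <= t_end", "nanocascade_bad_conditions")
  structure(list(initial = initial, t_end = t_end, sample_dt = sample_dt,
                 epsilon_nadh = epsilon_nadh, path_length_cm = path_length_cm,
                 k_cof = k_cof),
            class = "assay_conditions")
}

#' Standard assay conditions for a cascade preset
#'
#' The reported multienzyme assay compositions: for the upstream cascades
#' (7E-10E) 10 mM glucose and/or 120 mM sucrose / 4 mM maltoheptaose,
#' 7.5 mM ATP, 7.5 mM ADP, 1.13 mM NAD+ and 4 mM phosphate, monitored for
#' 18 h at one read per minute; for the downstream 4E cascade 7.5 mM
#' 3-phosphoglycerate, 1.5 mM NADH and 10 mM ADP, monitored for 90 h at one
#' read per five minutes.
#'
#' @param preset Cascade preset name.
#' @param t_end Optional override of the monitored span, s.
#' @return An [assay_conditions] object.
#' @export
default_conditions <- function(preset, t_end = NULL) {
  cc <- default_config()$conditions
  up <- cc$upstream
  init <- switch(preset,
    `7E` = c(GLC = up$glucose_uM),
    `8E` = c(SUC = up$sucrose_uM),
    `9E` = c(MH = up$maltoheptaose_uM),
    `10E` = c(SUC = up$sucrose_uM, MH = up$maltoheptaose_uM),
    `4E` = NULL,
    .abort(sprintf("unknown cascade preset '%s'", preset),
           "nanocascade_unknown_preset"))
  if (preset == "4E") {
    dn <- cc$downstream
    assay_conditions(
      initial = c(PG3 = dn$pg3_uM, NADH = dn$nadh_uM, ADP = dn$adp_uM,
                  Pi = dn$pi_uM),
      t_end = t_end %||% dn$t_end_s, sample_dt = dn$sample_dt_s,
      epsilon_nadh = cc$epsilon_nadh, path_length_cm = cc$path_length_cm)
  } else {
    assay_conditions(
      initial = c(init, ATP = up$atp_uM, ADP = up$adp_uM, NAD = up$nad_uM,
                  Pi = up$pi_uM),
      t_end = t_end %||% up$t_end_s, sample_dt = up$sample_dt_s,
      epsilon_nadh = cc$epsilon_nadh, path_length_cm = cc$path_length_cm)
  }
}

#' Simulate a cascade as coupled Michaelis-Menten rate laws
#'
#' Integrates the deterministic mass-action/MM ODE system of a cascade.
#' Each step proceeds at `kcat * E * S/(KM + S)` in its limiting substrate,
#' multiplied by a smooth availability factor `C/(C + k_cof)` for each
#' consumed co-substrate; all steps are irreversible. Concentrations of the
#' limiting substrate are floored at zero inside the rate function, so
#' trajectories cannot run negative, and each declared cofactor couple
#' (NAD+/NADH, ATP/ADP) is conserved exactly by the stoichiometry up to
#' integrator error.
#'
#' The stiff-capable `lsoda` integrator is used with absolute tolerance
#' 1e-6 uM and relative tolerance 1e-8: enzyme concentrations (nM) and
#' substrate pools (mM) span six orders of magnitude.
#'
#' @param spec A [cascade_spec].
#' @param conditions An [assay_conditions] object.
#' @param enzyme_concs Named numeric vector of enzyme concentrations, uM,
#'   covering every enzyme of `spec`.
#' @param context Kinetic-parameter context: "free" (in solution) or
#'   "bound" (nanoparticle-displayed).
#' @param atol,rtol Integrator tolerances (uM, relative).
#' @return An object of class `sim_result`: list with `time` (s), `conc`
#'   (time x species matrix, uM), `rates` (time x step matrix, uM/s),
#'   `spec`, `conditions`, `enzyme_concs`, `context`.
#' @examples
#' spec <- build_cascade("7E")
#' cond <- default_conditions("7E", t_end = 3600)
#' sim <- simulate_cascade(spec, cond, preset_enzyme_concs("7E"))
#' head(as.data.frame(sim))
#' @export
simulate_cascade <- function(spec, conditions, enzyme_concs,
                             context = c("free", "bound"),
                             atol = 1e-6, rtol = 1e-8) {
  context <- match.arg(context)
  stopifnot(inherits(spec, "cascade_spec"), inherits(conditions, "assay_conditions"))
  enz <- cascade_enzymes(spec)
  if (!all(enz %in% names(enzyme_concs)))
    .abort(sprintf("missing enzyme concentrations for: %s",
                   paste(setdiff(enz, names(enzyme_concs)), collapse = ", ")),
           "nanocascade_missing_enzyme")
  if (any(enzyme_concs < 0))
    .abort("enzyme concentrations must be non-negative", "nanocascade_bad_params")
  species <- spec$species
  ns <- length(species); nr <- length(spec$steps)

  # Precompute per-step vectors and the net stoichiometry matrix.
  vmax <- numeric(nr); km <- numeric(nr); lim <- integer(nr)
  cof <- vector("list", nr)
  S <- matrix(0, ns, nr, dimnames = list(species, NULL))
  for (j in seq_len(nr)) {
    st <- spec$steps[[j]]
    p <- enzyme_params(st$enzyme, context)
    vmax[j] <- p$kcat * enzyme_concs[[st$enzyme$abbrev]]
    km[j] <- p$km
    lim[j] <- match(st$limiting, species)
    cof[[j]] <- match(st$cofactors, species)
    S[names(st$substrates), j] <- S[names(st$substrates), j] - st$substrates
    S[names(st$products), j] <- S[names(st$products), j] + st$products
  }
  k_cof <- conditions$k_cof

  step_rates <- function(y) {
    y <- pmax(y, 0)
    r <- vmax * y[lim] / (km + y[lim])
    for (j in seq_len(nr))
      for (ci in cof[[j]]) r[j] <- r[j] * y[ci] / (y[ci] + k_cof)
    r
  }
  rhs <- function(t, y, p) list(as.vector(S %*% step_rates(y)))

  y0 <- setNames(numeric(ns), species)
  known <- intersect(names(conditions$initial), species)
  y0[known] <- conditions$initial[known]
  times <- seq(0, conditions$t_end, by = conditions$sample_dt)

  out <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = "lsoda", atol = atol, rtol = rtol)
  diagn <- attr(out, "istate")
  if (!is.null(diagn) && diagn[1] < 0)
    .abort(sprintf(paste0("ODE integration failed (istate = %d); the system ",
                          "is stiff beyond the supplied tolerances - ",
                          "consider loosening atol/rtol"), diagn[1]),
           "nanocascade_integration_failure")
  conc <- pmax(unclass(out)[, species, drop = FALSE], 0)
  rates <- matrix(apply(conc, 1L, step_rates), ncol = nr, byrow = TRUE,
                  dimnames = list(NULL, enz))
  structure(list(time = times, conc = conc, rates = rates, spec = spec,
                 conditions = conditions, enzyme_concs = enzyme_concs,
                 context = context),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  mon <- x$conc[, x$spec$monitored]
  cat(sprintf("Cascade simulation: %d steps, %d species, t = 0..%g s (%d samples)\n",
              ncol(x$rates), ncol(x$conc), max(x$time), length(x$time)))
  cat(sprintf("  monitored %s: %.3g -> %.3g uM\n", x$spec$monitored,
              mon[1], mon[length(mon)]))
  invisible(x)
}

#' Tidy data frame of a simulation
#'
#' @param x A `sim_result`.
#' @param row.names,optional Unused, for generic consistency.
#' @param ... Unused.
#' @return Data frame with columns `time_s`, `species`, `concentration_uM`.
#' @export
as.data.frame.sim_result <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(time_s = rep(x$time, times = ncol(x$conc)),
             species = rep(colnames(x$conc), each = length(x$time)),
             concentration_uM = as.vector(x$conc))
}

#' Monitored-species progress curve of a simulation
#'
#' @param sim A `sim_result`.
#' @param label Condition label for the curve.
#' @return A [progress_curve] in concentration units (uM).
#' @export
sim_progress_curve <- function(sim, label = sim$spec$preset %||% "sim") {
  progress_curve(sim$time, sim$conc[, sim$spec$monitored],
                 value_kind = "concentration", label = label)
}

#' Write a simulation to tidy CSV
#'
#' @param sim A `sim_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sim_csv <- function(sim, path) {
  write.csv(as.data.frame(sim), path, row.names = FALSE)
  invisible(path)
}

#' Check cofactor-couple conservation of a simulation
#'
#' For each declared couple (e.g. NAD+/NADH), the largest absolute drift of
#' the summed concentration from its initial total over all output times.
#'
#' @param sim A `sim_result`.
#' @return Named numeric vector of maximal absolute drifts, uM.
#' @export
couple_drift <- function(sim) {
  drifts <- vapply(sim$spec$couples, function(cp) {
    if (!all(cp %in% colnames(sim$conc))) return(NA_real_)
    tot <- rowSums(sim$conc[, cp, drop = FALSE])
    max(abs(tot - tot[1]))
  }, numeric(1))
  names(drifts) <- vapply(sim$spec$couples, paste, character(1), collapse = "+")
  drifts[!is.na(drifts)]
}
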