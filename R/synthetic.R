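#' Plate-reader noise model
#'
#' Additive Gaussian absorbance noise at a fixed sampling cadence, emulating
#' a microplate reader monitoring 340 nm once per minute.
#'
#' @param sigma_abs Absorbance-unit standard deviation (default 0.002 AU).
#' @param sample_dt Sampling interval, s (default 60).
#' @param seed RNG seed; must be supplied explicitly for any nonzero sigma
#'   (no wall-clock defaults).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma_abs = 0.002, sample_dt = 60, seed = NULL) {
  if (sigma_abs < 0 || sample_dt <= 0)
    .abort("need sigma_abs >= 0 and sample_dt > 0", "nanocascade_bad_params")
  if (sigma_abs > 0 && is.null(seed))
    .abort("a seed is mandatory for a stochastic noise model",
           "nanocascade_bad_params")
  structure(list(sigma_abs = sigma_abs, sample_dt = sample_dt, seed = seed),
            class = "noise_model")
}

#' Generate a noisy absorbance progress curve with known ground truth
#'
#' Simulates a cascade, converts the monitored-species trajectory to 340 nm
#' absorbance by Beer-Lambert, resamples it on the noise model's cadence and
#' adds Gaussian read noise. The noiseless simulation is returned alongside
#' as ground truth.
#'
#' @param spec A [cascade_spec].
#' @param conditions An [assay_conditions]; its `epsilon_nadh` and
#'   `path_length_cm` set the optical conversion.
#' @param enzyme_concs Named numeric vector, uM.
#' @param noise A [noise_model].
#' @param context Kinetic-parameter context.
#' @return List with `curve` (absorbance [progress_curve]) and `truth`
#'   (the `sim_result`).
#' @export
gen_progress_curve <- function(spec, conditions, enzyme_concs,
                               noise = noise_model(0),
                               context = c("free", "bound")) {
  stopifnot(inherits(noise, "noise_model"))
  if (is.null(conditions$path_length_cm))
    .abort("`conditions$path_length_cm` is required to emit absorbance",
           "nanocascade_bad_conditions")
  conditions$sample_dt <- noise$sample_dt
  sim <- simulate_cascade(spec, conditions, enzyme_concs, context = context)
  ab <- concentration_to_absorbance(sim_progress_curve(sim),
                                    epsilon = conditions$epsilon_nadh,
                                    path_length_cm = conditions$path_length_cm)
  if (noise$sigma_abs > 0) {
    set.seed(noise$seed)
    ab$value <- ab$value + rnorm(length(ab$value), 0, noise$sigma_abs)
  }
  list(curve = ab, truth = sim)
}

#' Generate a synthetic initial-rate titration
#'
#' Draws Michaelis-Menten initial rates at the requested substrate levels
#' (default: eight levels spanning 0.2-5 x KM) with multiplicative Gaussian
#' noise, in replicate -- the synthetic counterpart of a kinetic titration
#' run in triplicate against substrate concentrations bracketing the
#' Michaelis constant.
#'
#' @param params True [mm_params].
#' @param enzyme_conc Enzyme concentration, uM.
#' @param substrate_levels Optional substrate concentrations, uM.
#' @param reps Replicates per level (default 3).
#' @param noise_frac Multiplicative noise fraction (0 = noiseless).
#' @param seed RNG seed (required when `noise_frac > 0`).
#' @return A [rate_dataset] (all replicate points retained).
#' @export
gen_mm_dataset <- function(params, enzyme_conc, substrate_levels = NULL,
                           reps = 3, noise_frac = 0, seed = NULL) {
  stopifnot(inherits(params, "mm_params"))
  levels <- substrate_levels %||%
    (params$km * c(0.2, 0.5, 1, 1.5, 2, 3, 4, 5))
  if (length(levels) < 4L)
    .abort("at least 4 substrate levels are required", "nanocascade_bad_dataset")
  if (noise_frac > 0 && is.null(seed))
    .abort("a seed is mandatory for noisy datasets", "nanocascade_bad_params")
  s <- rep(levels, each = reps)
  v <- mm_rate(params, enzyme_conc, s)
  if (noise_frac > 0) {
    set.seed(seed)
    v <- v * (1 + rnorm(length(v), 0, noise_frac))
  }
  rate_dataset(s, pmax(v, 0))
}

#' Generate a closed-form lag (transient) progress curve
#'
#' The canonical single-intermediate lag kinetics
#' `P(t) = v_ss * (t - tau * (1 - exp(-t/tau)))`: product formation
#' approaches the asymptote `v_ss * (t - tau)`, whose x-intercept is the
#' transient time tau. `tau = 0` collapses to the pure line `v_ss * t`, the
#' strong-channeling limit. Optional read noise is applied on the
#' absorbance scale (`sigma_abs`, converted via Beer-Lambert with the
#' supplied optics) so that noise magnitudes match plate-reader practice.
#'
#' @param v_ss Steady-state product formation rate, uM/s (> 0).
#' @param tau Transient time, s (>= 0).
#' @param t_end Curve span, s.
#' @param noise A [noise_model] (absorbance-scale sigma).
#' @param epsilon,path_length_cm Optics used to scale absorbance noise onto
#'   the concentration curve.
#' @param label Curve label.
#' @return A [progress_curve] in concentration units (uM).
#' @examples
#' gen_lag_curve(v_ss = 0.02, tau = 2520, t_end = 25200)
#' @export
gen_lag_curve <- function(v_ss, tau, t_end, noise = noise_model(0),
                          epsilon = 6220, path_length_cm = 1,
                          label = sprintf("lag tau=%g", tau)) {
  if (v_ss <= 0 || tau < 0 || t_end <= 0)
    .abort("need v_ss > 0, tau >= 0, t_end > 0", "nanocascade_bad_params")
  stopifnot(inherits(noise, "noise_model"))
  t <- seq(0, t_end, by = noise$sample_dt)
  p <- if (tau == 0) v_ss * t else v_ss * (t - tau * (1 - exp(-t / tau)))
  if (noise$sigma_abs > 0) {
    set.seed(noise$seed)
    sigma_uM <- 1e6 * noise$sigma_abs / (epsilon * path_length_cm)
    p <- p + rnorm(length(p), 0, sigma_uM)
  }
  progress_curve(t, p, value_kind = "concentration", label = label)
}
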