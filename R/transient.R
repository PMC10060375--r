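#' Analytic transient time of a Michaelis-Menten cascade
#'
#' For a sequential MM cascade at steady state, each intermediate-consuming
#' step j contributes a transit time `tau_j = KM_j / (V_j - v0)`, where
#' `V_j = kcat_j * E_j` is the step's maximal velocity and `v0` the first
#' enzyme's velocity at the supplied substrate concentration; the cascade
#' transient time is the sum over the N downstream steps. In the strong
#' channeling limit (`V_j -> Inf`) every term, and hence tau, goes to zero.
#'
#' A step with `V_j <= v0` cannot keep pace with the input flux, no steady
#' state exists and its transit time is reported as `Inf` with
#' `steady_state = FALSE` (the cascade total is then also `Inf`).
#'
#' @param spec A [cascade_spec].
#' @param enzyme_concs Named numeric vector of enzyme concentrations, uM.
#' @param substrate_conc Initial substrate concentration seen by the first
#'   enzyme, uM (saturating in the reported assays).
#' @param context Kinetic-parameter context, "free" or "bound".
#' @return List with `tau` (s, possibly `Inf`), `v0` (uM/s), and
#'   `per_step`: data frame of enzyme, `km_uM`, `vmax_uM_s`, `tau_s`,
#'   `steady_state` for each downstream step.
#' @examples
#' spec <- build_cascade("7E")
#' tau_analytic(spec, preset_enzyme_concs("7E"), substrate_conc = 10000)
#' @export
tau_analytic <- function(spec, enzyme_concs, substrate_conc,
                         context = c("free", "bound")) {
  context <- match.arg(context)
  stopifnot(inherits(spec, "cascade_spec"))
  enz <- cascade_enzymes(spec)
  if (!all(enz %in% names(enzyme_concs)))
    .abort(sprintf("missing enzyme concentrations for: %s",
                   paste(setdiff(enz, names(enzyme_concs)), collapse = ", ")),
           "nanocascade_missing_enzyme")
  first <- spec$steps[[1L]]
  v0 <- mm_rate(enzyme_params(first$enzyme, context),
                enzyme_concs[[first$enzyme$abbrev]], substrate_conc)
  down <- spec$steps[-1L]
  per <- lapply(down, function(st) {
    p <- enzyme_params(st$enzyme, context)
    vmax <- p$kcat * enzyme_concs[[st$enzyme$abbrev]]
    ok <- vmax > v0
    data.frame(enzyme = st$enzyme$abbrev, km_uM = p$km, vmax_uM_s = vmax,
               tau_s = if (ok) p$km / (vmax - v0) else Inf,
               steady_state = ok)
  })
  per <- do.call(rbind, per)
  list(tau = sum(per$tau_s), v0 = v0, per_step = per)
}

#' Detect the linear region of a progress curve
#'
#' Scans all contiguous windows spanning at least `min_frac` of the curve
#' (and at least `min_points` samples) and returns the window of maximal
#' absolute slope among those whose linear fit reaches R^2 >= `r2_min`;
#' among windows of (numerically) equal slope the longest wins, and among
#' those the earliest -- so an exactly linear curve yields its full span.
#' Perfectly flat windows count as linear with slope zero.
#'
#' When no window qualifies -- as for a progress curve with pronounced
#' curvature throughout, the signature of a cascade that never reaches
#' steady-state flux within the observation span -- a condition of class
#' `nanocascade_no_linear_region` is raised.
#'
#' @param curve A [progress_curve] in concentration units with >= 20
#'   samples.
#' @param r2_min Linearity threshold (R^2).
#' @param min_frac Minimal window span as a fraction of the curve span.
#' @param min_points Minimal number of samples per window.
#' @return List with `start`, `end` (s), `idx` (indices), `slope`,
#'   `intercept`, `r2`, plus the fit standard errors.
#' @export
detect_linear_region <- function(curve, r2_min = 0.995, min_frac = 0.20,
                                 min_points = 20) {
  stopifnot(inherits(curve, "progress_curve"))
  if (curve$value_kind != "concentration")
    .abort("convert the curve to concentration units first", "nanocascade_bad_curve")
  tt <- curve$time; yy <- curve$value
  n <- length(tt)
  if (n < min_points)
    .abort(sprintf("need at least %d samples, got %d", min_points, n),
           "nanocascade_too_few_points")
  span <- tt[n] - tt[1]
  # prefix sums for O(1) window regression
  cx <- c(0, cumsum(tt)); cy <- c(0, cumsum(yy))
  cxx <- c(0, cumsum(tt^2)); cxy <- c(0, cumsum(tt * yy)); cyy <- c(0, cumsum(yy^2))
  best <- NULL
  for (i in seq_len(n - min_points + 1L)) {
    j <- seq.int(i + min_points - 1L, n)
    j <- j[tt[j] - tt[i] >= min_frac * span]
    if (!length(j)) next
    m <- j - i + 1
    sx <- cx[j + 1] - cx[i]; sy <- cy[j + 1] - cy[i]
    sxx <- cxx[j + 1] - cxx[i]; sxy <- cxy[j + 1] - cxy[i]
    syy <- cyy[j + 1] - cyy[i]
    Sxx <- sxx - sx^2 / m; Sxy <- sxy - sx * sy / m; Syy <- syy - sy^2 / m
    slope <- Sxy / Sxx
    r2 <- ifelse(Syy > 1e-300, Sxy^2 / (Sxx * Syy), 1)
    ok <- which(r2 >= r2_min)
    if (!length(ok)) next
    s_max <- max(abs(slope[ok]))
    near <- ok[abs(slope[ok]) >= s_max * (1 - 1e-9)]
    k <- near[length(near)]   # slope tie: prefer the longest window
    better <- is.null(best) ||
      abs(slope[k]) > abs(best$slope) * (1 + 1e-9) ||
      (abs(slope[k]) >= abs(best$slope) * (1 - 1e-9) &&
         j[k] - i > best$j - best$i)
    if (better) best <- list(i = i, j = j[k], slope = slope[k])
  }
  if (is.null(best))
    .abort("no linear region: every candidate window falls below the R^2 threshold",
           "nanocascade_no_linear_region")
  idx <- best$i:best$j
  f <- .linfit(tt[idx], yy[idx])
  list(start = tt[best$i], end = tt[best$j], idx = idx,
       slope = f$slope, intercept = f$intercept, r2 = f$r2,
       slope_se = f$slope_se, intercept_se = f$intercept_se, cov = f$cov)
}

#' Empirical transient time from a progress curve
#'
#' Fits a least-squares line to the curve's detected linear region and
#' reports the x-intercept `tau = -intercept/slope` -- the lag before the
#' cascade reaches steady-state product flux -- together with a
#' delta-method standard error propagated from the fit covariance.
#'
#' @param curve A [progress_curve] in concentration units.
#' @param sign Monitoring sign of the curve: +1 production (slope must be
#'   positive), -1 consumption (slope must be negative).
#' @param window Optional precomputed window from [detect_linear_region];
#'   detected automatically otherwise.
#' @param ... Passed to [detect_linear_region].
#' @return An object of class `transient_estimate`: `tau` (s), `tau_stderr`,
#'   `v_ss` (steady-state slope, uM/s), `window` (start/end, s), `r2`.
#' @examples
#' lag <- gen_lag_curve(v_ss = 0.02, tau = 1000, t_end = 10000)
#' tau_empirical(lag)
#' @export
tau_empirical <- function(curve, sign = 1L, window = NULL, ...) {
  stopifnot(inherits(curve, "progress_curve"))
  w <- window %||% detect_linear_region(curve, ...)
  if (sign > 0 && w$slope <= 0)
    .abort("non-positive steady-state slope on a production curve",
           "nanocascade_bad_fit")
  if (sign < 0 && w$slope >= 0)
    .abort("non-negative steady-state slope on a consumption curve",
           "nanocascade_bad_fit")
  a <- w$intercept; b <- w$slope
  tau <- -a / b
  # delta method on tau(a, b) with the fit covariance
  var_tau <- (w$intercept_se^2 / b^2) + (a^2 / b^4) * w$slope_se^2 -
    2 * (a / b^3) * w$cov
  structure(list(tau = tau, tau_stderr = sqrt(max(var_tau, 0)),
                 v_ss = b, window = c(w$start, w$end), r2 = w$r2),
            class = "transient_estimate")
}

#' @export
print.transient_estimate <- function(x, ...) {
  cat(sprintf("tau = %.0f +/- %.0f s (v_ss = %.3g uM/s, window %g-%g s, R^2 = %.4f)\n",
              x$tau, x$tau_stderr, x$v_ss, x$window[1], x$window[2], x$r2))
  invisible(x)
}

#' Diffusion-limited-regime report
#'
#' Channeling is observable only in the diffusion-limited regime, where the
#' catalytic rate exceeds the rate at which intermediates find the next
#' enzyme by diffusion. The encounter rate scales as
#' `min([E], [I])^(2/3) * D` with concentrations as number densities; this
#' function converts the supplied micromolar concentrations to molecules
#' per nm^3, forms the encounter scale in 1/s, and compares it with the
#' catalytic scale `kcat`.
#'
#' The comparison is an order-of-magnitude proportionality, not an
#' equality: `channeling_potential` is `TRUE` when
#' `kcat > crossover * encounter_scale`, with the crossover factor
#' configurable (default 1). Absolute regime boundaries should be read as
#' indicative only.
#'
#' @param enzyme_conc_uM Enzyme concentration, uM.
#' @param intermediate_conc_uM Intermediate concentration, uM.
#' @param diffusion_nm2_s Diffusion constant, nm^2/s (a small metabolite in
#'   water is ~5e8 nm^2/s).
#' @param kcat Catalytic rate, 1/s.
#' @param crossover Dimensionless crossover factor.
#' @return An object of class `regime_report` with fields `enzyme_conc`,
#'   `intermediate_conc`, `diffusion_const`, `encounter_scale` (1/s),
#'   `catalytic_scale` (1/s), `ratio` and `channeling_potential`.
#' @export
channeling_regime <- function(enzyme_conc_uM, intermediate_conc_uM,
                              diffusion_nm2_s, kcat, crossover = 1) {
  if (diffusion_nm2_s <= 0 || kcat <= 0 || crossover <= 0)
    .abort("diffusion constant, kcat and crossover must be positive",
           "nanocascade_bad_params")
  if (enzyme_conc_uM < 0 || intermediate_conc_uM < 0)
    .abort("concentrations must be non-negative", "nanocascade_bad_params")
  per_nm3 <- 6.02214076e-7   # molecules/nm^3 per uM
  n_min <- min(enzyme_conc_uM, intermediate_conc_uM) * per_nm3
  encounter <- n_min^(2 / 3) * diffusion_nm2_s
  ratio <- kcat / encounter
  structure(list(enzyme_conc = enzyme_conc_uM,
                 intermediate_conc = intermediate_conc_uM,
                 diffusion_const = diffusion_nm2_s,
                 encounter_scale = encounter, catalytic_scale = kcat,
                 ratio = ratio,
                 channeling_potential = ratio > crossover),
            class = "regime_report")
}

#' @export
print.regime_report <- function(x, ...) {
  cat(sprintf(paste0("Regime: encounter %.3g /s vs catalytic %.3g /s ",
                     "(ratio %.3g) -> channeling %sobservable\n"),
              x$encounter_scale, x$catalytic_scale, x$ratio,
              if (x$channeling_potential) "" else "not "))
  invisible(x)
}
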