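#' Plate-reader progress curve
#'
#' A time-stamped series of absorbance or concentration readings for one
#' well/condition.
#'
#' @param time Time stamps, s; strictly increasing, length >= 3.
#' @param value Readings: absorbance units (AU) or concentration (uM).
#' @param value_kind Either "absorbance" or "concentration".
#' @param label Condition identifier.
#' @return An object of class `progress_curve`.
#' @export
progress_curve <- function(time, value,
                           value_kind = c("concentration", "absorbance"),
                           label = "") {
  value_kind <- match.arg(value_kind)
  if (length(time) < 3L)
    .abort("a progress curve needs at least 3 samples", "nanocascade_bad_curve")
  if (length(time) != length(value))
    .abort("`time` and `value` must have equal length", "nanocascade_bad_curve")
  if (any(diff(time) <= 0))
    .abort("`time` must be strictly increasing", "nanocascade_bad_curve")
  structure(list(time = as.numeric(time), value = as.numeric(value),
                 value_kind = value_kind, label = label),
            class = "progress_curve")
}

#' @export
print.progress_curve <- function(x, ...) {
  cat(sprintf("Progress curve%s: %d samples over %g s (%s)\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$time), diff(range(x$time)), x$value_kind))
  invisible(x)
}

#' Convert absorbance to concentration (Beer-Lambert)
#'
#' `C [uM] = 1e6 * A / (epsilon * l)` with `epsilon` in 1/(M cm) and `l` in
#' cm. The NADH readout at 340 nm uses epsilon = 6220 1/(M cm).
#'
#' @param curve A [progress_curve] with `value_kind = "absorbance"`.
#' @param epsilon Extinction coefficient, 1/(M cm).
#' @param path_length_cm Optical path length, cm. No default: in plate
#'   readers the vertical path depends on fill volume and well geometry.
#' @return A [progress_curve] in concentration units (uM).
#' @export
absorbance_to_concentration <- function(curve, epsilon = 6220, path_length_cm) {
  stopifnot(inherits(curve, "progress_curve"))
  if (curve$value_kind != "absorbance")
    .abort("curve is already in concentration units", "nanocascade_bad_curve")
  if (epsilon <= 0 || path_length_cm <= 0)
    .abort("epsilon and path length must be positive", "nanocascade_bad_params")
  progress_curve(curve$time, 1e6 * curve$value / (epsilon * path_length_cm),
                 value_kind = "concentration", label = curve$label)
}

#' Convert concentration to absorbance (inverse Beer-Lambert)
#'
#' @inheritParams absorbance_to_concentration
#' @param curve A [progress_curve] with `value_kind = "concentration"`.
#' @return A [progress_curve] in absorbance units.
#' @export
concentration_to_absorbance <- function(curve, epsilon = 6220, path_length_cm) {
  stopifnot(inherits(curve, "progress_curve"))
  if (curve$value_kind != "concentration")
    .abort("curve is already in absorbance units", "nanocascade_bad_curve")
  if (epsilon <= 0 || path_length_cm <= 0)
    .abort("epsilon and path length must be positive", "nanocascade_bad_params")
  progress_curve(curve$time, curve$value * epsilon * path_length_cm * 1e-6,
                 value_kind = "absorbance", label = curve$label)
}

# Least-squares line on value ~ time over an index window; returns slope,
# intercept, their standard errors, covariance and R^2. Flat windows count
# as perfectly linear (R^2 = 1, zero slope).
.linfit <- function(time, value) {
  n <- length(time)
  mx <- mean(time); my <- mean(value)
  sxx <- sum((time - mx)^2)
  sxy <- sum((time - mx) * (value - my))
  syy <- sum((value - my)^2)
  slope <- sxy / sxx
  intercept <- my - slope * mx
  sse <- max(syy - slope * sxy, 0)
  r2 <- if (syy > 0) 1 - sse / syy else 1
  s2 <- if (n > 2) sse / (n - 2) else 0
  list(slope = slope, intercept = intercept, r2 = r2,
       slope_se = sqrt(s2 / sxx),
       intercept_se = sqrt(s2 * (1 / n + mx^2 / sxx)),
       cov = -s2 * mx / sxx, n = n)
}

#' Initial rate from the early linear portion of a progress curve
#'
#' Finds the earliest contiguous window of at least `min_points` samples
#' whose linear fit has R^2 >= `r2_min` and over which no more than
#' `max_depletion` of the substrate has been consumed, then extends it
#' while both criteria continue to hold, and reports the least-squares
#' slope.
#'
#' The depletion cap needs the initial substrate concentration `s0`; when
#' `s0` is not supplied only the linearity criteria apply (a late-time
#' plateau then simply fails the R^2 test).
#'
#' @param curve A [progress_curve] in concentration units.
#' @param min_points Minimum samples in the fitted window.
#' @param r2_min Linearity threshold.
#' @param max_depletion Maximal fraction of substrate consumed in-window.
#' @param s0 Optional initial substrate concentration, uM.
#' @return List with `rate` (uM/s, absolute value of the slope), `slope`,
#'   `stderr`, `window` (start/end times), `r2`, `n`.
#' @export
initial_rate <- function(curve, min_points = 10, r2_min = 0.99,
                         max_depletion = 0.10, s0 = NULL) {
  stopifnot(inherits(curve, "progress_curve"))
  if (curve$value_kind != "concentration")
    .abort("convert the curve to concentration units first", "nanocascade_bad_curve")
  n <- length(curve$time)
  if (n < min_points)
    .abort(sprintf("need at least %d samples, got %d", min_points, n),
           "nanocascade_too_few_points")
  budget <- if (!is.null(s0)) max_depletion * s0 else Inf
  ok <- function(i, j) {
    if (abs(curve$value[j] - curve$value[i]) > budget) return(NULL)
    f <- .linfit(curve$time[i:j], curve$value[i:j])
    if (f$r2 >= r2_min) f else NULL
  }
  for (i in seq_len(n - min_points + 1L)) {
    j <- i + min_points - 1L
    f <- ok(i, j)
    if (is.null(f)) next
    while (j < n) {
      f2 <- ok(i, j + 1L)
      if (is.null(f2)) break
      j <- j + 1L; f <- f2
    }
    return(list(rate = abs(f$slope), slope = f$slope, stderr = f$slope_se,
                window = c(curve$time[i], curve$time[j]), r2 = f$r2, n = f$n))
  }
  .abort("no early-time window satisfies the linearity policy",
         "nanocascade_no_linear_region")
}

#' Initial-rate dataset for Michaelis-Menten fitting
#'
#' @param substrate_uM Substrate concentrations, uM (non-negative).
#' @param rate_uM_s Matching initial rates, uM/s.
#' @param rate_se Optional per-point replicate spread (standard errors).
#' @return An object of class `rate_dataset`.
#' @export
rate_dataset <- function(substrate_uM, rate_uM_s, rate_se = NULL) {
  if (length(substrate_uM) != length(rate_uM_s))
    .abort("substrate and rate vectors must have equal length",
           "nanocascade_bad_dataset")
  if (any(substrate_uM < 0))
    .abort("substrate concentrations must be non-negative",
           "nanocascade_bad_dataset")
  structure(list(substrate_uM = as.numeric(substrate_uM),
                 rate_uM_s = as.numeric(rate_uM_s),
                 rate_se = rate_se),
            class = "rate_dataset")
}

#' Fit the Michaelis-Menten equation to an initial-rate dataset
#'
#' Nonlinear least squares (Levenberg-Marquardt) for `v = Vmax*S/(KM+S)`,
#' with `kcat = Vmax / enzyme_conc` and the catalytic efficiency
#' `kcat/KM` reported in 1/(mM s).
#'
#' A warning is raised when fewer than four distinct substrate levels are
#' available or when the levels do not straddle the fitted KM; in either
#' case KM is weakly identified and its standard error will be inflated.
#'
#' @param dataset A [rate_dataset].
#' @param enzyme_conc Enzyme concentration in the rate assays, uM.
#' @return An object of class `mm_fit`: `params` ([mm_params]), `vmax`,
#'   `vmax_se`, `kcat_se`, `km_se`, `efficiency_mM_s`, `residual_sd`,
#'   `n_levels`.
#' @export
fit_mm <- function(dataset, enzyme_conc) {
  stopifnot(inherits(dataset, "rate_dataset"))
  if (enzyme_conc <= 0)
    .abort("`enzyme_conc` must be positive (uM)", "nanocascade_bad_params")
  s <- dataset$substrate_uM; v <- dataset$rate_uM_s
  if (all(v == 0))
    .abort("all rates are zero; nothing to fit", "nanocascade_bad_dataset")
  n_levels <- length(unique(s[s > 0]))
  if (n_levels < 4L)
    warning("fewer than 4 distinct substrate levels; KM is weakly identified")
  # Hanes linearization (s/v ~ s) seeds the nonlinear fit; it stays sane
  # even when every level sits far below KM and v is near-linear in s.
  pos <- s > 0 & v > 0
  start <- list(vmax = max(v) * 1.2, km = max(median(s[s > 0]), 1e-6))
  if (sum(pos) >= 2) {
    h <- unname(coef(lm(I(s[pos] / v[pos]) ~ s[pos])))
    if (is.finite(h[2]) && h[2] > 0 && is.finite(h[1]) && h[1] > 0)
      start <- list(vmax = 1 / h[2], km = h[1] / h[2])
  }
  # a start far beyond the sampled range makes the (vmax, km) gradient
  # columns numerically collinear; cap it inside the identifiable zone
  start$km <- min(start$km, 10 * max(s))
  fit <- minpack.lm::nls.lm(
    par = c(vmax = start$vmax, km = start$km),
    fn = function(p) v - p[[1]] * s / (p[[2]] + s),
    lower = c(1e-12, 1e-9),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  if (fit$info == 0 || !all(is.finite(fit$par)))
    .abort("Michaelis-Menten fit failed to converge", "nanocascade_bad_fit")
  est <- fit$par
  dof <- max(length(v) - 2L, 1L)
  sigma2 <- fit$deviance / dof
  # covariance from the Gauss-Newton hessian; a numerically singular
  # hessian (flat KM ridge) yields infinite standard errors
  se <- tryCatch(sqrt(pmax(diag(solve(fit$hessian)) * sigma2, 0)),
                 error = function(e) c(Inf, Inf))
  if (est[["km"]] > max(s) || est[["km"]] < min(s[s > 0]) ||
      !all(is.finite(se)) || se[[2]] > est[["km"]])
    warning(sprintf(paste0("substrate levels (%g-%g uM) identify the fitted ",
                           "KM (%g uM) poorly; its uncertainty is inflated"),
                    min(s[s > 0]), max(s), est[["km"]]))
  kcat <- est[["vmax"]] / enzyme_conc
  structure(list(
    params = mm_params(kcat, est[["km"]],
                       kcat_se = se[[1]] / enzyme_conc, km_se = se[[2]]),
    vmax = est[["vmax"]], vmax_se = se[[1]],
    kcat_se = se[[1]] / enzyme_conc, km_se = se[[2]],
    efficiency_mM_s = kcat / (est[["km"]] / 1000),
    residual_sd = sqrt(sigma2),
    n_levels = n_levels, enzyme_conc = enzyme_conc),
    class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("MM fit: Vmax = %.4g uM/s, KM = %.4g uM, kcat = %.4g /s, kcat/KM = %.4g /(mM s)\n",
              x$vmax, x$params$km, x$params$kcat, x$efficiency_mM_s))
  invisible(x)
}

# ratio + delta-method standard error for b/f given independent fits
.ratio_se <- function(b, b_se, f, f_se) {
  r <- b / f
  se <- if (anyNA(c(b_se, f_se))) NA_real_
        else abs(r) * sqrt((b_se / b)^2 + (f_se / f)^2)
  c(ratio = r, se = se)
}

#' Free-versus-bound fold-enhancement table
#'
#' Per-enzyme ratios bound/free of kcat, KM, catalytic efficiency and
#' specific activity, with a not-significant ("NS") flag wherever the
#' two-sided 95% interval of the ratio (delta-method propagation of the two
#' fit standard errors) includes 1.
#'
#' Specific activity is proportional to kcat for a fixed enzyme mass, so
#' its fold change equals the kcat fold change and shares its flag.
#'
#' @param free_fits,bound_fits Named lists of [mm_fit] (or [mm_params])
#'   objects with matching enzyme keys.
#' @return Data frame with one row per enzyme: fold changes and NS flags.
#' @export
enhancement_table <- function(free_fits, bound_fits) {
  keys <- names(free_fits)
  if (!setequal(keys, names(bound_fits)))
    .abort("free and bound fit lists must have matching enzyme keys",
           "nanocascade_bad_dataset")
  as_params <- function(x) if (inherits(x, "mm_fit")) x$params else x
  rows <- lapply(keys, function(k) {
    f <- as_params(free_fits[[k]]); b <- as_params(bound_fits[[k]])
    kc <- .ratio_se(b$kcat, b$kcat_se, f$kcat, f$kcat_se)
    km <- .ratio_se(b$km, b$km_se, f$km, f$km_se)
    eff_f <- f$kcat / f$km; eff_b <- b$kcat / b$km
    eff_se <- function(p) if (anyNA(c(p$kcat_se, p$km_se))) NA_real_
                          else (p$kcat / p$km) * sqrt((p$kcat_se / p$kcat)^2 +
                                                      (p$km_se / p$km)^2)
    ef <- .ratio_se(eff_b, eff_se(b), eff_f, eff_se(f))
    ns <- function(x) is.na(x[["se"]]) || abs(x[["ratio"]] - 1) <= 1.96 * x[["se"]]
    data.frame(enzyme = k,
               fold_kcat = kc[["ratio"]], ns_kcat = ns(kc),
               fold_km = km[["ratio"]], ns_km = ns(km),
               fold_efficiency = ef[["ratio"]], ns_efficiency = ns(ef),
               fold_sa = kc[["ratio"]], ns_sa = ns(kc))
  })
  do.call(rbind, rows)
}

#' Read plate-reader progress curves from CSV
#'
#' Accepts either the tidy dialect (`time_s`, `label`, `value`,
#' `value_kind`) or a wide dialect (`time_s` plus one column per well, all
#' absorbance); the dialect is detected from the header.
#'
#' @param path CSV file path.
#' @return Named list of [progress_curve] objects.
#' @export
read_progress_csv <- function(path) {
  if (!file.exists(path))
    .abort(sprintf("progress-curve file not found: %s", path),
           "nanocascade_missing_file")
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"time_s" %in% names(df))
    .abort(sprintf("%s: expected a `time_s` column", path),
           "nanocascade_bad_format")
  if (all(c("label", "value", "value_kind") %in% names(df))) {
    out <- lapply(split(df, df$label), function(d)
      progress_curve(d$time_s, d$value, value_kind = d$value_kind[1],
                     label = d$label[1]))
  } else {
    wells <- setdiff(names(df), "time_s")
    out <- lapply(wells, function(w)
      progress_curve(df$time_s, df[[w]], value_kind = "absorbance", label = w))
    names(out) <- wells
  }
  out
}

#' Write progress curves to tidy CSV
#'
#' @param curves A [progress_curve] or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_progress_csv <- function(curves, path) {
  if (inherits(curves, "progress_curve")) curves <- list(curves)
  df <- do.call(rbind, lapply(curves, function(cu)
    data.frame(time_s = cu$time, label = cu$label, value = cu$value,
               value_kind = cu$value_kind)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write Michaelis-Menten fits to CSV
#'
#' Column order mirrors the kinetic-characterization tables: Vmax, KM,
#' kcat, kcat/KM.
#'
#' @param fits Named list of [mm_fit] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mm_fits_csv <- function(fits, path) {
  df <- do.call(rbind, lapply(names(fits), function(k) {
    f <- fits[[k]]
    data.frame(enzyme = k, vmax_uM_per_s = f$vmax, km_uM = f$params$km,
               kcat_per_s = f$params$kcat, eff_per_mM_s = f$efficiency_mM_s,
               vmax_se = f$vmax_se, km_se = f$km_se, kcat_se = f$kcat_se)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
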