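#' Cascade flux objective: monitored product formed by an observation time
#'
#' Signed displacement of the monitored species between t = 0 and `t_obs`
#' (production cascades count formation, consumption cascades count
#' depletion), the standard end-point readout for comparing enzyme
#' allocations.
#'
#' @param spec A [cascade_spec].
#' @param conditions An [assay_conditions]; must satisfy
#'   `t_obs <= conditions$t_end`.
#' @param enzyme_concs Named numeric vector of enzyme concentrations, uM.
#' @param t_obs Observation time, s (default 30000, the standard readout).
#' @param context Kinetic-parameter context.
#' @return Product formed (or consumed) by `t_obs`, uM (non-negative).
#' @export
objective_flux <- function(spec, conditions, enzyme_concs, t_obs = 30000,
                           context = c("free", "bound")) {
  context <- match.arg(context)
  if (t_obs > conditions$t_end)
    .abort("`t_obs` lies beyond the simulated span", "nanocascade_bad_conditions")
  sim <- simulate_cascade(spec, conditions, enzyme_concs, context = context)
  mon <- sim$conc[, spec$monitored]
  i <- which.min(abs(sim$time - t_obs))
  spec$sign * (mon[i] - mon[1])
}

#' Enzyme-stoichiometry optimization problem
#'
#' Bounds may be given directly in uM, or derived from per-particle display
#' capacities: with `np_conc_nM` set, each enzyme's bounds are its capacity
#' range for `np_name` (copies per particle) times the particle
#' concentration.
#'
#' @param spec A [cascade_spec].
#' @param conditions An [assay_conditions].
#' @param lower,upper Optional named bounds on enzyme concentrations, uM.
#' @param np_conc_nM Optional nanoparticle concentration, nM.
#' @param np_name Nanoparticle type name used to look up capacities.
#' @param budget Optional cap on the summed enzyme concentration, uM.
#' @param t_obs Objective observation time, s.
#' @param context Kinetic-parameter context.
#' @return An object of class `opt_problem`.
#' @export
opt_problem <- function(spec, conditions, lower = NULL, upper = NULL,
                        np_conc_nM = NULL, np_name = "QD520", budget = NULL,
                        t_obs = 30000, context = c("free", "bound")) {
  context <- match.arg(context)
  enz <- cascade_enzymes(spec)
  if (!is.null(np_conc_nM)) {
    caps <- lapply(spec$steps, function(st) {
      rng <- st$enzyme$capacity[[np_name]]
      if (is.null(rng))
        .abort(sprintf("enzyme %s has no capacity entry for %s",
                       st$enzyme$abbrev, np_name), "nanocascade_bad_params")
      unlist(rng) * np_conc_nM * 1e-3    # copies/NP * nM -> uM
    })
    lower <- setNames(vapply(caps, `[`, numeric(1), 1L), enz)
    upper <- setNames(vapply(caps, `[`, numeric(1), 2L), enz)
  }
  if (is.null(lower) || is.null(upper) ||
      !all(enz %in% names(lower)) || !all(enz %in% names(upper)))
    .abort("bounds must cover every enzyme (directly or via np_conc_nM)",
           "nanocascade_bad_params")
  lower <- lower[enz]; upper <- upper[enz]
  if (any(lower > upper))
    .abort("inconsistent bounds: lower > upper", "nanocascade_bad_params")
  if (!is.null(budget) && sum(lower) > budget)
    .abort("infeasible: the budget is below the summed lower bounds",
           "nanocascade_infeasible")
  if (t_obs > conditions$t_end)
    .abort("`t_obs` lies beyond the simulated span", "nanocascade_bad_conditions")
  structure(list(spec = spec, conditions = conditions, lower = lower,
                 upper = upper, budget = budget, t_obs = t_obs,
                 context = context),
            class = "opt_problem")
}

# Clip a candidate to bounds and to the budget. A move that would exceed
# the budget rescales the other coordinates down (a ratio move along the
# budget simplex); when they are already at their lower bounds the moved
# coordinate is shrunk instead. Returns NULL when the move is impossible.
.clip_move <- function(x, k, value, lower, upper, budget) {
  value <- min(max(value, lower[k]), upper[k])
  x[k] <- value
  if (!is.null(budget) && sum(x) > budget) {
    others <- setdiff(seq_along(x), k)
    room <- budget - value
    if (room >= sum(lower[others]) && sum(x[others]) > 0) {
      x[others] <- pmax(lower[others], x[others] * room / sum(x[others]))
    }
    if (sum(x) > budget + 1e-12) {
      x[k] <- budget - sum(x[others])
      if (x[k] < lower[k] - 1e-12) return(NULL)
      x[k] <- max(x[k], lower[k])
    }
  }
  x
}

#' Two-round numerical optimization of enzyme ratios
#'
#' Coordinate-wise multiplicative grid search in two consecutive rounds:
#' round 1 sweeps coarse factors (x1/2, x1, x2, x4) on each enzyme in turn,
#' repeating passes until no move improves the objective; round 2 refines
#' around the round-1 optimum with fine factors (x0.75 ... x1.5). Moves are
#' clipped to the bounds and, when a budget is set, the moved coordinate is
#' shrunk so the summed concentration stays within it. The incumbent is
#' only ever replaced by a strict improvement -- or by an equal objective
#' at a lower total enzyme concentration (parsimony tie-break) -- so the
#' best objective is non-decreasing across rounds.
#'
#' @param problem An [opt_problem].
#' @param rounds Number of rounds (default 2).
#' @param start Optional named starting allocation, uM; defaults to the
#'   bound midpoints (budget-scaled if needed).
#' @param factors List of per-round factor vectors; defaults to the
#'   two-round scheme above (rounds beyond 2 reuse the fine factors).
#' @param max_passes Cap on coordinate passes per round.
#' @param seed Optional RNG seed, recorded for provenance (the search
#'   itself is deterministic).
#' @return An object of class `opt_result`: `par` (uM), `ratios` (copies
#'   per particle if the problem was capacity-derived, else `par` scaled by
#'   its minimum), `objective`, `round_best` (best objective after each
#'   round), `evaluations`, `trace`.
#' @export
optimize_ratios <- function(problem, rounds = 2, start = NULL, factors = NULL,
                            max_passes = 5, seed = NULL) {
  stopifnot(inherits(problem, "opt_problem"))
  if (!is.null(seed)) set.seed(seed)
  lower <- problem$lower; upper <- problem$upper; budget <- problem$budget
  enz <- names(lower)
  factors <- factors %||% default_config()$optimize[
    c("round1_factors", "round2_factors")]
  factors <- lapply(factors, unlist)
  if (rounds > length(factors))
    factors <- c(factors, rep(factors[length(factors)], rounds - length(factors)))

  x <- start %||% (lower + upper) / 2
  x <- x[enz]
  if (!is.null(budget) && sum(x) > budget)
    x <- pmax(lower, x * budget / sum(x))
  evals <- 0L
  f_of <- function(x) {
    evals <<- evals + 1L
    objective_flux(problem$spec, problem$conditions, x, t_obs = problem$t_obs,
                   context = problem$context)
  }
  best_x <- x; best_f <- f_of(x)
  round_best <- numeric(0); trace <- list()

  for (r in seq_len(rounds)) {
    fs <- factors[[min(r, length(factors))]]
    for (pass in seq_len(max_passes)) {
      improved <- FALSE
      for (k in seq_along(enz)) {
        for (f in setdiff(fs, 1)) {
          cand <- .clip_move(best_x, k, best_x[k] * f, lower, upper, budget)
          if (is.null(cand) || isTRUE(all.equal(cand, best_x))) next
          fc <- f_of(cand)
          better <- fc > best_f + 1e-12 ||
            (abs(fc - best_f) <= 1e-12 && sum(cand) < sum(best_x))
          if (better) { best_x <- cand; best_f <- fc; improved <- TRUE }
        }
      }
      if (!improved) break
    }
    round_best <- c(round_best, best_f)
    trace[[r]] <- best_x
  }
  ratios <- best_x / min(best_x[best_x > 0])
  structure(list(par = best_x, ratios = ratios, objective = best_f,
                 round_best = round_best, evaluations = evals, trace = trace),
            class = "opt_result")
}

#' @export
print.opt_result <- function(x, ...) {
  cat(sprintf("Optimized allocation (objective %.4g uM, %d evaluations):\n",
              x$objective, x$evaluations))
  print(signif(x$par, 4))
  invisible(x)
}
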