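#' Michaelis-Menten parameter set
#'
#' Bundles the apparent per-monomer turnover number and Michaelis constant
#' of one enzyme in one measurement context (free in solution, or displayed
#' on a nanoparticle).
#'
#' @param kcat Turnover number, 1/s per monomer active site. Must be > 0.
#' @param km Michaelis constant, uM. Must be > 0.
#' @param kcat_se,km_se Optional standard errors (same units).
#' @param direction_note Optional free-text note, e.g. when the assay ran
#'   the reverse reaction for technical reasons.
#' @return An object of class `mm_params`.
#' @examples
#' mm_params(kcat = 2.6, km = 36)
#' @export
mm_params <- function(kcat, km, kcat_se = NA_real_, km_se = NA_real_,
                      direction_note = NULL) {
  if (!is.numeric(kcat) || length(kcat) != 1L || !is.finite(kcat) || kcat <= 0)
    .abort("`kcat` must be a single positive number (1/s)", "nanocascade_bad_params")
  if (!is.numeric(km) || length(km) != 1L || !is.finite(km) || km <= 0)
    .abort("`km` must be a single positive number (uM)", "nanocascade_bad_params")
  structure(list(kcat = as.numeric(kcat), km = as.numeric(km),
                 kcat_se = as.numeric(kcat_se), km_se = as.numeric(km_se),
                 direction_note = direction_note),
            class = "mm_params")
}

#' @export
print.mm_params <- function(x, ...) {
  cat(sprintf("MM params: kcat = %g /s, KM = %g uM\n", x$kcat, x$km))
  if (!is.null(x$direction_note)) cat("  note:", x$direction_note, "\n")
  invisible(x)
}

#' Enzyme definition
#'
#' Describes one cascade enzyme: oligomeric state, monomer mass, kinetic
#' parameters free in solution and (optionally) nanoparticle-bound, and the
#' estimated range of copies that fit per nanoparticle type.
#'
#' @param name Full enzyme name.
#' @param abbrev Short identifier used in cascade definitions (e.g. "Glk").
#' @param subunits Oligomeric count; one of 1, 2 or 4. Multimeric enzymes
#'   carry several terminal His6 motifs and can cross-link nanoparticles.
#' @param monomer_kda Monomer molecular weight, kDa.
#' @param params_free [mm_params] measured free in solution.
#' @param params_bound Optional [mm_params] measured nanoparticle-bound.
#' @param capacity Named list mapping nanoparticle type to an integer
#'   `c(min, max)` range of copies per particle.
#' @param delta_g Optional standard transformed reaction energy of the step
#'   this enzyme catalyses, kJ/mol.
#' @return An object of class `enzyme_def`.
#' @export
enzyme_def <- function(name, abbrev, subunits, monomer_kda, params_free,
                       params_bound = NULL, capacity = list(),
                       delta_g = NA_real_) {
  if (!subunits %in% c(1L, 2L, 4L))
    .abort(sprintf("%s: `subunits` must be 1, 2 or 4", abbrev),
           "nanocascade_bad_params")
  if (!is.numeric(monomer_kda) || monomer_kda <= 0)
    .abort(sprintf("%s: `monomer_kda` must be positive", abbrev),
           "nanocascade_bad_params")
  stopifnot(inherits(params_free, "mm_params"))
  if (!is.null(params_bound)) stopifnot(inherits(params_bound, "mm_params"))
  for (rng in capacity)
    if (length(rng) != 2L || rng[1] > rng[2] || any(rng < 1))
      .abort(sprintf("%s: capacity ranges must be c(min, max) with 1 <= min <= max",
                     abbrev), "nanocascade_bad_params")
  structure(list(name = name, abbrev = abbrev, subunits = as.integer(subunits),
                 monomer_kda = as.numeric(monomer_kda),
                 params_free = params_free, params_bound = params_bound,
                 capacity = capacity, delta_g = as.numeric(delta_g)),
            class = "enzyme_def")
}

#' @export
print.enzyme_def <- function(x, ...) {
  cat(sprintf("%s (%s): %d subunit(s), %g kDa/monomer\n",
              x$name, x$abbrev, x$subunits, x$monomer_kda))
  cat(sprintf("  free : kcat %g /s, KM %g uM\n",
              x$params_free$kcat, x$params_free$km))
  if (!is.null(x$params_bound))
    cat(sprintf("  bound: kcat %g /s, KM %g uM\n",
                x$params_bound$kcat, x$params_bound$km))
  invisible(x)
}

# Select the kinetic-parameter context; errors when bound params are absent.
enzyme_params <- function(enz, context = c("free", "bound")) {
  context <- match.arg(context)
  if (context == "free") return(enz$params_free)
  if (is.null(enz$params_bound))
    .abort(sprintf("enzyme %s has no nanoparticle-bound parameters", enz$abbrev),
           "nanocascade_missing_bound")
  enz$params_bound
}

#' Read an enzyme/nanoparticle configuration file
#'
#' Parses the package's structured YAML configuration format with sections
#' `cascade`, `conditions`, `assay`, `noise`, `optimize`, `np`, and
#' `enzymes.<abbrev>`. The packaged default (`system.file("extdata",
#' "enzymes.yaml", package = "nanocascade")`) encodes the full apparent
#' kinetic characterization of the fourteen cascade enzymes together with
#' per-particle display capacities and standard assay conditions.
#'
#' @param path Path to a YAML configuration file.
#' @return A list with elements `enzymes` (named list of [enzyme_def]),
#'   `np_types` (named list of [np_type]), and the raw `cascade`,
#'   `conditions`, `assay`, `noise`, `optimize` sections.
#' @export
read_enzyme_config <- function(path) {
  if (!file.exists(path))
    .abort(sprintf("configuration file not found: %s", path),
           "nanocascade_missing_file")
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$enzymes))
    .abort(sprintf("configuration %s has no [enzymes] section", path),
           "nanocascade_bad_config")
  enzymes <- lapply(names(cfg$enzymes), function(ab) {
    e <- cfg$enzymes[[ab]]
    mk <- function(block, note = NULL) {
      if (is.null(block)) return(NULL)
      mm_params(block$kcat, block$km,
                kcat_se = block$kcat_se %||% NA_real_,
                km_se = block$km_se %||% NA_real_,
                direction_note = note)
    }
    enzyme_def(name = e$name, abbrev = ab, subunits = e$subunits,
               monomer_kda = e$monomer_kda,
               params_free = mk(e$free, e$direction_note),
               params_bound = mk(e$bound, e$direction_note),
               capacity = e$capacity %||% list(),
               delta_g = e$delta_g %||% NA_real_)
  })
  names(enzymes) <- names(cfg$enzymes)
  np_types <- lapply(names(cfg$np %||% list()), function(nm) {
    n <- cfg$np[[nm]]
    np_type(nm, shape = n$shape, dims = unlist(n$dims),
            max_sites = n$max_sites %||% NULL)
  })
  names(np_types) <- names(cfg$np %||% list())
  list(enzymes = enzymes, np_types = np_types,
       cascade = cfg$cascade, conditions = cfg$conditions,
       assay = cfg$assay, noise = cfg$noise, optimize = cfg$optimize)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.config_cache <- new.env(parent = emptyenv())

default_config <- function() {
  if (is.null(.config_cache$cfg)) {
    path <- system.file("extdata", "enzymes.yaml", package = "nanocascade")
    .config_cache$cfg <- read_enzyme_config(path)
  }
  .config_cache$cfg
}

#' Packaged enzyme table
#'
#' The default definitions of the fourteen glycolysis/saccharification
#' enzymes: oligomeric state, monomer mass, apparent Michaelis-Menten
#' constants free in solution and quantum-dot-bound, display capacity
#' ranges per nanoparticle type, and the two printed standard transformed
#' reaction energies (GPD +15.9, PGK -20.2 kJ/mol).
#'
#' @return Named list of [enzyme_def] objects.
#' @examples
#' default_enzymes()$Glk
#' @export
default_enzymes <- function() default_config()$enzymes

#' Packaged nanoparticle types
#'
#' Spherical quantum dots of 4.0, 9.7 and 13.4 nm diameter (QD520, QD600,
#' QD660) and a 19.2 x 17.3 x 2.6 nm planar nanoplatelet (NPL).
#'
#' @return Named list of [np_type] objects.
#' @export
default_np_types <- function() default_config()$np_types

#' Printed working enzyme concentrations for cascade assays
#'
#' Free-enzyme working concentrations used in the reported cascade assays,
#' available for the 7E, 9E and 4E presets.
#'
#' @param preset One of "7E", "9E", "4E".
#' @return Named numeric vector of concentrations in uM.
#' @examples
#' preset_enzyme_concs("7E")
#' @export
preset_enzyme_concs <- function(preset) {
  tab <- default_config()$assay$enzyme_concs_nM
  if (is.null(tab[[preset]]))
    .abort(sprintf("no printed enzyme concentrations for preset %s", preset),
           "nanocascade_unknown_preset")
  unlist(tab[[preset]]) * 1e-3   # nM -> uM
}
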