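#' Michaelis-Menten rate
#'
#' Instantaneous rate `kcat * E * S / (KM + S)` of a single enzymatic step.
#'
#' @param params [mm_params] for the enzyme.
#' @param enzyme_conc Enzyme concentration, uM (monomer active sites).
#' @param substrate_conc Substrate concentration, uM.
#' @return Rate in uM/s.
#' @examples
#' glk <- default_enzymes()$Glk$params_free
#' mm_rate(glk, enzyme_conc = 1e-3, substrate_conc = glk$km)  # kcat*E/2
#' @export
mm_rate <- function(params, enzyme_conc, substrate_conc) {
  stopifnot(inherits(params, "mm_params"))
  if (any(enzyme_conc < 0) || any(substrate_conc < 0))
    .abort("enzyme and substrate concentrations must be non-negative",
           "nanocascade_bad_params")
  params$kcat * enzyme_conc * substrate_conc / (params$km + substrate_conc)
}

#' Reaction step of a cascade
#'
#' One enzymatic transformation: named substrate and product stoichiometries
#' over the species registry, the species whose Michaelis-Menten saturation
#' governs the rate, and the co-substrates whose availability multiplies it.
#'
#' @param enzyme [enzyme_def] catalysing the step.
#' @param substrates Named numeric vector, species -> positive coefficient.
#' @param products Named numeric vector, species -> positive coefficient.
#' @param limiting Name of the rate-governing (MM-saturating) substrate;
#'   must appear in `substrates`.
#' @param cofactors Character vector of consumed co-substrate species whose
#'   availability enters the rate as the smooth factor `C/(C + K_cof)`.
#'   Each must appear in `substrates`.
#' @param delta_g Optional step standard transformed reaction energy, kJ/mol;
#'   defaults to the enzyme definition's value.
#' @return An object of class `reaction_step`.
#' @export
reaction_step <- function(enzyme, substrates, products, limiting,
                          cofactors = character(), delta_g = NULL) {
  stopifnot(inherits(enzyme, "enzyme_def"))
  if (is.null(names(substrates)) || is.null(names(products)) ||
      any(substrates <= 0) || any(products <= 0))
    .abort("substrates/products must be named vectors of positive coefficients",
           "nanocascade_bad_step")
  if (!limiting %in% names(substrates))
    .abort(sprintf("limiting species %s is not a substrate of %s",
                   limiting, enzyme$abbrev), "nanocascade_bad_step")
  if (!all(cofactors %in% names(substrates)))
    .abort(sprintf("cofactors of %s must be declared substrates", enzyme$abbrev),
           "nanocascade_bad_step")
  structure(list(enzyme = enzyme, substrates = substrates, products = products,
                 limiting = limiting, cofactors = cofactors,
                 delta_g = delta_g %||% enzyme$delta_g),
            class = "reaction_step")
}

#' Cascade specification
#'
#' An ordered chain of [reaction_step]s over a species registry, with the
#' monitored species and the sign in which it is monitored (+1 = production,
#' -1 = consumption).
#'
#' @param steps List of [reaction_step].
#' @param monitored Name of the monitored species (e.g. "NADH").
#' @param sign +1 or -1.
#' @param couples List of 2-element character vectors naming conserved
#'   cofactor couples (e.g. `c("NAD", "NADH")`), used by conservation checks.
#' @param preset Optional preset label.
#' @return An object of class `cascade_spec`.
#' @export
cascade_spec <- function(steps, monitored, sign = 1L, couples = list(),
                         preset = NULL) {
  stopifnot(length(steps) >= 1L, all(vapply(steps, inherits, TRUE, "reaction_step")))
  species <- unique(unlist(lapply(steps, function(s)
    c(names(s$substrates), names(s$products)))))
  if (!monitored %in% species)
    .abort(sprintf("monitored species %s does not appear in any step", monitored),
           "nanocascade_bad_spec")
  if (!sign %in% c(-1L, 1L))
    .abort("`sign` must be +1 or -1", "nanocascade_bad_spec")
  for (cp in couples)
    if (!all(cp %in% species))
      .abort("every cofactor couple species must appear in the registry",
             "nanocascade_bad_spec")
  structure(list(steps = steps, species = species, monitored = monitored,
                 sign = as.integer(sign), couples = couples, preset = preset),
            class = "cascade_spec")
}

#' @export
print.cascade_spec <- function(x, ...) {
  cat(sprintf("Cascade%s: %d steps, %d species, monitors %s (%s)\n",
              if (is.null(x$preset)) "" else paste0(" [", x$preset, "]"),
              length(x$steps), length(x$species), x$monitored,
              if (x$sign > 0) "production" else "consumption"))
  for (s in x$steps)
    cat(sprintf("  %-4s: %s -> %s\n", s$enzyme$abbrev,
                paste(names(s$substrates), collapse = " + "),
                paste(names(s$products), collapse = " + ")))
  invisible(x)
}

#' Enzyme abbreviations of a cascade, in step order
#' @param spec A [cascade_spec].
#' @return Character vector.
#' @export
cascade_enzymes <- function(spec) {
  unname(vapply(spec$steps, function(s) s$enzyme$abbrev, character(1)))
}

# Step table shared by the presets. Maltoheptaose (7 glucose units) is
# hydrolysed to 3.5 maltose equivalents, maltase releases 2 glucose per
# maltose, so glucose-unit bookkeeping closes.
.preset_steps <- function(enzymes) {
  need <- function(ab) {
    if (is.null(enzymes[[ab]]))
      .abort(sprintf("enzyme table is missing a definition for %s", ab),
             "nanocascade_missing_enzyme")
    enzymes[[ab]]
  }
  list(
    Inv = reaction_step(need("Inv"),
      substrates = c(SUC = 1), products = c(GLC = 1, FRU = 1), limiting = "SUC"),
    Amy = reaction_step(need("Amy"),
      substrates = c(MH = 1), products = c(MAL = 3.5), limiting = "MH"),
    Mlt = reaction_step(need("Mlt"),
      substrates = c(MAL = 1), products = c(GLC = 2), limiting = "MAL"),
    Glk = reaction_step(need("Glk"),
      substrates = c(GLC = 1, ATP = 1), products = c(G6P = 1, ADP = 1),
      limiting = "GLC", cofactors = "ATP"),
    PGI = reaction_step(need("PGI"),
      substrates = c(G6P = 1), products = c(F6P = 1), limiting = "G6P"),
    PFK = reaction_step(need("PFK"),
      substrates = c(F6P = 1, ATP = 1), products = c(FBP = 1, ADP = 1),
      limiting = "F6P", cofactors = "ATP"),
    FBA = reaction_step(need("FBA"),
      substrates = c(FBP = 1), products = c(DHAP = 1, G3P = 1), limiting = "FBP"),
    TPI = reaction_step(need("TPI"),
      substrates = c(DHAP = 1), products = c(G3P = 1), limiting = "DHAP"),
    GPD = reaction_step(need("GPD"),
      substrates = c(G3P = 1, NAD = 1, Pi = 1), products = c(BPG = 1, NADH = 1),
      limiting = "G3P", cofactors = c("NAD", "Pi")),
    PGK = reaction_step(need("PGK"),
      substrates = c(BPG = 1, ADP = 1), products = c(PG3 = 1, ATP = 1),
      limiting = "BPG", cofactors = "ADP"),
    PGM = reaction_step(need("PGM"),
      substrates = c(PG3 = 1), products = c(PG2 = 1), limiting = "PG3"),
    Eno = reaction_step(need("Eno"),
      substrates = c(PG2 = 1), products = c(PEP = 1), limiting = "PG2"),
    PykA = reaction_step(need("PykA"),
      substrates = c(PEP = 1, ADP = 1), products = c(PYR = 1, ATP = 1),
      limiting = "PEP", cofactors = "ADP"),
    LDH = reaction_step(need("LDH"),
      substrates = c(PYR = 1, NADH = 1), products = c(LAC = 1, NAD = 1),
      limiting = "PYR", cofactors = "NADH")
  )
}

.preset_order <- list(
  `7E`  = c("Glk", "PGI", "PFK", "FBA", "TPI", "GPD", "PGK"),
  `8E`  = c("Inv", "Glk", "PGI", "PFK", "FBA", "TPI", "GPD", "PGK"),
  `9E`  = c("Amy", "Mlt", "Glk", "PGI", "PFK", "FBA", "TPI", "GPD", "PGK"),
  `10E` = c("Inv", "Amy", "Mlt", "Glk", "PGI", "PFK", "FBA", "TPI", "GPD", "PGK"),
  `4E`  = c("PGM", "Eno", "PykA", "LDH")
)

#' Build a preset cascade
#'
#' Constructs one of the studied cascade presets: the 7-enzyme glycolytic
#' core converting glucose to 3-phosphoglycerate (monitored by NADH
#' formation at the GPD step), its saccharification-extended 8E (sucrose),
#' 9E (maltoheptaose) and 10E (both) variants, or the downstream 4-enzyme
#' cascade converting 3-phosphoglycerate to lactate (monitored by NADH
#' consumption at the LDH step).
#'
#' Stoichiometry follows textbook glycolysis: aldolase splits fructose
#' 1,6-bisphosphate into DHAP plus G3P, triose phosphate isomerase converts
#' DHAP to G3P, so two NADH are formed per glucose in the excess-cofactor
#' limit. All steps are irreversible.
#'
#' @param preset One of "4E", "7E", "8E", "9E", "10E".
#' @param enzymes Named list of [enzyme_def]s; defaults to the packaged table.
#' @return A [cascade_spec].
#' @examples
#' build_cascade("7E")
#' @export
build_cascade <- function(preset, enzymes = default_enzymes()) {
  if (!preset %in% names(.preset_order))
    .abort(sprintf("unknown cascade preset '%s' (available: %s)", preset,
                   paste(names(.preset_order), collapse = ", ")),
           "nanocascade_unknown_preset")
  steps <- .preset_steps(enzymes)[.preset_order[[preset]]]
  couples <- list(c("NAD", "NADH"), c("ATP", "ADP"))
  cascade_spec(steps, monitored = "NADH",
               sign = if (preset == "4E") -1L else 1L,
               couples = couples, preset = preset)
}

#' Add a competing branch reaction to a cascade
#'
#' Appends a sink step consuming one of the cascade's existing species, the
#' in-silico analogue of challenging an intermediate with a competitor
#' enzyme (e.g. glucose oxidase drawing glucose away from glucokinase).
#'
#' @param spec A [cascade_spec].
#' @param competitor_step A [reaction_step] whose limiting substrate is a
#'   species already present in `spec`.
#' @return A new [cascade_spec] with the branch appended.
#' @export
add_competitor <- function(spec, competitor_step) {
  stopifnot(inherits(spec, "cascade_spec"), inherits(competitor_step, "reaction_step"))
  if (!competitor_step$limiting %in% spec$species)
    .abort(sprintf("competitor substrate %s is not a species of this cascade",
                   competitor_step$limiting), "nanocascade_bad_step")
  cascade_spec(c(spec$steps, list(competitor_step)), monitored = spec$monitored,
               sign = spec$sign, couples = spec$couples,
               preset = if (is.null(spec$preset)) NULL
                        else paste0(spec$preset, "+",
                                    competitor_step$enzyme$abbrev))
}

#' Per-step and cumulative reaction energies with bottleneck flags
#'
#' Tabulates the standard transformed reaction energy of each step and its
#' running sum. A step is flagged as a thermodynamic-kinetic bottleneck when
#' its energy is positive (product-unfavourable) *and* its Michaelis
#' constant exceeds `km_threshold_uM`: an endergonic step that also needs a
#' high intermediate concentration to approach saturation is where an
#' extended cascade stalls. Steps without a recorded energy are reported as
#' unknown, never imputed; the cumulative sum runs over known values only.
#'
#' @param spec A [cascade_spec] (may have zero steps via `spec$steps = list()`
#'   is not allowed; pass `NULL` for an empty profile).
#' @param km_threshold_uM Bottleneck KM threshold, uM. Default 1000 (1 mM).
#' @param context Parameter context for the KM used in the flag.
#' @return A data frame with columns `step`, `enzyme`, `delta_g`, `dg_known`,
#'   `cumulative`, `km_uM`, `bottleneck`.
#' @export
thermo_profile <- function(spec, km_threshold_uM = 1000,
                           context = c("free", "bound")) {
  context <- match.arg(context)
  if (is.null(spec))
    return(data.frame(step = integer(), enzyme = character(),
                      delta_g = numeric(), dg_known = logical(),
                      cumulative = numeric(), km_uM = numeric(),
                      bottleneck = logical()))
  stopifnot(inherits(spec, "cascade_spec"))
  dg <- vapply(spec$steps, function(s) s$delta_g %||% NA_real_, numeric(1))
  km <- vapply(spec$steps, function(s) enzyme_params(s$enzyme, context)$km,
               numeric(1))
  data.frame(
    step = seq_along(spec$steps),
    enzyme = cascade_enzymes(spec),
    delta_g = dg,
    dg_known = !is.na(dg),
    cumulative = cumsum(ifelse(is.na(dg), 0, dg)),
    km_uM = km,
    bottleneck = !is.na(dg) & dg > 0 & km > km_threshold_uM)
}
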