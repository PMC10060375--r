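#' Nanoparticle type
#'
#' Geometry of a scaffold nanoparticle: a sphere (diameter) or a planar
#' platelet (length x width x height). Surface area and surface-to-volume
#' ratio are derived from the dimensions.
#'
#' @param name Type name (e.g. "QD520").
#' @param shape "sphere" or "platelet".
#' @param dims Dimensions in nm: `c(diameter)` for spheres,
#'   `c(length, width, height)` for platelets.
#' @param max_sites Optional integer binding-site budget per particle; when
#'   unset, aggregation simulations derive it from [capacity_estimate].
#' @return An object of class `np_type`.
#' @examples
#' np_type("QD520", "sphere", 4.0)
#' @export
np_type <- function(name, shape = c("sphere", "platelet"), dims,
                    max_sites = NULL) {
  shape <- match.arg(shape)
  if (shape == "sphere") {
    if (length(dims) != 1L || dims <= 0)
      .abort("a sphere needs a single positive diameter (nm)",
             "nanocascade_bad_params")
    area <- pi * dims^2
    volume <- pi * dims^3 / 6
  } else {
    if (length(dims) != 3L || any(dims <= 0))
      .abort("a platelet needs positive length, width, height (nm)",
             "nanocascade_bad_params")
    area <- 2 * (dims[1] * dims[2] + dims[1] * dims[3] + dims[2] * dims[3])
    volume <- prod(dims)
  }
  structure(list(name = name, shape = shape, dims = dims,
                 surface_area = area, sv_ratio = area / volume,
                 max_sites = max_sites),
            class = "np_type")
}

#' @export
print.np_type <- function(x, ...) {
  cat(sprintf("%s: %s %s nm, area %.0f nm^2, S/V %.2f /nm\n", x$name, x$shape,
              paste(x$dims, collapse = " x "), x$surface_area, x$sv_ratio))
  invisible(x)
}

#' Poisson loading distribution of enzymes per nanoparticle
#'
#' Under stoichiometric self-assembly, the number of enzyme copies per
#' particle follows a Poisson distribution with the mixing ratio as its
#' mean; a finite binding-site budget truncates the distribution at
#' `max_sites` with renormalization.
#'
#' @param mean_ratio Mean enzymes per particle (mixing stoichiometry).
#' @param max_sites Truncation point (binding-site budget); `Inf` for
#'   untruncated.
#' @return Data frame with columns `copies` and `prob` (summing to 1), plus
#'   attribute `mean` (the truncated mean).
#' @examples
#' poisson_loading(4, max_sites = 10)
#' @export
poisson_loading <- function(mean_ratio, max_sites = Inf) {
  if (mean_ratio < 0)
    .abort("`mean_ratio` must be non-negative", "nanocascade_bad_params")
  if (mean_ratio == 0) {
    out <- data.frame(copies = 0L, prob = 1)
    attr(out, "mean") <- 0
    return(out)
  }
  kmax <- if (is.finite(max_sites)) as.integer(max_sites)
          else as.integer(ceiling(mean_ratio + 10 * sqrt(mean_ratio) + 10))
  k <- 0:kmax
  p <- dpois(k, mean_ratio)
  if (is.finite(max_sites)) p <- p / sum(p)
  out <- data.frame(copies = k, prob = p)
  attr(out, "mean") <- sum(k * p)
  out
}

#' Geometric estimate of enzyme copies per nanoparticle
#'
#' Treats the oligomeric enzyme as a sphere of volume proportional to its
#' total mass (globular-protein specific volume, 1.212e-3 nm^3 per Da) and
#' packs its circular footprint onto the accessible surface: for spherical
#' particles the shell at enzyme-contact distance, `4*pi*(r_np + r_enz)^2`;
#' for platelets the stated surface area. Square and hexagonal circle
#' packings bound the count from below and above; the range is clamped to
#' at least one copy.
#'
#' @param np An [np_type].
#' @param monomer_kda Monomer mass, kDa.
#' @param subunits Oligomeric count.
#' @return Integer vector `c(min, max)` copies per particle.
#' @examples
#' capacity_estimate(np_type("QD520", "sphere", 4), monomer_kda = 34.6,
#'                   subunits = 4)
#' @export
capacity_estimate <- function(np, monomer_kda, subunits = 1) {
  stopifnot(inherits(np, "np_type"))
  if (monomer_kda <= 0 || subunits < 1)
    .abort("positive mass and subunit count required", "nanocascade_bad_params")
  vol_nm3 <- 1.212e-3 * monomer_kda * 1000 * subunits
  r_enz <- (3 * vol_nm3 / (4 * pi))^(1 / 3)
  # an enzyme whose own footprint dwarfs the particle caps it at one copy
  if ((2 * r_enz)^2 > np$surface_area) return(c(1L, 1L))
  area <- if (np$shape == "sphere") 4 * pi * (np$dims[1] / 2 + r_enz)^2
          else np$surface_area
  n_square <- floor(area / (2 * r_enz)^2)        # square lattice of circles
  n_hex <- floor(area / (2 * sqrt(3) * r_enz^2)) # hexagonal lattice
  rng <- sort(c(n_square, n_hex))
  pmax(as.integer(rng), 1L)
}

#' Enzyme linker specification for aggregation simulations
#'
#' A multimeric enzyme displays one terminal His6 per subunit; only
#' linkers with valence >= 2 can bridge two particles.
#'
#' @param enzyme An [enzyme_def], or a character abbreviation resolved
#'   against the packaged table (valence then defaults to the subunit
#'   count).
#' @param conc_nM Enzyme concentration, nM.
#' @param valence Number of particle-binding termini; defaults to the
#'   enzyme's subunit count.
#' @return An object of class `linker_spec`.
#' @export
linker_spec <- function(enzyme, conc_nM, valence = NULL) {
  if (is.character(enzyme)) {
    tab <- default_enzymes()
    if (is.null(tab[[enzyme]]))
      .abort(sprintf("unknown enzyme abbreviation %s", enzyme),
             "nanocascade_missing_enzyme")
    enzyme <- tab[[enzyme]]
  }
  stopifnot(inherits(enzyme, "enzyme_def"))
  valence <- valence %||% enzyme$subunits
  if (valence < 1)
    .abort("`valence` must be >= 1", "nanocascade_bad_params")
  if (conc_nM < 0)
    .abort("`conc_nM` must be non-negative", "nanocascade_bad_params")
  structure(list(enzyme = enzyme, conc_nM = conc_nM,
                 valence = as.integer(valence)),
            class = "linker_spec")
}

#' Stochastic nanoparticle-enzyme aggregation
#'
#' Event-driven (Gillespie-style) cluster-cluster aggregation of
#' nanoparticles cross-linked by multivalent enzymes, the in-silico
#' counterpart of diffusion-limited aggregate growth. Enzymes first
#' self-assemble onto particles (one binding site per attached terminus,
#' random placement among particles with free sites; molecules beyond the
#' site budget stay in solution). Clusters then merge pairwise: a merge
#' requires a bound linker with an unused terminus on one cluster and a
#' binding site on the other, consuming one of each. A free site is taken
#' directly; on a saturated surface the incoming terminus can still attach
#' by displacing a resident singly-anchored enzyme, down-weighted by the
#' exchange efficiency `w_exch` (metal-affinity anchoring is dynamic, so
#' saturation slows but does not abolish cross-linking).
#'
#' Merge propensities follow the Brownian coagulation kernel
#' `K(i,j) = (r_i + r_j)(1/r_i + 1/r_j)` with `r = size^(1/3)` (platelet
#' scaffolds get a flat-shape collision enhancement), scaled by the
#' acceptor's bindable-surface fraction and by the simulated number
#' density, so aggregation accelerates with particle concentration exactly
#' as coagulation kinetics demand. Events are drawn until the observation
#' span `t_agg` elapses, `t_steps` events have occurred, or no eligible
#' pair remains. The kernel prefactor is not calibrated to physical time:
#' `t_agg` is in arbitrary coagulation units and only orderings and trends
#' across conditions are meaningful. Particle count is conserved
#' throughout.
#'
#' With only monomeric linkers (valence 1) no bridge can form and the
#' ensemble stays all-singleton.
#'
#' @param np_conc_nM Nanoparticle concentration, nM.
#' @param np An [np_type].
#' @param linkers List of [linker_spec] objects.
#' @param seed RNG seed (mandatory: ensembles are reproducible by
#'   construction).
#' @param t_agg Observation span in coagulation units.
#' @param t_steps Cap on merge events; `Inf` runs to the time cap.
#' @param particles_per_nM Simulated particles per nM of concentration
#'   (sets the ensemble size; enzyme counts scale identically).
#' @param shape_factor Collision enhancement for platelets.
#' @param w_exch Exchange efficiency of bridging into a saturated surface
#'   relative to a free site (0 = hard blockade, 1 = no penalty).
#' @return An object of class `cluster_ensemble`: `sizes` (particles per
#'   cluster), `n_np`, `n_events`, `t_final`, `seed`, `np`, `params`.
#' @export
simulate_aggregation <- function(np_conc_nM, np, linkers, seed,
                                 t_agg = 0.25, t_steps = Inf,
                                 particles_per_nM = 12,
                                 shape_factor = 2, w_exch = 0.1) {
  stopifnot(inherits(np, "np_type"),
            all(vapply(linkers, inherits, TRUE, "linker_spec")))
  if (missing(seed)) .abort("`seed` is mandatory", "nanocascade_bad_params")
  if (np_conc_nM <= 0) .abort("`np_conc_nM` must be positive",
                              "nanocascade_bad_params")
  if (t_agg < 0 || w_exch < 0 || w_exch > 1)
    .abort("need t_agg >= 0 and 0 <= w_exch <= 1", "nanocascade_bad_params")
  set.seed(seed)
  n_np <- max(2L, as.integer(round(np_conc_nM * particles_per_nM)))
  sites_per_np <- np$max_sites %||% {
    mids <- vapply(linkers, function(l)
      mean(capacity_estimate(np, l$enzyme$monomer_kda, l$enzyme$subunits)),
      numeric(1))
    max(1L, as.integer(round(mean(mids))))
  }
  valences <- if (length(linkers))
    vapply(linkers, function(l) l$valence, integer(1)) else 1L

  # Load enzymes onto particles: each molecule takes one site on a random
  # particle that still has room.
  free_sites <- rep(sites_per_np, n_np)
  bound <- matrix(0L, n_np, max(1L, length(linkers)))  # molecules per linker type
  counts <- vapply(linkers, function(l)
    as.integer(round(l$conc_nM * particles_per_nM)), integer(1))
  mols <- rep.int(seq_along(linkers), counts)
  if (length(mols) > 1L) mols <- mols[sample.int(length(mols))]
  for (mol in mols) {
    open <- which(free_sites > 0)
    if (!length(open)) break
    i <- if (length(open) == 1L) open else sample(open, 1L)
    free_sites[i] <- free_sites[i] - 1L
    bound[i, mol] <- bound[i, mol] + 1L
  }

  size <- rep(1L, n_np)
  shape <- if (np$shape == "platelet") shape_factor else 1
  vol <- n_np / np_conc_nM           # simulation volume, particles per nM
  spare_of <- function() as.vector(bound %*% pmax(valences - 1L, 0L))
  n_events <- 0L; t_now <- 0
  while (n_events < t_steps && t_now < t_agg) {
    spare <- spare_of()
    avail <- free_sites + w_exch * (size * sites_per_np - free_sites)
    donors <- which(spare > 0)
    acceptors <- which(avail > 0)
    if (!length(donors) || !length(acceptors) ||
        (length(donors) == 1L && length(acceptors) == 1L &&
         donors == acceptors)) break
    r <- size^(1 / 3)
    K <- shape * outer(r[donors], r[acceptors], "+") *
      outer(1 / r[donors], 1 / r[acceptors], "+")
    # bindable-surface fraction of the acceptor
    K <- sweep(K, 2L, avail[acceptors] / (size[acceptors] * sites_per_np), "*")
    K[outer(donors, acceptors, "==")] <- 0
    lambda <- sum(K) / vol
    if (lambda <= 0) break
    t_now <- t_now + stats::rexp(1L, lambda)
    if (t_now > t_agg) break
    pick <- sample.int(length(K), 1L, prob = as.vector(K))
    di <- donors[(pick - 1L) %% length(donors) + 1L]
    aj <- acceptors[(pick - 1L) %/% length(donors) + 1L]
    # One unused terminus of a multivalent linker on di binds a site on aj.
    w <- bound[di, ] * pmax(valences - 1L, 0L)
    src <- if (length(w) == 1L) 1L else sample.int(length(w), 1L, prob = w)
    bound[di, src] <- bound[di, src] - 1L   # its spare termini are now in use
    if (free_sites[aj] > 0L) {
      free_sites[aj] <- free_sites[aj] - 1L
    } else {
      # displace one resident molecule back into solution
      out <- if (ncol(bound) == 1L) 1L
             else sample.int(ncol(bound), 1L, prob = bound[aj, ])
      bound[aj, out] <- bound[aj, out] - 1L
    }
    size[di] <- size[di] + size[aj]
    free_sites[di] <- free_sites[di] + free_sites[aj]
    bound[di, ] <- bound[di, ] + bound[aj, ]
    keep <- seq_len(length(size)) != aj
    size <- size[keep]; free_sites <- free_sites[keep]
    bound <- bound[keep, , drop = FALSE]
    n_events <- n_events + 1L
  }
  structure(list(sizes = sort(size, decreasing = TRUE), n_np = n_np,
                 n_events = n_events, t_final = t_now, seed = seed, np = np,
                 params = list(np_conc_nM = np_conc_nM,
                               sites_per_np = sites_per_np,
                               particles_per_nM = particles_per_nM,
                               shape_factor = shape_factor,
                               t_agg = t_agg, w_exch = w_exch)),
            class = "cluster_ensemble")
}

#' @export
print.cluster_ensemble <- function(x, ...) {
  cat(sprintf("Cluster ensemble: %d particles in %d clusters (mean %.2f NPs/cluster)\n",
              x$n_np, length(x$sizes), mean(x$sizes)))
  invisible(x)
}

.size_bins <- list(`1` = c(1, 1), `2-4` = c(2, 4), `5-8` = c(5, 8),
                   `9-16` = c(9, 16), `17-32` = c(17, 32), `>32` = c(33, Inf))

#' Cluster-size statistics
#'
#' Number-weighted and particle-weighted summaries of a cluster ensemble,
#' histogrammed into the standard micrograph-analysis bins
#' (1, 2-4, 5-8, 9-16, 17-32, >32 particles per cluster). The
#' particle-weighted histogram weights each cluster by its size ("how many
#' particles sit in clusters of this size"); its mean is never below the
#' number-weighted mean (size-biased sampling).
#'
#' @param ensemble A `cluster_ensemble`, or a bare vector of cluster sizes.
#' @return List with `mean_size`, `np_weighted_mean`, `histogram` (counts
#'   per bin) and `np_histogram` (particles per bin).
#' @examples
#' cluster_stats(c(1, 1, 2, 4))
#' @export
cluster_stats <- function(ensemble) {
  sizes <- if (inherits(ensemble, "cluster_ensemble")) ensemble$sizes
           else as.numeric(ensemble)
  if (!length(sizes))
    .abort("empty ensemble", "nanocascade_bad_dataset")
  if (any(sizes < 1))
    .abort("cluster sizes must be >= 1", "nanocascade_bad_dataset")
  counts <- vapply(.size_bins, function(b)
    sum(sizes >= b[1] & sizes <= b[2]), numeric(1))
  weighted <- vapply(.size_bins, function(b)
    sum(sizes[sizes >= b[1] & sizes <= b[2]]), numeric(1))
  list(mean_size = mean(sizes),
       np_weighted_mean = sum(sizes^2) / sum(sizes),
       histogram = counts, np_histogram = weighted)
}

#' Write a cluster ensemble to CSV
#'
#' @param ensemble A `cluster_ensemble`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble_csv <- function(ensemble, path) {
  write.csv(data.frame(cluster_id = seq_along(ensemble$sizes),
                       size = ensemble$sizes),
            path, row.names = FALSE)
  invisible(path)
}
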