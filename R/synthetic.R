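#' Configuration for a synthetic mobility system
#'
#' Describes a stated synthetic world: locations scattered uniformly over a
#' planar square, heavy-tailed (lognormal by default) populations, integer
#' trips sampled multinomially from a ground-truth model variant with known
#' lambda, and optional sparsification of the observed network — emulating
#' the sparse empirical OD networks the models are fitted to.
#'
#' Defaults: 60 locations on a 100 km square, lognormal(meanlog 10, sdlog 1)
#' populations (median ~22,000 persons, a census-tract/ward scale), PIR truth
#' with lambda 0.5, 20,000 trips per origin.
#'
#' @param n_locations number of locations (>= 2).
#' @param extent side of the planar square, km.
#' @param population_law list: `list(type = "lognormal", meanlog, sdlog)` or
#'   `list(type = "zipf", exponent, max)` (Pareto tail capped at `max`).
#' @param variant ground-truth variant (`"PIR"`, `"PCR"`, `"AIR"`, `"ACR"`).
#' @param lambda ground-truth scaling exponent.
#' @param trips_per_origin trips emitted per origin (production variants) or
#'   absorbed per destination (attraction variants); scalar or length-N.
#' @param sparsify `list(type = "none")`, `list(type = "top_fraction", f = )`
#'   (keep the largest fraction f of positive pairs by flux) or
#'   `list(type = "bernoulli", p = )` (keep each positive pair with prob p).
#' @param seed integer RNG seed.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_locations = 60, extent = 100,
                             population_law = list(type = "lognormal",
                                                   meanlog = 10, sdlog = 1),
                             variant = "PIR", lambda = 0.5,
                             trips_per_origin = 2e4,
                             sparsify = list(type = "none"),
                             seed = 1) {
  stopifnot(n_locations >= 2, extent > 0, all(trips_per_origin > 0))
  stopifnot(population_law$type %in% c("lognormal", "zipf"))
  stopifnot(sparsify$type %in% c("none", "top_fraction", "bernoulli"))
  if (sparsify$type == "top_fraction") {
    stopifnot(sparsify$f > 0, sparsify$f <= 1)
  }
  if (sparsify$type == "bernoulli") stopifnot(sparsify$p > 0, sparsify$p <= 1)
  structure(
    list(n_locations = n_locations, extent = extent,
         population_law = population_law, variant = variant, lambda = lambda,
         trips_per_origin = trips_per_origin, sparsify = sparsify,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Generate a synthetic mobility system
#'
#' Locations are uniform over the square; populations follow the configured
#' law. Fully reproducible from `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return a [build_system()] object (planar).
#' @export
generate_system <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_locations
  law <- config$population_law
  pop <- if (law$type == "lognormal") {
    stats::rlnorm(n, meanlog = law$meanlog, sdlog = law$sdlog)
  } else {
    # Pareto with unit scale and the given tail exponent, capped at `max`
    pmin(stats::runif(n)^(-1 / (law$exponent - 1)), law$max)
  }
  build_system(data.frame(
    id = sprintf("L%03d", seq_len(n)),
    x = stats::runif(n, 0, config$extent),
    y = stats::runif(n, 0, config$extent),
    population = pop
  ), coord_mode = "planar")
}

#' Sample an observed OD network from a ground-truth model
#'
#' Production variants draw each origin's trips multinomially over
#' destinations with probabilities proportional to `kernel^lambda`;
#' attraction variants sample per destination over origins. Multinomial (not
#' Poisson) sampling means the constrained marginals hold exactly in the
#' sample, which keeps conservation tests sharp. kappa plays no role: shares
#' are normalized. Sparsification is applied after sampling.
#'
#' @param system a [build_system()] object.
#' @param s intervening-population matrix.
#' @param variant,lambda ground truth (see [synthetic_config()]).
#' @param trips_per_origin scalar or length-N trips.
#' @param sparsify sparsification rule (see [synthetic_config()]).
#' @param seed integer RNG seed.
#' @return an integer-valued [flux_matrix()].
#' @export
sample_flows <- function(system, s, variant = "PIR", lambda = 0.5,
                         trips_per_origin = 2e4,
                         sparsify = list(type = "none"), seed = 1) {
  set.seed(as.integer(seed))
  N <- system$N
  direction <- if (variant %in% c("PIR", "AIR")) "intervention" else "competition"
  K <- kernel_matrix(system, s, direction)
  margin <- if (variant %in% c("PIR", "PCR")) "row" else "col"
  al <- allocation_shares(K, lambda, margin)
  if (any(al$tot == 0)) {
    rf_stop("undefined_allocation",
            "zero allocation vector with positive trips requested")
  }
  trips <- rep_len(trips_per_origin, N)
  f <- matrix(0, N, N, dimnames = list(system$id, system$id))
  if (margin == "row") {
    for (i in seq_len(N)) {
      f[i, ] <- stats::rmultinom(1, trips[i], prob = al$share[i, ])
    }
  } else {
    for (j in seq_len(N)) {
      f[, j] <- stats::rmultinom(1, trips[j], prob = al$share[, j])
    }
  }
  if (sparsify$type != "none") {
    pos <- which(f > 0)
    keep <- if (sparsify$type == "top_fraction") {
      pos[order(f[pos], decreasing = TRUE)[seq_len(ceiling(sparsify$f * length(pos)))]]
    } else {
      pos[stats::runif(length(pos)) <= sparsify$p]
    }
    drop <- setdiff(pos, keep)
    f[drop] <- 0
  }
  flux_matrix(f)
}

#' One-call synthetic scenario
#'
#' Convenience wrapper: generates the system, distances, intervening
#' populations and the sampled observed network of a configuration.
#'
#' @param config a [synthetic_config()].
#' @param tie_policy forwarded to [intervening_population()].
#' @return list with `config`, `system`, `dist`, `s`, `observed`.
#' @export
simulate_scenario <- function(config, tie_policy = "strict") {
  system <- generate_system(config)
  dist <- pairwise_distances(system)
  s <- intervening_population(system, dist, tie_policy)
  observed <- sample_flows(system, s, variant = config$variant,
                           lambda = config$lambda,
                           trips_per_origin = config$trips_per_origin,
                           sparsify = config$sparsify,
                           seed = config$seed + 1L)
  list(config = config, system = system, dist = dist, s = s,
       observed = observed)
}
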