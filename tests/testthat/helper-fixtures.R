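# Shared fixtures and independent oracles.

# Four locations on a line at x = 0,1,2,3 km, populations 10,20,30,40.
line4_system <- function() {
  build_system(data.frame(
    id = c("L0", "L1", "L2", "L3"),
    x = 0:3, y = 0,
    population = c(10, 20, 30, 40)
  ), coord_mode = "planar")
}

line4 <- function(tie_policy = "strict") {
  sys <- line4_system()
  d <- pairwise_distances(sys)
  list(system = sys, dist = d,
       s = intervening_population(sys, d, tie_policy))
}

# Random planar system with lognormal populations; distinct coordinates a.s.
# integer_pop = TRUE rounds populations so that partial sums are exact in
# double arithmetic (order-independent), as the exact-oracle tests require.
random_system <- function(n, seed, integer_pop = FALSE) {
  set.seed(seed)
  pop <- rlnorm(n, 8, 1)
  if (integer_pop) pop <- round(pop) + 1
  build_system(data.frame(
    id = sprintf("R%03d", seq_len(n)),
    x = runif(n, 0, 100), y = runif(n, 0, 100),
    population = pop
  ), coord_mode = "planar")
}

# O(N^3) brute-force oracle for the intervening population, independent of
# the sorted-accumulation implementation.
brute_force_s <- function(system, dist, tie_policy = "strict") {
  N <- system$N
  m <- system$population
  s <- matrix(NA_real_, N, N, dimnames = list(system$id, system$id))
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i == j) next
    acc <- 0
    for (k in seq_len(N)) {
      if (k == i || k == j) next
      inside <- if (tie_policy == "strict") dist[i, k] < dist[i, j]
                else dist[i, k] <= dist[i, j]
      if (inside) acc <- acc + m[k]
    }
    s[i, j] <- acc
  }
  s
}

# Dense zero matrix keyed by a system's ids, for hand-built observed networks.
zero_flux <- function(system) {
  matrix(0, system$N, system$N, dimnames = list(system$id, system$id))
}

# A full-support observed matrix: expected PIR/PCR/AIR/ACR fluxes at a known
# lambda, given per-origin totals.
exact_variant_flux <- function(system, s, variant, lambda, totals) {
  obs <- zero_flux(system)
  if (variant %in% c("PIR", "PCR")) {
    obs[] <- rep(totals / (system$N - 1), system$N) # uniform marginals carrier
  } else {
    obs[] <- rep(totals / (system$N - 1), each = system$N)
  }
  diag(obs) <- 0
  spec <- model_spec(variant, lambda = lambda, kappa = 1)
  predict_generalized(system, s, spec, flux_matrix(obs))
}
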