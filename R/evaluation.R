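#' Sorensen-Dice flux similarity ("common part of commuters")
#'
#' `2 sum_ij min(model_ij, data_ij) / (sum_ij model_ij + sum_ij data_ij)`,
#' summed over the union of OD pairs (equivalently all pairs, absent = 0).
#' Equals 1 iff the matrices agree on the union support and 0 iff their
#' supports are disjoint. Symmetric and invariant under joint rescaling.
#'
#' @param model,data flux matrices on the same location set.
#' @return similarity in \[0, 1\].
#' @export
sorensen_index <- function(model, data) {
  al <- align_flux(model, data)
  tot <- sum(al$a) + sum(al$b)
  if (tot <= 0) {
    rf_stop("undefined_similarity", "both flux matrices have zero total")
  }
  2 * sum(pmin(al$a, al$b)) / tot
}

#' Pearson correlation of raw fluxes on the observed support
#'
#' Correlates actual (not log) flux values over the OD pairs with positive
#' observed flow only — predictions on unobserved pairs are ignored.
#'
#' @param model,data flux matrices on the same location set.
#' @return correlation in \[-1, 1\].
#' @export
pearson_flux <- function(model, data) {
  al <- align_flux(model, data)
  sup <- al$b > 0
  x <- al$a[sup]
  y <- al$b[sup]
  if (length(x) < 2 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    rf_stop("undefined_correlation",
            "need >= 2 observed pairs with nonconstant model and data values")
  }
  stats::cor(x, y)
}

# Trip-weighted binned probability mass function over a pair covariate.
binned_pmf <- function(values, weights, edges) {
  if (length(values) == 0) rf_stop("empty_flows", "no positive flux entries")
  edges <- sort(edges)
  bin <- findInterval(values, edges, rightmost.closed = TRUE)
  if (any(bin == 0 | bin >= length(edges))) {
    rf_stop("bin_coverage", "flux outside the bin range [%g, %g]",
            edges[1], edges[length(edges)])
  }
  mass <- numeric(length(edges) - 1)
  agg <- rowsum(weights, bin)
  mass[as.integer(rownames(agg))] <- agg[, 1]
  structure(list(edges = edges, mass = mass / sum(mass)),
            class = "binned_pmf")
}

#' @export
print.binned_pmf <- function(x, ...) {
  cat(sprintf("<binned_pmf> %d bins on [%g, %g], %d nonempty\n",
              length(x$mass), x$edges[1], x$edges[length(x$edges)],
              sum(x$mass > 0)))
  invisible(x)
}

#' Trip-distance distribution P_dist(r)
#'
#' Probability that a trip connects two locations at distance r: a
#' trip-weighted histogram of pair distances, normalized to 1.
#'
#' @param flows a flux matrix.
#' @param dist distance matrix (km).
#' @param bins bin edges in km covering every positive-flux pair distance.
#' @return a `binned_pmf` (list with `edges` and `mass`).
#' @export
trip_distance_distribution <- function(flows, dist, bins) {
  al <- align_flux(flows, dist)
  idx <- which(al$a > 0)
  binned_pmf(al$b[idx], al$a[idx], bins)
}

#' Trip-population distribution P_dist(n)
#'
#' Probability that a trip ends at (mode `"destination"`) or starts from
#' (mode `"origin"`) a location of population n. The destination mode probes
#' what production-constrained models do not enforce, and vice versa.
#'
#' @param flows a flux matrix.
#' @param system a [build_system()] object.
#' @param mode `"destination"` or `"origin"`.
#' @param bins bin edges in persons.
#' @return a `binned_pmf`.
#' @export
trip_population_distribution <- function(flows, system,
                                         mode = c("destination", "origin"),
                                         bins) {
  mode <- match.arg(mode)
  f <- unclass(flows)[system$id, system$id]
  idx <- which(f > 0, arr.ind = TRUE)
  pop_of <- if (mode == "destination") idx[, 2] else idx[, 1]
  binned_pmf(system$population[pop_of], f[which(f > 0)], bins)
}

# Asymptotic Kolmogorov tail probability Q(t) = 2 sum (-1)^(k-1) exp(-2 k^2 t^2)
kolmogorov_q <- function(t) {
  if (t < 1e-8) return(1)
  k <- 1:100
  min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))))
}

#' Two-sample Kolmogorov-Smirnov test on binned mass functions
#'
#' `D = max |CDF_a - CDF_b|` over shared bin edges. The p-value uses the
#' asymptotic Kolmogorov distribution with effective sample size
#' `n_eff = B_a B_b / (B_a + B_b)` where `B` counts each function's nonempty
#' bins. Treating each nonempty bin as one observation is a deliberate
#' convention: using raw trip counts as sample sizes would drive every
#' p-value of a trip-weighted distribution to zero.
#'
#' @param pmf_a,pmf_b `binned_pmf` objects on identical edges.
#' @param alpha significance level (default 0.05).
#' @return list with `statistic`, `p_value`, `same_distribution`.
#' @export
ks_two_sample <- function(pmf_a, pmf_b, alpha = 0.05) {
  if (!isTRUE(all.equal(pmf_a$edges, pmf_b$edges))) {
    rf_stop("bin_mismatch", "the two mass functions use different bin edges")
  }
  D <- max(abs(cumsum(pmf_a$mass) - cumsum(pmf_b$mass)))
  Ba <- sum(pmf_a$mass > 0)
  Bb <- sum(pmf_b$mass > 0)
  n_eff <- Ba * Bb / (Ba + Bb)
  p <- kolmogorov_q(sqrt(n_eff) * D)
  list(statistic = D, p_value = p, same_distribution = p > alpha)
}

#' Binned flux coverage table
#'
#' Observed fluxes are grouped into geometric bins (edges at powers of
#' `bin_factor`); within each bin the mean and the 5th/95th percentiles
#' (linear interpolation) of the model's predictions for those pairs are
#' reported. A bin is `covered` when the prediction band straddles the
#' diagonal, i.e. the \[5th, 95th\] band overlaps the bin's observed-flux
#' interval.
#'
#' @param model,data flux matrices on the same location set.
#' @param bin_factor geometric bin growth factor (default 2).
#' @return data.frame with one row per nonempty bin: `bin_lo`, `bin_hi`,
#'   `n_pairs`, `mean_pred`, `p5`, `p95`, `covered`.
#' @export
binned_flux_table <- function(model, data, bin_factor = 2) {
  al <- align_flux(model, data)
  sup <- which(al$b > 0)
  if (length(sup) == 0) rf_stop("empty_flows", "no observed flux entries")
  v <- al$b[sup]
  pred <- al$a[sup]
  k_lo <- floor(log(min(v)) / log(bin_factor))
  k_hi <- max(ceiling(log(max(v)) / log(bin_factor)), k_lo + 1)
  edges <- bin_factor^(k_lo:k_hi)
  if (max(v) >= edges[length(edges)]) edges <- c(edges, bin_factor^(k_hi + 1))
  bin <- findInterval(v, edges, rightmost.closed = TRUE)
  rows <- lapply(sort(unique(bin)), function(b) {
    p <- pred[bin == b]
    q <- stats::quantile(p, c(0.05, 0.95), names = FALSE, type = 7)
    lo <- edges[b]; hi <- edges[b + 1]
    data.frame(bin_lo = lo, bin_hi = hi, n_pairs = length(p),
               mean_pred = mean(p), p5 = q[1], p95 = q[2],
               covered = q[1] <= hi && q[2] >= lo)
  })
  do.call(rbind, rows)
}

#' Phase-space error grid over distance and destination population
#'
#' Partitions OD pairs into a 2-D grid of (pair distance, destination
#' population) cells and reports, per nonempty cell, the share of observed
#' trips falling in the cell and the Sorensen-Dice similarity restricted to
#' the cell's pairs — where in (r, n) space the model succeeds or fails.
#'
#' @param model,data flux matrices on the same location set.
#' @param dist distance matrix.
#' @param system a [build_system()] object.
#' @param r_bins distance bin edges (km), covering all support pairs.
#' @param n_bins destination-population bin edges (persons).
#' @return data.frame with columns `r_lo`, `r_hi`, `n_lo`, `n_hi`,
#'   `n_pairs`, `data_total`, `model_total`, `data_prob`, `sorensen`.
#' @export
phase_space_grid <- function(model, data, dist, system, r_bins, n_bins) {
  al <- align_flux(model, data)
  d <- unclass(dist)[rownames(al$a), colnames(al$a)]
  pop <- system$population[match(colnames(al$a), system$id)]
  sup <- which(al$a > 0 | al$b > 0, arr.ind = TRUE)
  if (nrow(sup) == 0) rf_stop("empty_flows", "no flux entries in either matrix")
  r <- d[sup]
  n <- pop[sup[, 2]]
  rb <- findInterval(r, sort(r_bins), rightmost.closed = TRUE)
  nb <- findInterval(n, sort(n_bins), rightmost.closed = TRUE)
  if (any(rb == 0 | rb >= length(r_bins)) || any(nb == 0 | nb >= length(n_bins))) {
    rf_stop("bin_coverage", "support pair outside the phase-space bin ranges")
  }
  mv <- al$a[sup]
  dv <- al$b[sup]
  cell <- (nb - 1L) * (length(r_bins) - 1L) + rb
  total_data <- sum(dv)
  rows <- lapply(sort(unique(cell)), function(cl) {
    in_cell <- cell == cl
    dt <- sum(dv[in_cell]); mt <- sum(mv[in_cell])
    b_r <- rb[in_cell][1]; b_n <- nb[in_cell][1]
    data.frame(
      r_lo = r_bins[b_r], r_hi = r_bins[b_r + 1],
      n_lo = n_bins[b_n], n_hi = n_bins[b_n + 1],
      n_pairs = sum(in_cell), data_total = dt, model_total = mt,
      data_prob = dt / total_data,
      sorensen = 2 * sum(pmin(mv[in_cell], dv[in_cell])) / (dt + mt)
    )
  })
  do.call(rbind, rows)
}

# Default bin schemes -------------------------------------------------------

#' Default bin edges
#'
#' `default_distance_bins()`: `n` logarithmically spaced bins spanning the
#' positive-flux pair distances (slightly padded). `default_population_bins()`:
#' decade (powers of ten) edges covering the system's positive populations.
#'
#' @param flows flux matrix (union support is covered if two are supplied
#'   via `flows2`).
#' @param dist distance matrix.
#' @param n number of log-spaced bins.
#' @param flows2 optional second flux matrix whose support must be covered too.
#' @export
default_distance_bins <- function(flows, dist, n = 30, flows2 = NULL) {
  f <- unclass(flows)
  sup <- f > 0
  if (!is.null(flows2)) sup <- sup | unclass(flows2) > 0
  d <- unclass(dist)[sup]
  d <- d[d > 0]
  if (length(d) == 0) rf_stop("empty_flows", "no positive-distance flux pairs")
  exp(seq(log(min(d) * 0.999), log(max(d) * 1.001), length.out = n + 1))
}

#' @rdname default_distance_bins
#' @param system a [build_system()] object.
#' @export
default_population_bins <- function(system) {
  p <- system$population[system$population > 0]
  10^seq(floor(log10(min(p))), ceiling(log10(max(p))) + 1e-9)
}

#' Full validation report for a model prediction
#'
#' Runs the whole battery: Sorensen-Dice similarity, Pearson correlation on
#' observed pairs, trip-distance and trip-population distributions for model
#' and data with two-sample KS tests, the binned flux coverage table, and the
#' phase-space error grid.
#'
#' @param model predicted flux matrix.
#' @param data observed flux matrix.
#' @param system a [build_system()] object.
#' @param dist distance matrix.
#' @param alpha KS significance level.
#' @param dist_bins,pop_bins bin edges (defaults via
#'   [default_distance_bins()] / [default_population_bins()]).
#' @param phase_r_bins,phase_n_bins phase-grid resolution (log-spaced).
#' @param pop_mode `"destination"` (for production-constrained models) or
#'   `"origin"` (for attraction-constrained ones).
#' @return object of class `eval_report`.
#' @export
evaluate_model <- function(model, data, system, dist, alpha = 0.05,
                           dist_bins = NULL, pop_bins = NULL,
                           phase_r_bins = 20, phase_n_bins = 20,
                           pop_mode = c("destination", "origin")) {
  pop_mode <- match.arg(pop_mode)
  if (is.null(dist_bins)) {
    dist_bins <- default_distance_bins(data, dist, flows2 = model)
  }
  if (is.null(pop_bins)) pop_bins <- default_population_bins(system)
  pd_data <- trip_distance_distribution(data, dist, dist_bins)
  pd_model <- trip_distance_distribution(model, dist, dist_bins)
  pn_data <- trip_population_distribution(data, system, pop_mode, pop_bins)
  pn_model <- trip_population_distribution(model, system, pop_mode, pop_bins)
  rr <- range(unclass(dist)[unclass(data) > 0 | unclass(model) > 0])
  r_edges <- exp(seq(log(max(rr[1], 1e-6) * 0.999), log(rr[2] * 1.001),
                     length.out = phase_r_bins + 1))
  pr <- range(system$population)
  n_edges <- exp(seq(log(max(pr[1], 1) * 0.999), log(pr[2] * 1.001),
                     length.out = phase_n_bins + 1))
  structure(
    list(
      sorensen = sorensen_index(model, data),
      pcc = tryCatch(pearson_flux(model, data),
                     radflux_undefined_correlation = function(e) NA_real_),
      dist_distribution = list(model = pd_model, data = pd_data),
      pop_distribution = list(model = pn_model, data = pn_data,
                              mode = pop_mode),
      ks_distance = ks_two_sample(pd_model, pd_data, alpha),
      ks_population = ks_two_sample(pn_model, pn_data, alpha),
      flux_bins = binned_flux_table(model, data),
      phase_grid = phase_space_grid(model, data, dist, system,
                                    r_edges, n_edges),
      alpha = alpha
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> Sorensen = %.4f, PCC = %.4f\n", x$sorensen, x$pcc))
  cat(sprintf("  KS distance:   D = %.4f, p = %.4f (%s)\n",
              x$ks_distance$statistic, x$ks_distance$p_value,
              if (x$ks_distance$same_distribution) "same" else "different"))
  cat(sprintf("  KS population: D = %.4f, p = %.4f (%s)\n",
              x$ks_population$statistic, x$ks_population$p_value,
              if (x$ks_population$same_distribution) "same" else "different"))
  cat(sprintf("  flux bins covered: %d / %d\n",
              sum(x$flux_bins$covered), nrow(x$flux_bins)))
  invisible(x)
}
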