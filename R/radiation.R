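#' Radiation transition kernels
#'
#' `intervention_kernel()` is the original radiation transition probability
#' seen from the origin: an individual at i accepts the closest opportunity
#' better than the best available at home, so the chance of ending at j falls
#' with the intervening population `s_ij` inside the circle of radius `d_ij`
#' centred at i:
#'
#'   p_ij = m_i n_j / ((m_i + s_ij) (m_i + n_j + s_ij))
#'
#' `competition_kernel()` reverses the search direction: demand is emitted by
#' the destination j and origins compete for it, with the circle centred at j:
#'
#'   q_ij = n_j m_i / ((n_j + s_ji) (n_j + m_i + s_ji))
#'
#' Both return 0 when the numerator vanishes (including the all-zero corner,
#' by convention rather than error). All arguments vectorize.
#'
#' @param m_i origin population (persons).
#' @param n_j destination population (persons).
#' @param s_ij intervening population inside the origin-centred circle.
#' @param s_ji intervening population inside the destination-centred circle.
#' @return dimensionless weight(s) in \[0, 1\].
#' @export
intervention_kernel <- function(m_i, n_j, s_ij) {
  den <- (m_i + s_ij) * (m_i + n_j + s_ij)
  ifelse(den > 0, m_i * n_j / den, 0)
}

#' @rdname intervention_kernel
#' @export
competition_kernel <- function(n_j, m_i, s_ji) {
  intervention_kernel(m_i = n_j, n_j = m_i, s_ij = s_ji)
}

#' Full kernel matrix over all ordered pairs
#'
#' @param system a [build_system()] object.
#' @param s intervening-population matrix from [intervening_population()].
#' @param direction `"intervention"` (circle at the origin) or
#'   `"competition"` (circle at the destination).
#' @param m,n origin-side and destination-side masses; default the system's
#'   populations. Supplying trip marginals instead implements the
#'   "population (or trips)" mass convention.
#' @return N x N matrix of kernel weights, zero diagonal.
#' @export
kernel_matrix <- function(system, s, direction = c("intervention", "competition"),
                          m = system$population, n = system$population) {
  direction <- match.arg(direction)
  N <- system$N
  Mi <- matrix(m, N, N)
  Nj <- matrix(n, N, N, byrow = TRUE)
  K <- if (direction == "intervention") {
    den <- (Mi + s) * (Mi + Nj + s)
    ifelse(!is.na(den) & den > 0, Mi * Nj / den, 0)
  } else {
    st <- t(s)                          # st[i, j] = s_ji, centred at j
    den <- (Nj + st) * (Nj + Mi + st)
    ifelse(!is.na(den) & den > 0, Nj * Mi / den, 0)
  }
  diag(K) <- 0
  dimnames(K) <- list(system$id, system$id)
  K
}

#' Model specification for the generalized radiation family
#'
#' @param variant one of `"radiation"` (original, unconstrained), `"PIR"`,
#'   `"PCR"`, `"AIR"`, `"ACR"` — Production/Attraction-constrained,
#'   Intervention/Competition-based.
#' @param lambda scaling exponent applied to the transition kernel before
#'   normalization (>= 0; `lambda = 1` with full support recovers the
#'   finite-size-normalized original model, `lambda = 0` allocates uniformly
#'   over eligible partners).
#' @param kappa normalization factor matching total predicted to total
#'   observed flux; `NULL` (default) computes it via [compute_kappa()].
#' @param marginal_source `"population"` (kernel masses are census
#'   populations) or `"trips"` (masses are the observed trip marginals).
#' @param kappa_support `"observed_pairs"` (default; kappa's denominator sums
#'   predictions over OD pairs present in the observed network, appropriate
#'   for sparse observed networks) or `"all_pairs"`.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(variant = c("PIR", "PCR", "AIR", "ACR", "radiation"),
                       lambda = 1,
                       kappa = NULL,
                       marginal_source = c("population", "trips"),
                       kappa_support = c("observed_pairs", "all_pairs")) {
  variant <- match.arg(variant)
  if (!is.numeric(lambda) || length(lambda) != 1 || !is.finite(lambda) ||
      lambda < 0) {
    rf_stop("invalid_lambda", "lambda must be a finite nonnegative number")
  }
  if (!is.null(kappa) &&
      (!is.numeric(kappa) || length(kappa) != 1 || !is.finite(kappa) ||
       kappa <= 0)) {
    rf_stop("invalid_kappa", "kappa must be a finite positive number")
  }
  structure(
    list(variant = variant, lambda = lambda, kappa = kappa,
         marginal_source = match.arg(marginal_source),
         kappa_support = match.arg(kappa_support)),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s, lambda = %g, kappa = %s, masses = %s, support = %s\n",
              x$variant, x$lambda,
              if (is.null(x$kappa)) "auto" else format(x$kappa),
              x$marginal_source, x$kappa_support))
  invisible(x)
}

# p^lambda with the 0 -> 0 shortcut; lambda = 0 keeps zero-kernel pairs at 0,
# giving a uniform allocation over the eligible (positive-kernel) partners.
pow_lambda <- function(K, lambda) {
  W <- matrix(0, nrow(K), ncol(K), dimnames = dimnames(K))
  pos <- K > 0
  W[pos] <- exp(lambda * log(K[pos]))
  W
}

# Row- or column-normalized allocation shares of K^lambda.
allocation_shares <- function(K, lambda, margin = c("row", "col")) {
  margin <- match.arg(margin)
  W <- pow_lambda(K, lambda)
  tot <- if (margin == "row") rowSums(W) else colSums(W)
  share <- if (margin == "row") W / ifelse(tot > 0, tot, 1)
           else sweep(W, 2, ifelse(tot > 0, tot, 1), "/")
  share[is.na(share)] <- 0
  list(share = share, tot = tot)
}

#' Original (unconstrained) radiation prediction
#'
#' The parameter-free flux `T_ij = T_i p_ij` summed over destinations does
#' not conserve `T_i` in a finite system: with distinct distances the row sum
#' telescopes to `T_i (1 - m_i / M)`.
#'
#' @param system,s as in [kernel_matrix()].
#' @param T_i per-origin production totals (trips), in system id order.
#' @param m,n kernel masses, defaulting to populations.
#' @return a [flux_matrix()] over all ordered pairs.
#' @export
predict_radiation <- function(system, s, T_i,
                              m = system$population, n = system$population) {
  stopifnot(length(T_i) == system$N)
  P <- kernel_matrix(system, s, "intervention", m = m, n = n)
  flux_matrix(T_i * P, ids = system$id)
}

#' Predict fluxes with a generalized radiation model
#'
#' Implements the four singly-constrained variants. Writing `p` for the
#' intervention kernel and `q` for the competition kernel:
#' \itemize{
#'   \item PIR: `kappa T_i p_ij^lambda / sum_k!=i p_ik^lambda`
#'   \item PCR: `kappa T_i q_ij^lambda / sum_k!=i q_ik^lambda`
#'   \item AIR: `kappa T_j p_ij^lambda / sum_k!=j p_kj^lambda`
#'   \item ACR: `kappa T_j q_ij^lambda / sum_k!=j q_kj^lambda`
#' }
#' Production-constrained variants conserve `kappa * T_i` per origin;
#' attraction-constrained variants conserve `kappa * T_j` per destination.
#' The constrained marginal is always taken from `observed`.
#'
#' @param system,s as in [kernel_matrix()].
#' @param spec a [model_spec()].
#' @param observed observed [flux_matrix()]; supplies the constrained
#'   marginals, the kernel masses when `marginal_source = "trips"`, and the
#'   kappa support.
#' @return a [flux_matrix()] with attributes `kappa` (realized value) and
#'   `model_spec`.
#' @export
predict_generalized <- function(system, s, spec, observed) {
  stopifnot(inherits(spec, "model_spec"))
  observed <- unclass(observed)
  if (spec$marginal_source == "population") {
    m <- system$population; n <- system$population
  } else {
    m <- rowSums(observed); n <- colSums(observed)
  }
  if (spec$variant == "radiation") {
    unscaled <- unclass(predict_radiation(system, s, rowSums(observed), m, n))
  } else {
    direction <- if (spec$variant %in% c("PIR", "AIR")) "intervention" else "competition"
    K <- kernel_matrix(system, s, direction, m = m, n = n)
    if (spec$variant %in% c("PIR", "PCR")) {
      al <- allocation_shares(K, spec$lambda, "row")
      T_i <- rowSums(observed)
      if (any(al$tot == 0 & T_i > 0)) {
        rf_stop("undefined_allocation",
                "origin(s) with positive T_i but zero allocation weight: %s",
                paste(system$id[al$tot == 0 & T_i > 0], collapse = ", "))
      }
      unscaled <- T_i * al$share
    } else {
      al <- allocation_shares(K, spec$lambda, "col")
      T_j <- colSums(observed)
      if (any(al$tot == 0 & T_j > 0)) {
        rf_stop("undefined_allocation",
                "destination(s) with positive T_j but zero allocation weight: %s",
                paste(system$id[al$tot == 0 & T_j > 0], collapse = ", "))
      }
      unscaled <- sweep(al$share, 2, T_j, "*")
    }
  }
  kappa <- spec$kappa
  if (is.null(kappa)) {
    kappa <- compute_kappa(unscaled, observed, spec$kappa_support)
  }
  out <- flux_matrix(kappa * unscaled, ids = system$id)
  spec$kappa <- kappa
  attr(out, "kappa") <- kappa
  attr(out, "model_spec") <- spec
  out
}

#' Normalization factor kappa
#'
#' Matches the total predicted flux to the total observed flux:
#' `kappa = sum(observed) / sum(unscaled over the support)`. With
#' `support = "observed_pairs"` the denominator is restricted to OD pairs
#' present in the observed network — the observed network is usually much
#' sparser than the all-pairs prediction, and an all-pairs denominator would
#' systematically deflate predictions on the observed pairs.
#'
#' @param unscaled prediction before scaling (matrix or `flux_matrix`).
#' @param observed observed fluxes on the same location set.
#' @param support `"observed_pairs"` (default) or `"all_pairs"`.
#' @return scalar kappa > 0.
#' @export
compute_kappa <- function(unscaled, observed,
                          support = c("observed_pairs", "all_pairs")) {
  support <- match.arg(support)
  al <- align_flux(unscaled, observed)
  denom <- if (support == "observed_pairs") sum(al$a[al$b > 0]) else sum(al$a)
  if (!is.finite(denom) || denom <= 0) {
    rf_stop("undefined_kappa",
            "kappa denominator is zero: no predicted flux on the %s support",
            support)
  }
  sum(al$b) / denom
}

#' Production-constrained gravity baseline
#'
#' A minimal power-law gravity model, `T_ij` proportional to
#' `T_i n_j r_ij^-beta` with row normalization, provided only as a
#' conventional comparison point; it is not part of the radiation family.
#'
#' @param system a [build_system()] object.
#' @param dist distance matrix (km).
#' @param T_i per-origin production totals.
#' @param beta nonnegative distance-decay exponent.
#' @return a [flux_matrix()].
#' @export
gravity_baseline <- function(system, dist, T_i, beta) {
  stopifnot(length(T_i) == system$N, is.numeric(beta), beta >= 0)
  n <- system$population
  N <- system$N
  Nj <- matrix(n, N, N, byrow = TRUE)
  if (beta > 0) {
    bad <- dist <= 0 & Nj > 0
    diag(bad) <- FALSE
    if (any(bad)) {
      rf_stop("undefined_deterrence",
              "zero distance between distinct locations with beta > 0")
    }
    W <- Nj * ifelse(dist > 0, dist^(-beta), 0)
  } else {
    W <- Nj + 0 * dist
  }
  diag(W) <- 0
  rs <- rowSums(W)
  share <- W / ifelse(rs > 0, rs, 1)
  flux_matrix(T_i * share, ids = system$id)
}
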