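#' Origin-destination flux matrix
#'
#' A nonnegative N x N matrix of trip counts (real-valued: expected fluxes are
#' allowed) with location ids as dimnames and a structurally zero diagonal —
#' the radiation family never emits intrazonal flux. Row sums are the
#' production marginals `T_i`, column sums the attraction marginals `T_j`.
#'
#' @param trips numeric matrix of trips, origins in rows.
#' @param ids optional character vector of location ids (defaults to existing
#'   dimnames).
#' @return object of class `flux_matrix` (a plain matrix underneath).
#' @export
flux_matrix <- function(trips, ids = NULL) {
  stopifnot(is.matrix(trips), nrow(trips) == ncol(trips))
  trips <- unclass(trips)
  if (is.null(ids)) ids <- rownames(trips)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(trips)))
  if (any(!is.finite(trips)) || any(trips < 0)) {
    rf_stop("invalid_flux", "flux entries must be finite and nonnegative")
  }
  if (any(diag(trips) != 0)) {
    ndrop <- sum(diag(trips) > 0)
    message(sprintf("dropping %d intrazonal (diagonal) flux entr%s",
                    ndrop, if (ndrop == 1) "y" else "ies"))
    diag(trips) <- 0
  }
  dimnames(trips) <- list(ids, ids)
  class(trips) <- c("flux_matrix", class(trips))
  trips
}

#' Build a flux matrix from an edge list
#'
#' Duplicate origin-destination rows are summed; intrazonal rows (origin ==
#' destination) are dropped with a message, since the models cannot emit them.
#'
#' @param edges data.frame with columns `origin`, `destination`, `trips`.
#' @param system a [build_system()] object supplying the id universe.
#' @return a [flux_matrix()].
#' @export
flux_from_edges <- function(edges, system) {
  stopifnot(is.data.frame(edges), inherits(system, "mobility_system"))
  need <- c("origin", "destination", "trips")
  missing_cols <- setdiff(need, names(edges))
  if (length(missing_cols) > 0) {
    rf_stop("schema_error", "flow table lacks column(s): %s",
            paste(missing_cols, collapse = ", "))
  }
  o <- as.character(edges$origin)
  d <- as.character(edges$destination)
  tr <- suppressWarnings(as.numeric(edges$trips))
  if (anyNA(tr)) {
    rf_stop("parse_error", "unparseable trips at row(s) %s",
            paste(which(is.na(tr)), collapse = ", "))
  }
  if (any(tr < 0)) rf_stop("invalid_flux", "negative trips are not allowed")
  unknown <- setdiff(unique(c(o, d)), system$id)
  if (length(unknown) > 0) {
    rf_stop("unknown_location", "unknown location id(s): %s",
            paste(unknown, collapse = ", "))
  }
  intra <- o == d
  if (any(intra)) {
    message(sprintf("dropping %d intrazonal flow row(s)", sum(intra)))
    o <- o[!intra]; d <- d[!intra]; tr <- tr[!intra]
  }
  N <- system$N
  f <- matrix(0, N, N, dimnames = list(system$id, system$id))
  if (length(tr) > 0) {
    io <- match(o, system$id)
    id_ <- match(d, system$id)
    agg <- rowsum(tr, (id_ - 1L) * N + io)  # sum duplicates per cell
    f[as.integer(rownames(agg))] <- agg[, 1L]
  }
  flux_matrix(f)
}

#' @rdname flux_matrix
#' @param x a `flux_matrix`.
#' @export
production_totals <- function(x) rowSums(unclass(x))

#' @rdname flux_matrix
#' @export
attraction_totals <- function(x) colSums(unclass(x))

#' @rdname flux_matrix
#' @export
total_trips <- function(x) sum(unclass(x))

#' Positive entries of a flux matrix as an edge list
#'
#' @param x a `flux_matrix` (or plain matrix).
#' @return data.frame `origin`, `destination`, `trips`, sorted by origin then
#'   destination for deterministic output.
#' @export
flux_edges <- function(x) {
  x <- unclass(x)
  idx <- which(x > 0, arr.ind = TRUE)
  out <- data.frame(
    origin = rownames(x)[idx[, 1]],
    destination = colnames(x)[idx[, 2]],
    trips = x[idx],
    stringsAsFactors = FALSE
  )
  out[order(out$origin, out$destination), , drop = FALSE]
}

#' @export
print.flux_matrix <- function(x, ...) {
  pos <- sum(unclass(x) > 0)
  cat(sprintf("<flux_matrix> %d x %d, %d positive OD pairs, %s total trips\n",
              nrow(x), ncol(x), pos, format(total_trips(x))))
  invisible(x)
}

# Reorder b's rows/cols to a's ids; both must cover the same id set.
align_flux <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  if (!is.null(rownames(a)) && !is.null(rownames(b))) {
    if (!setequal(rownames(a), rownames(b))) {
      rf_stop("unknown_location", "flux matrices are on different location sets")
    }
    b <- b[rownames(a), colnames(a), drop = FALSE]
  } else if (!all(dim(a) == dim(b))) {
    rf_stop("unknown_location", "flux matrices have different dimensions")
  }
  list(a = a, b = b)
}
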