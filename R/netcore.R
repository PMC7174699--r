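#' Construct a structural connectome
#'
#' A connectome is a weighted, symmetric, zero-diagonal region-by-region
#' matrix whose weights carry volume-normalized streamline-count semantics:
#' entry (i, j) is the number of tractography streamlines linking regions i
#' and j divided by the summed volumes of the two regions. Region identifiers
#' are carried as matrix dimnames so that lesioned (row/column-deleted)
#' networks keep their original region identities.
#'
#' @param weights numeric n x n matrix, symmetric, zero diagonal, entries >= 0.
#' @param region_ids integer vector of region identifiers matching the rows
#'   (defaults to `0:(n-1)`).
#' @param atlas_ref character label for the parcellation the rows refer to.
#' @return an object of class `connectome` with elements `weights`,
#'   `region_ids` and `atlas_ref`.
#' @export
connectome <- function(weights, region_ids = NULL, atlas_ref = "unknown") {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (ncol(weights) != n) stop_param("weights must be square, got %d x %d", n, ncol(weights))
  if (any(!is.finite(weights))) stop_param("weights must be finite")
  if (any(weights < 0)) stop_param("weights must be nonnegative")
  if (any(abs(weights - t(weights)) > 1e-12)) stop_param("weights must be symmetric")
  if (any(diag(weights) != 0)) stop_param("weights must have a zero diagonal")
  region_ids <- as.integer(region_ids %||% (seq_len(n) - 1L))
  if (length(region_ids) != n || anyDuplicated(region_ids)) {
    stop_param("region_ids must be %d unique integers", n)
  }
  dimnames(weights) <- list(as.character(region_ids), as.character(region_ids))
  structure(list(weights = weights, region_ids = region_ids, atlas_ref = atlas_ref),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  nz <- sum(x$weights > 0) / 2
  n <- length(x$region_ids)
  cat(sprintf("<connectome> %d regions, %d edges, density %.3f (atlas: %s)\n",
              n, nz, nz / choose(n, 2), x$atlas_ref))
  invisible(x)
}

n_regions <- function(conn) length(conn$region_ids)

as_igraph <- function(conn, norm_weight = NULL) {
  w <- conn$weights
  norm_weight <- norm_weight %||% max(w)
  if (norm_weight <= 0) return(igraph::make_empty_graph(n = nrow(w), directed = FALSE))
  len <- ifelse(w > 0, norm_weight / w, 0)
  igraph::graph_from_adjacency_matrix(len, mode = "undirected", weighted = TRUE,
                                      diag = FALSE)
}

#' Weighted shortest-path length matrix
#'
#' Converts connection weights to lengths by the connectivity-toolbox
#' convention length = 1/weight, applied after dividing every weight by the
#' matrix maximum (`norm_weight`) so that the strongest connection has length
#' 1 and all lengths are >= 1. Unreachable pairs get `Inf`; the diagonal is 0.
#'
#' @param conn a [connectome].
#' @param norm_weight weight used as the normalization reference; defaults to
#'   the maximum weight of `conn`. Lesion analyses pass the intact network's
#'   maximum so that efficiency loss is not masked by renormalization.
#' @param binarize treat every present connection as weight 1 (hop-count
#'   shortest paths) instead of using the weighted convention.
#' @return symmetric numeric matrix of shortest-path lengths with region ids
#'   as dimnames.
#' @export
path_lengths <- function(conn, norm_weight = NULL, binarize = FALSE) {
  stopifnot(inherits(conn, "connectome"))
  if (binarize) {
    conn <- connectome((conn$weights > 0) * 1, region_ids = conn$region_ids,
                       atlas_ref = conn$atlas_ref)
    norm_weight <- NULL
  }
  n <- n_regions(conn)
  norm_weight <- norm_weight %||% max(conn$weights)
  if (norm_weight <= 0) {
    d <- matrix(Inf, n, n, dimnames = dimnames(conn$weights))
    diag(d) <- 0
    return(d)
  }
  g <- as_igraph(conn, norm_weight)
  d <- igraph::distances(g, weights = igraph::E(g)$weight)
  dimnames(d) <- dimnames(conn$weights)
  d
}

#' Global efficiency of a weighted network
#'
#' Average inverse shortest-path length over ordered node pairs,
#' \deqn{E(G) = \frac{1}{n(n-1)} \sum_{i \ne j} \frac{1}{d(i,j)},}
#' with 1/Inf = 0 for unreachable pairs, normalized by the efficiency of the
#' ideal network in which every possible edge is present at the reference
#' (maximum) weight, so every ideal length is 1 and \eqn{E(G^{ideal}) = 1}.
#' The ratio GE = E(G)/E(G_ideal) lies in \[0, 1\] and equals 1 exactly for a
#' uniform complete network. Disconnected networks are permitted (lesioning
#' can disconnect): unreachable pairs simply contribute nothing.
#'
#' @inheritParams path_lengths
#' @return list of class `efficiency_result` with `raw_efficiency`,
#'   `ideal_efficiency` and `global_efficiency`.
#' @export
global_efficiency <- function(conn, norm_weight = NULL, binarize = FALSE) {
  stopifnot(inherits(conn, "connectome"))
  n <- n_regions(conn)
  if (n < 2) stop_param("global efficiency undefined for n = %d (< 2) nodes", n)
  d <- path_lengths(conn, norm_weight, binarize = binarize)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  raw <- sum(inv) / (n * (n - 1))
  structure(list(raw_efficiency = raw, ideal_efficiency = 1,
                 global_efficiency = raw),
            class = "efficiency_result")
}

#' @export
print.efficiency_result <- function(x, ...) {
  cat(sprintf("global efficiency %.6f (raw %.6f / ideal %.6f)\n",
              x$global_efficiency, x$raw_efficiency, x$ideal_efficiency))
  invisible(x)
}

#' Local efficiency of one region
#'
#' Global efficiency of the subgraph induced by the region's neighbors (the
#' region itself excluded), a measure of fault tolerance of communication in
#' the region's neighborhood. Regions with fewer than two neighbors score 0.
#'
#' @param conn a [connectome].
#' @param node a region id present in `conn`.
#' @return scalar in \[0, 1\].
#' @export
local_efficiency <- function(conn, node) {
  stopifnot(inherits(conn, "connectome"))
  key <- as.character(node)
  if (!key %in% rownames(conn$weights)) stop_param("unknown region id: %s", key)
  nbr <- which(conn$weights[key, ] > 0)
  if (length(nbr) < 2) return(0)
  sub <- conn$weights[nbr, nbr, drop = FALSE]
  subconn <- connectome(sub, region_ids = conn$region_ids[nbr],
                        atlas_ref = conn$atlas_ref)
  global_efficiency(subconn)$global_efficiency
}
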