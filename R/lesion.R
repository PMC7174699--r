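#' Delete regions (and all their connections) from a connectome
#'
#' Simulates a focal structural lesion: the rows and columns of the deleted
#' regions are removed outright; every remaining weight is untouched. Region
#' ids are preserved (not reindexed) so downstream tables stay traceable to
#' the atlas.
#'
#' @param conn a [connectome].
#' @param nodes region ids to delete; may be empty (identity).
#' @return a [connectome] on the surviving regions.
#' @export
delete_nodes <- function(conn, nodes) {
  stopifnot(inherits(conn, "connectome"))
  nodes <- unique(as.integer(nodes))
  if (length(nodes) == 0) return(conn)
  unknown <- setdiff(nodes, conn$region_ids)
  if (length(unknown)) stop_param("unknown region id(s): %s", toString(unknown))
  if (length(nodes) >= n_regions(conn)) stop_param("cannot delete all %d regions", n_regions(conn))
  keep <- !(conn$region_ids %in% nodes)
  connectome(conn$weights[keep, keep, drop = FALSE],
             region_ids = conn$region_ids[keep], atlas_ref = conn$atlas_ref)
}

#' Normalized change in global efficiency after deleting a node set
#'
#' The importance of a set of regions for network communication is codified
#' as the relative drop in global efficiency caused by removing them:
#' \deqn{\Delta GE = (GE_{intact} - GE_{lesioned}) / GE_{intact}.}
#' The lesioned network's efficiency uses its own node count in the
#' 1/(n(n-1)) prefactor but the intact network's maximum weight as the
#' length-normalization reference, so the quantity reflects lost
#' communication rather than rescaling. 1 means total disconnection; the
#' sign is kept, so removing a region that is a net drag on average
#' efficiency (e.g. an isolated node) yields a negative value.
#'
#' @param conn the intact [connectome].
#' @param nodes region ids to delete.
#' @return list of class `lesion_outcome` with `deleted`, `ge_intact`,
#'   `ge_lesioned`, `delta_ge`.
#' @export
delta_ge <- function(conn, nodes) {
  nodes <- sort(unique(as.integer(nodes)))
  if (length(nodes) == 0) stop_param("nodes must be nonempty")
  ge0 <- global_efficiency(conn)$global_efficiency
  if (ge0 <= 0) stop_param("intact global efficiency is 0; delta_ge undefined")
  wmax <- max(conn$weights)
  ge1 <- global_efficiency(delete_nodes(conn, nodes), norm_weight = wmax)$global_efficiency
  structure(list(deleted = nodes, ge_intact = ge0, ge_lesioned = ge1,
                 delta_ge = (ge0 - ge1) / ge0),
            class = "lesion_outcome")
}

#' Number of k-subsets of n regions
#'
#' Size of an exhaustive k-node deletion sweep: C(n, k). At the 129-region
#' parcellation this gives 129 single, 8256 pair and 349504 triple deletions.
#'
#' @param n number of regions; @param k deletion size.
#' @return integer C(n, k).
#' @export
sweep_size <- function(n, k) {
  if (k < 1 || k >= n) stop_param("need 1 <= k < n, got k = %d, n = %d", k, n)
  choose(n, k)
}

#' Number of deletion combinations containing a given region
#'
#' Each region appears in C(n-1, k-1) of the C(n, k) k-subsets; this is the
#' normalization used when aggregating combination ranks into per-region
#' scores (128 for pair deletions and 8128 for triple deletions at n = 129).
#'
#' @inheritParams sweep_size
#' @return integer C(n-1, k-1).
#' @export
appearance_count <- function(n, k) {
  if (k < 1 || k >= n) stop_param("need 1 <= k < n, got k = %d, n = %d", k, n)
  choose(n - 1, k - 1)
}

#' Exhaustive k-node deletion sweep
#'
#' Enumerates every k-subset of regions in lexicographic order of region id
#' and records the global-efficiency outcome of deleting each subset. The
#' enumeration is exhaustive and deterministic. `k = 3` on more than 60
#' regions enumerates hundreds of thousands of subsets and must be requested
#' explicitly via `allow_large = TRUE`.
#'
#' @param conn a [connectome].
#' @param k 1, 2 or 3 regions deleted at a time.
#' @param subject_id identifier carried into the result.
#' @param allow_large opt-in for k = 3 sweeps on networks over 60 regions.
#' @return object of class `deletion_sweep`: list with `k`, `subject_id`,
#'   `n_regions`, `region_ids`, `ge_intact`, and `outcomes`, a data.frame
#'   with columns `node_1..node_k`, `ge_lesioned`, `delta_ge` (one row per
#'   subset, C(n, k) rows in all).
#' @export
lesion_sweep <- function(conn, k, subject_id = "s1", allow_large = FALSE) {
  stopifnot(inherits(conn, "connectome"))
  if (!k %in% 1:3) stop_param("k must be 1, 2 or 3, got %s", toString(k))
  n <- n_regions(conn)
  if (k >= n) stop_param("k = %d must be below the region count %d", k, n)
  if (k == 3 && n > 60 && !allow_large) {
    stop_param("k = 3 on %d regions enumerates %d subsets; set allow_large = TRUE", n, choose(n, 3))
  }
  ids <- sort(conn$region_ids)
  subsets <- utils::combn(ids, k)
  ge0 <- global_efficiency(conn)$global_efficiency
  if (ge0 <= 0) stop_param("intact global efficiency is 0; sweep undefined")
  wmax <- max(conn$weights)
  ge1 <- apply(subsets, 2, function(s) {
    global_efficiency(delete_nodes(conn, s), norm_weight = wmax)$global_efficiency
  })
  outcomes <- as.data.frame(t(subsets))
  names(outcomes) <- paste0("node_", seq_len(k))
  outcomes$ge_lesioned <- ge1
  outcomes$delta_ge <- (ge0 - ge1) / ge0
  structure(list(k = k, subject_id = subject_id, n_regions = n,
                 region_ids = ids, ge_intact = ge0, outcomes = outcomes),
            class = "deletion_sweep")
}

#' @export
print.deletion_sweep <- function(x, ...) {
  cat(sprintf("<deletion_sweep> subject %s, k = %d, %d subsets of %d regions, GE_intact %.4f\n",
              x$subject_id, x$k, nrow(x$outcomes), x$n_regions, x$ge_intact))
  invisible(x)
}

rank_scores <- function(scores, region_ids) {
  # rank 1 = most important; ties broken by ascending region id
  ord <- order(-scores, region_ids)
  ranks <- integer(length(scores))
  ranks[ord] <- seq_along(scores)
  ranks
}

new_node_importance <- function(region_ids, scores, provenance) {
  structure(data.frame(region_id = region_ids, score = scores,
                       rank = rank_scores(scores, region_ids)),
            provenance = provenance, class = c("node_importance", "data.frame"))
}

#' @export
print.node_importance <- function(x, ...) {
  cat(sprintf("<node_importance> (%s) top regions:\n", attr(x, "provenance")))
  print.data.frame(utils::head(x[order(x$rank), ], 10), row.names = FALSE)
  invisible(x)
}

#' Aggregate a deletion sweep into per-region importance scores
#'
#' For single deletions a region's score is simply the ΔGE its removal
#' causes. For pair and triple deletions every combination is first
#' rank-ordered by ΔGE (rank 1 = largest drop, ties broken by lexicographic
#' subset order); each combination then contributes a weight to every region
#' it contains, and a region's score is its summed weight normalized by the
#' number of combinations in which it appears, C(n-1, k-1). The default
#' weight is the linear reverse rank w(r) = C(n,k) - r + 1; `"inverse"`
#' (w = 1/r) and `"top_m"` (indicator of the top m combinations) are
#' available alternatives.
#'
#' @param sweep a [lesion_sweep] result.
#' @param weight_fn `"linear_reverse"` (default), `"inverse"` or `"top_m"`.
#' @param top_m cutoff used by `weight_fn = "top_m"`.
#' @return a `node_importance` data.frame with `region_id`, `score`, `rank`
#'   (1 = most important; ties broken by ascending region id).
#' @export
aggregate_importance <- function(sweep, weight_fn = c("linear_reverse", "inverse", "top_m"),
                                 top_m = 100L) {
  stopifnot(inherits(sweep, "deletion_sweep"))
  weight_fn <- match.arg(weight_fn)
  out <- sweep$outcomes
  if (nrow(out) == 0) stop_param("empty sweep")
  ids <- sweep$region_ids
  if (sweep$k == 1) {
    scores <- out$delta_ge[match(ids, out$node_1)]
    return(new_node_importance(ids, scores, "single"))
  }
  ncomb <- nrow(out)
  # combinations are already in lexicographic subset order, the tie-break
  r <- order(order(-out$delta_ge, seq_len(ncomb)))
  w <- switch(weight_fn,
              linear_reverse = ncomb - r + 1,
              inverse = 1 / r,
              top_m = as.numeric(r <= top_m))
  member <- as.matrix(out[, paste0("node_", seq_len(sweep$k)), drop = FALSE])
  totals <- vapply(ids, function(id) sum(w[rowSums(member == id) > 0]), numeric(1))
  scores <- totals / appearance_count(sweep$n_regions, sweep$k)
  new_node_importance(ids, scores,
                      if (sweep$k == 2) "pair_aggregate" else "triple_aggregate")
}

#' Cohort-average region importance across subjects
#'
#' Averages per-subject importance over a cohort of deletion sweeps sharing
#' the same k and region set: for single deletions this is the mean ΔGE per
#' region across subjects; for pair/triple sweeps it is the mean of the
#' per-subject aggregated scores.
#'
#' @param sweeps list of [lesion_sweep] results, one per subject.
#' @param ... passed to [aggregate_importance].
#' @return a `node_importance` with provenance `cohort_average`.
#' @export
cohort_importance <- function(sweeps, ...) {
  stopifnot(length(sweeps) >= 1, all(vapply(sweeps, inherits, TRUE, "deletion_sweep")))
  k <- unique(vapply(sweeps, `[[`, numeric(1), "k"))
  if (length(k) != 1) stop_param("all sweeps must share k")
  ids <- sweeps[[1]]$region_ids
  for (s in sweeps) {
    if (!identical(s$region_ids, ids)) stop_param("sweeps must share the same region set")
  }
  per_subject <- vapply(sweeps, function(s) aggregate_importance(s, ...)$score,
                        numeric(length(ids)))
  new_node_importance(ids, rowMeans(as.matrix(per_subject)), "cohort_average")
}
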