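# Independent brute-force oracles. These deliberately share no code with the
# package: shortest paths by exhaustive simple-path enumeration, efficiency by
# direct summation, AUC by pair counting, and the rank-sum null distribution
# by complete enumeration of group labelings.

# all-pairs shortest path lengths by enumerating every simple path (n <= 8)
oracle_path_lengths <- function(w, norm = max(w)) {
  n <- nrow(w)
  len <- matrix(Inf, n, n)
  len[w > 0] <- norm / w[w > 0]
  best <- matrix(Inf, n, n)
  diag(best) <- 0
  explore <- function(node, target, visited, dist) {
    if (node == target) {
      if (dist < best[visited[1], target]) best[visited[1], target] <<- dist
      return(invisible())
    }
    for (nxt in seq_len(n)) {
      if (!(nxt %in% visited) && is.finite(len[node, nxt])) {
        explore(nxt, target, c(visited, nxt), dist + len[node, nxt])
      }
    }
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) explore(i, j, i, 0)
  }
  best
}

oracle_global_efficiency <- function(w, norm = max(w)) {
  n <- nrow(w)
  if (max(w) == 0) return(0)
  d <- oracle_path_lengths(w, norm)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

oracle_auc <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  pairs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(pairs)
}

# exact two-sided rank-sum p-value by enumerating all group labelings
oracle_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_len(n1)])
  all_w <- apply(utils::combn(length(pooled), n1), 2, function(idx) sum(ranks[idx]))
  mu <- mean(all_w)
  mean(abs(all_w - mu) >= abs(w_obs - mu) - 1e-9)
}

# seeded random symmetric weighted graph on n nodes
rand_graph <- function(n, density = 0.5, seed = 1, weights = NULL) {
  withr::with_seed(seed, {
    w <- matrix(0, n, n)
    up <- upper.tri(w)
    present <- runif(sum(up)) < density
    vals <- if (is.null(weights)) runif(sum(up), 0.2, 2) else sample(weights, sum(up), TRUE)
    w[up] <- present * vals
  })
  w + t(w)
}

toy_atlas <- function(n = 24, hubs = 3, strain = 3, seed = 1) {
  gen_atlas(n, hubs, strain, seed = seed)
}
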