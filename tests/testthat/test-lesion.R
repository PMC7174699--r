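chain3 <- function() {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.7
  w[2, 3] <- w[3, 2] <- 0.7
  connectome(w)
}

test_that("node deletion removes rows/columns, preserves weights and region ids", {
  cn <- chain3()
  # delete a leaf: remaining edge untouched
  lf <- delete_nodes(cn, 2)
  expect_equal(lf$region_ids, c(0L, 1L))
  expect_equal(unname(lf$weights["0", "1"]), 0.7)
  # identity deletion
  expect_identical(delete_nodes(cn, integer(0)), cn)
  # deleting the middle node leaves an edgeless pair with original ids
  mid <- delete_nodes(cn, 1)
  expect_equal(mid$region_ids, c(0L, 2L))
  expect_true(all(mid$weights == 0))
  expect_error(delete_nodes(cn, 7), "unknown region")
  expect_error(delete_nodes(cn, 0:2), "cannot delete all")
})

test_that("delta_ge handles total disconnection, symmetry and sign", {
  # star: deleting the hub disconnects everything -> delta = 1
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  out <- delta_ge(connectome(star), 0)
  expect_equal(out$ge_lesioned, 0)
  expect_equal(out$delta_ge, 1)

  # complete uniform graph: any deletion leaves a complete uniform graph
  comp <- matrix(1, 4, 4); diag(comp) <- 0
  for (node in 0:3) {
    expect_equal(delta_ge(connectome(comp), node)$delta_ge, 0)
  }

  # an isolated node drags the average down; removing it raises efficiency
  w <- matrix(1, 5, 5); diag(w) <- 0
  w[5, ] <- w[, 5] <- 0
  expect_lt(delta_ge(connectome(w), 4)$delta_ge, 0)

  expect_error(delta_ge(connectome(matrix(0, 3, 3)), 0), "undefined|efficiency is 0")
})

test_that("single deletions match brute-force recomputation on an 8-node graph", {
  w <- rand_graph(8, density = 0.5, seed = 3)
  cn <- connectome(w)
  ge0 <- oracle_global_efficiency(w)
  for (node in 0:7) {
    keep <- setdiff(1:8, node + 1)
    ge1 <- oracle_global_efficiency(w[keep, keep], norm = max(w))
    got <- delta_ge(cn, node)
    expect_equal(got$ge_intact, ge0, tolerance = 1e-12)
    expect_equal(got$ge_lesioned, ge1, tolerance = 1e-12)
    expect_equal(got$delta_ge, (ge0 - ge1) / ge0, tolerance = 1e-12)
  }
})

test_that("sweeps enumerate every subset once with the right appearance counts", {
  expect_equal(sweep_size(5, 2), 10)
  expect_equal(appearance_count(5, 1), 1)
  expect_error(appearance_count(5, 0), "1 <= k")
  expect_error(lesion_sweep(chain3(), 5), "k must be")

  w <- rand_graph(6, density = 0.7, seed = 2)
  cn <- connectome(w)
  for (k in 1:3) {
    sw <- lesion_sweep(cn, k)
    expect_equal(nrow(sw$outcomes), choose(6, k))
    member <- as.matrix(sw$outcomes[, paste0("node_", seq_len(k)), drop = FALSE])
    counts <- table(factor(member, levels = 0:5))
    expect_true(all(counts == choose(5, k - 1)))
    # lexicographic enumeration
    expect_false(is.unsorted(sw$outcomes$node_1))
  }
})

test_that("sweeps and aggregation are deterministic", {
  cn <- connectome(rand_graph(6, density = 0.7, seed = 5))
  s1 <- lesion_sweep(cn, 2)
  s2 <- lesion_sweep(cn, 2)
  expect_identical(s1$outcomes, s2$outcomes)
  expect_identical(aggregate_importance(s1), aggregate_importance(s2))
})

test_that("aggregation ranks a star hub first and recovers a cut vertex from pairs", {
  star <- matrix(0, 6, 6)
  star[1, 2:6] <- star[2:6, 1] <- 1
  imp <- aggregate_importance(lesion_sweep(connectome(star), 1))
  expect_equal(imp$region_id[imp$rank == 1], 0L)

  # two triangles joined only through node 2 (a cut vertex)
  w <- matrix(0, 5, 5)
  edge <- function(i, j) w[i + 1, j + 1] <<- w[j + 1, i + 1] <<- 1
  edge(0, 1); edge(1, 2); edge(0, 2); edge(2, 3); edge(2, 4); edge(3, 4)
  imp2 <- aggregate_importance(lesion_sweep(connectome(w), 2))
  expect_equal(imp2$region_id[imp2$rank == 1], 2L)
})

test_that("tied outcomes produce equal scores and region-id-ordered ranks", {
  comp <- matrix(1, 4, 4); diag(comp) <- 0
  imp <- aggregate_importance(lesion_sweep(connectome(comp), 1))
  expect_equal(length(unique(imp$score)), 1)
  expect_equal(imp$rank, 1:4)
  expect_equal(sort(imp$rank), 1:4)  # ranks are a permutation
})

test_that("cohort importance averages subjects and degenerates correctly", {
  cn <- connectome(rand_graph(6, density = 0.7, seed = 8))
  sw <- lesion_sweep(cn, 1)
  solo <- cohort_importance(list(sw))
  expect_equal(solo$score, aggregate_importance(sw)$score)
  expect_equal(attr(solo, "provenance"), "cohort_average")

  # two opposite profiles summing to a constant: cohort scores all equal
  ids <- 0:3
  mk <- function(deltas) {
    structure(list(k = 1, subject_id = "x", n_regions = 4, region_ids = ids,
                   ge_intact = 1,
                   outcomes = data.frame(node_1 = ids, ge_lesioned = 1 - deltas,
                                         delta_ge = deltas)),
              class = "deletion_sweep")
  }
  coh <- cohort_importance(list(mk(c(0.1, 0.2, 0.3, 0.4)), mk(c(0.4, 0.3, 0.2, 0.1))))
  expect_equal(length(unique(round(coh$score, 12))), 1)

  # planted shared hub ranked first in a small synthetic cohort
  atlas <- toy_atlas(20, hubs = 2, strain = 2, seed = 4)
  cohort <- gen_cohort(atlas, n_subjects = 5, between_subject_noise = 0.2, seed = 4,
                       density = 0.3)
  sweeps <- lapply(cohort, lesion_sweep, k = 1)
  imp <- cohort_importance(sweeps)
  hubs <- atlas$region_id[atlas$planted_role == "hub"]
  expect_true(imp$region_id[imp$rank == 1] %in% hubs)

  expect_error(cohort_importance(list(sw, lesion_sweep(cn, 2))), "share k")
})

test_that("pair-deletion importance agrees with single-deletion importance", {
  rhos <- sapply(1:3, function(seed) {
    atlas <- gen_atlas(40, 5, 5, seed = seed)
    cn <- gen_connectome(atlas, density = 0.2, hub_weight_boost = 3,
                         intra_module_bias = 2, seed = seed)
    i1 <- aggregate_importance(lesion_sweep(cn, 1))
    i2 <- aggregate_importance(lesion_sweep(cn, 2))
    cor(i1$rank, i2$rank, method = "spearman")
  })
  expect_gte(mean(rhos), 0.8)
})
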