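make_impacts <- function(rmps, outcome, kin = NULL) {
  n <- nrow(rmps)
  kin <- kin %||% matrix(1:n, n, 4)
  cases <- data.frame(case_id = sprintf("c%d", seq_len(n)), outcome = outcome,
                      peak_lin_vel = kin[, 1], peak_ang_vel = kin[, 2],
                      peak_lin_acc = kin[, 3], peak_ang_acc = kin[, 4],
                      mps95 = apply(rmps, 1, max))
  impact_set(cases, rmps)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("percentile95 follows linear interpolation between closest ranks", {
  expect_equal(percentile95(rep(0.2, 50)), 0.2)
  expect_equal(percentile95(1:100), 95.05)
  expect_equal(percentile95(0.4), 0.4)
  expect_error(percentile95(numeric(0)), "nonempty")
  # monotone: appending a value at or above the max never lowers it
  for (seed in 1:5) {
    v <- withr::with_seed(seed, runif(30))
    expect_gte(percentile95(c(v, max(v) + 0.1)), percentile95(v))
  }
})

test_that("strain ranking uses concussive cases only", {
  rmps <- matrix(c(0.3, 0.1, 0.2,
                   0.9, 0.9, 0.9), 2, 3, byrow = TRUE,
                 dimnames = list(NULL, 0:2))
  one <- make_impacts(rmps, c("concussion", "no_concussion"))
  rk <- rank_by_strain(one)
  # single concussive case: ranking is the sort of its rMPS vector
  expect_equal(rk$region_id[order(rk$rank)], c(0L, 2L, 1L))

  # perturbing non-concussive cases leaves the ranking fixed
  rmps2 <- rmps
  rmps2[2, ] <- c(5, 0.01, 7)
  rk2 <- rank_by_strain(make_impacts(rmps2, c("concussion", "no_concussion")))
  expect_equal(rk$rank, rk2$rank)

  # all-equal strain: ranks fall back to region-id order
  flat <- make_impacts(matrix(0.5, 2, 3, dimnames = list(NULL, 0:2)),
                       c("concussion", "concussion"))
  expect_equal(rank_by_strain(flat)$rank, 1:3)

  none <- make_impacts(rmps, rep("no_concussion", 2))
  expect_error(rank_by_strain(none), "no concussive")
})

test_that("rank-sum test matches exact enumeration and is symmetric", {
  # fully separated small groups: 2 of the 20 labelings are as extreme
  r <- ranksum_test(1:3, 4:6)
  expect_equal(r$p_value, 0.1)
  expect_equal(r$statistic, 6)  # ranks 1+2+3

  # fully tied data: every labeling equally extreme
  expect_equal(ranksum_test(rep(2, 4), rep(2, 5))$p_value, 1)

  for (seed in 1:6) {
    xy <- withr::with_seed(seed, {
      pool <- sample(5000, 11)  # tie-free, so the exact path is in force
      list(x = pool[1:5], y = pool[6:11])
    })
    got <- ranksum_test(xy$x, xy$y)
    expect_equal(got$p_value, oracle_ranksum_p(xy$x, xy$y), tolerance = 1e-12)
    # symmetry in the two-sided p-value
    expect_equal(got$p_value, ranksum_test(xy$y, xy$x)$p_value, tolerance = 1e-12)
  }
  expect_error(ranksum_test(numeric(0), 1:3), "nonempty")
})

test_that("rank-sum type-I error is calibrated at the nominal 0.05 level", {
  reject <- withr::with_seed(11, {
    replicate(1000, ranksum_test(rnorm(10), rnorm(10))$p_value < 0.05)
  })
  expect_gte(mean(reject), 0.03)
  expect_lte(mean(reject), 0.07)
})

test_that("regional tests flag planted effects and respect Bonferroni nesting", {
  atlas <- toy_atlas(30, hubs = 3, strain = 5, seed = 2)
  planted <- atlas$region_id[atlas$planted_role == "lateral_high_strain"]
  truth <- ground_truth(atlas$region_id[atlas$planted_role == "hub"], planted,
                        concussion_strain_shift = 2, kinematic_strain_coupling = 0.83)
  im <- gen_impacts(atlas, 53, 20, truth, seed = 5)
  res <- regional_tests(im)
  # Bonferroni flags nest inside uncorrected flags
  expect_true(all(res$regions$region_id[res$regions$significant_bonferroni] %in%
                  res$regions$region_id[res$regions$significant]))
  # a strong shift flags the majority of planted high-strain regions
  flagged <- res$regions$region_id[res$regions$significant_bonferroni]
  expect_gte(sum(planted %in% flagged), ceiling(length(planted) / 2))
  # kinematics and MPS95 separate the groups too
  expect_true(all(res$global$significant))

  # identical groups produce zero flags
  rmps <- matrix(rep(c(0.1, 0.2, 0.3), each = 6), 6, 3, dimnames = list(NULL, 0:2))
  same <- make_impacts(rmps, rep(c("concussion", "no_concussion"), 3))
  expect_equal(sum(regional_tests(same)$regions$significant), 0)

  one_group <- make_impacts(rmps, rep("concussion", 6))
  expect_error(regional_tests(one_group), "both outcome groups")
})

test_that("ranking correlation behaves on identity, reversal and independent noise", {
  atlas <- toy_atlas(20, 2, 2, seed = 3)
  cn <- gen_connectome(atlas, density = 0.3, seed = 3)
  a <- aggregate_importance(lesion_sweep(cn, 1))
  expect_equal(ranking_correlation(a, a)$rho, 1)

  rev <- a
  rev$score <- -a$score
  rev$rank <- netlesion:::rank_scores(rev$score, rev$region_id)
  expect_equal(ranking_correlation(a, rev, use = "ranks")$rho, -1)

  # independent random profiles: rho concentrates near 0 for 129 regions
  rhos <- withr::with_seed(7, replicate(500, {
    x <- netlesion:::new_node_importance(0:128, rnorm(129), "a")
    y <- netlesion:::new_node_importance(0:128, rnorm(129), "b")
    ranking_correlation(x, y)$rho
  }))
  expect_lt(abs(mean(rhos)), 0.05)
  expect_gte(mean(abs(rhos) < 0.2), 0.95)

  flat <- a; flat$score <- rep(1, nrow(flat))
  expect_error(ranking_correlation(a, flat), "zero-variance")
  b <- a[-1, ]
  expect_error(ranking_correlation(a, b), "different region sets")
})
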