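#' Construct an impact dataset
#'
#' Bundles per-impact records: a binary concussion outcome, four peak
#' resultant head kinematics (linear velocity in m/s, angular velocity in
#' rad/s, linear acceleration in g, angular acceleration in rad/s^2), a
#' whole-brain 95th-percentile maximum principal strain (MPS95), and the
#' per-region 95th-percentile maximum principal strain vector (rMPS).
#'
#' @param cases data.frame with columns `case_id`, `outcome` ("concussion" /
#'   "no_concussion"), `peak_lin_vel`, `peak_ang_vel`, `peak_lin_acc`,
#'   `peak_ang_acc`, `mps95`.
#' @param rmps numeric matrix, one row per case, one column per region;
#'   column names are region ids.
#' @return object of class `impact_set`.
#' @export
impact_set <- function(cases, rmps) {
  stopifnot(is.data.frame(cases), is.matrix(rmps), nrow(cases) == nrow(rmps))
  need <- c("case_id", "outcome", "peak_lin_vel", "peak_ang_vel",
            "peak_lin_acc", "peak_ang_acc", "mps95")
  miss <- setdiff(need, names(cases))
  if (length(miss)) stop_param("cases is missing columns: %s", toString(miss))
  if (!all(cases$outcome %in% c("concussion", "no_concussion"))) {
    stop_param("outcome must be 'concussion' or 'no_concussion'")
  }
  if (any(rmps < 0) || any(cases$mps95 < 0)) stop_param("strains must be nonnegative")
  if (is.null(colnames(rmps))) colnames(rmps) <- as.character(seq_len(ncol(rmps)) - 1L)
  structure(list(cases = cases, rmps = rmps), class = "impact_set")
}

#' @export
print.impact_set <- function(x, ...) {
  cat(sprintf("<impact_set> %d impacts (%d concussive), %d regions\n",
              nrow(x$cases), sum(x$cases$outcome == "concussion"), ncol(x$rmps)))
  invisible(x)
}

region_ids_of <- function(impacts) as.integer(colnames(impacts$rmps))

#' 95th percentile with linear interpolation between closest ranks
#'
#' The convention used to reduce an element-level strain sample to a single
#' regional or whole-brain value: the 95th percentile under linear
#' interpolation between order statistics (type 7 in the Hyndman-Fan
#' taxonomy). The interpolation type is configurable because finite-element
#' post-processing tools differ on this point.
#'
#' @param values nonempty numeric vector.
#' @param type quantile interpolation type, see [stats::quantile()].
#' @return scalar 95th percentile.
#' @export
percentile95 <- function(values, type = 7) {
  if (length(values) == 0) stop_param("values must be nonempty")
  unname(stats::quantile(values, 0.95, type = type, names = FALSE))
}

#' Rank regions by strain experienced in concussive impacts
#'
#' Scores each region by its mean (or median) rMPS over the concussive
#' impacts only; non-concussive impacts play no role. The resulting ranking
#' identifies the regions that deform most in injury-producing impacts.
#'
#' @param impacts an [impact_set] with at least one concussive case.
#' @param stat `"mean"` (default) or `"median"`.
#' @return a `node_importance` with provenance `strain_rank`.
#' @export
rank_by_strain <- function(impacts, stat = c("mean", "median")) {
  stopifnot(inherits(impacts, "impact_set"))
  stat <- match.arg(stat)
  conc <- impacts$cases$outcome == "concussion"
  if (!any(conc)) stop_param("no concussive cases; strain ranking undefined")
  f <- if (stat == "mean") colMeans else function(m) apply(m, 2, stats::median)
  scores <- f(impacts$rmps[conc, , drop = FALSE])
  new_node_importance(region_ids_of(impacts), unname(scores), "strain_rank")
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Compares two independent samples by the rank-sum (Mann-Whitney) test with
#' midranks for ties. The p-value comes from the exact null distribution
#' when the smaller group has at most `exact_cutoff` observations and the
#' data are tie-free, and from the normal approximation with continuity
#' correction otherwise.
#'
#' @param x,y nonempty numeric vectors.
#' @param exact_cutoff largest min-group size for which the exact
#'   distribution is used (default 8).
#' @return list with `statistic` (rank sum of `x`) and `p_value`.
#' @export
ranksum_test <- function(x, y, exact_cutoff = 8) {
  if (length(x) == 0 || length(y) == 0) stop_param("both groups must be nonempty")
  pooled <- c(x, y)
  if (all(pooled == pooled[1])) {
    # fully tied data: every labeling is equally extreme
    return(list(statistic = length(x) * (length(pooled) + 1) / 2, p_value = 1))
  }
  ties <- anyDuplicated(pooled) > 0
  use_exact <- min(length(x), length(y)) <= exact_cutoff && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = use_exact,
                                            correct = TRUE, alternative = "two.sided"))
  # wilcox.test reports Mann-Whitney U; convert to the rank sum of x
  list(statistic = unname(wt$statistic) + length(x) * (length(x) + 1) / 2,
       p_value = wt$p.value)
}

#' Regional and global strain/kinematics group tests
#'
#' For every region, tests whether rMPS differs between concussive and
#' non-concussive impacts (two-sided Wilcoxon rank-sum), flagging regions
#' that survive Bonferroni correction at `alpha / bonferroni_n`. The same
#' test is also applied, uncorrected, to the four peak kinematics and MPS95.
#'
#' @param impacts an [impact_set] with both outcome groups present.
#' @param alpha significance level (default 0.05).
#' @param bonferroni_n number of comparisons corrected for; defaults to the
#'   region count.
#' @return list with `regions` (data.frame: region_id, statistic, p_value,
#'   significant, significant_bonferroni) and `global` (data.frame:
#'   predictor, statistic, p_value, significant).
#' @export
regional_tests <- function(impacts, alpha = 0.05, bonferroni_n = NULL) {
  stopifnot(inherits(impacts, "impact_set"))
  conc <- impacts$cases$outcome == "concussion"
  if (!any(conc) || all(conc)) stop_param("both outcome groups must be nonempty")
  ids <- region_ids_of(impacts)
  bonferroni_n <- bonferroni_n %||% length(ids)
  per_region <- lapply(seq_along(ids), function(j) {
    ranksum_test(impacts$rmps[conc, j], impacts$rmps[!conc, j])
  })
  p <- vapply(per_region, `[[`, numeric(1), "p_value")
  regions <- data.frame(
    region_id = ids,
    statistic = vapply(per_region, `[[`, numeric(1), "statistic"),
    p_value = p,
    significant = p < alpha,
    significant_bonferroni = p < alpha / bonferroni_n)
  preds <- c("peak_lin_vel", "peak_ang_vel", "peak_lin_acc", "peak_ang_acc", "mps95")
  glob <- lapply(preds, function(v) {
    ranksum_test(impacts$cases[[v]][conc], impacts$cases[[v]][!conc])
  })
  gp <- vapply(glob, `[[`, numeric(1), "p_value")
  list(regions = regions,
       global = data.frame(predictor = preds,
                           statistic = vapply(glob, `[[`, numeric(1), "statistic"),
                           p_value = gp, significant = gp < alpha))
}

#' Correlation between two region-importance rankings
#'
#' Pearson correlation (with the usual t-based two-sided p-value) between
#' two importance profiles over the same region set, computed on the raw
#' scores by default or on the rank vectors on request. Used to ask whether
#' the regions that deform most under impact are also the regions most
#' important for network communication.
#'
#' @param a,b `node_importance` objects over the same regions.
#' @param use `"scores"` (default) or `"ranks"`.
#' @return list with `rho` and `p_value`.
#' @export
ranking_correlation <- function(a, b, use = c("scores", "ranks")) {
  use <- match.arg(use)
  if (!setequal(a$region_id, b$region_id)) stop_param("rankings cover different region sets")
  b <- b[match(a$region_id, b$region_id), ]
  va <- if (use == "scores") a$score else a$rank
  vb <- if (use == "scores") b$score else b$rank
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) stop_param("zero-variance ranking; correlation undefined")
  ct <- stats::cor.test(va, vb, method = "pearson")
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}
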