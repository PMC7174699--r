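#' Pipeline run configuration
#'
#' Collects every knob of the end-to-end analysis in one flat record. The
#' defaults are the study conditions of the reference analysis: a
#' 129-region parcellation, a 30-subject connectome cohort, and 53 impacts
#' of which 20 are concussive. Lesion sweeps default to single-node
#' deletion; pair and triple sweeps are available via `lesion_k` (triple
#' sweeps over 60 regions additionally require `allow_large = TRUE`).
#'
#' @param n_regions,n_hubs,n_strain_regions atlas parameters.
#' @param n_subjects,between_subject_noise connectome-cohort parameters.
#' @param n_cases,n_concussive impact-set parameters.
#' @param density,hub_weight_boost,intra_module_bias connectome parameters.
#' @param concussion_strain_shift,kinematic_strain_coupling effect sizes.
#' @param lesion_k integer vector of deletion sizes, subset of 1:3.
#' @param aggregation combination-rank weight strategy, see
#'   [aggregate_importance].
#' @param alpha,bonferroni_n group-test parameters (`bonferroni_n = NULL`
#'   means the region count).
#' @param max_predictors largest incremental region set (EPV-capped).
#' @param per_subject_k region count for per-subject evaluation.
#' @param seed root seed; every stage derives its own seed from it.
#' @param allow_large opt-in for k = 3 sweeps on networks over 60 regions.
#' @return object of class `run_config`.
#' @export
run_config <- function(n_regions = 129, n_hubs = 10, n_strain_regions = 10,
                       n_subjects = 30, between_subject_noise = 0.3,
                       n_cases = 53, n_concussive = 20,
                       density = 0.15, hub_weight_boost = 3, intra_module_bias = 2,
                       concussion_strain_shift = 1.5, kinematic_strain_coupling = 0.83,
                       lesion_k = 1L, aggregation = "linear_reverse",
                       alpha = 0.05, bonferroni_n = NULL,
                       max_predictors = 4, per_subject_k = 4,
                       seed = 1L, allow_large = FALSE) {
  if (!all(lesion_k %in% 1:3)) stop_param("lesion_k must be a subset of 1:3")
  cfg <- list(n_regions = n_regions, n_hubs = n_hubs, n_strain_regions = n_strain_regions,
              n_subjects = n_subjects, between_subject_noise = between_subject_noise,
              n_cases = n_cases, n_concussive = n_concussive,
              density = density, hub_weight_boost = hub_weight_boost,
              intra_module_bias = intra_module_bias,
              concussion_strain_shift = concussion_strain_shift,
              kinematic_strain_coupling = kinematic_strain_coupling,
              lesion_k = sort(unique(as.integer(lesion_k))),
              aggregation = aggregation, alpha = alpha,
              bonferroni_n = bonferroni_n %||% n_regions,
              max_predictors = max_predictors, per_subject_k = per_subject_k,
              seed = as.integer(seed), allow_large = isTRUE(allow_large))
  structure(cfg, class = "run_config")
}

serialize_config <- function(config) {
  vals <- vapply(unclass(config), function(v) paste(v, collapse = ","), character(1))
  paste0(names(config), " = ", vals)
}

#' @rdname run_config
#' @param config a `run_config`; @param path file path.
#' @export
write_run_config <- function(config, path) {
  writeLines(serialize_config(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, character(1), 1))
  num <- function(x) as.numeric(strsplit(x, ",")[[1]])
  do.call(run_config, list(
    n_regions = num(vals$n_regions), n_hubs = num(vals$n_hubs),
    n_strain_regions = num(vals$n_strain_regions), n_subjects = num(vals$n_subjects),
    between_subject_noise = num(vals$between_subject_noise),
    n_cases = num(vals$n_cases), n_concussive = num(vals$n_concussive),
    density = num(vals$density), hub_weight_boost = num(vals$hub_weight_boost),
    intra_module_bias = num(vals$intra_module_bias),
    concussion_strain_shift = num(vals$concussion_strain_shift),
    kinematic_strain_coupling = num(vals$kinematic_strain_coupling),
    lesion_k = num(vals$lesion_k), aggregation = vals$aggregation,
    alpha = num(vals$alpha), bonferroni_n = num(vals$bonferroni_n),
    max_predictors = num(vals$max_predictors), per_subject_k = num(vals$per_subject_k),
    seed = num(vals$seed), allow_large = vals$allow_large == "TRUE"))
}

config_hash <- function(config) {
  # FNV-1a over the serialized config; identifies a run in output headers
  bytes <- utf8ToInt(paste(serialize_config(config), collapse = "\n"))
  # h is kept as a double in [0, 2^32); xor touches only the low byte, and
  # the multiply is split so every product stays exact below 2^53
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b %% 256))
    h <- (h %% 65536 * 16777619 + h %/% 65536 * 16777619 %% 65536 * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the complete workflow: generate atlas, connectome cohort and
#' impact dataset; per-subject efficiency metrics; exhaustive deletion
#' sweeps at the configured k values; cohort-averaged network importance;
#' strain-based region ranking; correlation between the two rankings;
#' regional and kinematic group tests; incremental predictor-set LOOCV
#' evaluation under both rankings; and per-subject individualized-ranking
#' evaluation. All numeric artifacts (TSV tables, JSON reports) are written
#' under `out_dir`, each carrying the run's seed and configuration hash in
#' a header comment; rerunning with an identical configuration reproduces
#' them byte-identically. Stage timings go to the log only.
#'
#' @param config a [run_config].
#' @param out_dir output directory (created if missing).
#' @param quiet suppress progress messages (default FALSE).
#' @return invisibly, a list with the main in-memory results and the paths
#'   of everything written.
#' @export
run_pipeline <- function(config = run_config(), out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "connectomes"), showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.txt")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  t0 <- Sys.time()
  say <- function(fmt, ...) {
    msg <- sprintf("[%6.1fs] %s", as.numeric(Sys.time() - t0, units = "secs"),
                   sprintf(fmt, ...))
    writeLines(msg, log_con)
    if (!quiet) message(msg)
  }
  tag <- sprintf("seed: %d | config: %s", config$seed, config_hash(config))
  write_run_config(config, file.path(out_dir, "config.txt"))

  say("generate: atlas (%d regions), cohort (%d subjects), impacts (%d/%d concussive)",
      config$n_regions, config$n_subjects, config$n_cases, config$n_concussive)
  atlas <- gen_atlas(config$n_regions, config$n_hubs, config$n_strain_regions,
                     seed = config$seed)
  truth <- ground_truth(atlas_roles(atlas, "hub"),
                        atlas_roles(atlas, "lateral_high_strain"),
                        config$concussion_strain_shift,
                        config$kinematic_strain_coupling, config$seed)
  cohort <- gen_cohort(atlas, config$n_subjects, config$between_subject_noise,
                       seed = config$seed, density = config$density,
                       hub_weight_boost = config$hub_weight_boost,
                       intra_module_bias = config$intra_module_bias)
  impacts <- gen_impacts(atlas, config$n_cases, config$n_concussive, truth,
                         seed = config$seed)
  write_atlas(atlas, file.path(out_dir, "atlas.tsv"), tag)
  write_ground_truth(truth, file.path(out_dir, "ground_truth.json"))
  for (s in seq_along(cohort)) {
    write_connectome(cohort[[s]], file.path(out_dir, "connectomes",
                                            sprintf("subject_%02d.tsv", s)), tag)
  }
  write_impacts(impacts, file.path(out_dir, "impacts.tsv"), tag)

  say("metrics: per-subject global efficiency")
  ge <- vapply(cohort, function(cn) global_efficiency(cn)$global_efficiency, numeric(1))
  write_lines_tsv(data.frame(subject = seq_along(cohort), global_efficiency = ge),
                  file.path(out_dir, "metrics.tsv"), tag)

  rankings <- list()
  subject_sweeps_k1 <- NULL
  for (k in config$lesion_k) {
    say("lesion: k = %d sweep over %d subjects (%d subsets each)",
        k, length(cohort), choose(config$n_regions, k))
    sweeps <- lapply(seq_along(cohort), function(s) {
      lesion_sweep(cohort[[s]], k, subject_id = sprintf("subject_%02d", s),
                   allow_large = config$allow_large)
    })
    if (k == 1) subject_sweeps_k1 <- sweeps
    imp <- cohort_importance(sweeps, weight_fn = config$aggregation)
    rankings[[paste0("k", k)]] <- imp
    write_importance(imp, file.path(out_dir, sprintf("importance_dge_k%d.tsv", k)), tag)
  }

  say("strain: ranking + group tests")
  strain_rank <- rank_by_strain(impacts)
  write_importance(strain_rank, file.path(out_dir, "importance_strain.tsv"), tag)
  tests <- regional_tests(impacts, alpha = config$alpha, bonferroni_n = config$bonferroni_n)
  write_lines_tsv(tests$regions, file.path(out_dir, "tests_regions.tsv"), tag)
  write_lines_tsv(tests$global, file.path(out_dir, "tests_global.tsv"), tag)

  dge_rank <- rankings[[1]]
  corr <- list(scores = ranking_correlation(strain_rank, dge_rank, use = "scores"),
               ranks = ranking_correlation(strain_rank, dge_rank, use = "ranks"))
  say("correlate: strain vs network importance rho = %.3f (scores)", corr$scores$rho)

  say("predict: incremental LOOCV under both rankings")
  eval_strain <- suppressWarnings(
    evaluate_predictor_sets(impacts, strain_rank, max_k = config$max_predictors))
  eval_dge <- suppressWarnings(
    evaluate_predictor_sets(impacts, dge_rank, max_k = config$max_predictors,
                            include_univariate = FALSE))
  write_lines_tsv(rbind(eval_strain, eval_dge), file.path(out_dir, "predictor_sets.tsv"), tag)

  per_subject <- NULL
  if (!is.null(subject_sweeps_k1) && length(subject_sweeps_k1) > 1) {
    say("predict: per-subject individualized rankings (k = %d)", config$per_subject_k)
    subject_rankings <- lapply(subject_sweeps_k1, aggregate_importance)
    per_subject <- per_subject_evaluation(impacts, subject_rankings,
                                          k = config$per_subject_k)
    write_lines_tsv(per_subject$per_subject,
                    file.path(out_dir, "per_subject_accuracy.tsv"), tag)
  }

  report <- list(
    seed = config$seed, config_hash = config_hash(config),
    global_efficiency = list(mean = mean(ge), min = min(ge), max = max(ge)),
    delta_ge_single = if ("k1" %in% names(rankings)) {
      list(min = min(rankings$k1$score), max = max(rankings$k1$score))
    },
    ranking_correlation = corr,
    n_significant_regions = sum(tests$regions$significant_bonferroni),
    predictor_sets = rbind(eval_strain, eval_dge),
    per_subject_accuracy = if (!is.null(per_subject)) per_subject$summary)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  say("done: %s", out_dir)
  invisible(list(atlas = atlas, truth = truth, cohort = cohort, impacts = impacts,
                 rankings = rankings, strain_rank = strain_rank, tests = tests,
                 correlation = corr, eval_strain = eval_strain, eval_dge = eval_dge,
                 per_subject = per_subject, out_dir = out_dir))
}
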