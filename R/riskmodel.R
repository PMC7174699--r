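#' Maximum number of logistic predictors under the events-per-variable rule
#'
#' The 5-events-per-predictor-variable guideline caps the number of
#' predictors at floor(events / 5); with 20 concussion events this allows at
#' most 4 predictors without risking biased estimates.
#'
#' @param n_events number of positive (concussion) events.
#' @param epv events required per predictor (default 5).
#' @return integer predictor cap.
#' @export
epv_max_predictors <- function(n_events, epv = 5) {
  stopifnot(n_events >= 0, epv > 0)
  as.integer(floor(n_events / epv))
}

standardize_cols <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0] <- 1
  list(Xs = sweep(sweep(X, 2, mu), 2, sd, "/"), mu = mu, sd = sd)
}

ridge_irls <- function(Xs, y, lambda, max_iter = 100, tol = 1e-10) {
  # ridge-penalized binomial IRLS on standardized predictors; intercept unpenalized
  n <- nrow(Xs); p <- ncol(Xs)
  Z <- cbind(1, Xs)
  beta <- c(stats::qlogis(mean(pmin(pmax(y, 0.05), 0.95))), rep(0, p))
  pen <- diag(c(0, rep(lambda, p)), p + 1)
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    eta <- drop(Z %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(Z, y - mu)) - drop(pen %*% beta)
    H <- crossprod(Z, Z * w) + pen
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(grad)) < tol * n || max(abs(step)) < 1e-12) { converged <- TRUE; break }
  }
  list(beta = beta, converged = converged, n_iterations = iter)
}

#' Fit a binary logistic regression
#'
#' Maximizes the binomial log-likelihood (optionally ridge-penalized) with
#' predictors standardized internally; coefficients are reported on the
#' original predictor scale. With `regularization = 0` the fit is the
#' ordinary maximum-likelihood fit; if that fit diverges (complete or
#' quasi-complete separation, common in small near-separable injury
#' datasets) a warning is raised and the model is refit with a minimal
#' ridge penalty (1e-4 on standardized slopes) so that a finite,
#' deterministic model is always returned.
#'
#' @param X numeric case-by-predictor matrix.
#' @param y binary outcomes (0/1, logical, or "concussion"/"no_concussion").
#' @param regularization ridge penalty on standardized slopes (default 0).
#' @return object of class `logistic_model`: `coefficients` (original
#'   scale), `intercept`, `converged`, `n_iterations`, `regularization`,
#'   `separation_refit`.
#' @export
fit_logistic <- function(X, y, regularization = 0) {
  X <- as.matrix(X)
  y <- as_binary_outcome(y)
  if (nrow(X) != length(y)) stop_param("X has %d rows but y has %d outcomes", nrow(X), length(y))
  if (length(unique(y)) < 2) stop_param("y contains a single class; logistic fit degenerate")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  sdx <- apply(X, 2, stats::sd)
  if (any(sdx == 0) && regularization == 0) {
    stop_param("zero-variance predictor(s) %s require regularization > 0",
               toString(colnames(X)[sdx == 0]))
  }
  std <- standardize_cols(X)
  separation_refit <- FALSE
  if (regularization == 0) {
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm.fit(cbind(1, std$Xs), y, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1|did not converge", conditionMessage(w))) {
          sep <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    if (sep || !fit$converged || max(abs(fit$coefficients[-1])) > 15) {
      warning("separation detected; refitting with ridge penalty 1e-4", call. = FALSE)
      separation_refit <- TRUE
      res <- ridge_irls(std$Xs, y, 1e-4)
      beta <- res$beta; converged <- res$converged; n_iter <- res$n_iterations
      regularization <- 1e-4
    } else {
      beta <- fit$coefficients; converged <- fit$converged; n_iter <- fit$iter
    }
  } else {
    res <- ridge_irls(std$Xs, y, regularization)
    beta <- res$beta; converged <- res$converged; n_iter <- res$n_iterations
  }
  slopes <- beta[-1] / std$sd
  intercept <- beta[1] - sum(slopes * std$mu)
  names(slopes) <- colnames(X)
  structure(list(coefficients = slopes, intercept = unname(intercept),
                 converged = converged, n_iterations = n_iter,
                 regularization = regularization,
                 separation_refit = separation_refit),
            class = "logistic_model")
}

as_binary_outcome <- function(y) {
  if (is.character(y) || is.factor(y)) as.integer(as.character(y) == "concussion")
  else as.integer(y > 0)
}

#' @export
predict.logistic_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  stats::plogis(object$intercept + drop(newdata %*% object$coefficients))
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf("<logistic_model> %d predictor(s), intercept %.4f, %sconverged (%d iter, ridge %g)\n",
              length(x$coefficients), x$intercept, if (x$converged) "" else "NOT ",
              x$n_iterations, x$regularization))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation with midrank tie handling: the probability that
#' a randomly chosen positive case scores above a randomly chosen negative
#' case, counting ties as one half.
#'
#' @param scores per-case scores (higher = more concussion-like).
#' @param y binary outcomes; both classes must be present.
#' @return scalar AUC in \[0, 1\].
#' @export
auc <- function(scores, y) {
  y <- as_binary_outcome(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop_param("AUC undefined with a single class")
  r <- rank(scores)  # midranks
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Leave-one-out cross-validated logistic prediction
#'
#' Each case is predicted by a model trained on the other N-1 cases. The
#' testing AUC is computed once on the pooled out-of-fold probabilities;
#' the training AUC is averaged over folds. Classification metrics use a
#' 0.5 threshold on the out-of-fold probabilities. A training fold that
#' contains a single class predicts that fold's training class rate rather
#' than aborting; separation in a fold triggers the quiet ridge refit of
#' [fit_logistic] and is counted.
#'
#' @param X numeric case-by-predictor matrix.
#' @param y binary outcomes.
#' @param regularization ridge penalty passed to each fold's fit.
#' @param predictor_set character labels for the report.
#' @return object of class `cv_report` with `predictor_set`, `accuracy`,
#'   `sensitivity`, `specificity`, `auc_testing`, `auc_training_mean`,
#'   `oof_probabilities`, `n_degenerate_folds`, `n_separation_refits`.
#' @export
loocv <- function(X, y, regularization = 0, predictor_set = colnames(X)) {
  X <- as.matrix(X)
  y <- as_binary_outcome(y)
  n <- length(y)
  if (n < 3) stop_param("LOOCV needs at least 3 cases, got %d", n)
  if (length(unique(y)) < 2) stop_param("y contains a single class")
  oof <- numeric(n)
  train_auc <- rep(NA_real_, n)
  degenerate <- 0L; refits <- 0L
  for (i in seq_len(n)) {
    ytr <- y[-i]; Xtr <- X[-i, , drop = FALSE]
    if (length(unique(ytr)) < 2) {
      degenerate <- degenerate + 1L
      oof[i] <- mean(ytr)
      next
    }
    fit <- withCallingHandlers(
      fit_logistic(Xtr, ytr, regularization),
      warning = function(w) invokeRestart("muffleWarning"))
    if (fit$separation_refit) refits <- refits + 1L
    oof[i] <- predict(fit, X[i, , drop = FALSE])
    train_auc[i] <- auc(predict(fit, Xtr), ytr)
  }
  pred <- as.integer(oof > 0.5)
  tp <- sum(pred == 1 & y == 1); tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0); fn <- sum(pred == 0 & y == 1)
  structure(list(predictor_set = predictor_set %||% paste0("x", seq_len(ncol(X))),
                 accuracy = (tp + tn) / n,
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp),
                 auc_testing = auc(oof, y),
                 auc_training_mean = mean(train_auc, na.rm = TRUE),
                 oof_probabilities = oof,
                 n_degenerate_folds = degenerate,
                 n_separation_refits = refits),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> [%s] acc %.2f sens %.2f spec %.2f AUC-test %.2f AUC-train %.2f\n",
              toString(x$predictor_set), x$accuracy, x$sensitivity, x$specificity,
              x$auc_testing, x$auc_training_mean))
  invisible(x)
}

cv_row <- function(label, rep) {
  data.frame(predictor_set = label, n_predictors = length(rep$predictor_set),
             accuracy = rep$accuracy, sensitivity = rep$sensitivity,
             specificity = rep$specificity, auc_testing = rep$auc_testing,
             auc_training_mean = rep$auc_training_mean)
}

#' Evaluate incremental region sets and univariate predictors
#'
#' Builds logistic LOOCV reports for the top-1 through top-`max_k` regions
#' of an importance ranking (regions added strictly in rank order, region-id
#' tie-break), using each region's rMPS as a predictor, alongside univariate
#' reports for the four peak kinematics and MPS95. The number of rMPS
#' predictors is capped by the events-per-variable rule.
#'
#' @param impacts an [impact_set].
#' @param ranking a `node_importance` covering the impact regions.
#' @param max_k largest region set to evaluate (default 4).
#' @param regularization ridge penalty for every fit (default 0).
#' @param include_univariate also report the kinematic and MPS95 univariate
#'   models (default TRUE).
#' @return data.frame with one row per predictor set (columns
#'   predictor_set, n_predictors, accuracy, sensitivity, specificity,
#'   auc_testing, auc_training_mean); the full `cv_report` objects are
#'   attached as attribute `"reports"`.
#' @export
evaluate_predictor_sets <- function(impacts, ranking, max_k = 4,
                                    regularization = 0, include_univariate = TRUE) {
  stopifnot(inherits(impacts, "impact_set"))
  n_events <- sum(impacts$cases$outcome == "concussion")
  cap <- epv_max_predictors(n_events)
  if (max_k > cap) {
    stop_param("max_k = %d exceeds the events-per-variable cap of %d (%d events / 5)",
               max_k, cap, n_events)
  }
  ids <- region_ids_of(impacts)
  if (!all(ids %in% ranking$region_id)) stop_param("ranking does not cover the impact regions")
  y <- impacts$cases$outcome
  ordered_ids <- ranking$region_id[order(ranking$rank)]
  ordered_ids <- ordered_ids[ordered_ids %in% ids]
  prov <- attr(ranking, "provenance") %||% "ranking"
  reports <- list()
  rows <- list()
  if (include_univariate) {
    for (v in c("peak_lin_vel", "peak_ang_vel", "peak_lin_acc", "peak_ang_acc", "mps95")) {
      rep <- loocv(matrix(impacts$cases[[v]], dimnames = list(NULL, v)), y,
                   regularization, predictor_set = v)
      reports[[v]] <- rep
      rows[[v]] <- cv_row(v, rep)
    }
  }
  for (k in seq_len(max_k)) {
    top <- ordered_ids[seq_len(k)]
    Xk <- impacts$rmps[, as.character(top), drop = FALSE]
    colnames(Xk) <- paste0("rmps_", top)
    label <- sprintf("%s_top%d", prov, k)
    rep <- loocv(Xk, y, regularization, predictor_set = colnames(Xk))
    reports[[label]] <- rep
    rows[[label]] <- cv_row(label, rep)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reports") <- reports
  out
}

#' Per-subject individualized-ranking evaluation
#'
#' Repeats the top-k rMPS logistic LOOCV using each subject's own
#' network-importance ranking (rather than the cohort average), quantifying
#' how much predictive accuracy varies across individual brain
#' architectures.
#'
#' @param impacts an [impact_set].
#' @param subject_rankings list of `node_importance`, one per subject.
#' @param k number of top regions per subject (default 4, EPV-capped).
#' @param regularization ridge penalty for every fit.
#' @return list with `per_subject` (data.frame, one row per subject) and
#'   `summary` (min/mean/max of each metric across subjects).
#' @export
per_subject_evaluation <- function(impacts, subject_rankings, k = 4, regularization = 0) {
  stopifnot(length(subject_rankings) >= 1)
  n_events <- sum(impacts$cases$outcome == "concussion")
  if (k > epv_max_predictors(n_events)) {
    stop_param("k = %d exceeds the events-per-variable cap of %d", k, epv_max_predictors(n_events))
  }
  y <- impacts$cases$outcome
  ids <- region_ids_of(impacts)
  rows <- lapply(seq_along(subject_rankings), function(s) {
    rk <- subject_rankings[[s]]
    top <- rk$region_id[order(rk$rank)]
    top <- top[top %in% ids][seq_len(k)]
    Xk <- impacts$rmps[, as.character(top), drop = FALSE]
    rep <- suppressWarnings(loocv(Xk, y, regularization,
                                  predictor_set = paste0("rmps_", top)))
    cbind(data.frame(subject = s), cv_row(sprintf("subject%d_top%d", s, k), rep)[-1])
  })
  per_subject <- do.call(rbind, rows)
  metric_cols <- c("accuracy", "sensitivity", "specificity", "auc_testing", "auc_training_mean")
  summary <- lapply(per_subject[metric_cols], function(v) {
    c(min = min(v), mean = mean(v), max = max(v))
  })
  list(per_subject = per_subject, summary = summary)
}
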