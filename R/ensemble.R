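# Majority-vote aggregation to patient level and diagnostic-test evaluation.

#' Tally group votes for one patient
#'
#' Each voxel group casts one vote for a class; the patient's predicted
#' class is the majority. Exact ties are broken deterministically toward
#' `tie_break` (class IV by default, the study's majority class) and
#' flagged.
#'
#' @param predictions factor or character vector of per-group predicted
#'   classes, or a named count vector (e.g. `c(III = 74, IV = 226)`).
#' @param levels class levels, used when `predictions` is unnamed character.
#' @param tie_break class awarded on an exact tie.
#' @return An object of class `vote_tally`: `counts`, `total`, `predicted`,
#'   `probability` (winning share) and `tie`.
#' @export
#' @examples
#' tally_votes(c(III = 74, IV = 226))
tally_votes <- function(predictions, levels = NULL, tie_break = "IV") {
  if (is.numeric(predictions)) {
    counts <- predictions
    if (is.null(names(counts))) stop("count vector must be named", call. = FALSE)
  } else {
    f <- if (is.null(levels)) factor(predictions) else factor(predictions, levels)
    counts <- table(f)
  }
  counts <- setNames(as.numeric(counts), names(counts))
  if (sum(counts) < 1) stop("at least one vote is required", call. = FALSE)
  top <- which(counts == max(counts))
  tie <- length(top) > 1L
  winner <- if (tie && tie_break %in% names(counts)[top]) tie_break
            else names(counts)[top[1]]
  structure(list(counts = counts, total = sum(counts), predicted = winner,
                 probability = counts[[winner]] / sum(counts), tie = tie),
            class = "vote_tally")
}

#' @export
print.vote_tally <- function(x, ...) {
  cat(sprintf("votes: %s -> %s (%.1f%%%s)\n",
              paste(sprintf("%s %d", names(x$counts), x$counts), collapse = ", "),
              x$predicted, 100 * x$probability,
              if (x$tie) ", tie broken" else ""))
  invisible(x)
}

#' Confusion-matrix diagnostic metrics
#'
#' Sensitivity (true positives over all positive cases), specificity (true
#' negatives over all negative cases), overall accuracy, and Youden's index
#' `J = sensitivity + specificity - 1`, from paired prediction/truth label
#' vectors. If a class is absent from `truths` the affected rate is `NA`
#' and flagged.
#'
#' @param predictions,truths equal-length class label vectors.
#' @param positive label of the positive class (default `"IV"`).
#' @return An object of class `diagnostic_summary` with `tp`, `fp`, `tn`,
#'   `fn`, `sensitivity`, `specificity`, `accuracy`, `youden`, `positive`,
#'   and `undefined` (character vector of rates that could not be computed).
#' @export
diagnostic_metrics <- function(predictions, truths, positive = "IV") {
  predictions <- as.character(predictions)
  truths <- as.character(truths)
  if (length(predictions) != length(truths)) {
    stop("`predictions` and `truths` must have equal length", call. = FALSE)
  }
  pos <- truths == positive
  tp <- sum(predictions == positive & pos)
  fn <- sum(predictions != positive & pos)
  tn <- sum(predictions != positive & !pos)
  fp <- sum(predictions == positive & !pos)
  undefined <- character()
  sens <- if (tp + fn > 0) tp / (tp + fn) else { undefined <- c(undefined, "sensitivity"); NA_real_ }
  spec <- if (tn + fp > 0) tn / (tn + fp) else { undefined <- c(undefined, "specificity"); NA_real_ }
  acc <- (tp + tn) / length(truths)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, specificity = spec, accuracy = acc,
                 youden = sens + spec - 1, positive = positive,
                 undefined = undefined),
            class = "diagnostic_summary")
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  cat(sprintf("diagnostic summary (positive = %s): TP %d FP %d TN %d FN %d\n",
              x$positive, x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  sensitivity %.4f  specificity %.4f  accuracy %.4f  Youden %.4f\n",
              x$sensitivity, x$specificity, x$accuracy, x$youden))
  if (length(x$undefined)) cat("  undefined:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Area under the ROC curve
#'
#' The probability that a randomly chosen positive case receives a higher
#' score than a randomly chosen negative case, with ties counted 1/2 —
#' computed by the rank-sum (Mann-Whitney) formulation, equivalent to the
#' trapezoidal area under the empirical ROC curve.
#'
#' @param scores numeric scores (larger = more positive).
#' @param labels class labels.
#' @param positive positive-class label (default `"IV"`).
#' @return AUROC in `[0, 1]`.
#' @export
#' @examples
#' auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1), positive = 1)  # 0.75
auroc <- function(scores, labels, positive = "IV") {
  pos <- as.character(labels) == as.character(positive)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Placement values: for each positive case, the fraction of negatives it
# outscores (ties 1/2), and symmetrically for negatives. Used by DeLong.
.placements <- function(scores, pos) {
  x <- scores[pos]; y <- scores[!pos]
  v10 <- vapply(x, function(xi) mean((xi > y) + 0.5 * (xi == y)), 0)
  v01 <- vapply(y, function(yj) mean((x > yj) + 0.5 * (x == yj)), 0)
  list(v10 = v10, v01 = v01)
}

#' Compare two correlated AUROCs (DeLong test)
#'
#' Paired comparison of the AUROCs of two models scored on the same cases,
#' using the covariance of placement values (DeLong's nonparametric
#' approach). Two-sided normal p-value.
#'
#' @param scores_a,scores_b numeric score vectors from the two models, over
#'   the same cases in the same order.
#' @param labels shared class labels.
#' @param positive positive-class label.
#' @return List with `auc_a`, `auc_b`, `z`, `p.value`, `var_diff`.
#' @export
compare_auc <- function(scores_a, scores_b, labels, positive = "IV") {
  pos <- as.character(labels) == as.character(positive)
  if (length(scores_a) != length(labels) || length(scores_b) != length(labels)) {
    stop("score vectors must match `labels` in length", call. = FALSE)
  }
  m <- sum(pos); n <- sum(!pos)
  if (m == 0 || n == 0) stop("both classes must be present", call. = FALSE)
  pa <- .placements(scores_a, pos)
  pb <- .placements(scores_b, pos)
  auc_a <- mean(pa$v10); auc_b <- mean(pb$v10)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  var_diff <- max(var_diff, 0)
  d <- auc_a - auc_b
  if (var_diff < .Machine$double.eps) {
    z <- if (abs(d) < sqrt(.Machine$double.eps)) 0 else sign(d) * Inf
  } else {
    z <- d / sqrt(var_diff)
  }
  list(auc_a = auc_a, auc_b = auc_b, z = z,
       p.value = 2 * pnorm(-abs(z)), var_diff = var_diff)
}

#' Two-proportion z test
#'
#' Pooled-variance two-sided z test for the equality of two binomial
#' proportions, as used to compare group-level sensitivities or
#' specificities between models.
#'
#' @param k1,n1 successes and trials in the first sample.
#' @param k2,n2 successes and trials in the second sample.
#' @return List with `p1`, `p2`, `z`, `p.value`.
#' @export
#' @examples
#' two_proportion_test(958, 1500, 956, 1500)$p.value  # ~0.939
two_proportion_test <- function(k1, n1, k2, n2) {
  if (n1 < 1 || n2 < 1) stop("`n1` and `n2` must be >= 1", call. = FALSE)
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2) {
    stop("`k` must lie in [0, n]", call. = FALSE)
  }
  p1 <- k1 / n1; p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  list(p1 = p1, p2 = p2, z = z, p.value = 2 * pnorm(-abs(z)))
}

#' Leave-one-out cross-validation over a grouped cohort
#'
#' Refits a chosen classifier with one unit held out at a time and predicts
#' the held-out voxel groups. With `unit = "patient"` (the default) all of a
#' patient's groups leave the training set together, so no within-patient
#' information leaks into their own prediction; `unit = "group"` is the
#' per-case variant in which single groups are held out.
#'
#' @param features data frame of predictor columns (only the ten feature
#'   statistics; no metadata columns).
#' @param labels two-level factor/character vector, one label per group.
#' @param patient_id vector assigning every group to a patient.
#' @param model `"fisher"`, `"logistic"` or `"chaid"`.
#' @param unit `"patient"` or `"group"`.
#' @param model_args list of extra arguments for the trainer.
#' @param predictors columns of `features` to use (default: the published
#'   five-statistic predictor set intersected with available columns, or
#'   all columns if none match).
#' @return A `data.frame` with one row per group: `patient_id`, `truth`,
#'   `pred`, `score` (positive-class score usable for ROC), `fold`. Folds
#'   whose training data lose an entire class are skipped with a warning
#'   (`pred` is `NA` for those rows).
#' @export
loo_cv <- function(features, labels, patient_id,
                   model = c("fisher", "logistic", "chaid"),
                   unit = c("patient", "group"), model_args = list(),
                   predictors = NULL) {
  model <- match.arg(model)
  unit <- match.arg(unit)
  features <- as.data.frame(features)
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("`labels` must have two classes", call. = FALSE)
  n <- nrow(features)
  stopifnot(length(labels) == n, length(patient_id) == n)
  if (is.null(predictors)) {
    predictors <- intersect(published_predictors(), names(features))
    if (!length(predictors)) predictors <- names(features)
  }
  X <- features[, predictors, drop = FALSE]
  folds <- if (unit == "patient") as.character(patient_id) else as.character(seq_len(n))
  uf <- unique(folds)
  if (length(uf) < 3L) stop("need >= 3 cross-validation units", call. = FALSE)
  pred <- factor(rep(NA_character_, n), levels = levels(labels))
  score <- rep(NA_real_, n)
  pos <- levels(labels)[2]
  for (f in uf) {
    test_idx <- which(folds == f)
    train_idx <- setdiff(seq_len(n), test_idx)
    ytr <- labels[train_idx]
    if (length(unique(ytr)) < 2L) {
      warning(sprintf("fold %s skipped: training data lost a class", f),
              call. = FALSE)
      next
    }
    fit <- switch(model,
      fisher = do.call(train_fisher_lda, c(list(X[train_idx, , drop = FALSE], ytr), model_args)),
      logistic = do.call(train_logistic, c(list(X[train_idx, , drop = FALSE], ytr), model_args)),
      chaid = do.call(chaid_grow, c(list(X[train_idx, , drop = FALSE], ytr), model_args))
    )
    out <- switch(model,
      fisher = { r <- apply_fisher(fit, X[test_idx, , drop = FALSE])
                 list(class = r$class, score = r[[paste0("p_", fit$levels[2])]]) },
      logistic = { r <- apply_logistic(fit, X[test_idx, , drop = FALSE])
                   list(class = r$class, score = r$p) },
      chaid = { r <- chaid_predict(fit, X[test_idx, , drop = FALSE])
                list(class = r$class, score = r[[paste0("p_", fit$levels[2])]]) }
    )
    pred[test_idx] <- factor(as.character(out$class), levels = levels(labels))
    score[test_idx] <- out$score
  }
  data.frame(patient_id = as.character(patient_id), truth = labels,
             pred = pred, score = score, fold = folds,
             stringsAsFactors = FALSE)
}

#' Patient-level summary of per-group predictions
#'
#' Aggregates per-group predictions to one majority-vote class per patient
#' and compares against the patient's true class.
#'
#' @param group_predictions per-group predicted classes.
#' @param patient_id per-group patient assignment.
#' @param truth_by_patient named vector of true classes, one per patient.
#' @param tie_break class awarded on a tie.
#' @return A `data.frame` with one row per patient: `patient_id`, vote
#'   counts per class, `predicted`, `truth`, `correct`, `tie`.
#' @export
patient_vote_summary <- function(group_predictions, patient_id,
                                 truth_by_patient, tie_break = "IV") {
  f <- factor(group_predictions)
  ids <- unique(as.character(patient_id))
  rows <- lapply(ids, function(id) {
    tl <- tally_votes(f[patient_id == id], levels = levels(f),
                      tie_break = tie_break)
    cnt <- as.list(tl$counts)
    names(cnt) <- paste0("votes_", names(cnt))
    c(list(patient_id = id), cnt,
      list(predicted = tl$predicted,
           truth = as.character(truth_by_patient[[id]]),
           correct = tl$predicted == as.character(truth_by_patient[[id]]),
           tie = tl$tie))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}
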