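# End-to-end orchestration: simulate -> fit -> sample -> featurize ->
# train/apply -> vote -> evaluate, as one reproducible, provenance-logged run.

#' Run the full synthetic analysis pipeline
#'
#' Generates (or accepts) a synthetic cohort, fits R2* maps from the
#' multi-echo data, samples groups of consecutive ROI voxels from every
#' plane, computes the ten-statistic feature set, trains the three
#' group-level classifiers on the pooled groups (or cross-validates them
#' patient-wise), tallies per-patient votes, and evaluates each model at
#' the group level. A single master seed fans out into per-stage child
#' seeds so each stage is independently reproducible.
#'
#' @param config a [sim_config()]; its `seed` drives the whole run.
#' @param cohort optionally, a pre-built `ln_cohort` (then `config` is only
#'   used for sampling/feature settings).
#' @param n_groups groups sampled per plane (default 100; with 3 planes,
#'   300 votes per patient).
#' @param group_size voxels per group.
#' @param fit `"loglinear"` (default) or `"nonlinear"` voxelwise R2* fit.
#' @param loo if `TRUE`, per-group predictions come from patient-level
#'   leave-one-out cross-validation instead of in-sample application.
#' @param chaid_args extra arguments for [chaid_grow()].
#' @param out_dir optional directory; when given, the feature matrix,
#'   per-model vote tables, metrics and a provenance record are written
#'   there as CSV/JSON.
#' @return An object of class `ln_run`: `features` (with metadata columns),
#'   `models`, `group_predictions`, `votes` (per patient x model),
#'   `metrics` (per model `diagnostic_summary`), `concordance` (patient
#'   majority-vote accuracy per model), `provenance`.
#' @export
run_pipeline <- function(config = sim_config(), cohort = NULL,
                         n_groups = 100L, group_size = 100L,
                         fit = c("loglinear", "nonlinear"), loo = FALSE,
                         chaid_args = list(), out_dir = NULL) {
  fit <- match.arg(fit)
  t0 <- Sys.time()
  if (is.null(cohort)) cohort <- generate_cohort(config)
  n_planes_total <- sum(vapply(cohort, function(p) length(p$planes), 0L))
  samp_seeds <- child_seeds(config$seed + 1L, n_planes_total)

  rows <- list()
  k <- 0L
  for (pat in cohort) {
    for (pl_idx in seq_along(pat$planes)) {
      k <- k + 1L
      pl <- pat$planes[[pl_idx]]
      map <- fit_r2star_loglinear(pl$echoes, mask = pl$mask)
      if (fit == "nonlinear") map <- fit_r2star_nonlinear(pl$echoes, map)
      grp <- sample_voxel_groups(map, pl$mask, n_groups = n_groups,
                                 group_size = group_size,
                                 seed = samp_seeds[k])
      rows[[k]] <- feature_matrix(grp, patient_id = pat$patient_id,
                                  plane = pl_idx, label = pat$primary_class)
    }
  }
  features <- do.call(rbind, rows)
  features$label <- factor(features$label, levels = c("III", "IV"))
  preds <- published_predictors()
  X <- features[, preds]
  y <- features$label
  truth_by_patient <- vapply(cohort, function(p) p$primary_class, "")
  names(truth_by_patient) <- vapply(cohort, function(p) p$patient_id, "")

  models <- list()
  group_predictions <- list()
  if (loo) {
    for (m in c("fisher", "logistic", "chaid")) {
      args <- if (m == "chaid") chaid_args else list()
      cv <- loo_cv(X, y, features$patient_id, model = m, model_args = args)
      group_predictions[[m]] <- data.frame(class = cv$pred, score = cv$score)
    }
  } else {
    models$fisher <- train_fisher_lda(X, y)
    models$logistic <- train_logistic(X, y)
    models$chaid <- do.call(chaid_grow, c(list(X, y), chaid_args))
    rf <- apply_fisher(models$fisher, X)
    rl <- apply_logistic(models$logistic, X)
    rc <- chaid_predict(models$chaid, X)
    group_predictions <- list(
      fisher = data.frame(class = rf$class, score = rf$p_IV),
      logistic = data.frame(class = rl$class, score = rl$p),
      chaid = data.frame(class = rc$class, score = rc$p_IV)
    )
  }

  votes <- list(); metrics <- list(); concordance <- list()
  for (m in names(group_predictions)) {
    gp <- group_predictions[[m]]
    votes[[m]] <- patient_vote_summary(gp$class, features$patient_id,
                                       truth_by_patient)
    metrics[[m]] <- diagnostic_metrics(gp$class, y, positive = "IV")
    concordance[[m]] <- mean(votes[[m]]$correct)
  }

  provenance <- list(
    seed = config$seed,
    config = unclass(config),
    n_groups = n_groups, group_size = group_size, fit = fit, loo = loo,
    n_patients = length(cohort), n_features = nrow(features),
    package_version = as.character(utils::packageVersion("boldln")),
    r_version = R.version.string,
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  run <- structure(list(features = features, models = models,
                        group_predictions = group_predictions,
                        votes = votes, metrics = metrics,
                        concordance = concordance, provenance = provenance),
                   class = "ln_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.ln_run <- function(x, ...) {
  cat(sprintf("ln_run: %d patients, %d groups, %s predictions\n",
              x$provenance$n_patients, x$provenance$n_features,
              if (x$provenance$loo) "leave-one-out" else "in-sample"))
  for (m in names(x$metrics)) {
    s <- x$metrics[[m]]
    cat(sprintf("  %-9s sens %.3f spec %.3f acc %.3f | patient concordance %.0f%%\n",
                m, s$sensitivity, s$specificity, s$accuracy,
                100 * x$concordance[[m]]))
  }
  invisible(x)
}

#' Write a pipeline run to disk
#'
#' Feature matrix and per-model vote tables as CSV, group-level metrics and
#' the provenance record (config, seed, versions) as JSON.
#'
#' @param run an `ln_run`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(run$features, file.path(out_dir, "features.csv"), row.names = FALSE)
  for (m in names(run$votes)) {
    write.csv(run$votes[[m]], file.path(out_dir, paste0("votes_", m, ".csv")),
              row.names = FALSE)
  }
  metrics <- lapply(run$metrics, function(s) {
    s[c("tp", "fp", "tn", "fn", "sensitivity", "specificity",
        "accuracy", "youden")]
  })
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(run$provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Serialize / restore a trained model as JSON
#'
#' Fisher and logistic models are stored as coefficient lists, CHAID trees
#' as nested node objects; the JSON round-trips through
#' `read_model_json()`.
#'
#' @param model a `fisher_model`, `logit_model` or `chaid_tree`.
#' @param file path to write / read.
#' @return `write_model_json()` returns `file` invisibly;
#'   `read_model_json()` the restored model.
#' @export
write_model_json <- function(model, file) {
  kind <- class(model)[1]
  payload <- switch(kind,
    fisher_model = list(kind = kind, coef = as.data.frame(model$coef),
                        const = as.list(model$const), levels = model$levels,
                        predictors = model$predictors, prior = model$prior,
                        published = model$published),
    logit_model = list(kind = kind, coef = as.list(model$coef),
                       levels = model$levels, predictors = model$predictors,
                       published = model$published),
    chaid_tree = list(kind = kind, root = model$root, levels = model$levels,
                      predictors = model$predictors, params = model$params,
                      n_nodes = model$n_nodes, n_terminal = model$n_terminal),
    stop("unsupported model class: ", kind, call. = FALSE)
  )
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(file)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(file) {
  p <- jsonlite::read_json(file, simplifyVector = TRUE)
  switch(p$kind,
    fisher_model = structure(list(
      coef = as.matrix(p$coef), const = setNames(unlist(p$const), p$levels),
      w = NULL, J = NA_real_, levels = p$levels, predictors = p$predictors,
      prior = p$prior, means = NULL, published = isTRUE(p$published)),
      class = "fisher_model"),
    logit_model = structure(list(
      coef = unlist(p$coef), se = NULL, levels = p$levels,
      predictors = p$predictors, converged = TRUE, separation = FALSE,
      iter = 0L, loglik = NA_real_, published = isTRUE(p$published)),
      class = "logit_model"),
    chaid_tree = structure(list(
      root = .rebuild_chaid_node(jsonlite::read_json(file)$root),
      levels = p$levels, predictors = p$predictors,
      params = as.list(p$params), n_nodes = p$n_nodes,
      n_terminal = p$n_terminal), class = "chaid_tree"),
    stop("unknown model kind in ", file, call. = FALSE)
  )
}

# jsonlite round-trips nested lists with scalars; restore the numeric
# vectors a chaid node expects.
.rebuild_chaid_node <- function(nd) {
  node <- list(id = nd$id, depth = nd$depth, n = nd$n,
               counts = unlist(nd$counts), class = nd$class,
               terminal = isTRUE(nd$terminal),
               predictor = nd$predictor %||% NULL,
               breaks = if (length(nd$breaks)) unlist(nd$breaks),
               assign = if (length(nd$assign)) as.integer(unlist(nd$assign)),
               p_adj = nd$p_adj %||% NA_real_,
               statistic = nd$statistic %||% NA_real_,
               children = lapply(nd$children, .rebuild_chaid_node))
  node
}
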