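# Binary logistic regression via iteratively reweighted least squares.

#' Train a binary logistic regression
#'
#' Maximum-likelihood fit of `logit(P(Y = positive)) = b0 + b'x` by
#' Newton-Raphson / iteratively reweighted least squares. The positive class
#' is the second factor level of `y`. Convergence is declared when the
#' largest absolute coefficient change drops below `tol`. Complete or
#' quasi-complete separation (diverging coefficients with a perfectly
#' separating linear score) is detected, reported with a warning, and the
#' coefficients are capped at the last stable iterate.
#'
#' @param x predictor matrix or data frame.
#' @param y two-level factor (second level = positive class).
#' @param max_iter maximum IRLS iterations.
#' @param tol convergence tolerance on the max absolute coefficient change.
#' @return An object of class `logit_model`: `coef` (intercept first),
#'   `se` (Wald standard errors), `levels`, `predictors`, `converged`,
#'   `separation`, `iter`, `loglik`.
#' @seealso [apply_logistic()], [logistic_published()]
#' @export
train_logistic <- function(x, y, max_iter = 100L, tol = 1e-8) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- factor(y)
  if (nlevels(y) != 2L) stop("`y` must have exactly two classes", call. = FALSE)
  if (any(table(y) < 1L)) stop("both classes must be present", call. = FALSE)
  yy <- as.integer(y) - 1L
  X <- cbind(`(Intercept)` = 1, x)
  p <- ncol(X)
  beta <- numeric(p)
  separation <- FALSE
  converged <- FALSE
  iter <- 0L
  for (it in seq_len(max_iter)) {
    iter <- it
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    if (all(abs(eta[w > 0] ) == Inf) || max(w) < 1e-10) { separation <- TRUE; break }
    XtWX <- crossprod(X * sqrt(w))
    score <- crossprod(X, yy - mu)
    delta <- tryCatch(solve(XtWX, score), error = function(e) NULL)
    if (is.null(delta)) { separation <- TRUE; break }
    beta_new <- beta + drop(delta)
    # diverging slope norm with a perfectly separating score => separation
    if (max(abs(beta_new)) > 1e3 &&
        all((eta > 0) == (yy == 1L) | eta == 0)) {
      separation <- TRUE
      break
    }
    step <- max(abs(beta_new - beta))
    beta <- beta_new
    if (step < tol) { converged <- TRUE; break }
  }
  if (separation) {
    warning("(quasi-)separation detected; coefficients capped at last stable iterate",
            call. = FALSE)
  }
  eta <- drop(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  w <- pmax(mu * (1 - mu), 1e-12)
  se <- tryCatch(sqrt(diag(solve(crossprod(X * sqrt(w))))),
                 error = function(e) rep(NA_real_, p))
  loglik <- sum(yy * log(pmax(mu, 1e-300)) + (1 - yy) * log(pmax(1 - mu, 1e-300)))
  pred_names <- colnames(x) %||% paste0("X", seq_len(ncol(x)))
  structure(list(coef = setNames(beta, c("(Intercept)", pred_names)),
                 se = setNames(se, c("(Intercept)", pred_names)),
                 levels = levels(y), predictors = pred_names,
                 converged = converged, separation = separation,
                 iter = iter, loglik = loglik, published = FALSE),
            class = "logit_model")
}

#' The published logistic regression formula
#'
#' The fixed binary logistic model reported for classifying group-level R2*
#' statistics into class III vs IV:
#' `Logit(P) = 3.354 - 0.166 h + 0.117 k - 0.238 r - 0.377 s + 0.820 sd`
#' over harmonic mean, kurtosis, range, skewness and standard deviation.
#' The positive class of the printed formula is class IV: its coefficient
#' signs agree term by term with the difference `D_IV - D_III` of the
#' published discriminant functions, and only this reading makes the
#' recorded logistic vote counts coherent with the formula's direction.
#'
#' @param positive `"IV"` (default) or `"III"`: which class the modelled
#'   probability refers to; `"III"` flips all signs.
#' @return A `logit_model` with `published = TRUE`.
#' @export
#' @examples
#' apply_logistic(logistic_published(), c(harmonic_mean = 0, kurtosis = 0,
#'   range = 0, skewness = 0, standard_deviation = 0))
logistic_published <- function(positive = c("IV", "III")) {
  positive <- match.arg(positive)
  beta <- c(`(Intercept)` = 3.354, harmonic_mean = -0.166, kurtosis = 0.117,
            range = -0.238, skewness = -0.377, standard_deviation = 0.820)
  lev <- c("III", "IV")
  if (positive == "III") { beta <- -beta; lev <- c("IV", "III") }
  structure(list(coef = beta, se = NULL, levels = lev,
                 predictors = published_predictors(),
                 converged = TRUE, separation = FALSE, iter = 0L,
                 loglik = NA_real_, published = TRUE),
            class = "logit_model")
}

#' Evaluate a logistic model on feature vectors
#'
#' @param model a `logit_model`.
#' @param x named numeric vector, matrix or data frame supplying the
#'   predictors.
#' @param threshold decision threshold on the positive-class probability
#'   (default 0.5; `p >= threshold` predicts the positive class).
#' @return A `data.frame` with `p` (positive-class probability), `logit`
#'   and `class`.
#' @export
apply_logistic <- function(model, x, threshold = 0.5) {
  stopifnot(inherits(model, "logit_model"))
  X <- .predictor_matrix(x, model$predictors)
  eta <- drop(cbind(1, X) %*% model$coef[c("(Intercept)", model$predictors)])
  p <- 1 / (1 + exp(-eta))
  cls <- ifelse(p >= threshold, model$levels[2], model$levels[1])
  data.frame(p = p, logit = eta,
             class = factor(cls, levels = model$levels))
}

#' @export
predict.logit_model <- function(object, newdata, ...) apply_logistic(object, newdata, ...)

#' @export
print.logit_model <- function(x, ...) {
  cat(sprintf("Binary logistic model (%s): positive class %s\n",
              if (x$published) "published coefficients" else
                sprintf("IRLS, %d iterations%s", x$iter,
                        if (x$separation) ", separation capped" else ""),
              x$levels[2]))
  print(round(x$coef, 4))
  invisible(x)
}
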