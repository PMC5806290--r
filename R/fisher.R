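# Fisher linear discriminant analysis in classification-function form.

#' Train a two-class Fisher linear discriminant
#'
#' Finds the projection `w` maximising the Fisher criterion
#' `J(w) = |w' S_b w| / |w' S_w w|` (between- over within-class scatter);
#' for two classes the optimum is `w` proportional to
#' `S_w^{-1} (mu_2 - mu_1)`. The model is stored in classification-function
#' form, one linear function per class
#' `D_k(x) = b_k' x + c_k` with `b_k = Sigma^{-1} mu_k` and
#' `c_k = -mu_k' Sigma^{-1} mu_k / 2 + log(prior_k)` (`Sigma` the pooled
#' within-class covariance), so that assignment is `argmax_k D_k(x)`.
#'
#' @param x numeric matrix or data frame of predictors (rows = samples).
#' @param y two-level factor (or coercible) of class labels.
#' @param prior `"proportional"` (training frequencies, default) or
#'   `"equal"`.
#' @param ridge nonnegative scalar; if the pooled covariance is singular, a
#'   ridge `ridge * mean(diag(Sigma)) * I` is added. With `ridge = 0` a
#'   singular covariance is an error suggesting the ridge.
#' @return An object of class `fisher_model`: classification-function
#'   coefficients `coef` (p x 2) and `const` (length 2), projection `w`,
#'   criterion value `J`, class `levels`, `predictors`, `prior`.
#' @seealso [apply_fisher()], [fisher_published()]
#' @export
train_fisher_lda <- function(x, y, prior = c("proportional", "equal"),
                             ridge = 0) {
  prior <- match.arg(prior)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- factor(y)
  if (nlevels(y) != 2L) stop("`y` must have exactly two classes", call. = FALSE)
  if (any(table(y) < 2L)) stop("need >= 2 samples per class", call. = FALSE)
  n <- nrow(x); p <- ncol(x)
  lev <- levels(y)
  mu <- rbind(colMeans(x[y == lev[1], , drop = FALSE]),
              colMeans(x[y == lev[2], , drop = FALSE]))
  Sw <- matrix(0, p, p)
  for (k in 1:2) {
    xc <- scale(x[y == lev[k], , drop = FALSE], center = mu[k, ], scale = FALSE)
    Sw <- Sw + crossprod(xc)
  }
  Sigma <- Sw / (n - 2)
  if (ridge > 0) Sigma <- Sigma + ridge * mean(diag(Sigma)) * diag(p)
  Sigma_inv <- tryCatch(solve(Sigma), error = function(e) NULL)
  if (is.null(Sigma_inv)) {
    stop("pooled within-class covariance is singular; retry with ridge > 0",
         call. = FALSE)
  }
  pr <- if (prior == "proportional") as.vector(table(y)) / n else c(0.5, 0.5)
  b <- Sigma_inv %*% t(mu)                        # p x 2
  const <- -0.5 * colSums(t(mu) * b) + log(pr)
  w <- drop(Sigma_inv %*% (mu[2, ] - mu[1, ]))
  # Fisher criterion at the optimum, on the training scatter matrices
  gm <- colMeans(x)
  nk <- as.vector(table(y))
  Sb <- nk[1] * tcrossprod(mu[1, ] - gm) + nk[2] * tcrossprod(mu[2, ] - gm)
  J <- drop(crossprod(w, Sb %*% w) / crossprod(w, Sw %*% w))
  pred_names <- colnames(x) %||% paste0("X", seq_len(p))
  dimnames(b) <- list(pred_names, lev)
  structure(list(coef = b, const = setNames(const, lev), w = setNames(w, pred_names),
                 J = J, levels = lev, predictors = pred_names, prior = pr,
                 means = mu, published = FALSE),
            class = "fisher_model")
}

#' The published Fisher classification functions
#'
#' The fixed pair of linear discriminant functions reported for separating
#' class III from class IV lupus nephritis, over five group statistics
#' (harmonic mean, kurtosis, range, skewness, standard deviation):
#' `D_III = -24.065 + 1.858 h + 1.015 k + 0.516 r - 0.310 s + 2.964 sd` and
#' `D_IV  = -21.055 + 1.695 h + 1.119 k + 0.293 r - 0.680 s + 3.715 sd`.
#'
#' @return A `fisher_model` with `published = TRUE`.
#' @export
#' @examples
#' apply_fisher(fisher_published(),
#'              c(harmonic_mean = 20, kurtosis = 0, range = 10,
#'                skewness = 0, standard_deviation = 3))
fisher_published <- function() {
  preds <- published_predictors()
  b <- cbind(III = c(1.858, 1.015, 0.516, -0.310, 2.964),
             IV = c(1.695, 1.119, 0.293, -0.680, 3.715))
  rownames(b) <- preds
  structure(list(coef = b, const = c(III = -24.065, IV = -21.055),
                 w = NULL, J = NA_real_, levels = c("III", "IV"),
                 predictors = preds, prior = c(0.5, 0.5), means = NULL,
                 published = TRUE),
            class = "fisher_model")
}

#' Evaluate a Fisher discriminant on feature vectors
#'
#' Evaluates both classification functions and assigns the class with the
#' larger score; exact ties go to the second class (class IV for the
#' published model, the study's majority class).
#'
#' @param model a `fisher_model`.
#' @param x named numeric vector, matrix or data frame supplying the model's
#'   predictors (extra columns are ignored; missing ones are an error).
#' @return A `data.frame` with one row per sample: `class` (factor),
#'   `D_<level>` scores, and `p_<second level>` (softmax of the two scores,
#'   usable as an ROC score).
#' @export
apply_fisher <- function(model, x) {
  stopifnot(inherits(model, "fisher_model"))
  X <- .predictor_matrix(x, model$predictors)
  D <- X %*% model$coef + matrix(model$const, nrow(X), 2, byrow = TRUE)
  cls <- ifelse(D[, 2] >= D[, 1], model$levels[2], model$levels[1])
  p2 <- 1 / (1 + exp(D[, 1] - D[, 2]))
  out <- data.frame(class = factor(cls, levels = model$levels),
                    D1 = D[, 1], D2 = D[, 2], p2 = p2)
  names(out)[2:4] <- c(paste0("D_", model$levels), paste0("p_", model$levels[2]))
  rownames(out) <- NULL
  out
}

#' @export
predict.fisher_model <- function(object, newdata, ...) apply_fisher(object, newdata)

#' @export
print.fisher_model <- function(x, ...) {
  cat(sprintf("Fisher linear discriminant (%s): %s vs %s over %d predictors\n",
              if (x$published) "published coefficients" else "trained",
              x$levels[1], x$levels[2], length(x$predictors)))
  if (!is.na(x$J)) cat(sprintf("  training J(w) = %.4f\n", x$J))
  invisible(x)
}

.predictor_matrix <- function(x, predictors) {
  if (is.numeric(x) && is.null(dim(x))) x <- t(as.matrix(x))
  x <- as.data.frame(x)
  missing <- setdiff(predictors, names(x))
  if (length(missing)) {
    stop("missing predictor(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(x[, predictors, drop = FALSE])
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("predictors contain non-finite values", call. = FALSE)
  X
}
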