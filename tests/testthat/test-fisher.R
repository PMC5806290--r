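test_that("published classification functions evaluate exactly as printed", {
  pub <- fisher_published()
  zero <- c(harmonic_mean = 0, kurtosis = 0, range = 0, skewness = 0,
            standard_deviation = 0)
  r0 <- apply_fisher(pub, zero)
  expect_equal(r0$D_III, -24.065)
  expect_equal(r0$D_IV, -21.055)
  expect_identical(as.character(r0$class), "IV")

  x <- c(harmonic_mean = 20, kurtosis = 0, range = 10, skewness = 0,
         standard_deviation = 3)
  r <- apply_fisher(pub, x)
  expect_equal(r$D_III, 27.147, tolerance = 1e-12)
  expect_equal(r$D_IV, 26.920, tolerance = 1e-12)
  expect_identical(as.character(r$class), "III")

  # standard deviation alone pushes toward class IV
  xsd <- c(harmonic_mean = 0, kurtosis = 0, range = 0, skewness = 0,
           standard_deviation = 10)
  rsd <- apply_fisher(pub, xsd)
  expect_identical(as.character(rsd$class), "IV")
  expect_equal(rsd$D_IV - rsd$D_III, (3.715 - 2.964) * 10 + 24.065 - 21.055)
})

test_that("published Fisher and logistic formulas agree in direction term by term", {
  pub <- fisher_published()
  lg <- logistic_published()
  d_diff <- pub$coef[, "IV"] - pub$coef[, "III"]
  logit_slope <- lg$coef[pub$predictors]
  expect_true(all(sign(d_diff) == sign(logit_slope)))
})

test_that("published-model application is a pure function", {
  set.seed(99)
  x <- data.frame(harmonic_mean = rnorm(20, 20), kurtosis = rnorm(20),
                  range = rnorm(20, 10), skewness = rnorm(20),
                  standard_deviation = rnorm(20, 3))
  r1 <- apply_fisher(fisher_published(), x)
  r2 <- apply_fisher(fisher_published(), x)
  expect_identical(r1, r2)
})

test_that("well-separated Gaussian classes train to high accuracy", {
  set.seed(10)
  n <- 100
  x <- rbind(matrix(rnorm(2 * n), ncol = 2),
             matrix(rnorm(2 * n, mean = 5), ncol = 2))
  colnames(x) <- c("f1", "f2")
  y <- rep(c("III", "IV"), each = n)
  fit <- train_fisher_lda(x, y)
  pred <- apply_fisher(fit, x)
  expect_gt(mean(pred$class == y), 0.95)
  # projection points from class III toward class IV mean
  expect_true(all(fit$w > 0))
  expect_gt(fit$J, 1)
})

test_that("identical class means give a degenerate discriminant", {
  set.seed(11)
  x <- matrix(rnorm(400), ncol = 2, dimnames = list(NULL, c("f1", "f2")))
  y <- rep(c("III", "IV"), 100)
  fit <- train_fisher_lda(x, y)
  expect_lt(fit$J, 0.1)
  acc <- mean(apply_fisher(fit, x)$class == y)
  expect_lt(abs(acc - 0.5), 0.15)
})

test_that("1-D two-class projection reduces to the mean gap over the variance", {
  set.seed(12)
  x <- matrix(c(rnorm(50, 0, 2), rnorm(50, 3, 2)), ncol = 1)
  colnames(x) <- "f"
  y <- rep(c("III", "IV"), each = 50)
  fit <- train_fisher_lda(x, y)
  mu <- tapply(x[, 1], y, mean)
  s2 <- ((49 * var(x[y == "III", 1]) + 49 * var(x[y == "IV", 1])) / 98)
  expect_equal(unname(fit$w), unname((mu["IV"] - mu["III"]) / s2),
               tolerance = 1e-10)
})

test_that("trained discriminant matches the MASS reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(13)
  n <- 150
  x <- rbind(matrix(rnorm(3 * n), ncol = 3),
             matrix(rnorm(3 * n, mean = 1.5), ncol = 3))
  colnames(x) <- c("a", "b", "c")
  y <- factor(rep(c("III", "IV"), each = n))
  fit <- train_fisher_lda(x, y)
  ref <- MASS::lda(x, grouping = y)
  w_ref <- drop(ref$scaling)
  # same direction up to scale
  expect_equal(fit$w / sqrt(sum(fit$w^2)), w_ref / sqrt(sum(w_ref^2)),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(as.character(apply_fisher(fit, x)$class),
                   as.character(predict(ref, as.data.frame(x))$class))
})

test_that("singular within-class scatter errors unless ridged", {
  x <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8))  # collinear
  y <- c("III", "III", "IV", "IV")
  expect_error(train_fisher_lda(x, y), "ridge")
  expect_s3_class(train_fisher_lda(x, y, ridge = 1e-6), "fisher_model")
})

test_that("missing predictors are reported by name", {
  expect_error(apply_fisher(fisher_published(), c(harmonic_mean = 1)),
               "kurtosis")
})
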