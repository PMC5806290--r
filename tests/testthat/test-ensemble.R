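test_that("vote tallies reproduce the majority rule with a deterministic tie-break", {
  t1 <- tally_votes(c(III = 74, IV = 226))
  expect_identical(t1$predicted, "IV")
  expect_equal(t1$probability, 226 / 300)
  expect_false(t1$tie)

  t2 <- tally_votes(c(III = 300, IV = 0))
  expect_equal(t2$probability, 1)

  t3 <- tally_votes(c(III = 150, IV = 150))
  expect_true(t3$tie)
  expect_identical(t3$predicted, "IV")
  t4 <- tally_votes(c(III = 150, IV = 150), tie_break = "III")
  expect_identical(t4$predicted, "III")
})

test_that("diagnostic metrics match a brute-force confusion oracle", {
  expect_equal(diagnostic_metrics(c("IV", "III"), c("IV", "III"))$accuracy, 1)
  set.seed(40)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    pred <- sample(c("III", "IV"), n, replace = TRUE)
    truth <- sample(c("III", "IV"), n, replace = TRUE)
    if (length(unique(truth)) < 2) next
    m <- diagnostic_metrics(pred, truth)
    o <- oracle_metrics(pred, truth, "IV")
    expect_identical(m$tp, o$tp)
    expect_identical(m$tn, o$tn)
    expect_equal(m$sensitivity, o$sensitivity)
    expect_equal(m$specificity, o$specificity)
    expect_equal(m$accuracy, o$accuracy)
    expect_equal(m$youden, o$sensitivity + o$specificity - 1)
  }
})

test_that("single-class truths flag the undefined rate instead of failing", {
  m <- diagnostic_metrics(c("IV", "IV"), c("IV", "IV"))
  expect_true("specificity" %in% m$undefined)
  expect_true(is.na(m$specificity))
  expect_equal(m$sensitivity, 1)
})

test_that("AUROC equals the exhaustive pairwise oracle", {
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1), positive = 1), 0.75)
  expect_equal(auroc(c(1, 2, 3, 10), c("III", "III", "IV", "IV")), 1)
  expect_equal(auroc(rep(0.5, 10), rep(c("III", "IV"), 5)), 0.5)
  set.seed(41)
  for (i in 1:15) {
    n <- sample(c(10, 50, 200), 1)
    sc <- round(rnorm(n), 1)   # rounding forces ties
    lb <- sample(c("III", "IV"), n, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(lb)) < 2) next
    expect_equal(auroc(sc, lb), oracle_auroc(sc, lb, "IV"), tolerance = 1e-12)
  }
})

test_that("AUROC and the DeLong comparison agree with the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(42)
  n <- 120
  lb <- sample(c("III", "IV"), n, replace = TRUE)
  a <- rnorm(n) + (lb == "IV") * 1.2
  b <- rnorm(n) + (lb == "IV") * 0.3
  roc_a <- pROC::roc(lb, a, levels = c("III", "IV"), direction = "<",
                     quiet = TRUE)
  expect_equal(auroc(a, lb), as.numeric(pROC::auc(roc_a)), tolerance = 1e-12)
  roc_b <- pROC::roc(lb, b, levels = c("III", "IV"), direction = "<",
                     quiet = TRUE)
  ref <- pROC::roc.test(roc_a, roc_b, method = "delong", paired = TRUE)
  mine <- compare_auc(a, b, lb)
  expect_equal(abs(mine$z), abs(unname(ref$statistic)), tolerance = 1e-8)
  expect_equal(mine$p.value, ref$p.value, tolerance = 1e-8)
})

test_that("identical score vectors give z = 0, p = 1 and nonnegative variance", {
  set.seed(43)
  s <- rnorm(40)
  lb <- rep(c("III", "IV"), 20)
  r <- compare_auc(s, s, lb)
  expect_equal(r$z, 0)
  expect_equal(r$p.value, 1)
  for (i in 1:10) {
    a <- rnorm(40); b <- rnorm(40)
    expect_gte(compare_auc(a, b, lb)$var_diff, 0)
  }
})

test_that("the DeLong test detects a separating model against noise", {
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    n <- 500
    lb <- rep(c("III", "IV"), n / 2)
    a <- rnorm(n) + (lb == "IV") * 1.5
    b <- rnorm(n)
    if (compare_auc(a, b, lb)$p.value < 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("two-proportion z test reproduces printed and hand-derived values", {
  r <- two_proportion_test(958, 1500, 956, 1500)
  expect_equal(round(r$p.value, 3), 0.939)
  expect_equal(two_proportion_test(10, 50, 20, 100)$z, 0)
  expect_equal(two_proportion_test(10, 50, 20, 100)$p.value, 1)
  r2 <- two_proportion_test(1508, 2100, 1249, 2100)
  expect_gt(abs(r2$z), 8)
  expect_lt(r2$p.value, 0.001)
  expect_error(two_proportion_test(10, 5, 1, 10), "\\[0, n\\]")
})

test_that("pooled z test matches the chi-square equivalence in prop.test", {
  r <- two_proportion_test(30, 120, 50, 130)
  ref <- prop.test(c(30, 50), c(120, 130), correct = FALSE)
  expect_equal(r$p.value, ref$p.value, tolerance = 1e-12)
})

test_that("patient-level LOO removes whole patients and conserves predictions", {
  set.seed(44)
  n_pat <- 6L; g_per <- 30L
  pid <- rep(sprintf("P%02d", 1:n_pat), each = g_per)
  lab <- rep(rep(c("III", "IV"), 3), each = g_per)
  X <- data.frame(f1 = rnorm(n_pat * g_per) + (lab == "IV") * 4,
                  f2 = rnorm(n_pat * g_per))
  cv <- loo_cv(X, lab, pid, model = "fisher", predictors = c("f1", "f2"))
  expect_identical(nrow(cv), n_pat * g_per)
  expect_false(anyNA(cv$pred))
  # each fold's prediction cannot depend on the held-out patient: retrain
  # without P01 and compare its predictions
  keep <- pid != "P01"
  fit <- train_fisher_lda(X[keep, ], lab[keep])
  manual <- apply_fisher(fit, X[pid == "P01", ])$class
  expect_identical(as.character(cv$pred[pid == "P01"]), as.character(manual))
  expect_gt(mean(cv$pred == cv$truth), 0.9)
})

test_that("vote aggregation is invariant to group order", {
  set.seed(45)
  pred <- sample(c("III", "IV"), 90, replace = TRUE)
  pid <- sample(rep(c("A", "B", "C"), 30))
  truth <- c(A = "III", B = "IV", C = "IV")
  s1 <- patient_vote_summary(pred, pid, truth)
  perm <- sample(90)
  s2 <- patient_vote_summary(pred[perm], pid[perm], truth)
  s2 <- s2[match(s1$patient_id, s2$patient_id), ]
  rownames(s2) <- NULL
  expect_equal(s1, s2)
})
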