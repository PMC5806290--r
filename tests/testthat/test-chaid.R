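test_that("Pearson chi-square matches hand computations", {
  r <- chi2_independence(rbind(c(10, 0), c(0, 10)))
  expect_equal(r$statistic, 20)
  expect_identical(r$df, 1L)

  r2 <- chi2_independence(rbind(c(5, 5), c(5, 5)))
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p.value, 1)

  r3 <- chi2_independence(rbind(c(20, 10), c(10, 20)))
  expect_equal(r3$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(r3$p.value, 0.0098, tolerance = 1e-2)

  expect_error(chi2_independence(matrix(0, 2, 2)), "all-zero")
})

test_that("Pearson statistic agrees with the stats reference on random tables", {
  set.seed(30)
  for (i in 1:20) {
    tab <- matrix(rpois(6, 15) + 1, 3, 2)
    mine <- chi2_independence(tab)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("degenerate tables are pruned instead of producing NaN", {
  # both rows carry only one class: no evidence against independence
  r <- chi2_independence(rbind(c(5, 0), c(9, 0)))
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)
})

test_that("a perfectly separating predictor splits the root into pure leaves", {
  set.seed(31)
  x <- data.frame(good = c(rnorm(80, 0), rnorm(80, 20)), noise = rnorm(160))
  y <- rep(c("III", "IV"), each = 80)
  tree <- chaid_grow(x, y, min_parent = 20, min_child = 5)
  expect_identical(tree$root$predictor, "good")
  leaves_pure <- function(nd) {
    if (nd$terminal) return(min(nd$counts) == 0)
    all(vapply(nd$children, leaves_pure, TRUE))
  }
  expect_true(leaves_pure(tree$root))
  expect_true(all(chaid_predict(tree, x)$class == y))
})

test_that("null labels leave the root unsplit in most seeded replicates", {
  single <- 0L
  for (s in 1:100) {
    set.seed(s)
    x <- data.frame(a = rnorm(300), b = rnorm(300), c = rnorm(300))
    y <- sample(rep(c("III", "IV"), 150))
    tree <- chaid_grow(x, y)
    if (tree$n_nodes == 1L) single <- single + 1L
  }
  expect_gte(single, 80L)
})

test_that("depth limit and class-count conservation hold on cohort-like data", {
  set.seed(32)
  n <- 600L
  x <- data.frame(hm = c(rnorm(n / 2, 18), rnorm(n / 2, 15)),
                  sdv = rgamma(n, 4), rg = rnorm(n, 10))
  y <- rep(c("III", "IV"), each = n / 2)
  tree <- chaid_grow(x, y, max_depth = 3)
  check <- function(nd) {
    expect_lte(nd$depth, 3L)
    if (!nd$terminal) {
      kid_counts <- Reduce(`+`, lapply(nd$children, `[[`, "counts"))
      expect_identical(kid_counts, nd$counts)
      for (ch in nd$children) check(ch)
    }
  }
  check(tree$root)
  # every training sample routes to a leaf and leaf totals conserve n
  pred <- chaid_predict(tree, x)
  expect_identical(nrow(pred), n)
  leaf_n <- function(nd) if (nd$terminal) nd$n else
    sum(vapply(nd$children, leaf_n, 0L))
  expect_identical(leaf_n(tree$root), n)
})

test_that("Bonferroni adjustment never decreases a p-value", {
  set.seed(33)
  for (i in 1:20) {
    x <- rnorm(200)
    y <- factor(sample(rep(c("III", "IV"), 100)))
    ev <- boldln:::.chaid_eval_predictor(x, y, n_bins = 10, alpha_merge = 0.05)
    if (!is.null(ev)) expect_gte(ev$p_adj, ev$p_raw)
  }
})

test_that("values outside the training range are clamped to boundary bins", {
  set.seed(34)
  x <- data.frame(f = c(rnorm(100, 0), rnorm(100, 10)))
  y <- rep(c("III", "IV"), each = 100)
  tree <- chaid_grow(x, y, min_parent = 20, min_child = 5)
  lo <- chaid_predict(tree, data.frame(f = -1e6))
  hi <- chaid_predict(tree, data.frame(f = 1e6))
  expect_identical(as.character(lo$class), "III")
  expect_identical(as.character(hi$class), "IV")
})

test_that("a single-node tree predicts the root majority everywhere", {
  set.seed(35)
  x <- data.frame(f = rnorm(50))
  y <- c(rep("III", 20), rep("IV", 30))
  tree <- chaid_grow(x, y, alpha_split = 1e-12)  # force no split
  expect_identical(tree$n_nodes, 1L)
  pr <- chaid_predict(tree, data.frame(f = c(-5, 0, 5)))
  expect_true(all(pr$class == "IV"))
  expect_equal(pr$p_IV, rep(0.6, 3))
})
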