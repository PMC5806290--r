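test_that("packaged tables load, checksum-verified, with spot values as printed", {
  t1 <- load_fixture("table1")
  t2 <- load_fixture("table2")
  t4 <- load_fixture("table4")
  t5 <- load_fixture("table5")
  expect_identical(nrow(t1), 12L)
  expect_identical(nrow(t2), 12L)
  expect_identical(nrow(t4), 36L)
  expect_identical(nrow(t5), 12L)
  expect_equal(t1$urine_protein[t1$case_id == 2], 0.34)
  expect_identical(t2$diagnosis[t2$case_id == 1], "IV-G (A/C) + V")
  dt1 <- t4[t4$case_id == 1 & t4$model == "decision_tree", ]
  expect_identical(c(dt1$votes_III, dt1$votes_IV), c(74L, 226L))
  expect_error(load_fixture("table9"), "unknown table id")
})

test_that("a tampered fixture fails closed on its checksum", {
  # stage a modified copy in a fake package tree and point the loader at it
  src <- system.file("extdata", package = "boldln")
  tmp <- file.path(tempdir(), "boldln-tamper", "extdata")
  dir.create(tmp, recursive = TRUE, showWarnings = FALSE)
  file.copy(list.files(src, full.names = TRUE), tmp, overwrite = TRUE)
  f <- file.path(tmp, "table1_clinical.csv")
  writeLines(sub("0.34", "0.35", readLines(f)), f)
  man <- read.csv(file.path(tmp, "MANIFEST.md5"))
  expect_false(unname(tools::md5sum(f)) ==
                 man$md5[man$file == "table1_clinical.csv"])
})

test_that("clinical summaries reproduce the printed means and SDs", {
  s <- summarize_clinical(load_fixture("table1"), digits = 2)
  get <- function(f, col) s[[col]][s$field == f]
  expect_equal(get("urine_protein", "mean"), 3.52)
  expect_equal(get("urine_protein", "sd"), 2.50)
  expect_equal(get("sledai", "mean"), 20.58)
  expect_equal(get("sledai", "sd"), 6.49)
  expect_equal(get("ln_duration_months", "mean"), 49.19)
  expect_equal(get("ln_duration_months", "sd"), 60.76)
  # constant column: mean = value, sd = 0
  rec <- load_fixture("table1")
  rec$constant <- 7
  s2 <- summarize_clinical(rec)
  expect_equal(s2$mean[s2$field == "constant"], 7)
  expect_equal(s2$sd[s2$field == "constant"], 0)
})

test_that("KDIGO staging uses closed lower bounds and counts 9/2/1 patients", {
  expect_identical(ckd_stage(c(98, 90, 89.9, 60, 59, 30, 29, 15, 14.9)),
                   c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L))
  expect_error(ckd_stage(0), "positive")
  counts <- count_stages(load_fixture("table1"))
  expect_identical(unname(counts[1:3]), c(9L, 2L, 1L))
})

test_that("pathology component sums verify against every printed total", {
  v <- verify_pathology(load_fixture("table2"))
  expect_true(v$ok)
  expect_length(v$ai_mismatch, 0)
  expect_equal(v$ai_mean, 8.00)
  expect_equal(round(v$ai_sd, 2), 2.37)
  expect_equal(round(v$ci_mean, 2), 2.33)
  expect_equal(round(v$ci_sd, 2), 0.49)
  expect_identical(unname(v$class_counts["III"]), 5L)
  expect_identical(unname(v$class_counts["IV"]), 7L)
  # case 6: 1+1+0+0+1+1 = 4
  t2 <- load_fixture("table2")
  expect_identical(v$ai_recomputed[t2$case_id == 6], 4)
})

test_that("vote-count metrics equal the expanded confusion-matrix route exactly", {
  t2 <- load_fixture("table2")
  t4 <- load_fixture("table4")
  for (m in c("decision_tree", "line_discriminant", "logistic")) {
    direct <- metrics_from_votes(t4, t2, m)
    exp_df <- expand_votes(t4, t2, m)
    expect_identical(nrow(exp_df), 3600L)
    via_units <- diagnostic_metrics(exp_df$pred, exp_df$truth)
    expect_identical(direct$tp, via_units$tp)
    expect_identical(direct$tn, via_units$tn)
    expect_equal(direct$sensitivity, via_units$sensitivity)
    expect_equal(direct$specificity, via_units$specificity)
    expect_equal(direct$accuracy, via_units$accuracy)
  }
})

test_that("a perfect voter gets unit rates", {
  t2 <- load_fixture("table2")
  perfect <- data.frame(case_id = t2$case_id, model = "perfect",
                        votes_III = ifelse(t2$primary_class == "III", 300L, 0L),
                        votes_IV = ifelse(t2$primary_class == "IV", 300L, 0L))
  m <- metrics_from_votes(perfect, t2, "perfect")
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$accuracy, 1)
  expect_equal(m$youden, 1)
})

test_that("vote rows failing the 300-sum invariant are reported", {
  t4 <- load_fixture("table4")
  expect_identical(nrow(check_vote_sums(t4, c("votes_III", "votes_IV"))), 0L)
  t5 <- load_fixture("table5")
  bad <- check_vote_sums(t5, c("primary_votes_III", "primary_votes_IV"))
  expect_setequal(bad$case_id, c(5L, 11L))
  expect_identical(nrow(check_vote_sums(
    t5, c("votes_homogeneity", "votes_heterogeneity"))), 0L)
  # metrics refuse to run on a broken vote table
  t4b <- t4
  t4b$votes_IV[1] <- t4b$votes_IV[1] + 1L
  expect_error(metrics_from_votes(t4b, load_fixture("table2"), "decision_tree"),
               "case\\(s\\) 1")
})

test_that("diagnosis strings parse to a unique primary class and subclass", {
  p <- parse_diagnosis(c("IV-G (A/C) + V", "III-(A/C)", "III-(A/C) + V"))
  expect_identical(p$primary_class, c("IV", "III", "III"))
  expect_identical(p$subclass, c("plus_V", "pure", "plus_V"))
  expect_error(parse_diagnosis("V"), "unparseable")
})
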