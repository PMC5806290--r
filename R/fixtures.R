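# Machine-readable transcriptions of the published study's tables and the
# summaries/metrics recomputable from them.

.fixture_files <- c(
  table1 = "table1_clinical.csv",
  table2 = "table2_pathology.csv",
  table4 = "table4_primary_votes.csv",
  table5 = "table5_subclass_votes.csv"
)

#' Load a packaged study table
#'
#' Returns the verbatim transcription of one of the published study's
#' tables: `table1` (clinical and laboratory data of the 12 patients),
#' `table2` (pathology component scores, activity/chronicity indices and
#' ISN/RPS diagnoses), `table4` (per-case class III/IV vote counts out of
#' 300 groups for the three models), `table5` (sub-class vote counts for
#' the decision tree). Each file is verified against a packaged MD5
#' manifest and loading fails closed on any mismatch. `table2` and
#' `table5` gain derived columns `primary_class` (`III`/`IV`) and
#' `subclass` (`pure`/`plus_V`) parsed from the diagnosis strings.
#'
#' Two vote rows of `table5` are transcribed exactly as printed even though
#' their primary votes do not sum to 300 (cases 5 and 11);
#' [check_vote_sums()] reports them.
#'
#' @param table_id one of `"table1"`, `"table2"`, `"table4"`, `"table5"`.
#' @return A `data.frame`.
#' @export
#' @examples
#' votes <- load_fixture("table4")
#' subset(votes, case_id == 1 & model == "decision_tree")
load_fixture <- function(table_id) {
  if (!table_id %in% names(.fixture_files)) {
    stop("unknown table id: ", table_id, " (use table1/table2/table4/table5)",
         call. = FALSE)
  }
  path <- system.file("extdata", .fixture_files[[table_id]], package = "boldln")
  manifest <- system.file("extdata", "MANIFEST.md5", package = "boldln")
  if (!nzchar(path) || !nzchar(manifest)) {
    stop("packaged fixture files not found; is boldln installed?", call. = FALSE)
  }
  man <- read.csv(manifest, stringsAsFactors = FALSE)
  expect <- man$md5[man$file == basename(path)]
  if (length(expect) != 1L || unname(tools::md5sum(path)) != expect) {
    stop("fixture checksum mismatch for ", basename(path),
         "; refusing to load a modified transcription", call. = FALSE)
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  if ("diagnosis" %in% names(df)) {
    parsed <- parse_diagnosis(df$diagnosis)
    df$primary_class <- parsed$primary_class
    df$subclass <- parsed$subclass
  }
  df
}

#' Parse an ISN/RPS diagnosis string
#'
#' Maps strings such as `"IV-G (A/C) + V"` or `"III-(A/C)"` to the primary
#' proliferative class (`III` or `IV`) and the membranous subclass
#' (`plus_V` when a `+ V` suffix is present, else `pure`).
#'
#' @param x character vector of diagnosis strings.
#' @return List with `primary_class` and `subclass` character vectors.
#' @export
parse_diagnosis <- function(x) {
  primary <- ifelse(grepl("^\\s*IV", x), "IV",
                    ifelse(grepl("^\\s*III", x), "III", NA_character_))
  if (anyNA(primary)) {
    stop("unparseable diagnosis: ",
         paste(x[is.na(primary)], collapse = "; "), call. = FALSE)
  }
  subclass <- ifelse(grepl("\\+\\s*V\\s*$", x), "plus_V", "pure")
  list(primary_class = primary, subclass = subclass)
}

#' Mean and sample SD of every numeric clinical field
#'
#' Arithmetic mean and n-1-denominator standard deviation for each numeric
#' column of the clinical table, optionally rounded to the precision used
#' in the study's text (2 decimal places).
#'
#' @param records the `table1` data frame from [load_fixture()].
#' @param digits round to this many decimals (`NULL` = no rounding).
#' @return A `data.frame` with `field`, `mean`, `sd`, `n`.
#' @export
#' @examples
#' s <- summarize_clinical(load_fixture("table1"), digits = 2)
#' s[s$field == "urine_protein", ]
summarize_clinical <- function(records, digits = NULL) {
  num <- records[, setdiff(names(records), "case_id"), drop = FALSE]
  num <- num[, vapply(num, is.numeric, TRUE), drop = FALSE]
  if (anyNA(num)) stop("clinical records contain missing fields", call. = FALSE)
  out <- data.frame(field = names(num),
                    mean = vapply(num, mean, 0),
                    sd = vapply(num, sd, 0),
                    n = nrow(num), row.names = NULL)
  if (!is.null(digits)) {
    out$mean <- round(out$mean, digits)
    out$sd <- round(out$sd, digits)
  }
  out
}

#' KDIGO CKD G-stage from eGFR
#'
#' Stage thresholds on eGFR in ml/min/1.73 m^2: `>= 90` stage 1 (closed
#' lower bound), `60-89` stage 2, `30-59` stage 3, `15-29` stage 4,
#' `< 15` stage 5.
#'
#' @param egfr numeric vector of positive eGFR values.
#' @return Integer stages 1-5.
#' @export
#' @examples
#' ckd_stage(c(98, 90, 39))
ckd_stage <- function(egfr) {
  if (any(!is.finite(egfr)) || any(egfr <= 0)) {
    stop("`egfr` must be positive and finite", call. = FALSE)
  }
  5L - findInterval(egfr, c(15, 30, 60, 90))
}

#' @rdname ckd_stage
#' @param records the `table1` data frame.
#' @return `count_stages()`: named integer vector of patient counts over
#'   stages 1-5.
#' @export
count_stages <- function(records) {
  st <- ckd_stage(records$egfr)
  tab <- tabulate(st, nbins = 5L)
  setNames(tab, paste0("stage", 1:5))
}

#' Recompute and verify the pathology table
#'
#' Recomputes each case's activity index (sum of six component scores) and
#' chronicity index (sum of four components), compares them with the
#' printed totals, counts the primary classes parsed from the diagnosis
#' strings, and summarises AI/CI (mean, sample SD).
#'
#' @param records the `table2` data frame from [load_fixture()].
#' @return A list: `ai_recomputed`, `ci_recomputed`, `ai_mismatch` /
#'   `ci_mismatch` (case ids whose printed total disagrees),
#'   `class_counts`, `subclass_counts`, `ai_mean`, `ai_sd`, `ci_mean`,
#'   `ci_sd`, and `ok` (all totals verified).
#' @export
verify_pathology <- function(records) {
  ai_cols <- c("cell_proliferation", "leucocyte_exudation",
               "karyorrhexis_necrosis", "cellular_crescents",
               "hyaline_deposits", "interstitial_inflammation")
  ci_cols <- c("glomerular_sclerosis", "fibrous_crescents",
               "tubular_atrophy", "interstitial_fibrosis")
  ai <- rowSums(records[, ai_cols])
  ci <- rowSums(records[, ci_cols])
  ai_mm <- records$case_id[ai != records$ai_total]
  ci_mm <- records$case_id[ci != records$ci_total]
  list(ai_recomputed = ai, ci_recomputed = ci,
       ai_mismatch = ai_mm, ci_mismatch = ci_mm,
       class_counts = table(records$primary_class),
       subclass_counts = table(records$primary_class, records$subclass),
       ai_mean = mean(records$ai_total), ai_sd = sd(records$ai_total),
       ci_mean = mean(records$ci_total), ci_sd = sd(records$ci_total),
       ok = length(ai_mm) == 0 && length(ci_mm) == 0)
}

#' Check that vote rows sum to the expected group count
#'
#' @param votes a vote table with two count columns (`votes_III`/`votes_IV`
#'   or `votes_homogeneity`/`votes_heterogeneity`, or the
#'   `primary_votes_*` pair of `table5`).
#' @param columns the two count columns to sum.
#' @param expected expected per-case total (300 groups).
#' @return A `data.frame` of offending rows (`case_id`, plus `model` when
#'   present, and `total`); zero rows when all sums match.
#' @export
check_vote_sums <- function(votes, columns, expected = 300L) {
  tot <- rowSums(votes[, columns, drop = FALSE])
  bad <- which(tot != expected)
  cols <- intersect(c("case_id", "model"), names(votes))
  out <- votes[bad, cols, drop = FALSE]
  out$total <- tot[bad]
  rownames(out) <- NULL
  out
}

#' Group-level diagnostic metrics from printed vote counts
#'
#' Treats each of the 300 groups per case as one classified unit:
#' sensitivity is the share of class-IV votes among groups belonging to
#' class-IV patients, specificity the share of class-III votes in class-III
#' patients, accuracy the share of correct votes overall, and Youden's
#' index their sum minus one. Exactly reproduces the study's evaluation
#' table from its vote table.
#'
#' @param votes the `table4` data frame from [load_fixture()].
#' @param pathology the `table2` data frame (supplies true classes).
#' @param model `"decision_tree"`, `"line_discriminant"` or `"logistic"`.
#' @param positive positive-class label (default `"IV"`; this is the only
#'   choice under which the printed rates are recovered).
#' @return A `diagnostic_summary` (see [diagnostic_metrics()]).
#' @export
#' @examples
#' m <- metrics_from_votes(load_fixture("table4"), load_fixture("table2"),
#'                         "decision_tree")
#' round(m$sensitivity, 3)
metrics_from_votes <- function(votes, pathology, model, positive = "IV") {
  v <- votes[votes$model == model, ]
  if (nrow(v) != nrow(pathology)) {
    stop("vote records incomplete for model ", model, call. = FALSE)
  }
  bad <- check_vote_sums(v, c("votes_III", "votes_IV"))
  if (nrow(bad)) {
    stop("vote counts do not sum to 300 for case(s) ",
         paste(bad$case_id, collapse = ", "), call. = FALSE)
  }
  truth <- pathology$primary_class[match(v$case_id, pathology$case_id)]
  neg <- setdiff(c("III", "IV"), positive)
  pos_votes <- if (positive == "IV") v$votes_IV else v$votes_III
  neg_votes <- if (positive == "IV") v$votes_III else v$votes_IV
  tp <- sum(pos_votes[truth == positive])
  fn <- sum(neg_votes[truth == positive])
  tn <- sum(neg_votes[truth == neg])
  fp <- sum(pos_votes[truth == neg])
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, specificity = spec,
                 accuracy = (tp + tn) / sum(v$votes_III + v$votes_IV),
                 youden = sens + spec - 1, positive = positive,
                 undefined = character()),
            class = "diagnostic_summary")
}

#' Expand printed vote counts into one label per group
#'
#' Utility for unit-level analyses: each case contributes `votes_III`
#' literal `"III"` predictions and `votes_IV` `"IV"` predictions, paired
#' with the case's true class.
#'
#' @inheritParams metrics_from_votes
#' @return A `data.frame` with `case_id`, `pred`, `truth` (one row per
#'   group).
#' @export
expand_votes <- function(votes, pathology, model) {
  v <- votes[votes$model == model, ]
  truth <- pathology$primary_class[match(v$case_id, pathology$case_id)]
  data.frame(
    case_id = rep(v$case_id, v$votes_III + v$votes_IV),
    pred = unlist(mapply(function(a, b) c(rep("III", a), rep("IV", b)),
                         v$votes_III, v$votes_IV, SIMPLIFY = FALSE)),
    truth = rep(truth, v$votes_III + v$votes_IV),
    stringsAsFactors = FALSE
  )
}

#' Patient-level concordance of majority-vote predictions
#'
#' Derives each case's predicted class from its printed vote counts by
#' majority and compares with the biopsy-proven class. `variant =
#' "primary"` uses a model's III/IV votes from `table4`;
#' `variant = "secondary"` uses the decision tree's homogeneity (pure) vs
#' heterogeneity (+V) votes from `table5` against the parsed subclass.
#'
#' @param votes `table4` (primary) or `table5` (secondary) data frame.
#' @param pathology the `table2` data frame.
#' @param model model name, required for `variant = "primary"`.
#' @param variant `"primary"` or `"secondary"`.
#' @param tie_break class awarded on an exact vote tie.
#' @return A list with `cases` (per-case data frame: votes, `predicted`,
#'   `truth`, `correct`), `n_correct`, and `mismatches` (case ids).
#' @export
#' @examples
#' pc <- patient_concordance(load_fixture("table4"), load_fixture("table2"),
#'                           model = "line_discriminant")
#' pc$mismatches
patient_concordance <- function(votes, pathology, model = NULL,
                                variant = c("primary", "secondary"),
                                tie_break = "IV") {
  variant <- match.arg(variant)
  if (variant == "primary") {
    v <- votes[votes$model == model, ]
    if (nrow(v) == 0) stop("no vote records for model ", model, call. = FALSE)
    counts <- v[, c("votes_III", "votes_IV")]
    lev <- c("III", "IV")
    truth <- pathology$primary_class[match(v$case_id, pathology$case_id)]
  } else {
    v <- votes
    counts <- v[, c("votes_homogeneity", "votes_heterogeneity")]
    lev <- c("pure", "plus_V")
    truth <- pathology$subclass[match(v$case_id, pathology$case_id)]
    if (tie_break == "IV") tie_break <- "plus_V"
  }
  pred <- vapply(seq_len(nrow(v)), function(i) {
    tally_votes(setNames(as.numeric(counts[i, ]), lev),
                tie_break = tie_break)$predicted
  }, "")
  cases <- data.frame(case_id = v$case_id, counts,
                      predicted = pred, truth = truth,
                      correct = pred == truth, stringsAsFactors = FALSE)
  list(cases = cases, n_correct = sum(cases$correct),
       mismatches = cases$case_id[!cases$correct])
}
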