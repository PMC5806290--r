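# CHAID decision-tree induction: equal-frequency binning of continuous
# predictors, iterative merging of statistically indistinguishable adjacent
# bins, and Bonferroni-adjusted chi-square split selection.

#' Pearson chi-square test of independence
#'
#' Pearson's statistic `sum (O - E)^2 / E` on an r x c contingency table
#' with `df = (r - 1)(c - 1)` and upper-tail p-value. Rows and columns whose
#' margin is zero are pruned first; if fewer than two rows or columns
#' remain, the table carries no evidence against independence and
#' `statistic = 0`, `p = 1` is returned (this keeps the CHAID merge loop
#' well-defined on degenerate 2 x 2 tables). No continuity correction.
#'
#' @param tab matrix of nonnegative counts.
#' @return List with `statistic`, `df`, `p.value`.
#' @export
#' @examples
#' chi2_independence(rbind(c(10, 0), c(0, 10)))  # statistic 20, df 1
chi2_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(!is.finite(tab))) {
    stop("`tab` must contain nonnegative finite counts", call. = FALSE)
  }
  if (sum(tab) == 0) stop("all-zero table", call. = FALSE)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    return(list(statistic = 0, df = 0L, p.value = 1))
  }
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, df = df, p.value = pchisq(stat, df, lower.tail = FALSE))
}

# Equal-frequency discretisation of a continuous predictor: returns the
# internal break points and the bin index of every value. Empty bins
# (possible with heavy ties) are removed by construction since breaks are
# deduplicated quantiles.
.chaid_bins <- function(vals, n_bins) {
  probs <- seq(0, 1, length.out = n_bins + 1L)[-c(1L, n_bins + 1L)]
  breaks <- unique(quantile(vals, probs, type = 7, names = FALSE))
  bins <- findInterval(vals, breaks) + 1L
  # drop bin labels that received no observations (duplicate break edges)
  occupied <- sort(unique(bins))
  list(breaks = breaks, bins = match(bins, occupied), n_bins = length(occupied))
}

# Merge ordered categories a la CHAID: repeatedly merge the least
# significantly different adjacent pair while its pairwise chi-square
# p-value exceeds alpha_merge, never going below two categories.
# `counts` is an n_cat x n_class matrix; returns group assignment per
# original category plus the final table.
.chaid_merge <- function(counts, alpha_merge) {
  groups <- as.list(seq_len(nrow(counts)))
  tab <- counts
  while (nrow(tab) > 2L) {
    pvals <- vapply(seq_len(nrow(tab) - 1L), function(i) {
      chi2_independence(tab[c(i, i + 1L), , drop = FALSE])$p.value
    }, 0)
    i <- which.max(pvals)
    if (pvals[i] <= alpha_merge) break
    groups[[i]] <- c(groups[[i]], groups[[i + 1L]])
    groups[[i + 1L]] <- NULL
    merged <- tab[i, , drop = FALSE] + tab[i + 1L, , drop = FALSE]
    keep_before <- if (i > 1L) tab[seq_len(i - 1L), , drop = FALSE]
    keep_after <- if (i + 2L <= nrow(tab)) tab[seq(i + 2L, nrow(tab)), , drop = FALSE]
    tab <- rbind(keep_before, merged, keep_after)
  }
  assign <- integer(nrow(counts))
  for (g in seq_along(groups)) assign[groups[[g]]] <- g
  list(assign = assign, table = tab, n_final = length(groups))
}

# Evaluate one predictor at a node: bin, merge, test, Bonferroni-adjust.
.chaid_eval_predictor <- function(vals, y, n_bins, alpha_merge) {
  b <- .chaid_bins(vals, n_bins)
  if (b$n_bins < 2L) return(NULL)
  counts <- table(factor(b$bins, levels = seq_len(b$n_bins)), y)
  counts <- matrix(as.integer(counts), b$n_bins)
  m <- .chaid_merge(counts, alpha_merge)
  if (m$n_final < 2L) return(NULL)
  test <- chi2_independence(m$table)
  # Bonferroni multiplier for an ordinal predictor: the number of ways to
  # partition c ordered categories into r contiguous groups.
  mult <- choose(b$n_bins - 1L, m$n_final - 1L)
  list(p_raw = test$p.value, p_adj = min(1, test$p.value * mult),
       statistic = test$statistic, df = test$df,
       breaks = b$breaks, assign = m$assign, n_final = m$n_final,
       n_bins = b$n_bins)
}

#' Grow a CHAID decision tree
#'
#' Chi-squared automatic interaction detection for a two-class outcome over
#' continuous predictors. At each node every predictor is discretised into
#' at most `n_bins` equal-frequency bins; adjacent bins whose class
#' distributions do not differ (pairwise chi-square p > `alpha_merge`) are
#' merged iteratively, least-different pair first; each predictor is then
#' scored by the chi-square p-value of its merged table, Bonferroni-adjusted
#' by the number of contiguous partitions of its original bins. The
#' predictor with the smallest adjusted p splits the node if that p is at
#' most `alpha_split`, every child holds at least `min_child` samples, the
#' node holds at least `min_parent`, and the depth limit is not reached.
#' An unsplittable root yields a single-node tree.
#'
#' @param x data frame or matrix of numeric predictors.
#' @param y two-level factor of class labels.
#' @param max_depth maximum number of split levels below the root
#'   (default 3).
#' @param alpha_merge significance level for merging adjacent bins.
#' @param alpha_split significance level a Bonferroni-adjusted predictor
#'   p-value must reach for a split.
#' @param n_bins maximum number of initial equal-frequency bins.
#' @param min_parent minimum node size to attempt a split.
#' @param min_child minimum size of every resulting child.
#' @param bonferroni `"partition"` (contiguous-partition multiplier,
#'   default) or `"predictors"` (simplified: multiply by the number of
#'   candidate predictors).
#' @return An object of class `chaid_tree`; see [chaid_predict()].
#' @export
chaid_grow <- function(x, y, max_depth = 3L, alpha_merge = 0.05,
                       alpha_split = 0.05, n_bins = 10L,
                       min_parent = 30L, min_child = 10L,
                       bonferroni = c("partition", "predictors")) {
  bonferroni <- match.arg(bonferroni)
  x <- as.data.frame(x)
  if (!all(vapply(x, is.numeric, TRUE))) {
    stop("all predictors must be numeric", call. = FALSE)
  }
  y <- factor(y)
  if (nlevels(y) != 2L) stop("`y` must have exactly two classes", call. = FALSE)
  lev <- levels(y)
  node_counter <- new.env()
  node_counter$n <- 0L

  grow <- function(idx, depth) {
    node_counter$n <- node_counter$n + 1L
    counts <- table(factor(y[idx], levels = lev))
    node <- list(id = node_counter$n, depth = depth, n = length(idx),
                 counts = setNames(as.integer(counts), lev),
                 class = lev[which.max(counts)],
                 terminal = TRUE, predictor = NULL, breaks = NULL,
                 assign = NULL, p_adj = NA_real_, statistic = NA_real_,
                 children = list())
    if (depth >= max_depth || length(idx) < min_parent ||
        min(counts) == 0L) {
      return(node)
    }
    best <- NULL; best_var <- NULL
    for (v in names(x)) {
      ev <- .chaid_eval_predictor(x[idx, v], y[idx], n_bins, alpha_merge)
      if (is.null(ev)) next
      if (bonferroni == "predictors") {
        ev$p_adj <- min(1, ev$p_raw * ncol(x))
      }
      if (is.null(best) || ev$p_adj < best$p_adj) { best <- ev; best_var <- v }
    }
    if (is.null(best) || best$p_adj > alpha_split) return(node)
    bins <- findInterval(x[idx, best_var], best$breaks) + 1L
    bins <- pmin(pmax(bins, 1L), best$n_bins)
    child_of <- best$assign[bins]
    sizes <- tabulate(child_of, nbins = best$n_final)
    if (any(sizes < min_child)) return(node)
    node$terminal <- FALSE
    node$predictor <- best_var
    node$breaks <- best$breaks
    node$assign <- best$assign
    node$p_adj <- best$p_adj
    node$statistic <- best$statistic
    node$children <- lapply(seq_len(best$n_final), function(g) {
      grow(idx[child_of == g], depth + 1L)
    })
    node
  }

  root <- grow(seq_along(y), 0L)
  count_nodes <- function(nd) {
    if (nd$terminal) c(1L, 1L)
    else c(1L, 0L) + Reduce(`+`, lapply(nd$children, count_nodes))
  }
  cn <- count_nodes(root)
  structure(list(root = root, levels = lev, predictors = names(x),
                 params = list(max_depth = max_depth, alpha_merge = alpha_merge,
                               alpha_split = alpha_split, n_bins = n_bins,
                               min_parent = min_parent, min_child = min_child,
                               bonferroni = bonferroni),
                 n_nodes = cn[1], n_terminal = cn[2]),
            class = "chaid_tree")
}

#' Classify with a CHAID tree
#'
#' Routes each sample from the root to exactly one leaf by bin membership
#' (values outside the training range fall into the nearest boundary bin)
#' and predicts the leaf's majority class; the leaf's class proportions are
#' returned as the class distribution.
#'
#' @param tree a [chaid_grow()] result.
#' @param x data frame / matrix / named vector with the predictors the tree
#'   uses.
#' @return A `data.frame` with `class`, one proportion column per level
#'   (`p_<level>`), and `node` (the leaf id).
#' @export
chaid_predict <- function(tree, x) {
  stopifnot(inherits(tree, "chaid_tree"))
  X <- .predictor_matrix(x, tree$predictors)
  colnames(X) <- tree$predictors
  n <- nrow(X)
  cls <- character(n); node_id <- integer(n)
  probs <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    nd <- tree$root
    while (!nd$terminal) {
      v <- X[i, nd$predictor]
      bin <- findInterval(v, nd$breaks) + 1L
      bin <- min(max(bin, 1L), length(nd$assign))
      nd <- nd$children[[nd$assign[bin]]]
    }
    cls[i] <- nd$class
    node_id[i] <- nd$id
    probs[i, ] <- nd$counts / max(sum(nd$counts), 1L)
  }
  out <- data.frame(class = factor(cls, levels = tree$levels),
                    p1 = probs[, 1], p2 = probs[, 2], node = node_id)
  names(out)[2:3] <- paste0("p_", tree$levels)
  out
}

#' @export
predict.chaid_tree <- function(object, newdata, ...) chaid_predict(object, newdata)

#' @export
print.chaid_tree <- function(x, ...) {
  cat(sprintf("CHAID tree: %d nodes (%d terminal), depth limit %d, classes %s/%s\n",
              x$n_nodes, x$n_terminal, x$params$max_depth,
              x$levels[1], x$levels[2]))
  show <- function(nd, indent) {
    lab <- sprintf("%sn=%d [%s] %s", strrep("  ", indent), nd$n,
                   paste(nd$counts, collapse = "/"),
                   if (nd$terminal) paste0("-> ", nd$class)
                   else sprintf("split %s (p_adj=%.3g)", nd$predictor, nd$p_adj))
    cat(lab, "\n")
    for (ch in nd$children) show(ch, indent + 1L)
  }
  show(x$root, 0L)
  invisible(x)
}
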