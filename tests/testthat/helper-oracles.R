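# Independent brute-force oracles used to cross-check the implementation.

# Direct-formula evaluation of the ten group statistics, written as plain
# sums/products so it shares no code path with compute_features().
oracle_features <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  gm <- prod(x^(1 / n))
  hm <- n / sum(1 / x)
  ss <- sum((x - m)^2)
  s2 <- ss / (n - 1)
  s <- sqrt(s2)
  z <- (x - m) / s
  sk <- n / ((n - 1) * (n - 2)) * sum(z^3)
  ku <- n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) * sum(z^4) -
    3 * (n - 1)^2 / ((n - 2) * (n - 3))
  # weighted-average (type 6) quartiles by hand, on the sorted sample
  q6 <- function(p) {
    xs <- sort(x)
    h <- (n + 1) * p
    lo <- floor(h)
    if (lo < 1) return(xs[1])
    if (lo >= n) return(xs[n])
    xs[lo] + (h - lo) * (xs[lo + 1] - xs[lo])
  }
  c(arithmetic_mean = m, geometric_mean = gm, harmonic_mean = hm,
    range = max(x) - min(x), standard_deviation = s,
    quartile = q6(0.75) - q6(0.25), skewness = sk, kurtosis = ku,
    variance = s2, sum = sum(x))
}

# AUROC by exhaustive enumeration of positive-negative pairs, ties 1/2.
oracle_auroc <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Confusion-matrix rates by explicit counting loops.
oracle_metrics <- function(pred, truth, positive) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(pred)) {
    if (truth[i] == positive) {
      if (pred[i] == positive) tp <- tp + 1L else fn <- fn + 1L
    } else {
      if (pred[i] == positive) fp <- fp + 1L else tn <- tn + 1L
    }
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       accuracy = (tp + tn) / length(pred))
}

# A small, quick-to-simulate configuration reused by several tests.
small_config <- function(...) {
  sim_config(plane_shape = c(48L, 48L), ...)
}

# Configuration with a wide class separation for recovery runs.
separated_config <- function(seed = 11L, ...) {
  sim_config(seed = seed, class_effect = c(III = 0, IV = -6), ...)
}
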