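# The ten per-group summary statistics used as classifier predictors.

#' Ten summary statistics for one voxel group
#'
#' Computes the predictor set used by the group-level classifiers:
#' arithmetic, geometric and harmonic means, range, standard deviation,
#' quartile (interquartile range by default), skewness, kurtosis, variance,
#' and sum. Conventions follow the SPSS defaults under which the modelled
#' analysis was run: sample SD/variance with the n-1 denominator,
#' bias-adjusted skewness `G1` and excess kurtosis `G2` with the
#' small-sample correction, and linearly interpolated quantiles
#' (weighted-average definition, R quantile type 6).
#'
#' For a constant group, skewness and kurtosis are undefined; they are
#' returned as 0 and the result carries attribute `degenerate = TRUE`.
#' Geometric and harmonic means require strictly positive values; with any
#' nonpositive value they are returned as `NA` (flagged missing, never
#' silently dropped).
#'
#' @param x numeric vector of R2* values (one voxel group), or a
#'   `voxel_group_set` row passed via [feature_matrix()].
#' @param quartile `"iqr"` (Q3 - Q1, default), `"q1"` or `"q3"`: which
#'   single quartile-based number fills the `quartile` slot.
#' @param moments `"spss"` (bias-adjusted G1/G2, default) or `"moment"`
#'   (plain g1 and excess g2).
#' @param quantile_type passed to [stats::quantile()] (default 6, the
#'   SPSS weighted-average definition).
#'
#' @return Named numeric vector of length 10: `arithmetic_mean`,
#'   `geometric_mean`, `harmonic_mean`, `range`, `standard_deviation`,
#'   `quartile`, `skewness`, `kurtosis`, `variance`, `sum`.
#' @export
#' @examples
#' compute_features(c(1, 2, 4))[c("arithmetic_mean", "geometric_mean",
#'                                "harmonic_mean", "range", "sum")]
compute_features <- function(x, quartile = c("iqr", "q1", "q3"),
                             moments = c("spss", "moment"),
                             quantile_type = 6) {
  quartile <- match.arg(quartile)
  moments <- match.arg(moments)
  x <- as.numeric(x)
  n <- length(x)
  if (n == 0L || !all(is.finite(x))) {
    stop("`x` must be a nonempty vector of finite values", call. = FALSE)
  }
  am <- mean(x)
  gm <- if (all(x > 0)) exp(mean(log(x))) else NA_real_
  hm <- if (all(x > 0)) n / sum(1 / x) else NA_real_
  rg <- max(x) - min(x)
  s2 <- if (n > 1) var(x) else 0
  s <- sqrt(s2)
  qs <- quantile(x, c(0.25, 0.75), type = quantile_type, names = FALSE)
  qt <- switch(quartile, iqr = qs[2] - qs[1], q1 = qs[1], q3 = qs[2])
  degenerate <- s == 0 || n < 3
  if (degenerate) {
    sk <- 0
    ku <- 0
  } else {
    z <- (x - am) / s
    if (moments == "spss") {
      sk <- n / ((n - 1) * (n - 2)) * sum(z^3)
      ku <- if (n > 3) {
        n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) * sum(z^4) -
          3 * (n - 1)^2 / ((n - 2) * (n - 3))
      } else 0
    } else {
      m2 <- mean((x - am)^2); m3 <- mean((x - am)^3); m4 <- mean((x - am)^4)
      sk <- m3 / m2^1.5
      ku <- m4 / m2^2 - 3
    }
  }
  out <- c(arithmetic_mean = am, geometric_mean = gm, harmonic_mean = hm,
           range = rg, standard_deviation = s, quartile = unname(qt),
           skewness = sk, kurtosis = ku, variance = s2, sum = sum(x))
  if (degenerate) attr(out, "degenerate") <- TRUE
  out
}

#' Feature matrix for a set of voxel groups
#'
#' Applies [compute_features()] to every group and returns one row per
#' group, optionally tagged with patient/plane/label metadata columns for
#' downstream training.
#'
#' @param groups a `voxel_group_set` from [sample_voxel_groups()], or a
#'   numeric matrix with one group per row.
#' @param patient_id,plane,label optional scalars (or vectors of length
#'   `n_groups`) prepended as metadata columns.
#' @inheritParams compute_features
#' @return A `data.frame` with the metadata columns (if given) and the ten
#'   feature columns.
#' @export
feature_matrix <- function(groups, patient_id = NULL, plane = NULL,
                           label = NULL, quartile = "iqr", moments = "spss",
                           quantile_type = 6) {
  vals <- if (inherits(groups, "voxel_group_set")) groups$values else groups
  stopifnot(is.matrix(vals))
  feats <- t(apply(vals, 1, compute_features, quartile = quartile,
                   moments = moments, quantile_type = quantile_type))
  out <- as.data.frame(feats)
  meta <- list(label = label, plane = plane, patient_id = patient_id)
  for (nm in names(meta)) {
    if (!is.null(meta[[nm]])) out <- cbind(setNames(data.frame(meta[[nm]]), nm), out)
  }
  out
}

# Canonical predictor order of the published models.
published_predictors <- function() {
  c("harmonic_mean", "kurtosis", "range", "skewness", "standard_deviation")
}
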