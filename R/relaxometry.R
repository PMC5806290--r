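# Voxelwise R2* estimation from multi-echo magnitude data.

#' Multi-echo magnitude series
#'
#' Container for one coronal plane of multi-echo gradient-echo magnitudes:
#' a rows x cols x echoes array plus the echo-time vector.
#'
#' @param signal numeric array `rows x cols x E` of nonnegative magnitudes
#'   (a rows x cols matrix is promoted to a single echo only if `te_ms` has
#'   length 1, which is rejected anyway: at least two echoes are required).
#' @param te_ms echo times in milliseconds, strictly increasing, length `E`.
#' @return An object of class `echo_series`.
#' @export
echo_series <- function(signal, te_ms) {
  te_ms <- as.numeric(te_ms)
  if (length(dim(signal)) != 3L) {
    stop("`signal` must be a rows x cols x echoes array", call. = FALSE)
  }
  if (length(te_ms) != dim(signal)[3]) {
    stop("length(te_ms) must equal the number of echoes", call. = FALSE)
  }
  if (length(te_ms) < 2L || any(te_ms <= 0) || any(diff(te_ms) <= 0)) {
    stop("`te_ms` must be >= 2 strictly increasing positive echo times",
         call. = FALSE)
  }
  if (!all(is.finite(signal)) || any(signal < 0)) {
    stop("`signal` must be finite and nonnegative", call. = FALSE)
  }
  structure(list(signal = signal, te_ms = te_ms), class = "echo_series")
}

#' @export
print.echo_series <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("echo_series: %d x %d plane, %d echoes (TE %.1f-%.1f ms)\n",
              d[1], d[2], d[3], min(x$te_ms), max(x$te_ms)))
  invisible(x)
}

.new_r2star_map <- function(values, valid, s0, resid_norm, te_ms,
                            method = "loglinear", refined = NULL) {
  structure(list(values = values, valid = valid, s0 = s0,
                 resid_norm = resid_norm, te_ms = te_ms, method = method,
                 refined = refined,
                 nonphysiological = valid & values < 0),
            class = "r2star_map")
}

#' @export
print.r2star_map <- function(x, ...) {
  v <- x$values[x$valid]
  cat(sprintf("r2star_map (%s): %d x %d, %d valid voxels, median %.2f s^-1\n",
              x$method, nrow(x$values), ncol(x$values), sum(x$valid),
              if (length(v)) median(v) else NA_real_))
  invisible(x)
}

#' Log-linear voxelwise R2* fit
#'
#' Fits the monoexponential decay `S(TE) = S0 * exp(-TE * R2*)` at each voxel
#' by ordinary least squares of `log(S)` on TE (converted ms -> s); R2* is
#' the negated slope. Echoes at or below `min_signal` are excluded from a
#' voxel's fit; a voxel needs at least two usable echoes to be valid.
#' Negative fitted R2* values are retained but flagged in
#' `$nonphysiological`. Deterministic and closed-form.
#'
#' @param series an [echo_series()].
#' @param min_signal magnitude floor below which an echo is treated as noise
#'   and dropped from the log fit; default `1e-6 * max(signal)`.
#' @param mask optional logical matrix restricting the fit to a region of
#'   interest; voxels outside are invalid.
#'
#' @return An object of class `r2star_map` with `values` (s^-1), `valid`,
#'   `s0`, and the per-voxel residual norm in signal space (`resid_norm`).
#' @export
#' @examples
#' cfg <- sim_config(plane_shape = c(48, 48), noise_sd = 0)
#' pl <- simulate_r2star_plane(cfg, "III", "pure", seed = 1)
#' es <- simulate_multiecho(pl$r2star, cfg)
#' fit <- fit_r2star_loglinear(es, mask = pl$mask)
#' max(abs(fit$values[pl$mask] - pl$r2star[pl$mask]))
fit_r2star_loglinear <- function(series, min_signal = NULL, mask = NULL) {
  stopifnot(inherits(series, "echo_series"))
  d <- dim(series$signal)
  n_vox <- d[1] * d[2]
  E <- d[3]
  S <- matrix(series$signal, n_vox, E)
  if (is.null(min_signal)) min_signal <- 1e-6 * max(S)
  te <- series$te_ms / 1000
  usable <- S > min_signal
  if (!is.null(mask)) usable <- usable & as.vector(mask)
  W <- usable * 1
  nu <- rowSums(W)
  Y <- suppressWarnings(log(S))
  Y[!usable] <- 0
  te_mat <- matrix(te, n_vox, E, byrow = TRUE)
  # per-voxel weighted OLS of log-signal on TE
  sw_t <- rowSums(W * te_mat)
  sw_y <- rowSums(W * Y)
  mt <- ifelse(nu > 0, sw_t / pmax(nu, 1), 0)
  my <- ifelse(nu > 0, sw_y / pmax(nu, 1), 0)
  sxx <- rowSums(W * (te_mat - mt)^2)
  sxy <- rowSums(W * (te_mat - mt) * (Y - my))
  valid <- nu >= 2 & sxx > 0
  slope <- ifelse(valid, sxy / ifelse(sxx > 0, sxx, 1), NA_real_)
  r2 <- -slope
  s0 <- ifelse(valid, exp(my - slope * mt), NA_real_)
  pred <- s0 * exp(-r2 * te_mat)
  res2 <- rowSums(W * (S - pred)^2)
  resid_norm <- ifelse(valid, sqrt(res2), NA_real_)
  .new_r2star_map(
    values = matrix(r2, d[1], d[2]),
    valid = matrix(valid, d[1], d[2]),
    s0 = matrix(s0, d[1], d[2]),
    resid_norm = matrix(resid_norm, d[1], d[2]),
    te_ms = series$te_ms
  )
}

#' Nonlinear per-voxel refinement of an R2* map
#'
#' Refines a log-linear fit by Levenberg-Marquardt least squares of the
#' monoexponential model directly in signal space (which weights early, less
#' noisy echoes more faithfully than the log transform). Every voxel keeps
#' whichever of (initial estimate, refined estimate) has the smaller
#' signal-space residual norm, so the result is never worse than the
#' initialisation; voxels where the optimiser fails keep the initial value
#' and are flagged in `$refined`.
#'
#' @param series an [echo_series()].
#' @param init an `r2star_map` from [fit_r2star_loglinear()] used as the
#'   starting point; its validity mask is inherited.
#' @param max_iter maximum Levenberg-Marquardt iterations per voxel.
#' @return An `r2star_map` with `method = "nonlinear"` and a logical
#'   `refined` matrix (`TRUE` where the refit was accepted).
#' @export
fit_r2star_nonlinear <- function(series, init, max_iter = 50L) {
  stopifnot(inherits(series, "echo_series"), inherits(init, "r2star_map"))
  d <- dim(series$signal)
  S <- matrix(series$signal, d[1] * d[2], d[3])
  te <- series$te_ms / 1000
  values <- init$values; s0 <- init$s0
  resid_norm <- init$resid_norm
  refined <- matrix(FALSE, d[1], d[2])
  idx <- which(init$valid)
  for (v in idx) {
    y <- S[v, ]
    start <- c(s0 = init$s0[v], r2 = init$values[v])
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = start,
        fn = function(p) y - p[1] * exp(-p[2] * te),
        control = minpack.lm::nls.lm.control(maxiter = max_iter)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rn <- sqrt(sum(fit$fvec^2))
    if (is.finite(rn) && rn <= resid_norm[v] + 1e-12) {
      values[v] <- fit$par[["r2"]]
      s0[v] <- fit$par[["s0"]]
      resid_norm[v] <- rn
      refined[v] <- TRUE
    }
  }
  .new_r2star_map(values, init$valid, s0, resid_norm, series$te_ms,
                  method = "nonlinear", refined = refined)
}
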