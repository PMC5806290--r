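#' Configuration for the synthetic lupus-nephritis cohort
#'
#' Bundles every knob of the synthetic-data generator: cohort composition,
#' plane geometry, the cortex/medulla R2* distributions, class-conditional
#' shifts, and the forward multi-echo signal model. Defaults describe a
#' twelve-patient cohort mirroring the modelled study design (5 class III of
#' which 3 carry a superimposed membranous "+V" lesion, 7 class IV of which
#' 4 are "+V"), imaged with an 8-echo gradient-echo readout.
#'
#' @param n_patients_per_class named integer vector with entries `III`,
#'   `III_V`, `IV`, `IV_V`: patients per (class, subclass) cell.
#' @param plane_shape integer vector `c(rows, cols)` of each coronal plane.
#' @param planes_per_patient number of coronal planes simulated per patient;
#'   3 planes x 100 groups reproduce the 300-group-per-patient vote count.
#' @param cortex_mean,cortex_sd normal R2* distribution in the cortical band
#'   (s^-1). Cortical R2* near 18 s^-1 is typical at 3 T.
#' @param medulla_gamma_shape,medulla_gamma_scale shape and scale
#'   (s^-1) of the gamma-distributed medullary R2*; defaults give mean
#'   shape*scale = 28 s^-1 and a visibly right-skewed distribution.
#' @param medulla_frac fraction of the kidney ellipse radius occupied by the
#'   medullary core; `0` removes the medulla entirely (cortex-only phantom).
#' @param collecting_frac fraction of the radius occupied by the central
#'   collecting-system region, which is excluded from the ROI mask; `0`
#'   disables it.
#' @param gradient_amp amplitude (s^-1) of the smooth radial corticomedullary
#'   gradient added on top of the band distributions, so R2* rises gradually
#'   from the outer cortex toward the deepest medulla; `0` disables it.
#' @param class_effect named vector `c(III = , IV = )`: additive R2* shift
#'   (s^-1) applied to the whole kidney by primary class. The default lowers
#'   class IV by 3 s^-1, the direction reported for more proliferative
#'   disease; the magnitude is a simulation choice.
#' @param subclass_effect named vector `c(pure = , plus_V = )`: additive
#'   shift (s^-1) for the membranous subclass.
#' @param s0 baseline (TE = 0) signal, arbitrary units.
#' @param noise_sd standard deviation of the additive Gaussian noise on echo
#'   magnitudes, in signal units; magnitudes are rectified to be nonnegative.
#' @param te_ms echo times in milliseconds, strictly increasing; the default
#'   is the 8-echo readout 2.4, 6.2, 10.0, 13.8, 17.6, 21.4, 25.2, 29.0 ms.
#' @param seed integer master seed; every stage derives child seeds from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [generate_cohort()], [simulate_r2star_plane()],
#'   [simulate_multiecho()]
#' @export
#' @examples
#' cfg <- sim_config(plane_shape = c(48, 48), seed = 7)
#' cfg$te_ms
sim_config <- function(n_patients_per_class = c(III = 2L, III_V = 3L, IV = 3L, IV_V = 4L),
                       plane_shape = c(64L, 64L),
                       planes_per_patient = 3L,
                       cortex_mean = 18, cortex_sd = 2,
                       medulla_gamma_shape = 16, medulla_gamma_scale = 1.75,
                       medulla_frac = 0.62, collecting_frac = 0.15,
                       gradient_amp = 3,
                       class_effect = c(III = 0, IV = -3),
                       subclass_effect = c(pure = 0, plus_V = -1.5),
                       s0 = 1000, noise_sd = 5,
                       te_ms = c(2.4, 6.2, 10.0, 13.8, 17.6, 21.4, 25.2, 29.0),
                       seed = 1L) {
  cells <- c("III", "III_V", "IV", "IV_V")
  if (is.null(names(n_patients_per_class)) ||
      !all(cells %in% names(n_patients_per_class))) {
    stop("`n_patients_per_class` needs named entries III, III_V, IV, IV_V",
         call. = FALSE)
  }
  n_patients_per_class <- as.integer(n_patients_per_class[cells])
  if (any(n_patients_per_class < 0) || sum(n_patients_per_class) < 1) {
    stop("`n_patients_per_class` must be nonnegative with at least one patient",
         call. = FALSE)
  }
  plane_shape <- as.integer(plane_shape)
  if (length(plane_shape) != 2L || any(plane_shape < 8L)) {
    stop("`plane_shape` must be c(rows, cols) with both >= 8", call. = FALSE)
  }
  stopifnot_scalar_number(cortex_mean, "cortex_mean", positive = TRUE)
  stopifnot_scalar_number(cortex_sd, "cortex_sd")
  if (cortex_sd < 0) stop("`cortex_sd` must be >= 0", call. = FALSE)
  stopifnot_scalar_number(medulla_gamma_shape, "medulla_gamma_shape", positive = TRUE)
  stopifnot_scalar_number(medulla_gamma_scale, "medulla_gamma_scale", positive = TRUE)
  stopifnot_scalar_number(s0, "s0", positive = TRUE)
  stopifnot_scalar_number(noise_sd, "noise_sd")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (medulla_frac < 0 || medulla_frac >= 1) {
    stop("`medulla_frac` must lie in [0, 1)", call. = FALSE)
  }
  if (collecting_frac < 0 || collecting_frac >= max(medulla_frac, 0.5)) {
    stop("`collecting_frac` must be small relative to the kidney", call. = FALSE)
  }
  te_ms <- as.numeric(te_ms)
  if (length(te_ms) < 2L || any(te_ms <= 0) || any(diff(te_ms) <= 0)) {
    stop("`te_ms` must be >= 2 strictly increasing positive echo times",
         call. = FALSE)
  }
  if (!all(c("III", "IV") %in% names(class_effect))) {
    stop("`class_effect` needs entries named III and IV", call. = FALSE)
  }
  if (!all(c("pure", "plus_V") %in% names(subclass_effect))) {
    stop("`subclass_effect` needs entries named pure and plus_V", call. = FALSE)
  }
  structure(list(
    n_patients_per_class = n_patients_per_class,
    plane_shape = plane_shape,
    planes_per_patient = as.integer(planes_per_patient),
    cortex_mean = cortex_mean, cortex_sd = cortex_sd,
    medulla_gamma_shape = medulla_gamma_shape,
    medulla_gamma_scale = medulla_gamma_scale,
    medulla_frac = medulla_frac, collecting_frac = collecting_frac,
    gradient_amp = gradient_amp,
    class_effect = class_effect[c("III", "IV")],
    subclass_effect = subclass_effect[c("pure", "plus_V")],
    s0 = s0, noise_sd = noise_sd, te_ms = te_ms,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  n <- x$n_patients_per_class
  cat("Synthetic LN cohort configuration\n")
  cat(sprintf("  patients: %d (III %d, III+V %d, IV %d, IV+V %d)\n",
              sum(n), n[["III"]], n[["III_V"]], n[["IV"]], n[["IV_V"]]))
  cat(sprintf("  planes: %d x [%d x %d]; echoes: %d (%.1f-%.1f ms)\n",
              x$planes_per_patient, x$plane_shape[1], x$plane_shape[2],
              length(x$te_ms), min(x$te_ms), max(x$te_ms)))
  cat(sprintf("  cortex N(%.1f, %.1f); medulla Gamma(%.1f, %.2f) [mean %.1f s^-1]\n",
              x$cortex_mean, x$cortex_sd, x$medulla_gamma_shape,
              x$medulla_gamma_scale,
              x$medulla_gamma_shape * x$medulla_gamma_scale))
  cat(sprintf("  class effect IV %+.1f; +V %+.1f; s0 %.0f; noise sd %.1f; seed %d\n",
              x$class_effect[["IV"]], x$subclass_effect[["plus_V"]],
              x$s0, x$noise_sd, x$seed))
  invisible(x)
}
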