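test_that("config validation rejects degenerate inputs", {
  expect_error(sim_config(te_ms = c(5, 3, 1)), "strictly increasing")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(medulla_gamma_shape = 0), "positive")
  expect_error(sim_config(n_patients_per_class = c(a = 1)), "III")
  expect_error(simulate_r2star_plane(sim_config(plane_shape = c(8, 8)),
                                     "III", "pure"),
               "at least 100")
})

test_that("default echo times are the 8-echo readout", {
  cfg <- sim_config()
  expect_identical(cfg$te_ms, c(2.4, 6.2, 10.0, 13.8, 17.6, 21.4, 25.2, 29.0))
  pl <- simulate_r2star_plane(small_config(), "III", "pure", seed = 1)
  es <- simulate_multiecho(pl$r2star, small_config(), seed = 2)
  expect_identical(dim(es$signal)[3], 8L)
})

test_that("zero-variance cortex-only phantom is exactly constant", {
  cfg <- small_config(cortex_sd = 0, medulla_frac = 0, collecting_frac = 0,
                      gradient_amp = 0)
  pl <- simulate_r2star_plane(cfg, "IV", "pure", seed = 5)
  vals <- pl$r2star[pl$mask]
  expect_true(all(vals == cfg$cortex_mean + cfg$class_effect[["IV"]]))
})

test_that("medullary R2* follows the configured gamma law", {
  cfg <- sim_config(plane_shape = c(220L, 220L), gradient_amp = 0,
                    collecting_frac = 0, medulla_frac = 0.7)
  pl <- simulate_r2star_plane(cfg, "III", "pure", seed = 42)
  med <- pl$r2star[pl$mask & pl$radius <= cfg$medulla_frac]
  k <- cfg$medulla_gamma_shape; th <- cfg$medulla_gamma_scale
  n <- length(med)
  expect_gt(n, 5000)
  # law of large numbers: sample mean within 4 * theta * sqrt(k / n) of k*theta
  expect_lt(abs(mean(med) - k * th), 4 * th * sqrt(k / n))
  # right-skewed for moderate shape
  m3 <- mean((med - mean(med))^3)
  expect_gt(m3 / sd(med)^3, 0)
})

test_that("R2* rises from outer cortex to inner medulla", {
  cfg <- sim_config(plane_shape = c(128L, 128L),
                    class_effect = c(III = 0, IV = 0))
  # pool several planes so band means estimate the radial profile tightly
  u <- v <- numeric()
  for (s in 1:5) {
    pl <- simulate_r2star_plane(cfg, "III", "pure", seed = s)
    u <- c(u, pl$radius[pl$mask])
    v <- c(v, pl$r2star[pl$mask])
  }
  bands <- cut(u, breaks = c(cfg$collecting_frac, 0.4, cfg$medulla_frac,
                             0.8, 1.0001), include.lowest = TRUE)
  band_means <- tapply(v, bands, mean)
  # bands ordered inner -> outer, so means must strictly decrease outward
  expect_true(all(diff(band_means) < 0))
})

test_that("multi-echo forward model is exactly monoexponential when noiseless", {
  cfg <- small_config(noise_sd = 0, te_ms = c(10, 20, 30))
  truth0 <- matrix(0, 48, 48)
  es <- simulate_multiecho(truth0, cfg)
  expect_true(all(es$signal == cfg$s0))
  truth <- matrix(50, 48, 48)
  es2 <- simulate_multiecho(truth, cfg)
  expect_equal(es2$signal[1, 1, 2], 1000 * exp(-1), tolerance = 1e-12)
})

test_that("cohort generation is seed-deterministic with the study design", {
  cfg <- small_config(planes_per_patient = 1L, seed = 9L)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  expect_length(c1, 12L)
  cls <- vapply(c1, `[[`, "", "primary_class")
  sub <- vapply(c1, `[[`, "", "subclass")
  expect_identical(sum(cls == "III"), 5L)
  expect_identical(sum(cls == "IV"), 7L)
  expect_identical(sum(cls == "III" & sub == "plus_V"), 3L)
  expect_identical(sum(cls == "IV" & sub == "plus_V"), 4L)
  c3 <- generate_cohort(small_config(planes_per_patient = 1L, seed = 10L))
  expect_false(identical(c1[[1]]$planes[[1]]$r2star,
                         c3[[1]]$planes[[1]]$r2star))
})

test_that("noiseless cohort round-trips through the log-linear fit", {
  cfg <- small_config(noise_sd = 0, planes_per_patient = 1L, seed = 4L,
                      n_patients_per_class = c(III = 1, III_V = 0, IV = 1, IV_V = 0))
  coh <- generate_cohort(cfg)
  for (pat in coh) {
    pl <- pat$planes[[1]]
    fit <- fit_r2star_loglinear(pl$echoes, mask = pl$mask)
    err <- abs(fit$values[pl$mask] - pl$r2star[pl$mask])
    expect_lt(max(err), 1e-8)
  }
})
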