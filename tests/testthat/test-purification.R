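test_that("fractal structure factor matches the D=2 closed form", {
  # q -> 0 with xi ~ r0: S -> 1 + 2 (xi/r0)^2 = 3
  expect_equal(fractal_structure_factor(1e-9, 2, 40 + 1e-9, 40), 3,
               tolerance = 1e-6)
  # q xi = 1, xi = 100, r0 = 40: 1 + 2 * 6.25 / 2 = 7.25
  expect_equal(fractal_structure_factor(0.01, 2, 100, 40), 7.25,
               tolerance = 1e-12)
  # large-q limit
  expect_equal(fractal_structure_factor(1e3, 2, 300, 40), 1,
               tolerance = 1e-6)

  q <- exp(seq(log(1e-3), log(1), length.out = 200))
  S <- fractal_structure_factor(q, 2, 300, 40)
  closed <- 1 + 2 * (300 / 40)^2 / (1 + q^2 * 300^2)
  expect_equal(S, closed, tolerance = 1e-12)
  expect_true(all(S >= 1))
  expect_true(all(diff(S) < 0))

  expect_error(fractal_structure_factor(q, 1, 300, 40), "dimension")
  expect_error(fractal_structure_factor(q, 2, 30, 40))
})

test_that("composite fitting recovers a null aggregate and constant data", {
  fx <- make_two_state_fixture(n_frames = 20, seed = 3, n_q = 60)
  form <- ensemble_average_intensity(fx$M, fx$w_true, q_grid = fx$q)
  # noiseless aggregate-free data: the aggregate term must vanish and the
  # filtered curve must pass through unchanged
  clean <- gen_sans_dataset(fx$ts$ensemble, fx$w_true, aggregate = NULL,
                            background = 20, noise = NULL,
                            q_grid = fx$q)
  fit <- suppressWarnings(fit_composite(clean, form))
  expect_lt(fit$aggregate$c_a, 1e-6 * fit$c_tet)
  filt <- subtract_aggregate(clean, fit)
  expect_equal(filt$I, clean$I, tolerance = 1e-6)

  flat <- scattering_curve(fx$q, rep(7, 60), sigma = rep(0.07, 60))
  ffit <- suppressWarnings(fit_composite(flat, form))
  expect_equal(ffit$background, 7, tolerance = 0.05)
  expect_lt(abs(ffit$c_tet), 1e-4)
  expect_lt(abs(ffit$aggregate$c_a), 1e-4)
})

test_that("composite fitting recovers known contamination parameters", {
  fx <- make_two_state_fixture(n_frames = 40, seed = 3, n_q = 60)
  form <- ensemble_average_intensity(fx$M, fx$w_true, q_grid = fx$q)
  agg <- aggregate_params(c_a = 0.05, D = 2, xi = 300)  # r0 derived
  dat <- gen_sans_dataset(fx$ts$ensemble, fx$w_true, aggregate = agg,
                          background = 20, noise = noise_model(0.01),
                          q_grid = fx$q, seed = 14)
  fit <- fit_composite(dat, form)
  expect_equal(fit$c_tet, 1, tolerance = 0.1)
  expect_equal(fit$aggregate$c_a, 0.05, tolerance = 0.1)
  expect_equal(fit$aggregate$xi, 300, tolerance = 0.2)
  expect_equal(fit$background, 20, tolerance = 0.1)

  # filtered curve is statistically consistent with the clean truth
  filt <- subtract_aggregate(dat, fit)
  truth <- attr(dat, "truth")
  chi2r <- mean(((filt$I - truth$I) / dat$sigma)^2)
  expect_gt(chi2r, 0.5)
  expect_lt(chi2r, 1.6)

  # sigma and grid pass through the subtraction untouched
  expect_identical(filt$q, dat$q)
  expect_identical(filt$sigma, dat$sigma)

  # purification is idempotent: refitting finds no aggregate left
  refit <- suppressWarnings(fit_composite(filt, form))
  expect_lt(refit$aggregate$c_a, 0.02 * fit$aggregate$c_a +
              1e-3 * fit$c_tet)
})

test_that("IFT floor recovers sphere support and a calibrated chi-square", {
  dat <- sphere_curve(R = 40, seed = 4)
  ift <- ift_chi2_floor(dat, d_max_init = 100)
  # p(r) of a solid sphere ends at 2R
  supp <- max(ift$r[ift$p > 0.01 * max(ift$p)])
  expect_equal(supp, 80, tolerance = 0.1)
  expect_gt(ift$chi2_reduced_floor, 0.7)
  expect_lt(ift$chi2_reduced_floor, 1.3)

  # oversmoothing: forcing a huge alpha strictly worsens the fit
  over <- ift_chi2_floor(dat, d_max_init = ift$d_max, refine_dmax = FALSE,
                         alpha_grid = 1e12)
  expect_gt(over$chi2_reduced_floor, ift$chi2_reduced_floor)

  # too-small Dmax is flagged through p(r) pile-up
  expect_warning(ift_chi2_floor(dat, d_max_init = 45,
                                refine_dmax = FALSE), "pile")
})
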