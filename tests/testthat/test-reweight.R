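test_that("bias-to-weight conversion is Boltzmann and shift invariant", {
  tr <- bias_trace(c(1, 2, 3), c(5, 5, 5), kT = 2.686)
  expect_equal(bias_to_weights(tr), rep(1 / 3, 3))

  kT <- 2.686
  tr2 <- bias_trace(c(1, 2), c(kT * log(2), 0), kT = kT)
  expect_equal(bias_to_weights(tr2), c(2 / 3, 1 / 3), tolerance = 1e-12)

  v <- c(3.2, 8.9, 0.4)
  w_a <- bias_to_weights(bias_trace(1:3, v, kT))
  w_b <- bias_to_weights(bias_trace(1:3, v + 1e6, kT))
  expect_equal(w_a, w_b, tolerance = 1e-9)

  expect_error(bias_trace(1:2, c(1, Inf), kT))
})

test_that("Kish effective sample fraction follows its closed form", {
  w0 <- rep(0.25, 4)
  expect_equal(kish_phi_eff(w0, w0), 1)
  expect_equal(kish_phi_eff(c(1, 0, 0, 0), w0), 0.25, tolerance = 1e-12)

  # direct evaluation oracle, arithmetic done independently here
  w <- c(0.5, 0.25, 0.25); p <- rep(1 / 3, 3)
  s_direct <- -(0.5 * log(0.5 / (1 / 3)) + 0.25 * log(0.25 / (1 / 3)) +
                  0.25 * log(0.25 / (1 / 3)))
  expect_equal(kish_phi_eff(w, p), exp(s_direct), tolerance = 1e-12)

  expect_error(kish_phi_eff(c(0.5, 0.5), c(1, 0)), "zero prior")
})

test_that("BME limits: prior-dominated theta and self-consistent data", {
  fx <- make_two_state_fixture(n_frames = 30, seed = 9, n_q = 30)
  # huge theta: posterior stays at the prior
  res <- suppressWarnings(
    bme_optimize(fx$M, fx$dat, fx$w0, theta = 1e9, q_grid = fx$q))
  expect_equal(res$weights, fx$w0, tolerance = 1e-6)
  expect_equal(res$s_rel, 0, tolerance = 1e-9)
  expect_equal(res$phi_eff, 1, tolerance = 1e-9)

  # data generated exactly from the prior average: nothing to correct
  avg0 <- ensemble_average_intensity(fx$M, fx$w0, q_grid = fx$q)
  self_dat <- scattering_curve(fx$q, avg0$I, sigma = 0.01 * avg0$I)
  res2 <- suppressWarnings(
    bme_optimize(fx$M, self_dat, fx$w0, theta = 1, q_grid = fx$q))
  expect_equal(res2$chi2_reduced, 0, tolerance = 1e-6)
  expect_equal(res2$weights, fx$w0, tolerance = 1e-4)

  # weighted mean Rg is untouched by a no-information reweighting
  rg0 <- weighted_rg_distribution(fx$ts$ensemble, fx$w0)$weighted_mean
  rg1 <- weighted_rg_distribution(fx$ts$ensemble,
                                  res2$weights)$weighted_mean
  expect_lt(abs(rg1 - rg0), 0.1)

  bad <- fx$dat; bad$sigma[1] <- 0
  expect_error(bme_optimize(fx$M, bad, fx$w0, theta = 1, q_grid = fx$q))
})

test_that("two-state generator truth is recovered at the scan-selected theta", {
  fx <- make_two_state_fixture(n_frames = 100, seed = 104, n_q = 40)
  grid <- 10^seq(-2, 3, length.out = 11)
  scan <- suppressWarnings(
    theta_scan(fx$M, fx$dat, fx$w0, theta_grid = grid, q_grid = fx$q))
  chi <- vapply(scan, `[[`, numeric(1), "chi2_reduced")
  srel <- vapply(scan, `[[`, numeric(1), "s_rel")

  # monotone trade-off along the scan (grid is ascending in theta)
  expect_true(all(diff(chi) >= -1e-6))
  expect_true(all(diff(srel) >= -1e-8))

  sel <- select_theta(scan)
  expect_lte(sel$result$chi2_reduced, 1.5)
  frac <- splayed_fraction(fx$ts$ensemble, sel$result$weights,
                           fx$ts$cv_cutoff)
  expect_equal(frac, 0.5, tolerance = 0.1)

  # floor reporting: smallest theta whose chi2r reaches the floor
  self <- select_theta(scan, chi2_floor = max(chi))
  expect_equal(self$theta_at_floor, min(grid))
  expect_equal(select_theta(scan[5])$theta, grid[5])
})

test_that("posterior weights stay positive, normalized, and cutoff-consistent", {
  fx <- make_two_state_fixture(n_frames = 50, seed = 17, n_q = 30)
  res <- suppressWarnings(
    bme_optimize(fx$M, fx$dat, fx$w0, theta = 0.5, q_grid = fx$q))
  expect_true(all(res$weights > 0))
  expect_equal(sum(res$weights), 1, tolerance = 1e-9)

  cv <- fx$ts$ensemble$cv
  expect_equal(splayed_fraction(fx$ts$ensemble, rep(1, 50),
                                max(cv) - 1e-9),
               mean(cv > max(cv) - 1e-9))
  below <- suppressWarnings(
    splayed_fraction(fx$ts$ensemble, fx$w0, max(cv) + 1))
  expect_equal(below, 0)
  half <- splayed_fraction(fx$ts$ensemble, fx$w0, stats::median(cv))
  expect_equal(half, 0.5, tolerance = 0.05)
})
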