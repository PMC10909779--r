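test_that("Debye intensity matches limits and the brute-force oracle", {
  two <- bead_conformation(rbind(c(0, 0, 0), c(5, 0, 0)))
  cur <- debye_intensity(two, c(1e-8, pi / 5, 1))
  expect_equal(cur$I[1], 4, tolerance = 1e-10)     # (sum b)^2 at q -> 0
  expect_equal(cur$I[2], 2, tolerance = 1e-10)     # q d = pi: self terms

  set.seed(31)
  coords <- matrix(rnorm(30 * 3, sd = 15), ncol = 3)
  b <- runif(30, 0.5, 2)
  conf <- bead_conformation(coords, b)
  q <- default_q_grid(15)
  ref <- debye_brute_force(coords, b, q)
  expect_equal(debye_intensity(conf, q)$I, ref, tolerance = 1e-10)

  expect_error(debye_intensity(conf, numeric(0)), "empty")
})

test_that("Debye intensity is rotation and translation invariant", {
  set.seed(12)
  coords <- matrix(rnorm(40 * 3, sd = 10), ncol = 3)
  conf <- bead_conformation(coords)
  q <- default_q_grid(20)
  I0 <- debye_intensity(conf, q)$I
  th <- 0.7
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- bead_conformation(coords %*% Rz + 100)
  expect_equal(debye_intensity(moved, q)$I / I0, rep(1, 20),
               tolerance = 1e-10)
})

test_that("forward scattering bounds and Guinier consistency hold", {
  conf <- gen_toy_tetramer(toy_tetramer_spec(splay = 10, seed = 3))
  q <- c(0, default_q_grid(40))
  I <- debye_intensity(conf, q)$I
  expect_true(all(I <= I[1] + 1e-9))

  cur <- debye_intensity(conf, default_q_grid(60, 0.002, 0.1))
  rg_guinier <- ntdsplay:::guinier_rg(cur)
  expect_equal(rg_guinier, radius_of_gyration(conf), tolerance = 0.03)
})

test_that("distance-histogram Debye agrees with the exact sum", {
  conf <- gen_toy_tetramer(toy_tetramer_spec(splay = 20, seed = 9))
  q <- default_q_grid(30, 0.005, 0.5)
  exact <- debye_intensity(conf, q)$I
  approx <- debye_intensity(conf, q, method = "histogram")$I
  expect_lt(max(abs(approx / exact - 1)), 0.005)
})

test_that("radius of gyration follows closed-form cases", {
  expect_equal(radius_of_gyration(
    bead_conformation(rbind(c(-3, 0, 0), c(3, 0, 0)))), 3)
  expect_equal(radius_of_gyration(bead_conformation(rbind(c(1, 2, 3)))), 0)

  # thin spherical shell: Rg -> R
  set.seed(5)
  u <- matrix(rnorm(3000), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * 25
  expect_equal(radius_of_gyration(bead_conformation(u)), 25,
               tolerance = 0.02)

  expect_error(radius_of_gyration(
    bead_conformation(rbind(c(0, 0, 0), c(1, 0, 0)), c(0, 0))), "zero")
})

test_that("ensemble averaging is the pointwise weighted mean", {
  q <- default_q_grid(10)
  c1 <- debye_intensity(gen_toy_tetramer(toy_tetramer_spec(seed = 1)), q)
  c2 <- debye_intensity(
    gen_toy_tetramer(toy_tetramer_spec(splay = 25, seed = 1)), q)
  expect_equal(ensemble_average_intensity(list(c1), 1)$I, c1$I)
  expect_equal(ensemble_average_intensity(list(c1, c1), c(0.3, 0.7))$I,
               c1$I)
  avg <- ensemble_average_intensity(list(c1, c2), c(0.25, 0.75))
  expect_equal(avg$I, 0.25 * c1$I + 0.75 * c2$I, tolerance = 1e-12)
  expect_error(ensemble_average_intensity(list(c1, c2), c(-1, 2)),
               "negative")
})

test_that("scale/background fitting is exact on linear data and calibrated on noise", {
  q <- default_q_grid(200)
  conf <- gen_toy_tetramer(toy_tetramer_spec(seed = 2))
  model <- debye_intensity(conf, q)
  data <- scattering_curve(q, 3 * model$I + 5, sigma = rep(1, 200))
  fit <- fit_scale_background(model, data)
  expect_equal(fit$scale, 3, tolerance = 1e-10)
  expect_equal(fit$background, 5, tolerance = 1e-8)
  expect_equal(fit$chi2_reduced, 0, tolerance = 1e-15)

  noisy <- scattering_curve(
    q, ntdsplay:::with_seed(8, model$I + rnorm(200)),
    sigma = rep(1, 200))
  expect_equal(fit_scale_background(model, noisy)$chi2_reduced, 1,
               tolerance = 0.3)

  flat <- scattering_curve(q, rep(2, 200), computed = TRUE)
  expect_error(fit_scale_background(flat, data), "degenerate")
  expect_error(scattering_curve(q, model$I, sigma = rep(0, 200)))
})

test_that("weighted Rg distributions track the weights", {
  spec <- toy_tetramer_spec(seed = 6)
  fr_c <- gen_toy_tetramer(spec)
  fr_s <- gen_toy_tetramer(toy_tetramer_spec(splay = 30, seed = 6))
  ens <- conformational_ensemble(list(fr_c, fr_s), c(4, 7))

  d1 <- weighted_rg_distribution(ens, c(0.9, 0.1))
  d2 <- weighted_rg_distribution(ens, c(0.5, 0.5))
  expect_gt(d2$weighted_mean, d1$weighted_mean)
  expect_equal(sum(d1$density) * diff(d1$bin_edges[1:2]), 1,
               tolerance = 1e-9)

  same <- conformational_ensemble(list(fr_c, fr_c), c(4, 4))
  ds <- weighted_rg_distribution(same, c(0.4, 0.6))
  expect_equal(sum(ds$density > 0), 1)
  expect_equal(ds$weighted_mean, radius_of_gyration(fr_c))

  du <- weighted_rg_distribution(ens, c(0.5, 0.5))
  dh <- weighted_rg_distribution(ens, c(1, 1))
  expect_equal(du$density, dh$density)
})
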