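test_that("toy tetramer construction is deterministic and splay-exact", {
  s <- toy_tetramer_spec(splay = 0, seed = 42)
  expect_identical(gen_toy_tetramer(s)$coords, gen_toy_tetramer(s)$coords)

  c0 <- gen_toy_tetramer(toy_tetramer_spec(splay = 0, seed = 42))
  c20 <- gen_toy_tetramer(toy_tetramer_spec(splay = 20, seed = 42))
  expect_equal(ntd_distance(c20) - ntd_distance(c0), 20, tolerance = 1e-12)

  # splaying swells the particle: Rg strictly increases
  c30 <- gen_toy_tetramer(toy_tetramer_spec(splay = 30, seed = 42))
  expect_gt(radius_of_gyration(c30), radius_of_gyration(c0))

  expect_error(toy_tetramer_spec(n_beads_per_subunit = 0))
  expect_error(toy_tetramer_spec(subunit_radius = -1))
  expect_error(toy_tetramer_spec(splay = -5))
})

test_that("unbiased ensemble sampling reproduces the Boltzmann density", {
  kappa <- 50
  ps <- pmf_spec("harmonic", list(kappa = kappa, x0 = 6))
  spec <- toy_tetramer_spec(seed = 7)
  res <- gen_ensemble(spec, 50000, ps, range = c(4.5, 7.5), seed = 3)
  # analytic Gaussian: var = kT / kappa
  expect_equal(var(res$ensemble$cv), ps$kT / kappa, tolerance = 0.1)

  # Kolmogorov-Smirnov distance against the analytic CDF
  ks <- suppressWarnings(stats::ks.test(
    res$ensemble$cv, "pnorm", mean = 6, sd = sqrt(ps$kT / kappa)))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("a perfectly flattening bias yields uniform splay sampling", {
  ps <- pmf_spec("double_well",
                 list(x1 = 4.5, x2 = 6.5, barrier = 6), kT = 2.686)
  spec <- toy_tetramer_spec()
  res <- gen_ensemble(spec, 20000, ps,
                      bias = function(x) -pmf_energy(ps, x),
                      range = c(4.2, 6.8), seed = 11, thin = 20)
  h <- hist(res$ensemble$cv, breaks = seq(4.2, 6.8, length.out = 21),
            plot = FALSE)
  expect_gt(stats::chisq.test(h$counts)$p.value, 0.001)
})

test_that("minimal and invalid ensemble requests behave as specified", {
  ps <- pmf_spec("harmonic", list(kappa = 50, x0 = 5))
  res <- gen_ensemble(toy_tetramer_spec(), 2, ps, range = c(4, 6))
  expect_length(res$ensemble$frames, 2)
  expect_null(res$ensemble$weights)
  expect_error(gen_ensemble(toy_tetramer_spec(), 1, ps))
  expect_error(
    gen_ensemble(toy_tetramer_spec(), 10,
                 pmf_spec("harmonic"), bias = function(x) x * NA,
                 range = c(4, 6)),
    "non-finite")
})

test_that("synthetic SANS curves equal the weighted Debye average when clean", {
  fx <- make_two_state_fixture(n_frames = 12, seed = 5, n_q = 20)
  clean <- gen_sans_dataset(fx$ts$ensemble, fx$w_true, aggregate = NULL,
                            background = 0, noise = NULL, q_grid = fx$q)
  avg <- ensemble_average_intensity(attr(clean, "frame_curves"),
                                    fx$w_true, q_grid = fx$q)
  expect_equal(clean$I, avg$I, tolerance = 1e-12)

  # determinism of the noise realization
  a <- gen_sans_dataset(fx$ts$ensemble, fx$w_true, q_grid = fx$q, seed = 9)
  b <- gen_sans_dataset(fx$ts$ensemble, fx$w_true, q_grid = fx$q, seed = 9)
  expect_identical(a$I, b$I)

  expect_error(gen_sans_dataset(fx$ts$ensemble, fx$w_true[-1],
                                q_grid = fx$q), "mismatch")
})

test_that("aggregate contamination raises the low-q intensity", {
  fx <- make_two_state_fixture(n_frames = 12, seed = 5, n_q = 20)
  agg <- aggregate_params(c_a = 0.05, D = 2, xi = 300, r0 = 40)
  with_agg <- gen_sans_dataset(fx$ts$ensemble, fx$w_true, aggregate = agg,
                               noise = NULL, q_grid = fx$q)
  without <- gen_sans_dataset(fx$ts$ensemble, fx$w_true, aggregate = NULL,
                              noise = NULL, q_grid = fx$q)
  expect_gt(with_agg$I[1], without$I[1])
})

test_that("SANS noise is consistent with the attached sigma column", {
  fx <- make_two_state_fixture(n_frames = 8, seed = 2, n_q = 60)
  # pool z-scores over several independent noise realizations
  z <- unlist(lapply(1:5, function(sd) {
    dat <- gen_sans_dataset(fx$ts$ensemble, fx$w_true, q_grid = fx$q,
                            seed = sd)
    (dat$I - attr(dat, "truth")$I) / dat$sigma
  }))
  n <- length(z)
  expect_lt(abs(mean(z)), 3 / sqrt(n))
  expect_lt(abs(var(z) - 1), 3 * sqrt(2 / n))
})

test_that("umbrella window generation matches the harmonic oracle", {
  flat <- pmf_spec("square_well", list(x1 = 0, x2 = 0, depth = 0))
  k <- 1000
  wins <- gen_umbrella_windows(flat, c(1, 2, 3), k = k,
                               n_per_window = 4000, seed = 6)
  for (w in wins) {
    sem <- stats::sd(w$samples) / sqrt(length(w$samples))
    # 3 SEM band, inflated for Metropolis autocorrelation
    expect_lt(abs(mean(w$samples) - w$center), 3 * sem * 3)
    expect_equal(var(w$samples), flat$kT / k, tolerance = 0.15)
  }

  single <- gen_umbrella_windows(flat, c(1, 2), k = k, n_per_window = 1)
  expect_length(single[[1]]$samples, 1)

  expect_error(gen_umbrella_windows(flat, c(1, 2), k = k,
                                    support = c(1.5, 3)), "outside")
})

test_that("a window on a barrier top is broader than one in a well", {
  dw <- pmf_spec("double_well", list(x1 = 1, x2 = 3, barrier = 8))
  k <- 200   # soft enough that the local curvature matters
  wins <- gen_umbrella_windows(dw, c(1, 2), k = k, n_per_window = 8000,
                               seed = 8, support = c(0.3, 3.7))
  v_well <- var(wins[[1]]$samples)
  v_barrier <- var(wins[[2]]$samples)
  expect_gt(v_barrier, v_well)
})

test_that("current traces and recovery series follow their closed forms", {
  tr <- gen_current_trace(cbind(1, 10), duration = 50, dt = 0.5)
  expect_equal(tr$i[tr$t == 10], exp(-1), tolerance = 1e-12)

  tr2 <- gen_current_trace(cbind(c(2, 1), c(3, 9)), duration = 50,
                           dt = 0.5)
  expect_equal(tr2$i[tr2$t == 0], 3, tolerance = 1e-12)

  rec <- gen_recovery_series(17, c(5, 17, 50))
  expect_equal(rec$peak_ratios[2], 1 - exp(-1), tolerance = 1e-12)

  expect_error(gen_current_trace(cbind(1, 10), dt = 0), "dt")
  expect_error(gen_recovery_series(-1, c(1, 2)))

  # clipping keeps noisy ratios within [0, 1.05]
  noisy <- gen_recovery_series(17, c(1, 200, 400, 800), noise_sd = 0.3,
                               seed = 3)
  expect_true(all(noisy$peak_ratios >= 0 & noisy$peak_ratios <= 1.05))
})
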