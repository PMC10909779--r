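test_that("peak detection finds clean and noisy peaks", {
  tr <- gen_current_trace(cbind(1, 10), duration = 50, dt = 0.1,
                          onset = 1)
  pk <- detect_peak(tr, 20)
  expect_lt(abs(pk$t_peak - 1), 0.1 + 1e-9)

  flat <- current_trace(seq(0, 10, 0.1), rep(0, 101))
  expect_equal(detect_peak(flat, 5)$i_peak, 0)

  noisy <- gen_current_trace(cbind(1, 10), duration = 50, dt = 0.1,
                             noise_sd = 0.05, seed = 3)
  expect_equal(abs(detect_peak(noisy, 10)$i_peak), 1, tolerance = 0.1)

  expect_error(detect_peak(current_trace(0:10, rep(0, 11),
                                         stimulus_onset = 50), 5))
})

test_that("decay fitting recovers mono- and bi-exponential kinetics", {
  tr <- gen_current_trace(cbind(1, 8.9), duration = 250, dt = 0.05)
  fit <- fit_decay(tr, order = 1)
  expect_equal(fit$tau_weighted, 8.9, tolerance = 0.01 / 8.9)

  tr2 <- gen_current_trace(cbind(c(2, 1), c(3, 9)), duration = 100,
                           dt = 0.05)
  fit2 <- fit_decay(tr2, order = 2)
  expect_equal(fit2$taus, c(3, 9), tolerance = 1e-3)
  expect_equal(fit2$tau_weighted, 5, tolerance = 1e-3)
  expect_lt(fit2$taus[1], fit2$taus[2])

  # degenerate equal-tau data: weighted tau equals the common tau
  tr3 <- gen_current_trace(cbind(1, 5), duration = 100, dt = 0.05)
  fit3 <- fit_decay(tr3, order = 2)
  expect_equal(fit3$tau_weighted, 5, tolerance = 0.02)
})

test_that("decay fits are invariant to trace amplitude scaling", {
  base <- gen_current_trace(cbind(1, 12), duration = 150, dt = 0.1,
                            noise_sd = 0.02, seed = 7)
  scaled <- current_trace(base$t, base$i * 40,
                          stimulus_onset = base$stimulus_onset,
                          stimulus_end = base$stimulus_end)
  f1 <- fit_decay(base, order = 1)
  f2 <- fit_decay(scaled, order = 1)
  expect_equal(f2$tau_weighted, f1$tau_weighted, tolerance = 1e-8)
  expect_equal(f2$amplitudes, 40 * f1$amplitudes, tolerance = 1e-6)
})

test_that("automatic order selection rejects spurious second components", {
  picks <- vapply(1:40, function(sd) {
    tr <- gen_current_trace(cbind(1, 8.9), duration = 250, dt = 0.1,
                            noise_sd = 0.05, seed = sd + 300)
    fit_decay(tr)$order
  }, numeric(1))
  expect_gte(mean(picks == 1), 0.95)

  tr_bi <- gen_current_trace(cbind(c(0.6, 0.4), c(3, 20)),
                             duration = 250, dt = 0.1,
                             noise_sd = 0.02, seed = 1)
  expect_equal(fit_decay(tr_bi)$order, 2)
})

test_that("recovery ratios and first-order recovery fits are exact on clean data", {
  mk <- function(amp) gen_current_trace(cbind(amp, 8), duration = 40,
                                        dt = 0.1)
  ivs <- c(5, 10, 20, 40)
  rr <- recovery_ratios(lapply(c(1, 1, 1, 1), mk),
                        lapply(c(0.4, 0.6, 0.8, 1), mk), ivs)
  expect_equal(rr$peak_ratios, c(0.4, 0.6, 0.8, 1), tolerance = 1e-9)

  same <- recovery_ratios(list(mk(1)), list(mk(1)), 10)
  expect_equal(same$peak_ratios, 1)

  rec <- gen_recovery_series(17, c(3, 6, 12, 17, 25, 50, 100))
  fit <- fit_recovery(rec)
  expect_equal(fit$tau_recov, 17, tolerance = 0.1 / 17)
  expect_equal(rec$peak_ratios[4], 1 - exp(-1), tolerance = 1e-9)

  # 4-fold slower recovery is resolved as a 4-fold tau ratio
  iv <- c(5, 10, 20, 40, 80, 160, 320)
  t75 <- fit_recovery(gen_recovery_series(75, iv))$tau_recov
  t17 <- fit_recovery(gen_recovery_series(17, iv))$tau_recov
  expect_equal(t75 / t17, 75 / 17, tolerance = 0.01)

  expect_warning(
    fit_recovery(recovery_series(c(5, 10, 20, 40), rep(1, 4))),
    "no desensitization")
  expect_error(fit_recovery(gen_recovery_series(17, c(5, 10, 20))))
})

test_that("peak ratios between traces report relative amplitudes", {
  ref <- gen_current_trace(cbind(1, 8.9), duration = 50, dt = 0.05)
  expect_equal(peak_ratio_ph(ref, ref), 1)

  low <- current_trace(ref$t, ref$i * 0.12)
  expect_equal(peak_ratio_ph(low, ref), 0.12, tolerance = 1e-12)

  # single noisy pair: 3 sigma of the SNR-20 single-pair spread
  low_n <- gen_current_trace(cbind(0.12, 4.5), duration = 50, dt = 0.05,
                             noise_sd = 0.006, seed = 5)
  ref_n <- gen_current_trace(cbind(1, 8.9), duration = 50, dt = 0.05,
                             noise_sd = 0.05, seed = 6)
  expect_lt(abs(peak_ratio_ph(low_n, ref_n) - 0.12), 0.03)
})
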