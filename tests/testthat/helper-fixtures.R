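# Shared fixtures, built in code at test time.

# Two-state compact/splayed ensemble with a 50/50 "sample" and 90/10 prior.
make_two_state_fixture <- function(n_frames = 100, seed = 1, n_q = 40) {
  ts <- gen_two_state_ensemble(n_frames, frac_splayed = 0.1, seed = seed)
  w_true <- ntdsplay:::state_weights(ts$state, 0.5)
  q <- default_q_grid(n_q)
  dat <- gen_sans_dataset(ts$ensemble, w_true, aggregate = NULL,
                          background = 0, noise = noise_model(0.01),
                          q_grid = q, seed = seed)
  list(ts = ts, w_true = w_true, q = q, dat = dat,
       M = attr(dat, "frame_curves"),
       w0 = rep(1 / n_frames, n_frames))
}

# Analytic solid-sphere scattering curve with Gaussian noise.
sphere_curve <- function(R = 40, n_q = 100, rel_noise = 0.01, seed = 4,
                         scale = 1000) {
  q <- default_q_grid(n_q, 0.005, 0.3)
  P <- (3 * (sin(q * R) - q * R * cos(q * R)) / (q * R)^3)^2 * scale
  sig <- rel_noise * P + 1e-4 * max(P)
  I <- ntdsplay:::with_seed(seed, P + stats::rnorm(n_q, 0, sig))
  scattering_curve(q, I, sigma = sig)
}

# Independent brute-force Debye reference: plain double loop.
debye_brute_force <- function(coords, b, q_grid) {
  n <- nrow(coords)
  sapply(q_grid, function(q) {
    acc <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      acc <- acc + b[i] * b[j] *
        (if (q * r == 0) 1 else sin(q * r) / (q * r))
    }
    acc
  })
}
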