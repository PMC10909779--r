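#' @useDynLib ntdsplay, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Toy tetramer specification
#'
#' Parameters of the synthetic four-cluster bead tetramer used throughout:
#' two "NTD dimer" clusters whose centre-of-mass separation is a base
#' distance plus `splay`, and two anchor clusters (the LBD/TMD-like body)
#' that do not move.  Only the NTD-pair axis responds to `splay`, isolating
#' the one collective variable the analysis uses.
#'
#' @param n_beads_per_subunit beads per cluster (>= 1); default 15.
#' @param subunit_radius cluster radius in Angstrom (> 0); default 16.
#' @param splay extra separation (Angstrom, >= 0) added between the two
#'   NTD clusters on top of the base distance.
#' @param base_distance compact-state NTD centre-of-mass distance
#'   (Angstrom); default 40.
#' @param seed integer RNG seed fixing the bead jitter.
#' @return object of class `toy_tetramer_spec`.
#' @export
toy_tetramer_spec <- function(n_beads_per_subunit = 15,
                              subunit_radius = 16, splay = 0,
                              base_distance = 40, seed = 1) {
  if (n_beads_per_subunit < 1) stop("need at least one bead per subunit")
  if (subunit_radius <= 0) stop("subunit_radius must be positive")
  if (splay < 0) stop("splay must be non-negative")
  structure(list(n_beads_per_subunit = as.integer(n_beads_per_subunit),
                 subunit_radius = subunit_radius, splay = splay,
                 base_distance = base_distance, seed = as.integer(seed)),
            class = "toy_tetramer_spec")
}

# Seeded per-cluster bead offsets, exactly centred so cluster COMs are
# placed without error: uniform draws in a ball, COM removed.
tetramer_template <- function(spec) {
  with_seed(spec$seed, {
    lapply(1:4, function(k) {
      n <- spec$n_beads_per_subunit
      if (n == 1) return(matrix(0, 1, 3))
      u <- matrix(stats::rnorm(3 * n), n, 3)
      u <- u / sqrt(rowSums(u^2))
      r <- spec$subunit_radius * stats::runif(n)^(1 / 3)
      off <- u * r
      sweep(off, 2, colMeans(off))
    })
  })
}

# Assemble a conformation from template offsets at a given splay.
assemble_tetramer <- function(spec, template, splay) {
  d <- spec$base_distance + splay
  h <- spec$base_distance / 2
  centers <- rbind(c(-d / 2, 0,  h),   # NTD cluster 1
                   c( d / 2, 0,  h),   # NTD cluster 2
                   c(0, -spec$base_distance / 2, -h),  # anchor 1
                   c(0,  spec$base_distance / 2, -h))  # anchor 2
  coords <- do.call(rbind, lapply(1:4, function(k)
    sweep(template[[k]], 2, centers[k, ], "+")))
  labels <- rep(c("NTD1", "NTD2", "anchor1", "anchor2"),
                each = spec$n_beads_per_subunit)
  bead_conformation(coords, cluster = labels)
}

#' Generate a toy tetramer conformation
#'
#' Deterministic for a fixed spec seed; the distance between the
#' centres of mass of the two NTD clusters equals
#' `base_distance + splay` exactly.
#'
#' @param spec a [toy_tetramer_spec()].
#' @return a [bead_conformation()].
#' @export
gen_toy_tetramer <- function(spec) {
  assemble_tetramer(spec, tetramer_template(spec), spec$splay)
}

#' NTD-cluster centre-of-mass distance of a conformation
#'
#' @param conf a [bead_conformation()] with clusters `NTD1` and `NTD2`.
#' @param unit `"angstrom"` or `"nm"`.
#' @return the collective variable.
#' @export
ntd_distance <- function(conf, unit = c("angstrom", "nm")) {
  unit <- match.arg(unit)
  com <- function(tag) {
    sel <- conf$cluster == tag
    if (!any(sel)) stop("conformation lacks cluster ", tag)
    w <- conf$b[sel] / sum(conf$b[sel])
    colSums(conf$coords[sel, , drop = FALSE] * w)
  }
  d <- sqrt(sum((com("NTD1") - com("NTD2"))^2))
  if (unit == "nm") angstrom_to_nm(d) else d
}

#' Generate a biased conformational ensemble
#'
#' Draws `n_frames` splay values by Metropolis sampling from
#' \eqn{\exp(-(G(x) + V_{bias}(x))/kT)} along the NTD-distance coordinate
#' (nm) and builds one toy-tetramer conformation per frame.  The returned
#' [bias_trace()] records the bias energy per frame, emulating the final
#' bias of a converged metadynamics run; prior frame weights then follow
#' from [bias_to_weights()].
#'
#' @param spec a [toy_tetramer_spec()] (its `splay` field is ignored; the
#'   sampler sets splay per frame).
#' @param n_frames number of frames (>= 2).
#' @param splay_sampler a [pmf_spec()] G(x) along the NTD distance (nm).
#' @param bias vectorized function x -> V_bias (kJ/mol), or `NULL` for an
#'   unbiased run.
#' @param range sampling support in nm.
#' @param seed integer RNG seed.
#' @param thin Metropolis thinning.
#' @return list with `ensemble` (a [conformational_ensemble()], weights
#'   unset), `bias` (a [bias_trace()]) and `acceptance_rate`.
#' @export
gen_ensemble <- function(spec, n_frames, splay_sampler, bias = NULL,
                         range = NULL, seed = 1, thin = 10) {
  if (n_frames < 2) stop("need at least two frames")
  if (is.null(bias)) bias <- function(x) rep(0, length(x))
  kT <- splay_sampler$kT
  if (is.null(range)) {
    base_nm <- angstrom_to_nm(spec$base_distance)
    range <- c(base_nm, base_nm + 6)
  }
  energy <- function(x) pmf_energy(splay_sampler, x) + bias(x)
  res <- with_seed(seed,
    metropolis_sample(energy, range, n_frames, kT, thin = thin))
  cv <- res$samples                      # NTD distance, nm
  splays <- nm_to_angstrom(cv) - spec$base_distance
  splays[splays < 0] <- 0
  template <- tetramer_template(spec)
  frames <- lapply(splays, function(s) assemble_tetramer(spec, template, s))
  cv_real <- vapply(frames, ntd_distance, numeric(1), unit = "nm")
  ens <- conformational_ensemble(frames, cv_real)
  list(ensemble = ens,
       bias = bias_trace(cv_real, bias(cv_real), kT),
       acceptance_rate = res$acceptance_rate)
}

#' SANS-like noise model
#'
#' Relative Gaussian noise with low-q error inflation:
#' \eqn{\sigma(q) = \mathrm{relative\_sigma} \cdot I(q) \cdot
#' (1 + c\, q_{scale}/q)} with \eqn{q_{scale} = 0.01\
#' \mathrm{\AA}^{-1}}, emulating the larger relative error bars of SANS
#' detectors at low q.  An emulation of typical instrument behaviour, not
#' a reproduction of any specific instrument.
#'
#' @param relative_sigma fractional error at high q (> 0).
#' @param low_q_inflation dimensionless coefficient c (>= 0).
#' @param q_scale reference q (inverse Angstrom).
#' @return object of class `noise_model`.
#' @export
noise_model <- function(relative_sigma = 0.01, low_q_inflation = 1,
                        q_scale = 0.01) {
  if (relative_sigma <= 0) stop("relative_sigma must be positive")
  if (low_q_inflation < 0) stop("low_q_inflation must be non-negative")
  structure(list(relative_sigma = relative_sigma,
                 low_q_inflation = low_q_inflation, q_scale = q_scale),
            class = "noise_model")
}

noise_sigma <- function(noise, q, I_true) {
  noise$relative_sigma * abs(I_true) *
    (1 + noise$low_q_inflation * noise$q_scale / q)
}

#' Generate a contaminated SANS dataset from an ensemble
#'
#' Builds \eqn{I(q) = \sum_f w_f I_f(q) + I_{agg}(q) + b} with the
#' aggregate term \eqn{I_{agg} = c_a P_{tet}(q) S(q)} (the weighted
#' ensemble-average form factor times a fractal structure factor), then
#' adds Gaussian noise with the [noise_model()] sigma.  Deterministic for
#' a fixed seed.
#'
#' @param ensemble a [conformational_ensemble()].
#' @param true_weights normalized frame weights defining the "sample".
#' @param aggregate an [aggregate_params()] or `NULL` for no aggregates.
#' @param background constant background intensity.
#' @param noise a [noise_model()] or `NULL` for a noiseless curve (sigma
#'   is still attached, from `sigma_ref = noise_model()` defaults).
#' @param q_grid ascending q grid (inverse Angstrom, q > 0).
#' @param seed integer RNG seed.
#' @return a measured-style [scattering_curve()] with attributes
#'   `truth` (noiseless aggregate-free curve incl. background),
#'   `frame_curves` (q x frames intensity matrix) and `aggregate_truth`.
#' @export
gen_sans_dataset <- function(ensemble, true_weights, aggregate = NULL,
                             background = 0, noise = noise_model(),
                             q_grid = default_q_grid(), seed = 1) {
  if (length(true_weights) != length(ensemble$frames))
    stop("weight/frame length mismatch")
  if (any(q_grid <= 0) || any(diff(q_grid) <= 0))
    stop("q_grid must be ascending and positive")
  w <- true_weights / sum(true_weights)
  M <- vapply(ensemble$frames,
              function(fr) debye_intensity(fr, q_grid)$I,
              numeric(length(q_grid)))
  M <- matrix(M, nrow = length(q_grid))
  avg <- drop(M %*% w)
  I_agg <- rep(0, length(q_grid))
  if (!is.null(aggregate) && aggregate$c_a > 0) {
    r0 <- aggregate$r0
    if (is.na(r0)) {
      avg_curve <- scattering_curve(q_grid, avg, computed = TRUE)
      r0 <- sqrt(5 / 3) * guinier_rg(avg_curve)
      aggregate$r0 <- r0
    }
    S <- fractal_structure_factor(q_grid, aggregate$D, aggregate$xi, r0)
    I_agg <- aggregate$c_a * avg * S
  }
  I_true <- avg + I_agg + background
  sig_model <- if (is.null(noise)) noise_model() else noise
  sigma <- noise_sigma(sig_model, q_grid, I_true)
  I_obs <- if (is.null(noise)) I_true else
    with_seed(seed, I_true + stats::rnorm(length(q_grid), 0, sigma))
  out <- scattering_curve(q_grid, I_obs, sigma = sigma, label = "synthetic")
  attr(out, "truth") <- scattering_curve(q_grid, avg + background,
                                         sigma = sigma, label = "truth")
  attr(out, "frame_curves") <- M
  attr(out, "aggregate_truth") <- I_agg
  attr(out, "aggregate_used") <- aggregate
  out
}

#' Default SANS q grid
#'
#' 60 points, 0.005 to 0.35 inverse Angstrom, log-spaced — a typical SANS
#' measurement range for a large membrane-protein complex.
#'
#' @param n number of points.
#' @param q_min,q_max range (inverse Angstrom).
#' @return numeric grid.
#' @export
default_q_grid <- function(n = 60, q_min = 0.005, q_max = 0.35) {
  exp(seq(log(q_min), log(q_max), length.out = n))
}

#' Generate umbrella-sampling windows along a PMF
#'
#' Each window holds `n_per_window` Metropolis samples from
#' \eqn{\exp(-(G(x) + \frac{1}{2} k (x - c)^2)/kT)}; the acceptance rate
#' is recorded per window.
#'
#' @param pmf a [pmf_spec()].
#' @param centers ascending window centres (nm).
#' @param k harmonic force constant (kJ/mol/nm^2, > 0); 1000 mirrors a
#'   standard pull-code restraint.
#' @param n_per_window samples per window.
#' @param seed integer RNG seed.
#' @param support sampling support (nm); windows' centres must lie inside.
#' @param thin Metropolis thinning.
#' @return list of [umbrella_window()] objects.
#' @export
gen_umbrella_windows <- function(pmf, centers, k = 1000,
                                 n_per_window = 5000, seed = 1,
                                 support = NULL, thin = 5) {
  if (k <= 0) stop("force constant must be positive")
  if (any(diff(centers) <= 0)) stop("centers must be ascending")
  if (is.null(support))
    support <- range(centers) + c(-1, 1) * 3 * sqrt(pmf$kT / k) * 3
  if (any(centers < support[1] | centers > support[2]))
    stop("centers outside PMF support")
  with_seed(seed, lapply(seq_along(centers), function(i) {
    ci <- centers[i]
    energy <- function(x) pmf_energy(pmf, x) + 0.5 * k * (x - ci)^2
    # sample locally around the window centre
    halfw <- max(6 * sqrt(pmf$kT / k), 0.3)
    rng <- c(max(support[1], ci - halfw), min(support[2], ci + halfw))
    res <- metropolis_sample(energy, rng, n_per_window, pmf$kT,
                             x0 = ci, thin = thin,
                             step0 = sqrt(pmf$kT / k))
    umbrella_window(ci, k, res$samples,
                    acceptance_rate = res$acceptance_rate)
  }))
}

#' Current trace container
#'
#' @param t time in ms (uniform spacing).
#' @param i current (pA or normalized).
#' @param stimulus_onset onset time in ms.
#' @param stimulus_end end of agonist application in ms.
#' @return object of class `current_trace`.
#' @export
current_trace <- function(t, i, stimulus_onset = 0, stimulus_end = NULL) {
  if (length(t) != length(i)) stop("t/i length mismatch")
  dt <- diff(t)
  if (any(abs(dt - dt[1]) > 1e-9 * dt[1])) stop("t must be uniform")
  if (any(!is.finite(i))) stop("current must be finite")
  structure(list(t = as.numeric(t), i = as.numeric(i),
                 stimulus_onset = stimulus_onset,
                 stimulus_end = if (is.null(stimulus_end)) max(t)
                                else stimulus_end),
            class = "current_trace")
}

#' Generate a desensitizing current decay trace
#'
#' The trace is zero before `onset`, then a sum of exponentials
#' \eqn{\sum_i A_i \exp(-(t - onset)/\tau_i)} plus Gaussian noise —
#' the canonical mono/bi-exponential decay of a glutamate-evoked current
#' into desensitization.
#'
#' @param tau_entries two-column matrix or data frame `(A, tau_ms)`, one
#'   row per exponential component.
#' @param duration trace duration (ms).
#' @param dt sample interval (ms, > 0).
#' @param noise_sd additive Gaussian noise SD (same units as A).
#' @param onset stimulus onset (ms).
#' @param seed integer RNG seed.
#' @return a [current_trace()].
#' @export
gen_current_trace <- function(tau_entries, duration = 250, dt = 0.04,
                              noise_sd = 0, onset = 0, seed = 1) {
  if (dt <= 0) stop("dt must be positive")
  te <- as.matrix(tau_entries)
  if (ncol(te) != 2) stop("tau_entries must be (A, tau) pairs")
  if (any(te[, 2] <= 0)) stop("tau must be positive")
  t <- seq(0, duration, by = dt)
  i <- rep(0, length(t))
  on <- t >= onset
  for (r in seq_len(nrow(te)))
    i[on] <- i[on] + te[r, 1] * exp(-(t[on] - onset) / te[r, 2])
  if (noise_sd > 0)
    i <- with_seed(seed, i + stats::rnorm(length(i), 0, noise_sd))
  current_trace(t, i, stimulus_onset = onset, stimulus_end = duration)
}

#' Recovery series container
#'
#' @param interpulse_intervals ascending intervals (ms).
#' @param peak_ratios test/initial peak ratios in \[0, 1.1\].
#' @return object of class `recovery_series`.
#' @export
recovery_series <- function(interpulse_intervals, peak_ratios) {
  if (length(interpulse_intervals) != length(peak_ratios))
    stop("length mismatch")
  if (any(diff(interpulse_intervals) <= 0))
    stop("intervals must be ascending")
  if (any(peak_ratios < 0 | peak_ratios > 1.1))
    stop("ratios outside [0, 1.1]")
  structure(list(interpulse_intervals = as.numeric(interpulse_intervals),
                 peak_ratios = as.numeric(peak_ratios)),
            class = "recovery_series")
}

#' Generate a two-pulse recovery series
#'
#' First-order recovery from desensitization: the ratio of the test-pulse
#' peak to the initial-pulse peak is \eqn{1 - \exp(-\Delta t/\tau)} plus
#' Gaussian noise, clipped to \[0, 1.05\].
#'
#' @param tau_recov recovery time constant (ms, > 0).
#' @param intervals interpulse intervals (ms, > 0, ascending).
#' @param noise_sd additive noise SD on the ratio.
#' @param seed integer RNG seed.
#' @return a [recovery_series()].
#' @export
gen_recovery_series <- function(tau_recov, intervals, noise_sd = 0,
                                seed = 1) {
  if (tau_recov <= 0) stop("tau_recov must be positive")
  if (any(intervals <= 0)) stop("intervals must be positive")
  r <- 1 - exp(-intervals / tau_recov)
  if (noise_sd > 0)
    r <- with_seed(seed, r + stats::rnorm(length(r), 0, noise_sd))
  r <- pmin(pmax(r, 0), 1.05)
  recovery_series(intervals, r)
}
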