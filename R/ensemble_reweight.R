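#' Convert metadynamics bias energies to prior frame weights
#'
#' Final-bias reweighting: \eqn{w^0_i \propto \exp(+V_{bias,i}/kT)},
#' normalized, computed with a max-shifted exponent for overflow safety.
#' This is the standard conversion of a converged metadynamics bias to
#' frame weights ("inverse of the biasing potential" in the Boltzmann
#' sense, i.e. the exponential of +V/kT — not the reciprocal 1/V).
#'
#' @param trace a [bias_trace()].
#' @return normalized prior weights.
#' @export
bias_to_weights <- function(trace) {
  if (trace$kT <= 0) stop("kT must be positive")
  v <- trace$bias_energy / trace$kT
  if (any(!is.finite(v))) stop("non-finite bias energy")
  e <- exp(v - max(v))
  e / sum(e)
}

#' Kish effective sample fraction
#'
#' \eqn{\phi_{eff} = \exp(S_{rel})} with
#' \eqn{S_{rel} = -\sum_i w_i \ln(w_i/w^0_i) \le 0}; equals 1 iff the
#' posterior weights coincide with the prior.
#'
#' @param weights posterior weights (normalized).
#' @param w0 prior weights (normalized).
#' @return fraction in (0, 1\].
#' @export
kish_phi_eff <- function(weights, w0) {
  exp(relative_entropy(weights, w0))
}

# S_rel = -sum w log(w/w0) <= 0, with 0 log 0 = 0
relative_entropy <- function(w, w0) {
  w <- w / sum(w); w0 <- w0 / sum(w0)
  if (any(w0 <= 0 & w > 1e-15))
    stop("posterior weight on a frame with zero prior weight")
  nz <- w > 0 & w0 > 0
  -sum(w[nz] * log(w[nz] / w0[nz]))
}

# Frame curves as a q x n_frames matrix plus grid, from list or matrix.
as_frame_matrix <- function(frame_curves, q_grid = NULL) {
  if (is.matrix(frame_curves)) {
    if (is.null(q_grid)) stop("q_grid required for matrix frame curves")
    return(list(M = frame_curves, q = q_grid))
  }
  q <- frame_curves[[1]]$q
  for (fc in frame_curves) check_shared_grid(frame_curves[[1]], fc)
  list(M = vapply(frame_curves, function(fc) fc$I, numeric(length(q))),
       q = q)
}

#' Bayesian/maximum-entropy reweighting against a scattering curve
#'
#' Minimizes \eqn{Q = \chi^2_r - \theta S_{rel}} over frame weights, with
#' \eqn{S_{rel} = -\sum_i w_i \ln(w_i/w^0_i) \le 0}, so the entropy term
#' penalizes divergence from the prior weights `w0`.  Solved in the dual
#' parametrization \eqn{w_i \propto w^0_i \exp(-\sum_q \lambda_q
#' I_i(q)/\sigma_q)} with the Lagrange multipliers optimized by BFGS with
#' an analytic gradient; weights are therefore strictly positive wherever
#' the prior is.  A global scale and constant background are re-fitted in
#' closed form ([fit_scale_background()] algebra) inside every chi-square
#' evaluation, so the fit quality never depends on an arbitrary prior
#' calibration; \eqn{\chi^2_r} uses \eqn{n_q - 2} degrees of freedom for
#' those two parameters.
#'
#' @param frame_curves list of computed [scattering_curve()] on the data
#'   grid, or a q x frames intensity matrix (then give `q_grid`).
#' @param data measured [scattering_curve()] with `sigma`.
#' @param w0 prior weights; default uniform.
#' @param theta entropy-trade-off Lagrange multiplier (> 0).
#' @param q_grid grid when `frame_curves` is a matrix.
#' @param lambda_init warm-start multipliers.
#' @param maxit BFGS iteration cap per restart (up to 3 restarts).
#' @param grad_tol convergence tolerance on the dual gradient norm (the
#'   practical stationarity floor for sigma-scaled intensity features in
#'   double precision).
#' @return object of class `bme_result`: `theta`, `weights`,
#'   `chi2_reduced`, `s_rel`, `phi_eff`, `lambda`, `scale`, `background`,
#'   `converged`, `grad_norm`.
#' @export
bme_optimize <- function(frame_curves, data, w0 = NULL, theta = 1,
                         q_grid = NULL, lambda_init = NULL, maxit = 1000,
                         grad_tol = 1e-3) {
  if (theta <= 0) stop("theta must be positive")
  if (!has_sigma(data)) stop("data must carry sigma")
  if (any(data$sigma <= 0)) stop("zero-sigma data points rejected")
  fm <- as_frame_matrix(frame_curves, q_grid)
  if (length(fm$q) != nrow(data) || any(abs(fm$q - data$q) >
                                        1e-9 * pmax(1, abs(data$q))))
    stop("frames and data are not on the same q grid")
  M <- fm$M                       # q x frames
  nf <- ncol(M)
  nq <- nrow(M)
  if (is.null(w0)) w0 <- rep(1 / nf, nf)
  if (length(w0) != nf) stop("w0 length mismatch")
  w0 <- w0 / sum(w0)

  dof <- nq - 2
  Z <- t(M / data$sigma)          # frames x q, sigma-scaled features
  dz <- data$I / data$sigma
  oz <- 1 / data$sigma            # sigma-scaled constant column
  lw0 <- log(w0)

  weights_of <- function(lambda) {
    a <- lw0 - drop(Z %*% lambda)
    e <- exp(a - max(a))
    e / sum(e)
  }
  # closed-form (scale, background) against the current weighted average
  calib_of <- function(yhat) {
    sw <- sum(oz^2); sx <- sum(oz * yhat); sy <- sum(oz * dz)
    sxx <- sum(yhat^2); sxy <- sum(yhat * dz)
    det <- sw * sxx - sx^2
    if (abs(det) < 1e-300) return(c(scale = 1, background = 0))
    c(scale = (sw * sxy - sx * sy) / det,
      background = (sxx * sy - sx * sxy) / det)
  }
  resid_of <- function(yhat) {
    sb <- calib_of(yhat)
    sb[1] * yhat + sb[2] * oz - dz
  }
  objective <- function(lambda) {
    w <- weights_of(lambda)
    r <- resid_of(drop(crossprod(Z, w)))
    sum(r^2) / dof - theta * relative_entropy(w, w0)
  }
  gradient <- function(lambda) {
    w <- weights_of(lambda)
    yhat <- drop(crossprod(Z, w))
    sb <- calib_of(yhat)
    r <- sb[1] * yhat + sb[2] * oz - dz
    # envelope: (scale, background) are at their inner optimum
    gw <- (2 * sb[1] / dof) * drop(Z %*% r) +
      theta * (log(pmax(w, 1e-300) / w0) + 1)
    u <- w * gw
    -(drop(crossprod(Z, u)) - yhat * sum(u))
  }

  lambda <- if (is.null(lambda_init)) rep(0, nq) else lambda_init
  gn <- Inf
  for (restart in 1:3) {
    opt <- stats::optim(lambda, objective, gradient, method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-15))
    lambda <- opt$par
    gn <- sqrt(sum(gradient(lambda)^2))
    if (gn <= grad_tol) break
  }
  converged <- gn <= grad_tol
  if (!converged)
    warning(sprintf(
      "BME dual optimizer: gradient norm %.3g above tolerance %.3g (theta=%.3g)",
      gn, grad_tol, theta))
  w <- weights_of(lambda)
  yhat <- drop(crossprod(Z, w))
  sb <- calib_of(yhat)
  r <- sb[1] * yhat + sb[2] * oz - dz
  srel <- relative_entropy(w, w0)
  structure(list(theta = theta, weights = w,
                 chi2_reduced = sum(r^2) / dof,
                 s_rel = srel, phi_eff = exp(srel),
                 lambda = lambda,
                 scale = unname(sb[1]), background = unname(sb[2]),
                 converged = converged, grad_norm = gn),
            class = "bme_result")
}

#' @export
print.bme_result <- function(x, ...) {
  cat(sprintf(
    "<bme_result: theta=%.3g, chi2r=%.3f, S_rel=%.4f, phi_eff=%.3f>\n",
    x$theta, x$chi2_reduced, x$s_rel, x$phi_eff))
  invisible(x)
}

#' Scan the entropy-fit trade-off over a theta grid
#'
#' Runs [bme_optimize()] across a log-spaced theta grid with warm-started
#' multipliers (largest theta first), so the chi-square is non-increasing
#' as theta decreases within optimizer tolerance.
#'
#' @inheritParams bme_optimize
#' @param theta_grid positive thetas (>= 1 value; default 25 log-spaced
#'   points over 1e-3..1e3).
#' @return list of [bme_optimize()] results in `theta_grid` order.
#' @export
theta_scan <- function(frame_curves, data, w0 = NULL,
                       theta_grid = 10^seq(-3, 3, length.out = 25),
                       q_grid = NULL) {
  if (length(theta_grid) < 1) stop("empty theta grid")
  fm <- as_frame_matrix(frame_curves, q_grid)
  nf <- ncol(fm$M)
  if (is.null(w0)) w0 <- rep(1 / nf, nf)
  w0 <- w0 / sum(w0)
  ord <- order(theta_grid, decreasing = TRUE)
  out <- vector("list", length(theta_grid))
  lam <- NULL
  for (i in ord) {
    res <- bme_optimize(fm$M, data, w0, theta = theta_grid[i],
                        q_grid = fm$q, lambda_init = lam)
    lam <- res$lambda
    out[[i]] <- res
  }
  out
}

#' Select theta from a scan
#'
#' Picks the maximum-curvature (knee) point of the chi-square versus
#' effective-sample-fraction trade-off: the log chi-square and phi_eff
#' axes are normalized to \[0, 1\] and the point farthest below the chord
#' joining the endpoints is selected (log compression keeps the long
#' prior-dominated tail of the L-curve from hiding the knee).  When a
#' model-free chi-square floor (from
#' [ift_chi2_floor()]) is supplied, the smallest theta whose chi-square
#' is at or below the floor is also reported.
#'
#' @param results list from [theta_scan()].
#' @param chi2_floor optional reduced-chi-square floor.
#' @return list with `theta`, `index`, `result` (the selected
#'   [bme_optimize()] result) and `theta_at_floor` (NA when no floor
#'   given or never reached).
#' @export
select_theta <- function(results, chi2_floor = NULL) {
  th <- vapply(results, `[[`, numeric(1), "theta")
  if (length(results) == 1)
    return(list(theta = th[1], index = 1L, result = results[[1]],
                theta_at_floor = NA_real_))
  chi <- vapply(results, `[[`, numeric(1), "chi2_reduced")
  phi <- vapply(results, `[[`, numeric(1), "phi_eff")
  ord <- order(th, decreasing = TRUE)   # phi decreasing along the scan
  x <- phi[ord]; y <- log(chi[ord])
  xr <- diff(range(x)); yr <- diff(range(y))
  if (xr == 0 || yr == 0) {
    idx <- ord[length(ord)]
  } else {
    xn <- (x - min(x)) / xr
    yn <- (y - min(y)) / yr
    # signed distance below the chord from first to last scan point
    chord <- yn[1] + (yn[length(yn)] - yn[1]) *
      (xn - xn[1]) / (xn[length(xn)] - xn[1])
    idx <- ord[which.max(chord - yn)]
  }
  theta_at_floor <- NA_real_
  if (!is.null(chi2_floor)) {
    ok <- which(chi <= chi2_floor)
    if (length(ok)) theta_at_floor <- min(th[ok])
  }
  list(theta = th[idx], index = idx, result = results[[idx]],
       theta_at_floor = theta_at_floor)
}

#' Posterior splayed-state fraction
#'
#' Total posterior weight of frames whose collective variable (NTD
#' distance, nm) exceeds a cutoff.
#'
#' @param ensemble a [conformational_ensemble()].
#' @param weights normalized frame weights.
#' @param cv_cutoff cutoff (nm), within the CV range of the ensemble.
#' @return fraction in \[0, 1\].
#' @export
splayed_fraction <- function(ensemble, weights, cv_cutoff) {
  if (length(weights) != length(ensemble$cv))
    stop("weights length mismatch")
  if (cv_cutoff < min(ensemble$cv) || cv_cutoff > max(ensemble$cv))
    warning("cv_cutoff outside the sampled CV range")
  w <- weights / sum(weights)
  sum(w[ensemble$cv > cv_cutoff])
}
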