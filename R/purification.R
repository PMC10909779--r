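#' Fractal aggregate parameters
#'
#' Parameters of the mass-fractal aggregate scattering term used in
#' "in silico purification": overall scale `c_a`, fractal dimension `D`
#' (1 < D <= 3, fixed at 2 during fitting by default), correlation length
#' `xi` and building-block radius `r0` (Angstrom, `xi > r0 > 0`).
#'
#' @param c_a aggregate scale (>= 0, intensity units).
#' @param D fractal dimension.
#' @param xi correlation length (Angstrom).
#' @param r0 building-block radius (Angstrom), or `NA` to derive it from
#'   the tetramer form factor's Guinier Rg (\eqn{r_0 = \sqrt{5/3} R_g},
#'   the convention [fit_composite()] uses) wherever the parameters are
#'   consumed.
#' @return object of class `aggregate_params`.
#' @export
aggregate_params <- function(c_a = 0, D = 2, xi = 300, r0 = NA) {
  if (c_a < 0) stop("c_a must be non-negative")
  if (D <= 1 || D > 3) stop("fractal dimension must be in (1, 3]")
  if (!is.na(r0) && !(xi > r0 && r0 > 0)) stop("require xi > r0 > 0")
  structure(list(c_a = c_a, D = D, xi = xi, r0 = r0),
            class = "aggregate_params")
}

#' Teixeira fractal structure factor
#'
#' \deqn{S(q) = 1 + \frac{D\,\Gamma(D-1)}{(q r_0)^D
#'   \left(1 + 1/(q^2\xi^2)\right)^{(D-1)/2}}
#'   \sin\!\left[(D-1)\arctan(q\xi)\right]}
#' For `D = 2` this reduces to the closed form
#' \eqn{S(q) = 1 + 2(\xi/r_0)^2 / (1 + q^2\xi^2)}.  At \eqn{q \to 0} the
#' limit is \eqn{1 + \Gamma(D+1)(\xi/r_0)^D}.
#'
#' @param q_grid momentum transfer (inverse Angstrom, >= 0).
#' @param D fractal dimension (> 1; D = 1 diverges through Gamma(D-1)).
#' @param xi correlation length (Angstrom).
#' @param r0 building-block radius (Angstrom).
#' @return S(q) >= 1.
#' @export
fractal_structure_factor <- function(q_grid, D = 2, xi = 300, r0 = 40) {
  if (D <= 1) stop("fractal dimension must exceed 1 (Gamma(D-1) diverges)")
  if (!(xi > r0 && r0 > 0)) stop("require xi > r0 > 0")
  qx <- q_grid * xi
  S <- numeric(length(q_grid))
  small <- qx < 1e-6
  S[small] <- 1 + gamma(D + 1) * (xi / r0)^D
  qs <- q_grid[!small]
  S[!small] <- 1 + D * gamma(D - 1) /
    ((qs * r0)^D * (1 + 1 / (qs * xi)^2)^((D - 1) / 2)) *
    sin((D - 1) * atan(qs * xi))
  S
}

#' Fit tetramer + fractal aggregate + background composite model
#'
#' Weighted least squares of
#' \deqn{I_{fit}(q) = c_{tet} P_{tet}(q) + c_a P_{tet}(q) S(q;\xi) + b}
#' against a measured curve.  The fractal dimension is fixed (default
#' `D = 2`) and the building-block radius `r0` is fixed to the sphere
#' radius equivalent to the tetramer form factor's Guinier Rg
#' (\eqn{r_0 = \sqrt{5/3}\,R_g}); the aggregate is thus modelled as a
#' fractal of the tetramers themselves.  Only the correlation length is
#' nonlinear: it is profiled by 1-D minimization over `log(xi)` with the
#' three linear amplitudes solved in closed form at each step.  A negative
#' best-fit aggregate scale is clipped to zero with a warning.
#'
#' @param data measured [scattering_curve()] with `sigma`.
#' @param tetramer_form computed [scattering_curve()] on the same grid.
#' @param init an [aggregate_params()] giving the starting `xi` and
#'   (optionally non-default) fixed `D`.
#' @param xi_bounds search bounds for the correlation length (Angstrom).
#' @return list of class `aggregate_fit` with elements `c_tet`,
#'   `aggregate` ([aggregate_params()] with fitted `c_a`, `xi`),
#'   `background`, `chi2_reduced`, `covariance` (of `c_tet`, `c_a`, `b`,
#'   `xi`) and `fitted` curve.
#' @export
fit_composite <- function(data, tetramer_form,
                          init = aggregate_params(c_a = 1),
                          xi_bounds = c(30, 5000)) {
  check_shared_grid(data, tetramer_form)
  if (!has_sigma(data)) stop("data must carry sigma")
  q <- data$q
  P <- tetramer_form$I
  D <- init$D
  rg <- guinier_rg(tetramer_form)
  r0 <- sqrt(5 / 3) * rg
  w <- 1 / data$sigma^2
  lo <- max(xi_bounds[1], r0 * 1.001)

  lin_solve <- function(xi) {
    S <- fractal_structure_factor(q, D, xi, r0)
    X <- cbind(tet = P, agg = P * S, bkg = 1)
    XtW <- t(X * w)
    A <- XtW %*% X
    beta <- tryCatch(solve(A, XtW %*% data$I),
                     error = function(e) matrix(NA_real_, 3))
    if (any(!is.finite(beta))) return(list(rss = Inf))
    # non-negative amplitudes: refit with c_a (and/or c_tet) pinned at 0
    if (beta[2] < 0 || beta[1] < 0) {
      # active-set pass: drop the negative amplitude(s) and refit
      keep <- c(TRUE, TRUE, TRUE)
      if (beta[2] < 0) keep[2] <- FALSE
      if (beta[1] < 0) keep[1] <- FALSE
      Xk <- X[, keep, drop = FALSE]
      bk <- solve(t(Xk * w) %*% Xk, t(Xk * w) %*% data$I)
      beta <- matrix(0, 3)
      beta[keep] <- bk
    }
    r <- data$I - X %*% beta
    list(rss = sum(w * r^2), beta = drop(beta), X = X)
  }

  opt <- stats::optimize(function(lxi) lin_solve(exp(lxi))$rss,
                         interval = log(c(lo, xi_bounds[2])),
                         tol = 1e-8)
  xi_hat <- exp(opt$minimum)
  sol <- lin_solve(xi_hat)
  beta <- unname(sol$beta)
  clipped <- FALSE
  if (beta[2] == 0) clipped <- TRUE
  if (clipped)
    warning("best-fit aggregate scale was negative; clipped to 0")
  n <- length(q)
  npar <- 4L
  chi2r <- sol$rss / max(1, n - npar)

  # covariance from the Jacobian of (c_tet, c_a, b, xi) at the optimum
  S <- fractal_structure_factor(q, D, xi_hat, r0)
  dS <- (fractal_structure_factor(q, D, xi_hat * 1.0001, r0) - S) /
    (xi_hat * 1e-4)
  J <- cbind(P, P * S, 1, beta[2] * P * dS)
  JtWJ <- t(J * w) %*% J
  covar <- tryCatch(solve(JtWJ) * chi2r,
                    error = function(e) matrix(NA_real_, 4, 4))
  dimnames(covar) <- list(c("c_tet", "c_a", "background", "xi"),
                          c("c_tet", "c_a", "background", "xi"))

  structure(list(
    c_tet = beta[1],
    aggregate = aggregate_params(c_a = beta[2], D = D, xi = xi_hat,
                                 r0 = r0),
    background = beta[3],
    chi2_reduced = chi2r,
    covariance = covar,
    clipped = clipped,
    fitted = scattering_curve(q, drop(sol$X %*% beta), computed = TRUE,
                              label = "composite fit"),
    aggregate_intensity = beta[2] * P * S),
    class = "aggregate_fit")
}

#' @export
print.aggregate_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "<aggregate_fit: c_tet=%.4g, c_a=%.4g, xi=%.1f A, bkg=%.4g, ",
    "chi2r=%.3f>\n"),
    x$c_tet, x$aggregate$c_a, x$aggregate$xi, x$background,
    x$chi2_reduced))
  invisible(x)
}

# Guinier Rg of a computed form factor: slope of ln I vs q^2 over the
# range q*Rg < 1 (iterated once to find the range).
guinier_rg <- function(curve, qrg_max = 1.0) {
  q <- curve$q; I <- curve$I
  sel <- seq_len(max(5, min(15, length(q))))
  for (it in 1:4) {
    fit <- stats::lm(log(I[sel]) ~ I(q[sel]^2))
    rg <- sqrt(max(0, -3 * stats::coef(fit)[2]))
    if (rg == 0) break
    sel_new <- which(q * rg < qrg_max)
    if (length(sel_new) < 5) sel_new <- seq_len(5)
    if (identical(sel_new, sel)) break
    sel <- sel_new
  }
  unname(rg)
}

#' Subtract the fitted aggregate term from a measured curve
#'
#' \deqn{I_{filtered}(q) = I_{original}(q) - I_{aggregate,fit}(q)}
#' The sigma column is copied unchanged (the subtracted term is a smooth
#' fitted model, treated as noise-free) and the constant background is
#' not subtracted — it remains part of any subsequent fit.
#'
#' @param data the original measured [scattering_curve()].
#' @param fit an `aggregate_fit` from [fit_composite()] on this grid.
#' @return the filtered [scattering_curve()].
#' @export
subtract_aggregate <- function(data, fit) {
  if (length(fit$aggregate_intensity) != nrow(data))
    stop("fit was not derived from this q grid")
  scattering_curve(data$q, data$I - fit$aggregate_intensity,
                   sigma = if (has_sigma(data)) data$sigma,
                   label = "filtered")
}

#' Model-free chi-square floor by Bayesian indirect Fourier transformation
#'
#' Fits a free-form pair-distance distribution p(r) on \[0, Dmax\] to the
#' curve through the Debye transform
#' \eqn{I(q) = \int_0^{D_{max}} p(r)\,\mathrm{sinc}(qr)\,dr} plus a
#' constant background, with a second-difference smoothness prior of
#' weight alpha.  Alpha is selected by maximizing a Laplace-approximation
#' Bayesian evidence over a log-spaced grid; Dmax is refined by
#' golden-section search around the initial guess.  The resulting reduced
#' chi-square estimates the floor any structural model can aim for on
#' this dataset; the effective number of parameters
#' \eqn{N_g = \mathrm{tr}(H^{-1} A^T W A)} is subtracted from the degrees
#' of freedom.
#'
#' @param data measured [scattering_curve()] with `sigma`.
#' @param d_max_init initial maximum dimension guess (Angstrom).
#' @param n_r number of p(r) grid points.
#' @param alpha_grid regularization-weight grid; default 41 log steps over
#'   1e-2..1e18.
#' @param refine_dmax logical, golden-section refinement of Dmax.
#' @return list with `chi2_reduced_floor`, `d_max`, `alpha`, `pr` (data
#'   frame `r`, `p`), `n_eff`, `evidence`, and `dmax_pileup` (TRUE when
#'   p(r) mass piles up near Dmax, indicating Dmax is too small).
#' @export
ift_chi2_floor <- function(data, d_max_init = 200, n_r = 50,
                           alpha_grid = 10^seq(-2, 18, length.out = 41),
                           refine_dmax = TRUE) {
  if (!has_sigma(data)) stop("data must carry sigma")
  if (d_max_init <= 0) stop("d_max_init must be positive")

  fit_at <- function(dmax) ift_fit(data, dmax, n_r, alpha_grid)

  if (refine_dmax) {
    # golden-section on evidence over [0.6, 1.8] x initial guess
    gr <- (sqrt(5) - 1) / 2
    a <- 0.6 * d_max_init; b <- 1.8 * d_max_init
    x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
    f1 <- fit_at(x1)$evidence; f2 <- fit_at(x2)$evidence
    for (it in 1:12) {
      if (f1 > f2) { b <- x2; x2 <- x1; f2 <- f1
        x1 <- b - gr * (b - a); f1 <- fit_at(x1)$evidence
      } else { a <- x1; x1 <- x2; f1 <- f2
        x2 <- a + gr * (b - a); f2 <- fit_at(x2)$evidence }
    }
    d_max <- (a + b) / 2
  } else d_max <- d_max_init
  best <- fit_at(d_max)

  tail_mass <- sum(best$p[best$r > 0.9 * d_max]) / max(sum(best$p), 1e-30)
  best$dmax_pileup <- is.finite(tail_mass) && tail_mass > 0.05
  if (best$dmax_pileup)
    warning("p(r) piles up at Dmax: Dmax may be below the particle extent")
  best$d_max <- d_max
  best
}

# Ridge-regularized p(r) inversion at fixed Dmax; evidence-selected alpha.
ift_fit <- function(data, d_max, n_r, alpha_grid) {
  q <- data$q; y <- data$I; s <- data$sigma
  nq <- length(q)
  r <- seq(0, d_max, length.out = n_r + 2)[2:(n_r + 1)]  # endpoints at 0
  dr <- r[2] - r[1]
  A <- outer(q, r, function(qq, rr) {
    x <- qq * rr
    ifelse(x == 0, 1, sin(x) / x) * dr
  })
  A <- cbind(A, 1)  # constant background column (unpenalized, tiny prior)
  W <- 1 / s^2
  AtWA <- t(A * W) %*% A
  Atwy <- t(A * W) %*% y
  # second-difference penalty incl. implicit zero boundaries
  Dm <- matrix(0, n_r, n_r)
  for (j in seq_len(n_r)) {
    Dm[j, j] <- -2
    if (j > 1) Dm[j, j - 1] <- 1
    if (j < n_r) Dm[j, j + 1] <- 1
  }
  Om <- rbind(cbind(t(Dm) %*% Dm, 0), 0)
  Om[n_r + 1, n_r + 1] <- 1e-12   # proper but negligible background prior

  best <- NULL
  for (alpha in alpha_grid) {
    H <- AtWA + alpha * Om
    ch <- tryCatch(chol(H), error = function(e) NULL)
    if (is.null(ch)) next
    p <- backsolve(ch, forwardsolve(t(ch), Atwy))
    resid <- (y - A %*% p) / s
    chi2 <- sum(resid^2)
    pen <- alpha * drop(t(p) %*% Om %*% p)
    # Laplace evidence: -0.5 chi2 - 0.5 pen + 0.5 log det(alpha Om)
    #                   - 0.5 log det(H)   (Gaussian prior/posterior)
    ldH <- 2 * sum(log(diag(ch)))
    ldP <- (n_r) * log(alpha) + ld_omega(Dm) - 12 * log(10)
    ev <- -0.5 * chi2 - 0.5 * pen + 0.5 * ldP - 0.5 * ldH
    n_eff <- sum(diag(backsolve(ch, forwardsolve(t(ch), AtWA))))
    if (is.null(best) || ev > best$evidence)
      best <- list(alpha = alpha, evidence = ev, chi2 = chi2,
                   n_eff = n_eff, p = pmax(drop(p)[seq_len(n_r)], -Inf),
                   background = drop(p)[n_r + 1])
  }
  if (is.null(best)) stop("IFT inversion failed at every alpha")
  dof <- max(1, nq - best$n_eff)
  list(chi2_reduced_floor = best$chi2 / dof,
       alpha = best$alpha, evidence = best$evidence,
       n_eff = best$n_eff, r = r, p = best$p,
       pr = data.frame(r = r, p = best$p),
       background = best$background)
}

# log det of the (full-rank, boundary-anchored) second-difference Gram
# matrix, cached per size
ld_omega <- local({
  cache <- new.env(parent = emptyenv())
  function(Dm) {
    key <- as.character(nrow(Dm))
    if (is.null(cache[[key]]))
      cache[[key]] <- determinant(t(Dm) %*% Dm, logarithm = TRUE)$modulus
    as.numeric(cache[[key]])
  }
})
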