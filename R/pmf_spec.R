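#' Analytic free-energy profiles for synthetic sampling
#'
#' A `pmf_spec` defines a one-dimensional free-energy surface G(x) along
#' the NTD-distance coordinate (x in nm, G in kJ/mol), used to drive the
#' synthetic samplers.  Supported forms:
#' \describe{
#'   \item{harmonic}{`0.5 * kappa * (x - x0)^2`; parameters `kappa`
#'     (kJ/mol/nm^2), `x0` (nm).}
#'   \item{double_well}{quartic with wells at `x1`, `x2` (G = 0) and a
#'     barrier of height `barrier` (kJ/mol) between them; optional `tilt`
#'     (kJ/mol) lowers the second well by `tilt`.}
#'   \item{morse_like}{`depth * ((1 - exp(-a (x - x0)))^2 - 1)`: a bound
#'     minimum of depth `-depth` at `x0` relaxing to a flat plateau at 0;
#'     parameters `depth` (kJ/mol), `a` (1/nm), `x0` (nm).  The wall on
#'     the short side rises steeply, as for a binding PMF.}
#'   \item{square_well}{`-depth` on `[x1, x2]`, 0 elsewhere.}
#' }
#'
#' @param form one of `"harmonic"`, `"double_well"`, `"morse_like"`,
#'   `"square_well"`.
#' @param parameters named list of reals (see Details).
#' @param kT thermal energy in kJ/mol; default 2.494 (300 K).  Use 2.686
#'   (323 K) for coarse-grained-analog stages.
#' @return object of class `pmf_spec`.
#' @export
pmf_spec <- function(form = c("harmonic", "double_well", "morse_like",
                              "square_well"),
                     parameters = list(), kT = 2.494) {
  form <- match.arg(form)
  if (kT <= 0) stop("kT must be positive")
  defaults <- switch(form,
    harmonic    = list(kappa = 50, x0 = 2),
    double_well = list(x1 = 1, x2 = 3, barrier = 5, tilt = 0),
    morse_like  = list(depth = 26, a = 2, x0 = 0.8),
    square_well = list(x1 = 0.5, x2 = 1.5, depth = 10))
  p <- utils::modifyList(defaults, parameters)
  if (any(!vapply(p, is.finite, logical(1))))
    stop("PMF parameters must be finite")
  structure(list(form = form, parameters = p, kT = kT),
            class = "pmf_spec")
}

#' Evaluate a pmf_spec
#'
#' @param spec a [pmf_spec()].
#' @param x positions (nm).
#' @return G(x) in kJ/mol.
#' @export
pmf_energy <- function(spec, x) {
  p <- spec$parameters
  switch(spec$form,
    harmonic = 0.5 * p$kappa * (x - p$x0)^2,
    double_well = {
      m <- (p$x1 + p$x2) / 2
      a <- (p$x2 - p$x1) / 2
      p$barrier * (((x - m)^2 - a^2)^2) / a^4 +
        p$tilt * (x - p$x2) / (p$x1 - p$x2) - p$tilt
    },
    morse_like = p$depth * ((1 - exp(-p$a * (x - p$x0)))^2 - 1),
    square_well = ifelse(x >= p$x1 & x <= p$x2, -p$depth, 0))
}

#' Metropolis sampling from a one-dimensional Boltzmann density
#'
#' Draws samples from \eqn{\propto \exp(-E(x)/kT)} with a random-walk
#' Metropolis chain (compiled).  The step size is auto-tuned to a 30-50%
#' acceptance rate during burn-in (the first 10% of the chain, which is
#' discarded).  Energies are tabulated on a fine grid and linearly
#' interpolated; outside `range` the energy is infinite.
#'
#' @param energy_fn vectorized function x -> energy (kJ/mol).
#' @param range numeric length-2 support (nm).
#' @param n number of retained samples.
#' @param kT thermal energy (kJ/mol).
#' @param x0 starting point; default mid-range.
#' @param thin keep every `thin`-th post-burn-in step.
#' @param step0 initial step size; default a tenth of the range.
#' @param n_grid energy-table resolution.
#' @return list with `samples`, `acceptance_rate`, `step`.
#' @export
metropolis_sample <- function(energy_fn, range, n, kT, x0 = NULL,
                              thin = 10, step0 = NULL, n_grid = 2001) {
  stopifnot(length(range) == 2, range[2] > range[1], n >= 1, kT > 0)
  gx <- seq(range[1], range[2], length.out = n_grid)
  gE <- energy_fn(gx)
  if (any(is.na(gE)))
    stop("non-finite energy on the requested range")
  gE[!is.finite(gE)] <- 1e6  # hard walls inside the table
  if (is.null(x0)) x0 <- gx[which.min(gE)]
  if (is.null(step0)) step0 <- diff(range) / 10
  burnin <- max(200L, ceiling(0.1 * n * thin))
  res <- metropolis_tabulated(gx, gE, x0, as.integer(n), as.integer(thin),
                              as.integer(burnin), step0, kT, TRUE)
  res
}
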