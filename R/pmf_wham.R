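#' Umbrella window
#'
#' Samples of the NTD-distance coordinate under one harmonic restraint.
#'
#' @param center restraint centre (nm).
#' @param k force constant (kJ/mol/nm^2, > 0).
#' @param samples numeric samples (nm); at least one.  `k = 0` is
#'   accepted as the unbiased limit.
#' @param acceptance_rate optional sampler diagnostic.
#' @return object of class `umbrella_window`.
#' @export
umbrella_window <- function(center, k, samples, acceptance_rate = NA) {
  if (k < 0) stop("force constant must be non-negative")
  if (length(samples) < 1) stop("need at least one sample")
  structure(list(center = center, k = k, samples = as.numeric(samples),
                 acceptance_rate = acceptance_rate),
            class = "umbrella_window")
}

#' Weighted histogram analysis of umbrella windows
#'
#' Standard WHAM self-consistent iteration: with bin centres \eqn{x_j},
#' bias \eqn{b_{kj} = \frac{1}{2} k_k (x_j - c_k)^2} and window counts
#' \eqn{n_{kj}}, iterate the free-energy offsets \eqn{f_k} until
#' \eqn{\max_k |\Delta f_k| < tol \cdot kT}, then
#' \eqn{G(x_j) = -kT \ln p_j}, anchored so \eqn{\min G = 0}.  A single
#' window with `k = 0` degenerates to the unbiased histogram estimate.
#' Windows must overlap: disconnected histogram support raises an error
#' naming the gap.
#'
#' @param windows list of [umbrella_window()].
#' @param bin_width histogram bin width (nm).
#' @param tol offset convergence tolerance in units of kT.
#' @param max_iter iteration cap.
#' @param kT thermal energy (kJ/mol); 2.494 corresponds to 300 K.
#' @param bin_edges optional fixed bin edges (nm), e.g. for bootstrap
#'   replicates on a common grid.
#' @param min_count occupancy threshold: bins with fewer total samples
#'   report `G = NA` (their free energy is dominated by shot noise in the
#'   far tails of the window biases); all samples still enter the
#'   self-consistent iteration.
#' @return object of class `pmf_profile`: `r` (bin centres, nm), `G`
#'   (kJ/mol, `NA` on unoccupied bins, min 0), `sem` (`NA` until
#'   [pmf_bootstrap()]), `kT`, `counts`, `offsets`, `n_iter`,
#'   `residuals` (per-iteration max offset change, kT units).
#' @export
wham <- function(windows, bin_width = 0.02, tol = 1e-6, max_iter = 1e5,
                 kT = 2.494, bin_edges = NULL, min_count = 10) {
  if (bin_width <= 0) stop("bin_width must be positive")
  K <- length(windows)
  if (K < 1) stop("no windows")
  allx <- unlist(lapply(windows, `[[`, "samples"))
  if (is.null(bin_edges)) {
    lo <- floor(min(allx) / bin_width) * bin_width
    hi <- ceiling(max(allx) / bin_width) * bin_width
    if (hi <= lo) hi <- lo + bin_width
    bin_edges <- seq(lo, hi + bin_width / 2, by = bin_width)
  }
  J <- length(bin_edges) - 1
  mids <- bin_edges[-1] - diff(bin_edges) / 2
  counts <- vapply(windows, function(w) {
    idx <- findInterval(w$samples, bin_edges, rightmost.closed = TRUE)
    tabulate(idx[idx >= 1 & idx <= J], J)
  }, numeric(J))                      # J x K
  counts <- matrix(counts, nrow = J)
  Nk <- colSums(counts)
  cj <- rowSums(counts)
  occ <- cj >= max(1, min(min_count, max(cj)))

  check_window_overlap(windows, counts)

  B <- vapply(seq_len(K), function(k)
    0.5 * windows[[k]]$k * (mids - windows[[k]]$center)^2,
    numeric(J))                       # J x K bias, kJ/mol
  B <- matrix(B, nrow = J)
  M <- exp(-(B - min(B)) / kT)        # shifted for range safety
  f <- rep(0, K)                      # offsets in kJ/mol
  residuals <- numeric(0)
  for (it in seq_len(max_iter)) {
    ef <- Nk * exp(f / kT)
    denom <- drop(M %*% ef)
    p <- ifelse(denom > 0, cj / denom, 0)
    fnew <- -kT * log(pmax(drop(crossprod(M, p)), 1e-300))
    fnew <- fnew - fnew[1]
    res <- max(abs(fnew - f)) / kT
    residuals <- c(residuals, res)
    f <- fnew
    if (res < tol) break
  }
  if (res >= tol)
    warning(sprintf(
      "WHAM not converged after %d iterations (residual %.3g kT)",
      max_iter, res))
  p <- p / sum(p)
  G <- rep(NA_real_, J)
  G[occ] <- -kT * log(p[occ])
  G <- G - min(G, na.rm = TRUE)
  structure(list(r = mids, G = G, sem = rep(NA_real_, J), kT = kT,
                 counts = counts, offsets = f, n_iter = it,
                 residuals = residuals, bin_edges = bin_edges),
            class = "pmf_profile")
}

# Error if the occupied-bin graph of the windows is disconnected.
check_window_overlap <- function(windows, counts) {
  K <- ncol(counts)
  if (K <= 1) return(invisible(TRUE))
  occ <- counts > 0
  comp <- rep(0L, K)
  comp[1] <- 1L
  repeat {
    grown <- FALSE
    for (k in which(comp > 0)) for (l in which(comp == 0)) {
      if (any(occ[, k] & occ[, l])) { comp[l] <- 1L; grown <- TRUE }
    }
    if (!grown) break
  }
  if (any(comp == 0)) {
    inside <- vapply(windows[comp > 0], `[[`, numeric(1), "center")
    outside <- vapply(windows[comp == 0], `[[`, numeric(1), "center")
    stop(sprintf(
      "umbrella windows do not overlap: gap between centers %.3g and %.3g nm",
      max(inside[inside < min(outside)], -Inf), min(outside)))
  }
  invisible(TRUE)
}

#' @export
print.pmf_profile <- function(x, ...) {
  occ <- !is.na(x$G)
  cat(sprintf(
    "<pmf_profile: %d occupied bins over [%.3g, %.3g] nm, max G %.2f kJ/mol, %d WHAM iterations>\n",
    sum(occ), min(x$r[occ]), max(x$r[occ]), max(x$G, na.rm = TRUE),
    x$n_iter))
  invisible(x)
}

#' NTD binding free energy from a PMF
#'
#' \eqn{\Delta G = G(\mathrm{bound\ minimum}) - \langle G \rangle_{plateau}}:
#' the depth of the bound minimum relative to the mean free energy over
#' the large-separation plateau (the unbound reference).  Negative for an
#' attractive interface.  By convention the plateau is the last 0.5 nm of
#' the sampled range when no range is given.
#'
#' @param pmf a `pmf_profile` from [wham()].
#' @param plateau_range length-2 interval (nm) within the profile.
#' @return Delta G in kJ/mol.
#' @export
binding_free_energy <- function(pmf, plateau_range = NULL) {
  occ <- !is.na(pmf$G)
  if (is.null(plateau_range)) {
    hi <- max(pmf$r[occ])
    plateau_range <- c(hi - 0.5, hi)
  }
  pl <- occ & pmf$r >= plateau_range[1] & pmf$r <= plateau_range[2]
  if (!any(pl)) stop("no occupied bins in the plateau range")
  min(pmf$G[occ]) - mean(pmf$G[pl])
}

#' Bootstrap standard errors for a WHAM profile
#'
#' Resamples each window's samples with replacement, recomputes WHAM on
#' the original bin grid, and reports the per-bin standard deviation of
#' G and (when a plateau range is given) the standard error of the
#' binding free energy.
#'
#' @param windows list of [umbrella_window()].
#' @param n_boot number of bootstrap replicates (>= 2).
#' @param seed integer RNG seed.
#' @param plateau_range optional plateau interval (nm) for a Delta G SEM.
#' @param ... passed to [wham()].
#' @return list with `pmf` (the point-estimate profile with `sem`
#'   filled), `dG` (point estimate, or `NA` without plateau) and
#'   `dG_sem`.
#' @export
pmf_bootstrap <- function(windows, n_boot = 20, seed = 1,
                          plateau_range = NULL, ...) {
  if (n_boot < 2) stop("need at least two bootstrap replicates")
  base <- wham(windows, ...)
  reps <- with_seed(seed, lapply(seq_len(n_boot), function(b) {
    wb <- lapply(windows, function(w)
      umbrella_window(w$center, w$k,
                      sample(w$samples, length(w$samples),
                             replace = TRUE)))
    wham(wb, bin_edges = base$bin_edges, ...)
  }))
  Gmat <- vapply(reps, `[[`, numeric(length(base$r)), "G")
  base$sem <- apply(Gmat, 1, stats::sd, na.rm = TRUE)
  dG <- binding_free_energy(base, plateau_range)
  dGs <- vapply(reps, function(p)
    tryCatch(binding_free_energy(p, plateau_range),
             error = function(e) NA_real_), numeric(1))
  dG_sem <- stats::sd(dGs, na.rm = TRUE)
  list(pmf = base, dG = dG, dG_sem = dG_sem)
}

#' Read / write umbrella windows as CSV
#'
#' Dialect: first line `center_nm,k_kJ_mol_nm2`, second line the two
#' values, then one sample (nm) per line.
#'
#' @param window an [umbrella_window()].
#' @param path file path.
#' @return `write_umbrella_csv` returns `path` invisibly;
#'   `read_umbrella_csv` an [umbrella_window()].
#' @export
write_umbrella_csv <- function(window, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("center_nm,k_kJ_mol_nm2",
               sprintf("%.10g,%.10g", window$center, window$k),
               sprintf("%.10g", window$samples)), con)
  invisible(path)
}

#' @rdname write_umbrella_csv
#' @export
read_umbrella_csv <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "center_nm,k_kJ_mol_nm2")
    stop("not an umbrella-window CSV")
  hdr <- as.numeric(strsplit(lines[2], ",")[[1]])
  umbrella_window(hdr[1], hdr[2], as.numeric(lines[-(1:2)]))
}
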