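#' Detect the peak of a current trace
#'
#' Extremum (largest absolute current) of a 3-point-median-smoothed trace
#' within a window after stimulus onset.
#'
#' @param trace a [current_trace()].
#' @param window_after_onset search window length (ms).
#' @return list with `t_peak` (ms), `i_peak` (signed, on the raw trace)
#'   and `index`.
#' @export
detect_peak <- function(trace, window_after_onset = 20) {
  t0 <- trace$stimulus_onset
  if (t0 < min(trace$t) || t0 > max(trace$t))
    stop("stimulus onset outside trace")
  sel <- which(trace$t >= t0 & trace$t <= t0 + window_after_onset)
  if (length(sel) == 0) stop("peak window outside trace")
  sm <- stats::runmed(trace$i, 3)[sel]
  j <- which.max(abs(sm))
  k <- sel[j]
  # the smoothed extremum, not the raw sample: a single noisy sample at
  # the argmax would bias peak amplitudes upward
  list(t_peak = trace$t[k], i_peak = unname(sm[j]), index = k)
}

#' Fit exponential decay of desensitization entry
#'
#' Fits \eqn{y(t) = \sum_i A_i \exp(-t/\tau_i) + y_\infty} (first- or
#' second-order) to the segment from the detected peak to the end of the
#' agonist application, by nonlinear least squares from log-linear /
#' tail-peeling initial guesses.  When `order` is `NULL` the order is
#' selected by AIC.  The trace is normalized to peak = 1 for fitting;
#' amplitudes are reported on the original scale.  The baseline
#' \eqn{y_\infty} is fixed to the pre-stimulus mean.  Weighted time
#' constant: \eqn{\tau_w = \sum_i A_i\tau_i / \sum_i A_i}
#' (amplitude-fraction weighting).
#'
#' @param trace a [current_trace()].
#' @param order 1, 2, or `NULL` for automatic selection: the
#'   second-order fit is kept when it lowers the AIC by more than 10 (the
#'   conventional "strong evidence" margin; a genuine second kinetic
#'   component at these sampling rates improves the AIC by hundreds) *and*
#'   its extra component is meaningful (each amplitude at least 5% of the
#'   total, time constants separated by at least 1.5-fold) — a negligible
#'   or degenerate second exponential is noise, not kinetics.
#' @param peak_window passed to [detect_peak()].
#' @return object of class `decay_fit`: `order`, `amplitudes`, `taus`
#'   (ascending for order 2), `tau_weighted`, `baseline`, `rss`, `aic`,
#'   `at_bounds`.
#' @export
fit_decay <- function(trace, order = NULL, peak_window = 20) {
  pk <- detect_peak(trace, peak_window)
  sel <- which(trace$t >= pk$t_peak & trace$t <= trace$stimulus_end)
  if (length(sel) < 10) stop("decay segment has fewer than 10 samples")
  pre <- trace$i[trace$t < trace$stimulus_onset]
  baseline <- if (length(pre)) mean(pre) else 0
  sgn <- sign(pk$i_peak - baseline)
  amp0 <- abs(pk$i_peak - baseline)
  if (amp0 == 0) stop("zero peak amplitude")
  tt <- trace$t[sel] - pk$t_peak
  yy <- sgn * (trace$i[sel] - baseline) / amp0   # decays from ~1 to ~0

  fits <- list()
  if (is.null(order) || order == 1) fits$`1` <- fit_exp_sum(tt, yy, 1)
  if (is.null(order) || order == 2) {
    # a biexponential fit can be degenerate on truly monoexponential
    # data; fall back to order 1 rather than fail
    f2 <- tryCatch(fit_exp_sum(tt, yy, 2), error = function(e) NULL)
    if (!is.null(f2)) fits$`2` <- f2
    else if (!is.null(order)) stop("second-order decay fit failed")
  }
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  best <- fits[[which.min(aics)]]
  if (is.null(order) && best$order == 2 && !is.null(fits$`1`)) {
    afrac <- min(abs(best$A)) / sum(abs(best$A))
    sep <- max(best$tau) / max(min(best$tau), 1e-12)
    if (fits$`1`$aic - best$aic < 10 || afrac < 0.05 || sep < 1.5)
      best <- fits$`1`
  }
  ord <- best$order
  A <- best$A * amp0 * sgn
  taus <- best$tau
  o <- order(taus)
  taus <- taus[o]; A <- A[o]
  at_bounds <- any(taus <= 1.001e-3 | taus >= 0.999e4)
  if (at_bounds) warning("fitted tau at parameter bounds")
  structure(list(order = ord, amplitudes = A, taus = taus,
                 tau_weighted = sum(abs(A) * taus) / sum(abs(A)),
                 baseline = baseline, rss = best$rss, aic = best$aic,
                 at_bounds = at_bounds),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "<decay_fit: order %d, tau = %s ms, tau_weighted = %.3g ms>\n",
    x$order, paste(sprintf("%.3g", x$taus), collapse = ", "),
    x$tau_weighted))
  invisible(x)
}

# Sum-of-exponentials least squares on normalized data (Levenberg-
# Marquardt on the residual function); bounds 1e-3..1e4 ms on tau.
fit_exp_sum <- function(tt, yy, order) {
  pos <- yy > 0.02
  # log-linear guess for the dominant (slow for tail, fast overall) decay
  tau1 <- tryCatch({
    f <- stats::lm(log(yy[pos]) ~ tt[pos])
    max(min(-1 / stats::coef(f)[2], 1e4), 1e-3)
  }, error = function(e) max(tt) / 3)
  if (!is.finite(tau1) || tau1 <= 0) tau1 <- max(tt) / 3
  if (order == 1) {
    start <- c(A1 = 1, lt1 = log(tau1))
  } else {
    # peel: slow component from the tail of the informative region
    t_half <- if (any(pos)) stats::median(tt[pos]) else stats::median(tt)
    tail_sel <- tt > t_half & pos
    tau_s <- tryCatch({
      f <- stats::lm(log(yy[tail_sel]) ~ tt[tail_sel])
      max(min(-1 / stats::coef(f)[2], 1e4), 1e-3)
    }, error = function(e) tau1 * 3)
    if (!is.finite(tau_s) || tau_s <= 0) tau_s <- tau1 * 3
    tau_f <- max(tau_s / 5, 1e-3)
    start <- c(A1 = 0.6, lt1 = log(tau_f), A2 = 0.4, lt2 = log(tau_s))
  }
  model <- function(p) {
    m <- rep(0, length(tt))
    for (k in seq_len(order))
      m <- m + p[2 * k - 1] * exp(-tt / exp(p[2 * k]))
    m
  }
  run_lm <- function(st) minpack.lm::nls.lm(
    st, fn = function(p) yy - model(p),
    lower = rep(c(-2, log(1e-3)), order),
    upper = rep(c(2, log(1e4)), order),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  fit <- run_lm(start)
  if (order == 2) {
    # second start bracketing the log-linear guess; keep the better fit
    alt <- run_lm(c(A1 = 0.5, lt1 = log(max(tau1 / 4, 2e-3)),
                    A2 = 0.5, lt2 = log(min(tau1 * 4, 9e3))))
    if (sum(alt$fvec^2) < sum(fit$fvec^2)) fit <- alt
  }
  p <- fit$par
  A <- p[seq(1, 2 * order, by = 2)]
  tau <- exp(p[seq(2, 2 * order, by = 2)])
  rss <- sum(fit$fvec^2)
  n <- length(yy)
  aic <- n * log(rss / n) + 2 * (2 * order)
  list(order = order, A = unname(A), tau = unname(tau), rss = rss,
       aic = aic)
}

#' Peak-ratio recovery series from paired pulses
#'
#' For each interpulse interval, the test-pulse peak amplitude as a
#' fraction of the initial-pulse peak amplitude.
#'
#' @param initial_pulses list of [current_trace()] (first pulse), one per
#'   interval.
#' @param test_pulses list of [current_trace()] (second pulse), matched.
#' @param intervals interpulse intervals (ms), ascending.
#' @param peak_window passed to [detect_peak()].
#' @return a [recovery_series()].
#' @export
recovery_ratios <- function(initial_pulses, test_pulses, intervals,
                            peak_window = 20) {
  if (length(initial_pulses) != length(test_pulses) ||
      length(intervals) != length(initial_pulses))
    stop("need one pulse pair per interval")
  o <- order(intervals)
  r <- vapply(seq_along(intervals), function(j) {
    p1 <- detect_peak(initial_pulses[[j]], peak_window)
    p2 <- detect_peak(test_pulses[[j]], peak_window)
    if (p1$i_peak == 0) stop("zero initial-pulse peak")
    abs(p2$i_peak) / abs(p1$i_peak)
  }, numeric(1))
  recovery_series(intervals[o], pmin(r[o], 1.1))
}

#' Fit first-order recovery from desensitization
#'
#' Fits \eqn{r(\Delta t) = 1 - (1 - r_0)\exp(-\Delta t/\tau)} to a
#' two-pulse recovery series, with the zero-interval ratio \eqn{r_0 \ge 0}
#' free by default.
#'
#' @param series a [recovery_series()] with at least 4 intervals.
#' @param r0 fix the zero-interval ratio, or `NULL` (default) to fit it.
#' @return list with `tau_recov` (ms), `r0` and the `fit` object.
#' @export
fit_recovery <- function(series, r0 = NULL) {
  ivl <- series$interpulse_intervals   # avoid masking stats::dt in nls
  r <- series$peak_ratios
  if (length(ivl) < 4) stop("need at least 4 intervals")
  if (all(abs(r - 1) < 0.02)) {
    warning("all ratios ~ 1: no desensitization to recover from")
  }
  tau0 <- max(ivl[which.min(abs(r - (1 - exp(-1))))], min(ivl))
  if (is.null(r0)) {
    fit <- minpack.lm::nls.lm(
      c(r0f = max(0, min(r) / 2), ltau = log(tau0)),
      fn = function(p) r - (1 - (1 - p[1]) * exp(-ivl / exp(p[2]))),
      lower = c(0, log(1e-3)), upper = c(1, log(1e5)),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    list(tau_recov = unname(exp(fit$par[2])), r0 = unname(fit$par[1]),
         fit = fit)
  } else {
    fit <- minpack.lm::nls.lm(
      c(ltau = log(tau0)),
      fn = function(p) r - (1 - (1 - r0) * exp(-ivl / exp(p[1]))),
      lower = log(1e-3), upper = log(1e5),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    list(tau_recov = unname(exp(fit$par[1])), r0 = r0, fit = fit)
  }
}

#' Peak-amplitude ratio between two traces
#'
#' Ratio of absolute peak amplitudes, e.g. the low-pH versus neutral-pH
#' glutamate-evoked peak.
#'
#' @param trace_low_ph,trace_ref [current_trace()] objects.
#' @param peak_window passed to [detect_peak()].
#' @return |peak_low| / |peak_ref|.
#' @export
peak_ratio_ph <- function(trace_low_ph, trace_ref, peak_window = 20) {
  p1 <- detect_peak(trace_low_ph, peak_window)
  p2 <- detect_peak(trace_ref, peak_window)
  if (p2$i_peak == 0) stop("zero reference peak")
  abs(p1$i_peak) / abs(p2$i_peak)
}

#' Read / write current traces and recovery series as CSV
#'
#' Trace CSV: metadata header lines `# onset_ms=...`, `# end_ms=...`,
#' then `t_ms,i_pA` rows.  Recovery CSV: `interval_ms,ratio`.
#'
#' @param trace a [current_trace()].
#' @param path file path.
#' @return writers return `path` invisibly; readers the parsed object.
#' @export
write_trace_csv <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# onset_ms=%.10g", trace$stimulus_onset),
               sprintf("# end_ms=%.10g", trace$stimulus_end),
               "t_ms,i_pA",
               sprintf("%.10g,%.10g", trace$t, trace$i)), con)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  getval <- function(key, default) {
    m <- grep(paste0("^# ", key, "="), meta, value = TRUE)
    if (length(m)) as.numeric(sub(paste0("^# ", key, "="), "", m[1]))
    else default
  }
  tab <- utils::read.csv(text = lines[!startsWith(lines, "#")])
  current_trace(tab[[1]], tab[[2]],
                stimulus_onset = getval("onset_ms", 0),
                stimulus_end = getval("end_ms", max(tab[[1]])))
}

#' @rdname write_trace_csv
#' @param series a [recovery_series()].
#' @export
write_recovery_csv <- function(series, path) {
  utils::write.csv(data.frame(interval_ms = series$interpulse_intervals,
                              ratio = series$peak_ratios),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_recovery_csv <- function(path) {
  tab <- utils::read.csv(path)
  recovery_series(tab$interval_ms, tab$ratio)
}
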