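#' Small-angle scattering curve
#'
#' Container for a measured or computed small-angle scattering profile:
#' momentum transfer `q` (\eqn{\mathrm{\AA}^{-1}}, strictly increasing),
#' intensity `I` (arbitrary units) and, optionally, the standard error
#' `sigma` of `I`.  Measured curves must have `q > 0`; computed curves may
#' carry a `q = 0` anchor point.
#'
#' @param q numeric, momentum transfer in inverse Angstrom, strictly
#'   increasing.
#' @param I numeric, intensity, same length as `q`.
#' @param sigma optional numeric, standard error of `I`, positive where
#'   present.
#' @param label optional character tag.
#' @param computed logical; computed curves may include `q = 0`.
#' @return An object of class `scattering_curve`: a data frame with columns
#'   `q`, `I` and (if given) `sigma`.
#' @export
scattering_curve <- function(q, I, sigma = NULL, label = NULL,
                             computed = FALSE) {
  q <- as.numeric(q); I <- as.numeric(I)
  if (length(q) != length(I)) stop("q and I must have the same length")
  if (any(!is.finite(q)) || any(!is.finite(I)))
    stop("q and I must be finite")
  if (any(diff(q) <= 0)) stop("q must be strictly increasing")
  if (computed) {
    if (q[1] < 0) stop("q must be non-negative")
  } else if (q[1] <= 0) stop("measured curves require q > 0")
  df <- data.frame(q = q, I = I)
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q)) stop("sigma length mismatch")
    if (any(!is.finite(sigma)) || any(sigma <= 0))
      stop("sigma must be finite and positive")
    df$sigma <- sigma
  }
  structure(df, class = c("scattering_curve", "data.frame"),
            label = label)
}

#' @export
print.scattering_curve <- function(x, ...) {
  lab <- attr(x, "label")
  cat(sprintf("<scattering_curve%s: %d points, q in [%.4g, %.4g] A^-1%s>\n",
              if (is.null(lab)) "" else paste0(" '", lab, "'"),
              nrow(x), min(x$q), max(x$q),
              if ("sigma" %in% names(x)) ", with sigma" else ""))
  invisible(x)
}

has_sigma <- function(curve) "sigma" %in% names(curve)

check_shared_grid <- function(a, b, tol = 1e-9) {
  if (nrow(a) != nrow(b) || any(abs(a$q - b$q) > tol * pmax(1, abs(a$q))))
    stop("curves are not on the same q grid")
  invisible(TRUE)
}

#' Read / write three-column scattering data
#'
#' Plain-text `.dat` dialect: whitespace-separated columns
#' `q[A^-1] I sigma` (sigma optional), `#`-prefixed header lines ignored.
#'
#' @param path file path.
#' @param computed see [scattering_curve()].
#' @return `read_sas_dat` returns a [scattering_curve()];
#'   `write_sas_dat` returns `path` invisibly.
#' @export
read_sas_dat <- function(path, computed = FALSE) {
  nf <- max(utils::count.fields(path, comment.char = "#"), na.rm = TRUE)
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("q", "I", "sigma")[seq_len(nf)])
  scattering_curve(tab$q, tab$I, sigma = tab$sigma, computed = computed)
}

#' @rdname read_sas_dat
#' @param curve a [scattering_curve()].
#' @param header character vector of comment lines to prepend.
#' @export
write_sas_dat <- function(curve, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(sprintf("# q[A^-1]  I  %s",
                     if (has_sigma(curve)) "sigma" else ""), con)
  cols <- if (has_sigma(curve)) cbind(curve$q, curve$I, curve$sigma)
          else cbind(curve$q, curve$I)
  utils::write.table(format(cols, digits = 10, scientific = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Unit conversion between nm and Angstrom
#'
#' The scattering layer works in Angstrom (coordinates) and inverse
#' Angstrom (q); the collective-variable / free-energy layer works in nm.
#' These helpers are the single conversion point.
#'
#' @param x numeric length(s).
#' @return converted numeric.
#' @export
nm_to_angstrom <- function(x) 10 * x

#' @rdname nm_to_angstrom
#' @export
angstrom_to_nm <- function(x) x / 10
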