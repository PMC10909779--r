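#' Titratable site
#'
#' A residue with an (externally computed) pKa and burial fraction; pKa
#' prediction itself is out of scope and consumed as input.
#'
#' @param label residue label, e.g. `"H229"`.
#' @param pKa acid dissociation constant (dimensionless).
#' @param burial_fraction fraction buried, in \[0, 1\].
#' @return object of class `titratable_site`.
#' @export
titratable_site <- function(label, pKa, burial_fraction = 0) {
  if (burial_fraction < 0 || burial_fraction > 1)
    stop("burial fraction must be in [0, 1]")
  if (!is.finite(pKa)) stop("pKa must be finite")
  structure(list(label = label, pKa = pKa,
                 burial_fraction = burial_fraction),
            class = "titratable_site")
}

#' Henderson-Hasselbalch protonated fraction
#'
#' \deqn{f = \frac{1}{1 + 10^{\,pH - pK_a}}}
#' Strictly decreasing in pH, 0.5 at the midpoint, a 10-fold occupancy
#' change per pH unit on either side of the pKa.
#'
#' @param site a [titratable_site()] or a numeric pKa.
#' @param pH solution pH.
#' @return fraction protonated in (0, 1).
#' @export
protonated_fraction <- function(site, pH) {
  pKa <- if (inherits(site, "titratable_site")) site$pKa else site
  if (!is.finite(pKa) || any(!is.finite(pH))) stop("inputs must be finite")
  1 / (1 + 10^(pH - pKa))
}

#' Read titratable sites from CSV (`label,pKa,burial`)
#'
#' @param path file path.
#' @return list of [titratable_site()].
#' @export
read_sites_csv <- function(path) {
  tab <- utils::read.csv(path)
  lapply(seq_len(nrow(tab)), function(j)
    titratable_site(tab$label[j], tab$pKa[j], tab$burial[j]))
}
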