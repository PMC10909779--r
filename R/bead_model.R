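#' Bead conformation
#'
#' A coarse bead representation of one conformer: coordinates in Angstrom,
#' per-bead scattering lengths (arbitrary units) and a cluster label
#' identifying subunit / NTD membership.
#'
#' @param coords numeric matrix, n x 3, Angstrom.
#' @param scattering_lengths per-bead scattering length; default 1.
#' @param cluster per-bead character or factor tag.
#' @return object of class `bead_conformation`.
#' @export
bead_conformation <- function(coords, scattering_lengths = NULL,
                              cluster = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coords must be an n x 3 matrix")
  if (nrow(coords) < 1) stop("need at least one bead")
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  n <- nrow(coords)
  if (is.null(scattering_lengths)) scattering_lengths <- rep(1, n)
  if (length(scattering_lengths) != n)
    stop("scattering_lengths length mismatch")
  if (is.null(cluster)) cluster <- rep("bead", n)
  if (length(cluster) != n) stop("cluster length mismatch")
  structure(list(coords = coords,
                 b = as.numeric(scattering_lengths),
                 cluster = as.character(cluster)),
            class = "bead_conformation")
}

#' @export
print.bead_conformation <- function(x, ...) {
  cat(sprintf("<bead_conformation: %d beads, clusters: %s>\n",
              nrow(x$coords),
              paste(unique(x$cluster), collapse = ", ")))
  invisible(x)
}

#' Conformational ensemble
#'
#' A list of [bead_conformation()] frames with a per-frame collective
#' variable (NTD-cluster centre-of-mass distance, nm) and optional frame
#' weights.
#'
#' @param frames list of [bead_conformation()].
#' @param cv numeric per-frame collective variable (nm).
#' @param weights optional normalized frame weights.
#' @return object of class `conformational_ensemble`.
#' @export
conformational_ensemble <- function(frames, cv, weights = NULL) {
  if (length(frames) < 1) stop("empty ensemble")
  if (length(cv) != length(frames)) stop("cv length mismatch")
  if (!is.null(weights)) {
    if (length(weights) != length(frames)) stop("weights length mismatch")
    if (any(weights < 0)) stop("weights must be non-negative")
    weights <- weights / sum(weights)
  }
  structure(list(frames = frames, cv = as.numeric(cv), weights = weights),
            class = "conformational_ensemble")
}

#' @export
print.conformational_ensemble <- function(x, ...) {
  cat(sprintf(
    "<conformational_ensemble: %d frames, cv in [%.3g, %.3g] nm%s>\n",
    length(x$frames), min(x$cv), max(x$cv),
    if (is.null(x$weights)) ", unweighted" else ", weighted"))
  invisible(x)
}

#' Bias trace of a biased (metadynamics-like) simulation
#'
#' Per-frame collective-variable values (nm) and bias energies (kJ/mol),
#' with the thermal energy kT used to convert bias to weights.
#'
#' @param cv numeric, NTD distance per frame (nm).
#' @param bias_energy numeric, bias potential per frame (kJ/mol).
#' @param kT thermal energy (kJ/mol).
#' @return object of class `bias_trace`.
#' @export
bias_trace <- function(cv, bias_energy, kT) {
  if (length(cv) != length(bias_energy)) stop("length mismatch")
  if (any(!is.finite(bias_energy))) stop("bias energies must be finite")
  if (kT <= 0) stop("kT must be positive")
  structure(list(cv = as.numeric(cv),
                 bias_energy = as.numeric(bias_energy),
                 kT = kT),
            class = "bias_trace")
}

# ---- minimal PDB / XYZ round-trip for bead models -------------------------

#' Write / read bead ensembles as minimal multi-model PDB
#'
#' One `MODEL`/`ENDMDL` block per frame, beads as CA `ATOM` records
#' (occupancy column carries the scattering length, chain id the cluster).
#' This is a minimal bead-model dialect, not general PDB handling.
#'
#' @param ensemble a [conformational_ensemble()] or single
#'   [bead_conformation()].
#' @param path file path.
#' @return `write_bead_pdb` returns `path` invisibly; `read_bead_pdb`
#'   returns a list of [bead_conformation()].
#' @export
write_bead_pdb <- function(ensemble, path) {
  frames <- if (inherits(ensemble, "bead_conformation")) list(ensemble)
            else ensemble$frames
  con <- file(path, "w")
  on.exit(close(con))
  chains <- c(LETTERS, letters, 0:9)
  for (m in seq_along(frames)) {
    fr <- frames[[m]]
    writeLines(sprintf("MODEL     %4d", m), con)
    cl <- factor(fr$cluster, levels = unique(fr$cluster))
    writeLines(sprintf(
      "ATOM  %5d  CA  BEA %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      seq_len(nrow(fr$coords)),
      chains[pmin(as.integer(cl), length(chains))],
      seq_len(nrow(fr$coords)),
      fr$coords[, 1], fr$coords[, 2], fr$coords[, 3],
      fr$b, 0), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' @rdname write_bead_pdb
#' @export
read_bead_pdb <- function(path) {
  lines <- readLines(path)
  frames <- list()
  cur <- NULL
  cluster_of <- character()
  for (ln in lines) {
    tag <- substr(ln, 1, 6)
    if (tag == "MODEL ") {
      cur <- character()
    } else if (startsWith(tag, "ATOM")) {
      cur <- c(cur, ln)
    } else if (tag == "ENDMDL") {
      x <- as.numeric(substr(cur, 31, 38))
      y <- as.numeric(substr(cur, 39, 46))
      z <- as.numeric(substr(cur, 47, 54))
      b <- as.numeric(substr(cur, 55, 60))
      ch <- substr(cur, 22, 22)
      frames[[length(frames) + 1L]] <-
        bead_conformation(cbind(x, y, z), b, ch)
      cur <- NULL
    }
  }
  if (length(frames) == 0) stop("no MODEL/ENDMDL blocks found")
  frames
}

#' Write / read bead coordinates as whitespace XYZ
#'
#' Columns: cluster label, x, y, z (Angstrom), scattering length; `#`
#' comments allowed.
#'
#' @param conf a [bead_conformation()].
#' @param path file path.
#' @return `write_bead_xyz` returns `path` invisibly; `read_bead_xyz` a
#'   [bead_conformation()].
#' @export
write_bead_xyz <- function(conf, path) {
  df <- data.frame(cluster = conf$cluster, conf$coords, b = conf$b)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# cluster x[A] y[A] z[A] b", con)
  utils::write.table(df, con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_bead_xyz
#' @export
read_bead_xyz <- function(path) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("cluster", "x", "y", "z", "b"))
  bead_conformation(as.matrix(tab[, c("x", "y", "z")]), tab$b, tab$cluster)
}
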