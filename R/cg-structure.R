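#' Coarse-grained structure (one bead per residue)
#'
#' A `cg_structure` holds per-bead coordinates (nm), bead radii (nm), chain
#' identifiers and integer residue indices. Both simulated configurations and
#' reference (native) conformations use this container. All lengths are nm
#' throughout the package; PDB Angstroms are converted on read.
#'
#' Structures entering the dynamics and topology builders need at least two
#' beads; single-bead (or empty) structures are permitted so renderers can be
#' exercised on minimal fixtures.
#'
#' @param coords numeric n x 3 matrix of bead centers (nm).
#' @param radius bead radii in nm; scalar recycled, default 0.38 (about half
#'   the Calpha-Calpha spacing).
#' @param chain chain identifier per bead; scalar recycled.
#' @param resid integer residue index per bead, strictly increasing within
#'   each chain; default sequential.
#' @param label free-text label (e.g. `"down_up"`).
#' @return an object of class `cg_structure`.
#' @export
cg_structure <- function(coords, radius = 0.38, chain = "A", resid = NULL,
                         label = "") {
  coords <- as.matrix(coords)
  if (length(coords) == 0L) coords <- matrix(numeric(0), 0L, 3L)
  if (ncol(coords) != 3L) stop("coords must have 3 columns")
  n <- nrow(coords)
  radius <- rep_len(as.numeric(radius), n)
  chain <- rep_len(as.character(chain), n)
  if (is.null(resid)) {
    resid <- integer(n)
    for (ch in unique(chain)) resid[chain == ch] <- seq_len(sum(chain == ch))
  }
  resid <- rep_len(as.integer(resid), n)
  x <- structure(list(coords = coords, radius = radius, chain = chain,
                      resid = resid, label = as.character(label)[1]),
                 class = "cg_structure")
  validate_cg_structure(x)
  x
}

validate_cg_structure <- function(x) {
  if (nrow(x$coords) > 0 && !all(is.finite(x$coords)))
    stop("cg_structure: coordinates must be finite")
  if (any(x$radius <= 0)) stop("cg_structure: bead radii must be > 0")
  for (ch in unique(x$chain)) {
    r <- x$resid[x$chain == ch]
    if (length(r) > 1 && any(diff(r) <= 0))
      stop("cg_structure: residue indices must be strictly increasing within chain ", ch)
  }
  invisible(x)
}

#' @export
print.cg_structure <- function(x, ...) {
  cat(sprintf("<cg_structure> %d beads, %d chain(s)%s\n", nrow(x$coords),
              length(unique(x$chain)),
              if (nzchar(x$label)) paste0(", label: ", x$label) else ""))
  invisible(x)
}

#' Number of beads in a structure
#' @param x a `cg_structure`.
#' @export
n_beads <- function(x) nrow(x$coords)

#' Read a PDB file as a coarse-grained structure
#'
#' Extracts one bead per residue at the Calpha position and converts
#' coordinates from Angstrom to nm. Residues without a Calpha atom are
#' skipped with a warning; a file yielding zero beads is an error.
#'
#' @param path path to a PDB file.
#' @param radius bead radius in nm applied to every bead (default 0.38).
#' @param label label stored on the returned structure.
#' @return a [cg_structure()].
#' @export
read_pdb_as_cg <- function(path, radius = 0.38, label = "") {
  pdb <- bio3d::read.pdb(path)
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no ATOM records in ", path)
  atoms$chain[is.na(atoms$chain)] <- " "
  res_key <- paste(atoms$chain, atoms$resno, atoms$insert)
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  ca_key <- paste(ca$chain, ca$resno, ca$insert)
  missing_ca <- setdiff(unique(res_key), unique(ca_key))
  if (length(missing_ca) > 0)
    warning(length(missing_ca), " residue(s) without a Calpha atom skipped")
  ca <- ca[!duplicated(ca_key), , drop = FALSE]
  if (nrow(ca) == 0L) stop("no Calpha atoms found in ", path)
  ord <- order(ca$chain, ca$resno)
  ca <- ca[ord, , drop = FALSE]
  cg_structure(coords = cbind(ca$x, ca$y, ca$z) / 10,
               radius = radius, chain = ca$chain, resid = ca$resno,
               label = label)
}

#' Write a coarse-grained structure as a Calpha-only PDB file
#'
#' Coordinates are converted nm to Angstrom. Chains longer than single
#' characters are truncated to their first character in the PDB output.
#'
#' @param x a `cg_structure`.
#' @param path output path.
#' @export
write_cg_pdb <- function(x, path) {
  xyz <- x$coords * 10
  ch <- substr(x$chain, 1L, 1L)
  lines <- sprintf(
    "ATOM  %5d  CA  ALA %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(xyz)) %% 100000L, ch, x$resid %% 10000L,
    xyz[, 1], xyz[, 2], xyz[, 3])
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Root-mean-square deviation between two structures
#'
#' With `superpose = TRUE` the optimal rigid superposition (Kabsch) of `a`
#' onto `b` is removed first, leaving only internal deformation.
#'
#' @param a,b `cg_structure`s with identical bead counts.
#' @param superpose remove the best-fit rigid transform first?
#' @export
rmsd <- function(a, b, superpose = FALSE) {
  if (n_beads(a) != n_beads(b)) stop("bead counts differ")
  X <- a$coords; Y <- b$coords
  if (superpose) {
    Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
    s <- svd(crossprod(Xc, Yc))
    d <- sign(det(s$u %*% t(s$v)))
    R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
    X <- Xc %*% R; Y <- Yc
  }
  sqrt(mean(rowSums((X - Y)^2)))
}
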