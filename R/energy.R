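#' Build a structure-based (Go-type) topology from a reference structure
#'
#' The potential's terms are derived from exactly one reference
#' conformation, which thereby becomes the model's energy minimum:
#' * harmonic bonds `k_b (d - d0)^2` for every pair of consecutive beads
#'   within a chain, at the reference length;
#' * harmonic angles `k_a (theta - theta0)^2` for consecutive bead triples;
#' * Gaussian native-contact wells `-eps exp(-(d - d0)^2 / (2 w^2))` for all
#'   bead pairs closer than `contact_cutoff` in the reference that are at
#'   least 3 residues apart (or on different chains);
#' * soft-core excluded volume `e [(s/d)^12 - 2 (s/d)^6 + 1]` for `d < s =
#'   r_i + r_j` between all remaining pairs.
#'
#' This is the classic structure-based substitute for a full sequence-
#' dependent coarse-grained force field: the fitting method only relies on
#' the chosen reference being the stable state.
#'
#' @param reference a [cg_structure()] (the native conformation).
#' @param contact_cutoff native-contact distance cutoff between bead centers
#'   (nm). Default 0.65, suiting one-bead-per-residue protein models; larger
#'   toy geometries need a cutoff on their own length scale.
#' @param bond_k,angle_k harmonic constants (energy/nm^2, energy/rad^2).
#' @param contact_eps,contact_width well depth (energy) and width (nm).
#' @param ev_eps excluded-volume strength (energy).
#' @return an object of class `topology`.
#' @export
build_topology <- function(reference, contact_cutoff = 0.65,
                           bond_k = 10, angle_k = 10,
                           contact_eps = 3, contact_width = 0.7,
                           ev_eps = 0.2) {
  if (contact_cutoff <= 0) stop("contact_cutoff must be > 0")
  if (n_beads(reference) < 2L) stop("reference needs at least 2 beads")
  xyz <- reference$coords
  chain <- reference$chain
  resid <- reference$resid
  n <- nrow(xyz)

  bonds <- list(); angles <- list()
  for (ch in unique(chain)) {
    idx <- which(chain == ch)
    if (length(idx) < 2L) {
      warning("chain ", ch, " has < 2 beads: no bonded terms for it")
      next
    }
    i <- idx[-length(idx)]; j <- idx[-1]
    bonds[[ch]] <- data.frame(i = i, j = j,
                              r0 = sqrt(rowSums((xyz[i, , drop = FALSE] -
                                                 xyz[j, , drop = FALSE])^2)),
                              k = bond_k)
    if (length(idx) >= 3L) {
      a <- idx[1:(length(idx) - 2)]; b <- idx[2:(length(idx) - 1)]
      c_ <- idx[3:length(idx)]
      th0 <- vapply(seq_along(a), function(t) {
        u <- xyz[a[t], ] - xyz[b[t], ]; v <- xyz[c_[t], ] - xyz[b[t], ]
        acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
      }, numeric(1))
      angles[[ch]] <- data.frame(i = a, j = b, k = c_, th0 = th0,
                                 kang = angle_k)
    }
  }
  bonds <- if (length(bonds)) do.call(rbind, unname(bonds)) else
    data.frame(i = integer(0), j = integer(0), r0 = numeric(0), k = numeric(0))
  angles <- if (length(angles)) do.call(rbind, unname(angles)) else
    data.frame(i = integer(0), j = integer(0), k = integer(0),
               th0 = numeric(0), kang = numeric(0))

  # native contacts: all pairs within cutoff, >= 3 residues apart or on
  # different chains
  D <- as.matrix(stats::dist(xyz))
  eligible <- outer(chain, chain, "!=") |
    abs(outer(resid, resid, "-")) >= 3L
  pick <- which(upper.tri(D) & D < contact_cutoff & eligible, arr.ind = TRUE)
  contacts <- data.frame(i = as.integer(pick[, 1]), j = as.integer(pick[, 2]),
                         r0 = D[pick],
                         eps = rep_len(contact_eps, nrow(pick)),
                         width = rep_len(contact_width, nrow(pick)))

  structure(list(bonds = bonds, angles = angles, contacts = contacts,
                 ev_eps = ev_eps, n_beads = n,
                 chain = chain, resid = resid,
                 reference_label = reference$label,
                 build_args = list(contact_cutoff = contact_cutoff,
                                   bond_k = bond_k, angle_k = angle_k,
                                   contact_eps = contact_eps,
                                   contact_width = contact_width,
                                   ev_eps = ev_eps)),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("<topology> %d beads: %d bonds, %d angles, %d contacts%s\n",
              x$n_beads, nrow(x$bonds), nrow(x$angles), nrow(x$contacts),
              if (nzchar(x$reference_label))
                paste0(" (reference: ", x$reference_label, ")") else ""))
  invisible(x)
}

topo_to_cpp <- function(topo) {
  list(bonds_ij = cbind(topo$bonds$i, topo$bonds$j) - 1L,
       bonds_r0 = topo$bonds$r0, bonds_k = topo$bonds$k,
       angles_ijk = cbind(topo$angles$i, topo$angles$j, topo$angles$k) - 1L,
       angles_th0 = topo$angles$th0, angles_k = topo$angles$kang,
       contacts_ij = cbind(topo$contacts$i, topo$contacts$j) - 1L,
       contacts_r0 = topo$contacts$r0, contacts_eps = topo$contacts$eps,
       contacts_w = topo$contacts$width,
       ev_eps = topo$ev_eps)
}

#' Rebuild a topology from a different reference conformation
#'
#' Builds a new topology from `reference_to` with the identical term rules
#' and constants used for `topology_from`. Switching the reference switches
#' which conformational state the potential stabilizes; term counts may
#' differ because the native-contact set changes with the geometry.
#'
#' @param topology_from the existing `topology` (supplies the build rules).
#' @param reference_to a [cg_structure()] with the same bead count and chain
#'   layout.
#' @return a new `topology`.
#' @export
switch_reference <- function(topology_from, reference_to) {
  if (n_beads(reference_to) != topology_from$n_beads ||
      !identical(as.character(reference_to$chain), as.character(topology_from$chain)) ||
      !identical(as.integer(reference_to$resid), as.integer(topology_from$resid)))
    stop("chain layout mismatch: reference_to must match the existing topology")
  do.call(build_topology, c(list(reference = reference_to),
                            topology_from$build_args))
}

#' Protein energy and forces under a structure-based topology
#'
#' @param structure a [cg_structure()] with the topology's bead count.
#' @param topology a [build_topology()] result.
#' @return list with `energy` (scalar) and `forces` (n x 3, analytic
#'   negative gradient).
#' @export
protein_energy_forces <- function(structure, topology) {
  if (n_beads(structure) != topology$n_beads)
    stop("structure and topology bead counts differ")
  cpp_protein_energy_forces(structure$coords, structure$radius,
                            topo_to_cpp(topology))
}

#' Lennard-Jones stage wall parameters
#'
#' A per-bead 12-6 potential in the bead's z coordinate only (flat infinite
#' stage at z = 0): `eps [(sigma/z)^12 - 2 (sigma/z)^6]`, minimum `-eps` at
#' `z = sigma`; the force is purely vertical.
#'
#' @param epsilon well depth (energy), >= 0.
#' @param sigma minimum position (nm) — scalar, or `NULL` to use each bead's
#'   radius.
#' @export
stage_params <- function(epsilon = 0.2, sigma = NULL) {
  if (epsilon < 0) stop("epsilon must be >= 0")
  if (!is.null(sigma) && any(sigma <= 0)) stop("sigma must be > 0")
  structure(list(epsilon = epsilon, sigma = sigma), class = "stage_params")
}

stage_sigma_vec <- function(structure, params) {
  if (is.null(params$sigma)) structure$radius
  else rep_len(params$sigma, n_beads(structure))
}

#' Stage energy and forces
#'
#' Below `0.7 sigma` the wall is continued linearly (value and slope
#' matched) so a bead that ever penetrates the stage still feels a finite
#' restoring force; a message reports when the cap was active.
#'
#' @param structure a [cg_structure()].
#' @param params a [stage_params()].
#' @return list with `energy` and `forces` (n x 3).
#' @export
stage_energy_forces <- function(structure, params = stage_params()) {
  out <- cpp_stage_energy_forces(structure$coords,
                                 stage_sigma_vec(structure, params),
                                 params$epsilon)
  if (out$n_capped > 0)
    message(out$n_capped, " bead(s) below the stage cap height; ",
            "linear continuation applied")
  out[c("energy", "forces")]
}

#' Harmonic restraint set with a stepwise strength schedule
#'
#' Used for assembly: e.g. pulling a motif onto its binding site by
#' gradually increasing the restraint strength over five steps.
#'
#' @param anchors data frame with columns `bead` (index), `x`, `y`, `z`
#'   (target point, nm), `k` (energy/nm^2) and `d0` (equilibrium distance,
#'   nm); may be empty.
#' @param pairs data frame with columns `i`, `j`, `k`, `d0`; may be empty.
#' @param schedule non-decreasing strength multipliers; default the
#'   five-step ramp `(0.2, 0.4, 0.6, 0.8, 1.0)`.
#' @export
restraint_set <- function(anchors = NULL, pairs = NULL,
                          schedule = c(0.2, 0.4, 0.6, 0.8, 1.0)) {
  if (is.null(anchors))
    anchors <- data.frame(bead = integer(0), x = numeric(0), y = numeric(0),
                          z = numeric(0), k = numeric(0), d0 = numeric(0))
  if (is.null(pairs))
    pairs <- data.frame(i = integer(0), j = integer(0), k = numeric(0),
                        d0 = numeric(0))
  if (any(anchors$k < 0) || any(pairs$k < 0))
    stop("restraint spring constants must be >= 0")
  if (is.unsorted(schedule)) stop("schedule must be non-decreasing")
  structure(list(anchors = anchors, pairs = pairs, schedule = schedule),
            class = "restraint_set")
}

restraints_to_cpp <- function(r, n) {
  if (is.null(r)) r <- restraint_set()
  if (nrow(r$anchors) > 0 && (any(r$anchors$bead < 1) || any(r$anchors$bead > n)))
    stop("anchor bead index out of range")
  list(an_idx = as.integer(r$anchors$bead) - 1L,
       an_xyz = cbind(r$anchors$x, r$anchors$y, r$anchors$z),
       an_k = as.numeric(r$anchors$k), an_d0 = as.numeric(r$anchors$d0),
       pr_ij = cbind(as.integer(r$pairs$i), as.integer(r$pairs$j)) - 1L,
       pr_k = as.numeric(r$pairs$k), pr_d0 = as.numeric(r$pairs$d0))
}

#' Restraint energy and forces at a schedule stage
#'
#' `sum 0.5 k_eff (d - d0)^2` with `k_eff = k * schedule[stage_index]`.
#'
#' @param structure a [cg_structure()].
#' @param restraints a [restraint_set()].
#' @param stage_index 1-based index into the schedule.
#' @return list with `energy` and `forces`.
#' @export
restraint_energy_forces <- function(structure, restraints, stage_index = 1L) {
  if (stage_index < 1L || stage_index > length(restraints$schedule))
    stop("stage_index outside the schedule")
  rc <- restraints_to_cpp(restraints, n_beads(structure))
  cpp_restraint_energy_forces(structure$coords, rc$an_idx, rc$an_xyz,
                              rc$an_k, rc$an_d0, rc$pr_ij, rc$pr_k, rc$pr_d0,
                              restraints$schedule[stage_index])
}

#' Position restraints anchoring beads at their current coordinates
#'
#' Convenience builder, typically used to keep filament beads near their
#' placed positions during fitting while the motor deforms.
#'
#' @param structure a [cg_structure()].
#' @param beads bead indices to anchor (default: all).
#' @param k spring constant (energy/nm^2) per anchored bead.
#' @return a [restraint_set()] with schedule `1`.
#' @export
position_restraints <- function(structure, beads = seq_len(n_beads(structure)),
                                k = 0.2) {
  restraint_set(anchors = data.frame(bead = beads,
                                     x = structure$coords[beads, 1],
                                     y = structure$coords[beads, 2],
                                     z = structure$coords[beads, 3],
                                     k = k, d0 = 0),
                schedule = 1)
}

# ---------------------------------------------------------------------------
# Topology serialization (plain-text, self-describing)
# ---------------------------------------------------------------------------

#' Write a topology to a plain-text file
#'
#' Sections `[meta]`, `[beads]`, `[bonds]`, `[angles]`, `[contacts]` with
#' one whitespace-separated record per line. [read_topology()] inverts it.
#'
#' @param topology a `topology`.
#' @param path output path.
#' @export
write_topology <- function(topology, path) {
  con <- file(path, "w"); on.exit(close(con))
  ba <- topology$build_args
  writeLines(c("# afmflex topology v1", "[meta]",
               paste("n_beads", topology$n_beads),
               paste("ev_eps", sprintf("%.17g", topology$ev_eps)),
               paste("reference_label",
                     if (nzchar(topology$reference_label))
                       gsub("\\s+", "_", topology$reference_label)
                     else "_none_"),
               paste("contact_cutoff", sprintf("%.17g", ba$contact_cutoff)),
               paste("bond_k", sprintf("%.17g", ba$bond_k)),
               paste("angle_k", sprintf("%.17g", ba$angle_k)),
               paste("contact_eps", sprintf("%.17g", ba$contact_eps)),
               paste("contact_width", sprintf("%.17g", ba$contact_width)),
               "[beads]"), con)
  writeLines(paste(topology$chain, topology$resid), con)
  writeLines("[bonds]", con)
  with(topology$bonds, writeLines(sprintf("%d %d %.17g %.17g", i, j, r0, k), con))
  writeLines("[angles]", con)
  with(topology$angles, writeLines(sprintf("%d %d %d %.17g %.17g",
                                           i, j, k, th0, kang), con))
  writeLines("[contacts]", con)
  with(topology$contacts, writeLines(sprintf("%d %d %.17g %.17g %.17g",
                                             i, j, r0, eps, width), con))
  invisible(path)
}

#' Read a topology written by [write_topology()]
#' @param path input path.
#' @return a `topology`.
#' @export
read_topology <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  sec <- cumsum(grepl("^\\[", lines))
  secname <- gsub("\\[|\\]", "", lines[grepl("^\\[", lines)])
  parts <- split(lines, sec)
  get_sec <- function(nm) {
    k <- which(secname == nm)
    if (length(k) == 0) character(0) else parts[[k]][-1]
  }
  meta <- get_sec("meta")
  kv <- do.call(rbind, strsplit(meta, "\\s+", perl = TRUE))
  mv <- function(key) kv[kv[, 1] == key, 2]
  beads <- strsplit(get_sec("beads"), "\\s+")
  chain <- vapply(beads, `[`, character(1), 1)
  resid <- as.integer(vapply(beads, `[`, character(1), 2))
  parse_tab <- function(nm, cols, ints) {
    rows <- get_sec(nm)
    if (length(rows) == 0)
      return(as.data.frame(stats::setNames(
        lapply(seq_along(cols), function(i)
          if (i %in% ints) integer(0) else numeric(0)), cols)))
    m <- do.call(rbind, lapply(strsplit(rows, "\\s+"), as.numeric))
    df <- as.data.frame(m); names(df) <- cols
    for (i in ints) df[[i]] <- as.integer(df[[i]])
    df
  }
  structure(list(
    bonds = parse_tab("bonds", c("i", "j", "r0", "k"), 1:2),
    angles = parse_tab("angles", c("i", "j", "k", "th0", "kang"), 1:3),
    contacts = parse_tab("contacts", c("i", "j", "r0", "eps", "width"), 1:2),
    ev_eps = as.numeric(mv("ev_eps")),
    n_beads = as.integer(mv("n_beads")),
    chain = chain, resid = resid,
    reference_label = {
      lb <- mv("reference_label")
      if (length(lb) == 0 || identical(lb, "_none_")) "" else lb
    },
    build_args = list(contact_cutoff = as.numeric(mv("contact_cutoff")),
                      bond_k = as.numeric(mv("bond_k")),
                      angle_k = as.numeric(mv("angle_k")),
                      contact_eps = as.numeric(mv("contact_eps")),
                      contact_width = as.numeric(mv("contact_width")),
                      ev_eps = as.numeric(mv("ev_eps")))),
    class = "topology")
}
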