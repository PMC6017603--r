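# Geometric binding-mode annotation: hydrogen bonds by donor-acceptor
# distance (plus donor angle when explicit hydrogens are present) and
# pi-pi stacking by aromatic ring-centroid distance.

# Ring atom names of the aromatic residue templates.
.aromatic_rings <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(c("CG", "CD1", "CD2", "NE1", "CE2"),
             c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")))

# Enumerate simple 5-/6-cycles in a small bond graph (adjacency list).
.small_cycles <- function(adj, n) {
  found <- list()
  seen <- character(0)
  walk <- function(path) {
    last <- path[length(path)]
    for (nxt in adj[[last]]) {
      if (length(path) >= 3L && nxt == path[1]) {
        if (length(path) %in% c(5L, 6L)) {
          key <- paste(sort(path), collapse = "-")
          if (!key %in% seen) {
            seen <<- c(seen, key)
            found[[length(found) + 1L]] <<- path
          }
        }
      } else if (!(nxt %in% path) && nxt > path[1] && length(path) < 6L) {
        walk(c(path, nxt))
      }
    }
  }
  for (s in seq_len(n)) walk(s)
  found
}

# Perceive planar 5/6-membered rings in a ligand from distance-based
# connectivity (bond if heavy-atom distance <= bond_cutoff).
.ligand_rings <- function(xyz, elements, bond_cutoff = 1.8,
                          planarity_tol = 0.3) {
  heavy <- which(elements != "H")
  if (length(heavy) < 5L) return(list())
  hx <- xyz[heavy, , drop = FALSE]
  d <- as.matrix(stats::dist(hx))
  adj <- lapply(seq_len(nrow(hx)), function(i) {
    which(d[i, ] <= bond_cutoff & seq_len(nrow(hx)) != i)
  })
  cycles <- .small_cycles(adj, nrow(hx))
  keep <- Filter(function(cyc) {
    pts <- hx[cyc, , drop = FALSE]
    ctr <- colMeans(pts)
    sv <- svd(sweep(pts, 2, ctr))
    normal <- sv$v[, 3]
    all(abs(sweep(pts, 2, ctr) %*% normal) <= planarity_tol)
  }, cycles)
  lapply(keep, function(cyc) heavy[cyc])
}

.ring_centroid <- function(xyz, idx) colMeans(xyz[idx, , drop = FALSE])

#' Annotate protein-ligand contacts of a pose
#'
#' Geometric detection on one protein conformation and one ligand pose:
#'
#' * **H-bond** — donor-acceptor heavy-atom (N/O/S) distance at most
#'   `hbond_dist_max`; when an explicit hydrogen sits on the donor
#'   (within 1.25 A) the donor angle H-D...A must also reach
#'   `hbond_angle_min`, otherwise the distance criterion alone is used
#'   and the angle is reported as NA.
#' * **pi-pi** — aromatic ring-centroid distance at most `pipi_dist_max`
#'   between a protein aromatic residue (PHE/TYR/TRP/HIS templates) and
#'   a planar 5/6-membered ligand ring perceived from distance-based
#'   connectivity (bond cutoff 1.8 A).
#'
#' @param frame a [structure3d()] protein conformation.
#' @param pose_xyz ligand pose coordinates (matrix, Angstrom).
#' @param ligand_topology ligand atom table.
#' @param hbond_dist_max donor-acceptor heavy-atom cutoff (A, default 3.5).
#' @param hbond_angle_min minimal donor angle in degrees (default 120).
#' @param pipi_dist_max ring-centroid cutoff (A, default 5.5).
#' @return data.frame of class `contact_report` with columns `type`
#'   ("hbond"/"pipi"), `ligand_atom`, `protein_residue`, `protein_resid`,
#'   `distance`, `angle` (degrees, NA when no explicit hydrogen).
#' @export
annotate_contacts <- function(frame, pose_xyz, ligand_topology,
                              hbond_dist_max = 3.5, hbond_angle_min = 120,
                              pipi_dist_max = 5.5) {
  stopifnot(inherits(frame, "structure3d"))
  pose_xyz <- .as_coords(pose_xyz)
  topo <- frame$topology
  out <- data.frame(type = character(0), ligand_atom = character(0),
                    protein_residue = character(0),
                    protein_resid = integer(0), distance = numeric(0),
                    angle = numeric(0))
  polar_p <- which(topo$element %in% c("N", "O", "S"))
  polar_l <- which(ligand_topology$element %in% c("N", "O", "S"))
  lig_h <- which(ligand_topology$element == "H")
  prot_h <- which(topo$element == "H")
  donor_angle <- function(d_xyz, h_candidates_xyz, a_xyz) {
    # angle at the hydrogen closest to the donor, D-H...A convention
    if (!nrow(h_candidates_xyz)) return(NA_real_)
    dh <- sqrt(rowSums(sweep(h_candidates_xyz, 2, d_xyz)^2))
    if (min(dh) > 1.25) return(NA_real_)
    h <- h_candidates_xyz[which.min(dh), ]
    v1 <- d_xyz - h; v2 <- a_xyz - h
    acos(pmin(1, pmax(-1, sum(v1 * v2) /
                        (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
  }
  for (ip in polar_p) {
    for (il in polar_l) {
      dist <- sqrt(sum((frame$xyz[ip, ] - pose_xyz[il, ])^2))
      if (dist > hbond_dist_max) next
      # try both donor assignments; keep the contact if either passes
      ang_l <- donor_angle(pose_xyz[il, ],
                           pose_xyz[lig_h, , drop = FALSE],
                           frame$xyz[ip, ])
      ang_p <- donor_angle(frame$xyz[ip, ],
                           frame$xyz[prot_h, , drop = FALSE],
                           pose_xyz[il, ])
      angs <- c(ang_l, ang_p)
      ok <- if (all(is.na(angs))) TRUE else any(angs >= hbond_angle_min,
                                                na.rm = TRUE)
      if (!ok) next
      ang <- if (all(is.na(angs))) NA_real_ else max(angs, na.rm = TRUE)
      out <- rbind(out, data.frame(
        type = "hbond", ligand_atom = ligand_topology$name[il],
        protein_residue = topo$resname[ip], protein_resid = topo$resid[ip],
        distance = dist, angle = ang))
    }
  }
  lig_rings <- .ligand_rings(pose_xyz, ligand_topology$element)
  if (length(lig_rings)) {
    arom <- unique(topo$resid[topo$resname %in% names(.aromatic_rings)])
    for (res in arom) {
      rn <- topo$resname[match(res, topo$resid)]
      for (ring_names in .aromatic_rings[[rn]]) {
        idx <- which(topo$resid == res & topo$name %in% ring_names)
        if (length(idx) < length(ring_names)) next
        cp <- .ring_centroid(frame$xyz, idx)
        for (lr in lig_rings) {
          cl <- .ring_centroid(pose_xyz, lr)
          dist <- sqrt(sum((cp - cl)^2))
          if (dist <= pipi_dist_max) {
            out <- rbind(out, data.frame(
              type = "pipi",
              ligand_atom = paste(ligand_topology$name[lr], collapse = "+"),
              protein_residue = rn, protein_resid = res,
              distance = dist, angle = NA_real_))
          }
        }
      }
    }
  }
  rownames(out) <- NULL
  class(out) <- c("contact_report", "data.frame")
  out
}
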