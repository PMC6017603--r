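# Shrake-Rupley solvent-accessible surface area.
#
# The sphere point set is a deterministic golden-spiral lattice, not a
# random sampling, so areas are exactly reproducible across platforms.

#' Golden-spiral unit sphere points
#'
#' Deterministic quasi-uniform lattice of `n` points on the unit sphere
#' (Fibonacci/golden-angle construction).
#'
#' @param n number of points (>= 1).
#' @return `n x 3` matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (3 - sqrt(5)) * (i - 0.5)
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

.atom_radii <- function(elements, radii) {
  unknown <- setdiff(unique(elements), names(radii))
  if (length(unknown)) {
    stop("no van der Waals radius for element(s): ",
         paste(unknown, collapse = ", "))
  }
  unname(radii[elements])
}

# Core SASA kernel on a coordinate matrix; returns per-atom areas (A^2).
.sasa_atoms <- function(xyz, radii_per_atom, probe, pts) {
  n <- nrow(xyz)
  expanded <- radii_per_atom + probe
  areas <- numeric(n)
  # neighbour pruning: atom j can occlude i only within r_i + r_j (expanded)
  for (i in seq_len(n)) {
    ri <- expanded[i]
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (ri + expanded)^2 & seq_len(n) != i)
    if (!length(nb)) {
      areas[i] <- 4 * pi * ri^2
      next
    }
    surf <- sweep(pts * ri, 2, xyz[i, ], `+`)      # test points on sphere i
    acc <- rep(TRUE, nrow(surf))
    for (j in nb) {
      if (!any(acc)) break
      dj2 <- rowSums(sweep(surf[acc, , drop = FALSE], 2, xyz[j, ])^2)
      acc[acc] <- dj2 >= expanded[j]^2
    }
    areas[i] <- 4 * pi * ri^2 * sum(acc) / nrow(surf)
  }
  areas
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Each atom is covered by a deterministic golden-spiral point lattice on
#' its expanded sphere (vdW radius + probe); a point is accessible iff it
#' lies outside every other atom's expanded sphere.  Atom area is
#' `4*pi*(r+probe)^2` times the accessible fraction.
#'
#' @param struct a [structure3d()] (or bare coordinate matrix plus
#'   `elements`).
#' @param n_points points per atomic sphere (default 1200).
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param radii named per-element radii (Angstrom); see [default_radii()].
#' @param elements element vector, only needed when `struct` is a bare
#'   matrix.
#' @return List of class `sasa_result`: `atom_area`, `residue_area`
#'   (named by residue id), `total`, `probe_radius`, `n_points`.
#' @export
shrake_rupley <- function(struct, n_points = 1200, probe = 1.4,
                          radii = default_radii(), elements = NULL) {
  if (inherits(struct, "structure3d")) {
    xyz <- struct$xyz
    elements <- struct$topology$element
    resid <- struct$topology$resid
  } else {
    xyz <- .as_coords(struct)
    if (is.null(elements)) stop("'elements' required for bare coordinates")
    resid <- rep(1L, nrow(xyz))
  }
  stopifnot(n_points >= 1, probe >= 0)
  r <- .atom_radii(elements, radii)
  atom_area <- .sasa_atoms(xyz, r, probe, sphere_points(n_points))
  residue_area <- tapply(atom_area, resid, sum)
  structure(list(atom_area = atom_area,
                 residue_area = setNames(as.numeric(residue_area),
                                         names(residue_area)),
                 total = sum(atom_area),
                 probe_radius = probe, n_points = as.integer(n_points)),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result> total %.2f A^2 over %d atoms (probe %.2f A, %d points)\n",
              x$total, length(x$atom_area), x$probe_radius, x$n_points))
  invisible(x)
}

#' Per-frame hydrophobic exposed surface
#'
#' For every frame, the solvent-accessible surface summed over the
#' hydrophobic residues inside a region of interest.  Occlusion is
#' computed against the full structure; only the summation is restricted.
#' The region must be supplied: a meaningful hydrophobic-patch analysis
#' is local, not whole-protein.
#'
#' @param traj a [trajectory()].
#' @param region integer residue ids defining the analysed region.
#' @param hydrophobic residue names treated as hydrophobic (default ALA,
#'   VAL, LEU, ILE, PRO, PHE, MET, TRP).
#' @inheritParams shrake_rupley
#' @return Numeric vector, one area (A^2) per frame; class `hs_series`.
#' @export
hydrophobic_surface_series <- function(traj, region,
                                       hydrophobic = .default_hydrophobic,
                                       n_points = 1200, probe = 1.4,
                                       radii = default_radii()) {
  stopifnot(inherits(traj, "trajectory"))
  if (!length(region)) stop("region selection must be non-empty")
  topo <- traj$topology
  if (!any(topo$resid %in% region)) {
    stop("region selection matches no residues in the topology")
  }
  target <- unique(topo$resid[topo$resid %in% region &
                                topo$resname %in% hydrophobic])
  r <- .atom_radii(topo$element, radii)
  pts <- sphere_points(n_points)
  out <- numeric(n_frames(traj))
  if (length(target)) {
    for (k in seq_len(n_frames(traj))) {
      areas <- .sasa_atoms(frame_coords(traj$coords, k), r, probe, pts)
      out[k] <- sum(areas[topo$resid %in% target])
    }
  }
  class(out) <- c("hs_series", "numeric")
  out
}

#' Frame with the largest hydrophobic exposed surface
#'
#' Ties are broken towards the lowest frame index.
#'
#' @param series per-frame areas from [hydrophobic_surface_series()].
#' @return List with `frame_index` (1-based) and `area` (A^2).
#' @export
max_hydrophobic_frame <- function(series) {
  series <- as.numeric(series)
  if (!length(series)) stop("empty series")
  i <- which.max(series)   # which.max returns the first maximum
  list(frame_index = i, area = series[i])
}
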