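#' @importFrom stats approx coef lm median nls sd setNames cor rnorm runif
#'   rbinom quantile
#' @importFrom utils head read.csv write.csv
NULL

# Standard amino acids used to flag hetero residues.
.standard_aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

# Default hydrophobic residue class (configurable in the SASA-series API).
.default_hydrophobic <- c("ALA", "VAL", "LEU", "ILE", "PRO", "PHE", "MET",
                          "TRP")

# Shape-safe extraction of frame i from an [n_frames, n_atoms, 3] array:
# plain `[i, , ]` would collapse single-atom frames to a bare vector.
frame_coords <- function(coords, i) {
  matrix(coords[i, , ], ncol = 3L)
}

#' Default van der Waals radii (Angstrom)
#'
#' Bondi-like radii used by [shrake_rupley()] when no explicit radius set
#' is supplied.
#'
#' @return Named numeric vector of radii in Angstrom, indexed by element.
#' @export
#' @examples
#' default_radii()[["C"]]
default_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
}

#' Construct a molecular structure
#'
#' A `structure3d` couples an atom table (topology) with an `n x 3`
#' coordinate matrix in Angstrom.  Residue names outside the 20 standard
#' amino acids are flagged as hetero.
#'
#' @param topology data.frame with columns `serial`, `name`, `element`,
#'   `resid`, `resname`, `chain` (optional `hetero`; recomputed if absent).
#' @param xyz numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @return Object of class `structure3d`.
#' @export
structure3d <- function(topology, xyz) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  stopifnot(is.data.frame(topology), ncol(xyz) == 3L,
            nrow(xyz) == nrow(topology))
  required <- c("serial", "name", "element", "resid", "resname", "chain")
  missing_cols <- setdiff(required, names(topology))
  if (length(missing_cols)) {
    stop("topology lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(topology$serial)) {
    stop("atom serial numbers must be unique")
  }
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  if (any(!nzchar(topology$element))) stop("element field must be non-empty")
  # blank chain identifiers are legal in generated files; canonicalise to "A"
  topology$chain[!nzchar(trimws(topology$chain))] <- "A"
  topology$hetero <- !(topology$resname %in% .standard_aa)
  rownames(topology) <- NULL
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(list(topology = topology, xyz = xyz), class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  nres <- length(unique(paste(x$topology$chain, x$topology$resid)))
  cat(sprintf("<structure3d> %d atoms, %d residues, %d hetero atoms\n",
              nrow(x$xyz), nres, sum(x$topology$hetero)))
  invisible(x)
}

#' Construct a trajectory
#'
#' An ordered set of conformations (frames) sharing one topology, stored
#' as a `n_frames x n_atoms x 3` array.  Frame indices are 1-based and
#' frames are uniformly spaced in time.
#'
#' @param topology atom table as in [structure3d()].
#' @param coords 3-d array `[frame, atom, xyz]` in Angstrom, or a list of
#'   `n_atoms x 3` matrices.
#' @param timestep_ps positive time spacing between consecutive frames (ps).
#' @return Object of class `trajectory`.
#' @export
trajectory <- function(topology, coords, timestep_ps = 1) {
  if (is.list(coords)) {
    nat <- vapply(coords, nrow, integer(1))
    if (length(unique(nat)) != 1L) {
      stop("all frames must have the same atom count")
    }
    arr <- array(0, dim = c(length(coords), nat[1], 3L))
    for (i in seq_along(coords)) arr[i, , ] <- as.matrix(coords[[i]])
    coords <- arr
  }
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  if (dim(coords)[1] < 1L) stop("a trajectory needs at least one frame")
  if (dim(coords)[2] != nrow(topology)) {
    stop("coordinate array does not match topology atom count")
  }
  if (!is.numeric(timestep_ps) || timestep_ps <= 0) {
    stop("timestep_ps must be positive")
  }
  # reuse structure3d() validation of the topology
  topology <- structure3d(topology, frame_coords(coords, 1L))$topology
  structure(list(topology = topology, coords = coords,
                 timestep_ps = timestep_ps),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms, timestep %.4g ps (%.4g ns total)\n",
              n_frames(x), nrow(x$topology), x$timestep_ps,
              (n_frames(x) - 1) * x$timestep_ps / 1000))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [trajectory()].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  dim(traj$coords)[1]
}

#' Extract one frame of a trajectory as a structure
#' @param traj a [trajectory()].
#' @param i 1-based frame index.
#' @return A [structure3d()].
#' @export
get_frame <- function(traj, i) {
  stopifnot(inherits(traj, "trajectory"))
  i <- as.integer(i)
  if (i < 1L || i > n_frames(traj)) stop("frame index out of range: ", i)
  structure3d(traj$topology, frame_coords(traj$coords, i))
}

#' Select atom indices by atom name and/or residue
#'
#' @param topology atom table of a [structure3d()] or [trajectory()].
#' @param atom_names character vector of atom names (e.g. backbone
#'   `c("N","CA","C","O")`), or NULL for all.
#' @param resid integer residue ids to keep, or NULL for all.
#' @param heavy_only drop hydrogens if TRUE.
#' @return Integer vector of atom indices (rows of the topology).
#' @export
atom_select <- function(topology, atom_names = NULL, resid = NULL,
                        heavy_only = FALSE) {
  if (inherits(topology, c("structure3d", "trajectory"))) {
    topology <- topology$topology
  }
  keep <- rep(TRUE, nrow(topology))
  if (!is.null(atom_names)) keep <- keep & topology$name %in% atom_names
  if (!is.null(resid)) keep <- keep & topology$resid %in% resid
  if (heavy_only) keep <- keep & topology$element != "H"
  which(keep)
}

#' Backbone atom indices (N, CA, C, O)
#' @inheritParams atom_select
#' @return Integer vector of backbone atom indices.
#' @export
backbone_selection <- function(topology) {
  atom_select(topology, atom_names = c("N", "CA", "C", "O"))
}

#' Define a binding pocket by its lining residues
#'
#' @param label pocket name (e.g. "BSP1").
#' @param residues integer vector of residue ids lining the pocket.
#' @return Object of class `pocket`.
#' @export
pocket <- function(label, residues) {
  residues <- sort(unique(as.integer(residues)))
  if (!length(residues)) stop("a pocket needs at least one residue")
  structure(list(label = label, residues = residues), class = "pocket")
}

#' @export
print.pocket <- function(x, ...) {
  cat(sprintf("<pocket> %s: %d residues (%s)\n", x$label, length(x$residues),
              paste(utils::head(x$residues, 8), collapse = ",")))
  invisible(x)
}
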