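# Rigid-body superposition and fluctuation analysis.
#
# All superpositions are proper rotations (det = +1); reflections are
# excluded so mirror images are never matched.

.as_coords <- function(x) {
  if (inherits(x, "structure3d")) x <- x$xyz
  x <- as.matrix(x)
  stopifnot(ncol(x) == 3L)
  x
}

# Kabsch solution on pre-centred coordinate blocks.
.kabsch_rotation <- function(mob_c, ref_c) {
  h <- crossprod(mob_c, ref_c)           # 3x3 cross-covariance
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)    # maps mobile -> reference
}

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Least-squares rigid transform (proper rotation + translation) mapping
#' the selected atoms of `mobile` onto those of `reference`.
#'
#' @param mobile,reference coordinate matrices (or [structure3d()]).
#' @param selection atom indices used for the fit (same indices applied
#'   to both); default: all atoms.
#' @return List of class `superposition`: `rotation` (3x3, det +1),
#'   `translation` (length 3), `rmsd_after` (Angstrom).  Apply as
#'   `coords %*% t(rotation) + translation` (rowwise).
#' @export
kabsch_superpose <- function(mobile, reference,
                             selection = NULL) {
  mobile <- .as_coords(mobile); reference <- .as_coords(reference)
  if (is.null(selection)) selection <- seq_len(nrow(mobile))
  a <- mobile[selection, , drop = FALSE]
  b <- reference[selection, , drop = FALSE]
  if (nrow(a) != nrow(b)) stop("selections must have equal length")
  if (nrow(a) < 3L) stop("degenerate geometry: need at least 3 atoms")
  ca <- colMeans(a); cb <- colMeans(b)
  a_c <- sweep(a, 2, ca); b_c <- sweep(b, 2, cb)
  # collinear point sets leave a rotation degree of freedom undetermined
  if (svd(a_c)$d[2] < 1e-8 * max(1, svd(a_c)$d[1])) {
    stop("degenerate geometry: selection is (near-)collinear")
  }
  rot <- .kabsch_rotation(a_c, b_c)
  fitted <- a_c %*% t(rot)
  rmsd_after <- sqrt(mean(rowSums((fitted - b_c)^2)))
  structure(list(rotation = rot,
                 translation = as.numeric(cb - ca %*% t(rot)),
                 rmsd_after = rmsd_after),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("<superposition> rotation %.2f deg, |t| = %.3f A, rmsd_after = %.4f A\n",
              ang, sqrt(sum(x$translation^2)), x$rmsd_after))
  invisible(x)
}

#' Apply a superposition to coordinates
#' @param sup a `superposition` from [kabsch_superpose()].
#' @param coords coordinate matrix to transform.
#' @return Transformed coordinate matrix.
#' @export
apply_superposition <- function(sup, coords) {
  coords <- .as_coords(coords)
  sweep(coords %*% t(sup$rotation), 2, sup$translation, `+`)
}

#' Root mean square deviation between two conformations
#'
#' @param a,b coordinate matrices (or [structure3d()]).
#' @param selection atom indices compared (default all).
#' @param superpose optimally superpose `a` onto `b` on the selection
#'   first (default TRUE).
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b, selection = NULL, superpose = TRUE) {
  a <- .as_coords(a); b <- .as_coords(b)
  if (is.null(selection)) {
    if (nrow(a) != nrow(b)) stop("selections must have equal length")
    selection <- seq_len(nrow(a))
  }
  if (max(selection) > nrow(a) || max(selection) > nrow(b)) {
    stop("selections must have equal length within both coordinate sets")
  }
  pa <- a[selection, , drop = FALSE]
  pb <- b[selection, , drop = FALSE]
  if (superpose) {
    sup <- kabsch_superpose(a, b, selection)
    pa <- apply_superposition(sup, pa)
  }
  sqrt(mean(rowSums((pa - pb)^2)))
}

# Superpose every frame of a coordinate array onto a reference coordinate
# set, fitting on `selection`; returns the transformed array.
.superpose_frames <- function(coords, reference, selection) {
  out <- coords
  for (k in seq_len(dim(coords)[1])) {
    sup <- kabsch_superpose(frame_coords(coords, k), reference, selection)
    out[k, , ] <- apply_superposition(sup, frame_coords(coords, k))
  }
  out
}

#' Per-residue root mean square fluctuation
#'
#' Frames are superposed onto the ensemble-average structure, the average
#' is recomputed and the superposition repeated (two refinement passes),
#' then per-atom fluctuations `sqrt(<|r - <r>|^2>)` are averaged over each
#' residue's selected atoms.
#'
#' @param traj a [trajectory()] with at least 2 frames.
#' @param selection atom indices entering the analysis and the fit;
#'   default: backbone N, CA, C, O.
#' @return data.frame of class `rmsf_profile` with columns `resid`,
#'   `rmsf` (Angstrom); attribute `selection` describes the atom set.
#' @export
rmsf <- function(traj, selection = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (n_frames(traj) < 2L) stop("RMSF needs at least 2 frames")
  if (is.null(selection)) selection <- backbone_selection(traj)
  if (!length(selection)) stop("empty selection")
  coords <- traj$coords
  ref <- frame_coords(coords, 1L)
  for (pass in 1:2) {
    coords <- .superpose_frames(coords, ref, selection)
    ref <- apply(coords, c(2, 3), mean)
  }
  nf <- dim(coords)[1]
  dev2 <- matrix(0, nrow = length(selection), ncol = 1)
  sub <- coords[, selection, , drop = FALSE]
  mean_sub <- ref[selection, , drop = FALSE]
  # sum over frames of squared displacement from the mean structure
  acc <- matrix(0, nrow = length(selection), ncol = 3)
  for (k in seq_len(nf)) {
    acc <- acc + (sub[k, , , drop = TRUE] - mean_sub)^2
  }
  atom_rmsf <- sqrt(rowSums(acc) / nf)
  resid <- traj$topology$resid[selection]
  prof <- data.frame(resid = sort(unique(resid)),
                     rmsf = as.numeric(tapply(atom_rmsf, resid, mean)))
  attr(prof, "selection") <- sprintf("%d atoms", length(selection))
  class(prof) <- c("rmsf_profile", "data.frame")
  prof
}

#' Time-equidistant frame subsampling
#'
#' Selects frames at a constant stride starting from frame 1, either
#' `n` time-equidistant frames or an explicit `stride`.  The timestep
#' metadata is rescaled accordingly.
#'
#' @param traj a [trajectory()].
#' @param n number of equidistant frames to keep (stride = floor(N/n)).
#' @param stride keep every `stride`-th frame starting at frame 1.
#' @return A [trajectory()]; attribute `frame_indices` maps the new
#'   frames back to 1-based indices of the input.
#' @export
subsample_frames <- function(traj, n = NULL, stride = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- n_frames(traj)
  if (is.null(n) == is.null(stride)) {
    stop("supply exactly one of 'n' or 'stride'")
  }
  if (!is.null(n)) {
    n <- as.integer(n)
    if (n > nf) stop(sprintf("cannot take %d frames from %d", n, nf))
    if (n < 1L) stop("n must be >= 1")
    stride <- nf %/% n
    idx <- 1L + (0:(n - 1L)) * stride
  } else {
    stride <- as.integer(stride)
    if (stride < 1L) stop("stride must be >= 1")
    idx <- seq.int(1L, nf, by = stride)
  }
  out <- trajectory(traj$topology, traj$coords[idx, , , drop = FALSE],
                    timestep_ps = traj$timestep_ps * stride)
  attr(out, "frame_indices") <- idx
  out
}
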