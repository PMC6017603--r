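# Toy rigid-body docking engine.
#
# A deterministic, pluggable stand-in for a production docking program:
# rigid translations of the ligand on a grid spanning the pocket
# bounding box, combined with seeded random orientations, scored by a
# transparent soft-sphere / contact / H-bond function.  Useful because
# its optimum is checkable by brute force; not a physical scoring
# function.

#' Default toy docking score coefficients
#'
#' @return List: `w_clash` (kcal/mol/A^2 penalty inside vdW contact),
#'   `w_contact` (reward per distance-weighted contact pair),
#'   `w_hbond` (bonus per geometric H-bond pair), `contact_max`
#'   (outer contact distance, A), `hbond_max` (donor-acceptor heavy-atom
#'   distance, A).
#' @export
dock_params <- function() {
  list(w_clash = 10, w_contact = 0.2, w_hbond = 0.5,
       contact_max = 4.5, hbond_max = 3.5)
}

#' Score one rigid ligand placement against a protein conformation
#'
#' Score = soft-sphere clash penalty + distance-weighted contact reward
#' + geometric H-bond bonus; lower is better (pseudo-kcal/mol).
#' Invariant under any rigid motion applied jointly to protein and pose.
#'
#' @param frame a [structure3d()] protein conformation.
#' @param ligand_xyz ligand coordinates (matrix, Angstrom).
#' @param ligand_elements element symbols per ligand atom.
#' @param params coefficients from [dock_params()].
#' @param radii per-element vdW radii.
#' @return Scalar score (lower = better).
#' @export
score_pose <- function(frame, ligand_xyz, ligand_elements,
                       params = dock_params(), radii = default_radii()) {
  ligand_xyz <- .as_coords(ligand_xyz)
  rp <- .atom_radii(frame$topology$element, radii)
  rl <- .atom_radii(ligand_elements, radii)
  # all protein-ligand pair distances
  d <- sqrt(outer(rowSums(frame$xyz^2), rowSums(ligand_xyz^2), `+`) -
              2 * frame$xyz %*% t(ligand_xyz))
  rsum <- outer(rp, rl, `+`)
  clash <- pmax(0, rsum - d)
  contact <- d >= rsum & d < params$contact_max
  w <- pmax(0, 1 - (d - rsum) / (params$contact_max - rsum))
  polar_p <- frame$topology$element %in% c("N", "O", "S")
  polar_l <- ligand_elements %in% c("N", "O", "S")
  hb <- outer(polar_p, polar_l, `&`) & d <= params$hbond_max & d >= 2.4
  params$w_clash * sum(clash^2) -
    params$w_contact * sum(w[contact]) -
    params$w_hbond * sum(hb)
}

# Seeded uniform random rotation matrices (via QR of Gaussian matrices,
# sign-fixed, det forced to +1). First orientation is the identity.
.seeded_rotations <- function(n, seed) {
  set.seed(seed)
  rots <- vector("list", n)
  rots[[1]] <- diag(3)
  for (i in seq_len(n)[-1]) {
    qr_ <- qr(matrix(rnorm(9), 3))
    q <- qr.Q(qr_)
    q <- q %*% diag(sign(diag(qr.R(qr_))))
    if (det(q) < 0) q[, 3] <- -q[, 3]
    rots[[i]] <- q
  }
  rots
}

#' Dock a rigid ligand into a pocket of one conformation
#'
#' Deterministic given the seed: the ligand (centred on its centroid) is
#' placed at every grid point of the pocket bounding box, in each of
#' `n_orientations` orientations (identity first, then seeded uniform
#' rotations), and each placement is scored with [score_pose()].  The
#' `top_k` best placements are returned sorted by ascending score.
#'
#' @param frame a [structure3d()] protein conformation.
#' @param ligand a [structure3d()] ligand (hetero).
#' @param pk a [pocket()]; its residues' atoms define the search box.
#' @param grid_step translation grid spacing (Angstrom, default 1.0).
#' @param box_margin expansion of the pocket bounding box (Angstrom,
#'   default 2) before requiring the ligand's bounding sphere to fit;
#'   a pocket too small for the ligand yields a no-pose error.
#' @param n_orientations rigid orientations sampled (default 8).
#' @param seed integer seed for the orientation sampling.
#' @param top_k poses to keep (default 5).
#' @param frame_index 1-based ensemble frame index recorded in the poses.
#' @param params,radii scoring configuration (see [score_pose()]).
#' @return A [pose_set()] with `top_k` poses sorted ascending by score.
#' @export
toy_dock <- function(frame, ligand, pk, grid_step = 1.0,
                     n_orientations = 8, seed = 1, top_k = 5,
                     frame_index = 1L, box_margin = 2,
                     params = dock_params(), radii = default_radii()) {
  stopifnot(inherits(frame, "structure3d"), inherits(ligand, "structure3d"),
            inherits(pk, "pocket"), grid_step > 0, n_orientations >= 1)
  pocket_atoms <- atom_select(frame, resid = pk$residues)
  if (!length(pocket_atoms)) stop("pocket residues not found in frame")
  box <- apply(frame$xyz[pocket_atoms, , drop = FALSE], 2, range)
  lig0 <- sweep(ligand$xyz, 2, colMeans(ligand$xyz))
  lig_radius <- sqrt(max(rowSums(lig0^2)))
  # grid points where the ligand bounding sphere stays inside the box
  axes <- lapply(1:3, function(k) {
    lo <- box[1, k] - box_margin + lig_radius
    hi <- box[2, k] + box_margin - lig_radius
    if (lo > hi) return(numeric(0))
    seq(lo, hi, by = grid_step)
  })
  if (any(!lengths(axes))) {
    stop("no grid placements: pocket box too small for the ligand")
  }
  grid <- as.matrix(expand.grid(x = axes[[1]], y = axes[[2]], z = axes[[3]]))
  rots <- .seeded_rotations(n_orientations, seed)
  best <- data.frame()
  coords <- list()
  scores <- numeric(0)
  for (rot_i in seq_along(rots)) {
    ligr <- lig0 %*% t(rots[[rot_i]])
    for (g in seq_len(nrow(grid))) {
      xyz <- sweep(ligr, 2, grid[g, ], `+`)
      scores[length(scores) + 1L] <-
        score_pose(frame, xyz, ligand$topology$element, params, radii)
      coords[[length(coords) + 1L]] <- xyz
    }
  }
  keep <- order(scores)[seq_len(min(top_k, length(scores)))]
  pose_set(ligand$topology,
           data.frame(frame = as.integer(frame_index),
                      model = seq_along(keep), score = scores[keep]),
           coords[keep], n_frames = max(1L, as.integer(frame_index)))
}

#' Dock a ligand across every frame of an ensemble
#'
#' Runs [toy_dock()] on each trajectory frame (keeping `top_k` poses per
#' frame) and concatenates the results into one [pose_set()].
#'
#' @param traj a [trajectory()].
#' @inheritParams toy_dock
#' @return A [pose_set()] covering all frames.
#' @export
dock_ensemble <- function(traj, ligand, pk, grid_step = 1.0,
                          n_orientations = 8, seed = 1, top_k = 1,
                          params = dock_params(), radii = default_radii()) {
  stopifnot(inherits(traj, "trajectory"))
  sets <- lapply(seq_len(n_frames(traj)), function(k) {
    toy_dock(get_frame(traj, k), ligand, pk, grid_step, n_orientations,
             seed = seed + k, top_k = top_k, frame_index = k,
             params = params, radii = radii)
  })
  poses <- do.call(rbind, lapply(sets, `[[`, "poses"))
  poses$model <- seq_len(nrow(poses))
  arr <- array(0, dim = c(nrow(poses), nrow(ligand$topology), 3L))
  i <- 0L
  for (s in sets) {
    for (j in seq_len(nrow(s$poses))) {
      i <- i + 1L
      arr[i, , ] <- frame_coords(s$coords, j)
    }
  }
  pose_set(ligand$topology, poses, arr, n_frames = n_frames(traj))
}
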