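# Inverse-docking aggregation: per-frame poses are compared to a
# reference pose; a frame is binding-competent when its best pose is both
# geometrically close to the reference and favourably scored.  The
# fraction of competent frames is the ligand's binding propensity
# ("pocket time availability" across the ensemble).

.heavy_idx <- function(topology) which(topology$element != "H")

#' Ligand-pocket distance of a pose to the reference pose
#'
#' The pose's frame is superposed onto the reference frame using the
#' pocket's backbone atoms, the transform is applied to the pose, and the
#' ligand heavy-atom RMSD to the reference pose is returned without any
#' ligand re-fitting (so both translation and orientation differences
#' count).
#'
#' @param pose_xyz ligand coordinates of the pose (matrix, Angstrom).
#' @param reference_pose a [structure3d()] holding the reference ligand
#'   pose (in the reference frame's coordinate system).
#' @param frame,reference_frame [structure3d()] protein conformations the
#'   pose and reference pose belong to; pass NULL for both when all poses
#'   already share one coordinate system.
#' @param pk a [pocket()] whose backbone atoms drive the superposition.
#' @param ligand_topology atom table of the posed ligand; defaults to the
#'   reference pose's topology (must match it).
#' @return Distance in Angstrom.
#' @export
pose_distance <- function(pose_xyz, reference_pose, frame = NULL,
                          reference_frame = NULL, pk = NULL,
                          ligand_topology = NULL) {
  stopifnot(inherits(reference_pose, "structure3d"))
  pose_xyz <- .as_coords(pose_xyz)
  if (is.null(ligand_topology)) ligand_topology <- reference_pose$topology
  if (nrow(pose_xyz) != nrow(reference_pose$xyz) ||
      !all(ligand_topology$name == reference_pose$topology$name)) {
    stop("ligand topology mismatch between pose and reference pose")
  }
  if (!is.null(frame)) {
    stopifnot(inherits(frame, "structure3d"),
              inherits(reference_frame, "structure3d"),
              inherits(pk, "pocket"))
    sel <- intersect(backbone_selection(frame),
                     atom_select(frame, resid = pk$residues))
    if (length(sel) < 3L) stop("pocket backbone selection too small")
    sup <- kabsch_superpose(frame$xyz, reference_frame$xyz, sel)
    pose_xyz <- apply_superposition(sup, pose_xyz)
  }
  heavy <- .heavy_idx(ligand_topology)
  sqrt(mean(rowSums((pose_xyz[heavy, , drop = FALSE] -
                       reference_pose$xyz[heavy, , drop = FALSE])^2)))
}

# Best (lowest-score) pose per frame; returns row indices into ps$poses.
.best_pose_rows <- function(ps) {
  ord <- order(ps$poses$frame, ps$poses$score, ps$poses$model)
  rows <- ord[!duplicated(ps$poses$frame[ord])]
  rows[order(ps$poses$frame[rows])]
}

# Distance of each listed pose row to the reference pose.
.pose_row_distances <- function(ps, rows, reference_pose, traj,
                                reference_frame, pk) {
  vapply(rows, function(r) {
    fr <- NULL; ref_fr <- NULL
    if (!is.null(traj)) {
      fr <- get_frame(traj, ps$poses$frame[r])
      ref_fr <- if (inherits(reference_frame, "structure3d")) reference_frame
                else get_frame(traj, reference_frame)
    }
    pose_distance(frame_coords(ps$coords, r), reference_pose,
                  frame = fr, reference_frame = ref_fr, pk = pk,
                  ligand_topology = ps$ligand_topology)
  }, numeric(1))
}

#' Group best poses by ligand-pocket distance to the reference pose
#'
#' Per frame the lowest-score pose is kept; best poses are histogrammed
#' into distance bins of `bin_width`, and each group's mean score and
#' mean distance are reported.
#'
#' @param ps a [pose_set()].
#' @param reference_pose reference ligand pose ([structure3d()]).
#' @param bin_width bin width in Angstrom (default 2).
#' @param traj optional [trajectory()] for per-frame superposition (see
#'   [pose_distance()]).
#' @param reference_frame frame index (or [structure3d()]) the reference
#'   pose lives in; required when `traj` is given.
#' @param pk [pocket()] used for the superposition when `traj` is given.
#' @return data.frame with one row per occupied bin: `bin`, `d_min`,
#'   `d_max` (bounds, Angstrom), `n`, `mean_score`, `mean_distance`.
#' @export
group_poses <- function(ps, reference_pose, bin_width = 2, traj = NULL,
                        reference_frame = NULL, pk = NULL) {
  stopifnot(inherits(ps, "pose_set"), bin_width > 0)
  rows <- .best_pose_rows(ps)
  d <- .pose_row_distances(ps, rows, reference_pose, traj,
                           reference_frame, pk)
  bin <- pmax(0L, as.integer(floor(d / bin_width)))
  sc <- ps$poses$score[rows]
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    m <- bin == b
    data.frame(bin = b, d_min = b * bin_width, d_max = (b + 1) * bin_width,
               n = sum(m), mean_score = mean(sc[m]),
               mean_distance = mean(d[m]))
  }))
  rownames(out) <- NULL
  out
}

#' Ensemble binding propensity of a ligand
#'
#' A frame is "bound" iff its best (lowest-score) pose lies within
#' `distance_cutoff` of the reference pose and scores at or below
#' `score_threshold`.  Propensity is the bound fraction over all frames
#' of the ensemble.
#'
#' @inheritParams group_poses
#' @param distance_cutoff Angstrom (default 2).
#' @param score_threshold kcal/mol; a natural choice is the reference
#'   pose's score + 1 kcal/mol.
#' @param ligand ligand label carried into the result.
#' @return List of class `propensity_result`: `ligand`, `n_frames`,
#'   `n_bound`, `propensity`, `distance_cutoff`, `score_threshold`,
#'   `bound_frames` (1-based indices).
#' @export
binding_propensity <- function(ps, reference_pose, distance_cutoff = 2,
                               score_threshold, traj = NULL,
                               reference_frame = NULL, pk = NULL,
                               ligand = "") {
  stopifnot(inherits(ps, "pose_set"),
            is.finite(distance_cutoff), is.finite(score_threshold))
  if (ps$n_frames < 1L) stop("pose set covers zero frames")
  rows <- .best_pose_rows(ps)
  d <- .pose_row_distances(ps, rows, reference_pose, traj,
                           reference_frame, pk)
  bound <- d <= distance_cutoff & ps$poses$score[rows] <= score_threshold
  structure(list(ligand = ligand, n_frames = ps$n_frames,
                 n_bound = sum(bound),
                 propensity = sum(bound) / ps$n_frames,
                 distance_cutoff = distance_cutoff,
                 score_threshold = score_threshold,
                 bound_frames = ps$poses$frame[rows][bound]),
            class = "propensity_result")
}

#' @export
print.propensity_result <- function(x, ...) {
  cat(sprintf("<propensity_result> %s: %d/%d frames bound (%.1f%%) [d <= %.2f A, score <= %.2f]\n",
              x$ligand, x$n_bound, x$n_frames, 100 * x$propensity,
              x$distance_cutoff, x$score_threshold))
  invisible(x)
}

#' Overlap between two binding pockets
#'
#' @param a,b [pocket()] objects on the same topology.
#' @return List: `shared` residue ids, `jaccard` fraction
#'   (|intersection| / |union|).
#' @export
pocket_overlap <- function(a, b) {
  stopifnot(inherits(a, "pocket"), inherits(b, "pocket"))
  shared <- intersect(a$residues, b$residues)
  list(shared = shared,
       jaccard = length(shared) / length(union(a$residues, b$residues)))
}
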