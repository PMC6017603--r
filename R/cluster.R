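# Leader-style (GROMOS) conformational clustering on pairwise
# superposed RMSD: repeatedly take the frame with the most neighbours
# within the cutoff as a cluster centroid, remove it and its neighbours,
# and iterate.  Deterministic: ties break towards the lowest frame index.

#' Pairwise superposed-RMSD matrix of a trajectory
#'
#' Each pair of frames is optimally superposed on the selection before
#' the RMSD is taken.  Computed blockwise over rows so memory stays at
#' O(block * n); for very large ensembles subsample first.
#'
#' @param traj a [trajectory()].
#' @param selection atom indices (default backbone).
#' @return Symmetric `n x n` matrix of RMSD values (Angstrom).
#' @export
pairwise_rmsd <- function(traj, selection = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(selection)) selection <- backbone_selection(traj)
  nf <- n_frames(traj)
  # pre-centre the selected coordinates once per frame
  cs <- vector("list", nf)
  for (k in seq_len(nf)) {
    a <- traj$coords[k, selection, , drop = TRUE]
    cs[[k]] <- sweep(a, 2, colMeans(a))
  }
  d <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1L)) {
    ai <- cs[[i]]
    for (j in (i + 1L):nf) {
      rot <- .kabsch_rotation(ai, cs[[j]])
      v <- sqrt(mean(rowSums((ai %*% t(rot) - cs[[j]])^2)))
      d[i, j] <- v; d[j, i] <- v
    }
  }
  d
}

#' Cluster trajectory frames by conformational similarity
#'
#' Leader clustering on the pairwise superposed-RMSD matrix: the frame
#' with the most neighbours within `cutoff` becomes a centroid, it and
#' its neighbours form a cluster and are removed, and the step repeats
#' until every frame is assigned.  Clusters are reported in decreasing
#' occupancy.
#'
#' @param traj a [trajectory()].
#' @param selection atom indices used for the RMSD (default backbone).
#' @param cutoff neighbour cutoff in Angstrom (default 2.0).
#' @param dist optional precomputed matrix from [pairwise_rmsd()].
#' @return List of class `cluster_assignment`: `labels` (cluster id per
#'   frame, 1 = most populated), `centroids` (frame index per cluster),
#'   `occupancy` (fractions summing to 1), `cutoff`.
#' @export
cluster_conformations <- function(traj, selection = NULL, cutoff = 2.0,
                                  dist = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(dist)) dist <- pairwise_rmsd(traj, selection)
  nf <- nrow(dist)
  within <- dist <= cutoff
  active <- rep(TRUE, nf)
  labels <- integer(nf)
  centroids <- integer(0)
  sizes <- integer(0)
  cl <- 0L
  while (any(active)) {
    cl <- cl + 1L
    counts <- colSums(within[active, , drop = FALSE])
    counts[!active] <- -1L
    centroid <- which.max(counts)        # first max = lowest frame index
    members <- which(active & within[, centroid])
    labels[members] <- cl
    centroids[cl] <- centroid
    sizes[cl] <- length(members)
    active[members] <- FALSE
  }
  # reorder clusters by occupancy (stable: ties keep extraction order)
  ord <- order(-sizes, seq_along(sizes))
  relabel <- integer(cl); relabel[ord] <- seq_len(cl)
  structure(list(labels = relabel[labels],
                 centroids = centroids[ord],
                 occupancy = sizes[ord] / nf,
                 cutoff = cutoff),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d clusters at %.2f A cutoff\n",
              length(x$centroids), x$cutoff))
  for (i in seq_along(x$centroids)) {
    cat(sprintf("  cluster %d: occupancy %.1f%%, centroid frame %d\n",
                i, 100 * x$occupancy[i], x$centroids[i]))
  }
  invisible(x)
}

#' Representative conformation of an ensemble
#'
#' The centroid frame of the most populated cluster (the neighbour-count
#' maximiser of the leader algorithm; ties towards the lowest index).
#'
#' @param assignment a `cluster_assignment`.
#' @return 1-based frame index of the representative conformation.
#' @export
representative_conformation <- function(assignment) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  assignment$centroids[1]
}
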