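# Fixed-column multi-model PDB reading/writing.
#
# Only ATOM/HETATM/MODEL/ENDMDL records are interpreted; coordinates are
# written with %8.3f so round-trips are exact to 1e-3 A (PDB precision).
# Frame/MODEL indices are 1-based throughout.

.parse_atom_line <- function(line, lineno) {
  get <- function(from, to) trimws(substr(line, from, to))
  xyz <- suppressWarnings(as.numeric(c(get(31, 38), get(39, 46), get(47, 54))))
  serial <- suppressWarnings(as.integer(get(7, 11)))
  resid <- suppressWarnings(as.integer(get(23, 26)))
  if (anyNA(xyz) || is.na(serial) || is.na(resid)) {
    stop(sprintf("malformed ATOM/HETATM record at line %d: '%s'",
                 lineno, line), call. = FALSE)
  }
  element <- get(77, 78)
  name <- get(13, 16)
  if (!nzchar(element)) {
    # fall back on the first alphabetic character of the atom name
    element <- sub("^[0-9]*", "", name)
    element <- toupper(substr(element, 1, 1))
  }
  list(serial = serial, name = name, resname = get(18, 20),
       chain = substr(line, 22, 22), resid = resid, xyz = xyz,
       element = element)
}

.atoms_to_frame <- function(atoms) {
  topology <- data.frame(
    serial = vapply(atoms, `[[`, integer(1), "serial"),
    name = vapply(atoms, `[[`, character(1), "name"),
    element = vapply(atoms, `[[`, character(1), "element"),
    resid = vapply(atoms, `[[`, integer(1), "resid"),
    resname = vapply(atoms, `[[`, character(1), "resname"),
    chain = vapply(atoms, `[[`, character(1), "chain"),
    stringsAsFactors = FALSE)
  xyz <- do.call(rbind, lapply(atoms, `[[`, "xyz"))
  list(topology = topology, xyz = xyz)
}

# Split raw PDB lines into per-MODEL blocks of parsed atoms. Returns a list
# with one element per model; files without MODEL records yield one block.
.read_pdb_models <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  models <- list()
  remarks <- list()
  cur_atoms <- NULL
  cur_remarks <- character()
  seen_model <- FALSE
  flush <- function() {
    if (!is.null(cur_atoms) && length(cur_atoms)) {
      models[[length(models) + 1L]] <<- cur_atoms
      remarks[[length(remarks) + 1L]] <<- cur_remarks
    }
    cur_atoms <<- NULL
    cur_remarks <<- character()
  }
  for (i in seq_along(lines)) {
    r <- rec[i]
    if (startsWith(r, "MODEL")) {
      flush()
      seen_model <- TRUE
      cur_atoms <- list()
    } else if (startsWith(r, "ENDMDL")) {
      flush()
    } else if (r == "ATOM  " || r == "HETATM") {
      if (is.null(cur_atoms)) cur_atoms <- list()
      cur_atoms[[length(cur_atoms) + 1L]] <- .parse_atom_line(lines[i], i)
    } else if (startsWith(r, "REMARK")) {
      cur_remarks <- c(cur_remarks, lines[i])
    }
  }
  flush()
  if (!length(models)) stop("no ATOM/HETATM records found in ", path)
  list(models = lapply(models, .atoms_to_frame), remarks = remarks,
       multi = seen_model)
}

.check_same_topology <- function(ref, frame, k) {
  if (nrow(frame$topology) != nrow(ref$topology)) {
    stop(sprintf(
      "topology error: frame %d has %d atoms, frame 1 has %d",
      k, nrow(frame$topology), nrow(ref$topology)), call. = FALSE)
  }
  same <- all(frame$topology$name == ref$topology$name) &&
    all(frame$topology$resid == ref$topology$resid) &&
    all(frame$topology$resname == ref$topology$resname)
  if (!same) {
    stop(sprintf("topology error: frame %d atom records differ from frame 1",
                 k), call. = FALSE)
  }
}

#' Read a multi-model PDB file as a trajectory
#'
#' Each MODEL becomes one frame; the topology is taken from the first
#' MODEL and every later MODEL must match it atom for atom.  Files
#' without MODEL records are read as a single frame.
#'
#' @param path PDB file path.
#' @param timestep_ps time spacing to attach to the trajectory (ps).
#' @return A [trajectory()].
#' @export
read_multimodel_pdb <- function(path, timestep_ps = 1) {
  parsed <- .read_pdb_models(path)
  frames <- parsed$models
  ref <- frames[[1]]
  for (k in seq_along(frames)[-1]) .check_same_topology(ref, frames[[k]], k)
  trajectory(ref$topology, lapply(frames, `[[`, "xyz"),
             timestep_ps = timestep_ps)
}

.format_atom_line <- function(rec, serial, name, resname, chain, resid, xyz) {
  name_fmt <- if (nchar(name) < 4) sprintf(" %-3s", name) else substr(name, 1, 4)
  sprintf("%-6s%5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial %% 100000L, name_fmt, resname, chain, resid,
          xyz[1], xyz[2], xyz[3], 1, 0, "")
}

.frame_atom_lines <- function(topology, xyz) {
  rec <- ifelse(topology$hetero, "HETATM", "ATOM")
  vapply(seq_len(nrow(topology)), function(i) {
    .format_atom_line(rec[i], topology$serial[i], topology$name[i],
                      topology$resname[i], topology$chain[i],
                      topology$resid[i], xyz[i, ])
  }, character(1))
}

#' Write a trajectory (or single structure) as a multi-model PDB file
#'
#' @param x a [trajectory()] or [structure3d()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(x, path) {
  if (inherits(x, "structure3d")) {
    x <- trajectory(x$topology, list(x$xyz))
  }
  stopifnot(inherits(x, "trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(n_frames(x))) {
    writeLines(sprintf("MODEL %8d", k), con)
    writeLines(.frame_atom_lines(x$topology, frame_coords(x$coords, k)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Construct a pose set
#'
#' Scored rigid placements of one ligand across trajectory frames.
#' Scores are in kcal/mol, lower is better.
#'
#' @param ligand_topology atom table of the ligand (one pose's worth).
#' @param poses data.frame with columns `frame`, `model`, `score`.
#' @param coords array `[pose, atom, 3]` of ligand coordinates per pose.
#' @param n_frames total number of frames the ensemble contains (poses may
#'   cover a subset); defaults to `max(poses$frame)`.
#' @return Object of class `pose_set`.
#' @export
pose_set <- function(ligand_topology, poses, coords,
                     n_frames = max(poses$frame)) {
  stopifnot(is.data.frame(poses),
            all(c("frame", "model", "score") %in% names(poses)))
  if (!nrow(poses)) stop("a pose set needs at least one pose")
  if (is.list(coords)) {
    arr <- array(0, dim = c(length(coords), nrow(coords[[1]]), 3L))
    for (i in seq_along(coords)) arr[i, , ] <- as.matrix(coords[[i]])
    coords <- arr
  }
  stopifnot(length(dim(coords)) == 3L, dim(coords)[1] == nrow(poses),
            dim(coords)[2] == nrow(ligand_topology))
  if (!all(is.finite(poses$score))) stop("pose scores must be finite")
  if (any(poses$frame < 1L | poses$frame > n_frames)) {
    stop("pose references a frame outside 1..n_frames")
  }
  structure(list(ligand_topology = ligand_topology, poses = poses,
                 coords = coords, n_frames = as.integer(n_frames)),
            class = "pose_set")
}

#' @export
print.pose_set <- function(x, ...) {
  cat(sprintf("<pose_set> %d poses over %d frames; score range [%.2f, %.2f] kcal/mol\n",
              nrow(x$poses), x$n_frames, min(x$poses$score),
              max(x$poses$score)))
  invisible(x)
}

#' Read a scored pose file
#'
#' Poses are stored as a multi-model PDB in which every MODEL is preceded
#' by `REMARK SCORE <float>` (kcal/mol, lower better) and
#' `REMARK FRAME <int>` (1-based ensemble frame the pose was docked into).
#'
#' @param path pose PDB file.
#' @return A [pose_set()].
#' @export
read_pose_file <- function(path) {
  parsed <- .read_pdb_models(path)
  frames <- parsed$models
  ref <- frames[[1]]
  for (k in seq_along(frames)[-1]) .check_same_topology(ref, frames[[k]], k)
  grab <- function(remarks, key, k) {
    hit <- grep(paste0("^REMARK\\s+", key, "\\s"), remarks, value = TRUE)
    if (!length(hit)) {
      stop(sprintf("pose %d lacks a REMARK %s record", k, key), call. = FALSE)
    }
    val <- suppressWarnings(as.numeric(sub(paste0("^REMARK\\s+", key, "\\s+"),
                                           "", hit[1])))
    if (is.na(val)) {
      stop(sprintf("pose %d has a non-numeric REMARK %s value", k, key),
           call. = FALSE)
    }
    val
  }
  scores <- vapply(seq_along(frames), function(k) {
    grab(parsed$remarks[[k]], "SCORE", k)
  }, numeric(1))
  frame_ids <- vapply(seq_along(frames), function(k) {
    grab(parsed$remarks[[k]], "FRAME", k)
  }, numeric(1))
  if (any(frame_ids != round(frame_ids)) || any(frame_ids < 1)) {
    stop("REMARK FRAME values must be positive integers")
  }
  topo <- structure3d(ref$topology, ref$xyz)$topology
  pose_set(topo,
           data.frame(frame = as.integer(frame_ids),
                      model = seq_along(frames), score = scores),
           lapply(frames, `[[`, "xyz"))
}

#' Write a pose set in the REMARK SCORE / REMARK FRAME dialect
#'
#' Scores are written with six decimals; a write/read round-trip
#' preserves them exactly as formatted.
#'
#' @param ps a [pose_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pose_file <- function(ps, path) {
  stopifnot(inherits(ps, "pose_set"))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(nrow(ps$poses))) {
    writeLines(c(sprintf("MODEL %8d", k),
                 sprintf("REMARK SCORE %.6f", ps$poses$score[k]),
                 sprintf("REMARK FRAME %d", ps$poses$frame[k])), con)
    writeLines(.frame_atom_lines(ps$ligand_topology,
                                 frame_coords(ps$coords, k)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
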