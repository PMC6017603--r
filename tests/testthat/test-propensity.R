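test_that("pose distance closed forms hold", {
  ref <- make_toy_ligand()
  expect_equal(pose_distance(ref$xyz, ref), 0)
  shifted <- sweep(ref$xyz, 2, c(3, 0, 0), `+`)
  expect_equal(pose_distance(shifted, ref), 3.0)
  expect_error(pose_distance(ref$xyz[1:3, ], ref), "topology mismatch")
})

test_that("pose distance is computed in the reference frame's coordinates", {
  # a rigidly moved copy of the frame carrying the same pose must be at
  # distance ~0 once the frames are superposed on the pocket backbone
  g <- make_trajectory(trajectory_spec(n_residues = 10, sigma = 0,
                                       n_frames = 1, seed = 1))
  f1 <- get_frame(g$trajectory, 1)
  ref <- make_toy_ligand()
  ref_pose <- structure3d(ref$topology,
                          sweep(ref$xyz, 2, c(0, 0, 8), `+`))
  rot <- random_rotation(5)
  f2 <- structure3d(f1$topology,
                    sweep(f1$xyz %*% t(rot), 2, c(4, -2, 7), `+`))
  moved_pose <- sweep(ref_pose$xyz %*% t(rot), 2, c(4, -2, 7), `+`)
  pk <- pocket("P", 1:10)
  d <- pose_distance(moved_pose, ref_pose, frame = f2,
                     reference_frame = f1, pk = pk)
  expect_lt(d, 1e-8)
  # and the oracle route: superpose with an independently computed
  # transform, then compare plain RMSD
  sup <- kabsch_superpose(f2$xyz, f1$xyz)
  heavy <- which(ref$topology$element != "H")
  oracle <- sqrt(mean(rowSums((apply_superposition(sup, moved_pose)[heavy, ] -
                                 ref_pose$xyz[heavy, ])^2)))
  expect_equal(d, oracle, tolerance = 1e-3)
})

test_that("grouping by distance reproduces generator counts", {
  ref <- make_toy_ligand()
  g <- make_pose_sets(200, ref, bound_fraction = 0.35, bound_noise = 0.3,
                      unbound_offset = 6, seed = 31)
  groups <- group_poses(g$pose_set, ref, bin_width = 2)
  near <- groups$n[groups$bin == 0]
  expect_equal(near, length(g$truth$bound_frames))
  expect_equal(sum(groups$n), 200)
  # group means are plain arithmetic means of member scores
  ps <- g$pose_set
  best <- ps$poses
  d0 <- vapply(seq_len(nrow(best)), function(i) {
    pose_distance(ps$coords[i, , , drop = TRUE], ref)
  }, numeric(1))
  expect_equal(groups$mean_score[groups$bin == 0],
               mean(best$score[d0 < 2]))
})

test_that("all-near pose sets form a single group", {
  ref <- make_toy_ligand()
  g <- make_pose_sets(50, ref, bound_fraction = 1, seed = 2)
  groups <- group_poses(g$pose_set, ref, bin_width = 2)
  expect_equal(nrow(groups), 1L)
  expect_equal(groups$n, 50)
})

test_that("binding propensity matches the generator's ground truth", {
  ref <- make_toy_ligand()
  g1 <- make_pose_sets(300, ref, bound_fraction = 1, seed = 4)
  expect_equal(binding_propensity(g1$pose_set, ref, 2, -5)$propensity, 1.0)
  g0 <- make_pose_sets(300, ref, bound_fraction = 0, seed = 4)
  expect_equal(binding_propensity(g0$pose_set, ref, 2, -5)$propensity, 0.0)
  g <- make_pose_sets(400, ref, bound_fraction = 0.3, seed = 4)
  pr <- binding_propensity(g$pose_set, ref, 2, -5)
  expect_equal(pr$propensity, g$truth$realized_fraction)
  expect_setequal(pr$bound_frames, g$truth$bound_frames)
})

test_that("propensity is monotone in both cutoffs and bounded", {
  ref <- make_toy_ligand()
  g <- make_pose_sets(150, ref, bound_fraction = 0.5, seed = 8)
  cuts <- c(0.5, 1, 2, 4, 8)
  p_d <- vapply(cuts, function(dc) {
    binding_propensity(g$pose_set, ref, dc, -5)$propensity
  }, numeric(1))
  expect_true(all(diff(p_d) >= 0))
  thr <- c(-8, -6, -4, -2, 0)
  p_s <- vapply(thr, function(st) {
    binding_propensity(g$pose_set, ref, 2, st)$propensity
  }, numeric(1))
  expect_true(all(diff(p_s) >= 0))
  expect_true(all(c(p_d, p_s) >= 0 & c(p_d, p_s) <= 1))
})

test_that("toy docking is deterministic and centres a probe in a cavity", {
  cage <- make_cavity_frame(radius = 5, n_wall = 14)
  probe <- single_atom_ligand()
  pk <- pocket("CAV", cage$topology$resid)
  d1 <- toy_dock(cage, probe, pk, grid_step = 1, n_orientations = 2,
                 seed = 7)
  d2 <- toy_dock(cage, probe, pk, grid_step = 1, n_orientations = 2,
                 seed = 7)
  expect_identical(d1$poses, d2$poses)
  expect_equal(d1$coords, d2$coords)
  # brute-force oracle: independently enumerate the same grid and score
  box <- apply(cage$xyz[atom_select(cage, resid = pk$residues), ], 2, range)
  best <- Inf; best_at <- NULL
  for (x in seq(box[1, 1] - 2, box[2, 1] + 2, by = 1))
    for (y in seq(box[1, 2] - 2, box[2, 2] + 2, by = 1))
      for (z in seq(box[1, 3] - 2, box[2, 3] + 2, by = 1)) {
        sc <- score_pose(cage, matrix(c(x, y, z), 1), "C")
        if (sc < best) { best <- sc; best_at <- c(x, y, z) }
      }
  expect_equal(d1$poses$score[1], best, tolerance = 1e-9)
  expect_lt(sqrt(sum((d1$coords[1, 1, ] - best_at)^2)), 1e-9)
})

test_that("clashing poses always score worse than clash-free ones", {
  cage <- make_cavity_frame()
  clash <- score_pose(cage, cage$xyz[1, , drop = FALSE], "C")
  free <- score_pose(cage, matrix(0, 1, 3), "C")
  expect_gt(clash, free)
})

test_that("docking scores are invariant under joint rigid motion", {
  cage <- make_cavity_frame()
  lig <- make_toy_ligand()
  pose <- sweep(lig$xyz, 2, colMeans(lig$xyz))
  s0 <- score_pose(cage, pose, lig$topology$element)
  rot <- random_rotation(13); tr <- c(3, -7, 2)
  cage2 <- structure3d(cage$topology,
                       sweep(cage$xyz %*% t(rot), 2, tr, `+`))
  pose2 <- sweep(pose %*% t(rot), 2, tr, `+`)
  expect_equal(score_pose(cage2, pose2, lig$topology$element), s0,
               tolerance = 1e-9)
})

test_that("a pocket too small for the ligand raises a no-pose error", {
  cage <- make_cavity_frame(radius = 1, n_wall = 4)
  lig <- make_toy_ligand()
  pk <- pocket("tiny", cage$topology$resid)
  expect_error(toy_dock(cage, lig, pk, box_margin = 0), "no grid placements")
})

test_that("pocket overlap follows set arithmetic", {
  expect_equal(pocket_overlap(pocket("a", 1:5), pocket("b", 1:5))$jaccard, 1)
  expect_equal(pocket_overlap(pocket("a", 1:5), pocket("b", 6:9))$jaccard, 0)
  ov <- pocket_overlap(pocket("a", 1:10), pocket("b", 6:15))
  expect_equal(ov$shared, 6:10)
  expect_equal(ov$jaccard, 5 / 15)
})
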