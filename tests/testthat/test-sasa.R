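test_that("an isolated atom has the full expanded-sphere area", {
  res <- shrake_rupley(matrix(0, 1, 3), elements = "C")
  expect_equal(res$total, 4 * pi * 3.1^2, tolerance = 1e-12)
  res_o <- shrake_rupley(matrix(0, 1, 3), elements = "O", probe = 1.4)
  expect_equal(res_o$total, 4 * pi * (1.52 + 1.4)^2, tolerance = 1e-12)
})

test_that("well-separated atoms keep their isolated areas", {
  xyz <- rbind(c(0, 0, 0), c(10, 0, 0))
  res <- shrake_rupley(xyz, elements = c("C", "C"))
  expect_equal(res$atom_area, rep(4 * pi * 3.1^2, 2), tolerance = 1e-12)
})

test_that("partial burial matches the analytic spherical-cap area", {
  R <- 1.7 + 1.4
  for (d in c(2, 3, 4, 5, 5.9)) {
    res <- shrake_rupley(rbind(c(0, 0, 0), c(d, 0, 0)),
                         elements = c("C", "C"))
    expect_equal(res$atom_area[1], two_sphere_cap_area(R, d),
                 tolerance = 0.02 * two_sphere_cap_area(R, d))
  }
})

test_that("areas are additive and consistent across groupings", {
  pep <- make_peptide(6, jitter = 0.1)
  res <- shrake_rupley(pep)
  expect_equal(res$total, sum(res$atom_area), tolerance = 1e-9)
  expect_equal(sum(res$residue_area), sum(res$atom_area), tolerance = 1e-6)
  expect_true(all(res$atom_area >= 0))
})

test_that("a distant atom never changes other atoms' areas", {
  pep <- make_peptide(4)
  base <- shrake_rupley(pep)
  extra <- pep$topology[1, ]
  extra$serial <- max(pep$topology$serial) + 1L
  extra$name <- "C1"; extra$element <- "C"
  extra$resid <- 99L; extra$resname <- "LIG"
  topo <- rbind(pep$topology, extra)
  aug <- structure3d(topo, rbind(pep$xyz, c(500, 500, 500)))
  res <- shrake_rupley(aug)
  expect_equal(res$atom_area[seq_len(nrow(pep$xyz))], base$atom_area,
               tolerance = 1e-12)
})

test_that("moving two atoms closer never increases accessibility", {
  R <- 3.1
  areas <- vapply(seq(6.5, 1, by = -0.5), function(d) {
    shrake_rupley(rbind(c(0, 0, 0), c(d, 0, 0)),
                  elements = c("C", "C"))$atom_area[1]
  }, numeric(1))
  expect_true(all(diff(areas) <= 1e-9))
})

test_that("unknown elements are reported by name", {
  expect_error(shrake_rupley(matrix(0, 1, 3), elements = "ZZ"), "ZZ")
})

test_that("hydrophobic surface series tracks the planted pocket state", {
  g <- make_trajectory(trajectory_spec(n_residues = 16, sigma = 0.15,
                                       n_frames = 40, open_fraction = 0.4,
                                       sequence = "LEU",
                                       target_separation = 5, seed = 17))
  traj <- g$trajectory
  hs <- hydrophobic_surface_series(traj, region = g$truth$pocket_residues,
                                   n_points = 300)
  open <- seq_len(n_frames(traj)) %in% g$truth$open_frames
  expect_true(sum(open) > 0 && sum(!open) > 0)
  # displaced (open) pocket residues detach from the helix body and
  # expose more surface; the two states separate cleanly
  expect_gt(min(hs[open]), max(hs[!open]))
})

test_that("series edge cases: static input, empty or apolar regions", {
  pep <- make_peptide(6)  # ALA/GLY/SER pattern
  traj <- trajectory(pep$topology, list(pep$xyz, pep$xyz))
  hs <- hydrophobic_surface_series(traj, region = 1:6, n_points = 200)
  expect_equal(hs[1], hs[2], tolerance = 1e-12)
  expect_error(hydrophobic_surface_series(traj, region = integer(0)),
               "non-empty")
  expect_error(hydrophobic_surface_series(traj, region = 99), "no residues")
  # region made only of polar residues contributes nothing
  polar <- which(pep$topology$resname[match(1:6, pep$topology$resid)] %in%
                   c("GLY", "SER"))
  hs0 <- hydrophobic_surface_series(traj, region = polar, n_points = 200)
  expect_true(all(hs0 == 0))
})

test_that("the maximum-surface frame uses first-index tie-breaking", {
  expect_equal(max_hydrophobic_frame(c(3, 3, 3))$frame_index, 1L)
  s <- c(1, 4, 2, 4)
  expect_equal(max_hydrophobic_frame(s)$frame_index, 2L)
  expect_equal(max_hydrophobic_frame(s)$area, 4)
  expect_error(max_hydrophobic_frame(numeric(0)), "empty")
})
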