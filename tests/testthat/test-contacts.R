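# Fixture: one serine whose side-chain oxygen can accept an H-bond, and
# one phenylalanine ring for stacking, with hand-placed coordinates.
make_contact_frame <- function() {
  topo <- data.frame(
    serial = 1:9,
    name = c("N", "CA", "C", "OG",
             "CG", "CD1", "CD2", "CE1", "CE2"),
    element = c("N", "C", "C", "O", rep("C", 5)),
    resid = c(1, 1, 1, 1, 2, 2, 2, 2, 2),
    resname = c(rep("SER", 4), rep("PHE", 5)),
    chain = "A", stringsAsFactors = FALSE)
  # PHE ring needs all six atoms; add CZ
  topo <- rbind(topo, data.frame(serial = 10, name = "CZ", element = "C",
                                 resid = 2, resname = "PHE", chain = "A"))
  ang <- (0:5) * pi / 3
  ring <- cbind(10 + 1.4 * cos(ang), 1.4 * sin(ang), 0)
  xyz <- rbind(c(0, 3, 0), c(1.5, 3.5, 0), c(3, 3, 0), c(0, 0, 0),
               ring[1:5, ], ring[6, , drop = FALSE])
  structure3d(topo, xyz)
}

test_that("an in-criteria donor-acceptor pair is reported as an H-bond", {
  frame <- make_contact_frame()
  lig <- make_toy_ligand()
  # place the ligand N1 atom 2.9 A from the serine OG, H pointing at it
  n1 <- which(lig$topology$name == "N1")
  hn <- which(lig$topology$name == "HN1")
  shift <- c(0, -2.9, 0) - lig$xyz[n1, ]
  pose <- sweep(lig$xyz, 2, shift, `+`)
  pose[hn, ] <- pose[n1, ] + c(0, 0.95, 0)   # D-H...A at 180 deg
  rep <- annotate_contacts(frame, pose, lig$topology)
  hb <- rep[rep$type == "hbond" & rep$protein_residue == "SER", ]
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$distance, 2.9, tolerance = 1e-6)
  expect_gt(hb$angle, 160)
})

test_that("pairs beyond 3.5 A are not H-bonds", {
  frame <- make_contact_frame()
  lig <- make_toy_ligand()
  n1 <- which(lig$topology$name == "N1")
  pose <- sweep(lig$xyz, 2, c(0, -4.0, 0) - lig$xyz[n1, ], `+`)
  pose <- pose + c(0, 0, 50)  # move everything far away
  rep <- annotate_contacts(frame, pose, lig$topology)
  expect_equal(nrow(rep), 0L)
})

test_that("a bad donor angle suppresses the H-bond", {
  frame <- make_contact_frame()
  lig <- make_toy_ligand()
  n1 <- which(lig$topology$name == "N1")
  hn <- which(lig$topology$name == "HN1")
  ho <- which(lig$topology$name == "HO1")
  o1 <- which(lig$topology$name == "O1")
  pose <- sweep(lig$xyz, 2, c(0, -2.9, 0) - lig$xyz[n1, ], `+`)
  pose[hn, ] <- pose[n1, ] + c(0, -0.95, 0)  # H points away: angle ~0
  # park the other polar atoms out of range
  pose[c(o1, ho), ] <- pose[c(o1, ho), ] + 50
  rep <- annotate_contacts(frame, pose, lig$topology)
  expect_equal(nrow(rep[rep$type == "hbond", ]), 0L)
})

test_that("ring stacking within the centroid cutoff is detected", {
  frame <- make_contact_frame()
  lig <- make_toy_ligand()
  # ligand ring centroid 4 A above the PHE ring centroid (at x = 10)
  pose <- sweep(lig$xyz, 2, c(10, 0, 4), `+`)
  rep <- annotate_contacts(frame, pose, lig$topology)
  pp <- rep[rep$type == "pipi", ]
  expect_equal(nrow(pp), 1L)
  expect_equal(pp$protein_residue, "PHE")
  expect_equal(pp$distance, 4, tolerance = 1e-6)
})

test_that("H-bond detection agrees with exhaustive pair enumeration", {
  g <- make_trajectory(trajectory_spec(n_residues = 8, sigma = 0,
                                       n_frames = 1,
                                       sequence = c("SER", "LEU")))
  frame <- get_frame(g$trajectory, 1)
  lig <- make_toy_ligand()
  set.seed(77)
  for (trial in 1:5) {
    pose <- sweep(lig$xyz, 2, colMeans(frame$xyz) + runif(3, -4, 4), `+`)
    # strip ligand hydrogens so the criterion is purely distance-based
    heavy <- lig$topology$element != "H"
    ltop <- lig$topology[heavy, ]
    rep <- annotate_contacts(frame, pose[heavy, ], ltop)
    oracle <- brute_force_hbonds(frame, pose[heavy, ], ltop$element)
    expect_equal(nrow(rep[rep$type == "hbond", ]), length(oracle))
    if (length(oracle)) {
      expect_equal(sort(rep$distance[rep$type == "hbond"]),
                   sort(vapply(oracle, `[[`, numeric(1), "d")),
                   tolerance = 1e-9)
    }
  }
})
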