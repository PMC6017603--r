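test_that("noise-free generators reproduce the template exactly", {
  g <- make_trajectory(trajectory_spec(n_residues = 6, sigma = 0,
                                       n_frames = 4, seed = 1))
  for (k in 2:4) {
    expect_equal(g$trajectory$coords[k, , ], g$trajectory$coords[1, , ])
  }
})

test_that("trajectory generation is bit-identical under a fixed seed", {
  sp <- trajectory_spec(n_residues = 8, sigma = 0.4, n_frames = 20,
                        open_fraction = 0.3, seed = 55)
  g1 <- make_trajectory(sp); g2 <- make_trajectory(sp)
  expect_identical(g1$trajectory$coords, g2$trajectory$coords)
  expect_identical(g1$truth$open_frames, g2$truth$open_frames)
  g3 <- make_trajectory(trajectory_spec(n_residues = 8, sigma = 0.4,
                                        n_frames = 20, open_fraction = 0.3,
                                        seed = 56))
  expect_false(identical(g1$trajectory$coords, g3$trajectory$coords))
  # changing the seed changes realisations, not the planted parameters
  expect_identical(g1$truth$sigma, g3$truth$sigma)
  expect_identical(g1$truth$open_fraction, g3$truth$open_fraction)
})

test_that("the planted between-state separation is honoured", {
  g <- make_trajectory(trajectory_spec(n_residues = 20, sigma = 0.2,
                                       n_frames = 2, open_fraction = 0.5,
                                       target_separation = 5, seed = 2))
  expect_equal(g$truth$between_state_separation, 5, tolerance = 1e-6)
})

test_that("pose-set generation respects its bound/unbound contract", {
  ref <- make_toy_ligand()
  g <- make_pose_sets(120, ref, bound_fraction = 0.4, bound_noise = 0.3,
                      unbound_offset = 6, score_threshold = -5, seed = 3)
  ps <- g$pose_set
  d <- vapply(seq_len(nrow(ps$poses)), function(i) {
    pose_distance(ps$coords[i, , , drop = TRUE], ref)
  }, numeric(1))
  bound <- seq_len(120) %in% g$truth$bound_frames
  expect_true(all(d[bound] < 2))
  expect_true(all(d[!bound] >= 6))
  expect_true(all(ps$poses$score[bound] < -5))
  expect_true(all(ps$poses$score[!bound] > -5))
})

test_that("the Langmuir generator satisfies detailed balance at Req", {
  sp <- sensorgram_spec(Kd_M = 24.2e-6, kon_M_s = 1e4, Rmax_RU = 60)
  ss <- make_sensorgram_set(sp)
  tr <- ss$truth
  for (i in seq_along(tr$concentrations_M)) {
    on <- tr$kon_M_s * tr$concentrations_M[i] *
      (tr$Rmax_RU - tr$Req_true_RU[i])
    off <- tr$koff_s * tr$Req_true_RU[i]
    expect_equal(on, off, tolerance = 1e-9)
  }
})

test_that("the long-time association limit at C = Kd is Rmax/2", {
  sp <- sensorgram_spec(Kd_M = 1e-5, kon_M_s = 1e5, Rmax_RU = 80,
                        concentrations_M = 1e-5, association_s = 3000,
                        dissociation_s = 10)
  ss <- make_sensorgram_set(sp)
  s <- ss$sensorgrams[[1]]
  at_end <- s$response_RU[max(which(s$time_s <= s$injection_end_s))]
  expect_equal(at_end, 40, tolerance = 1e-6)
})

test_that("noise-free SPR data round-trips through the full analysis", {
  sp <- sensorgram_spec(Kd_M = 24.2e-6, Rmax_RU = 60, seed = 4)
  ss <- make_sensorgram_set(sp)
  req <- vapply(ss$sensorgrams, function(s) {
    extract_equilibrium(s)$Req_RU
  }, numeric(1))
  fit <- fit_steady_state(isotherm(sp$concentrations_M, req))
  expect_equal(fit$Kd_M, 24.2e-6, tolerance = 2e-3)
  expect_equal(fit$Bmax_RU, 60, tolerance = 1e-3)
})

test_that("competition generator plants the requested effect", {
  cs <- make_competition_set(35, effect_percent = -50, seed = 6)
  got <- competition_metrics(extract_equilibrium(cs$alone)$Req_RU,
                             extract_equilibrium(cs$mix)$Req_RU)
  expect_equal(got$percent_change, -50, tolerance = 1e-6)
  cs0 <- make_competition_set(35, effect_percent = 0, seed = 6)
  got0 <- competition_metrics(extract_equilibrium(cs0$alone)$Req_RU,
                              extract_equilibrium(cs0$mix)$Req_RU)
  expect_equal(got0$percent_change, 0, tolerance = 1e-6)
})

test_that("a planted +94% enhancement is recovered under noise", {
  effects <- vapply(1:25, function(s) {
    cs <- make_competition_set(35, effect_percent = 94, noise_sd_RU = 1,
                               seed = s)
    competition_metrics(extract_equilibrium(cs$alone)$Req_RU,
                        extract_equilibrium(cs$mix)$Req_RU)$percent_change
  }, numeric(1))
  expect_lt(abs(mean(effects) - 94), 2)
})
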