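# Synthetic-data generators with known ground truth.
#
# Every generator is deterministic under a fixed seed (Mersenne-Twister,
# R's default; recorded in each truth block) and returns the parameters
# a downstream analysis should recover.  The trajectory model is
# deliberately simple - i.i.d. Gaussian atomic noise around an ideal
# helical template, plus a Bernoulli two-state pocket shift - which gives
# RMSF, clustering and SASA closed-form or enumerable targets without a
# molecular-dynamics engine.  It is not a physical model.

#' Ideal helical peptide template
#'
#' Builds an idealised alpha-helical backbone (rise 1.5 A per residue,
#' 100 degrees per turn step) with atoms N, CA, C, O and CB per residue.
#' Geometry is regular by construction so downstream areas and pockets
#' are reproducible from formulas rather than stored fixtures.
#'
#' @param n_residues number of residues.
#' @param sequence residue names (length `n_residues` or recycled);
#'   default alternates LEU (hydrophobic) and SER (polar).
#' @param chain chain identifier.
#' @return A [structure3d()].
#' @export
make_helix_structure <- function(n_residues,
                                 sequence = c("LEU", "SER"),
                                 chain = "A") {
  n_residues <- as.integer(n_residues)
  stopifnot(n_residues >= 1)
  sequence <- rep(sequence, length.out = n_residues)
  rise <- 1.5; twist <- 100 * pi / 180
  # (radius, phase offset rad, z offset) per backbone atom type
  geom <- list(N = c(1.60, -0.47, -0.90), CA = c(2.30, 0.00, 0.00),
               C = c(1.70, 0.47, 0.80), O = c(1.70, 0.47, 2.03),
               CB = c(3.80, 0.00, 0.00))
  rows <- list(); xyz <- list(); serial <- 0L
  for (i in seq_len(n_residues)) {
    theta <- (i - 1L) * twist; z0 <- (i - 1L) * rise
    for (nm in names(geom)) {
      if (nm == "CB" && sequence[i] == "GLY") next
      g <- geom[[nm]]
      serial <- serial + 1L
      rows[[serial]] <- data.frame(
        serial = serial, name = nm,
        element = substr(nm, 1, 1), resid = i, resname = sequence[i],
        chain = chain, stringsAsFactors = FALSE)
      xyz[[serial]] <- c(g[1] * cos(theta + g[2]),
                         g[1] * sin(theta + g[2]), z0 + g[3])
    }
  }
  structure3d(do.call(rbind, rows), do.call(rbind, xyz))
}

#' Build a small rigid toy ligand
#'
#' A planar six-membered carbon ring (bond length 1.40 A, so ring
#' perception finds it) with one amine nitrogen and one hydroxyl oxygen
#' substituent, plus a polar hydrogen on each - enough chemistry for
#' H-bond and pi-pi annotation.
#'
#' @param label residue name given to the ligand (default "LIG").
#' @return A [structure3d()] flagged hetero.
#' @export
make_toy_ligand <- function(label = "LIG") {
  ang <- (0:5) * pi / 3
  ring <- cbind(1.40 * cos(ang), 1.40 * sin(ang), 0)
  nx <- c(2.80, 0, 0)          # N bonded to ring atom 1 (at 1.40,0,0)
  ox <- c(-2.10, 1.21, 0)      # O bonded to ring atom 3
  hn <- nx + c(0.95, 0, 0.3)
  ho <- ox + c(-0.80, 0.4, 0.2)
  xyz <- rbind(ring, nx, ox, hn, ho)
  topo <- data.frame(
    serial = seq_len(nrow(xyz)),
    name = c(paste0("C", 1:6), "N1", "O1", "HN1", "HO1"),
    element = c(rep("C", 6), "N", "O", "H", "H"),
    resid = 1L, resname = label, chain = "L", stringsAsFactors = FALSE)
  structure3d(topo, xyz)
}

#' Specify a synthetic trajectory
#'
#' @param n_residues residues of the helical template.
#' @param sigma per-residue Gaussian fluctuation amplitude (A); scalar or
#'   length-`n_residues` vector.  Applied per coordinate, so the expected
#'   per-residue RMSF is `sigma * sqrt(3)`.
#' @param n_frames frames to generate.
#' @param timestep_ps frame spacing (ps).
#' @param open_fraction Bernoulli probability that a frame is in the
#'   open-pocket state (0 disables the two-state dynamics).
#' @param pocket_residues residue ids shifted in open frames; default the
#'   last quarter of the chain.
#' @param displacement 3-vector (A) added to pocket-residue atoms in open
#'   frames; see `target_separation`.
#' @param target_separation if non-NULL, `displacement` is rescaled so
#'   the superposed backbone RMSD between the closed and open templates
#'   equals this value (A) - the planted between-state separation.
#' @param sequence residue names for [make_helix_structure()].
#' @param seed RNG seed.
#' @return List of class `trajectory_spec`.
#' @export
trajectory_spec <- function(n_residues = 24, sigma = 0.3, n_frames = 200,
                            timestep_ps = 200, open_fraction = 0,
                            pocket_residues = NULL,
                            displacement = c(5, 0, 0),
                            target_separation = NULL,
                            sequence = c("LEU", "SER"), seed = 1) {
  sigma <- rep(sigma, length.out = n_residues)
  stopifnot(all(sigma >= 0), open_fraction >= 0, open_fraction <= 1,
            n_frames >= 1)
  if (is.null(pocket_residues)) {
    pocket_residues <- seq.int(n_residues - n_residues %/% 4 + 1L,
                               n_residues)
  }
  structure(list(n_residues = as.integer(n_residues), sigma = sigma,
                 n_frames = as.integer(n_frames), timestep_ps = timestep_ps,
                 open_fraction = open_fraction,
                 pocket_residues = as.integer(pocket_residues),
                 displacement = displacement,
                 target_separation = target_separation,
                 sequence = sequence, seed = as.integer(seed)),
            class = "trajectory_spec")
}

#' Generate a synthetic trajectory with known ground truth
#'
#' Frames are the helical template plus independent Gaussian per-atom
#' displacements scaled by the per-residue `sigma`; in two-state mode
#' each frame is open with probability `open_fraction`, and open frames
#' additionally shift the pocket-lining residues by the displacement
#' vector.
#'
#' @param spec a [trajectory_spec()].
#' @return List: `trajectory` (a [trajectory()]) and `truth` with the
#'   prescribed `sigma`, `expected_rmsf` (= sigma * sqrt(3)), the open
#'   frame indices and realised open fraction, the pocket residues, the
#'   realised between-state separation (A), and the RNG used.
#' @export
make_trajectory <- function(spec) {
  stopifnot(inherits(spec, "trajectory_spec"))
  template <- make_helix_structure(spec$n_residues, spec$sequence)
  topo <- template$topology
  nat <- nrow(topo)
  atom_sigma <- spec$sigma[topo$resid]
  pocket_atoms <- which(topo$resid %in% spec$pocket_residues)
  disp <- spec$displacement
  sep <- 0
  if (spec$open_fraction > 0 && length(pocket_atoms)) {
    open_template <- template$xyz
    open_template[pocket_atoms, ] <-
      sweep(open_template[pocket_atoms, , drop = FALSE], 2, disp, `+`)
    bb <- backbone_selection(topo)
    sep <- rmsd(template$xyz, open_template, bb, superpose = TRUE)
    if (!is.null(spec$target_separation)) {
      # superposed RMSD is only approximately linear in the displacement
      # scale (the optimal rotation shifts with it); fixed-point iterate
      for (it in 1:8) {
        disp <- disp * spec$target_separation / sep
        open_template <- template$xyz
        open_template[pocket_atoms, ] <-
          sweep(open_template[pocket_atoms, , drop = FALSE], 2, disp, `+`)
        sep <- rmsd(template$xyz, open_template, bb, superpose = TRUE)
        if (abs(sep - spec$target_separation) < 1e-6) break
      }
    }
  }
  set.seed(spec$seed)
  open <- if (spec$open_fraction > 0) {
    as.logical(rbinom(spec$n_frames, 1, spec$open_fraction))
  } else rep(FALSE, spec$n_frames)
  coords <- array(0, dim = c(spec$n_frames, nat, 3L))
  for (k in seq_len(spec$n_frames)) {
    fr <- template$xyz + matrix(rnorm(nat * 3L), nat, 3L) * atom_sigma
    if (open[k]) {
      fr[pocket_atoms, ] <- sweep(fr[pocket_atoms, , drop = FALSE], 2,
                                  disp, `+`)
    }
    coords[k, , ] <- fr
  }
  list(trajectory = trajectory(topo, coords, spec$timestep_ps),
       truth = list(sigma = spec$sigma,
                    expected_rmsf = spec$sigma * sqrt(3),
                    open_frames = which(open),
                    open_fraction = spec$open_fraction,
                    realized_open_fraction = mean(open),
                    pocket_residues = spec$pocket_residues,
                    displacement = disp,
                    between_state_separation = sep,
                    rng = "Mersenne-Twister", seed = spec$seed))
}

#' Generate per-frame scored pose sets with a known bound fraction
#'
#' Each frame is bound with probability `bound_fraction`.  Bound frames
#' get a pose jittered around the reference pose (per-coordinate
#' Gaussian, so the expected heavy-atom RMSD is about `bound_noise`) and
#' a score strictly below `score_threshold`; unbound frames get a pose
#' displaced by at least `unbound_offset` in a random direction and a
#' score strictly above the threshold.
#'
#' @param n_frames ensemble size.
#' @param reference_pose a [structure3d()] ligand pose.
#' @param bound_fraction probability a frame is binding-competent.
#' @param bound_noise jitter amplitude for bound poses (A, default 0.3).
#' @param unbound_offset minimum displacement of unbound poses (A,
#'   default 6).
#' @param score_threshold score separating bound from unbound
#'   (kcal/mol, default -5).
#' @param score_sd score spread on either side of the threshold.
#' @param seed RNG seed.
#' @return List: `pose_set` (a [pose_set()], one pose per frame) and
#'   `truth` (`bound_frames`, `bound_fraction`, realised fraction,
#'   thresholds, RNG).
#' @export
make_pose_sets <- function(n_frames, reference_pose, bound_fraction,
                           bound_noise = 0.3, unbound_offset = 6,
                           score_threshold = -5, score_sd = 1, seed = 1) {
  stopifnot(inherits(reference_pose, "structure3d"),
            bound_fraction >= 0, bound_fraction <= 1, n_frames >= 1)
  set.seed(seed)
  nat <- nrow(reference_pose$xyz)
  bound <- as.logical(rbinom(n_frames, 1, bound_fraction))
  coords <- array(0, dim = c(n_frames, nat, 3L))
  scores <- numeric(n_frames)
  for (k in seq_len(n_frames)) {
    if (bound[k]) {
      jit <- matrix(rnorm(nat * 3L, sd = bound_noise / sqrt(3)), nat, 3L)
      coords[k, , ] <- reference_pose$xyz + jit
      scores[k] <- score_threshold - 0.05 - abs(rnorm(1, sd = score_sd))
    } else {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      shift <- (unbound_offset + abs(rnorm(1))) * u
      coords[k, , ] <- sweep(reference_pose$xyz, 2, shift, `+`)
      scores[k] <- score_threshold + 0.05 + abs(rnorm(1, sd = score_sd))
    }
  }
  ps <- pose_set(reference_pose$topology,
                 data.frame(frame = seq_len(n_frames),
                            model = seq_len(n_frames), score = scores),
                 coords, n_frames = n_frames)
  list(pose_set = ps,
       truth = list(bound_frames = which(bound),
                    bound_fraction = bound_fraction,
                    realized_fraction = mean(bound),
                    score_threshold = score_threshold,
                    unbound_offset = unbound_offset,
                    bound_noise = bound_noise,
                    rng = "Mersenne-Twister", seed = seed))
}

#' Specify a synthetic SPR experiment
#'
#' @param Kd_M equilibrium dissociation constant (M).
#' @param kon_M_s association rate (1/(M s)); `koff = Kd * kon`.
#' @param Rmax_RU maximal binding capacity (RU).
#' @param concentrations_M analyte concentrations (M).
#' @param association_s injection length (s, default 90).
#' @param dissociation_s wash length after injection (s).
#' @param baseline_s flat baseline before injection (s).
#' @param noise_sd_RU additive Gaussian noise (RU).
#' @param drift_RU_s linear drift (RU/s).
#' @param sample_hz sampling rate (1/s).
#' @param label analyte label.
#' @param seed RNG seed.
#' @return List of class `sensorgram_spec`.
#' @export
sensorgram_spec <- function(Kd_M, kon_M_s = 1e4, Rmax_RU = 100,
                            concentrations_M = Kd_M * c(0.25, 0.5, 1, 2, 4, 8),
                            association_s = 90, dissociation_s = 120,
                            baseline_s = 10, noise_sd_RU = 0,
                            drift_RU_s = 0, sample_hz = 2, label = "",
                            seed = 1) {
  stopifnot(Kd_M > 0, kon_M_s > 0, Rmax_RU > 0,
            all(concentrations_M > 0))
  structure(list(Kd_M = Kd_M, kon_M_s = kon_M_s, koff_s = Kd_M * kon_M_s,
                 Rmax_RU = Rmax_RU, concentrations_M = concentrations_M,
                 association_s = association_s,
                 dissociation_s = dissociation_s, baseline_s = baseline_s,
                 noise_sd_RU = noise_sd_RU, drift_RU_s = drift_RU_s,
                 sample_hz = sample_hz, label = label,
                 seed = as.integer(seed)),
            class = "sensorgram_spec")
}

#' Generate 1:1 Langmuir sensorgrams and their isotherm
#'
#' The association phase follows the closed-form solution of
#' `dR/dt = kon C (Rmax - R) - koff R`, i.e.
#' `R(t) = Req (1 - exp(-(kon C + koff) t))` with
#' `Req = Rmax C / (C + Kd)`; after the injection the response decays as
#' `exp(-koff t)`.  Seeded Gaussian noise and a linear drift are added;
#' the isotherm holds the true Req values plus noise.
#'
#' @param spec a [sensorgram_spec()].
#' @return List: `sensorgrams` (one [sensorgram()] per concentration),
#'   `isotherm` (an [isotherm()]), and `truth` (Kd, kon, koff, Rmax,
#'   per-concentration true Req, RNG).
#' @export
make_sensorgram_set <- function(spec) {
  stopifnot(inherits(spec, "sensorgram_spec"))
  set.seed(spec$seed)
  t_tot <- spec$baseline_s + spec$association_s + spec$dissociation_s
  tt <- seq(0, t_tot, by = 1 / spec$sample_hz)
  t0 <- spec$baseline_s; t1 <- spec$baseline_s + spec$association_s
  req_true <- spec$Rmax_RU * spec$concentrations_M /
    (spec$concentrations_M + spec$Kd_M)
  sgs <- vector("list", length(spec$concentrations_M))
  for (i in seq_along(spec$concentrations_M)) {
    cc <- spec$concentrations_M[i]
    kobs <- spec$kon_M_s * cc + spec$koff_s
    r <- numeric(length(tt))
    assoc <- tt >= t0 & tt <= t1
    r[assoc] <- req_true[i] * (1 - exp(-kobs * (tt[assoc] - t0)))
    r_end <- req_true[i] * (1 - exp(-kobs * spec$association_s))
    dissoc <- tt > t1
    r[dissoc] <- r_end * exp(-spec$koff_s * (tt[dissoc] - t1))
    r <- r + rnorm(length(tt), sd = spec$noise_sd_RU) +
      spec$drift_RU_s * tt
    sgs[[i]] <- sensorgram(tt, r, t0, t1,
                           label = sprintf("%s %.3g M", spec$label, cc))
  }
  iso <- isotherm(spec$concentrations_M,
                  req_true + rnorm(length(req_true),
                                   sd = spec$noise_sd_RU),
                  ligand = spec$label)
  list(sensorgrams = sgs, isotherm = iso,
       truth = list(Kd_M = spec$Kd_M, kon_M_s = spec$kon_M_s,
                    koff_s = spec$koff_s, Rmax_RU = spec$Rmax_RU,
                    Req_true_RU = req_true,
                    concentrations_M = spec$concentrations_M,
                    rng = "Mersenne-Twister", seed = spec$seed))
}

#' Generate a paired alone/mixture competition experiment
#'
#' Two fast-equilibrating traces whose plateaus implement a signed
#' percent effect: `Req_mix = Req_alone * (1 + effect_percent/100)`
#' (negative = inhibition, positive = enhancement).
#'
#' @param Req_alone equilibrium response of the analyte alone (RU, > 0).
#' @param effect_percent signed percent change planted in the mixture.
#' @param noise_sd_RU additive Gaussian noise (RU).
#' @param association_s,dissociation_s,baseline_s,sample_hz trace layout.
#' @param seed RNG seed.
#' @return List: `alone`, `mix` ([sensorgram()]s) and `truth`.
#' @export
make_competition_set <- function(Req_alone, effect_percent,
                                 noise_sd_RU = 0, association_s = 90,
                                 dissociation_s = 60, baseline_s = 10,
                                 sample_hz = 2, seed = 1) {
  stopifnot(Req_alone > 0)
  set.seed(seed)
  t_tot <- baseline_s + association_s + dissociation_s
  tt <- seq(0, t_tot, by = 1 / sample_hz)
  t0 <- baseline_s; t1 <- baseline_s + association_s
  trace <- function(plateau, label) {
    kobs <- 0.5  # fast equilibration relative to the 90 s injection
    r <- numeric(length(tt))
    assoc <- tt >= t0 & tt <= t1
    r[assoc] <- plateau * (1 - exp(-kobs * (tt[assoc] - t0)))
    r_end <- plateau * (1 - exp(-kobs * association_s))
    r[tt > t1] <- r_end * exp(-0.1 * (tt[tt > t1] - t1))
    sensorgram(tt, r + rnorm(length(tt), sd = noise_sd_RU), t0, t1,
               label = label)
  }
  req_mix <- Req_alone * (1 + effect_percent / 100)
  list(alone = trace(Req_alone, "alone"),
       mix = trace(req_mix, "mix"),
       truth = list(Req_alone_RU = Req_alone, Req_mix_RU = req_mix,
                    effect_percent = effect_percent,
                    rng = "Mersenne-Twister", seed = seed))
}
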