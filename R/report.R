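# Pipeline summary report and the umbrella driver that runs the whole
# synthetic workflow (trajectory -> ensemble statistics -> propensity ->
# SPR -> correlation) from one configuration.

#' Assemble the pipeline summary report
#'
#' Merges the per-stage results into one structured report: per-ligand
#' propensity, fitted Kd (flagged presumed when the design did not
#' saturate, `NA` for non-binders), maximal equilibrium binding,
#' competition outcomes and the propensity-vs-binding correlation.
#' Ligands present in only some blocks are listed under `unmatched`
#' (with a warning), not dropped silently.  Non-binders
#' (`propensity = NA` or no fit) are excluded from the correlation and
#' listed separately.
#'
#' @param cluster_summary a `cluster_assignment`, or NULL.
#' @param propensity_results list of `propensity_result` objects.
#' @param fit_results named list of `spr_fit` objects (by ligand).
#' @param correlation a `correlation_result`, or NULL (recomputed from
#'   the blocks when NULL and n >= 3).
#' @param competition_results named list of `competition_result`, or NULL.
#' @param max_req named numeric of maximal observed Req per ligand (RU);
#'   used as the binding value when a fit is non-saturable.
#' @return List of class `flexbind_report` (schema version "1.0").
#' @export
build_report <- function(cluster_summary = NULL,
                         propensity_results = list(),
                         fit_results = list(),
                         correlation = NULL,
                         competition_results = NULL,
                         max_req = NULL) {
  prop_ligs <- vapply(propensity_results, `[[`, character(1), "ligand")
  names(propensity_results) <- prop_ligs
  fit_ligs <- names(fit_results)
  all_ligs <- union(prop_ligs, fit_ligs)
  unmatched <- c(setdiff(prop_ligs, fit_ligs), setdiff(fit_ligs, prop_ligs))
  if (length(unmatched)) {
    warning("ligand(s) present in only one block: ",
            paste(unmatched, collapse = ", "))
  }
  ligands <- lapply(all_ligs, function(lg) {
    pr <- propensity_results[[lg]]
    ft <- fit_results[[lg]]
    binding <- NA_real_
    if (!is.null(ft)) {
      binding <- if (ft$saturable) ft$Bmax_RU else {
        if (!is.null(max_req) && lg %in% names(max_req)) {
          unname(max_req[lg])
        } else ft$Bmax_RU
      }
    }
    list(ligand = lg,
         propensity = if (is.null(pr)) NA_real_ else pr$propensity,
         n_bound = if (is.null(pr)) NA_integer_ else pr$n_bound,
         Kd_M = if (is.null(ft)) NA_real_ else ft$Kd_M,
         Kd_presumed = if (is.null(ft)) NA else ft$presumed,
         Bmax_RU = if (is.null(ft)) NA_real_ else ft$Bmax_RU,
         max_binding_RU = binding,
         competition_percent =
           if (is.null(competition_results) ||
               !lg %in% names(competition_results)) NA_real_
           else competition_results[[lg]]$percent_change)
  })
  names(ligands) <- all_ligs
  usable <- vapply(ligands, function(l) {
    is.finite(l$propensity) && is.finite(l$max_binding_RU)
  }, logical(1))
  if (is.null(correlation) && sum(usable) >= 3L) {
    correlation <- correlate(
      setNames(vapply(ligands[usable], `[[`, numeric(1), "propensity"),
               all_ligs[usable]),
      setNames(vapply(ligands[usable], `[[`, numeric(1), "max_binding_RU"),
               all_ligs[usable]))
  }
  structure(list(
    schema_version = "1.0",
    clusters = if (is.null(cluster_summary)) NULL else list(
      occupancy = cluster_summary$occupancy,
      centroids = cluster_summary$centroids,
      cutoff = cluster_summary$cutoff),
    ligands = ligands,
    non_binders = all_ligs[!usable],
    unmatched = unmatched,
    correlation = correlation,
    correlation_available = !is.null(correlation)),
    class = "flexbind_report")
}

#' @export
print.flexbind_report <- function(x, ...) {
  cat("<flexbind_report> schema", x$schema_version, "\n")
  if (!is.null(x$clusters)) {
    cat(sprintf("  clusters: %s (cutoff %.1f A)\n",
                paste(sprintf("%.1f%%", 100 * x$clusters$occupancy),
                      collapse = "/"), x$clusters$cutoff))
  }
  for (l in x$ligands) {
    cat(sprintf("  %-8s propensity %s  Kd %s%s  maxRU %s  competition %s\n",
                l$ligand,
                ifelse(is.na(l$propensity), "n.d.",
                       sprintf("%.3f", l$propensity)),
                ifelse(is.na(l$Kd_M), "n.d.", sprintf("%.3g M", l$Kd_M)),
                ifelse(isTRUE(l$Kd_presumed), " (presumed)", ""),
                ifelse(is.na(l$max_binding_RU), "n.d.",
                       sprintf("%.1f", l$max_binding_RU)),
                ifelse(is.na(l$competition_percent), "-",
                       sprintf("%+.1f%%", l$competition_percent))))
  }
  if (x$correlation_available) print(x$correlation)
  else cat("  correlation: unavailable (fewer than 3 usable ligands)\n")
  invisible(x)
}

#' Default configuration of the synthetic end-to-end pipeline
#'
#' The ligand panel mirrors a four-compound study: planted binding
#' propensities 0.48/0.22/0.15/0.15, dissociation constants
#' 24.2/197.9/40.3/99.3 uM, and competition effects
#' +94%/0%/+29%/-50%.  Trajectory: 24-residue helix, 200 frames at
#' 200 ps, per-coordinate noise 0.3 A, two-state pocket open 30% of the
#' time with a planted 5 A between-state separation.
#'
#' @param n_frames_traj frames generated for the ensemble analyses.
#' @param n_frames_poses frames per ligand for the propensity stage.
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function(n_frames_traj = 200,
                                    n_frames_poses = 1000) {
  list(
    trajectory = list(n_residues = 24, sigma = 0.3,
                      n_frames = n_frames_traj, timestep_ps = 200,
                      open_fraction = 0.3, target_separation = 5),
    ligands = data.frame(
      ligand = c("ligA", "ligB", "ligC", "ligD"),
      bound_fraction = c(0.48, 0.22, 0.15, 0.15),
      Kd_M = c(24.2e-6, 197.9e-6, 40.3e-6, 99.3e-6),
      Rmax_RU = c(60, 30, 22, 18),
      competition_percent = c(94, 0, 29, -50),
      stringsAsFactors = FALSE),
    poses = list(n_frames = n_frames_poses, distance_cutoff = 2,
                 score_threshold = -5, bound_noise = 0.3,
                 unbound_offset = 6),
    spr = list(noise_frac = 0.01, association_s = 90,
               dissociation_s = 120,
               conc_factors = c(0.25, 0.5, 1, 2, 4, 8)),
    competition = list(Req_alone = 35, noise_sd_RU = 0.5),
    cluster = list(cutoff = 2.0),
    hs_region = NULL)  # default: the trajectory's pocket residues
}

#' Run the full synthetic pipeline
#'
#' Generates a two-state ensemble and a ligand panel with known ground
#' truth, then runs every analysis stage: RMSF, conformational
#' clustering and representative-frame selection, hydrophobic-surface
#' series over the pocket region, per-ligand binding propensity,
#' sensorgram generation, blank subtraction, equilibrium extraction,
#' one-site Kd fitting, competition metrics, and the
#' propensity-vs-binding permutation correlation, assembled by
#' [build_report()].
#'
#' @param config configuration from [default_pipeline_config()].
#' @param seed master seed; stage seeds are derived from it.
#' @param verbose print per-stage progress with timings.
#' @return A `flexbind_report` with an additional `truth` element
#'   holding every generator's ground-truth record.
#' @export
run_pipeline <- function(config = default_pipeline_config(), seed = 1,
                         verbose = FALSE) {
  t_start <- proc.time()["elapsed"]
  say <- function(fmt, ...) {
    if (verbose) {
      cat(sprintf("[%6.1fs] ", proc.time()["elapsed"] - t_start),
          sprintf(fmt, ...), "\n", sep = "")
    }
  }
  tc <- config$trajectory
  ts <- trajectory_spec(n_residues = tc$n_residues, sigma = tc$sigma,
                        n_frames = tc$n_frames,
                        timestep_ps = tc$timestep_ps,
                        open_fraction = tc$open_fraction,
                        target_separation = tc$target_separation,
                        seed = seed)
  gen <- make_trajectory(ts)
  traj <- gen$trajectory
  say("trajectory: %d frames, %d atoms", n_frames(traj),
      nrow(traj$topology))

  prof <- rmsf(traj)
  say("rmsf: %d residues, median %.2f A", nrow(prof), median(prof$rmsf))

  cl <- cluster_conformations(traj, cutoff = config$cluster$cutoff)
  rep_frame <- representative_conformation(cl)
  say("clustering: %d clusters, occupancies %s; representative frame %d",
      length(cl$centroids),
      paste(sprintf("%.2f", cl$occupancy), collapse = "/"), rep_frame)

  region <- config$hs_region
  if (is.null(region)) region <- gen$truth$pocket_residues
  hs <- hydrophobic_surface_series(traj, region)
  hs_max <- max_hydrophobic_frame(hs)
  say("hydrophobic surface: max %.1f A^2 at frame %d", hs_max$area,
      hs_max$frame_index)

  # reference pose: the toy ligand centred on the pocket of the
  # representative conformation
  lig <- make_toy_ligand()
  pocket_atoms <- atom_select(traj, resid = region)
  centre <- colMeans(get_frame(traj, rep_frame)$xyz[pocket_atoms, ,
                                                    drop = FALSE])
  ref_pose <- structure3d(lig$topology,
                          sweep(sweep(lig$xyz, 2, colMeans(lig$xyz)), 2,
                                centre, `+`))

  lig_tab <- config$ligands
  prop_results <- list()
  pose_truth <- list()
  for (i in seq_len(nrow(lig_tab))) {
    pg <- make_pose_sets(config$poses$n_frames, ref_pose,
                         lig_tab$bound_fraction[i],
                         bound_noise = config$poses$bound_noise,
                         unbound_offset = config$poses$unbound_offset,
                         score_threshold = config$poses$score_threshold,
                         seed = seed + 100 + i)
    prop_results[[i]] <- binding_propensity(
      pg$pose_set, ref_pose,
      distance_cutoff = config$poses$distance_cutoff,
      score_threshold = config$poses$score_threshold,
      ligand = lig_tab$ligand[i])
    pose_truth[[lig_tab$ligand[i]]] <- pg$truth
    say("propensity %s: %.3f (planted %.2f)", lig_tab$ligand[i],
        prop_results[[i]]$propensity, lig_tab$bound_fraction[i])
  }

  fit_results <- list()
  spr_truth <- list()
  max_req <- numeric(0)
  for (i in seq_len(nrow(lig_tab))) {
    sp <- sensorgram_spec(
      Kd_M = lig_tab$Kd_M[i], Rmax_RU = lig_tab$Rmax_RU[i],
      concentrations_M = lig_tab$Kd_M[i] * config$spr$conc_factors,
      association_s = config$spr$association_s,
      dissociation_s = config$spr$dissociation_s,
      noise_sd_RU = config$spr$noise_frac * lig_tab$Rmax_RU[i],
      label = lig_tab$ligand[i], seed = seed + 200 + i)
    sset <- make_sensorgram_set(sp)
    # blank: an analyte-free reference trace with the same noise level
    blank_sp <- sensorgram_spec(
      Kd_M = lig_tab$Kd_M[i], Rmax_RU = 1e-9,
      concentrations_M = sp$concentrations_M[1],
      association_s = config$spr$association_s,
      dissociation_s = config$spr$dissociation_s,
      noise_sd_RU = config$spr$noise_frac * lig_tab$Rmax_RU[i],
      label = "blank", seed = seed + 300 + i)
    blank <- make_sensorgram_set(blank_sp)$sensorgrams[[1]]
    req <- vapply(sset$sensorgrams, function(s) {
      extract_equilibrium(blank_subtract(s, blank))$Req_RU
    }, numeric(1))
    iso <- isotherm(sp$concentrations_M, req, ligand = lig_tab$ligand[i])
    fit_results[[lig_tab$ligand[i]]] <- fit_steady_state(iso)
    max_req[lig_tab$ligand[i]] <- max(req)
    spr_truth[[lig_tab$ligand[i]]] <- sset$truth
    say("SPR %s: Kd = %.3g M (true %.3g), %s", lig_tab$ligand[i],
        fit_results[[lig_tab$ligand[i]]]$Kd_M, lig_tab$Kd_M[i],
        if (fit_results[[lig_tab$ligand[i]]]$saturable) "saturable"
        else "presumed")
  }

  comp_results <- list()
  comp_truth <- list()
  for (i in seq_len(nrow(lig_tab))) {
    cs <- make_competition_set(config$competition$Req_alone,
                               lig_tab$competition_percent[i],
                               noise_sd_RU = config$competition$noise_sd_RU,
                               seed = seed + 400 + i)
    comp_results[[lig_tab$ligand[i]]] <- competition_metrics(
      extract_equilibrium(cs$alone)$Req_RU,
      extract_equilibrium(cs$mix)$Req_RU)
    comp_truth[[lig_tab$ligand[i]]] <- cs$truth
  }
  say("competition metrics done")

  report <- build_report(cluster_summary = cl,
                         propensity_results = prop_results,
                         fit_results = fit_results,
                         competition_results = comp_results,
                         max_req = max_req)
  report$rmsf_profile <- prof
  report$hs_series_max <- hs_max
  report$representative_frame <- rep_frame
  report$truth <- list(trajectory = gen$truth, poses = pose_truth,
                       spr = spr_truth, competition = comp_truth,
                       ligands = lig_tab)
  say("report assembled")
  report
}

#' Write a report as JSON
#'
#' @param report a `flexbind_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  out <- report
  out$truth <- NULL
  out$correlation <- if (!is.null(out$correlation)) {
    unclass(out$correlation)
  }
  out$clusters$occupancy <- as.numeric(out$clusters$occupancy)
  jsonlite::write_json(unclass(out), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}
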