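# End-to-end workflow: equilibration trimming -> RMSD/RMSF -> angle
# descriptor -> pooled GROMOS clustering -> transition counting, with
# per-stage TSV outputs and a JSON summary.

#' Build a run configuration
#'
#' @param trajectories character vector of multi-model PDB paths, or
#'   `NULL` when `spec` is given.
#' @param spec optional [trajectory_spec()]; a synthetic trajectory is
#'   generated instead of reading files.
#' @param out_dir output directory (created if needed).
#' @param equilibration_cut_ps analysis uses only frames strictly after
#'   this time; default 200000 ps (200 ns), the conventional relaxation
#'   allowance.
#' @param fit_sel,measure_sel Selections for superposition and RMSD
#'   measurement.
#' @param cluster_cutoff_A GROMOS cutoff, default 5.
#' @param anchors [default_anchors()] or an override.
#' @param map optional [numbering_map()] if structures use chimera
#'   numbering.
#' @param seed integer seed recorded in the log.
#' @export
run_config <- function(trajectories = NULL, spec = NULL, out_dir = tempfile("conformscape_"),
                       equilibration_cut_ps = 200000,
                       fit_sel = core_fit_selection(),
                       measure_sel = selection(NULL, c("N", "CA", "C", "O")),
                       cluster_cutoff_A = 5, anchors = default_anchors(),
                       map = NULL, seed = 1L) {
  if (is.null(trajectories) && is.null(spec))
    stop("provide either trajectory paths or a synthetic spec")
  if (!is.null(trajectories)) {
    missing <- trajectories[!file.exists(trajectories)]
    if (length(missing)) stop("missing trajectory file(s): ",
                              paste(missing, collapse = ", "))
  }
  if (cluster_cutoff_A <= 0) stop("cluster cutoff must be positive")
  structure(list(trajectories = trajectories, spec = spec, out_dir = out_dir,
                 equilibration_cut_ps = equilibration_cut_ps,
                 fit_sel = fit_sel, measure_sel = measure_sel,
                 cluster_cutoff_A = cluster_cutoff_A, anchors = anchors,
                 map = map, seed = as.integer(seed)),
            class = "RunConfig")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Stages: load or generate trajectories; drop frames at or before the
#' equilibration cut; per trajectory, RMSD series against the
#' trailing-window average structure, per-residue RMSF, and the
#' three-angle series; pool all post-equilibration frames, cluster at the
#' configured cutoff, count lag-1 transitions per trajectory; evaluate
#' the descriptor on each cluster representative.  All tables are written
#' as TSV under `cfg$out_dir` together with `summary.json` and a run log.
#'
#' @param cfg a [run_config()].
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(cfg$out_dir, "run.log")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = logf, append = TRUE)
  cat("", file = logf)
  logline("conformscape %s | R %s", as.character(utils::packageVersion("conformscape")),
          paste(R.version$major, R.version$minor, sep = "."))
  logline("seed=%d equilibration_cut_ps=%g cluster_cutoff_A=%g",
          cfg$seed, cfg$equilibration_cut_ps, cfg$cluster_cutoff_A)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  trajs <- stage("load", {
    if (!is.null(cfg$spec)) {
      sim <- make_trajectory(cfg$spec)
      write_tsv(sim$labels, file.path(cfg$out_dir, "true_labels.tsv"))
      list(synthetic = sim$trajectory)
    } else {
      out <- lapply(cfg$trajectories, read_pdb)
      names(out) <- basename(cfg$trajectories)
      out
    }
  })

  kept <- stage("equilibration", {
    lapply(trajs, function(tr) {
      keep <- which(frame_times(tr) > cfg$equilibration_cut_ps)
      if (!length(keep)) stop("no frames after equilibration cut")
      tr$coords <- tr$coords[, , keep, drop = FALSE]
      attr(tr, "orig_frames") <- keep
      tr
    })
  })
  logline("trajectories=%d, post-equilibration frames: %s", length(kept),
          paste(vapply(kept, n_frames, integer(1)), collapse = ","))

  per_traj <- stage("per-trajectory", {
    lapply(names(kept), function(nm) {
      tr <- kept[[nm]]
      avg <- average_structure(tr, NULL, cfg$fit_sel)
      rs <- rmsd_series(tr, avg, cfg$fit_sel, cfg$measure_sel)
      rp <- rmsf(tr, NULL, cfg$fit_sel, construct_label = nm)
      as_ <- angle_series(tr, cfg$anchors, cfg$map)
      write_tsv(rs, file.path(cfg$out_dir, paste0("rmsd_", nm, ".tsv")))
      write_tsv(rp, file.path(cfg$out_dir, paste0("rmsf_", nm, ".tsv")))
      write_tsv(as_, file.path(cfg$out_dir, paste0("angles_", nm, ".tsv")))
      list(rmsd = rs, rmsf = rp, angles = as_)
    })
  })

  pooled <- stage("pool", {
    nf <- vapply(kept, n_frames, integer(1))
    co <- array(NA_real_, dim = c(n_atoms(kept[[1]]), 3L, sum(nf)))
    at <- 0L
    for (tr in kept) {
      co[, , at + seq_len(n_frames(tr))] <- tr$coords
      at <- at + n_frames(tr)
    }
    list(traj = new_trajectory(kept[[1]]$topology, co,
                               kept[[1]]$frame_spacing_ps),
         origin = rep(seq_along(kept), nf))
  })

  cl <- stage("cluster", {
    d <- pairwise_rmsd(pooled$traj, cfg$fit_sel, cfg$measure_sel)
    gromos_cluster(d, cfg$cluster_cutoff_A)
  })
  labels_df <- data.frame(pooled_frame = seq_along(cl$labels),
                          trajectory = names(kept)[pooled$origin],
                          cluster = cl$labels)
  write_tsv(labels_df, file.path(cfg$out_dir, "cluster_labels.tsv"))
  write_tsv(cluster_summary(cl), file.path(cfg$out_dir, "cluster_summary.tsv"))
  logline("clusters=%d, top population=%.3f", length(cl$sizes), max(cl$populations))

  tm <- stage("transitions", {
    count_transitions(split(cl$labels, pooled$origin), k = length(cl$sizes))
  })
  tmat <- as.data.frame(tm$counts)
  names(tmat) <- paste0("to_", seq_len(tm$k))
  write_tsv(cbind(from = seq_len(tm$k), tmat),
            file.path(cfg$out_dir, "transitions.tsv"))

  rep_angles <- stage("representative-angles", {
    t(vapply(cl$representatives, function(f)
      angle_triple(get_frame(pooled$traj, f), cfg$anchors, cfg$map), numeric(3)))
  })

  summary <- list(
    n_trajectories = length(kept),
    n_frames_pooled = n_frames(pooled$traj),
    equilibration_cut_ps = cfg$equilibration_cut_ps,
    cluster_cutoff_A = cfg$cluster_cutoff_A,
    n_clusters = length(cl$sizes),
    cluster_table = cbind(cluster_summary(cl),
                          theta1_deg = round(rep_angles[, 1], 1),
                          theta2_deg = round(rep_angles[, 2], 1),
                          theta3_deg = round(rep_angles[, 3], 1)),
    n_transitions = tm$n_transitions,
    self_transition_fraction = sum(diag(tm$counts)) / max(1, tm$n_transitions),
    symmetry_score = if (sum(tm$counts) - sum(diag(tm$counts)) > 0)
      symmetry_score(tm) else NA_real_,
    seed = cfg$seed)
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  logline("done")
  invisible(summary)
}
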