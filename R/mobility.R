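# Per-residue RMSF over a trailing window, and cross-construct
# differential RMSF reconciled through the numbering map.

#' Per-residue root-mean-square fluctuation
#'
#' Frames in the window are superposed onto the window's average structure
#' over `fit_sel`; per residue the RMSF is the root of the mean (over
#' frames and that residue's selected atoms) squared deviation from the
#' time-mean atomic position.
#'
#' @param traj Trajectory.
#' @param window frame indices or `c(first, last)`; `NULL` = all frames.
#'   Conventionally the post-equilibration portion of a run.
#' @param fit_sel Selection for superposition (default core helices E/F).
#' @param per_residue_atoms atom names contributing to each residue's
#'   value; default `"CA"`.
#' @param construct_label label stored with the profile.
#' @return data.frame of class `RmsfProfile` with columns `chain`,
#'   `resid`, `rmsf_A`.
#' @export
rmsf <- function(traj, window = NULL, fit_sel = core_fit_selection(),
                 per_residue_atoms = "CA", construct_label = "") {
  win <- resolve_window(traj, window)
  if (length(win) < 2L) stop("RMSF needs a window of at least 2 frames")
  fit_idx <- select_indices(traj, fit_sel)
  avg <- average_structure(traj, win, fit_sel)
  ref_fit <- avg$coords[fit_idx, , drop = FALSE]

  sel <- selection(NULL, per_residue_atoms)
  idx <- select_indices(traj, sel)
  at <- traj$topology$atoms[idx, , drop = FALSE]

  # first pass: fitted coordinates; accumulate mean
  fitted <- array(0, dim = c(length(idx), 3L, length(win)))
  for (j in seq_along(win)) {
    fr <- traj$coords[, , win[j]]
    tf <- kabsch(fr[fit_idx, , drop = FALSE], ref_fit)
    fitted[, , j] <- apply_transform(fr[idx, , drop = FALSE], tf)
  }
  mean_pos <- apply(fitted, c(1, 2), mean)
  dev2 <- sweep(fitted, c(1, 2), mean_pos)^2
  msf_atom <- apply(dev2, 1, sum) / length(win)   # per-atom mean squared fluct.

  key <- paste(at$chain, at$resid)
  grp <- match(key, unique(key))
  msf_res <- tapply(msf_atom, grp, mean)
  first <- !duplicated(key)
  out <- data.frame(chain = at$chain[first], resid = at$resid[first],
                    rmsf_A = as.numeric(sqrt(msf_res)))
  attr(out, "construct_label") <- construct_label
  attr(out, "n_atoms_per_residue") <- as.numeric(table(grp)[as.character(seq_len(sum(first)))])
  class(out) <- c("RmsfProfile", class(out))
  out
}

#' Differential RMSF between two constructs
#'
#' Computes `a - b` on the residue range shared by both profiles after
#' mapping, excluding residues below `from_residue` (the first residue
#' common to chimera and wild type, native numbering).  With the default
#' sign convention, positive values indicate greater fluctuation in `a`
#' (the chimera).
#'
#' @param a,b RmsfProfile objects (e.g. chimera and wild type), both in
#'   native-extended numbering unless `map_a`/`map_b` are supplied.
#' @param map_a,map_b optional [numbering_map()] applied
#'   (chimera-to-native) to the corresponding profile's residue numbers
#'   before intersection.
#' @param from_residue first native residue included, default 15.
#' @return data.frame of class `RmsfProfile` with columns `resid`,
#'   `delta_rmsf_A`.
#' @export
differential_rmsf <- function(a, b, map_a = NULL, map_b = NULL, from_residue = 15L) {
  res_a <- a$resid
  res_b <- b$resid
  if (!is.null(map_a)) res_a <- map_residue(res_a, map_a, "chimera_to_native")
  if (!is.null(map_b)) res_b <- map_residue(res_b, map_b, "chimera_to_native")
  shared <- sort(intersect(res_a[res_a >= from_residue], res_b[res_b >= from_residue]))
  if (!length(shared)) stop("profiles share no residues at or above residue ", from_residue)
  out <- data.frame(resid = shared,
                    delta_rmsf_A = a$rmsf_A[match(shared, res_a)] -
                      b$rmsf_A[match(shared, res_b)])
  class(out) <- c("RmsfProfile", class(out))
  out
}
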