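# Least-squares rigid-body superposition and RMSD machinery.
#
# The rotation is obtained from the SVD of the weighted covariance matrix
# with the usual determinant correction so that only proper rotations
# (det = +1, no reflection) are returned.

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation `R` and translation `t` minimizing the
#' (weighted) sum of squared distances `sum w_i |R x_i + t - y_i|^2`
#' between paired point sets.
#'
#' @param mobile n x 3 matrix of points to be moved.
#' @param target n x 3 matrix of reference points.
#' @param weights optional non-negative weights, length n.
#' @return A list of class `RigidTransform` with elements `rotation`
#'   (3 x 3, det +1) and `translation` (length 3), to be applied as
#'   `x %*% t(rotation) + translation`.
#' @export
kabsch <- function(mobile, target, weights = NULL) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  n <- nrow(mobile)
  if (n != nrow(target)) stop("point counts differ")
  if (n < 3L) stop("need at least 3 point pairs for superposition")
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  cm <- colSums(mobile * w); ct <- colSums(target * w)
  A <- sweep(mobile, 2, cm); B <- sweep(target, 2, ct)
  H <- t(A * w) %*% B
  sv <- svd(H)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1))
    stop("degenerate (collinear) point set: superposition is not unique")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  tr <- as.numeric(ct - R %*% cm)
  structure(list(rotation = R, translation = tr), class = "RigidTransform")
}

#' Apply a rigid transform to coordinates
#' @param coords n x 3 matrix.
#' @param tf RigidTransform from [kabsch()].
#' @export
apply_transform <- function(coords, tf) {
  sweep(as.matrix(coords) %*% t(tf$rotation), 2, tf$translation, `+`)
}

#' Root-mean-square deviation between paired point sets
#' @param a,b n x 3 matrices with matched rows.
#' @return RMSD in the coordinate units (Angstrom), symmetric in `a`, `b`.
#' @export
rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b)) stop("point counts differ")
  if (nrow(a) < 1L) stop("empty point sets")
  sqrt(mean(rowSums((a - b)^2)))
}

resolve_window <- function(traj, window) {
  nf <- n_frames(traj)
  if (is.null(window)) return(seq_len(nf))
  window <- as.integer(window)
  if (length(window) == 2L && window[2] >= window[1] &&
      !anyNA(window) && window[1] >= 1L) {
    window <- seq.int(window[1], min(window[2], nf))
  }
  if (!length(window) || any(window < 1L | window > nf))
    stop("invalid frame window")
  window
}

#' Average structure over a frame window
#'
#' Each frame of the window is superposed onto the window's first frame
#' using `fit_sel`, then coordinates are averaged atomwise.  This is the
#' reference used for trailing-window RMSD relaxation checks (e.g. the
#' average over the last 50 ns of a run).
#'
#' @param traj Trajectory.
#' @param window frame indices, or `c(first, last)`; `NULL` = all frames.
#' @param fit_sel Selection used for the superposition fit.
#' @return A [Structure] with the averaged coordinates.
#' @export
average_structure <- function(traj, window = NULL, fit_sel = core_fit_selection()) {
  win <- resolve_window(traj, window)
  fit_idx <- select_indices(traj, fit_sel)
  ref <- traj$coords[, , win[1]]
  acc <- ref
  if (length(win) > 1L) for (k in win[-1]) {
    fr <- traj$coords[, , k]
    tf <- kabsch(fr[fit_idx, , drop = FALSE], ref[fit_idx, , drop = FALSE])
    acc <- acc + apply_transform(fr, tf)
  }
  new_structure(traj$topology$atoms, acc / length(win),
                label = sprintf("average[%d frames]", length(win)))
}

#' RMSD time series against a reference structure
#'
#' Every frame is superposed onto `ref` over `fit_sel` (typically the
#' immobile core helices E/F) and the RMSD is then measured over
#' `measure_sel`, which may exclude mobile N-terminal residues.
#'
#' @param traj Trajectory.
#' @param ref Structure sharing the trajectory's atom identities.
#' @param fit_sel Selection for the superposition fit.
#' @param measure_sel Selection over which RMSD is computed.
#' @return data.frame of class `RmsdSeries` with columns `frame`,
#'   `time_ps`, `rmsd_A`.
#' @export
rmsd_series <- function(traj, ref, fit_sel = core_fit_selection(),
                        measure_sel = selection(NULL, c("N", "CA", "C", "O"))) {
  fit_idx <- select_indices(traj, fit_sel)
  meas_idx <- select_indices(traj, measure_sel)
  ref_fit <- ref$coords[select_indices(ref, fit_sel), , drop = FALSE]
  ref_meas <- ref$coords[select_indices(ref, measure_sel), , drop = FALSE]
  nf <- n_frames(traj)
  vals <- numeric(nf)
  for (k in seq_len(nf)) {
    fr <- traj$coords[, , k]
    tf <- kabsch(fr[fit_idx, , drop = FALSE], ref_fit)
    vals[k] <- rmsd(apply_transform(fr[meas_idx, , drop = FALSE], tf), ref_meas)
  }
  out <- data.frame(frame = seq_len(nf), time_ps = frame_times(traj), rmsd_A = vals)
  class(out) <- c("RmsdSeries", class(out))
  out
}
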