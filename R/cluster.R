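# GROMOS neighbor-count RMSD clustering: compute an all-versus-all
# superposed backbone-RMSD matrix, then iteratively peel off the
# unassigned frame with the most neighbors within the cutoff together
# with those neighbors.

#' All-versus-all superposed RMSD matrix
#'
#' Entry (i, j) is the RMSD over `measure_sel` after superposing frame j
#' onto frame i over `fit_sel`; the matrix is symmetrized by averaging the
#' two directions (they are equal when the two selections coincide).
#'
#' @param traj Trajectory (at least 2 frames).
#' @param fit_sel Selection used for the Kabsch fit (default core helices
#'   E/F backbone).
#' @param measure_sel Selection over which RMSD is measured (default all
#'   backbone atoms).
#' @return Symmetric matrix of class `DistanceMatrix` with a zero
#'   diagonal, in Angstrom.
#' @export
pairwise_rmsd <- function(traj, fit_sel = core_fit_selection(),
                          measure_sel = selection(NULL, c("N", "CA", "C", "O"))) {
  if (n_frames(traj) < 2L) stop("pairwise RMSD needs at least 2 frames")
  fit_idx <- select_indices(traj, fit_sel)
  meas_idx <- select_indices(traj, measure_sel)
  m <- cpp_pairwise_rmsd(traj$coords, fit_idx, meas_idx)
  class(m) <- c("DistanceMatrix", class(m))
  m
}

#' GROMOS neighbor-count clustering
#'
#' Repeatedly: count, among unassigned frames, each frame's neighbors at
#' RMSD strictly below `cutoff_A`; the frame with the most neighbors
#' becomes the next cluster's center and is removed together with its
#' unassigned neighbors.  Ties are broken by lowest frame index.
#' Singleton clusters are allowed.
#'
#' @param d DistanceMatrix from [pairwise_rmsd()] (any symmetric
#'   non-negative matrix with zero diagonal works).
#' @param cutoff_A neighbor cutoff in Angstrom; the conventional value for
#'   backbone clustering of the fusion-kinase ensemble is 5.
#' @return List of class `ClusterResult`: `labels` (per frame, 1-based in
#'   discovery order), `populations` (fractions, sum to 1), `centers`
#'   (max-neighbor frame per cluster), `representatives` (min mean
#'   intra-cluster RMSD frame per cluster), `sizes`, `cutoff_A`.
#' @export
gromos_cluster <- function(d, cutoff_A = 5) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("d must be a square matrix")
  if (cutoff_A <= 0) stop("cutoff must be positive")
  n <- nrow(d)
  labels <- integer(n)
  centers <- integer(0)
  active <- seq_len(n)
  cl <- 0L
  while (length(active)) {
    cl <- cl + 1L
    if (length(active) == 1L) {
      centre <- active
      members <- active
    } else {
      sub <- d[active, active, drop = FALSE] < cutoff_A
      counts <- colSums(sub) - 1L          # exclude self
      centre <- active[which.max(counts)]  # which.max: first max = lowest index
      members <- active[sub[, which.max(counts)]]
    }
    labels[members] <- cl
    centers[cl] <- centre
    active <- setdiff(active, members)
  }
  sizes <- tabulate(labels, nbins = cl)
  reps <- vapply(seq_len(cl), function(k) representative(d, which(labels == k)),
                 integer(1))
  structure(list(labels = labels, populations = sizes / n, centers = centers,
                 representatives = reps, sizes = sizes, cutoff_A = cutoff_A),
            class = "ClusterResult")
}

#' Representative frame of a cluster
#'
#' The member with the smallest mean RMSD distance to every other member;
#' a singleton represents itself.  Ties go to the lowest frame index.
#'
#' @param d DistanceMatrix.
#' @param members integer vector of member frame indices.
#' @return Frame index of the representative.
#' @export
representative <- function(d, members) {
  members <- as.integer(members)
  if (!length(members)) stop("empty member set")
  if (length(members) == 1L) return(members)
  sub <- d[members, members, drop = FALSE]
  mean_d <- (colSums(sub)) / (length(members) - 1L)
  members[which.min(mean_d)]
}

#' @export
print.ClusterResult <- function(x, ...) {
  k <- length(x$sizes)
  cat(sprintf("<ClusterResult: %d clusters over %d frames, cutoff %g A>\n",
              k, length(x$labels), x$cutoff_A))
  show <- head(order(-x$sizes), 8L)
  for (i in show)
    cat(sprintf("  cluster %d: %5.1f%%  center %d  representative %d\n",
                i, 100 * x$populations[i], x$centers[i], x$representatives[i]))
  if (k > 8L) cat(sprintf("  ... %d more\n", k - 8L))
  invisible(x)
}

#' Cluster summary table
#'
#' @param cr ClusterResult.
#' @return data.frame with columns `cluster`, `size`, `fraction`,
#'   `center_frame`, `representative_frame`.
#' @export
cluster_summary <- function(cr) {
  data.frame(cluster = seq_along(cr$sizes), size = cr$sizes,
             fraction = cr$populations, center_frame = cr$centers,
             representative_frame = cr$representatives)
}
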