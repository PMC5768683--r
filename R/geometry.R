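# Three-angle appendage mobility descriptor.
#
# Six C-alpha anchors define the descriptor: three along the A-helix
# (base, mid, top), the appendage tip, and two large-lobe anchors.
#   theta1: A-helix bend  = angle( top - mid , base - mid );
#           a straight helix gives theta1 ~ 180 deg.
#   theta2: appendage elevation = angle( mid - base , tip - base ).
#   theta3: shear, |dihedral(top, lobe1, lobe2, tip)| in [0, 180].
# All three are invariant under global rigid motion, so no superposition
# is required before evaluation.

#' Default anchor residues for the appendage descriptor
#'
#' Native-extended numbering: A-helix top Lys29, mid Val15, base Pro2,
#' appendage tip Lys(-19), large-lobe anchors Leu160 and Glu140.
#'
#' @param a_helix_top,a_helix_mid,a_helix_base,j_tip,lobe_1,lobe_2
#'   residue numbers (native-extended numbering).
#' @param atom_name anchor atom, default `"CA"`.
#' @param chain chain id, default `"A"`.
#' @return A list of class `AnchorSet`.
#' @export
default_anchors <- function(a_helix_top = 29L, a_helix_mid = 15L,
                            a_helix_base = 2L, j_tip = -19L,
                            lobe_1 = 160L, lobe_2 = 140L,
                            atom_name = "CA", chain = "A") {
  structure(list(a_helix_top = a_helix_top, a_helix_mid = a_helix_mid,
                 a_helix_base = a_helix_base, j_tip = j_tip,
                 lobe_1 = lobe_1, lobe_2 = lobe_2,
                 atom_name = atom_name, chain = chain),
            class = "AnchorSet")
}

#' Angle between two vectors in degrees
#' @param u,v non-zero numeric 3-vectors.
#' @return Angle in `[0, 180]` degrees.
#' @export
angle_between <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("zero vector in angle computation")
  acos(max(-1, min(1, sum(u * v) / (nu * nv)))) * 180 / pi
}

#' Signed dihedral angle through four points, degrees
#'
#' IUPAC sign convention: looking down the p2 -> p3 axis, a clockwise
#' rotation of the far bond is positive; range `(-180, 180]`.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  nb2 <- sqrt(sum(b2^2))
  if (nb2 == 0 || sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20)
    stop("degenerate geometry in dihedral computation")
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / nb2
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

anchor_positions <- function(frame, anchors, map = NULL) {
  force(frame)
  res <- c(top = anchors$a_helix_top, mid = anchors$a_helix_mid,
           base = anchors$a_helix_base, tip = anchors$j_tip,
           lobe1 = anchors$lobe_1, lobe2 = anchors$lobe_2)
  if (!is.null(map)) res <- setNames(map_residue(res, map, "native_to_chimera"), names(res))
  pos <- lapply(seq_along(res), function(i) {
    tryCatch(residue_xyz(frame, res[i], anchors$atom_name, anchors$chain),
             error = function(e) stop(sprintf(
               "anchor '%s' (residue %d) does not resolve: %s",
               names(res)[i], res[i], conditionMessage(e)), call. = FALSE))
  })
  names(pos) <- names(res)
  pos
}

#' Evaluate the three-angle descriptor on one conformation
#'
#' @param frame Structure.
#' @param anchors [default_anchors()] or an override.
#' @param map optional [numbering_map()] when `frame` is stored in chimera
#'   author numbering rather than native-extended numbering.
#' @return Named numeric vector `theta1_deg`, `theta2_deg`, `theta3_deg`.
#' @export
angle_triple <- function(frame, anchors = default_anchors(), map = NULL) {
  p <- anchor_positions(frame, anchors, map)
  v1 <- p$top - p$mid           # along the A-helix, mid -> top
  v2r <- p$base - p$mid         # mid -> base (theta1 reference)
  v2 <- p$mid - p$base          # base -> mid (theta2 reference)
  v3 <- p$tip - p$base          # base -> appendage tip
  c(theta1_deg = angle_between(v1, v2r),
    theta2_deg = angle_between(v2, v3),
    theta3_deg = abs(dihedral(p$top, p$lobe1, p$lobe2, p$tip)))
}

#' Three-angle descriptor along a trajectory
#'
#' @param traj Trajectory.
#' @param anchors anchor set.
#' @param map optional numbering map (see [angle_triple()]).
#' @param window frame indices or `c(first, last)`; `NULL` = all frames.
#' @return data.frame of class `AngleSeries` with columns `frame`,
#'   `time_ps`, `theta1_deg`, `theta2_deg`, `theta3_deg`.
#' @export
angle_series <- function(traj, anchors = default_anchors(), map = NULL,
                         window = NULL) {
  win <- resolve_window(traj, window)
  tt <- frame_times(traj)
  vals <- vapply(win, function(k) angle_triple(get_frame(traj, k), anchors, map),
                 numeric(3))
  out <- data.frame(frame = win, time_ps = tt[win],
                    theta1_deg = vals[1, ], theta2_deg = vals[2, ],
                    theta3_deg = vals[3, ])
  class(out) <- c("AngleSeries", class(out))
  out
}
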