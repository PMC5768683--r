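# Seeded synthetic-data generators.
#
# The toy protein is a stylized core-plus-appendage kinase: two immobile
# anchor helices (residues 140-160 and 217-233, the "large lobe"), an
# A-helix whose lower arm (residues 2-15) is part of the core and whose
# upper arm (16-29) can kink at residue 15, and a 19-residue appendage
# (residues -19..-1) hinged at the helix base (residue 2).  The appendage
# pose is constructed directly from target descriptor angles
# (theta1, theta2, theta3), so the angle module has an exact oracle.
# Trajectories follow a discrete reversible Markov chain over poses with
# Gaussian coordinate noise and optional random global rigid motion.

unit <- function(v) v / sqrt(sum(v^2))

toy_geometry <- function() {
  rise <- 1.5
  dir_a <- unit(c(0.25, 0.15, 1))
  e1 <- dir_a
  w <- c(1, 0, 0)
  e2 <- unit(w - sum(w * e1) * e1)
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  p2 <- c(-6, -4, -16)
  list(rise = rise, e1 = e1, e2 = e2, e3 = e3, p2 = p2,
       v15 = p2 + 13 * rise * e1, arm_len = 14 * rise,
       app_len = 19 * rise)
}

helix_ca <- function(n, origin, axis = c(1, 0, 0)) {
  axis <- unit(axis)
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unit(ref - sum(ref * axis) * axis)
  v <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  i <- seq_len(n) - 1
  ang <- i * 100 * pi / 180
  t(origin + outer(axis, i * 1.5)) + 2.3 * (outer(cos(ang), u) + outer(sin(ang), v))
}

# CA positions of every residue for one pose; core residues are fixed,
# the upper arm and appendage are functions of the target angles.
toy_ca_positions <- function(theta = c(164, 82, 164)) {
  g <- toy_geometry()
  th1 <- theta[1] * pi / 180
  th2 <- theta[2] * pi / 180

  coreE <- helix_ca(21, c(0, 0, 0))              # residues 140..160
  coreF <- helix_ca(17, c(0, 8, -4))             # residues 217..233
  lower <- t(sapply(0:13, function(i) g$p2 + i * g$rise * g$e1))  # 2..15

  alpha <- pi - th1
  d1 <- cos(alpha) * g$e1 + sin(alpha) * g$e2
  upper <- t(sapply(1:14, function(j) g$v15 + j * g$rise * d1))   # 16..29
  k29 <- upper[14, ]

  l160 <- coreE[21, ]; e140 <- coreE[1, ]
  tip_at <- function(phi) {
    u <- cos(th2) * g$e1 + sin(th2) * (cos(phi) * g$e2 + sin(phi) * g$e3)
    g$p2 + g$app_len * u
  }
  f <- function(phi) abs(dihedral(k29, l160, e140, tip_at(phi))) - theta[3]
  grid <- seq(0, 2 * pi, length.out = 721)
  fg <- vapply(grid, f, numeric(1))
  hit <- which(fg[-1] * fg[-length(fg)] <= 0)
  if (!length(hit))
    stop(sprintf("theta3 = %g deg unreachable at theta2 = %g deg", theta[3], theta[2]))
  # several azimuths can satisfy the target; keep the best-conditioned
  # pose (tip farthest from the dihedral axis), so that the descriptor
  # stays well defined under coordinate noise
  ax <- unit(e140 - l160)
  axis_dist <- function(x) {
    v <- x - l160
    sqrt(sum((v - sum(v * ax) * ax)^2))
  }
  roots <- vapply(hit, function(h)
    uniroot(f, c(grid[h], grid[h + 1]), tol = 1e-13)$root, numeric(1))
  phi <- roots[which.max(vapply(roots, function(r) axis_dist(tip_at(r)), numeric(1)))]
  tip <- tip_at(phi)
  appendage <- t(sapply(1:19, function(k) g$p2 + (k / 19) * (tip - g$p2)))  # -1..-19

  resid <- c(2:15, 16:29, -(1:19), 140:160, 217:233)
  ca <- rbind(lower, upper, appendage, coreE, coreF)
  ord <- order(resid)
  list(resid = resid[ord], ca = ca[ord, , drop = FALSE])
}

#' Deterministic toy core-plus-appendage protein
#'
#' A stylized single-chain structure on which every anchor of
#' [default_anchors()] resolves: anchor helices at residues 140-160 and
#' 217-233, an A-helix spanning residues 2-29, and an appendage reaching
#' residue -19.  Each residue carries backbone atoms N, CA, C, O placed
#' at fixed offsets from the C-alpha.  The pose is constructed from the
#' requested descriptor angles, so `angle_triple()` on the result returns
#' `theta` (to numerical root-finding precision).  The default pose uses
#' the crystal-conformation angles of the fusion kinase, 164/82/164
#' degrees.
#'
#' @param theta target `c(theta1, theta2, theta3)` in degrees.
#' @param label structure label.
#' @return A [Structure] in native-extended numbering, chain A.
#' @export
make_toy_protein <- function(theta = c(164, 82, 164), label = "toy") {
  pose <- toy_ca_positions(theta)
  nres <- length(pose$resid)
  offs <- rbind(N = c(-0.50, 0.60, 0.15), CA = c(0, 0, 0),
                C = c(0.72, 0.55, -0.10), O = c(1.05, 1.45, 0.30))
  atoms <- data.frame(
    chain = "A",
    resid = rep(pose$resid, each = 4L),
    resname = rep(toy_resname(pose$resid), each = 4L),
    atom = rep(rownames(offs), nres),
    element = rep(c("N", "C", "C", "O"), nres))
  coords <- pose$ca[rep(seq_len(nres), each = 4L), ] +
    offs[rep(1:4, nres), ]
  new_structure(atoms, coords, label = label)
}

toy_resname <- function(resid) {
  nm <- rep("ALA", length(resid))
  nm[resid %in% c(29, -19)] <- "LYS"
  nm[resid == 15] <- "VAL"
  nm[resid == 2] <- "PRO"
  nm[resid == 160] <- "LEU"
  nm[resid == 140] <- "GLU"
  nm
}

random_rotation <- function() {
  # uniform random rotation from a normalized quaternion
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

#' Specification of a synthetic multi-state trajectory
#'
#' @param states list of states, each `list(theta = c(t1, t2, t3),
#'   population = p)`; populations must sum to 1.
#' @param n_frames number of frames.
#' @param frame_spacing_ps snapshot stride, default 50 ps.
#' @param persistence probability of keeping the current state per step
#'   through the non-resampling branch (see Details), in `[0, 1)`.
#' @param coord_noise_A isotropic Gaussian sigma added to every
#'   coordinate, Angstrom.
#' @param rigid_jitter apply a random global rotation + translation to
#'   every frame (default TRUE, so downstream stages must superpose).
#' @param seed integer RNG seed.
#'
#' @details The state sequence follows the reversible chain
#' `T = persistence * I + (1 - persistence) * 1 p'` (stay, or resample
#' from the stationary populations), whose stationary distribution is
#' exactly `p` and which satisfies detailed balance.
#' @export
trajectory_spec <- function(states, n_frames = 1000L, frame_spacing_ps = 50,
                            persistence = 0.98, coord_noise_A = 0.2,
                            rigid_jitter = TRUE, seed = 1L) {
  p <- vapply(states, `[[`, numeric(1), "population")
  if (abs(sum(p) - 1) > 1e-9) stop("state populations must sum to 1")
  if (persistence < 0 || persistence >= 1) stop("persistence must be in [0, 1)")
  if (coord_noise_A < 0) stop("coordinate noise must be non-negative")
  structure(list(states = states, n_frames = as.integer(n_frames),
                 frame_spacing_ps = frame_spacing_ps, persistence = persistence,
                 coord_noise_A = coord_noise_A, rigid_jitter = rigid_jitter,
                 seed = as.integer(seed)),
            class = "TrajectorySpec")
}

#' Generate a synthetic trajectory with known state structure
#'
#' Each frame is the toy protein posed at its state's target angles, plus
#' isotropic Gaussian coordinate noise and (optionally) a random global
#' rigid motion.  Ground-truth state labels are returned alongside.
#'
#' @param spec a [trajectory_spec()].
#' @return List with `trajectory` (a [Trajectory]) and `labels`
#'   (data.frame `frame`, `time_ps`, `state`).
#' @export
make_trajectory <- function(spec) {
  stopifnot(inherits(spec, "TrajectorySpec"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(spec$seed)

  base <- lapply(spec$states, function(s) make_toy_protein(s$theta))
  topo <- base[[1]]
  na <- n_atoms(topo)
  p <- vapply(spec$states, `[[`, numeric(1), "population")
  k <- length(p)

  lab <- integer(spec$n_frames)
  lab[1] <- sample.int(k, 1, prob = p)
  if (spec$n_frames > 1) for (i in 2:spec$n_frames) {
    lab[i] <- if (runif(1) < spec$persistence) lab[i - 1]
              else sample.int(k, 1, prob = p)
  }

  co <- array(NA_real_, dim = c(na, 3L, spec$n_frames))
  for (i in seq_len(spec$n_frames)) {
    x <- base[[lab[i]]]$coords
    if (spec$coord_noise_A > 0)
      x <- x + matrix(rnorm(3 * na, sd = spec$coord_noise_A), na, 3)
    if (spec$rigid_jitter)
      x <- sweep(x %*% t(random_rotation()), 2, runif(3, -20, 20), `+`)
    co[, , i] <- x
  }
  traj <- new_trajectory(topo, co, frame_spacing_ps = spec$frame_spacing_ps)
  list(trajectory = traj,
       labels = data.frame(frame = seq_len(spec$n_frames),
                           time_ps = frame_times(traj), state = lab))
}

#' Generate synthetic relaxation decay curves
#'
#' `I(t) = 100 exp(-t / T) + eps`, `eps ~ N(0, noise_frac * 100)`, on the
#' standard delay grids.
#'
#' @param residues residue numbers.
#' @param t1_ms,t2_ms per-residue decay times (recycled to
#'   `length(residues)`).
#' @param t1_delays,t2_delays delay grids in ms; defaults
#'   [default_delays()].
#' @param noise_frac noise sigma as a fraction of the amplitude 100.
#' @param seed RNG seed.
#' @return List of [decay_curve()] objects, T1 and T2 per residue.
#' @export
make_decays <- function(residues, t1_ms, t2_ms,
                        t1_delays = default_delays("T1"),
                        t2_delays = default_delays("T2"),
                        noise_frac = 0, seed = 1L) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  t1_ms <- rep_len(t1_ms, length(residues))
  t2_ms <- rep_len(t2_ms, length(residues))
  out <- list()
  for (i in seq_along(residues)) {
    y1 <- 100 * exp(-t1_delays / t1_ms[i]) + rnorm(length(t1_delays), sd = noise_frac * 100)
    y2 <- 100 * exp(-t2_delays / t2_ms[i]) + rnorm(length(t2_delays), sd = noise_frac * 100)
    out[[length(out) + 1L]] <- decay_curve(residues[i], "T1", t1_delays, y1)
    out[[length(out) + 1L]] <- decay_curve(residues[i], "T2", t2_delays, y2)
  }
  out
}

#' Synthetic holoenzyme template
#'
#' A toy R2C2-like assembly: the toy catalytic subunit as chain C, a second
#' copy as chain D, and two small regulatory-subunit blobs (chains R and
#' S) placed either near the appendage (to force clashes) or away from it.
#'
#' @param r_offset translation applied to the regulatory blobs relative to
#'   the appendage tip; default places them well clear of the appendage.
#' @return A multi-chain [Structure].
#' @export
make_toy_holoenzyme <- function(r_offset = c(25, 25, 0)) {
  cs <- make_toy_protein(label = "C-subunit")
  cs$atoms$chain <- "C"
  cd <- make_toy_protein(label = "C-subunit-2")
  cd$atoms$chain <- "D"
  cd$coords <- sweep(cd$coords, 2, c(0, -40, 0), `+`)
  blob <- function(chain, origin) {
    grid <- as.matrix(expand.grid(x = 0:2, y = 0:2, z = 0:2)) * 3
    n <- nrow(grid)
    new_structure(data.frame(chain = chain, resid = seq_len(n),
                             resname = "GLY", atom = "CA", element = "C"),
                  sweep(grid, 2, origin, `+`), label = "R blob")
  }
  tip <- residue_xyz(cs, -19L, "CA", "C")
  r1 <- blob("R", tip + r_offset)
  r2 <- blob("S", tip + r_offset + c(0, -40, 0))
  atoms <- rbind(cs$atoms, cd$atoms, r1$atoms, r2$atoms)
  coords <- rbind(cs$coords, cd$coords, r1$coords, r2$coords)
  new_structure(atoms, coords, label = "toy holoenzyme (synthetic)")
}
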