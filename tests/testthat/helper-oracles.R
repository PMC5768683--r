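# Independent brute-force oracles and small fixture builders shared by
# the unit and acceptance tests.  Every oracle is written as a direct
# transcription of the operation's definition, independent of the
# package implementation it checks.

oracle_rmsd <- function(a, b) {
  s <- 0
  for (i in seq_len(nrow(a))) s <- s + sum((a[i, ] - b[i, ])^2)
  sqrt(s / nrow(a))
}

# per-pair kabsch + rmsd, both directions averaged
oracle_pairwise <- function(traj, fit_sel, measure_sel) {
  fit <- select_indices(traj, fit_sel)
  meas <- select_indices(traj, measure_sel)
  nf <- n_frames(traj)
  out <- matrix(0, nf, nf)
  for (i in seq_len(nf)) for (j in seq_len(nf)) {
    if (i == j) next
    a <- traj$coords[, , i]; b <- traj$coords[, , j]
    tf <- kabsch(b[fit, , drop = FALSE], a[fit, , drop = FALSE])
    out[i, j] <- oracle_rmsd(apply_transform(b[meas, , drop = FALSE], tf),
                             a[meas, , drop = FALSE])
  }
  (out + t(out)) / 2
}

# literal transcription of the neighbor-count peeling algorithm
oracle_gromos <- function(d, cutoff) {
  n <- nrow(d)
  labels <- integer(n)
  remaining <- seq_len(n)
  cl <- 0L
  centers <- integer(0)
  while (length(remaining)) {
    cl <- cl + 1L
    best <- remaining[1]; best_n <- -1L
    for (f in remaining) {
      cnt <- sum(d[f, remaining] < cutoff) - 1L
      if (cnt > best_n) { best <- f; best_n <- cnt }
    }
    members <- remaining[d[best, remaining] < cutoff]
    labels[members] <- cl
    centers[cl] <- best
    remaining <- setdiff(remaining, members)
  }
  list(labels = labels, centers = centers)
}

oracle_representative <- function(d, members) {
  if (length(members) == 1L) return(members)
  best <- members[1]; best_m <- Inf
  for (f in members) {
    m <- mean(d[f, setdiff(members, f)])
    if (m < best_m) { best <- f; best_m <- m }
  }
  best
}

oracle_transitions <- function(series, k) {
  counts <- matrix(0L, k, k)
  for (s in series) {
    if (length(s) < 2L) next
    for (i in seq_len(length(s) - 1L))
      counts[s[i], s[i + 1L]] <- counts[s[i], s[i + 1L]] + 1L
  }
  counts
}

oracle_clash <- function(p1, p2, thr) {
  hits <- data.frame(i = integer(0), j = integer(0), d = numeric(0))
  mind <- Inf
  for (i in seq_len(nrow(p1))) for (j in seq_len(nrow(p2))) {
    dd <- sqrt(sum((p1[i, ] - p2[j, ])^2))
    mind <- min(mind, dd)
    if (dd < thr) hits <- rbind(hits, data.frame(i = i, j = j, d = dd))
  }
  list(pairs = hits, min_d = mind)
}

# --- fixture builders ----------------------------------------------------

rot_z <- function(deg) {
  r <- deg * pi / 180
  matrix(c(cos(r), -sin(r), 0, sin(r), cos(r), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

random_rotation_matrix <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

rigidly_move <- function(coords) {
  sweep(coords %*% t(random_rotation_matrix()), 2, runif(3, -30, 30), `+`)
}

# minimal CA-only structure: residues 1..n at given coordinates
ca_structure <- function(coords, resid = seq_len(nrow(coords)), chain = "A") {
  new_structure(data.frame(chain = chain, resid = resid, resname = "ALA",
                           atom = "CA", element = "C"),
                coords, label = "ca-toy")
}

# trajectory from a list of coordinate matrices sharing one topology
traj_from_frames <- function(topology, frames, dt = 50) {
  co <- array(NA_real_, dim = c(nrow(frames[[1]]), 3L, length(frames)))
  for (k in seq_along(frames)) co[, , k] <- frames[[k]]
  new_trajectory(topology, co, frame_spacing_ps = dt)
}

# non-degenerate 8-point scaffold used as a rigid fit region
cube_coords <- function(scale = 5) {
  as.matrix(expand.grid(x = c(0, 1), y = c(0, 1), z = c(0, 1))) * scale +
    matrix(rep(c(0.3, 0.1, 0.2), each = 8), 8, 3) * seq_len(8)  # break symmetry
}

# canonical 3-state spec used across tests (well separated states:
# pairwise pose RMSD 7.8-15.3 A versus 5 A cutoff)
three_state_spec <- function(n_frames = 400L, seed = 11L,
                             persistence = 0.98, noise = 0.2,
                             jitter = TRUE) {
  trajectory_spec(
    states = list(list(theta = c(164, 82, 164), population = 0.62),
                  list(theta = c(119, 64, 100), population = 0.25),
                  list(theta = c(150, 110, 150), population = 0.13)),
    n_frames = n_frames, persistence = persistence,
    coord_noise_A = noise, rigid_jitter = jitter, seed = seed)
}
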