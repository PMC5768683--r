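# Kabsch superposition, RMSD, trailing-window averages, RMSD series.

test_that("kabsch recovers rigid motions and rejects degenerate input", {
  set.seed(1)
  pts <- cube_coords()

  tf <- kabsch(pts, pts)
  expect_equal(tf$rotation, diag(3), tolerance = 1e-10)
  expect_equal(tf$translation, c(0, 0, 0), tolerance = 1e-10)

  shifted <- sweep(pts, 2, c(1, 2, 3), `+`)
  tf2 <- kabsch(pts, shifted)
  expect_equal(tf2$rotation, diag(3), tolerance = 1e-10)
  expect_equal(tf2$translation, c(1, 2, 3), tolerance = 1e-10)
  expect_equal(rmsd(apply_transform(pts, tf2), shifted), 0, tolerance = 1e-10)

  R90 <- rot_z(90)
  rotated <- pts[1:4, ] %*% t(R90)
  tf3 <- kabsch(pts[1:4, ], rotated)
  expect_equal(tf3$rotation, R90, tolerance = 1e-8)
  expect_equal(rmsd(apply_transform(pts[1:4, ], tf3), rotated), 0, tolerance = 1e-8)
  expect_equal(det(tf3$rotation), 1, tolerance = 1e-10)

  expect_error(kabsch(pts[1:2, ], pts[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch(line, line), "collinear")
  expect_error(kabsch(pts, pts[1:4, ]), "counts differ")
})

test_that("kabsch never produces a reflection and never increases RMSD", {
  set.seed(42)
  for (rep in 1:25) {
    a <- matrix(rnorm(30), 10, 3)
    b <- matrix(rnorm(30), 10, 3)
    tf <- kabsch(a, b)
    expect_equal(det(tf$rotation), 1, tolerance = 1e-8)
    expect_equal(crossprod(tf$rotation), diag(3), tolerance = 1e-8)
    expect_lte(rmsd(apply_transform(a, tf), b), rmsd(a, b) + 1e-12)
    # left invariance of the post-fit RMSD
    R <- random_rotation_matrix()
    tfR <- kabsch(a %*% t(R), b)
    expect_equal(rmsd(apply_transform(a %*% t(R), tfR), b),
                 rmsd(apply_transform(a, tf), b), tolerance = 1e-8)
  }
})

test_that("rmsd matches the direct summation oracle and is symmetric", {
  expect_equal(rmsd(cube_coords(), cube_coords()), 0)
  two <- matrix(c(0, 0, 0, 1, 1, 1), 2, 3, byrow = TRUE)
  expect_equal(rmsd(two, sweep(two, 2, c(2, 0, 0), `+`)), 2)
  set.seed(3)
  a <- matrix(rnorm(30), 10, 3); b <- matrix(rnorm(30), 10, 3)
  expect_equal(rmsd(a, b), oracle_rmsd(a, b))
  expect_equal(rmsd(a, b), rmsd(b, a))
  expect_error(rmsd(a, b[1:3, ]), "counts differ")
})

test_that("average_structure removes rigid motion and averages atomwise", {
  base <- cube_coords()
  topo <- ca_structure(rbind(base, c(10, 10, 10)))   # atom 9 is mobile
  fit <- selection(data.frame(chain = "A", start = 1L, end = 8L))

  tr1 <- traj_from_frames(topo, list(topo$coords))
  expect_equal(average_structure(tr1, NULL, fit)$coords, topo$coords)

  # two frames related by pure translation -> average equals frame 1
  f2 <- sweep(topo$coords, 2, c(3, -1, 2), `+`)
  tr2 <- traj_from_frames(topo, list(topo$coords, f2))
  expect_equal(average_structure(tr2, NULL, fit)$coords, topo$coords,
               tolerance = 1e-9)

  # mobile atom at z = 0, 1, 2 over rigid core -> averaged z = 1
  mk <- function(z) { x <- topo$coords; x[9, 3] <- z; x }
  tr3 <- traj_from_frames(topo, list(mk(0), mk(1), mk(2)))
  avg <- average_structure(tr3, NULL, fit)
  expect_equal(avg$coords[9, 3], 1, tolerance = 1e-9)
  expect_equal(avg$coords[1:8, ], topo$coords[1:8, ], tolerance = 1e-9)

  expect_error(average_structure(tr3, integer(0), fit), "invalid frame window")
})

test_that("rmsd_series matches brute force and respects measure selections", {
  topo <- ca_structure(rbind(cube_coords(), c(10, 10, 10)))
  fit <- selection(data.frame(chain = "A", start = 1L, end = 8L))
  all_sel <- selection(NULL, "CA")

  # frames = reference under random rigid motion -> all zeros
  set.seed(7)
  frames <- lapply(1:5, function(i) rigidly_move(topo$coords))
  tr <- traj_from_frames(topo, frames)
  rs <- rmsd_series(tr, topo, fit, all_sel)
  expect_true(all(rs$rmsd_A < 1e-6))
  expect_equal(rs$time_ps, (0:4) * 50)

  # one measured atom displaced 3 A in frame 2, rigid fit region
  f2 <- topo$coords; f2[9, ] <- f2[9, ] + c(0, 0, 3)
  tr2 <- traj_from_frames(topo, list(topo$coords, f2))
  one <- selection(data.frame(chain = "A", start = 9L, end = 9L))
  rs2 <- rmsd_series(tr2, topo, fit, one)
  expect_equal(rs2$rmsd_A, c(0, 3), tolerance = 1e-9)
  # brute-force per-frame value over all atoms: sqrt(3^2 / 9)
  rs3 <- rmsd_series(tr2, topo, fit, all_sel)
  expect_equal(rs3$rmsd_A[2], 1, tolerance = 1e-9)

  # appendage-only motion (noise-free): core-only <= all-atom measurement
  sim <- make_trajectory(three_state_spec(n_frames = 20L, seed = 9L, noise = 0))
  core_meas <- selection("A:140-160,A:217-233", c("N", "CA", "C", "O"))
  full_meas <- selection(NULL, c("N", "CA", "C", "O"))
  ref <- get_frame(sim$trajectory, 1)
  a <- rmsd_series(sim$trajectory, ref, core_fit_selection(), core_meas)
  b <- rmsd_series(sim$trajectory, ref, core_fit_selection(), full_meas)
  expect_true(all(a$rmsd_A <= b$rmsd_A + 1e-9))
})
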