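# Holoenzyme placement by anchor-helix superposition and clash scanning.

chainsel <- function(chain) selection(data.frame(chain = chain,
                                                 start = -100000L, end = 100000L), NULL)

test_that("placing a template's own catalytic subunit reproduces the template", {
  holo <- make_toy_holoenzyme()
  own <- make_toy_protein(label = "conformer")
  asm <- place_conformer(own, holo, "C")
  expect_equal(asm$fit_rmsd_A, 0, tolerance = 1e-8)
  ord <- function(s) order(s$atoms$chain, s$atoms$resid, s$atoms$atom)
  a <- asm$structure; h <- holo
  expect_equal(a$coords[ord(a), ], h$coords[ord(h), ], tolerance = 1e-6)

  # pre-rotated copy places identically (placement is pose-independent)
  set.seed(61)
  rot <- own; rot$coords <- rigidly_move(own$coords)
  asm2 <- place_conformer(rot, holo, "C")
  expect_equal(asm2$fit_rmsd_A, 0, tolerance = 1e-6)
  expect_equal(asm2$structure$coords[ord(asm2$structure), ],
               h$coords[ord(h), ], tolerance = 1e-5)

  # idempotence: re-placing the placed conformer is a no-op
  placed <- asm$structure
  conf2 <- new_structure(placed$atoms[placed$atoms$chain == "C", ],
                         placed$coords[placed$atoms$chain == "C", ],
                         label = "again")
  asm3 <- place_conformer(conf2, holo, "C")
  expect_equal(asm3$fit_rmsd_A, 0, tolerance = 1e-8)
})

test_that("placed coordinates equal a manually applied kabsch transform", {
  holo <- make_toy_holoenzyme()
  conf <- make_toy_protein(c(119, 64, 100), label = "swung")
  fit <- core_fit_selection(chain = "C")
  asm <- place_conformer(conf, holo, "C")

  cfit <- selection(data.frame(chain = "A", start = c(140L, 217L),
                               end = c(160L, 233L)), c("N", "CA", "C", "O"))
  A <- as.matrix(select_atoms(conf, cfit)[c("x", "y", "z")])
  B <- as.matrix(select_atoms(holo, fit)[c("x", "y", "z")])
  tf <- kabsch(A, B)
  manual <- apply_transform(conf$coords, tf)
  placed <- asm$structure
  got <- placed$coords[placed$atoms$chain == "C", ]
  expect_equal(got, manual, tolerance = 1e-9)
})

test_that("clash_scan handles the two-atom contract cases", {
  s <- ca_structure(rbind(c(0, 0, 0), c(5, 0, 0)), resid = 1:2)
  r <- clash_scan(s, selection(data.frame(chain = "A", start = 1L, end = 1L), NULL),
                  selection(data.frame(chain = "A", start = 2L, end = 2L), NULL),
                  threshold_A = 2.5)
  expect_equal(r$pair_count, 0L)
  expect_equal(r$min_distance_A, 5)

  s2 <- ca_structure(rbind(c(1, 1, 1), c(1, 1, 1) + 1e-12), resid = 1:2)
  r2 <- clash_scan(s2, selection(data.frame(chain = "A", start = 1L, end = 1L), NULL),
                   selection(data.frame(chain = "A", start = 2L, end = 2L), NULL),
                   threshold_A = 2.5)
  expect_equal(r2$pair_count, 1L)
  expect_equal(r2$pairs$distance_A, 0, tolerance = 1e-9)

  expect_error(clash_scan(s, selection(NULL, NULL), chainsel("A"), 2), "overlap")
})

test_that("grid scan equals brute force and hydrogens are excluded", {
  set.seed(41)
  for (i in 1:12) {
    n1 <- sample(10:40, 1); n2 <- sample(10:40, 1)
    p1 <- matrix(runif(3 * n1, 0, 15), n1, 3)
    p2 <- matrix(runif(3 * n2, 0, 15), n2, 3)
    s <- new_structure(
      data.frame(chain = rep(c("A", "B"), c(n1, n2)),
                 resid = c(seq_len(n1), seq_len(n2)),
                 resname = "GLY", atom = "CA", element = "C"),
      rbind(p1, p2))
    thr <- runif(1, 1, 6)
    g <- clash_scan(s, chainsel("A"), chainsel("B"), thr, method = "grid")
    b <- clash_scan(s, chainsel("A"), chainsel("B"), thr, method = "brute")
    expect_equal(g$pairs, b$pairs)
    expect_equal(g$min_distance_A, b$min_distance_A, tolerance = 1e-12)
    o <- oracle_clash(p1, p2, thr)
    expect_equal(g$pair_count, nrow(o$pairs))
    expect_equal(g$min_distance_A, o$min_d, tolerance = 1e-12)
    expect_true(all(diff(g$pairs$distance_A) >= 0))  # ascending order
    expect_true(all(g$pairs$distance_A < thr))
  }

  # monotonicity in the threshold
  set.seed(43)
  p1 <- matrix(runif(60, 0, 10), 20, 3); p2 <- matrix(runif(60, 0, 10), 20, 3)
  s <- new_structure(data.frame(chain = rep(c("A", "B"), each = 20),
                                resid = rep(1:20, 2), resname = "GLY",
                                atom = "CA", element = "C"), rbind(p1, p2))
  r1 <- clash_scan(s, chainsel("A"), chainsel("B"), 2)
  r2 <- clash_scan(s, chainsel("A"), chainsel("B"), 4)
  key <- function(r) paste(r$pairs$atom1, r$pairs$atom2)
  expect_true(all(key(r1) %in% key(r2)))

  # hydrogen atoms are invisible to the scan
  sh <- new_structure(data.frame(chain = c("A", "B", "B"), resid = c(1L, 1L, 2L),
                                 resname = "GLY", atom = c("CA", "H", "CA"),
                                 element = c("C", "H", "C")),
                      rbind(c(0, 0, 0), c(0.5, 0, 0), c(1.5, 0, 0)))
  rh <- clash_scan(sh, chainsel("A"), chainsel("B"), 2.5)
  expect_equal(rh$pair_count, 1L)   # only the heavy-heavy pair
  expect_equal(rh$pairs$distance_A, 1.5)
})

test_that("a holoenzyme with clear appendage corridor reports no clashes", {
  holo <- make_toy_holoenzyme(r_offset = c(30, 30, 0))
  conf <- make_toy_protein(c(150, 110, 150))
  asm <- place_conformer(conf, holo, "C")
  appendage <- selection(data.frame(chain = "C", start = -19L, end = -1L), NULL)
  rsub <- chainsel(c("R", "S"))
  rep <- clash_scan(asm, appendage, rsub, 2.5)
  expect_equal(rep$pair_count, 0L)
  expect_gt(rep$min_distance_A, 2.5)

  # regulatory blobs placed on top of the appendage do clash
  holo2 <- make_toy_holoenzyme(r_offset = c(0, 0, 0))
  asm2 <- place_conformer(make_toy_protein(), holo2, "C")
  rep2 <- clash_scan(asm2, appendage, rsub, 2.5)
  expect_gt(rep2$pair_count, 0L)
})
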