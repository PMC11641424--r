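test_that("superposition of identical and rigidly moved sets is exact", {
  set.seed(1)
  a <- matrix(rnorm(30), ncol = 3)
  s <- kabsch_superpose(a, a)
  expect_equal(s$rmsd, 0, tolerance = 1e-10)
  expect_equal(s$rotation, diag(3), tolerance = 1e-8)

  b <- sweep(a %*% t(rotate_about_z(37 * pi / 180)), 2, c(5, 5, 5), `+`)
  s2 <- kabsch_superpose(a, b)
  expect_lt(s2$rmsd, 1e-8)
  # returned transform maps b onto a
  expect_lt(max(abs(apply_superposition(s2, b) - a)), 1e-6)
  # proper rotation
  expect_equal(det(s2$rotation), 1, tolerance = 1e-6)
  expect_equal(crossprod(s2$rotation), diag(3), tolerance = 1e-6)
})

test_that("Kabsch RMSD agrees with the quaternion oracle on a fixed toy and random clouds", {
  a <- matrix(c(0, 0, 0,
                1.5, 0.2, -0.3,
                0.4, 2.1, 0.7,
                -1.1, 0.8, 1.9), ncol = 3, byrow = TRUE)
  b <- matrix(c(0.1, -0.2, 0.05,
                1.7, 0.1, 0.2,
                0.2, 1.8, 1.1,
                -0.9, 1.2, 1.5), ncol = 3, byrow = TRUE)
  expect_equal(kabsch_superpose(a, b)$rmsd, horn_rmsd(a, b),
               tolerance = 1e-8)

  set.seed(7)
  for (i in 1:25) {
    n <- sample(3:500, 1)
    p <- matrix(rnorm(3 * n), ncol = 3)
    q <- p %*% t(random_rotation()) + matrix(rnorm(3 * n, sd = 0.5), ncol = 3)
    expect_equal(kabsch_superpose(p, q)$rmsd, horn_rmsd(p, q),
                 tolerance = 1e-8)
  }
})

test_that("superposed RMSD behaves as a metric and flags degenerate sets", {
  set.seed(11)
  p <- matrix(rnorm(60), ncol = 3)
  q <- matrix(rnorm(60), ncol = 3)
  expect_equal(kabsch_superpose(p, q)$rmsd, kabsch_superpose(q, p)$rmsd,
               tolerance = 1e-10)
  # zero iff congruent
  congr <- sweep(p %*% t(random_rotation()), 2, c(1, 2, 3), `+`)
  expect_lt(kabsch_superpose(p, congr)$rmsd, 1e-8)
  expect_gt(kabsch_superpose(p, q)$rmsd, 0.1)

  line <- cbind(1:10, 0, 0)                    # collinear: still solved
  s <- kabsch_superpose(line, line)
  expect_true(s$degenerate)
  expect_equal(s$rmsd, 0, tolerance = 1e-10)

  expect_error(kabsch_superpose(p[1:2, ], q[1:2, ]), "3 points")
  expect_error(kabsch_superpose(p, q[1:10, ]), "equal N")
})

test_that("d0 follows the TM-align closed form", {
  expect_equal(tm_d0(100), 1.24 * 85^(1 / 3) - 1.8, tolerance = 1e-12)
  expect_equal(tm_d0(10), 0.5)                 # floored for short chains
})

test_that("TM-score is 1 for self, rigid-motion invariant, and noise-monotone", {
  m <- synthetic_hinge_structure(40)
  corr <- build_correspondence(m, m)
  expect_equal(as.numeric(tm_score(m, m, corr)), 1.0, tolerance = 1e-12)

  moved <- m
  xyz <- as.matrix(m$atoms[, c("x", "y", "z")])
  moved$atoms[, c("x", "y", "z")] <-
    sweep(xyz %*% t(random_rotation()), 2, c(10, -4, 2), `+`)
  expect_equal(as.numeric(tm_score(m, moved, corr)), 1.0, tolerance = 1e-6)

  set.seed(3)
  z <- matrix(rnorm(nrow(m$atoms) * 3), ncol = 3)
  tms <- vapply(seq(0, 4.5, by = 0.5), function(s) {
    noisy <- m
    noisy$atoms[, c("x", "y", "z")] <- xyz + s * z
    as.numeric(tm_score(m, noisy, corr))
  }, numeric(1))
  expect_true(all(diff(tms) <= 1e-9))
})

test_that("hinge-pair RMSD matches an explicit transform-plus-formula oracle", {
  theta <- 30 * pi / 180
  open <- synthetic_hinge_structure(30, angle = 0)
  closed <- synthetic_hinge_structure(30, angle = theta)
  corr <- build_correspondence(open, closed)

  # oracle: re-apply the documented hinge transform to the open coordinates,
  # then optimal-superposition RMSD via the quaternion route
  xyz <- as.matrix(open$atoms[, c("x", "y", "z")])
  ca <- xyz[open$atoms$elety == "CA", ]
  hinge <- ca[30, ]
  rot <- matrix(c(1, 0, 0,
                  0, cos(theta), -sin(theta),
                  0, sin(theta), cos(theta)), 3, 3, byrow = TRUE)
  move <- open$atoms$resno > 30
  expected <- xyz
  expected[move, ] <- sweep(sweep(xyz[move, ], 2, hinge) %*% t(rot),
                            2, hinge, `+`)
  oracle <- horn_rmsd(xyz, expected)

  got <- rmsd_between(open, closed, corr, atom_set = "backbone")
  expect_equal(as.numeric(got), oracle, tolerance = 1e-6)
  expect_equal(attr(got, "n_atoms"), 240L)
})

test_that("characterize_pair fills consistent metrics", {
  m <- synthetic_hinge_structure(30)
  self_pair <- characterize_pair(reference_pair(m, m))
  expect_equal(self_pair$metrics$rmsd_backbone, 0, tolerance = 1e-10)
  expect_equal(self_pair$metrics$rmsd_ca, 0, tolerance = 1e-10)
  expect_equal(self_pair$metrics$tm_score, 1.0, tolerance = 1e-12)

  hp <- synthetic_hinge_pair(30, target_rmsd = 3.5)
  pair <- characterize_pair(reference_pair(hp$open, hp$closed))
  expect_equal(pair$metrics$rmsd_backbone, 3.5, tolerance = 1e-4)
  expect_gt(pair$metrics$tm_score, 0.5)        # same fold
  expect_lt(pair$metrics$tm_score, 1)
  expect_equal(pair$metrics$n_matched, 60)
})

test_that("pocket side-chain atom set requires a pocket", {
  m <- synthetic_hinge_structure(30)
  corr <- build_correspondence(m, m)
  expect_error(rmsd_between(m, m, corr, atom_set = "pocket_sidechain_heavy"),
               "pocket")
})
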