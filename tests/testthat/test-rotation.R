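# Independent dihedral oracle: project the outer bonds onto the plane
# perpendicular to the central bond and take the signed angle there.
dihedral_oracle <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2
  b1 <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  b2 <- p4 - p3
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  atan2(sum(pracma::cross(b1, v) * w), sum(v * w)) * 180 / pi
}

test_that("dihedral angles match independent oracles and conventions", {
  # cis arrangement of four coplanar atoms -> 0
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                              c(1, 1, 0)), 0)
  # right-angle staircase: +/-90 by sign convention
  ref <- dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1))
  expect_equal(abs(ref), 90)
  expect_equal(ref, dihedral_oracle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                                    c(1, 1, 1)))
  for (seed in 1:10) {
    set.seed(seed)
    p <- matrix(stats::rnorm(12), ncol = 3)
    mine <- dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ])
    expect_equal(mine, dihedral_oracle(p[1, ], p[2, ], p[3, ], p[4, ]),
                 tolerance = 1e-9)
    expect_equal(mine, bio3d::torsion.xyz(as.numeric(t(p))),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("constructed tyrosines return their construction chi angles", {
  st <- make_tyrosine_pair(chi1 = -60, chi2 = 90)$a
  expect_equal(unname(chi_angles(st, "A", 191)), c(-60, 90),
               tolerance = 1e-6)
  st2 <- make_tyrosine_pair(chi1 = 177, chi2 = -35)$a
  expect_equal(unname(chi_angles(st2, "A", 191)), c(177, -35),
               tolerance = 1e-6)
  # missing atom is named in the error
  broken <- st
  broken$atoms <- broken$atoms[broken$atoms$elety != "CG", ]
  expect_error(chi_angles(broken, "A", 191), "CG")
})

test_that("ring plane normal is correct, label-swap and rotation covariant", {
  hex <- do.call(rbind, lapply(0:5, function(k) {
    a <- k * 60 * pi / 180
    atom_df("A", 1, "PHE", c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")[k + 1],
            1.39 * c(cos(a), sin(a), 0))
  }))
  flat <- structure3d(hex, id = "hex")
  n0 <- ring_plane_normal(flat, "A", 1)
  expect_equal(abs(n0[3]), 1, tolerance = 1e-9)
  # rotate 30 degrees about x: normal tilts by 30
  rot <- flat
  xyz <- wins7:::rotate_about_axis(atom_xyz(flat), c(0, 0, 0), c(1, 0, 0), 30)
  rot$atoms$x <- xyz[, 1]; rot$atoms$y <- xyz[, 2]; rot$atoms$z <- xyz[, 3]
  n1 <- ring_plane_normal(rot, "A", 1)
  expect_equal(acos(abs(sum(n0 * n1))) * 180 / pi, 30, tolerance = 1e-6)
  # CD1<->CD2, CE1<->CE2 swap leaves the plane unchanged
  swap <- flat
  swap$atoms$elety <- c("CG", "CD2", "CE2", "CZ", "CE1", "CD1")
  n2 <- ring_plane_normal(swap, "A", 1)
  expect_equal(abs(sum(n0 * n2)), 1, tolerance = 1e-9)
  broken <- flat
  broken$atoms <- broken$atoms[broken$atoms$elety != "CZ", ]
  expect_error(ring_plane_normal(broken, "A", 1), "CZ")
})

frame_for <- function(pair) {
  superpose_ca(pair$b, pair$a, "A", "A", resno_range = c(186L, 195L))
}

test_that("sidechain rotation recovers constructed ring rotations", {
  same <- make_tyrosine_pair(ring_rotation_deg = 0)
  r0 <- sidechain_rotation(same$a, same$b, "A", "A", 191, 191,
                           frame = frame_for(same))
  expect_equal(r0$ring_plane_angle, 0, tolerance = 1e-9)
  expect_equal(r0$delta_chi1, 0, tolerance = 1e-9)
  expect_equal(r0$delta_chi2, 0, tolerance = 1e-9)
  for (theta in c(5, 15, 25, 30, 60, 85, 88.2)) {
    pair <- make_tyrosine_pair(ring_rotation_deg = theta)
    r <- sidechain_rotation(pair$a, pair$b, "A", "A", 191, 191,
                            frame = frame_for(pair))
    expect_equal(r$ring_plane_angle, theta, tolerance = 0.1)
  }
})

test_that("rotation metric is symmetric, fold-invariant and frame-stable", {
  pair <- make_tyrosine_pair(ring_rotation_deg = 40)
  fab <- superpose_ca(pair$b, pair$a, "A", "A", resno_range = c(186L, 195L))
  fba <- superpose_ca(pair$a, pair$b, "A", "A", resno_range = c(186L, 195L))
  rab <- sidechain_rotation(pair$a, pair$b, "A", "A", 191, 191, frame = fab)
  rba <- sidechain_rotation(pair$b, pair$a, "A", "A", 191, 191, frame = fba)
  expect_equal(rab$ring_plane_angle, rba$ring_plane_angle, tolerance = 1e-9)
  # rotations beyond 90 fold back into [0, 90]
  over <- make_tyrosine_pair(ring_rotation_deg = 130)
  rov <- sidechain_rotation(over$a, over$b, "A", "A", 191, 191,
                            frame = frame_for(over))
  expect_equal(rov$ring_plane_angle, 50, tolerance = 0.1)
  # rigidly moving both structures together changes nothing
  moved_a <- make_rigid_copy(pair$a, 33, c(2, 1, 0), c(8, 8, 8))
  moved_b <- make_rigid_copy(pair$b, 33, c(2, 1, 0), c(8, 8, 8))
  fm <- superpose_ca(moved_b, moved_a, "A", "A",
                     resno_range = c(186L, 195L))
  rm_ <- sidechain_rotation(moved_a, moved_b, "A", "A", 191, 191, frame = fm)
  expect_equal(rm_$ring_plane_angle, rab$ring_plane_angle, tolerance = 1e-6)
})

test_that("non-aromatic residues are refused", {
  pair <- make_tyrosine_pair()
  expect_error(
    sidechain_rotation(pair$a, pair$b, "A", "A", 188, 188,
                       frame = frame_for(pair)),
    "Tyr/Phe")
})
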