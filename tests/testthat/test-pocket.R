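test_that("anchor-based site definitions sit where direct arithmetic says", {
  st <- mini_propeller()
  s7 <- site_definition(st, "S7", "A")
  ring133 <- colMeans(atom_xyz(select_atoms(
    st, selection(resno = 133, elety = c("CG", "CD1", "CD2", "CE1", "CE2",
                                         "CZ")))))
  ring149 <- colMeans(atom_xyz(select_atoms(
    st, selection(resno = 149, elety = c("CG", "CD1", "CD2", "CE1", "CE2",
                                         "CZ")))))
  expected <- colMeans(rbind(ring133, ring149, c(4, 8, 0), c(4, 4, 6)))
  expect_equal(s7$center, expected, tolerance = 1e-9)
  win <- site_definition(st, "WIN", "A")
  expect_equal(win$center, colMeans(rbind(c(0, 4, 1), c(2, 4, 1),
                                          c(4, 0, 1))), tolerance = 1e-9)
  mid <- win_s7_center(st, "A")
  expect_equal(mid, (s7$center + win$center) / 2)
  # a missing anchor residue is a site error
  broken <- st
  broken$atoms <- broken$atoms[broken$atoms$resno != 173, ]
  expect_error(site_definition(broken, "S7", "A"), "anchor")
  expect_error(site_sphere(c(1, 2, NA)), "finite")
})

test_that("a site sphere in bulk solvent has zero buried volume", {
  st <- make_tyrosine_pair()$a
  expect_warning(
    v <- pocket_volume(st, site_sphere(c(500, 500, 500), 6)),
    "no protein atoms")
  expect_equal(as.numeric(v), 0)
})

test_that("hollow-shell volume matches the analytic interior sphere", {
  for (r_int in c(3, 4)) {
    sh <- make_interaction_fixture("hollow_shell", distance = r_int)
    v <- pocket_volume(sh, site_sphere(c(0, 0, 0), r_int + 1.2))
    analytic <- 4 / 3 * pi * r_int^3
    expect_lt(abs(as.numeric(v) - analytic) / analytic, 0.2)
  }
})

test_that("pocket volume is invariant to rigid motion of the structure", {
  gg <- make_pocket_gate(0)
  v0 <- pocket_volume(gg$structure, gg$site)
  R <- wins7:::rotation_matrix(c(1, 0, 1), 40)
  ctr <- colMeans(atom_xyz(gg$structure))
  moved <- make_rigid_copy(gg$structure, 40, c(1, 0, 1), c(10, -5, 3))
  new_centre <- as.numeric(R %*% (gg$site$center - ctr) + ctr + c(10, -5, 3))
  v1 <- pocket_volume(moved, site_sphere(new_centre, gg$site$radius))
  # the grid is site-anchored; residual is grid-phase discretisation only
  expect_lt(abs(as.numeric(v1) - as.numeric(v0)) / as.numeric(v0), 0.05)
})

test_that("halving the grid spacing moves calibration volumes < 15%", {
  for (g in c(0, 90)) {
    gg <- make_pocket_gate(g)
    v1 <- pocket_volume(gg$structure, gg$site, grid_spacing = 0.5)
    v2 <- pocket_volume(gg$structure, gg$site, grid_spacing = 0.25)
    expect_lt(abs(as.numeric(v2) - as.numeric(v1)) / as.numeric(v1), 0.15)
  }
})

test_that("swinging the aromatic gate out of the mouth frees volume monotonically", {
  vols <- vapply(c(0, 30, 60, 90), function(g) {
    gg <- make_pocket_gate(g)
    as.numeric(pocket_volume(gg$structure, gg$site))
  }, numeric(1))
  expect_true(all(diff(vols) > 0))
})

test_that("classification separates the calibration pair at the midpoint", {
  calib <- s7_calibration()
  expect_equal(calib$threshold, (calib$v_closed + calib$v_open) / 2)
  expect_gt(calib$v_open, calib$v_closed)
  expect_equal(calib$source, "synthetic")
  closed <- make_pocket_gate(0)
  open <- make_pocket_gate(90)
  expect_equal(classify_s7(closed$structure, site = closed$site,
                           calibration = calib)$state, "closed")
  expect_equal(classify_s7(open$structure, site = open$site,
                           calibration = calib)$state, "open")
  # intermediate gate angles classify on the correct side of their volume
  half <- make_pocket_gate(45)
  pr <- classify_s7(half$structure, site = half$site, calibration = calib)
  expect_equal(pr$state,
               if (pr$volume > calib$threshold) "open" else "closed")
})

test_that("a structure compared against itself is closed with zero rotation", {
  st <- make_tyrosine_pair()$a
  calib <- s7_calibration()
  suppressWarnings(
    pr <- classify_s7(st, reference = st, chain = "A",
                      calibration = calib,
                      site = site_sphere(c(500, 500, 500), 4))
  )
  expect_equal(pr$state, "closed")
  expect_equal(pr$tyr191_rotation_vs_reference, 0, tolerance = 1e-6)
  expect_equal(pr$reference_id, st$id)
})

test_that("user-supplied calibration structures override the synthetic pair", {
  closed <- make_pocket_gate(10)
  open <- make_pocket_gate(80)
  calib <- s7_calibration(closed = closed, open = open)
  expect_equal(calib$source, "user")
  expect_equal(calib$threshold, (calib$v_closed + calib$v_open) / 2)
})
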