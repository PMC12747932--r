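# Synthetic structure generators. Residue geometry uses idealised bond
# lengths/angles (hard-coded templates), so fixtures need no chemical
# library and every construction parameter is recoverable exactly.

atom_row <- function(chain, resno, resid, elety, xyz, elesy = NULL,
                     hetero = FALSE, model = 1L, o = 1, b = 0) {
  if (is.null(elesy)) elesy <- guess_element(elety, resid)
  data.frame(model = model, chain = chain, resno = as.integer(resno),
             insert = "", resid = resid, elety = elety, alt = "",
             elesy = elesy, x = xyz[1], y = xyz[2], z = xyz[3],
             o = o, b = b, is_water = resid %in% WATER_NAMES,
             is_hetero = hetero, stringsAsFactors = FALSE)
}

# Extended-backbone builder: residues of N/CA/C/O (GLY), NeRF-chained with
# idealised geometry (N-CA 1.458, CA-C 1.525, C-N 1.329, C=O 1.231 A;
# phi -139, psi 135, omega 180 degrees).
build_backbone <- function(n_res, chain = "A", resno_start = 1L) {
  phi <- -139; psi <- 135; omega <- 180
  rows <- list()
  N <- c(0, 0, 0)
  CA <- c(1.458, 0, 0)
  C <- CA + 1.525 * c(cos(deg2rad(69)), sin(deg2rad(69)), 0)
  for (i in seq_len(n_res)) {
    resno <- resno_start + i - 1L
    N_next <- place_atom(N, CA, C, 1.329, 116.2, psi)
    O <- place_atom(N, CA, C, 1.231, 120.8, psi + 180)
    rows[[length(rows) + 1L]] <- rbind(
      atom_row(chain, resno, "GLY", "N", N),
      atom_row(chain, resno, "GLY", "CA", CA),
      atom_row(chain, resno, "GLY", "C", C),
      atom_row(chain, resno, "GLY", "O", O)
    )
    if (i < n_res) {
      CA_next <- place_atom(CA, C, N_next, 1.458, 121.7, omega)
      C_next <- place_atom(C, N_next, CA_next, 1.525, 111.0, phi)
      N <- N_next; CA <- CA_next; C <- C_next
    }
  }
  do.call(rbind, rows)
}

# Attach an idealised tyrosine side chain to a backbone residue whose
# N/CA/C atoms are given; chi1 = N-CA-CB-CG, chi2 = CA-CB-CG-CD1 exactly.
tyrosine_sidechain <- function(N, CA, C, chi1, chi2) {
  CB <- place_atom(C, N, CA, 1.530, 110.5, -122)
  CG <- place_atom(N, CA, CB, 1.512, 113.8, chi1)
  CD1 <- place_atom(CA, CB, CG, 1.389, 120.9, chi2)
  CD2 <- place_atom(CA, CB, CG, 1.389, 120.9, chi2 + 180)
  CE1 <- place_atom(CB, CG, CD1, 1.389, 121.1, 180)
  CE2 <- place_atom(CB, CG, CD2, 1.389, 121.1, 180)
  CZ <- place_atom(CG, CD1, CE1, 1.389, 119.6, 0)
  OH <- place_atom(CD1, CE1, CZ, 1.376, 119.9, 180)
  list(CB = CB, CG = CG, CD1 = CD1, CD2 = CD2, CE1 = CE1, CE2 = CE2,
       CZ = CZ, OH = OH)
}

TYR_RING_MOVABLE <- c("CD1", "CD2", "CE1", "CE2", "CZ", "OH")

#' Synthetic tyrosine pair with a known ring rotation
#'
#' Builds an idealised tyrosine (requested chi1/chi2) at residue 191 of a
#' 10-residue extended scaffold (author numbers 186-195, chain A), then a
#' second copy whose ring atoms are rotated by `ring_rotation_deg` about
#' the CB-CG axis. Scaffold and side-chain stem atoms are identical in the
#' two copies, so propeller-frame superposition is exact and the
#' construction angle is the ground truth for the rotation metric. (The
#' CB-CG axis lies in the ring plane, so the ring-plane normal rotates by
#' exactly the construction angle.)
#'
#' @param chi1,chi2 Side-chain dihedrals of the first copy, degrees.
#' @param ring_rotation_deg Ring rotation applied to the second copy.
#' @param seed Unused (the construction is deterministic); kept so all
#'   fixture generators share a signature.
#' @return list of two [structure3d]: `a` and `b`.
#' @export
make_tyrosine_pair <- function(chi1 = -60, chi2 = 90, ring_rotation_deg = 0,
                               seed = NULL) {
  bb <- build_backbone(10, chain = "A", resno_start = 186L)
  tyr_no <- 191L
  pick <- function(el) {
    as.numeric(bb[bb$resno == tyr_no & bb$elety == el, c("x", "y", "z")])
  }
  sc <- tyrosine_sidechain(pick("N"), pick("CA"), pick("C"), chi1, chi2)
  bb$resid[bb$resno == tyr_no] <- "TYR"
  sc_rows <- do.call(rbind, lapply(names(sc), function(el) {
    atom_row("A", tyr_no, "TYR", el, sc[[el]])
  }))
  atoms <- rbind(bb, sc_rows)
  a <- structure3d(atoms, id = "tyr_pair_a")
  b <- a
  b$id <- "tyr_pair_b"
  if (ring_rotation_deg != 0) {
    move <- b$atoms$resno == tyr_no & b$atoms$elety %in% TYR_RING_MOVABLE
    xyz <- atom_xyz(b$atoms[move, , drop = FALSE])
    rotated <- rotate_about_axis(xyz, sc$CB, sc$CG - sc$CB,
                                 ring_rotation_deg)
    b$atoms$x[move] <- rotated[, 1]
    b$atoms$y[move] <- rotated[, 2]
    b$atoms$z[move] <- rotated[, 3]
  }
  list(a = a, b = b)
}

#' Rigid (optionally noisy) copy of a structure
#'
#' Applies a rotation about `axis` through the centroid plus a translation,
#' then optional isotropic Gaussian coordinate noise — the synthetic
#' analogue of a second crystallographically independent copy.
#'
#' @param structure A [structure3d].
#' @param rotation_deg Rotation angle, degrees.
#' @param axis Rotation axis (3-vector).
#' @param translation Translation (3-vector, A).
#' @param coord_noise_sd Per-coordinate Gaussian sd, A.
#' @param seed Seed for the noise (explicit, never global).
#' @return The transformed [structure3d].
#' @export
make_rigid_copy <- function(structure, rotation_deg = 0, axis = c(0, 0, 1),
                            translation = c(0, 0, 0), coord_noise_sd = 0,
                            seed = NULL) {
  xyz <- atom_xyz(structure)
  ctr <- colMeans(xyz)
  moved <- rotate_about_axis(xyz, ctr, axis, rotation_deg)
  moved <- sweep(moved, 2, translation, `+`)
  if (coord_noise_sd > 0) {
    moved <- moved + with_seed(seed, matrix(
      stats::rnorm(length(moved), 0, coord_noise_sd), ncol = 3))
  }
  structure$atoms$x <- moved[, 1]
  structure$atoms$y <- moved[, 2]
  structure$atoms$z <- moved[, 3]
  structure$id <- paste0(structure$id, "_copy")
  structure
}

# Place a point at `dist` from p, with angle `ang` (deg) at p relative to
# the direction towards q, rotated in the plane defined by `ref_normal`.
point_at_angle <- function(p, q, dist, ang, ref_normal = c(0, 0, 1)) {
  u <- vunit(q - p)
  as.numeric(p + dist * (rotation_matrix(ref_normal, ang) %*% u))
}

#' Minimal constructed interaction fixtures
#'
#' Two-group (plus optional water) structures with exactly stated
#' geometry, for exercising each contact detector:
#' \describe{
#'   \item{hbond_pair}{Ser OG (chain A) donating to a backbone carbonyl O
#'     (chain B) at `distance`, with antecedent angle `angle` (default
#'     120).}
#'   \item{salt_bridge_pair}{Arg guanidinium (chain A) opposite an Asp
#'     carboxylate (chain B); NH1-OD1 and NH2-OD2 both at `distance`, the
#'     cross pairs splayed wider.}
#'   \item{cation_pi}{Phe ring (chain B) centred at the origin in the
#'     xy-plane; Arg CZ (chain A) at centroid distance `distance` and
#'     elevation `angle` degrees above the plane.}
#'   \item{water_bridge}{Backbone O (chain A) and backbone N (chain B)
#'     both at `distance` from a water oxygen.}
#'   \item{hollow_shell}{A spherical shell of carbon pseudo-atoms with an
#'     empty interior of radius `distance`; atom centres sit at
#'     `distance + probe` so the probe-accessible interior is exactly the
#'     stated sphere.}
#' }
#'
#' @param kind Fixture kind (see above).
#' @param distance Key distance, A (defaults per kind).
#' @param angle Key angle, degrees (defaults per kind).
#' @param probe Probe radius used to offset the hollow-shell atoms.
#' @param seed Unused; signature symmetry.
#' @return A [structure3d].
#' @export
make_interaction_fixture <- function(kind = c("hbond_pair",
                                              "salt_bridge_pair",
                                              "cation_pi", "water_bridge",
                                              "hollow_shell"),
                                     distance = NULL, angle = NULL,
                                     probe = 1.4, seed = NULL) {
  kind <- match.arg(kind)
  if (kind == "hbond_pair") {
    if (is.null(distance)) distance <- 2.8
    if (is.null(angle)) angle <- 120
    N <- c(0, 0, 0); CA <- c(1.458, 0, 0)
    CB <- place_atom(c(-1, 0.5, 0), N, CA, 1.53, 110, 60)
    OG <- place_atom(N, CA, CB, 1.42, 111, 180)
    O_acc <- point_at_angle(OG, CB, distance, angle)
    C_b <- O_acc + c(0, 1.23, 0)
    CA_b <- C_b + c(1.52, 0, 0)
    atoms <- rbind(
      atom_row("A", 1, "SER", "N", N),
      atom_row("A", 1, "SER", "CA", CA),
      atom_row("A", 1, "SER", "CB", CB),
      atom_row("A", 1, "SER", "OG", OG),
      atom_row("B", 1, "GLY", "CA", CA_b),
      atom_row("B", 1, "GLY", "C", C_b),
      atom_row("B", 1, "GLY", "O", O_acc)
    )
    return(structure3d(atoms, id = "fix_hbond"))
  }
  if (kind == "salt_bridge_pair") {
    if (is.null(distance)) distance <- 3.0
    if (is.null(angle)) angle <- 30  # splay of the cross pairs
    CZ <- c(0, 0, 0)
    NE <- c(-1.33, 0, 0)
    NH1 <- 1.33 * c(cos(deg2rad(60)), sin(deg2rad(60)), 0)
    NH2 <- 1.33 * c(cos(deg2rad(60)), -sin(deg2rad(60)), 0)
    CD <- place_atom(CZ, c(-2, 1, 0), NE, 1.46, 124, 180)
    sp <- deg2rad(angle)
    OD1 <- NH1 + distance * c(cos(sp), sin(sp), 0)
    OD2 <- NH2 + distance * c(cos(sp), -sin(sp), 0)
    CG <- (OD1 + OD2) / 2 + c(0.4, 0, 0)
    CB <- CG + c(1.52, 0, 0)
    atoms <- rbind(
      atom_row("A", 1, "ARG", "CD", CD),
      atom_row("A", 1, "ARG", "NE", NE),
      atom_row("A", 1, "ARG", "CZ", CZ),
      atom_row("A", 1, "ARG", "NH1", NH1),
      atom_row("A", 1, "ARG", "NH2", NH2),
      atom_row("B", 1, "ASP", "CB", CB),
      atom_row("B", 1, "ASP", "CG", CG),
      atom_row("B", 1, "ASP", "OD1", OD1),
      atom_row("B", 1, "ASP", "OD2", OD2)
    )
    return(structure3d(atoms, id = "fix_salt_bridge"))
  }
  if (kind == "cation_pi") {
    if (is.null(distance)) distance <- 4.0
    if (is.null(angle)) angle <- 90
    ring_names <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
    ring_angles <- c(0, 60, 120, 180, 240, 300)
    ring_rows <- do.call(rbind, lapply(seq_along(ring_names), function(i) {
      a <- deg2rad(ring_angles[i])
      atom_row("B", 1, "PHE", ring_names[i],
               1.39 * c(cos(a), sin(a), 0))
    }))
    e <- deg2rad(angle)
    CZ_arg <- distance * c(cos(e), 0, sin(e))
    NH1 <- CZ_arg + c(1.1, 0.7, 0)
    NH2 <- CZ_arg + c(1.1, -0.7, 0)
    NE <- CZ_arg + c(-1.33, 0, 0)
    atoms <- rbind(
      ring_rows,
      atom_row("A", 1, "ARG", "NE", NE),
      atom_row("A", 1, "ARG", "CZ", CZ_arg),
      atom_row("A", 1, "ARG", "NH1", NH1),
      atom_row("A", 1, "ARG", "NH2", NH2)
    )
    return(structure3d(atoms, id = "fix_cation_pi"))
  }
  if (kind == "water_bridge") {
    if (is.null(distance)) distance <- 2.9
    if (is.null(angle)) angle <- 104
    W <- c(0, 0, 0)
    O_a <- c(-distance, 0, 0)
    b <- deg2rad(angle)
    N_b <- distance * c(cos(b), sin(b), 0)
    C_a <- O_a + c(-0.6, 1.1, 0)
    CA_b <- N_b + c(1.2, 0.8, 0)
    atoms <- rbind(
      atom_row("A", 1, "GLY", "C", C_a),
      atom_row("A", 1, "GLY", "O", O_a),
      atom_row("B", 2, "GLY", "N", N_b),
      atom_row("B", 2, "GLY", "CA", CA_b),
      atom_row("W", 100, "HOH", "O", W, hetero = TRUE)
    )
    return(structure3d(atoms, id = "fix_water_bridge"))
  }
  # hollow_shell
  if (is.null(distance)) distance <- 3.0
  r_shell <- distance + probe
  # Fibonacci sphere dense enough that no probe-sized gap leaks
  n <- max(200L, ceiling(4 * pi * r_shell^2 / 0.55^2))
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  xyz <- r_shell * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta),
                         cos(phi))
  atoms <- do.call(rbind, lapply(seq_len(n), function(k) {
    atom_row("S", k, "ALA", "CA", xyz[k, ])
  }))
  structure3d(atoms, id = "fix_hollow_shell")
}

#' Synthetic gated-pocket fixture
#'
#' An open-topped box cavity of carbon pseudo-atom walls with a tyrosine
#' "gate" hinged at the cavity mouth. At `gate_rotation_deg = 0` the side
#' chain hangs straight down through the mouth into the cavity (the
#' closed state, displacing pocket volume); rotating the side chain about
#' the horizontal CA-CB axis swings the ring up out of the mouth,
#' monotonically freeing volume until it lies flat outside the cavity at
#' 90 degrees (the open state). This is the package's desk-scale analogue
#' of the aromatic-gate mechanism of cryptic-subsite opening, and
#' supplies the default open/closed calibration pair.
#'
#' @param gate_rotation_deg Side-chain rotation about the CA-CB hinge
#'   axis, degrees (0 = closed, 90 = open).
#' @return list with `structure` (a [structure3d]), `site` (a
#'   [site_sphere]), and `exclude` (`NULL`; the gate is part of the
#'   protein).
#' @export
make_pocket_gate <- function(gate_rotation_deg = 0) {
  sp <- 0.9
  wall_rows <- list()
  add_wall <- function(xs, ys, zs) {
    grid <- as.matrix(expand.grid(xs, ys, zs))
    wall_rows[[length(wall_rows) + 1L]] <<- grid
  }
  half <- 5.4; zbot <- -8.4; ztop <- 1.0
  xs <- seq(-half, half, by = sp)
  zs <- seq(zbot, ztop, by = sp)
  add_wall(xs, xs, zbot)          # floor
  add_wall(-half, xs, zs)         # -x wall
  add_wall(half, xs, zs)          # +x wall
  add_wall(xs, -half, zs)         # -y wall
  add_wall(xs, half, zs)          # +y wall
  wall <- unique(do.call(rbind, wall_rows))
  atoms <- do.call(rbind, lapply(seq_len(nrow(wall)), function(k) {
    atom_row("A", k, "ALA", "CA", wall[k, ])
  }))
  # tyrosine gate hinged on the horizontal CA-CB axis (along x, above the
  # mouth); at 0 degrees the CB->CG bond points straight down (-z) and the
  # ring (xz-plane) plus hydroxyl reach deep into the cavity
  CA <- c(-3.5, 0, 1.8)
  CB <- c(-2.0, 0, 1.8)
  N <- c(-4.7, 0.9, 2.2)
  C <- c(-3.2, -0.9, 2.6)
  CG <- CB + c(0, 0, -1.51)
  ring_centre <- CG + c(0, 0, -1.39)
  hex <- list(CD1 = 30, CD2 = 150, CE1 = -30, CE2 = 210, CZ = 270)
  ring <- lapply(hex, function(a) {
    ring_centre + 1.39 * c(cos(deg2rad(a)), 0, sin(deg2rad(a)))
  })
  ring$OH <- ring_centre + (1.39 + 1.38) * c(0, 0, -1)
  movable_names <- c("CG", names(ring))
  movable <- rbind(
    atom_row("A", 1L, "TYR", "CG", CG),
    do.call(rbind, lapply(names(ring), function(el) {
      atom_row("A", 1L, "TYR", el, ring[[el]])
    }))
  )
  if (gate_rotation_deg != 0) {
    xyz <- atom_xyz(movable)
    rotated <- rotate_about_axis(xyz, CB, CB - CA, gate_rotation_deg)
    movable$x <- rotated[, 1]; movable$y <- rotated[, 2]
    movable$z <- rotated[, 3]
  }
  tyr_no <- max(atoms$resno) + 1L
  movable$resno <- tyr_no
  tyr <- rbind(
    atom_row("A", tyr_no, "TYR", "N", N),
    atom_row("A", tyr_no, "TYR", "CA", CA),
    atom_row("A", tyr_no, "TYR", "C", C),
    atom_row("A", tyr_no, "TYR", "CB", CB),
    movable
  )
  st <- structure3d(rbind(atoms, tyr),
                    id = sprintf("pocket_gate_%03d", round(gate_rotation_deg)))
  list(structure = st, site = site_sphere(c(0, 0, -3.5), 4, "gate"),
       exclude = NULL)
}

#' Write a synthetic thermogram fixture
#'
#' Wraps [simulate_thermogram()] and [write_thermogram()].
#'
#' @inheritParams simulate_thermogram
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
make_thermogram <- function(path, setup = titration_setup(), N = 0.91,
                            K_D = 0.78e-6, dH = -15.7, noise_sd = 0,
                            seed = NULL) {
  tg <- simulate_thermogram(setup, N, K_D, dH, noise_sd, seed)
  write_thermogram(tg, path)
}

#' Materialise the full synthetic fixture corpus
#'
#' Writes every generator's output (tyrosine pairs as PDB, interaction
#' fixtures as PDB, pocket gates as PDB, thermograms as TSV) into `dir`.
#' Deterministic under `seed`.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed for the noisy members.
#' @return Character vector of written paths, invisibly.
#' @export
make_all_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  put <- function(st, name) {
    p <- file.path(dir, name)
    write_structure(st, p, "pdb")
    paths <<- c(paths, p)
  }
  for (ang in c(0, 25, 60, 88.2)) {
    pair <- make_tyrosine_pair(ring_rotation_deg = ang)
    tag <- gsub("\\.", "p", sprintf("%g", ang))
    put(pair$a, sprintf("tyr_rot%s_a.pdb", tag))
    put(pair$b, sprintf("tyr_rot%s_b.pdb", tag))
  }
  for (kind in c("hbond_pair", "salt_bridge_pair", "cation_pi",
                 "water_bridge", "hollow_shell")) {
    put(make_interaction_fixture(kind), paste0(kind, ".pdb"))
  }
  put(make_pocket_gate(0)$structure, "pocket_gate_closed.pdb")
  put(make_pocket_gate(90)$structure, "pocket_gate_open.pdb")
  base <- make_tyrosine_pair()$a
  put(make_rigid_copy(base, 30, c(1, 1, 0), c(5, -3, 2),
                      coord_noise_sd = 0.1, seed = seed), "rigid_copy.pdb")
  p <- file.path(dir, "thermogram_wt.tsv")
  make_thermogram(p)
  paths <- c(paths, p)
  p <- file.path(dir, "thermogram_noisy.tsv")
  make_thermogram(p, noise_sd = 0.3, seed = seed)
  paths <- c(paths, p)
  invisible(paths)
}
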