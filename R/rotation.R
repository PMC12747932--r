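#' Side-chain chi angles of a residue
#'
#' Standard IUPAC dihedrals: chi1 = N-CA-CB-CG, chi2 = CA-CB-CG-CD1 (the
#' CD1 branch, as appropriate for Tyr/Phe/Trp/His). Both lie in (-180, 180].
#'
#' @param structure A [structure3d].
#' @param chain Chain id.
#' @param resno Author residue number.
#' @param insert Insertion code (default none).
#' @return Named numeric vector `c(chi1, chi2)` in degrees.
#' @export
chi_angles <- function(structure, chain, resno, insert = "") {
  need <- c("N", "CA", "CB", "CG", "CD1")
  pos <- lapply(need, function(el) {
    residue_atom_xyz(structure, chain, resno, el, insert)
  })
  missing <- need[vapply(pos, is.null, logical(1))]
  if (length(missing) > 0) {
    stop(sprintf("residue %s/%s%s is missing atom(s): %s",
                 chain, resno, insert, paste(missing, collapse = ", ")))
  }
  names(pos) <- need
  c(chi1 = dihedral_angle(pos$N, pos$CA, pos$CB, pos$CG),
    chi2 = dihedral_angle(pos$CA, pos$CB, pos$CG, pos$CD1))
}

RING_ATOMS <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")

ring_coords <- function(structure, chain, resno, insert = "") {
  pos <- lapply(RING_ATOMS, function(el) {
    residue_atom_xyz(structure, chain, resno, el, insert)
  })
  missing <- RING_ATOMS[vapply(pos, is.null, logical(1))]
  if (length(missing) > 0) {
    stop(sprintf("residue %s/%s%s is missing ring atom(s): %s",
                 chain, resno, insert, paste(missing, collapse = ", ")))
  }
  do.call(rbind, pos)
}

#' Least-squares plane normal of a six-membered aromatic ring
#'
#' The unit normal of the best-fit plane through CG, CD1, CD2, CE1, CE2, CZ
#' (smallest-singular-vector of the centred coordinates). The sign of the
#' normal is arbitrary; it is only ever used up to +/-, which also makes
#' the result invariant to the CD1/CD2-CE1/CE2 ring-label swap.
#'
#' @inheritParams chi_angles
#' @return Unit 3-vector.
#' @export
ring_plane_normal <- function(structure, chain, resno, insert = "") {
  xyz <- ring_coords(structure, chain, resno, insert)
  centred <- sweep(xyz, 2, colMeans(xyz))
  sv <- svd(centred)
  vunit(sv$v[, 3])
}

angle_between_normals <- function(n1, n2) {
  rad2deg(acos(clamp1(abs(sum(vunit(n1) * vunit(n2))))))
}

#' Ring rotation of an aromatic side chain between two structures
#'
#' The package's primary rotamer-switch observable: after mapping structure
#' B into structure A's propeller frame, the angle between the least-squares
#' ring-plane normals of the two aromatic side chains, folded into
#' \[0, 90\] degrees. Well-defined for Tyr-vs-Phe comparisons (only the six
#' ring carbons are used) and invariant to ring-label ambiguity. Chi-angle
#' differences are reported alongside as secondary metrics: `delta_chi1` in
#' (-180, 180\], `delta_chi2` folded to \[0, 90\] under the ring's 2-fold
#' symmetry.
#'
#' @param struct_a,struct_b [structure3d] objects.
#' @param chain_a,chain_b Chain of the residue in each structure.
#' @param resno_a,resno_b Author residue numbers (e.g. 191 in WDR5).
#' @param frame A `superposition` mapping `struct_b` coordinates into
#'   `struct_a`'s frame (e.g. from
#'   `superpose_ca(struct_b, struct_a, ...)`), or `NULL` if the structures
#'   are already in a common frame.
#' @return An object of class `rotation_report`.
#' @export
sidechain_rotation <- function(struct_a, struct_b, chain_a, chain_b,
                               resno_a, resno_b, frame = NULL) {
  res_a <- residue_table(struct_a, chain_a)
  res_b <- residue_table(struct_b, chain_b)
  name_a <- res_a$resid[res_a$resno == resno_a][1]
  name_b <- res_b$resid[res_b$resno == resno_b][1]
  aromatic <- c("TYR", "PHE")
  if (is.na(name_a) || is.na(name_b) ||
      !(name_a %in% aromatic) || !(name_b %in% aromatic)) {
    stop("sidechain_rotation supports Tyr/Phe residues only (got ",
         name_a, " / ", name_b, ")")
  }
  if (!is.null(frame)) struct_b <- apply_transform(struct_b, frame)
  n_a <- ring_plane_normal(struct_a, chain_a, resno_a)
  n_b <- ring_plane_normal(struct_b, chain_b, resno_b)
  chi_a <- chi_angles(struct_a, chain_a, resno_a)
  chi_b <- chi_angles(struct_b, chain_b, resno_b)
  out <- list(
    residue_a = sprintf("%s/%s%d", chain_a, name_a, resno_a),
    residue_b = sprintf("%s/%s%d", chain_b, name_b, resno_b),
    ring_plane_angle = angle_between_normals(n_a, n_b),
    delta_chi1 = wrap180(chi_b["chi1"] - chi_a["chi1"]),
    delta_chi2 = fold90(chi_b["chi2"] - chi_a["chi2"]),
    frame = if (is.null(frame)) "common frame (none applied)" else
      sprintf("superposed on %d atoms, rmsd %.3f A", frame$n_atoms, frame$rmsd)
  )
  out$delta_chi1 <- unname(out$delta_chi1)
  out$delta_chi2 <- unname(out$delta_chi2)
  class(out) <- "rotation_report"
  out
}

#' @export
print.rotation_report <- function(x, ...) {
  cat(sprintf("<rotation_report> %s vs %s\n", x$residue_a, x$residue_b))
  cat(sprintf("  ring-plane rotation: %.2f deg\n", x$ring_plane_angle))
  cat(sprintf("  delta chi1: %.2f deg, delta chi2 (folded): %.2f deg\n",
              x$delta_chi1, x$delta_chi2))
  cat(sprintf("  frame: %s\n", x$frame))
  invisible(x)
}

#' @export
as.data.frame.rotation_report <- function(x, ...) {
  data.frame(residue_a = x$residue_a, residue_b = x$residue_b,
             ring_plane_angle = x$ring_plane_angle,
             delta_chi1 = x$delta_chi1, delta_chi2 = x$delta_chi2,
             frame = x$frame, stringsAsFactors = FALSE)
}
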