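#' Geometric criteria for interface contacts
#'
#' All criteria are heavy-atom based: the crystal structures this package
#' targets (1.6-1.9 A) carry no hydrogens, so hydrogen-bond plausibility is
#' enforced with a donor-antecedent angle rule rather than explicit
#' hydrogen positions. Defaults are standard values from the contact-
#' analysis literature.
#'
#' @param hbond_max_da Max donor-acceptor heavy-atom distance, A.
#' @param hbond_min_angle Min antecedent-donor-acceptor angle, degrees;
#'   applied only when the donor's antecedent atom is present (waters have
#'   none).
#' @param salt_bridge_max Max cation-nitrogen to carboxylate-oxygen
#'   distance, A.
#' @param vdw_min,vdw_max Apolar heavy-atom contact window, A.
#' @param cation_pi_max_centroid Max cation-to-ring-centroid distance, A.
#' @param cation_pi_min_elevation Min elevation of the cation above the
#'   ring plane, degrees.
#' @param water_contact_max Max water-oxygen to polar-atom distance, A.
#' @param water_ring_max Water-oxygen to aromatic-ring-centroid distance
#'   below which a water-aromatic contact is noted, A.
#' @param site_radius Radius of the site sphere used for the ordered-water
#'   census, A.
#' @return A list of class `interaction_criteria`.
#' @export
interaction_criteria <- function(hbond_max_da = 3.5,
                                 hbond_min_angle = 90,
                                 salt_bridge_max = 4.0,
                                 vdw_max = 4.0,
                                 vdw_min = 3.0,
                                 cation_pi_max_centroid = 6.0,
                                 cation_pi_min_elevation = 45,
                                 water_contact_max = 3.5,
                                 water_ring_max = 3.6,
                                 site_radius = 8.0) {
  crit <- list(hbond_max_da = hbond_max_da, hbond_min_angle = hbond_min_angle,
               salt_bridge_max = salt_bridge_max, vdw_max = vdw_max,
               vdw_min = vdw_min,
               cation_pi_max_centroid = cation_pi_max_centroid,
               cation_pi_min_elevation = cation_pi_min_elevation,
               water_contact_max = water_contact_max,
               water_ring_max = water_ring_max,
               site_radius = site_radius)
  dists <- unlist(crit[c("hbond_max_da", "salt_bridge_max", "vdw_max",
                         "vdw_min", "cation_pi_max_centroid",
                         "water_contact_max", "water_ring_max",
                         "site_radius")])
  if (any(dists <= 0)) stop("all distance criteria must be positive")
  if (vdw_min >= vdw_max) stop("vdw_min must be smaller than vdw_max")
  class(crit) <- "interaction_criteria"
  crit
}

# Chemical typing table for polar heavy atoms of the standard residues.
# role: d = donor, a = acceptor, da = both. ante: the donor's bonded heavy
# atom used for the angle rule.
POLAR_SIDECHAIN <- list(
  SER = list(OG  = list(role = "da", ante = "CB")),
  THR = list(OG1 = list(role = "da", ante = "CB")),
  TYR = list(OH  = list(role = "da", ante = "CZ")),
  CYS = list(SG  = list(role = "da", ante = "CB")),
  ASN = list(OD1 = list(role = "a", ante = NA),
             ND2 = list(role = "d", ante = "CG")),
  GLN = list(OE1 = list(role = "a", ante = NA),
             NE2 = list(role = "d", ante = "CD")),
  LYS = list(NZ  = list(role = "d", ante = "CE")),
  ARG = list(NE  = list(role = "d", ante = "CD"),
             NH1 = list(role = "d", ante = "CZ"),
             NH2 = list(role = "d", ante = "CZ")),
  HIS = list(ND1 = list(role = "da", ante = "CG"),
             NE2 = list(role = "da", ante = "CD2")),
  ASP = list(OD1 = list(role = "a", ante = NA),
             OD2 = list(role = "a", ante = NA)),
  GLU = list(OE1 = list(role = "a", ante = NA),
             OE2 = list(role = "a", ante = NA)),
  TRP = list(NE1 = list(role = "d", ante = "CD1")),
  MET = list(SD  = list(role = "a", ante = NA))
)

STANDARD_RESIDUES <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU",
                       "GLY", "HIS", "ILE", "LEU", "LYS", "MET", "PHE",
                       "PRO", "SER", "THR", "TRP", "TYR", "VAL")

CATION_ATOMS <- list(
  ARG = c("NE", "NH1", "NH2"),
  LYS = "NZ",
  HIS = c("ND1", "NE2")
)

AROMATIC_RINGS <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TRP = list(c("CG", "CD1", "CD2", "NE1", "CE2"),
             c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2"))
)

#' Donor/acceptor typing of polar heavy atoms
#'
#' Labels every polar heavy atom of the selected residues as hydrogen-bond
#' donor, acceptor, or both, with the donor's antecedent atom name for the
#' angle rule. Covers the 20 standard residues (backbone N as donor except
#' proline; backbone O and OXT as acceptors) and water oxygen
#' (donor+acceptor, no antecedent). Atoms of non-standard residues are
#' skipped with a warning.
#'
#' @param atoms Atom rows as returned by [select_atoms()].
#' @return The polar subset of `atoms` with extra columns `donor`,
#'   `acceptor`, `ante`.
#' @export
donors_acceptors <- function(atoms) {
  nonstd <- setdiff(unique(atoms$resid),
                    c(STANDARD_RESIDUES, WATER_NAMES))
  if (length(nonstd) > 0) {
    warning("skipping atoms of non-standard residue(s): ",
            paste(nonstd, collapse = ", "))
    atoms <- atoms[!(atoms$resid %in% nonstd), , drop = FALSE]
  }
  n <- nrow(atoms)
  donor <- logical(n); acceptor <- logical(n); ante <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    resid <- atoms$resid[i]; elety <- atoms$elety[i]
    if (resid %in% WATER_NAMES) {
      if (atoms$elesy[i] == "O") { donor[i] <- TRUE; acceptor[i] <- TRUE }
      next
    }
    if (elety == "N" && resid != "PRO") { donor[i] <- TRUE; ante[i] <- "CA" }
    if (elety %in% c("O", "OXT")) acceptor[i] <- TRUE
    sc <- POLAR_SIDECHAIN[[resid]]
    if (!is.null(sc) && elety %in% names(sc)) {
      info <- sc[[elety]]
      if (info$role %in% c("d", "da")) { donor[i] <- TRUE; ante[i] <- info$ante }
      if (info$role %in% c("a", "da")) acceptor[i] <- TRUE
    }
  }
  keep <- donor | acceptor
  out <- atoms[keep, , drop = FALSE]
  out$donor <- donor[keep]
  out$acceptor <- acceptor[keep]
  out$ante <- ante[keep]
  out
}

atom_id <- function(atoms, i = seq_len(nrow(atoms))) {
  sprintf("%s/%s%d%s/%s", atoms$chain[i], atoms$resid[i], atoms$resno[i],
          atoms$insert[i], atoms$elety[i])
}

res_id <- function(atoms, i = seq_len(nrow(atoms))) {
  sprintf("%s/%s%d%s", atoms$chain[i], atoms$resid[i], atoms$resno[i],
          atoms$insert[i])
}

interaction_record <- function(kind, atoms_a, ia, atoms_b, ib, dist,
                               waters = "", note = "") {
  data.frame(kind = kind,
             res_a = res_id(atoms_a, ia), atom_a = atoms_a$elety[ia],
             res_b = res_id(atoms_b, ib), atom_b = atoms_b$elety[ib],
             distance = dist, waters = waters, note = note,
             stringsAsFactors = FALSE)
}

empty_records <- function() {
  data.frame(kind = character(), res_a = character(), atom_a = character(),
             res_b = character(), atom_b = character(), distance = numeric(),
             waters = character(), note = character(),
             stringsAsFactors = FALSE)
}

check_disjoint <- function(structure, sel_a, sel_b) {
  ma <- selection_mask(structure$atoms, sel_a)
  mb <- selection_mask(structure$atoms, sel_b)
  if (any(ma & mb)) stop("selections must be disjoint")
}

# Directed donor->acceptor search used symmetrically by find_hbonds.
# `don`/`acc` must already be restricted to donors/acceptors respectively.
hbond_pairs_directed <- function(don, acc, criteria, structure) {
  if (nrow(don) == 0L || nrow(acc) == 0L) return(NULL)
  hits <- close_pairs(atom_xyz(don), atom_xyz(acc), criteria$hbond_max_da)
  if (nrow(hits) == 0L) return(NULL)
  keep <- logical(nrow(hits)); angles <- rep(NA_real_, nrow(hits))
  for (k in seq_len(nrow(hits))) {
    i <- hits$i[k]; j <- hits$j[k]
    ante_name <- don$ante[i]
    if (is.na(ante_name)) { keep[k] <- TRUE; next }
    ante <- residue_atom_xyz(structure, don$chain[i], don$resno[i],
                             ante_name, don$insert[i])
    if (is.null(ante)) { keep[k] <- TRUE; next }  # antecedent unmodelled
    d_xyz <- as.numeric(don[i, c("x", "y", "z")])
    a_xyz <- as.numeric(acc[j, c("x", "y", "z")])
    ang <- rad2deg(acos(clamp1(sum(vunit(ante - d_xyz) * vunit(a_xyz - d_xyz)))))
    angles[k] <- ang
    keep[k] <- ang >= criteria$hbond_min_angle
  }
  hits <- hits[keep, , drop = FALSE]
  if (nrow(hits) == 0L) return(NULL)
  data.frame(don_id = atom_id(don, hits$i), acc_id = atom_id(acc, hits$j),
             i = hits$i, j = hits$j, dist = hits$dist,
             angle = angles[keep],
             don_side = rep(NA_character_, nrow(hits)),
             stringsAsFactors = FALSE)
}

#' Find hydrogen bonds between two selections
#'
#' Donor-acceptor heavy-atom pairs across the interface with distance at
#' most `hbond_max_da` and, where the donor's antecedent is modelled, an
#' antecedent-donor-acceptor angle of at least `hbond_min_angle` degrees.
#' The search is symmetric in the two selections; a pair of mutual
#' donor/acceptor atoms (e.g. two hydroxyls) yields one record.
#'
#' @param structure A [structure3d].
#' @param sel_a,sel_b Disjoint [selection]s (by convention `sel_a` is the
#'   peptide/ligand side).
#' @param criteria An [interaction_criteria] list.
#' @return A data.frame of interaction records (possibly empty).
#' @export
find_hbonds <- function(structure, sel_a, sel_b,
                        criteria = interaction_criteria()) {
  check_disjoint(structure, sel_a, sel_b)
  pa <- suppressWarnings(donors_acceptors(select_atoms(structure, sel_a)))
  pb <- suppressWarnings(donors_acceptors(select_atoms(structure, sel_b)))
  if (nrow(pa) == 0L || nrow(pb) == 0L) return(empty_records())
  don_a <- pa[pa$donor, , drop = FALSE]
  acc_a <- pa[pa$acceptor, , drop = FALSE]
  don_b <- pb[pb$donor, , drop = FALSE]
  acc_b <- pb[pb$acceptor, , drop = FALSE]
  fwd <- hbond_pairs_directed(don_a, acc_b, criteria, structure)
  rev <- hbond_pairs_directed(don_b, acc_a, criteria, structure)
  recs <- list()
  seen <- character(0)
  add <- function(atoms_a, ia, atoms_b, ib, dist, ang, dir) {
    key <- paste(atom_id(atoms_a, ia), atom_id(atoms_b, ib))
    if (key %in% seen) return(invisible(NULL))
    seen <<- c(seen, key)
    recs[[length(recs) + 1L]] <<- interaction_record(
      "hbond", atoms_a, ia, atoms_b, ib, dist,
      note = sprintf("donor=%s%s", dir,
                     ifelse(is.na(ang), "", sprintf(" angle=%.1f", ang))))
  }
  if (!is.null(fwd)) {
    for (k in seq_len(nrow(fwd))) {
      add(don_a, fwd$i[k], acc_b, fwd$j[k], fwd$dist[k], fwd$angle[k], "a")
    }
  }
  if (!is.null(rev)) {
    # record stays ordered (sel_a partner first): acceptor in a, donor in b
    for (k in seq_len(nrow(rev))) {
      add(acc_a, rev$j[k], don_b, rev$i[k], rev$dist[k], rev$angle[k], "b")
    }
  }
  if (length(recs) == 0L) return(empty_records())
  out <- do.call(rbind, recs)
  out[order(out$res_a, out$res_b, out$distance), , drop = FALSE]
}

#' Find salt bridges between two selections
#'
#' Pairs of cationic side-chain nitrogens (Arg NE/NH1/NH2, Lys NZ, His
#' ND1/NE2) and carboxylate/carboxy-terminal oxygens (Asp OD1/OD2, Glu
#' OE1/OE2, OXT) within `salt_bridge_max`, in either orientation across the
#' interface.
#'
#' @inheritParams find_hbonds
#' @return A data.frame of interaction records.
#' @export
find_salt_bridges <- function(structure, sel_a, sel_b,
                              criteria = interaction_criteria()) {
  check_disjoint(structure, sel_a, sel_b)
  a <- select_atoms(structure, sel_a)
  b <- select_atoms(structure, sel_b)
  is_cation <- function(at) {
    if (nrow(at) == 0L) return(logical(0))
    unlist(Map(function(r, e) {
      !is.null(CATION_ATOMS[[r]]) && e %in% CATION_ATOMS[[r]]
    }, at$resid, at$elety), use.names = FALSE)
  }
  is_anion <- function(at) {
    (at$resid == "ASP" & at$elety %in% c("OD1", "OD2")) |
      (at$resid == "GLU" & at$elety %in% c("OE1", "OE2")) |
      at$elety == "OXT"
  }
  one_way <- function(cat_at, an_at) {
    cat_at <- cat_at[is_cation(cat_at), , drop = FALSE]
    an_at <- an_at[is_anion(an_at), , drop = FALSE]
    if (nrow(cat_at) == 0L || nrow(an_at) == 0L) return(NULL)
    hits <- close_pairs(atom_xyz(cat_at), atom_xyz(an_at),
                        criteria$salt_bridge_max)
    if (nrow(hits) == 0L) return(NULL)
    list(cat = cat_at, an = an_at, hits = hits)
  }
  recs <- empty_records()
  fw <- one_way(a, b)
  if (!is.null(fw)) {
    recs <- rbind(recs, interaction_record("salt_bridge", fw$cat, fw$hits$i,
                                           fw$an, fw$hits$j, fw$hits$dist))
  }
  bw <- one_way(b, a)
  if (!is.null(bw)) {
    recs <- rbind(recs, interaction_record("salt_bridge", bw$an, bw$hits$j,
                                           bw$cat, bw$hits$i, bw$hits$dist))
  }
  recs[order(recs$res_a, recs$res_b, recs$distance), , drop = FALSE]
}

ring_centroids <- function(atoms) {
  out <- list()
  key <- paste(atoms$chain, atoms$resno, atoms$insert)
  for (rk in unique(key)) {
    sub <- atoms[key == rk, , drop = FALSE]
    rings <- AROMATIC_RINGS[[sub$resid[1]]]
    if (is.null(rings)) next
    for (ring in rings) {
      got <- sub[match(ring, sub$elety), , drop = FALSE]
      if (anyNA(got$elety)) next
      xyz <- atom_xyz(got)
      centred <- sweep(xyz, 2, colMeans(xyz))
      out[[length(out) + 1L]] <- list(
        res = res_id(sub, 1L), atoms = paste(ring, collapse = "+"),
        centroid = colMeans(xyz), normal = vunit(svd(centred)$v[, 3]),
        row = sub[1, , drop = FALSE])
    }
  }
  out
}

#' Find cation-pi interactions between two selections
#'
#' A cationic group centre (Arg guanidinium, represented by CZ; Lys NZ;
#' His imidazole centroid) within `cation_pi_max_centroid` of an aromatic
#' ring centroid (Phe/Tyr/Trp/His), with the cation elevated at least
#' `cation_pi_min_elevation` degrees above the ring plane.
#'
#' @inheritParams find_hbonds
#' @return A data.frame of interaction records; `distance` is the
#'   centroid-cation distance and the elevation is recorded in `note`.
#' @export
find_cation_pi <- function(structure, sel_a, sel_b,
                           criteria = interaction_criteria()) {
  check_disjoint(structure, sel_a, sel_b)
  a <- select_atoms(structure, sel_a)
  b <- select_atoms(structure, sel_b)
  cation_centres <- function(at) {
    out <- list()
    key <- paste(at$chain, at$resno, at$insert)
    for (rk in unique(key)) {
      sub <- at[key == rk, , drop = FALSE]
      resid <- sub$resid[1]
      if (resid == "ARG" && "CZ" %in% sub$elety) {
        i <- which(sub$elety == "CZ")[1]
        out[[length(out) + 1L]] <- list(row = sub[i, , drop = FALSE],
                                        centre = as.numeric(sub[i, c("x", "y", "z")]))
      } else if (resid == "LYS" && "NZ" %in% sub$elety) {
        i <- which(sub$elety == "NZ")[1]
        out[[length(out) + 1L]] <- list(row = sub[i, , drop = FALSE],
                                        centre = as.numeric(sub[i, c("x", "y", "z")]))
      }
    }
    out
  }
  one_way <- function(cat_side, ring_side, flip) {
    cats <- cation_centres(cat_side)
    rings <- ring_centroids(ring_side)
    recs <- empty_records()
    for (ct in cats) {
      for (rg in rings) {
        v <- ct$centre - rg$centroid
        d <- vnorm(v)
        if (d > criteria$cation_pi_max_centroid || d < 1e-6) next
        elev <- rad2deg(asin(clamp1(abs(sum(vunit(v) * rg$normal)))))
        if (elev < criteria$cation_pi_min_elevation) next
        rec <- interaction_record("cation_pi",
                                  ct$row, 1L, rg$row, 1L, d,
                                  note = sprintf("ring=%s elevation=%.1f",
                                                 rg$atoms, elev))
        rec$atom_b <- "ring"
        if (flip) {
          rec <- rec[, c("kind", "res_b", "atom_b", "res_a", "atom_a",
                         "distance", "waters", "note")]
          names(rec) <- names(empty_records())
        }
        recs <- rbind(recs, rec)
      }
    }
    recs
  }
  recs <- rbind(one_way(a, b, flip = FALSE), one_way(b, a, flip = TRUE))
  recs[order(recs$res_a, recs$res_b, recs$distance), , drop = FALSE]
}

#' Find van der Waals contacts between two selections
#'
#' Apolar heavy-atom pairs (carbon or sulfur on both sides) with distance
#' inside the `[vdw_min, vdw_max]` window, reported once per residue pair
#' with the minimum distance retained.
#'
#' @inheritParams find_hbonds
#' @return A data.frame of interaction records (one per residue pair).
#' @export
find_vdw_contacts <- function(structure, sel_a, sel_b,
                              criteria = interaction_criteria()) {
  check_disjoint(structure, sel_a, sel_b)
  a <- select_atoms(structure, sel_a)
  b <- select_atoms(structure, sel_b)
  a <- a[a$elesy %in% c("C", "S"), , drop = FALSE]
  b <- b[b$elesy %in% c("C", "S"), , drop = FALSE]
  if (nrow(a) == 0L || nrow(b) == 0L) return(empty_records())
  hits <- close_pairs(atom_xyz(a), atom_xyz(b), criteria$vdw_max)
  hits <- hits[hits$dist >= criteria$vdw_min, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty_records())
  recs <- interaction_record("vdw", a, hits$i, b, hits$j, hits$dist)
  pair_key <- paste(recs$res_a, recs$res_b)
  recs <- recs[order(pair_key, recs$distance), , drop = FALSE]
  recs <- recs[!duplicated(paste(recs$res_a, recs$res_b)), , drop = FALSE]
  recs[order(recs$res_a, recs$res_b), , drop = FALSE]
}

#' Census of ordered site waters and the bridges they mediate
#'
#' Identifies ordered water molecules within `site_radius` of
#' `site_center` that make at least two polar contacts (each at most
#' `water_contact_max`) to non-water atoms, at least one of which belongs
#' to `sel_a` or `sel_b`. Site membership (not strict a-to-b bridging)
#' qualifies a water, so waters knitting the peptide to itself or
#' contacting aromatic rings are counted, as appropriate for an
#' interface-stabilising water network. A water oxygen within
#' `water_ring_max` of an aromatic ring centroid gets a water-aromatic
#' geometry note.
#'
#' @inheritParams find_hbonds
#' @param site_center 3-vector, e.g. from [win_s7_center()].
#' @return A data.frame of `water_bridge` records, one per qualifying
#'   water; `waters` holds the water id and `note` the bridged atoms.
#' @export
find_water_bridges <- function(structure, sel_a, sel_b, site_center,
                               criteria = interaction_criteria()) {
  check_disjoint(structure, sel_a, sel_b)
  at <- structure$atoms
  wat <- at[at$is_water & at$elesy == "O", , drop = FALSE]
  if (nrow(wat) == 0L) {
    warning("structure contains no waters")
    return(empty_records())
  }
  dist_to_site <- sqrt(colSums((t(atom_xyz(wat)) - site_center)^2))
  wat <- wat[dist_to_site <= criteria$site_radius, , drop = FALSE]
  if (nrow(wat) == 0L) return(empty_records())
  polar <- suppressWarnings(donors_acceptors(at[!at$is_water, , drop = FALSE]))
  in_a <- selection_mask(polar, sel_a)
  in_b <- selection_mask(polar, sel_b)
  rings <- ring_centroids(select_atoms(structure, sel_b))
  rings_a <- ring_centroids(select_atoms(structure, sel_a))
  rings <- c(rings, rings_a)
  recs <- empty_records()
  for (w in seq_len(nrow(wat))) {
    w_xyz <- as.numeric(wat[w, c("x", "y", "z")])
    d <- sqrt(colSums((t(atom_xyz(polar)) - w_xyz)^2))
    contacts <- which(d <= criteria$water_contact_max)
    if (length(contacts) < 2L) next
    if (!any(in_a[contacts] | in_b[contacts])) next
    ord <- contacts[order(d[contacts])]
    sided <- ord[in_a[ord] | in_b[ord]]
    i_first <- sided[1]
    i_second <- setdiff(ord, i_first)[1]
    note <- paste0("bridges=", paste(atom_id(polar, ord), collapse = ","))
    ring_note <- ""
    for (rg in rings) {
      dr <- vnorm(w_xyz - rg$centroid)
      if (dr <= criteria$water_ring_max) {
        ring_note <- paste0(ring_note, sprintf(" ring_contact=%s@%.2f",
                                               rg$res, dr))
      }
    }
    rec <- interaction_record("water_bridge", polar, i_first, polar, i_second,
                              d[i_first],
                              waters = res_id(wat, w),
                              note = paste0(note, ring_note))
    recs <- rbind(recs, rec)
  }
  recs
}

#' Full typed interaction fingerprint of an interface
#'
#' Union of hydrogen bonds, salt bridges, cation-pi, van der Waals, and
#' (when `site_center` is supplied) water-bridge records, sorted by the
#' `sel_a` (peptide) residue and kind — the package's contact-schematic
#' equivalent in tabular form.
#'
#' @inheritParams find_hbonds
#' @param site_center Optional 3-vector for the water census; water bridges
#'   are omitted when `NULL`.
#' @return A data.frame of class `interaction_table`.
#' @export
fingerprint <- function(structure, sel_a, sel_b,
                        criteria = interaction_criteria(),
                        site_center = NULL) {
  tab <- rbind(
    find_hbonds(structure, sel_a, sel_b, criteria),
    find_salt_bridges(structure, sel_a, sel_b, criteria),
    find_cation_pi(structure, sel_a, sel_b, criteria),
    find_vdw_contacts(structure, sel_a, sel_b, criteria),
    if (!is.null(site_center)) {
      find_water_bridges(structure, sel_a, sel_b, site_center, criteria)
    } else empty_records()
  )
  resno_a <- suppressWarnings(as.integer(gsub("[^0-9]", "", tab$res_a)))
  tab <- tab[order(resno_a, tab$res_a, tab$kind, tab$res_b), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "criteria") <- criteria
  class(tab) <- c("interaction_table", "data.frame")
  tab
}

#' Write an interaction table to TSV or JSON
#'
#' @param table An `interaction_table` (or any interaction record
#'   data.frame).
#' @param path Output path; format chosen by extension (`.json` vs TSV).
#' @return `path`, invisibly.
#' @export
write_interactions <- function(table, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.data.frame(table), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else {
    utils::write.table(as.data.frame(table), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
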