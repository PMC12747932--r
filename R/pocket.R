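#' Site sphere
#'
#' A named spherical region of interest: centre (Angstrom) plus radius.
#' Used directly for synthetic fixtures and produced from anchor residues
#' by [site_definition()] for WDR5-like structures.
#'
#' @param center Numeric 3-vector.
#' @param radius Radius, A.
#' @param name Site name.
#' @return A list of class `site_sphere`.
#' @export
site_sphere <- function(center, radius = 8, name = "site") {
  center <- as.numeric(center)
  if (length(center) != 3 || !all(is.finite(center))) {
    stop("site centre must be a finite 3-vector")
  }
  if (radius <= 0) stop("site radius must be positive")
  out <- list(name = name, center = center, radius = radius)
  class(out) <- "site_sphere"
  out
}

#' @export
print.site_sphere <- function(x, ...) {
  cat(sprintf("<site_sphere> %s: centre (%.2f, %.2f, %.2f), radius %.1f A\n",
              x$name, x$center[1], x$center[2], x$center[3], x$radius))
  invisible(x)
}

ring_centroid_of <- function(structure, chain, resno) {
  xyz <- ring_coords(structure, chain, resno)
  colMeans(xyz)
}

#' Anchor-based WIN / S7 site definition for WDR5-like structures
#'
#' The S7 subsite centre is the centroid of four anchors on its walls: the
#' Phe133 and Phe149 ring centroids, Pro173 CA, and the CB of residue 191
#' (Tyr in the wild type, Phe in the Y191F variant). The WIN site centre is
#' the centroid of the backbone carbonyl oxygens of Ser91, Phe133 and
#' Cys261 — the atoms that coordinate the WIN-motif arginine in the central
#' channel of the beta-propeller.
#'
#' @param structure A [structure3d] containing a WDR5 propeller.
#' @param name `"S7"` or `"WIN"`.
#' @param chain Chain id of the propeller.
#' @param radius Site-sphere radius, A (default 8).
#' @return A [site_sphere].
#' @export
site_definition <- function(structure, name = c("S7", "WIN"), chain,
                            radius = 8) {
  name <- match.arg(name)
  need <- function(xyz, what) {
    if (is.null(xyz)) stop("missing site anchor: ", what)
    xyz
  }
  if (name == "S7") {
    center <- colMeans(rbind(
      need(tryCatch(ring_centroid_of(structure, chain, 133),
                    error = function(e) NULL), "Phe133 ring"),
      need(tryCatch(ring_centroid_of(structure, chain, 149),
                    error = function(e) NULL), "Phe149 ring"),
      need(residue_atom_xyz(structure, chain, 173, "CA"), "Pro173 CA"),
      need(residue_atom_xyz(structure, chain, 191, "CB"), "residue 191 CB")
    ))
  } else {
    center <- colMeans(rbind(
      need(residue_atom_xyz(structure, chain, 91, "O"), "Ser91 O"),
      need(residue_atom_xyz(structure, chain, 133, "O"), "Phe133 O"),
      need(residue_atom_xyz(structure, chain, 261, "O"), "Cys261 O")
    ))
  }
  site_sphere(center, radius, name)
}

#' Centre of the combined WIN-S7 region
#'
#' Midpoint of the WIN and S7 site centres; the reference point for the
#' ordered-water census of the interface.
#'
#' @inheritParams site_definition
#' @return Numeric 3-vector.
#' @export
win_s7_center <- function(structure, chain) {
  s7 <- site_definition(structure, "S7", chain)
  win <- site_definition(structure, "WIN", chain)
  (s7$center + win$center) / 2
}

#' Probe-accessible buried volume of a site
#'
#' A deterministic, grid-based stand-in for rendered-surface pocket
#' inspection. A cubic grid (spacing `grid_spacing`) is laid over the site
#' sphere; a grid point is *free* when it lies at least `probe_radius` from
#' every retained protein heavy atom, and *buried* when rays cast along at
#' least `burial_min` of the 6 axis directions pass within `probe_radius`
#' of some atom centre. The pocket volume is the count of buried free
#' points times the grid-cell volume. Peptides, compounds and waters must
#' be excluded via `exclude` (or by passing a protein-only structure) so
#' that openness measures the protein pocket, not its occupancy. The grid
#' is anchored to the site, making the measure invariant to rigid motions
#' of the whole structure.
#'
#' @param structure A [structure3d].
#' @param site A [site_sphere].
#' @param probe_radius Probe radius, A (default 1.4, a water-sized probe).
#' @param grid_spacing Grid spacing, A (default 0.5).
#' @param exclude Optional [selection] of atoms to drop before scanning
#'   (waters are always dropped).
#' @param burial_min Minimum number of blocked axis directions (default 4
#'   of 6).
#' @return Volume in cubic Angstrom (>= 0), with attribute `n_points`.
#' @export
pocket_volume <- function(structure, site, probe_radius = 1.4,
                          grid_spacing = 0.5, exclude = NULL,
                          burial_min = 4L) {
  a <- structure$atoms
  keep <- !a$is_water & a$elesy != "H"
  if (!is.null(exclude)) keep <- keep & !selection_mask(a, exclude)
  atoms <- as.matrix(a[keep, c("x", "y", "z")])
  ctr <- site$center; r <- site$radius
  if (nrow(atoms) == 0L ||
      min(sqrt(colSums((t(atoms) - ctr)^2))) > r + 4 * probe_radius) {
    warning("no protein atoms near the site sphere; volume is 0")
    out <- 0
    attr(out, "n_points") <- 0L
    return(out)
  }
  ax <- seq(ctr[1] - r, ctr[1] + r, by = grid_spacing)
  ay <- seq(ctr[2] - r, ctr[2] + r, by = grid_spacing)
  az <- seq(ctr[3] - r, ctr[3] + r, by = grid_spacing)
  pts <- as.matrix(expand.grid(x = ax, y = ay, z = az))
  inside <- colSums((t(pts) - ctr)^2) <= r^2
  pts <- pts[inside, , drop = FALSE]
  # free: no atom centre within probe_radius
  occ_hits <- close_pairs(pts, atoms, probe_radius)
  free <- setdiff(seq_len(nrow(pts)), unique(occ_hits$i))
  if (length(free) == 0L) {
    out <- 0
    attr(out, "n_points") <- 0L
    return(out)
  }
  pts <- pts[free, , drop = FALSE]
  # burial ray test along +-x, +-y, +-z, in chunks to bound memory
  blocked <- matrix(FALSE, nrow(pts), 6L)
  dirs <- list(c(1, 2, 3, +1), c(1, 2, 3, -1),
               c(2, 1, 3, +1), c(2, 1, 3, -1),
               c(3, 1, 2, +1), c(3, 1, 2, -1))
  chunk <- 2000L
  starts <- seq(1L, nrow(pts), by = chunk)
  for (d in seq_along(dirs)) {
    ax1 <- dirs[[d]][1]; lat1 <- dirs[[d]][2]; lat2 <- dirs[[d]][3]
    sgn <- dirs[[d]][4]
    for (s in starts) {
      idx <- s:min(s + chunk - 1L, nrow(pts))
      p <- pts[idx, , drop = FALSE]
      # atom ahead along the ray and within probe_radius of its axis
      ahead <- outer(p[, ax1], atoms[, ax1],
                     function(pp, aa) sgn * (aa - pp) > 0)
      d1 <- outer(p[, lat1], atoms[, lat1], `-`)
      d2 <- outer(p[, lat2], atoms[, lat2], `-`)
      near <- (d1 * d1 + d2 * d2) < probe_radius^2
      blocked[idx, d] <- rowSums(ahead & near) > 0
    }
  }
  n_buried <- sum(rowSums(blocked) >= burial_min)
  out <- n_buried * grid_spacing^3
  attr(out, "n_points") <- n_buried
  out
}

#' Default S7 calibration
#'
#' The open/closed decision threshold is the midpoint of the pocket
#' volumes of a closed and an open calibration structure. When local
#' copies of a closed reference (arginine-bound WDR5) and an open
#' reference (WIN-motif-peptide-bound WDR5) are available, pass them here
#' to calibrate against real structures. Without them, the default
#' calibration is computed from the package's own synthetic pocket-gate
#' fixtures ([make_pocket_gate()] at gate rotations 0 and 90 degrees) and
#' is labelled `source = "synthetic"`.
#'
#' @param closed,open Optional lists `list(structure=, site=, exclude=)`
#'   (or [structure3d] objects, in which case `chain` locates the S7 site).
#' @param chain Chain id used when structures are given directly.
#' @param ... Passed to [pocket_volume()].
#' @return A list of class `s7_calibration`: `v_closed`, `v_open`,
#'   `threshold`, `source`.
#' @export
s7_calibration <- function(closed = NULL, open = NULL, chain = "A", ...) {
  vol_of <- function(x) {
    if (inherits(x, "structure3d")) {
      site <- site_definition(x, "S7", chain)
      pocket_volume(x, site, ...)
    } else {
      pocket_volume(x$structure, x$site, exclude = x$exclude, ...)
    }
  }
  if (is.null(closed) || is.null(open)) {
    key <- paste0("calib_", paste(deparse(list(...)), collapse = ""))
    if (!is.null(.wins7_cache[[key]])) return(.wins7_cache[[key]])
    closed <- make_pocket_gate(0)
    open <- make_pocket_gate(90)
    src <- "synthetic"
  } else {
    src <- "user"
    key <- NULL
  }
  v_closed <- as.numeric(vol_of(closed))
  v_open <- as.numeric(vol_of(open))
  if (v_open <= v_closed) {
    warning("open calibration volume does not exceed closed volume")
  }
  out <- list(v_closed = v_closed, v_open = v_open,
              threshold = (v_closed + v_open) / 2, source = src)
  class(out) <- "s7_calibration"
  if (!is.null(key)) .wins7_cache[[key]] <- out
  out
}

#' @export
print.s7_calibration <- function(x, ...) {
  cat(sprintf(
    "<s7_calibration> closed %.1f A^3, open %.1f A^3, threshold %.1f A^3 (%s)\n",
    x$v_closed, x$v_open, x$threshold, x$source))
  invisible(x)
}

#' Classify S7 openness of a structure
#'
#' Computes the S7 pocket volume (ligand/peptide/waters excluded) and calls
#' the site *open* when it exceeds the calibration threshold. When a
#' reference structure is supplied, the Tyr191 (or Phe191) ring rotation
#' relative to the reference, measured in the propeller frame, is reported
#' alongside.
#'
#' @param structure A [structure3d] containing a WDR5-like propeller.
#' @param reference Optional reference [structure3d] (e.g. a closed,
#'   arginine-bound propeller).
#' @param chain,chain_ref Propeller chain ids.
#' @param calibration An `s7_calibration`; default is the synthetic
#'   calibration from [s7_calibration()].
#' @param exclude [selection] of non-propeller content to exclude from the
#'   volume scan (waters are always excluded). Default: everything outside
#'   `chain` plus all HETATM records.
#' @param site Optional [site_sphere] overriding [site_definition()] (used
#'   for synthetic fixtures).
#' @param ... Passed to [pocket_volume()].
#' @return A list of class `pocket_report`: `volume`, `state`
#'   (`"open"`/`"closed"`), `threshold`, `tyr191_rotation_vs_reference`
#'   (degrees or `NA`), `reference_id`.
#' @export
classify_s7 <- function(structure, reference = NULL, chain = "A",
                        chain_ref = chain,
                        calibration = s7_calibration(),
                        exclude = NULL, site = NULL, ...) {
  if (is.null(site)) site <- site_definition(structure, "S7", chain)
  if (is.null(exclude)) {
    other <- setdiff(unique(structure$atoms$chain), chain)
    exclude <- if (length(other) > 0) selection(chain = other) else
      selection(hetero = TRUE)
  }
  vol <- pocket_volume(structure, site, exclude = exclude, ...)
  rot <- NA_real_
  ref_id <- NA_character_
  if (!is.null(reference)) {
    ref_id <- reference$id
    frame <- tryCatch(
      superpose_ca(reference, structure, chain_ref, chain),
      error = function(e) stop("cannot superpose reference: ",
                               conditionMessage(e), call. = FALSE))
    rep_rot <- sidechain_rotation(structure, reference, chain, chain_ref,
                                  191, 191, frame = frame)
    rot <- rep_rot$ring_plane_angle
  }
  out <- list(volume = as.numeric(vol),
              state = if (as.numeric(vol) > calibration$threshold) "open"
              else "closed",
              threshold = calibration$threshold,
              calibration_source = calibration$source,
              tyr191_rotation_vs_reference = rot,
              reference_id = ref_id)
  class(out) <- "pocket_report"
  out
}

#' @export
print.pocket_report <- function(x, ...) {
  cat(sprintf("<pocket_report> S7 %s (volume %.1f A^3, threshold %.1f A^3, %s calibration)\n",
              toupper(x$state), x$volume, x$threshold, x$calibration_source))
  if (!is.na(x$tyr191_rotation_vs_reference)) {
    cat(sprintf("  residue-191 ring rotation vs %s: %.1f deg\n",
                x$reference_id, x$tyr191_rotation_vs_reference))
  }
  invisible(x)
}
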