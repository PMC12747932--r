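#' Pair residues between two structures
#'
#' Supports two schemes. `by_author_number` pairs residues whose author
#' numbers (and insertion codes) occur in both chains — appropriate when the
#' two structures share a numbering convention, as deposited WDR5 entries
#' do. `by_alignment` aligns the one-letter sequences globally (identity
#' scoring, affine gaps, via Biostrings) and pairs identically aligned
#' positions.
#'
#' @param struct_a,struct_b [structure3d] objects.
#' @param chain_a,chain_b Chain identifiers.
#' @param scheme `"by_author_number"` or `"by_alignment"`.
#' @return A data.frame of class `residue_pairs` with columns
#'   `resno_a`, `insert_a`, `resid_a`, `resno_b`, `insert_b`, `resid_b`.
#' @export
match_residues <- function(struct_a, struct_b, chain_a, chain_b,
                           scheme = c("by_author_number", "by_alignment")) {
  scheme <- match.arg(scheme)
  ra <- residue_table(struct_a, chain_a)
  rb <- residue_table(struct_b, chain_b)
  ra <- ra[!ra$is_water & ra$model == ra$model[1], , drop = FALSE]
  rb <- rb[!rb$is_water & rb$model == rb$model[1], , drop = FALSE]
  if (nrow(ra) == 0L || nrow(rb) == 0L) {
    stop("chain not found or contains no non-water residues")
  }
  if (scheme == "by_author_number") {
    key_a <- paste(ra$resno, ra$insert)
    key_b <- paste(rb$resno, rb$insert)
    common <- intersect(key_a, key_b)
    if (length(common) == 0L) stop("no residues with common author numbers")
    ia <- match(common, key_a)
    ib <- match(common, key_b)
  } else {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      stop("scheme 'by_alignment' requires the Biostrings package")
    }
    seq_a <- bio3d::aa321(ra$resid)
    seq_b <- bio3d::aa321(rb$resid)
    seq_a[is.na(seq_a) | seq_a == ""] <- "X"
    seq_b[is.na(seq_b) | seq_b == ""] <- "X"
    letters_all <- sort(unique(c(seq_a, seq_b)))
    subst <- matrix(-1, length(letters_all), length(letters_all),
                    dimnames = list(letters_all, letters_all))
    diag(subst) <- 1
    aln <- Biostrings::pairwiseAlignment(
      paste(seq_a, collapse = ""), paste(seq_b, collapse = ""),
      type = "global", substitutionMatrix = subst,
      gapOpening = 5, gapExtension = 0.5
    )
    pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    ps <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    ia <- integer(0); ib <- integer(0)
    ca <- 0L; cb <- 0L
    for (k in seq_along(pa)) {
      if (pa[k] != "-") ca <- ca + 1L
      if (ps[k] != "-") cb <- cb + 1L
      if (pa[k] != "-" && ps[k] != "-" && pa[k] == ps[k]) {
        ia <- c(ia, ca); ib <- c(ib, cb)
      }
    }
    if (length(ia) == 0L) stop("alignment produced no identical positions")
  }
  out <- data.frame(
    resno_a = ra$resno[ia], insert_a = ra$insert[ia], resid_a = ra$resid[ia],
    resno_b = rb$resno[ib], insert_b = rb$insert[ib], resid_b = rb$resid[ib],
    stringsAsFactors = FALSE
  )
  attr(out, "scheme") <- scheme
  attr(out, "chain_a") <- chain_a
  attr(out, "chain_b") <- chain_b
  class(out) <- c("residue_pairs", "data.frame")
  out
}

#' Kabsch least-squares rigid-body superposition
#'
#' Finds the proper rotation `R` and translation `t` minimising the RMSD of
#' `x' = R x + t` over the rows of `coords_a` onto `coords_b`, via SVD of
#' the covariance matrix with the usual determinant sign correction.
#'
#' @param coords_a,coords_b Matched n x 3 coordinate matrices, n >= 3,
#'   non-collinear.
#' @return An object of class `superposition`: list with `rotation` (3 x 3,
#'   det +1), `translation` (length 3), `n_atoms`, `rmsd` (Angstrom, after
#'   transform).
#' @export
kabsch <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (!all(dim(coords_a) == dim(coords_b)) || ncol(coords_a) != 3) {
    stop("coordinate sets must be matched n x 3 matrices")
  }
  n <- nrow(coords_a)
  if (n < 3) stop("superposition needs at least 3 matched atoms")
  ca <- colMeans(coords_a); cb <- colMeans(coords_b)
  a0 <- sweep(coords_a, 2, ca); b0 <- sweep(coords_b, 2, cb)
  sv_a <- svd(a0)$d
  if (sv_a[2] < 1e-8 * max(sv_a[1], 1)) {
    stop("degenerate (collinear) coordinate set; superposition is ill-posed")
  }
  H <- t(a0) %*% b0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- as.numeric(cb - R %*% ca)
  moved <- sweep(coords_a %*% t(R), 2, t_vec, `+`)
  rmsd <- sqrt(mean(rowSums((moved - coords_b)^2)))
  out <- list(rotation = R, translation = t_vec, n_atoms = n, rmsd = rmsd)
  class(out) <- "superposition"
  out
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> %d atoms, rmsd %.4f A\n", x$n_atoms, x$rmsd))
  cat("rotation:\n"); print(round(x$rotation, 6))
  cat("translation:", paste(sprintf("%.4f", x$translation), collapse = " "), "\n")
  invisible(x)
}

#' Apply a rigid transform to a structure
#'
#' @param structure A [structure3d].
#' @param sp A `superposition` (or any list with `rotation`/`translation`).
#' @return The transformed [structure3d]; composition unchanged.
#' @export
apply_transform <- function(structure, sp) {
  xyz <- atom_xyz(structure)
  moved <- sweep(xyz %*% t(sp$rotation), 2, sp$translation, `+`)
  structure$atoms$x <- moved[, 1]
  structure$atoms$y <- moved[, 2]
  structure$atoms$z <- moved[, 3]
  structure
}

#' Invert a rigid transform
#'
#' @param sp A `superposition`.
#' @return The inverse transform as a `superposition` (rmsd/n carried over).
#' @export
invert_transform <- function(sp) {
  Rt <- t(sp$rotation)
  out <- list(rotation = Rt, translation = as.numeric(-Rt %*% sp$translation),
              n_atoms = sp$n_atoms, rmsd = sp$rmsd)
  class(out) <- "superposition"
  out
}

#' C-alpha superposition in the propeller frame
#'
#' Convenience wrapper: pairs residues of the two chains, restricts to an
#' author-number window (default 31-334, the modelled WD40 propeller of
#' WDR5 — the frame in which all rotamer comparisons in this package are
#' made), extracts C-alpha atoms present in both, and runs [kabsch()]
#' superposing `struct_a` onto `struct_b`. Superposition is unweighted.
#'
#' @inheritParams match_residues
#' @param resno_range Length-2 integer window of author numbers, or `NULL`
#'   for no restriction.
#' @return A `superposition` mapping `struct_a` coordinates into
#'   `struct_b`'s frame, with the residue pair list attached as attribute
#'   `pairs`.
#' @export
superpose_ca <- function(struct_a, struct_b, chain_a, chain_b,
                         resno_range = c(31L, 334L),
                         scheme = c("by_author_number", "by_alignment")) {
  pairs <- match_residues(struct_a, struct_b, chain_a, chain_b,
                          scheme = match.arg(scheme))
  if (!is.null(resno_range)) {
    keep <- pairs$resno_a >= resno_range[1] & pairs$resno_a <= resno_range[2]
    pairs <- pairs[keep, , drop = FALSE]
  }
  xa <- t(vapply(seq_len(nrow(pairs)), function(i) {
    p <- residue_atom_xyz(struct_a, chain_a, pairs$resno_a[i], "CA",
                          pairs$insert_a[i])
    if (is.null(p)) rep(NA_real_, 3) else p
  }, numeric(3)))
  xb <- t(vapply(seq_len(nrow(pairs)), function(i) {
    p <- residue_atom_xyz(struct_b, chain_b, pairs$resno_b[i], "CA",
                          pairs$insert_b[i])
    if (is.null(p)) rep(NA_real_, 3) else p
  }, numeric(3)))
  ok <- stats::complete.cases(xa) & stats::complete.cases(xb)
  if (sum(ok) < 3) stop("fewer than 3 common C-alpha atoms in range")
  sp <- kabsch(xa[ok, , drop = FALSE], xb[ok, , drop = FALSE])
  attr(sp, "pairs") <- pairs[ok, , drop = FALSE]
  sp
}
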