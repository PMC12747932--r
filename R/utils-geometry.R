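# Small 3-D geometry helpers shared by all modules. Coordinates are always
# Angstrom; angles are degrees at the API surface, radians internally.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

vunit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  a / n
}

clamp1 <- function(x) pmin(1, pmax(-1, x))

#' Torsion (dihedral) angle of four points
#'
#' Standard IUPAC sign convention: looking from `p2` to `p3`, the angle is
#' positive for a clockwise rotation of the far bond relative to the near
#' bond. Result lies in (-180, 180].
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Angstrom).
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(vcross(n1, n2) * vunit(b2))
  ang <- rad2deg(atan2(y, x))
  if (ang <= -180) ang <- ang + 360
  ang
}

# Wrap an angle difference into (-180, 180].
wrap180 <- function(x) {
  x <- (x + 180) %% 360 - 180
  ifelse(x == -180, 180, x)
}

# Fold an angle difference into [0, 90] under a 2-fold (180 deg) symmetry,
# as appropriate for phenyl/tyrosyl ring label ambiguity.
fold90 <- function(x) {
  x <- abs(wrap180(x))
  ifelse(x > 90, 180 - x, x)
}

# Proper rotation matrix for a rotation of `deg` degrees about `axis`
# (Rodrigues formula). Columns convention: y = R %*% x.
rotation_matrix <- function(axis, deg) {
  u <- vunit(axis)
  th <- deg2rad(deg)
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy,
                uz, 0, -ux,
                -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * (u %o% u)
}

# Rotate points (rows of n x 3 matrix) about an axis through `origin`.
rotate_about_axis <- function(xyz, origin, axis, deg) {
  R <- rotation_matrix(axis, deg)
  sweep(sweep(xyz, 2, origin) %*% t(R), 2, origin, `+`)
}

# NeRF atom placement: position atom D given three predecessors A-B-C, the
# C-D bond length, the B-C-D angle (deg) and the A-B-C-D torsion (deg).
place_atom <- function(a, b, c, bond, angle, torsion) {
  th <- deg2rad(angle)
  ph <- deg2rad(torsion)
  d_local <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- cbind(bc, vcross(n, bc), n)
  as.numeric(m %*% d_local + c)
}

# All pairs (i in A, j in B) with distance <= cutoff. `method = "cell"` bins
# B into cubic cells of edge `cutoff` and only scans the 27 neighbouring
# cells; "brute" is the quadratic reference used as an oracle in tests.
close_pairs <- function(xyz_a, xyz_b, cutoff, method = c("cell", "brute")) {
  method <- match.arg(method)
  empty <- data.frame(i = integer(), j = integer(), dist = numeric())
  na <- nrow(xyz_a); nb <- nrow(xyz_b)
  if (is.null(na) || is.null(nb) || na == 0L || nb == 0L) return(empty)
  if (method == "brute" || na * nb <= 10000) {
    d2 <- outer(rowSums(xyz_a^2), rowSums(xyz_b^2), `+`) -
      2 * xyz_a %*% t(xyz_b)
    d2[d2 < 0] <- 0
    hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
    out <- data.frame(i = hit[, 1], j = hit[, 2],
                      dist = sqrt(d2[hit]))
    return(out[order(out$i, out$j), , drop = FALSE])
  }
  cell_of <- function(xyz) {
    floor(sweep(xyz, 2, origin_) / cutoff)
  }
  origin_ <- apply(rbind(xyz_a, xyz_b), 2, min)
  key <- function(cells) paste(cells[, 1], cells[, 2], cells[, 3])
  cb <- cell_of(xyz_b)
  bins <- split(seq_len(nb), key(cb))
  ca <- cell_of(xyz_a)
  res_i <- vector("list", na)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (i in seq_len(na)) {
    neigh <- sweep(offsets, 2, as.numeric(ca[i, ]), `+`)
    js <- unlist(bins[paste(neigh[, 1], neigh[, 2], neigh[, 3])],
                 use.names = FALSE)
    if (length(js) == 0L) next
    d <- sqrt(colSums((t(xyz_b[js, , drop = FALSE]) - xyz_a[i, ])^2))
    keep <- d <= cutoff
    if (any(keep)) {
      res_i[[i]] <- data.frame(i = i, j = js[keep], dist = d[keep])
    }
  }
  out <- do.call(rbind, res_i)
  if (is.null(out)) return(empty)
  out[order(out$i, out$j), , drop = FALSE]
}

# Evaluate a function with a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
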