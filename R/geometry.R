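## Cartesian geometry primitives.  All lengths in Angstrom, angles in
## degrees at the interfaces (radians only inside formulas).

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(v) sqrt(sum(v * v))

#' Bond angle between three atoms
#'
#' @param p1,p2,p3 length-3 Cartesian positions; the angle is at `p2`.
#' @return angle in degrees in `[0, 180]`.
#' @export
bond_angle <- function(p1, p2, p3) {
  u <- p1 - p2
  v <- p3 - p2
  cosa <- sum(u * v) / (vnorm(u) * vnorm(v))
  cosa <- max(-1, min(1, cosa))
  acos(cosa) * 180 / pi
}

#' Signed dihedral angle of four atoms
#'
#' IUPAC sign convention: looking down the `p2 -> p3` bond, a clockwise
#' rotation of the far bond relative to the near bond is positive.  The
#' value is normalized to `[0, 360)`.
#'
#' @param p1,p2,p3,p4 length-3 Cartesian positions of the bonded quadruple.
#' @return dihedral angle in degrees in `[0, 360)`.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10) {
    stop("degenerate dihedral frame: three colinear reference atoms")
  }
  m1 <- cross3(n1, b2 / vnorm(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  normalize_angle(atan2(y, x) * 180 / pi)
}

## place atom D with bond length r to A, angle theta D-A-B, dihedral phi
## D-A-B-C (degrees); errors out when A, B, C are colinear.
place_atom <- function(A, B, C, r, theta, phi) {
  th <- theta * pi / 180
  ph <- phi * pi / 180
  ab <- A - B
  bc <- B - C
  nab <- vnorm(ab)
  if (nab < 1e-10) stop("degenerate frame: coincident reference atoms")
  u <- ab / nab
  n <- cross3(bc, ab)
  nn <- vnorm(n)
  if (nn < 1e-10) stop("degenerate dihedral frame: colinear reference atoms")
  n <- n / nn
  m <- cross3(n, u)
  # local displacement: along -u for theta = 180 (extended chain)
  d_loc <- r * c(-cos(th), sin(th) * cos(ph), -sin(th) * sin(ph))
  A + d_loc[1] * u + d_loc[2] * m + d_loc[3] * n
}

#' Bond perception through covalent radii
#'
#' Builds the 0/1 adjacency (connectivity) matrix of a geometry: atoms i and
#' j are bonded when their distance is below `k_bond` times the sum of their
#' covalent radii (Cordero single-bond radii bundled with the package).
#' The matrix is the fingerprint used by the connectivity test to discard
#' strained or rearranged guess geometries.
#'
#' @param cart N x 3 Cartesian coordinates, Angstrom.
#' @param elements character vector of element symbols, length N.
#' @param k_bond dimensionless scale factor for the bonding threshold.
#' @return N x N symmetric 0/1 integer matrix with zero diagonal.
#' @examples
#' perceive_adjacency(rbind(c(0, 0, 0), c(0.74, 0, 0)), c("H", "H"))
#' @export
perceive_adjacency <- function(cart, elements, k_bond = 1.3) {
  cart <- as.matrix(cart)
  n <- nrow(cart)
  stopifnot(length(elements) == n)
  radii <- element_radius(elements)
  A <- matrix(0L, n, n)
  if (n > 1) {
    d <- as.matrix(stats::dist(cart))
    thr <- outer(radii, radii, `+`) * k_bond
    A[d < thr] <- 1L
    diag(A) <- 0L
  }
  A
}

#' Principal moments of inertia
#'
#' Eigenvalues of the inertia tensor about the center of mass, sorted
#' ascending, in amu Angstrom^2.
#'
#' @param cart N x 3 Cartesian coordinates, Angstrom.
#' @param masses atomic masses, amu.
#' @return numeric length-3 vector, ascending, all non-negative.
#' @export
principal_moments <- function(cart, masses) {
  cart <- as.matrix(cart)
  stopifnot(nrow(cart) == length(masses))
  com <- colSums(cart * masses) / sum(masses)
  x <- sweep(cart, 2, com)
  I <- matrix(0, 3, 3)
  r2 <- rowSums(x^2)
  for (k in 1:3) for (l in 1:3) {
    I[k, l] <- sum(masses * ((k == l) * r2 - x[, k] * x[, l]))
  }
  ev <- sort(eigen(I, symmetric = TRUE, only.values = TRUE)$values)
  pmax(ev, 0)
}

## mirror a geometry through the xy plane (z -> -z); negates all dihedrals
mirror_cartesian <- function(cart) {
  cart <- as.matrix(cart)
  cart[, 3] <- -cart[, 3]
  cart
}

#' Write geometries in XYZ format
#'
#' Standard XYZ: atom count, comment line, then `element x y z` rows in
#' Angstrom.  A list of geometries produces a multi-frame trajectory file.
#'
#' @param cart N x 3 matrix or a list of such matrices.
#' @param elements element symbols, length N.
#' @param path output file path.
#' @param comment one comment string per frame (recycled).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(cart, elements, path, comment = "") {
  frames <- if (is.list(cart)) cart else list(cart)
  comment <- rep_len(comment, length(frames))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(frames)) {
    m <- as.matrix(frames[[f]])
    writeLines(c(
      as.character(nrow(m)),
      comment[f],
      sprintf("%-3s %14.8f %14.8f %14.8f", elements, m[, 1], m[, 2], m[, 3])
    ), con)
  }
  invisible(path)
}

#' Read an XYZ file
#'
#' @param path file written by [write_xyz()] (or any standard XYZ file).
#' @return list with `elements` and `frames` (list of N x 3 matrices).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  elements <- NULL
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- as.integer(trimws(lines[i]))
    block <- lines[(i + 2):(i + 1 + n)]
    toks <- strsplit(trimws(block), "\\s+")
    elements <- vapply(toks, `[[`, "", 1)
    xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
    frames[[length(frames) + 1]] <- xyz
    i <- i + 2 + n
  }
  list(elements = elements, frames = frames)
}
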