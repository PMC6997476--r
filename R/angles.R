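#' Normalize angles to the canonical torsional range
#'
#' Torsional points live on the t-dimensional torus; every angle is stored
#' in degrees in `[0, 360)`.
#'
#' @param phi numeric vector of angles in degrees.
#' @return numeric vector with each component reduced modulo 360 into
#'   `[0, 360)`.
#' @examples
#' normalize_angle(c(-60, 360, 725.5))
#' @export
normalize_angle <- function(phi) {
  x <- phi %% 360
  # guard against 360 - eps rounding up to exactly 360 after %%
  x[x >= 360] <- 0
  x
}

#' Circular distance between two angles
#'
#' Shortest arc between two angles on the circle, in degrees.  This is the
#' metric used by the similarity and redundancy tests, so that e.g. 355 and
#' 5 degrees are recognized as 10 degrees apart rather than 350.
#'
#' @param a,b angles in degrees (vectors recycle).
#' @return distances in `[0, 180]`.
#' @examples
#' circular_distance(100, 60)  # 40
#' circular_distance(355, 5)   # 10
#' @export
circular_distance <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

# signed wrapped difference a - b in (-180, 180]
signed_angle_diff <- function(a, b) {
  d <- (a - b) %% 360
  d[d > 180] <- d[d > 180] - 360
  d
}

#' Conformational enantiomer of a torsional point
#'
#' The mirror image of a conformer of a molecule with a plane of symmetry is
#' reached by negating every torsion: each dihedral phi becomes
#' `360 - phi` (modulo 360).  Applying the operator twice is the identity.
#'
#' @param phi torsional point, degrees.
#' @return the enantiomeric torsional point, normalized to `[0, 360)`.
#' @examples
#' enantiomer(c(180, 60, 300))  # c(180, 300, 60)
#' @export
enantiomer <- function(phi) {
  normalize_angle(360 - normalize_angle(phi))
}

#' Is a torsional point its own enantiomer?
#'
#' @param phi torsional point, degrees.
#' @param tol per-torsion circular tolerance in degrees.
#' @return logical scalar.
#' @export
is_self_enantiomeric <- function(phi, tol = 1e-6) {
  all(circular_distance(normalize_angle(phi), enantiomer(phi)) <= tol)
}

#' Canonical representative of an enantiomer pair
#'
#' Returns the lexicographically smaller of a torsional point and its
#' enantiomer, comparing angle tuples component by component.  Used to keep
#' exactly one member of each pair during the symmetry-reduced systematic
#' enumeration.
#'
#' @param phi torsional point, degrees.
#' @return the canonical member of `{phi, enantiomer(phi)}`.
#' @export
canonical_representative <- function(phi) {
  a <- normalize_angle(phi)
  b <- enantiomer(phi)
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(a)
    if (b[i] < a[i]) return(b)
  }
  a
}
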