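#' Screening-test reports
#'
#' Every acceptance test returns a small report object recording the test
#' name, the verdict and a human-readable reason (mandatory on failure),
#' which the search appends to its run log.
#'
#' @param test one of `"connectivity"`, `"similarity"`, `"redundancy"`,
#'   `"hessian"`.
#' @param passed logical verdict.
#' @param detail reason string; must be non-empty when `passed` is `FALSE`.
#' @return object of class `tors_test_report`.
#' @keywords internal
test_report <- function(test, passed, detail = "") {
  if (!passed && !nzchar(detail)) stop("failing report requires a detail")
  structure(list(test = test, passed = passed, detail = detail),
            class = "tors_test_report")
}

#' @export
print.tors_test_report <- function(x, ...) {
  cat(sprintf("[%s] %s%s\n", x$test, if (x$passed) "pass" else "FAIL",
              if (nzchar(x$detail)) paste0(" - ", x$detail) else ""))
  invisible(x)
}

## index of the first stored point whose hypercube of half-edge d captures
## phi (all torsions within d, circular metric); 0 if phi escapes them all
first_capturing_point <- function(phi, stored, d) {
  for (p in seq_along(stored)) {
    if (all(circular_distance(phi, stored[[p]]) <= d)) return(p)
  }
  0L
}

#' Connectivity test
#'
#' A geometry is chemically intact when its adjacency matrix equals the
#' reference one: this discards guesses with superimposed atoms, broken
#' bonds or spurious new contacts.
#'
#' @param A_ref,A_guess adjacency matrices over the same atom ordering.
#' @return a test report; passes iff the matrices are identical.
#' @export
connectivity_test <- function(A_ref, A_guess) {
  if (!all(dim(A_ref) == dim(A_guess))) {
    stop("adjacency matrices have different dimensions: ",
         nrow(A_ref), " vs ", nrow(A_guess), " atoms")
  }
  diff <- which(A_ref != A_guess, arr.ind = TRUE)
  if (nrow(diff) == 0) {
    test_report("connectivity", TRUE)
  } else {
    i <- diff[1, 1]; j <- diff[1, 2]
    test_report("connectivity", FALSE,
                sprintf("connectivity differs from reference at atom pair (%d, %d)%s",
                        i, j,
                        if (nrow(diff) > 2) sprintf(" and %d more", nrow(diff) / 2 - 1) else ""))
  }
}

#' Similarity test
#'
#' A guess torsional point is worth optimizing only if it escapes the
#' hypercube of half-edge `d` around every stored point: for each stored
#' point there must exist at least one torsion further than `d` away
#' (circular metric).  An empty pool accepts everything.
#'
#' @param phi_g guess torsional point, degrees.
#' @param stored list of stored torsional points.
#' @param d hypercube half-edge, degrees (`>= 0`; 0 degenerates to exact
#'   coincidence in all components).
#' @return a test report.
#' @export
similarity_test <- function(phi_g, stored, d) {
  stopifnot(d >= 0)
  cap <- first_capturing_point(normalize_angle(phi_g), stored, d)
  if (cap == 0L) {
    test_report("similarity", TRUE)
  } else {
    test_report("similarity", FALSE,
                sprintf("inside hypercube (half-edge %g deg) of stored point %d",
                        d, cap))
  }
}

#' Redundancy test
#'
#' An optimized geometry is a candidate new conformer only if it does not
#' coincide, within `eps_red` in every torsion, with an already accepted
#' equilibrium structure.  Enantiomers are distinct torsional points and
#' are not folded together here.
#'
#' @param phi_opt optimized torsional point, degrees.
#' @param equilibria list of accepted equilibrium torsional points.
#' @param eps_red coincidence tolerance per torsion, degrees (`> 0`).
#' @return a test report; passes when the point is new.
#' @export
redundancy_test <- function(phi_opt, equilibria, eps_red = 3) {
  stopifnot(eps_red > 0)
  cap <- first_capturing_point(normalize_angle(phi_opt), equilibria, eps_red)
  if (cap == 0L) {
    test_report("redundancy", TRUE)
  } else {
    test_report("redundancy", FALSE,
                sprintf("duplicate of equilibrium structure %d (within %g deg)",
                        cap, eps_red))
  }
}

#' Hessian test
#'
#' Mass-weights a Cartesian Hessian, projects out the three translational
#' and three rotational directions (five for linear geometries, detected by
#' a principal moment below 1e-6 amu Angstrom^2), diagonalizes, and accepts
#' the geometry as a true minimum iff all remaining vibrational wavenumbers
#' exceed `-eps_freq` (a small negative tolerance absorbing
#' finite-difference noise).  On success the harmonic wavenumbers are
#' attached to the report.
#'
#' @param hessian symmetric 3N x 3N matrix, kcal/mol/Angstrom^2.
#' @param cart N x 3 Cartesian coordinates, Angstrom.
#' @param masses atomic masses, amu.
#' @param eps_freq wavenumber tolerance, cm^-1.
#' @return a test report; on pass, field `frequencies` holds the 3N-6
#'   (3N-5 linear) harmonic wavenumbers in cm^-1, ascending.
#' @export
hessian_test <- function(hessian, cart, masses, eps_freq = 5) {
  cart <- as.matrix(cart)
  n <- nrow(cart)
  if (!isTRUE(all.equal(hessian, t(hessian), tolerance = 1e-7))) {
    stop("Hessian matrix is not symmetric")
  }
  invsqm <- rep(1 / sqrt(masses), each = 3)
  Hmw <- hessian * outer(invsqm, invsqm)

  # translation / rotation basis in mass-weighted coordinates
  com <- colSums(cart * masses) / sum(masses)
  xc <- sweep(cart, 2, com)
  sqm <- sqrt(masses)
  D <- matrix(0, 3 * n, 6)
  for (k in 1:3) D[seq(k, 3 * n, by = 3), k] <- sqm
  axes <- diag(3)
  for (k in 1:3) {
    rot <- t(vapply(seq_len(n), function(a)
      sqm[a] * cross3(axes[k, ], xc[a, ]), numeric(3)))
    D[, 3 + k] <- as.vector(t(rot))
  }
  linear <- n > 1 && principal_moments(cart, masses)[1] < 1e-6
  n_tr <- if (n == 1) 3 else if (linear) 5 else 6
  keep <- colSums(D^2) > 1e-10
  D <- D[, keep, drop = FALSE]
  Q <- qr.Q(qr(D))[, seq_len(min(n_tr, ncol(D))), drop = FALSE]
  P <- diag(3 * n) - Q %*% t(Q)
  Hp <- P %*% Hmw %*% P
  ev <- eigen((Hp + t(Hp)) / 2, symmetric = TRUE, only.values = TRUE)$values
  # drop the projected-out near-zero modes
  ord <- order(abs(ev))
  vib <- sort(ev[ord[-seq_len(min(n_tr, length(ev)))]])
  wavenumbers <- sign(vib) * .const$freq_factor * sqrt(abs(vib))
  if (length(wavenumbers) == 0 || all(wavenumbers > -eps_freq)) {
    rep <- test_report("hessian", TRUE)
    rep$frequencies <- wavenumbers
    rep
  } else {
    rep <- test_report("hessian", FALSE,
                       sprintf("%d imaginary frequenc%s (lowest %.1f cm^-1): not a minimum",
                               sum(wavenumbers <= -eps_freq),
                               if (sum(wavenumbers <= -eps_freq) == 1) "y" else "ies",
                               min(wavenumbers)))
    rep$frequencies <- wavenumbers
    rep
  }
}

#' Guess-geometry test battery
#'
#' A guess must pass the connectivity test and then the similarity test,
#' in that order and short-circuiting, before it is promoted to a trial
#' geometry.
#'
#' @param phi_g guess torsional point, degrees.
#' @param cart guess Cartesian geometry.
#' @param context list with `A_ref`, `elements`, `k_bond`,
#'   `similarity_pool` (list of stored torsional points) and `d`.
#' @return list with `accepted` (logical) and `reports`.
#' @export
run_guess_battery <- function(phi_g, cart, context) {
  reports <- list()
  A_g <- perceive_adjacency(cart, context$elements, context$k_bond)
  r1 <- connectivity_test(context$A_ref, A_g)
  reports <- c(reports, list(r1))
  if (!r1$passed) return(list(accepted = FALSE, reports = reports))
  r2 <- similarity_test(phi_g, context$similarity_pool, context$d)
  reports <- c(reports, list(r2))
  list(accepted = r2$passed, reports = reports)
}

#' Optimized-geometry test battery
#'
#' An optimized trial must pass connectivity, then redundancy, then the
#' Hessian test, in that exact order and short-circuiting: the Hessian is
#' only ever computed after the two cheap tests have passed, so no time is
#' lost diagonalizing duplicates or broken geometries.
#'
#' @param phi_opt optimized torsional point, degrees.
#' @param cart_opt optimized Cartesian geometry.
#' @param context list with `A_ref`, `elements`, `k_bond`, `equilibria`
#'   (list of accepted torsional points), `eps_red`, `eps_freq`, `masses`
#'   and `backend` (for the Hessian).
#' @return list with `accepted`, `reports`, and on acceptance
#'   `frequencies` (cm^-1).
#' @export
run_optimized_battery <- function(phi_opt, cart_opt, context) {
  reports <- list()
  A_o <- perceive_adjacency(cart_opt, context$elements, context$k_bond)
  r1 <- connectivity_test(context$A_ref, A_o)
  reports <- c(reports, list(r1))
  if (!r1$passed) return(list(accepted = FALSE, reports = reports))
  r2 <- redundancy_test(phi_opt, context$equilibria, context$eps_red)
  reports <- c(reports, list(r2))
  if (!r2$passed) return(list(accepted = FALSE, reports = reports))
  H <- pes_hessian(context$backend, cart_opt)
  r3 <- hessian_test(H, cart_opt, context$masses, context$eps_freq)
  reports <- c(reports, list(r3))
  list(accepted = r3$passed, reports = reports,
       frequencies = if (r3$passed) r3$frequencies)
}
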