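#' Potential-energy-surface backend contract
#'
#' A backend bundles the electronic-structure-like capabilities the search
#' needs: `energy` (kcal/mol), optionally `gradient` (kcal/mol/Angstrom),
#' optionally an analytic `hessian`.  The search only ever talks to this
#' contract, so the bundled analytic model potentials and an external
#' quantum-chemistry program are interchangeable.  Units are fixed at the
#' contract boundary: kcal/mol and Angstrom.
#'
#' @param name backend name (recorded in run metadata).
#' @param energy function(cart) -> scalar energy.
#' @param gradient function(cart) -> N x 3 gradient, or `NULL`.
#' @param hessian function(cart) -> 3N x 3N matrix, or `NULL` (a
#'   finite-difference Hessian is used instead).
#' @param meta free-form list of backend parameters (recorded for
#'   reproducibility; the toy backends expose their torsional terms here).
#' @return an object of class `pes_backend`.
#' @export
pes_backend <- function(name, energy, gradient = NULL, hessian = NULL,
                        meta = list()) {
  stopifnot(is.function(energy))
  structure(list(name = name, energy = energy, gradient = gradient,
                 hessian = hessian, meta = meta,
                 units = c(energy = "kcal/mol", length = "Angstrom")),
            class = "pes_backend")
}

#' @export
print.pes_backend <- function(x, ...) {
  caps <- c("energy",
            if (!is.null(x$gradient)) "gradient",
            if (!is.null(x$hessian)) "hessian(analytic)")
  cat("PES backend '", x$name, "': ", paste(caps, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Evaluate backend energy
#' @param backend a [pes_backend()].
#' @param cart N x 3 Cartesian coordinates, Angstrom.
#' @return energy in kcal/mol.
#' @export
pes_energy <- function(backend, cart) backend$energy(as.matrix(cart))

#' Evaluate backend gradient
#' @inheritParams pes_energy
#' @return N x 3 gradient in kcal/mol/Angstrom.
#' @export
pes_gradient <- function(backend, cart) {
  if (is.null(backend$gradient)) {
    stop("backend '", backend$name, "' does not support gradients")
  }
  backend$gradient(as.matrix(cart))
}

#' Hessian matrix of a backend
#'
#' Analytic when the backend provides one; otherwise central finite
#' differences of the analytic gradient (step `step` Angstrom), symmetrized
#' as `(H + t(H))/2`.
#'
#' @inheritParams pes_energy
#' @param step finite-difference displacement, Angstrom.
#' @return 3N x 3N symmetric matrix, kcal/mol/Angstrom^2 (row-major atom
#'   blocks: x1, y1, z1, x2, ...).
#' @export
pes_hessian <- function(backend, cart, step = 1e-4) {
  cart <- as.matrix(cart)
  if (!is.null(backend$hessian)) {
    H <- backend$hessian(cart)
  } else {
    if (is.null(backend$gradient)) {
      stop("backend '", backend$name,
           "' supports neither hessian nor gradient")
    }
    n <- nrow(cart)
    H <- matrix(0, 3 * n, 3 * n)
    for (a in seq_len(n)) for (k in 1:3) {
      col <- 3 * (a - 1) + k
      xp <- cart; xp[a, k] <- xp[a, k] + step
      xm <- cart; xm[a, k] <- xm[a, k] - step
      H[, col] <- (as.vector(t(backend$gradient(xp))) -
                     as.vector(t(backend$gradient(xm)))) / (2 * step)
    }
  }
  (H + t(H)) / 2
}

## ---- analytic chain model potential ----------------------------------

## internal-coordinate term lists derived from a Z-matrix: every atom's
## bond/angle reference defines a harmonic restraint at its frozen value;
## the declared target torsions carry the torsional terms.
chain_terms_from_zmatrix <- function(zm) {
  n <- length(zm$elements)
  bonds <- angles <- NULL
  if (n >= 2) {
    bonds <- do.call(rbind, lapply(2:n, function(a)
      c(a, zm$ref[a, 1], zm$values[a, 1])))
  }
  if (n >= 3) {
    angles <- do.call(rbind, lapply(3:n, function(a)
      c(a, zm$ref[a, 1], zm$ref[a, 2], zm$values[a, 2])))
  }
  tors <- lapply(seq_along(zm$torsions), function(k) {
    i <- zm$torsion_atom[k]
    c(i, zm$ref[i, 1], zm$ref[i, 2], zm$ref[i, 3])
  })
  list(bonds = bonds, angles = angles, torsion_atoms = tors)
}

## per-torsion potential in degrees: cosine series + optional localized
## Gaussian wells.  Returns V (kcal/mol) and dV/dphi in kcal/mol/deg.
torsion_term_eval <- function(phi_deg, terms, wells) {
  V <- 0; dVdeg <- 0
  if (!is.null(terms) && nrow(terms) > 0) {
    arg <- (terms$mult * phi_deg - terms$phase) * pi / 180
    V <- V + sum(terms$amp * (1 + cos(arg)))
    # d/dphi_deg
    dVdeg <- dVdeg + sum(-terms$amp * terms$mult * sin(arg)) * pi / 180
  }
  if (!is.null(wells) && nrow(wells) > 0) {
    delta <- signed_angle_diff(phi_deg, wells$center)
    g <- exp(-(delta / wells$width)^2)
    V <- V - sum(wells$depth * g)
    dVdeg <- dVdeg + sum(wells$depth * g * 2 * delta / wells$width^2)
  }
  c(V, dVdeg)
}

#' Analytic model potential for a chain molecule
#'
#' A transparent stand-in for an electronic-structure surface, rich enough
#' to exercise the whole search loop: harmonic restraints hold every bond
#' length and bond angle at its Z-matrix reference value, while each
#' declared target torsion carries a periodic potential given as a cosine
#' series `sum_k amp_k * (1 + cos(mult_k * phi - phase_k))` plus optional
#' localized Gaussian wells `-depth * exp(-(dphi/width)^2)` (all angles in
#' degrees, energies kcal/mol).  With all phases 0 or 180 and no off-center
#' wells the surface is mirror symmetric, `V(Phi) = V(-Phi)`, so
#' conformational enantiomers are exactly isoenergetic.  Energy and
#' gradient are analytic; the gradient is assembled by the chain rule
#' through the standard derivatives of bond lengths, angles and dihedrals
#' with respect to Cartesians.
#'
#' @param zm a [zmatrix()]; its frozen values define the restraint minima.
#' @param torsion_terms list of length `t`; element `k` is a data frame
#'   with columns `amp`, `mult`, `phase` (degrees) for torsion `k`.
#' @param torsion_wells optional list of length `t` of data frames with
#'   columns `depth`, `center`, `width` (degrees); `NULL` entries allowed.
#' @param k_bond harmonic bond force constant, kcal/mol/Angstrom^2.
#' @param k_angle harmonic angle force constant, kcal/mol/rad^2.
#' @return a [pes_backend()] with analytic energy and gradient; the term
#'   parameters are exposed in `$meta` for reproducibility records.
#' @export
toy_chain_pes <- function(zm, torsion_terms, torsion_wells = NULL,
                          k_bond = 300, k_angle = 60) {
  t <- n_torsions(zm)
  stopifnot(length(torsion_terms) == t)
  if (is.null(torsion_wells)) torsion_wells <- vector("list", t)
  stopifnot(length(torsion_wells) == t)
  geom <- chain_terms_from_zmatrix(zm)

  eval_all <- function(cart, want_grad) {
    cart <- as.matrix(cart)
    V <- 0
    G <- if (want_grad) matrix(0, nrow(cart), 3) else NULL
    b <- geom$bonds
    if (!is.null(b)) for (r in seq_len(nrow(b))) {
      i <- b[r, 1]; j <- b[r, 2]; r0 <- b[r, 3]
      dv <- cart[i, ] - cart[j, ]
      d <- vnorm(dv)
      V <- V + k_bond * (d - r0)^2
      if (want_grad) {
        g <- 2 * k_bond * (d - r0) * dv / d
        G[i, ] <- G[i, ] + g
        G[j, ] <- G[j, ] - g
      }
    }
    a <- geom$angles
    if (!is.null(a)) for (r in seq_len(nrow(a))) {
      i <- a[r, 1]; j <- a[r, 2]; k <- a[r, 3]
      th0 <- a[r, 4] * pi / 180
      u <- cart[i, ] - cart[j, ]
      v <- cart[k, ] - cart[j, ]
      nu <- vnorm(u); nv <- vnorm(v)
      cth <- max(-1, min(1, sum(u * v) / (nu * nv)))
      th <- acos(cth)
      V <- V + k_angle * (th - th0)^2
      if (want_grad) {
        sth <- sqrt(max(1 - cth^2, 1e-12))
        dthi <- (cth * u / nu - v / nv) / (nu * sth)
        dthk <- (cth * v / nv - u / nu) / (nv * sth)
        pref <- 2 * k_angle * (th - th0)
        G[i, ] <- G[i, ] + pref * dthi
        G[k, ] <- G[k, ] + pref * dthk
        G[j, ] <- G[j, ] - pref * (dthi + dthk)
      }
    }
    for (k in seq_len(t)) {
      at <- geom$torsion_atoms[[k]]
      p1 <- cart[at[1], ]; p2 <- cart[at[2], ]
      p3 <- cart[at[3], ]; p4 <- cart[at[4], ]
      phi <- dihedral_angle(p1, p2, p3, p4)
      vd <- torsion_term_eval(phi, torsion_terms[[k]], torsion_wells[[k]])
      V <- V + vd[1]
      if (want_grad && vd[2] != 0) {
        dVdrad <- vd[2] * 180 / pi
        # Blondel-Karplus dihedral derivatives, adapted to this package's
        # sign convention (positive phi = clockwise looking down p2 -> p3)
        b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
        m <- cross3(b1, b2); n <- cross3(b2, b3)
        nb2 <- vnorm(b2)
        mm <- sum(m * m); nn <- sum(n * n)
        s12 <- sum(b1 * b2) / (mm * nb2)
        s32 <- sum(b3 * b2) / (nn * nb2)
        dp1 <- nb2 / mm * m
        dp4 <- -nb2 / nn * n
        dp2 <- -dp1 - s12 * m - s32 * n
        dp3 <- -dp4 + s12 * m + s32 * n
        G[at[1], ] <- G[at[1], ] + dVdrad * dp1
        G[at[2], ] <- G[at[2], ] + dVdrad * dp2
        G[at[3], ] <- G[at[3], ] + dVdrad * dp3
        G[at[4], ] <- G[at[4], ] + dVdrad * dp4
      }
    }
    list(V = V, G = G)
  }

  pes_backend(
    name = "toy_chain",
    energy = function(cart) eval_all(cart, FALSE)$V,
    gradient = function(cart) eval_all(cart, TRUE)$G,
    meta = list(torsion_terms = torsion_terms,
                torsion_wells = torsion_wells,
                k_bond = k_bond, k_angle = k_angle))
}

#' Quadratic test potential
#'
#' `V(x) = 0.5 * (x - x0)' H (x - x0)` over flattened coordinates, with
#' analytic gradient and constant analytic Hessian.  Used to validate the
#' Hessian machinery against a known matrix.
#'
#' @param H symmetric 3N x 3N matrix, kcal/mol/Angstrom^2.
#' @param center N x 3 matrix, the stationary point.
#' @return a [pes_backend()].
#' @export
quadratic_pes <- function(H, center) {
  center_v <- as.vector(t(as.matrix(center)))
  n <- nrow(as.matrix(center))
  pes_backend(
    name = "quadratic",
    energy = function(cart) {
      d <- as.vector(t(as.matrix(cart))) - center_v
      0.5 * sum(d * (H %*% d))
    },
    gradient = function(cart) {
      d <- as.vector(t(as.matrix(cart))) - center_v
      matrix(as.vector(H %*% d), n, 3, byrow = TRUE)
    },
    hessian = function(cart) H)
}

#' Local geometry optimization
#'
#' Quasi-Newton (BFGS) minimization of the backend energy with all
#' Cartesian degrees of freedom free (full relaxation).  Convergence is
#' declared when the largest gradient component falls below `gtol`; the
#' optimizer is restarted (rebuilding its curvature estimate) until that
#' criterion or the restart budget is met.
#'
#' @param backend a [pes_backend()] with gradient capability.
#' @param cart starting geometry, N x 3 Angstrom.
#' @param gtol convergence threshold on `max |dV/dx|`, kcal/mol/Angstrom.
#' @param maxit BFGS iterations per restart.
#' @param restarts maximum number of BFGS restarts.
#' @return list with `cart`, `energy`, `converged`, `max_grad`.
#' @export
optimize_geometry <- function(backend, cart, gtol = 1e-6, maxit = 500,
                              restarts = 6) {
  if (is.null(backend$gradient)) {
    stop("backend '", backend$name, "' does not support gradients")
  }
  cart <- as.matrix(cart)
  n <- nrow(cart)
  fn <- function(x) backend$energy(matrix(x, n, 3, byrow = TRUE))
  gr <- function(x) as.vector(t(backend$gradient(matrix(x, n, 3,
                                                        byrow = TRUE))))
  x <- as.vector(t(cart))
  for (k in seq_len(restarts)) {
    res <- stats::optim(x, fn, gr, method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-16))
    x <- res$par
    mg <- max(abs(gr(x)))
    if (mg < gtol) break
  }
  out <- matrix(x, n, 3, byrow = TRUE)
  mg <- max(abs(gr(x)))
  list(cart = out, energy = fn(x), converged = mg < gtol, max_grad = mg)
}

#' Adapter for an external electronic-structure program
#'
#' Builds a [pes_backend()] whose energy is obtained by templating an input
#' file, running a user-supplied command on it and parsing the output.  No
#' quantum-chemistry driver ships with the package; this is the hook
#' through which real low-level/high-level calculations plug into the
#' search.  The template may use the placeholders `{natoms}` and `{coords}`
#' (the latter expands to `element x y z` rows).
#'
#' @param command path to the executable; invoked as `command input_file`.
#' @param template input-file template string with placeholders.
#' @param parser function(character lines) -> energy in kcal/mol; must
#'   raise an error (with the raw output attached) on unparseable output.
#' @param elements element symbols of the molecule the adapter serves.
#' @param name backend name.
#' @return a [pes_backend()] with energy capability only.
#' @export
external_pes_adapter <- function(command, template, parser, elements,
                                 name = "external") {
  render <- function(cart) {
    cart <- as.matrix(cart)
    coords <- paste(sprintf("%-3s %14.8f %14.8f %14.8f",
                            elements, cart[, 1], cart[, 2], cart[, 3]),
                    collapse = "\n")
    out <- gsub("{natoms}", as.character(nrow(cart)), template, fixed = TRUE)
    gsub("{coords}", coords, out, fixed = TRUE)
  }
  pes_backend(
    name = name,
    energy = function(cart) {
      inp <- tempfile(fileext = ".inp")
      on.exit(unlink(inp))
      writeLines(render(cart), inp)
      raw <- tryCatch(
        suppressWarnings(system2(command, shQuote(inp), stdout = TRUE,
                                 stderr = TRUE)),
        error = function(e) stop("external backend '", name,
                                 "' failed to run: ", conditionMessage(e)))
      val <- tryCatch(parser(raw), error = function(e) {
        stop("external backend '", name, "' output not parseable: ",
             conditionMessage(e), "\n--- raw output ---\n",
             paste(raw, collapse = "\n"))
      })
      if (!is.numeric(val) || length(val) != 1 || !is.finite(val)) {
        stop("external backend '", name, "' parser returned a non-scalar",
             "\n--- raw output ---\n", paste(raw, collapse = "\n"))
      }
      val
    },
    meta = list(command = command))
  }

## expose the template renderer for tests of the adapter
render_external_input <- function(template, elements, cart) {
  cart <- as.matrix(cart)
  coords <- paste(sprintf("%-3s %14.8f %14.8f %14.8f",
                          elements, cart[, 1], cart[, 2], cart[, 3]),
                  collapse = "\n")
  out <- gsub("{natoms}", as.character(nrow(cart)), template, fixed = TRUE)
  gsub("{coords}", coords, out, fixed = TRUE)
}
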