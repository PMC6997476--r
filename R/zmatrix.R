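#' Z-matrix molecular template
#'
#' Internal-coordinate description of a molecule: for each atom an element
#' symbol plus references to previously defined atoms together with a bond
#' length (Angstrom), bond angle and dihedral angle (degrees).  A subset of
#' the dihedral entries is declared as the `t` target torsions; these are
#' the coordinates of the conformational search, and each target torsion
#' must be carried by exactly one dihedral slot so the torsional point of
#' any geometry is defined unambiguously.
#'
#' @param elements character vector of element symbols (construction order).
#' @param ref integer N x 3 matrix of reference-atom indices (`NA` where the
#'   slot does not apply: atom 1 has none, atom 2 a bond only, atom 3 bond
#'   and angle).
#' @param values numeric N x 3 matrix of internal coordinates (bond length,
#'   angle, dihedral); `NA` in unused slots.
#' @param varnames character N x 3 matrix naming the variable carried by
#'   each slot (`NA` for literal values).
#' @param torsions character vector of dihedral variable names flagged as
#'   target torsions (in torsional-point order).
#' @return an object of class `zmatrix` with fields `elements`, `ref`,
#'   `values`, `varnames`, `torsions`, `torsion_atom` (the atom row carrying
#'   each target torsion) and `masses` (amu).
#' @seealso [read_zmatrix()], [make_chain_fixture()], [zmatrix_to_cartesian()]
#' @export
zmatrix <- function(elements, ref, values, varnames, torsions) {
  n <- length(elements)
  ref <- matrix(as.integer(ref), n, 3)
  values <- matrix(as.numeric(values), n, 3)
  varnames <- matrix(as.character(varnames), n, 3)
  if (n < 1) stop("empty Z-matrix")
  needed <- pmin(0:(n - 1), 3)   # slots required per atom row
  for (i in seq_len(n)) {
    k <- needed[i]
    if (k > 0 && (anyNA(ref[i, seq_len(k)]) || anyNA(values[i, seq_len(k)]))) {
      stop("atom ", i, ": missing internal coordinate or reference")
    }
    if (k > 0 && any(ref[i, seq_len(k)] >= i | ref[i, seq_len(k)] < 1)) {
      stop("atom ", i, ": reference atoms must be previously defined")
    }
    if (k > 0 && anyDuplicated(ref[i, seq_len(k)])) {
      stop("atom ", i, ": repeated reference atom")
    }
    if (k > 0 && (values[i, 1] <= 0)) {
      stop("atom ", i, ": non-positive bond length")
    }
    if (k > 1 && (values[i, 2] <= 0 || values[i, 2] >= 180)) {
      stop("atom ", i, ": bond angle must lie in (0, 180) degrees")
    }
  }
  if (length(torsions) < 1) stop("at least one target torsion is required")
  torsion_atom <- integer(length(torsions))
  for (k in seq_along(torsions)) {
    hits <- which(!is.na(varnames[, 3]) & varnames[, 3] == torsions[k])
    if (length(hits) == 0) {
      stop("target torsion '", torsions[k], "' not found in any dihedral slot")
    }
    if (length(hits) > 1) {
      stop("target torsion '", torsions[k],
           "' is ambiguous: declared on atom lines ",
           paste(hits, collapse = ", "))
    }
    torsion_atom[k] <- hits
  }
  structure(
    list(elements = elements, ref = ref, values = values,
         varnames = varnames, torsions = torsions,
         torsion_atom = torsion_atom, masses = element_mass(elements)),
    class = "zmatrix")
}

#' @export
print.zmatrix <- function(x, ...) {
  cat("Z-matrix:", length(x$elements), "atoms,",
      length(x$torsions), "target torsion(s):",
      paste(x$torsions, collapse = ", "), "\n")
  invisible(x)
}

#' Number of target torsions of a Z-matrix
#' @param zm a [zmatrix()].
#' @return integer `t`.
#' @export
n_torsions <- function(zm) length(zm$torsions)

#' Reference torsional point of a Z-matrix
#'
#' The torsional point of the reference geometry, i.e. the values stored in
#' the target-torsion slots.
#'
#' @param zm a [zmatrix()].
#' @return numeric vector of length `t`, degrees in `[0, 360)`.
#' @export
reference_torsions <- function(zm) {
  normalize_angle(zm$values[cbind(zm$torsion_atom, 3L)])
}

#' Build a Cartesian geometry from a Z-matrix
#'
#' Sequential internal-to-Cartesian construction: atom 1 at the origin,
#' atom 2 along x, atom 3 in the xy plane, every later atom placed from its
#' bond length, bond angle and dihedral angle.  The target-torsion slots are
#' overridden by `phi`; all other internal coordinates keep their frozen
#' reference values.
#'
#' @param zm a [zmatrix()].
#' @param phi torsional point (degrees, length `t`); `NULL` uses the
#'   reference values stored in the Z-matrix.
#' @return N x 3 matrix of Cartesian coordinates, Angstrom.
#' @export
zmatrix_to_cartesian <- function(zm, phi = NULL) {
  n <- length(zm$elements)
  vals <- zm$values
  if (!is.null(phi)) {
    if (length(phi) != length(zm$torsions)) {
      stop("phi has length ", length(phi), ", expected ", length(zm$torsions))
    }
    vals[cbind(zm$torsion_atom, 3L)] <- normalize_angle(phi)
  }
  cart <- matrix(0, n, 3)
  if (n >= 2) {
    A <- cart[zm$ref[2, 1], ]
    cart[2, ] <- A + c(vals[2, 1], 0, 0)
  }
  if (n >= 3) {
    A <- cart[zm$ref[3, 1], ]
    B <- cart[zm$ref[3, 2], ]
    v <- (B - A) / vnorm(B - A)
    w <- c(-v[2], v[1], 0)
    nw <- vnorm(w)
    if (nw < 1e-10) w <- c(0, 1, 0) else w <- w / nw
    th <- vals[3, 2] * pi / 180
    cart[3, ] <- A + vals[3, 1] * (cos(th) * v + sin(th) * w)
  }
  if (n >= 4) {
    for (i in 4:n) {
      cart[i, ] <- place_atom(cart[zm$ref[i, 1], ], cart[zm$ref[i, 2], ],
                              cart[zm$ref[i, 3], ],
                              vals[i, 1], vals[i, 2], vals[i, 3])
    }
  }
  cart
}

#' Measure the target torsions of a Cartesian geometry
#'
#' Returns the signed dihedral angles of the Z-matrix target torsions,
#' measured on `cart` and normalized to `[0, 360)`.  Round-trips with
#' [zmatrix_to_cartesian()].
#'
#' @param cart N x 3 Cartesian coordinates with the same atom order as `zm`.
#' @param zm a [zmatrix()].
#' @return torsional point, numeric vector of length `t`.
#' @export
measure_torsions <- function(cart, zm) {
  cart <- as.matrix(cart)
  if (nrow(cart) != length(zm$elements)) {
    stop("geometry has ", nrow(cart), " atoms, Z-matrix has ",
         length(zm$elements))
  }
  vapply(seq_along(zm$torsions), function(k) {
    i <- zm$torsion_atom[k]
    dihedral_angle(cart[i, ], cart[zm$ref[i, 1], ],
                   cart[zm$ref[i, 2], ], cart[zm$ref[i, 3], ])
  }, numeric(1))
}

#' Read a Gaussian-style Z-matrix file
#'
#' Parses the common Gaussian dialect: one atom per line
#' (`element ref1 val1 ref2 val2 ref3 val3`), values either literal numbers
#' or variable names resolved in a trailing `Variables:` block
#' (`name value` lines).  Target torsions are identified either by the
#' explicit `torsions` argument or by a reserved name prefix.
#'
#' @param path file path.
#' @param torsions character vector naming the target-torsion variables in
#'   torsional-point order; `NULL` selects, in order of appearance, every
#'   dihedral variable whose name starts with `torsion_prefix`.
#' @param torsion_prefix reserved prefix marking torsion variables.
#' @return a [zmatrix()].
#' @export
read_zmatrix <- function(path, torsions = NULL, torsion_prefix = "PHI") {
  if (!file.exists(path)) stop("Z-matrix file not found: ", path)
  raw <- readLines(path)
  lines <- trimws(raw)
  keep <- nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "!")
  idx <- which(keep)
  varstart <- which(toupper(lines) %in% c("VARIABLES:", "VARIABLES"))
  if (length(varstart) > 1) stop("multiple Variables blocks")
  body_idx <- idx[if (length(varstart)) idx < varstart else TRUE]
  var_idx <- if (length(varstart)) idx[idx > varstart] else integer()

  variables <- numeric(0)
  for (i in var_idx) {
    tok <- strsplit(lines[i], "[=[:space:]]+")[[1]]
    tok <- tok[nzchar(tok)]
    v <- suppressWarnings(as.numeric(tok[2]))
    if (length(tok) < 2 || is.na(v)) {
      stop("malformed variable line ", i, ": '", raw[i], "'")
    }
    variables[tok[1]] <- v
  }

  n <- length(body_idx)
  if (n == 0) stop("no atom lines found in ", path)
  elements <- character(n)
  ref <- matrix(NA_integer_, n, 3)
  values <- matrix(NA_real_, n, 3)
  varnames <- matrix(NA_character_, n, 3)
  for (a in seq_len(n)) {
    i <- body_idx[a]
    tok <- strsplit(lines[i], "[,[:space:]]+")[[1]]
    tok <- tok[nzchar(tok)]
    nslots <- min(a - 1, 3)
    if (length(tok) != 1 + 2 * nslots) {
      stop("malformed Z-matrix line ", i, ": '", raw[i], "'")
    }
    elements[a] <- tok[1]
    for (s in seq_len(nslots)) {
      r <- suppressWarnings(as.integer(tok[2 * s]))
      if (is.na(r)) stop("malformed reference index on line ", i)
      ref[a, s] <- r
      vt <- tok[2 * s + 1]
      v <- suppressWarnings(as.numeric(vt))
      if (is.na(v)) {
        sign <- 1
        nm <- vt
        if (startsWith(nm, "-")) { sign <- -1; nm <- substring(nm, 2) }
        if (!nm %in% names(variables)) {
          stop("undefined variable '", vt, "' on line ", i)
        }
        values[a, s] <- sign * variables[nm]
        varnames[a, s] <- nm
      } else {
        values[a, s] <- v
      }
    }
  }
  if (is.null(torsions)) {
    dvars <- varnames[, 3]
    torsions <- unique(dvars[!is.na(dvars) &
                               startsWith(dvars, torsion_prefix)])
    if (length(torsions) == 0) {
      stop("no dihedral variables with prefix '", torsion_prefix,
           "' found; declare target torsions explicitly")
    }
  }
  zmatrix(elements, ref, values, varnames, torsions)
}

#' Write a Z-matrix file
#'
#' Writes the Gaussian-style dialect read by [read_zmatrix()]; variable
#' slots are re-emitted as variables with their current values.
#'
#' @param zm a [zmatrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_zmatrix <- function(zm, path) {
  n <- length(zm$elements)
  body <- character(n)
  vars <- list()
  for (a in seq_len(n)) {
    parts <- zm$elements[a]
    for (s in seq_len(min(a - 1, 3))) {
      nm <- zm$varnames[a, s]
      if (!is.na(nm)) {
        vars[[nm]] <- zm$values[a, s]
        parts <- c(parts, zm$ref[a, s], nm)
      } else {
        parts <- c(parts, zm$ref[a, s], format(zm$values[a, s], digits = 10))
      }
    }
    body[a] <- paste(parts, collapse = " ")
  }
  out <- c(body, "Variables:",
           sprintf("%s %.10f", names(vars), unlist(vars)))
  writeLines(out, path)
  invisible(path)
}

#' Model chain-molecule fixture
#'
#' Generates the Z-matrix of a heavy-atom model chain (a united-atom style
#' alkane/alkanol backbone without explicit hydrogens) with exactly
#' `n_torsions` declared target torsions, named `PHI1 ... PHIt`.  With
#' `terminal = "OH"` the last backbone atom is an oxygen, mimicking the
#' n-alcohol series; with `"CH3"` the chain is all carbon.  Methyl-type
#' terminal rotors, which only generate indistinguishable structures, have
#' no counterpart in this heavy-atom model, so every backbone dihedral is a
#' target torsion.  Standard bond lengths are used with slightly widened
#' backbone angles (115 degrees C-C-C, 111 C-C-O) so that no combination
#' of anti/gauche torsions brings nonbonded atoms inside the covalent
#' bonding threshold; all target torsions default to 180 degrees (the
#' all-anti chain).
#'
#' @param n_torsions number of target torsions `t >= 1`.
#' @param terminal `"OH"` or `"CH3"`.
#' @return a [zmatrix()] with `t = n_torsions` (and `n_torsions + 3` atoms).
#' @export
make_chain_fixture <- function(n_torsions, terminal = c("OH", "CH3")) {
  terminal <- match.arg(terminal)
  if (n_torsions < 1) stop("n_torsions must be >= 1")
  n <- n_torsions + 3
  elements <- rep("C", n)
  if (terminal == "OH") elements[n] <- "O"
  cc <- 1.526
  co <- 1.43
  ref <- matrix(NA_integer_, n, 3)
  values <- matrix(NA_real_, n, 3)
  varnames <- matrix(NA_character_, n, 3)
  for (a in 2:n) {
    ref[a, 1] <- a - 1
    values[a, 1] <- if (elements[a] == "O" || elements[a - 1] == "O") co else cc
    if (a >= 3) {
      ref[a, 2] <- a - 2
      values[a, 2] <- if (elements[a] == "O") 111 else 115
    }
    if (a >= 4) {
      ref[a, 3] <- a - 3
      values[a, 3] <- 180
      varnames[a, 3] <- paste0("PHI", a - 3)
    }
  }
  zmatrix(elements, ref, values, varnames,
          torsions = paste0("PHI", seq_len(n_torsions)))
}
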