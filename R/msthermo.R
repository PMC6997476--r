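#' Conformer ensemble input for multi-structural partition functions
#'
#' Per-conformer thermochemical data: relative energy `U` (kcal/mol,
#' re-referenced so the ensemble minimum is 0), harmonic wavenumbers
#' (cm^-1, all strictly positive — each conformer passed the Hessian
#' test), the three principal moments of inertia (amu Angstrom^2), the
#' rotational symmetry number `sigma_rot` (user-supplied; automatic
#' point-group detection is out of scope) and the enantiomer weight
#' `w` (1 for self-enantiomeric structures, 2 otherwise).
#'
#' @param U relative energies, kcal/mol (any common offset is removed).
#' @param frequencies list of numeric vectors of wavenumbers, cm^-1.
#' @param inertia J x 3 matrix of principal moments, amu Angstrom^2.
#' @param sigma_rot rotational symmetry numbers (recycled).
#' @param w enantiomer weights, 1 or 2 (recycled).
#' @param provenance optional character labels (`"systematic"` /
#'   `"stochastic..."`) used by the population split.
#' @param lambda_zpe quasi-harmonic frequency scale factor in `(0, 1.2]`;
#'   1 recovers the plain harmonic treatment.
#' @return object of class `thermo_input`.
#' @export
thermo_input <- function(U, frequencies, inertia, sigma_rot = 1L, w = 1L,
                         provenance = NULL, lambda_zpe = 1) {
  J <- length(U)
  stopifnot(J >= 1, length(frequencies) == J)
  inertia <- matrix(as.numeric(inertia), J, 3)
  sigma_rot <- rep_len(as.integer(sigma_rot), J)
  w <- rep_len(as.integer(w), J)
  if (any(sigma_rot < 1)) stop("sigma_rot must be a positive integer")
  if (!all(w %in% c(1L, 2L))) stop("enantiomer weights must be 1 or 2")
  if (!(lambda_zpe > 0 && lambda_zpe <= 1.2)) {
    stop("lambda_zpe must lie in (0, 1.2]")
  }
  for (j in seq_len(J)) {
    if (length(frequencies[[j]]) > 0 && any(frequencies[[j]] <= 0)) {
      stop("conformer ", j, " has non-positive frequencies; ",
           "only true minima enter the ensemble")
    }
  }
  if (any(inertia <= 0)) {
    stop("all principal moments must be positive (nonlinear conformers)")
  }
  if (is.null(provenance)) provenance <- rep("unknown", J)
  structure(list(U = as.numeric(U) - min(U),
                 frequencies = lapply(frequencies, as.numeric),
                 inertia = inertia, sigma_rot = sigma_rot, w = w,
                 provenance = rep_len(as.character(provenance), J),
                 lambda_zpe = lambda_zpe),
            class = "thermo_input")
}

#' @export
print.thermo_input <- function(x, ...) {
  cat("thermo_input:", length(x$U), "conformer(s), lambda_zpe =",
      x$lambda_zpe, "\n")
  invisible(x)
}

#' Build a thermo input from search results
#'
#' @param state a `search_state` (or plain list of conformers, e.g. after
#'   [expand_enantiomers()] with `w` forced to 1).
#' @param lambda_zpe frequency scale factor.
#' @param use_weights logical; `FALSE` sets every `w` to 1 (used when the
#'   conformer list has already been enantiomer-expanded).
#' @return a [thermo_input()].
#' @export
thermo_from_search <- function(state, lambda_zpe = 1, use_weights = TRUE) {
  confs <- if (inherits(state, "search_state")) state$conformers else state
  if (length(confs) == 0) stop("no conformers in the search state")
  thermo_input(
    U = vapply(confs, `[[`, numeric(1), "energy"),
    frequencies = lapply(confs, `[[`, "frequencies"),
    inertia = do.call(rbind, lapply(confs, `[[`, "inertia")),
    sigma_rot = vapply(confs, `[[`, integer(1), "sigma_rot"),
    w = if (use_weights) vapply(confs, `[[`, integer(1), "weight") else 1L,
    provenance = sub(":enantiomer$", "",
                     vapply(confs, `[[`, character(1), "provenance")),
    lambda_zpe = lambda_zpe)
}

#' Classical rigid-rotor rotational partition function
#'
#' `Q_rot = (8 pi^2 / sigma) * (kB T / (2 pi hbar^2))^(3/2) *
#' sqrt(I1 I2 I3)` for a nonlinear top, with the moments supplied in amu
#' Angstrom^2.
#'
#' @param inertia three principal moments, amu Angstrom^2 (all `> 0`).
#' @param sigma_rot rotational symmetry number.
#' @param T temperature(s), K.
#' @return dimensionless partition function, one value per temperature.
#' @export
q_rot <- function(inertia, sigma_rot = 1, T = 298.15) {
  if (length(inertia) != 3 || any(inertia <= 0)) {
    stop("q_rot needs three positive moments (linear molecules unsupported)")
  }
  stopifnot(all(T > 0))
  I_SI <- inertia * .const$amu * 1e-20          # kg m^2
  (8 * pi^2 / sigma_rot) *
    (.const$kB * T / (2 * pi * .const$hbar^2))^1.5 *
    sqrt(prod(I_SI))
}

#' Harmonic zero-point energy
#'
#' `sum(hbar w / 2)` over the normal modes, converted from cm^-1 to
#' kcal/mol.
#'
#' @param frequencies wavenumbers, cm^-1.
#' @return zero-point energy, kcal/mol.
#' @export
zpe_ho <- function(frequencies) {
  sum(frequencies / 2) / .const$kcal_per_mol_in_wavenumber
}

#' Harmonic-oscillator vibrational partition function
#'
#' `Qtilde = prod_m 1 / (1 - exp(-beta hbar w_m))`, i.e. the vibrational
#' partition function referenced to the zero-point energy, together with
#' that reference energy.  The full HO partition function is
#' `Qtilde * exp(-beta E_zpe)`.
#'
#' @param frequencies wavenumbers, cm^-1.
#' @param T temperature(s), K.
#' @return list with `Qtilde` (per temperature) and `E` (ZPE, kcal/mol).
#' @export
q_ho <- function(frequencies, T = 298.15) {
  stopifnot(all(T > 0))
  Qtilde <- vapply(T, function(temp) {
    beta_hw <- frequencies * .const$h * .const$c * 100 /
      (.const$kB * temp)
    prod(1 / (1 - exp(-beta_hw)))
  }, numeric(1))
  list(Qtilde = Qtilde, E = zpe_ho(frequencies))
}

#' Quasi-harmonic vibrational partition function
#'
#' [q_ho()] with every frequency multiplied by the empirical scale factor
#' `lambda_zpe` (parametrized to reproduce experimental zero-point
#' energies); `lambda_zpe = 1` reduces exactly to the harmonic case, and
#' the quasi-harmonic ZPE is `lambda_zpe` times the harmonic one.
#'
#' @inheritParams q_ho
#' @param lambda_zpe frequency scale factor.
#' @return list with `Qtilde` and `E` (kcal/mol).
#' @export
q_qh <- function(frequencies, lambda_zpe = 1, T = 298.15) {
  q_ho(lambda_zpe * frequencies, T)
}

## per-conformer full rovibrational contribution Q_rot * Q_vib at each T,
## where Q_vib = Qtilde * exp(-beta E_zpe); returns J x nT matrix
conformer_terms <- function(input, T, lambda = input$lambda_zpe) {
  J <- length(input$U)
  out <- matrix(0, J, length(T))
  for (j in seq_len(J)) {
    qr_ <- q_rot(input$inertia[j, ], input$sigma_rot[j], T)
    qv <- q_qh(input$frequencies[[j]], lambda, T)
    out[j, ] <- qr_ * qv$Qtilde * exp(-qv$E / (.const$R_kcal * T))
  }
  out
}

#' Multi-structural partition function (MS-HO / MS-QH)
#'
#' Boltzmann-weighted sum of rigid-rotor x (quasi-)harmonic contributions
#' over the distinguishable non-enantiomeric conformers,
#' `Q = sum_j w_j Qrot_j Qvib_j exp(-U_j / kB T)` with `w_j` in `{1, 2}`.
#' Identical to the sum over all structures with each enantiomer pair
#' counted explicitly.
#'
#' @param input a [thermo_input()].
#' @param T temperature(s), K.
#' @param flavor `"QH"` (frequencies scaled by `lambda_zpe`) or `"HO"`
#'   (unscaled).
#' @return partition-function values, one per temperature.
#' @export
q_ms <- function(input, T = 298.15, flavor = c("QH", "HO")) {
  flavor <- match.arg(flavor)
  lambda <- if (flavor == "HO") 1 else input$lambda_zpe
  terms <- conformer_terms(input, T, lambda)
  boltz <- exp(-outer(input$U, 1 / (.const$R_kcal * T)))
  colSums(input$w * terms * boltz)
}

#' Rovibrational Gibbs free energy per conformer
#'
#' `G_j = U_j - kB T ln(Qrot_j Qvib_j)` (kcal/mol), the free energy that
#' governs the equilibrium population of conformer `j`.
#'
#' @inheritParams q_ms
#' @return J x length(T) matrix, kcal/mol.
#' @export
gibbs_free_energy <- function(input, T = 298.15) {
  terms <- conformer_terms(input, T)
  RT <- .const$R_kcal * T
  sweep(-log(terms), 2, RT, `*`) + input$U
}

#' Equilibrium conformer populations
#'
#' `chi_j = w_j exp(-G_j / kB T) / sum_j w_j exp(-G_j / kB T)`, the
#' fractional contribution of each conformer to the MS-QH partition
#' function (normalized to sum exactly to 1 at every temperature).
#'
#' @inheritParams q_ms
#' @return J x length(T) matrix of populations.
#' @export
chi_populations <- function(input, T = 298.15) {
  terms <- conformer_terms(input, T)
  boltz <- exp(-outer(input$U, 1 / (.const$R_kcal * T)))
  raw <- input$w * terms * boltz
  sweep(raw, 2, colSums(raw), `/`)
}

#' Minimum number of conformers recovering a population fraction
#'
#' Sorts the conformers by decreasing population and reports, per
#' temperature, the smallest count `m` whose cumulative population reaches
#' `threshold` (e.g. 0.9 to recover 90\% of the MS-QH partition function),
#' split by search provenance (systematic vs stochastic).
#'
#' @inheritParams q_ms
#' @param threshold population fraction in `(0, 1]`.
#' @return data frame with columns `T`, `m`, `m_systematic`,
#'   `m_stochastic`.
#' @export
min_conformers_for_fraction <- function(input, T = 298.15,
                                        threshold = 0.9) {
  stopifnot(threshold > 0, threshold <= 1)
  chi <- chi_populations(input, T)
  out <- lapply(seq_along(T), function(i) {
    ord <- order(chi[, i], decreasing = TRUE)
    m <- which(cumsum(chi[ord, i]) >= threshold - 1e-12)[1]
    if (is.na(m)) m <- length(ord)
    top <- input$provenance[ord[seq_len(m)]]
    data.frame(T = T[i], m = m,
               m_systematic = sum(top == "systematic"),
               m_stochastic = sum(startsWith(top, "stochastic")))
  })
  do.call(rbind, out)
}

#' Coupled-torsional multi-structural partition function (MS-T(C))
#'
#' MS-QH augmented by a multiplicative torsional-anharmonicity factor per
#' conformer, `F_j = prod_eta f_{j,eta}`, one factor per target torsion.
#' The `f` factors (ratios of reference-classical to classical-harmonic
#' torsional partition functions) are accepted as user inputs — their
#' internal construction belongs to the coupled-torsional potential model
#' and is not rebuilt here; with all `f = 1` the result equals the MS-QH
#' partition function exactly.
#'
#' @inheritParams q_ms
#' @param f_factors J x t matrix of positive anharmonicity factors
#'   (conformers x torsions).
#' @return partition-function values, one per temperature.
#' @export
q_mst <- function(input, f_factors, T = 298.15) {
  J <- length(input$U)
  f_factors <- as.matrix(f_factors)
  if (nrow(f_factors) != J) {
    stop("f_factors must have one row per conformer (", J, ")")
  }
  if (any(f_factors <= 0)) stop("anharmonicity factors must be positive")
  Fj <- apply(f_factors, 1, prod)
  terms <- conformer_terms(input, T)
  boltz <- exp(-outer(input$U, 1 / (.const$R_kcal * T)))
  colSums(input$w * Fj * terms * boltz)
}

#' Partition-function ratio report
#'
#' The three diagnostic ratios of a conformer ensemble as functions of
#' temperature: MS-QH over the single-well (global-minimum, `w = 1`)
#' quasi-harmonic value, MS-T(C) over MS-QH, and MS-T(C) over 1W-QH.  The
#' first ratio is always `>= 1` since the multi-structural sum contains
#' the single-well term.
#'
#' @inheritParams q_mst
#' @param f_factors J x t matrix of anharmonicity factors; default all 1.
#' @return data frame with columns `T`, `ms_qh_over_1w`, `mst_over_ms_qh`,
#'   `mst_over_1w`.
#' @export
ratio_report <- function(input, T = 298.15, f_factors = NULL) {
  if (is.null(f_factors)) {
    f_factors <- matrix(1, length(input$U), 1)
  }
  jmin <- which.min(input$U)
  terms_min <- conformer_terms(input, T)[jmin, ]
  q1w <- terms_min * exp(-input$U[jmin] / (.const$R_kcal * T))
  qms <- q_ms(input, T, "QH")
  qmst <- q_mst(input, f_factors, T)
  data.frame(T = T,
             ms_qh_over_1w = qms / q1w,
             mst_over_ms_qh = qmst / qms,
             mst_over_1w = qmst / q1w)
}

#' Full per-temperature thermochemistry table
#'
#' @inheritParams q_mst
#' @param f_factors optional J x t anharmonicity factor matrix (default 1).
#' @return data frame with `T`, `Q_MS_HO`, `Q_MS_QH`, `Q_MS_T`,
#'   `ms_qh_over_1w`, `mst_over_ms_qh`, `mst_over_1w`.
#' @export
thermo_table <- function(input, T = 298.15, f_factors = NULL) {
  if (is.null(f_factors)) f_factors <- matrix(1, length(input$U), 1)
  ratios <- ratio_report(input, T, f_factors)
  data.frame(T = T,
             Q_MS_HO = q_ms(input, T, "HO"),
             Q_MS_QH = q_ms(input, T, "QH"),
             Q_MS_T = q_mst(input, f_factors, T),
             ms_qh_over_1w = ratios$ms_qh_over_1w,
             mst_over_ms_qh = ratios$mst_over_ms_qh,
             mst_over_1w = ratios$mst_over_1w)
}

#' Write / read the conformer thermochemistry table
#'
#' CSV interchange format: columns `id`, `U`, `w`, `sigma_rot`, `I1`,
#' `I2`, `I3`, `provenance`, `frequencies` (semicolon-separated
#' wavenumbers).
#'
#' @param input a [thermo_input()].
#' @param path file path.
#' @return `path` (writer) or a [thermo_input()] (reader).
#' @export
write_thermo_input <- function(input, path) {
  J <- length(input$U)
  tab <- data.frame(
    id = seq_len(J), U = input$U, w = input$w,
    sigma_rot = input$sigma_rot,
    I1 = input$inertia[, 1], I2 = input$inertia[, 2],
    I3 = input$inertia[, 3],
    provenance = input$provenance,
    frequencies = vapply(input$frequencies, function(f)
      paste(sprintf("%.8g", f), collapse = ";"), character(1)))
  utils::write.csv(tab, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_thermo_input
#' @param lambda_zpe scale factor attached to the returned input.
#' @export
read_thermo_input <- function(path, lambda_zpe = 1) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  thermo_input(
    U = tab$U,
    frequencies = lapply(strsplit(tab$frequencies, ";"), as.numeric),
    inertia = as.matrix(tab[, c("I1", "I2", "I3")]),
    sigma_rot = tab$sigma_rot, w = tab$w,
    provenance = tab$provenance, lambda_zpe = lambda_zpe)
}
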