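# small random ensembles for property checks
random_ensemble <- function(J, t_freq = 6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  thermo_input(
    U = c(0, runif(J - 1, 0, 4)),
    frequencies = replicate(J, sort(runif(t_freq, 80, 3200)),
                            simplify = FALSE),
    inertia = matrix(runif(3 * J, 20, 400), J, 3),
    sigma_rot = 1L,
    w = sample(c(1L, 2L), J, replace = TRUE),
    provenance = sample(c("systematic", "stochastic1"), J, replace = TRUE),
    lambda_zpe = 0.951)
}

test_that("rigid-rotor partition function follows the classical formula", {
  # frozen value from an independent hand evaluation of the formula
  expect_equal(q_rot(c(10, 20, 30), sigma_rot = 1, T = 300),
               5972.3812604267, tolerance = 1e-9)
  # doubling sigma halves Q at any temperature
  for (temp in c(100, 300, 2500)) {
    expect_equal(q_rot(c(10, 20, 30), 2, temp),
                 q_rot(c(10, 20, 30), 1, temp) / 2)
  }
  # scaling all moments by 4 multiplies Q by 8
  expect_equal(q_rot(4 * c(10, 20, 30), 1, 300),
               8 * q_rot(c(10, 20, 30), 1, 300), tolerance = 1e-12)
  expect_error(q_rot(c(0, 10, 20), 1, 300), "positive")
})

test_that("zero-point energies convert correctly from wavenumbers", {
  # 1000 cm^-1 mode: ZPE = 500 cm^-1 = 1.42957 kcal/mol
  expect_equal(zpe_ho(1000), 1.4295717691, tolerance = 1e-9)
  expect_equal(zpe_ho(numeric(0)), 0)
  expect_equal(zpe_ho(c(750, 750)), 2 * zpe_ho(750))
})

test_that("harmonic vibrational partition function obeys its limits", {
  # T -> 0: every factor -> 1
  expect_equal(q_ho(c(500, 1500), T = 1)$Qtilde, 1, tolerance = 1e-12)
  # high-T single mode: Qtilde -> kB T / (hbar w) within 1% at beta hw = 0.01
  kB_over_hc <- 0.6950348                      # cm^-1 per K
  temp <- 100 / (0.01 * kB_over_hc)            # so that beta hw = 0.01 for 100 cm^-1
  q <- q_ho(100, T = temp)$Qtilde
  expect_equal(q, 1 / 0.01, tolerance = 0.01)
  # two modes factorize
  expect_equal(q_ho(c(200, 900), T = 700)$Qtilde,
               q_ho(200, T = 700)$Qtilde * q_ho(900, T = 700)$Qtilde,
               tolerance = 1e-12)
})

test_that("quasi-harmonic scaling reduces to the harmonic case at lambda = 1", {
  freqs <- c(120, 800, 1600, 3100)
  temps <- c(100, 298.15, 1000, 2500)
  qh1 <- q_qh(freqs, 1, temps)
  ho <- q_ho(freqs, temps)
  expect_equal(qh1$Qtilde, ho$Qtilde)
  expect_equal(qh1$E, ho$E)
  # scaling by 0.951 equals the harmonic treatment of scaled modes
  expect_equal(q_qh(freqs, 0.951, temps)$Qtilde,
               q_ho(0.951 * freqs, temps)$Qtilde)
  expect_equal(q_qh(freqs, 0.951, temps)$E, 0.951 * ho$E, tolerance = 1e-12)
})

test_that("multi-structural sums respect enantiomer weights", {
  temps <- c(200, 298.15, 1000)
  one <- thermo_input(U = 0, frequencies = list(c(300, 1200)),
                      inertia = matrix(c(50, 60, 70), 1), w = 1L)
  # single conformer: the one-well limit
  expect_equal(q_ms(one, temps, "HO"),
               q_rot(c(50, 60, 70), 1, temps) *
                 q_ho(c(300, 1200), temps)$Qtilde *
                 exp(-zpe_ho(c(300, 1200)) / (1.987204259e-3 * temps)),
               tolerance = 1e-8)
  # one w = 2 conformer equals the same conformer listed twice with w = 1
  paired <- thermo_input(U = c(0, 0),
                         frequencies = list(c(300, 1200), c(300, 1200)),
                         inertia = matrix(c(50, 60, 70), 2, 3, byrow = TRUE),
                         w = 1L)
  doubled <- thermo_input(U = 0, frequencies = list(c(300, 1200)),
                          inertia = matrix(c(50, 60, 70), 1), w = 2L)
  expect_equal(q_ms(paired, temps), q_ms(doubled, temps),
               tolerance = 1e-12)
  # Boltzmann suppression of a very high-energy conformer
  two <- thermo_input(U = c(0, 500), frequencies = list(c(300, 1200),
                                                        c(300, 1200)),
                      inertia = matrix(c(50, 60, 70), 2, 3, byrow = TRUE),
                      w = 1L)
  expect_equal(q_ms(two, 298.15), q_ms(one, 298.15), tolerance = 1e-10)
})

test_that("populations normalize, order by free energy and split provenance", {
  temps <- c(150, 600, 2000)
  ens <- random_ensemble(6, seed = 61)
  chi <- chi_populations(ens, temps)
  expect_equal(colSums(chi), rep(1, 3), tolerance = 1e-12)
  G <- gibbs_free_energy(ens, temps)
  for (i in seq_along(temps)) {
    # within equal weights, lower G means higher population
    for (j in 2:6) for (k in seq_len(j - 1)) {
      if (ens$w[j] == ens$w[k]) {
        expect_equal(G[j, i] < G[k, i], chi[j, i] > chi[k, i])
      }
    }
  }
  # two identical conformers share the population equally
  twin <- thermo_input(U = c(0, 0), frequencies = list(c(400, 900),
                                                       c(400, 900)),
                       inertia = matrix(c(30, 40, 50), 2, 3, byrow = TRUE),
                       w = 1L)
  expect_equal(as.vector(chi_populations(twin, 300)), c(0.5, 0.5))
  single <- thermo_input(U = 0, frequencies = list(c(400, 900)),
                         inertia = matrix(c(30, 40, 50), 1))
  expect_equal(as.vector(chi_populations(single, temps)), rep(1, 3))
})

test_that("minimum conformer counts accumulate sorted populations", {
  # engineer exact populations via U = -RT log(p) with identical rovib terms
  R <- 1.987204259e-3
  temp <- 400
  make <- function(p, prov) thermo_input(
    U = -R * temp * log(p / max(p)),
    frequencies = replicate(length(p), c(400, 900), simplify = FALSE),
    inertia = matrix(c(30, 40, 50), length(p), 3, byrow = TRUE),
    w = 1L, provenance = prov)
  ens <- make(c(0.5, 0.3, 0.2), rep("systematic", 3))
  expect_equal(min_conformers_for_fraction(ens, temp, 0.9)$m, 3)
  ens2 <- make(c(0.6, 0.35, 0.05),
               c("systematic", "stochastic1", "systematic"))
  res <- min_conformers_for_fraction(ens2, temp, 0.9)
  expect_equal(res$m, 2)
  expect_equal(res$m_systematic, 1)
  expect_equal(res$m_stochastic, 1)
  single <- make(1, "systematic")
  expect_equal(min_conformers_for_fraction(single, temp, 1)$m, 1)
})

test_that("coupled-torsional factors act multiplicatively", {
  temps <- c(298.15, 1000)
  ens <- random_ensemble(4, seed = 62)
  t <- 3
  # all factors 1: exact collapse onto MS-QH
  f1 <- matrix(1, 4, t)
  expect_equal(q_mst(ens, f1, temps), q_ms(ens, temps, "QH"),
               tolerance = 1e-12)
  # constant factor c over t torsions scales by c^t
  fc <- matrix(1.3, 4, t)
  expect_equal(q_mst(ens, fc, temps), 1.3^t * q_ms(ens, temps, "QH"),
               tolerance = 1e-10)
  # doubling one conformer's one factor changes only that term
  f2 <- f1; f2[2, 1] <- 2
  delta <- q_mst(ens, f2, temps) - q_mst(ens, f1, temps)
  term2 <- q_mst(ens, f1, temps) -
    q_mst(thermo_input(U = ens$U[-2], frequencies = ens$frequencies[-2],
                       inertia = ens$inertia[-2, ], sigma_rot = 1,
                       w = ens$w[-2], lambda_zpe = ens$lambda_zpe),
          f1[-2, , drop = FALSE], temps)
  expect_equal(delta, term2, tolerance = 1e-8)
  expect_error(q_mst(ens, matrix(1, 2, t)), "one row per conformer")
})

test_that("partition-function ratios behave as a two-level closed form", {
  temps <- seq(200, 2000, by = 300)
  single <- thermo_input(U = 0, frequencies = list(c(400, 900)),
                         inertia = matrix(c(30, 40, 50), 1))
  r1 <- ratio_report(single, temps)
  expect_equal(r1$ms_qh_over_1w, rep(1, length(temps)))
  expect_equal(r1$mst_over_ms_qh, rep(1, length(temps)))
  # two-level system: ratio = 1 + exp(-u / kB T), rising with T
  u <- 1.2
  R <- 1.987204259e-3
  two <- thermo_input(U = c(0, u),
                      frequencies = list(c(400, 900), c(400, 900)),
                      inertia = matrix(c(30, 40, 50), 2, 3, byrow = TRUE),
                      w = 1L)
  r2 <- ratio_report(two, temps)
  expect_equal(r2$ms_qh_over_1w, 1 + exp(-u / (R * temps)),
               tolerance = 1e-10)
  expect_true(all(diff(r2$ms_qh_over_1w) > 0))
  expect_true(all(r2$ms_qh_over_1w >= 1))
})

test_that("thermo input validates physics and re-references energies", {
  expect_error(thermo_input(0, list(c(-5, 100)), matrix(c(1, 2, 3), 1)),
               "non-positive")
  expect_error(thermo_input(0, list(100), matrix(c(0, 2, 3), 1)),
               "positive")
  expect_error(thermo_input(0, list(100), matrix(c(1, 2, 3), 1), w = 3),
               "1 or 2")
  expect_error(thermo_input(0, list(100), matrix(c(1, 2, 3), 1),
                            lambda_zpe = 1.5), "lambda_zpe")
  shifted <- thermo_input(c(5, 7), list(c(100), c(100)),
                          matrix(1:6, 2, 3))
  expect_equal(shifted$U, c(0, 2))
})

test_that("thermo tables round-trip through CSV", {
  ens <- random_ensemble(5, seed = 63)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_thermo_input(ens, tmp)
  back <- read_thermo_input(tmp, lambda_zpe = ens$lambda_zpe)
  expect_equal(back$U, ens$U, tolerance = 1e-10)
  expect_equal(back$w, ens$w)
  expect_equal(back$inertia, ens$inertia, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(q_ms(back, 500), q_ms(ens, 500), tolerance = 1e-6)
})
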