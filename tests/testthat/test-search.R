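test_that("systematic pool enumerates the preconditioned product", {
  lists3 <- rep(list(c(180, 60, 300)), 3)
  full <- systematic_pool(lists3, has_sym_plane = FALSE)
  expect_equal(nrow(full), 27)
  expect_equal(attr(full, "K1_full"), 27)
  reduced <- systematic_pool(lists3, has_sym_plane = TRUE)
  expect_equal(nrow(reduced), 14)
  expect_equal(attr(reduced, "K1_full"), 27)
  # one representative per enantiomer pair, none lost
  keys <- apply(reduced, 1, function(p)
    paste(canonical_representative(p), collapse = "|"))
  expect_equal(anyDuplicated(keys), 0L)
  full_keys <- unique(apply(full, 1, function(p)
    paste(canonical_representative(p), collapse = "|")))
  expect_setequal(keys, full_keys)

  expect_equal(nrow(systematic_pool(list(180))), 1)
  expect_error(systematic_pool(list(c(60, 60))), "duplicate")
  # symmetry flag requires reflection-closed angle lists
  expect_error(systematic_pool(list(c(180, 60)), has_sym_plane = TRUE),
               "closed")
})

test_that("stochastic draws are reproducible, uniform and in range", {
  set.seed(99)
  a <- sample_stochastic_point(4)
  set.seed(99)
  expect_identical(sample_stochastic_point(4), a)
  set.seed(100)
  draws <- replicate(1e4, sample_stochastic_point(1))
  expect_true(all(draws >= 0 & draws < 360))
  se <- 360 / sqrt(12) / sqrt(1e4)
  expect_lt(abs(mean(draws) - 180), 3 * se)
})

test_that("a single-well surface yields one conformer from one pool point", {
  fx <- toy_pes_fixture("single_well")
  pool <- systematic_pool(list(180))
  st <- run_systematic(fx$zm, fx$backend, pool)
  expect_equal(st$K1, 1L)
  expect_equal(st$K1_star, 1L)
  expect_equal(state_J(st), 1L)
  expect_equal(circular_distance(st$conformers[[1]]$phi, 180), 0,
               tolerance = 1)
})

test_that("guesses sharing a basin are caught by redundancy, not similarity", {
  fx <- toy_pes_fixture("shared_basin")   # well at 180; guesses 60 and 80
  pool <- systematic_pool(fx$angles)
  st <- run_systematic(fx$zm, fx$backend, pool)
  # both guesses escape the equilibria hypercube (the only equilibrium is
  # at 180), so both become trials; the second relaxes onto the first
  # conformer and is rejected as redundant
  expect_equal(st$K1, 2L)
  expect_equal(st$K1_star, 2L)
  expect_equal(state_J(st), 1L)
  expect_match(st$log[2], "redundancy")
})

test_that("systematic similarity consults equilibria only, stochastic the full pool", {
  fx <- toy_pes_fixture("shared_basin")
  # systematic phase: guess 80 is within d = 30 of the earlier trial at 60
  # but far from the only equilibrium (180); with the equilibria-only pool
  # it must still be promoted to a trial
  st <- run_systematic(fx$zm, fx$backend, systematic_pool(list(c(60, 80))))
  expect_equal(st$K1_star, 2L)

  # stochastic phase replaying the same point: now the full stored pool
  # applies, and the trial at 60 captures it
  st2 <- run_systematic(fx$zm, fx$backend, systematic_pool(list(60)))
  expect_equal(st2$K1_star, 1L)
  st2 <- run_stochastic(fx$zm, fx$backend, st2, cycles = 1, d = 30,
                        points = list(80))
  expect_equal(st2$K2, 1L)
  expect_equal(st2$K2_star, 0L)   # rejected by similarity against the trial
  expect_match(st2$log[length(st2$log)], "similarity")
})

test_that("a hypercube wider than the torus freezes the stochastic phase", {
  fx <- toy_pes_fixture("single_well")
  st <- run_systematic(fx$zm, fx$backend, systematic_pool(list(180)))
  st <- run_stochastic(fx$zm, fx$backend, st, cycles = 10, d = 200,
                       control = list(trace = FALSE))
  expect_equal(st$K2, 10L)
  expect_equal(st$K2_star, 0L)
})

test_that("enantiomer expansion doubles all non-self-mirror conformers", {
  fx <- toy_pes_fixture("grid3")
  st <- conformer_search(fx$zm, fx$backend, angles = fx$angles,
                         has_sym_plane = TRUE, seed = 3)
  expect_equal(state_J(st), 5L)
  n_self <- sum(vapply(st$conformers, function(cf) cf$weight == 1L,
                       logical(1)))
  expect_equal(n_self, 1L)   # only the all-anti structure mirrors onto itself
  ex <- expand_enantiomers(st)
  expect_length(ex, 2L * 5L - 1L)
  # mirror partners carry identical energies and inertia moments
  for (cf in st$conformers[vapply(st$conformers, `[[`, integer(1),
                                  "weight") == 2L]) {
    mir <- Filter(function(x)
      all(circular_distance(x$phi, enantiomer(cf$phi)) < 1e-6), ex)
    expect_length(mir, 1)
    expect_equal(mir[[1]]$energy, cf$energy, tolerance = 1e-10)
    expect_equal(mir[[1]]$inertia, cf$inertia, tolerance = 1e-8)
    expect_equal(pes_energy(fx$backend, mir[[1]]$cart), cf$energy,
                 tolerance = 1e-7)
  }
})

test_that("pool bookkeeping identity holds after every event", {
  fx <- toy_pes_fixture("grid3")
  st <- conformer_search(fx$zm, fx$backend, angles = fx$angles,
                         has_sym_plane = TRUE,
                         batches = list(list(cycles = 60, d = 30)),
                         seed = 17)
  ev <- st$events
  expect_equal(nrow(ev), st$K1 + st$K2)
  expect_true(all(ev$P == ev$K1_star + ev$K2_star + ev$J))
  expect_true(all(ev$K1_star <= ev$K1))
  expect_true(all(ev$K2_star <= ev$K2))
  expect_true(all(diff(ev$J) >= 0))
  # no two accepted conformers coincide within eps_red in all torsions
  phis <- conformer_phis(st)
  for (i in seq_len(nrow(phis))) for (j in seq_len(i - 1)) {
    expect_true(any(circular_distance(phis[i, ], phis[j, ]) > 3))
  }
})

test_that("identical seed and config reproduce the run byte for byte", {
  fx <- toy_pes_fixture("grid3")
  run_once <- function() {
    st <- conformer_search(fx$zm, fx$backend, angles = fx$angles,
                           has_sym_plane = TRUE,
                           batches = list(list(cycles = 40, d = 30)),
                           seed = 11)
    f <- tempfile(fileext = ".tsv")
    write_conformer_table(st, f)
    on.exit(unlink(f))
    readLines(f)
  }
  expect_identical(run_once(), run_once())
})

test_that("a run resumed from a checkpoint matches an uninterrupted one", {
  fx <- toy_pes_fixture("grid3")
  batches <- list(list(cycles = 15, d = 30), list(cycles = 15, d = 20))
  full <- conformer_search(fx$zm, fx$backend, angles = fx$angles,
                           has_sym_plane = TRUE, batches = batches,
                           seed = 23)

  # interrupted variant: stop after the first batch, checkpoint, resume
  part <- conformer_search(fx$zm, fx$backend, angles = fx$angles,
                           has_sym_plane = TRUE, batches = batches[1],
                           seed = 23)
  ck <- withr::local_tempfile(fileext = ".json")
  write_checkpoint(part, ck)
  set.seed(1e6)   # scramble the RNG to prove the checkpoint restores it
  resumed <- read_checkpoint(ck)
  resumed <- run_stochastic(fx$zm, fx$backend, resumed, cycles = 15,
                            d = 20, batch = 2L)

  expect_equal(state_J(resumed), state_J(full))
  expect_equal(conformer_phis(resumed), conformer_phis(full),
               tolerance = 1e-12)
  expect_equal(resumed$K2, full$K2)
  expect_equal(resumed$K2_star, full$K2_star)
  f1 <- tempfile(); f2 <- tempfile()
  write_conformer_table(resumed, f1); write_conformer_table(full, f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("an empty stochastic configuration skips the Monte Carlo phase", {
  fx <- toy_pes_fixture("single_well")
  st <- conformer_search(fx$zm, fx$backend, angles = fx$angles, seed = 2)
  expect_equal(st$K2, 0L)
  expect_equal(st$K2_star, 0L)
})
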