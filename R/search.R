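#' Systematic preconditioned pool
#'
#' Cartesian product of the per-torsion lists of chemically intuitive guess
#' angles (anti and gauche positions for sp3 chains).  The full pool has
#' `K1 = prod(P_tau)` points.  For a molecule with a plane of symmetry,
#' torsional points come in conformational-enantiomer pairs `{Phi, -Phi}`
#' of which only one member needs to be optimized; the reduction keeps
#' exactly one representative per pair (self-enantiomeric points once),
#' which yields `(K1 + 1) / 2` points for symmetric angle lists with one
#' self-paired angle per torsion.
#'
#' @param angles list of `t` numeric vectors of guess angles, degrees;
#'   duplicates within a list are rejected (they would only generate
#'   indistinguishable structures).
#' @param has_sym_plane logical; apply the enantiomer reduction.  Requires
#'   every angle list to be closed under `phi -> 360 - phi`.
#' @return matrix with one torsional point per row (`t` columns), in
#'   deterministic enumeration order, with attribute `K1_full` = the
#'   unreduced product count.
#' @examples
#' nrow(systematic_pool(rep(list(c(180, 60, 300)), 3), FALSE))  # 27
#' nrow(systematic_pool(rep(list(c(180, 60, 300)), 3), TRUE))   # 14
#' @export
systematic_pool <- function(angles, has_sym_plane = FALSE) {
  stopifnot(is.list(angles), length(angles) >= 1)
  angles <- lapply(angles, normalize_angle)
  for (k in seq_along(angles)) {
    if (length(angles[[k]]) == 0) stop("empty angle list for torsion ", k)
    if (anyDuplicated(angles[[k]])) {
      stop("duplicate guess angles for torsion ", k,
           ": only angles generating distinguishable structures belong in the pool")
    }
  }
  if (has_sym_plane) {
    for (k in seq_along(angles)) {
      refl <- normalize_angle(360 - angles[[k]])
      if (!all(vapply(refl, function(a)
        any(circular_distance(a, angles[[k]]) < 1e-9), logical(1)))) {
        stop("angle list for torsion ", k,
             " is not closed under phi -> 360 - phi; ",
             "the enantiomer of every grid point must lie on the grid")
      }
    }
  }
  # lexicographic enumeration: last torsion varies fastest
  grid <- expand.grid(rev(angles), KEEP.OUT.ATTRS = FALSE)
  pool <- as.matrix(grid[, rev(seq_along(angles)), drop = FALSE])
  dimnames(pool) <- list(NULL, paste0("phi", seq_along(angles)))
  K1_full <- nrow(pool)
  if (has_sym_plane) {
    seen <- character(0)
    keep <- logical(K1_full)
    for (i in seq_len(K1_full)) {
      key <- paste(sprintf("%.6f", canonical_representative(pool[i, ])),
                   collapse = "|")
      if (!key %in% seen) {
        seen <- c(seen, key)
        keep[i] <- TRUE
      }
    }
    pool <- pool[keep, , drop = FALSE]
  }
  attr(pool, "K1_full") <- K1_full
  pool
}

#' Random torsional point
#'
#' One Monte Carlo guess: `t` independent draws uniform on `[0, 360)`
#' degrees, using R's global random number generator (seed the run with
#' `set.seed()` or the `seed` argument of [conformer_search()] for
#' reproducibility).
#'
#' @param t number of torsions.
#' @return numeric vector of length `t`.
#' @export
sample_stochastic_point <- function(t) {
  stats::runif(t, 0, 360)
}

#' Fresh search state
#'
#' The evolving bookkeeping of a search: the pool of accepted equilibrium
#' conformers, the pool of trial torsional points, and the counters
#' `K1` / `K1_star` (systematic guesses generated / promoted to trials),
#' `K2` / `K2_star` (same for the stochastic phase) and `J` (conformers).
#' The stored pool used by the stochastic similarity test is the union of
#' trials and equilibria, of size `P = K1_star + K2_star + J`.
#'
#' @param t number of target torsions.
#' @param has_sym_plane logical; when the molecule has a plane of symmetry
#'   the mirror partner of every stored point counts as visited too, so
#'   the similarity and redundancy pools are augmented with the
#'   enantiomers of their members (mirror structures are generated
#'   afterwards by [expand_enantiomers()], never re-optimized).
#' @return object of class `search_state`.
#' @export
new_search_state <- function(t, has_sym_plane = FALSE) {
  structure(list(
    t = as.integer(t),
    has_sym_plane = isTRUE(has_sym_plane),
    conformers = list(),
    trials = list(),
    K1 = 0L, K1_star = 0L, K2 = 0L, K2_star = 0L,
    events = NULL,
    log = character(0),
    A_ref = NULL,
    rng = NULL
  ), class = "search_state")
}

#' @export
print.search_state <- function(x, ...) {
  cat(sprintf(
    "search_state: t=%d | K1=%d K1*=%d | K2=%d K2*=%d | J=%d (P=%d)\n",
    x$t, x$K1, x$K1_star, x$K2, x$K2_star, state_J(x), state_P(x)))
  invisible(x)
}

#' Counters of a search state
#'
#' `state_J` is the number of accepted conformers, `state_P` the size of
#' the stored pool (`K1_star + K2_star + J`).
#' @param state a [new_search_state()].
#' @return integer.
#' @export
state_J <- function(state) length(state$conformers)

#' @rdname state_J
#' @export
state_P <- function(state) length(state$trials) + length(state$conformers)

## mirror-augment a pool when the molecule has a plane of symmetry: the
## enantiomer of every visited point is known without optimization, so its
## area of influence is excluded as well
augment_mirror <- function(pts, state) {
  if (!isTRUE(state$has_sym_plane)) return(pts)
  c(pts, lapply(pts, enantiomer))
}

## stored pool: trials followed by equilibrium torsional points
stored_pool <- function(state) {
  augment_mirror(c(state$trials, lapply(state$conformers, `[[`, "phi")),
                 state)
}

equilibria_pool <- function(state) {
  augment_mirror(lapply(state$conformers, `[[`, "phi"), state)
}

search_log <- function(state, phase, phi, verdict, detail = "") {
  line <- sprintf("%s | phi=(%s) | %s%s", phase,
                  paste(sprintf("%.2f", phi), collapse = ", "),
                  verdict,
                  if (nzchar(detail)) paste0(" | ", detail) else "")
  state$log <- c(state$log, line)
  state
}

record_event <- function(state, phase) {
  row <- data.frame(phase = phase, K1 = state$K1, K1_star = state$K1_star,
                    K2 = state$K2, K2_star = state$K2_star,
                    J = state_J(state), P = state_P(state))
  state$events <- rbind(state$events, row)
  state
}

search_control <- function(control = list()) {
  defaults <- list(d = 30, eps_red = 3, eps_freq = 5, k_bond = 1.3,
                   gtol = 1e-6, maxit = 500, trace = TRUE)
  defaults[names(control)] <- control
  defaults
}

## shared per-guess pipeline: battery on the guess, optimization, battery
## on the optimized structure, state update.  similarity_pool distinguishes
## the systematic phase (equilibria only) from the stochastic one (full
## stored pool).
process_guess <- function(phi, state, zm, backend, similarity_pool, d,
                          ctl, phase, provenance) {
  phi <- normalize_angle(phi)
  cart <- zmatrix_to_cartesian(zm, phi)
  guess_ctx <- list(A_ref = state$A_ref, elements = zm$elements,
                    k_bond = ctl$k_bond, similarity_pool = similarity_pool,
                    d = d)
  g <- run_guess_battery(phi, cart, guess_ctx)
  if (!g$accepted) {
    fail <- g$reports[[length(g$reports)]]
    return(search_log(state, phase, phi,
                      paste0("rejected:", fail$test), fail$detail))
  }
  state$trials <- c(state$trials, list(phi))
  if (phase == "systematic") state$K1_star <- state$K1_star + 1L
  else state$K2_star <- state$K2_star + 1L
  opt <- optimize_geometry(backend, cart, gtol = ctl$gtol, maxit = ctl$maxit)
  if (!opt$converged) {
    return(search_log(state, phase, phi, "discarded:optimization",
                      sprintf("no convergence (max |g| = %.2e)",
                              opt$max_grad)))
  }
  phi_opt <- measure_torsions(opt$cart, zm)
  opt_ctx <- list(A_ref = state$A_ref, elements = zm$elements,
                  k_bond = ctl$k_bond, equilibria = equilibria_pool(state),
                  eps_red = ctl$eps_red, eps_freq = ctl$eps_freq,
                  masses = zm$masses, backend = backend)
  o <- run_optimized_battery(phi_opt, opt$cart, opt_ctx)
  if (!o$accepted) {
    fail <- o$reports[[length(o$reports)]]
    return(search_log(state, phase, phi,
                      paste0("rejected:", fail$test), fail$detail))
  }
  conf <- list(
    id = state_J(state) + 1L,
    phi = normalize_angle(phi_opt),
    cart = opt$cart,
    energy = opt$energy,
    frequencies = o$frequencies,
    inertia = principal_moments(opt$cart, zm$masses),
    sigma_rot = 1L,
    weight = if (is_self_enantiomeric(phi_opt, tol = ctl$eps_red)) 1L else 2L,
    provenance = provenance)
  state$conformers <- c(state$conformers, list(conf))
  search_log(state, phase, phi, "accepted:new-conformer",
             sprintf("phi_opt=(%s) E=%.6f",
                     paste(sprintf("%.2f", conf$phi), collapse = ", "),
                     conf$energy))
}

#' Systematic search phase
#'
#' Walks the preconditioned pool in enumeration order.  Each pool point is
#' built into a Cartesian guess, screened by the guess battery — during
#' this phase the similarity test compares against the accepted equilibria
#' only, because the hypercubes around the preconditioned grid points do
#' not overlap — then optimized and screened by the optimized battery.
#'
#' @param zm a [zmatrix()].
#' @param backend a [pes_backend()].
#' @param pool matrix of torsional points from [systematic_pool()].
#' @param state a [new_search_state()] (may carry earlier results).
#' @param control list overriding the defaults `d = 30`, `eps_red = 3`,
#'   `eps_freq = 5` (cm^-1), `k_bond = 1.3`, `gtol = 1e-6`,
#'   `trace = TRUE` (record a counter snapshot after every guess).
#' @return the updated `search_state`.
#' @export
run_systematic <- function(zm, backend, pool, state = NULL,
                           control = list()) {
  ctl <- search_control(control)
  if (is.null(state)) state <- new_search_state(n_torsions(zm))
  if (is.null(state$A_ref)) {
    ref <- zmatrix_to_cartesian(zm)
    state$A_ref <- perceive_adjacency(ref, zm$elements, ctl$k_bond)
  }
  pool <- as.matrix(pool)
  for (i in seq_len(nrow(pool))) {
    state$K1 <- state$K1 + 1L
    state <- process_guess(pool[i, ], state, zm, backend,
                           similarity_pool = equilibria_pool(state),
                           d = ctl$d, ctl = ctl, phase = "systematic",
                           provenance = "systematic")
    if (ctl$trace) state <- record_event(state, "systematic")
  }
  state
}

#' Stochastic (Monte Carlo) search phase
#'
#' Runs `cycles` Monte Carlo cycles: each cycle draws a uniform random
#' torsional point and pushes it through the same pipeline as the
#' systematic phase, except that the similarity test consults the full
#' stored pool (trials and equilibria), since a random point may fall into
#' the area of influence of an earlier trial that never became a
#' conformer.  Several batches with different hypercube half-edges `d` can
#' be chained by repeated calls (see [conformer_search()]).
#'
#' @inheritParams run_systematic
#' @param cycles number of Monte Carlo cycles (every generated point counts
#'   toward `K2`, accepted or not).
#' @param d hypercube half-edge for this batch, degrees.
#' @param batch batch index recorded in the conformer provenance.
#' @param points optional list of torsional points replayed instead of
#'   random draws (a reproducibility/testing hook; `cycles` is ignored).
#' @return the updated `search_state`.
#' @export
run_stochastic <- function(zm, backend, state, cycles, d = 30,
                           control = list(), batch = 1L, points = NULL) {
  ctl <- search_control(control)
  ctl$d <- d
  if (is.null(state$A_ref)) {
    ref <- zmatrix_to_cartesian(zm)
    state$A_ref <- perceive_adjacency(ref, zm$elements, ctl$k_bond)
  }
  n <- if (is.null(points)) cycles else length(points)
  for (i in seq_len(n)) {
    phi <- if (is.null(points)) sample_stochastic_point(state$t)
           else points[[i]]
    state$K2 <- state$K2 + 1L
    state <- process_guess(phi, state, zm, backend,
                           similarity_pool = stored_pool(state),
                           d = d, ctl = ctl, phase = "stochastic",
                           provenance = sprintf("stochastic%d", batch))
    if (ctl$trace) state <- record_event(state, "stochastic")
  }
  state
}

#' Expand conformational enantiomers
#'
#' For a molecule with a plane of symmetry the search optimizes only one
#' member of each enantiomer pair; this generates the mirror partners
#' automatically: each conformer with weight 2 emits a copy at `-Phi` with
#' mirrored Cartesian coordinates and identical energy, frequencies and
#' inertia moments.  The expanded list has `2 J - n_self` structures,
#' where `n_self` counts the self-enantiomeric conformers.
#'
#' @param conformers list of conformers, or a `search_state`.
#' @return list of conformers including the generated mirror structures.
#' @export
expand_enantiomers <- function(conformers) {
  if (inherits(conformers, "search_state")) {
    conformers <- conformers$conformers
  }
  out <- conformers
  for (conf in conformers) {
    if (conf$weight == 2L) {
      mir <- conf
      mir$id <- length(out) + 1L
      mir$phi <- enantiomer(conf$phi)
      mir$cart <- mirror_cartesian(conf$cart)
      mir$provenance <- paste0(conf$provenance, ":enantiomer")
      out <- c(out, list(mir))
    }
  }
  out
}

#' Combined systematic + stochastic conformer search
#'
#' The full driver: builds and validates the reference geometry (its
#' adjacency matrix becomes the connectivity fingerprint), runs the
#' preconditioned systematic phase, then zero or more Monte Carlo batches,
#' each with its own cycle count and hypercube half-edge.  Fully
#' reproducible for a fixed `seed`.
#'
#' @param zm a [zmatrix()].
#' @param backend a [pes_backend()].
#' @param angles per-torsion preconditioned guess angles; default three
#'   positions `{180, 60, 300}` (anti and the two gauche wells) for every
#'   torsion.
#' @param has_sym_plane logical; reduce the systematic pool to one
#'   representative per enantiomer pair.
#' @param batches list of stochastic batches, each `list(cycles =, d =)`;
#'   empty list skips the stochastic phase.
#' @param control see [run_systematic()].
#' @param seed integer seed for the Monte Carlo draws; `NULL` leaves the
#'   RNG state untouched.
#' @param systematic logical; run the systematic phase.
#' @return the final `search_state`.
#' @export
conformer_search <- function(zm, backend,
                             angles = rep(list(c(180, 60, 300)),
                                          n_torsions(zm)),
                             has_sym_plane = FALSE,
                             batches = list(),
                             control = list(), seed = NULL,
                             systematic = TRUE) {
  if (!inherits(zm, "zmatrix")) stop("zm must be a zmatrix")
  if (!is.null(seed)) set.seed(seed)
  ctl <- search_control(control)
  state <- new_search_state(n_torsions(zm), has_sym_plane)
  ref <- zmatrix_to_cartesian(zm)
  state$A_ref <- perceive_adjacency(ref, zm$elements, ctl$k_bond)
  if (systematic) {
    pool <- systematic_pool(angles, has_sym_plane)
    state <- run_systematic(zm, backend, pool, state, control)
    state$K1_full <- attr(pool, "K1_full")
  }
  for (b in seq_along(batches)) {
    bat <- batches[[b]]
    state <- run_stochastic(zm, backend, state,
                            cycles = bat$cycles,
                            d = if (is.null(bat$d)) ctl$d else bat$d,
                            control = control, batch = b)
  }
  state
}

#' Conformer table of a search state
#'
#' @param state a `search_state`.
#' @return data frame with columns `id`, `phi1 ... phit`, `energy`
#'   (kcal/mol, re-referenced to the ensemble minimum), `weight`, `n_imag`
#'   (always 0 for accepted conformers) and `provenance`.
#' @export
conformer_table <- function(state) {
  confs <- state$conformers
  t <- state$t
  if (length(confs) == 0) {
    tab <- as.data.frame(matrix(numeric(0), 0, t + 4))
    names(tab) <- c("id", paste0("phi", seq_len(t)), "energy", "weight",
                    "n_imag")
    tab$provenance <- character(0)
    return(tab)
  }
  phis <- do.call(rbind, lapply(confs, `[[`, "phi"))
  e <- vapply(confs, `[[`, numeric(1), "energy")
  tab <- data.frame(id = vapply(confs, `[[`, integer(1), "id"))
  for (k in seq_len(t)) tab[[paste0("phi", k)]] <- phis[, k]
  tab$energy <- e - min(e)
  tab$weight <- vapply(confs, `[[`, integer(1), "weight")
  tab$n_imag <- 0L
  tab$provenance <- vapply(confs, `[[`, character(1), "provenance")
  tab
}

#' Write the conformer table as TSV
#'
#' @param state a `search_state`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_conformer_table <- function(state, path) {
  tab <- conformer_table(state)
  num <- vapply(tab, is.double, logical(1))
  tab[num] <- lapply(tab[num], function(x) sprintf("%.6f", x))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Checkpoint a search state to disk
#'
#' Versioned plain-text (JSON) serialization of the full state, including
#' the random-number-generator state, so an interrupted run resumed from
#' the checkpoint reproduces an uninterrupted one exactly.
#'
#' @param state a `search_state`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_checkpoint <- function(state, path) {
  payload <- unclass(state)
  payload$events <- NULL   # trace metadata, not needed to resume
  payload$format_version <- 1L
  payload$rng <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Restore a search state from a checkpoint
#'
#' @param path file written by [write_checkpoint()].
#' @param restore_rng logical; restore the saved RNG state so the
#'   stochastic phase continues exactly where it left off.
#' @return a `search_state`.
#' @export
read_checkpoint <- function(path, restore_rng = TRUE) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = TRUE)
  if (is.null(raw$format_version) || raw$format_version != 1L) {
    stop("unsupported checkpoint format in ", path)
  }
  state <- new_search_state(raw$t, isTRUE(raw$has_sym_plane))
  state$K1 <- as.integer(raw$K1)
  state$K1_star <- as.integer(raw$K1_star)
  state$K2 <- as.integer(raw$K2)
  state$K2_star <- as.integer(raw$K2_star)
  state$A_ref <- if (!is.null(raw$A_ref)) {
    m <- as.matrix(raw$A_ref); storage.mode(m) <- "integer"; m
  }
  state$log <- as.character(unlist(raw$log))
  state$trials <- if (is.matrix(raw$trials)) {
    lapply(seq_len(nrow(raw$trials)), function(i) as.numeric(raw$trials[i, ]))
  } else {
    lapply(raw$trials, function(x) as.numeric(unlist(x)))
  }
  state$conformers <- lapply(raw$conformers, function(cf) {
    list(id = as.integer(cf$id), phi = as.numeric(unlist(cf$phi)),
         cart = as.matrix(cf$cart), energy = as.numeric(cf$energy),
         frequencies = as.numeric(unlist(cf$frequencies)),
         inertia = as.numeric(unlist(cf$inertia)),
         sigma_rot = as.integer(cf$sigma_rot),
         weight = as.integer(cf$weight),
         provenance = as.character(cf$provenance))
  })
  if (!is.null(raw$K1_full)) state$K1_full <- as.integer(raw$K1_full)
  if (restore_rng && !is.null(raw$rng)) {
    assign(".Random.seed", as.integer(raw$rng), envir = globalenv())
  }
  state
}
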