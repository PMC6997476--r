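# Independent brute-force oracle for the torsional minima of the bundled
# analytic surfaces.  It re-evaluates the per-torsion potential directly
# from the backend's recorded parameters (cosine series + Gaussian wells)
# and relaxes every node of a dense grid by bisected local descent --
# no Z-matrix, no Cartesian optimizer, no screening machinery involved.
# The bundled fixtures are separable across torsions, so the full minima
# set is the Cartesian product of the per-torsion minima.

oracle_torsion_value <- function(phi, terms, wells) {
  v <- 0
  if (!is.null(terms) && nrow(terms) > 0) {
    v <- v + sum(terms$amp * (1 + cos((terms$mult * phi - terms$phase) *
                                        pi / 180)))
  }
  if (!is.null(wells) && nrow(wells) > 0) {
    d <- (phi - wells$center) %% 360
    d <- ifelse(d > 180, d - 360, d)
    v <- v - sum(wells$depth * exp(-(d / wells$width)^2))
  }
  v
}

# all local minima of one torsional potential: relax every node of a
# `step`-degree grid downhill on a fine mesh, then polish by golden-section
# search in the surrounding bracket
oracle_torsion_minima <- function(terms, wells, step = 10, fine = 0.05) {
  f <- function(p) vapply(p, oracle_torsion_value, numeric(1),
                          terms = terms, wells = wells)
  mins <- numeric(0)
  for (start in seq(0, 360 - step, by = step)) {
    x <- start
    repeat {
      lo <- f(x - fine); mid <- f(x); hi <- f(x + fine)
      if (lo < mid) x <- x - fine
      else if (hi < mid) x <- x + fine
      else break
      x <- x %% 360
    }
    opt <- stats::optimize(f, lower = x - fine, upper = x + fine,
                           tol = 1e-10)
    xm <- opt$minimum %% 360
    if (!any(abs(((mins - xm + 180) %% 360) - 180) < 1)) {
      mins <- c(mins, xm)
    }
  }
  sort(mins)
}

# full minima set of a separable toy surface, one torsional point per row
oracle_minima <- function(backend, step = 10) {
  meta <- backend$meta
  per <- lapply(seq_along(meta$torsion_terms), function(k)
    oracle_torsion_minima(meta$torsion_terms[[k]],
                          meta$torsion_wells[[k]], step))
  grid <- expand.grid(rev(per), KEEP.OUT.ATTRS = FALSE)
  as.matrix(grid[, rev(seq_along(per)), drop = FALSE])
}

# do two torsional point sets match one-to-one within tol (circular)?
phi_sets_match <- function(found, expected, tol = 3) {
  found <- as.matrix(found); expected <- as.matrix(expected)
  if (nrow(found) != nrow(expected)) return(FALSE)
  used <- rep(FALSE, nrow(expected))
  for (i in seq_len(nrow(found))) {
    hit <- FALSE
    for (j in which(!used)) {
      if (all(torsconf::circular_distance(found[i, ], expected[j, ]) <= tol)) {
        used[j] <- TRUE; hit <- TRUE; break
      }
    }
    if (!hit) return(FALSE)
  }
  all(used)
}

conformer_phis <- function(confs) {
  if (inherits(confs, "search_state")) confs <- confs$conformers
  do.call(rbind, lapply(confs, `[[`, "phi"))
}
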