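#' Bundled toy potential-energy-surface fixtures
#'
#' A small library of analytic surfaces on model chain molecules, each a
#' [toy_chain_pes()] over a [make_chain_fixture()] Z-matrix.  They exercise
#' specific behaviors of the search:
#'
#' * `"single_well"` — one torsion, a single broad well at 180 degrees.
#' * `"shared_basin"` — same surface, but the suggested preconditioned
#'   angles `{60, 80}` both relax into the 180 well, so the second pool
#'   point must be caught by the redundancy test.
#' * `"grid3"` — two torsions, a 3-fold cosine per torsion: nine wells at
#'   the preconditioned 60/180/300 grid.
#' * `"grid27"` — three torsions, twenty-seven wells.
#' * `"offgrid95"` — one torsion, the 3-fold background plus a localized
#'   well near 95 degrees whose basin (roughly 75-123 degrees) contains no
#'   preconditioned angle: the systematic phase must miss it and the
#'   stochastic phase can find it.
#' * `"ll_hl"` — a low-level/high-level pair on the `grid3` molecule; the
#'   high-level surface has its 3-fold terms phase-shifted by 15 degrees so
#'   every low-level minimum relaxes to a nearby, distinct high-level one.
#'
#' @param name fixture name.
#' @return list with elements `zm`, `backend` (for `"ll_hl"`: `backend_ll`
#'   and `backend_hl`), `angles` (suggested preconditioned lists),
#'   `has_sym_plane`, and `d` (suggested hypercube half-edge, degrees).
#' @export
toy_pes_fixture <- function(name = c("single_well", "shared_basin", "grid3",
                                     "grid27", "offgrid95", "ll_hl")) {
  name <- match.arg(name)
  threefold <- data.frame(amp = 1.4, mult = 3, phase = 0)
  onefold <- data.frame(amp = 1.5, mult = 1, phase = 0)
  std_angles <- c(180, 60, 300)
  out <- switch(
    name,
    single_well = {
      zm <- make_chain_fixture(1)
      list(zm = zm, backend = toy_chain_pes(zm, list(onefold)),
           angles = list(std_angles), has_sym_plane = FALSE, d = 30)
    },
    shared_basin = {
      zm <- make_chain_fixture(1)
      list(zm = zm, backend = toy_chain_pes(zm, list(onefold)),
           angles = list(c(60, 80)), has_sym_plane = FALSE, d = 30)
    },
    grid3 = {
      zm <- make_chain_fixture(2)
      list(zm = zm,
           backend = toy_chain_pes(zm, list(threefold, threefold)),
           angles = list(std_angles, std_angles),
           has_sym_plane = TRUE, d = 30)
    },
    grid27 = {
      zm <- make_chain_fixture(3)
      list(zm = zm,
           backend = toy_chain_pes(zm,
                                   list(threefold, threefold, threefold)),
           angles = list(std_angles, std_angles, std_angles),
           has_sym_plane = TRUE, d = 30)
    },
    offgrid95 = {
      zm <- make_chain_fixture(1)
      wells <- list(data.frame(depth = 2.5, center = 95, width = 12))
      list(zm = zm,
           backend = toy_chain_pes(zm, list(threefold), wells),
           angles = list(std_angles), has_sym_plane = FALSE, d = 30)
    },
    ll_hl = {
      zm <- make_chain_fixture(2)
      shifted <- data.frame(amp = 1.4, mult = 3, phase = 15)
      list(zm = zm,
           backend_ll = toy_chain_pes(zm, list(threefold, threefold)),
           backend_hl = toy_chain_pes(zm, list(shifted, shifted)),
           angles = list(std_angles, std_angles),
           has_sym_plane = TRUE, d = 30)
    })
  out$name <- name
  out
}
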