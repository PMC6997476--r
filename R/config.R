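#' Read a run configuration file
#'
#' Declarative YAML configuration of a search run.  Recognized keys (all
#' except `zmatrix` have defaults):
#'
#' * `zmatrix` — path to the Gaussian-style Z-matrix file (required).
#' * `torsions` — target torsion variable names; default: every dihedral
#'   variable starting with `torsion_prefix` (default `"PHI"`).
#' * `angles` — per-torsion preconditioned guess lists; default
#'   `{180, 60, 300}` for every torsion.
#' * `has_sym_plane` — logical, default `FALSE`.
#' * `backend` — `name: toy_chain` with optional `torsion_terms`
#'   (`amp`/`mult`/`phase` per torsion) and `torsion_wells`
#'   (`depth`/`center`/`width`).
#' * `batches` — list of `{cycles, d}` stochastic batches; default none.
#' * `d`, `eps_red`, `eps_freq`, `k_bond`, `gtol` — screening and
#'   optimizer controls (defaults 30, 3, 5, 1.3, 1e-6).
#' * `seed` — RNG seed (default 1).
#' * `temperatures` — K, default `c(300, 1000, 2500)`; `lambda_zpe`
#'   (default 1); `outdir` (default `"torsconf_out"`).
#'
#' @param path YAML file path.
#' @return validated configuration list (class `torsconf_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$zmatrix)) stop("config must name a 'zmatrix' file")
  defaults <- list(torsions = NULL, torsion_prefix = "PHI", angles = NULL,
                   has_sym_plane = FALSE, backend = list(name = "toy_chain"),
                   batches = list(), d = 30, eps_red = 3, eps_freq = 5,
                   k_bond = 1.3, gtol = 1e-6, seed = 1,
                   temperatures = c(300, 1000, 2500), lambda_zpe = 1,
                   outdir = "torsconf_out")
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  for (b in cfg$batches) {
    if (is.null(b$cycles)) stop("every stochastic batch needs 'cycles'")
    if (!is.null(b$d) && b$d <= 0) stop("batch hypercube half-edge must be > 0")
  }
  if (cfg$d <= 0) stop("hypercube half-edge d must be > 0")
  if (any(cfg$temperatures <= 0)) stop("temperatures must be positive")
  cfg$config_path <- normalizePath(path)
  class(cfg) <- "torsconf_config"
  cfg
}

## assemble zmatrix + backend + angle lists from a config
build_run <- function(cfg) {
  zmdir <- dirname(cfg$config_path)
  zmpath <- cfg$zmatrix
  if (!file.exists(zmpath)) zmpath <- file.path(zmdir, cfg$zmatrix)
  zm <- read_zmatrix(zmpath, torsions = cfg$torsions,
                     torsion_prefix = cfg$torsion_prefix)
  t <- n_torsions(zm)
  angles <- cfg$angles
  if (is.null(angles)) {
    angles <- rep(list(c(180, 60, 300)), t)
  } else {
    angles <- lapply(angles, as.numeric)
    if (length(angles) != t) {
      stop("config declares ", length(angles), " angle lists for ", t,
           " torsions")
    }
  }
  bk <- cfg$backend
  if (is.null(bk$name)) bk$name <- "toy_chain"
  backend <- switch(
    bk$name,
    toy_chain = {
      terms <- if (is.null(bk$torsion_terms)) {
        rep(list(data.frame(amp = 1.4, mult = 3, phase = 0)), t)
      } else {
        lapply(bk$torsion_terms, function(tt)
          data.frame(amp = as.numeric(tt$amp),
                     mult = as.numeric(tt$mult),
                     phase = as.numeric(if (is.null(tt$phase)) 0 else tt$phase)))
      }
      wells <- if (is.null(bk$torsion_wells)) NULL else {
        lapply(bk$torsion_wells, function(wl) {
          if (is.null(wl)) return(NULL)
          data.frame(depth = as.numeric(wl$depth),
                     center = as.numeric(wl$center),
                     width = as.numeric(wl$width))
        })
      }
      toy_chain_pes(zm, terms, wells)
    },
    stop("unknown backend '", bk$name,
         "'; bundled backends: toy_chain (external programs plug in via ",
         "external_pes_adapter())"))
  list(zm = zm, backend = backend, angles = angles)
}

#' Execute a configured search run
#'
#' Reads the configuration, runs the systematic and/or stochastic phases,
#' writes all reports plus a metadata file (`run_meta.json`: config file
#' MD5, seed, package version, counters) into the output directory, and
#' returns the final state.
#'
#' @param cfg a [read_run_config()] object or a path to a YAML file.
#' @param systematic,stochastic logical switches for the two phases.
#' @return the final `search_state`, invisibly.
#' @export
run_from_config <- function(cfg, systematic = TRUE, stochastic = TRUE) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  parts <- build_run(cfg)
  control <- list(d = cfg$d, eps_red = cfg$eps_red, eps_freq = cfg$eps_freq,
                  k_bond = cfg$k_bond, gtol = cfg$gtol)
  state <- conformer_search(
    parts$zm, parts$backend, angles = parts$angles,
    has_sym_plane = isTRUE(cfg$has_sym_plane),
    batches = if (stochastic) cfg$batches else list(),
    control = control, seed = cfg$seed, systematic = systematic)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  thermo <- if (length(state$conformers) > 0) {
    thermo_from_search(state, lambda_zpe = cfg$lambda_zpe)
  }
  write_reports(state, parts$zm, cfg$outdir, thermo,
                temperatures = cfg$temperatures)
  write_checkpoint(state, file.path(cfg$outdir, "checkpoint.json"))
  meta <- list(
    config_md5 = unname(tools::md5sum(cfg$config_path)),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("torsconf")),
    r_version = as.character(getRversion()),
    backend = parts$backend$name,
    backend_meta = parts$backend$meta,
    k_bond = cfg$k_bond, d = cfg$d, eps_red = cfg$eps_red,
    eps_freq = cfg$eps_freq, lambda_zpe = cfg$lambda_zpe,
    counters = list(K1 = state$K1, K1_star = state$K1_star,
                    K2 = state$K2, K2_star = state$K2_star,
                    J = state_J(state)))
  jsonlite::write_json(meta, file.path(cfg$outdir, "run_meta.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(state)
}
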