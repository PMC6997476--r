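#' Search-efficiency table
#'
#' One-row summary of a finished run: number of torsions, systematic pool
#' size `K1` and promoted trials `K1*`, conformers from the systematic
#' phase `J1`, stochastic cycles `K2` and promoted trials `K2*`,
#' stochastic conformers `J2`, and the total `J_LL = J1 + J2`.
#'
#' @param state a `search_state`.
#' @return one-row data frame.
#' @export
efficiency_table <- function(state) {
  prov <- vapply(state$conformers, `[[`, character(1), "provenance")
  J1 <- sum(prov == "systematic")
  J2 <- sum(startsWith(prov, "stochastic"))
  data.frame(t = state$t, K1 = state$K1, K1_star = state$K1_star,
             J1 = J1, K2 = state$K2, K2_star = state$K2_star, J2 = J2,
             J_LL = J1 + J2)
}

#' Write run reports
#'
#' Writes the tabular artifacts of a run into `dir`: the efficiency table
#' (`efficiency.tsv`), the conformer table (`conformers.tsv`), the
#' plain-text run log (`run.log`, one line per guess with phase, torsional
#' point, verdict and reason), an XYZ trajectory of the conformers
#' (`conformers.xyz`) and, when a thermo input and temperatures are given,
#' the per-temperature partition-function table (`thermo.csv`) and the
#' minimum-conformer-count table (`minconf.tsv`).  Angles in the reports
#' are printed with two decimals; full precision is retained in the
#' checkpoint.
#'
#' @param state a `search_state`.
#' @param zm the [zmatrix()] of the run (for element symbols).
#' @param dir output directory (created if missing).
#' @param thermo optional [thermo_input()].
#' @param temperatures temperatures (K) for the thermo tables.
#' @param threshold population fraction for the minimum-conformer table.
#' @return character vector of the files written, invisibly.
#' @export
write_reports <- function(state, zm, dir, thermo = NULL,
                          temperatures = NULL, threshold = 0.9) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  p <- file.path(dir, "efficiency.tsv")
  utils::write.table(efficiency_table(state), p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, p)
  p <- file.path(dir, "conformers.tsv")
  write_conformer_table(state, p)
  files <- c(files, p)
  p <- file.path(dir, "run.log")
  writeLines(state$log, p)
  files <- c(files, p)
  if (length(state$conformers) > 0) {
    p <- file.path(dir, "conformers.xyz")
    write_xyz(lapply(state$conformers, `[[`, "cart"), zm$elements, p,
              comment = vapply(state$conformers, function(cf)
                sprintf("conformer %d  E = %.6f kcal/mol  phi = (%s)",
                        cf$id, cf$energy,
                        paste(sprintf("%.2f", cf$phi), collapse = ", ")),
                character(1)))
    files <- c(files, p)
  }
  if (!is.null(thermo) && !is.null(temperatures)) {
    p <- file.path(dir, "thermo.csv")
    utils::write.csv(thermo_table(thermo, temperatures), p,
                     row.names = FALSE)
    files <- c(files, p)
    p <- file.path(dir, "minconf.tsv")
    utils::write.table(
      min_conformers_for_fraction(thermo, temperatures, threshold), p,
      sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, p)
  }
  invisible(files)
}
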