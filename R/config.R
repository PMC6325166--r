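# Run configuration shared by the profiling, assignment and pipeline layers.

#' Workflow configuration
#'
#' All tunable thresholds of the three-stage workflow in one list, echoed
#' verbatim into pipeline outputs for provenance. Defaults reflect a
#' unit-resolution QTRAP acquisition with HILIC subclass separation.
#'
#' @param tolerance_da Peak-matching half-window in Da (default 0.3).
#' @param rel_int_floor Peak-picking floor for profile scans, as a percentage
#'   of the subclass base peak (default 0.1).
#' @param rt_windows Named list of per-subclass retention-time windows
#'   (minutes) used both to gate profile hits and to carry into target lists.
#' @param grid_carbons,grid_db Total-composition grid (carbons, double bonds)
#'   that profile peaks are matched against; odd totals allowed (odd-carbon
#'   chains occur).
#' @param chain_carbons Per-chain carbon range enumerated during chain
#'   assignment.
#' @param dominance_ratio Rank-1 : rank-2 intensity ratio above which a single
#'   acyl composition is called dominant (default 3).
#' @param s_min Minimum signal-to-noise for each diagnostic ion (default 3).
#' @param fa_fo_ratio_limit The aldehyde and olefin ions of one C=C must have
#'   intensities within a factor `r` of each other (default 5); encodes the
#'   expectation that a true pair appears at similar intensities.
#' @param mz_range Named list of per-subclass m/z acquisition ranges applied
#'   when exporting PB target lists.
#' @param constraint Candidate-position constraint for polyunsaturated chains:
#'   `"methylene-interrupted"` (default) or `"unconstrained"`.
#' @param enable_pa_ps Include PA/PS in profiling grids (default `FALSE`;
#'   templates exist but no profiling scans are defined for them).
#' @param ether_cc Attempt C=C assignment on ether chains (default `FALSE`).
#' @param seed Seed recorded for any stochastic step.
#' @return A list with class `pb_config`.
#' @export
pb_config <- function(tolerance_da = 0.3,
                      rel_int_floor = 0.1,
                      rt_windows = list(PE = c(5.1, 6.5), PC = c(13.8, 15.1),
                                        PG = c(0, 5), PI = c(0, 5),
                                        FA = c(0, 20)),
                      grid_carbons = 24:48,
                      grid_db = 0:8,
                      chain_carbons = 2:26,
                      dominance_ratio = 3,
                      s_min = 3,
                      fa_fo_ratio_limit = 5,
                      mz_range = list(PE = c(350, 1000), PC = c(500, 1000),
                                      PG = c(100, 400), PI = c(100, 400),
                                      FA = c(100, 400)),
                      constraint = "methylene-interrupted",
                      enable_pa_ps = FALSE,
                      ether_cc = FALSE,
                      seed = 1L) {
  stopifnot(tolerance_da > 0, rel_int_floor >= 0, dominance_ratio >= 1,
            s_min >= 0, fa_fo_ratio_limit >= 1)
  structure(list(
    tolerance_da = tolerance_da, rel_int_floor = rel_int_floor,
    rt_windows = rt_windows, grid_carbons = grid_carbons, grid_db = grid_db,
    chain_carbons = chain_carbons, dominance_ratio = dominance_ratio,
    s_min = s_min, fa_fo_ratio_limit = fa_fo_ratio_limit,
    mz_range = mz_range, constraint = constraint,
    enable_pa_ps = enable_pa_ps, ether_cc = ether_cc, seed = seed
  ), class = "pb_config")
}

#' @export
print.pb_config <- function(x, ...) {
  cat("<pb_config>\n")
  cat("  tolerance:", x$tolerance_da, "Da | floor:", x$rel_int_floor,
      "% | S/N >=", x$s_min, "| F_A:F_O within", x$fa_fo_ratio_limit,
      "x | dominance", x$dominance_ratio, ": 1\n")
  cat("  grid: C", min(x$grid_carbons), "-", max(x$grid_carbons), ", DB ",
      min(x$grid_db), "-", max(x$grid_db), "; candidate constraint: ",
      x$constraint, "\n", sep = "")
  invisible(x)
}
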