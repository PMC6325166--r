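# End-to-end orchestration of the three-stage workflow: subclass profiling ->
# chain assignment -> PB targets -> C=C assignment -> isomer ratios, with an
# optional cohort statistics stage, per-stage counts and CSV/TSV exports.

#' Run the full C=C localization workflow
#'
#' Executes [profile_subclass()] over the requested subclasses,
#' [build_chain_targets()], [assign_chains()], [build_pb_targets()],
#' [assign_cc()] and [isomer_ratio()] on one body of spectra (in-memory
#' tibble or MGF files). Stage failures are isolated per lipid: species that
#' cannot be carried forward are counted and reported, not fatal.
#'
#' @param spectra A spectra tibble, or `NULL` if `mgf` is given.
#' @param mgf Character vector of MGF paths read with [read_mgf()].
#' @param config A [pb_config()].
#' @param subclasses Subclasses to profile.
#' @param fa_species Free fatty acids to target directly (e.g. `"FA 18:1"`);
#'   free acids have no headgroup scan, so their PB targets are declared
#'   rather than profiled.
#' @param cohort Optional long sample-ratio table; when present the
#'   statistics stage ([compare_groups()], [hcluster()]) is run on it.
#' @param output_dir Optional directory: reports are written as CSV and the
#'   target lists as instrument-ready TSV.
#' @return A list of tibbles: `hits`, `chain_targets`, `chain_assignments`,
#'   `pb_targets`, `cc`, `ratios`, `ratio_summary`, `stats` (or `NULL`),
#'   `summary` (per-stage counts), and the echoed `config`.
#' @export
run_pipeline <- function(spectra = NULL, mgf = NULL, config = pb_config(),
                         subclasses = c("PE", "PC", "PG", "PI"),
                         fa_species = NULL, cohort = NULL,
                         output_dir = NULL) {
  if (is.null(spectra) && is.null(mgf)) {
    stop("supply `spectra` or `mgf`", call. = FALSE)
  }
  if (!inherits(config, "pb_config")) stop("`config` must be a pb_config()",
                                           call. = FALSE)
  if (!is.null(mgf)) {
    spectra <- dplyr::bind_rows(lapply(mgf, read_mgf))
  }

  hits <- dplyr::bind_rows(lapply(subclasses, function(sc)
    profile_subclass(spectra, sc, config)))
  chain_targets <- build_chain_targets(hits, config)
  chain_assignments <- assign_chains(spectra, chain_targets, config)
  if (!is.null(fa_species)) {
    fa_rows <- dplyr::bind_rows(lapply(fa_species, function(s) {
      sp <- parse_lipid(s)
      for (sid in unique(spectra$sample_id)) {
        return(tibble::tibble(
          hit_id = paste0(sid, "|", format(sp, level = "chain")),
          sample_id = sid, subclass = "FA",
          species = format(sp, level = "chain"),
          chain_1 = format(sp$chains[[1]], show_positions = FALSE),
          chain_2 = NA_character_, anion_mz_1 = acyl_anion_mz(sp$chains[[1]]),
          anion_mz_2 = NA_real_, score = NA_real_, rank = 1L,
          dominant = TRUE, chains_resolved = TRUE, rt_min = NA_real_,
          scan_id = NA_character_))
      }
    }))
    chain_assignments <- dplyr::bind_rows(chain_assignments, fa_rows)
  }
  pb_targets <- build_pb_targets(chain_assignments, config)
  cc <- assign_cc(spectra, chain_assignments, config)
  if (nrow(cc) > 0) cc <- annotate_omega(cc)
  ratios <- isomer_ratio(cc)
  ratio_summary <- if (nrow(ratios) > 0) summarize_ratios(ratios) else
    ratios[0, 0]

  stats_out <- NULL
  if (!is.null(cohort)) {
    stats_out <- list(
      comparisons = compare_groups(cohort),
      clustering_ratio = hcluster(cohort, kind = "ratio"),
      clustering_subclass = hcluster(cohort, kind = "subclass"),
      rsd = rsd_decomposition(cohort))
  }

  n_unsat <- sum(chain_assignments$dominant & chain_assignments$chains_resolved &
                   .total_db(chain_assignments) > 0, na.rm = TRUE)
  localized <- if (nrow(cc) > 0) {
    cc |>
      dplyr::filter(.data$composition_rank == 1) |>
      dplyr::group_by(.data$sample_id, .data$lipid) |>
      dplyr::summarise(ok = any(!.data$unassigned), .groups = "drop")
  } else tibble::tibble(ok = logical())
  summary <- tibble::tibble(
    stage = c("profile_hits", "species_annotated", "chains_resolved",
              "pb_targets", "species_cc_attempted", "species_cc_localized",
              "pct_localized"),
    value = c(nrow(hits), sum(hits$matched),
              sum(chain_assignments$dominant &
                    chain_assignments$chains_resolved, na.rm = TRUE),
              nrow(pb_targets), nrow(localized), sum(localized$ok),
              if (nrow(localized) > 0)
                round(100 * mean(localized$ok), 1) else NA_real_))

  out <- list(hits = hits, chain_targets = chain_targets,
              chain_assignments = chain_assignments, pb_targets = pb_targets,
              cc = cc, ratios = ratios, ratio_summary = ratio_summary,
              stats = stats_out, summary = summary, config = config)
  if (!is.null(output_dir)) export_reports(out, output_dir)
  out
}

.total_db <- function(assignments) {
  db <- function(x) ifelse(is.na(x), 0L, as.integer(sub(".*:", "", x)))
  db(assignments$chain_1) + db(assignments$chain_2)
}

#' Export pipeline reports to disk
#'
#' CSV identification/ratio tables plus tab-delimited instrument target lists.
#'
#' @param reports Output of [run_pipeline()].
#' @param output_dir Directory (created if needed).
#' @return `output_dir`, invisibly.
#' @export
export_reports <- function(reports, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    if (is.null(df) || nrow(df) == 0) return(invisible(NULL))
    df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
    utils::write.csv(df, file.path(output_dir, paste0(name, ".csv")),
                     row.names = FALSE)
  }
  wr(reports$hits, "subclass_hits")
  wr(reports$chain_assignments, "chain_assignments")
  wr(reports$cc, "cc_assignments")
  wr(reports$ratios, "isomer_ratios")
  wr(reports$ratio_summary, "isomer_ratio_summary")
  wr(reports$summary, "pipeline_summary")
  if (!is.null(reports$stats)) {
    wr(tibble::as_tibble(reports$stats$comparisons), "group_comparisons")
    wr(reports$stats$rsd, "rsd_decomposition")
  }
  make_target_lists(reports, "chain",
                    file.path(output_dir, "targets_chain.tsv"))
  make_target_lists(reports, "pb", file.path(output_dir, "targets_pb.tsv"))
  cfg <- reports$config
  writeLines(utils::capture.output(utils::str(unclass(cfg))),
             file.path(output_dir, "config_echo.txt"))
  invisible(output_dir)
}

#' Export an instrument-ready precursor target list
#'
#' Tab-delimited columns: m/z, RT window, polarity and a collision-energy
#' placeholder, in the shape consumed by triple-quadrupole acquisition
#' software.
#'
#' @param reports Output of [run_pipeline()] (or a list holding
#'   `chain_targets` / `pb_targets`).
#' @param stage `"chain"` or `"pb"`.
#' @param path Output TSV path, or `NULL` to return the tibble only.
#' @return The target tibble, invisibly when written.
#' @export
make_target_lists <- function(reports, stage = c("chain", "pb"),
                              path = NULL) {
  stage <- match.arg(stage)
  tg <- if (stage == "chain") reports$chain_targets else reports$pb_targets
  if (is.null(tg) || nrow(tg) == 0) {
    warning("no ", stage, " targets to export", call. = FALSE)
    out <- tibble::tibble(mz = numeric(), rt_lo = numeric(),
                          rt_hi = numeric(), polarity = character(),
                          collision_energy = numeric(), species = character())
  } else if (stage == "chain") {
    out <- tibble::tibble(mz = round(tg$target_mz, 4), rt_lo = tg$rt_lo,
                          rt_hi = tg$rt_hi, polarity = tg$polarity,
                          collision_energy = NA_real_, species = tg$species)
  } else {
    out <- tibble::tibble(mz = round(tg$pb_mz, 4), rt_lo = tg$rt_lo,
                          rt_hi = tg$rt_hi, polarity = tg$polarity,
                          collision_energy = NA_real_, species = tg$species)
  }
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}
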