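# Seeded simulator for the three scan layers of the workflow (subclass
# profiling, negative-mode chain analysis, PB-MS/MS) and for cohort ratio
# tables. This is the package's test and demonstration substrate: the
# generator's defaults encode the study conditions (PB conversion yield
# 20-30%, > 90% single acetone addition, a PE/PC isobaric pair resolved only
# by retention time, odd-carbon chains, the canonical mammalian isomer
# ratios), and every random draw is controlled by a single seed.

#' Generate a ground-truth lipidome
#'
#' Each row is one molecular species at C=C location level; rows sharing
#' subclass + chains are C=C location isomers whose `fraction`s give the true
#' isomer mixing ratio. The `"bovine_liver"` template carries the canonical
#' mammalian isomer pairs (C18:1 delta-9 major / delta-11 minor, C16:1
#' delta-9 / delta-7, PUFA omega-3/omega-6 mixtures), the PE 39:4 / PC 36:4
#' isobaric pair (identical formula C44H80NO8P, separated only by scan type
#' and retention time), odd-carbon chains and a free fatty acid.
#'
#' @param n_species Number of acyl-level species to keep (>= 20 retains the
#'   isobar pair and an odd-carbon species; the full template holds 24).
#' @param template `"bovine_liver"` (the only built-in) or a tibble in the
#'   same shape to use directly.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A tibble: `species_id`, `subclass`, `chain_1`, `chain_2`,
#'   `cc_chain`, `positions`, `fraction`, `abundance`, `rt_min`.
#' @export
generate_lipidome <- function(n_species = 20, template = "bovine_liver",
                              seed = 1L) {
  if (is.data.frame(template)) {
    truth <- tibble::as_tibble(template)
  } else {
    truth <- .bovine_liver_template()
  }
  if (n_species == 0) return(truth[0, ])
  keep <- unique(truth$acyl_id)[seq_len(min(n_species, length(unique(truth$acyl_id))))]
  truth <- truth[truth$acyl_id %in% keep, ]
  withr_seed <- .with_seed(seed, {
    # per-species abundance: log-normal spread around the template weight,
    # reproducing the wide dynamic range of a real profile
    truth$abundance <- truth$weight *
      stats::rlnorm(nrow(truth), 0, 0.25) * truth$fraction
    truth$rt_min <- truth$rt_center +
      stats::rnorm(nrow(truth), 0, 0.1)  # chromatographic jitter, sigma 0.1 min
  })
  truth$rt_min <- pmin(pmax(truth$rt_min, truth$rt_lo), truth$rt_hi)
  truth$species_id <- paste0(truth$acyl_id, "|", truth$positions)
  truth[, c("species_id", "acyl_id", "subclass", "chain_1", "chain_2",
            "cc_chain", "positions", "fraction", "abundance", "rt_min")]
}

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(code))
}

.bovine_liver_template <- function() {
  row <- function(subclass, chain_1, chain_2, cc_chain, positions, fraction,
                  weight) {
    windows <- list(PE = c(5.1, 6.5), PC = c(13.8, 15.1), PG = c(1, 4.5),
                    PI = c(1, 4.5), FA = c(0.5, 2))
    w <- windows[[subclass]]
    chains <- if (is.na(chain_2)) chain_1 else paste(chain_1, chain_2,
                                                     sep = "_")
    tibble::tibble(acyl_id = paste(subclass, chains),
                   subclass = subclass, chain_1 = chain_1, chain_2 = chain_2,
                   cc_chain = cc_chain, positions = positions,
                   fraction = fraction, weight = weight,
                   rt_lo = w[1], rt_hi = w[2])
  }
  tpl <- dplyr::bind_rows(
    # C18:1 delta-9 major / delta-11 minor throughout
    row("PE", "16:0", "18:1", "18:1", "9", 0.75, 1.0),
    row("PE", "16:0", "18:1", "18:1", "11", 0.25, 1.0),
    row("PE", "17:0", "22:4", "22:4", "7,10,13,16", 1.0, 0.02),  # odd chain
    row("PC", "16:0", "20:4", "20:4", "5,8,11,14", 1.0, 0.6),    # isobar of PE 39:4
    row("PC", "16:0", "18:1", "18:1", "9", 6 / 7, 1.0),
    row("PC", "16:0", "18:1", "18:1", "11", 1 / 7, 1.0),
    row("PE", "18:0", "18:1", "18:1", "9", 0.75, 0.5),
    row("PE", "18:0", "18:1", "18:1", "11", 0.25, 0.5),
    row("PE", "18:1", "18:1", "18:1", "9", 0.75, 0.3),
    row("PE", "18:1", "18:1", "18:1", "11", 0.25, 0.3),
    row("PC", "18:1", "18:1", "18:1", "9", 0.72, 0.4),
    row("PC", "18:1", "18:1", "18:1", "11", 0.24, 0.4),
    row("PC", "18:1", "18:1", "18:1", "10", 0.04, 0.4),  # unusual minor isomer
    row("PE", "16:0", "16:1", "16:1", "9", 5 / 6, 0.35),
    row("PE", "16:0", "16:1", "16:1", "7", 1 / 6, 0.35),
    row("PC", "15:0", "18:2", "18:2", "9,12", 0.8, 0.25),   # omega-6 major
    row("PC", "15:0", "18:2", "18:2", "6,9", 0.2, 0.25),    # omega-9 minor
    row("PE", "18:0", "18:2", "18:2", "9,12", 0.8, 0.45),
    row("PE", "18:0", "18:2", "18:2", "6,9", 0.2, 0.45),
    row("PC", "16:0", "18:3", "18:3", "9,12,15", 0.6, 0.15),  # omega-3
    row("PC", "16:0", "18:3", "18:3", "6,9,12", 0.4, 0.15),   # omega-6
    row("PE", "18:0", "20:4", "20:4", "5,8,11,14", 1.0, 0.8),
    row("PC", "16:0", "16:0", NA, NA, 1.0, 0.7),  # saturated: no PB target
    row("PE", "16:0", "18:0", NA, NA, 1.0, 0.25),
    row("PG", "16:0", "18:1", "18:1", "9", 0.8, 0.3),
    row("PG", "16:0", "18:1", "18:1", "11", 0.2, 0.3),
    row("PI", "18:0", "20:4", "20:4", "5,8,11,14", 1.0, 0.5),
    row("FA", "18:1", NA, "18:1", "9", 0.9, 0.4),
    row("FA", "18:1", NA, "18:1", "11", 0.1, 0.4)
  )
  tpl$rt_center <- NA_real_
  for (id in unique(tpl$acyl_id)) {
    i <- tpl$acyl_id == id
    lo <- tpl$rt_lo[i][1]; hi <- tpl$rt_hi[i][1]
    # deterministic spread of species across the subclass window
    pos <- which(unique(tpl$acyl_id) == id)
    tpl$rt_center[i] <- lo + (hi - lo) * ((pos * 7) %% 13 + 1) / 14
  }
  tpl
}

#' Simulation parameters for [simulate_run()]
#'
#' @param pb_yield PB conversion yield (fraction of precursor converted;
#'   default 0.25, within the moderate 20-30% regime).
#' @param single_addition_fraction Fraction of PB product carrying a single
#'   acetone (default 0.93, > 0.9); the remainder appears as a +116 Da
#'   double-addition background ion.
#' @param mz_jitter_sd Gaussian m/z jitter applied to every peak (Da).
#' @param intensity_cv Multiplicative (log-normal) intensity noise CV.
#' @param background_density Uniform-random background peaks per 100 Da of
#'   spectrum range (Norrish-type side products and chemical noise).
#' @param background_intensity Mean intensity of background peaks relative to
#'   the base diagnostic ion (default 0.02).
#' @param base_intensity Intensity scale of the most abundant species.
#' @return A list.
#' @export
sim_params <- function(pb_yield = 0.25, single_addition_fraction = 0.93,
                       mz_jitter_sd = 0.01, intensity_cv = 0.05,
                       background_density = 2, background_intensity = 0.02,
                       base_intensity = 1e4) {
  stopifnot(pb_yield > 0, pb_yield <= 1,
            single_addition_fraction > 0, single_addition_fraction <= 1)
  list(pb_yield = pb_yield,
       single_addition_fraction = single_addition_fraction,
       mz_jitter_sd = mz_jitter_sd, intensity_cv = intensity_cv,
       background_density = background_density,
       background_intensity = background_intensity,
       base_intensity = base_intensity)
}

#' Noise-free simulation parameters
#'
#' Zero jitter, zero intensity noise, no background: every theoretical ion
#' appears at its exact m/z, so a correct pipeline recovers the ground truth
#' completely.
#' @return A list (see [sim_params()]).
#' @export
sim_params_noise_free <- function() {
  sim_params(mz_jitter_sd = 0, intensity_cv = 0, background_density = 0)
}

#' Simulate the three scan layers for a ground-truth lipidome
#'
#' Emits (1) NLS/PIS profile pseudo-spectra whose peaks are species precursor
#' ions with intensity proportional to abundance, (2) negative-mode EPI chain
#' spectra containing the carboxylate anions of both chains, and (3) PB EPI
#' spectra containing the full aldehyde/olefin diagnostic pair of every true
#' C=C with intensity proportional to isomer fraction x PB yield, plus a
#' residual (unreacted + double-addition) precursor region and optional
#' uniform background. All randomness is governed by `seed`; a fixed seed
#' gives byte-identical MGF output.
#'
#' @param truth Output of [generate_lipidome()].
#' @param params [sim_params()].
#' @param seed Integer seed.
#' @param sample_id Sample identifier stamped on every scan.
#' @return A single spectra tibble holding all three layers (distinguished by
#'   `scan_type`).
#' @export
simulate_run <- function(truth, params = sim_params(), seed = 1L,
                         sample_id = "sample") {
  .with_seed(seed, .simulate_run_impl(truth, params, sample_id))
}

.simulate_run_impl <- function(truth, params, sample_id) {
  jit <- function(mz) mz + if (params$mz_jitter_sd > 0)
    stats::rnorm(length(mz), 0, params$mz_jitter_sd) else 0
  noisy <- function(x) x * if (params$intensity_cv > 0)
    stats::rlnorm(length(x), -params$intensity_cv^2 / 2,
                  params$intensity_cv) else 1
  background <- function(lo, hi) {
    n <- stats::rpois(1, params$background_density * (hi - lo) / 100)
    if (n == 0 || params$background_density == 0) {
      return(tibble::tibble(mz = numeric(), intensity = numeric()))
    }
    tibble::tibble(
      mz = stats::runif(n, lo, hi),
      intensity = stats::rexp(n, 1 / (params$background_intensity *
                                        params$base_intensity)))
  }
  scale <- params$base_intensity / max(truth$abundance)

  specs <- list()
  add <- function(s) specs[[length(specs) + 1]] <<- s

  map <- subclass_adducts()
  acyl <- truth |>
    dplyr::group_by(.data$acyl_id, .data$subclass, .data$chain_1,
                    .data$chain_2) |>
    dplyr::summarise(abundance = sum(.data$abundance),
                     rt_min = mean(.data$rt_min), .groups = "drop")

  # ---- layer 1: profile pseudo-spectra, one per subclass per RT cluster ----
  for (sc in intersect(unique(acyl$subclass), c("PE", "PC", "PG", "PI"))) {
    rows <- acyl[acyl$subclass == sc, ]
    scan <- headgroup_scan(sc, map$profile_polarity[map$subclass == sc])
    delta <- adduct_info(map$profile_adduct[map$subclass == sc])$delta
    rows$rt_bin <- round(rows$rt_min, 1)
    for (b in unique(rows$rt_bin)) {
      rb <- rows[rows$rt_bin == b, ]
      mz <- vapply(seq_len(nrow(rb)), function(i) {
        chains <- if (is.na(rb$chain_2[i])) rb$chain_1[i] else
          c(rb$chain_1[i], rb$chain_2[i])
        monoisotopic_mass(formula_of_species(lipid_species(sc, chains))) +
          delta
      }, numeric(1))
      pk <- tibble::tibble(mz = jit(mz),
                           intensity = noisy(rb$abundance * scale))
      pk <- dplyr::bind_rows(pk, background(min(mz) - 50, max(mz) + 50))
      add(spectra_tibble(
        scan_id = sprintf("%s_profile_%s_rt%.1f", sample_id, sc, b),
        scan_type = scan$mode, polarity = scan$polarity,
        precursor_mz = NA_real_, rt_min = b, peaks = list(pk),
        sample_id = sample_id))
    }
  }

  # ---- layer 2: negative-mode chain-analysis EPI spectra ----
  for (i in seq_len(nrow(acyl))) {
    a <- acyl[i, ]
    if (a$subclass == "FA") next
    chains <- c(a$chain_1, a$chain_2)
    sp <- lipid_species(a$subclass, chains)
    prec <- precursor_mz(sp, map$chain_adduct[map$subclass == a$subclass])
    anions <- vapply(chains, acyl_anion_mz, numeric(1))
    ints <- a$abundance * scale * c(1, 0.9)  # near-equal anion response
    pk <- tibble::tibble(mz = jit(unname(anions)), intensity = noisy(ints))
    pk <- dplyr::bind_rows(pk, background(100, prec + 10))
    add(spectra_tibble(
      scan_id = sprintf("%s_chain_%s", sample_id, gsub("[ :]", "", a$acyl_id)),
      scan_type = "EPI-MS2", polarity = "negative", precursor_mz = prec,
      rt_min = a$rt_min, peaks = list(pk), sample_id = sample_id))
  }

  # ---- layer 3: PB-MS/MS EPI spectra ----
  pb <- truth[!is.na(truth$positions), ]
  for (id in unique(pb$acyl_id)) {
    rows <- pb[pb$acyl_id == id, ]
    sc <- rows$subclass[1]
    chains <- if (is.na(rows$chain_2[1])) rows$chain_1[1] else
      c(rows$chain_1[1], rows$chain_2[1])
    sp <- lipid_species(sc, chains)
    total_ab <- sum(rows$abundance)
    if (sc %in% c("PE", "PC")) {
      adduct <- "[M+H]+"; polarity <- "positive"
      prec_list <- list(list(prec = pb_precursor_mz(sp, adduct),
                             chain_filter = NA_character_))
    } else if (sc == "FA") {
      adduct <- "[M-H]-"; polarity <- "negative"
      prec_list <- list(list(prec = pb_precursor_mz(sp, adduct),
                             chain_filter = NA_character_))
    } else {
      adduct <- "[M-H]-"; polarity <- "negative"
      prec_list <- lapply(unique(rows$cc_chain), function(ch)
        list(prec = acyl_anion_mz(ch) + 58.041865, chain_filter = ch))
    }
    for (pl in prec_list) {
      pk <- tibble::tibble(mz = numeric(), intensity = numeric())
      for (r in seq_len(nrow(rows))) {
        if (!is.na(pl$chain_filter) &&
            rows$cc_chain[r] != pl$chain_filter) next
        set <- as.integer(strsplit(rows$positions[r], ",")[[1]])
        ch <- parse_chain(rows$cc_chain[r])
        ch <- acyl_chain(ch$carbons, length(set), positions = set)
        pr <- diagnostic_pairs(sp, ch, set, adduct)
        ion_int <- rows$abundance[r] * scale * params$pb_yield /
          (2 * length(set))
        pk <- dplyr::bind_rows(pk, tibble::tibble(
          mz = jit(c(pr$fa_mz, pr$fo_mz)),
          intensity = noisy(rep(ion_int, 2 * nrow(pr)))))
      }
      if (nrow(pk) == 0) next
      # residual single-addition precursor + double-addition satellite
      prec_int <- total_ab * scale * params$pb_yield * 0.5
      pk <- dplyr::bind_rows(pk, tibble::tibble(
        mz = jit(pl$prec), intensity = noisy(prec_int)))
      if (params$single_addition_fraction < 1) {
        dbl <- prec_int * (1 - params$single_addition_fraction) /
          params$single_addition_fraction
        pk <- dplyr::bind_rows(pk, tibble::tibble(
          mz = jit(pl$prec + 58.041865), intensity = noisy(dbl)))
      }
      pk <- dplyr::bind_rows(pk, background(100, pl$prec + 80))
      add(spectra_tibble(
        scan_id = sprintf("%s_pb_%s%s", sample_id,
                          gsub("[ :]", "", id),
                          if (is.na(pl$chain_filter)) "" else
                            paste0("_", gsub(":", "", pl$chain_filter))),
        scan_type = "EPI-PB", polarity = polarity, precursor_mz = pl$prec,
        rt_min = rows$rt_min[1], peaks = list(pk), sample_id = sample_id))
    }
  }
  dplyr::bind_rows(specs)
}

#' Simulate a two-group cohort of isomer-ratio and subclass measurements
#'
#' Generates a long sample-ratio table with nested technical repeats. Ratio
#' measurements carry small biological variation (default CV 10%); subclass
#' I/I_IS measurements carry large biological variation (default CV 40%),
#' reproducing the precision contrast between the two measurement kinds.
#' Group effects are supplied as per-lipid mean shifts.
#'
#' @param effects A tibble with columns `lipid`, `kind` (`"ratio"` or
#'   `"subclass"`), `mean_1`, `mean_2` (group means). `NULL` uses a built-in
#'   plasma-like panel: 19 C18:1 delta-9/delta-11 ratio pairs of which 7 are
#'   shifted (magnitudes like 5.0 -> 3.7 and 2.4 -> 4.8), and 20 subclass
#'   measurements of which 2 are modestly shifted.
#' @param n_per_group Biological individuals per group (default 6).
#' @param tech_reps Technical repeats per individual (default 3).
#' @param bio_cv_ratio,bio_cv_subclass Biological (inter-individual) CVs.
#' @param tech_cv Technical repeat CV (default 0.08).
#' @param seed Integer seed.
#' @param groups Group labels.
#' @return A long table: `sample_id`, `group`, `individual`, `tech_rep`,
#'   `lipid`, `kind`, `value`; the effects panel is attached as
#'   `attr(, "effects")`.
#' @export
simulate_cohort <- function(effects = NULL, n_per_group = 6, tech_reps = 3,
                            bio_cv_ratio = 0.10, bio_cv_subclass = 0.40,
                            tech_cv = 0.08, seed = 1L,
                            groups = c("control", "case")) {
  stopifnot(length(groups) >= 2)
  if (is.null(effects)) effects <- cohort_effects_plasma()
  .with_seed(seed, {
    rows <- list()
    for (g in seq_along(groups)) {
      for (ind in seq_len(n_per_group)) {
        ind_id <- paste0(groups[g], "_", ind)
        for (l in seq_len(nrow(effects))) {
          mu <- effects[[if (g == 1) "mean_1" else "mean_2"]][l]
          cv <- if (effects$kind[l] == "ratio") bio_cv_ratio else
            bio_cv_subclass
          ind_mean <- mu * stats::rlnorm(1, -cv^2 / 2, cv)
          for (r in seq_len(tech_reps)) {
            rows[[length(rows) + 1]] <- tibble::tibble(
              sample_id = ind_id, group = groups[g], individual = ind_id,
              tech_rep = r, lipid = effects$lipid[l], kind = effects$kind[l],
              value = ind_mean * stats::rlnorm(1, -tech_cv^2 / 2, tech_cv))
          }
        }
      }
    }
    out <- dplyr::bind_rows(rows)
    attr(out, "effects") <- effects
    if (n_per_group == 1) attr(out, "untestable") <- TRUE
    out
  })
}

#' Built-in plasma-like cohort effect panel
#'
#' 19 C18:1 delta-9/delta-11 isomer-ratio measurements (7 with group shifts
#' of the magnitude seen between control and disease plasma, e.g. 5.0 -> 3.7
#' and 2.4 -> 4.8) and 20 subclass-level I/I_IS measurements (2 modestly
#' shifted); the remainder null.
#'
#' @return An effects tibble for [simulate_cohort()].
#' @export
cohort_effects_plasma <- function() {
  ratio_base <- c(5.0, 2.4, 3.0, 4.2, 2.8, 6.0, 3.5,
                  4.0, 3.2, 2.6, 5.5, 4.8, 3.8, 2.9, 4.4, 3.3, 5.1, 2.7, 3.6)
  ratio_shift <- c(3.7, 4.8, 6.1, 2.9, 4.1, 4.2, 5.2,  # 7 shifted pairs
                   ratio_base[8:19])                    # 12 null
  subclass_base <- seq(0.1, 2.0, length.out = 20)
  subclass_shift <- subclass_base
  subclass_shift[c(3, 11)] <- subclass_base[c(3, 11)] * 1.3
  dplyr::bind_rows(
    tibble::tibble(lipid = paste0("ratio_lipid_", sprintf("%02d", 1:19)),
                   kind = "ratio", mean_1 = ratio_base, mean_2 = ratio_shift),
    tibble::tibble(lipid = paste0("subclass_lipid_", sprintf("%02d", 1:20)),
                   kind = "subclass", mean_1 = subclass_base,
                   mean_2 = subclass_shift))
}
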