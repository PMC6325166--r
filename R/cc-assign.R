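# Stage 3: de novo C=C localization from PB-MS/MS spectra and relative
# quantitation of C=C location isomers.

#' De novo C=C assignment from PB-MS/MS spectra
#'
#' For every PB target whose spectrum is found (precursor within tolerance,
#' retention time in window, same sample), each unsaturated chain of the
#' dominant composition is interrogated: candidate positions (monounsaturated)
#' or candidate position sets (polyunsaturated, methylene-interrupted by
#' default) are enumerated, the theoretical aldehyde/olefin pair is computed
#' for every position, and a candidate survives only when *both* ions of
#' *every* position match, each with signal-to-noise at or above `s_min` and
#' with the two intensities within a factor `fa_fo_ratio_limit` of each other.
#'
#' Surviving single-bond positions are reported as coexisting C=C location
#' isomers (the chain's declared double-bond count says how many bonds one
#' molecule carries; surplus complete pairs are isomers, not extra bonds).
#' For polyunsaturated chains every complete candidate set is reported,
#' ranked by summed evidence; the top set is the major isomer. Assignments
#' whose summed intensity falls below 10 percent of the chain's top assignment
#' are flagged `low_confidence` (alternative structures possible) but not
#' suppressed.
#'
#' Ions that collide (within tolerance) with ions of another accepted
#' assignment are flagged; collision-tainted assignments are excluded from
#' isomer ratios. Minor (non-dominant) compositions are only assigned where
#' their ions are collision-free against every candidate ion of the dominant
#' composition, mirroring the "do not report overlapped minor species" rule.
#' Chains with no surviving candidate are returned flagged `unassigned`.
#'
#' @param spectra A spectra tibble holding `EPI-PB` scans.
#' @param assignments Output of [assign_chains()]; dominant and (optionally)
#'   minor compositions.
#' @param config A [pb_config()].
#' @param include_minor Attempt minor-composition assignment (default `TRUE`).
#' @return A tibble with one row per (chain, isomer assignment): `sample_id`,
#'   `subclass`, `species`, `lipid` (acyl-level name), `chain`, `positions`
#'   (comma-separated deltas), `omega`, `sum_intensity`, `rank`,
#'   `pair_complete`, `collision_free`, `snr_ok`, `low_confidence`,
#'   `composition_rank`, `unassigned`, `scan_id`, and an `evidence`
#'   list-column of per-position matched-ion tables.
#' @export
assign_cc <- function(spectra, assignments, config = pb_config(),
                      include_minor = TRUE) {
  targets <- build_pb_targets(assignments, config)
  out <- list()
  dominant <- assignments[assignments$dominant & assignments$chains_resolved, ]
  minors <- assignments[!assignments$dominant & assignments$chains_resolved, ]
  for (i in seq_len(nrow(targets))) {
    tg <- targets[i, ]
    sel <- spectra$scan_type == "EPI-PB" & spectra$polarity == tg$polarity &
      spectra$sample_id == tg$sample_id & !is.na(spectra$precursor_mz) &
      abs(spectra$precursor_mz - tg$pb_mz) <= config$tolerance_da &
      !is.na(spectra$rt_min) & spectra$rt_min >= tg$rt_lo &
      spectra$rt_min <= tg$rt_hi
    idx <- which(sel)
    if (length(idx) == 0) next
    # prefer the scan closest in RT to the target (precursor-sharing species
    # within one subclass window are separated chromatographically)
    scan <- if (!is.na(tg$rt_min)) {
      idx[which.min(abs(spectra$rt_min[idx] - tg$rt_min))]
    } else {
      idx[which.max(vapply(idx, function(j)
        sum(spectra$peaks[[j]]$intensity), numeric(1)))]
    }
    pk <- spectra$peaks[[scan]]

    comp_rows <- dominant[dominant$hit_id == tg$hit_id, ]
    if (nrow(comp_rows) == 0) next
    res <- .assign_cc_one(pk, tg, comp_rows[1, ], config,
                          composition_rank = 1L,
                          scan_id = spectra$scan_id[scan])
    # minor compositions: only collision-free vs the dominant candidates
    if (include_minor) {
      mrows <- minors[minors$hit_id == tg$hit_id, ]
      for (j in seq_len(nrow(mrows))) {
        mres <- .assign_cc_one(pk, tg, mrows[j, ], config,
                               composition_rank = mrows$rank[j],
                               scan_id = spectra$scan_id[scan],
                               veto_ions = .candidate_mz(tg, comp_rows[1, ],
                                                         config))
        res <- dplyr::bind_rows(res, mres)
      }
    }
    out[[length(out) + 1]] <- res
  }
  if (length(out) == 0) {
    return(tibble::tibble(
      sample_id = character(), subclass = character(), species = character(),
      lipid = character(), chain = character(), positions = character(),
      omega = integer(), sum_intensity = numeric(), rank = integer(),
      pair_complete = logical(), collision_free = logical(),
      snr_ok = logical(), low_confidence = logical(),
      composition_rank = integer(), unassigned = logical(),
      scan_id = character(), evidence = list()))
  }
  dplyr::bind_rows(out)
}

# All theoretical candidate ion m/z for the chains covered by one target and
# one composition (used to veto minor-composition assignments).
.candidate_mz <- function(tg, comp, config) {
  sp <- .target_species(tg, comp)
  chains <- .cc_chains(tg, comp, config)
  mz <- numeric(0)
  for (ch in chains) {
    sets <- enumerate_candidate_positions(ch, config$constraint)
    for (set in sets) {
      pr <- diagnostic_pairs(sp, ch, set, tg$adduct)
      mz <- c(mz, pr$fa_mz, pr$fo_mz)
    }
  }
  mz
}

.target_species <- function(tg, comp) {
  if (tg$subclass == "FA") {
    lipid_species("FA", comp$chain_1)
  } else {
    lipid_species(tg$subclass, c(comp$chain_1, comp$chain_2))
  }
}

# The chains to interrogate for one target under one composition.
.cc_chains <- function(tg, comp, config) {
  if (!is.na(tg$cc_chain) && tg$basis == "fatty-acyl-anion") {
    chains <- list(parse_chain(tg$cc_chain))
  } else if (tg$subclass == "FA") {
    chains <- list(parse_chain(comp$chain_1))
  } else {
    chains <- lapply(c(comp$chain_1, comp$chain_2), parse_chain)
  }
  keep <- vapply(chains, function(ch) {
    ch$double_bonds > 0 && (ch$linkage == "acyl" || config$ether_cc)
  }, logical(1))
  chains <- chains[keep]
  # identical chains (e.g. 18:1_18:1) are indistinguishable: assign once
  chains[!duplicated(vapply(chains, format, character(1),
                            show_positions = FALSE))]
}

.assign_cc_one <- function(pk, tg, comp, config, composition_rank, scan_id,
                           veto_ions = NULL) {
  sp <- .target_species(tg, comp)
  lipid <- format(sp, level = "chain")
  chains <- .cc_chains(tg, comp, config)
  rows <- list()
  for (ch in chains) {
    sets <- enumerate_candidate_positions(ch, config$constraint)
    accepted <- list()
    for (set in sets) {
      pr <- diagnostic_pairs(sp, ch, set, tg$adduct)
      ev <- .match_pairs(pk, pr, config)
      if (is.null(ev)) next
      if (!is.null(veto_ions) &&
          any(vapply(c(ev$fa_mz_obs, ev$fo_mz_obs), function(m)
            any(abs(veto_ions - m) < config$tolerance_da), logical(1)))) {
        next  # minor-composition ions overlap the dominant candidates
      }
      accepted[[length(accepted) + 1]] <- list(set = set, evidence = ev)
    }
    chain_lab <- format(ch, show_positions = FALSE)
    if (length(accepted) == 0) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        sample_id = tg$sample_id, subclass = tg$subclass, species = tg$species,
        lipid = lipid, chain = chain_lab, positions = NA_character_,
        omega = NA_integer_, sum_intensity = NA_real_, rank = NA_integer_,
        pair_complete = FALSE, collision_free = NA, snr_ok = NA,
        low_confidence = NA, composition_rank = composition_rank,
        unassigned = TRUE, scan_id = scan_id,
        evidence = list(tibble::tibble()))
      next
    }
    sums <- vapply(accepted, function(a)
      sum(a$evidence$fa_int + a$evidence$fo_int), numeric(1))
    ord <- order(sums, decreasing = TRUE)
    accepted <- accepted[ord]; sums <- sums[ord]
    # collision flags among accepted assignments of this chain
    all_mz <- lapply(accepted, function(a) c(a$evidence$fa_mz, a$evidence$fo_mz))
    collision_free <- vapply(seq_along(accepted), function(u) {
      others <- unlist(all_mz[-u])
      if (length(others) == 0) return(TRUE)
      !any(vapply(all_mz[[u]], function(m)
        any(abs(others - m) < config$tolerance_da), logical(1)))
    }, logical(1))
    for (u in seq_along(accepted)) {
      set <- accepted[[u]]$set
      rows[[length(rows) + 1]] <- tibble::tibble(
        sample_id = tg$sample_id, subclass = tg$subclass, species = tg$species,
        lipid = lipid, chain = chain_lab,
        positions = paste(set, collapse = ","),
        omega = omega_of(set, ch), sum_intensity = sums[u],
        rank = u, pair_complete = TRUE, collision_free = collision_free[u],
        snr_ok = TRUE, low_confidence = sums[u] < 0.10 * sums[1],
        composition_rank = composition_rank, unassigned = FALSE,
        scan_id = scan_id, evidence = list(accepted[[u]]$evidence))
    }
  }
  if (length(rows) == 0) return(NULL)
  dplyr::bind_rows(rows)
}

# Match every pair of a candidate set; NULL unless all positions have both
# ions with adequate S/N and similar F_A / F_O intensities.
.match_pairs <- function(pk, pr, config) {
  ev <- vector("list", nrow(pr))
  for (i in seq_len(nrow(pr))) {
    fa <- match_peak(pk, pr$fa_mz[i], config$tolerance_da)
    fo <- match_peak(pk, pr$fo_mz[i], config$tolerance_da)
    if (nrow(fa) == 0 || nrow(fo) == 0) return(NULL)
    if (fa$snr < config$s_min || fo$snr < config$s_min) return(NULL)
    ratio <- fa$intensity / fo$intensity
    if (ratio > config$fa_fo_ratio_limit ||
        ratio < 1 / config$fa_fo_ratio_limit) return(NULL)
    ev[[i]] <- tibble::tibble(
      position = pr$position[i],
      fa_mz = pr$fa_mz[i], fo_mz = pr$fo_mz[i],
      fa_mz_obs = fa$mz, fo_mz_obs = fo$mz,
      fa_int = fa$intensity, fo_int = fo$intensity,
      fa_snr = fa$snr, fo_snr = fo$snr)
  }
  dplyr::bind_rows(ev)
}

#' Relative quantitation of C=C location isomers
#'
#' For every lipid chain with two or more coexisting collision-free
#' assignments, computes the abundance ratio of the summed diagnostic-ion
#' intensities, e.g. `Rel. C9/C11 = (I_467 + I_493) / (I_495 + I_521)` for
#' the delta-9/delta-11 pair of PE 16:0_18:1. All pairwise ratios are
#' reported; by convention isomer A is the lower delta set (so the canonical
#' major/minor ratio for C18:1 is delta-9 over delta-11).
#'
#' @param cc Output of [assign_cc()].
#' @return A tibble with one row per (sample, lipid, chain, isomer pair):
#'   `sample_id`, `lipid`, `chain`, `isomer_a`, `isomer_b`, `intensity_a`,
#'   `intensity_b`, `ratio`. Ratios with a zero denominator are returned as
#'   `NA` with `undefined = TRUE`.
#' @export
isomer_ratio <- function(cc) {
  ok <- cc[!cc$unassigned & cc$pair_complete &
             !is.na(cc$collision_free) & cc$collision_free, ]
  empty <- tibble::tibble(sample_id = character(), lipid = character(),
                          chain = character(), isomer_a = character(),
                          isomer_b = character(), intensity_a = numeric(),
                          intensity_b = numeric(), ratio = numeric(),
                          undefined = logical())
  if (nrow(ok) == 0) return(empty)
  ok |>
    dplyr::group_by(.data$sample_id, .data$lipid, .data$chain) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 2) {
        return(tibble::tibble(isomer_a = character(), isomer_b = character(),
                              intensity_a = numeric(), intensity_b = numeric(),
                              ratio = numeric(), undefined = logical()))
      }
      df <- df[order(.first_position(df$positions)), ]
      idx <- utils::combn(nrow(df), 2)
      tibble::tibble(
        isomer_a = df$positions[idx[1, ]],
        isomer_b = df$positions[idx[2, ]],
        intensity_a = df$sum_intensity[idx[1, ]],
        intensity_b = df$sum_intensity[idx[2, ]],
        ratio = ifelse(df$sum_intensity[idx[2, ]] > 0,
                       df$sum_intensity[idx[1, ]] /
                         df$sum_intensity[idx[2, ]], NA_real_),
        undefined = df$sum_intensity[idx[2, ]] == 0)
    }) |>
    dplyr::ungroup()
}

.first_position <- function(positions) {
  vapply(strsplit(positions, ","), function(p) as.integer(p[1]), integer(1))
}

#' Summarize isomer ratios over replicates
#'
#' @param ratios Output of [isomer_ratio()], with `sample_id` carrying the
#'   replicate structure.
#' @return One row per (lipid, chain, isomer pair): `n`, `mean_ratio`,
#'   `sd_ratio`, `rsd_pct`.
#' @export
summarize_ratios <- function(ratios) {
  ratios |>
    dplyr::filter(!.data$undefined) |>
    dplyr::group_by(.data$lipid, .data$chain, .data$isomer_a,
                    .data$isomer_b) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_ratio = mean(.data$ratio),
      sd_ratio = stats::sd(.data$ratio),
      rsd_pct = stats::sd(.data$ratio) / mean(.data$ratio) * 100,
      .groups = "drop")
}

#' Append omega nomenclature to assignments
#'
#' @param cc Output of [assign_cc()].
#' @return `cc` with an `omega_label` column, e.g. `"18:2 ω-6"` for the
#'   delta-9,12 assignment of an 18:2 chain.
#' @export
annotate_omega <- function(cc) {
  cc$omega_label <- ifelse(is.na(cc$omega), NA_character_,
                           paste0(cc$chain, " ω-", cc$omega))
  cc
}
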