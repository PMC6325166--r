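# Stage 1-2 of the workflow: subclass profiling from NLS/PIS scans, fatty acyl
# chain assignment from negative-mode MS/MS, and target-list generation for
# both the chain-analysis and PB-MS/MS acquisitions.

#' Profile one subclass from its NLS/PIS scans
#'
#' Selects the profile pseudo-spectra whose scan type and polarity match the
#' subclass's headgroup scan and whose retention time falls in the configured
#' subclass window, picks peaks above the relative-intensity floor, undoes the
#' profiling adduct and matches the neutral mass against the total-composition
#' grid. Peaks with no grid species within tolerance are retained, flagged
#' unmatched.
#'
#' @param spectra A spectra tibble (see [spectra_tibble()]).
#' @param subclass One of `"PE"`, `"PC"`, `"PG"`, `"PI"`.
#' @param config A [pb_config()].
#' @return A tibble of subclass hits: `sample_id`, `subclass`, `mz`, `rt_min`,
#'   `intensity`, `carbons`, `double_bonds`, `species` (e.g. `"PE 34:1"`),
#'   `theoretical_mz`, `mass_error_da`, `matched`, `rel_int_pct`, `bin`.
#' @export
profile_subclass <- function(spectra, subclass, config = pb_config()) {
  scan <- headgroup_scan(subclass,
                         subclass_adducts()$profile_polarity[
                           subclass_adducts()$subclass == subclass])
  window <- config$rt_windows[[subclass]]
  sel <- spectra$scan_type == scan$mode & spectra$polarity == scan$polarity &
    !is.na(spectra$rt_min) & spectra$rt_min >= window[1] &
    spectra$rt_min <= window[2]
  sub <- spectra[sel, ]
  empty <- tibble::tibble(
    sample_id = character(), subclass = character(), mz = numeric(),
    rt_min = numeric(), intensity = numeric(), carbons = integer(),
    double_bonds = integer(), species = character(),
    theoretical_mz = numeric(), mass_error_da = numeric(),
    matched = logical(), rel_int_pct = numeric(), bin = character())
  if (nrow(sub) == 0) return(empty)

  adduct <- subclass_adducts()$profile_adduct[
    subclass_adducts()$subclass == subclass]
  delta <- adduct_info(adduct)$delta

  grid <- tidyr::expand_grid(carbons = config$grid_carbons,
                             double_bonds = config$grid_db)
  grid$mass <- species_grid_mass(subclass, grid$carbons, grid$double_bonds)
  grid$mz <- grid$mass + delta

  peaks <- dplyr::bind_rows(lapply(seq_len(nrow(sub)), function(i) {
    pk <- sub$peaks[[i]]
    if (nrow(pk) == 0) return(NULL)
    tibble::tibble(sample_id = sub$sample_id[i], mz = pk$mz,
                   rt_min = sub$rt_min[i], intensity = pk$intensity)
  }))
  if (is.null(peaks) || nrow(peaks) == 0) return(empty)
  base <- max(peaks$intensity)
  peaks <- peaks[peaks$intensity >= base * config$rel_int_floor / 100, ]

  nearest <- vapply(peaks$mz, function(m) which.min(abs(grid$mz - m)),
                    integer(1))
  err <- peaks$mz - grid$mz[nearest]
  ok <- abs(err) <= config$tolerance_da
  hits <- tibble::tibble(
    sample_id = peaks$sample_id, subclass = subclass, mz = peaks$mz,
    rt_min = peaks$rt_min, intensity = peaks$intensity,
    carbons = ifelse(ok, grid$carbons[nearest], NA_integer_),
    double_bonds = ifelse(ok, grid$double_bonds[nearest], NA_integer_),
    theoretical_mz = ifelse(ok, grid$mz[nearest], NA_real_),
    mass_error_da = ifelse(ok, err, NA_real_),
    matched = ok
  )
  hits$species <- ifelse(hits$matched,
                         paste0(subclass, " ", hits$carbons, ":",
                                hits$double_bonds),
                         NA_character_)
  hits <- hits |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(rel_int_pct = .data$intensity / max(.data$intensity) * 100) |>
    dplyr::ungroup()
  hits$bin <- cut(hits$rel_int_pct, breaks = c(0, 1, 10, 100),
                  labels = c("<1%", "1-10%", ">10%"), include.lowest = FALSE)
  hits$bin <- as.character(hits$bin)
  hits[, c("sample_id", "subclass", "mz", "rt_min", "intensity", "carbons",
           "double_bonds", "species", "theoretical_mz", "mass_error_da",
           "matched", "rel_int_pct", "bin")]
}

#' Build negative-mode chain-analysis targets from subclass hits
#'
#' One target per annotated hit, under the subclass's negative-mode adduct
#' (`[M-H]-` for PE/PG/PI, `[M+CH3COO]-` for PC). Saturated species are
#' targeted too: chain analysis precedes the C=C stage.
#'
#' @param hits Output of [profile_subclass()] (rows with `matched = FALSE`
#'   are dropped).
#' @param config A [pb_config()].
#' @return A tibble of targets: `sample_id`, `subclass`, `species`, `carbons`,
#'   `double_bonds`, `adduct`, `target_mz`, `rt_min`, `rt_lo`, `rt_hi`,
#'   `polarity`, `rel_int_pct`.
#' @export
build_chain_targets <- function(hits, config = pb_config()) {
  hits <- hits[hits$matched, ]
  if (nrow(hits) == 0) {
    return(tibble::tibble(hit_id = character(), sample_id = character(),
                          subclass = character(), species = character(),
                          carbons = integer(), double_bonds = integer(),
                          adduct = character(), target_mz = numeric(),
                          rt_min = numeric(), rt_lo = numeric(),
                          rt_hi = numeric(), polarity = character(),
                          rel_int_pct = numeric()))
  }
  map <- subclass_adducts()
  adduct <- map$chain_adduct[match(hits$subclass, map$subclass)]
  delta <- adducts()$delta[match(adduct, adducts()$adduct)]
  mass <- species_grid_mass(hits$subclass, hits$carbons, hits$double_bonds)
  windows <- t(vapply(hits$subclass, function(s) config$rt_windows[[s]],
                      numeric(2)))
  tibble::tibble(
    hit_id = sprintf("%s|%s|%.1f", hits$sample_id, hits$species,
                     hits$rt_min),
    sample_id = hits$sample_id, subclass = hits$subclass,
    species = hits$species, carbons = hits$carbons,
    double_bonds = hits$double_bonds, adduct = adduct,
    target_mz = mass + delta, rt_min = hits$rt_min,
    rt_lo = windows[, 1], rt_hi = windows[, 2],
    polarity = "negative", rel_int_pct = hits$rel_int_pct
  )
}

# Enumerate two-chain compositions summing to (carbons, double_bonds).
# Canonical order: chain1 <= chain2 (by carbons, then double bonds).
enumerate_chain_pairs <- function(carbons, double_bonds, chain_carbons = 2:26) {
  out <- list()
  for (c1 in chain_carbons) {
    c2 <- carbons - c1
    if (c2 < c1 || !(c2 %in% chain_carbons)) next
    d1_max <- floor((c1 - 2) / 2) + 1
    d2_max <- floor((c2 - 2) / 2) + 1
    for (d1 in 0:min(double_bonds, d1_max)) {
      d2 <- double_bonds - d1
      if (d2 > d2_max) next
      if (c1 == c2 && d1 > d2) next  # avoid mirrored duplicates
      out[[length(out) + 1]] <- c(c1, d1, c2, d2)
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(c1 = integer(), d1 = integer(), c2 = integer(),
                          d2 = integer()))
  }
  m <- do.call(rbind, out)
  tibble::tibble(c1 = m[, 1], d1 = m[, 2], c2 = m[, 3], d2 = m[, 4])
}

#' Assign fatty acyl chains from negative-mode MS/MS
#'
#' For every chain-analysis target, locates EPI scans whose precursor m/z,
#' retention time and sample match, enumerates two-chain compositions summing
#' to the target's total composition, and scores each composition by the
#' summed intensity of its two matched carboxylate anions. Both anions must
#' match; compositions with no evidence are dropped. The top-ranked
#' composition is flagged dominant when it out-scores the runner-up by the
#' configured dominance ratio (or is the only one).
#'
#' @param spectra A spectra tibble holding `EPI-MS2` negative-mode scans.
#' @param targets Output of [build_chain_targets()].
#' @param config A [pb_config()].
#' @return A tibble with one row per scored composition (plus one flagged row
#'   per unresolved target): `sample_id`, `subclass`, `species`, `chain_1`,
#'   `chain_2`, `anion_mz_1`, `anion_mz_2`, `score`, `rank`, `dominant`,
#'   `chains_resolved`, `rt_min`, `scan_id`.
#' @export
assign_chains <- function(spectra, targets, config = pb_config()) {
  rows <- list()
  for (i in seq_len(nrow(targets))) {
    tg <- targets[i, ]
    sel <- spectra$scan_type == "EPI-MS2" & spectra$polarity == "negative" &
      spectra$sample_id == tg$sample_id & !is.na(spectra$precursor_mz) &
      abs(spectra$precursor_mz - tg$target_mz) <= config$tolerance_da &
      !is.na(spectra$rt_min) & spectra$rt_min >= tg$rt_lo &
      spectra$rt_min <= tg$rt_hi
    idx <- which(sel)
    unresolved <- tibble::tibble(
      hit_id = tg$hit_id,
      sample_id = tg$sample_id, subclass = tg$subclass, species = tg$species,
      chain_1 = NA_character_, chain_2 = NA_character_,
      anion_mz_1 = NA_real_, anion_mz_2 = NA_real_, score = NA_real_,
      rank = NA_integer_, dominant = FALSE, chains_resolved = FALSE,
      rt_min = tg$rt_min, scan_id = NA_character_)
    if (length(idx) == 0) { rows[[length(rows) + 1]] <- unresolved; next }
    # merge peak evidence over all matching scans (repeat acquisitions)
    combos <- enumerate_chain_pairs(tg$carbons, tg$double_bonds,
                                    config$chain_carbons)
    if (nrow(combos) == 0) { rows[[length(rows) + 1]] <- unresolved; next }
    a1 <- acyl_anion_mz_fast(combos$c1, combos$d1)
    a2 <- acyl_anion_mz_fast(combos$c2, combos$d2)
    # the scan closest in RT to the profile hit: RT separates species that
    # share a total composition (e.g. 18:0_18:2 vs 18:1_18:1 isomers)
    best_scan <- idx[which.min(abs(spectra$rt_min[idx] - tg$rt_min))]
    pk <- spectra$peaks[[best_scan]]
    s1 <- matched_intensity(pk, a1, config$tolerance_da)
    s2 <- matched_intensity(pk, a2, config$tolerance_da)
    score <- ifelse(is.na(s1) | is.na(s2), NA_real_, s1 + s2)
    keep <- which(!is.na(score))
    if (length(keep) == 0) { rows[[length(rows) + 1]] <- unresolved; next }
    ord <- keep[order(score[keep], decreasing = TRUE)]
    n <- length(ord)
    dominant <- rep(FALSE, n)
    dominant[1] <- n == 1 ||
      score[ord[1]] >= config$dominance_ratio * score[ord[2]]
    rows[[length(rows) + 1]] <- tibble::tibble(
      hit_id = tg$hit_id,
      sample_id = tg$sample_id, subclass = tg$subclass, species = tg$species,
      chain_1 = paste0(combos$c1[ord], ":", combos$d1[ord]),
      chain_2 = paste0(combos$c2[ord], ":", combos$d2[ord]),
      anion_mz_1 = a1[ord], anion_mz_2 = a2[ord],
      score = score[ord], rank = seq_len(n), dominant = dominant,
      chains_resolved = TRUE, rt_min = tg$rt_min,
      scan_id = spectra$scan_id[best_scan])
  }
  if (length(rows) == 0) {
    return(tibble::tibble(hit_id = character(), sample_id = character(),
                          subclass = character(),
                          species = character(), chain_1 = character(),
                          chain_2 = character(), anion_mz_1 = numeric(),
                          anion_mz_2 = numeric(), score = numeric(),
                          rank = integer(), dominant = logical(),
                          chains_resolved = logical(), rt_min = numeric(),
                          scan_id = character()))
  }
  dplyr::bind_rows(rows)
}

# Vectorized carboxylate anion m/z without object construction.
acyl_anion_mz_fast <- function(carbons, double_bonds) {
  carbons * .ELEMENT_MASS[["C"]] +
    (2 * carbons - 2 * double_bonds) * .ELEMENT_MASS[["H"]] +
    2 * .ELEMENT_MASS[["O"]] - .PROTON
}

# Summed intensity of the most intense peak within tolerance of each target,
# NA where no peak matches.
matched_intensity <- function(peaks, targets, tolerance) {
  vapply(targets, function(t) {
    hit <- which(abs(peaks$mz - t) <= tolerance)
    if (length(hit) == 0) NA_real_ else max(peaks$intensity[hit])
  }, numeric(1))
}

#' Build the PB-MS/MS target list
#'
#' One PB target per unsaturated dominant composition: the intact-lipid
#' `[M+H]+` plus 58.0419 for PE/PC (filtered to the subclass acquisition m/z
#' range), or one acyl-anion-basis target per unsaturated chain for PG/PI
#' (second precursor = acyl anion + 58). Free fatty acids are targeted as
#' `[M-H]-` + 58. Saturated species never enter the list.
#'
#' @param assignments Output of [assign_chains()] (dominant rows are used);
#'   may also contain `FA` rows whose `chain_1` is the acid itself.
#' @param config A [pb_config()].
#' @return A tibble of PB targets: `sample_id`, `subclass`, `species`,
#'   `chain_1`, `chain_2`, `basis`, `adduct`, `pb_mz`, `polarity`, `rt_lo`,
#'   `rt_hi`, `cc_chain` (the chain analyzed under acyl basis, `NA` for
#'   intact basis).
#' @export
build_pb_targets <- function(assignments, config = pb_config()) {
  empty <- tibble::tibble(
    hit_id = character(), sample_id = character(), subclass = character(),
    species = character(),
    chain_1 = character(), chain_2 = character(), basis = character(),
    adduct = character(), pb_mz = numeric(), polarity = character(),
    rt_min = numeric(), rt_lo = numeric(), rt_hi = numeric(),
    cc_chain = character())
  asg <- assignments[assignments$dominant & assignments$chains_resolved, ]
  if (nrow(asg) == 0) return(empty)
  rows <- list()
  for (i in seq_len(nrow(asg))) {
    a <- asg[i, ]
    chains <- if (a$subclass == "FA") a$chain_1 else c(a$chain_1, a$chain_2)
    db <- sum(vapply(chains, function(x)
      as.integer(sub(".*:", "", x)), integer(1)))
    if (db == 0) next
    window <- config$rt_windows[[a$subclass]]
    if (a$subclass %in% c("PE", "PC")) {
      sp <- lipid_species(a$subclass, chains)
      mz <- pb_precursor_mz(sp, "[M+H]+")
      rng <- config$mz_range[[a$subclass]]
      if (mz < rng[1] || mz > rng[2]) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        hit_id = a$hit_id,
        sample_id = a$sample_id, subclass = a$subclass, species = a$species,
        chain_1 = a$chain_1, chain_2 = a$chain_2, basis = "intact-lipid",
        adduct = "[M+H]+", pb_mz = mz, polarity = "positive",
        rt_min = a$rt_min, rt_lo = window[1], rt_hi = window[2],
        cc_chain = NA_character_)
    } else if (a$subclass == "FA") {
      sp <- lipid_species("FA", chains)
      mz <- pb_precursor_mz(sp, "[M-H]-")
      rows[[length(rows) + 1]] <- tibble::tibble(
        hit_id = a$hit_id,
        sample_id = a$sample_id, subclass = "FA", species = a$species,
        chain_1 = a$chain_1, chain_2 = NA_character_, basis = "intact-lipid",
        adduct = "[M-H]-", pb_mz = mz, polarity = "negative",
        rt_min = a$rt_min, rt_lo = window[1], rt_hi = window[2],
        cc_chain = a$chain_1)
    } else {  # PG / PI: acyl-anion basis, one target per unsaturated chain
      for (ch in chains) {
        d <- as.integer(sub(".*:", "", ch))
        if (d == 0) next
        mz <- acyl_anion_mz(ch) + 58.041865
        rng <- config$mz_range[[a$subclass]]
        if (mz < rng[1] || mz > rng[2]) next
        rows[[length(rows) + 1]] <- tibble::tibble(
          hit_id = a$hit_id,
          sample_id = a$sample_id, subclass = a$subclass, species = a$species,
          chain_1 = a$chain_1, chain_2 = a$chain_2,
          basis = "fatty-acyl-anion", adduct = "[M-H]-", pb_mz = mz,
          polarity = "negative", rt_min = a$rt_min, rt_lo = window[1],
          rt_hi = window[2], cc_chain = ch)
      }
    }
  }
  if (length(rows) == 0) return(empty)
  dplyr::bind_rows(rows)
}
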