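# Fixture builders used across the suite. Everything is generated in code;
# no binary or stored data.

# A PB-MS/MS spectrum assembled directly from theoretical diagnostic ions.
# `isomers` is a list of list(positions = c(...), fa_int = ..., fo_int = ...)
# (intensities recycled over positions); `drop_mz` removes specific ions.
pb_fixture_spectrum <- function(species, chain, isomers, adduct = "[M+H]+",
                                rt_min = 5.7, sample_id = "fix",
                                drop_mz = numeric(0), extra = NULL) {
  sp <- if (is.character(species)) parse_lipid(species) else species
  pk <- dplyr::bind_rows(lapply(isomers, function(iso) {
    pr <- diagnostic_pairs(sp, chain, iso$positions, adduct)
    tibble::tibble(
      mz = c(pr$fa_mz, pr$fo_mz),
      intensity = c(rep_len(iso$fa_int, nrow(pr)),
                    rep_len(iso$fo_int, nrow(pr))))
  }))
  if (length(drop_mz) > 0) {
    keep <- !vapply(pk$mz, function(m) any(abs(drop_mz - m) < 0.01),
                    logical(1))
    pk <- pk[keep, ]
  }
  if (!is.null(extra)) pk <- dplyr::bind_rows(pk, extra)
  prec <- pb_precursor_mz(sp, adduct)
  polarity <- adduct_info(adduct)$polarity
  spectra_tibble(scan_id = "pbfix", scan_type = "EPI-PB",
                 polarity = polarity, precursor_mz = prec, rt_min = rt_min,
                 peaks = list(pk), sample_id = sample_id)
}

# Chain-assignment rows as assign_chains() would emit them, for driving
# assign_cc() without the profiling stages.
chain_assignment_fixture <- function(subclass, chain_1, chain_2,
                                     sample_id = "fix", rt_min = 5.7) {
  chains <- if (is.na(chain_2)) chain_1 else c(chain_1, chain_2)
  sp <- lipid_species(subclass, chains)
  species <- format(sp, level = "subclass")
  tibble::tibble(
    hit_id = sprintf("%s|%s|%.1f", sample_id, species, rt_min),
    sample_id = sample_id, subclass = subclass, species = species,
    chain_1 = chain_1, chain_2 = chain_2,
    anion_mz_1 = acyl_anion_mz(chain_1),
    anion_mz_2 = if (is.na(chain_2)) NA_real_ else acyl_anion_mz(chain_2),
    score = 100, rank = 1L, dominant = TRUE, chains_resolved = TRUE,
    rt_min = rt_min, scan_id = "chainfix")
}

# Element-mass summation oracle, independent of the formula machinery: sums
# masses straight from the printed IUPAC monoisotopic values.
oracle_mass <- function(C = 0, H = 0, N = 0, O = 0, P = 0) {
  C * 12 + H * 1.00782503207 + N * 14.0030740048 + O * 15.9949146196 +
    P * 30.97376163
}
ORACLE_PROTON <- 1.007276

# Building-block assembly of a diacyl GP mass: glycerol + H3PO4 + headgroup
# alcohol + the two free fatty acids - 4 H2O (one per ester/phosphoester
# bond; PA has no headgroup alcohol, - 3 H2O; FA is the acid itself).
oracle_species_mass <- function(subclass, c1, d1, c2 = NULL, d2 = NULL) {
  acid <- function(cc, dd) oracle_mass(C = cc, H = 2 * cc - 2 * dd, O = 2)
  if (subclass == "FA") return(acid(c1, d1))
  glycerol <- oracle_mass(C = 3, H = 8, O = 3)
  h3po4 <- oracle_mass(H = 3, O = 4, P = 1)
  h2o <- oracle_mass(H = 2, O = 1)
  alcohol <- switch(subclass,
    PC = oracle_mass(C = 5, H = 13, N = 1, O = 1),
    PE = oracle_mass(C = 2, H = 7, N = 1, O = 1),
    PG = oracle_mass(C = 3, H = 8, O = 3),
    PI = oracle_mass(C = 6, H = 12, O = 6),
    PS = oracle_mass(C = 3, H = 7, N = 1, O = 3),
    PA = 0)
  n_h2o <- if (subclass == "PA") 3 else 4
  glycerol + h3po4 + alcohol + acid(c1, d1) + acid(c2, d2) - n_h2o * h2o
}
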