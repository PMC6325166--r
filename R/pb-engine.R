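# In-silico Paterno-Buchi chemistry: PB product precursor masses and the
# theoretical aldehyde/olefin (F_A / F_O) diagnostic-ion pairs that localize
# each C=C. CID of the acetone-PB oxetane cleaves at the former double bond,
# yielding two ions 26.0157 Da (C2H2) apart; their masses pin the position.

.ACETONE <- 58.041865      # C3H6O, the single-addition PB tag
.ETHYNE <- 26.0156500      # C2H2, F_O - F_A spacing

# Headgroup neutral loss applied before reading off diagnostic ions, by
# subclass and polarity. PE ions appear after the 141.0191 Da
# phosphoethanolamine loss; PC ions retain the intact headgroup.
.PB_NEUTRAL_LOSS <- c(
  `PE.positive` = NA_real_,  # filled at load: C2H8NO4P
  `PC.positive` = 0,
  `FA.negative` = 0,
  `PG.negative` = 0,
  `PI.negative` = 0
)

.pb_nl <- function(subclass, polarity) {
  key <- paste(subclass, polarity, sep = ".")
  nl <- .PB_NEUTRAL_LOSS[key]
  if (is.na(nl)) {
    if (key == "PE.positive") return(.fmass(c(C = 2, H = 8, N = 1, O = 4, P = 1)))
    stop("no PB diagnostic-ion rule for ", subclass, " in ", polarity,
         " mode", call. = FALSE)
  }
  unname(nl)
}

# Subclasses whose PB-MS/MS is run against the fatty acyl anion (MS3-style
# second precursor = acyl anion + 58) rather than the intact lipid ion.
.ACYL_BASIS <- c("PG", "PI")

#' PB product precursor m/z
#'
#' Single acetone addition across a C=C shifts the precursor by +58.0419 Da;
#' this signature shift defines the PB target list.
#'
#' @param species A `lipid_species` or shorthand string; must carry at least
#'   one double bond.
#' @param adduct Adduct name (see [adducts()]).
#' @return m/z of the PB product ion.
#' @examples
#' pb_precursor_mz("FA 18:1", "[M-H]-")      # 339.2905
#' pb_precursor_mz("PE 16:0_18:1", "[M+H]+") # 776.5799
#' @export
pb_precursor_mz <- function(species, adduct) {
  if (is.character(species)) species <- parse_lipid(species)
  if (species_composition(species)$double_bonds == 0) {
    stop("species is saturated: no PB product is formed", call. = FALSE)
  }
  precursor_mz(species, adduct) + .ACETONE
}

#' Theoretical C=C diagnostic-ion pair
#'
#' For a double bond at delta position `n` on a chain with `carbons` carbons,
#' CID of the PB product cleaves between carbons `n` and `n+1`. The aldehyde
#' ion F_A retains the carboxyl side plus one oxygen of the acetone tag; the
#' olefin ion F_O is F_A + C2H2. In closed form,
#' `F_A = precursor - mass(C_m H_{2m-2k}) + mass(O) - NL`, where
#' `m = carbons - n` is the number of methyl-side carbons, `k` the number of
#' the chain's other double bonds methyl-side of the cleavage, and `NL` the
#' subclass/polarity headgroup neutral loss (141.0191 Da for PE positive, 0
#' for PC positive and all negative-mode bases).
#'
#' For PG/PI the same rule is applied on the fatty-acyl-anion basis
#' ([acyl_anion_mz()] as the precursor, `NL = 0`).
#'
#' @param species A `lipid_species` or shorthand (used for the precursor basis
#'   and neutral-loss rule). For the plain-chain bases (`"FA"`), the species is
#'   the free acid itself.
#' @param chain Which chain carries the bond: an `acyl_chain`, shorthand, or
#'   the index of the chain within `species`.
#' @param positions Integer vector: the full candidate position set for this
#'   chain (its length must not exceed the chain's double-bond count). A pair
#'   is returned for every element.
#' @param adduct Adduct name.
#' @return A tibble with one row per position: `position`, `m` (methyl-side
#'   carbons), `k` (methyl-side co-bonds), `fa_mz`, `fo_mz`, `basis`,
#'   `neutral_loss`, `precursor_mz`.
#' @examples
#' diagnostic_pairs("PE 16:0_18:1", "18:1", 9, "[M+H]+")   # 467.3731 / 493.3888
#' diagnostic_pairs("PE 16:0_18:1", "18:1", 11, "[M+H]+")  # 495.4044 / 521.4201
#' @export
diagnostic_pairs <- function(species, chain, positions, adduct) {
  if (is.character(species)) species <- parse_lipid(species)
  if (is.numeric(chain)) chain <- species$chains[[chain]]
  if (is.character(chain)) chain <- parse_chain(chain)
  stopifnot(inherits(chain, "acyl_chain"))
  positions <- sort(as.integer(positions))
  if (chain$double_bonds < 1) {
    stop("chain carries no double bond", call. = FALSE)
  }
  if (length(positions) > chain$double_bonds) {
    stop("more positions than the chain's declared double bonds", call. = FALSE)
  }
  if (any(positions < 2 | positions > chain$carbons - 1)) {
    stop("position out of range [2, carbons - 1]", call. = FALSE)
  }
  subclass <- species$subclass
  polarity <- if (subclass %in% c("PE", "PC")) "positive" else "negative"
  if (subclass %in% .ACYL_BASIS) {
    basis <- "fatty-acyl-anion"
    prec <- acyl_anion_mz(chain)
    if (is.na(prec)) stop("ether chain has no acyl-anion basis", call. = FALSE)
    nl <- 0
  } else {
    basis <- "intact-lipid"
    adduct_pol <- adduct_info(adduct)$polarity
    if (adduct_pol != polarity) {
      stop("adduct polarity ", adduct_pol, " does not match the ", subclass,
           " PB-MS/MS mode (", polarity, ")", call. = FALSE)
    }
    prec <- precursor_mz(species, adduct)
    nl <- .pb_nl(subclass, polarity)
  }
  m <- chain$carbons - positions
  k <- vapply(positions, function(n) sum(positions > n), integer(1))
  loss <- vapply(seq_along(m), function(i) {
    .fmass(c(C = m[i], H = 2 * m[i] - 2 * k[i]))
  }, numeric(1))
  fa <- prec - loss + .ELEMENT_MASS[["O"]] - nl
  tibble::tibble(
    chain = format(chain, show_positions = FALSE),
    position = positions, m = m, k = k,
    fa_mz = fa, fo_mz = fa + .ETHYNE,
    basis = basis, neutral_loss = nl,
    precursor_mz = prec + .ACETONE
  )
}

#' Enumerate candidate C=C positions for de novo assignment
#'
#' For a monounsaturated chain, every position in `[2, carbons - 2]` is a
#' candidate. For polyunsaturated chains the default constraint is the
#' methylene-interrupted pattern (`n, n+3, n+6, ...`) found in almost all
#' mammalian PUFA; `"unconstrained"` enumerates every strictly increasing
#' d-subset (use with care: combinatorial).
#'
#' @param chain `acyl_chain` or shorthand.
#' @param constraint `"methylene-interrupted"` (default) or `"unconstrained"`.
#' @return A list of integer position vectors (each of length
#'   `double_bonds`); empty list for saturated chains.
#' @examples
#' length(enumerate_candidate_positions("18:1"))  # 15
#' enumerate_candidate_positions("22:4")          # includes c(7, 10, 13, 16)
#' @export
enumerate_candidate_positions <- function(chain,
    constraint = c("methylene-interrupted", "unconstrained")) {
  constraint <- match.arg(constraint)
  if (is.character(chain)) chain <- parse_chain(chain)
  d <- chain$double_bonds
  cc <- chain$carbons
  if (d == 0) return(list())
  hi <- cc - 2
  if (d == 1) return(as.list(2:hi))
  if (constraint == "methylene-interrupted") {
    starts <- 2:(hi - 3 * (d - 1))
    if (length(starts) == 0 || hi - 3 * (d - 1) < 2) return(list())
    return(lapply(starts, function(s) s + 3 * (0:(d - 1))))
  }
  combos <- utils::combn(2:hi, d, simplify = FALSE)
  combos
}

#' Omega (methyl-end) number of a double bond
#'
#' `omega = carbons - last delta position` of the bond set; the conventional
#' PUFA family label (omega-3, omega-6, ...).
#'
#' @param positions Integer vector of delta positions (the full set for the
#'   chain).
#' @param chain `acyl_chain` or shorthand.
#' @return Integer omega number.
#' @examples
#' omega_of(c(9, 12), "18:2")      # 6
#' omega_of(9, "18:1")             # 9
#' omega_of(c(9, 12, 15), "18:3")  # 3
#' @export
omega_of <- function(positions, chain) {
  if (is.character(chain)) chain <- parse_chain(chain)
  as.integer(chain$carbons - max(positions))
}

#' Report theoretical diagnostic-ion collisions among candidate positions
#'
#' Enumerates all candidate positions (or candidate sets) for every
#' unsaturated chain of a species and reports every pair of theoretical
#' diagnostic ions closer than `tolerance`. Colliding ions cannot be uniquely
#' attributed, so downstream assignment flags them and excludes them from
#' isomer ratios.
#'
#' @param species `lipid_species` or shorthand.
#' @param adduct Adduct for the intact-lipid bases.
#' @param tolerance m/z distance (Da) below which two theoretical ions collide.
#' @param constraint Candidate constraint passed to
#'   [enumerate_candidate_positions()].
#' @return A tibble with one row per colliding ion pair: chain/position/ion
#'   type for both members and their m/z difference.
#' @export
pair_collision_report <- function(species, adduct, tolerance = 0.3,
    constraint = "methylene-interrupted") {
  if (is.character(species)) species <- parse_lipid(species)
  ions <- candidate_ion_table(species, adduct, constraint)
  if (nrow(ions) < 2) {
    return(tibble::tibble(chain_1 = character(), set_1 = character(),
                          position_1 = integer(), ion_1 = character(),
                          mz_1 = numeric(), chain_2 = character(),
                          set_2 = character(), position_2 = integer(),
                          ion_2 = character(), mz_2 = numeric(),
                          delta_mz = numeric()))
  }
  idx <- utils::combn(nrow(ions), 2)
  d <- abs(ions$mz[idx[1, ]] - ions$mz[idx[2, ]])
  keep <- which(d < tolerance &
                  !(ions$set[idx[1, ]] == ions$set[idx[2, ]] &
                      ions$chain[idx[1, ]] == ions$chain[idx[2, ]] &
                      ions$position[idx[1, ]] == ions$position[idx[2, ]]))
  tibble::tibble(
    chain_1 = ions$chain[idx[1, keep]], set_1 = ions$set[idx[1, keep]],
    position_1 = ions$position[idx[1, keep]], ion_1 = ions$ion[idx[1, keep]],
    mz_1 = ions$mz[idx[1, keep]],
    chain_2 = ions$chain[idx[2, keep]], set_2 = ions$set[idx[2, keep]],
    position_2 = ions$position[idx[2, keep]], ion_2 = ions$ion[idx[2, keep]],
    mz_2 = ions$mz[idx[2, keep]],
    delta_mz = d[keep]
  )
}

# All theoretical candidate diagnostic ions of a species, one row per
# (chain, candidate set, position, F_A/F_O).
candidate_ion_table <- function(species, adduct,
                                constraint = "methylene-interrupted") {
  if (is.character(species)) species <- parse_lipid(species)
  rows <- list()
  for (ch in species$chains) {
    if (ch$double_bonds == 0 || ch$linkage != "acyl") next
    sets <- enumerate_candidate_positions(ch, constraint)
    for (set in sets) {
      pr <- diagnostic_pairs(species, ch, set, adduct)
      set_id <- paste(set, collapse = ",")
      rows[[length(rows) + 1]] <- tibble::tibble(
        chain = rep(pr$chain, 2), set = set_id,
        position = rep(pr$position, 2),
        ion = rep(c("F_A", "F_O"), each = nrow(pr)),
        mz = c(pr$fa_mz, pr$fo_mz)
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(chain = character(), set = character(),
                          position = integer(), ion = character(),
                          mz = numeric()))
  }
  dplyr::bind_rows(rows)
}
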