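# Exact monoisotopic mass arithmetic, lipid formula templates, adduct m/z and
# headgroup scan constants. Everything downstream (diagnostic-ion prediction,
# profiling grids, target lists) is built on these few functions.

# Monoisotopic element masses (Da). CODATA/IUPAC values; charge bookkeeping is
# done with the proton mass so electron mass never needs separate handling.
.ELEMENT_MASS <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.97376163,
  Na = 22.9897692809
)

.PROTON <- 1.007276

#' Monoisotopic element mass table
#'
#' Returns the monoisotopic masses (Da) used for all m/z arithmetic in the
#' package, plus the named neutral/charge-carrier constants that recur in the
#' Paterno-Buchi (PB) workflow: the 58.0419 Da acetone addition that tags PB
#' products, the 26.0157 Da ethyne (C2H2) spacing between the aldehyde and
#' olefin diagnostic ions, and the 141.0191 Da phosphoethanolamine neutral
#' loss characteristic of PE in positive mode.
#'
#' @return A tibble with columns `name`, `formula` and `mass_da`.
#' @examples
#' element_masses()
#' @export
element_masses <- function() {
  tibble::tibble(
    name = c(names(.ELEMENT_MASS), "proton", "acetone", "ethyne",
             "oxygen_atom", "pe_headgroup_loss", "acetate"),
    formula = c(names(.ELEMENT_MASS), "H+", "C3H6O", "C2H2", "O",
                "C2H8NO4P", "C2H3O2"),
    mass_da = c(unname(.ELEMENT_MASS), .PROTON,
                unname(.fmass(c(C = 3, H = 6, O = 1))),
                unname(.fmass(c(C = 2, H = 2))),
                unname(.ELEMENT_MASS[["O"]]),
                unname(.fmass(c(C = 2, H = 8, N = 1, O = 4, P = 1))),
                unname(.fmass(c(C = 2, H = 3, O = 2))))
  )
}

.fmass <- function(counts) {
  sum(.ELEMENT_MASS[names(counts)] * as.numeric(counts))
}

#' Build a chemical formula
#'
#' A chemical formula is a named integer vector (element -> count) with class
#' `chem_formula`. Addition and subtraction are element-wise; subtraction that
#' would drive any count negative is an error.
#'
#' @param ... Named integer element counts, e.g. `chem_formula(C = 3, H = 6, O = 1)`.
#' @return A `chem_formula` object.
#' @examples
#' chem_formula(C = 3, H = 6, O = 1)
#' parse_formula("C44H80NO8P")
#' @export
chem_formula <- function(...) {
  counts <- c(...)
  if (length(counts) == 0) {
    counts <- integer(0)
    names(counts) <- character(0)
  }
  if (is.null(names(counts)) || any(names(counts) == "")) {
    stop("all element counts must be named", call. = FALSE)
  }
  unknown <- setdiff(names(counts), names(.ELEMENT_MASS))
  if (length(unknown) > 0) {
    stop("unknown element(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(counts < 0)) stop("element counts must be >= 0", call. = FALSE)
  counts <- counts[counts > 0]
  storage.mode(counts) <- "integer"
  structure(counts, class = "chem_formula")
}

#' @rdname chem_formula
#' @param x A formula string such as `"C3H6O"` (element symbols followed by
#'   optional counts).
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  if (nchar(x) == 0) return(chem_formula())
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)[[1]]
  parts <- regmatches(x, list(m))[[1]]
  if (sum(nchar(parts)) != nchar(x)) {
    stop("cannot parse formula: ", x, call. = FALSE)
  }
  el <- sub("[0-9]*$", "", parts)
  n <- as.integer(ifelse(grepl("[0-9]+$", parts),
                         sub("^[A-Za-z]+", "", parts), "1"))
  counts <- tapply(n, el, sum)
  do.call(chem_formula, as.list(counts))
}

#' @export
format.chem_formula <- function(x, ...) {
  order <- intersect(c("C", "H", "N", "O", "P", "Na"), names(x))
  paste0(vapply(order, function(e) {
    if (x[[e]] == 1) e else paste0(e, x[[e]])
  }, character(1)), collapse = "")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula> ", format(x), "  (", sprintf("%.6f", monoisotopic_mass(x)),
      " Da)\n", sep = "")
  invisible(x)
}

#' @export
Ops.chem_formula <- function(e1, e2) {
  if (!.Generic %in% c("+", "-")) {
    stop("operation '", .Generic, "' not defined for chem_formula", call. = FALSE)
  }
  els <- union(names(e1), names(e2))
  a <- ifelse(els %in% names(e1), unclass(e1)[els], 0L)
  b <- ifelse(els %in% names(e2), unclass(e2)[els], 0L)
  out <- if (.Generic == "+") a + b else a - b
  if (any(out < 0)) {
    stop("formula subtraction produced a negative element count", call. = FALSE)
  }
  names(out) <- els
  out <- out[out > 0]
  structure(as.integer(stats::setNames(out, names(out))),
            names = names(out), class = "chem_formula")
}

#' Monoisotopic mass of a chemical formula
#'
#' @param formula A `chem_formula` or a formula string (e.g. `"C3H6O"`).
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("H2O")    # 18.010565
#' monoisotopic_mass("C3H6O")  # 58.041865, the PB acetone tag
#' @export
monoisotopic_mass <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  if (!inherits(formula, "chem_formula")) {
    stop("`formula` must be a chem_formula or formula string", call. = FALSE)
  }
  if (length(formula) == 0) return(0)
  .fmass(unclass(formula))
}

#' Round m/z to its nominal (unit-resolution) value
#'
#' Round-half-up to the nearest integer, used whenever package output is
#' compared against unit-resolution QTRAP readings.
#'
#' @param mz Numeric m/z value(s).
#' @return Integer vector.
#' @examples
#' nominal_mz(467.3731)  # 467
#' @export
nominal_mz <- function(mz) as.integer(floor(mz + 0.5))

# ---- acyl chains -------------------------------------------------------------

#' Fatty acyl chain
#'
#' @param carbons Number of chain carbons (>= 2).
#' @param double_bonds Number of C=C double bonds (>= 0).
#' @param positions Optional delta positions (counted from the carboxyl
#'   carbon), strictly increasing, each in `[2, carbons - 1]`, of length
#'   `double_bonds` when supplied.
#' @param linkage `"acyl"` (ester), `"O-alkyl"` or `"O-alkenyl"` ether.
#' @return An `acyl_chain` object.
#' @examples
#' acyl_chain(18, 1, positions = 9)
#' acyl_chain(22, 4, positions = c(7, 10, 13, 16))
#' @export
acyl_chain <- function(carbons, double_bonds = 0, positions = NULL,
                       linkage = c("acyl", "O-alkyl", "O-alkenyl")) {
  linkage <- match.arg(linkage)
  carbons <- as.integer(carbons)
  double_bonds <- as.integer(double_bonds)
  if (carbons < 2) stop("chain must have >= 2 carbons", call. = FALSE)
  if (double_bonds < 0) stop("double_bonds must be >= 0", call. = FALSE)
  d_max <- floor((carbons - 2) / 2) + 1
  if (double_bonds > d_max) {
    stop("a C", carbons, " chain supports at most ", d_max, " double bonds",
         call. = FALSE)
  }
  if (!is.null(positions)) {
    positions <- as.integer(positions)
    if (length(positions) != double_bonds) {
      stop("length(positions) must equal double_bonds", call. = FALSE)
    }
    if (any(duplicated(positions)) || is.unsorted(positions, strictly = TRUE)) {
      stop("positions must be strictly increasing", call. = FALSE)
    }
    if (any(positions < 2 | positions > carbons - 1)) {
      stop("positions must lie in [2, carbons - 1]", call. = FALSE)
    }
  }
  structure(list(carbons = carbons, double_bonds = double_bonds,
                 positions = positions, linkage = linkage),
            class = "acyl_chain")
}

#' @export
format.acyl_chain <- function(x, show_positions = TRUE, ...) {
  prefix <- switch(x$linkage, acyl = "", `O-alkyl` = "O-", `O-alkenyl` = "P-")
  out <- paste0(prefix, x$carbons, ":", x$double_bonds)
  if (show_positions && !is.null(x$positions) && length(x$positions) > 0) {
    out <- paste0(out, "(", paste0("Δ", x$positions, collapse = ","), ")")
  }
  out
}

#' @export
print.acyl_chain <- function(x, ...) {
  cat("<acyl_chain> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Parse a chain shorthand such as "18:1", "O-16:1" or "18:1(9)"
#'
#' @param x Shorthand string; delta positions may be given with or without the
#'   Greek Delta, e.g. `"18:2(9,12)"`.
#' @return An `acyl_chain`.
#' @export
parse_chain <- function(x) {
  x <- trimws(x)
  linkage <- "acyl"
  if (grepl("^O-", x)) { linkage <- "O-alkyl"; x <- sub("^O-", "", x) }
  if (grepl("^P-", x)) { linkage <- "O-alkenyl"; x <- sub("^P-", "", x) }
  m <- regmatches(x, regexec("^([0-9]+):([0-9]+)(\\(([^)]*)\\))?$", x))[[1]]
  if (length(m) == 0) stop("cannot parse chain: ", x, call. = FALSE)
  pos <- NULL
  if (nchar(m[5]) > 0) {
    pos <- as.integer(gsub("[^0-9,]", "", strsplit(m[5], ",")[[1]]))
  }
  acyl_chain(as.integer(m[2]), as.integer(m[3]), positions = pos,
             linkage = linkage)
}

# ---- lipid species -----------------------------------------------------------

.SUBCLASSES <- c("PC", "PE", "PG", "PI", "PA", "PS", "FA")

# Diacyl glycerophospholipid templates as functions of total chain carbons c
# and total double bonds D. Built from glycerol + H3PO4 + headgroup alcohol +
# c-carbon acids - 4 H2O; each O-alkyl ether chain modifies by -O +2H.
.TEMPLATE <- list(
  PC = function(c, D) c(C = c + 8, H = 2 * c + 16 - 2 * D, N = 1, O = 8, P = 1),
  PE = function(c, D) c(C = c + 5, H = 2 * c + 10 - 2 * D, N = 1, O = 8, P = 1),
  PG = function(c, D) c(C = c + 6, H = 2 * c + 11 - 2 * D, O = 10, P = 1),
  PI = function(c, D) c(C = c + 9, H = 2 * c + 15 - 2 * D, O = 13, P = 1),
  PA = function(c, D) c(C = c + 3, H = 2 * c + 5 - 2 * D, O = 8, P = 1),
  PS = function(c, D) c(C = c + 6, H = 2 * c + 10 - 2 * D, N = 1, O = 10, P = 1),
  FA = function(c, D) c(C = c, H = 2 * c - 2 * D, O = 2)
)

#' Lipid species
#'
#' A glycerophospholipid (two chains) or free fatty acid (one chain). The
#' sn-positions of the chains are never resolved by this workflow, so chains
#' are stored order-normalized and displayed with the `_` separator.
#'
#' @param subclass One of PC, PE, PG, PI, PA, PS or FA.
#' @param chains A list of [acyl_chain()] objects (length 1 for FA, 2
#'   otherwise), or a character vector of chain shorthands.
#' @return A `lipid_species` object.
#' @examples
#' lipid_species("PE", c("16:0", "18:1(9)"))
#' parse_lipid("PE 17:0_22:4(7,10,13,16)")
#' @export
lipid_species <- function(subclass, chains) {
  subclass <- match.arg(subclass, .SUBCLASSES)
  if (is.character(chains)) chains <- lapply(chains, parse_chain)
  if (!all(vapply(chains, inherits, logical(1), "acyl_chain"))) {
    stop("`chains` must be acyl_chain objects or shorthand strings", call. = FALSE)
  }
  n_expected <- if (subclass == "FA") 1L else 2L
  if (length(chains) != n_expected) {
    stop(subclass, " species must have ", n_expected, " chain(s)", call. = FALSE)
  }
  if (subclass == "FA" && chains[[1]]$linkage != "acyl") {
    stop("a free fatty acid cannot carry an ether linkage", call. = FALSE)
  }
  structure(list(subclass = subclass, chains = chains, sn_resolved = FALSE),
            class = "lipid_species")
}

#' @export
format.lipid_species <- function(x, level = c("cc", "chain", "subclass"), ...) {
  level <- match.arg(level)
  c_tot <- sum(vapply(x$chains, `[[`, integer(1), "carbons"))
  d_tot <- sum(vapply(x$chains, `[[`, integer(1), "double_bonds"))
  if (level == "subclass") {
    if (x$subclass == "FA") return(paste0("FA ", c_tot, ":", d_tot))
    return(paste0(x$subclass, " ", c_tot, ":", d_tot))
  }
  chains <- vapply(x$chains, format.acyl_chain, character(1),
                   show_positions = (level == "cc"))
  paste0(x$subclass, " ", paste(chains, collapse = "_"))
}

#' @export
print.lipid_species <- function(x, ...) {
  cat("<lipid_species> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @rdname lipid_species
#' @param x A shorthand string such as `"PE 16:0_18:1"`,
#'   `"PE 16:0_18:1(Δ9)"` or `"PC O-16:1/16:0"`.
#' @export
parse_lipid <- function(x) {
  x <- trimws(x)
  m <- regmatches(x, regexec("^([A-Z]+)[ ]+(.+)$", x))[[1]]
  if (length(m) == 0) stop("cannot parse lipid shorthand: ", x, call. = FALSE)
  chains <- strsplit(m[3], "[_/]")[[1]]
  lipid_species(m[2], chains)
}

#' Total composition of a species
#'
#' @param species A `lipid_species`.
#' @return Named list with `carbons`, `double_bonds`, `n_ether`.
#' @export
species_composition <- function(species) {
  stopifnot(inherits(species, "lipid_species"))
  list(
    carbons = sum(vapply(species$chains, `[[`, integer(1), "carbons")),
    double_bonds = sum(vapply(species$chains, `[[`, integer(1), "double_bonds")),
    n_ether = sum(vapply(species$chains, function(ch) ch$linkage != "acyl",
                         logical(1)))
  )
}

#' Molecular formula of a lipid species
#'
#' Applies the diacyl (or free-acid) subclass template to the summed chain
#' composition; each ether chain modifies the template by -O +2H.
#'
#' @param species A `lipid_species` or shorthand string.
#' @return A `chem_formula`.
#' @examples
#' formula_of_species("PE 17:0_22:4")  # C44H80NO8P, 781.5622 Da
#' @export
formula_of_species <- function(species) {
  if (is.character(species)) species <- parse_lipid(species)
  comp <- species_composition(species)
  counts <- .TEMPLATE[[species$subclass]](comp$carbons, comp$double_bonds)
  if (comp$n_ether > 0) {
    counts["O"] <- counts["O"] - comp$n_ether
    counts["H"] <- counts["H"] + 2L * comp$n_ether
  }
  do.call(chem_formula, as.list(counts))
}

#' Neutral monoisotopic mass of a species (template grid form)
#'
#' Vectorized over `carbons`/`double_bonds`; used for fast matching of profile
#' peaks against the species grid without constructing objects.
#'
#' @param subclass Subclass code (recycled).
#' @param carbons,double_bonds Total chain composition.
#' @param n_ether Number of ether chains (default 0).
#' @return Neutral mass in Da.
#' @export
species_grid_mass <- function(subclass, carbons, double_bonds, n_ether = 0) {
  n <- max(length(subclass), length(carbons), length(double_bonds))
  subclass <- rep_len(subclass, n)
  carbons <- rep_len(carbons, n)
  double_bonds <- rep_len(double_bonds, n)
  n_ether <- rep_len(n_ether, n)
  vapply(seq_len(n), function(i) {
    counts <- .TEMPLATE[[subclass[i]]](carbons[i], double_bonds[i])
    counts["O"] <- counts["O"] - n_ether[i]
    counts["H"] <- counts["H"] + 2 * n_ether[i]
    .fmass(counts)
  }, numeric(1))
}

# ---- adducts -----------------------------------------------------------------

.ADDUCTS <- tibble::tibble(
  adduct = c("[M+H]+", "[M-H]-", "[M+CH3COO]-", "[M+NH4]+", "[M+Na]+"),
  polarity = c("positive", "negative", "negative", "positive", "positive"),
  # deltas follow the proton-mass charge convention throughout:
  # cation m/z = M + (carrier formula) + proton, anion m/z = M - proton (+ carrier)
  delta = c(
    1.007276,
    -1.007276,
    NA_real_,  # filled below: CH3COOH - proton
    NA_real_,  # NH3 + proton
    NA_real_   # Na - H + proton  (sodium replaces nothing: M + Na+, Na - electron)
  ),
  charge = c(1L, -1L, -1L, 1L, 1L)
)
.ADDUCTS$delta[3] <- .fmass(c(C = 2, H = 4, O = 2)) - .PROTON
.ADDUCTS$delta[4] <- .fmass(c(N = 1, H = 3)) + .PROTON
.ADDUCTS$delta[5] <- .ELEMENT_MASS[["Na"]] - .ELEMENT_MASS[["H"]] + .PROTON

#' Supported adducts
#'
#' All singly charged. Deltas use the proton-mass convention
#' (`[M+H]+ = M + 1.007276`), which reproduces printed four-decimal ion masses.
#'
#' @return A tibble with columns `adduct`, `polarity`, `delta`, `charge`.
#' @export
adducts <- function() .ADDUCTS

adduct_info <- function(adduct) {
  row <- .ADDUCTS[.ADDUCTS$adduct == adduct, ]
  if (nrow(row) == 0) stop("unknown adduct: ", adduct, call. = FALSE)
  row
}

#' Precursor m/z of a species under an adduct
#'
#' @param species A `lipid_species` or shorthand string.
#' @param adduct Adduct name, e.g. `"[M+H]+"`, `"[M-H]-"`, `"[M+CH3COO]-"`.
#' @param check_polarity If `TRUE` (default), an adduct whose polarity is not
#'   meaningful for the subclass-mode combination raises an error rather than
#'   being silently accepted.
#' @return m/z in Th.
#' @examples
#' precursor_mz("PE 16:0_18:1", "[M+H]+")   # 718.5381
#' precursor_mz("FA 18:1", "[M-H]-")        # 281.2486
#' @export
precursor_mz <- function(species, adduct, check_polarity = TRUE) {
  if (is.character(species)) species <- parse_lipid(species)
  info <- adduct_info(adduct)
  if (check_polarity && species$subclass == "FA" &&
      info$polarity == "positive") {
    stop("free fatty acids are analyzed in negative mode; got ", adduct,
         call. = FALSE)
  }
  monoisotopic_mass(formula_of_species(species)) + info$delta
}

#' Fatty acyl carboxylate anion m/z
#'
#' The [RCOO]- fragment observed in negative-mode chain analysis, i.e. the
#' free-acid monoisotopic mass minus a proton.
#'
#' @param chain An `acyl_chain` or shorthand (e.g. `"16:0"`).
#' @return m/z in Th, or `NA_real_` for ether chains (which produce no
#'   carboxylate anion).
#' @examples
#' acyl_anion_mz("16:0")  # 255.2330
#' acyl_anion_mz("18:1")  # 281.2486
#' @export
acyl_anion_mz <- function(chain) {
  if (is.character(chain)) chain <- parse_chain(chain)
  stopifnot(inherits(chain, "acyl_chain"))
  if (chain$linkage != "acyl") return(NA_real_)
  counts <- c(C = chain$carbons, H = 2 * chain$carbons - 2 * chain$double_bonds,
              O = 2)
  .fmass(counts) - .PROTON
}

# ---- headgroup scans ---------------------------------------------------------

.HEADGROUP_SCANS <- list(
  `PE.positive` = list(subclass = "PE", polarity = "positive", mode = "NLS",
                       formula = "C2H8NO4P"),
  `PC.positive` = list(subclass = "PC", polarity = "positive", mode = "PIS",
                       formula = "C5H14NO4P", charge = +1L),
  `PG.negative` = list(subclass = "PG", polarity = "negative", mode = "PIS",
                       formula = "C3H7O5P", charge = -1L),
  `PI.negative` = list(subclass = "PI", polarity = "negative", mode = "PIS",
                       formula = "C6H11O8P", charge = -1L)
)

#' Headgroup-specific profiling scan descriptor
#'
#' The triple-quadrupole scan used to profile each subclass: PE by a 141 Da
#' neutral-loss scan in positive mode, PC by a precursor-ion scan of the
#' phosphocholine fragment m/z 184 in positive mode, PG and PI by negative-mode
#' precursor-ion scans of m/z 153 and 241 respectively.
#'
#' @param subclass One of PE, PC, PG, PI.
#' @param polarity `"positive"` or `"negative"`.
#' @return A tibble with `subclass`, `polarity`, `mode` (`"NLS"` or `"PIS"`),
#'   `mz` (exact neutral-loss mass or fragment m/z) and `nominal`.
#' @examples
#' headgroup_scan("PE", "positive")  # NLS 141.0191
#' headgroup_scan("PI", "negative")  # PIS 241.0119
#' @export
headgroup_scan <- function(subclass, polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  key <- paste(subclass, polarity, sep = ".")
  sc <- .HEADGROUP_SCANS[[key]]
  if (is.null(sc)) {
    stop("no profiling scan defined for ", subclass, " in ", polarity,
         " mode", call. = FALSE)
  }
  mz <- monoisotopic_mass(sc$formula)
  if (sc$mode == "PIS") mz <- mz + sign(sc$charge) * .PROTON  # ionized fragment
  tibble::tibble(subclass = subclass, polarity = polarity, mode = sc$mode,
                 mz = mz, nominal = nominal_mz(mz))
}

#' Profiling adduct conventions per subclass
#'
#' The adduct under which each subclass appears in its profiling scan, and the
#' negative-mode adduct used for chain-analysis MS/MS.
#'
#' @return A tibble with `subclass`, `profile_polarity`, `profile_adduct`,
#'   `chain_adduct`.
#' @export
subclass_adducts <- function() {
  tibble::tibble(
    subclass = c("PE", "PC", "PG", "PI", "FA"),
    profile_polarity = c("positive", "positive", "negative", "negative",
                         "negative"),
    profile_adduct = c("[M+H]+", "[M+H]+", "[M-H]-", "[M-H]-", "[M-H]-"),
    chain_adduct = c("[M-H]-", "[M+CH3COO]-", "[M-H]-", "[M-H]-", "[M-H]-")
  )
}
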