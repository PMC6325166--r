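# Exact-mass substrate: element table, formula arithmetic, lipid templates,
# adducts and headgroup scan constants.

test_that("element masses match IUPAC monoisotopic values and constants are self-consistent", {
  em <- element_masses()
  ref <- c(C = 12, H = 1.0078250319, N = 14.0030740052, O = 15.9949146221,
           P = 30.97376151)
  for (el in names(ref)) {
    expect_lt(abs(em$mass_da[em$name == el] - ref[[el]]), 1e-4)
  }
  # named constants equal the mass of their own formulas
  for (nm in c("acetone", "ethyne", "pe_headgroup_loss", "acetate")) {
    row <- em[em$name == nm, ]
    expect_equal(row$mass_da, monoisotopic_mass(row$formula), tolerance = 1e-9)
  }
  expect_equal(em$mass_da[em$name == "acetone"], 58.041865, tolerance = 1e-4)
  expect_equal(em$mass_da[em$name == "ethyne"], 26.0157, tolerance = 1e-4)
  expect_equal(em$mass_da[em$name == "proton"], 1.007276, tolerance = 1e-6)
})

test_that("formula arithmetic is element-wise and guards against negative counts", {
  a <- chem_formula(C = 3, H = 6, O = 1)
  b <- chem_formula(H = 2, O = 1)
  expect_equal(format(a + b), "C3H8O2")
  expect_equal(format(a - b), "C3H4")
  expect_error(b - a, "negative")
  expect_error(chem_formula(C = -1), ">= 0")
  expect_error(chem_formula(Xx = 2), "unknown element")
  expect_equal(format(parse_formula("C44H80NO8P")), "C44H80NO8P")
  expect_equal(monoisotopic_mass(chem_formula()), 0)
})

test_that("monoisotopic_mass reproduces hand-summed values", {
  expect_equal(monoisotopic_mass("H2O"), 18.010565, tolerance = 1e-6)
  expect_equal(monoisotopic_mass("C3H6O"), oracle_mass(C = 3, H = 6, O = 1),
               tolerance = 1e-9)
  expect_equal(monoisotopic_mass("C3H6O"), 58.041865, tolerance = 1e-6)
  expect_error(monoisotopic_mass(42), "chem_formula")
})

test_that("species formula templates hit the printed reference masses", {
  f <- formula_of_species("PE 17:0_22:4")
  expect_equal(format(f), "C44H80NO8P")
  expect_equal(monoisotopic_mass(f), 781.5622, tolerance = 1e-4)
  # frozen from the building-block oracle
  expect_equal(format(formula_of_species("PE 16:0_18:1")), "C39H76NO8P")
  expect_equal(monoisotopic_mass(formula_of_species("PE 16:0_18:1")),
               oracle_species_mass("PE", 16, 0, 18, 1), tolerance = 1e-6)
  expect_equal(monoisotopic_mass(formula_of_species("PE 16:0_18:1")),
               717.5309, tolerance = 1e-4)
  expect_equal(monoisotopic_mass(formula_of_species("FA 18:1")),
               282.2559, tolerance = 1e-4)
  # the PE 39:4 / PC 36:4 isobar pair shares one molecular formula
  expect_equal(format(formula_of_species("PC 16:0_20:4")),
               format(formula_of_species("PE 17:0_22:4")))
  # each ether chain modifies the template by -O +2H
  diacyl <- formula_of_species("PC 16:1/16:0")
  ether <- formula_of_species("PC O-16:1/16:0")
  expect_equal(monoisotopic_mass(ether) - monoisotopic_mass(diacyl),
               2 * 1.00782503207 - 15.9949146196, tolerance = 1e-6)
})

test_that("closed-form templates equal building-block assembly for 200 random species", {
  set.seed(42)
  subclasses <- c("PC", "PE", "PG", "PI", "PA", "PS")
  for (i in 1:200) {
    sc <- sample(subclasses, 1)
    c1 <- sample(8:26, 1); c2 <- sample(8:26, 1)
    d1 <- sample(0:4, 1); d2 <- sample(0:4, 1)
    sp <- lipid_species(sc, c(paste0(c1, ":", d1), paste0(c2, ":", d2)))
    expect_equal(monoisotopic_mass(formula_of_species(sp)),
                 oracle_species_mass(sc, c1, d1, c2, d2), tolerance = 1e-6)
  }
})

test_that("precursor m/z follows the proton-mass adduct convention", {
  expect_equal(precursor_mz("PE 16:0_18:1", "[M+H]+"), 718.5381,
               tolerance = 1e-4)
  expect_equal(precursor_mz("FA 18:1", "[M-H]-"), 281.2486, tolerance = 1e-4)
  # +H / -H differ by exactly two proton masses, any species
  for (s in c("PE 16:0_18:1", "PC 15:0_18:2", "PI 18:0_20:4")) {
    expect_equal(precursor_mz(s, "[M+H]+", check_polarity = FALSE) -
                   precursor_mz(s, "[M-H]-", check_polarity = FALSE),
                 2 * 1.007276, tolerance = 1e-9)
  }
  ad <- adducts()
  expect_equal(ad$delta[ad$adduct == "[M+NH4]+"], 18.033823, tolerance = 1e-4)
  expect_equal(ad$delta[ad$adduct == "[M+Na]+"], 22.989218, tolerance = 1e-4)
  # acetate delta = CH3COOH - proton (convention-consistent)
  expect_equal(ad$delta[ad$adduct == "[M+CH3COO]-"],
               oracle_mass(C = 2, H = 4, O = 2) - ORACLE_PROTON,
               tolerance = 1e-6)
  expect_error(precursor_mz("FA 18:1", "[M+H]+"), "negative mode")
  expect_error(adduct_info("[M+K]+"), "unknown adduct")
})

test_that("acyl anions hit the printed fragment masses; ether chains yield none", {
  expect_equal(acyl_anion_mz("16:0"), 255.2330, tolerance = 1e-4)
  expect_equal(acyl_anion_mz("18:1"), 281.2486, tolerance = 1e-4)
  expect_equal(acyl_anion_mz("2:0"), 59.0133, tolerance = 1e-3)  # acetate
  expect_true(is.na(acyl_anion_mz(parse_chain("O-16:1"))))
})

test_that("headgroup scan constants round to the instrument's nominal settings", {
  pe <- headgroup_scan("PE", "positive")
  expect_equal(pe$mode, "NLS")
  expect_equal(pe$mz, 141.0191, tolerance = 1e-4)
  expect_equal(pe$nominal, 141L)
  pc <- headgroup_scan("PC", "positive")
  expect_equal(pc$mode, "PIS")
  expect_equal(pc$mz, 184.0733, tolerance = 1e-4)
  expect_equal(pc$nominal, 184L)
  pg <- headgroup_scan("PG", "negative")
  expect_equal(pg$mz, 152.9958, tolerance = 1e-4)
  expect_equal(pg$nominal, 153L)
  pi_ <- headgroup_scan("PI", "negative")
  expect_equal(pi_$mz, 241.0119, tolerance = 1e-4)
  expect_equal(pi_$nominal, 241L)
  expect_error(headgroup_scan("PS", "negative"), "no profiling scan")
  expect_error(headgroup_scan("PE", "negative"), "no profiling scan")
})

test_that("chain and species shorthand round-trips, with validation", {
  ch <- parse_chain("18:2(9,12)")
  expect_equal(ch$positions, c(9L, 12L))
  expect_equal(format(ch), "18:2(Δ9,Δ12)")
  sp <- parse_lipid("PC O-16:1/16:0")
  expect_equal(sp$chains[[1]]$linkage, "O-alkyl")
  expect_equal(format(sp, level = "chain"), "PC O-16:1_16:0")
  expect_false(sp$sn_resolved)
  expect_equal(format(parse_lipid("PE 16:0_18:1(Δ9)"), level = "subclass"),
               "PE 34:1")
  expect_error(acyl_chain(18, 1, positions = c(18)), "positions must lie")
  expect_error(acyl_chain(18, 2, positions = c(12, 9)),
               "strictly increasing")
  expect_error(acyl_chain(4, 3), "at most")
  expect_error(lipid_species("FA", c("16:0", "18:1")), "1 chain")
  expect_error(lipid_species("FA", list(parse_chain("O-16:1"))), "ether")
})

test_that("nominal m/z rounds half up", {
  expect_equal(nominal_mz(c(467.3731, 493.3888, 152.9958, 141.5)),
               c(467L, 493L, 153L, 142L))
})
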