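# Subclass profiling, chain assignment and target-list generation.

make_profile_spectrum <- function(subclass, mz, intensity, rt,
                                  sample_id = "s1") {
  scan <- headgroup_scan(subclass,
                         subclass_adducts()$profile_polarity[
                           subclass_adducts()$subclass == subclass])
  spectra_tibble(
    scan_id = paste0("prof_", subclass, "_", rt), scan_type = scan$mode,
    polarity = scan$polarity, precursor_mz = NA_real_, rt_min = rt,
    peaks = list(tibble::tibble(mz = mz, intensity = intensity)),
    sample_id = sample_id)
}

test_that("profile_subclass annotates NLS/PIS peaks against the species grid", {
  sp <- make_profile_spectrum("PE", c(718.54, 768.55, 655.00),
                              c(5000, 10000, 400), rt = 5.2)
  hits <- profile_subclass(sp, "PE")  # peaks come back in ascending m/z
  expect_equal(nrow(hits), 3)
  expect_equal(hits$species[hits$mz == 718.54], "PE 34:1")
  expect_equal(hits$species[hits$mz == 768.55], "PE 38:4")
  expect_false(hits$matched[hits$mz == 655])  # off-grid peak retained, flagged
  expect_equal(hits$rel_int_pct[order(hits$mz)], c(4, 50, 100),
               tolerance = 0.01)
  expect_equal(hits$bin[order(hits$mz)], c("1-10%", ">10%", ">10%"))
  expect_equal(nrow(profile_subclass(sp[0, ], "PE")), 0)
})

test_that("isobaric PE/PC pair is separated by scan type and retention time", {
  # PE 39:4 and PC 36:4 share m/z 782.57 but appear in different scans/RTs
  pe <- make_profile_spectrum("PE", 782.57, 1000, rt = 5.2)
  pc <- make_profile_spectrum("PC", 782.57, 1000, rt = 14.3)
  both <- dplyr::bind_rows(pe, pc)
  hits_pe <- profile_subclass(both, "PE")
  hits_pc <- profile_subclass(both, "PC")
  expect_equal(hits_pe$species, "PE 39:4")
  expect_equal(hits_pe$rt_min, 5.2)
  expect_equal(hits_pc$species, "PC 36:4")
  expect_equal(hits_pc$rt_min, 14.3)
  # the PE scan at PC-like retention time is never profiled as PC
  stray <- make_profile_spectrum("PE", 782.57, 1000, rt = 14.3)
  expect_equal(nrow(profile_subclass(stray, "PE")), 0)  # outside PE window
  expect_equal(nrow(profile_subclass(stray, "PC")), 0)  # wrong scan type
})

test_that("chain-analysis targets use the subclass negative-mode adduct", {
  pe <- make_profile_spectrum("PE", 718.54, 1000, rt = 5.2)
  pc <- make_profile_spectrum("PC", 782.57, 1000, rt = 14.3)
  tg <- build_chain_targets(dplyr::bind_rows(
    profile_subclass(pe, "PE"), profile_subclass(pc, "PC")))
  expect_equal(tg$adduct, c("[M-H]-", "[M+CH3COO]-"))
  expect_equal(tg$target_mz[1], 716.5236, tolerance = 1e-3)
  expect_equal(tg$target_mz[2], 840.5760, tolerance = 1e-3)
  expect_equal(tg$polarity, c("negative", "negative"))
  # saturated species are targeted too
  sat <- make_profile_spectrum("PE", 692.52, 1000, rt = 5.3)
  hit <- profile_subclass(sat, "PE")
  expect_equal(hit$species, "PE 32:0")
  expect_equal(nrow(build_chain_targets(hit)), 1)
})

test_that("assign_chains scores compositions by matched acyl-anion intensity", {
  pe <- make_profile_spectrum("PE", 718.54, 1000, rt = 5.2)
  tg <- build_chain_targets(profile_subclass(pe, "PE"))
  ms2 <- spectra_tibble(
    "chain1", "EPI-MS2", "negative", tg$target_mz, 5.2,
    list(tibble::tibble(mz = c(255.233, 281.249, 253.217, 283.264),
                        intensity = c(500, 480, 60, 55))),
    sample_id = "s1")
  asg <- assign_chains(ms2, tg)
  expect_equal(nrow(asg), 2)
  expect_equal(asg$chain_1[1], "16:0")
  expect_equal(asg$chain_2[1], "18:1")
  expect_true(asg$dominant[1])
  expect_equal(asg$chain_1[2], "16:1")   # weaker 16:1_18:0 ranked second
  expect_equal(asg$chain_2[2], "18:0")
  expect_false(asg$dominant[2])
  expect_equal(asg$score, c(980, 115))
  # odd-carbon composition: PE 39:4 from 269.2 / 331.3
  pe2 <- make_profile_spectrum("PE", 782.57, 800, rt = 5.3)
  tg2 <- build_chain_targets(profile_subclass(pe2, "PE"))
  ms2b <- spectra_tibble(
    "chain2", "EPI-MS2", "negative", tg2$target_mz, 5.3,
    list(tibble::tibble(mz = c(269.249, 331.264), intensity = c(300, 280))),
    sample_id = "s1")
  asg2 <- assign_chains(ms2b, tg2)
  expect_equal(asg2$chain_1[1], "17:0")
  expect_equal(asg2$chain_2[1], "22:4")
  # no matching composition: flagged unresolved
  ms2c <- spectra_tibble(
    "chain3", "EPI-MS2", "negative", tg$target_mz, 5.2,
    list(tibble::tibble(mz = 100.0, intensity = 10)), sample_id = "s1")
  asg3 <- assign_chains(ms2c, tg)
  expect_false(asg3$chains_resolved)
})

test_that("PB targets: one per unsaturated assignment, none saturated, range-filtered", {
  asg <- dplyr::bind_rows(
    chain_assignment_fixture("PE", "16:0", "18:1", rt_min = 5.7),
    chain_assignment_fixture("PC", "16:0", "16:0", rt_min = 14.2),
    chain_assignment_fixture("FA", "18:1", NA_character_, rt_min = 1.0))
  tg <- build_pb_targets(asg)
  expect_equal(nrow(tg), 2)  # saturated PC 32:0 excluded
  pe <- tg[tg$subclass == "PE", ]
  expect_equal(pe$pb_mz, 776.5799, tolerance = 1e-3)
  expect_equal(pe$adduct, "[M+H]+")
  fa <- tg[tg$subclass == "FA", ]
  expect_equal(fa$pb_mz, 339.2905, tolerance = 1e-3)
  expect_equal(fa$polarity, "negative")
  # PG runs on the acyl-anion basis, one target per unsaturated chain
  pg <- build_pb_targets(chain_assignment_fixture("PG", "16:0", "18:1",
                                                  rt_min = 2.0))
  expect_equal(nrow(pg), 1)
  expect_equal(pg$basis, "fatty-acyl-anion")
  expect_equal(pg$pb_mz, acyl_anion_mz("18:1") + 58.041865, tolerance = 1e-6)
  expect_equal(pg$cc_chain, "18:1")
  # the PE m/z acquisition window (350-1000) filters out-of-range targets
  cfg <- pb_config(mz_range = list(PE = c(350, 700), PC = c(500, 1000),
                                   PG = c(100, 400), PI = c(100, 400),
                                   FA = c(100, 400)))
  expect_equal(nrow(build_pb_targets(
    chain_assignment_fixture("PE", "16:0", "18:1"), cfg)), 0)
})

test_that("simulated noise-free profiling recovers every species above the floor", {
  tr <- generate_lipidome(24, seed = 3)
  sp <- simulate_run(tr, sim_params_noise_free(), seed = 3)
  hits <- dplyr::bind_rows(lapply(c("PE", "PC", "PG", "PI"), function(s)
    profile_subclass(sp, s)))
  truth_species <- unique(vapply(unique(tr$acyl_id), function(id) {
    rows <- tr[tr$acyl_id == id, ][1, ]
    chains <- if (is.na(rows$chain_2)) rows$chain_1 else
      c(rows$chain_1, rows$chain_2)
    format(lipid_species(rows$subclass, chains), level = "subclass")
  }, character(1)))
  truth_species <- setdiff(truth_species, "FA 18:1")  # no FA headgroup scan
  expect_true(all(truth_species %in% hits$species))
})
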