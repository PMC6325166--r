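# De novo C=C assignment and isomer relative quantitation.

test_that("noise-free PB spectrum yields exactly the ground-truth isomer calls", {
  asg <- chain_assignment_fixture("PE", "16:0", "18:1")
  spec <- pb_fixture_spectrum(
    "PE 16:0_18:1", "18:1",
    list(list(positions = 9, fa_int = 300, fo_int = 290),
         list(positions = 11, fa_int = 100, fo_int = 95)))
  cc <- assign_cc(spec, asg)
  called <- cc[!cc$unassigned, ]
  expect_equal(sort(called$positions), c("11", "9"))
  expect_equal(called$rank[called$positions == "9"], 1L)
  expect_true(all(called$collision_free))
  expect_equal(called$omega[called$positions == "9"], 9L)
  expect_equal(called$omega[called$positions == "11"], 7L)
})

test_that("removing one ion of a pair removes that call and only that call", {
  asg <- chain_assignment_fixture("PE", "16:0", "18:1")
  d9 <- diagnostic_pairs("PE 16:0_18:1", "18:1", 9, "[M+H]+")
  spec <- pb_fixture_spectrum(
    "PE 16:0_18:1", "18:1",
    list(list(positions = 9, fa_int = 300, fo_int = 290),
         list(positions = 11, fa_int = 100, fo_int = 95)),
    drop_mz = d9$fo_mz)  # remove 493: delta-9 pair incomplete
  cc <- assign_cc(spec, asg)
  called <- cc[!cc$unassigned, ]
  expect_equal(called$positions, "11")
  # dropping every ion leaves the chain flagged unassigned
  all_mz <- c(d9$fa_mz, d9$fo_mz,
              diagnostic_pairs("PE 16:0_18:1", "18:1", 11, "[M+H]+")$fa_mz,
              diagnostic_pairs("PE 16:0_18:1", "18:1", 11, "[M+H]+")$fo_mz)
  spec2 <- pb_fixture_spectrum(
    "PE 16:0_18:1", "18:1",
    list(list(positions = 9, fa_int = 300, fo_int = 290),
         list(positions = 11, fa_int = 100, fo_int = 95)),
    drop_mz = all_mz)
  cc2 <- assign_cc(spec2, asg)
  expect_true(all(cc2$unassigned))
})

test_that("polyunsaturated chains resolve to the complete methylene-interrupted set", {
  asg <- chain_assignment_fixture("PE", "17:0", "22:4", rt_min = 5.2)
  spec <- pb_fixture_spectrum(
    "PE 17:0_22:4", "22:4",
    list(list(positions = c(7, 10, 13, 16), fa_int = 200, fo_int = 190)),
    rt_min = 5.2)
  cc <- assign_cc(spec, asg)
  called <- cc[!cc$unassigned, ]
  expect_equal(called$positions, "7,10,13,16")
  expect_equal(called$omega, 6L)
  expect_equal(nrow(called), 1)  # no other candidate set is pair-complete
})

test_that("F_A:F_O intensity similarity and S/N floors gate acceptance", {
  asg <- chain_assignment_fixture("PE", "16:0", "18:1")
  # wildly asymmetric pair (ratio 20 > limit 5): rejected
  spec <- pb_fixture_spectrum(
    "PE 16:0_18:1", "18:1",
    list(list(positions = 9, fa_int = 2000, fo_int = 100)))
  expect_true(all(assign_cc(spec, asg)$unassigned))
  # intensities below the S/N floor (3 with unit noise floor): rejected
  spec2 <- pb_fixture_spectrum(
    "PE 16:0_18:1", "18:1",
    list(list(positions = 9, fa_int = 2, fo_int = 2)))
  expect_true(all(assign_cc(spec2, asg)$unassigned))
})

test_that("isomer_ratio implements the summed diagnostic-ion formula verbatim", {
  asg <- chain_assignment_fixture("PE", "16:0", "18:1")
  spec <- pb_fixture_spectrum(
    "PE 16:0_18:1", "18:1",
    list(list(positions = 9, fa_int = 300, fo_int = 290),
         list(positions = 11, fa_int = 100, fo_int = 95)))
  r <- isomer_ratio(assign_cc(spec, asg))
  expect_equal(nrow(r), 1)
  expect_equal(r$isomer_a, "9")   # lower delta is the numerator
  expect_equal(r$isomer_b, "11")
  expect_equal(r$ratio, (300 + 290) / (100 + 95), tolerance = 1e-9)
  expect_equal(r$ratio, 3.026, tolerance = 1e-3)
  # swapping isomer intensities inverts the ratio exactly
  spec_swap <- pb_fixture_spectrum(
    "PE 16:0_18:1", "18:1",
    list(list(positions = 9, fa_int = 100, fo_int = 95),
         list(positions = 11, fa_int = 300, fo_int = 290)))
  r_swap <- isomer_ratio(assign_cc(spec_swap, asg))
  expect_equal(r_swap$ratio, 1 / r$ratio, tolerance = 1e-9)
  # a single isomer emits no ratio
  single <- pb_fixture_spectrum(
    "PE 16:0_18:1", "18:1",
    list(list(positions = 9, fa_int = 300, fo_int = 290)))
  expect_equal(nrow(isomer_ratio(assign_cc(single, asg))), 0)
})

test_that("replicate ratios aggregate to mean and RSD", {
  ratios <- tibble::tibble(
    sample_id = c("r1", "r2", "r3"), lipid = "PE 16:0_18:1", chain = "18:1",
    isomer_a = "9", isomer_b = "11", intensity_a = 1, intensity_b = 1,
    ratio = c(3.0, 3.1, 2.9), undefined = FALSE)
  s <- summarize_ratios(ratios)
  expect_equal(s$n, 3L)
  expect_equal(s$mean_ratio, 3.0, tolerance = 1e-9)
  expect_equal(s$rsd_pct, 100 * sd(c(3, 3.1, 2.9)) / 3, tolerance = 1e-9)
  expect_equal(s$rsd_pct, 3.33, tolerance = 1e-2)
})

test_that("omega annotation follows PUFA family nomenclature", {
  cc <- tibble::tibble(chain = c("18:3", "20:2", "18:1", "16:1"),
                       positions = c("9,12,15", "11,14", "9", NA),
                       omega = c(3L, 6L, 9L, NA_integer_),
                       unassigned = c(FALSE, FALSE, FALSE, TRUE))
  out <- annotate_omega(cc)
  expect_equal(out$omega_label,
               c("18:3 ω-3", "20:2 ω-6", "18:1 ω-9", NA))
})

test_that("simulated duplex ratios are recovered within 10% with replicate RSD <= 15%", {
  # PB-MS/MS duplexes at true delta-9/delta-11 ratios {1, 3, 6, 10} with 5%
  # multiplicative intensity noise, three technical repeats per seed
  truth_for_ratio <- function(rho) {
    tibble::tibble(
      species_id = c("a", "b"), acyl_id = "PE 16:0_18:1", subclass = "PE",
      chain_1 = "16:0", chain_2 = "18:1", cc_chain = "18:1",
      positions = c("9", "11"), fraction = c(rho / (rho + 1), 1 / (rho + 1)),
      abundance = c(rho, 1), rt_min = 5.7)
  }
  params <- sim_params(mz_jitter_sd = 0.005, intensity_cv = 0.05,
                       background_density = 0)
  asg <- chain_assignment_fixture("PE", "16:0", "18:1",
                                  sample_id = "sample")
  for (rho in c(1, 3, 6, 10)) {
    recovered <- vapply(1:20, function(seed) {
      reps <- vapply(1:3, function(r) {
        sp <- simulate_run(truth_for_ratio(rho), params,
                           seed = seed * 100 + r)
        rt <- isomer_ratio(assign_cc(sp, asg))
        rt$ratio[rt$isomer_a == "9"]
      }, numeric(1))
      c(mean(reps), sd(reps) / mean(reps) * 100)
    }, numeric(2))
    expect_lt(abs(mean(recovered[1, ]) - rho) / rho, 0.10)
    expect_lte(mean(recovered[2, ]), 15)
  }
})
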