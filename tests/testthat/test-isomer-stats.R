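# Biomarker statistics: group comparisons, FDR, clustering, RSD structure.

make_table <- function(values_by_group, lipid = "L1", kind = "ratio") {
  dplyr::bind_rows(lapply(names(values_by_group), function(g) {
    v <- values_by_group[[g]]
    tibble::tibble(sample_id = paste0(g, "_", seq_along(v)), group = g,
                   individual = paste0(g, "_", seq_along(v)), tech_rep = 1L,
                   lipid = lipid, kind = kind, value = v)
  }))
}

test_that("relative quantitation is a guarded ratio with replicate summaries", {
  expect_equal(relative_quant(0.34, 2.0), 0.17)
  expect_warning(out <- relative_quant(c(1, 2), c(2, 0)), "dropped")
  expect_equal(out, c(0.5, NA))
  reps <- c(0.15, 0.17, 0.19)
  expect_equal(mean(reps), 0.17)
  expect_equal(sd(reps), 0.02)
})

test_that("group comparison matches the closed-form Student t oracle", {
  x <- c(5.0, 4.6, 5.4); y <- c(3.7, 3.5, 3.9)
  res <- compare_groups(make_table(list(a = x, b = y)))
  # pooled-variance t statistic and two-sided p from the t CDF, by hand
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  p_oracle <- 2 * pt(-abs(tstat), df = length(x) + length(y) - 2)
  expect_equal(res$p_value, p_oracle, tolerance = 1e-12)
  expect_lt(res$p_value, 0.01)
  expect_equal(res$direction, "decrease")
  expect_equal(res$stars, "**")
  # identical groups: p = 1, degenerate-variance path
  same <- compare_groups(make_table(list(a = c(2, 2, 2), b = c(2, 2, 2))))
  expect_equal(same$p_value, 1.0)
  # n = 1 in a group is an error
  expect_error(compare_groups(make_table(list(a = 5, b = c(1, 2)))),
               ">= 2")
  # Welch option changes the degrees of freedom
  resw <- compare_groups(make_table(list(a = x, b = c(3.7, 3.5, 3.9, 10))),
                         var_equal = FALSE)
  expect_true(is.finite(resw$p_value))
})

test_that("BH adjustment matches hand computation and is monotone", {
  expect_equal(adjust_pvalues(c(0.001, 0.02, 0.9)), c(0.003, 0.03, 0.9))
  expect_equal(adjust_pvalues(0.04), 0.04)
  expect_equal(adjust_pvalues(rep(0.02, 5)), rep(0.02, 5))
  expect_error(adjust_pvalues(c(0.5, 1.2)))
  set.seed(9)
  p <- runif(50)
  adj <- adjust_pvalues(p)
  expect_true(all(adj >= p - 1e-12))
  # monotone non-decreasing in raw p rank
  ord <- order(p)
  expect_true(all(diff(adj[ord]) >= -1e-12))
})

test_that("type-I error of the t test is nominal under the null", {
  set.seed(11)
  n_sim <- 2000
  x <- matrix(rnorm(n_sim * 6), ncol = 6)
  y <- matrix(rnorm(n_sim * 6), ncol = 6)
  p <- vapply(seq_len(n_sim), function(i)
    t.test(x[i, ], y[i, ], var.equal = TRUE)$p.value, numeric(1))
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.015)
})

test_that("clustering on isomer ratios recovers groups; subclass profiling does not", {
  cohort <- simulate_cohort(seed = 5)
  hc_ratio <- hcluster(cohort, kind = "ratio")
  expect_equal(hc_ratio$rand_index, 1.0)
  expect_equal(length(unique(hc_ratio$clusters)), 2)
  hc_sub <- hcluster(cohort, kind = "subclass")
  expect_lt(hc_sub$rand_index, 1.0)
  # broom-style accessors
  td <- tidy(hc_ratio)
  expect_true(all(c("sample_id", "cluster", "group") %in% names(td)))
  gl <- glance(hc_ratio)
  expect_equal(gl$rand_index, 1.0)
  expect_error(hcluster(cohort, kind = "ratio", k = 100), "k exceeds")
})

test_that("clustering is invariant to column order and per-lipid scaling", {
  cohort <- simulate_cohort(seed = 5)
  ratio <- cohort[cohort$kind == "ratio", ]
  shuffled <- ratio[sample(nrow(ratio)), ]
  expect_equal(hcluster(ratio)$clusters, hcluster(shuffled)$clusters)
  scaled <- ratio
  pick <- scaled$lipid == scaled$lipid[1]
  scaled$value[pick] <- scaled$value[pick] * 7  # absorbed by standardization
  expect_equal(hcluster(ratio)$clusters, hcluster(scaled)$clusters)
})

test_that("rand_index agrees with pair counting on small partitions", {
  a <- c(1, 1, 2, 2)
  expect_equal(rand_index(a, c(1, 1, 2, 2)), 1)
  expect_equal(rand_index(a, c(2, 2, 1, 1)), 1)  # label-invariant
  # one swapped member: 3 of 6 pairs disagree
  expect_equal(rand_index(a, c(1, 2, 2, 2)), 0.5)
  expect_equal(rand_index(c(1, 2, 3), c(1, 1, 1)), 0)
})

test_that("RSD decomposition separates technical from inter-individual spread", {
  reps <- c(4.9, 5.0, 5.1)
  means <- c(5.0, 4.5, 5.5, 5.2, 4.8, 5.0)
  tab <- dplyr::bind_rows(lapply(seq_along(means), function(i) {
    tibble::tibble(sample_id = paste0("ind", i), group = "all",
                   individual = paste0("ind", i), tech_rep = 1:3,
                   lipid = "L1", kind = "ratio",
                   value = reps - 5.0 + means[i])
  }))
  out <- rsd_decomposition(tab)
  expect_equal(out$technical_rsd_pct, 2, tolerance = 0.2)
  expect_equal(out$inter_individual_rsd_pct, 100 * sd(means) / mean(means),
               tolerance = 1e-6)
  expect_equal(out$inter_individual_rsd_pct, 7, tolerance = 0.5)
  # constant data: both zero
  const <- tab; const$value <- 3
  outc <- rsd_decomposition(const)
  expect_equal(outc$technical_rsd_pct, 0)
  expect_equal(outc$inter_individual_rsd_pct, 0)
})

test_that("simulated cohorts return the generating CVs within 20% relative", {
  tech_ratio <- c(); inter_ratio <- c(); inter_sub <- c()
  for (seed in 1:20) {
    cohort <- simulate_cohort(n_per_group = 6, tech_reps = 3,
                              bio_cv_ratio = 0.10, bio_cv_subclass = 0.40,
                              tech_cv = 0.08, seed = seed)
    out <- rsd_decomposition(cohort)
    inter_ratio <- c(inter_ratio,
                     mean(out$inter_individual_rsd_pct[out$kind == "ratio"]))
    inter_sub <- c(inter_sub,
                   mean(out$inter_individual_rsd_pct[out$kind == "subclass"]))
    tech_ratio <- c(tech_ratio,
                    mean(out$technical_rsd_pct[out$kind == "ratio"]))
  }
  expect_lt(abs(mean(tech_ratio) - 8) / 8, 0.20)
  expect_lt(abs(mean(inter_ratio) - 10) / 10, 0.20)
  expect_lt(abs(mean(inter_sub) - 40) / 40, 0.20)
  # the precision contrast: isomer ratios are far tighter than subclass
  expect_lt(mean(inter_ratio) * 2, mean(inter_sub))
})

test_that("comparison results expose tidy/glance and plots build", {
  cohort <- simulate_cohort(seed = 5)
  res <- compare_groups(cohort)
  expect_true(all(res$p_adjusted >= res$p_value - 1e-12))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  gl <- glance(res)
  expect_equal(gl$n_tests, nrow(res))
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(autoplot(hcluster(cohort, kind = "ratio")), "ggplot")
})
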