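# Biomarker-screening statistics over sample x measurement tables: internal
# standard normalization, two-group comparisons with FDR control, RSD
# decomposition and hierarchical clustering of isomer-ratio matrices.
#
# The long "sample ratio table" format used throughout:
#   sample_id, group, individual, tech_rep, lipid, kind, value
# where kind is "subclass" (I/I_IS relative quantitation) or "ratio"
# (diagnostic-ion isomer ratio I_dA/I_dB).

#' Relative quantitation against an internal standard
#'
#' @param intensity Species intensity (vectorized).
#' @param is_intensity Internal-standard intensity; non-positive or missing
#'   values yield `NA` with a warning (the measurement is dropped, not
#'   silently zeroed).
#' @return `intensity / is_intensity`.
#' @examples
#' relative_quant(0.34, 2.0)  # 0.17
#' @export
relative_quant <- function(intensity, is_intensity) {
  bad <- is.na(is_intensity) | is_intensity <= 0
  if (any(bad)) {
    warning(sum(bad), " measurement(s) dropped: missing or non-positive ",
            "internal standard", call. = FALSE)
  }
  ifelse(bad, NA_real_, intensity / is_intensity)
}

#' Two-group comparison per measurement
#'
#' Equal-variance two-tailed Student's t-test by default (Welch switchable)
#' per lipid measurement, with group means, standard deviations, per-group
#' RSDs, Benjamini-Hochberg adjusted p-values and significance stars
#' (* < 0.05, ** < 0.01, *** < 0.001 on the raw p-value). Technical repeats
#' are averaged within individual before testing, so the test's n is the
#' number of biological individuals.
#'
#' @param table A long sample-ratio table (see file header; minimally
#'   `group`, `individual`, `lipid`, `kind`, `value`).
#' @param var_equal Equal-variance Student (default `TRUE`); `FALSE` = Welch.
#' @param adjust_method Multiple-testing method for [stats::p.adjust()]
#'   (default `"BH"`).
#' @return A `pb_compare` tibble: `lipid`, `kind`, per-group `mean`/`sd`/
#'   `rsd_pct`/`n`, `p_value`, `p_adjusted`, `stars`, `direction`.
#' @export
compare_groups <- function(table, var_equal = TRUE, adjust_method = "BH") {
  groups <- sort(unique(table$group))
  if (length(groups) != 2) {
    stop("compare_groups requires exactly 2 groups; found ",
         length(groups), call. = FALSE)
  }
  if (!"individual" %in% names(table)) table$individual <- table$sample_id
  by_ind <- table |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$lipid, .data$kind, .data$group, .data$individual) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  res <- by_ind |>
    dplyr::group_by(.data$lipid, .data$kind) |>
    dplyr::group_modify(function(df, key) {
      x <- df$value[df$group == groups[1]]
      y <- df$value[df$group == groups[2]]
      if (length(x) < 2 || length(y) < 2) {
        stop("each group needs >= 2 individuals for ", key$lipid,
             call. = FALSE)
      }
      p <- if (stats::sd(x) == 0 && stats::sd(y) == 0) {
        if (isTRUE(all.equal(mean(x), mean(y)))) 1.0 else NA_real_
      } else {
        stats::t.test(x, y, var.equal = var_equal)$p.value
      }
      tibble::tibble(
        mean_1 = mean(x), sd_1 = stats::sd(x),
        rsd_pct_1 = stats::sd(x) / mean(x) * 100, n_1 = length(x),
        mean_2 = mean(y), sd_2 = stats::sd(y),
        rsd_pct_2 = stats::sd(y) / mean(y) * 100, n_2 = length(y),
        p_value = p,
        direction = dplyr::case_when(
          mean(y) > mean(x) ~ "increase",
          mean(y) < mean(x) ~ "decrease",
          TRUE ~ "none"))
    }) |>
    dplyr::ungroup()
  res$p_adjusted <- adjust_pvalues(res$p_value, adjust_method)
  res$stars <- significance_stars(res$p_value)
  attr(res, "groups") <- groups
  attr(res, "var_equal") <- var_equal
  attr(res, "adjust_method") <- adjust_method
  class(res) <- c("pb_compare", class(res))
  res
}

significance_stars <- function(p) {
  dplyr::case_when(is.na(p) ~ NA_character_, p < 0.001 ~ "***",
                   p < 0.01 ~ "**", p < 0.05 ~ "*", TRUE ~ "")
}

#' Adjust p-values for multiple testing
#'
#' Thin wrapper over [stats::p.adjust()]; Benjamini-Hochberg by default.
#'
#' @param pvals Numeric p-values in `[0, 1]` (`NA` passed through).
#' @param method Any [stats::p.adjust.methods] entry.
#' @return Adjusted values, same length and order.
#' @examples
#' adjust_pvalues(c(0.001, 0.02, 0.9))  # 0.003 0.030 0.900
#' @export
adjust_pvalues <- function(pvals, method = "BH") {
  stopifnot(all(is.na(pvals) | (pvals >= 0 & pvals <= 1)))
  stats::p.adjust(pvals, method = method)
}

#' Hierarchical clustering of a sample x measurement matrix
#'
#' Pivots the table to samples x lipids (technical repeats averaged),
#' standardizes each lipid (z-score of log2 values by default), clusters with
#' Euclidean distance and average linkage, cuts at `k` groups and scores the
#' agreement between the cut and the known group labels with the Rand index.
#'
#' @param table Long sample-ratio table.
#' @param kind Which measurement kind to cluster on (`"ratio"` or
#'   `"subclass"`); `NULL` uses all.
#' @param k Number of flat clusters to cut (default: number of groups).
#' @param standardize `"log2_z"` (default), `"z"` or `"none"`.
#' @param distance,linkage Passed to [stats::dist()] / [stats::hclust()].
#' @return A `pb_hclust` object: the `hclust` tree, the cut labels, the known
#'   groups, the Rand index and the processing options.
#' @export
hcluster <- function(table, kind = NULL, k = NULL,
                     standardize = c("log2_z", "z", "none"),
                     distance = "euclidean", linkage = "average") {
  standardize <- match.arg(standardize)
  if (!is.null(kind)) table <- table[table$kind %in% kind, ]
  wide <- table |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$sample_id, .data$group, .data$lipid) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "lipid", values_from = "value")
  m <- as.matrix(wide[, setdiff(names(wide), c("sample_id", "group"))])
  rownames(m) <- wide$sample_id
  if (anyNA(m)) stop("clustering requires a complete matrix; impute first",
                     call. = FALSE)
  if (is.null(k)) k <- length(unique(wide$group))
  if (k > nrow(m)) stop("k exceeds the number of samples", call. = FALSE)
  if (standardize == "log2_z") m <- scale(log2(m))
  if (standardize == "z") m <- scale(m)
  # a constant lipid column scales to NaN; it carries no information
  m <- m[, colSums(!is.finite(m)) == 0, drop = FALSE]
  tree <- stats::hclust(stats::dist(m, method = distance), method = linkage)
  cut <- stats::cutree(tree, k = k)
  structure(list(
    tree = tree, clusters = cut, groups = stats::setNames(wide$group,
                                                          wide$sample_id),
    k = k, rand_index = rand_index(cut, wide$group),
    options = list(kind = kind, standardize = standardize,
                   distance = distance, linkage = linkage)
  ), class = "pb_hclust")
}

#' Rand index between two partitions
#'
#' Fraction of sample pairs on which two partitions agree (together in both
#' or apart in both); 1 means identical grouping.
#'
#' @param a,b Two label vectors of equal length.
#' @return Numeric in `[0, 1]`.
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2) return(1)
  idx <- utils::combn(n, 2)
  same_a <- a[idx[1, ]] == a[idx[2, ]]
  same_b <- b[idx[1, ]] == b[idx[2, ]]
  mean(same_a == same_b)
}

#' @export
print.pb_hclust <- function(x, ...) {
  cat("<pb_hclust> ", length(x$clusters), " samples, k = ", x$k,
      ", Rand index vs groups = ", sprintf("%.3f", x$rand_index), "\n",
      sep = "")
  invisible(x)
}

#' Decompose technical vs inter-individual variation
#'
#' Technical RSD is the mean over individuals of the per-individual RSD
#' across technical repeats; inter-individual RSD is the RSD of the
#' individual means. Reported per measurement kind (and per group when
#' present). Without nesting (one repeat per individual) only the pooled RSD
#' is returned.
#'
#' @param table Long sample-ratio table with `individual` and `tech_rep`.
#' @return A tibble: `kind`, `group`, `lipid`, `technical_rsd_pct`,
#'   `inter_individual_rsd_pct`, `pooled_rsd_pct`.
#' @export
rsd_decomposition <- function(table) {
  if (!"individual" %in% names(table)) table$individual <- table$sample_id
  if (!"group" %in% names(table)) table$group <- "all"
  has_reps <- "tech_rep" %in% names(table) &&
    any(duplicated(table[, c("individual", "group", "lipid", "kind",
                             "tech_rep")][, 1:4]))
  table |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$kind, .data$group, .data$lipid) |>
    dplyr::group_modify(function(df, key) {
      ind <- df |>
        dplyr::group_by(.data$individual) |>
        dplyr::summarise(m = mean(.data$value),
                         rsd = if (dplyr::n() > 1)
                           stats::sd(.data$value) / mean(.data$value) * 100
                         else NA_real_,
                         .groups = "drop")
      tibble::tibble(
        technical_rsd_pct = if (has_reps) mean(ind$rsd, na.rm = TRUE)
                            else NA_real_,
        inter_individual_rsd_pct = if (nrow(ind) > 1)
          stats::sd(ind$m) / mean(ind$m) * 100 else NA_real_,
        pooled_rsd_pct = stats::sd(df$value) / mean(df$value) * 100)
    }) |>
    dplyr::ungroup()
}
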