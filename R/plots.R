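# ggplot2 displays and broom-style accessors for the package's result types.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a centroided spectrum with optional diagnostic-ion annotation
#'
#' @param spectrum One row of a spectra tibble, or a peaks tibble.
#' @param annotate Optional tibble with `mz` and `label` columns (e.g. the
#'   theoretical diagnostic ions of an assignment) drawn over the matching
#'   peaks.
#' @param tolerance Label-to-peak matching window (Da).
#' @return A ggplot.
#' @export
plot_spectrum <- function(spectrum, annotate = NULL, tolerance = 0.3) {
  pk <- if (is.data.frame(spectrum) && "peaks" %in% names(spectrum)) {
    spectrum$peaks[[1]]
  } else spectrum
  p <- ggplot2::ggplot(pk, ggplot2::aes(x = .data$mz, y = .data$intensity)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, yend = 0),
                          linewidth = 0.4) +
    ggplot2::labs(x = "m/z", y = "intensity") +
    ggplot2::theme_minimal()
  if (!is.null(annotate) && nrow(annotate) > 0) {
    ann <- annotate
    ann$intensity <- vapply(ann$mz, function(m) {
      hit <- which(abs(pk$mz - m) <= tolerance)
      if (length(hit) == 0) 0 else max(pk$intensity[hit])
    }, numeric(1))
    p <- p + ggplot2::geom_text(
      data = ann, ggplot2::aes(label = .data$label, y = .data$intensity),
      vjust = -0.4, size = 3, color = "firebrick")
  }
  p
}

#' @method autoplot pb_compare
#' @export
autoplot.pb_compare <- function(object, ..., top_n = 20) {
  groups <- attr(object, "groups")
  df <- tibble::as_tibble(object)
  df <- df[order(df$p_value), ][seq_len(min(top_n, nrow(df))), ]
  long <- dplyr::bind_rows(
    tibble::tibble(lipid = df$lipid, group = groups[1], mean = df$mean_1,
                   sd = df$sd_1, stars = df$stars),
    tibble::tibble(lipid = df$lipid, group = groups[2], mean = df$mean_2,
                   sd = df$sd_2, stars = df$stars))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$lipid, y = .data$mean,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(0.8), width = 0.25) +
    ggplot2::geom_text(
      data = long[long$group == groups[1], ],
      ggplot2::aes(label = .data$stars, y = (.data$mean + .data$sd) * 1.05),
      size = 4) +
    ggplot2::labs(x = NULL, y = "measurement") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @method tidy pb_compare
#' @export
tidy.pb_compare <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- class(tibble::tibble())
  out
}

#' @method glance pb_compare
#' @export
glance.pb_compare <- function(x, ...) {
  tibble::tibble(
    n_tests = nrow(x),
    n_sig_raw = sum(x$p_value < 0.05, na.rm = TRUE),
    n_sig_adjusted = sum(x$p_adjusted < 0.05, na.rm = TRUE),
    adjust_method = attr(x, "adjust_method"),
    var_equal = attr(x, "var_equal"))
}

#' @method tidy pb_hclust
#' @export
tidy.pb_hclust <- function(x, ...) {
  tibble::tibble(sample_id = names(x$clusters),
                 cluster = unname(x$clusters),
                 group = unname(x$groups[names(x$clusters)]))
}

#' @method glance pb_hclust
#' @export
glance.pb_hclust <- function(x, ...) {
  tibble::tibble(n_samples = length(x$clusters), k = x$k,
                 rand_index = x$rand_index,
                 linkage = x$options$linkage,
                 distance = x$options$distance,
                 standardize = x$options$standardize)
}

#' @method autoplot pb_hclust
#' @export
autoplot.pb_hclust <- function(object, ...) {
  tree <- object$tree
  dend <- stats::as.dendrogram(tree)
  seg <- .dendrogram_segments(dend)$segments
  labels <- tibble::tibble(
    x = seq_along(tree$labels), label = tree$labels[tree$order],
    group = unname(object$groups[tree$labels[tree$order]]))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg, ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                               yend = .data$yend)) +
    ggplot2::geom_text(
      data = labels,
      ggplot2::aes(x = .data$x, y = -0.02 * max(seg$y), label = .data$label,
                   color = .data$group),
      angle = 90, hjust = 1, size = 3) +
    ggplot2::scale_y_continuous(expand = ggplot2::expansion(mult = c(0.3, 0.05))) +
    ggplot2::labs(x = NULL, y = "height", color = "group") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

# Flatten a dendrogram into plottable segments.
.dendrogram_segments <- function(node, x_offset = 0) {
  if (stats::is.leaf(node)) {
    return(list(x = x_offset + 1, segments = NULL))
  }
  left <- .dendrogram_segments(node[[1]], x_offset)
  n_left <- if (stats::is.leaf(node[[1]])) 1 else attr(node[[1]], "members")
  right <- .dendrogram_segments(node[[2]], x_offset + n_left)
  h <- attr(node, "height")
  hl <- if (stats::is.leaf(node[[1]])) 0 else attr(node[[1]], "height")
  hr <- if (stats::is.leaf(node[[2]])) 0 else attr(node[[2]], "height")
  seg <- tibble::tibble(
    x = c(left$x, left$x, right$x),
    y = c(hl, h, h),
    xend = c(left$x, right$x, right$x),
    yend = c(h, h, hr))
  list(x = (left$x + right$x) / 2,
       segments = dplyr::bind_rows(left$segments, seg, right$segments))
}

utils::globalVariables(".data")
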