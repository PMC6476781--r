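#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Boxplots of coverage, complementarity or dissimilarity distributions
#'
#' Per-sample distributions of the chosen statistic across aggregation
#' levels (and primer sets, where the statistic is per primer set).
#'
#' @param object An `olsp_metrics` from [compute_metrics()].
#' @param metric One of `"bc"` (coverage), `"com"` (complementarity),
#'   `"wsd"` (within-sample dissimilarity), `"bsd"` (between-sample
#'   dissimilarity).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot olsp_metrics
#' @export
autoplot.olsp_metrics <- function(object, metric = c("bc", "com", "wsd",
                                                     "bsd"), ...) {
  metric <- match.arg(metric)
  lv <- metric_levels()
  d <- switch(metric,
              bc = object$bc_sample,
              com = object$com_sample,
              wsd = object$wsd,
              bsd = object$bsd)
  d <- dplyr::mutate(d, level = factor(.data$level, levels = lv))
  ylab <- switch(metric, bc = "coverage (Bc)", com = "complementarity (Com)",
                 wsd = "within-sample dissimilarity (Wsd)",
                 bsd = "between-sample dissimilarity (Bsd)")
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$level, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 17) +
    ggplot2::labs(x = "taxonomic level", y = ylab) +
    ggplot2::theme_minimal()
  if (metric == "bc") {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$marker))
  }
  p
}

#' Per-sample MNI distribution by group
#'
#' @param metrics An `olsp_metrics` object (computed with a grouping
#'   column).
#' @return A ggplot object; boxplot of per-sample total MNI per group.
#' @export
plot_mni <- function(metrics) {
  d <- metrics$mni_summary$per_sample
  grp <- setdiff(names(d), c("sample", "mni"))
  if (length(grp) == 0) {
    d$group <- "all samples"
  } else {
    d$group <- d[[grp[1]]]
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$mni)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 3) +
    ggplot2::labs(x = NULL, y = "MNI per sample") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Occurrences removed per filtering step
#'
#' @param pipeline An `olsp_pipeline` result.
#' @return A ggplot bar chart of occurrences removed by each LFN sub-filter
#'   and surviving counts.
#' @export
plot_filter_trace <- function(pipeline) {
  tr <- pipeline$trace
  d <- dplyr::bind_rows(
    tr$lfn_trace |>
      dplyr::transmute(stage = .data$filter, n = .data$occurrences_removed),
    tibble::tibble(stage = "validated", n = tr$occurrences_validated))
  d$stage <- factor(d$stage, levels = d$stage)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "occurrences") +
    ggplot2::theme_minimal()
}
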