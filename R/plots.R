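# ggplot2 displays for the main result types.

#' Forest plot of pooled cross-receptor correlations
#'
#' @param meta_tbl a [correlate_paired_metrics()] result.
#' @param condition optional condition filter.
#' @return a ggplot: pooled r with 95% CI per metric, ordered by r.
#' @export
plot_meta_forest <- function(meta_tbl, condition = NULL) {
  df <- as_tibble(meta_tbl)
  if (!is.null(condition)) df <- filter(df, .data$condition == !!condition)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$r, y = stats::reorder(.data$metric, .data$r)
  )) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf_low, xmax = .data$conf_high), height = 0.2
    ) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_total), shape = 15) +
    ggplot2::scale_size_area(max_size = 4, guide = "none") +
    ggplot2::labs(x = "pooled Spearman r (Fisher-z fixed effect)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of the pooled B x T pair-correlation matrix
#'
#' @param object a `bt_cor` from [pairwise_bt_correlations()].
#' @param ... unused.
#' @return a ggplot tile map of pooled r (NA shown blank), rows/columns in
#'   hierarchically clustered order.
#' @export
autoplot.bt_cor <- function(object, ...) {
  r <- object$r
  rimp <- r; rimp[is.na(rimp)] <- 0
  ob <- hclust(dist(rimp))$order
  ot <- hclust(dist(t(rimp)))$order
  df <- tidy(object) %>%
    mutate(
      b_clonotype = factor(.data$b_clonotype, levels = rownames(r)[ob]),
      t_clonotype = factor(.data$t_clonotype, levels = colnames(r)[ot])
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$t_clonotype, .data$b_clonotype,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1)) +
    ggplot2::labs(x = "T clonotypes", y = "B clonotypes", fill = "pooled r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Null distribution and observed slope of the replication test
#'
#' @param object a `replication_fit` from [replication_test()].
#' @param ... unused.
#' @return a ggplot histogram of null slopes with the observed slope marked.
#' @export
autoplot.replication_fit <- function(object, ...) {
  if (is.null(object$null_slopes)) abort("fit carries no permutation null")
  ggplot2::ggplot(tibble(slope = object$null_slopes),
                  ggplot2::aes(.data$slope)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$slope, colour = "#B2182B",
                        linewidth = 1) +
    ggplot2::labs(
      x = "slope of fr_t ~ fr_b + c_total",
      y = "null iterations",
      title = sprintf("observed slope %.3f, empirical p = %.4f",
                      object$slope, object$empirical_p)
    ) +
    ggplot2::theme_minimal()
}

#' Cluster feature averages against the random-group null
#'
#' @param null a [null_feature_distribution()] tibble.
#' @param cluster_stats a [cluster_feature_stats()] tibble (one locus).
#' @param feature feature column to display (default `"mean_pairwise_ld"`).
#' @return a ggplot: null density with per-cluster averages overlaid.
#' @export
plot_feature_null <- function(null, cluster_stats, feature = "mean_pairwise_ld") {
  ggplot2::ggplot(as_tibble(null), ggplot2::aes(.data[[feature]])) +
    ggplot2::geom_density(fill = "grey80", colour = "grey50") +
    ggplot2::geom_vline(
      data = as_tibble(cluster_stats),
      ggplot2::aes(xintercept = .data[[feature]]),
      colour = "#B2182B", linewidth = 0.8
    ) +
    ggplot2::labs(x = feature, y = "null density") +
    ggplot2::theme_minimal()
}
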