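#' Plot a 3-D embedding as paired 2-D projections
#'
#' @param embedding Tibble from [embed_tsne()].
#' @param labels Optional tibble `protein_id`, `cluster` (or any grouping
#'   column named by `color`) used to color points.
#' @param color Name of the coloring column in `labels`.
#' @return A ggplot object (TSNE1 vs TSNE2, colored by cluster).
#' @export
plot_embedding <- function(embedding, labels = NULL, color = "cluster") {
  d <- embedding
  if (!is.null(labels)) {
    d <- left_join(d, labels, by = "protein_id")
    d[[color]] <- factor(d[[color]])
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$TSNE1, .data$TSNE2)) +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2") +
    ggplot2::theme_minimal()
  if (!is.null(labels)) {
    p + ggplot2::geom_point(ggplot2::aes(color = .data[[color]]),
                            size = 0.8, alpha = 0.8)
  } else {
    p + ggplot2::geom_point(size = 0.8, alpha = 0.8)
  }
}

#' BIC curve of the mixture-model selection
#'
#' @param object An `organsort_gmm`.
#' @param ... Unused.
#' @return A ggplot of best BIC per candidate k, with the selected k marked.
#' @export
autoplot.organsort_gmm <- function(object, ...) {
  best <- object$bic |>
    group_by(.data$k) |>
    summarise(bic = max(.data$bic), .groups = "drop")
  ggplot2::ggplot(best, ggplot2::aes(.data$k, .data$bic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k, linetype = "dashed") +
    ggplot2::labs(x = "number of clusters (k)", y = "BIC") +
    ggplot2::theme_minimal()
}

#' Precision-recall curves behind a threshold calibration
#'
#' @param thresholds Threshold tibble from [calibrate_thresholds()] (the
#'   PR curves travel in its `pr_curves` attribute).
#' @return A ggplot of per-class precision-recall step curves with the
#'   selected operating points.
#' @export
plot_threshold_curves <- function(thresholds) {
  curves <- attr(thresholds, "pr_curves")
  if (is.null(curves)) abort("no PR curves attached to this threshold table")
  sel <- thresholds |> dplyr::filter(!is.na(.data$threshold))
  ggplot2::ggplot(curves, ggplot2::aes(.data$recall, .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(data = sel, color = "red", size = 1.5) +
    ggplot2::facet_wrap(~class) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Cumulative correlation curves: complex members versus random pairs
#'
#' @param object An `organsort_null` from [random_pair_null()].
#' @param ... Unused.
#' @return A ggplot of the two empirical CDFs.
#' @export
autoplot.organsort_null <- function(object, ...) {
  d <- bind_rows(
    object$complex_pairs |> transmute(pcc = .data$pcc, set = "complex members"),
    object$null_pairs |> transmute(pcc = .data$pcc, set = "random pairs"))
  ggplot2::ggplot(d, ggplot2::aes(.data$pcc, color = .data$set)) +
    ggplot2::stat_ecdf() +
    ggplot2::labs(x = "pairwise profile PCC", y = "cumulative fraction",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Dot plot of enriched domains
#'
#' @param enrichment Output of [domain_enrichment()].
#' @param max_domains Show at most this many domains (by q-value).
#' @return A ggplot dot plot (domain x class, size = carriers, color =
#'   -log10 q).
#' @export
plot_domain_enrichment <- function(enrichment, max_domains = 25) {
  d <- enrichment |> dplyr::filter(.data$enriched)
  if (nrow(d) == 0) {
    inform("no enriched domains to plot; showing top tests instead")
    d <- enrichment |> arrange(.data$q) |> head(max_domains)
  }
  d <- d |> arrange(.data$q) |> head(max_domains)
  ggplot2::ggplot(d, ggplot2::aes(.data$class, .data$domain)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$b,
                                     color = -log10(.data$q))) +
    ggplot2::labs(x = NULL, y = NULL, size = "carriers",
                  color = expression(-log[10] ~ q)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
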