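#' @importFrom ggplot2 ggplot aes geom_density geom_histogram geom_line
#'   geom_vline geom_tile geom_rect labs theme_minimal autoplot
#'   scale_fill_gradient2 facet_wrap annotate
NULL

#' Density of interference correlations by orientation
#'
#' Mirrors the standard presentation of the rho statistic: per-orientation
#' density with a reference line at 0 and, when supplied, the null-max
#' threshold.
#'
#' @param rhos Rho table from [correlate_pairs()].
#' @param threshold Optional numeric threshold or `icgi_null` object.
#' @return A ggplot object.
#' @export
plot_rho_distribution <- function(rhos, threshold = NULL) {
  if (inherits(threshold, "icgi_null")) threshold <- threshold$threshold
  d <- filter(rhos, .data$valid)
  p <- ggplot(d, aes(x = .data$rho)) +
    geom_density(fill = "grey80") +
    geom_vline(xintercept = 0, linetype = "dashed", colour = "blue") +
    facet_wrap(~orientation) +
    labs(x = expression(rho), y = "density") +
    theme_minimal()
  if (!is.null(threshold)) {
    p <- p + geom_vline(xintercept = threshold, linetype = "dashed",
                        colour = "darkgreen")
  }
  p
}

#' @describeIn build_null Histogram of the null rho sample with the
#'   threshold marked.
#' @param object,x,... Method arguments.
#' @export
autoplot.icgi_null <- function(object, ...) {
  ggplot(tibble(rho = object$null_rhos), aes(x = .data$rho)) +
    geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    geom_vline(xintercept = object$threshold, colour = "darkgreen",
               linetype = "dashed") +
    labs(x = expression("null" ~ rho),
         y = "control loci",
         title = sprintf("max-null threshold = %.3f (n = %d)",
                         object$threshold, object$n_valid)) +
    theme_minimal()
}

#' @describeIn metagene Line plot of the averaged profile with the island
#'   segment shaded.
#' @param object,... Method arguments.
#' @export
autoplot.icgi_metagene <- function(object, ...) {
  v <- object$values
  ic <- range(v$position[v$segment == "icgi"])
  ggplot(v, aes(x = .data$position, y = .data$mean)) +
    annotate("rect", xmin = ic[1], xmax = ic[2], ymin = -Inf, ymax = Inf,
             fill = "lightgreen", alpha = 0.3) +
    geom_line() +
    labs(x = "scaled position (5' flank | upstream | iCGI | downstream | 3' flank)",
         y = "mean log fold enrichment") +
    theme_minimal()
}

#' Expression heatmap with hierarchical ordering
#'
#' Column-wise z-scores a locus x condition FPKM matrix, orders rows and
#' columns by hierarchical clustering, and renders a tile heatmap.
#'
#' @param m Numeric matrix (loci in rows, conditions in columns).
#' @param metric,linkage Passed to [hcluster()].
#' @param zscore Standardize column-wise first (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_expression_heatmap <- function(m, metric = "euclidean",
                                    linkage = "complete", zscore = TRUE) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- sprintf("locus_%d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("cond_%d", seq_len(ncol(m)))
  z <- if (zscore) zscore_matrix(m, "column") else m
  ro <- if (nrow(z) > 1) hcluster(z, metric, linkage)$labels else rownames(z)
  co <- if (ncol(z) > 1) hcluster(t(z), metric, linkage)$labels else colnames(z)
  d <- as_tibble(as.table(z), .name_repair = ~c("locus", "condition", "z"))
  d$locus <- factor(d$locus, levels = ro)
  d$condition <- factor(d$condition, levels = co)
  ggplot(d, aes(x = .data$condition, y = .data$locus, fill = .data$z)) +
    geom_tile() +
    scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    labs(x = NULL, y = NULL, fill = "z-score") +
    theme_minimal()
}
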