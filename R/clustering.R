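#' Z-score a matrix by row or column
#'
#' `(x - mean) / sd` per axis using the sample SD. Constant vectors map to
#' all-zero and are flagged in the `constant` attribute of the result.
#'
#' @param m Numeric matrix (or data frame coercible to one).
#' @param axis `"column"` (default, as used for expression heatmaps) or
#'   `"row"`.
#' @return A matrix of the same dimensions with a logical `constant`
#'   attribute (one entry per standardized vector).
#' @export
zscore_matrix <- function(m, axis = c("column", "row")) {
  axis <- match.arg(axis)
  m <- as.matrix(m)
  if (length(m) == 0) abort("empty matrix")
  f <- function(x) {
    s <- sd(x)
    if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  if (axis == "column") {
    out <- apply(m, 2, f)
    constant <- apply(m, 2, function(x) sd(x) == 0 || is.na(sd(x)))
  } else {
    out <- t(apply(m, 1, f))
    constant <- apply(m, 1, function(x) sd(x) == 0 || is.na(sd(x)))
  }
  dimnames(out) <- dimnames(m)
  attr(out, "constant") <- constant
  out
}

#' Agglomerative hierarchical clustering of an expression matrix
#'
#' Thin, deterministic wrapper around [stats::dist()] + [stats::hclust()]
#' that records the leaf order and merge heights and can export the tree as
#' Newick text. Rows are clustered; transpose to cluster columns.
#'
#' @param m Numeric matrix with at least 2 rows.
#' @param metric Distance ([stats::dist()] method; default `"euclidean"`).
#' @param linkage Linkage ([stats::hclust()] method; default `"complete"`).
#' @return An `icgi_hclust` object: list with `hclust`, `labels` (in leaf
#'   order), `merge`, `height`, `metric`, `linkage`.
#' @export
hcluster <- function(m, metric = "euclidean", linkage = "complete") {
  m <- as.matrix(m)
  if (nrow(m) < 2) abort("need at least 2 rows to cluster")
  if (any(!is.finite(m))) {
    abort("non-finite values in matrix; impute or remove them before clustering")
  }
  if (is.null(rownames(m))) rownames(m) <- sprintf("row_%d", seq_len(nrow(m)))
  hc <- hclust(dist(m, method = metric), method = linkage)
  structure(
    list(hclust = hc, labels = hc$labels[hc$order], merge = hc$merge,
         height = hc$height, metric = metric, linkage = linkage),
    class = "icgi_hclust"
  )
}

#' @export
print.icgi_hclust <- function(x, ...) {
  cat(sprintf("<icgi_hclust> %d leaves, %s distance, %s linkage\n",
              length(x$labels), x$metric, x$linkage))
  invisible(x)
}

#' Export a clustering as Newick text
#'
#' @param x An `icgi_hclust` object.
#' @param path Optional file to write to.
#' @return The Newick string, invisibly when `path` is given.
#' @export
as_newick <- function(x, path = NULL) {
  stopifnot(inherits(x, "icgi_hclust"))
  tr <- ape::as.phylo(x$hclust)
  if (is.null(path)) {
    ape::write.tree(tr)
  } else {
    ape::write.tree(tr, file = path)
    invisible(ape::write.tree(tr))
  }
}

#' Assign host/island expression classes
#'
#' Clusters host-gene expression upstream of the island and island
#' expression separately (1-D hierarchical clustering, 2-way cut) and labels
#' the higher-mean cluster on each axis `active` (host) / `high` (island),
#' yielding the four classes `active_host_high_icgi`,
#' `active_host_low_icgi`, `inactive_host_high_icgi`,
#' `inactive_host_low_icgi`.
#'
#' @param upstream_expr,icgi_expr Numeric vectors (e.g. FPKM), one value per
#'   pair, in the same order.
#' @param pair_ids Optional identifiers (default names of `upstream_expr` or
#'   an index).
#' @param metric,linkage Clustering parameters, as in [hcluster()].
#' @return Tibble: `pair_id`, `host_class`, `icgi_class`, `class`.
#' @export
assign_expression_classes <- function(upstream_expr, icgi_expr,
                                      pair_ids = NULL,
                                      metric = "euclidean",
                                      linkage = "complete") {
  if (length(upstream_expr) != length(icgi_expr)) {
    abort("upstream_expr and icgi_expr must cover the same pairs")
  }
  if (length(upstream_expr) < 4) abort("need at least 4 pairs to form classes")
  pair_ids <- pair_ids %||% names(upstream_expr) %||%
    sprintf("pair_%05d", seq_along(upstream_expr))
  cut2 <- function(v, labels) {
    if (sd(v) == 0) {
      warn("constant expression vector; assigning a single class")
      return(rep(labels[1], length(v)))
    }
    hc <- hclust(dist(matrix(v, ncol = 1), method = metric), method = linkage)
    grp <- cutree(hc, k = 2)
    hi <- which.max(tapply(v, grp, mean))
    ifelse(grp == hi, labels[1], labels[2])
  }
  host <- cut2(upstream_expr, c("active", "inactive"))
  icgi <- cut2(icgi_expr, c("high", "low"))
  tibble(pair_id = pair_ids, host_class = host, icgi_class = icgi,
         class = paste0(host, "_host_", icgi, "_icgi"))
}
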