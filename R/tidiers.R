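#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @describeIn build_null Per-control placements and null rho values as a
#'   tibble.
#' @export
tidy.icgi_null <- function(x, ...) {
  select(x$placements, "gene_id", "chrom", "icgi_start", "icgi_end",
         "rho", "valid")
}

#' @describeIn build_null One-row summary (controls, valid rho count,
#'   threshold, seed).
#' @export
glance.icgi_null <- function(x, ...) {
  tibble(n_controls = x$n_controls, n_valid = x$n_valid,
         threshold = x$threshold, mean_null_rho = mean(x$null_rhos),
         seed = x$seed)
}

#' @describeIn metagene Per-position profile values as a tibble.
#' @export
tidy.icgi_metagene <- function(x, ...) x$values

#' @describeIn metagene One-row summary of the profile geometry.
#' @export
glance.icgi_metagene <- function(x, ...) {
  tibble(n_loci = x$n_loci, flank_bp = x$flank_bp,
         upstream_bp = unname(x$interval_lengths["up"]),
         icgi_bp = unname(x$interval_lengths["icgi"]),
         downstream_bp = unname(x$interval_lengths["down"]))
}

#' @describeIn hcluster Merge heights as a tibble.
#' @export
tidy.icgi_hclust <- function(x, ...) {
  tibble(merge1 = x$merge[, 1], merge2 = x$merge[, 2], height = x$height)
}
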