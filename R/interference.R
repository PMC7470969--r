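#' Interference correlation between island activity and upstream termination
#'
#' For one iCGI/host-gene pair across conditions \eqn{i}, computes
#' \deqn{\rho = corr\left(\log(U_i+1) - \log(A_i+1),\;
#'   \frac{G_i - median(G+1)}{mad(G+1) + 0.1}\right)}
#' where \eqn{U} and \eqn{A} are upstream and across read counts, \eqn{G}
#' the island read counts, logs are natural, and `mad` is the raw median
#' absolute deviation of \eqn{G+1} (no consistency factor). The robust
#' scaling of \eqn{G} is a positive affine map, so \eqn{\rho} equals the
#' plain Pearson correlation of \eqn{\log(U+1)-\log(A+1)} with \eqn{G};
#' intermediates are nevertheless computed exactly as written.
#'
#' @param U,A,G Equal-length non-negative count vectors over conditions.
#' @return One-row tibble: `rho`, `n_conditions`, `valid`. `valid` is
#'   `FALSE` (and `rho` `NA`) when fewer than 3 conditions are available or
#'   either transformed vector has zero variance.
#' @export
icgi_rho <- function(U, A, G) {
  if (length(U) != length(A) || length(U) != length(G)) {
    abort("U, A and G must have equal length")
  }
  if (any(c(U, A, G) < 0)) abort("counts must be non-negative")
  keep <- !(is.na(U) | is.na(A) | is.na(G))
  U <- U[keep]; A <- A[keep]; G <- G[keep]
  n <- length(U)
  if (n < 3) {
    return(tibble(rho = NA_real_, n_conditions = n, valid = FALSE))
  }
  x <- log(U + 1) - log(A + 1)
  g1 <- G + 1
  m <- median(g1)
  s <- median(abs(g1 - m))           # raw MAD, no 1.4826 factor
  y <- (G - m) / (s + 0.1)
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble(rho = NA_real_, n_conditions = n, valid = FALSE))
  }
  tibble(rho = cor(x, y), n_conditions = n, valid = TRUE)
}

#' Compute rho for every pair in both orientations
#'
#' @param counts Long count table from [count_pairs()] (`pair_id`,
#'   `condition`, `U`, `A`, `G_sense`, `G_antisense`).
#' @return Tibble with two rows per pair (`orientation` `"sense"` /
#'   `"antisense"`): `pair_id`, `orientation`, `rho`, `n_conditions`,
#'   `valid`. Conditions with missing counts or zero library size are
#'   dropped pairwise.
#' @export
correlate_pairs <- function(counts) {
  .check_cols(counts, c("pair_id", "condition", "U", "A", "G_sense",
                        "G_antisense"), "count table")
  if ("library_size" %in% names(counts)) {
    zero <- !is.na(counts$library_size) & counts$library_size <= 0
    if (any(zero)) {
      warn(sprintf("dropping %d pair-condition row(s) with zero library size", sum(zero)))
      counts <- counts[!zero, , drop = FALSE]
    }
  }
  res <- counts |>
    group_by(.data$pair_id) |>
    summarise(
      res = list(bind_rows(
        mutate(icgi_rho(.data$U, .data$A, .data$G_sense), orientation = "sense"),
        mutate(icgi_rho(.data$U, .data$A, .data$G_antisense), orientation = "antisense")
      )),
      .groups = "drop"
    ) |>
    tidyr::unnest("res") |>
    select("pair_id", "orientation", "rho", "n_conditions", "valid")
  n_invalid <- sum(!res$valid)
  if (n_invalid > 0) {
    inform(sprintf("%d pair-orientation rho value(s) undefined (constant input or < 3 conditions)", n_invalid))
  }
  res
}

#' Place one artificial island on a control locus
#'
#' Draws a normalized position and a size (with replacement) from the
#' empirical distributions of the real pairs and anchors the island inside
#' the eligible span of the control gene (the gene body after the
#' `min_tss_dist` / `min_last_exon_dist` exclusions), so the artificial pair
#' satisfies the same positional filters as real pairs. If a drawn size does
#' not fit, it is redrawn up to `max_retries` times, then the largest
#' observed size that fits is used. Uses the current RNG state; seed at the
#' caller (see [build_null()]).
#'
#' @param gene One-row gene tibble (`chrom`, `start`, `end`, `strand`,
#'   `last_exon_start`).
#' @param position_dist Numeric vector of normalized positions in \[0, 1\].
#' @param size_dist Integer vector of island sizes (bp).
#' @param min_tss_dist,min_last_exon_dist Positional filters (bp).
#' @param max_retries Size redraw attempts before falling back.
#' @return One-row tibble (`chrom`, `start`, `end`) or `NULL` (with a
#'   warning) when even the smallest observed size cannot fit.
#' @export
simulate_artificial_icgi <- function(gene, position_dist, size_dist,
                                     min_tss_dist = 1000,
                                     min_last_exon_dist = 500,
                                     max_retries = 10) {
  stopifnot(length(position_dist) > 0, length(size_dist) > 0)
  if (gene$strand == "+") {
    elig_start <- gene$start + min_tss_dist
    elig_end <- gene$last_exon_start - min_last_exon_dist
  } else {
    elig_start <- gene$last_exon_start + min_last_exon_dist
    elig_end <- gene$end - min_tss_dist
  }
  elig_len <- elig_end - elig_start
  if (elig_len < min(size_dist)) {
    warn(sprintf("control locus %s skipped: eligible span (%d bp) shorter than smallest island",
                 gene$gene_id %||% gene$chrom, max(0, elig_len)))
    return(NULL)
  }
  s <- sample(size_dist, 1)
  tries <- 0
  while (s > elig_len && tries < max_retries) {
    s <- sample(size_dist, 1)
    tries <- tries + 1
  }
  if (s > elig_len) s <- max(size_dist[size_dist <= elig_len])
  p <- sample(position_dist, 1)
  offset <- round(p * (elig_len - s))
  # anchor the TSS-proximal edge at fraction p of the placeable extent
  if (gene$strand == "+") {
    start <- elig_start + offset
  } else {
    start <- elig_end - offset - s
  }
  tibble(chrom = gene$chrom, start = as.integer(start),
         end = as.integer(start + s))
}

#' Build the empirical null and its max threshold
#'
#' Places one artificial island on each eligible control locus (position and
#' size drawn from the real pairs' empirical distributions), counts reads on
#' the artificial partitions, computes the sense-orientation rho per control,
#' and sets the candidate threshold to the maximum valid null rho.
#'
#' @param controls Output of [select_control_loci()] (only `eligible` rows
#'   are used).
#' @param pairs Real pair table from [identify_icgi_pairs()] (supplies the
#'   position and size distributions).
#' @param reads Read table covering the control loci (see [count_reads()]).
#' @param seed Integer seed; recorded in the result so the null is
#'   bit-reproducible.
#' @param min_controls Minimum number of eligible controls required.
#' @param min_tss_dist,min_last_exon_dist Positional filters (bp), matching
#'   those used for the real pairs.
#' @return An object of class `icgi_null`: list with `placements` (tibble of
#'   per-control artificial islands and their rho), `null_rhos`, `threshold`
#'   (= max over valid null rhos) and `seed`. Has `print()`, `tidy()`,
#'   `glance()` and `autoplot()` methods.
#' @export
build_null <- function(controls, pairs, reads, seed,
                       min_controls = 30,
                       min_tss_dist = 1000, min_last_exon_dist = 500) {
  .check_cols(controls, c("gene_id", "chrom", "start", "end", "strand",
                          "last_exon_start", "eligible"), "control table")
  elig <- filter(controls, .data$eligible)
  if (nrow(elig) < min_controls) {
    abort(sprintf("only %d eligible control loci (< %d); supply more controls",
                  nrow(elig), min_controls))
  }
  if (nrow(pairs) == 0) abort("no real pairs to draw position/size distributions from")
  position_dist <- .normalized_positions(pairs, min_tss_dist, min_last_exon_dist)
  size_dist <- pairs$icgi_end - pairs$icgi_start
  placements <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(elig)), function(i) {
      g <- elig[i, ]
      iv <- simulate_artificial_icgi(g, position_dist, size_dist,
                                     min_tss_dist, min_last_exon_dist)
      if (is.null(iv)) return(NULL)
      tibble(pair_id = paste0(g$gene_id, "|art"),
             gene_id = g$gene_id, chrom = g$chrom,
             gene_start = g$start, gene_end = g$end, strand = g$strand,
             tss = g$tss, last_exon_start = g$last_exon_start,
             icgi_start = iv$start, icgi_end = iv$end)
    })
  })
  if (nrow(placements) == 0) abort("no artificial islands could be placed")
  parts <- partition_regions(placements)
  counts <- count_pairs(reads, parts)
  rhos <- correlate_pairs(counts) |>
    filter(.data$orientation == "sense")
  placements <- left_join(placements,
                          select(rhos, "pair_id", "rho", "valid"),
                          by = "pair_id")
  null_rhos <- rhos$rho[rhos$valid]
  if (length(null_rhos) == 0) {
    abort("all null rho values are undefined; supply more conditions or controls")
  }
  structure(
    list(placements = placements, null_rhos = null_rhos,
         threshold = max(null_rhos), seed = seed,
         n_controls = nrow(elig), n_valid = length(null_rhos)),
    class = "icgi_null"
  )
}

# normalized position of each real island's TSS-proximal edge within the
# eligible span of its host
.normalized_positions <- function(pairs, min_tss_dist, min_last_exon_dist) {
  span <- pairs$tss_distance + pairs$last_exon_distance +
    (pairs$icgi_end - pairs$icgi_start) - min_tss_dist - min_last_exon_dist
  size <- pairs$icgi_end - pairs$icgi_start
  avail <- span - size
  p <- ifelse(avail > 0, (pairs$tss_distance - min_tss_dist) / avail, 0)
  pmin(pmax(p, 0), 1)
}

#' @export
print.icgi_null <- function(x, ...) {
  cat(sprintf("<icgi_null> %d control loci, %d valid null rho values\n",
              x$n_controls, x$n_valid))
  cat(sprintf("  threshold (max null rho): %.4f   seed: %d\n",
              x$threshold, x$seed))
  invisible(x)
}

#' Select candidate pairs above the null-max threshold
#'
#' Keeps pairs whose valid sense-orientation rho is strictly greater than the
#' threshold, sorted by rho descending. The selected fraction (of valid
#' sense rho values) is attached as attribute `fraction`.
#'
#' @param rhos Rho table from [correlate_pairs()].
#' @param threshold Numeric threshold, or an `icgi_null` object.
#' @return Tibble of candidates with attribute `fraction`.
#' @export
select_candidates <- function(rhos, threshold) {
  if (inherits(threshold, "icgi_null")) threshold <- threshold$threshold
  if (!is.finite(threshold)) abort("threshold must be finite")
  sense <- filter(rhos, .data$orientation == "sense", .data$valid)
  out <- sense |>
    filter(.data$rho > threshold) |>
    arrange(desc(.data$rho))
  frac <- if (nrow(sense) > 0) nrow(out) / nrow(sense) else NA_real_
  if (is.na(frac)) warn("no valid sense rho values; selected fraction undefined")
  attr(out, "fraction") <- frac
  out
}
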