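#' Per-base values of a coverage track over an interval
#'
#' Tracks are bedGraph-style tibbles (`chrom`, `start`, `end`, `value`,
#' 0-based half-open). Positions not covered by any track interval are `NA`
#' (missing signal, not zero).
#'
#' @param track Track tibble.
#' @param chrom,start,end Query interval (0-based half-open).
#' @return Numeric vector of length `end - start`.
#' @export
track_values <- function(track, chrom, start, end) {
  .check_cols(track, c("chrom", "start", "end", "value"), "track")
  stopifnot(end > start)
  out <- rep(NA_real_, end - start)
  t <- track[track$chrom == chrom & track$start < end & track$end > start, ,
             drop = FALSE]
  for (i in seq_len(nrow(t))) {
    a <- max(t$start[i], start) - start + 1
    b <- min(t$end[i], end) - start
    out[a:b] <- t$value[i]
  }
  out
}

#' Log fold enrichment over input at single-base resolution
#'
#' `log2((treatment + pseudocount) / (input + pseudocount))` per base;
#' missing coverage in either track propagates as `NA`.
#'
#' @param treatment,input Equal-length per-base numeric vectors (e.g. from
#'   [track_values()]).
#' @param pseudocount Positive stabilizer added to both tracks (default 1).
#' @param base Logarithm base (default 2; base only rescales the y-axis).
#' @return Per-base numeric vector.
#' @export
log_fold_enrichment <- function(treatment, input, pseudocount = 1, base = 2) {
  if (length(treatment) != length(input)) abort("track lengths differ")
  if (pseudocount <= 0) abort("pseudocount must be positive")
  log((treatment + pseudocount) / (input + pseudocount), base = base)
}

# linear-interpolation resampling of a per-base series onto `target` points;
# NA in either neighbour propagates
.resample <- function(v, target) {
  L <- length(v)
  if (L == target) return(v)
  pos <- seq(1, L, length.out = target)
  lo <- floor(pos); hi <- ceiling(pos); w <- pos - lo
  v[lo] * (1 - w) + v[hi] * w
}

#' Three-interval metagene profile of ChIP enrichment over host-gene bodies
#'
#' For each fully intronic pair, the gene body is split strand-aware into
#' TSS-to-island, island, and island-to-TTS intervals. Each interval's
#' per-base log fold enrichment is linearly rescaled to the cohort's average
#' length for that interval; `flank_bp` flanks beyond the TSS and TTS are
#' taken unscaled. The profile is the per-position mean across loci (missing
#' signal is excluded per position, with the contributing count tracked).
#'
#' @param pairs Pair tibble; every pair must be `fully_intronic`.
#' @param treatment Track tibble of ChIP signal, or of precomputed log fold
#'   enrichment when `input` is `NULL`.
#' @param input Optional track tibble of input/control signal.
#' @param flank_bp Flank size in bp (default 3000).
#' @param pseudocount Passed to [log_fold_enrichment()].
#' @return An `icgi_metagene` object: list with `values` (tibble `position`,
#'   `segment`, `mean`, `n`), `interval_lengths` (named averages, bp),
#'   `flank_bp`, `n_loci`.
#' @export
metagene <- function(pairs, treatment, input = NULL, flank_bp = 3000,
                     pseudocount = 1) {
  .check_cols(pairs, c("pair_id", "chrom", "strand", "gene_start", "gene_end",
                       "icgi_start", "icgi_end", "placement"), "pair table")
  if (nrow(pairs) == 0) abort("no pairs supplied")
  if (any(pairs$placement != "fully_intronic")) {
    abort("metagene() requires fully intronic pairs (island reads are ambiguous at exons)")
  }
  seglen <- function(p) {
    if (p$strand == "+") {
      c(up = p$icgi_start - p$gene_start, icgi = p$icgi_end - p$icgi_start,
        down = p$gene_end - p$icgi_end)
    } else {
      c(up = p$gene_end - p$icgi_end, icgi = p$icgi_end - p$icgi_start,
        down = p$icgi_start - p$gene_start)
    }
  }
  lens <- purrr::map(seq_len(nrow(pairs)), function(i) seglen(pairs[i, ]))
  ok <- vapply(lens, function(l) all(l > 0), logical(1))
  if (!all(ok)) {
    warn(sprintf("excluding %d locus/loci with a zero-length interval", sum(!ok)))
    pairs <- pairs[ok, , drop = FALSE]
    lens <- lens[ok]
  }
  if (nrow(pairs) == 0) abort("no usable loci remain")
  avg <- round(colMeans(do.call(rbind, lens)))
  avg[avg < 1] <- 1
  locus_series <- function(p) {
    v <- track_values(treatment, p$chrom, p$gene_start - flank_bp,
                      p$gene_end + flank_bp)
    if (!is.null(input)) {
      iv <- track_values(input, p$chrom, p$gene_start - flank_bp,
                         p$gene_end + flank_bp)
      v <- log_fold_enrichment(v, iv, pseudocount)
    }
    if (p$strand == "-") v <- rev(v)
    # v now runs 5' flank .. gene .. 3' flank in transcript orientation
    gl <- p$gene_end - p$gene_start
    sl <- seglen(p)
    f5 <- v[seq_len(flank_bp)]
    up <- v[flank_bp + seq_len(sl["up"])]
    ic <- v[flank_bp + sl["up"] + seq_len(sl["icgi"])]
    dn <- v[flank_bp + sl["up"] + sl["icgi"] + seq_len(sl["down"])]
    f3 <- v[flank_bp + gl + seq_len(flank_bp)]
    c(f5, .resample(up, avg["up"]), .resample(ic, avg["icgi"]),
      .resample(dn, avg["down"]), f3)
  }
  mat <- do.call(rbind, purrr::map(seq_len(nrow(pairs)),
                                   function(i) locus_series(pairs[i, ])))
  segment <- c(rep("flank5", flank_bp), rep("upstream", avg["up"]),
               rep("icgi", avg["icgi"]), rep("downstream", avg["down"]),
               rep("flank3", flank_bp))
  values <- tibble(
    position = seq_len(ncol(mat)),
    segment = segment,
    mean = colMeans(mat, na.rm = TRUE),
    n = colSums(!is.na(mat))
  )
  values$mean[values$n == 0] <- NA_real_
  structure(
    list(values = values, interval_lengths = avg, flank_bp = flank_bp,
         n_loci = nrow(pairs)),
    class = "icgi_metagene"
  )
}

#' @export
print.icgi_metagene <- function(x, ...) {
  cat(sprintf("<icgi_metagene> %d loci, flank %d bp, intervals (up/icgi/down): %s bp\n",
              x$n_loci, x$flank_bp, paste(x$interval_lengths, collapse = "/")))
  invisible(x)
}

#' Read a bedGraph track into a tibble
#'
#' @param path bedGraph file.
#' @return Track tibble (`chrom`, `start`, `end`, `value`, 0-based
#'   half-open).
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) abort(sprintf("bedGraph not found: %s", path))
  gr <- rtracklayer::import(path, format = "bedGraph")
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1L,
         end = GenomicRanges::end(gr),
         value = as.numeric(gr$score))
}

#' Read a bedMethyl file
#'
#' Accepts the 11-column ENCODE bedMethyl layout (percent methylation in
#' column 11) or a minimal 4-column `chrom start end percent` table.
#'
#' @param path bedMethyl file (plain text).
#' @return Tibble `chrom`, `start`, `end`, `pct` with `pct` in \[0, 100\].
#' @export
read_bedmethyl <- function(path) {
  if (!file.exists(path)) abort(sprintf("bedMethyl not found: %s", path))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) >= 11) {
    out <- tibble(chrom = as.character(df[[1]]), start = df[[2]],
                  end = df[[3]], pct = as.numeric(df[[11]]))
  } else if (ncol(df) >= 4) {
    out <- tibble(chrom = as.character(df[[1]]), start = df[[2]],
                  end = df[[3]], pct = as.numeric(df[[4]]))
  } else {
    abort(sprintf("bedMethyl %s has %d columns; need >= 4", path, ncol(df)))
  }
  bad <- which(!is.finite(out$pct) | out$pct < 0 | out$pct > 100 |
                 !is.finite(out$start) | !is.finite(out$end))
  if (length(bad) > 0) {
    abort(sprintf("malformed bedMethyl record at line %d of %s", bad[1], path))
  }
  out
}

#' CpG methylation around islands
#'
#' Bins the window island +/- `flank_bp` into `n_bins` equal bins (oriented
#' 5' to 3' along the host strand) and averages the percent methylation of
#' the CpG records falling in each bin. Bins containing no covered CpG are
#' `NA`, not zero.
#'
#' @param bedmethyl Tibble from [read_bedmethyl()].
#' @param pairs Pair tibble.
#' @param flank_bp Flank in bp (default 5000).
#' @param n_bins Number of bins over the window (default 50).
#' @return Long tibble: `pair_id`, `bin`, `pct`, `n_cpg`.
#' @export
methylation_at_icgi <- function(bedmethyl, pairs, flank_bp = 5000, n_bins = 50) {
  .check_cols(bedmethyl, c("chrom", "start", "end", "pct"), "bedMethyl table")
  .check_cols(pairs, c("pair_id", "chrom", "strand", "icgi_start", "icgi_end"),
              "pair table")
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    p <- pairs[i, ]
    w0 <- p$icgi_start - flank_bp
    w1 <- p$icgi_end + flank_bp
    m <- bedmethyl[bedmethyl$chrom == p$chrom & bedmethyl$start >= w0 &
                     bedmethyl$start < w1, , drop = FALSE]
    edges <- seq(w0, w1, length.out = n_bins + 1)
    bin <- findInterval(m$start, edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
    agg <- tibble(bin = bin, pct = m$pct) |>
      group_by(.data$bin) |>
      summarise(pct = mean(.data$pct), n_cpg = n(), .groups = "drop")
    out <- tibble(pair_id = p$pair_id, bin = seq_len(n_bins)) |>
      left_join(agg, by = "bin") |>
      mutate(n_cpg = dplyr::coalesce(.data$n_cpg, 0L))
    if (p$strand == "-") {
      out$pct <- rev(out$pct)
      out$n_cpg <- rev(out$n_cpg)
    }
    out
  })
}
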