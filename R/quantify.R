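#' Partition a pair into upstream / across / island regions
#'
#' The upstream region runs from the host TSS to the TSS-proximal island
#' edge (strand-aware); the "across" and "island" regions share the island's
#' coordinates and differ only in which reads are assigned to them.
#'
#' @param pairs Pair tibble from [identify_icgi_pairs()] (one or more rows).
#' @return Tibble: `pair_id`, `chrom`, `strand`, `upstream_start`,
#'   `upstream_end`, `icgi_start`, `icgi_end`, `gene_start`, `gene_end`.
#' @export
partition_regions <- function(pairs) {
  .check_cols(pairs, c("pair_id", "chrom", "strand", "gene_start", "gene_end",
                       "icgi_start", "icgi_end"), "pair table")
  pairs |>
    mutate(
      upstream_start = ifelse(.data$strand == "+", .data$gene_start, .data$icgi_end),
      upstream_end = ifelse(.data$strand == "+", .data$icgi_start, .data$gene_end)
    ) |>
    select("pair_id", "chrom", "strand", "upstream_start", "upstream_end",
           "icgi_start", "icgi_end", "gene_start", "gene_end")
}

# classify each read for one partition; returns labels U/A/G_sense/G_antisense/none.
# "across" is judged on the fragment's genomic span [start, end): a spliced
# read whose gap bridges the island still witnesses a traversing transcript.
.classify_reads <- function(reads, part) {
  p5 <- .five_prime(reads$start, reads$end, reads$strand)
  in_icgi <- p5 >= part$icgi_start & p5 < part$icgi_end
  sense <- reads$strand == part$strand
  ov <- .overlaps(reads$start, reads$end, part$icgi_start, part$icgi_end)
  in_up <- p5 >= part$upstream_start & p5 < part$upstream_end
  dplyr::case_when(
    in_icgi & sense ~ "G_sense",
    in_icgi & !sense ~ "G_antisense",
    sense & ov ~ "A",
    sense & in_up ~ "U",
    .default = "none"
  )
}

#' Count reads in the three regions of one pair, per condition
#'
#' Assignment rules (strand-aware, each read lands in at most one class):
#' a read whose 5' end lies inside the island is an island-initiated read,
#' `G_sense` or `G_antisense` by orientation relative to the host gene; a
#' host-strand read whose 5' end lies outside the island but whose genomic
#' span overlaps it is a traversing read, `A` (this includes spliced reads
#' bridging the island); a host-strand read whose 5' end lies in the upstream
#' region and which does not touch the island is `U`; anything else is
#' unassigned. `library_size` is the total number of reads in the condition.
#'
#' @param reads Read table: `chrom`, `start`, `end` (0-based half-open
#'   fragment span), `strand` (`+`/`-`; unstranded input is an error),
#'   optional `condition`, and optional `gap_start`/`gap_end` for one spliced
#'   gap. Paired-end data should be collapsed to one row per fragment.
#' @param partition One row of [partition_regions()] output.
#' @param library_sizes Optional named vector of per-condition totals; by
#'   default computed from `reads` (so pass the full, unfiltered table or
#'   supply the totals explicitly).
#' @return Tibble: `pair_id`, `condition`, `U`, `A`, `G_sense`,
#'   `G_antisense`, `library_size`.
#' @export
count_reads <- function(reads, partition, library_sizes = NULL) {
  .check_cols(reads, c("chrom", "start", "end", "strand"), "read table")
  .check_strand(reads$strand)
  if (any(reads$start >= reads$end)) abort("read with start >= end")
  if (nrow(partition) != 1) abort("count_reads() takes a single partition row")
  if (!"condition" %in% names(reads)) reads$condition <- "all"
  if (is.null(library_sizes)) {
    library_sizes <- table(reads$condition)
  }
  conds <- as.character(names(library_sizes))
  sel <- reads$chrom == partition$chrom
  r <- reads[sel, , drop = FALSE]
  cls <- if (nrow(r)) .classify_reads(r, partition) else character(0)
  out <- tidyr::expand_grid(condition = conds) |>
    mutate(
      U = vapply(conds, function(cc) sum(cls == "U" & r$condition == cc), 0,
                 USE.NAMES = FALSE),
      A = vapply(conds, function(cc) sum(cls == "A" & r$condition == cc), 0,
                 USE.NAMES = FALSE),
      G_sense = vapply(conds, function(cc) sum(cls == "G_sense" & r$condition == cc),
                       0, USE.NAMES = FALSE),
      G_antisense = vapply(conds, function(cc) sum(cls == "G_antisense" & r$condition == cc),
                           0, USE.NAMES = FALSE),
      library_size = as.numeric(library_sizes[conds]),
      pair_id = partition$pair_id
    ) |>
    select("pair_id", "condition", "U", "A", "G_sense", "G_antisense",
           "library_size")
  out
}

#' Count reads for many pairs at once
#'
#' Applies [count_reads()] to every partition, pre-splitting the read table
#' by chromosome so each locus only scans local reads.
#'
#' @param reads Read table (see [count_reads()]); must contain a `condition`
#'   column when more than one condition is present.
#' @param partitions Output of [partition_regions()].
#' @return Long tibble of per-pair, per-condition counts.
#' @export
count_pairs <- function(reads, partitions) {
  .check_cols(reads, c("chrom", "start", "end", "strand"), "read table")
  .check_strand(reads$strand)
  if (!"condition" %in% names(reads)) reads$condition <- "all"
  library_sizes <- table(reads$condition)
  bychrom <- split(reads, reads$chrom)
  purrr::map_dfr(seq_len(nrow(partitions)), function(i) {
    part <- partitions[i, ]
    local <- bychrom[[part$chrom]]
    if (is.null(local)) local <- reads[0, , drop = FALSE]
    count_reads(local, part, library_sizes = library_sizes)
  })
}

#' Fragments per kilobase per million mapped reads
#'
#' @param count Non-negative read count (vectorized).
#' @param region_length Region length in bp (> 0).
#' @param library_size Total mapped reads in the library (> 0).
#' @return `count / (region_length/1e3) / (library_size/1e6)`.
#' @export
fpkm <- function(count, region_length, library_size) {
  if (any(region_length <= 0)) abort("region_length must be positive")
  if (any(library_size <= 0)) abort("library_size must be positive")
  if (any(count < 0)) abort("count must be non-negative")
  count / (region_length / 1e3) / (library_size / 1e6)
}
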