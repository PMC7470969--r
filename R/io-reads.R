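# cigar reference-consumed length and (first) skipped-region gap
.cigar_span <- function(cigar) {
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)
  purrr::map_dfr(seq_along(cigar), function(i) {
    toks <- regmatches(cigar[i], ops[i])[[1]]
    n <- as.integer(sub("[A-Z=]", "", toks))
    op <- sub("\\d+", "", toks)
    consume <- op %in% c("M", "D", "N", "=", "X")
    span <- sum(n[consume])
    gap_start <- NA_integer_; gap_end <- NA_integer_
    wn <- which(op == "N")
    if (length(wn) >= 1) {
      off <- if (wn[1] > 1) sum(n[seq_len(wn[1] - 1)][consume[seq_len(wn[1] - 1)]]) else 0L
      gap_start <- off
      if (length(wn) == 1) {
        gap_end <- off + n[wn[1]]
      } else {
        # multi-gap read: keep the outermost blocks only
        last <- wn[length(wn)]
        gap_end <- sum(n[seq_len(last)][consume[seq_len(last)]])
      }
    }
    tibble(span = span, gap_off = gap_start, gap_end_off = gap_end)
  })
}

#' Read stranded alignments from SAM or BAM
#'
#' Returns the tidy read table consumed by [count_reads()] /
#' [count_pairs()]: 0-based half-open fragment spans with strand from the
#' FLAG field and (for spliced reads) one `gap_start`/`gap_end` pair from
#' the first `N` CIGAR operation. Reads with more than one `N` gap are
#' represented by their outermost aligned blocks. Unmapped records are
#' dropped. BAM input requires the Rsamtools package.
#'
#' @param path `.sam` (plain text) or `.bam` file.
#' @param condition Condition label attached to every read.
#' @return Read tibble: `chrom`, `start`, `end`, `strand`, `gap_start`,
#'   `gap_end`, `condition`.
#' @export
read_alignments <- function(path, condition = "all") {
  if (!file.exists(path)) abort(sprintf("alignment file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "bam") {
    if (!requireNamespace("Rsamtools", quietly = TRUE)) {
      abort("BAM input requires the Rsamtools package")
    }
    b <- Rsamtools::scanBam(path, param = Rsamtools::ScanBamParam(
      what = c("flag", "rname", "pos", "cigar")))[[1]]
    keep <- !is.na(b$pos)
    df <- tibble(flag = b$flag[keep], chrom = as.character(b$rname[keep]),
                 pos = b$pos[keep], cigar = b$cigar[keep])
  } else if (ext == "sam") {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "@")]
    if (length(lines) == 0) {
      return(tibble(chrom = character(), start = integer(), end = integer(),
                    strand = character(), gap_start = integer(),
                    gap_end = integer(), condition = character()))
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(fields) < 11)
    if (length(short) > 0) {
      abort(sprintf("malformed SAM record at alignment line %d of %s", short[1], path))
    }
    df <- tibble(
      flag = as.integer(vapply(fields, `[[`, "", 2)),
      chrom = vapply(fields, `[[`, "", 3),
      pos = as.integer(vapply(fields, `[[`, "", 4)),
      cigar = vapply(fields, `[[`, "", 6)
    )
    df <- df[bitwAnd(df$flag, 4L) == 0L, , drop = FALSE]  # drop unmapped
  } else {
    abort(sprintf("unsupported alignment format '.%s' (use .sam or .bam)", ext))
  }
  sp <- .cigar_span(df$cigar)
  start <- df$pos - 1L                                    # to 0-based
  tibble(
    chrom = df$chrom,
    start = start,
    end = start + sp$span,
    strand = ifelse(bitwAnd(df$flag, 16L) > 0L, "-", "+"),
    gap_start = start + sp$gap_off,
    gap_end = start + sp$gap_end_off,
    condition = condition
  )
}

#' Write a read table as SAM
#'
#' @param reads Read tibble (`chrom`, `start`, `end`, `strand`, optional
#'   `gap_start`/`gap_end`).
#' @param path Output `.sam` path.
#' @param contigs Tibble `chrom`, `length` for the header.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, path, contigs) {
  .check_cols(reads, c("chrom", "start", "end", "strand"), "read table")
  .check_cols(contigs, c("chrom", "length"), "contig table")
  gs <- if ("gap_start" %in% names(reads)) reads$gap_start else rep(NA, nrow(reads))
  ge <- if ("gap_end" %in% names(reads)) reads$gap_end else rep(NA, nrow(reads))
  has_gap <- !is.na(gs) & !is.na(ge)
  cigar <- ifelse(has_gap,
                  sprintf("%dM%dN%dM", gs - reads$start, ge - gs, reads$end - ge),
                  sprintf("%dM", reads$end - reads$start))
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", contigs$chrom, contigs$length))
  body <- sprintf("r%06d\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*",
                  seq_len(nrow(reads)),
                  ifelse(reads$strand == "-", 16L, 0L),
                  reads$chrom, reads$start + 1L, cigar)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Build a read table from stranded start-count bedGraph tracks
#'
#' Interprets a plus/minus bedGraph pair as per-base counts of read 5'
#' ends and expands them into 1 bp stranded reads. Note that start-count
#' tracks carry no fragment extent, so traversing reads cannot be
#' represented: `A` counts from such input are always zero. Use alignments
#' (SAM/BAM or a read tibble) when across-island counts matter.
#'
#' @param plus_path,minus_path bedGraph files of 5'-end counts on the plus
#'   and minus strand.
#' @param condition Condition label.
#' @return Read tibble of 1 bp reads.
#' @export
reads_from_bedgraph <- function(plus_path, minus_path, condition = "all") {
  expand <- function(path, strand) {
    tr <- read_bedgraph(path)
    tr <- tr[tr$value > 0, , drop = FALSE]
    purrr::map_dfr(seq_len(nrow(tr)), function(i) {
      pos <- seq(tr$start[i], tr$end[i] - 1L)
      n <- as.integer(round(tr$value[i]))
      tibble(chrom = tr$chrom[i],
             start = rep(pos, each = n),
             strand = strand)
    })
  }
  out <- bind_rows(expand(plus_path, "+"), expand(minus_path, "-"))
  out |>
    mutate(end = .data$start + 1L, condition = condition) |>
    select("chrom", "start", "end", "strand", "condition")
}

#' Write synthetic fixtures to disk
#'
#' Serializes a simulation as mutually consistent plain-text files: genome
#' FASTA (optional), gene models as GFF3 and BED12, islands as BED, reads as
#' one SAM per condition plus a combined TSV, simple ChIP treatment/input
#' bedGraphs (island-centred enrichment step) and a bedMethyl file (islands
#' hypomethylated against a methylated background).
#'
#' @param sim Output of [simulate_counts()].
#' @param dir Output directory (created if needed).
#' @param genome Optional `DNAStringSet` from [generate_genome()].
#' @return Named list of written paths, invisibly.
#' @export
write_fixtures <- function(sim, dir, genome = NULL) {
  ann <- sim$annotation
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list()
  if (!is.null(genome)) {
    paths$genome <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(genome, paths$genome)
  }
  paths$gff3 <- file.path(dir, "genes.gff3")
  .write_gff3(ann$genes, paths$gff3)
  paths$bed12 <- file.path(dir, "genes.bed")
  .write_bed12(ann$genes, paths$bed12)
  paths$cgis <- file.path(dir, "cgis.bed")
  readr::write_tsv(select(ann$cgis, "chrom", "start", "end", "cgi_id"),
                   paths$cgis, col_names = FALSE)
  if (!is.null(sim$reads)) {
    paths$reads_tsv <- file.path(dir, "reads.tsv")
    readr::write_tsv(sim$reads, paths$reads_tsv)
    paths$sam <- purrr::map_chr(sim$conditions, function(cc) {
      p <- file.path(dir, sprintf("reads_%s.sam", cc))
      write_sam(sim$reads[sim$reads$condition == cc, , drop = FALSE], p,
                ann$contigs)
      p
    })
  }
  chip <- .synthetic_chip_tracks(ann)
  paths$chip_treatment <- file.path(dir, "chip_treatment.bedGraph")
  paths$chip_input <- file.path(dir, "chip_input.bedGraph")
  readr::write_tsv(chip$treatment, paths$chip_treatment, col_names = FALSE)
  readr::write_tsv(chip$input, paths$chip_input, col_names = FALSE)
  paths$bedmethyl <- file.path(dir, "methylation.bed")
  readr::write_tsv(.synthetic_bedmethyl(ann), paths$bedmethyl,
                   col_names = FALSE)
  invisible(paths)
}

.write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    lines <- c(lines,
      sprintf("%s\ticgi_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$chrom, g$start + 1L, g$end, g$strand, g$gene_id),
      sprintf("%s\ticgi_sim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              g$chrom, g$start + 1L, g$end, g$strand, g$transcript_id, g$gene_id))
    e <- g$exons[[1]]
    lines <- c(lines,
      sprintf("%s\ticgi_sim\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
              g$chrom, e$start + 1L, e$end, g$strand, g$transcript_id,
              seq_len(nrow(e)), g$transcript_id))
  }
  writeLines(lines, path)
}

.write_bed12 <- function(genes, path) {
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    e <- g$exons[[1]]
    paste(g$chrom, g$start, g$end, g$gene_id, 0, g$strand, g$start, g$end,
          "0,0,0", nrow(e),
          paste0(paste(e$end - e$start, collapse = ","), ","),
          paste0(paste(e$start - g$start, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
}

# step tracks: flat input, treatment enriched 4x over the island +/- 500 bp
.synthetic_chip_tracks <- function(ann) {
  treat <- purrr::map_dfr(seq_len(nrow(ann$contigs)), function(i) {
    chrom <- ann$contigs$chrom[i]
    L <- ann$contigs$length[i]
    cg <- ann$cgis[ann$cgis$chrom == chrom, , drop = FALSE]
    if (nrow(cg) == 0) {
      return(tibble(chrom = chrom, start = 0L, end = L, value = 2))
    }
    a <- max(0L, cg$start[1] - 500L); b <- min(L, cg$end[1] + 500L)
    tibble(chrom = chrom, start = c(0L, a, b), end = c(a, b, L),
           value = c(2, 8, 2))
  })
  input <- tibble(chrom = ann$contigs$chrom, start = 0L,
                  end = ann$contigs$length, value = 2)
  list(treatment = filter(treat, .data$end > .data$start), input = input)
}

# CpG records every 97 bp; 85% methylated background, 5% inside islands
.synthetic_bedmethyl <- function(ann) {
  purrr::map_dfr(seq_len(nrow(ann$contigs)), function(i) {
    chrom <- ann$contigs$chrom[i]
    pos <- seq(0L, ann$contigs$length[i] - 2L, by = 97L)
    cg <- ann$cgis[ann$cgis$chrom == chrom, , drop = FALSE]
    inside <- rep(FALSE, length(pos))
    for (k in seq_len(nrow(cg))) {
      inside <- inside | (pos >= cg$start[k] & pos < cg$end[k])
    }
    tibble(chrom = chrom, start = pos, end = pos + 2L,
           pct = ifelse(inside, 5, 85))
  })
}
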