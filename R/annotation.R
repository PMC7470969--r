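#' Load gene models from GFF3, GTF or BED12
#'
#' Parses transcript structures into a tidy gene-model table with strand-aware
#' transcription start site (TSS) and last-exon start coordinates. All
#' coordinates are converted to the 0-based half-open (BED) convention
#' internally; GFF3/GTF inputs (1-based closed) are shifted at parse time.
#'
#' When several isoforms exist for a gene, `dedup = "gene"` keeps the longest
#' ("canonical-like") transcript per gene; `dedup = "transcript"` keeps every
#' transcript as its own model.
#'
#' @param path Path to an annotation file.
#' @param dialect One of `"auto"`, `"gff3"`, `"gtf"`, `"bed12"`. `"auto"`
#'   guesses from the file extension.
#' @param dedup `"gene"` (longest transcript per gene, default) or
#'   `"transcript"`.
#' @return A tibble with one row per gene model: `gene_id`, `transcript_id`,
#'   `chrom`, `start`, `end`, `strand`, `tss`, `last_exon_start`, `n_exons`,
#'   and a list-column `exons` of tibbles (`start`, `end`) sorted by
#'   coordinate. `tss` is the gene's `start` on `+` and its `end` on `-`;
#'   `last_exon_start` is the strand-aware start coordinate of the 3'-most
#'   exon.
#' @export
load_gene_models <- function(path, dialect = c("auto", "gff3", "gtf", "bed12"),
                             dedup = c("gene", "transcript")) {
  dialect <- match.arg(dialect)
  dedup <- match.arg(dedup)
  if (!file.exists(path)) abort(sprintf("annotation file not found: %s", path))
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    dialect <- switch(ext,
      gff = "gff3", gff3 = "gff3", gtf = "gtf", bed = "bed12",
      abort(sprintf("cannot guess annotation dialect from extension '.%s'", ext))
    )
  }
  models <- switch(dialect,
    bed12 = .models_from_bed12(path),
    gtf   = .models_from_gxf(path, "gtf"),
    gff3  = .models_from_gxf(path, "gff3")
  )
  if (nrow(models) == 0) abort("no gene models parsed from input")
  models <- finalize_gene_models(models)
  if (dedup == "gene") {
    models <- models |>
      mutate(.len = .data$end - .data$start) |>
      group_by(.data$gene_id) |>
      arrange(desc(.data$.len), .data$transcript_id, .by_group = TRUE) |>
      dplyr::slice(1L) |>
      ungroup() |>
      select(-".len")
  }
  arrange(models, .data$chrom, .data$start, .data$end)
}

.models_from_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (is.null(gr$blocks)) {
    abort(sprintf("BED input %s has no block (exon) structure; BED12 required", path))
  }
  starts <- GenomicRanges::start(gr) - 1L   # to 0-based
  ends <- GenomicRanges::end(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  .check_strand(strand)
  blocks <- gr$blocks                        # IRangesList, 1-based within gene
  exons <- purrr::map(seq_along(gr), function(i) {
    b <- blocks[[i]]
    tibble(start = starts[i] + GenomicRanges::start(b) - 1L,
           end = starts[i] + GenomicRanges::end(b)) |>
      arrange(.data$start)
  })
  nm <- gr$name %||% sprintf("gene_%05d", seq_along(gr))
  tibble(
    gene_id = nm, transcript_id = nm,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = starts, end = ends, strand = strand, exons = exons
  )
}

.models_from_gxf <- function(path, format) {
  gr <- rtracklayer::import(path, format = format)
  type <- tolower(as.character(gr$type))
  ex <- gr[type == "exon"]
  if (length(ex) == 0) abort(sprintf("no exon records in %s", path))
  if (format == "gtf") {
    txid <- as.character(ex$transcript_id)
    gene <- as.character(ex$gene_id %||% txid)
  } else {
    parent <- ex$Parent
    txid <- vapply(as.list(parent), function(p) {
      if (length(p) == 0) NA_character_ else as.character(p[[1]])
    }, character(1))
    # map transcript -> gene through the parent transcript records if present
    tx <- gr[type %in% c("mrna", "transcript")]
    if (length(tx) > 0 && !is.null(tx$ID)) {
      txparent <- vapply(as.list(tx$Parent), function(p) {
        if (length(p) == 0) NA_character_ else as.character(p[[1]])
      }, character(1))
      gmap <- setNames(ifelse(is.na(txparent), as.character(tx$ID), txparent),
                       as.character(tx$ID))
      gene <- unname(gmap[txid])
      gene[is.na(gene)] <- txid[is.na(gene)]
    } else {
      gene <- txid
    }
  }
  if (anyNA(txid)) {
    abort(sprintf("exon record without transcript identifier in %s (line unknown to importer; check Parent/transcript_id attributes)", path))
  }
  df <- tibble(
    gene_id = sub("^(gene:|transcript:)", "", gene),
    transcript_id = sub("^transcript:", "", txid),
    chrom = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(GenomicRanges::strand(ex)),
    estart = GenomicRanges::start(ex) - 1L,  # to 0-based half-open
    eend = GenomicRanges::end(ex)
  )
  .check_strand(df$strand)
  df |>
    tidyr::nest(exons = c("estart", "eend")) |>
    mutate(
      exons = purrr::map(.data$exons, function(e) {
        tibble(start = e$estart, end = e$eend) |> arrange(.data$start)
      }),
      start = purrr::map_int(.data$exons, ~min(.x$start)),
      end = purrr::map_int(.data$exons, ~max(.x$end))
    ) |>
    select("gene_id", "transcript_id", "chrom", "start", "end", "strand", "exons")
}

#' Finalize a gene-model table
#'
#' Validates exon structure and computes the strand-aware `tss`,
#' `last_exon_start` and `n_exons` columns. Used by the file loaders and by
#' the synthetic-annotation generator; exported so that programmatically
#' built models go through the same checks.
#'
#' @param models Tibble with `gene_id`, `transcript_id`, `chrom`, `start`,
#'   `end`, `strand` and an `exons` list-column.
#' @return The input with `tss`, `last_exon_start` and `n_exons` added;
#'   zero-exon models are dropped with a warning.
#' @export
finalize_gene_models <- function(models) {
  .check_cols(models, c("gene_id", "transcript_id", "chrom", "start", "end",
                        "strand", "exons"), "gene-model table")
  nex <- vapply(models$exons, nrow, integer(1))
  if (any(nex == 0)) {
    warn(sprintf("dropping %d gene model(s) with zero exons: %s",
                 sum(nex == 0),
                 paste(head(models$gene_id[nex == 0], 5), collapse = ", ")))
    models <- models[nex > 0, , drop = FALSE]
    nex <- nex[nex > 0]
  }
  if (nrow(models) == 0) abort("no gene models with exons remain")
  bad <- vapply(seq_len(nrow(models)), function(i) {
    e <- models$exons[[i]]
    any(e$start >= e$end) ||
      any(e$start < models$start[i]) || any(e$end > models$end[i]) ||
      (nrow(e) > 1 && any(e$end[-nrow(e)] > e$start[-1]))
  }, logical(1))
  if (any(bad)) {
    abort(sprintf("malformed exon structure (overlapping, inverted or outside gene) for: %s",
                  paste(head(models$gene_id[bad], 5), collapse = ", ")))
  }
  models |>
    mutate(
      n_exons = nex,
      tss = ifelse(.data$strand == "+", .data$start, .data$end),
      last_exon_start = purrr::map2_dbl(.data$exons, .data$strand, function(e, s) {
        if (s == "+") e$start[nrow(e)] else e$end[1]
      })
    )
}

#' Read CpG-island annotations from BED
#'
#' @param path BED file (BED4/BED6; name column optional) of CGI intervals.
#' @return Tibble with `cgi_id`, `chrom`, `start`, `end` (0-based half-open).
#' @export
read_cgis <- function(path) {
  if (!file.exists(path)) abort(sprintf("CGI file not found: %s", path))
  gr <- rtracklayer::import(path, format = "bed")
  out <- tibble(
    cgi_id = gr$name %||% sprintf("cgi_%05d", seq_along(gr)),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  if (any(out$end - out$start < 1)) abort("CGI interval of length < 1 bp")
  out
}

#' Identify iCGI/host-gene pairs under positional filters
#'
#' A CpG island pairs with a host gene when it lies fully inside the gene
#' body, its TSS-proximal edge is at least `min_tss_dist` bp from the host
#' TSS, and its 3'-proximal edge is at least `min_last_exon_dist` bp from the
#' strand-aware start of the host's last exon. Distances are measured to the
#' nearest island edge. Each retained pair is classified as
#' `fully_intronic` (the island touches no exon) or `exon_overlapping`.
#'
#' @param genes Gene-model tibble from [load_gene_models()] /
#'   [finalize_gene_models()].
#' @param cgis CGI tibble from [read_cgis()] (columns `cgi_id`, `chrom`,
#'   `start`, `end`).
#' @param min_tss_dist Minimum TSS-to-island distance in bp (default 1000).
#' @param min_last_exon_dist Minimum island-to-last-exon-start distance in bp
#'   (default 500).
#' @return Tibble of pairs: `pair_id`, gene columns (`gene_id`, `chrom`,
#'   `gene_start`, `gene_end`, `strand`, `tss`, `last_exon_start`),
#'   `cgi_id`, `icgi_start`, `icgi_end`, `tss_distance`,
#'   `last_exon_distance`, `placement`.
#' @export
identify_icgi_pairs <- function(genes, cgis, min_tss_dist = 1000,
                                min_last_exon_dist = 500) {
  .check_cols(genes, c("gene_id", "chrom", "start", "end", "strand",
                       "last_exon_start", "exons"), "gene table")
  .check_cols(cgis, c("cgi_id", "chrom", "start", "end"), "CGI table")
  stopifnot(min_tss_dist > 0, min_last_exon_dist > 0)
  orphan <- !(cgis$chrom %in% unique(genes$chrom))
  if (any(orphan)) {
    inform(sprintf("%d CGI(s) on chromosomes absent from the gene set were left unpaired", sum(orphan)))
  }
  g <- genes |>
    dplyr::rename(gene_start = "start", gene_end = "end")
  cand <- inner_join(g, dplyr::rename(cgis, icgi_start = "start", icgi_end = "end"),
                     by = "chrom", relationship = "many-to-many")
  if (nrow(cand) == 0) return(.empty_pairs())
  cand <- cand |>
    filter(.contains(.data$gene_start, .data$gene_end,
                     .data$icgi_start, .data$icgi_end)) |>
    mutate(
      tss_distance = ifelse(.data$strand == "+",
                            .data$icgi_start - .data$gene_start,
                            .data$gene_end - .data$icgi_end),
      last_exon_distance = ifelse(.data$strand == "+",
                                  .data$last_exon_start - .data$icgi_end,
                                  .data$icgi_start - .data$last_exon_start)
    ) |>
    filter(.data$tss_distance >= min_tss_dist,
           .data$last_exon_distance >= min_last_exon_dist)
  if (nrow(cand) == 0) return(.empty_pairs())
  cand |>
    mutate(
      placement = purrr::pmap_chr(
        list(.data$exons, .data$icgi_start, .data$icgi_end),
        function(e, s, x) {
          if (any(.overlaps(e$start, e$end, s, x))) "exon_overlapping"
          else "fully_intronic"
        }),
      pair_id = paste(.data$gene_id, .data$cgi_id, sep = "|")
    ) |>
    select("pair_id", "gene_id", "cgi_id", "chrom", "gene_start", "gene_end",
           "strand", "tss", "last_exon_start", "icgi_start", "icgi_end",
           "tss_distance", "last_exon_distance", "placement") |>
    arrange(.data$chrom, .data$gene_start, .data$icgi_start)
}

.empty_pairs <- function() {
  tibble(pair_id = character(), gene_id = character(), cgi_id = character(),
         chrom = character(), gene_start = integer(), gene_end = integer(),
         strand = character(), tss = double(), last_exon_start = double(),
         icgi_start = integer(), icgi_end = integer(),
         tss_distance = double(), last_exon_distance = double(),
         placement = character())
}

#' Select negative-control loci
#'
#' A gene is an eligible control when its body intersects no CpG island and
#' its interval overlaps no other gene's interval (same chromosome, half-open
#' overlap, strand-agnostic). Ineligible genes are retained with
#' `eligible = FALSE` for audit.
#'
#' @param genes Gene-model tibble.
#' @param cgis CGI tibble.
#' @return The gene table with logical columns `has_cgi`, `overlaps_gene`
#'   and `eligible`.
#' @export
select_control_loci <- function(genes, cgis) {
  .check_cols(genes, c("gene_id", "chrom", "start", "end"), "gene table")
  .check_cols(cgis, c("chrom", "start", "end"), "CGI table")
  has_cgi <- vapply(seq_len(nrow(genes)), function(i) {
    k <- cgis$chrom == genes$chrom[i]
    any(.overlaps(cgis$start[k], cgis$end[k], genes$start[i], genes$end[i]))
  }, logical(1))
  overlaps_gene <- vapply(seq_len(nrow(genes)), function(i) {
    k <- genes$chrom == genes$chrom[i] & seq_len(nrow(genes)) != i
    any(.overlaps(genes$start[k], genes$end[k], genes$start[i], genes$end[i]))
  }, logical(1))
  genes |>
    mutate(has_cgi = has_cgi, overlaps_gene = overlaps_gene,
           eligible = !has_cgi & !overlaps_gene)
}

#' Write pairs as TSV and BED
#'
#' @param pairs Pair tibble from [identify_icgi_pairs()].
#' @param tsv,bed Output paths; either may be `NULL` to skip.
#' @return `pairs`, invisibly.
#' @export
write_pairs <- function(pairs, tsv = NULL, bed = NULL) {
  if (!is.null(tsv)) {
    readr::write_tsv(select(pairs, -dplyr::any_of("exons")), tsv)
  }
  if (!is.null(bed)) {
    bedtbl <- tibble(chrom = pairs$chrom, start = pairs$icgi_start,
                     end = pairs$icgi_end, name = pairs$pair_id,
                     score = 0L, strand = pairs$strand)
    readr::write_tsv(bedtbl, bed, col_names = FALSE)
  }
  invisible(pairs)
}
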