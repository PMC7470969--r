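two_locus_pairs <- function() {
  g1 <- make_gene("gA", "chr1", 10000, 20000, "+",
                  exons = list(c(10000, 10200), c(14800, 15000), c(19800, 20000)))
  g2 <- make_gene("gB", "chr2", 10000, 30000, "+",
                  exons = list(c(10000, 10200), c(24800, 25000), c(29800, 30000)))
  cgis <- tibble::tibble(cgi_id = c("cA", "cB"), chrom = c("chr1", "chr2"),
                         start = c(12000, 14000), end = c(13000, 16000))
  identify_icgi_pairs(dplyr::bind_rows(g1, g2), cgis)
}

test_that("track extraction and log fold enrichment behave per definition", {
  tr <- tibble::tibble(chrom = "chr1", start = c(0L, 100L), end = c(100L, 150L),
                       value = c(2, 4))
  v <- track_values(tr, "chr1", 90, 110)
  expect_equal(v, c(rep(2, 10), rep(4, 10)))
  expect_true(all(is.na(track_values(tr, "chr1", 200, 210))))
  expect_true(all(is.na(track_values(tr, "chr9", 0, 10))))

  t <- c(1, 2, 4); i <- c(1, 2, 4)
  expect_equal(log_fold_enrichment(t, i), c(0, 0, 0))
  expect_equal(log_fold_enrichment(2 * i, i, pseudocount = 1e-9), c(1, 1, 1),
               tolerance = 1e-6)
  expect_error(log_fold_enrichment(1:3, 1:2), "lengths")
  expect_error(log_fold_enrichment(1:3, 1:3, pseudocount = 0), "positive")
  # NA propagates
  expect_true(is.na(log_fold_enrichment(c(1, NA), c(1, 1))[2]))
  # random tracks match per-base brute force
  withr::with_seed(4, { tt <- runif(50); ii <- runif(50) })
  expect_equal(log_fold_enrichment(tt, ii, 0.5),
               log2((tt + 0.5) / (ii + 0.5)))
})

test_that("constant signal gives a flat metagene at that constant", {
  pairs <- two_locus_pairs()
  sig <- tibble::tibble(chrom = c("chr1", "chr2"), start = 0L,
                        end = c(40000L, 40000L), value = 3.5)
  prof <- metagene(pairs, sig, flank_bp = 500)
  expect_equal(unique(prof$values$mean), 3.5)
  expect_equal(unique(prof$values$n), 2L)
  expect_equal(nrow(prof$values),
               2 * 500 + sum(prof$interval_lengths))
})

test_that("two-locus step signals match the hand-computed rescaled mean", {
  pairs <- two_locus_pairs()
  # locus A: upstream 2000 bp at value 1, island 1000 bp at 5, downstream 7000 at 2
  # locus B: upstream 4000 bp at value 3, island 2000 bp at 7, downstream 14000 at 4
  sig <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2", "chr2", "chr2", "chr2"),
    start = c(0L, 12000L, 13000L, 20000L, 0L, 14000L, 16000L, 30000L),
    end = c(12000L, 13000L, 20000L, 40000L, 14000L, 16000L, 30000L, 40000L),
    value = c(1, 5, 2, 0, 3, 7, 4, 0))
  prof <- metagene(pairs, sig, flank_bp = 100)
  v <- prof$values
  # each segment is constant per locus, so rescaling preserves the constants
  # and the mean is the plain average of the two values
  expect_equal(unname(prof$interval_lengths),
               c(mean(c(2000, 4000)), mean(c(1000, 2000)), mean(c(7000, 14000))))
  expect_equal(unique(v$mean[v$segment == "upstream"]), mean(c(1, 3)),
               tolerance = 1e-9)
  expect_equal(unique(v$mean[v$segment == "icgi"]), mean(c(5, 7)),
               tolerance = 1e-9)
  expect_equal(unique(v$mean[v$segment == "downstream"]), mean(c(2, 4)),
               tolerance = 1e-9)
  # flanks are unscaled: 5' flank averages the two upstream-of-TSS values
  expect_equal(unique(v$mean[v$segment == "flank5"]), mean(c(1, 3)),
               tolerance = 1e-9)
})

test_that("metagene is linear in the signal and mirror-symmetric", {
  pairs <- two_locus_pairs()
  withr::with_seed(44, {
    sig <- tibble::tibble(
      chrom = rep(c("chr1", "chr2"), each = 40),
      start = rep(seq(0L, 39000L, by = 1000L), 2)) |>
      dplyr::mutate(end = start + 1000L, value = runif(80, 0, 4))
  })
  p1 <- metagene(pairs, sig, flank_bp = 300)
  p3 <- metagene(pairs, dplyr::mutate(sig, value = 3 * value), flank_bp = 300)
  expect_equal(p3$values$mean, 3 * p1$values$mean, tolerance = 1e-9)

  # mirror: reflect coordinates and strands; profile reverses
  M <- 40000L
  mg <- function(g) {
    ex <- lapply(g$exons, function(e) tibble::tibble(start = M - e$end, end = M - e$start) |>
                   dplyr::arrange(start))
    out <- g
    tmp <- out$start; out$start <- M - out$end; out$end <- M - tmp
    out$strand <- "-"; out$exons <- ex
    finalize_gene_models(dplyr::select(out, gene_id, transcript_id, chrom,
                                       start, end, strand, exons))
  }
  g1 <- make_gene("gA", "chr1", 10000, 20000, "+",
                  exons = list(c(10000, 10200), c(14800, 15000), c(19800, 20000)))
  g2 <- make_gene("gB", "chr2", 10000, 30000, "+",
                  exons = list(c(10000, 10200), c(24800, 25000), c(29800, 30000)))
  cgis_m <- tibble::tibble(cgi_id = c("cA", "cB"), chrom = c("chr1", "chr2"),
                           start = M - c(13000L, 16000L), end = M - c(12000L, 14000L))
  pairs_m <- identify_icgi_pairs(dplyr::bind_rows(mg(g1), mg(g2)), cgis_m)
  sig_m <- sig |>
    dplyr::mutate(s = M - end, e = M - start, start = s, end = e) |>
    dplyr::select(chrom, start, end, value)
  p_m <- metagene(pairs_m, sig_m, flank_bp = 300)
  expect_equal(p_m$values$mean, p1$values$mean, tolerance = 1e-9)
})

test_that("metagene refuses exon-overlapping pairs", {
  pairs <- two_locus_pairs()
  pairs$placement[1] <- "exon_overlapping"
  expect_error(metagene(pairs, tibble::tibble(chrom = "chr1", start = 0L,
                                              end = 100L, value = 1)),
               "intronic")
})

test_that("bedMethyl parsing and island methylation binning are exact", {
  dir <- withr::local_tempdir()
  bm <- file.path(dir, "m.bed")
  # minimal 4-column form
  writeLines(c("chr1\t100\t102\t80", "chr1\t200\t202\t40"), bm)
  m <- read_bedmethyl(bm)
  expect_equal(m$pct, c(80, 40))
  writeLines(c("chr1\t100\t102\t80", "chr1\t200\t202\t140"), bm)
  expect_error(read_bedmethyl(bm), "line 2")

  pairs <- two_locus_pairs()[1, ]  # island chr1:12000-13000
  # all CpGs at 100% -> every covered bin = 100
  cov <- tibble::tibble(chrom = "chr1", start = seq(11000L, 14000L, by = 50L)) |>
    dplyr::mutate(end = start + 2L, pct = 100)
  out <- methylation_at_icgi(cov, pairs, flank_bp = 2000, n_bins = 10)
  expect_true(all(out$pct[out$n_cpg > 0] == 100))
  # no CpGs in window -> all bins missing
  far <- tibble::tibble(chrom = "chr1", start = 1000000L, end = 1000002L, pct = 50)
  out <- methylation_at_icgi(far, pairs, flank_bp = 2000, n_bins = 10)
  expect_true(all(is.na(out$pct)))
  expect_equal(nrow(out), 10)
  # known per-bin means: window 10000..15000, 5 bins of 1000
  known <- tibble::tibble(chrom = "chr1",
                          start = c(10100L, 10200L, 12100L, 14500L),
                          end = c(10102L, 10202L, 12102L, 14502L),
                          pct = c(10, 30, 60, 90))
  out <- methylation_at_icgi(known, pairs, flank_bp = 2000, n_bins = 5)
  expect_equal(out$pct, c(20, NA, 60, NA, 90))
  expect_equal(out$n_cpg, c(2L, 0L, 1L, 0L, 1L))
})

test_that("minus-strand methylation windows are reported 5' to 3'", {
  g <- make_gene("gm", "chr3", 10000, 20000, "-",
                 exons = list(c(10000, 10200), c(14800, 15000), c(19800, 20000)))
  cg <- tibble::tibble(cgi_id = "cm", chrom = "chr3", start = 12000, end = 13000)
  pairs <- identify_icgi_pairs(g, cg)
  rec <- tibble::tibble(chrom = "chr3", start = c(11500L, 13500L),
                        end = c(11502L, 13502L), pct = c(25, 75))
  out <- methylation_at_icgi(rec, pairs, flank_bp = 1000, n_bins = 3)
  # genomically: bin1 has 25, bin3 has 75; on the minus strand the order flips
  expect_equal(out$pct, c(75, NA, 25))
})
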