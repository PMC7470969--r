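# Fixture builders and independent brute-force oracles used across tests.
# Every oracle here is a deliberately naive re-derivation (per-element loops,
# direct formulas) kept independent of the package's vectorized code paths.

make_gene <- function(gene_id, chrom, start, end, strand,
                      exons = list(c(start, start + 200),
                                   c((start + end) %/% 2, (start + end) %/% 2 + 200),
                                   c(end - 200, end))) {
  ex <- dplyr::bind_rows(lapply(exons, function(e) {
    tibble::tibble(start = e[1], end = e[2])
  })) |> dplyr::arrange(start)
  finalize_gene_models(tibble::tibble(
    gene_id = gene_id, transcript_id = paste0(gene_id, ".t1"),
    chrom = chrom, start = start, end = end, strand = strand,
    exons = list(ex)
  ))
}

random_gene_fixture <- function(n_genes, seed, chroms = c("chrA", "chrB")) {
  withr::with_seed(seed, {
    dplyr::bind_rows(lapply(seq_len(n_genes), function(i) {
      start <- sample(0:50000, 1)
      len <- sample(5000:30000, 1)
      end <- start + len
      make_gene(sprintf("g%03d", i), sample(chroms, 1), start, end,
                sample(c("+", "-"), 1))
    }))
  })
}

random_cgi_fixture <- function(n_cgis, seed, chroms = c("chrA", "chrB", "chrZ")) {
  withr::with_seed(seed, {
    tibble::tibble(
      cgi_id = sprintf("c%03d", seq_len(n_cgis)),
      chrom = sample(chroms, n_cgis, replace = TRUE),
      start = sample(0:80000, n_cgis, replace = TRUE)
    ) |>
      dplyr::mutate(end = start + sample(200:1500, n_cgis, replace = TRUE))
  })
}

# brute-force all-pairs containment + distance scan (the oracle for
# identify_icgi_pairs); loops row by row, no joins
oracle_pairs <- function(genes, cgis, min_tss = 1000, min_le = 500) {
  out <- list()
  for (i in seq_len(nrow(genes))) {
    for (j in seq_len(nrow(cgis))) {
      g <- genes[i, ]; c <- cgis[j, ]
      if (g$chrom != c$chrom) next
      if (!(c$start >= g$start && c$end <= g$end)) next
      if (g$strand == "+") {
        tssd <- c$start - g$start
        led <- g$last_exon_start - c$end
      } else {
        tssd <- g$end - c$end
        led <- c$start - g$last_exon_start
      }
      if (tssd < min_tss || led < min_le) next
      ex <- g$exons[[1]]
      intronic <- TRUE
      for (k in seq_len(nrow(ex))) {
        if (ex$start[k] < c$end && ex$end[k] > c$start) intronic <- FALSE
      }
      out[[length(out) + 1]] <- tibble::tibble(
        pair_id = paste(g$gene_id, c$cgi_id, sep = "|"),
        tss_distance = tssd, last_exon_distance = led,
        placement = if (intronic) "fully_intronic" else "exon_overlapping")
    }
  }
  if (length(out) == 0) return(tibble::tibble(pair_id = character()))
  dplyr::bind_rows(out) |> dplyr::arrange(pair_id)
}

# brute-force per-read classification loop (the oracle for count_reads)
oracle_classify <- function(read, part) {
  p5 <- if (read$strand == "+") read$start else read$end - 1
  if (p5 >= part$icgi_start && p5 < part$icgi_end) {
    return(if (read$strand == part$strand) "G_sense" else "G_antisense")
  }
  if (read$strand != part$strand) return("none")
  if (read$start < part$icgi_end && read$end > part$icgi_start) return("A")
  if (p5 >= part$upstream_start && p5 < part$upstream_end) return("U")
  "none"
}

oracle_counts <- function(reads, part) {
  conds <- sort(unique(reads$condition))
  res <- list()
  for (cc in conds) {
    U <- A <- Gs <- Ga <- 0
    sub <- reads[reads$condition == cc & reads$chrom == part$chrom, ]
    for (i in seq_len(nrow(sub))) {
      cl <- oracle_classify(sub[i, ], part)
      if (cl == "U") U <- U + 1
      if (cl == "A") A <- A + 1
      if (cl == "G_sense") Gs <- Gs + 1
      if (cl == "G_antisense") Ga <- Ga + 1
    }
    res[[cc]] <- tibble::tibble(condition = cc, U = U, A = A,
                                G_sense = Gs, G_antisense = Ga)
  }
  dplyr::bind_rows(res)
}

# independent Pearson on the exact transformed vectors of the statistic
oracle_rho <- function(U, A, G) {
  x <- log(U + 1) - log(A + 1)
  g1 <- G + 1
  med <- sort(g1)[ceiling(length(g1) / 2)]
  if (length(g1) %% 2 == 0) {
    s <- sort(g1)
    med <- (s[length(g1) / 2] + s[length(g1) / 2 + 1]) / 2
  }
  dev <- abs(g1 - med)
  sdev <- sort(dev)
  mad_raw <- if (length(dev) %% 2 == 1) sdev[ceiling(length(dev) / 2)] else
    (sdev[length(dev) / 2] + sdev[length(dev) / 2 + 1]) / 2
  y <- (G - med) / (mad_raw + 0.1)
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
  num / den
}

# naive character-loop tallies for composition metrics
oracle_composition <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  nC <- sum(ch == "C"); nG <- sum(ch == "G"); nN <- sum(ch == "N")
  L <- length(ch) - nN
  ncpg <- 0
  for (i in seq_len(length(ch) - 1)) {
    if (ch[i] == "C" && ch[i + 1] == "G") ncpg <- ncpg + 1
  }
  list(gc = (nC + nG) / L,
       oe = if (nC == 0 || nG == 0) NA_real_ else ncpg / (nC * nG / L),
       dens = ncpg / L)
}

random_dna <- function(n, len_range = c(50, 300), with_n = FALSE) {
  letters <- c("A", "C", "G", "T", if (with_n) "N")
  vapply(seq_len(n), function(i) {
    paste(sample(letters, sample(len_range[1]:len_range[2], 1),
                 replace = TRUE), collapse = "")
  }, character(1))
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

# small simulation shared by several acceptance checks
small_sim <- function(seed = 42, n_genes = 30, n_conditions = 10, ...) {
  cfg <- simulation_config(n_genes = n_genes, n_conditions = n_conditions,
                           frac_with_icgi = 0.5, seed = seed, ...)
  ann <- generate_annotation(cfg)
  sim <- simulate_counts(ann)
  list(cfg = cfg, ann = ann, sim = sim,
       cgis = dplyr::select(ann$cgis, cgi_id, chrom, start, end))
}
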