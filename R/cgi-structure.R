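.as_dnastringset <- function(seq) {
  if (inherits(seq, "DNAStringSet")) return(seq)
  if (inherits(seq, "DNAString")) return(Biostrings::DNAStringSet(seq))
  if (is.character(seq)) {
    bad <- grepl("[^ACGTNacgtn]", seq)
    if (any(bad)) abort("sequence contains characters outside {A,C,G,T,N}")
    return(Biostrings::DNAStringSet(toupper(seq)))
  }
  abort("seq must be a character vector or a Biostrings DNAStringSet")
}

.base_counts <- function(ds) {
  lf <- Biostrings::letterFrequency(ds, letters = c("C", "G", "N"))
  tibble(
    width = Biostrings::width(ds),
    C = lf[, "C"], G = lf[, "G"], N = lf[, "N"],
    L = Biostrings::width(ds) - lf[, "N"],          # length excluding N
    CpG = Biostrings::vcountPattern("CG", ds)
  )
}

#' C+G content of a sequence
#'
#' `(#C + #G) / L` with `L` the sequence length excluding `N` bases, which
#' are dropped from both numerator and denominator. Case-insensitive.
#'
#' @param seq Character vector of DNA sequences (or a `DNAStringSet`).
#' @return Numeric vector of fractions in \[0, 1\].
#' @export
gc_content <- function(seq) {
  ds <- .as_dnastringset(seq)
  bc <- .base_counts(ds)
  if (any(bc$width == 0) || any(bc$L == 0)) abort("empty or all-N sequence")
  unname((bc$C + bc$G) / bc$L)
}

#' CpG observed/expected ratio
#'
#' `#CpG / (#C * #G / L)` (Gardiner-Garden & Frommer), with `L` excluding
#' `N`. Undefined (returned as `NA` with a warning) when the sequence has no
#' `C` or no `G`.
#'
#' @inheritParams gc_content
#' @return Numeric vector of non-negative ratios.
#' @export
cpg_obs_exp <- function(seq) {
  ds <- .as_dnastringset(seq)
  bc <- .base_counts(ds)
  if (any(bc$width == 0) || any(bc$L == 0)) abort("empty or all-N sequence")
  undef <- bc$C == 0 | bc$G == 0
  if (any(undef)) {
    warn(sprintf("CpG obs/exp undefined for %d sequence(s) with no C or no G", sum(undef)))
  }
  unname(ifelse(undef, NA_real_, bc$CpG / (bc$C * bc$G / bc$L)))
}

#' CpG dinucleotide density
#'
#' `#CpG / L` per bp (`L` excluding `N`); multiply by 100 for the per-100-bp
#' convention.
#'
#' @inheritParams gc_content
#' @return Numeric vector in \[0, 0.5\].
#' @export
cpg_density <- function(seq) {
  ds <- .as_dnastringset(seq)
  bc <- .base_counts(ds)
  if (any(bc$width == 0) || any(bc$L == 0)) abort("empty or all-N sequence")
  unname(bc$CpG / bc$L)
}

#' Composition metrics for a set of CGIs
#'
#' @param seq Character vector or `DNAStringSet` of CGI sequences.
#' @param cgi_id Identifiers (defaults to sequence names or an index).
#' @return Tibble: `cgi_id`, `length`, `gc_content`, `cpg_obs_exp`,
#'   `cpg_density`, `n_fraction`, `low_confidence` (`TRUE` when more than
#'   half the bases are `N`).
#' @export
cgi_composition <- function(seq, cgi_id = NULL) {
  ds <- .as_dnastringset(seq)
  if (is.null(cgi_id)) {
    cgi_id <- names(ds) %||% sprintf("cgi_%05d", seq_along(ds))
  }
  bc <- .base_counts(ds)
  tibble(
    cgi_id = cgi_id,
    length = bc$width,
    gc_content = gc_content(ds),
    cpg_obs_exp = cpg_obs_exp(ds),
    cpg_density = cpg_density(ds),
    n_fraction = bc$N / bc$width,
    low_confidence = bc$N / bc$width > 0.5
  )
}

#' Extract CGI sequences from a genome
#'
#' @param genome FASTA path or named `DNAStringSet`.
#' @param cgis CGI tibble (`cgi_id`, `chrom`, `start`, `end`, 0-based
#'   half-open).
#' @return Named `DNAStringSet` of island sequences.
#' @export
cgi_sequences <- function(genome, cgis) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  .check_cols(cgis, c("cgi_id", "chrom", "start", "end"), "CGI table")
  nm <- sub("\\s.*$", "", names(genome))
  miss <- setdiff(cgis$chrom, nm)
  if (length(miss) > 0) {
    abort(sprintf("chromosome(s) absent from genome: %s", paste(miss, collapse = ", ")))
  }
  idx <- match(cgis$chrom, nm)
  out <- Biostrings::DNAStringSet(purrr::map(seq_len(nrow(cgis)), function(i) {
    Biostrings::subseq(genome[[idx[i]]], start = cgis$start[i] + 1, end = cgis$end[i])
  }))
  names(out) <- cgis$cgi_id
  out
}

#' Compare composition metrics between candidate and other islands
#'
#' Descriptive group summaries (median and quartiles) per metric plus a
#' two-sample Wilcoxon rank-sum comparison. The comparison is skipped (with
#' `NA` statistics) when either group has fewer than 2 members.
#'
#' @param compositions Output of [cgi_composition()].
#' @param candidate_ids Character vector of `cgi_id`s in the candidate group
#'   (e.g. islands of pairs with rho above the null-max threshold).
#' @return Tibble with one row per metric: group sizes, medians, quartiles,
#'   `statistic` (Wilcoxon W) and `p_value`.
#' @export
compare_compositions <- function(compositions, candidate_ids) {
  .check_cols(compositions, c("cgi_id", "gc_content", "cpg_obs_exp",
                              "cpg_density"), "composition table")
  grp <- ifelse(compositions$cgi_id %in% candidate_ids, "candidate", "other")
  if (!all(c("candidate", "other") %in% grp)) {
    abort("both groups (candidate / other) must be non-empty")
  }
  purrr::map_dfr(c("gc_content", "cpg_obs_exp", "cpg_density"), function(met) {
    v <- compositions[[met]]
    a <- v[grp == "candidate" & !is.na(v)]
    b <- v[grp == "other" & !is.na(v)]
    qs <- function(x) quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    qa <- qs(a); qb <- qs(b)
    if (length(a) >= 2 && length(b) >= 2) {
      wt <- wilcox.test(a, b, exact = FALSE)
      stat <- unname(wt$statistic); pv <- wt$p.value
    } else {
      stat <- NA_real_; pv <- NA_real_
    }
    tibble(metric = met,
           n_candidate = length(a), n_other = length(b),
           median_candidate = qa[2], q25_candidate = qa[1], q75_candidate = qa[3],
           median_other = qb[2], q25_other = qb[1], q75_other = qb[3],
           statistic = stat, p_value = pv)
  })
}
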