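#' @importFrom rlang %||% abort warn inform
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   bind_rows bind_cols left_join inner_join n row_number desc across
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats cor median sd dist hclust cutree quantile rnbinom rlnorm
#'   runif approx wilcox.test setNames as.dendrogram
#' @importFrom utils head tail
NULL

# half-open interval overlap; all coordinates 0-based half-open (BED)
.overlaps <- function(s1, e1, s2, e2) s1 < e2 & e1 > s2

.contains <- function(s_out, e_out, s_in, e_in) s_in >= s_out & e_in <= e_out

.check_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(miss, collapse = ", ")))
  }
  invisible(df)
}

.check_strand <- function(strand, allow_dot = FALSE) {
  ok <- c("+", "-", if (allow_dot) ".")
  bad <- setdiff(unique(strand), ok)
  if (length(bad) > 0) {
    abort(sprintf("invalid strand value(s): %s (strand-specific data required)",
                  paste(bad, collapse = ", ")))
  }
  invisible(strand)
}

# strand-aware 5' end of a read/fragment, 0-based position of the 5'-most base
.five_prime <- function(start, end, strand) {
  ifelse(strand == "+", start, end - 1L)
}
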