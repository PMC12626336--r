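#' @importFrom stats median optimize pchisq phyper pnorm cor sd quantile
#'   rnbinom runif rnorm setNames complete.cases kruskal.test hclust as.dist
#'   p.adjust
#' @importFrom utils read.delim write.table head combn
NULL

#' Derive a stage-specific RNG seed from a base seed
#'
#' Hashes a stage name into the base seed so independent stochastic stages
#' draw from distinct streams while remaining reproducible from one seed.
#' The result stays below 2^31 - 1.
#'
#' @param seed base integer seed.
#' @param stage stage name.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg adjustment with input validation
#'
#' Step-up false-discovery-rate adjustment. Missing values propagate; values
#' outside \[0, 1\] are rejected rather than clamped.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return numeric vector of BH-adjusted p-values, same length as `p`.
#' @export
adjust_bh <- function(p) {
  if (!is.numeric(p)) stop("p-values must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

# 0-based half-open data.frame intervals -> GRanges (1-based inclusive)
df_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

stop_if_not_cols <- function(df, cols, what = "input") {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s is missing column(s): %s", what, paste(miss, collapse = ", ")))
  invisible(TRUE)
}
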