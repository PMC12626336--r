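# Small fixtures built in code.

# standard six-timepoint sample sheet
make_samples <- function(n_tp = 6, reps = 4, rin = NULL, seed = 1) {
  set.seed(seed)
  tps <- paste0("P", seq(0, by = 7, length.out = n_tp))
  df <- data.frame(sample = sprintf("s%02d", seq_len(n_tp * reps)),
                   timepoint = rep(tps, each = reps),
                   stringsAsFactors = FALSE)
  df$rin <- if (is.null(rin)) round(runif(nrow(df), 6.7, 10), 1) else rin
  df
}

# NB counts with an optional per-timepoint log2 effect vector
make_counts <- function(samples, n_features = 20, base_mu = 100,
                        dispersion = 0.1, log2_effect = NULL, seed = 1) {
  set.seed(seed)
  tps <- unique(as.character(samples$timepoint))
  eff <- if (is.null(log2_effect)) rep(0, length(tps)) else log2_effect
  mu <- base_mu * 2^eff[match(as.character(samples$timepoint), tps)]
  m <- t(vapply(seq_len(n_features), function(i) {
    rnbinom(nrow(samples), mu = mu, size = 1 / dispersion)
  }, numeric(nrow(samples))))
  rownames(m) <- sprintf("f%03d", seq_len(n_features))
  colnames(m) <- samples$sample
  storage.mode(m) <- "integer"
  m
}

# brute-force one-sided hypergeometric tail by direct PMF summation
hyper_tail_bruteforce <- function(k, K, n, N) {
  hi <- min(n, K)
  if (k > hi) return(0)
  i <- max(k, max(0, n + K - N)):hi
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# brute-force step-up BH definition
bh_bruteforce <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# brute-force interval overlap (0-based half-open)
overlaps_any <- function(chrom, start, end, set) {
  any(set$chrom == chrom & set$start < end & start < set$end)
}

# tiny peak-gene pairs object for unit tests
make_pairs <- function(acc, expr, peak_ids = NULL, gene_ids = NULL,
                       timepoints = NULL) {
  n <- nrow(acc)
  structure(list(
    pairs = data.frame(
      peak_id = peak_ids %||% sprintf("pk%02d", seq_len(n)),
      gene_id = gene_ids %||% sprintf("g%02d", seq_len(n)),
      stringsAsFactors = FALSE),
    acc = acc, expr = expr,
    timepoints = timepoints %||% paste0("P", seq(0, by = 7,
                                                 length.out = ncol(acc)))),
    class = "peak_gene_pairs")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
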