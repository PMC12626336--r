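# PWM motif scanning and enrichment.
#
# Motifs are scored by log2 odds against a background base distribution at
# every position of a sequence window, on both strands. A hit requires the
# score to reach a fraction of the motif's maximal attainable score.
# Enrichment of hits in a foreground set of peaks (or promoters) against the
# remaining universe is tested with a one-sided hypergeometric test.

#' Construct a position weight matrix object
#'
#' @param id motif identifier.
#' @param counts 4 x L numeric matrix (rows A, C, G, T) of counts or
#'   probabilities.
#' @param family transcription-factor family label (e.g. "TEA", "MADS").
#' @param background base frequencies (A, C, G, T), defaults to uniform.
#' @param pseudocount added to probabilities before log-odds to avoid
#'   minus-infinity cells.
#' @param threshold_frac default hit threshold as a fraction of the motif's
#'   maximal log-odds score.
#' @return object of class `pwm` with probability matrix, log2-odds matrix,
#'   consensus string and maximal score.
#' @export
make_pwm <- function(id, counts, family = "unassigned",
                     background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                     pseudocount = 0.01, threshold_frac = 0.6) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stop("PWM counts must have 4 rows (A, C, G, T)")
  if (ncol(counts) < 4) stop("PWM must span at least 4 positions")
  rownames(counts) <- c("A", "C", "G", "T")
  ppm_raw <- sweep(counts, 2, colSums(counts), "/")
  ppm <- sweep(ppm_raw + pseudocount, 2, colSums(ppm_raw + pseudocount), "/")
  lo <- log2(ppm / background)
  consensus <- paste(rownames(ppm)[apply(ppm, 2, which.max)], collapse = "")
  structure(list(id = id, family = family, ppm = ppm, ppm_raw = ppm_raw,
                 log_odds = lo, background = background,
                 consensus = consensus, max_score = sum(apply(lo, 2, max)),
                 threshold_frac = threshold_frac),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM %s (%s), length %d, consensus %s\n",
              x$id, x$family, ncol(x$ppm), x$consensus))
  invisible(x)
}

#' Build a PWM from a consensus string
#'
#' Each consensus base receives probability `strength`; the remainder is
#' split evenly over the other three bases.
#'
#' @param id motif identifier.
#' @param consensus consensus sequence (ACGT).
#' @param family family label.
#' @param strength probability of the consensus base at each position.
#' @inheritParams make_pwm
#' @return a `pwm` object.
#' @export
pwm_from_consensus <- function(id, consensus, family = "unassigned",
                               strength = 0.85, ...) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T")))
    stop("consensus must contain only ACGT")
  m <- matrix((1 - strength) / 3, nrow = 4, ncol = length(bases),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(bases)) m[bases[j], j] <- strength
  make_pwm(id, m, family = family, ...)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# reverse-complement a log-odds matrix: reverse positions, swap A<->T, C<->G
rc_matrix <- function(m) {
  m[c("T", "G", "C", "A"), rev(seq_len(ncol(m))), drop = FALSE]
}

seq_to_index <- function(s) {
  idx <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
  idx  # NA for N or other letters
}

score_positions <- function(idx, lo) {
  L <- ncol(lo)
  n <- length(idx) - L + 1
  if (n < 1) return(numeric(0))
  sc <- numeric(n)
  for (j in seq_len(L)) {
    v <- lo[, j][idx[j:(j + n - 1)]]
    v[is.na(v)] <- -Inf  # ambiguous base disqualifies the window
    sc <- sc + v
  }
  sc
}

#' Scan sequence windows for PWM hits
#'
#' Scores every position of every window on both strands with log2 odds
#' against the PWM background; positions scoring at least
#' `threshold_frac * max_score` are reported. Overlapping hits of the same
#' motif on the same strand within 1 bp are collapsed to the best-scoring
#' one. Offsets are reported relative to the window center (the peak summit
#' for summit-centered windows, the TSS for promoter windows), measured at
#' the motif midpoint.
#'
#' @param windows named character vector of uppercase ACGTN sequences, all
#'   centered on the feature of interest.
#' @param pwms a `pwm` object or list of them.
#' @param threshold_frac hit threshold as a fraction of each motif's maximal
#'   score; defaults to the PWM's own setting.
#' @return data.frame with id, motif, family, start (0-based within the
#'   window), offset (motif midpoint minus window center), strand, score.
#' @export
scan_pwm <- function(windows, pwms, threshold_frac = NULL) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  if (is.null(names(windows)))
    names(windows) <- paste0("seq_", seq_along(windows))
  res <- list()
  for (pwm in pwms) {
    if (pwm$max_score <= 0) next  # indistinguishable from background
    thr_frac <- threshold_frac %||% pwm$threshold_frac
    thr <- thr_frac * pwm$max_score
    L <- ncol(pwm$log_odds)
    lo_f <- pwm$log_odds
    lo_r <- rc_matrix(pwm$log_odds)
    for (w in names(windows)) {
      s <- windows[[w]]
      width <- nchar(s)
      if (width < L) next
      idx <- seq_to_index(s)
      center <- width %/% 2
      for (strand in c("+", "-")) {
        sc <- score_positions(idx, if (strand == "+") lo_f else lo_r)
        hit <- which(sc >= thr)
        if (!length(hit)) next
        df <- data.frame(id = w, motif = pwm$id, family = pwm$family,
                         start = hit - 1L,
                         offset = (hit - 1L) + L %/% 2 - center,
                         strand = strand, score = sc[hit],
                         stringsAsFactors = FALSE)
        res[[length(res) + 1L]] <- collapse_hits(df)
      }
    }
  }
  if (!length(res))
    return(data.frame(id = character(), motif = character(),
                      family = character(), start = integer(),
                      offset = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# keep the best of runs of same-motif same-strand hits within 1 bp
collapse_hits <- function(df) {
  df <- df[order(df$start), ]
  kept <- integer(0)
  for (r in seq_len(nrow(df))) {
    tail_idx <- if (length(kept)) kept[length(kept)] else NA_integer_
    if (!is.na(tail_idx) && df$start[r] - df$start[tail_idx] <= 1) {
      if (df$score[r] > df$score[tail_idx]) kept[length(kept)] <- r
    } else {
      kept <- c(kept, r)
    }
  }
  df[kept, , drop = FALSE]
}

#' Histogram of motif-hit distances from the peak summit
#'
#' @param hits data.frame from [scan_pwm()] on summit-centered windows.
#' @param bin_width,max_dist histogram bins for `|offset|` (defaults 25 bp
#'   bins from 0 to 250).
#' @return list with `histogram` (bin start, bin end, count) and
#'   `frac_within_100`, the fraction of hits within 100 bp of the summit.
#' @export
summit_distance_profile <- function(hits, bin_width = 25, max_dist = 250) {
  d <- abs(hits$offset)
  edges <- seq(0, max_dist, by = bin_width)
  counts <- vapply(seq_len(length(edges) - 1), function(i) {
    sum(d >= edges[i] & d < edges[i + 1])
  }, integer(1))
  list(histogram = data.frame(from = edges[-length(edges)],
                              to = edges[-1], count = counts),
       frac_within_100 = if (length(d)) mean(d <= 100) else NA_real_)
}

hyper_test <- function(k, K, n, N) {
  # one-sided enrichment: P(X >= k) for X ~ Hypergeometric(N, K, n)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Motif enrichment in a foreground peak set
#'
#' For each motif, counts the peaks carrying at least one hit in the
#' foreground and in the whole universe and computes a one-sided
#' hypergeometric enrichment p-value, BH-adjusted across motifs. The q-value
#' column equals the BH-adjusted p. Significance is gated at
#' `padj < 0.01` and `q < 0.05`.
#'
#' @param hits data.frame from [scan_pwm()].
#' @param foreground character vector of foreground unit ids (peaks or
#'   genes); must be a subset of `universe`.
#' @param universe character vector of all unit ids; the background is
#'   `universe` minus `foreground`.
#' @return data.frame with motif, family, counts, p, padj, q, significant.
#' @export
motif_enrichment <- function(hits, foreground, universe) {
  if (!length(foreground)) stop("empty foreground set")
  if (length(universe) < 2) stop("degenerate universe (fewer than 2 units)")
  if (!all(foreground %in% universe))
    stop("foreground must be a subset of the universe")
  N <- length(unique(universe)); n <- length(unique(foreground))
  motifs <- unique(hits$motif)
  rows <- lapply(motifs, function(m) {
    with_hit <- unique(hits$id[hits$motif == m])
    K <- sum(universe %in% with_hit)
    k <- sum(foreground %in% with_hit)
    data.frame(motif = m,
               family = hits$family[match(m, hits$motif)],
               n_fg = n, n_fg_hit = k, n_universe = N, n_universe_hit = K,
               p = hyper_test(k, K, n, N), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(motif = character(), family = character(),
                      n_fg = integer(), n_fg_hit = integer(),
                      n_universe = integer(), n_universe_hit = integer(),
                      p = numeric(), stringsAsFactors = FALSE)
  out$padj <- adjust_bh(out$p)
  out$q <- out$padj
  out$significant <- out$padj < 0.01 & out$q < 0.05
  rownames(out) <- NULL
  out[order(out$p), ]
}

#' Motif enrichment in promoter windows
#'
#' Identical statistic to [motif_enrichment()] with genes as the counting
#' unit: `hits` must come from scanning promoter windows named by gene id.
#'
#' @param hits promoter-scan hits (ids are gene ids).
#' @param module_genes genes of the module under test.
#' @param universe_genes all genes considered.
#' @return as [motif_enrichment()].
#' @export
promoter_enrichment <- function(hits, module_genes, universe_genes) {
  motif_enrichment(hits, module_genes, universe_genes)
}

#' Family-level motif enrichment
#'
#' Pools motifs into families: a unit carries a family hit if any member
#' motif hits it. The hypergeometric test is run on the pooled indicator and
#' the best (smallest-p) member motif is reported per family.
#'
#' @param hits data.frame from [scan_pwm()].
#' @param family_map data.frame with columns `motif` and `family`; motifs
#'   absent from the map are grouped as "unassigned" with a warning.
#' @inheritParams motif_enrichment
#' @return data.frame with family, member count, counts, p, padj, q,
#'   best_motif.
#' @export
family_aggregate <- function(hits, family_map, foreground, universe) {
  if (!length(foreground)) stop("empty foreground set")
  hits <- hits[hits$motif %in% unique(hits$motif), , drop = FALSE]
  fam <- family_map$family[match(hits$motif, family_map$motif)]
  if (anyNA(fam)) {
    warning("motif(s) missing from family map grouped as 'unassigned': ",
            paste(unique(hits$motif[is.na(fam)]), collapse = ", "))
    fam[is.na(fam)] <- "unassigned"
  }
  hits$family <- fam
  per_motif <- motif_enrichment(hits, foreground, universe)
  N <- length(unique(universe)); n <- length(unique(foreground))
  rows <- lapply(split(hits, hits$family), function(h) {
    with_hit <- unique(h$id)
    K <- sum(universe %in% with_hit)
    k <- sum(foreground %in% with_hit)
    members <- unique(h$motif)
    best <- per_motif$motif[per_motif$motif %in% members][1]
    data.frame(family = h$family[1], n_members = length(members),
               n_fg = n, n_fg_hit = k, n_universe = N, n_universe_hit = K,
               p = hyper_test(k, K, n, N), best_motif = best,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- adjust_bh(out$p)
  out$q <- out$padj
  out$significant <- out$padj < 0.01 & out$q < 0.05
  rownames(out) <- NULL
  out[order(out$p), ]
}
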