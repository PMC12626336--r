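# Peak-gene integration.
#
# Differentially accessible peaks are linked to their assigned nearest
# gene; accessibility and expression are reduced to per-timepoint means of
# quantile-normalized log2 CPM on the timepoints shared by both assays
# (replicate counts differ between assays and a timepoint may be missing
# from one of them), and each pair is scored by the Pearson correlation of
# the two temporal profiles. Pairs with r > 0.5 are putative activating
# (enhancer-like) links, r < -0.5 putative repressive links; positive pairs
# are re-clustered on their joint profiles.

tp_means <- function(mat, timepoints, shared) {
  tp <- as.character(timepoints)
  out <- vapply(shared, function(t) {
    cols <- tp == t
    rowMeans(mat[, cols, drop = FALSE])
  }, numeric(nrow(mat)))
  matrix(out, nrow = nrow(mat),
         dimnames = list(rownames(mat), shared))
}

zscore_rows <- function(m) {
  mu <- rowMeans(m); s <- apply(m, 1, sd)
  s[s == 0] <- 1
  z <- sweep(sweep(m, 1, mu, "-"), 1, s, "/")
  z[apply(m, 1, sd) == 0, ] <- 0
  z
}

#' Build peak-gene pairs from DA peaks and their assigned genes
#'
#' Emits one pair per (DA peak, assigned nearest gene) for genes whose
#' expression is detected at every shared timepoint. Profiles are
#' per-timepoint means of quantile-normalized log2 CPM, restricted to
#' timepoints present in both assays.
#'
#' @param annotation peak annotation from [annotate_peaks()] (peak_id,
#'   nearest_gene).
#' @param da_peaks character vector of differentially accessible peak ids.
#' @param rna_counts,rna_samples full RNA count matrix and sample sheet.
#' @param atac_counts,atac_samples full reads-in-peaks matrix and sample
#'   sheet.
#' @return object of class `peak_gene_pairs`: `pairs` data.frame (peak_id,
#'   gene_id), profile matrices `acc` and `expr` (pairs x shared
#'   timepoints), and `timepoints`.
#' @export
pair_peaks_genes <- function(annotation, da_peaks, rna_counts, rna_samples,
                             atac_counts, atac_samples) {
  shared <- intersect(unique(as.character(rna_samples$timepoint)),
                      unique(as.character(atac_samples$timepoint)))
  if (!length(shared)) stop("no timepoint shared between the two assays")
  ann <- annotation[annotation$peak_id %in% da_peaks &
                      !is.na(annotation$nearest_gene), , drop = FALSE]
  ann <- ann[ann$nearest_gene %in% rownames(rna_counts), , drop = FALSE]
  ## expression detected throughout: positive mean raw count at every shared tp
  raw_tp <- tp_means(rna_counts[unique(ann$nearest_gene), , drop = FALSE],
                     rna_samples$timepoint, shared)
  detected <- rownames(raw_tp)[apply(raw_tp > 0, 1, all)]
  ann <- ann[ann$nearest_gene %in% detected, , drop = FALSE]
  if (!nrow(ann)) {
    return(structure(list(pairs = data.frame(peak_id = character(),
                                             gene_id = character(),
                                             stringsAsFactors = FALSE),
                          acc = NULL, expr = NULL, timepoints = shared),
                     class = "peak_gene_pairs"))
  }
  norm_assay <- function(counts, samples, features) {
    x <- log2(cpm(counts) + 1)
    x <- limma::normalizeQuantiles(x, ties = TRUE)
    tp_means(x[features, , drop = FALSE], samples$timepoint, shared)
  }
  acc <- norm_assay(atac_counts, atac_samples, ann$peak_id)
  expr <- norm_assay(rna_counts, rna_samples, ann$nearest_gene)
  pairs <- data.frame(peak_id = ann$peak_id, gene_id = ann$nearest_gene,
                      tss_distance = ann$distance %||% NA_real_,
                      stringsAsFactors = FALSE)
  rownames(acc) <- rownames(expr) <- NULL
  structure(list(pairs = pairs, acc = acc, expr = expr, timepoints = shared),
            class = "peak_gene_pairs")
}

#' Pearson correlation between accessibility and expression profiles
#'
#' Requires at least three shared timepoints; zero-variance profiles leave
#' the pair's correlation undefined (NA) with a warning.
#'
#' @param pg a `peak_gene_pairs` object.
#' @return the object with an `r` column added to `pairs`.
#' @export
pair_correlation <- function(pg) {
  if (length(pg$timepoints) < 3)
    stop("correlation needs at least three shared timepoints")
  n <- nrow(pg$pairs)
  r <- rep(NA_real_, n)
  degenerate <- 0L
  for (i in seq_len(n)) {
    a <- pg$acc[i, ]; e <- pg$expr[i, ]
    if (sd(a) == 0 || sd(e) == 0) { degenerate <- degenerate + 1L; next }
    r[i] <- cor(a, e)
  }
  if (degenerate)
    warning(degenerate, " pair(s) with a zero-variance profile left unclassified")
  pg$pairs$r <- r
  pg
}

#' Classify pairs by correlation sign
#'
#' Strict thresholds: positive iff r > `threshold`, negative iff
#' r < `-threshold`, otherwise (including undefined r) unclassified.
#'
#' @param pg a `peak_gene_pairs` object with correlations.
#' @param threshold classification cutoff (default 0.5).
#' @return the object with a `class` column added to `pairs`.
#' @export
classify_pairs <- function(pg, threshold = 0.5) {
  if (is.null(pg$pairs$r)) pg <- pair_correlation(pg)
  r <- pg$pairs$r
  cls <- rep("unclassified", length(r))
  cls[!is.na(r) & r > threshold] <- "positive"
  cls[!is.na(r) & r < -threshold] <- "negative"
  pg$pairs$class <- cls
  pg
}

pair_feature_matrix <- function(pg, idx) {
  m <- cbind(zscore_rows(pg$acc[idx, , drop = FALSE]),
             zscore_rows(pg$expr[idx, , drop = FALSE]))
  rownames(m) <- paste(pg$pairs$peak_id[idx], pg$pairs$gene_id[idx], sep = "|")
  m
}

#' Co-cluster positively correlated pairs
#'
#' Each positive pair is represented by the concatenation of its z-scored
#' accessibility and expression profiles and clustered with
#' [pam_cluster()].
#'
#' @param pg a classified `peak_gene_pairs` object.
#' @param k number of modules (default 5).
#' @return list with `modules` (a `pam_modules` object) and `pairs`, the
#'   positive-pair table annotated with module labels.
#' @export
cocluster_pairs <- function(pg, k = 5) {
  if (is.null(pg$pairs$class)) pg <- classify_pairs(pg)
  idx <- which(pg$pairs$class == "positive")
  if (length(idx) < k)
    stop(sprintf("need at least k = %d positive pairs, have %d", k, length(idx)))
  m <- pair_feature_matrix(pg, idx)
  if (all(apply(m, 1, function(x) all(x == m[1, ])))) {
    warning("all pairs identical; a single effective module is returned")
    k <- 1
  }
  mods <- pam_cluster(m, k = k)
  pairs <- pg$pairs[idx, , drop = FALSE]
  pairs$module <- mods$assignment$module
  rownames(pairs) <- NULL
  list(modules = mods, pairs = pairs)
}

#' Subset positive pairs by motif family and re-cluster
#'
#' Keeps positive pairs whose peak carries at least one hit from any motif
#' of the given family and re-clusters their joint profiles.
#'
#' @param pg a classified `peak_gene_pairs` object.
#' @param hits motif hits from [scan_pwm()] on peak windows.
#' @param family_map data.frame mapping `motif` to `family`.
#' @param family family label to keep (default "TEA").
#' @param k number of modules (default 2).
#' @return as [cocluster_pairs()], restricted to the subset.
#' @export
subset_by_motif_family <- function(pg, hits, family_map, family = "TEA",
                                   k = 2) {
  if (is.null(pg$pairs$class)) pg <- classify_pairs(pg)
  members <- family_map$motif[family_map$family == family]
  with_hit <- unique(hits$id[hits$motif %in% members])
  idx <- which(pg$pairs$class == "positive" & pg$pairs$peak_id %in% with_hit)
  if (!length(idx))
    stop(sprintf("no positive pair carries a %s-family motif hit", family))
  if (length(idx) < k) k <- length(idx)
  m <- pair_feature_matrix(pg, idx)
  mods <- pam_cluster(m, k = k)
  pairs <- pg$pairs[idx, , drop = FALSE]
  pairs$module <- mods$assignment$module
  rownames(pairs) <- NULL
  list(modules = mods, pairs = pairs)
}
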