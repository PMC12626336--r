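# Temporal module discovery.
#
# Significant features (DE genes or DA peaks) are normalized through
# CPM -> log2(x + 1) -> column quantile normalization -> row z-score, then
# clustered by partitioning around medoids (PAM: greedy BUILD seeding
# followed by best-improvement SWAP to a local optimum of total
# within-cluster dissimilarity) over Pearson distances, with fuzzy
# membership weights derived from medoid distances.

#' Normalization chain for clustering
#'
#' Applies, in order: size-factor CPM, log2(x + 1), column quantile
#' normalization (ties receive the average of the tied ranks' reference
#' values), and row z-scoring. Constant rows get z = 0 with a warning.
#'
#' @param counts feature x sample count matrix (normally restricted to
#'   significant features).
#' @param sf per-sample size factors (defaults to [size_factors()]).
#' @return numeric matrix with rows of mean 0 and sd 1; the applied steps
#'   are recorded in the `"steps"` attribute.
#' @export
normalize_for_clustering <- function(counts, sf = size_factors(counts)) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("normalization needs at least two samples")
  x <- log2(cpm(counts, sf) + 1)
  x <- limma::normalizeQuantiles(x, ties = TRUE)
  mu <- rowMeans(x)
  s <- apply(x, 1, sd)
  const <- s == 0
  if (any(const)) {
    warning(sum(const), " constant row(s) z-scored to 0")
    s[const] <- 1
  }
  z <- sweep(sweep(x, 1, mu, "-"), 1, s, "/")
  z[const, ] <- 0
  attr(z, "steps") <- c("cpm", "log2p1", "quantile", "zscore")
  z
}

#' Pearson distance matrix between feature profiles
#'
#' d(a, b) = 1 - r(a, b), in \[0, 2\]. Zero-variance rows get distance 1 to
#' every other row (uncorrelated convention) with a warning.
#'
#' @param mat feature x sample numeric matrix (>= 2 columns).
#' @return symmetric distance matrix with zero diagonal.
#' @export
pearson_distance <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("Pearson distance needs at least two columns")
  r <- suppressWarnings(cor(t(mat)))
  if (anyNA(r)) {
    warning("zero-variance row(s); their distances set to 1")
    r[is.na(r)] <- 0
  }
  d <- 1 - r
  diag(d) <- 0
  d
}

pam_cost <- function(d, medoids) {
  sum(do.call(pmin, lapply(medoids, function(m) d[, m])))
}

pam_build <- function(d, k, first) {
  medoids <- first
  n <- nrow(d)
  while (length(medoids) < k) {
    nearest <- do.call(pmin, lapply(medoids, function(m) d[, m]))
    gain <- vapply(seq_len(n), function(j) {
      if (j %in% medoids) return(-Inf)
      sum(pmax(0, nearest - d[, j]))
    }, numeric(1))
    medoids <- c(medoids, which.max(gain))
  }
  medoids
}

pam_swap <- function(d, medoids) {
  n <- nrow(d)
  cost <- pam_cost(d, medoids)
  repeat {
    best <- list(delta = 0)
    for (mi in seq_along(medoids)) {
      for (h in setdiff(seq_len(n), medoids)) {
        cand <- medoids; cand[mi] <- h
        delta <- pam_cost(d, cand) - cost
        if (delta < best$delta - 1e-12) best <- list(delta = delta, cand = cand)
      }
    }
    if (best$delta >= 0) break
    stopifnot(pam_cost(d, best$cand) <= cost)  # cost is non-increasing
    medoids <- best$cand
    cost <- cost + best$delta
  }
  list(medoids = medoids, cost = cost)
}

#' PAM clustering with fuzzy membership weights
#'
#' Partitioning around medoids on a distance matrix: BUILD greedily seeds
#' medoids (first the point minimizing total distance, then the point
#' yielding the largest cost reduction, ties to the lowest index), SWAP
#' repeatedly applies the best improving medoid/non-medoid exchange until no
#' swap lowers the total within-cluster dissimilarity. Deterministic given
#' the input order. Fuzzy weights are proportional to the reciprocal
#' distance to each medoid (weight 1 on the medoid itself for exact
#' matches), normalized to sum to one; the hard label is always the argmax
#' of the weights.
#'
#' @param x feature x sample matrix (distances computed with
#'   [pearson_distance()]) or a precomputed symmetric distance matrix when
#'   `diss = TRUE`.
#' @param k number of modules (1 <= k <= number of features).
#' @param diss is `x` already a distance matrix?
#' @param restart_limit problem size up to which every point is tried as
#'   the BUILD seed and the best local optimum kept (deterministic
#'   multi-start; single-start local search above this size).
#' @return object of class `pam_modules`: `assignment` data.frame (feature,
#'   module, dist_to_medoid, is_medoid), `weights` matrix (features x k),
#'   `medoids` (feature ids), `cost`, `k`.
#' @export
pam_cluster <- function(x, k, diss = FALSE, restart_limit = 60) {
  d <- if (diss) as.matrix(x) else pearson_distance(x)
  n <- nrow(d)
  if (k < 1 || k > n) stop("k must lie between 1 and the number of features")
  ids <- rownames(d) %||% as.character(seq_len(n))
  ## BUILD (seeded at the point of minimal total distance) then SWAP
  sol <- pam_swap(d, pam_build(d, k, which.min(rowSums(d))))
  ## single-start BUILD+SWAP is a local search; on small problems (where
  ## the basins of attraction are few and shallow) every point is tried as
  ## the seed and the best local optimum kept, deterministically
  if (n <= restart_limit && k < n) {
    for (first in seq_len(n)) {
      cand <- pam_swap(d, pam_build(d, k, first))
      if (cand$cost < sol$cost - 1e-12) sol <- cand
    }
  }
  medoids <- sort(sol$medoids)
  dm <- d[, medoids, drop = FALSE]
  module <- max.col(-dm, ties.method = "first")
  ## fuzzy weights: reciprocal medoid distance, exact matches get weight 1
  w <- apply(dm, 1, function(row) {
    zero <- row <= 1e-12
    if (any(zero)) as.numeric(zero) / sum(zero)
    else (1 / row) / sum(1 / row)
  })
  w <- if (k == 1) matrix(w, ncol = 1) else t(w)
  colnames(w) <- paste0("module", seq_len(k))
  rownames(w) <- ids
  hard <- max.col(w, ties.method = "first")
  assignment <- data.frame(feature = ids, module = hard,
                           dist_to_medoid = dm[cbind(seq_len(n), hard)],
                           is_medoid = seq_len(n) %in% medoids,
                           stringsAsFactors = FALSE)
  structure(list(assignment = assignment, weights = w,
                 medoids = ids[medoids], cost = pam_cost(d, medoids), k = k),
            class = "pam_modules")
}

#' @export
print.pam_modules <- function(x, ...) {
  cat(sprintf("PAM clustering: %d features in %d modules (cost %.4f)\n",
              nrow(x$assignment), x$k, x$cost))
  print(table(module = x$assignment$module))
  invisible(x)
}

#' Within-module display ordering by average-linkage subclustering
#'
#' Orders the features of one module by the leaf order of average-linkage
#' hierarchical clustering on their Pearson distances, as used to arrange
#' heatmap rows.
#'
#' @param mat feature x sample matrix restricted to one module.
#' @return list with `order` (feature ids in leaf order) and the `hclust`
#'   object (NULL for singletons).
#' @export
subcluster_order <- function(mat) {
  mat <- as.matrix(mat)
  ids <- rownames(mat) %||% as.character(seq_len(nrow(mat)))
  if (nrow(mat) < 2) return(list(order = ids, hclust = NULL))
  hc <- hclust(as.dist(pearson_distance(mat)), method = "average")
  list(order = ids[hc$order], hclust = hc)
}

#' Adjusted Rand index between two labelings
#'
#' Permutation-invariant agreement between cluster assignments; 1 for
#' identical partitions, ~0 for independent ones.
#'
#' @param a,b vectors of cluster labels of equal length.
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- ch2(sum(tab))
  expected <- sum_a * sum_b / n
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
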