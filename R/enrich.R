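# Gene-set over-representation and small-sample qPCR statistics.

#' Gene-set over-representation analysis
#'
#' One-sided hypergeometric test of the overlap between a module and each
#' gene set, BH-adjusted across sets. The universe defaults to all detected
#' features (the conventional conservative background); the module must be
#' a subset of it. The gene ratio (overlap / module size) is reported.
#' Significance is gated at `padj < 0.01` and `q < 0.05`.
#'
#' @param module character vector of module gene ids.
#' @param collection named list of gene sets (e.g. from [read_gmt()]).
#' @param universe character vector of all eligible gene ids.
#' @return data.frame with set, set size (restricted to the universe),
#'   overlap, gene_ratio, p, padj, q, significant, ordered by p.
#' @export
ora <- function(module, collection, universe) {
  module <- unique(module); universe <- unique(universe)
  if (!length(module)) stop("empty module")
  if (!all(module %in% universe))
    stop("module must be a subset of the universe")
  N <- length(universe); n <- length(module)
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(unique(collection[[nm]]), universe)
    k <- length(intersect(module, set))
    data.frame(set = nm, set_size = length(set), overlap = k,
               gene_ratio = k / n,
               p = hyper_test(k, length(set), n, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- adjust_bh(out$p)
  out$q <- out$padj
  out$significant <- out$padj < 0.01 & out$q < 0.05
  rownames(out) <- NULL
  out[order(out$p), ]
}

#' Delta-delta-Ct relative expression
#'
#' Technical replicates are collapsed by mean; per sample,
#' `dct = Ct_target - Ct_reference`; `ddct = dct - mean(dct in the
#' calibrator group)`; fold change `2^(-ddct)`. Downstream group statistics
#' should operate on the `dct` values.
#'
#' @param ct data.frame with columns sample, timepoint (or group), ct_target
#'   and ct_reference (reference-gene cycles, e.g. Ppia); technical
#'   replicates may appear as repeated sample rows.
#' @param calibrator the timepoint/group used as calibrator.
#' @return data.frame with sample, timepoint, dct, ddct, fold.
#' @export
ddct <- function(ct, calibrator) {
  stop_if_not_cols(ct, c("sample", "timepoint", "ct_target", "ct_reference"),
                   "Ct table")
  miss <- is.na(ct$ct_reference)
  if (any(miss)) {
    warning(sum(miss), " sample row(s) without reference Ct dropped")
    ct <- ct[!miss, , drop = FALSE]
  }
  agg <- stats::aggregate(cbind(ct_target, ct_reference) ~ sample + timepoint,
                          data = ct, FUN = mean)
  agg$dct <- agg$ct_target - agg$ct_reference
  cal <- agg$dct[as.character(agg$timepoint) == as.character(calibrator)]
  if (!length(cal)) stop("calibrator group absent from Ct table")
  agg$ddct <- agg$dct - mean(cal)
  agg$fold <- 2^(-agg$ddct)
  agg[, c("sample", "timepoint", "dct", "ddct", "fold")]
}

#' Kruskal-Wallis test with Dunn post-hoc comparisons
#'
#' Overall Kruskal-Wallis rank-sum test (midranks, tie-corrected) followed
#' by pairwise Dunn z tests on rank means with the tie-corrected variance,
#' BH-adjusted across pairs.
#'
#' @param values numeric observations.
#' @param groups group labels, same length as `values`; every group needs
#'   at least two observations.
#' @return list with `kw` (statistic, df, p) and `pairs` data.frame
#'   (group_a, group_b, z, p, padj).
#' @export
kw_dunn <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  sizes <- table(groups)
  if (any(sizes < 2))
    stop("group(s) with fewer than two observations: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  kw <- kruskal.test(values, groups)
  N <- length(values)
  rk <- rank(values)  # midranks
  ties <- table(values)
  tie_term <- sum(ties^3 - ties)
  mean_rank <- tapply(rk, groups, mean)
  lev <- levels(groups)
  combos <- combn(lev, 2)
  z <- apply(combos, 2, function(pr) {
    a <- pr[1]; b <- pr[2]
    se <- sqrt((N * (N + 1) / 12 - tie_term / (12 * (N - 1))) *
                 (1 / sizes[[a]] + 1 / sizes[[b]]))
    (mean_rank[[a]] - mean_rank[[b]]) / se
  })
  p <- 2 * pnorm(-abs(z))
  pairs <- data.frame(group_a = combos[1, ], group_b = combos[2, ],
                      z = as.numeric(z), p = p, padj = adjust_bh(p),
                      stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  list(kw = list(stat = unname(kw$statistic), df = unname(kw$parameter),
                 p = kw$p.value),
       pairs = pairs)
}
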