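# Consensus peak construction and annotation.
#
# All interval columns are 0-based half-open (BED arithmetic); overlap means
# at least one shared base. A consensus peak must be supported by every
# replicate of at least one timepoint and is emitted at a fixed width
# centered on the best-scoring summit of its merged region. Peaks are
# annotated by strand-aware summit-to-TSS distance with a nearest-gene
# assignment capped at +/- 50 kb.

#' Remove peaks overlapping blacklist or naked-DNA control regions
#'
#' Any peak sharing at least one base with a blacklist interval or a peak
#' called from the naked-DNA (Tn5 bias) control is deemed spurious and
#' dropped. Order-preserving and idempotent.
#'
#' @param peaks data.frame of peak calls (chrom, start, end, ...).
#' @param blacklist,control_peaks data.frames of intervals (chrom, start,
#'   end); either may be empty or NULL.
#' @return the surviving rows of `peaks`.
#' @export
filter_spurious <- function(peaks, blacklist = NULL, control_peaks = NULL) {
  bad <- rbind(
    if (!is.null(blacklist) && nrow(blacklist))
      blacklist[, c("chrom", "start", "end")],
    if (!is.null(control_peaks) && nrow(control_peaks))
      control_peaks[, c("chrom", "start", "end")])
  if (is.null(bad) || !nrow(bad) || !nrow(peaks)) return(peaks)
  if (!any(bad$chrom %in% peaks$chrom)) {
    pc <- table(peaks$chrom); bc <- table(bad$chrom)
    warning("no chromosome shared between peaks and filter sets; peaks: ",
            paste(sprintf("%s=%d", names(pc), pc), collapse = ", "),
            "; filters: ",
            paste(sprintf("%s=%d", names(bc), bc), collapse = ", "))
  }
  ov <- GenomicRanges::findOverlaps(df_to_granges(peaks), df_to_granges(bad))
  drop <- unique(S4Vectors::queryHits(ov))
  if (length(drop)) peaks[-drop, , drop = FALSE] else peaks
}

#' Build a fixed-width consensus peak set
#'
#' Overlapping peak calls across replicates and timepoints are merged into
#' candidate regions. A candidate enters the consensus set only if, for at
#' least one timepoint, every replicate of that timepoint contributes an
#' overlapping call; peaks failing this reproducibility rule are excluded.
#' Each consensus peak is re-centered to `width` bp around the merged
#' region's representative summit (the summit of the highest-scoring
#' supporting call; ties break to the leftmost summit). Timepoints with a
#' single replicate are excluded with a warning.
#'
#' @param calls data.frame of peak calls with chrom, start, end, summit,
#'   score, timepoint, replicate.
#' @param width emitted consensus width in bp (default 500).
#' @return data.frame with peak_id, chrom, start, end, summit, n_support and
#'   a comma-separated `support` provenance column of timepoint:replicate
#'   pairs.
#' @export
build_consensus <- function(calls, width = 500) {
  stop_if_not_cols(calls, c("chrom", "start", "end", "summit", "score",
                            "timepoint", "replicate"), "peak calls")
  calls$timepoint <- as.character(calls$timepoint)
  reps_per_tp <- lapply(split(calls$replicate, calls$timepoint), unique)
  single <- names(reps_per_tp)[vapply(reps_per_tp, length, integer(1)) < 2]
  if (length(single)) {
    warning("timepoint(s) with a single replicate excluded from consensus: ",
            paste(single, collapse = ", "))
    calls <- calls[!calls$timepoint %in% single, , drop = FALSE]
    reps_per_tp <- reps_per_tp[setdiff(names(reps_per_tp), single)]
  }
  if (!nrow(calls)) stop("no timepoint with two replicates; consensus undefined")
  gr <- df_to_granges(calls)
  merged <- GenomicRanges::reduce(gr)
  ov <- GenomicRanges::findOverlaps(merged, gr)
  by_region <- split(S4Vectors::subjectHits(ov), S4Vectors::queryHits(ov))
  half <- width %/% 2
  rows <- lapply(by_region, function(idx) {
    sub <- calls[idx, , drop = FALSE]
    supported <- FALSE
    for (tp in unique(sub$timepoint)) {
      have <- unique(sub$replicate[sub$timepoint == tp])
      if (all(reps_per_tp[[tp]] %in% have)) { supported <- TRUE; break }
    }
    if (!supported) return(NULL)
    best <- which(sub$score == max(sub$score))
    rep_summit <- min(sub$summit[best])  # ties -> leftmost summit
    support <- sort(unique(sprintf("%s:%s", sub$timepoint, sub$replicate)))
    data.frame(chrom = sub$chrom[1], start = rep_summit - half,
               end = rep_summit - half + width, summit = rep_summit,
               n_support = length(support),
               support = paste(support, collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(peak_id = character(), chrom = character(),
                      start = integer(), end = integer(), summit = integer(),
                      n_support = integer(), support = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), ]
  out <- data.frame(peak_id = sprintf("consensus_%05d", seq_len(nrow(out))),
                    out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Count fragments in consensus peaks by midpoint containment
#'
#' A fragment is assigned to a peak when its midpoint (floor of the interval
#' midpoint) lies inside the half-open peak interval, so a midpoint exactly
#' at `start` counts and one at `end` does not.
#'
#' @param fragments named list of data.frames (chrom, start, end), one per
#'   replicate/sample.
#' @param peaks consensus peak data.frame from [build_consensus()].
#' @return integer matrix, peaks x replicates.
#' @export
count_in_peaks <- function(fragments, peaks) {
  if (is.data.frame(fragments)) fragments <- list(sample1 = fragments)
  pk <- df_to_granges(peaks)
  out <- matrix(0L, nrow(peaks), length(fragments),
                dimnames = list(peaks$peak_id,
                                names(fragments) %||%
                                  paste0("rep", seq_along(fragments))))
  for (j in seq_along(fragments)) {
    fr <- fragments[[j]]
    if (is.null(fr) || !nrow(fr)) next
    mid <- (fr$start + fr$end) %/% 2L
    pts <- GenomicRanges::GRanges(fr$chrom,
                                  IRanges::IRanges(mid + 1L, width = 1L))
    ov <- GenomicRanges::findOverlaps(pk, pts)
    tab <- table(S4Vectors::queryHits(ov))
    out[as.integer(names(tab)), j] <- as.integer(tab)
  }
  out
}

#' Differential accessibility across timepoints
#'
#' Runs the nested NB likelihood-ratio test on reads-in-peaks counts with
#' full model = timepoint and reduced model = intercept (no quality
#' covariate is measured for ATAC libraries).
#'
#' @param counts peaks x samples count matrix.
#' @param samples ATAC sample sheet with `timepoint` (and `replicate`).
#' @param alpha adjusted-p significance threshold.
#' @param filter apply independent filtering.
#' @return data.frame as [de_timecourse()].
#' @export
differential_accessibility <- function(counts, samples, alpha = 0.05,
                                       filter = TRUE) {
  tp <- as.character(samples$timepoint)
  if (length(unique(tp)) < 2)
    stop("differential accessibility needs at least two timepoints")
  few <- names(which(table(tp) < 2))
  if (length(few))
    stop("timepoint(s) with fewer than two replicates: ",
         paste(few, collapse = ", "))
  de_timecourse(counts, samples, use_rin = FALSE, alpha = alpha,
                filter = filter)
}

tss_bins_kb <- c(0, 1, 3, 5, 10, 100, Inf)

bin_tss_distance <- function(d) {
  akb <- abs(d) / 1000
  i <- findInterval(akb, tss_bins_kb, rightmost.closed = FALSE,
                    left.open = FALSE)
  i <- pmin(i, length(tss_bins_kb) - 1)
  lab <- sprintf("%g-%g kb", tss_bins_kb[i], tss_bins_kb[i + 1])
  lab[i == length(tss_bins_kb) - 1] <- ">100 kb"
  ifelse(d < 0, paste0("-", lab), lab)
}

#' Annotate consensus peaks to genomic features and nearest genes
#'
#' For each peak summit, computes the strand-aware signed distance to every
#' TSS (positive = downstream of the TSS in the gene's orientation), assigns
#' the nearest gene when the distance is within `max_tss_dist` (ties break
#' to the lexicographically smaller gene id), and categorizes the summit by
#' precedence: promoter > 5' UTR > 3' UTR > exon > intron > downstream >
#' distal intergenic. UTR categories apply only when UTR annotations are
#' provided.
#'
#' @param peaks consensus peaks (peak_id, chrom, summit).
#' @param genes gene models (gene_id, chrom, start, end, strand, tss).
#' @param exons optional exon data.frame (gene_id, chrom, start, end).
#' @param utr5,utr3 optional UTR interval data.frames.
#' @param promoter_window promoter bounds around the TSS in signed-distance
#'   units, default c(-3000, 3000).
#' @param max_tss_dist nearest-gene assignment cap (bp from summit to TSS).
#' @param downstream_window bp past the gene 3' end called "downstream".
#' @return data.frame with peak_id, category, distance (signed bp to the
#'   nearest TSS), nearest_gene (NA beyond the cap) and tss_bin.
#' @export
annotate_peaks <- function(peaks, genes, exons = NULL, utr5 = NULL,
                           utr3 = NULL, promoter_window = c(-3000, 3000),
                           max_tss_dist = 50000, downstream_window = 3000) {
  if (!nrow(genes)) stop("gene set is empty")
  res <- vector("list", nrow(peaks))
  in_any <- function(df, chrom, pos) {
    !is.null(df) && nrow(df) > 0 &&
      any(df$chrom == chrom & df$start <= pos & pos < df$end)
  }
  for (i in seq_len(nrow(peaks))) {
    ch <- peaks$chrom[i]; s <- peaks$summit[i]
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (!nrow(g)) {
      res[[i]] <- data.frame(peak_id = peaks$peak_id[i],
                             category = "distal intergenic",
                             distance = NA_real_,
                             nearest_gene = NA_character_,
                             tss_bin = NA_character_,
                             stringsAsFactors = FALSE)
      next
    }
    signed <- ifelse(g$strand == "-", g$tss - s, s - g$tss)
    ord <- order(abs(signed), g$gene_id)  # nearest TSS; ties -> smaller id
    nearest <- ord[1]
    d <- signed[nearest]
    assigned <- if (abs(d) <= max_tss_dist) g$gene_id[nearest] else NA_character_
    promoter <- any(signed >= promoter_window[1] & signed <= promoter_window[2])
    category <- if (promoter) "promoter"
    else if (in_any(utr5, ch, s)) "5' UTR"
    else if (in_any(utr3, ch, s)) "3' UTR"
    else if (in_any(exons, ch, s)) "exon"
    else if (any(g$start <= s & s < g$end)) "intron"
    else if (any(ifelse(g$strand == "-",
                        s < g$start & s >= g$start - downstream_window,
                        s >= g$end & s < g$end + downstream_window)))
      "downstream"
    else "distal intergenic"
    res[[i]] <- data.frame(peak_id = peaks$peak_id[i], category = category,
                           distance = d, nearest_gene = assigned,
                           tss_bin = bin_tss_distance(d),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
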