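# Readers/writers for the plain-text formats the pipeline exchanges.
# Interval columns follow BED conventions: 0-based, half-open.

#' Read or write a counts matrix as TSV
#'
#' The TSV layout is one row per feature with the feature id in the first
#' column (`feature`) and one column per sample.
#'
#' @param path file path.
#' @return integer matrix with feature row names and sample column names.
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_counts_tsv
#' @param counts matrix of counts (features x samples).
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(feature = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet TSV
#'
#' Expected columns: `sample`, `timepoint`, plus optional covariates such as
#' `rin`, `sex`, `pool`, `replicate`. Timepoints are ordered by their numeric
#' suffix (e.g. P0 < P7 < P35) when they follow the `P<number>` convention,
#' otherwise by first appearance.
#'
#' @param path file path.
#' @return data.frame with `timepoint` as an ordered factor.
#' @export
read_samples_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stop_if_not_cols(df, c("sample", "timepoint"), "sample sheet")
  df$timepoint <- order_timepoints(df$timepoint)
  df
}

order_timepoints <- function(x) {
  u <- unique(as.character(x))
  num <- suppressWarnings(as.numeric(sub("^P", "", u)))
  lev <- if (!anyNA(num)) u[order(num)] else u
  factor(as.character(x), levels = lev, ordered = TRUE)
}

#' Read/write ENCODE narrowPeak files
#'
#' narrowPeak is BED6+4: chrom, start, end, name, score, strand, signalValue,
#' pValue, qValue, and the summit offset from `start` in column 10.
#'
#' @param path file path.
#' @return data.frame with columns chrom, start, end, name, score, strand,
#'   signal, pval, qval, summit_offset and a convenience `summit` column
#'   (absolute 0-based position).
#' @export
read_narrowpeak <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "name", "score", "strand",
                 "signal", "pval", "qval", "summit_offset")[seq_len(ncol(df))]
  df$summit <- df$start + df$summit_offset
  df
}

#' @rdname read_narrowpeak
#' @param peaks data.frame of peak calls with at least chrom, start, end,
#'   name, score and summit (absolute position).
#' @export
write_narrowpeak <- function(peaks, path) {
  out <- data.frame(
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    name = peaks$name %||% paste0("peak_", seq_len(nrow(peaks))),
    score = round(peaks$score %||% 0),
    strand = ".",
    signal = peaks$signal %||% 0,
    pval = peaks$pval %||% -1,
    qval = peaks$qval %||% -1,
    summit_offset = peaks$summit - peaks$start
  )
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3+ interval file
#'
#' @param path file path.
#' @return data.frame with chrom, start, end (0-based half-open).
#' @export
read_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  df
}

#' @rdname read_bed
#' @param intervals data.frame with chrom, start, end.
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(intervals))
  write.table(intervals[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write gene models in GTF-lite format
#'
#' GTF-lite carries `gene` and `exon` feature lines with 1-based inclusive
#' coordinates and a `gene_id "<id>";` attribute. On read, coordinates are
#' converted to the package's 0-based half-open convention and the
#' strand-aware TSS is derived (interval start for `+`, end - 1 for `-`).
#'
#' @param path file path.
#' @return list with `genes` (gene_id, chrom, start, end, strand, tss) and
#'   `exons` (gene_id, chrom, start, end) data.frames.
#' @export
read_gtf_lite <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#")
  names(df) <- c("chrom", "source", "feature", "start", "end", "score",
                 "strand", "frame", "attr")[seq_len(ncol(df))]
  gid <- sub('.*gene_id "([^"]+)".*', "\\1", df$attr)
  start0 <- df$start - 1L  # to 0-based half-open
  genes <- df$feature == "gene"
  g <- data.frame(gene_id = gid[genes], chrom = df$chrom[genes],
                  start = start0[genes], end = df$end[genes],
                  strand = df$strand[genes], stringsAsFactors = FALSE)
  g$tss <- ifelse(g$strand == "-", g$end - 1L, g$start)
  e <- df[df$feature == "exon", ]
  exons <- data.frame(gene_id = gid[df$feature == "exon"], chrom = e$chrom,
                      start = start0[df$feature == "exon"], end = e$end,
                      stringsAsFactors = FALSE)
  list(genes = g[order(g$gene_id), ], exons = exons)
}

#' @rdname read_gtf_lite
#' @param genes data.frame (gene_id, chrom, start, end, strand) in 0-based
#'   half-open coordinates.
#' @param exons optional data.frame (gene_id, chrom, start, end).
#' @export
write_gtf_lite <- function(genes, exons = NULL, path) {
  fmt <- function(df, feature) {
    sprintf("%s\ttempomics\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
            df$chrom, feature, df$start + 1L, df$end,
            df$strand %||% rep("+", nrow(df)), df$gene_id)
  }
  lines <- fmt(genes, "gene")
  if (!is.null(exons) && nrow(exons)) {
    exons$strand <- genes$strand[match(exons$gene_id, genes$gene_id)]
    lines <- c(lines, fmt(exons, "exon"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read/write JASPAR-style PWM files
#'
#' The format is a `>motif_id name` header followed by four lines
#' `A [ counts... ]` (and C, G, T). Counts are converted to position
#' probability matrices with a pseudocount.
#'
#' @param path file path.
#' @param pseudocount added to each cell before normalization.
#' @return list of PWM objects (see [make_pwm()]).
#' @export
read_jaspar <- function(path, pseudocount = 0.01) {
  lines <- readLines(path)
  heads <- grep("^>", lines)
  out <- list()
  for (i in seq_along(heads)) {
    hdr <- sub("^>", "", lines[heads[i]])
    parts <- strsplit(hdr, "[ \t]+")[[1]]
    id <- parts[1]
    fam <- if (length(parts) > 1) parts[2] else "unassigned"
    block <- lines[(heads[i] + 1):(heads[i] + 4)]
    rows <- lapply(block, function(l) {
      v <- strsplit(gsub("^[ACGT]\\s*\\[|\\]", "", l), "\\s+")[[1]]
      as.numeric(v[nzchar(v)])
    })
    m <- do.call(rbind, rows)
    rownames(m) <- c("A", "C", "G", "T")
    out[[id]] <- make_pwm(id, m, family = fam, pseudocount = pseudocount)
  }
  out
}

#' @rdname read_jaspar
#' @param pwms list of PWM objects.
#' @export
write_jaspar <- function(pwms, path) {
  lines <- unlist(lapply(pwms, function(p) {
    counts <- round(p$ppm_raw * 100)
    c(sprintf(">%s %s", p$id, p$family),
      vapply(c("A", "C", "G", "T"), function(b) {
        sprintf("%s [ %s ]", b, paste(counts[b, ], collapse = " "))
      }, character(1)))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' @param path file path to a GMT file (set name, description, then gene ids,
#'   tab-separated).
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- strsplit(readLines(path), "\t")
  sets <- lapply(lines, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(lines, `[[`, character(1), 1)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
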