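# End-to-end orchestration on a simulated study: differential expression,
# consensus peaks, differential accessibility, module discovery, peak-gene
# integration, motif and gene-set enrichment, and a reproducibility report.

#' Run the full integrative pipeline on a synthetic study
#'
#' Executes simulate -> differential expression -> spurious-peak filtering
#' -> consensus construction -> differential accessibility -> gene module
#' clustering -> peak annotation -> peak-gene pairing and classification ->
#' positive-pair co-clustering -> motif scanning and per-module enrichment
#' -> gene-set ORA, and assembles a stage-by-stage report. Any stage
#' failure propagates with the stage name.
#'
#' @param config a [sim_config()]; its seed governs all stochastic stages
#'   through stage-derived seeds.
#' @param alpha adjusted-p significance threshold for DE and DA.
#' @param corr_threshold peak-gene correlation classification cutoff.
#' @param k_genes,k_pairs modules for gene clustering and pair co-clustering.
#' @param family motif family for the focused re-clustering (default TEA).
#' @param k_family modules for the family subset re-clustering.
#' @param max_tss_dist nearest-gene assignment cap in bp.
#' @param promoter_window promoter bounds around the TSS.
#' @return list of class `tempomics_run` with all intermediate results and
#'   a `report` summary (stage counts, thresholds, seed).
#' @export
run_pipeline <- function(config = sim_config(), alpha = 0.05,
                         corr_threshold = 0.5, k_genes = 6, k_pairs = 5,
                         family = "TEA", k_family = 2,
                         max_tss_dist = 50000,
                         promoter_window = c(-3000, 3000)) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  sim <- stage("simulate", simulate_experiment(config))

  de <- stage("diffexpr", de_timecourse(sim$rna$counts, sim$rna$samples,
                                        use_rin = TRUE, alpha = alpha))
  de_genes <- de$feature[de$significant]

  calls <- stage("filter_spurious",
                 filter_spurious(sim$peak_calls, sim$blacklist,
                                 sim$control_peaks))
  consensus <- stage("consensus", build_consensus(calls, width = config$peak_width))

  ## reads-in-peaks: consensus peaks inherit the counts of the simulated
  ## accessible region whose interval contains their summit
  truth_gr <- df_to_granges(sim$peaks)
  summit_gr <- GenomicRanges::GRanges(consensus$chrom,
                                      IRanges::IRanges(consensus$summit + 1L,
                                                       width = 1L))
  ov <- GenomicRanges::findOverlaps(summit_gr, truth_gr)
  ov <- ov[!duplicated(S4Vectors::queryHits(ov))]
  matched <- S4Vectors::queryHits(ov)
  peak_counts <- sim$atac$counts[S4Vectors::subjectHits(ov), , drop = FALSE]
  rownames(peak_counts) <- consensus$peak_id[matched]
  consensus_counted <- consensus[matched, , drop = FALSE]

  da <- stage("diffacc", differential_accessibility(peak_counts,
                                                    sim$atac$samples,
                                                    alpha = alpha))
  da_peaks <- da$feature[da$significant]

  gene_modules <- if (length(de_genes) >= k_genes) {
    stage("cluster_genes", {
      nm <- normalize_for_clustering(sim$rna$counts[de_genes, , drop = FALSE],
                                     sf = size_factors(sim$rna$counts))
      pam_cluster(nm, k = k_genes)
    })
  } else NULL

  annotation <- stage("annotate",
                      annotate_peaks(consensus_counted, sim$genes, sim$exons,
                                     promoter_window = promoter_window,
                                     max_tss_dist = max_tss_dist))

  pg <- stage("integrate", {
    p <- pair_peaks_genes(annotation, da_peaks, sim$rna$counts,
                          sim$rna$samples, peak_counts, sim$atac$samples)
    classify_pairs(pair_correlation(p), threshold = corr_threshold)
  })
  n_pos <- sum(pg$pairs$class == "positive")
  pair_modules <- if (n_pos >= k_pairs)
    stage("cocluster", cocluster_pairs(pg, k = k_pairs)) else NULL

  ## motif analysis over consensus windows (sequences follow the truth
  ## region matched to each consensus peak)
  windows <- sim$sequences[rownames(sim$atac$counts)[S4Vectors::subjectHits(ov)]]
  names(windows) <- consensus$peak_id[matched]
  hits <- stage("motif_scan", scan_pwm(windows, sim$pwms))
  motif_mod <- NULL
  if (!is.null(pair_modules)) {
    motif_mod <- stage("motif_enrich", {
      lapply(split(pair_modules$pairs$peak_id, pair_modules$pairs$module),
             function(fg) {
               list(motifs = motif_enrichment(hits, unique(fg),
                                              consensus_counted$peak_id),
                    families = family_aggregate(hits, sim$family_map,
                                                unique(fg),
                                                consensus_counted$peak_id))
             })
    })
  }
  family_modules <- if (!is.null(pair_modules) &&
                          any(pg$pairs$class == "positive"))
    tryCatch(subset_by_motif_family(pg, hits, sim$family_map,
                                    family = family, k = k_family),
             error = function(e) NULL) else NULL

  detected <- de$feature[!de$filtered & !is.na(de$pvalue)]
  ora_results <- if (!is.null(gene_modules)) {
    stage("ora", {
      lapply(split(gene_modules$assignment$feature,
                   gene_modules$assignment$module), function(genes) {
        ora(intersect(genes, detected), sim$gene_sets, detected)
      })
    })
  } else NULL

  cls_tab <- table(factor(pg$pairs$class,
                          levels = c("positive", "negative", "unclassified")))
  report <- list(
    seed = config$seed,
    thresholds = list(alpha = alpha, corr_threshold = corr_threshold,
                      max_tss_dist = max_tss_dist,
                      consensus_width = config$peak_width,
                      promoter_window = promoter_window,
                      k_genes = k_genes, k_pairs = k_pairs),
    counts = list(
      genes = nrow(sim$rna$counts),
      rna_samples = ncol(sim$rna$counts),
      de_genes = length(de_genes),
      frac_de = length(de_genes) / sum(!de$filtered & !is.na(de$pvalue)),
      peak_calls = nrow(sim$peak_calls),
      peak_calls_after_filter = nrow(calls),
      consensus_peaks = nrow(consensus),
      da_peaks = length(da_peaks),
      pairs_total = nrow(pg$pairs),
      pairs_positive = unname(cls_tab[["positive"]]),
      pairs_negative = unname(cls_tab[["negative"]]),
      pairs_unclassified = unname(cls_tab[["unclassified"]]),
      gene_module_sizes = if (!is.null(gene_modules))
        as.integer(table(gene_modules$assignment$module)) else integer(0),
      pair_module_sizes = if (!is.null(pair_modules))
        as.integer(table(pair_modules$pairs$module)) else integer(0),
      motif_hits = nrow(hits),
      enriched_sets = if (!is.null(ora_results))
        sum(vapply(ora_results, function(o) sum(o$significant), integer(1)))
      else NA_integer_
    ),
    fingerprints = list(
      rna_counts = unname(sum(as.numeric(sim$rna$counts))),
      atac_counts = unname(sum(as.numeric(sim$atac$counts)))
    )
  )

  structure(list(sim = sim, de = de, consensus = consensus,
                 peak_counts = peak_counts, da = da,
                 gene_modules = gene_modules, annotation = annotation,
                 pairs = pg, pair_modules = pair_modules,
                 motif_hits = hits, motif_enrichment = motif_mod,
                 family_modules = family_modules, ora = ora_results,
                 report = report),
            class = "tempomics_run")
}

#' @export
print.tempomics_run <- function(x, ...) {
  r <- x$report
  cat("tempomics pipeline run (seed ", r$seed, ")\n", sep = "")
  for (nm in names(r$counts)) {
    v <- r$counts[[nm]]
    cat(sprintf("  %-24s %s\n", nm, paste(signif(v, 4), collapse = " ")))
  }
  invisible(x)
}

#' Write a pipeline report as JSON and Markdown
#'
#' @param run a `tempomics_run` object.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(run$report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  r <- run$report
  md <- c("# Pipeline report", "",
          sprintf("- seed: %s", r$seed), "",
          "## Thresholds",
          sprintf("- %s: %s", names(r$thresholds),
                  vapply(r$thresholds, function(v) paste(v, collapse = ":"),
                         character(1))),
          "", "## Stage counts",
          sprintf("- %s: %s", names(r$counts),
                  vapply(r$counts, function(v)
                    paste(signif(v, 6), collapse = " "), character(1))))
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}
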