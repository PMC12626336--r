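# Synthetic study generator.
#
# Emulates the design of a postnatal growth time course: six weekly
# timepoints (P0..P35), 6-9 RNA-seq replicates per timepoint with a RIN
# quality covariate, 2 ATAC-seq replicates per timepoint with one droppable
# timepoint, negative-binomial counts with planted temporal modules
# (monotone up/down and intermittent shapes), peaks linked to genes with a
# planted accessibility-expression correlation sign, and PWM motif instances
# planted near peak summits. Every stochastic quantity is drawn under the
# config seed, so identical configs give byte-identical outputs.

#' Default temporal module shapes
#'
#' Six mean-shape vectors (log2 units, unit peak-to-trough range before
#' amplitude scaling): early and late monotone decreases, early and late
#' monotone increases, and two intermittent patterns. Shapes defined on six
#' timepoints are linearly interpolated for other series lengths.
#'
#' @param n_timepoints length of the time series.
#' @return named list of numeric vectors of length `n_timepoints`.
#' @export
default_module_profiles <- function(n_timepoints = 6) {
  base <- list(
    down_early   = c( 0.5,  0.5,  0.0, -0.5, -0.5, -0.5),
    down_late    = c( 0.5,  0.5,  0.5,  0.5,  0.0, -0.5),
    up_early     = c(-0.5, -0.5,  0.0,  0.5,  0.5,  0.5),
    up_late      = c(-0.5, -0.5, -0.5, -0.5,  0.0,  0.5),
    pulse_odd    = c( 0.5, -0.5,  0.25, -0.5, -0.25, 0.5),
    pulse_even   = c(-0.5,  0.5, -0.5,  0.25,  0.5, -0.5)
  )
  if (n_timepoints == 6) return(base)
  lapply(base, function(v) {
    stats::approx(seq(0, 1, length.out = 6), v,
                  xout = seq(0, 1, length.out = n_timepoints))$y
  })
}

#' Built-in PWM library for planting and scanning
#'
#' Small JASPAR-style library of strong-consensus motifs spanning the
#' families the analysis cares about (TEA, MADS, bHLH, KLF, SMAD).
#'
#' @return named list of `pwm` objects.
#' @export
default_motif_library <- function() {
  defs <- list(
    TEAD1 = list("ACATTCCA", "TEA"),
    TEAD4 = list("GGAATGTG", "TEA"),
    MEF2A = list("CTAAAAATAG", "MADS"),
    MYOD1 = list("GCAGCTGT", "bHLH"),
    KLF4  = list("GGGGTGGGG", "KLF"),
    SMAD3 = list("GTCTAGAC", "SMAD")
  )
  out <- lapply(names(defs), function(nm) {
    pwm_from_consensus(nm, defs[[nm]][[1]], family = defs[[nm]][[2]])
  })
  names(out) <- names(defs)
  out
}

#' Simulation configuration
#'
#' Collects the knobs of the synthetic study. Defaults emulate the study
#' design this package targets: 6 weekly timepoints, 6-9 RNA replicates and
#' 2 ATAC replicates per timepoint with the 4th ATAC timepoint dropped, 22%
#' of genes differentially expressed across six temporal module shapes, a
#' RIN covariate drawn from U(6.7, 10) acting on log mean counts, half the
#' peaks linked to DE genes with a 62/38 positive/negative correlation-sign
#' mixture, and family-specific motifs planted near the summits of linked
#' peaks.
#'
#' @param n_timepoints number of weekly timepoints (labels P0, P7, ...).
#' @param rna_reps_per_tp length-2 range of RNA replicates per timepoint.
#' @param atac_reps_per_tp ATAC replicates per timepoint.
#' @param dropped_atac_tp index of a timepoint with no usable ATAC data
#'   (0 or NA for none).
#' @param n_genes,n_peaks numbers of genes and accessible regions.
#' @param module_profiles named list of temporal mean shapes (log2 units).
#' @param frac_de fraction of genes assigned a non-flat profile.
#' @param profile_amplitude log2 peak-to-trough range multiplier; 2 gives a
#'   4-fold swing for the monotone shapes.
#' @param nb_dispersion,atac_dispersion length-2 ranges of per-feature NB
#'   dispersions.
#' @param rin_effect coefficient of (RIN - midrange) on natural-log mean.
#' @param rin_range RIN sampling range; floor matches a 6.7 inclusion cutoff.
#' @param base_log2_mean,atac_log2_mean per-feature baseline log2 mean count
#'   ranges.
#' @param lib_log_sd sd of per-sample library-size offsets (natural log).
#' @param linked_frac fraction of peaks linked to a DE gene.
#' @param positive_link_frac fraction of links with positive planted sign.
#' @param noise_peak_frac per-replicate fraction of irreproducible peaks.
#' @param control_peak_frac fraction of naked-DNA control (Tn5 bias) peaks.
#' @param n_blacklist number of blacklist regions per genome.
#' @param peak_width consensus/window width in bp.
#' @param motif_library named list of `pwm` objects to plant.
#' @param motif_offset_sd sd (bp) of planted motif offsets from the summit.
#' @param seed integer RNG seed.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_timepoints = 6,
                       rna_reps_per_tp = c(6, 9),
                       atac_reps_per_tp = 2,
                       dropped_atac_tp = 4,
                       n_genes = 1000,
                       n_peaks = 800,
                       module_profiles = default_module_profiles(n_timepoints),
                       frac_de = 0.22,
                       profile_amplitude = 2,
                       nb_dispersion = c(0.05, 0.2),
                       atac_dispersion = c(0.05, 0.2),
                       rin_effect = 0.08,
                       rin_range = c(6.7, 10),
                       base_log2_mean = c(4, 9),
                       atac_log2_mean = c(4, 7),
                       lib_log_sd = 0.15,
                       linked_frac = 0.5,
                       positive_link_frac = 0.62,
                       noise_peak_frac = 0.1,
                       control_peak_frac = 0.03,
                       n_blacklist = 4,
                       peak_width = 500,
                       motif_library = default_motif_library(),
                       motif_offset_sd = 40,
                       seed = 1) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  pos <- c("n_timepoints", "atac_reps_per_tp", "n_genes", "n_peaks",
           "peak_width")
  for (nm in pos) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || cfg[[nm]] <= 0)
      stop(sprintf("invalid config: %s must be a positive count", nm))
  }
  if (length(cfg$rna_reps_per_tp) != 2 || any(cfg$rna_reps_per_tp < 2))
    stop("invalid config: rna_reps_per_tp must be a range with minimum >= 2")
  for (frac in c("frac_de", "linked_frac", "positive_link_frac")) {
    if (cfg[[frac]] < 0 || cfg[[frac]] > 1)
      stop(sprintf("invalid config: %s must lie in [0, 1]", frac))
  }
  bad <- vapply(cfg$module_profiles, function(v) length(v) != cfg$n_timepoints,
                logical(1))
  if (any(bad))
    stop("invalid config: module profile length must equal n_timepoints")
  if (any(cfg$nb_dispersion <= 0) || any(cfg$atac_dispersion <= 0))
    stop("invalid config: dispersions must be positive")
  invisible(TRUE)
}

#' Plant PWM consensus sequences into background windows
#'
#' Positions outside plants are drawn from the background distribution by
#' the caller; this function overwrites the planted positions with the
#' motif's consensus (or its reverse complement on the minus strand).
#' Offsets follow the [scan_pwm()] convention: motif midpoint relative to
#' the window center, so offset 0 centers the motif on the summit.
#'
#' @param windows named character vector of sequences.
#' @param pwms named list of `pwm` objects.
#' @param placements data.frame with columns `seq_id`, `motif_id`, `offset`,
#'   `strand`.
#' @return the windows with motifs planted.
#' @export
plant_motifs <- function(windows, pwms, placements) {
  if (!nrow(placements)) return(windows)
  stop_if_not_cols(placements, c("seq_id", "motif_id", "offset", "strand"),
                   "placements")
  for (i in seq_len(nrow(placements))) {
    pl <- placements[i, ]
    pwm <- pwms[[pl$motif_id]]
    if (is.null(pwm)) stop(sprintf("unknown motif id %s", pl$motif_id))
    s <- windows[[pl$seq_id]]
    width <- nchar(s)
    L <- nchar(pwm$consensus)
    start <- width %/% 2 + pl$offset - L %/% 2  # 0-based
    if (start < 0 || start + L > width)
      stop(sprintf("planted offset %d for motif %s does not fit in window %s",
                   pl$offset, pl$motif_id, pl$seq_id))
    ins <- if (pl$strand == "-") revcomp(pwm$consensus) else pwm$consensus
    substr(s, start + 1, start + L) <- ins
    windows[[pl$seq_id]] <- s
  }
  windows
}

random_sequences <- function(n, width, names,
                             bg = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(names(bg), width, replace = TRUE, prob = bg), collapse = "")
  }, character(1))
  names(seqs) <- names
  seqs
}

profile_direction <- function(shape) {
  r <- suppressWarnings(cor(shape, seq_along(shape)))
  if (is.na(r)) "flat" else if (r > 0.3) "up" else if (r < -0.3) "down"
  else "intermittent"
}

#' Simulate a complete synthetic study
#'
#' Generates RNA-seq counts, per-replicate ATAC peak calls, reads-in-peaks
#' counts, gene models, peak-window sequences with planted motifs, a PWM
#' library, blacklist/control peak sets, per-module gene sets and truth
#' tables, all with the statistical structure the downstream analysis
#' assumes. See [sim_config()] for the design being emulated.
#'
#' @param config a [sim_config()] object.
#' @param dir optional directory; when given, all outputs are serialized
#'   there in their standard plain-text formats (see [write_simulation()]).
#' @return list of class `tempomics_sim` with elements `rna` (counts,
#'   samples), `atac` (counts, samples), `peaks` (truth intervals),
#'   `peak_calls`, `blacklist`, `control_peaks`, `genes`, `exons`,
#'   `sequences`, `pwms`, `family_map`, `gene_sets`, `truth` (gene and peak
#'   tables) and `config`.
#' @export
simulate_experiment <- function(config = sim_config(), dir = NULL) {
  validate_sim_config(config)
  cfg <- config
  set.seed(cfg$seed)
  ntp <- cfg$n_timepoints
  tps <- paste0("P", seq(0, by = 7, length.out = ntp))
  amp <- cfg$profile_amplitude
  ln2 <- log(2)

  ## ---- gene models on a synthetic genome ----
  n_chrom <- 4L
  spacing <- 120000L
  gene_len <- 2000L
  per_chrom <- ceiling(cfg$n_genes / n_chrom)
  chrom_len <- (per_chrom + 1L) * spacing
  gene_id <- sprintf("gene_%04d", seq_len(cfg$n_genes))
  chrom <- paste0("chr", ((seq_len(cfg$n_genes) - 1L) %% n_chrom) + 1L)
  slot <- (seq_len(cfg$n_genes) - 1L) %/% n_chrom
  gstart <- slot * spacing + 50000L
  strand <- rep(c("+", "-"), length.out = cfg$n_genes)
  genes <- data.frame(gene_id = gene_id, chrom = chrom, start = gstart,
                      end = gstart + gene_len, strand = strand,
                      stringsAsFactors = FALSE)
  genes$tss <- ifelse(genes$strand == "-", genes$end - 1L, genes$start)
  exons <- rbind(
    data.frame(gene_id = gene_id, chrom = chrom, start = gstart,
               end = gstart + 500L, stringsAsFactors = FALSE),
    data.frame(gene_id = gene_id, chrom = chrom, start = gstart + 1500L,
               end = gstart + gene_len, stringsAsFactors = FALSE))
  exons <- exons[order(exons$gene_id, exons$start), ]

  ## ---- gene truth: DE modules ----
  n_de <- round(cfg$frac_de * cfg$n_genes)
  de_genes <- if (n_de > 0) sample(gene_id, n_de) else character(0)
  prof_names <- names(cfg$module_profiles)
  gene_module <- setNames(rep("flat", cfg$n_genes), gene_id)
  if (n_de > 0)
    gene_module[de_genes] <- rep(prof_names, length.out = n_de)
  truth_genes <- data.frame(gene_id = gene_id,
                            module = gene_module[gene_id],
                            de = gene_module[gene_id] != "flat",
                            stringsAsFactors = FALSE)
  # per-gene generative parameters (filled below, exported for checks)
  truth_genes$base_log2_mean <- NA_real_
  truth_genes$dispersion <- NA_real_

  ## ---- RNA samples and counts ----
  reps <- sample(seq(cfg$rna_reps_per_tp[1], cfg$rna_reps_per_tp[2]),
                 ntp, replace = TRUE)
  rna_samples <- data.frame(
    sample = unlist(lapply(seq_len(ntp), function(t)
      sprintf("%s_r%d", tps[t], seq_len(reps[t])))),
    timepoint = rep(tps, reps), stringsAsFactors = FALSE)
  rna_samples$rin <- round(runif(nrow(rna_samples), cfg$rin_range[1],
                                 cfg$rin_range[2]), 1)
  rna_samples$sex <- rep(c("F", "M"), length.out = nrow(rna_samples))
  rna_samples$pool <- paste0("pool", ((seq_len(nrow(rna_samples)) - 1L) %% 3L) + 1L)
  rna_samples$timepoint <- order_timepoints(rna_samples$timepoint)
  tp_idx <- match(as.character(rna_samples$timepoint), tps)
  rin_mid <- mean(cfg$rin_range)
  lib_rna <- rnorm(nrow(rna_samples), 0, cfg$lib_log_sd)

  base_g <- runif(cfg$n_genes, cfg$base_log2_mean[1], cfg$base_log2_mean[2])
  disp_g <- runif(cfg$n_genes, cfg$nb_dispersion[1], cfg$nb_dispersion[2])
  truth_genes$base_log2_mean <- base_g
  truth_genes$dispersion <- disp_g
  shape_of <- function(module) {
    if (module == "flat") rep(0, ntp) else cfg$module_profiles[[module]]
  }
  rna_counts <- matrix(0L, cfg$n_genes, nrow(rna_samples),
                       dimnames = list(gene_id, rna_samples$sample))
  for (i in seq_len(cfg$n_genes)) {
    sh <- shape_of(gene_module[i])
    log_mu <- ln2 * (base_g[i] + amp * sh[tp_idx]) +
      cfg$rin_effect * (rna_samples$rin - rin_mid) + lib_rna
    rna_counts[i, ] <- rnbinom(nrow(rna_samples), mu = exp(log_mu),
                               size = 1 / disp_g[i])
  }

  ## ---- peak truth: placement and links ----
  n_linked <- round(cfg$linked_frac * cfg$n_peaks)
  if (!length(de_genes)) n_linked <- 0L
  half <- cfg$peak_width %/% 2
  linked_gene <- if (n_linked > 0)
    sample(de_genes, n_linked, replace = TRUE) else character(0)
  link_sign <- if (n_linked > 0)
    ifelse(runif(n_linked) < cfg$positive_link_frac, 1L, -1L) else integer(0)
  gidx <- match(linked_gene, gene_id)
  linked_summit <- genes$tss[gidx] +
    round(runif(n_linked, -40000, 40000))
  n_unlinked <- cfg$n_peaks - n_linked
  ugene <- sample(gene_id, n_unlinked, replace = TRUE)
  unlinked_summit <- genes$tss[match(ugene, gene_id)] +
    round(runif(n_unlinked, 55000, 60000))
  peaks <- data.frame(
    chrom = c(genes$chrom[gidx], genes$chrom[match(ugene, gene_id)]),
    summit = c(linked_summit, unlinked_summit),
    linked_gene = c(linked_gene, rep(NA_character_, n_unlinked)),
    link_sign = c(link_sign, rep(NA_integer_, n_unlinked)),
    stringsAsFactors = FALSE)
  peaks$summit <- pmax(half, pmin(peaks$summit, chrom_len - half - 1L))
  peaks <- peaks[order(peaks$chrom, peaks$summit), ]
  peaks$peak_id <- sprintf("pk_%04d", seq_len(nrow(peaks)))
  peaks$start <- peaks$summit - half
  peaks$end <- peaks$start + cfg$peak_width
  gm <- gene_module[peaks$linked_gene]
  peaks$direction <- ifelse(
    is.na(peaks$linked_gene), "flat",
    vapply(seq_len(nrow(peaks)), function(i) {
      if (is.na(peaks$linked_gene[i])) return("flat")
      profile_direction(peaks$link_sign[i] * shape_of(gm[i]))
    }, character(1)))

  ## ---- ATAC samples and reads-in-peaks counts ----
  atac_tp_idx <- setdiff(seq_len(ntp),
                         if (is.na(cfg$dropped_atac_tp) || cfg$dropped_atac_tp < 1)
                           integer(0) else cfg$dropped_atac_tp)
  atac_samples <- expand.grid(replicate = seq_len(cfg$atac_reps_per_tp),
                              timepoint = tps[atac_tp_idx],
                              stringsAsFactors = FALSE)
  atac_samples <- data.frame(
    sample = sprintf("%s_atac_r%d", atac_samples$timepoint,
                     atac_samples$replicate),
    timepoint = atac_samples$timepoint, replicate = atac_samples$replicate,
    stringsAsFactors = FALSE)
  atac_samples$timepoint <- order_timepoints(atac_samples$timepoint)
  a_tp_idx <- match(as.character(atac_samples$timepoint), tps)
  lib_atac <- rnorm(nrow(atac_samples), 0, cfg$lib_log_sd)
  base_p <- runif(nrow(peaks), cfg$atac_log2_mean[1], cfg$atac_log2_mean[2])
  disp_p <- runif(nrow(peaks), cfg$atac_dispersion[1], cfg$atac_dispersion[2])
  atac_counts <- matrix(0L, nrow(peaks), nrow(atac_samples),
                        dimnames = list(peaks$peak_id, atac_samples$sample))
  for (i in seq_len(nrow(peaks))) {
    sh <- if (is.na(peaks$linked_gene[i])) rep(0, ntp)
    else peaks$link_sign[i] * shape_of(gm[i])
    log_mu <- ln2 * (base_p[i] + amp * sh[a_tp_idx]) + lib_atac
    atac_counts[i, ] <- rnbinom(nrow(atac_samples), mu = exp(log_mu),
                                size = 1 / disp_p[i])
  }

  ## ---- per-replicate peak calls (with irreproducible noise) ----
  call_rows <- list()
  for (s in seq_len(nrow(atac_samples))) {
    jit1 <- round(runif(nrow(peaks), -50, 50))
    jit2 <- round(runif(nrow(peaks), -50, 50))
    calls <- data.frame(
      chrom = peaks$chrom,
      start = peaks$summit - half + jit1,
      end = peaks$summit + half + jit2,
      name = sprintf("%s_%s", atac_samples$sample[s], peaks$peak_id),
      score = round(runif(nrow(peaks), 100, 1000)),
      summit = peaks$summit,
      timepoint = as.character(atac_samples$timepoint[s]),
      replicate = atac_samples$replicate[s],
      stringsAsFactors = FALSE)
    n_noise <- round(cfg$noise_peak_frac * cfg$n_peaks)
    if (n_noise > 0) {
      nchrom <- paste0("chr", sample.int(n_chrom, n_noise, replace = TRUE))
      npos <- round(runif(n_noise, half + 1, chrom_len - half - 1))
      noise <- data.frame(
        chrom = nchrom, start = npos - half, end = npos + half,
        name = sprintf("%s_noise%03d", atac_samples$sample[s], seq_len(n_noise)),
        score = round(runif(n_noise, 50, 300)),
        summit = npos,
        timepoint = as.character(atac_samples$timepoint[s]),
        replicate = atac_samples$replicate[s], stringsAsFactors = FALSE)
      calls <- rbind(calls, noise)
    }
    call_rows[[s]] <- calls
  }

  ## ---- blacklist and naked-DNA control peaks (spurious calls) ----
  bl_gene <- sample(gene_id, cfg$n_blacklist)
  blacklist <- data.frame(
    chrom = genes$chrom[match(bl_gene, gene_id)],
    start = genes$tss[match(bl_gene, gene_id)] + 63000L,
    stringsAsFactors = FALSE)
  blacklist$end <- blacklist$start + 2000L
  n_ctrl <- max(1L, round(cfg$control_peak_frac * cfg$n_peaks))
  ctrl_gene <- sample(gene_id, n_ctrl)
  control_peaks <- data.frame(
    chrom = genes$chrom[match(ctrl_gene, gene_id)],
    start = genes$tss[match(ctrl_gene, gene_id)] + 70000L,
    stringsAsFactors = FALSE)
  control_peaks$end <- control_peaks$start + cfg$peak_width
  spurious <- rbind(
    data.frame(chrom = blacklist$chrom,
               summit = (blacklist$start + blacklist$end) %/% 2L),
    data.frame(chrom = control_peaks$chrom,
               summit = (control_peaks$start + control_peaks$end) %/% 2L))
  for (s in seq_len(nrow(atac_samples))) {
    sp <- data.frame(
      chrom = spurious$chrom, start = spurious$summit - half,
      end = spurious$summit + half,
      name = sprintf("%s_spur%03d", atac_samples$sample[s],
                     seq_len(nrow(spurious))),
      score = round(runif(nrow(spurious), 200, 800)),
      summit = spurious$summit,
      timepoint = as.character(atac_samples$timepoint[s]),
      replicate = atac_samples$replicate[s], stringsAsFactors = FALSE)
    call_rows[[s]] <- rbind(call_rows[[s]], sp)
  }
  peak_calls <- do.call(rbind, call_rows)
  rownames(peak_calls) <- NULL

  ## ---- motif planting in peak windows ----
  motif_by_dir <- list(down = "TEAD1", up = "MEF2A", intermittent = "KLF4")
  placements <- list()
  for (i in seq_len(nrow(peaks))) {
    m <- motif_by_dir[[peaks$direction[i]]]
    if (is.null(m) || !m %in% names(cfg$motif_library)) next
    L <- nchar(cfg$motif_library[[m]]$consensus)
    max_off <- half - L %/% 2 - L
    off <- round(rnorm(1, 0, cfg$motif_offset_sd))
    off <- max(-max_off, min(max_off, off))
    placements[[length(placements) + 1L]] <- data.frame(
      seq_id = peaks$peak_id[i], motif_id = m, offset = off,
      strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
  }
  placements <- if (length(placements)) do.call(rbind, placements)
  else data.frame(seq_id = character(), motif_id = character(),
                  offset = integer(), strand = character(),
                  stringsAsFactors = FALSE)
  sequences <- random_sequences(nrow(peaks), cfg$peak_width, peaks$peak_id)
  sequences <- plant_motifs(sequences, cfg$motif_library, placements)

  truth_peaks <- data.frame(
    peak_id = peaks$peak_id, chrom = peaks$chrom, start = peaks$start,
    end = peaks$end, summit = peaks$summit,
    linked_gene = peaks$linked_gene, link_sign = peaks$link_sign,
    direction = peaks$direction,
    planted_motif = placements$motif_id[match(peaks$peak_id, placements$seq_id)],
    planted_offset = placements$offset[match(peaks$peak_id, placements$seq_id)],
    planted_strand = placements$strand[match(peaks$peak_id, placements$seq_id)],
    stringsAsFactors = FALSE)

  family_map <- data.frame(
    motif = vapply(cfg$motif_library, `[[`, character(1), "id"),
    family = vapply(cfg$motif_library, `[[`, character(1), "family"),
    stringsAsFactors = FALSE, row.names = NULL)

  ## ---- gene sets: one per planted module plus decoys ----
  gene_sets <- lapply(split(truth_genes$gene_id[truth_genes$de],
                            truth_genes$module[truth_genes$de]), identity)
  gene_sets <- gene_sets[lengths(gene_sets) > 0]
  if (length(gene_sets)) names(gene_sets) <- paste0("module_", names(gene_sets))
  gene_sets$decoy_a <- sample(gene_id, min(50, cfg$n_genes))
  gene_sets$decoy_b <- sample(gene_id, min(50, cfg$n_genes))

  sim <- structure(list(
    config = cfg,
    timepoints = tps,
    rna = list(counts = rna_counts, samples = rna_samples),
    atac = list(counts = atac_counts, samples = atac_samples),
    peaks = peaks[, c("peak_id", "chrom", "start", "end", "summit")],
    peak_calls = peak_calls,
    blacklist = blacklist,
    control_peaks = control_peaks,
    genes = genes, exons = exons,
    sequences = sequences,
    pwms = cfg$motif_library,
    family_map = family_map,
    gene_sets = gene_sets,
    truth = list(genes = truth_genes, peaks = truth_peaks)
  ), class = "tempomics_sim")
  if (!is.null(dir)) write_simulation(sim, dir)
  sim
}

#' Serialize a simulated study to standard plain-text formats
#'
#' Writes counts and sample sheets as TSV, per-replicate peak calls as
#' narrowPeak, blacklist/control intervals as BED, gene models as GTF-lite,
#' peak windows as FASTA, PWMs as JASPAR text, gene sets as GMT and the
#' truth tables as TSV.
#'
#' @param sim a `tempomics_sim` object.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  write_counts_tsv(sim$rna$counts, fp("rna_counts.tsv"))
  smp <- sim$rna$samples; smp$timepoint <- as.character(smp$timepoint)
  write.table(smp, fp("rna_samples.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_counts_tsv(sim$atac$counts, fp("atac_counts.tsv"))
  asmp <- sim$atac$samples; asmp$timepoint <- as.character(asmp$timepoint)
  write.table(asmp, fp("atac_samples.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (key in split(sim$peak_calls,
                    list(sim$peak_calls$timepoint, sim$peak_calls$replicate),
                    drop = TRUE)) {
    f <- sprintf("peaks_%s_rep%d.narrowPeak", key$timepoint[1], key$replicate[1])
    write_narrowpeak(key, fp(f))
  }
  write_bed(sim$blacklist, fp("blacklist.bed"))
  write_bed(sim$control_peaks, fp("control_peaks.bed"))
  write_gtf_lite(sim$genes, sim$exons, fp("genes.gtf"))
  writeLines(unlist(lapply(names(sim$sequences), function(nm) {
    c(paste0(">", nm), sim$sequences[[nm]])
  })), fp("peak_windows.fa"))
  write_jaspar(sim$pwms, fp("motifs.jaspar"))
  write_gmt(sim$gene_sets, fp("gene_sets.gmt"))
  write.table(sim$truth$genes, fp("truth_genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$truth$peaks, fp("truth_peaks.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$family_map, fp("family_map.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
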