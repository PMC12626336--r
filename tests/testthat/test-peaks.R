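# Spurious-peak filtering, consensus construction, counting, annotation.

random_calls <- function(n, seed, tps = c("P0", "P7"), reps = 1:2,
                         chroms = c("chrA", "chrB"), span = 5000) {
  set.seed(seed)
  start <- sample(span, n, replace = TRUE)
  width <- sample(80:200, n, replace = TRUE)
  df <- data.frame(chrom = sample(chroms, n, replace = TRUE),
                   start = start, end = start + width,
                   score = runif(n, 10, 1000),
                   timepoint = sample(tps, n, replace = TRUE),
                   replicate = sample(reps, n, replace = TRUE),
                   stringsAsFactors = FALSE)
  df$summit <- df$start + sample(0:79, n, replace = TRUE)
  df
}

test_that("filter_spurious: identity, boundary, idempotence", {
  pk <- data.frame(chrom = "chr1", start = c(0, 100, 300),
                   end = c(50, 200, 400), stringsAsFactors = FALSE)
  expect_identical(filter_spurious(pk, NULL, NULL), pk)
  ## abutting interval (end == blacklist start) is not an overlap
  bl <- data.frame(chrom = "chr1", start = 50, end = 90)
  expect_identical(filter_spurious(pk, bl), pk)
  bl2 <- data.frame(chrom = "chr1", start = 49, end = 90)
  expect_equal(filter_spurious(pk, bl2)$start, c(100, 300))
  expect_identical(filter_spurious(filter_spurious(pk, bl2), bl2),
                   filter_spurious(pk, bl2))
})

test_that("filter_spurious warns on disjoint chromosome naming", {
  pk <- data.frame(chrom = "chr1", start = 0, end = 10)
  bl <- data.frame(chrom = "1", start = 0, end = 10)
  w <- capture_warnings(filter_spurious(pk, bl))
  expect_true(any(grepl("no chromosome shared", w)))
})

test_that("filter_spurious matches the brute-force overlap oracle", {
  set.seed(21)
  for (trial in 1:5) {
    pk <- random_calls(200, seed = 21 + trial)
    bl <- random_calls(15, seed = 100 + trial)[, c("chrom", "start", "end")]
    ctrl <- random_calls(10, seed = 200 + trial)[, c("chrom", "start", "end")]
    got <- filter_spurious(pk, bl, ctrl)
    bad <- rbind(bl, ctrl)
    keep <- !vapply(seq_len(nrow(pk)), function(i)
      overlaps_any(pk$chrom[i], pk$start[i], pk$end[i], bad), logical(1))
    expect_identical(got, pk[keep, , drop = FALSE])
  }
})

test_that("consensus: identical peak in both replicates gives one 500 bp peak", {
  calls <- data.frame(chrom = "chr1", start = 1000, end = 1200,
                      summit = c(1100, 1100), score = c(50, 60),
                      timepoint = "P0", replicate = c(1, 2))
  cons <- build_consensus(calls)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$end - cons$start, 500)
  expect_equal(cons$summit, 1100)
  expect_equal(cons$start, 1100 - 250)
})

test_that("consensus: single-replicate support is excluded", {
  calls <- data.frame(chrom = "chr1", start = c(1000, 5000), end = c(1200, 5200),
                      summit = c(1100, 5100), score = 50,
                      timepoint = "P0", replicate = c(1, 1))
  calls2 <- rbind(calls,
                  data.frame(chrom = "chr1", start = 1010, end = 1190,
                             summit = 1090, score = 70,
                             timepoint = "P0", replicate = 2))
  cons <- build_consensus(calls2)
  ## the 1000-1200 region is in both replicates, the 5000 one is not
  expect_equal(nrow(cons), 1)
  expect_equal(cons$summit, 1090)  # higher score wins the summit
})

test_that("consensus: timepoints with one replicate are dropped with a warning", {
  calls <- data.frame(chrom = "chr1", start = c(1000, 1010), end = c(1200, 1190),
                      summit = c(1100, 1090), score = 50,
                      timepoint = c("P0", "P0"), replicate = c(1, 2))
  lone <- data.frame(chrom = "chr1", start = 8000, end = 8200, summit = 8100,
                     score = 90, timepoint = "P7", replicate = 1)
  expect_warning(cons <- build_consensus(rbind(calls, lone)),
                 "single replicate")
  expect_equal(nrow(cons), 1)
  expect_error(suppressWarnings(build_consensus(lone)), "consensus undefined")
})

# brute-force oracle for the consensus rule: connected overlap components,
# both-replicate support of some timepoint, best-score summit
consensus_bruteforce <- function(calls, width = 500) {
  n <- nrow(calls)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (comp[i] != comp[j] &&
          calls$chrom[i] == calls$chrom[j] &&
          calls$start[i] < calls$end[j] && calls$start[j] < calls$end[i]) {
        comp[comp == comp[j]] <- comp[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- NULL
  for (cc in unique(comp)) {
    sub <- calls[comp == cc, , drop = FALSE]
    ok <- FALSE
    for (tp in unique(calls$timepoint)) {
      reps <- unique(calls$replicate[calls$timepoint == tp])
      have <- unique(sub$replicate[sub$timepoint == tp])
      if (length(reps) >= 2 && all(reps %in% have)) ok <- TRUE
    }
    if (!ok) next
    best <- sub[sub$score == max(sub$score), , drop = FALSE]
    smt <- min(best$summit)
    out <- rbind(out, data.frame(chrom = sub$chrom[1], summit = smt,
                                 start = smt - width %/% 2,
                                 end = smt - width %/% 2 + width))
  }
  out[order(out$chrom, out$start), , drop = FALSE]
}

test_that("consensus matches brute-force enumeration on random call sets", {
  for (trial in 1:6) {
    calls <- random_calls(40, seed = 300 + trial)
    got <- suppressWarnings(build_consensus(calls))
    want <- consensus_bruteforce(calls)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got$summit, want$summit)
      expect_equal(got$start, want$start)
      expect_equal(got$chrom, want$chrom)
    }
    ## invariant: exact width and both-replicate support recorded
    if (nrow(got)) {
      expect_true(all(got$end - got$start == 500))
      expect_true(all(got$n_support >= 2))
    }
  }
})

test_that("count_in_peaks: boundaries and brute-force agreement", {
  peaks <- data.frame(peak_id = c("a", "b"), chrom = "chr1",
                      start = c(100, 1000), end = c(600, 1500),
                      stringsAsFactors = FALSE)
  ## midpoint exactly at start counts, at end does not
  frag_at_start <- data.frame(chrom = "chr1", start = 90, end = 110)   # mid 100
  frag_at_end <- data.frame(chrom = "chr1", start = 590, end = 610)    # mid 600
  m <- count_in_peaks(list(r1 = frag_at_start, r2 = frag_at_end), peaks)
  expect_equal(m["a", "r1"], 1L)
  expect_equal(m["a", "r2"], 0L)
  expect_equal(unname(count_in_peaks(list(r = frag_at_start[0, ]), peaks)[, 1]),
               c(0L, 0L))

  set.seed(31)
  frags <- data.frame(chrom = sample(c("chr1", "chr2"), 1000, replace = TRUE),
                      start = sample(2000, 1000, replace = TRUE))
  frags$end <- frags$start + sample(50:300, 1000, replace = TRUE)
  got <- count_in_peaks(list(x = frags), peaks)
  mid <- (frags$start + frags$end) %/% 2
  want <- vapply(seq_len(2), function(i) {
    sum(frags$chrom == peaks$chrom[i] & mid >= peaks$start[i] &
          mid < peaks$end[i])
  }, integer(1))
  expect_equal(unname(got[, 1]), want)
})

test_that("differential accessibility rejects degenerate designs and finds planted peaks", {
  samples1 <- data.frame(sample = c("a", "b"), timepoint = "P0",
                         replicate = 1:2)
  cm <- matrix(5L, 3, 2, dimnames = list(letters[1:3], c("a", "b")))
  expect_error(differential_accessibility(cm, samples1), "two timepoints")

  samples2 <- data.frame(sample = c("a", "b", "c"),
                         timepoint = c("P0", "P0", "P7"), replicate = c(1, 2, 1))
  expect_error(differential_accessibility(cm[, c(1, 2, 1)], samples2),
               "fewer than two replicates")

  sim <- simulate_experiment(sim_config(n_genes = 150, n_peaks = 200, seed = 41))
  da <- differential_accessibility(sim$atac$counts, sim$atac$samples)
  truth <- sim$truth$peaks
  sig <- da$significant[match(truth$peak_id, da$feature)]
  monotone <- truth$direction %in% c("up", "down")
  expect_gte(mean(sig[monotone]), 0.9)           # planted 4-fold swings found
  expect_lte(mean(sig[truth$direction == "flat"]), 0.05)
})

test_that("annotation: distances, 50 kb cap, category partition", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                      start = c(10000, 200000), end = c(12000, 202000),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  genes$tss <- ifelse(genes$strand == "-", genes$end - 1L, genes$start)
  peaks <- data.frame(peak_id = c("at_tss", "far", "downstream_minus"),
                      chrom = "chr1",
                      summit = c(10000, 70000, 201999 + 400))
  ann <- annotate_peaks(peaks, genes)
  expect_equal(ann$distance[1], 0)
  expect_equal(ann$category[1], "promoter")
  expect_equal(ann$nearest_gene[1], "gA")
  ## nearest TSS 60 kb away -> no assignment
  expect_true(is.na(ann$nearest_gene[2]))
  expect_equal(ann$category[2], "distal intergenic")
  ## minus-strand gene: summit 400 bp 5-prime of the TSS in genome
  ## coordinates is downstream distance -400... strand-aware sign
  expect_equal(ann$nearest_gene[3], "gB")
  expect_equal(ann$distance[3], -400)
})

test_that("annotation matches exhaustive nearest-TSS search on random genomes", {
  for (trial in 1:3) {
    set.seed(50 + trial)
    ng <- 40
    genes <- data.frame(gene_id = sprintf("g%02d", 1:ng),
                        chrom = sample(c("chr1", "chr2"), ng, replace = TRUE),
                        start = sample(5e5, ng), stringsAsFactors = FALSE)
    genes$end <- genes$start + 2000L
    genes$strand <- sample(c("+", "-"), ng, replace = TRUE)
    genes$tss <- ifelse(genes$strand == "-", genes$end - 1L, genes$start)
    peaks <- data.frame(peak_id = sprintf("p%03d", 1:100),
                        chrom = sample(c("chr1", "chr2"), 100, replace = TRUE),
                        summit = sample(5e5, 100))
    ann <- annotate_peaks(peaks, genes)
    for (i in seq_len(100)) {
      g <- genes[genes$chrom == peaks$chrom[i], ]
      signed <- ifelse(g$strand == "-", g$tss - peaks$summit[i],
                       peaks$summit[i] - g$tss)
      best <- order(abs(signed), g$gene_id)[1]
      want <- if (abs(signed[best]) <= 50000) g$gene_id[best] else NA_character_
      expect_identical(ann$nearest_gene[i], want)
      expect_equal(ann$distance[i], signed[best])
    }
    ## the category partition is exhaustive
    expect_equal(nrow(ann), 100)
    expect_true(all(ann$category %in% c("promoter", "5' UTR", "3' UTR",
                                        "exon", "intron", "downstream",
                                        "distal intergenic")))
  }
})

test_that("annotation category precedence: promoter > exon > intron > downstream", {
  genes <- data.frame(gene_id = "g", chrom = "c", start = 10000, end = 30000,
                      strand = "+", tss = 10000, stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = "g", chrom = "c", start = 15000, end = 16000)
  peaks <- data.frame(peak_id = c("prom", "ex", "intr", "down", "distal"),
                      chrom = "c",
                      summit = c(9000, 15500, 20000, 31000, 90000))
  ann <- annotate_peaks(peaks, genes, exons)
  expect_equal(ann$category,
               c("promoter", "exon", "intron", "downstream",
                 "distal intergenic"))
})
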