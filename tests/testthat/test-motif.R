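# PWM construction, scanning, summit-distance profiles, enrichment.

test_that("PWM construction validates shape and derives the consensus", {
  p <- pwm_from_consensus("X", "ACGTAC")
  expect_equal(p$consensus, "ACGTAC")
  expect_equal(unname(colSums(p$ppm)), rep(1, 6), tolerance = 1e-12)
  expect_error(make_pwm("bad", matrix(1, 3, 6)), "4 rows")
  expect_error(pwm_from_consensus("short", "ACG"), "at least 4")
  expect_error(pwm_from_consensus("bad", "ACGX"), "only ACGT")
})

test_that("a background-equal PWM scores zero everywhere and yields no hits", {
  m <- matrix(0.25, 4, 6)
  p <- make_pwm("bg", m, pseudocount = 0)
  expect_equal(max(abs(p$log_odds)), 0)
  set.seed(71)
  win <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
               collapse = "")
  hits <- scan_pwm(c(w1 = win), p, threshold_frac = 0.5)
  expect_equal(nrow(hits), 0)  # threshold 0.5 * 0 = 0 but max_score is 0
})

test_that("planted consensus is recovered at the planted offset with maximal score", {
  pwm <- pwm_from_consensus("TEAD1", "ACATTCCA", family = "TEA")
  set.seed(72)
  n <- 60
  wins <- vapply(1:n, function(i)
    paste(sample(c("A", "C", "G", "T"), 501, replace = TRUE), collapse = ""),
    character(1))
  names(wins) <- sprintf("w%02d", 1:n)
  offs <- sample(-200:200, n, replace = TRUE)
  placements <- data.frame(seq_id = names(wins), motif_id = "TEAD1",
                           offset = offs, strand = "+")
  planted <- plant_motifs(wins, list(TEAD1 = pwm), placements)
  hits <- scan_pwm(planted, pwm)
  found <- vapply(seq_len(n), function(i) {
    h <- hits[hits$id == names(wins)[i], ]
    any(abs(h$offset - offs[i]) <= 2)
  }, logical(1))
  expect_gte(mean(found), 0.95)
  ## the planted position carries the maximal possible score, verified
  ## against a brute-force scan of every window position
  h1 <- hits[hits$id == "w01" & hits$strand == "+", ]
  expect_true(any(abs(h1$score - pwm$max_score) < 1e-9))
  s <- planted[["w01"]]
  L <- nchar(pwm$consensus)
  brute <- vapply(1:(nchar(s) - L + 1), function(i) {
    sub <- strsplit(substr(s, i, i + L - 1), "")[[1]]
    sum(vapply(seq_len(L), function(j)
      pwm$log_odds[sub[j], j], numeric(1)))
  }, numeric(1))
  expect_equal(max(h1$score), max(brute), tolerance = 1e-9)
})

test_that("reverse-complement symmetry: strands flip, positions mirror, scores match", {
  pwm <- pwm_from_consensus("M", "GCAGCTGA")
  set.seed(73)
  wins <- c(a = paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                      collapse = ""))
  wins <- plant_motifs(wins, list(M = pwm),
                       data.frame(seq_id = "a", motif_id = "M",
                                  offset = -30, strand = "+"))
  rc <- c(a = as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(wins[["a"]]))))
  fw <- scan_pwm(wins, pwm)
  bw <- scan_pwm(rc, pwm)
  fw <- fw[order(fw$start), ]; bw <- bw[order(-bw$start), ]
  L <- nchar(pwm$consensus); W <- nchar(wins[["a"]])
  expect_equal(nrow(fw), nrow(bw))
  expect_equal(bw$start, W - L - fw$start)
  expect_equal(bw$strand, ifelse(fw$strand == "+", "-", "+"))
  expect_equal(sort(bw$score), sort(fw$score), tolerance = 1e-12)
})

test_that("minus-strand plants are reported on the minus strand at the same offset", {
  pwm <- pwm_from_consensus("M", "ACGGTCAT")
  set.seed(74)
  wins <- c(w = paste(sample(c("A", "C", "G", "T"), 301, replace = TRUE),
                      collapse = ""))
  wins <- plant_motifs(wins, list(M = pwm),
                       data.frame(seq_id = "w", motif_id = "M",
                                  offset = 40, strand = "-"))
  hits <- scan_pwm(wins, pwm)
  minus <- hits[hits$strand == "-", ]
  expect_true(any(abs(minus$offset - 40) <= 2))
})

test_that("plant_motifs rejects out-of-bounds offsets and unknown motifs", {
  pwm <- pwm_from_consensus("M", "ACGT")
  wins <- c(w = strrep("A", 20))
  expect_error(plant_motifs(wins, list(M = pwm),
                            data.frame(seq_id = "w", motif_id = "M",
                                       offset = 15, strand = "+")),
               "does not fit")
  expect_error(plant_motifs(wins, list(M = pwm),
                            data.frame(seq_id = "w", motif_id = "Z",
                                       offset = 0, strand = "+")),
               "unknown motif")
  ## empty placements: sequences unchanged
  expect_identical(plant_motifs(wins, list(M = pwm),
                                data.frame(seq_id = character(),
                                           motif_id = character(),
                                           offset = integer(),
                                           strand = character())),
                   wins)
})

test_that("summit distance profile: degenerate and analytic uniform cases", {
  at_summit <- data.frame(offset = rep(0, 30))
  expect_equal(summit_distance_profile(at_summit)$frac_within_100, 1)

  empty <- data.frame(offset = numeric(0))
  prof <- summit_distance_profile(empty)
  expect_true(all(prof$histogram$count == 0))
  expect_true(is.na(prof$frac_within_100))

  ## uniform offsets over a 500 bp window: P(|offset| <= 100) = 201/491
  set.seed(75)
  unif <- data.frame(offset = sample(-245:245, 5000, replace = TRUE))
  got <- summit_distance_profile(unif)$frac_within_100
  expect_equal(got, 201 / 491, tolerance = 0.05)
  expect_equal(sum(summit_distance_profile(unif)$histogram$count),
               sum(abs(unif$offset) < 250))
})

test_that("hypergeometric enrichment matches exhaustive PMF summation (universe <= 30)", {
  for (N in c(5, 10, 17, 23, 30)) {
    for (n in unique(c(1, 2, N %/% 2, N - 1))) {
      for (K in 0:N) {
        for (k in max(0, n + K - N):min(n, K)) {
          expect_equal(tempomics:::hyper_test(k, K, n, N),
                       hyper_tail_bruteforce(k, K, n, N), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("motif enrichment: equal hit fractions are not enriched; planting is detected", {
  ## identical hit fraction in foreground and background -> p >= 0.5
  hits_even <- data.frame(id = sprintf("p%02d", 1:20), motif = "M",
                          family = "F", stringsAsFactors = FALSE)
  res <- motif_enrichment(hits_even, sprintf("p%02d", 1:5),
                          sprintf("p%02d", 1:20))
  expect_gte(res$p, 0.5)

  ## motif only in (most of) the foreground -> q < 0.05
  universe <- sprintf("p%03d", 1:120)
  fg <- universe[1:30]
  hits <- data.frame(id = universe[1:20], motif = "planted", family = "F",
                     stringsAsFactors = FALSE)
  res2 <- motif_enrichment(hits, fg, universe)
  expect_lt(res2$q[res2$motif == "planted"], 0.05)

  expect_error(motif_enrichment(hits, character(0), universe),
               "empty foreground")
  expect_error(motif_enrichment(hits, "zzz", universe), "subset")
})

test_that("family aggregation pools member hits as a union", {
  universe <- sprintf("p%02d", 1:40)
  hits <- rbind(
    data.frame(id = universe[1:10], motif = "A1", family = NA),
    data.frame(id = universe[6:15], motif = "A2", family = NA),
    data.frame(id = universe[30:35], motif = "B1", family = NA))
  fam_map <- data.frame(motif = c("A1", "A2", "B1"),
                        family = c("famA", "famA", "famB"))
  res <- family_aggregate(hits, fam_map, universe[1:15], universe)
  famA <- res[res$family == "famA", ]
  expect_equal(famA$n_universe_hit, length(union(universe[1:10],
                                                 universe[6:15])))
  expect_equal(famA$n_members, 2)
  ## single-member family equals the member's own counts
  famB <- res[res$family == "famB", ]
  per <- motif_enrichment(hits, universe[1:15], universe)
  expect_equal(famB$p, per$p[per$motif == "B1"])
  ## unmapped motifs are pooled as unassigned, with a warning
  w <- capture_warnings(
    family_aggregate(hits, fam_map[1:2, ], universe[1:15], universe))
  expect_true(any(grepl("unassigned", w)))
})

test_that("promoter enrichment uses genes as units and rejects degenerate universes", {
  genes <- sprintf("g%02d", 1:30)
  hits <- data.frame(id = genes[1:8], motif = "T", family = "TEA")
  res <- promoter_enrichment(hits, genes[1:8], genes)
  expect_lt(res$p, 0.01)
  nohit <- data.frame(id = character(), motif = character(),
                      family = character())
  res0 <- promoter_enrichment(nohit, genes[1:8], genes)
  expect_equal(nrow(res0), 0)
  expect_error(promoter_enrichment(hits, "g01", "g01"), "degenerate")
})

test_that("expression-gated enrichment recovers exactly the planted factors", {
  ## TEAD1 planted in down peaks, MEF2A in up peaks, KLF4 in intermittent;
  ## gating enriched motifs on expressed factors reproduces that list
  sim <- simulate_experiment(sim_config(n_genes = 150, n_peaks = 250,
                                        seed = 81))
  hits <- scan_pwm(sim$sequences, sim$pwms)
  truth <- sim$truth$peaks
  planted <- sort(unique(truth$planted_motif[!is.na(truth$planted_motif)]))
  expressed <- c(planted, "SMAD3")  # expressed but never planted
  enriched <- character(0)
  for (dir in c("down", "up", "intermittent")) {
    fg <- truth$peak_id[truth$direction == dir]
    res <- motif_enrichment(hits, fg, truth$peak_id)
    enriched <- union(enriched, res$motif[res$significant])
  }
  expect_setequal(intersect(enriched, expressed), planted)
})
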