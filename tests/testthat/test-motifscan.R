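# PWM scoring against a Markov background, genome scanning, the
# bimodal class split, and the motif-centric distance/composition
# profiles.

uniform_bg <- function(order = 0) {
  # equal-composition sequence gives exactly 0.25 conditionals after
  # strand symmetrization and smoothing
  fit_background(strrep("ACGT", 500), order = order)
}

test_that("background fitting matches brute-force context counting", {
  expect_gt(uniform_bg()$cond[[1]][1, "A"] - 0.2499, 0)
  expect_lt(max(abs(uniform_bg()$cond[[1]] - 0.25)), 1e-12)

  # near-pure-A sequence: P(A) close to 1 at order 0
  bgA <- fit_background(strrep("A", 2000), order = 0)
  expect_gt(bgA$cond[[1]][1, "A"], 0.45)   # RC symmetrization adds T
  expect_gt(bgA$cond[[1]][1, "A"] + bgA$cond[[1]][1, "T"], 0.99)

  # order-2 conditionals equal direct 3-mer hash counting on random DNA
  seq <- withr::with_seed(5, paste(sample(c("A", "C", "G", "T"), 10000,
                                          replace = TRUE,
                                          prob = c(.3, .2, .2, .3)),
                                   collapse = ""))
  bg2 <- fit_background(seq, order = 2)
  oracle <- brute_force_markov(seq, 2)
  expect_lt(max(abs(bg2$cond[[3]] - unname(oracle))), 1e-12)
})

test_that("window scores follow the log-odds arithmetic exactly", {
  # uniform PWM vs uniform background scores 0 everywhere
  up <- pwm(matrix(0.25, 4, 6), pseudocount = 0)
  expect_equal(score_window("ACGTAC", up, uniform_bg()), 0)

  # hand arithmetic: six columns of (0.7, .1, .1, .1) on consensus
  hp <- pwm(matrix(c(0.7, 0.1, 0.1, 0.1), 4, 6), pseudocount = 0)
  expect_equal(score_window("AAAAAA", hp, uniform_bg()),
               6 * log2(0.7 / 0.25), tolerance = 1e-9)

  # equivalence with a brute-force per-position sum on random windows
  g <- default_genome()
  bg <- default_background()
  p <- default_gc_pwm()
  wins <- withr::with_seed(8, vapply(1:100, function(i) {
    paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = "")
  }, character(1)))
  for (w in wins) {
    expect_equal(score_window(w, p, bg), brute_force_score(w, p, bg),
                 tolerance = 1e-9)
  }
})

test_that("best hits recover planted occurrences with deterministic ties", {
  bg <- uniform_bg()
  p <- default_gc_pwm()
  cons <- pwm_consensus(p)
  flank <- withr::with_seed(3, paste(sample(c("A", "T"), 200, TRUE),
                                     collapse = ""))
  seqs <- c(planted = paste0(substr(flank, 1, 37), cons,
                             substr(flank, 38, 150)))
  hit <- best_hit_per_sequence(seqs, p, bg)
  expect_equal(hit$offset, 37L)
  expect_equal(hit$strand, "+")

  # two identical occurrences: the lower offset wins
  twice <- c(s = paste0(cons, strrep("AT", 30), cons))
  hit2 <- best_hit_per_sequence(twice, p, bg)
  expect_equal(hit2$offset, 0L)

  # sequences shorter than the motif are reported and skipped
  expect_warning(res <- best_hit_per_sequence(
    c(ok = paste0(cons, "ACGT"), tiny = "ACGT"), p, bg), "skipped")
  expect_equal(res$seq_id, "ok")
  expect_equal(attr(res, "too_short"), "tiny")
})

test_that("genome scans find planted copies, respect masks and thresholds", {
  g <- default_genome()
  bg <- default_background()
  p <- default_gc_pwm()

  hits <- scan_genome(g, p, bg, score_threshold = 15)
  gc <- g$truth[g$truth$class == "GC", ]
  found <- vapply(seq_len(nrow(gc)), function(i) {
    any(hits$chrom == gc$chrom[i] & hits$start == gc$start[i] &
          hits$strand == gc$strand[i])
  }, logical(1))
  expect_true(all(found))

  # absurd threshold -> empty
  none <- scan_genome(g, p, bg, score_threshold = 1e6)
  expect_equal(nrow(none), 0)

  # intergene mask keeps all hits outside genes
  masked <- scan_genome(g, p, bg, score_threshold = 10,
                        intergenes = g$intergenes)
  for (i in seq_len(nrow(masked))) {
    genes <- g$genes[g$genes$chrom == masked$chrom[i], ]
    expect_false(any(genes$start < masked$end[i] &
                       genes$end > masked$start[i]))
  }

  # strand antisymmetry: scanning the reverse-complemented genome
  # yields the mirror-image hit set with identical scores
  rc <- Biostrings::reverseComplement(g$seq)
  hits_rc <- scan_genome(rc, p, bg, score_threshold = 15)
  lens <- Biostrings::width(g$seq)
  names(lens) <- names(g$seq)
  mirrored <- dplyr::arrange(
    tibble::tibble(chrom = hits_rc$chrom,
                   start = unname(lens[hits_rc$chrom]) - hits_rc$end,
                   strand = ifelse(hits_rc$strand == "+", "-", "+"),
                   score = hits_rc$score),
    chrom, start)
  expect_equal(mirrored$start, hits$start)
  expect_equal(mirrored$strand, hits$strand)
  expect_equal(mirrored$score, hits$score, tolerance = 1e-9)
})

test_that("the mixture split separates well-separated score modes", {
  scores <- withr::with_seed(11, c(rnorm(150, 5, 2), rnorm(150, 20, 2)))
  truth <- rep(c("AT", "GC"), each = 150)
  fit <- split_bimodal(scores)
  expect_true(fit$split)
  expect_gt(fit$threshold, 9)
  expect_lt(fit$threshold, 16)
  expect_gte(mean(tidy(fit)$class == truth), 0.99)
  # component means recovered within 0.5 score units
  expect_lt(abs(fit$means["AT"] - 5), 0.5)
  expect_lt(abs(fit$means["GC"] - 20), 0.5)

  # unimodal scores: no split
  uni <- split_bimodal(withr::with_seed(12, rnorm(300, 10, 2)))
  expect_false(uni$split)
  # degenerate identical scores: no split
  expect_false(split_bimodal(rep(3, 50))$split)
  # too few scores error
  expect_error(split_bimodal(1:5), "at least 10")

  gl <- glance(fit)
  expect_equal(gl$n, 300)
  expect_true(gl$bic_two > gl$bic_one)
})

test_that("flank profiles are orientation-aware and expose the poly(dA) tract", {
  g <- string_genome(chr1 = "AACCGGTTAACCGGTTAACC")
  hit <- tibble::tibble(chrom = "chr1", start = 8L, end = 12L, strand = "+")
  prof <- flank_base_frequencies(g, hit, halfwidth_bp = 2)
  # single hit: one-hot encoding of the flanked window TTAACCGG
  win <- c("T", "T", "A", "A", "C", "C", "G", "G")
  for (k in seq_along(win)) {
    off <- k - 3L     # offsets -2..5
    expect_equal(prof$freq[prof$offset == off & prof$base == win[k]], 1)
  }
  # the same hit on the minus strand contributes the reverse complement
  prof_m <- flank_base_frequencies(
    g, dplyr::mutate(hit, strand = "-"), halfwidth_bp = 2)
  win_rc <- c("C", "C", "G", "G", "T", "T", "A", "A")
  for (k in seq_along(win_rc)) {
    off <- k - 3L
    expect_equal(prof_m$freq[prof_m$offset == off & prof_m$base == win_rc[k]],
                 1)
  }

  # planted poly(dA) 10-35 bp upstream of every GC motif
  gd <- default_genome()
  gc <- gd$truth[gd$truth$class == "GC", ]
  hits <- tibble::tibble(chrom = gc$chrom, start = gc$start, end = gc$end,
                         strand = gc$strand)
  fp <- flank_base_frequencies(gd, hits, halfwidth_bp = 60)
  band <- fp$freq[fp$base == "A" & fp$offset >= -35 & fp$offset <= -10]
  global_a <- mean(fp$freq[fp$base == "A" & fp$offset > 25])
  expect_gte(mean(band) - global_a, 0.2)
})

test_that("motif-TSS distances keep only genes transcribing away", {
  genes <- tibble::tibble(
    chrom = "chr1",
    start = c(1000L, 5000L), end = c(2000L, 6000L),
    strand = c("-", "+"),
    gene_id = c("gL", "gR"),
    tss = c(1999L, 5000L))
  # plus-strand hit between the genes
  hit <- tibble::tibble(chrom = "chr1", start = 3000L, end = 3020L,
                        strand = "+")
  d <- motif_to_tss_distances(hit, genes)
  expect_setequal(d$side, c("5p", "3p"))
  expect_equal(d$distance[d$side == "3p"], 5000 - 3020)
  expect_equal(d$distance[d$side == "5p"], 3000 - 1 - 1999)

  # TSS abutting the motif edge: distance 0
  abut <- tibble::tibble(chrom = "chr1", start = 4980L, end = 5000L,
                         strand = "+")
  expect_equal(motif_to_tss_distances(abut, genes)$distance[1], 0)

  # genes transcribing toward the motif are excluded
  toward <- dplyr::mutate(genes, strand = c("+", "-"),
                          tss = c(1000L, 5999L))
  expect_equal(nrow(motif_to_tss_distances(hit, toward)), 0)

  # planted geometry: TSS 120 bp 3' of each motif
  planted_genes <- tibble::tibble(
    chrom = "chr1", start = 3140L, end = 4000L, strand = "+",
    gene_id = "g1", tss = 3140L)
  d120 <- motif_to_tss_distances(hit, planted_genes)
  expect_equal(d120$distance, 120)
  expect_equal(d120$side, "3p")
})

test_that("core-edge distances are measured in the motif frame", {
  ars <- tibble::tibble(core_start = c(275L, 100L, 100L),
                        core_end = c(425L, 120L, 300L),
                        hit_start = c(280L, 100L, 90L),
                        hit_end = c(300L, 120L, 110L),
                        hit_strand = c("+", "+", "+"))
  d <- core_edge_distances(ars)
  expect_equal(d$dist_5p, c(5L, 0L, -10L))
  expect_equal(d$dist_3p, c(125L, 0L, 190L))
  expect_equal(d$core_flagged, c(FALSE, FALSE, TRUE))

  # minus strand swaps the sides
  minus <- core_edge_distances(dplyr::mutate(ars[1, ], hit_strand = "-"))
  expect_equal(minus$dist_5p, 125L)
  expect_equal(minus$dist_3p, 5L)
})
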