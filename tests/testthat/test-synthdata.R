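# Synthetic genome and assay simulators: determinism, degenerate
# inputs, and distributional properties of the planted material.

test_that("genome generation is deterministic and respects the layout contract", {
  cfg <- synth_config(chrom_len = 2e5L, n_genes = 80L, n_gc_origins = 3L,
                      n_at_origins = 3L, min_origin_spacing_bp = 2e4)
  g1 <- make_genome(cfg, seed = 7)
  g2 <- make_genome(cfg, seed = 7)
  expect_identical(as.character(g1$seq), as.character(g2$seq))
  expect_identical(g1$truth, g2$truth)
  expect_identical(g1$genes, g2$genes)

  # every planted element lies inside an intergene; intervals disjoint
  for (i in seq_len(nrow(g1$truth))) {
    el <- g1$truth[i, ]
    host <- g1$intergenes[g1$intergenes$chrom == el$chrom &
                            g1$intergenes$start <= el$start &
                            g1$intergenes$end >= el$end, ]
    expect_gte(nrow(host), 1)
  }
  tr <- dplyr::arrange(g1$truth, chrom, start)
  by_chr <- split(tr, tr$chrom)
  for (d in by_chr) {
    if (nrow(d) > 1) expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  }

  # planted GC motifs carry the TYGAAC core on the planted strand
  for (i in which(tr$class == "GC")) {
    s <- as.character(Biostrings::subseq(g1$seq[[tr$chrom[i]]],
                                         tr$start[i] + 1, tr$end[i]))
    if (tr$strand[i] == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    expect_match(substr(s, 8, 13), "^T[CT]GAAC$")
  }
})

test_that("a geneless chromosome is one intergene with no orientation classes", {
  cfg <- synth_config(n_chroms = 1L, chrom_len = 5e4L, n_genes = 0L,
                      n_gc_origins = 0L, n_at_origins = 0L)
  g <- make_genome(cfg, seed = 1)
  expect_equal(nrow(g$genes), 0)
  expect_equal(nrow(g$intergenes), 1)
  expect_equal(g$intergenes$start, 0L)
  expect_equal(g$intergenes$end, 5e4L)
  expect_true(is.na(g$intergenes$orientation))
})

test_that("sampled intergene lengths match the configured log-normal", {
  g <- default_genome()
  med <- median(g$intergenes$length)
  expect_lt(abs(med - exp(g$config$intergene_mu)) / exp(g$config$intergene_mu),
            0.10)
})

test_that("infeasible packing fails with an explicit constraint message", {
  cfg <- synth_config(chrom_len = 5e4L, n_genes = 200L,
                      n_gc_origins = 0L, n_at_origins = 0L)
  expect_error(make_genome(cfg, seed = 1), "infeasible packing")
})

test_that("ARS-seq fragments sit on enzyme boundaries and track element strength", {
  g <- default_genome()
  frags <- simulate_arsseq(g, seed = 11)
  expect_gt(nrow(frags), 0)

  # empty truth -> empty library
  empty <- simulate_arsseq(g, truth = g$truth[0, ], seed = 11)
  expect_equal(nrow(empty), 0)

  # all fragment ends are enzyme-site boundaries (or chromosome ends)
  for (chrom in unique(frags$chrom)) {
    s <- g$seq[[chrom]]
    sites <- c(0L, Biostrings::start(
      Biostrings::matchPattern(g$config$enzyme_site, s)) - 1L, length(s))
    f <- frags[frags$chrom == chrom, ]
    expect_true(all(f$start %in% sites))
    expect_true(all(f$end %in% sites))
  }

  # every fragment overlaps its element
  tr <- g$truth
  for (i in seq_len(nrow(frags))) {
    el <- tr[tr$element_id == frags$element_id[i], ]
    expect_true(frags$start[i] <= el$start && frags$end[i] >= el$end)
  }
})

test_that("GC elements are captured at higher read depth than AT elements", {
  cfg <- synth_config(n_chroms = 2L, chrom_len = 1e6L, n_gc_origins = 25L,
                      n_at_origins = 25L, min_origin_spacing_bp = 1e4)
  g <- make_genome(cfg, seed = 21)
  frags <- simulate_arsseq(g, seed = 22)
  depth <- frags |>
    dplyr::left_join(dplyr::select(g$truth, element_id, class),
                     by = "element_id") |>
    dplyr::group_by(element_id, class) |>
    dplyr::summarise(rd = sum(read_depth), .groups = "drop")
  tt <- t.test(depth$rd[depth$class == "GC"], depth$rd[depth$class == "AT"],
               alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})

test_that("miniARS subfragments always contain the planted element", {
  g <- default_genome()
  frags <- simulate_arsseq(g, seed = 31)
  mini <- simulate_miniars(frags, g$truth, subfrags_per_fragment = 30,
                           seed = 32)
  expect_gt(nrow(mini), 0)
  tr <- g$truth
  for (el_id in unique(mini$element_id)) {
    el <- tr[tr$element_id == el_id, ]
    m <- mini[mini$element_id == el_id, ]
    expect_true(all(m$start <= el$start & m$end >= el$end))
    # intersection of retained subfragments contains the element and its
    # width is element width + the two minimal flank overhangs
    inter_lo <- max(m$start); inter_hi <- min(m$end)
    expect_lte(inter_lo, el$start)
    expect_gte(inter_hi, el$end)
    expect_equal(inter_hi - inter_lo,
                 (el$end - el$start) + (el$start - inter_lo) +
                   (inter_hi - el$end))
  }

  # element longer than the maximum subfragment length -> zero retained
  long_truth <- tibble::tibble(
    element_id = "big", chrom = names(g$seq)[1], start = 1000L, end = 1500L,
    class = "AT", strand = "+", strength = 5,
    mean_firing_time_min = 20, efficiency = 0.8)
  parent <- tibble::tibble(
    chrom = names(g$seq)[1], start = 500L, end = 2500L, name = "p",
    read_depth = 10L, strand = "*", enzyme = "GATC", source = "arsseq",
    element_id = "big")
  none <- simulate_miniars(parent, long_truth, len_range = c(100, 400),
                           subfrags_per_fragment = 50, seed = 5)
  expect_equal(nrow(none), 0)
})

test_that("neutral competition libraries stay homogeneous across timepoints", {
  el <- paste(rep(c("A", "C", "G", "T"), 25), collapse = "")
  cnt <- simulate_mutars(el, fitness_fn = NULL, reads_per_tp = 1e6,
                         n_variants = 5000, n_replicates = 1, seed = 41)
  # per-position chi-squared homogeneity between t0 and t36
  pvals <- vapply(seq(5, 95, by = 5), function(pos) {
    d0 <- cnt[cnt$timepoint_h == 0 & cnt$position == pos, ]
    d1 <- cnt[cnt$timepoint_h == 36 & cnt$position == pos, ]
    keep <- d0$count + d1$count > 0
    suppressWarnings(chisq.test(cbind(d0$count[keep], d1$count[keep]))$p.value)
  }, numeric(1))
  expect_lte(mean(pvals < 0.01), 0.15)

  # expected mutations per 100-mer = 100 x 0.02 = 2.0
  vm <- attr(cnt, "variants")
  ref <- match(strsplit(el, "")[[1]], c("A", "C", "G", "T"))
  mism <- rowSums(vm != matrix(ref, nrow(vm), 100, byrow = TRUE))
  expect_lt(abs(mean(mism) - 2), 0.1)
})

test_that("the stated growth law holds: w = 2 over 5 doublings gives ratio 2^5", {
  el <- strrep("A", 100)
  # variants carrying G at position 1 get fitness 2, everything else 1
  fit_fn <- function(v) if (substr(v, 1, 1) == "G") 2 else 1
  cnt <- simulate_mutars(el, fit_fn, timepoints_h = c(0, 36),
                         reads_per_tp = 2e6, n_variants = 20000,
                         growth_per_h = 5 / 36, n_replicates = 1, seed = 43)
  enr <- enrichment_ratio(cnt, 36, min_count = 5)
  g_row <- enr[enr$position == 1 & enr$base == "G", ]
  a_row <- enr[enr$position == 1 & enr$base == "A", ]
  # log2 enrichment of the fit allele relative to the neutral reference
  expect_lt(abs((g_row$log2_ratio - a_row$log2_ratio) - 5), 0.3)
})

test_that("timing reads reflect the fork model geometry", {
  # zero origins: flat ratio profile
  cfg0 <- synth_config(n_chroms = 1L, chrom_len = 2e5L, n_genes = 100L,
                       n_gc_origins = 0L, n_at_origins = 0L)
  g0 <- make_genome(cfg0, seed = 51)
  reads0 <- simulate_timing_reads(g0, reads_per_bin = 2000,
                                  n_replicates = 1, seed = 52)
  s0 <- bin_reads(reads0[reads0$phase == "S", ], g0)
  g1_0 <- bin_reads(reads0[reads0$phase == "G1", ], g0)
  r0 <- ratio_profile(s0, g1_0)
  expect_lt(abs(mean(r0$ratio, na.rm = TRUE) - 1.5), 0.05)
  expect_lt(stats::sd(r0$ratio, na.rm = TRUE), 0.1)

  # single always-firing origin: copy number decays with distance
  cfg1 <- synth_config(n_chroms = 1L, chrom_len = 4e5L, n_genes = 200L,
                       n_gc_origins = 1L, n_at_origins = 0L,
                       gc_efficiency = 1, fire_sd = 0.01)
  g1 <- make_genome(cfg1, seed = 53)
  reads1 <- simulate_timing_reads(g1, reads_per_bin = 2900,
                                  n_replicates = 2, firing_sd_min = 0.01,
                                  seed = 54)
  tracks <- purrr::map_dfr(1:2, function(r) {
    st <- bin_reads(reads1[reads1$replicate == r & reads1$phase == "S", ], g1)
    gt <- bin_reads(reads1[reads1$replicate == r & reads1$phase == "G1", ], g1)
    dplyr::mutate(ratio_profile(st, gt), replicate = r)
  })
  prof <- smooth_and_normalize(tracks)
  # monotone decay holds within fork reach of the origin
  origin_mid <- arscan:::interval_mid(g1$truth$start[1], g1$truth$end[1])
  dist <- abs(prof$start + 500 - origin_mid)
  ok <- !is.na(prof$smoothed) & dist <= 40000
  expect_lt(cor(prof$smoothed[ok], dist[ok], method = "spearman"), -0.95)
})

test_that("scaled S/G1 ratios stay inside the [1, 2] copy band up to noise", {
  tracks <- default_timing()$tracks
  expect_gte(mean(tracks$ratio >= 0.9 & tracks$ratio <= 2.1, na.rm = TRUE),
             0.99)
})

test_that("MNase fragments avoid NDRs and phase at the configured spacing", {
  g <- default_genome()
  frags <- simulate_mnase(g, n_fragments = 1e5, seed = 61)
  ndrs <- attr(frags, "ndrs")
  expect_gt(nrow(frags), 0)

  # no fragment midpoint inside an NDR
  mids <- arscan:::interval_mid(frags$start, frags$end)
  in_ndr <- rep(FALSE, nrow(frags))
  for (chr in unique(frags$chrom)) {
    nd <- ndrs[ndrs$chrom == chr, ]
    sel <- frags$chrom == chr
    hit <- IRanges::findOverlaps(
      IRanges::IRanges(mids[sel] + 1L, mids[sel] + 1L),
      IRanges::IRanges(nd$start + 1L, nd$end))
    in_ndr[which(sel)[S4Vectors::queryHits(hit)]] <- TRUE
  }
  expect_lt(mean(in_ndr), 0.005)

  # zero fragments -> empty table
  none <- simulate_mnase(g, n_fragments = 0, seed = 61)
  expect_equal(nrow(none), 0)

  # autocorrelation of midpoint density peaks near the 165 bp repeat
  chrom <- names(g$seq)[1]
  dens <- tabulate(mids[frags$chrom == chrom] + 1L, nbins = length(g$seq[[chrom]]))
  ac <- stats::acf(dens, lag.max = 250, plot = FALSE)$acf[-1]
  peak_lag <- which.max(ac[100:250]) + 99
  expect_gte(peak_lag, 155)
  expect_lte(peak_lag, 175)
})
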