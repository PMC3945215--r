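# Fragment end validation, contig assembly (with a brute-force oracle),
# depth filters, bridge resolution, core inference and table compilation.

frag_row <- function(chrom, start, end, rd = 1L, enzyme = "GATC") {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(end),
                 name = sprintf("%s_%d_%d", chrom, start, end),
                 read_depth = as.integer(rd), strand = "*",
                 enzyme = enzyme, source = "arsseq")
}

test_that("fragment ends snap outward to enzyme sites within tolerance", {
  # GATC at 0-based positions 10, 40, 80
  seq <- paste0(strrep("A", 10), "GATC", strrep("C", 26), "GATC",
                strrep("T", 36), "GATC", strrep("A", 16))
  g <- string_genome(chr1 = seq)

  # ends exactly on boundaries: unchanged
  f0 <- validate_fragment_ends(frag_row("chr1", 10, 40), g)
  expect_equal(f0$start, 10L)
  expect_equal(f0$end, 40L)
  expect_equal(f0$enzyme, "GATC")

  # end 3 bp inside the nearest site, tolerance 10: moved to the site
  f1 <- validate_fragment_ends(frag_row("chr1", 13, 37), g, tolerance_bp = 10)
  expect_equal(f1$start, 10L)
  expect_equal(f1$end, 40L)

  # no site within tolerance: coordinates unchanged, enzyme = "unk"
  f2 <- validate_fragment_ends(frag_row("chr1", 55, 60), g, tolerance_bp = 5)
  expect_equal(f2$start, 55L)
  expect_equal(f2$end, 60L)
  expect_equal(f2$enzyme, "unk")

  # fragment outside the chromosome errors
  expect_error(validate_fragment_ends(frag_row("chr1", 50, 9999), g),
               "bounds")
})

test_that("contig assembly merges transitive overlaps and sums depth", {
  expect_equal(nrow(assemble_contigs(frag_row("chr1", 1, 1)[0, ])), 0)

  two <- dplyr::bind_rows(frag_row("chr1", 100, 400, rd = 3),
                          frag_row("chr1", 300, 700, rd = 2))
  ctg <- assemble_contigs(two)
  expect_equal(nrow(ctg), 1)
  expect_equal(ctg$start, 100L)
  expect_equal(ctg$end, 700L)
  expect_equal(ctg$combined_rd, 5L)
  expect_equal(ctg$fragment_count, 2L)

  # disjoint fragments stay separate; touching half-open intervals too
  expect_equal(nrow(assemble_contigs(dplyr::bind_rows(
    frag_row("chr1", 100, 200), frag_row("chr1", 300, 400)))), 2)
  expect_equal(nrow(assemble_contigs(dplyr::bind_rows(
    frag_row("chr1", 100, 200), frag_row("chr1", 200, 300)))), 2)
})

test_that("assembly matches the brute-force connected-components oracle", {
  frags <- random_fragment_set(1000, seed = 77)
  got <- assemble_contigs(frags)
  want <- brute_force_contigs(frags)
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$start, want$start)
  expect_equal(got$end, want$end)
  expect_equal(got$combined_rd, want$combined_rd)
  expect_equal(got$fragment_count, want$fragment_count)

  # order independence and idempotence
  perm <- withr::with_seed(9, frags[sample.int(nrow(frags)), ])
  got2 <- assemble_contigs(perm)
  expect_equal(got2$start, got$start)
  expect_equal(got2$end, got$end)
  expect_equal(got2$combined_rd, got$combined_rd)
})

test_that("depth and fragment-count filters use the documented boundaries", {
  frags <- dplyr::bind_rows(
    frag_row("chr1", 100, 400, rd = 1),           # rd 1 -> removed
    frag_row("chr1", 1000, 1400, rd = 2),         # rd 2 -> retained
    frag_row("chr2", 100, 400, rd = 1))
  ctg <- assemble_contigs(frags)
  kept <- filter_contigs_arsseq(ctg)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$combined_rd, 2L)
  expect_equal(nrow(filter_contigs_arsseq(assemble_contigs(
    frag_row("chr1", 1, 50, rd = 1)))), 0)

  # miniARS: fewer than three unique fragments removed, duplicates
  # counted once
  mini <- dplyr::bind_rows(
    frag_row("chr1", 100, 300, rd = 3), frag_row("chr1", 150, 350, rd = 2),
    frag_row("chr1", 200, 380, rd = 2),
    frag_row("chr2", 100, 300, rd = 3), frag_row("chr2", 100, 300, rd = 2),
    frag_row("chr2", 150, 350, rd = 2))
  mc <- filter_contigs_miniars(assemble_contigs(mini))
  expect_equal(nrow(mc), 1)
  expect_equal(mc$chrom, "chr1")
})

test_that("bridged contigs split at deep valleys and keep honest ones", {
  # two depth-50 blocks joined by one depth-1 bridge
  bridged <- dplyr::bind_rows(
    frag_row("chr1", 0, 400, rd = 50),
    frag_row("chr1", 800, 1200, rd = 50),
    frag_row("chr1", 300, 900, rd = 1))
  res <- resolve_bridged_contigs(assemble_contigs(bridged))
  expect_equal(nrow(res), 2)
  expect_equal(res$start, c(0L, 800L))
  expect_equal(res$end, c(400L, 1200L))

  # unimodal profile unchanged
  uni <- dplyr::bind_rows(frag_row("chr1", 0, 400, rd = 10),
                          frag_row("chr1", 200, 600, rd = 10))
  expect_equal(nrow(resolve_bridged_contigs(assemble_contigs(uni))), 1)

  # valley exactly at bridge_fraction x flank: strict inequality, no split
  exact <- dplyr::bind_rows(
    frag_row("chr1", 0, 400, rd = 9),
    frag_row("chr1", 800, 1200, rd = 9),
    frag_row("chr1", 300, 900, rd = 1))
  expect_equal(nrow(resolve_bridged_contigs(assemble_contigs(exact),
                                            bridge_fraction = 0.1)), 1)
})

test_that("core inference intersects members and applies the 150 bp rule", {
  lens <- c(chr1 = 10000L)
  ctg <- assemble_contigs(dplyr::bind_rows(
    frag_row("chr1", 100, 400, rd = 3), frag_row("chr1", 300, 700, rd = 2)))
  core <- infer_core(ctg, lens)
  expect_equal(core$core_start, 275L)    # raw [300, 400) extended to 150 bp
  expect_equal(core$core_end, 425L)
  expect_false(core$core_flagged)

  # a single long fragment is its own core, no extension
  one <- infer_core(assemble_contigs(frag_row("chr1", 0, 600, rd = 2)), lens)
  expect_equal(one$core_start, 0L)
  expect_equal(one$core_end, 600L)

  # clipping at the chromosome start pushes the deficit rightward
  edge <- infer_core(assemble_contigs(dplyr::bind_rows(
    frag_row("chr1", 0, 40, rd = 2), frag_row("chr1", 10, 300, rd = 2))), lens)
  expect_equal(edge$core_start, 0L)      # raw [10, 40) -> [0, 150)
  expect_equal(edge$core_end, 150L)
})

test_that("low-depth contigs far from any timing peak are flagged, not dropped", {
  peaks <- tibble::tibble(chrom = "chr1", coord = 50500)
  ctgs <- assemble_contigs(dplyr::bind_rows(
    frag_row("chr1", 50000, 50400, rd = 5),     # at a peak
    frag_row("chr1", 100000, 100400, rd = 5),   # 50 kb away
    frag_row("chr1", 200000, 200400, rd = 500)))# depth out of range
  flagged <- flag_low_depth_off_peak(ctgs, peaks, near_kb = 20)
  expect_equal(flagged$flagged_candidate, c(FALSE, TRUE, FALSE))
  expect_equal(nrow(flagged), nrow(ctgs))
})

test_that("the compiled table names ARSs by chromosome letter and kb", {
  lens <- c(chr1 = 3e6L, chr2 = 3e6L)
  ctg <- infer_core(assemble_contigs(dplyr::bind_rows(
    frag_row("chr1", 2772000, 2772800, rd = 20),
    frag_row("chr2", 500000, 500600, rd = 10))), lens)
  out <- compile_ars_table(ctg, chrom_order = c("chr1", "chr2"))
  expect_equal(out$ars$ARS_name, c("A2772", "B500"))
  # exported coordinates are 1-based inclusive
  expect_equal(out$ars$start[1], 2772001)
  expect_equal(out$ars$end[1], 2772800)

  # same-name collisions get deterministic suffixes by coordinate
  ctg2 <- infer_core(assemble_contigs(dplyr::bind_rows(
    frag_row("chr1", 2772000, 2772300, rd = 20),
    frag_row("chr1", 2772500, 2772900, rd = 20))), lens)
  out2 <- compile_ars_table(ctg2, chrom_order = c("chr1", "chr2"))
  expect_equal(out2$ars$ARS_name, c("A2772", "A2772.2"))

  # miniARS cores join by overlap; non-overlapping ones are reported
  mini <- infer_core(assemble_contigs(dplyr::bind_rows(
    frag_row("chr1", 2772100, 2772400, rd = 3),
    frag_row("chr1", 2772150, 2772500, rd = 3),
    frag_row("chr1", 2772200, 2772600, rd = 3))), lens)
  lost <- infer_core(assemble_contigs(dplyr::bind_rows(
    frag_row("chr2", 1000000, 1000300, rd = 3),
    frag_row("chr2", 1000050, 1000350, rd = 3),
    frag_row("chr2", 1000100, 1000400, rd = 3))), lens)
  mini_all <- filter_contigs_miniars(dplyr::bind_rows(mini, lost))
  out3 <- compile_ars_table(ctg, mini_all, chrom_order = c("chr1", "chr2"))
  expect_false(is.na(out3$ars$miniARS_core_start[1]))
  expect_equal(nrow(out3$unmatched_miniars), 1)
  expect_equal(out3$unmatched_miniars$chrom, "chr2")
})

test_that("miniARS cores recover planted elements on synthetic screens", {
  g <- default_genome()
  frags <- simulate_arsseq(g, seed = 301)
  mini <- simulate_miniars(frags, g$truth, subfrags_per_fragment = 25,
                           seed = 302)
  mini_ctg <- mini |>
    dplyr::filter(read_depth >= 2) |>
    assemble_contigs() |>
    filter_contigs_miniars() |>
    infer_core(g)
  # match each contig to its element and require the core to contain it
  hit <- 0L; total <- 0L
  for (i in seq_len(nrow(mini_ctg))) {
    m <- mini_ctg$members[[i]]
    el <- g$truth[g$truth$element_id == m$element_id[1], ]
    if (nrow(m) < 20) next
    total <- total + 1L
    if (mini_ctg$core_start[i] <= el$start && mini_ctg$core_end[i] >= el$end) {
      hit <- hit + 1L
    }
  }
  expect_gte(total, 10)
  expect_gte(hit / total, 0.99)
})
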