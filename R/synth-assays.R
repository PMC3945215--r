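# Simulators for every assay the pipeline consumes: partial-digest ARS
# fragment libraries, miniARS subfragment screens, mutagenized
# competition libraries, S/G1 sorted read sets and MNase fragments.
# All are deterministic under a fixed seed.

#' Simulate an ARS-seq fragment library
#'
#' Emulates a partial restriction digest screen: for every planted
#' element, fragments are unions of consecutive enzyme-delimited
#' intervals covering the element (the number of skipped sites on each
#' side is geometric), and read depth is negative-binomial with mean
#' proportional to the element's strength, so the GC class (higher
#' strength by default) is captured at higher depth.
#'
#' @param genome A `synth_genome`.
#' @param truth Ground-truth tibble (defaults to `genome$truth`).
#' @param frags_per_element Mean number of distinct fragments recovered
#'   per element (Poisson, at least 1).
#' @param skip_prob Geometric parameter for the number of restriction
#'   sites skipped by the partial digest on each side.
#' @param depth_per_strength Mean read depth per unit of element
#'   strength.
#' @param nb_size Negative-binomial dispersion of read depth.
#' @param seed Integer seed.
#'
#' @return A fragment tibble: `chrom, start, end, name, read_depth,
#'   strand, enzyme, source, element_id` (0-based half-open).
#' @export
simulate_arsseq <- function(genome, truth = genome$truth,
                            frags_per_element = 8, skip_prob = 0.5,
                            depth_per_strength = 1, nb_size = 2,
                            seed = genome$config$seed) {
  cfg <- genome$config
  site <- cfg$enzyme_site %||% "GATC"
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), read_depth = integer(),
                  strand = character(), enzyme = character(),
                  source = character(), element_id = character())
  if (nrow(truth) == 0) return(empty)
  seqs <- genome_seqs(genome)
  sites <- lapply(as.character(seqs), function(s) {
    m <- Biostrings::matchPattern(site, Biostrings::DNAString(s))
    pos <- Biostrings::start(m) - 1L            # 0-based cut positions
    if (length(pos) < 2) {
      abort(sprintf("enzyme site %s occurs fewer than 2 times on a chromosome",
                    site))
    }
    c(0L, pos, nchar(s))                        # include chromosome ends
  })
  with_seed(seed, {
    rows <- purrr::map_dfr(seq_len(nrow(truth)), function(i) {
      el <- truth[i, ]
      bnd <- sites[[el$chrom]]
      li0 <- max(which(bnd <= el$start))
      ri0 <- min(which(bnd >= el$end))
      nf <- max(1L, rpois(1, frags_per_element))
      purrr::map_dfr(seq_len(nf), function(k) {
        li <- max(1L, li0 - rgeom(1, skip_prob))
        ri <- min(length(bnd), ri0 + rgeom(1, skip_prob))
        depth <- 1L + rnbinom(1, size = nb_size,
                              mu = el$strength * depth_per_strength)
        tibble(chrom = el$chrom, start = bnd[li], end = bnd[ri],
               read_depth = as.integer(depth), strand = "*",
               enzyme = site, source = "arsseq", element_id = el$element_id)
      })
    })
    rows <- rows %>%
      mutate(name = sprintf("%s_%d_%d", .data$chrom, .data$start, .data$end)) %>%
      select("chrom", "start", "end", "name", "read_depth", "strand",
             "enzyme", "source", "element_id")
    rows
  })
}

#' Simulate a miniARS-seq subfragment screen
#'
#' Draws random subfragments (uniform breakpoints, length ~ U[100, 400]
#' by default) of each input fragment and retains a subfragment as
#' functional only if it fully contains the planted element, so the
#' intersection of retained subfragments always contains the element.
#'
#' @param fragments ARS-seq fragment tibble (with `element_id`).
#' @param truth Ground-truth tibble giving each element's interval.
#' @param subfrags_per_fragment Subfragments drawn per input fragment.
#' @param len_range Subfragment length range (bp).
#' @param depth_mean Mean retained-subfragment read depth (negative
#'   binomial, shifted to be >= 2 as the screen filter requires).
#' @param seed Integer seed.
#'
#' @return A fragment tibble like [simulate_arsseq()] with
#'   `source = "miniars"`.
#' @export
simulate_miniars <- function(fragments, truth, subfrags_per_fragment = 12,
                             len_range = c(100, 400), depth_mean = 5,
                             seed = 1L) {
  empty <- fragments[0, ]
  if (nrow(fragments) == 0) return(empty)
  with_seed(seed, {
    rows <- purrr::map_dfr(seq_len(nrow(fragments)), function(i) {
      fr <- fragments[i, ]
      el <- truth[truth$element_id == fr$element_id, ]
      if (nrow(el) != 1) return(NULL)
      len <- as.integer(round(runif(subfrags_per_fragment,
                                    len_range[1], len_range[2])))
      len <- pmin(len, fr$end - fr$start)
      start <- fr$start +
        as.integer(floor(runif(subfrags_per_fragment) *
                           (fr$end - fr$start - len + 1)))
      end <- start + len
      keep <- start <= el$start & end >= el$end
      if (!any(keep)) return(NULL)
      depth <- 2L + rnbinom(sum(keep), size = 2, mu = depth_mean)
      tibble(chrom = fr$chrom, start = start[keep], end = end[keep],
             read_depth = as.integer(depth), strand = "*", enzyme = "unk",
             source = "miniars", element_id = fr$element_id)
    })
    if (nrow(rows) == 0) return(empty)
    rows %>%
      mutate(name = sprintf("%s_%d_%d", .data$chrom, .data$start, .data$end)) %>%
      select("chrom", "start", "end", "name", "read_depth", "strand",
             "enzyme", "source", "element_id")
  })
}

#' Fitness function tied to a planted motif
#'
#' Returns a function mapping a variant of `ref_seq` to a growth
#' fitness: fitness declines linearly with the log-odds score lost at
#' the planted motif, floored at `floor`.
#'
#' @param ref_seq Reference element sequence.
#' @param motif_pwm The planted [pwm].
#' @param motif_offset 0-based offset of the motif within `ref_seq`.
#' @param slope Fitness lost per bit of motif score loss.
#' @param floor Minimum fitness.
#'
#' @return `function(variant_seq) -> numeric fitness`.
#' @export
motif_fitness_fn <- function(ref_seq, motif_pwm, motif_offset,
                             slope = 0.05, floor = 0.05) {
  w <- pwm_width(motif_pwm)
  lp <- log2(motif_pwm$freq)
  score_of <- function(s) {
    b <- encode_dna(substr(s, motif_offset + 1, motif_offset + w))
    sum(lp[cbind(b, seq_len(w))])
  }
  ref_score <- score_of(ref_seq)
  function(variant_seq) {
    loss <- ref_score - score_of(variant_seq)
    max(floor, 1 - slope * max(0, loss))
  }
}

#' Simulate a deep-mutational-scanning competition
#'
#' Builds a library of variants of a 100 bp element with an independent
#' 2% chance of a random substitution at each position, grows it
#' competitively (variant frequency at time `t` proportional to
#' `f0 * w^(g t)`), and samples position x base read counts at each
#' timepoint by multinomial sequencing.
#'
#' @param element_seq Reference element sequence (typically 100 bp).
#' @param fitness_fn `function(variant) -> w > 0`; defaults to neutral
#'   (`w = 1` for every variant).  See [motif_fitness_fn()].
#' @param timepoints_h Sampling times in hours.
#' @param reads_per_tp Reads sequenced per timepoint and replicate.
#' @param n_variants Library size.
#' @param mut_rate Per-base substitution probability.
#' @param growth_per_h Effective doublings-equivalent per hour (`g`).
#' @param n_replicates Biological replicates (independent sampling of
#'   the same library).
#' @param seed Integer seed.
#'
#' @return A tibble `timepoint_h, replicate, position, base, count`
#'   (1-based positions) with the variant matrix, fitnesses and
#'   parameters attached as attributes (`variants`, `fitness`,
#'   `ref_seq`).
#' @export
simulate_mutars <- function(element_seq, fitness_fn = NULL,
                            timepoints_h = c(0, 12, 24, 36),
                            reads_per_tp = 5e5, n_variants = 20000,
                            mut_rate = 0.02, growth_per_h = 10 / 36,
                            n_replicates = 2, seed = 1L) {
  L <- nchar(element_seq)
  ref <- encode_dna(element_seq)
  check_that(!anyNA(ref), "element_seq must be plain ACGT")
  with_seed(seed, {
    # variant matrix: n_variants x L integer codes
    vm <- matrix(rep(ref, each = n_variants), nrow = n_variants)
    mut <- matrix(runif(n_variants * L) < mut_rate, nrow = n_variants)
    if (any(mut)) {
      idx <- which(mut)
      old <- vm[idx]
      shift <- sample.int(3, length(idx), replace = TRUE)
      vm[idx] <- ((old - 1L + shift) %% 4L) + 1L   # uniform over alternatives
    }
    w <- if (is.null(fitness_fn)) {
      rep(1, n_variants)
    } else {
      seqs <- apply(vm, 1, decode_dna)
      vapply(seqs, fitness_fn, numeric(1), USE.NAMES = FALSE)
    }
    check_that(all(w > 0), "fitness must be positive")
    f0 <- rep(1 / n_variants, n_variants)
    out <- purrr::map_dfr(timepoints_h, function(t) {
      ft <- f0 * w^(growth_per_h * t)
      ft <- ft / sum(ft)
      purrr::map_dfr(seq_len(n_replicates), function(rep_i) {
        reads <- as.integer(rmultinom(1, size = reads_per_tp, prob = ft))
        counts <- matrix(0, nrow = 4, ncol = L)
        for (bse in 1:4) {
          counts[bse, ] <- colSums((vm == bse) * reads)
        }
        tibble(timepoint_h = t, replicate = rep_i,
               position = rep(seq_len(L), each = 4),
               base = rep(DNA_BASES, times = L),
               count = as.integer(counts[cbind(rep(1:4, times = L),
                                               rep(seq_len(L), each = 4))]))
      })
    })
    attr(out, "variants") <- vm
    attr(out, "fitness") <- w
    attr(out, "ref_seq") <- element_seq
    out
  })
}

#' Simulate sorted S/G1 sequencing reads
#'
#' Per-cell fork model: each origin fires with probability `efficiency`
#' at a normal time around its mean; forks move outward at constant
#' speed; a locus is replicated at the minimum over fired origins of
#' firing time + distance / fork rate.  S cells are sampled uniformly
#' through S phase, giving a per-bin copy number in [1, 2]; reads are
#' Poisson with mean proportional to copy number (G1: copy 1).
#'
#' @param genome A `synth_genome`.
#' @param truth Ground-truth tibble (defaults to `genome$truth`).
#' @param reads_per_bin Target mean reads per 1 kb bin per sample.
#' @param bin_size Bin width used to discretize positions (bp).
#' @param n_replicates Biological replicates.
#' @param n_cells Cells simulated per replicate for the copy-number
#'   expectation.
#' @param firing_sd_min SD of origin firing time (minutes).
#' @param seed Integer seed.
#'
#' @return A tibble `chrom, pos, phase, replicate` of mapped read start
#'   positions (0-based).
#' @export
simulate_timing_reads <- function(genome, truth = genome$truth,
                                  reads_per_bin = 2900, bin_size = 1000,
                                  n_replicates = 2, n_cells = 1000,
                                  firing_sd_min = 2.5,
                                  seed = genome$config$seed) {
  cfg <- genome$config
  lens <- chrom_lengths(genome)
  with_seed(seed, {
    purrr::map_dfr(seq_len(n_replicates), function(rep_i) {
      purrr::map_dfr(names(lens), function(chrom) {
        len <- lens[[chrom]]
        n_bins <- ceiling(len / bin_size)
        mids <- (seq_len(n_bins) - 0.5) * bin_size
        org <- truth[truth$chrom == chrom, ]
        copy <- rep(1, n_bins)
        if (nrow(org) > 0) {
          o_mid <- interval_mid(org$start, org$end)
          # cells x origins firing times (NA = did not fire)
          fire <- matrix(rnorm(n_cells * nrow(org),
                               rep(org$mean_firing_time_min, each = n_cells),
                               firing_sd_min),
                         nrow = n_cells)
          fire[fire < 0] <- 0
          fired <- matrix(runif(n_cells * nrow(org)) <
                            rep(org$efficiency, each = n_cells),
                          nrow = n_cells)
          fire[!fired] <- Inf
          u <- runif(n_cells, 0, cfg$s_phase_min)
          # replication time per (bin, cell): min over fired origins
          dist <- abs(outer(mids, o_mid, "-"))
          t_min <- matrix(Inf, n_bins, n_cells)
          for (o in seq_len(nrow(org))) {
            t_min <- pmin(t_min,
                          outer(dist[, o] / cfg$fork_rate_bp_per_min,
                                fire[, o], "+"))
          }
          repl_frac <- rowMeans(sweep(t_min, 2, u, "<="))
          copy <- 1 + repl_frac
        }
        total_g1 <- reads_per_bin * n_bins
        lam_s <- copy / sum(copy) * total_g1 * mean(copy)
        counts_g1 <- rpois(n_bins, reads_per_bin)
        counts_s <- rpois(n_bins, lam_s)
        mk <- function(counts, phase) {
          pos <- rep.int((seq_len(n_bins) - 1L) * bin_size, counts) +
            as.integer(floor(runif(sum(counts)) * bin_size))
          pos <- pmin(pos, len - 1L)
          tibble(chrom = chrom, pos = pos, phase = phase,
                 replicate = rep_i)
        }
        bind_rows(mk(counts_g1, "G1"), mk(counts_s, "S"))
      })
    })
  })
}

# Nucleosome-depleted regions implied by a genome's annotation + truth:
# a wide NDR 5' of each GC motif, a narrow NDR centred on each AT
# element, and a promoter NDR at every TSS.
ndr_intervals <- function(genome, truth = genome$truth) {
  cfg <- genome$config
  rows <- list()
  if (nrow(truth) > 0) {
    gc <- truth[truth$class == "GC", ]
    if (nrow(gc) > 0) {
      plus <- gc$strand == "+"
      ndr_start <- ifelse(plus, gc$start - cfg$ndr_gc_gap - cfg$ndr_gc_bp,
                          gc$end + cfg$ndr_gc_gap)
      rows <- c(rows, list(tibble(
        chrom = gc$chrom, start = as.integer(ndr_start),
        end = as.integer(ndr_start + cfg$ndr_gc_bp), kind = "GC")))
    }
    at <- truth[truth$class == "AT", ]
    if (nrow(at) > 0) {
      mid <- interval_mid(at$start, at$end)
      rows <- c(rows, list(tibble(
        chrom = at$chrom, start = as.integer(mid - cfg$ndr_at_bp %/% 2),
        end = as.integer(mid - cfg$ndr_at_bp %/% 2 + cfg$ndr_at_bp),
        kind = "AT")))
    }
  }
  if (nrow(genome$genes) > 0) {
    g <- genome$genes
    rows <- c(rows, list(tibble(
      chrom = g$chrom, start = as.integer(g$tss - cfg$ndr_tss_bp %/% 2),
      end = as.integer(g$tss - cfg$ndr_tss_bp %/% 2 + cfg$ndr_tss_bp),
      kind = "TSS")))
  }
  ndr <- bind_rows(rows)
  if (nrow(ndr) == 0) return(ndr)
  lens <- chrom_lengths(genome)
  ndr %>%
    mutate(start = pmax(.data$start, 0L),
           end = pmin(.data$end, as.integer(lens[.data$chrom]))) %>%
    filter(.data$end > .data$start) %>%
    arrange(.data$chrom, .data$start)
}

#' Simulate MNase mononucleosome fragments
#'
#' Places nucleosome dyads by statistical positioning against barriers:
#' every nucleosome-depleted region (wide NDR 5' of GC motifs, narrow
#' NDR at AT elements, promoter NDR at TSSs) acts as a barrier, and
#' arrays phase off both edges with Normal(spacing, sd) repeat lengths.
#' Fragments have Normal(150, 10) lengths centred on sampled dyads;
#' fragment midpoints never fall inside an NDR.
#'
#' @param genome A `synth_genome`.
#' @param truth Ground-truth tibble (defaults to `genome$truth`).
#' @param n_fragments Total fragments to sample.
#' @param frag_len_mean,frag_len_sd Fragment length distribution.
#' @param dyad_jitter_sd Per-fragment jitter of the dyad position (bp).
#' @param seed Integer seed.
#'
#' @return A tibble `chrom, start, end` (0-based half-open), with the
#'   NDR table attached as attribute `ndrs`.
#' @export
simulate_mnase <- function(genome, truth = genome$truth, n_fragments = 2e5,
                           frag_len_mean = 150, frag_len_sd = 10,
                           dyad_jitter_sd = 3, seed = genome$config$seed) {
  cfg <- genome$config
  lens <- chrom_lengths(genome)
  ndrs <- ndr_intervals(genome, truth)
  if (n_fragments == 0) {
    out <- tibble(chrom = character(), start = integer(), end = integer())
    attr(out, "ndrs") <- ndrs
    return(out)
  }
  with_seed(seed, {
    # dyad positions per chromosome
    dyads <- purrr::map_dfr(names(lens), function(chrom) {
      len <- lens[[chrom]]
      nd <- ndrs[ndrs$chrom == chrom, ]
      # merge overlapping NDRs into disjoint barriers
      if (nrow(nd) > 0) {
        ir <- IRanges::reduce(IRanges::IRanges(nd$start + 1L, nd$end))
        b_start <- IRanges::start(ir) - 1L
        b_end <- IRanges::end(ir)
      } else {
        b_start <- integer(0); b_end <- integer(0)
      }
      # linker regions between consecutive barriers (and chromosome ends)
      edges_l <- c(0L, b_end)        # left edge of each free region
      edges_r <- c(b_start, len)     # right edge
      pos <- purrr::map(seq_along(edges_l), function(k) {
        lo <- edges_l[k]; hi <- edges_r[k]
        if (hi - lo < 147) return(numeric(0))
        midpt <- (lo + hi) / 2
        # phase rightward from the left barrier up to the region middle
        p_r <- numeric(0); cur <- lo + 73
        while (cur <= midpt) {
          p_r <- c(p_r, cur)
          cur <- cur + rnorm(1, cfg$mnase_spacing_bp, cfg$mnase_spacing_sd %||% 8)
        }
        p_l <- numeric(0); cur <- hi - 73
        while (cur > midpt) {
          p_l <- c(p_l, cur)
          cur <- cur - rnorm(1, cfg$mnase_spacing_bp, cfg$mnase_spacing_sd %||% 8)
        }
        c(p_r, p_l)
      })
      tibble(chrom = chrom, dyad = unlist(pos))
    })
    check_that(nrow(dyads) > 0, "no room to place nucleosomes")
    idx <- sample.int(nrow(dyads), n_fragments, replace = TRUE)
    mid <- dyads$dyad[idx] + rnorm(n_fragments, 0, dyad_jitter_sd)
    chrom <- dyads$chrom[idx]
    flen <- pmax(100, round(rnorm(n_fragments, frag_len_mean, frag_len_sd)))
    start <- as.integer(round(mid - flen / 2))
    end <- as.integer(start + flen)
    keep <- start >= 0 & end <= lens[chrom]
    # reject fragments whose midpoint drifted into an NDR
    m <- as.integer(round(mid))
    if (nrow(ndrs) > 0) {
      in_ndr <- logical(n_fragments)
      for (chr in unique(chrom)) {
        nd <- ndrs[ndrs$chrom == chr, ]
        if (nrow(nd) == 0) next
        sel <- which(chrom == chr)
        ov <- IRanges::findOverlaps(
          IRanges::IRanges(m[sel] + 1L, m[sel] + 1L),
          IRanges::IRanges(nd$start + 1L, nd$end))
        in_ndr[sel[S4Vectors::queryHits(ov)]] <- TRUE
      }
      keep <- keep & !in_ndr
    }
    out <- tibble(chrom = chrom[keep], start = start[keep], end = end[keep]) %>%
      arrange(.data$chrom, .data$start)
    attr(out, "ndrs") <- ndrs
    out
  })
}
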