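# Shared fixtures (built in code) and independent brute-force oracles.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, expr, envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# one default synthetic genome reused across test files
default_genome <- function() {
  cached_fixture("genome", make_genome(synth_config(), seed = 101))
}

# timing reads + ratio tracks + smoothed profile for the default genome
# at the sequencing depth of the sorted-cell experiments (2,900 reads
# per 1 kb bin per sample)
default_timing <- function() {
  cached_fixture("timing", {
    g <- default_genome()
    reads <- simulate_timing_reads(g, reads_per_bin = 2900,
                                   n_replicates = 2, seed = 202)
    tracks <- purrr::map_dfr(1:2, function(r) {
      st <- bin_reads(reads[reads$replicate == r & reads$phase == "S", ], g)
      gt <- bin_reads(reads[reads$replicate == r & reads$phase == "G1", ], g)
      dplyr::mutate(ratio_profile(st, gt), replicate = r)
    })
    profile <- smooth_and_normalize(tracks)
    list(tracks = tracks, profile = profile,
         peaks = call_peaks(profile))
  })
}

default_background <- function() {
  cached_fixture("bg", {
    g <- default_genome()
    fit_background(arscan:::intergenic_seqs(g), order = 5)
  })
}

# Brute-force contig assembly: O(n^2) pairwise-overlap connected
# components, independent of the package's sweep implementation.
brute_force_contigs <- function(frags) {
  n <- nrow(frags)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && frags$chrom[i] == frags$chrom[j] &&
          frags$start[i] < frags$end[j] && frags$end[i] > frags$start[j]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  out <- lapply(split(seq_len(n), root), function(idx) {
    m <- frags[idx, ]
    data.frame(chrom = m$chrom[1], start = min(m$start), end = max(m$end),
               combined_rd = sum(m$read_depth),
               fragment_count = length(unique(paste(m$start, m$end))))
  })
  out <- do.call(rbind, out)
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Brute-force window score: explicit per-position log-ratio sum using
# string operations only.
brute_force_score <- function(window, pwm_obj, bg, flank5 = "") {
  full <- paste0(flank5, window)
  chars <- strsplit(full, "")[[1]]
  codes <- match(chars, c("A", "C", "G", "T"))
  off <- nchar(flank5)
  total <- 0
  for (j in seq_len(nchar(window))) {
    i <- off + j
    m <- min(bg$order, i - 1)
    ctx <- 0L
    if (m > 0) {
      for (k in 1:m) ctx <- ctx + (codes[i - k] - 1L) * 4L^(k - 1L)
    }
    p_bg <- bg$cond[[m + 1]][ctx + 1L, codes[i]]
    total <- total + log2(pwm_obj$freq[codes[i], j]) - log2(p_bg)
  }
  unname(total)
}

# Brute-force order-m conditional estimates by direct string counting
# with reverse-complement symmetrization and add-one smoothing.
brute_force_markov <- function(seqs, m) {
  rc <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  all_ctx <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), m),
                                         stringsAsFactors = FALSE))
  if (m == 0) all_ctx <- ""
  counts <- matrix(1, nrow = length(all_ctx), ncol = 4,
                   dimnames = list(all_ctx, c("A", "C", "G", "T")))
  for (s0 in seqs) {
    for (s in c(s0, rc(s0))) {
      n <- nchar(s)
      for (i in (m + 1):n) {
        ctx <- if (m == 0) "" else
          paste(rev(strsplit(substr(s, i - m, i - 1), "")[[1]]), collapse = "")
        # package convention: most recent base is the low digit
        counts[ctx, substr(s, i, i)] <- counts[ctx, substr(s, i, i)] + 1
      }
    }
  }
  counts / rowSums(counts)
}

random_fragment_set <- function(n, seed, chroms = c("chrA", "chrB"),
                                span = 50000) {
  withr::with_seed(seed, {
    start <- sample.int(span, n, replace = TRUE)
    len <- sample(50:800, n, replace = TRUE)
    tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                   start = start, end = start + len,
                   name = paste0("f", seq_len(n)),
                   read_depth = sample(1:50, n, replace = TRUE),
                   strand = "*", enzyme = "GATC", source = "arsseq")
  })
}

# a minimal genome built from explicit sequences
string_genome <- function(...) {
  seqs <- c(...)
  Biostrings::DNAStringSet(seqs)
}
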