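# From mapped screen fragments to filtered ARS contigs with inferred
# functional cores.  Fragment and contig tables are plain tibbles;
# contigs keep their member fragments in a `members` list-column.

#' Snap fragment ends to restriction-site boundaries
#'
#' Each fragment end is moved outward to the nearest enzyme-site
#' boundary within `tolerance_bp`, removing truncation products.  If no
#' site lies within tolerance of an end, the fragment's enzyme is set to
#' `"unk"` and its coordinates are left unchanged.
#'
#' @param fragments Fragment tibble (`chrom, start, end, ...`).
#' @param genome A `synth_genome` or `DNAStringSet`.
#' @param enzyme_site Restriction site (4-mer).
#' @param tolerance_bp Maximum snap distance.
#'
#' @return The fragment tibble with adjusted `start`/`end` and `enzyme`.
#' @export
validate_fragment_ends <- function(fragments, genome, enzyme_site = "GATC",
                                   tolerance_bp = 10) {
  seqs <- genome_seqs(genome)
  lens <- chrom_lengths(genome)
  sites <- lapply(as.character(seqs), function(s) {
    m <- Biostrings::matchPattern(enzyme_site, Biostrings::DNAString(s))
    sort(c(0L, Biostrings::start(m) - 1L, nchar(s)))
  })
  out <- fragments
  for (i in seq_len(nrow(out))) {
    fr <- out[i, ]
    check_that(fr$chrom %in% names(sites), "fragment on unknown chromosome")
    check_that(fr$start >= 0 && fr$end <= lens[[fr$chrom]],
               sprintf("fragment %d outside chromosome bounds", i))
    pos <- sites[[fr$chrom]]
    # outward snap: start moves left, end moves right
    left_ok <- pos[pos <= fr$start & fr$start - pos <= tolerance_bp]
    right_ok <- pos[pos >= fr$end & pos - fr$end <= tolerance_bp]
    if (length(left_ok) > 0 && length(right_ok) > 0) {
      out$start[i] <- max(left_ok)
      out$end[i] <- min(right_ok)
    } else {
      out$enzyme[i] <- "unk"
    }
  }
  out
}

#' Assemble overlapping fragments into contigs
#'
#' Maximal sets of transitively overlapping fragments (>= 1 bp overlap;
#' half-open intervals, so touching fragments do not overlap) become one
#' contig spanning their union.  `combined_rd` is the sum of member read
#' depths and `fragment_count` the number of unique member intervals.
#' The result is independent of input order.
#'
#' @param fragments Fragment tibble (`chrom, start, end, read_depth`).
#'
#' @return A contig tibble: `contig_id, chrom, start, end, combined_rd,
#'   fragment_count`, with member fragments in the `members`
#'   list-column.
#' @export
assemble_contigs <- function(fragments) {
  empty <- tibble(contig_id = character(), chrom = character(),
                  start = integer(), end = integer(),
                  combined_rd = integer(), fragment_count = integer(),
                  members = list())
  if (nrow(fragments) == 0) return(empty)
  frags <- arrange(fragments, .data$chrom, .data$start, .data$end)
  out <- frags %>%
    group_by(.data$chrom) %>%
    dplyr::group_modify(function(d, key) {
      # single sweep: a new contig starts when start >= running max end
      run_end <- cummax(d$end)
      new_grp <- c(TRUE, d$start[-1] >= head(run_end, -1))
      grp <- cumsum(new_grp)
      purrr::map_dfr(split(d, grp), function(m) {
        m$chrom <- key$chrom            # group_modify strips the key
        tibble(start = min(m$start), end = max(m$end),
               combined_rd = sum(m$read_depth),
               fragment_count = dplyr::n_distinct(paste(m$start, m$end)),
               members = list(m))
      })
    }) %>%
    ungroup() %>%
    arrange(.data$chrom, .data$start) %>%
    mutate(contig_id = sprintf("%s_%d_%d", .data$chrom, .data$start,
                               .data$end)) %>%
    select("contig_id", "chrom", "start", "end", "combined_rd",
           "fragment_count", "members")
  out
}

#' Filter ARS-seq contigs on combined read depth
#'
#' Removes contigs whose combined read depth is 1 (i.e. retains
#' `combined_rd >= min_rd`, default 2).
#'
#' @param contigs Contig tibble from [assemble_contigs()].
#' @param min_rd Minimum combined read depth retained.
#' @return The filtered contig tibble.
#' @export
filter_contigs_arsseq <- function(contigs, min_rd = 2) {
  filter(contigs, .data$combined_rd >= min_rd)
}

#' Filter miniARS contigs on unique fragment count
#'
#' Retains contigs consisting of at least `min_fragments` unique member
#' fragment intervals (default 3); member fragments are expected to
#' carry read depth >= 2 already.
#'
#' @param contigs Contig tibble from [assemble_contigs()].
#' @param min_fragments Minimum unique fragment intervals.
#' @return The filtered contig tibble.
#' @export
filter_contigs_miniars <- function(contigs, min_fragments = 3) {
  filter(contigs, .data$fragment_count >= min_fragments)
}

# per-bp read-depth profile of one contig (vector over [start, end))
contig_depth_profile <- function(contig) {
  m <- contig$members[[1]]
  n <- contig$end - contig$start
  depth <- numeric(n)
  for (i in seq_len(nrow(m))) {
    a <- m$start[i] - contig$start + 1L
    b <- m$end[i] - contig$start
    depth[a:b] <- depth[a:b] + m$read_depth[i]
  }
  depth
}

#' Split contigs bridged by spurious low-depth fragments
#'
#' Automated stand-in for manual resolution of discontinuous contigs
#' joined by chimeric fragments: if the per-bp depth profile has an
#' internal valley strictly below `bridge_fraction` times the smaller of
#' the two flanking local maxima, the contig is split at the valley and
#' fragments spanning it are dropped; otherwise the contig is returned
#' unchanged.
#'
#' @param contigs Contig tibble.
#' @param bridge_fraction Valley-to-flank depth ratio below which a
#'   bridge is severed.
#' @return A contig tibble (possibly with more rows than the input).
#' @export
resolve_bridged_contigs <- function(contigs, bridge_fraction = 0.1) {
  if (nrow(contigs) == 0) return(contigs)
  pieces <- purrr::map_dfr(seq_len(nrow(contigs)), function(i) {
    ctg <- contigs[i, ]
    depth <- contig_depth_profile(ctg)
    n <- length(depth)
    # deepest internal valley between the two highest flanking maxima
    split_at <- NA_integer_
    if (n >= 3) {
      vmin_idx <- which.min(depth[2:(n - 1)]) + 1L
      left_max <- max(depth[1:(vmin_idx - 1)])
      right_max <- max(depth[(vmin_idx + 1):n])
      if (depth[vmin_idx] < bridge_fraction * min(left_max, right_max)) {
        split_at <- ctg$start + vmin_idx - 1L   # genome coordinate
      }
    }
    if (is.na(split_at)) return(ctg)
    m <- ctg$members[[1]]
    spanning <- m$start < split_at & m$end > split_at
    keep <- m[!spanning, ]
    if (nrow(keep) == 0) return(ctg)
    assemble_contigs(keep)
  })
  pieces %>%
    arrange(.data$chrom, .data$start) %>%
    mutate(contig_id = sprintf("%s_%d_%d", .data$chrom, .data$start, .data$end))
}

#' Infer the functional core of each contig
#'
#' The raw core is the intersection of all member fragment intervals;
#' cores shorter than `min_len` are extended symmetrically to exactly
#' `min_len`, clipping at chromosome ends and adding the deficit to the
#' opposite side.  Contigs whose members have an empty intersection
#' (possible after chimera splitting) are flagged and fall back to the
#' intersection of the highest-depth fragment's overlap set.
#'
#' @param contigs Contig tibble.
#' @param chrom_lens Named vector of chromosome lengths (or a
#'   `synth_genome`).
#' @param min_len Minimum core length after extension.
#'
#' @return The contig tibble with `core_start, core_end, core_flagged`.
#' @export
infer_core <- function(contigs, chrom_lens, min_len = 150) {
  lens <- chrom_lengths(chrom_lens)
  if (nrow(contigs) == 0) {
    return(mutate(contigs, core_start = integer(), core_end = integer(),
                  core_flagged = logical()))
  }
  res <- purrr::map_dfr(seq_len(nrow(contigs)), function(i) {
    ctg <- contigs[i, ]
    m <- ctg$members[[1]]
    check_that(nrow(m) >= 1, "contig without member fragments")
    lo <- max(m$start); hi <- min(m$end)
    flagged <- FALSE
    if (hi <= lo) {
      flagged <- TRUE
      top <- which.max(m$read_depth)
      ov <- m$start < m$end[top] & m$end > m$start[top]
      lo <- max(m$start[ov]); hi <- min(m$end[ov])
    }
    len <- hi - lo
    if (len < min_len) {
      deficit <- min_len - len
      add_l <- deficit %/% 2 + deficit %% 2
      add_r <- deficit %/% 2
      lo2 <- lo - add_l; hi2 <- hi + add_r
      cl <- lens[[ctg$chrom]]
      if (lo2 < 0) { hi2 <- hi2 - lo2; lo2 <- 0L }
      if (hi2 > cl) { lo2 <- lo2 - (hi2 - cl); hi2 <- cl }
      lo <- max(0L, lo2); hi <- min(cl, hi2)
    }
    tibble(core_start = as.integer(lo), core_end = as.integer(hi),
           core_flagged = flagged)
  })
  bind_rows(dplyr::bind_cols(contigs, res))
}

#' Flag low-depth contigs far from any replication peak
#'
#' Contigs with combined read depth in `[rd_lo, rd_hi]` whose midpoint
#' is farther than `near_kb` from every called timing peak on the same
#' chromosome are flagged as candidates for false-positive review.
#' Nothing is removed.
#'
#' @param contigs Contig tibble.
#' @param peaks Peak tibble (`chrom, coord`) from [call_peaks()].
#' @param rd_lo,rd_hi Read-depth band subject to review.
#' @param near_kb Distance threshold in kb.
#'
#' @return The contig tibble with a `flagged_candidate` column.
#' @export
flag_low_depth_off_peak <- function(contigs, peaks, rd_lo = 2, rd_hi = 10,
                                    near_kb = 20) {
  mid <- interval_mid(contigs$start, contigs$end)
  near <- vapply(seq_len(nrow(contigs)), function(i) {
    p <- peaks[peaks$chrom == contigs$chrom[i], ]
    if (nrow(p) == 0) return(FALSE)
    min(abs(p$coord - mid[i])) <= near_kb * 1000
  }, logical(1))
  mutate(contigs,
         flagged_candidate = .data$combined_rd >= rd_lo &
           .data$combined_rd <= rd_hi & !near)
}

# systematic ARS name: chromosome letter (A, B, C, ...) + midpoint kb
systematic_ars_name <- function(chrom, start, end, chrom_order) {
  letter <- LETTERS[match(chrom, chrom_order)]
  kb <- floor(interval_mid(start, end) / 1000)
  sprintf("%s%d", letter, kb)
}

#' Compile the final ARS table
#'
#' Joins miniARS-seq cores onto ARS-seq contigs by interval overlap and
#' assigns systematic names from the chromosome letter plus the contig
#' midpoint in kb (duplicate names are disambiguated with a `.2`, `.3`
#' suffix in coordinate order).  Coordinates in the returned table are
#' 1-based inclusive, matching the supplementary-table convention.
#'
#' @param arsseq_contigs Filtered, core-annotated ARS-seq contig tibble.
#' @param miniars_contigs Filtered, core-annotated miniARS contig tibble
#'   (may be empty).
#' @param chrom_order Chromosome order determining the letter prefix.
#'
#' @return A list with `ars` (the compiled table) and `unmatched_miniars`
#'   (miniARS contigs overlapping no ARS-seq contig).
#' @export
compile_ars_table <- function(arsseq_contigs, miniars_contigs = NULL,
                              chrom_order = NULL) {
  if (is.null(chrom_order)) chrom_order <- sort(unique(arsseq_contigs$chrom))
  ars <- arrange(arsseq_contigs, .data$chrom, .data$start)
  mini_core <- rep(NA_integer_, nrow(ars))
  mini_core_end <- rep(NA_integer_, nrow(ars))
  unmatched <- NULL
  if (!is.null(miniars_contigs) && nrow(miniars_contigs) > 0) {
    matched <- logical(nrow(miniars_contigs))
    for (j in seq_len(nrow(miniars_contigs))) {
      mc <- miniars_contigs[j, ]
      hit <- which(ars$chrom == mc$chrom & ars$start < mc$end &
                     ars$end > mc$start)
      if (length(hit) > 0) {
        matched[j] <- TRUE
        i <- hit[1]
        mini_core[i] <- mc$core_start
        mini_core_end[i] <- mc$core_end
      }
    }
    unmatched <- miniars_contigs[!matched, ]
  }
  name <- systematic_ars_name(ars$chrom, ars$start, ars$end, chrom_order)
  # deterministic suffix disambiguation by coordinate order
  dup <- ave(seq_along(name), name, FUN = seq_along)
  name <- ifelse(dup > 1, paste0(name, ".", dup), name)
  out <- tibble(
    ARS_name = name,
    contig_name = ars$contig_id,
    chrom = ars$chrom,
    start = ars$start + 1L,                  # 1-based inclusive export frame
    end = ars$end,
    combined_rd = ars$combined_rd,
    fragment_count = ars$fragment_count,
    ARSseq_core_start = ars$core_start + 1L,
    ARSseq_core_end = ars$core_end,
    ARSseq_core_len = ars$core_end - ars$core_start,
    miniARS_core_start = mini_core + 1L,
    miniARS_core_end = mini_core_end,
    miniARS_core_len = mini_core_end - mini_core,
    flagged_candidate = if ("flagged_candidate" %in% names(ars))
      ars$flagged_candidate else FALSE
  )
  list(ars = out, unmatched_miniars = unmatched)
}
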