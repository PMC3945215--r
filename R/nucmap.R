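# Nucleosome occupancy from mononucleosome fragments: per-bp density
# tracks and anchored, strand-oriented, ranked metaprofile matrices.

#' Per-bp nucleosome density from mononucleosome fragments
#'
#' In `"dyad"` mode each fragment contributes coverage over its
#' midpoint +/- 73 bp (the mononucleosome footprint); in `"span"` mode
#' over its full extent.  The track is scaled to a genome-wide mean of
#' 1.
#'
#' @param fragments Tibble `chrom, start, end` (0-based half-open).
#' @param chrom_lens Named chromosome lengths or a `synth_genome`.
#' @param mode `"dyad"` or `"span"`.
#' @param halfwidth Dyad half-footprint (bp), used in dyad mode.
#'
#' @return An object of class `"density_track"`: a named list of
#'   per-bp numeric vectors, one per chromosome.
#' @export
fragment_density <- function(fragments, chrom_lens, mode = c("dyad", "span"),
                             halfwidth = 73) {
  mode <- match.arg(mode)
  lens <- chrom_lengths(chrom_lens)
  track <- lapply(names(lens), function(chrom) {
    len <- lens[[chrom]]
    fr <- fragments[fragments$chrom == chrom, ]
    if (nrow(fr) == 0) return(numeric(len))
    if (mode == "dyad") {
      mid <- interval_mid(fr$start, fr$end)
      s <- pmax(mid - halfwidth, 0L)
      e <- pmin(mid + halfwidth + 1L, len)     # half-open
    } else {
      s <- pmax(fr$start, 0L)
      e <- pmin(fr$end, len)
    }
    cov <- IRanges::coverage(IRanges::IRanges(s + 1L, e), width = len)
    as.numeric(cov)
  })
  names(track) <- names(lens)
  total <- sum(vapply(track, sum, numeric(1)))
  glen <- sum(lens)
  if (total == 0) {
    warn("no fragments: returning an all-zero track (scaling skipped)")
  } else {
    track <- lapply(track, function(v) v / (total / glen))
  }
  structure(track, class = "density_track", mode = mode)
}

#' @export
print.density_track <- function(x, ...) {
  cat(sprintf("<density_track> %d chromosome(s), %s bp, mode %s\n",
              length(x), format(sum(lengths(x)), big.mark = ","),
              attr(x, "mode")))
  invisible(x)
}

#' @export
as_tibble.density_track <- function(x, ...) {
  purrr::map_dfr(names(x), function(chrom) {
    tibble(chrom = chrom, coord = seq_along(x[[chrom]]) - 1L,
           density = x[[chrom]])
  })
}

#' Anchored, oriented, ranked metaprofile matrix
#'
#' One row per anchor covering `position +/- window_bp`; minus-strand
#' rows are reversed so the anchor's plus direction reads rightward;
#' rows are ordered by `rank_score` descending.  Anchors whose window
#' runs past a chromosome end are dropped and counted.
#'
#' @param track A [fragment_density()] track.
#' @param anchors Tibble `chrom, position, strand, rank_score`
#'   (`strand`/`rank_score` optional).
#' @param window_bp Half-window (bp).
#'
#' @return An object of class `"meta_profile"`: list with `matrix`
#'   (anchors x offsets), `anchors` (the retained, ordered anchor
#'   tibble), `offsets`, `column_means` and `n_dropped`.
#' @export
metaprofile <- function(track, anchors, window_bp = 1000) {
  if (!"strand" %in% names(anchors)) anchors$strand <- "+"
  if (!"rank_score" %in% names(anchors)) anchors$rank_score <- 0
  lens <- vapply(track, length, numeric(1))
  ok <- anchors$position - window_bp >= 0 &
    anchors$position + window_bp < lens[anchors$chrom]
  dropped <- sum(!ok)
  anchors <- anchors[ok, ]
  check_that(nrow(anchors) > 0, "no anchor fits inside its chromosome")
  anchors <- arrange(anchors, desc(.data$rank_score))
  offs <- seq(-window_bp, window_bp)
  m <- t(vapply(seq_len(nrow(anchors)), function(i) {
    a <- anchors[i, ]
    v <- track[[a$chrom]][(a$position - window_bp):(a$position + window_bp) + 1L]
    if (a$strand == "-") v <- rev(v)
    v
  }, numeric(length(offs))))
  colnames(m) <- offs
  structure(list(matrix = m, anchors = anchors, offsets = offs,
                 column_means = colMeans(m), n_dropped = dropped),
            class = "meta_profile")
}

#' @export
print.meta_profile <- function(x, ...) {
  cat(sprintf("<meta_profile> %d anchors x %d offsets (%d dropped at edges)\n",
              nrow(x$matrix), ncol(x$matrix), x$n_dropped))
  invisible(x)
}

#' @exportS3Method generics::tidy
#' @describeIn metaprofile Long tibble `anchor, offset, density` plus
#'   the column means as `anchor = "mean"`.
#' @param x A `meta_profile`.
#' @param ... Unused.
tidy.meta_profile <- function(x, ...) {
  n <- nrow(x$matrix)
  bind_rows(
    tibble(anchor = rep(seq_len(n), each = length(x$offsets)),
           offset = rep(x$offsets, times = n),
           density = as.vector(t(x$matrix))),
    tibble(anchor = NA_integer_, offset = x$offsets,
           density = x$column_means))
}

#' Restrict anchors to isolated, single-hit ARSs
#'
#' Keeps ARSs with exactly one motif hit whose metaprofile window does
#' not overlap another ARS's window.
#'
#' @param ars Tibble with `ars_name, chrom, start, end`.
#' @param hits Motif hits with an `ars_name` column tying each hit to
#'   its ARS, plus `chrom, start, end, strand, score`.
#' @param window_bp Half-window used for overlap exclusion.
#'
#' @return An anchor tibble `chrom, position, strand, rank_score,
#'   ars_name` (position = hit midpoint).
#' @export
filter_anchors_single_match <- function(ars, hits, window_bp = 1000) {
  counts <- hits %>% dplyr::count(.data$ars_name, name = "n_hits")
  single <- ars %>%
    left_join(counts, by = "ars_name") %>%
    filter(dplyr::coalesce(.data$n_hits, 0L) == 1)
  anchors <- single %>%
    left_join(hits, by = "ars_name", suffix = c("", "_hit")) %>%
    mutate(position = interval_mid(.data$start_hit, .data$end_hit),
           strand = .data$strand,
           rank_score = .data$score) %>%
    select("ars_name", chrom = "chrom", "position", "strand", "rank_score")
  # exclude anchors whose windows overlap another ARS's window
  keep <- vapply(seq_len(nrow(anchors)), function(i) {
    others <- ars[ars$ars_name != anchors$ars_name[i] &
                    ars$chrom == anchors$chrom[i], ]
    if (nrow(others) == 0) return(TRUE)
    o_mid <- interval_mid(others$start, others$end)
    all(abs(o_mid - anchors$position[i]) > 2 * window_bp)
  }, logical(1))
  anchors[keep, ]
}

#' Width of the depletion trough in a mean metaprofile
#'
#' Measures the contiguous run of offsets, containing the profile
#' minimum, whose density stays below `threshold` (the track is scaled
#' to mean 1, so 0.5 marks half-depletion).
#'
#' @param meta A [metaprofile()] object (its column means are used).
#' @param threshold Density below which an offset counts as depleted.
#'
#' @return A one-row tibble `width, centre_offset, min_density`.
#' @export
ndr_width <- function(meta, threshold = 0.5) {
  y <- meta$column_means
  lo <- which.min(y)
  below <- y < threshold
  if (!below[lo]) {
    return(tibble(width = 0L, centre_offset = meta$offsets[lo],
                  min_density = y[lo]))
  }
  a <- lo; while (a > 1 && below[a - 1]) a <- a - 1
  b <- lo; while (b < length(y) && below[b + 1]) b <- b + 1
  tibble(width = b - a + 1L,
         centre_offset = as.integer(round(mean(meta$offsets[c(a, b)]))),
         min_density = y[lo])
}
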