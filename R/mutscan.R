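# Deep-mutational-scanning analysis: positional allele frequencies,
# log2 enrichment ratios between competition timepoints, replicate
# averaging, constrained-region calling, and conversion of enrichment
# ratios into a position weight matrix.

#' Positional allele frequencies from an allele-count table
#'
#' `freq(b, i) = count(b, i) / sum_b count(b, i)` at every covered
#' position.  Positions with zero coverage are masked (`freq = NA`), not
#' 0/0.
#'
#' @param counts Tibble `timepoint_h, replicate, position, base, count`.
#' @param timepoint,replicate Which slice to tabulate.
#'
#' @return A tibble `position, base, count, coverage, freq`.
#' @export
allele_frequencies <- function(counts, timepoint, replicate = 1) {
  rep_i <- replicate
  d <- filter(counts, .data$timepoint_h == timepoint,
              .data$replicate == rep_i)
  check_that(nrow(d) > 0, "no counts for that timepoint/replicate")
  d %>%
    group_by(.data$position) %>%
    mutate(coverage = sum(.data$count)) %>%
    ungroup() %>%
    mutate(freq = ifelse(.data$coverage > 0,
                         .data$count / .data$coverage, NA_real_)) %>%
    select("position", "base", "count", "coverage", "freq") %>%
    arrange(.data$position, .data$base)
}

#' Log2 enrichment ratios between two timepoints
#'
#' For every (position, base) cell,
#' `log2( freq_t(b, i) / freq_0(b, i) )`; cells with a read count below
#' `min_count` at either timepoint are masked.  Computed per replicate.
#'
#' @param counts Tibble `timepoint_h, replicate, position, base, count`.
#' @param timepoint_h Later timepoint (hours).
#' @param ref_timepoint_h Reference timepoint (default 0).
#' @param min_count Mask cells below this count at either timepoint.
#'
#' @return A tibble of class `"enrichment_matrix"`: `replicate,
#'   position, base, log2_ratio, masked`, with `timepoint_h` and
#'   `min_count` attributes.  The log base (2) is recorded in the
#'   `log_base` attribute.
#' @export
enrichment_ratio <- function(counts, timepoint_h = 36, ref_timepoint_h = 0,
                             min_count = 5) {
  t1 <- timepoint_h; t0 <- ref_timepoint_h
  reps <- sort(unique(counts$replicate))
  out <- purrr::map_dfr(reps, function(rep_i) {
    f1 <- allele_frequencies(counts, t1, rep_i)
    f0 <- allele_frequencies(counts, t0, rep_i)
    j <- dplyr::inner_join(f1, f0, by = c("position", "base"),
                           suffix = c("_t", "_0"))
    j %>%
      mutate(masked = is.na(.data$freq_t) | is.na(.data$freq_0) |
               .data$count_t < min_count | .data$count_0 < min_count,
             log2_ratio = ifelse(.data$masked, NA_real_,
                                 log2(.data$freq_t / .data$freq_0)),
             replicate = rep_i) %>%
      select("replicate", "position", "base", "log2_ratio", "masked")
  })
  structure(out, class = c("enrichment_matrix", class(out)),
            timepoint_h = t1, ref_timepoint_h = t0, min_count = min_count,
            log_base = 2, averaged = FALSE)
}

#' Average enrichment matrices over replicates
#'
#' Cell-wise mean of `log2_ratio` over replicates; a cell masked in any
#' replicate stays masked.  Replicate concordance (Pearson r over cells
#' unmasked in both replicates, for each replicate pair) is attached as
#' the `concordance` attribute.
#'
#' @param matrix An [enrichment_ratio()] result with >= 1 replicate.
#'
#' @return An averaged `"enrichment_matrix"` (replicate column dropped).
#' @export
average_replicates <- function(matrix) {
  reps <- sort(unique(matrix$replicate))
  conc <- NULL
  if (length(reps) >= 2) {
    pairs <- utils::combn(reps, 2)
    conc <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
      a <- filter(matrix, .data$replicate == pairs[1, k])
      b <- filter(matrix, .data$replicate == pairs[2, k])
      j <- dplyr::inner_join(a, b, by = c("position", "base"),
                             suffix = c("_a", "_b"))
      j <- filter(j, !.data$masked_a, !.data$masked_b)
      tibble(rep_a = pairs[1, k], rep_b = pairs[2, k],
             pearson_r = cor(j$log2_ratio_a, j$log2_ratio_b),
             n_cells = nrow(j))
    })
  }
  avg <- matrix %>%
    group_by(.data$position, .data$base) %>%
    summarise(masked = any(.data$masked),
              log2_ratio = ifelse(masked[1], NA_real_,
                                  mean(.data$log2_ratio)),
              .groups = "drop") %>%
    select("position", "base", "log2_ratio", "masked") %>%
    arrange(.data$position, .data$base)
  structure(avg, class = c("enrichment_matrix", class(avg)),
            timepoint_h = attr(matrix, "timepoint_h"),
            ref_timepoint_h = attr(matrix, "ref_timepoint_h"),
            min_count = attr(matrix, "min_count"), log_base = 2,
            averaged = TRUE, concordance = conc)
}

# mean enrichment of non-reference bases at each position
nonref_depletion <- function(matrix, ref_seq) {
  ref <- strsplit(toupper(ref_seq), "")[[1]]
  matrix %>%
    mutate(ref_base = ref[.data$position]) %>%
    filter(.data$base != .data$ref_base, !.data$masked) %>%
    group_by(.data$position) %>%
    summarise(mean_nonref = mean(.data$log2_ratio), .groups = "drop")
}

#' Call constrained regions from an enrichment matrix
#'
#' Positions where the mean enrichment of non-reference bases falls
#' below `drop_threshold` are merged into intervals when separated by at
#' most `window_bp`, and ranked by mean depletion.
#'
#' @param matrix An averaged [enrichment_ratio()] matrix.
#' @param ref_seq Reference element sequence (defines the reference base
#'   per position).
#' @param drop_threshold Log2-ratio ceiling defining constraint.
#' @param window_bp Merge gap (bp).
#'
#' @return A tibble `start, end, n_positions, mean_depletion` (1-based
#'   inclusive positions within the element), most depleted first.
#' @export
constrained_region <- function(matrix, ref_seq, drop_threshold = -1,
                               window_bp = 10) {
  dep <- nonref_depletion(matrix, ref_seq)
  hitpos <- sort(dep$position[dep$mean_nonref < drop_threshold])
  if (length(hitpos) == 0) {
    return(tibble(start = integer(), end = integer(),
                  n_positions = integer(), mean_depletion = numeric()))
  }
  grp <- cumsum(c(1, diff(hitpos) > window_bp))
  purrr::map_dfr(split(hitpos, grp), function(p) {
    tibble(start = min(p), end = max(p), n_positions = length(p),
           mean_depletion = mean(dep$mean_nonref[dep$position %in% p]))
  }) %>%
    arrange(.data$mean_depletion)
}

#' Convert enrichment ratios in a region to a PWM
#'
#' Within the region, every (position, base) enrichment value is floored
#' at `cutoff` and the column is normalized to relative allele
#' frequencies: `freq(b) = max(ratio(b), cutoff) / sum_b max(ratio(b),
#' cutoff)`.  Masked cells take the cutoff value.  The reference base's
#' cell carries its own enrichment score, so a strongly selected
#' reference base dominates its column.
#'
#' @param matrix An averaged enrichment matrix.
#' @param region A one-row tibble or list with `start`, `end` (1-based
#'   inclusive positions).
#' @param ref_seq Optional reference sequence.  When supplied, each
#'   column is expressed in the reference-relative frame: the reference
#'   base's cell is set to its own selection score -- its advantage over
#'   the average non-reference allele, `-mean(non-reference ratios)` --
#'   since positional frequencies of a 2%-mutagenized library leave the
#'   reference base's raw frequency ratio pinned near zero.  Without
#'   `ref_seq` the column values are used as given.
#' @param cutoff Floor applied to enrichment values before
#'   normalization.
#' @param name Name of the resulting motif.
#'
#' @return An [pwm] object of width `end - start + 1`.
#' @export
ratios_to_pwm <- function(matrix, region, ref_seq = NULL, cutoff = 0.2,
                          name = "mutARS-motif") {
  pos <- seq(region$start[1], region$end[1])
  ref <- if (!is.null(ref_seq)) strsplit(toupper(ref_seq), "")[[1]] else NULL
  cols <- vapply(pos, function(p) {
    d <- filter(matrix, .data$position == p)
    v <- setNames(rep(NA_real_, 4), DNA_BASES)
    v[d$base] <- d$log2_ratio
    if (!is.null(ref)) {
      rb <- ref[p]
      nonref <- v[setdiff(DNA_BASES, rb)]
      v[rb] <- if (all(is.na(nonref))) cutoff else -mean(nonref, na.rm = TRUE)
    }
    v[is.na(v)] <- cutoff
    pmax(v, cutoff)
  }, numeric(4))
  freq <- sweep(cols, 2, colSums(cols), "/")
  pwm(freq, name = name, pseudocount = 0)
}
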