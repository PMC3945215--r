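# S/G1 sort-seq replication timing: binned read counts, scaled copy
# ratios, LOESS smoothing with baseline normalization, turning-point
# peak calling, and the timing comparisons between origin classes.

#' Bin mapped read positions into fixed-width windows
#'
#' Each read's mapped start position increments exactly one
#' non-overlapping bin; bins tile every chromosome.
#'
#' @param reads Tibble with `chrom, pos` (0-based positions).
#' @param chrom_lens Named vector of chromosome lengths or a
#'   `synth_genome`.
#' @param bin_size Bin width in bp (default 1000).
#'
#' @return A bin track tibble: `bin_name, chrom, bin, start, count`
#'   (`bin` is the 0-based bin index, `start` its 0-based start).
#' @export
bin_reads <- function(reads, chrom_lens, bin_size = 1000) {
  lens <- chrom_lengths(chrom_lens)
  grid <- purrr::map_dfr(names(lens), function(chrom) {
    n_bins <- ceiling(lens[[chrom]] / bin_size)
    tibble(chrom = chrom, bin = 0:(n_bins - 1L))
  })
  counted <- reads %>%
    mutate(bin = as.integer(.data$pos %/% bin_size)) %>%
    dplyr::count(.data$chrom, .data$bin, name = "count")
  grid %>%
    left_join(counted, by = c("chrom", "bin")) %>%
    mutate(count = dplyr::coalesce(.data$count, 0L),
           start = .data$bin * as.integer(bin_size),
           bin_name = sprintf("%s:%d", .data$chrom, .data$bin)) %>%
    select("bin_name", "chrom", "bin", "start", "count")
}

#' Scaled S/G1 copy-number ratio per bin
#'
#' Equalizes totals between the two samples and scales by 1.5 so that
#' the average mid-S cell (having replicated half its DNA) maps the
#' ratio into the [1, 2] copy band:
#' `ratio(i) = 1.5 * (s(i) / S_total) / (g1(i) / G1_total)`.
#' Bins with zero G1 reads are masked (`NA`), not infinite.
#'
#' @param s_track,g1_track Bin tracks from [bin_reads()] with identical
#'   binning.
#' @param scale_factor The mid-S-phase scaling (default 1.5).
#'
#' @return The bin track with a `ratio` column.
#' @export
ratio_profile <- function(s_track, g1_track, scale_factor = 1.5) {
  check_that(identical(s_track$bin_name, g1_track$bin_name),
             "S and G1 tracks must share binning")
  s_tot <- sum(s_track$count); g_tot <- sum(g1_track$count)
  check_that(s_tot > 0 && g_tot > 0, "both samples need reads")
  ratio <- ifelse(g1_track$count > 0,
                  scale_factor * (s_track$count / s_tot) /
                    (g1_track$count / g_tot),
                  NA_real_)
  s_track %>%
    select("bin_name", "chrom", "bin", "start") %>%
    mutate(ratio = ratio)
}

# local-linear tricube LOESS of y over x with a bandwidth given in the
# same units as x; NA y values are dropped from the fit and predictions
# are returned for every x.
loess_bandwidth <- function(x, y, bandwidth) {
  ok <- !is.na(y)
  n_ok <- sum(ok)
  if (n_ok < 5) return(rep(NA_real_, length(x)))
  span <- min(1, (2 * bandwidth) / (max(x[ok]) - min(x[ok]) + 1e-9))
  span <- max(span, 10 / n_ok)       # keep enough points in each window
  fit <- loess(y[ok] ~ x[ok], span = span, degree = 1,
               family = "gaussian",
               control = loess.control(surface = "direct"))
  predict(fit, newdata = x)
}

#' Average, smooth and normalize replicate ratio tracks
#'
#' Averages the replicate ratio tracks per bin (masked bins excluded
#' from the mean), fits a local-linear tricube LOESS curve per
#' chromosome with a bandwidth expressed in kb, and normalizes the
#' smoothed curve to a baseline of 1 by dividing by a low quantile of
#' the genome-wide smoothed distribution (the late-replicating floor).
#'
#' @param ratio_tracks Long tibble of replicate ratio tracks:
#'   `bin_name, chrom, bin, start, replicate, ratio`.
#' @param bandwidth_kb LOESS half-bandwidth in kb.
#' @param baseline_quantile Quantile of smoothed values used as the
#'   baseline.
#'
#' @return A tibble of class `"timing_profile"`: one row per bin with
#'   per-replicate ratio columns (`ratio_rep1`, ...), `mean_ratio`,
#'   `smoothed` and `normalized`.
#' @export
smooth_and_normalize <- function(ratio_tracks, bandwidth_kb = 30,
                                 baseline_quantile = 0.02) {
  wide <- ratio_tracks %>%
    mutate(replicate = paste0("ratio_rep", .data$replicate)) %>%
    tidyr::pivot_wider(names_from = "replicate", values_from = "ratio")
  rep_cols <- grep("^ratio_rep", names(wide), value = TRUE)
  wide$mean_ratio <- rowMeans(as.matrix(wide[rep_cols]), na.rm = TRUE)
  wide$mean_ratio[is.nan(wide$mean_ratio)] <- NA_real_
  out <- wide %>%
    group_by(.data$chrom) %>%
    dplyr::group_modify(function(d, key) {
      d$smoothed <- loess_bandwidth(d$start / 1000, d$mean_ratio,
                                    bandwidth_kb)
      d
    }) %>%
    ungroup() %>%
    arrange(.data$chrom, .data$bin)
  pos_vals <- out$smoothed[!is.na(out$smoothed) & out$smoothed > 0]
  check_that(length(pos_vals) > 0, "smoothed track has no positive values")
  baseline <- quantile(pos_vals, baseline_quantile)
  out$normalized <- out$smoothed / baseline
  structure(out, class = c("timing_profile", class(out)),
            bandwidth_kb = bandwidth_kb, baseline = unname(baseline))
}

#' @exportS3Method generics::glance
#' @describeIn smooth_and_normalize One-row summary of a timing profile
#'   (bin count, baseline, replicate concordance if >= 2 replicates).
#' @param x A `timing_profile`.
#' @param ... Unused.
glance.timing_profile <- function(x, ...) {
  rep_cols <- grep("^ratio_rep", names(x), value = TRUE)
  conc <- if (length(rep_cols) >= 2) {
    replicate_concordance(x[[rep_cols[1]]], x[[rep_cols[2]]])
  } else tibble(pearson = NA_real_, spearman = NA_real_)
  tibble(n_bins = nrow(x), n_chroms = dplyr::n_distinct(x$chrom),
         baseline = attr(x, "baseline"),
         bandwidth_kb = attr(x, "bandwidth_kb"),
         pearson = conc$pearson, spearman = conc$spearman)
}

# prominence of a local maximum: height above the higher of the two
# lowest points separating it from higher terrain (or the track edge)
peak_prominence <- function(y, peaks) {
  vapply(peaks, function(p) {
    h <- y[p]
    left <- y[seq_len(p - 1)]
    higher_l <- which(left > h)
    base_l <- if (length(higher_l) == 0) min(left, h) else
      min(left[(max(higher_l)):(p - 1)])
    right <- y[seq(p + 1, length(y))]
    higher_r <- which(right > h)
    base_r <- if (length(higher_r) == 0) min(right, h) else
      min(right[1:(min(higher_r))])
    h - max(base_l, base_r)
  }, numeric(1))
}

#' Call peaks on a smoothed timing profile
#'
#' Turning points of the smoothed curve (sign changes of the first
#' difference; plateaus yield their centre bin), filtered by a minimum
#' prominence in normalized-ratio units to suppress small shoulders.
#'
#' @param profile A [smooth_and_normalize()] profile.
#' @param min_prominence Minimum peak prominence (normalized units);
#'   `0` keeps every turning point.
#' @param value Column to find peaks on (default `normalized`).
#'
#' @return A peak tibble: `bin_name, chrom, bin, coord, height,
#'   prominence` (`coord` = bin centre, bp).
#' @export
call_peaks <- function(profile, min_prominence = 0.02, value = "normalized") {
  bin_size <- diff(sort(unique(profile$start)))[1]
  profile %>%
    group_by(.data$chrom) %>%
    dplyr::group_modify(function(d, key) {
      y <- d[[value]]
      ok <- !is.na(y)
      empty <- mutate(d[0, c("bin_name", "bin", "start")],
                      height = numeric(0), prominence = numeric(0))
      if (sum(ok) < 3) return(empty)
      yy <- y[ok]; idx_map <- which(ok)
      n <- length(yy)
      dy <- diff(yy)
      tol <- 1e-9 * max(abs(yy), 1)    # ignore numeric ripple
      dy[abs(dy) < tol] <- 0
      sgn <- sign(dy)
      # collapse plateaus: carry the previous non-zero slope through runs
      runs <- rle(sgn)
      peaks <- integer(0)
      for (r in seq_along(runs$values)) {
        if (runs$values[r] != 0) next
        runs$values[r] <- if (r > 1) runs$values[r - 1] else 0
      }
      filled <- inverse.rle(runs)
      up_down <- which(head(filled, -1) > 0 & tail(filled, -1) < 0)
      for (i in up_down) {
        # plateau centre: extend over the zero-slope run around i + 1
        lo <- i + 1L; hi <- i + 1L
        while (lo > 1 && abs(yy[lo - 1] - yy[i + 1]) < tol) lo <- lo - 1L
        while (hi < n && abs(yy[hi + 1] - yy[i + 1]) < tol) hi <- hi + 1L
        peaks <- c(peaks, (lo + hi) %/% 2L)
      }
      if (length(peaks) == 0) return(empty)
      prom <- peak_prominence(yy, peaks)
      keep <- prom >= min_prominence
      sel <- idx_map[peaks[keep]]
      out <- d[sel, c("bin_name", "bin", "start")]
      out$height <- y[sel]
      out$prominence <- prom[keep]
      out
    }) %>%
    ungroup() %>%
    mutate(coord = .data$start + bin_size %/% 2) %>%
    select("bin_name", "chrom", "bin", "coord", "height", "prominence")
}

#' Distances from ARSs to the nearest timing peak, with random controls
#'
#' For each ARS, the minimum distance from its midpoint to any called
#' peak on the same chromosome; compared per class against same-size
#' sets of uniform random loci and between classes by two-sample
#' Kolmogorov-Smirnov tests.
#'
#' @param ars Tibble with `chrom, midpoint` and optionally `class`.
#' @param peaks A [call_peaks()] table.
#' @param chrom_lens Named chromosome lengths or a `synth_genome`.
#' @param n_random Random control sets drawn.
#' @param seed Integer seed for the controls.
#'
#' @return A list with `distances` (tibble: `class, distance, set`)
#'   and `tests` (KS results per class vs random and between classes).
#' @export
ars_peak_distances <- function(ars, peaks, chrom_lens, n_random = 100,
                               seed = 1L) {
  lens <- chrom_lengths(chrom_lens)
  if (!"class" %in% names(ars)) ars$class <- "all"
  dist_to_peak <- function(chrom, pos) {
    vapply(seq_along(pos), function(i) {
      p <- peaks[peaks$chrom == chrom[i], ]
      if (nrow(p) == 0) return(NA_real_)
      min(abs(p$coord - pos[i]))
    }, numeric(1))
  }
  obs <- tibble(class = ars$class, chrom = ars$chrom,
                distance = dist_to_peak(ars$chrom, ars$midpoint),
                set = "observed")
  rand <- with_seed(seed, {
    purrr::map_dfr(seq_len(n_random), function(k) {
      chroms <- sample(names(lens), nrow(ars), replace = TRUE,
                       prob = lens / sum(lens))
      pos <- floor(runif(nrow(ars)) * lens[chroms])
      tibble(class = "random", chrom = chroms,
             distance = dist_to_peak(chroms, pos),
             set = paste0("random_", k))
    })
  })
  classes <- unique(obs$class)
  tests <- purrr::map_dfr(classes, function(cl) {
    x <- obs$distance[obs$class == cl]
    y <- rand$distance
    kt <- suppressWarnings(ks.test(x, y, alternative = "greater"))
    tibble(comparison = paste0(cl, "_vs_random"),
           statistic = unname(kt$statistic), p_value = kt$p.value,
           n = length(x))
  })
  if (length(classes) == 2) {
    kt <- suppressWarnings(
      ks.test(obs$distance[obs$class == classes[1]],
              obs$distance[obs$class == classes[2]]))
    tests <- bind_rows(tests, tibble(
      comparison = paste0(classes[1], "_vs_", classes[2]),
      statistic = unname(kt$statistic), p_value = kt$p.value,
      n = nrow(obs)))
  }
  list(distances = bind_rows(obs, rand), tests = tests)
}

#' Smoothed timing values at ARS positions
#'
#' Looks up the normalized profile value in the bin containing each ARS
#' midpoint, flags ARSs with no neighbour within `isolation_kb` on both
#' sides as "isolated", and reports Welch t-tests between classes (and
#' against the genome-wide distribution).
#'
#' @param profile A [smooth_and_normalize()] profile.
#' @param ars Tibble with `chrom, midpoint` and optionally `class`.
#' @param isolation_kb Two-sided isolation radius in kb.
#'
#' @return A list with `values` (per-ARS tibble: `chrom, midpoint,
#'   class, value, isolated`) and `tests` (Welch t-test tibble).
#' @export
value_at_ars <- function(profile, ars, isolation_kb = 40) {
  bin_size <- diff(sort(unique(profile$start)))[1]
  if (!"class" %in% names(ars)) ars$class <- "all"
  vals <- purrr::map_dbl(seq_len(nrow(ars)), function(i) {
    b <- as.integer(ars$midpoint[i] %/% bin_size)
    row <- profile[profile$chrom == ars$chrom[i] & profile$bin == b, ]
    if (nrow(row) == 0) NA_real_ else row$normalized[1]
  })
  isolated <- purrr::map_lgl(seq_len(nrow(ars)), function(i) {
    same <- ars[-i, ]
    same <- same[same$chrom == ars$chrom[i], ]
    if (nrow(same) == 0) return(TRUE)
    all(abs(same$midpoint - ars$midpoint[i]) > isolation_kb * 1000)
  })
  values <- tibble(chrom = ars$chrom, midpoint = ars$midpoint,
                   class = ars$class, value = vals, isolated = isolated)
  classes <- unique(values$class)
  genome_vals <- profile$normalized[!is.na(profile$normalized)]
  tests <- purrr::map_dfr(classes, function(cl) {
    x <- values$value[values$class == cl & !is.na(values$value)]
    if (length(x) < 2) {
      return(tibble(comparison = paste0(cl, "_vs_genome"),
                    statistic = NA_real_, p_value = NA_real_,
                    mean_diff = mean(x) - mean(genome_vals), n = length(x)))
    }
    tt <- t.test(x, genome_vals)
    tibble(comparison = paste0(cl, "_vs_genome"),
           statistic = unname(tt$statistic), p_value = tt$p.value,
           mean_diff = mean(x) - mean(genome_vals), n = length(x))
  })
  if (length(classes) == 2 &&
      all(table(values$class[!is.na(values$value)]) >= 2)) {
    x <- values$value[values$class == classes[1] & !is.na(values$value)]
    y <- values$value[values$class == classes[2] & !is.na(values$value)]
    tt <- t.test(x, y)
    tests <- bind_rows(tests, tibble(
      comparison = paste0(classes[1], "_vs_", classes[2]),
      statistic = unname(tt$statistic), p_value = tt$p.value,
      mean_diff = mean(x) - mean(y), n = length(x) + length(y)))
  }
  list(values = values, tests = tests)
}

#' Remove windows around loci and compare the remaining distribution
#'
#' Drops every bin whose centre lies within `halfwidth_kb` of any locus
#' midpoint and Welch-t-tests the remaining normalized values against
#' the full distribution.
#'
#' @param profile A [smooth_and_normalize()] profile.
#' @param loci Tibble with `chrom, midpoint`.
#' @param halfwidth_kb Window half-width in kb (two-sided).
#'
#' @return A list with `remaining` (the surviving profile rows) and
#'   `test` (a one-row tibble).
#' @export
ablate_windows <- function(profile, loci, halfwidth_kb = 30) {
  if (nrow(loci) == 0) {
    full <- profile$normalized[!is.na(profile$normalized)]
    return(list(remaining = profile,
                test = tibble(statistic = 0, p_value = 1,
                              mean_shift = 0, n_removed = 0L,
                              n_remaining = length(full))))
  }
  bin_size <- diff(sort(unique(profile$start)))[1]
  centre <- profile$start + bin_size / 2
  drop <- rep(FALSE, nrow(profile))
  for (chr in unique(loci$chrom)) {
    mids <- loci$midpoint[loci$chrom == chr]
    sel <- profile$chrom == chr
    if (!any(sel) || length(mids) == 0) next
    dmin <- purrr::map_dbl(centre[sel], function(x) min(abs(mids - x)))
    drop[sel] <- dmin <= halfwidth_kb * 1000
  }
  remaining <- profile[!drop, ]
  rem_vals <- remaining$normalized[!is.na(remaining$normalized)]
  full_vals <- profile$normalized[!is.na(profile$normalized)]
  check_that(length(rem_vals) >= 2,
             "ablation removed the whole profile; nothing remains to compare")
  tt <- t.test(rem_vals, full_vals)
  list(remaining = remaining,
       test = tibble(statistic = unname(tt$statistic), p_value = tt$p.value,
                     mean_shift = mean(rem_vals) - mean(full_vals),
                     n_removed = sum(drop), n_remaining = nrow(remaining)))
}

#' Concordance between two replicate tracks
#'
#' Pearson and Spearman correlation over bins with values in both
#' tracks.
#'
#' @param rep1,rep2 Numeric vectors (e.g. smoothed replicate ratios).
#' @return A one-row tibble `pearson, spearman, n`.
#' @export
replicate_concordance <- function(rep1, rep2) {
  ok <- !is.na(rep1) & !is.na(rep2)
  tibble(pearson = cor(rep1[ok], rep2[ok]),
         spearman = cor(rep1[ok], rep2[ok], method = "spearman"),
         n = sum(ok))
}
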