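# Association statistics: composition binomial tests, Monte-Carlo
# intergene-length enrichment, hypergeometric set overlaps, the
# orientation chi-squared test, and distribution comparisons.  Every
# test returns a one-row broom-style tibble.

test_result <- function(method, statistic, p_value, n,
                        alternative = "two.sided", seed = NA_integer_, ...) {
  tibble(method = method, statistic = statistic, p_value = p_value,
         n = n, alternative = alternative, seed = seed, ...)
}

#' Exact binomial test of G/C composition against a background fraction
#'
#' @param obs_gc Observed G+C base count.
#' @param obs_total Total bases observed.
#' @param bg_gc_fraction Background G+C fraction.
#' @param alternative Test sidedness (default two-sided).
#'
#' @return A one-row result tibble.
#' @export
binomial_composition_test <- function(obs_gc, obs_total, bg_gc_fraction,
                                      alternative = "two.sided") {
  check_that(obs_total > 0, "obs_total must be positive")
  check_that(obs_gc >= 0 && obs_gc <= obs_total, "obs_gc out of range")
  bt <- binom.test(obs_gc, obs_total, p = bg_gc_fraction,
                   alternative = alternative)
  test_result("binomial_composition", unname(bt$statistic) / obs_total,
              bt$p.value, obs_total, alternative)
}

#' Monte-Carlo test of intergene-length enrichment
#'
#' Draws `m` random sets of `length(observed_lengths)` intergenes from
#' the genome-wide pool -- either uniformly or with probability
#' proportional to length (an element lands in an intergene with chance
#' proportional to its length) -- and reports the add-one-corrected
#' fraction of draws whose median length is at least the observed
#' median: `p = (b + 1) / (m + 1)`.
#'
#' @param observed_lengths Lengths of the intergenes hosting the
#'   elements of interest.
#' @param all_lengths Lengths of all intergenes.
#' @param m Monte-Carlo draws.
#' @param weighting `"length"` (default) or `"uniform"` sampling.
#' @param seed Integer seed.
#'
#' @return A one-row result tibble (`statistic` = observed median).
#' @export
montecarlo_intergene_test <- function(observed_lengths, all_lengths,
                                      m = 10000,
                                      weighting = c("length", "uniform"),
                                      seed = 1L) {
  weighting <- match.arg(weighting)
  k <- length(observed_lengths)
  check_that(k >= 1 && length(all_lengths) >= k, "not enough intergenes")
  obs_med <- median(observed_lengths)
  prob <- if (weighting == "length") all_lengths else NULL
  b <- with_seed(seed, {
    draws <- vapply(seq_len(m), function(i) {
      median(sample(all_lengths, k, replace = FALSE, prob = prob))
    }, numeric(1))
    sum(draws >= obs_med)
  })
  test_result("montecarlo_intergene", obs_med, (b + 1) / (m + 1), k,
              alternative = "greater", seed = seed,
              n_draws = m, weighting = weighting)
}

#' Hypergeometric test of gene-set overlap
#'
#' Upper-tail probability of observing at least the seen overlap
#' between two sets drawn from a common universe.
#'
#' @param set_a,set_b Vectors of identifiers (or `NULL` when passing
#'   counts directly).
#' @param universe_n Universe size.
#' @param n_a,n_b,n_overlap Counts, derived from the sets when given.
#'
#' @return A one-row result tibble (`statistic` = observed overlap).
#' @export
hypergeom_overlap <- function(set_a = NULL, set_b = NULL, universe_n,
                              n_a = length(unique(set_a)),
                              n_b = length(unique(set_b)),
                              n_overlap = length(intersect(set_a, set_b))) {
  check_that(universe_n >= max(n_a, n_b), "universe smaller than a set")
  p <- phyper(n_overlap - 1, n_a, universe_n - n_a, n_b, lower.tail = FALSE)
  test_result("hypergeom_overlap", n_overlap, p, universe_n,
              alternative = "greater", n_a = n_a, n_b = n_b)
}

#' Chi-squared test of intergene orientation composition
#'
#' Compares observed counts of element-bearing intergenes per
#' orientation class (convergent / divergent / tandem) against expected
#' proportions from all intergenes; expected counts are reported
#' alongside.
#'
#' @param observed_counts Named counts for the element-bearing
#'   intergenes.
#' @param background_counts Named counts (or proportions) over the same
#'   categories for all intergenes.
#'
#' @return A one-row result tibble with `expected_*` columns.
#' @export
orientation_chisq <- function(observed_counts, background_counts) {
  cats <- names(observed_counts)
  check_that(!is.null(cats) && setequal(cats, names(background_counts)),
             "observed and background categories must match")
  obs <- as.numeric(observed_counts[cats])
  bg <- as.numeric(background_counts[cats])
  p_exp <- bg / sum(bg)
  expected <- sum(obs) * p_exp
  if (any(expected == 0)) {
    abort("a category has expected count 0; merge categories before testing")
  }
  ct <- suppressWarnings(chisq.test(obs, p = p_exp))
  out <- test_result("orientation_chisq", unname(ct$statistic), ct$p.value,
                     sum(obs), alternative = "two.sided",
                     df = unname(ct$parameter))
  for (i in seq_along(cats)) out[[paste0("expected_", cats[i])]] <- expected[i]
  out
}

#' Compare two value distributions (Welch t or Kolmogorov-Smirnov)
#'
#' @param x,y Numeric samples.
#' @param method `"welch_t"` or `"ks"`.
#' @param alternative Alternative hypothesis passed through.
#'
#' @return A one-row result tibble.
#' @export
compare_distributions <- function(x, y, method = c("welch_t", "ks"),
                                  alternative = "two.sided") {
  method <- match.arg(method)
  check_that(length(x) >= 2 && length(y) >= 2,
             "both samples need at least 2 values")
  if (method == "welch_t") {
    tt <- t.test(x, y, alternative = alternative)
    test_result("welch_t", unname(tt$statistic), tt$p.value,
                length(x) + length(y), alternative)
  } else {
    kt <- suppressWarnings(ks.test(x, y, alternative = alternative))
    test_result("ks", unname(kt$statistic), kt$p.value,
                length(x) + length(y), alternative)
  }
}

#' Orientation classes and lengths of element-bearing intergenes
#'
#' Maps element midpoints onto a genome's intergene table (intergenes
#' longer than 1 bp), returning one row per element with the hosting
#' intergene's orientation class and length -- the inputs to
#' [orientation_chisq()] and [montecarlo_intergene_test()].
#'
#' @param genome A `synth_genome` (its `intergenes` table is used) or an
#'   intergene tibble.
#' @param elements Tibble with `chrom` and `midpoint` (or `start`/`end`).
#'
#' @return A tibble `chrom, midpoint, intergene_start, intergene_end,
#'   length, orientation` (elements outside any intergene are dropped).
#' @export
element_intergenes <- function(genome, elements) {
  inter <- if (inherits(genome, "synth_genome")) genome$intergenes
           else as_tibble(genome)
  inter <- filter(inter, .data$end - .data$start > 1)
  if (!"midpoint" %in% names(elements)) {
    elements$midpoint <- interval_mid(elements$start, elements$end)
  }
  purrr::map_dfr(seq_len(nrow(elements)), function(i) {
    el <- elements[i, ]
    host <- inter[inter$chrom == el$chrom & inter$start <= el$midpoint &
                    inter$end > el$midpoint, ]
    if (nrow(host) == 0) return(NULL)
    tibble(chrom = el$chrom, midpoint = el$midpoint,
           intergene_start = host$start[1], intergene_end = host$end[1],
           length = host$end[1] - host$start[1],
           orientation = host$orientation[1])
  })
}
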