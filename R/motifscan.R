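# Motif scanning against a Markov background, and the downstream
# motif-centric analyses: best hit per ARS, genome-wide scans, the
# bimodal GC/AT score split, flank composition and distance profiles.

#' Fit a Markov background model
#'
#' Estimates conditional base probabilities of order `0..order` from a
#' set of sequences (typically all intergenic sequence), with counts
#' symmetrized over both strands and add-one smoothing, so unseen
#' contexts are defined.  Lower orders are kept so windows close to a
#' sequence edge can be scored with the longest available context.
#'
#' @param seqs Character vector or `DNAStringSet`.
#' @param order Markov order (default 5).
#'
#' @return An object of class `"markov_bg"`: a list of conditional
#'   probability matrices, element `m + 1` holding the order-`m`
#'   conditionals as a `4^m x 4` matrix.
#' @export
fit_background <- function(seqs, order = 5) {
  if (inherits(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  check_that(length(seqs) >= 1 && sum(nchar(seqs)) > order,
             "need sequence longer than the model order")
  counts <- lapply(0:order, function(m) matrix(0, nrow = 4^m, ncol = 4))
  add_counts <- function(s) {
    b <- encode_dna(s) - 1L
    b <- b[!is.na(b)]
    n <- length(b)
    for (m in 0:order) {
      if (n < m + 1) next
      idx <- b[(m + 1):n]                      # emitted base, 0..3
      ctx <- integer(n - m)
      if (m > 0) {
        for (j in 1:m) ctx <- ctx + b[(m + 1 - j):(n - j)] * 4L^(j - 1L)
      }
      tab <- tabulate(ctx * 4L + idx + 1L, nbins = 4^(m + 1))
      counts[[m + 1]] <<- counts[[m + 1]] +
        matrix(tab, nrow = 4^m, ncol = 4, byrow = TRUE)
    }
  }
  for (s in seqs) {
    add_counts(s)
    add_counts(revcomp(s))
  }
  cond <- lapply(counts, function(cm) {
    cm <- cm + 1                               # add-one smoothing
    cm <- cm / rowSums(cm)
    colnames(cm) <- DNA_BASES
    cm
  })
  structure(list(order = order, cond = cond), class = "markov_bg")
}

#' @export
print.markov_bg <- function(x, ...) {
  cat(sprintf("<markov_bg> order %d\n", x$order))
  invisible(x)
}

# log2 background probability of each base given its preceding context,
# truncated to the available prefix near the sequence start.
# `b` is a 0..3 integer vector; returns a vector the same length.
bg_logprob <- function(b, bg) {
  n <- length(b)
  out <- numeric(n)
  k <- bg$order
  na <- is.na(b)
  if (any(na)) b[na] <- 0L
  for (i in seq_len(min(k, n))) {
    m <- i - 1L
    ctx <- 0L
    if (m > 0) for (j in 1:m) ctx <- ctx + b[i - j] * 4L^(j - 1L)
    out[i] <- log2(bg$cond[[m + 1]][ctx + 1L, b[i] + 1L])
  }
  if (n > k) {
    idx <- (k + 1):n
    ctx <- integer(length(idx))
    if (k > 0) for (j in 1:k) ctx <- ctx + b[idx - j] * 4L^(j - 1L)
    out[idx] <- log2(bg$cond[[k + 1]][cbind(ctx + 1L, b[idx] + 1L)])
  }
  out[na] <- NA_real_
  out
}

#' Score one window against a PWM and Markov background
#'
#' The score is the sum over motif positions of
#' `log2( p_pwm(base) / p_bg(base | context) )` in bits.  Context for
#' the background comes from `flank5` followed by the window itself and
#' is truncated to whatever prefix is available.
#'
#' @param window Character scalar, length equal to the motif width.
#' @param pwm An [pwm] object.
#' @param bg A [fit_background()] model.
#' @param flank5 Sequence immediately 5' of the window (may be `""`).
#'
#' @return Log-odds score in bits.
#' @export
score_window <- function(window, pwm, bg, flank5 = "") {
  w <- pwm_width(pwm)
  check_that(nchar(window) == w, "window length must equal the motif width")
  b <- encode_dna(paste0(flank5, window)) - 1L
  lp_bg <- bg_logprob(b, bg)
  keep <- (nchar(flank5) + 1):(nchar(flank5) + w)
  lp_pwm <- log2(pwm$freq[cbind(b[keep] + 1L, seq_len(w))])
  sum(lp_pwm) - sum(lp_bg[keep])
}

# all window scores on one strand of an encoded sequence (0..3 codes,
# NA allowed).  Returns a numeric vector of length n - w + 1.
scan_scores <- function(b, pwm, bg) {
  n <- length(b); w <- pwm_width(pwm)
  if (n < w) return(numeric(0))
  lp_bg <- bg_logprob(b, bg)
  lpw <- log2(pwm$freq)                        # 4 x w
  n_off <- n - w + 1L
  acc <- numeric(n_off)
  bad <- logical(n_off)
  for (j in seq_len(w)) {
    bj <- b[j:(j + n_off - 1L)]
    miss <- is.na(bj)
    bad <- bad | miss
    bj[miss] <- 1L
    acc <- acc + lpw[cbind(bj + 1L, j)]
  }
  cs <- cumsum(c(0, ifelse(is.na(lp_bg), 0, lp_bg)))
  bgsum <- cs[(w + 1):(n + 1)] - cs[1:n_off]
  out <- acc - bgsum
  out[bad] <- NA_real_
  out
}

# both-strand scan of one character sequence -> tibble(offset, strand, score)
# offsets are 0-based starts on the plus strand.
scan_one_sequence <- function(seq, pwm, bg) {
  b <- encode_dna(seq) - 1L
  n <- length(b); w <- pwm_width(pwm)
  if (n < w) return(tibble(offset = integer(), strand = character(),
                           score = numeric()))
  plus <- scan_scores(b, pwm, bg)
  brc <- encode_dna(revcomp(seq)) - 1L
  minus_rc <- scan_scores(brc, pwm, bg)
  # rc offset o (0-based) covers plus-strand interval [n - o - w, n - o)
  n_off <- n - w + 1L
  bind_rows(
    tibble(offset = 0:(n_off - 1L), strand = "+", score = plus),
    tibble(offset = n - (0:(n_off - 1L)) - w, strand = "-", score = minus_rc)
  )
}

#' Best motif occurrence in each sequence
#'
#' Scans both strands of every sequence and reports the single
#' highest-scoring occurrence, breaking ties by lowest offset and then
#' plus strand.  Sequences shorter than the motif are dropped with a
#' warning and listed in the `too_short` attribute.
#'
#' @param seqs Named character vector or `DNAStringSet`.
#' @inheritParams score_window
#'
#' @return A tibble with `seq_id, offset, strand, score` (0-based
#'   offsets).
#' @export
best_hit_per_sequence <- function(seqs, pwm, bg) {
  if (inherits(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  w <- pwm_width(pwm)
  short <- names(seqs)[nchar(seqs) < w]
  if (length(short) > 0) {
    warn(sprintf("%d sequence(s) shorter than the motif width were skipped: %s",
                 length(short), paste(head(short, 5), collapse = ", ")))
  }
  keep <- setdiff(names(seqs), short)
  res <- purrr::map_dfr(keep, function(id) {
    sc <- scan_one_sequence(seqs[[id]], pwm, bg)
    sc <- sc[!is.na(sc$score), ]
    if (nrow(sc) == 0) return(NULL)
    sc <- sc[order(-sc$score, sc$offset, sc$strand), ]
    tibble(seq_id = id, offset = sc$offset[1], strand = sc$strand[1],
           score = sc$score[1])
  })
  attr(res, "too_short") <- short
  res
}

#' Scan a genome for motif occurrences above a score threshold
#'
#' Scores all windows on both strands of every chromosome, keeps those
#' at or above `score_threshold`, and collapses mutually overlapping
#' hits to the local score maximum.  If an intergene mask is supplied,
#' only hits fully inside intergenes are reported.
#'
#' @param genome A `synth_genome` or `DNAStringSet`.
#' @inheritParams score_window
#' @param score_threshold Minimum score in bits.
#' @param intergenes Optional tibble with `chrom, start, end` used as an
#'   inclusion mask.
#'
#' @return A tibble `chrom, start, end, strand, score` (0-based
#'   half-open).
#' @export
scan_genome <- function(genome, pwm, bg, score_threshold, intergenes = NULL) {
  seqs <- as.character(genome_seqs(genome))
  w <- pwm_width(pwm)
  hits <- purrr::map_dfr(names(seqs), function(chrom) {
    sc <- scan_one_sequence(seqs[[chrom]], pwm, bg)
    sc <- sc[!is.na(sc$score) & sc$score >= score_threshold, ]
    if (nrow(sc) == 0) return(NULL)
    tibble(chrom = chrom, start = sc$offset, end = sc$offset + w,
           strand = sc$strand, score = sc$score)
  })
  if (nrow(hits) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), score = numeric()))
  }
  # collapse overlapping self-hits: greedy by descending score
  hits <- hits %>%
    group_by(.data$chrom) %>%
    dplyr::group_modify(function(d, key) {
      d <- d[order(-d$score, d$start, d$strand), ]
      kept_s <- integer(0); kept_e <- integer(0); keep <- logical(nrow(d))
      for (i in seq_len(nrow(d))) {
        if (!any(d$start[i] < kept_e & d$end[i] > kept_s)) {
          keep[i] <- TRUE
          kept_s <- c(kept_s, d$start[i]); kept_e <- c(kept_e, d$end[i])
        }
      }
      d[keep, ]
    }) %>%
    ungroup() %>%
    arrange(.data$chrom, .data$start)
  if (!is.null(intergenes)) {
    hits <- hits %>%
      dplyr::rowwise() %>%
      filter(any(intergenes$chrom == .data$chrom &
                   intergenes$start <= .data$start &
                   intergenes$end >= .data$end)) %>%
      ungroup()
  }
  hits
}

#' Split best-hit scores into two classes at a bimodal threshold
#'
#' Fits one- and two-component Gaussian mixtures to motif scores and, if
#' the two-component model is favoured by BIC, classifies each sequence:
#' the upper component is labelled `GC`, the lower `AT`, with the class
#' boundary at the equal-posterior score.  With no BIC support for two
#' components (or degenerate input) the fit reports "no split".
#'
#' @param data A data frame of best hits (or a numeric vector of scores).
#' @param score Column holding the scores (tidy-eval).
#'
#' @return An object of class `"ars_class_fit"`; see [tidy.ars_class_fit()]
#'   and [glance.ars_class_fit()].
#' @export
split_bimodal <- function(data, score = score) {
  if (is.numeric(data)) {
    scores <- data
    base <- tibble(score = scores)
  } else {
    base <- as_tibble(data)
    scores <- dplyr::pull(base, {{ score }})
  }
  check_that(length(scores) >= 10, "need at least 10 scores to fit a split")
  no_split <- function(reason) {
    structure(list(split = FALSE, reason = reason, threshold = NA_real_,
                   means = NA_real_, sds = NA_real_, proportions = NA_real_,
                   bic = c(one = NA_real_, two = NA_real_),
                   data = mutate(base, class = NA_character_)),
              class = "ars_class_fit")
  }
  if (sd(scores) < .Machine$double.eps^0.5) return(no_split("degenerate scores"))
  fit <- tryCatch(
    Mclust(scores, G = 1:2, modelNames = c("E", "V"), verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit) || fit$G == 1) return(no_split("one component favoured by BIC"))
  mu <- fit$parameters$mean
  sig <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sig) == 1) sig <- rep(sig, 2)
  pi_k <- fit$parameters$pro
  hi <- which.max(mu); lo <- which.min(mu)
  f <- function(x) {
    pi_k[lo] * dnorm(x, mu[lo], sig[lo]) - pi_k[hi] * dnorm(x, mu[hi], sig[hi])
  }
  thr <- tryCatch(uniroot(f, lower = mu[lo], upper = mu[hi])$root,
                  error = function(e) mean(mu))
  out <- mutate(base, class = ifelse(scores >= thr, "GC", "AT"))
  bic1 <- max(fit$BIC[1, ], na.rm = TRUE)
  bic2 <- max(fit$BIC[2, ], na.rm = TRUE)
  structure(list(split = TRUE, reason = NULL, threshold = thr,
                 means = c(AT = unname(mu[lo]), GC = unname(mu[hi])),
                 sds = c(AT = unname(sig[lo]), GC = unname(sig[hi])),
                 proportions = c(AT = unname(pi_k[lo]), GC = unname(pi_k[hi])),
                 bic = c(one = bic1, two = bic2),
                 data = out),
            class = "ars_class_fit")
}

#' @export
print.ars_class_fit <- function(x, ...) {
  if (!x$split) {
    cat("<ars_class_fit> no split:", x$reason, "\n")
  } else {
    cat(sprintf("<ars_class_fit> threshold %.2f bits: %d GC / %d AT\n",
                x$threshold, sum(x$data$class == "GC"),
                sum(x$data$class == "AT")))
  }
  invisible(x)
}

#' @describeIn split_bimodal Per-sequence class labels as a tibble.
#' @param x An `ars_class_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.ars_class_fit <- function(x, ...) x$data

#' @describeIn split_bimodal One-row model summary (threshold, component
#'   means/SDs/weights, BIC for 1 and 2 components).
#' @exportS3Method generics::glance
glance.ars_class_fit <- function(x, ...) {
  tibble(split = x$split, threshold = x$threshold,
         mean_at = unname(x$means["AT"]), mean_gc = unname(x$means["GC"]),
         sd_at = unname(x$sds["AT"]), sd_gc = unname(x$sds["GC"]),
         prop_gc = unname(x$proportions["GC"]),
         bic_one = unname(x$bic["one"]), bic_two = unname(x$bic["two"]),
         n = nrow(x$data))
}

#' Average base frequencies around motif hits
#'
#' Orients every hit so the motif reads in its consensus (TYGAAC-strand)
#' direction, stacks the flanked sequences and averages base identity
#' per offset.  Offsets run from `-halfwidth_bp` (5' flank) through the
#' motif (`0 .. width-1`) to `width - 1 + halfwidth_bp`; offsets that run
#' off a chromosome end are normalized by the number of hits that do
#' contribute.
#'
#' @param genome A `synth_genome` or `DNAStringSet`.
#' @param hits Tibble with `chrom, start, end, strand`.
#' @param halfwidth_bp Flank width on each side.
#'
#' @return A tibble `offset, base, freq, n` in long form.
#' @export
flank_base_frequencies <- function(genome, hits, halfwidth_bp = 100) {
  check_that(nrow(hits) >= 1, "need at least one hit")
  seqs <- as.character(genome_seqs(genome))
  w <- unique(hits$end - hits$start)
  check_that(length(w) == 1, "hits must share one motif width")
  total <- 2L * halfwidth_bp + w
  counts <- matrix(0, nrow = 4, ncol = total, dimnames = list(DNA_BASES, NULL))
  contrib <- numeric(total)
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    len <- nchar(seqs[[h$chrom]])
    lo <- h$start - halfwidth_bp          # 0-based window start
    hi <- h$end + halfwidth_bp            # half-open end
    from <- max(lo, 0L); to <- min(hi, len)
    s <- substr(seqs[[h$chrom]], from + 1L, to)
    chars <- strsplit(s, "")[[1]]
    codes <- match(chars, DNA_BASES)
    full <- rep(NA_integer_, total)
    full[(from - lo + 1):(to - lo)] <- codes
    if (h$strand == "-") full <- rev(5L - full)   # reverse complement
    ok <- !is.na(full)
    contrib <- contrib + ok
    counts[cbind(full[ok], which(ok))] <- counts[cbind(full[ok], which(ok))] + 1
  }
  offs <- seq(-halfwidth_bp, w - 1L + halfwidth_bp)
  freq <- sweep(counts, 2, pmax(contrib, 1), "/")
  tibble(offset = rep(offs, each = 4),
         base = rep(DNA_BASES, times = total),
         freq = as.vector(freq),
         n = rep(contrib, each = 4))
}

#' Distances from motif hits to TSSs of genes transcribing away
#'
#' For each hit, takes the nearest flanking gene on either side and, if
#' it is transcribed away from the motif and has a TSS annotation,
#' records the gap between the nearest motif edge and the TSS, tagged as
#' the 5' or 3' side in the motif's orientation.
#'
#' @param hits Tibble with `chrom, start, end, strand`.
#' @param genome A `synth_genome` (its `genes` table is used) or a gene
#'   tibble with `chrom, start, end, strand, tss`.
#'
#' @return A tibble `chrom, hit_start, side, distance, gene_id`.
#' @export
motif_to_tss_distances <- function(hits, genome) {
  genes <- if (inherits(genome, "synth_genome")) genome$genes else as_tibble(genome)
  out <- purrr::map_dfr(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    g <- genes[genes$chrom == h$chrom, ]
    right <- g[g$start >= h$end, ]
    left <- g[g$end <= h$start, ]
    rows <- list()
    if (nrow(right) > 0) {
      r <- right[which.min(right$start), ]
      if (r$strand == "+") {                 # transcribing away, rightward
        rows <- c(rows, list(tibble(
          chrom = h$chrom, hit_start = h$start,
          side = if (h$strand == "+") "3p" else "5p",
          distance = r$tss - h$end, gene_id = r$gene_id)))
      }
    }
    if (nrow(left) > 0) {
      l <- left[which.max(left$end), ]
      if (l$strand == "-") {                 # transcribing away, leftward
        rows <- c(rows, list(tibble(
          chrom = h$chrom, hit_start = h$start,
          side = if (h$strand == "+") "5p" else "3p",
          distance = h$start - 1L - l$tss, gene_id = l$gene_id)))
      }
    }
    bind_rows(rows)
  })
  out
}

#' Distances between the motif edges and the functional core edges
#'
#' For each ARS with an inferred core and a located motif, measures the
#' sequence length between the motif edge and the core edge on the 5'
#' and 3' side of the motif (in motif orientation).  A motif partially
#' outside its core yields a negative length and is flagged.
#'
#' @param ars Tibble with `core_start, core_end, hit_start, hit_end,
#'   hit_strand` (0-based half-open).
#'
#' @return The input with `dist_5p, dist_3p, core_flagged` columns added.
#' @export
core_edge_distances <- function(ars) {
  left <- ars$hit_start - ars$core_start
  right <- ars$core_end - ars$hit_end
  plus <- ars$hit_strand == "+"
  ars %>%
    mutate(dist_5p = ifelse(plus, left, right),
           dist_3p = ifelse(plus, right, left),
           core_flagged = .data$dist_5p < 0 | .data$dist_3p < 0)
}
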