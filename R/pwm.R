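#' Position weight matrix
#'
#' Constructs a position weight matrix from a 4 x width matrix of base
#' frequencies or counts (rows A, C, G, T).  A pseudocount is added to
#' every cell and columns are renormalized to sum to 1.
#'
#' @param freq 4 x width numeric matrix (rows in A, C, G, T order).
#' @param name Motif name carried through to exports.
#' @param pseudocount Added to every cell before normalization.
#'
#' @return An object of class `"ars_pwm"`.
#' @export
pwm <- function(freq, name = "motif", pseudocount = 0.5) {
  freq <- as.matrix(freq)
  check_that(nrow(freq) == 4, "`freq` must have 4 rows (A, C, G, T)")
  check_that(ncol(freq) >= 4, "motif width must be >= 4")
  check_that(all(freq >= 0), "frequencies must be non-negative")
  freq <- freq + pseudocount
  freq <- sweep(freq, 2, colSums(freq), "/")
  rownames(freq) <- DNA_BASES
  structure(list(freq = freq, name = name, pseudocount = pseudocount),
            class = "ars_pwm")
}

#' @export
print.ars_pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s, width %d, consensus %s\n",
              x$name, pwm_width(x), pwm_consensus(x)))
  invisible(x)
}

#' @rdname pwm
#' @param x A pwm object.
#' @export
pwm_width <- function(x) ncol(x$freq)

#' Consensus string of a PWM (per-column argmax)
#' @param x A pwm object.
#' @return A character scalar.
#' @export
pwm_consensus <- function(x) {
  paste(DNA_BASES[apply(x$freq, 2, which.max)], collapse = "")
}

#' Build a PWM from aligned instance sequences
#'
#' Count-and-normalize estimation with a pseudocount, for turning
#' planted or recovered motif instances into a scanning matrix.
#'
#' @param seqs Character vector of equal-length sequences.
#' @inheritParams pwm
#' @return An `"ars_pwm"` object.
#' @export
pwm_from_sequences <- function(seqs, name = "motif", pseudocount = 0.5) {
  check_that(length(seqs) >= 1, "need at least one sequence")
  w <- unique(nchar(seqs))
  check_that(length(w) == 1, "instance sequences must have equal length")
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  counts <- vapply(seq_len(w), function(j) {
    tabulate(match(m[, j], DNA_BASES), nbins = 4)
  }, numeric(4))
  pwm(counts, name = name, pseudocount = pseudocount)
}

#' Reverse-complement a PWM
#' @param x A pwm object.
#' @return The reverse-complemented pwm.
#' @export
pwm_revcomp <- function(x) {
  f <- x$freq[4:1, rev(seq_len(pwm_width(x))), drop = FALSE]
  rownames(f) <- DNA_BASES
  structure(list(freq = f, name = x$name, pseudocount = x$pseudocount),
            class = "ars_pwm")
}
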