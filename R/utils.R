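# Internal helpers shared across modules.  Coordinates are 0-based
# half-open everywhere inside the package; conversion to the 1-based
# inclusive convention of exported tables happens only in io.R.

DNA_BASES <- c("A", "C", "G", "T")

# character string -> integer codes 1..4 (NA for anything else)
encode_dna <- function(seq) {
  x <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  match(x, DNA_BASES)
}

decode_dna <- function(codes) {
  paste(DNA_BASES[codes], collapse = "")
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# stopifnot-style check with a readable message
check_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
}

# lengths of a genome's chromosomes as a named integer vector
chrom_lengths <- function(genome) {
  if (inherits(genome, "synth_genome")) {
    setNames(Biostrings::width(genome$seq), names(genome$seq))
  } else if (inherits(genome, "DNAStringSet")) {
    setNames(Biostrings::width(genome), names(genome))
  } else if (is.numeric(genome)) {
    genome
  } else {
    abort("cannot derive chromosome lengths from this object")
  }
}

genome_seqs <- function(genome) {
  if (inherits(genome, "synth_genome")) genome$seq
  else if (inherits(genome, "DNAStringSet")) genome
  else abort("expected a `synth_genome` or DNAStringSet")
}

# midpoint of a 0-based half-open interval
interval_mid <- function(start, end) floor((start + end) / 2)

# run a block under a local RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}
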