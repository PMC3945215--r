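# Readers and writers for the standard formats the pipeline touches.
# Internal records are 0-based half-open; exported supplementary-style
# TSV tables are 1-based inclusive, and the conversion happens exactly
# once, here.  BED keeps its native 0-based half-open convention.

#' Write / read genome FASTA
#' @param genome A `synth_genome` or `DNAStringSet`.
#' @param path File path.
#' @return `read_genome_fasta()` returns a `DNAStringSet`.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome_seqs(genome), path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write / read gene annotation as GFF3
#'
#' Genes are exported as `gene` features with their `ID`; coordinates
#' follow the 1-based inclusive GFF convention.  Reading converts back
#' to the internal 0-based frame and recomputes each TSS from strand.
#'
#' @param genes Gene tibble (`chrom, start, end, strand, gene_id`).
#' @param path File path.
#' @return `read_genes_gff()` returns the gene tibble.
#' @export
write_genes_gff <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(genes$start + 1L, genes$end),
    strand = genes$strand)
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_genes_gff
#' @export
read_genes_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  start <- GenomicRanges::start(gr) - 1L
  end <- GenomicRanges::end(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = start, end = end, strand = strand,
         gene_id = gr$ID,
         tss = ifelse(strand == "+", start, end - 1L))
}

#' Write / read screen fragment tables
#'
#' TSV with the fragment-table schema: `fragment_name, chrom, start,
#' end, rd, restriction_fragment, strand, source, element_id`
#' (coordinates 1-based inclusive in the file).
#'
#' @param fragments Internal fragment tibble.
#' @param path File path.
#' @return `read_fragments()` returns the internal fragment tibble.
#' @export
write_fragments <- function(fragments, path) {
  out <- tibble(fragment_name = fragments$name, chrom = fragments$chrom,
                start = fragments$start + 1L, end = fragments$end,
                rd = fragments$read_depth,
                restriction_fragment = fragments$enzyme,
                strand = fragments$strand, source = fragments$source,
                element_id = if ("element_id" %in% names(fragments))
                  fragments$element_id else NA_character_)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_fragments
#' @export
read_fragments <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("fragment_name", "chrom", "start", "end", "rd")
  missing <- setdiff(needed, names(d))
  check_that(length(missing) == 0,
             paste("fragment table missing columns:",
                   paste(missing, collapse = ", ")))
  bad <- which(d$start > d$end)
  if (length(bad) > 0) {
    abort(sprintf("fragment table line %d: start > end", bad[1] + 1L))
  }
  tibble(chrom = d$chrom, start = as.integer(d$start) - 1L,
         end = as.integer(d$end), name = d$fragment_name,
         read_depth = as.integer(d$rd),
         strand = d$strand %||% "*",
         enzyme = d$restriction_fragment %||% "unk",
         source = d$source %||% "arsseq",
         element_id = d$element_id %||% NA_character_)
}

#' Write / read BED6 interval files
#'
#' Native BED convention: 0-based half-open, columns chrom, start, end,
#' name, score, strand.
#'
#' @param intervals Tibble with `chrom, start, end` and optionally
#'   `name, score, strand`.
#' @param path File path.
#' @return `read_bed()` returns the interval tibble.
#' @export
write_bed <- function(intervals, path) {
  out <- tibble(chrom = intervals$chrom, start = intervals$start,
                end = intervals$end,
                name = intervals$name %||% ".",
                score = intervals$score %||% 0,
                strand = intervals$strand %||% ".")
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  d <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       progress = FALSE)
  check_that(ncol(d) >= 3, "BED needs at least 3 columns")
  names(d)[1:3] <- c("chrom", "start", "end")
  if (ncol(d) >= 6) names(d)[4:6] <- c("name", "score", "strand")
  bad <- which(d$start >= d$end)
  if (length(bad) > 0) {
    abort(sprintf("BED line %d: start >= end", bad[1]))
  }
  as_tibble(d)
}

#' Export a binned track as bedGraph
#'
#' @param track Bin track tibble (`chrom, start`) plus the value column.
#' @param path File path.
#' @param value Name of the value column.
#' @param bin_size Bin width (bp); inferred from consecutive starts when
#'   `NULL`.
#' @export
write_bedgraph <- function(track, path, value = "normalized",
                           bin_size = NULL) {
  if (is.null(bin_size)) bin_size <- diff(sort(unique(track$start)))[1]
  keep <- !is.na(track[[value]])
  gr <- GenomicRanges::GRanges(
    seqnames = track$chrom[keep],
    ranges = IRanges::IRanges(track$start[keep] + 1L,
                              track$start[keep] + bin_size),
    score = track[[value]][keep])
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Write / read the replication-timing table
#'
#' Schema: `bin_name, chrom, coord_kb, replicate1_ratio, ...,
#' normalized_ratio` (`coord_kb` = first coordinate of the bin, in kb).
#'
#' @param profile A [smooth_and_normalize()] profile.
#' @param path File path.
#' @return `read_timing_table()` returns a tibble in the same shape.
#' @export
write_timing_table <- function(profile, path) {
  rep_cols <- grep("^ratio_rep", names(profile), value = TRUE)
  out <- tibble(bin_name = profile$bin_name, chrom = profile$chrom,
                coord_kb = profile$start / 1000)
  for (i in seq_along(rep_cols)) {
    out[[sprintf("replicate%d_ratio", i)]] <- profile[[rep_cols[i]]]
  }
  out$normalized_ratio <- profile$normalized
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_timing_table
#' @export
read_timing_table <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("bin_name", "chrom", "coord_kb")
  check_that(all(needed %in% names(d)),
             "timing table must have bin_name, chrom, coord_kb columns")
  as_tibble(d)
}

#' Write the timing-peak table
#'
#' Schema: `bin_name, chrom, coord_kb`.
#' @param peaks A [call_peaks()] table.
#' @param path File path.
#' @export
write_peaks_table <- function(peaks, path) {
  readr::write_tsv(tibble(bin_name = peaks$bin_name, chrom = peaks$chrom,
                          coord_kb = (peaks$coord - 500) / 1000), path)
  invisible(path)
}

#' Write a nucleosome density table
#'
#' Schema: `chrom, coord`, one column per replicate track, `mean`.
#' Rows are emitted every `stride` bp.
#'
#' @param tracks A named list of [fragment_density()] tracks (or one
#'   track).
#' @param path File path.
#' @param stride Emit every `stride`-th coordinate (default 10).
#' @export
write_nucleosome_table <- function(tracks, path, stride = 10) {
  if (inherits(tracks, "density_track")) tracks <- list(rep1 = tracks)
  chroms <- names(tracks[[1]])
  out <- purrr::map_dfr(chroms, function(chrom) {
    len <- length(tracks[[1]][[chrom]])
    idx <- seq(1, len, by = stride)
    d <- tibble(chrom = chrom, coord = idx - 1L)
    for (nm in names(tracks)) d[[nm]] <- tracks[[nm]][[chrom]][idx]
    d$mean <- rowMeans(as.matrix(d[names(tracks)]))
    d
  })
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write / read allele count tables
#'
#' TSV schema `timepoint_h, replicate, position, base, count` (1-based
#' element positions).
#'
#' @param counts Allele-count tibble.
#' @param path File path.
#' @return `read_allele_counts()` returns the tibble.
#' @export
write_allele_counts <- function(counts, path) {
  readr::write_tsv(counts[c("timepoint_h", "replicate", "position",
                            "base", "count")], path)
  invisible(path)
}

#' @rdname write_allele_counts
#' @export
read_allele_counts <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("timepoint_h", "replicate", "position", "base", "count")
  missing <- setdiff(needed, names(d))
  check_that(length(missing) == 0,
             paste("allele count table missing columns:",
                   paste(missing, collapse = ", ")))
  as_tibble(d[needed])
}

#' Write / read a PWM in MEME minimal text format
#'
#' @param x A [pwm] object.
#' @param path File path.
#' @param bg Background base frequencies written to the header.
#' @return `read_meme_pwm()` returns a [pwm] object.
#' @export
write_meme_pwm <- function(x, path, bg = rep(0.25, 4)) {
  w <- pwm_width(x)
  lines <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    sprintf("A %.5f C %.5f G %.5f T %.5f", bg[1], bg[2], bg[3], bg[4]), "",
    sprintf("MOTIF %s", x$name),
    sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0", w),
    vapply(seq_len(w), function(j) {
      sprintf(" %.6f %.6f %.6f %.6f",
              x$freq[1, j], x$freq[2, j], x$freq[3, j], x$freq[4, j])
    }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_meme_pwm
#' @export
read_meme_pwm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  m_line <- grep("^MOTIF", lines)
  check_that(length(m_line) >= 1, "no MOTIF record in MEME file")
  name <- strsplit(trimws(lines[m_line[1]]), "\\s+")[[1]][2]
  h_line <- grep("^letter-probability matrix", lines)
  check_that(length(h_line) >= 1, "no letter-probability matrix in MEME file")
  w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[h_line[1]]))
  rows <- lines[(h_line[1] + 1):(h_line[1] + w)]
  vals <- do.call(rbind, lapply(seq_along(rows), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(rows[i]), "\\s+")[[1]]))
    if (length(v) != 4 || anyNA(v)) {
      abort(sprintf("MEME file line %d: expected 4 numeric fields",
                    h_line[1] + i))
    }
    v
  }))
  pwm(t(vals), name = name, pseudocount = 0)
}

#' Write the compiled ARS table
#' @param ars_table The `ars` element of [compile_ars_table()].
#' @param path File path.
#' @return `read_ars_table()` returns the tibble.
#' @export
write_ars_table <- function(ars_table, path) {
  readr::write_tsv(ars_table, path)
  invisible(path)
}

#' @rdname write_ars_table
#' @export
read_ars_table <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_that(all(c("ARS_name", "chrom", "start", "end") %in% names(d)),
             "not an ARS table")
  as_tibble(d)
}

#' Write the ground-truth table of a synthetic genome as BED6
#' @param truth Ground-truth tibble.
#' @param path File path.
#' @export
write_truth_bed <- function(truth, path) {
  write_bed(tibble(chrom = truth$chrom, start = truth$start,
                   end = truth$end, name = truth$element_id,
                   score = truth$strength, strand = truth$strand), path)
}
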