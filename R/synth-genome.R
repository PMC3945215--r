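#' Default GC-ACS position weight matrix
#'
#' A 20-column position weight matrix for the G/C-rich origin consensus
#' used by the synthetic genome generator.  Columns 8-13 carry the
#' TYGAAC core (Y = C/T at equal weight); the flanking columns are
#' G/C-rich.  Consensus bases have probability 0.85, alternatives 0.05.
#'
#' @return A [pwm] object of width 20.
#' @export
default_gc_pwm <- function() {
  consensus <- strsplit("GGCGGGCTTGAACGGGCGGC", "")[[1]]
  freq <- matrix(0.05, nrow = 4, ncol = 20, dimnames = list(DNA_BASES, NULL))
  for (j in seq_along(consensus)) freq[consensus[j], j] <- 0.85
  # Y position (column 9 overall, the second base of the TYGAAC core)
  freq[, 9] <- c(A = 0.05, C = 0.45, G = 0.05, T = 0.45)
  pwm(freq, name = "GC-ACS-synthetic", pseudocount = 0)
}

#' Default repetitive A/T-rich origin element
#'
#' A 35 bp repetitive A/T-rich template emulating the second,
#' motif-poor class of origin determinants.
#'
#' @return A character scalar of length 35.
#' @export
default_at_element <- function() {
  "ATTTATTTTTATTTATTTTTATTTATTTTTATTTA"
}

#' Configuration for the synthetic origin genome
#'
#' Bundles every knob of the synthetic-data generator.  The defaults
#' describe a gene-dense yeast-like genome: short intergenes (median
#' `exp(intergene_mu)` = 216 bp), planted 20 bp G/C-rich motifs with a
#' TYGAAC core sitting in deliberately longer intergenes, planted
#' repetitive A/T-rich elements, GC origins firing earlier and captured
#' at ~10x the read depth of AT origins, and nucleosome-depleted regions
#' of 450 bp (5' of GC motifs) and 150 bp (centred on AT elements).
#'
#' @param seed Integer seed fixing all randomness downstream of this
#'   config (generators also accept their own `seed`).
#' @param n_chroms,chrom_len Number of chromosomes and their length (bp).
#' @param n_genes Genes per chromosome.  `0` gives a single
#'   chromosome-spanning intergene.
#' @param intergene_mu,intergene_sigma Log-normal parameters of the
#'   intergene length distribution (bp); the median is `exp(intergene_mu)`.
#' @param gene_len_mu,gene_len_sigma Log-normal parameters for gene length.
#' @param n_gc_origins,n_at_origins Planted origin counts (genome-wide).
#' @param gc_intergene_factor Multiplier applied to the drawn length of
#'   intergenes that receive a GC origin, emulating the observed
#'   association of the GC class with long intergenes.
#' @param gc_motif A [pwm] the GC motif instances are sampled from.
#' @param at_element Sequence template for the A/T-rich element.
#' @param gc_strength,at_strength Mean screen capture strength per class
#'   (drives simulated fragment read depth; GC is set ~10x AT).
#' @param gc_fire_mean,at_fire_mean,fire_sd Mean/SD of origin firing time
#'   (minutes into S phase) per class.
#' @param gc_efficiency,at_efficiency Per-cell firing probabilities.
#' @param fork_rate_bp_per_min Replication fork speed.
#' @param s_phase_min Length of S phase in minutes.
#' @param enzyme_site Restriction site used by the fragment-library
#'   simulator (a 4-mer).
#' @param min_origin_spacing_bp Minimum distance between planted origin
#'   midpoints, so that each origin can resolve as its own timing peak.
#' @param polyA_len,polyA_gap Length of the poly(dA) tract planted 5' of
#'   each GC motif (in TYGAAC orientation) and its gap to the motif edge.
#' @param mnase_spacing_bp,mnase_spacing_sd Nucleosome repeat length and
#'   its jitter.
#' @param ndr_gc_bp Width of the nucleosome-depleted region planted on
#'   the 5' side of each GC motif.
#' @param ndr_gc_gap Gap between the GC NDR and the motif 5' edge.
#' @param ndr_at_bp Width of the NDR centred on each AT element.
#' @param ndr_tss_bp Width of the promoter NDR centred on each TSS.
#'
#' @return A list with class `"synth_config"`.
#' @export
synth_config <- function(seed = 1L,
                         n_chroms = 2L,
                         chrom_len = 1e6L,
                         n_genes = 500L,
                         intergene_mu = log(216),
                         intergene_sigma = 0.95,
                         gene_len_mu = log(1300),
                         gene_len_sigma = 0.3,
                         n_gc_origins = 12L,
                         n_at_origins = 10L,
                         gc_intergene_factor = 4,
                         gc_motif = default_gc_pwm(),
                         at_element = default_at_element(),
                         gc_strength = 50,
                         at_strength = 5,
                         gc_fire_mean = 12,
                         at_fire_mean = 22,
                         fire_sd = 2.5,
                         gc_efficiency = 0.9,
                         at_efficiency = 0.85,
                         fork_rate_bp_per_min = 2000,
                         s_phase_min = 40,
                         enzyme_site = "GATC",
                         min_origin_spacing_bp = 4e4,
                         polyA_len = 26L,
                         polyA_gap = 10L,
                         mnase_spacing_bp = 165,
                         mnase_spacing_sd = 8,
                         ndr_gc_bp = 450,
                         ndr_gc_gap = 40L,
                         ndr_at_bp = 150,
                         ndr_tss_bp = 150) {
  check_that(n_chroms >= 1 && chrom_len >= 1000, "need >=1 chromosome of >=1 kb")
  check_that(inherits(gc_motif, "ars_pwm"), "`gc_motif` must be a pwm object")
  check_that(nchar(enzyme_site) == 4, "`enzyme_site` must be a 4-mer")
  cfg <- as.list(environment())
  structure(cfg, class = "synth_config")
}

# sample one motif instance (character string) from a pwm.  Columns in
# `core_cols` (the TYGAAC core in the default motif) are restricted to
# their strong bases (>= 25% of the column maximum) so sampling noise
# never destroys the functional core; flanking columns sample freely.
sample_pwm_instance <- function(p, core_cols = integer(0)) {
  paste(vapply(seq_len(pwm_width(p)), function(j) {
    f <- p$freq[, j]
    if (j %in% core_cols) {
      keep <- f >= 0.25 * max(f)
      sample(DNA_BASES[keep], 1L, prob = f[keep])
    } else {
      sample(DNA_BASES, 1L, prob = f)
    }
  }, character(1)), collapse = "")
}

random_dna <- function(n, gc = 0.42) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  sample(DNA_BASES, n, replace = TRUE, prob = p)
}

#' Generate a synthetic genome with planted replication origins
#'
#' Lays out genes and log-normal intergenes along each chromosome,
#' plants G/C-rich motif instances (with an upstream poly(dA) tract) in
#' deliberately long intergenes and repetitive A/T-rich elements in
#' ordinary intergenes, and records full ground truth (coordinates,
#' class, strand, strength, firing time, efficiency) for every planted
#' element.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#'
#' @return A list of class `"synth_genome"` with elements
#'   \describe{
#'     \item{seq}{`DNAStringSet` of chromosome sequences.}
#'     \item{genes}{tibble of genes: `chrom, start, end, strand, gene_id,
#'       tss` (0-based half-open; `tss` is the first transcribed base).}
#'     \item{intergenes}{tibble with `chrom, start, end, length,
#'       orientation` (convergent / divergent / tandem, `NA` at
#'       chromosome ends).}
#'     \item{truth}{tibble of planted elements: `element_id, chrom,
#'       start, end, class, strand, strength, mean_firing_time_min,
#'       efficiency`.}
#'     \item{config}{the config used.}
#'   }
#' @export
make_genome <- function(config = synth_config(), seed = config$seed) {
  cfg <- config
  with_seed(seed, {
    chrom_names <- paste0("chr", seq_len(cfg$n_chroms))
    # split origin counts across chromosomes as evenly as possible
    split_count <- function(n) {
      base <- n %/% cfg$n_chroms
      extra <- n %% cfg$n_chroms
      base + (seq_len(cfg$n_chroms) <= extra)
    }
    gc_per_chrom <- split_count(cfg$n_gc_origins)
    at_per_chrom <- split_count(cfg$n_at_origins)

    seqs <- character(cfg$n_chroms)
    genes_l <- list(); inter_l <- list(); truth_l <- list()

    for (ci in seq_len(cfg$n_chroms)) {
      chrom <- chrom_names[ci]
      layout <- layout_chromosome(cfg, chrom, gc_per_chrom[ci], at_per_chrom[ci])
      bases <- random_dna(cfg$chrom_len)

      # plant elements
      tr <- layout$truth
      if (nrow(tr) > 0) {
        for (k in seq_len(nrow(tr))) {
          el <- tr[k, ]
          if (el$class == "GC") {
            inst <- sample_pwm_instance(cfg$gc_motif, core_cols = 8:13)
            polyA <- strrep("A", cfg$polyA_len)
            if (el$strand == "+") {
              bases[(el$start + 1):(el$end)] <- strsplit(inst, "")[[1]]
              a_end <- el$start - cfg$polyA_gap          # half-open end
              a_start <- a_end - cfg$polyA_len
              if (a_start >= 0) {
                bases[(a_start + 1):a_end] <- strsplit(polyA, "")[[1]]
              }
            } else {
              bases[(el$start + 1):(el$end)] <- strsplit(revcomp(inst), "")[[1]]
              a_start <- el$end + cfg$polyA_gap
              a_end <- a_start + cfg$polyA_len
              if (a_end <= cfg$chrom_len) {
                bases[(a_start + 1):a_end] <- strsplit(strrep("T", cfg$polyA_len), "")[[1]]
              }
            }
          } else {
            inst <- if (el$strand == "+") cfg$at_element else revcomp(cfg$at_element)
            bases[(el$start + 1):(el$end)] <- strsplit(inst, "")[[1]]
          }
        }
      }
      seqs[ci] <- paste(bases, collapse = "")
      genes_l[[ci]] <- layout$genes
      inter_l[[ci]] <- layout$intergenes
      truth_l[[ci]] <- layout$truth
    }

    truth <- bind_rows(truth_l)
    if (nrow(truth) > 0) {
      truth$element_id <- sprintf("%s_%s_%d", truth$class, truth$chrom,
                                  seq_len(nrow(truth)))
      truth <- truth[, c("element_id", "chrom", "start", "end", "class",
                         "strand", "strength", "mean_firing_time_min",
                         "efficiency")]
    }
    structure(list(
      seq = Biostrings::DNAStringSet(setNames(seqs, chrom_names)),
      genes = bind_rows(genes_l),
      intergenes = bind_rows(inter_l),
      truth = truth,
      config = cfg
    ), class = "synth_genome")
  })
}

# Lay out one chromosome: alternating intergene/gene blocks, pick origin
# intergenes subject to the minimum spacing constraint.
layout_chromosome <- function(cfg, chrom, n_gc, n_at) {
  empty_genes <- tibble(chrom = character(), start = integer(),
                        end = integer(), strand = character(),
                        gene_id = character(), tss = integer())
  empty_truth <- tibble(chrom = character(), start = integer(),
                        end = integer(), class = character(),
                        strand = character(), strength = numeric(),
                        mean_firing_time_min = numeric(),
                        efficiency = numeric())

  if (cfg$n_genes == 0) {
    inter <- tibble(chrom = chrom, start = 0L, end = as.integer(cfg$chrom_len),
                    length = as.integer(cfg$chrom_len),
                    orientation = NA_character_)
    truth <- plant_in_intervals(cfg, chrom, inter, n_gc, n_at, empty_truth)
    return(list(genes = empty_genes, intergenes = inter, truth = truth))
  }

  ng <- cfg$n_genes
  gene_len <- pmax(300L, as.integer(round(rlnorm(ng, cfg$gene_len_mu,
                                                 cfg$gene_len_sigma))))
  inter_len <- pmax(2L, as.integer(round(rlnorm(ng + 1, cfg$intergene_mu,
                                                cfg$intergene_sigma))))

  # interior intergenes eligible to host origins; origins are spread on
  # a jittered even grid so each can resolve as its own timing peak
  interior <- 2:ng
  n_orig <- n_gc + n_at
  check_that(length(interior) >= n_orig, "too few intergenes for requested origins")
  host <- integer(0)
  cls_order <- character(0)
  if (n_orig > 0) {
    block <- inter_len[seq_len(ng)] + gene_len
    prov_mid <- c(0, cumsum(block)) + inter_len / 2
    spacing <- sum(block) / n_orig
    targets <- (seq_len(n_orig) - 0.5) * spacing +
      runif(n_orig, -0.2, 0.2) * spacing
    avail <- interior
    for (tg in targets) {
      pick <- avail[which.min(abs(prov_mid[avail] - tg))]
      host <- c(host, pick)
      avail <- setdiff(avail, pick)
    }
    cls_order <- sample(c(rep("GC", n_gc), rep("AT", n_at)))
  }
  gc_host <- host[cls_order == "GC"]
  at_host <- host[cls_order == "AT"]
  inter_len[gc_host] <- pmax(as.integer(round(inter_len[gc_host] *
                                              cfg$gc_intergene_factor)), 500L)
  at_min <- nchar(cfg$at_element) + 80L
  inter_len[at_host] <- pmax(inter_len[at_host], at_min)

  total <- sum(gene_len) + sum(inter_len)
  if (total > cfg$chrom_len) {
    abort(sprintf(paste0("infeasible packing on %s: genes + intergenes need ",
                         "%d bp but chrom_len is %d"),
                  chrom, total, cfg$chrom_len))
  }
  inter_len[ng + 1] <- inter_len[ng + 1] + (cfg$chrom_len - total)

  # cumulative layout: I1 G1 I2 G2 ... Gn I(n+1)
  strand <- sample(c("+", "-"), ng, replace = TRUE)
  g_start <- integer(ng); g_end <- integer(ng)
  i_start <- integer(ng + 1); i_end <- integer(ng + 1)
  pos <- 0L
  for (i in seq_len(ng)) {
    i_start[i] <- pos; pos <- pos + inter_len[i]; i_end[i] <- pos
    g_start[i] <- pos; pos <- pos + gene_len[i]; g_end[i] <- pos
  }
  i_start[ng + 1] <- pos; i_end[ng + 1] <- pos + inter_len[ng + 1]

  genes <- tibble(
    chrom = chrom, start = g_start, end = g_end, strand = strand,
    gene_id = sprintf("%s_g%04d", chrom, seq_len(ng)),
    tss = ifelse(strand == "+", g_start, g_end - 1L)
  )

  left_strand <- c(NA, strand)    # gene upstream of intergene i
  right_strand <- c(strand, NA)   # gene downstream
  orientation <- dplyr::case_when(
    is.na(left_strand) | is.na(right_strand) ~ NA_character_,
    left_strand == "+" & right_strand == "-" ~ "convergent",
    left_strand == "-" & right_strand == "+" ~ "divergent",
    TRUE ~ "tandem"
  )
  inter <- tibble(chrom = chrom, start = i_start, end = i_end,
                  length = i_end - i_start, orientation = orientation)

  host_df <- inter[host, ]
  host_df$class <- ifelse(host %in% gc_host, "GC", "AT")
  truth <- plant_in_hosts(cfg, chrom, host_df, empty_truth)
  list(genes = genes, intergenes = inter, truth = truth)
}

# place elements centred in their host intergenes, honouring min spacing
plant_in_hosts <- function(cfg, chrom, host_df, empty_truth) {
  if (nrow(host_df) == 0) return(empty_truth)
  host_df <- host_df[order(host_df$start), ]
  mids <- interval_mid(host_df$start, host_df$end)
  keep <- logical(nrow(host_df)); last <- -Inf
  for (i in seq_len(nrow(host_df))) {
    if (mids[i] - last >= cfg$min_origin_spacing_bp) {
      keep[i] <- TRUE; last <- mids[i]
    }
  }
  if (!all(keep)) {
    abort(sprintf(paste0("infeasible packing on %s: cannot place %d origins ",
                         "with min_origin_spacing_bp = %d; reduce origin count ",
                         "or spacing"),
                  chrom, nrow(host_df), cfg$min_origin_spacing_bp))
  }
  rows <- lapply(seq_len(nrow(host_df)), function(i) {
    h <- host_df[i, ]
    w <- if (h$class == "GC") pwm_width(cfg$gc_motif) else nchar(cfg$at_element)
    mid <- interval_mid(h$start, h$end)
    s <- as.integer(mid - w %/% 2); e <- s + w
    is_gc <- h$class == "GC"
    tibble(chrom = chrom, start = s, end = as.integer(e), class = h$class,
           strand = sample(c("+", "-"), 1L),
           strength = (if (is_gc) cfg$gc_strength else cfg$at_strength) *
             exp(rnorm(1, 0, 0.25)),
           mean_firing_time_min = rnorm(1,
             if (is_gc) cfg$gc_fire_mean else cfg$at_fire_mean, 1),
           efficiency = if (is_gc) cfg$gc_efficiency else cfg$at_efficiency)
  })
  bind_rows(rows)
}

# geneless chromosome: spread origins evenly with jitter
plant_in_intervals <- function(cfg, chrom, inter, n_gc, n_at, empty_truth) {
  n <- n_gc + n_at
  if (n == 0) return(empty_truth)
  mids <- as.integer(seq(cfg$chrom_len * 0.1, cfg$chrom_len * 0.9,
                         length.out = n))
  cls <- sample(c(rep("GC", n_gc), rep("AT", n_at)))
  host <- tibble(chrom = chrom,
                 start = mids - 300L, end = mids + 300L, class = cls)
  plant_in_hosts(cfg, chrom, host, empty_truth)
}

#' @export
print.synth_genome <- function(x, ...) {
  cat(sprintf("<synth_genome> %d chromosome(s), %s bp total\n",
              length(x$seq), format(sum(Biostrings::width(x$seq)),
                                    big.mark = ",")))
  cat(sprintf("  genes: %d   intergenes: %d   planted elements: %d (GC %d / AT %d)\n",
              nrow(x$genes), nrow(x$intergenes), nrow(x$truth),
              sum(x$truth$class == "GC"), sum(x$truth$class == "AT")))
  invisible(x)
}
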