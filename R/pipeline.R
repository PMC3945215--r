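# End-to-end pipeline on synthetic data: generate a genome, run every
# assay simulator, and push the results through fragment assembly,
# motif classification and replication timing, measuring recovery
# against the planted ground truth.

# sequence of a 0-based half-open interval
get_seq <- function(genome, chrom, start, end) {
  s <- genome_seqs(genome)[[chrom]]
  as.character(Biostrings::subseq(s, start + 1L, end))
}

# extract intergenic sequences for background fitting
intergenic_seqs <- function(genome, min_len = 20) {
  ig <- genome$intergenes
  ig <- ig[ig$end - ig$start >= min_len, ]
  vapply(seq_len(nrow(ig)), function(i) {
    get_seq(genome, ig$chrom[i], ig$start[i], ig$end[i])
  }, character(1))
}

# match contigs to planted elements by interval overlap
match_truth <- function(contigs, truth) {
  vapply(seq_len(nrow(contigs)), function(i) {
    hit <- which(truth$chrom == contigs$chrom[i] &
                   truth$start < contigs$end[i] &
                   truth$end > contigs$start[i])
    if (length(hit) == 0) NA_character_ else truth$element_id[hit[1]]
  }, character(1))
}

#' Run the full origin-mapping pipeline on synthetic data
#'
#' Generates a genome with planted origins, simulates the fragment
#' screen, the miniARS subfragment screen and the S/G1 sorted reads,
#' and runs contig assembly + core inference, motif classification and
#' replication-timing peak calling, scoring each stage against the
#' planted truth.
#'
#' @param config A [synth_config()].
#' @param seed Integer master seed; stage seeds are derived from it.
#' @param reads_per_bin Mean reads per 1 kb timing bin per sample.
#' @param score_threshold Motif score (bits) for the genome scan used in
#'   classification support (best-hit scoring is threshold-free).
#' @param min_prominence Peak-calling prominence.
#'
#' @return A list: `genome`, `fragments`, `contigs`, `miniars_contigs`,
#'   `ars_table`, `class_fit`, `profile`, `peaks`, and a `metrics`
#'   one-row tibble (element recovery, class accuracy, peak recovery,
#'   false peaks per Mb, replicate concordance).
#' @export
run_ars_pipeline <- function(config = synth_config(), seed = config$seed,
                             reads_per_bin = 1000, score_threshold = 15,
                             min_prominence = 0.02) {
  genome <- make_genome(config, seed = seed)
  truth <- genome$truth

  # --- fragment screen -> contigs -> cores ---------------------------------
  frags <- simulate_arsseq(genome, seed = seed + 1L)
  frags <- validate_fragment_ends(frags, genome,
                                  enzyme_site = config$enzyme_site)
  contigs <- frags %>%
    assemble_contigs() %>%
    filter_contigs_arsseq() %>%
    resolve_bridged_contigs() %>%
    infer_core(genome)

  mini <- simulate_miniars(frags, truth, seed = seed + 2L)
  mini_contigs <- mini %>%
    filter(.data$read_depth >= 2) %>%
    assemble_contigs() %>%
    filter_contigs_miniars() %>%
    infer_core(genome)

  compiled <- compile_ars_table(contigs, mini_contigs)
  ars_table <- compiled$ars

  contigs$element_id <- match_truth(contigs, truth)
  recovered <- truth$element_id %in% contigs$element_id
  element_recovery <- mean(recovered)

  # --- motif classification ------------------------------------------------
  bg <- fit_background(intergenic_seqs(genome), order = 5)
  ars_seqs <- setNames(
    vapply(seq_len(nrow(contigs)), function(i) {
      get_seq(genome, contigs$chrom[i], contigs$start[i], contigs$end[i])
    }, character(1)),
    contigs$contig_id)
  hits <- best_hit_per_sequence(ars_seqs, config$gc_motif, bg)
  hits <- left_join(hits,
                    select(contigs, "contig_id", "element_id"),
                    by = c(seq_id = "contig_id"))
  fit <- split_bimodal(hits)
  labelled <- tidy(fit) %>%
    left_join(select(truth, "element_id", truth_class = "class"),
              by = "element_id")
  with_truth <- filter(labelled, !is.na(.data$truth_class))
  class_accuracy <- if (fit$split && nrow(with_truth) > 0) {
    mean(with_truth$class == with_truth$truth_class)
  } else NA_real_

  # --- replication timing --------------------------------------------------
  reads <- simulate_timing_reads(genome, reads_per_bin = reads_per_bin,
                                 seed = seed + 3L)
  ratio_tracks <- purrr::map_dfr(sort(unique(reads$replicate)), function(r) {
    s_tr <- bin_reads(reads[reads$replicate == r & reads$phase == "S", ],
                      genome)
    g_tr <- bin_reads(reads[reads$replicate == r & reads$phase == "G1", ],
                      genome)
    mutate(ratio_profile(s_tr, g_tr), replicate = r)
  })
  profile <- smooth_and_normalize(ratio_tracks)
  peaks <- call_peaks(profile, min_prominence = min_prominence)

  t_mid <- interval_mid(truth$start, truth$end)
  high_eff <- truth$efficiency >= 0.8
  peak_dist <- vapply(seq_len(nrow(truth)), function(i) {
    p <- peaks[peaks$chrom == truth$chrom[i], ]
    if (nrow(p) == 0) return(Inf)
    min(abs(p$coord - t_mid[i]))
  }, numeric(1))
  peak_recovery <- mean(peak_dist[high_eff] <= 2000)
  false_peaks <- sum(vapply(seq_len(nrow(peaks)), function(i) {
    t_chr <- t_mid[truth$chrom == peaks$chrom[i]]
    length(t_chr) == 0 || min(abs(t_chr - peaks$coord[i])) > 10000
  }, logical(1)))
  genome_mb <- sum(chrom_lengths(genome)) / 1e6
  conc <- glance(profile)

  metrics <- tibble(
    n_elements = nrow(truth),
    element_recovery = element_recovery,
    class_accuracy = class_accuracy,
    split_threshold = fit$threshold,
    peak_recovery_2kb = peak_recovery,
    false_peaks_per_mb = false_peaks / genome_mb,
    n_peaks = nrow(peaks),
    timing_pearson = conc$pearson,
    timing_spearman = conc$spearman)

  list(genome = genome, fragments = frags, contigs = contigs,
       miniars_contigs = mini_contigs, ars_table = ars_table,
       hits = hits, class_fit = fit, profile = profile, peaks = peaks,
       metrics = metrics)
}
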