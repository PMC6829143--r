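# End-to-end convenience wrappers: simulate -> features -> labels -> table.
# These keep the replicate-training and evaluation code (and the examples)
# to a few lines; each step remains available individually.

#' Simulate a labeled training (or test) set
#'
#' Runs the full simulation pipeline for one contig: sample a truth set,
#' build the pool of haplotypes, simulate mapped reads, compute sub-window
#' statistics, assemble focal +/- k feature vectors, and label them from the
#' truth set.
#'
#' @param config A [sim_config()].
#' @param ref_length Reference contig length in bp.
#' @param contig Contig name.
#' @param window_size Sub-window size in bp.
#' @param k Flanking sub-windows per side.
#' @param allowed_regions Optional placement regions for [sample_cnvs()].
#' @param repeats,mask_mode Optional repeat intervals and masking mode
#'   forwarded to [apply_repeat_mask()].
#' @return List: `truth`, `alignments`, `normalizer`, `stats`, `vectors`,
#'   `labels`, `table` (the training table).
#' @export
simulate_training_set <- function(config, ref_length, contig = "chr1",
                                  window_size = 50L, k = 5L,
                                  allowed_regions = NULL,
                                  repeats = NULL,
                                  mask_mode = "no_repeats") {
  truth <- sample_cnvs(setNames(ref_length, contig), allowed_regions, config)
  pool <- build_pool(ref_length, truth, config)
  aln <- simulate_alignments(pool, config, contig = contig,
                             ref_length = ref_length)
  norm <- compute_normalizer(aln, contig, window_size)
  stats <- window_stats(aln, norm)
  if (!is.null(repeats)) stats <- apply_repeat_mask(stats, repeats, mask_mode)
  vec <- vectorize_windows(stats, k)
  lab <- label_windows(stats[, c("contig", "start", "end")], truth,
                       pool_size = config$pool_size)
  tab <- build_training_table(vec, lab)
  list(truth = truth, alignments = aln, normalizer = norm, stats = stats,
       vectors = vec, labels = lab, table = tab)
}
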