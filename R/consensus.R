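# Bootstrap-consensus calling: many classifiers trained on independently
# simulated training sets vote on each window. The consensus fraction is the
# false-positive filter: artifacts of any single simulated training set
# rarely replicate across independent sets.

#' Consensus configuration
#'
#' @param n_replicates Number of independently simulated training sets /
#'   classifiers (1, 10 and 100 are the canonical settings).
#' @param min_support Consensus-fraction cutoff in \[0, 1\] for keeping a
#'   CNV-class call.
#' @param min_probability Per-replicate probability cutoff in \[0, 1\]; a
#'   replicate vote below it is converted to `normal` before voting.
#' @param base_seed Seed; replicate r uses `base_seed + r` throughout.
#' @return Object of class `consensus_config`.
#' @export
consensus_config <- function(n_replicates = 10L, min_support = 0.9,
                             min_probability = 0, base_seed = 1L) {
  stopifnot(n_replicates >= 1, min_support >= 0, min_support <= 1,
            min_probability >= 0, min_probability <= 1)
  structure(list(n_replicates = as.integer(n_replicates),
                 min_support = min_support,
                 min_probability = min_probability,
                 base_seed = as.integer(base_seed)),
            class = "consensus_config")
}

#' Train replicate classifiers on independent simulated training sets
#'
#' Replicate `r` re-runs the whole simulator (CNV placement, pool
#' assignment, read simulation) with seed `base_seed + r`, then trains one
#' classifier on the resulting table; classifier seeds follow the same
#' scheme, so each replicate is individually reproducible.
#'
#' @param sim_cfg A [sim_config()] template (its `seed` is overridden per
#'   replicate).
#' @param spec A [classifier_spec()] template (idem).
#' @param n_replicates Number of replicates.
#' @param base_seed Base seed.
#' @param ref_length,contig,window_size,k,allowed_regions,repeats,mask_mode
#'   Forwarded to [simulate_training_set()].
#' @return List of `n_replicates` fitted `cnv_classifier` models.
#' @export
replicate_training <- function(sim_cfg, spec, n_replicates = 10L,
                               base_seed = 1L, ref_length = 1e6,
                               contig = "chr1", window_size = 50L, k = 5L,
                               allowed_regions = NULL, repeats = NULL,
                               mask_mode = "no_repeats") {
  stopifnot(n_replicates >= 1)
  lapply(seq_len(n_replicates), function(r) {
    cfg_r <- sim_cfg
    cfg_r$seed <- as.integer(base_seed + r)
    spec_r <- spec
    spec_r$seed <- as.integer(base_seed + r)
    ts <- tryCatch(
      simulate_training_set(cfg_r, ref_length, contig, window_size, k,
                            allowed_regions, repeats, mask_mode),
      error = function(e) abort(sprintf("replicate %d failed: %s", r,
                                        conditionMessage(e)), parent = e))
    train_classifier(ts$table, spec_r)
  })
}

#' Combine replicate window calls into consensus calls
#'
#' For each focal window, every replicate casts one class vote; votes whose
#' probability is below `min_probability` are converted to `normal` first,
#' so the support denominator stays fixed at `n_replicates`. The consensus
#' class is the plurality vote (ties broken toward `normal`, then
#' `deletion`), `bootstrap_support` is the consensus class's vote fraction,
#' the consensus copy number is the median of the consensus-class
#' replicates' copy numbers, and `probability` is their median probability.
#'
#' @param call_tables List of [predict.cnv_classifier()] tibbles, one per
#'   replicate, on identical focal windows.
#' @param config A [consensus_config()].
#' @return Tibble: focal interval, `cnv_class`, `bootstrap_support`,
#'   `probability`, `copy_number`.
#' @export
consensus_calls <- function(call_tables, config = consensus_config()) {
  n_rep <- length(call_tables)
  stopifnot(n_rep >= 1)
  key0 <- call_tables[[1]][, c("contig", "start", "end")]
  for (ct in call_tables) {
    if (!identical(ct[, c("contig", "start", "end")], key0))
      abort("replicate call tables disagree on focal intervals",
            class = "cnvforest_integrity_error")
  }
  n_win <- nrow(key0)
  cls <- matrix("", n_win, n_rep)
  prob <- matrix(0, n_win, n_rep)
  cn <- matrix(NA_real_, n_win, n_rep)
  for (r in seq_len(n_rep)) {
    v <- call_tables[[r]]$cnv_class
    below <- call_tables[[r]]$probability < config$min_probability
    v[below & v != "normal"] <- "normal"
    cls[, r] <- v
    prob[, r] <- call_tables[[r]]$probability
    cn[, r] <- call_tables[[r]]$copy_number
  }
  votes <- vapply(CLASS_LEVELS, function(cl) rowSums(cls == cl),
                  numeric(n_win))
  if (n_win == 1) votes <- matrix(votes, nrow = 1,
                                  dimnames = list(NULL, CLASS_LEVELS))
  # plurality; ties.method="first" on normal/deletion/duplication order
  # breaks ties toward normal, then deletion
  pick <- max.col(votes, ties.method = "first")
  consensus <- CLASS_LEVELS[pick]
  support <- votes[cbind(seq_len(n_win), pick)] / n_rep
  med_of_class <- function(m) {
    vapply(seq_len(n_win), function(i) {
      sel <- cls[i, ] == consensus[i]
      if (!any(sel)) return(NA_real_)
      median(m[i, sel])
    }, numeric(1))
  }
  out <- key0
  out$cnv_class <- consensus
  out$bootstrap_support <- support
  out$probability <- med_of_class(prob)
  out$copy_number <- med_of_class(cn)
  out
}

#' Filter consensus calls by bootstrap support
#'
#' CNV-class calls with `bootstrap_support >= min_support` are retained;
#' those below the cutoff are reclassified as `normal` (copy number 1).
#' Normal calls pass through untouched.
#'
#' @param calls A [consensus_calls()] tibble.
#' @param min_support Support cutoff in \[0, 1\].
#' @return Filtered calls tibble.
#' @export
filter_consensus <- function(calls, min_support = 0.95) {
  drop <- calls$cnv_class != "normal" & calls$bootstrap_support < min_support
  calls$cnv_class[drop] <- "normal"
  calls$copy_number[drop] <- 1
  calls
}
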