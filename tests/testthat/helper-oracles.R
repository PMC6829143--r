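# Independent brute-force oracles. These deliberately share no code with the
# package internals they check.

# Naive per-base window statistics from a raw depth vector + record table.
oracle_window_stats <- function(depth, records, start, end, window_size,
                                contig_len = length(depth)) {
  mean_c <- mean(depth)
  median_c <- median(depth)
  v <- depth[(start + 1):end]
  n_bins <- contig_len %/% window_size
  bin_counts <- function(starts) {
    cnt <- numeric(n_bins)
    for (s in starts) {
      b <- s %/% window_size + 1
      if (b >= 1 && b <= n_bins) cnt[b] <- cnt[b] + 1
    }
    cnt
  }
  imp_all <- bin_counts(records$start[records$improper & !records$supplementary])
  sup_all <- bin_counts(records$start[records$supplementary])
  in_win <- function(starts) sum(starts >= start & starts < end)
  imp_n <- in_win(records$start[records$improper & !records$supplementary])
  sup_n <- in_win(records$start[records$supplementary])
  std_cnt <- function(cnt, m) if (m > 0) cnt / m else if (cnt == 0) 1 else cnt
  q <- unname(quantile(v / mean_c, c(0.25, 0.75)))
  list(std_mean = mean(v) / mean_c,
       std_median = median(v) / median_c,
       std_sd = sd(v / mean_c),
       std_iqr = q[2] - q[1],
       improper_std = std_cnt(imp_n, mean(imp_all)),
       supplementary_std = std_cnt(sup_n, mean(sup_all)))
}

# Pool-average copies of the focal sequence by explicit haplotype enumeration.
oracle_copy_number <- function(cnv_type, copies, carriers, pool_size) {
  per_hap <- rep(1, pool_size)
  c_eff <- if (cnv_type == "deletion") 0 else copies
  if (carriers > 0) per_hap[seq_len(carriers)] <- c_eff
  mean(per_hap)
}

# Brute-force gap-tolerant merging of same-class window runs: two same-class
# windows join only when every window between them is normal and there are at
# most max_gap of them.
oracle_merge <- function(calls, max_gap) {
  runs <- list()
  for (cl in setdiff(unique(calls$cnv_class), "normal")) {
    idx <- which(calls$cnv_class == cl)
    if (length(idx) == 0) next
    joined <- c(FALSE, vapply(seq_along(idx)[-1], function(t) {
      between <- if (idx[t] - idx[t - 1] <= 1) character(0)
                 else calls$cnv_class[(idx[t - 1] + 1):(idx[t] - 1)]
      length(between) <= max_gap && all(between == "normal")
    }, logical(1)))
    grp <- cumsum(!joined)
    for (g in unique(grp)) {
      members <- idx[grp == g]
      runs[[length(runs) + 1]] <- data.frame(
        start = calls$start[members[1]],
        end = calls$end[members[length(members)]],
        cnv_type = cl, n_windows = length(members))
    }
  }
  if (length(runs) == 0) return(data.frame(start = integer(), end = integer(),
                                           cnv_type = character(),
                                           n_windows = integer()))
  out <- do.call(rbind, runs)
  out[order(out$start), ]
}

# Brute-force interval evaluation by all-pairs reciprocal overlap.
oracle_evaluate <- function(calls, truth, min_recip) {
  detected <- logical(nrow(truth))
  call_hit <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) for (j in seq_len(nrow(truth))) {
    if (calls$cnv_type[i] != truth$cnv_type[j]) next
    ov <- min(calls$end[i], truth$end[j]) - max(calls$start[i], truth$start[j])
    if (ov <= 0) next
    recip <- min(ov / (calls$end[i] - calls$start[i]),
                 ov / (truth$end[j] - truth$start[j]))
    if (recip >= min_recip) { detected[j] <- TRUE; call_hit[i] <- TRUE }
  }
  list(tp = sum(detected), fn = sum(!detected), fp = sum(!call_hit))
}

# Class calls from rounded standardized median coverage (the pure-coverage
# baseline a classifier must beat at low coverage).
rounding_baseline_calls <- function(stats) {
  cn <- as.integer(sign(stats$std_median) * floor(abs(stats$std_median) + 0.5))
  cls <- ifelse(cn < 1, "deletion", ifelse(cn > 1, "duplication", "normal"))
  out <- stats[, c("contig", "start", "end")]
  out$cnv_class <- cls
  out$copy_number <- cn
  out
}
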