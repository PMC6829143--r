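# From window calls to CNV interval calls, evaluation against truth, and
# copy-number estimation baselines (coverage rounding, loess smoothing).

#' Merge classified windows into CNV interval calls
#'
#' Maximal runs of same-class CNV windows become one call, tolerating up to
#' `max_gap_windows` interleaved windows of a different class (default 1, so
#' a single misclassified interior window does not split a long CNV). The
#' call spans the first to the last member window; copy number is the mean
#' and support/probability the minimum over member CNV windows.
#'
#' @param window_calls Tibble of window calls sorted by position on one
#'   contig, with `cnv_class` and optionally `copy_number`,
#'   `bootstrap_support`, `probability`.
#' @param max_gap_windows Gap tolerance in windows.
#' @return Tibble of CNV calls: `contig`, `start`, `end`, `cnv_type`,
#'   `copy_number`, `bootstrap_support`, `probability`, `n_windows`.
#' @export
merge_windows <- function(window_calls, max_gap_windows = 1L) {
  x <- window_calls
  if (nrow(x) == 0) {
    return(tibble(contig = character(), start = integer(), end = integer(),
                  cnv_type = character(), copy_number = double(),
                  bootstrap_support = double(), probability = double(),
                  n_windows = integer()))
  }
  if (length(unique(x$contig)) > 1)
    abort("merge_windows runs on a single contig", class = "cnvforest_order_error")
  if (is.unsorted(x$start))
    abort("window calls must be sorted by position", class = "cnvforest_order_error")

  out <- list()
  cur <- NULL
  gap <- 0L
  flush <- function(cur) {
    members <- cur$members
    tibble(contig = members$contig[1],
           start = min(members$start), end = max(members$end),
           cnv_type = cur$class,
           copy_number = mean(members$copy_number %||% NA_real_),
           bootstrap_support = if ("bootstrap_support" %in% names(members))
             min(members$bootstrap_support) else NA_real_,
           probability = if ("probability" %in% names(members))
             min(members$probability) else NA_real_,
           n_windows = nrow(members))
  }
  for (i in seq_len(nrow(x))) {
    cl <- x$cnv_class[i]
    if (is.null(cur)) {
      if (cl != "normal") cur <- list(class = cl, members = x[i, ]); next
    }
    if (cl == cur$class) {
      cur$members <- bind_rows(cur$members, x[i, ])
      gap <- 0L
    } else if (cl == "normal" && gap < max_gap_windows) {
      gap <- gap + 1L
    } else {
      out[[length(out) + 1]] <- flush(cur)
      cur <- NULL
      gap <- 0L
      if (cl != "normal") cur <- list(class = cl, members = x[i, ])
    }
  }
  if (!is.null(cur)) out[[length(out) + 1]] <- flush(cur)
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(contig = character(), start = integer(), end = integer(),
                  cnv_type = character(), copy_number = double(),
                  bootstrap_support = double(), probability = double(),
                  n_windows = integer()))
  }
  res
}

#' Evaluate CNV calls against a truth set
#'
#' Interval level: a truth CNV counts as detected when some call of the same
#' type reaches reciprocal overlap `>= min_reciprocal_overlap` (both the
#' call and the truth interval must be covered by that fraction); calls
#' matching no truth record are false positives, undetected truth records
#' false negatives; `TPR = TP / (TP + FN)`. Window level (when window calls
#' and labels are supplied): TPR is the fraction of truly CNV windows called
#' with the correct CNV class, FPR the fraction of truly normal windows
#' called as any CNV.
#'
#' @param cnv_calls A [merge_windows()] tibble.
#' @param truth_cnvs Truth-set tibble.
#' @param min_reciprocal_overlap Reciprocal-overlap cutoff (default 0.5).
#' @param window_calls,window_labels Optional window-level calls and
#'   [label_windows()] labels for the window-level metrics.
#' @return Object of class `cnv_eval`: list with `intervals` (counts and
#'   rates, overall and per type), `windows` (or `NULL`), and `params`.
#' @export
evaluate_calls <- function(cnv_calls, truth_cnvs, min_reciprocal_overlap = 0.5,
                           window_calls = NULL, window_labels = NULL) {
  n_truth <- nrow(truth_cnvs)
  matched_truth <- logical(n_truth)
  matched_call <- logical(nrow(cnv_calls))
  if (nrow(cnv_calls) > 0 && n_truth > 0) {
    ov <- interval_overlaps(cnv_calls, truth_cnvs)
    if (nrow(ov) > 0) {
      same_type <- cnv_calls$cnv_type[ov$query] == truth_cnvs$cnv_type[ov$subject]
      w_call <- cnv_calls$end[ov$query] - cnv_calls$start[ov$query]
      w_truth <- truth_cnvs$end[ov$subject] - truth_cnvs$start[ov$subject]
      recip <- pmin(ov$overlap / w_call, ov$overlap / w_truth)
      ok <- same_type & recip >= min_reciprocal_overlap
      matched_truth[unique(ov$subject[ok])] <- TRUE
      matched_call[unique(ov$query[ok])] <- TRUE
    }
  }
  per_type <- function(sel_truth, sel_call) {
    tp <- sum(matched_truth[sel_truth])
    fn <- sum(!matched_truth[sel_truth])
    fp <- sum(!matched_call[sel_call])
    tibble(true_positives = tp, false_positives = fp, false_negatives = fn,
           TPR = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
  }
  intervals <- bind_rows(
    mutate(per_type(rep(TRUE, n_truth), rep(TRUE, nrow(cnv_calls))),
           cnv_type = "all", .before = 1),
    mutate(per_type(truth_cnvs$cnv_type == "duplication",
                    cnv_calls$cnv_type == "duplication"),
           cnv_type = "duplication", .before = 1),
    mutate(per_type(truth_cnvs$cnv_type == "deletion",
                    cnv_calls$cnv_type == "deletion"),
           cnv_type = "deletion", .before = 1)
  )
  windows <- NULL
  if (!is.null(window_calls) && !is.null(window_labels)) {
    windows <- evaluate_windows(window_calls, window_labels)
  }
  structure(list(intervals = intervals, windows = windows,
                 params = list(min_reciprocal_overlap = min_reciprocal_overlap)),
            class = "cnv_eval")
}

#' Window-level classification rates
#'
#' @param window_calls Window calls with `cnv_class`.
#' @param window_labels [label_windows()] truth labels on the same windows.
#' @return Tibble with window-level TP/FP/FN counts, `TPR` (truly CNV
#'   windows called with the correct class) and `FPR` (truly normal windows
#'   called as CNV).
#' @export
evaluate_windows <- function(window_calls, window_labels) {
  key <- c("contig", "start", "end")
  j <- inner_join(window_calls[, c(key, "cnv_class")],
                  window_labels[, c(key, "cnv_class")],
                  by = key, suffix = c("_call", "_truth"))
  truth_cnv <- j$cnv_class_truth != "normal"
  call_cnv <- j$cnv_class_call != "normal"
  correct <- j$cnv_class_call == j$cnv_class_truth
  tibble(
    n_windows = nrow(j),
    true_positives = sum(truth_cnv & correct),
    false_positives = sum(!truth_cnv & call_cnv),
    false_negatives = sum(truth_cnv & !correct),
    TPR = if (any(truth_cnv)) sum(truth_cnv & correct) / sum(truth_cnv)
          else NA_real_,
    FPR = if (any(!truth_cnv)) sum(!truth_cnv & call_cnv) / sum(!truth_cnv)
          else NA_real_
  )
}

#' @export
print.cnv_eval <- function(x, ...) {
  cat("<cnv_eval> interval level (reciprocal overlap >=",
      x$params$min_reciprocal_overlap, "):\n")
  print(as.data.frame(x$intervals), row.names = FALSE)
  if (!is.null(x$windows)) {
    cat("window level:\n")
    print(as.data.frame(x$windows), row.names = FALSE)
  }
  invisible(x)
}

#' Coverage-rounding copy-number baseline
#'
#' The classical estimate: the window's standardized median coverage rounded
#' to the nearest whole value (half away from zero).
#'
#' @param std_median Standardized median coverage (vectorized).
#' @return Integer copy estimates.
#' @export
coverage_copy_number <- function(std_median) {
  as.integer(round_half_away(std_median))
}

#' Loess-smoothed copy-number baseline
#'
#' Fits a local quadratic regression (span 0.75) of true copy number on
#' standardized median coverage over training pairs, predicts at the query
#' coverages (clamped to the training range, so extrapolation returns the
#' boundary prediction), and rounds to the nearest value on the training
#' copy grid.
#'
#' @param train_pairs Tibble (`std_median`, `copy_number`) of training pairs.
#' @param query_std_median Query coverages.
#' @param span Loess span.
#' @return Copy estimates on the training grid.
#' @export
smoothed_copy_number <- function(train_pairs, query_std_median, span = 0.75) {
  if (is.null(train_pairs) || nrow(train_pairs) == 0)
    abort("empty training set for the smoothed estimator",
          class = "cnvforest_estimation_error")
  fit <- loess(copy_number ~ std_median, data = train_pairs, span = span,
               degree = 2, surface = "direct")
  rng <- range(train_pairs$std_median)
  q <- pmin(pmax(query_std_median, rng[1]), rng[2])
  pred <- predict(fit, newdata = data.frame(std_median = q))
  grid <- sort(unique(train_pairs$copy_number))
  grid[pmax(1, findInterval(pred, grid[-length(grid)] + diff(grid) / 2) + 1)]
}

#' Compare the copy-number estimators
#'
#' Per true copy number, the exact-match rate and mean absolute error of the
#' classifier's copy-number prediction, the coverage-rounding baseline, and
#' the loess-smoothed baseline, all on the same windows.
#'
#' @param model A [train_classifier()] model trained for copy number.
#' @param feature_vectors Feature vectors of the query windows.
#' @param window_stats Stats tibble of the query windows (for `std_median`).
#' @param truth_copy True copy number per query window.
#' @param train_pairs Training pairs for [smoothed_copy_number()].
#' @param max_copy Largest copy number to tabulate.
#' @return Tibble: `copy_number`, `n`, then `<estimator>_exact` and
#'   `<estimator>_mae` for classifier, rounding, smoothed.
#' @export
compare_copy_estimators <- function(model, feature_vectors, window_stats,
                                    truth_copy, train_pairs,
                                    max_copy = NULL) {
  if (length(truth_copy) == 0) {
    return(tibble(copy_number = double(), n = integer()))
  }
  key <- c("contig", "start", "end")
  stats_m <- inner_join(feature_vectors[, key], window_stats, by = key)
  est <- tibble(
    truth = truth_copy,
    classifier = predict(model, feature_vectors)$copy_number,
    rounding = coverage_copy_number(stats_m$std_median),
    smoothed = smoothed_copy_number(train_pairs, stats_m$std_median)
  )
  max_copy <- max_copy %||% max(est$truth)
  est <- est[est$truth <= max_copy, ]
  est %>%
    group_by(copy_number = .data$truth) %>%
    summarise(
      n = dplyr::n(),
      classifier_exact = mean(.data$classifier == .data$copy_number),
      classifier_mae = mean(abs(.data$classifier - .data$copy_number)),
      rounding_exact = mean(.data$rounding == .data$copy_number),
      rounding_mae = mean(abs(.data$rounding - .data$copy_number)),
      smoothed_exact = mean(.data$smoothed == .data$copy_number),
      smoothed_mae = mean(abs(.data$smoothed - .data$copy_number)),
      .groups = "drop"
    )
}

#' Write CNV calls as BED6+
#'
#' Columns: contig, start, end, cnv_type, bootstrap support, strand (`.`),
#' copy number.
#'
#' @param calls A [merge_windows()] tibble.
#' @param path Output path.
#' @export
write_calls_bed <- function(calls, path) {
  bed <- data.frame(calls$contig, calls$start, calls$end, calls$cnv_type,
                    calls$bootstrap_support, ".", calls$copy_number)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
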