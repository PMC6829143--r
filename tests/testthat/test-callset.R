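win_calls <- function(classes, w = 50L, support = 1, prob = 0.99) {
  n <- length(classes)
  tibble::tibble(contig = "chr1", start = (seq_len(n) - 1L) * w,
                 end = seq_len(n) * w, cnv_class = classes,
                 copy_number = ifelse(classes == "duplication", 2,
                                      ifelse(classes == "deletion", 0, 1)),
                 bootstrap_support = support, probability = prob)
}

test_that("merge_windows joins runs, tolerates gaps, and splits on class change", {
  m1 <- merge_windows(win_calls(c("duplication", "duplication")))
  expect_equal(nrow(m1), 1)
  expect_equal(c(m1$start, m1$end), c(0, 100))
  expect_equal(m1$n_windows, 2)

  # one interleaved normal window bridges with gap tolerance 1
  m2 <- merge_windows(win_calls(c("duplication", "normal", "duplication")), 1)
  expect_equal(nrow(m2), 1)
  expect_equal(c(m2$start, m2$end), c(0, 150))
  # but not with tolerance 0
  m2b <- merge_windows(win_calls(c("duplication", "normal", "duplication")), 0)
  expect_equal(nrow(m2b), 2)

  # class change splits even when adjacent
  m3 <- merge_windows(win_calls(c("duplication", "normal", "normal",
                                  "deletion")))
  expect_equal(nrow(m3), 2)
  expect_equal(m3$cnv_type, c("duplication", "deletion"))

  # summary stats over members
  calls <- win_calls(c("duplication", "duplication"),
                     support = c(0.9, 1), prob = c(0.97, 0.99))
  calls$copy_number <- c(2, 3)
  m4 <- merge_windows(calls)
  expect_equal(m4$copy_number, 2.5)
  expect_equal(m4$bootstrap_support, 0.9)
  expect_equal(m4$probability, 0.97)

  expect_error(merge_windows(win_calls(c("normal", "normal"))[2:1, ]),
               class = "cnvforest_order_error")
  expect_equal(nrow(merge_windows(win_calls(rep("normal", 5)))), 0)
})

test_that("merge_windows agrees with the brute-force oracle on random tracks", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      gap <- sample(0:2, 1)
      classes <- sample(c("normal", "deletion", "duplication"), 60, TRUE,
                        prob = c(0.6, 0.2, 0.2))
      got <- merge_windows(win_calls(classes), gap)
      want <- oracle_merge(win_calls(classes), gap)
      expect_equal(nrow(got), nrow(want))
      if (nrow(want)) {
        got <- got[order(got$start), ]
        expect_equal(got$start, want$start)
        expect_equal(got$end, want$end)
        expect_equal(got$cnv_type, want$cnv_type)
        expect_equal(got$n_windows, want$n_windows)
      }
      # disjoint per class, span covered by members
      for (cl in unique(got$cnv_type)) {
        g <- got[got$cnv_type == cl, ]
        g <- g[order(g$start), ]
        if (nrow(g) > 1) expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
      }
    }
  })
})

test_that("evaluate_calls applies reciprocal overlap and matches the oracle", {
  truth <- tibble::tibble(contig = "chr1", start = c(100L, 1000L),
                          end = c(500L, 1600L),
                          cnv_type = c("duplication", "deletion"),
                          copies = c(2L, 0L), frequency = 1)
  # calls identical to truth
  calls <- tibble::tibble(contig = "chr1", start = truth$start,
                          end = truth$end, cnv_type = truth$cnv_type)
  ev <- evaluate_calls(calls, truth)
  all_row <- ev$intervals[ev$intervals$cnv_type == "all", ]
  expect_equal(all_row$TPR, 1)
  expect_equal(all_row$false_positives, 0)

  # one of two detected
  ev2 <- evaluate_calls(calls[1, ], truth)
  expect_equal(ev2$intervals$TPR[ev2$intervals$cnv_type == "all"], 0.5)

  # 40% reciprocal overlap at cutoff 0.5: both FP and FN
  off <- tibble::tibble(contig = "chr1", start = 340L, end = 740L,
                        cnv_type = "duplication")
  # overlap [340,500) = 160 bp of 400 => 40% both ways
  ev3 <- evaluate_calls(off, truth[1, ], min_reciprocal_overlap = 0.5)
  row3 <- ev3$intervals[ev3$intervals$cnv_type == "all", ]
  expect_equal(row3$false_positives, 1)
  expect_equal(row3$false_negatives, 1)
  # the same call passes at cutoff 0.4
  ev4 <- evaluate_calls(off, truth[1, ], min_reciprocal_overlap = 0.4)
  expect_equal(ev4$intervals$TPR[ev4$intervals$cnv_type == "all"], 1)

  # type must match
  wrong_type <- dplyr::mutate(calls[1, ], cnv_type = "deletion")
  ev5 <- evaluate_calls(wrong_type, truth[1, ])
  expect_equal(ev5$intervals$true_positives[ev5$intervals$cnv_type == "all"], 0)
})

test_that("evaluate_calls matches the all-pairs oracle on random sets", {
  withr::with_seed(77, {
    for (rep in 1:10) {
      truth <- tibble::tibble(
        contig = "chr1", start = sort(sample(seq(0, 20000, 400), 12)),
        cnv_type = sample(c("duplication", "deletion"), 12, TRUE))
      truth$end <- truth$start + sample(100:390, 12, TRUE)
      calls <- tibble::tibble(
        contig = "chr1",
        start = pmax(0L, truth$start + sample(-200:200, 12, TRUE)))
      calls$end <- calls$start + sample(100:390, 12, TRUE)
      calls$cnv_type <- sample(c("duplication", "deletion"), 12, TRUE)
      got <- evaluate_calls(calls, truth, 0.5)
      row <- got$intervals[got$intervals$cnv_type == "all", ]
      want <- oracle_evaluate(calls, truth, 0.5)
      expect_equal(row$true_positives, want$tp)
      expect_equal(row$false_positives, want$fp)
      expect_equal(row$false_negatives, want$fn)
      # TP + FN always equals the truth-set size
      expect_equal(row$true_positives + row$false_negatives, nrow(truth))
    }
  })
})

test_that("coverage_copy_number rounds half away from zero", {
  expect_equal(coverage_copy_number(2.6), 3L)
  expect_equal(coverage_copy_number(0.2), 0L)
  expect_equal(coverage_copy_number(1.0), 1L)
  expect_equal(coverage_copy_number(c(0.5, 1.5, 2.5)), c(1L, 2L, 3L))
})

test_that("almost all windows of a CNV-free 40x contig estimate copy 1", {
  cfg <- sim_config(n_duplications = 0, n_deletions = 0, pool_size = 1,
                    target_coverage = 40, seed = 12)
  aln <- simulate_alignments(list(apply_cnvs(200000L, NULL)), cfg)
  s <- window_stats(aln, compute_normalizer(aln, "chr1", 50))
  expect_gte(mean(coverage_copy_number(s$std_median) == 1L), 0.99)
})

test_that("smoothed_copy_number recovers linear data and clamps extrapolation", {
  train <- tibble::tibble(std_median = rep(0:10, each = 5) + 0,
                          copy_number = rep(0:10, each = 5))
  expect_equal(smoothed_copy_number(train, 4.0), 4)
  expect_equal(smoothed_copy_number(train, c(0.1, 3.9, 7.2)), c(0, 4, 7))
  # below / above the training range clamps to the boundary prediction
  expect_equal(smoothed_copy_number(train, -5), 0)
  expect_equal(smoothed_copy_number(train, 99), 10)
  expect_error(smoothed_copy_number(train[0, ], 1),
               class = "cnvforest_estimation_error")
})

test_that("smoothing beats raw rounding under noise (simulation oracle)", {
  withr::with_seed(8, {
    copy <- sample(0:10, 500, TRUE)
    stdm <- copy + rnorm(500, 0, 0.1)
    # mild nonlinearity akin to diminishing coverage response
    stdm <- stdm * 0.97 + 0.05
    train <- tibble::tibble(std_median = stdm, copy_number = copy)
    query_copy <- sample(0:10, 300, TRUE)
    query <- query_copy + rnorm(300, 0, 0.1)
    query <- query * 0.97 + 0.05
  })
  sm <- smoothed_copy_number(train, query)
  rd <- coverage_copy_number(query)
  expect_lte(mean(abs(sm - query_copy)), mean(abs(rd - query_copy)))
})

test_that("compare_copy_estimators is exact on the noiseless fixture", {
  tab <- noiseless_table(60)
  m <- train_classifier(tab, classifier_spec(seed = 2))
  sch_cols <- setdiff(names(tab), c("cnv_class", "copy_number"))
  vec <- tab[, sch_cols]
  stats <- tab[, c("contig", "start", "end")]
  stats$std_median <- tab$std_median_0
  train_pairs <- tibble::tibble(std_median = tab$std_median_0,
                                copy_number = tab$copy_number)
  # three distinct coverage levels make the quadratic loess singular; the
  # boundary-clamped predictions are still exact
  res <- suppressWarnings(
    compare_copy_estimators(m, vec, stats, tab$copy_number, train_pairs))
  expect_equal(res$classifier_exact, rep(1, nrow(res)))
  expect_equal(res$rounding_exact, rep(1, nrow(res)))
  expect_equal(res$smoothed_exact, rep(1, nrow(res)))
  expect_equal(res$classifier_mae, rep(0, nrow(res)))

  empty <- compare_copy_estimators(m, vec[0, ], stats[0, ], numeric(0),
                                   train_pairs)
  expect_equal(nrow(empty), 0)
})

test_that("calls round-trip to BED", {
  calls <- merge_windows(win_calls(c("duplication", "duplication", "normal",
                                     "deletion")))
  path <- tempfile(fileext = ".bed")
  write_calls_bed(calls, path)
  bed <- utils::read.table(path, sep = "\t")
  expect_equal(nrow(bed), 2)
  expect_equal(bed$V2, calls$start)
  expect_equal(bed$V4, calls$cnv_type)
})
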