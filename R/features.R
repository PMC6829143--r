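# Per-sub-window statistics and feature-vector assembly.
#
# Six statistics per sub-window, standardized against contig-wide baselines:
# mean and median depth (divided by the contig mean and median respectively),
# SD and IQR of per-base standardized depth (elevated at CNV edges), and
# improper-pair / supplementary-read counts divided by their contig-wide
# per-window means. Feature vectors concatenate the statistics of a focal
# sub-window and k flanking sub-windows on each side.

STAT_NAMES <- c("std_mean", "std_median", "std_sd", "std_iqr",
                "improper_std", "supplementary_std")

#' Contig-wide standardization baselines
#'
#' Computes the mean and median of per-base depth over *all* bases of the
#' contig (zero-depth bases included) and the mean improper-pair and
#' supplementary-record counts per sub-window-sized bin. These are the
#' denominators that turn raw window statistics into standardized ones, so
#' statistics are centered near 1 regardless of sequencing depth.
#'
#' @param alignments A `cnv_alignments` object.
#' @param contig Contig name.
#' @param window_size Sub-window size in bp (bin size for the count means).
#' @return An object of class `contig_normalizer`.
#' @export
compute_normalizer <- function(alignments, contig, window_size = 50L) {
  d <- depth_vector(alignments, contig)
  mean_depth <- mean(d)
  median_depth <- median(d)
  if (mean_depth <= 0)
    abort(sprintf("contig '%s' has zero mean depth; cannot standardize", contig),
          class = "cnvforest_standardization_error")
  L <- length(d)
  n_bins <- L %/% window_size
  rec <- alignments$records
  rec <- rec[rec$contig == contig, ]
  counts <- function(sel) {
    s <- rec$start[sel]
    s <- s[s < n_bins * window_size]
    if (n_bins == 0) return(0)
    tabulate(s %/% window_size + 1L, nbins = n_bins)
  }
  imp <- counts(rec$improper & !rec$supplementary)
  sup <- counts(rec$supplementary)
  structure(list(contig = contig, window_size = as.integer(window_size),
                 mean_depth = mean_depth, median_depth = median_depth,
                 mean_improper = mean(imp), mean_supplementary = mean(sup)),
            class = "contig_normalizer")
}

#' @export
print.contig_normalizer <- function(x, ...) {
  cat(sprintf(
    "<contig_normalizer> %s: mean depth %.3f, median %.3f (%d bp bins)\n",
    x$contig, x$mean_depth, x$median_depth, x$window_size))
  invisible(x)
}

#' Tile a contig into fixed-size sub-windows
#'
#' Adjacent non-overlapping tiles (slide equals size); a trailing remainder
#' shorter than `window_size` is dropped so all statistics are computed on
#' equal-width windows.
#'
#' @param contig_length Contig length in bp.
#' @param window_size Tile size in bp.
#' @param contig Contig name.
#' @return Tibble (`contig`, `start`, `end`), ordered by position.
#' @export
tile_windows <- function(contig_length, window_size, contig = "chr1") {
  stopifnot(window_size >= 1)
  n <- contig_length %/% window_size
  if (n == 0)
    return(tibble(contig = character(), start = integer(), end = integer()))
  start <- (seq_len(n) - 1L) * as.integer(window_size)
  tibble(contig = contig, start = start, end = start + as.integer(window_size))
}

#' Standardized statistics for sub-windows
#'
#' Computes the six per-sub-window statistics from per-base depth and
#' breakpoint-read counts. Depth statistics standardize per-base depth by the
#' contig mean (mean, SD, IQR) or contig median (median). Count statistics
#' divide the window count by the contig-wide mean count per window; when
#' that mean is zero the ratio is defined as 1 for a zero count and as the
#' raw count otherwise.
#'
#' @param alignments A `cnv_alignments` object.
#' @param normalizer A [compute_normalizer()] result. Usually computed on the
#'   windows' own contig; passing another contig's normalizer expresses
#'   coverage relative to that contig instead (the design used to estimate
#'   the copy number of a target sequence, e.g. a viral genome, relative to a
#'   host chromosome).
#' @param windows Tibble of windows on a single contig; defaults to tiling
#'   the normalizer's contig at its window size. Equal-width contiguous tiles
#'   use a fast vectorized path.
#' @return Tibble: window coordinates plus `std_mean`, `std_median`,
#'   `std_sd`, `std_iqr`, `improper_std`, `supplementary_std`,
#'   `masked_fraction` (0 until a repeat mask is applied).
#' @export
window_stats <- function(alignments, normalizer, windows = NULL) {
  contig <- if (!is.null(windows) && nrow(windows) > 0) {
    cc <- unique(windows$contig)
    if (length(cc) != 1) abort("windows must lie on a single contig")
    cc
  } else {
    normalizer$contig
  }
  if (!contig %in% names(alignments$contig_lengths))
    abort(sprintf("contig '%s' absent from alignments", contig),
          class = "cnvforest_coordinate_error")
  L <- alignments$contig_lengths[[contig]]
  if (is.null(windows)) windows <- tile_windows(L, normalizer$window_size, contig)
  if (nrow(windows) == 0) return(empty_stats())
  if (any(windows$start < 0 | windows$end > L | windows$start >= windows$end))
    abort("window outside contig bounds", class = "cnvforest_coordinate_error")

  d <- depth_vector(alignments, contig)
  w <- windows$end - windows$start
  equal <- length(unique(w)) == 1
  if (equal) {
    ww <- w[1]
    m <- matrix(d[rep(windows$start, each = ww) + seq_len(ww)], nrow = ww)
    mu <- colMeans(m)
    med <- matrixStats::colMedians(m)
    sdv <- matrixStats::colSds(m)
    qs <- matrixStats::colQuantiles(m, probs = c(0.25, 0.75), drop = FALSE)
    iqr <- unname(qs[, 2] - qs[, 1])
  } else {
    per <- purrr::map(seq_len(nrow(windows)), function(i) {
      v <- d[(windows$start[i] + 1):windows$end[i]]
      q <- quantile(v, c(0.25, 0.75), names = FALSE)
      c(mean(v), median(v), sd(v), q[2] - q[1])
    })
    per <- do.call(rbind, per)
    mu <- per[, 1]; med <- per[, 2]; sdv <- per[, 3]; iqr <- per[, 4]
  }

  rec <- alignments$records
  rec <- rec[rec$contig == contig, ]
  count_in <- function(sel) {
    s <- rec$start[sel]
    if (equal && length(unique(diff(windows$start))) <= 1) {
      # contiguous equal tiles: bin by integer division
      off <- s - windows$start[1]
      ok <- off >= 0 & off < nrow(windows) * w[1]
      tabulate(off[ok] %/% w[1] + 1L, nbins = nrow(windows))
    } else {
      iv <- IRanges::IRanges(windows$start + 1L, windows$end)
      pts <- IRanges::IRanges(s + 1L, s + 1L)
      IRanges::countOverlaps(iv, pts)
    }
  }
  imp <- count_in(rec$improper & !rec$supplementary)
  sup <- count_in(rec$supplementary)
  std_count <- function(cnt, baseline) {
    if (baseline > 0) cnt / baseline else ifelse(cnt == 0, 1, cnt)
  }

  bind_cols(windows, tibble(
    std_mean = mu / normalizer$mean_depth,
    std_median = if (normalizer$median_depth > 0)
      med / normalizer$median_depth else med / normalizer$mean_depth,
    std_sd = sdv / normalizer$mean_depth,
    std_iqr = iqr / normalizer$mean_depth,
    improper_std = std_count(imp, normalizer$mean_improper),
    supplementary_std = std_count(sup, normalizer$mean_supplementary),
    masked_fraction = 0
  ))
}

empty_stats <- function() {
  tibble(contig = character(), start = integer(), end = integer(),
         std_mean = double(), std_median = double(), std_sd = double(),
         std_iqr = double(), improper_std = double(),
         supplementary_std = double(), masked_fraction = double())
}

#' Drop or annotate repeat-overlapping sub-windows
#'
#' Mode `"no_repeats"` removes every sub-window overlapping a repeat interval
#' by at least 1 bp (the repeat-masked analysis); mode `"with_repeats"` keeps
#' all windows and records the overlapped fraction in `masked_fraction`.
#'
#' @param stats A [window_stats()] tibble.
#' @param repeats Tibble (`contig`, `start`, `end`) of repeat intervals
#'   (BED3), or `NULL` for no masking.
#' @param mode `"no_repeats"` or `"with_repeats"`.
#' @return Filtered/annotated stats tibble.
#' @export
apply_repeat_mask <- function(stats, repeats, mode = c("no_repeats", "with_repeats")) {
  mode <- match.arg(mode)
  if (is.null(repeats) || nrow(repeats) == 0) return(stats)
  ov <- interval_overlaps(stats, repeats)
  per_window <- rep(0, nrow(stats))
  if (nrow(ov) > 0) {
    agg <- tapply(ov$overlap, ov$query, sum)
    per_window[as.integer(names(agg))] <- agg
  }
  if (mode == "no_repeats") {
    stats[per_window == 0, ]
  } else {
    stats$masked_fraction <- per_window / (stats$end - stats$start)
    stats
  }
}

#' Feature-vector column schema
#'
#' @param k Flanking sub-windows per side.
#' @return Tibble (`column`, `statistic`, `offset`) in vector order: offsets
#'   -k..k in genomic order, six statistics per offset.
#' @export
feature_schema <- function(k) {
  offsets <- seq(-k, k)
  tibble(
    column = as.vector(vapply(offsets, function(o) {
      paste0(STAT_NAMES, "_", ifelse(o < 0, paste0("m", -o),
                                     ifelse(o > 0, paste0("p", o), "0")))
    }, character(length(STAT_NAMES)))),
    statistic = rep(STAT_NAMES, length(offsets)),
    offset = rep(offsets, each = length(STAT_NAMES))
  )
}

#' Assemble focal +/- k feature vectors
#'
#' For every focal sub-window with k tiles on each side, concatenates the six
#' statistics of tiles focal-k .. focal+k in genomic order, giving vectors of
#' length `6 * (2k + 1)`. Focal windows within k tiles of a contig end are
#' skipped silently (their count is available as the difference in row
#' numbers).
#'
#' @param stats A [window_stats()] tibble for one contig, ordered, with
#'   contiguous equal-width tiles.
#' @param k Flanking sub-windows per side (default 5; 10 reproduces the
#'   21-sub-window description).
#' @return Tibble: focal `contig`, `start`, `end`, then the schema columns.
#' @export
vectorize_windows <- function(stats, k = 5L) {
  stopifnot(k >= 0)
  n <- nrow(stats)
  if (n < 2 * k + 1) {
    sch <- feature_schema(k)
    out <- tibble(contig = character(), start = integer(), end = integer())
    for (cl in sch$column) out[[cl]] <- double()
    return(out)
  }
  if (n > 1) {
    wdt <- unique(stats$end - stats$start)
    if (length(wdt) != 1 || any(diff(stats$start) != wdt))
      abort("vectorize_windows needs contiguous equal-width tiles on one contig")
  }
  focal <- seq(k + 1L, n - k)
  out <- stats[focal, c("contig", "start", "end")]
  for (off in seq(-k, k)) {
    suff <- if (off < 0) paste0("m", -off) else if (off > 0) paste0("p", off) else "0"
    for (s in STAT_NAMES) {
      out[[paste0(s, "_", suff)]] <- stats[[s]][focal + off]
    }
  }
  # column order: by offset block, six statistics per block
  out[, c("contig", "start", "end", feature_schema(k)$column)]
}

#' Write / read a stats or feature-vector table as TSV
#'
#' @param x Tibble to write.
#' @param path Output path (gzip-compressed if it ends in `.gz`).
#' @export
write_stats <- function(x, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_stats
#' @export
read_stats <- function(path) {
  as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE))
}
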