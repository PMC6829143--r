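# Internal helpers shared across modules. All genomic intervals in this
# package are 0-based half-open ([start, end), BED convention); IRanges is
# 1-based closed, so conversions happen only inside these helpers.

`%||%` <- function(x, y) if (is.null(x)) y else x

# tibble(contig, start, end) -> GRanges
as_granges0 <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$contig,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# pairwise overlap widths (in bp) between two 0-based interval tables;
# returns tibble(queryHits, subjectHits, overlap)
interval_overlaps <- function(query, subject) {
  gq <- as_granges0(query)
  gs <- as_granges0(subject)
  hits <- GenomicRanges::findOverlaps(gq, gs)
  ov <- GenomicRanges::pintersect(gq[S4Vectors::queryHits(hits)],
                                  gs[S4Vectors::subjectHits(hits)])
  tibble(
    query = S4Vectors::queryHits(hits),
    subject = S4Vectors::subjectHits(hits),
    overlap = GenomicRanges::width(ov)
  )
}

assert_nonoverlapping <- function(cnvs, what = "truth set") {
  if (nrow(cnvs) < 2) return(invisible(TRUE))
  by_contig <- split(cnvs, cnvs$contig)
  for (cc in by_contig) {
    cc <- cc[order(cc$start), ]
    if (any(cc$start[-1] < cc$end[-nrow(cc)])) {
      abort(sprintf("invalid %s: overlapping CNV intervals on contig %s",
                    what, cc$contig[[1]]), class = "cnvforest_invalid_truth")
    }
  }
  invisible(TRUE)
}

# round half away from zero (round() in R rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# deterministic child seeds; kept < 2^31
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(stream)) %% 2147483647)
}
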