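#' Alignment evidence container
#'
#' Holds everything the feature module consumes: per-record positions and
#' breakpoint flags, per-base depth per contig, contig lengths, and the
#' insert-size model. Built either by the simulator
#' ([simulate_alignments()]) or from a real coordinate-sorted BAM/SAM
#' ([read_alignments()]), so simulated and real data flow through the same
#' feature code.
#'
#' @param records Tibble with columns `pair_id`, `read`, `contig`, `start`,
#'   `end` (0-based half-open), `strand`, `improper`, `supplementary`.
#' @param depth Named list of [S4Vectors::Rle] per-base depth vectors.
#' @param contig_lengths Named integer vector.
#' @param insert_mean,insert_sd Insert-size model (bp).
#' @return An object of class `cnv_alignments`.
#' @export
new_cnv_alignments <- function(records, depth, contig_lengths,
                               insert_mean = 500, insert_sd = 50) {
  structure(list(records = records, depth = depth,
                 contig_lengths = contig_lengths,
                 insert_mean = insert_mean, insert_sd = insert_sd),
            class = "cnv_alignments")
}

#' @export
print.cnv_alignments <- function(x, ...) {
  cat(sprintf("<cnv_alignments> %d records on %d contig(s): %s\n",
              nrow(x$records), length(x$contig_lengths),
              paste0(names(x$contig_lengths), " (", x$contig_lengths, " bp)",
                     collapse = ", ")))
  invisible(x)
}

#' Per-base depth of one contig as an integer vector
#'
#' @param alignments A `cnv_alignments` object.
#' @param contig Contig name.
#' @return Integer vector of length `contig_lengths[contig]`.
#' @export
depth_vector <- function(alignments, contig) {
  if (!contig %in% names(alignments$contig_lengths))
    abort(sprintf("contig '%s' absent from alignments", contig),
          class = "cnvforest_coordinate_error")
  as.integer(alignments$depth[[contig]])
}

#' Read alignment evidence from a BAM or SAM file
#'
#' Extracts the three signals the classifier uses from a coordinate-sorted
#' alignment file: per-base depth from primary, non-duplicate alignments (no
#' mapping-quality filter), improper-pair flags, and supplementary (split)
#' records. A read is improper when its primary record lacks the
#' proper-pair flag, its mate maps to a different contig, or its insert size
#' falls outside `mean +/- 3 SD`, with the insert model estimated from the
#' proper pairs in the file itself.
#'
#' @param path BAM or SAM file (SAM is converted in a temporary directory).
#' @param contigs Optional character vector restricting contigs.
#' @return A `cnv_alignments` object.
#' @export
read_alignments <- function(path, contigs = NULL) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = TRUE)
  } else if (!file.exists(paste0(path, ".bai"))) {
    Rsamtools::indexBam(path)
  }
  hdr <- Rsamtools::scanBamHeader(path)[[1]]$targets
  if (!is.null(contigs)) hdr <- hdr[names(hdr) %in% contigs]
  if (length(hdr) == 0) abort("no contigs to read")

  param <- Rsamtools::ScanBamParam(
    what = c("flag", "rname", "pos", "cigar", "mrnm", "isize"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  bam <- Rsamtools::scanBam(path, param = param)[[1]]
  keep <- !is.na(bam$pos) & as.character(bam$rname) %in% names(hdr)
  flag <- bam$flag[keep]
  supplementary <- bitwAnd(flag, 2048L) > 0L
  secondary <- bitwAnd(flag, 256L) > 0L
  duplicate <- bitwAnd(flag, 1024L) > 0L
  paired <- bitwAnd(flag, 1L) > 0L
  proper <- bitwAnd(flag, 2L) > 0L
  rname <- as.character(bam$rname)[keep]
  mrnm <- as.character(bam$mrnm)[keep]
  isize <- bam$isize[keep]
  # reference-space footprint from the CIGAR (soft clips excluded)
  qw <- GenomicAlignments::cigarWidthAlongReferenceSpace(bam$cigar[keep])
  qw[is.na(qw)] <- 0L
  pos0 <- bam$pos[keep] - 1L

  prim <- !supplementary & !secondary
  ins <- abs(isize[prim & paired & proper & !is.na(isize) & isize != 0])
  insert_mean <- if (length(ins)) mean(ins) else 500
  insert_sd <- if (length(ins) > 1) sd(ins) else 50
  out_of_range <- !is.na(isize) & isize != 0 &
    (abs(isize) < insert_mean - 3 * insert_sd |
       abs(isize) > insert_mean + 3 * insert_sd)
  improper <- paired & prim &
    (!proper | (!is.na(mrnm) & mrnm != rname) | out_of_range)

  # depth counts primary and supplementary portions (the split parts of a
  # junction-spanning read cover real sequence; samtools depth does the same)
  use <- !secondary & !duplicate
  records <- tibble(
    pair_id = seq_len(sum(keep)),
    read = ifelse(bitwAnd(flag, 128L) > 0L, 2L, 1L),
    contig = rname,
    start = as.numeric(pos0),
    end = as.numeric(pos0 + qw),
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    improper = improper,
    supplementary = supplementary
  )
  depth <- records_depth(records[use, ], hdr)
  new_cnv_alignments(records, depth, hdr, insert_mean, insert_sd)
}

#' Write simulated alignments as SAM
#'
#' Emits standard flags (0x1 paired, 0x2 proper pair, 0x10/0x20 strands,
#' 0x40/0x80 mate ordering, 0x800 supplementary) so the stream round-trips
#' through samtools and [read_alignments()]. Junction-crossing reads carry a
#' soft-clipped CIGAR for the off-segment part. When `reference` is given,
#' read sequences are emitted with uniform base-substitution errors at the
#' configured rate; otherwise SEQ/QUAL are `*`.
#'
#' @param alignments A `cnv_alignments` object from [simulate_alignments()].
#' @param path Output SAM path.
#' @param reference Optional named character vector of contig sequences.
#' @param base_error Substitution rate used when sequences are emitted.
#' @param seed Seed for the error draw.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, path, reference = NULL, base_error = 0.05,
                      seed = 1L) {
  rec <- alignments$records
  rec <- rec[order(rec$contig, rec$start), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  for (cc in names(alignments$contig_lengths)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", cc,
                       as.integer(alignments$contig_lengths[[cc]])), con)
  }
  if (nrow(rec) == 0) return(invisible(path))

  # mate lookup: primary record of the other read in the pair
  prim <- rec[!rec$supplementary, ]
  key <- paste(prim$pair_id, prim$read)
  mate_key <- paste(rec$pair_id, 3L - rec$read)
  mi <- match(mate_key, key)
  mate_pos <- ifelse(is.na(mi), 0, prim$start[mi] + 1)

  len <- as.integer(rec$end - rec$start)
  rl <- max(len)
  # mate is always on the opposite strand by construction (FR orientation)
  flag <- 1L +
    ifelse(rec$improper, 0L, 2L) +
    ifelse(rec$strand == "-", 16L, 32L) +
    ifelse(rec$read == 1L, 64L, 128L) +
    ifelse(rec$supplementary, 2048L, 0L)
  cigar <- ifelse(len >= rl, paste0(len, "M"),
                  ifelse(rec$supplementary,
                         paste0(rl - len, "S", len, "M"),
                         paste0(len, "M", rl - len, "S")))
  seq_field <- "*"
  qual_field <- "*"
  if (!is.null(reference)) {
    withr::local_seed(child_seed(seed, 5))
    seq_field <- vapply(seq_len(nrow(rec)), function(i) {
      s <- substring(reference[[rec$contig[i]]], rec$start[i] + 1, rec$end[i])
      b <- strsplit(s, "")[[1]]
      err <- runif(length(b)) < base_error
      if (any(err)) b[err] <- sample(c("A", "C", "G", "T"), sum(err), TRUE)
      paste0(b, collapse = "")
    }, character(1))
    qual_field <- vapply(len, function(l) strrep("I", l), character(1))
  }
  lines <- sprintf("pair_%d\t%d\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t%s",
                   rec$pair_id, flag, rec$contig, as.integer(rec$start + 1),
                   cigar, as.integer(mate_pos),
                   as.integer(rec$tlen %||% 0),
                   seq_field, qual_field)
  writeLines(lines, con)
  invisible(path)
}
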