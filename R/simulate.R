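#' Simulation configuration
#'
#' Bundles every knob of the training-set simulator: how many tandem
#' duplications and deletions to plant, their size and copy-number ranges, the
#' pool of chromosomes they segregate in, and the sequencing model used to
#' generate paired-end reads (read length, insert-size distribution, target
#' fold-coverage, base error rate).
#'
#' The defaults reproduce the canonical training design for a
#' *Drosophila*-sized chromosome arm: 2000 duplications and 2000 deletions of
#' 100-5000 bp, 100 bp paired-end reads with a 500 +/- 50 bp insert, base
#' error 0.05, mutation rate 0.01 and indel fraction 0.15 (wgsim-style
#' parameters), at 20-fold median coverage. Pool frequencies are multiples of
#' `1/pool_size`, so a pool of 2 yields frequencies \{0.5, 1\} and a pool of
#' 20 admits singletons at 5%.
#'
#' @param n_duplications,n_deletions Number of CNVs of each type to plant.
#' @param size_range Length-2 integer vector, CNV sizes in bp (uniform draw).
#' @param copy_range Length-2 integer vector, total tandem copies on a carrier
#'   haplotype for duplications (uniform draw; default `c(2, 2)`, i.e. one
#'   extra copy).
#' @param pool_size Number of chromosomes in the sequenced pool.
#' @param target_coverage Median fold-coverage per base across the pool.
#' @param read_length Read length in bp.
#' @param insert_mean,insert_sd Insert-size (outer fragment) mean and standard
#'   deviation in bp; fragments are truncated at +/- 3 SD.
#' @param base_error Per-base substitution error rate, applied when read
#'   sequences are materialized (SAM/FASTQ export); depth and breakpoint
#'   signals are unaffected.
#' @param mutation_rate,indel_fraction Haplotype divergence parameters kept
#'   for provenance with the wgsim-style design; small-scale divergence does
#'   not move window depth statistics and is not applied to coordinates.
#' @param seed Integer seed; all simulator draws are deterministic given it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_duplications = 2000, n_deletions = 2000,
                       size_range = c(100L, 5000L), copy_range = c(2L, 2L),
                       pool_size = 1L, target_coverage = 20,
                       read_length = 100L, insert_mean = 500, insert_sd = 50,
                       base_error = 0.05, mutation_rate = 0.01,
                       indel_fraction = 0.15, seed = 1L) {
  stopifnot(length(size_range) == 2, size_range[1] >= 1,
            size_range[2] >= size_range[1],
            length(copy_range) == 2, copy_range[1] >= 2,
            copy_range[2] >= copy_range[1])
  rates <- c(base_error, mutation_rate, indel_fraction)
  if (any(rates < 0 | rates > 1)) abort("rates must lie in [0, 1]")
  if (target_coverage <= 0) abort("target_coverage must be > 0")
  if (pool_size < 1) abort("pool_size must be >= 1")
  structure(list(
    n_duplications = as.integer(n_duplications),
    n_deletions = as.integer(n_deletions),
    size_range = as.integer(size_range),
    copy_range = as.integer(copy_range),
    pool_size = as.integer(pool_size),
    target_coverage = target_coverage,
    read_length = as.integer(read_length),
    insert_mean = insert_mean, insert_sd = insert_sd,
    base_error = base_error, mutation_rate = mutation_rate,
    indel_fraction = indel_fraction,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d dup + %d del, %d-%d bp, pool %d, %gx coverage, seed %d\n",
    x$n_duplications, x$n_deletions, x$size_range[1], x$size_range[2],
    x$pool_size, x$target_coverage, x$seed))
  invisible(x)
}

#' Sample a truth set of non-overlapping CNVs
#'
#' Places `n_duplications + n_deletions` tandem duplications and deletions
#' uniformly at random inside the allowed regions, without overlap. Sizes are
#' uniform on `config$size_range`; pool frequencies are uniform on the grid
#' \{1/n, 2/n, ..., 1\} for a pool of n chromosomes; duplication copy counts
#' are uniform on `config$copy_range` (deletions carry 0 copies).
#'
#' Placement uses the order-statistics construction: within each region the
#' chosen intervals are laid down with gaps drawn as sorted uniforms over the
#' free space, which samples uniformly among all non-overlapping layouts.
#'
#' @param reference_lengths Named integer vector of contig lengths (bp).
#' @param allowed_regions Optional tibble (`contig`, `start`, `end`,
#'   0-based half-open) of non-repetitive regions eligible for placement;
#'   defaults to whole contigs.
#' @param config A [sim_config()].
#' @return Tibble with columns `contig`, `start`, `end`, `cnv_type`
#'   ("duplication"/"deletion"), `copies`, `frequency`.
#' @export
sample_cnvs <- function(reference_lengths, allowed_regions = NULL, config = sim_config()) {
  if (is.null(names(reference_lengths)) && length(reference_lengths) == 1)
    names(reference_lengths) <- "chr1"
  if (is.null(allowed_regions)) {
    allowed_regions <- tibble(contig = names(reference_lengths),
                              start = 0L, end = as.integer(reference_lengths))
  }
  if (nrow(allowed_regions) == 0) abort("allowed_regions is empty")
  n_total <- config$n_duplications + config$n_deletions
  if (n_total == 0) {
    return(tibble(contig = character(), start = integer(), end = integer(),
                  cnv_type = character(), copies = integer(),
                  frequency = double()))
  }
  withr::local_seed(child_seed(config$seed, 1))

  size_pool <- seq(config$size_range[1], config$size_range[2])
  sizes <- if (length(size_pool) == 1) rep(size_pool, n_total)
           else sample(size_pool, n_total, replace = TRUE)
  types <- sample(rep(c("duplication", "deletion"),
                      c(config$n_duplications, config$n_deletions)))

  # greedy capacity-aware assignment of each CNV to a region
  cap <- as.numeric(allowed_regions$end - allowed_regions$start)
  region_of <- integer(n_total)
  for (i in seq_len(n_total)) {
    room <- cap - sizes[i]
    ok <- which(room >= 0)
    if (length(ok) == 0) {
      abort(sprintf(
        "placement failure: no remaining region can hold CNV %d of %d (size %d bp; largest free space %d bp)",
        i, n_total, sizes[i], max(0, floor(max(cap)))),
        class = "cnvforest_placement_failure")
    }
    r <- if (length(ok) == 1) ok else sample(ok, 1, prob = room[ok] + 1)
    region_of[i] <- r
    cap[r] <- cap[r] - sizes[i]
  }

  out <- vector("list", nrow(allowed_regions))
  for (r in seq_len(nrow(allowed_regions))) {
    members <- which(region_of == r)
    if (length(members) == 0) next
    reg_len <- allowed_regions$end[r] - allowed_regions$start[r]
    s <- sizes[members]
    free <- reg_len - sum(s)
    ord <- sample(length(members))            # random left-to-right order
    gaps <- sort(floor(runif(length(members), 0, free + 1)))
    starts <- allowed_regions$start[r] + gaps + c(0, cumsum(s[ord][-length(s)]))
    out[[r]] <- tibble(
      contig = allowed_regions$contig[r],
      start = as.integer(starts),
      end = as.integer(starts + s[ord]),
      idx = members[ord]
    )
  }
  placed <- bind_rows(out)
  placed <- placed[order(placed$idx), ]
  n <- config$pool_size
  freq <- sample.int(n, n_total, replace = TRUE) / n
  copy_pool <- seq(config$copy_range[1], config$copy_range[2])
  copy_draw <- if (length(copy_pool) == 1) rep(copy_pool, n_total)
               else sample(copy_pool, n_total, replace = TRUE)
  copies <- ifelse(types == "duplication", copy_draw, 0L)
  res <- tibble(contig = placed$contig, start = placed$start, end = placed$end,
                cnv_type = types, copies = as.integer(copies),
                frequency = freq)
  res <- res[order(res$contig, res$start), ]
  assert_nonoverlapping(res)
  res
}

#' Apply CNVs to a reference to build one haplotype
#'
#' Excises deletions and expands tandem duplications to their total copy
#' count, producing a haplotype together with a segment-wise coordinate lift
#' back to the reference. The lift is what lets simulated reads be placed
#' directly in reference coordinates, emulating the result of mapping.
#'
#' @param reference Either an integer contig length (coordinate-only
#'   haplotype), a character DNA string, or a [Biostrings::DNAString].
#' @param cnvs Tibble of CNVs carried by this haplotype (may be empty);
#'   must be sorted, non-overlapping and within bounds.
#' @param id Haplotype identifier.
#' @return An object of class `cnv_haplotype`: fields `id`, `length`,
#'   `segments` (tibble `hap_start`, `hap_end`, `ref_start`, `ref_end`),
#'   `cnvs`, and `sequence` (character or `NULL`).
#' @export
apply_cnvs <- function(reference, cnvs = NULL, id = 1L) {
  seq_chr <- NULL
  if (inherits(reference, "DNAString")) seq_chr <- as.character(reference)
  else if (is.character(reference)) seq_chr <- reference
  ref_len <- if (is.null(seq_chr)) as.integer(reference) else nchar(seq_chr)
  if (is.null(cnvs)) cnvs <- tibble(contig = character(), start = integer(),
                                    end = integer(), cnv_type = character(),
                                    copies = integer(), frequency = double())
  if (nrow(cnvs) > 0) {
    cnvs <- cnvs[order(cnvs$start), ]
    assert_nonoverlapping(cnvs, "haplotype CNV set")
    if (any(cnvs$start < 0 | cnvs$end > ref_len))
      abort("CNV outside reference bounds")
  }

  ref_starts <- integer(0); ref_ends <- integer(0)
  cur <- 0L
  for (i in seq_len(nrow(cnvs))) {
    s <- cnvs$start[i]; e <- cnvs$end[i]
    if (s > cur) { ref_starts <- c(ref_starts, cur); ref_ends <- c(ref_ends, s) }
    if (cnvs$cnv_type[i] == "deletion") {
      cur <- e
    } else {
      reps <- cnvs$copies[i]
      ref_starts <- c(ref_starts, rep(s, reps))
      ref_ends <- c(ref_ends, rep(e, reps))
      cur <- e
    }
  }
  if (cur < ref_len) { ref_starts <- c(ref_starts, cur); ref_ends <- c(ref_ends, ref_len) }
  w <- ref_ends - ref_starts
  hap_ends <- cumsum(as.numeric(w))
  hap_starts <- hap_ends - w
  segments <- tibble(hap_start = hap_starts, hap_end = hap_ends,
                     ref_start = as.numeric(ref_starts), ref_end = as.numeric(ref_ends))
  hap_len <- if (nrow(segments)) segments$hap_end[nrow(segments)] else 0
  hap_seq <- NULL
  if (!is.null(seq_chr) && nrow(segments) > 0) {
    hap_seq <- paste0(substring(seq_chr, ref_starts + 1L, ref_ends), collapse = "")
  }
  structure(list(id = id, length = hap_len, segments = segments,
                 cnvs = cnvs, sequence = hap_seq),
            class = "cnv_haplotype")
}

#' Lift haplotype positions to reference positions
#'
#' @param haplotype A [apply_cnvs()] result.
#' @param pos 0-based haplotype positions.
#' @return Numeric vector of 0-based reference positions.
#' @export
lift_to_reference <- function(haplotype, pos) {
  seg <- haplotype$segments
  i <- findInterval(pos, seg$hap_start)
  seg$ref_start[i] + (pos - seg$hap_start[i])
}

#' Assemble a pool of haplotypes carrying a truth set
#'
#' Each CNV is assigned to exactly `frequency * pool_size` carrier
#' haplotypes, sampled without replacement; carrier sets are independent
#' across CNVs. Carrier counts must be integral.
#'
#' @param reference Contig length, character sequence, or `DNAString`.
#' @param truth_cnvs Truth-set tibble from [sample_cnvs()].
#' @param config A [sim_config()] (supplies `pool_size` and `seed`).
#' @return List of `pool_size` [apply_cnvs()] haplotypes.
#' @export
build_pool <- function(reference, truth_cnvs, config = sim_config()) {
  n <- config$pool_size
  carriers_n <- truth_cnvs$frequency * n
  if (any(abs(carriers_n - round(carriers_n)) > 1e-9))
    abort("frequency * pool_size must be an integer for every CNV",
          class = "cnvforest_config_error")
  carriers_n <- as.integer(round(carriers_n))
  withr::local_seed(child_seed(config$seed, 2))
  carried <- vector("list", n)
  for (j in seq_len(nrow(truth_cnvs))) {
    who <- if (carriers_n[j] == n) seq_len(n) else sample(n, carriers_n[j])
    for (h in who) carried[[h]] <- c(carried[[h]], j)
  }
  lapply(seq_len(n), function(h) {
    apply_cnvs(reference, truth_cnvs[sort(carried[[h]]), ], id = h)
  })
}

#' Simulate mapped paired-end reads for a pool of haplotypes
#'
#' Draws 100 bp paired-end fragments uniformly from each haplotype (each
#' haplotype receives an equal share of the target coverage) and places them
#' in reference coordinates through the haplotype lift map, emulating the
#' outcome of mapping without running a mapper:
#'
#' * a read crossing a CNV junction (tandem-duplication copy boundary or
#'   deletion edge) is emitted as a primary alignment for the first portion
#'   plus a soft-clipped supplementary (split) record for the remainder;
#' * a pair whose implied reference insert falls outside
#'   `insert_mean +/- 3 * insert_sd` (as happens to fragments spanning a
#'   deletion or a duplication junction) is flagged improper.
#'
#' Fragment lengths are normal `(insert_mean, insert_sd)` truncated at
#' +/- 3 SD and below at twice the read length, so every improper or
#' supplementary record lies within `insert_mean + 3 * insert_sd` of a true
#' breakpoint.
#'
#' @param pool List of haplotypes from [build_pool()] (or one haplotype).
#' @param config A [sim_config()].
#' @param contig Contig name for the emitted records.
#' @param ref_length Reference contig length; inferred from the haplotype
#'   segments when omitted.
#' @return A `cnv_alignments` object (see [new_cnv_alignments()]).
#' @export
simulate_alignments <- function(pool, config = sim_config(), contig = "chr1",
                                ref_length = NULL) {
  if (inherits(pool, "cnv_haplotype")) pool <- list(pool)
  if (length(pool) == 0) abort("pool is empty")
  ref_length <- ref_length %||%
    max(vapply(pool, function(h) max(h$segments$ref_end), numeric(1)))
  ref_length <- as.integer(ref_length)
  rl <- config$read_length
  withr::local_seed(child_seed(config$seed, 3))

  frag_lo <- max(2 * rl, config$insert_mean - 3 * config$insert_sd)
  frag_hi <- config$insert_mean + 3 * config$insert_sd

  all_rec <- vector("list", length(pool))
  pair_base <- 0L
  for (hix in seq_along(pool)) {
    hap <- pool[[hix]]
    n_pairs <- round(config$target_coverage / length(pool) *
                       hap$length / (2 * rl))
    if (n_pairs < 1) next
    frag <- pmin(pmax(round(rnorm(n_pairs, config$insert_mean,
                                  config$insert_sd)), frag_lo), frag_hi)
    frag <- pmin(frag, hap$length)
    s <- floor(runif(n_pairs, 0, hap$length - frag + 1))
    r1 <- map_read(hap, s, rl)
    r2 <- map_read(hap, s + frag - rl, rl)
    implied <- (r2$ref_start + rl) - r1$ref_start
    improper <- implied < frag_lo | implied > frag_hi
    pid <- pair_base + seq_len(n_pairs)
    rec <- bind_rows(
      tibble(pair_id = pid, read = 1L, start = r1$ref_start,
             end = r1$ref_start + r1$len1, strand = "+",
             improper = improper, supplementary = FALSE, tlen = implied),
      tibble(pair_id = pid[r1$split], read = 1L, start = r1$ref2_start[r1$split],
             end = r1$ref2_start[r1$split] + r1$len2[r1$split], strand = "+",
             improper = improper[r1$split], supplementary = TRUE, tlen = 0),
      tibble(pair_id = pid, read = 2L, start = r2$ref_start,
             end = r2$ref_start + r2$len1, strand = "-",
             improper = improper, supplementary = FALSE, tlen = -implied),
      tibble(pair_id = pid[r2$split], read = 2L, start = r2$ref2_start[r2$split],
             end = r2$ref2_start[r2$split] + r2$len2[r2$split], strand = "-",
             improper = improper[r2$split], supplementary = TRUE, tlen = 0)
    )
    rec$hap <- hix
    all_rec[[hix]] <- rec
    pair_base <- pair_base + n_pairs
  }
  records <- bind_rows(all_rec)
  if (nrow(records) == 0) {
    warn("target coverage too low: zero read pairs simulated")
    records <- tibble(pair_id = integer(), read = integer(), start = numeric(),
                      end = numeric(), strand = character(),
                      improper = logical(), supplementary = logical(),
                      tlen = numeric(), hap = integer())
  }
  records$contig <- contig
  records$start <- pmin(pmax(records$start, 0), ref_length)
  records$end <- pmin(pmax(records$end, records$start), ref_length)
  records <- records[order(records$start), ]

  depth <- records_depth(records, setNames(ref_length, contig))
  new_cnv_alignments(records, depth,
                     contig_lengths = setNames(ref_length, contig),
                     insert_mean = config$insert_mean,
                     insert_sd = config$insert_sd)
}

# Map reads of length rl starting at hap positions a onto the reference.
# Returns primary portion (ref_start, len1) and, where a discontiguous
# junction is crossed, the second portion (ref2_start, len2).
map_read <- function(hap, a, rl) {
  seg <- hap$segments
  i <- findInterval(a, seg$hap_start)
  ref_start <- seg$ref_start[i] + (a - seg$hap_start[i])
  room <- seg$hap_end[i] - a
  crosses <- room < rl & i < nrow(seg)
  jump <- rep(0, length(a))
  jump[crosses] <- seg$ref_start[i[crosses] + 1] - seg$ref_end[i[crosses]]
  split <- crosses & jump != 0
  len1 <- ifelse(split, room, rl)
  len2 <- rep(0, length(a))
  ref2_start <- rep(0, length(a))
  if (any(split)) {
    j <- i[split] + 1
    len2[split] <- pmin(rl - len1[split], seg$hap_end[j] - seg$hap_start[j])
    ref2_start[split] <- seg$ref_start[j]
  }
  list(ref_start = ref_start, len1 = len1, split = split,
       ref2_start = ref2_start, len2 = len2)
}

records_depth <- function(records, contig_lengths) {
  out <- lapply(names(contig_lengths), function(cc) {
    r <- records[records$contig == cc & records$end > records$start, ]
    if (nrow(r) == 0) {
      return(S4Vectors::Rle(0L, contig_lengths[[cc]]))
    }
    cov <- IRanges::coverage(IRanges::IRanges(start = r$start + 1, end = r$end),
                             width = contig_lengths[[cc]])
    cov
  })
  setNames(out, names(contig_lengths))
}

#' Inject noisy depth into selected regions
#'
#' Multiplies the per-base depth inside each region, chunk by chunk, by
#' independent Gaussian factors centered on 1. Used to build "decoy" regions
#' whose coverage drifts like mapping artifacts in real data: the chunk-level
#' shifts generate spurious duplication/deletion-like windows that a single
#' classifier tends to call, which is what the bootstrap-consensus filter is
#' designed to suppress.
#'
#' @param alignments A `cnv_alignments` object.
#' @param regions Tibble (`contig`, `start`, `end`) of regions to perturb.
#' @param noise_sd SD of the multiplicative factor (default 0.5).
#' @param chunk_size Chunk length in bp sharing one factor (default 250).
#' @param seed Integer seed.
#' @return The modified `cnv_alignments` object.
#' @export
add_depth_noise <- function(alignments, regions, noise_sd = 0.5,
                            chunk_size = 250L, seed = 1L) {
  withr::local_seed(child_seed(seed, 4))
  for (cc in unique(regions$contig)) {
    d <- as.integer(alignments$depth[[cc]])
    rg <- regions[regions$contig == cc, ]
    for (r in seq_len(nrow(rg))) {
      idx0 <- rg$start[r]
      len <- rg$end[r] - rg$start[r]
      n_chunks <- ceiling(len / chunk_size)
      fac <- pmax(0, rnorm(n_chunks, 1, noise_sd))
      per_base <- rep(fac, each = chunk_size)[seq_len(len)]
      sel <- (idx0 + 1):(idx0 + len)
      d[sel] <- as.integer(round(d[sel] * per_base))
    }
    alignments$depth[[cc]] <- S4Vectors::Rle(d)
  }
  alignments
}

#' Pick random regions avoiding a set of intervals
#'
#' Convenience for placing decoy regions on CNV-free sequence.
#'
#' @param contig_length Contig length in bp.
#' @param n Number of regions.
#' @param size Region size in bp.
#' @param avoid Optional tibble (`contig`, `start`, `end`) to stay clear of.
#' @param contig Contig name.
#' @param seed Integer seed.
#' @return Tibble (`contig`, `start`, `end`).
#' @export
sample_regions <- function(contig_length, n, size, avoid = NULL,
                           contig = "chr1", seed = 1L) {
  cfg <- sim_config(n_duplications = n, n_deletions = 0,
                    size_range = c(size, size), seed = seed)
  allowed <- tibble(contig = contig, start = 0L,
                    end = as.integer(contig_length))
  if (!is.null(avoid) && nrow(avoid) > 0) {
    g_all <- as_granges0(allowed)
    g_avoid <- GenomicRanges::reduce(as_granges0(avoid))
    g_free <- GenomicRanges::setdiff(g_all, g_avoid)
    allowed <- tibble(contig = as.character(GenomicRanges::seqnames(g_free)),
                      start = GenomicRanges::start(g_free) - 1L,
                      end = GenomicRanges::end(g_free))
    allowed <- allowed[allowed$end - allowed$start > size, ]
  }
  out <- sample_cnvs(setNames(contig_length, contig), allowed, cfg)
  out[, c("contig", "start", "end")]
}

#' Write a truth set to a BED-like TSV
#'
#' Columns: contig, start, end, cnv_type, copies, frequency (0-based
#' half-open).
#' @param truth Truth-set tibble.
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE))
}

#' Export pool haplotypes as FASTA
#'
#' For users who prefer to run an external read simulator and mapper on the
#' mutated haplotypes. Requires haplotypes built from an actual sequence.
#'
#' @param pool List of haplotypes from [build_pool()].
#' @param path Output FASTA path.
#' @export
write_haplotypes_fasta <- function(pool, path) {
  seqs <- lapply(pool, function(h) {
    if (is.null(h$sequence))
      abort("haplotypes carry no sequence; build the pool from a DNA string")
    h$sequence
  })
  x <- Biostrings::DNAStringSet(unlist(seqs))
  names(x) <- paste0("haplotype_", vapply(pool, function(h) h$id, numeric(1)))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
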