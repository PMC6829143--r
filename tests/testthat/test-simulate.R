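test_that("sample_cnvs places the requested non-overlapping CNVs inside allowed regions", {
  cfg <- sim_config(n_duplications = 200, n_deletions = 200, pool_size = 10,
                    seed = 42)
  regions <- tibble::tibble(contig = "2L", start = c(0L, 1200000L),
                            end = c(1000000L, 2000000L))
  cnvs <- sample_cnvs(c("2L" = 2000000L), regions, cfg)
  expect_equal(nrow(cnvs), 400)
  expect_setequal(unique(cnvs$cnv_type), c("duplication", "deletion"))
  expect_equal(sum(cnvs$cnv_type == "duplication"), 200)
  sizes <- cnvs$end - cnvs$start
  expect_true(all(sizes >= 100 & sizes <= 5000))
  # every CNV inside exactly one allowed region
  in_region <- mapply(function(s, e) {
    any(regions$start <= s & e <= regions$end)
  }, cnvs$start, cnvs$end)
  expect_true(all(in_region))
  # non-overlap
  ord <- cnvs[order(cnvs$start), ]
  expect_true(all(ord$start[-1] >= ord$end[-nrow(ord)]))
  # frequency grid for the pool
  expect_true(all(abs(cnvs$frequency * 10 - round(cnvs$frequency * 10)) < 1e-12))
  # determinism
  expect_identical(cnvs, sample_cnvs(c("2L" = 2000000L), regions, cfg))
})

test_that("sample_cnvs handles the zero case and pool-of-2 frequencies", {
  cfg0 <- sim_config(n_duplications = 0, n_deletions = 0)
  expect_equal(nrow(sample_cnvs(c(chr1 = 100000L), config = cfg0)), 0)

  cfg2 <- sim_config(n_duplications = 40, n_deletions = 40, pool_size = 2,
                     size_range = c(100, 500), seed = 3)
  cnvs <- sample_cnvs(c(chr1 = 500000L), config = cfg2)
  expect_true(all(cnvs$frequency %in% c(0.5, 1)))
})

test_that("sample_cnvs errors when the allowed space cannot hold the request", {
  cfg <- sim_config(n_duplications = 50, n_deletions = 50,
                    size_range = c(900, 1000), seed = 1)
  expect_error(sample_cnvs(c(chr1 = 20000L), config = cfg),
               class = "cnvforest_placement_failure")
})

test_that("apply_cnvs does the length arithmetic and lift mapping", {
  del <- tibble::tibble(contig = "chr1", start = 2000L, end = 2500L,
                        cnv_type = "deletion", copies = 0L, frequency = 1)
  h <- apply_cnvs(10000L, del)
  expect_equal(h$length, 9500)

  dup <- tibble::tibble(contig = "chr1", start = 5000L, end = 5300L,
                        cnv_type = "duplication", copies = 3L, frequency = 1)
  h2 <- apply_cnvs(10000L, dup)
  expect_equal(h2$length, 10000 + (3 - 1) * 300)

  h0 <- apply_cnvs(10000L, NULL)
  expect_equal(h0$length, 10000)
  expect_equal(lift_to_reference(h0, c(0, 1234, 9999)), c(0, 1234, 9999))

  # lift across a deletion: haplotype position 2000 is reference 2500
  expect_equal(lift_to_reference(h, c(1999, 2000)), c(1999, 2500))
  # lift across the duplication copies: positions in the second copy map back
  expect_equal(lift_to_reference(h2, 5300), 5000)

  both <- dplyr::bind_rows(del, dup)
  expect_equal(apply_cnvs(10000L, both)$length, 10100)
  overlapping <- tibble::tibble(contig = "chr1", start = c(100L, 300L),
                                end = c(400L, 600L),
                                cnv_type = c("deletion", "deletion"),
                                copies = 0L, frequency = 1)
  expect_error(apply_cnvs(10000L, overlapping),
               class = "cnvforest_invalid_truth")
})

test_that("apply_cnvs rebuilds sequences consistently with coordinates", {
  set.seed(9)
  ref <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  dup <- tibble::tibble(contig = "chr1", start = 100L, end = 150L,
                        cnv_type = "duplication", copies = 2L, frequency = 1)
  h <- apply_cnvs(ref, dup)
  expect_equal(nchar(h$sequence), 650)
  expect_equal(substr(h$sequence, 101, 150), substr(ref, 101, 150))
  expect_equal(substr(h$sequence, 151, 200), substr(ref, 101, 150))
  expect_equal(substr(h$sequence, 201, 650), substr(ref, 151, 600))
})

test_that("build_pool assigns exactly frequency * pool_size carriers", {
  truth <- tibble::tibble(
    contig = "chr1", start = c(1000L, 5000L, 9000L),
    end = c(1400L, 5600L, 9900L),
    cnv_type = c("duplication", "deletion", "duplication"),
    copies = c(2L, 0L, 2L), frequency = c(1, 0.5, 0.2))
  cfg <- sim_config(pool_size = 20, seed = 8)
  pool <- build_pool(50000L, truth, cfg)
  expect_length(pool, 20)
  carriers <- sapply(seq_len(3), function(j) {
    sum(sapply(pool, function(h) any(h$cnvs$start == truth$start[j])))
  })
  expect_equal(carriers, c(20, 10, 4))

  # haploid pool: single haplotype carries everything at frequency 1
  pool1 <- build_pool(50000L, dplyr::mutate(truth, frequency = 1),
                      sim_config(pool_size = 1, seed = 8))
  expect_length(pool1, 1)
  expect_equal(nrow(pool1[[1]]$cnvs), 3)

  expect_error(build_pool(50000L, truth, sim_config(pool_size = 3, seed = 8)),
               class = "cnvforest_config_error")
})

test_that("simulate_alignments yields the expected pair count and depth signals", {
  cfg <- sim_config(n_duplications = 0, n_deletions = 0, pool_size = 1,
                    target_coverage = 20, seed = 21)
  h <- apply_cnvs(1000000L, NULL)
  aln <- simulate_alignments(list(h), cfg)
  n_pairs <- length(unique(aln$records$pair_id))
  expect_lt(abs(n_pairs - 100000) / 100000, 0.05)
  # conservation: total mapped bases ~ coverage * length within 5%
  d <- depth_vector(aln, "chr1")
  expect_lt(abs(sum(as.numeric(d)) - 20 * 1e6) / (20 * 1e6), 0.05)
  # determinism
  aln2 <- simulate_alignments(list(h), cfg)
  expect_identical(aln$records, aln2$records)
})

test_that("fixed deletions null out depth and fixed duplications double it", {
  truth <- tibble::tibble(
    contig = "chr1", start = c(20000L, 60000L), end = c(23000L, 63000L),
    cnv_type = c("deletion", "duplication"), copies = c(0L, 2L),
    frequency = c(1, 1))
  cfg <- sim_config(pool_size = 1, target_coverage = 30, seed = 31)
  pool <- build_pool(100000L, truth, cfg)
  aln <- simulate_alignments(pool, cfg, ref_length = 100000L)
  d <- depth_vector(aln, "chr1")
  base <- mean(d[c(1:19000, 70000:100000)])
  # interior of the CNV (a read length in from each edge avoids the ramps)
  del_int <- mean(d[20101:22900])
  dup_int <- mean(d[60101:62900])
  expect_lt(del_int / base, 0.02)
  expect_gt(dup_int / base, 1.8)
  expect_lt(dup_int / base, 2.2)
})

test_that("standardized depth inside a CNV follows f*c + (1-f) in pools", {
  truth <- tibble::tibble(
    contig = "chr1", start = c(30000L, 90000L, 150000L),
    end = c(34000L, 94000L, 154000L),
    cnv_type = c("duplication", "deletion", "duplication"),
    copies = c(2L, 0L, 3L), frequency = c(0.5, 0.8, 1))
  cfg <- sim_config(pool_size = 10, target_coverage = 40, seed = 77)
  pool <- build_pool(200000L, truth, cfg)
  aln <- simulate_alignments(pool, cfg, ref_length = 200000L)
  d <- depth_vector(aln, "chr1")
  norm_depth <- mean(d[c(1:29000, 160000:200000)])
  expected <- truth$frequency * ifelse(truth$cnv_type == "deletion", 0,
                                       truth$copies) + (1 - truth$frequency)
  for (j in 1:3) {
    interior <- mean(d[(truth$start[j] + 101):(truth$end[j] - 100)])
    expect_lt(abs(interior / norm_depth - expected[j]) / expected[j], 0.1)
  }
})

test_that("breakpoint reads cluster at true junctions", {
  truth <- tibble::tibble(
    contig = "chr1", start = c(20000L, 60000L), end = c(22000L, 62000L),
    cnv_type = c("deletion", "duplication"), copies = c(0L, 2L),
    frequency = c(1, 1))
  cfg <- sim_config(pool_size = 1, target_coverage = 30, seed = 13)
  pool <- build_pool(100000L, truth, cfg)
  aln <- simulate_alignments(pool, cfg, ref_length = 100000L)
  rec <- aln$records
  margin <- cfg$insert_mean + 3 * cfg$insert_sd
  junctions <- c(20000, 22000, 60000, 62000)
  flagged <- rec[rec$improper | rec$supplementary, ]
  expect_gt(nrow(flagged), 0)
  dist <- sapply(seq_len(nrow(flagged)), function(i) {
    min(abs(c(flagged$start[i], flagged$end[i]) -
              rep(junctions, each = 2)))
  })
  expect_true(all(dist <= margin))
  # supplementary records exist for the tandem duplication junction
  sup <- rec[rec$supplementary, ]
  expect_gt(sum(sup$start >= 59000 & sup$start <= 63000), 0)
})

test_that("vanishing coverage warns and returns an empty stream", {
  cfg <- sim_config(pool_size = 1, target_coverage = 1e-5, seed = 2)
  h <- apply_cnvs(50000L, NULL)
  expect_warning(aln <- simulate_alignments(list(h), cfg), "zero read pairs")
  expect_equal(nrow(aln$records), 0)
  expect_equal(sum(depth_vector(aln, "chr1")), 0)
})

test_that("add_depth_noise perturbs only the chosen regions", {
  cfg <- sim_config(pool_size = 1, target_coverage = 20, seed = 4)
  h <- apply_cnvs(100000L, NULL)
  aln <- simulate_alignments(list(h), cfg)
  regions <- tibble::tibble(contig = "chr1", start = 10000L, end = 15000L)
  noisy <- add_depth_noise(aln, regions, noise_sd = 0.6, seed = 9)
  d0 <- depth_vector(aln, "chr1")
  d1 <- depth_vector(noisy, "chr1")
  expect_identical(d0[1:10000], d1[1:10000])
  expect_identical(d0[15001:100000], d1[15001:100000])
  expect_gt(sd(d1[10001:15000] / pmax(d0[10001:15000], 1)), 0.2)
})
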