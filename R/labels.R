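# Window labeling: CNV class and pool-averaged copy number for each focal
# sub-window, derived from a truth set.

#' Pool-averaged copy-number label
#'
#' The copy number of a sequence relative to the chromosome average, averaged
#' over a pool in which a fraction `frequency` of chromosomes carry the
#' variant: `frequency * c + (1 - frequency) * 1`, where `c` is 0 for a
#' deletion and the total tandem copy count for a duplication. A fixed
#' deletion labels 0, a 50% deletion 0.5, a 75% two-copy duplication 1.75,
#' and a fixed three-copy duplication 3.
#'
#' @param cnv_type `"duplication"` or `"deletion"` (vectorized).
#' @param copies Total copies on a carrier haplotype (ignored for deletions;
#'   must be >= 2 for duplications).
#' @param frequency Fraction of pool chromosomes carrying the variant, in
#'   (0, 1].
#' @return Numeric copy-number label(s).
#' @export
copy_number_label <- function(cnv_type, copies = 2, frequency = 1) {
  n <- max(length(cnv_type), length(copies), length(frequency))
  cnv_type <- rep_len(cnv_type, n)
  copies <- rep_len(copies, n)
  frequency <- rep_len(frequency, n)
  if (any(frequency <= 0 | frequency > 1))
    abort("frequency must lie in (0, 1]", class = "cnvforest_domain_error")
  if (!all(cnv_type %in% c("duplication", "deletion")))
    abort("cnv_type must be 'duplication' or 'deletion'",
          class = "cnvforest_domain_error")
  if (any(cnv_type == "duplication" & copies < 2))
    abort("duplications must have copies >= 2", class = "cnvforest_domain_error")
  c_eff <- ifelse(cnv_type == "deletion", 0, copies)
  frequency * c_eff + (1 - frequency) * 1
}

#' Label focal sub-windows from a truth set
#'
#' A window takes the class and pool-averaged copy number of a truth CNV when
#' it overlaps that CNV by more than half the window width; otherwise it is
#' `normal` with copy number 1. Windows overlapping a CNV by 1 bp up to half
#' their width stay `normal` but are flagged `breakpoint` for evaluation
#' audits. Ties are impossible because truth CNVs do not overlap.
#'
#' @param windows Tibble (`contig`, `start`, `end`) of focal sub-windows.
#' @param truth_cnvs Truth-set tibble ([sample_cnvs()] format).
#' @param pool_size Unused for the label value itself (frequencies already
#'   encode the pool) but validated against the frequency grid when given.
#' @return `windows` plus `cnv_class`, `copy_number`, `breakpoint`.
#' @export
label_windows <- function(windows, truth_cnvs, pool_size = NULL) {
  assert_nonoverlapping(truth_cnvs)
  if (!is.null(pool_size) && nrow(truth_cnvs) > 0) {
    g <- truth_cnvs$frequency * pool_size
    if (any(abs(g - round(g)) > 1e-9))
      abort("truth frequencies are not multiples of 1/pool_size",
            class = "cnvforest_config_error")
  }
  out <- windows
  out$cnv_class <- "normal"
  out$copy_number <- 1
  out$breakpoint <- FALSE
  if (nrow(truth_cnvs) == 0 || nrow(windows) == 0) return(out)
  ov <- interval_overlaps(windows, truth_cnvs)
  if (nrow(ov) == 0) return(out)
  width <- windows$end - windows$start
  ov$frac <- ov$overlap / width[ov$query]
  # max-overlap CNV per window (non-overlapping truth => >50% hit is unique)
  best <- ov[order(ov$query, -ov$frac), ]
  best <- best[!duplicated(best$query), ]
  hit <- best[best$frac > 0.5, ]
  touch <- best[best$frac <= 0.5 & best$overlap >= 1, ]
  if (nrow(hit) > 0) {
    out$cnv_class[hit$query] <- truth_cnvs$cnv_type[hit$subject]
    out$copy_number[hit$query] <- copy_number_label(
      truth_cnvs$cnv_type[hit$subject], truth_cnvs$copies[hit$subject],
      truth_cnvs$frequency[hit$subject])
  }
  if (nrow(touch) > 0) out$breakpoint[touch$query] <- TRUE
  out
}

#' Join feature vectors with window labels into a training table
#'
#' Inner join on the focal interval: labels whose vectors were skipped at
#' contig edges drop out; duplicate focal intervals are an error.
#'
#' @param feature_vectors A [vectorize_windows()] tibble.
#' @param window_labels A [label_windows()] tibble.
#' @return Tibble of feature columns plus `cnv_class` and `copy_number`.
#' @export
build_training_table <- function(feature_vectors, window_labels) {
  key <- c("contig", "start", "end")
  if (anyDuplicated(feature_vectors[key]) || anyDuplicated(window_labels[key]))
    abort("duplicate focal intervals", class = "cnvforest_integrity_error")
  lab <- window_labels[, c(key, "cnv_class", "copy_number")]
  out <- inner_join(feature_vectors, lab, by = key)
  if (nrow(out) == 0)
    warn("no focal intervals shared between vectors and labels")
  out
}
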