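# Shared simulated fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# 500 kb haploid contig at 20x with 50 dup + 50 del: the standard desk-scale
# training world.
std_train <- function() fixture("std_train", function() {
  cfg <- sim_config(n_duplications = 50, n_deletions = 50,
                    size_range = c(100, 2000), pool_size = 1,
                    target_coverage = 20, seed = 101)
  simulate_training_set(cfg, ref_length = 5e5)
})

std_test <- function() fixture("std_test", function() {
  cfg <- sim_config(n_duplications = 50, n_deletions = 50,
                    size_range = c(100, 2000), pool_size = 1,
                    target_coverage = 20, seed = 202)
  simulate_training_set(cfg, ref_length = 5e5)
})

std_model <- function() fixture("std_model", function() {
  train_classifier(std_train()$table, classifier_spec(seed = 11))
})

# Noiseless, perfectly separable feature table: std_median/std_mean exactly
# 2 inside duplications, 0 inside deletions, 1 elsewhere; other features 0.
noiseless_table <- function(n_per_class = 120, k = 5, seed = 5) {
  withr::with_seed(seed, {
    sch <- feature_schema(k)
    n <- 3 * n_per_class
    cls <- rep(c("normal", "deletion", "duplication"), each = n_per_class)
    level <- c(normal = 1, deletion = 0, duplication = 2)[cls]
    X <- matrix(0, n, nrow(sch), dimnames = list(NULL, sch$column))
    for (j in seq_len(nrow(sch))) {
      if (sch$statistic[j] %in% c("std_mean", "std_median")) {
        X[, j] <- if (sch$offset[j] == 0) level else 1
      }
    }
    tab <- tibble::as_tibble(X)
    tab$contig <- "chr1"
    tab$start <- (seq_len(n) - 1L) * 50L
    tab$end <- tab$start + 50L
    tab$cnv_class <- cls
    tab$copy_number <- level
    tab[, c("contig", "start", "end", sch$column, "cnv_class", "copy_number")]
  })
}
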