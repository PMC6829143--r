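# Tree-ensemble window classifier: class (duplication / deletion / normal)
# and discrete copy-number prediction over the grid seen in training.

CLASS_LEVELS <- c("normal", "deletion", "duplication")

#' Classifier specification
#'
#' @param algorithm `"random_forest"` (bagged trees, per-split feature
#'   subsampling), `"extra_trees"` (randomized thresholds, no bagging), or
#'   `"decision_tree"` (a single exhaustive CART tree).
#' @param n_estimators Trees in the ensemble (ignored for `decision_tree`);
#'   100 by default, 500 gives indistinguishable results.
#' @param seed Integer seed; training is fully deterministic given it.
#' @param targets `"both"` (default) fits a class model and a copy-number
#'   model on the same features; `"class"` or `"copy_number"` fit one.
#' @param mtry Features tried per split; default `floor(sqrt(p))`.
#' @param min_split Minimum node size to attempt a split.
#' @param max_depth Maximum tree depth, 0 for unlimited.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(algorithm = c("random_forest", "extra_trees",
                                          "decision_tree"),
                            n_estimators = 100L, seed = 1L,
                            targets = c("both", "class", "copy_number"),
                            mtry = NULL, min_split = 5L, max_depth = 0L) {
  algorithm <- match.arg(algorithm)
  targets <- match.arg(targets)
  if (n_estimators < 1) abort("n_estimators must be >= 1")
  structure(list(algorithm = algorithm,
                 n_estimators = as.integer(n_estimators),
                 seed = as.integer(seed), targets = targets, mtry = mtry,
                 min_split = as.integer(min_split),
                 max_depth = as.integer(max_depth)),
            class = "classifier_spec")
}

fit_forest <- function(X, y_factor, spec, seed_offset = 0) {
  K <- nlevels(y_factor)
  p <- ncol(X)
  mtry <- spec$mtry %||% max(1L, floor(sqrt(p)))
  n_trees <- if (spec$algorithm == "decision_tree") 1L else spec$n_estimators
  bootstrap <- spec$algorithm == "random_forest"
  random_splits <- spec$algorithm == "extra_trees"
  if (spec$algorithm == "decision_tree") mtry <- p
  cpp_grow_forest(X, as.integer(y_factor) - 1L, K, n_trees,
                  as.integer(mtry), spec$min_split, 1L, spec$max_depth,
                  bootstrap, random_splits,
                  as.numeric(spec$seed) + seed_offset)
}

#' Train the window classifier
#'
#' Fits the configured tree ensemble to a labeled training table. The class
#' model discriminates `normal` / `deletion` / `duplication`; when `targets`
#' includes copy number, a second ensemble is fitted over the discrete
#' copy-number grid present in the table (copy number is a classification
#' target on multiples of `1/pool_size`, not a regression target). The
#' fitted model is plain R data: `saveRDS()`/`readRDS()` round-trips it
#' bit-compatibly.
#'
#' @param training_table A [build_training_table()] tibble.
#' @param spec A [classifier_spec()].
#' @return An object of class `cnv_classifier`.
#' @export
train_classifier <- function(training_table, spec = classifier_spec()) {
  feat <- setdiff(names(training_table),
                  c("contig", "start", "end", "cnv_class", "copy_number",
                    "breakpoint"))
  if (length(feat) == 0) abort("no feature columns in training table")
  X <- as.matrix(training_table[, feat])
  if (anyNA(X)) abort("missing feature values", class = "cnvforest_schema_error")
  classes <- intersect(CLASS_LEVELS, unique(training_table$cnv_class))
  model <- list(spec = spec, feature_names = feat, classes = classes,
                copy_grid = NULL, class_forest = NULL, copy_forest = NULL,
                n_train = table(training_table$cnv_class))
  if (spec$targets %in% c("both", "class")) {
    if (length(classes) < 2)
      abort("training table holds a single class; cannot train",
            class = "cnvforest_training_error")
    y <- factor(training_table$cnv_class, levels = classes)
    model$class_forest <- fit_forest(X, y, spec, seed_offset = 0)
  }
  if (spec$targets %in% c("both", "copy_number")) {
    grid <- sort(unique(training_table$copy_number))
    if (length(grid) < 2)
      abort("copy-number grid has a single value; cannot train",
            class = "cnvforest_training_error")
    yc <- factor(training_table$copy_number, levels = grid)
    model$copy_grid <- grid
    model$copy_forest <- fit_forest(X, yc, spec, seed_offset = 10^6)
  }
  structure(model, class = "cnv_classifier")
}

#' @export
print.cnv_classifier <- function(x, ...) {
  cat(sprintf("<cnv_classifier> %s (%d trees), %d features, classes: %s\n",
              x$spec$algorithm,
              if (x$spec$algorithm == "decision_tree") 1L else x$spec$n_estimators,
              length(x$feature_names), paste(x$classes, collapse = "/")))
  if (!is.null(x$copy_grid))
    cat(sprintf("  copy-number grid: %s\n",
                paste(signif(x$copy_grid, 4), collapse = " ")))
  invisible(x)
}

check_schema <- function(model, feature_vectors) {
  missing <- setdiff(model$feature_names, names(feature_vectors))
  if (length(missing) > 0)
    abort(paste0("feature vectors lack model columns: ",
                 paste(utils::head(missing, 5), collapse = ", ")),
          class = "cnvforest_schema_error")
  as.matrix(feature_vectors[, model$feature_names])
}

#' Predict window calls
#'
#' One call per feature vector: the predicted class, its probability (mean
#' vote share across trees), per-class probabilities, and the copy-number
#' prediction when the model was trained for it. Exact probability ties are
#' broken conservatively in the order normal > deletion > duplication.
#'
#' @param object A [train_classifier()] model.
#' @param feature_vectors A [vectorize_windows()] tibble.
#' @param ... Unused.
#' @return Tibble: focal interval, `cnv_class`, `probability`, one
#'   `p_<class>` column per class, and `copy_number` (NA when not trained).
#' @export
predict.cnv_classifier <- function(object, feature_vectors, ...) {
  out <- feature_vectors[, intersect(c("contig", "start", "end"),
                                     names(feature_vectors))]
  if (nrow(feature_vectors) == 0) {
    out$cnv_class <- character()
    out$probability <- double()
    out$copy_number <- double()
    return(out)
  }
  X <- check_schema(object, feature_vectors)
  if (!is.null(object$class_forest)) {
    pr <- cpp_predict_forest(object$class_forest$trees, X,
                             length(object$classes))
    colnames(pr) <- object$classes
    # ties broken toward the conservative end of CLASS_LEVELS order
    pref <- pr[, intersect(CLASS_LEVELS, object$classes), drop = FALSE]
    pick <- max.col(pref, ties.method = "first")
    out$cnv_class <- colnames(pref)[pick]
    out$probability <- pref[cbind(seq_len(nrow(pref)), pick)]
    for (cl in object$classes) out[[paste0("p_", cl)]] <- pr[, cl]
  }
  if (!is.null(object$copy_forest)) {
    prc <- cpp_predict_forest(object$copy_forest$trees, X,
                              length(object$copy_grid))
    out$copy_number <- object$copy_grid[max.col(prc, ties.method = "first")]
  } else {
    out$copy_number <- NA_real_
  }
  out
}

#' Feature importances keyed by statistic and sub-window offset
#'
#' Mean-decrease-in-impurity importances of the class model (or copy model),
#' normalized to sum to 1, joined to the feature schema so they can be
#' aggregated by flank offset or by statistic.
#'
#' @param model A [train_classifier()] model.
#' @param target `"class"` or `"copy_number"`.
#' @return Tibble (`column`, `statistic`, `offset`, `importance`).
#' @export
feature_importances <- function(model, target = c("class", "copy_number")) {
  target <- match.arg(target)
  forest <- if (target == "class") model$class_forest else model$copy_forest
  if (is.null(forest)) abort(sprintf("model was not trained for target '%s'", target))
  imp <- forest$importance
  tot <- sum(imp)
  if (tot > 0) imp <- imp / tot
  k <- (length(model$feature_names) / length(STAT_NAMES) - 1) / 2
  sch <- feature_schema(as.integer(k))
  stopifnot(identical(sch$column, model$feature_names))
  sch$importance <- imp
  sch
}

#' Receiver operating characteristic for CNV-vs-normal window calls
#'
#' Scores each window by its predicted CNV probability (`1 - p_normal`) and
#' sweeps the threshold against binary truth (any CNV class vs normal).
#' Points are accumulated per distinct score, run from (0,0) to (1,1), and
#' the area is the trapezoid rule.
#'
#' @param calls A [predict.cnv_classifier()] tibble (needs `p_normal`).
#' @param truth_labels A [label_windows()] tibble on the same focal
#'   intervals.
#' @return Object of class `cnv_roc`: list with `points` (tibble `fpr`,
#'   `tpr`, `threshold`) and `auc`.
#' @export
roc_curve <- function(calls, truth_labels) {
  key <- c("contig", "start", "end")
  lab <- truth_labels[, key]
  lab$.truth_class <- truth_labels$cnv_class
  joined <- inner_join(calls, lab, by = key)
  truth_pos <- joined$.truth_class != "normal"
  if (all(truth_pos) || !any(truth_pos))
    abort("truth contains a single class; ROC undefined",
          class = "cnvforest_roc_error")
  score <- 1 - joined$p_normal
  ord <- order(-score)
  score <- score[ord]; truth_pos <- truth_pos[ord]
  tp <- cumsum(truth_pos); fp <- cumsum(!truth_pos)
  last <- !duplicated(score, fromLast = TRUE)   # one point per threshold
  pts <- tibble(threshold = score[last],
                tpr = tp[last] / sum(truth_pos),
                fpr = fp[last] / sum(!truth_pos))
  pts <- bind_rows(tibble(threshold = Inf, tpr = 0, fpr = 0), pts)
  if (pts$fpr[nrow(pts)] < 1 || pts$tpr[nrow(pts)] < 1)
    pts <- bind_rows(pts, tibble(threshold = -Inf, tpr = 1, fpr = 1))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc), class = "cnv_roc")
}

#' @export
print.cnv_roc <- function(x, ...) {
  cat(sprintf("<cnv_roc> %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' @export
tidy.cnv_classifier <- function(x, target = "class", ...) {
  feature_importances(x, target)
}

#' @export
glance.cnv_classifier <- function(x, ...) {
  tibble(algorithm = x$spec$algorithm,
         n_estimators = if (x$spec$algorithm == "decision_tree") 1L
                        else x$spec$n_estimators,
         n_features = length(x$feature_names),
         n_train = sum(x$n_train),
         n_classes = length(x$classes),
         copy_grid_size = length(x$copy_grid %||% numeric(0)),
         seed = x$spec$seed)
}

#' Save / load a fitted classifier
#'
#' Thin wrappers over `saveRDS()`; models are plain R data so a reloaded
#' model predicts identically.
#'
#' @param model A `cnv_classifier`.
#' @param path File path.
#' @export
write_classifier <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "cnv_classifier")) abort("not a cnv_classifier file")
  m
}
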