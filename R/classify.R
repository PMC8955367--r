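# SVM state classification from node-importance features ----------------------

#' Assemble a labelled feature dataset from importance profiles
#'
#' One row per epoch profile; columns are the per-node importance scores `Q`
#' in canonical montage order (identical for every row). Feature-length
#' reduction to the top-`m` nodes is carried out inside [evaluate_states()]
#' on training folds only (default), or globally here when
#' `selection = "global"`.
#'
#' @param profiles list of [node_importance()] profiles sharing one montage.
#' @param labels condition label per profile (two classes).
#' @param m feature-vector length, `1 <= m <= n`; `NULL` keeps all nodes.
#' @param selection `"train_only"` (top-m chosen per split on training data;
#'   default) or `"global"` (top-m chosen once from all samples, accepting
#'   the leakage that implies).
#' @param band,method optional annotations.
#' @return object of class `state_dataset`.
#' @export
build_features <- function(profiles, labels, m = NULL,
                           selection = c("train_only", "global"),
                           band = NA_character_, method = "wkpn") {
  selection <- match.arg(selection)
  stopifnot(length(profiles) == length(labels), length(profiles) >= 2)
  get_q <- function(p) if (inherits(p, "importance_profile")) p$Q else p
  ref <- names(get_q(profiles[[1]]))
  feats <- t(vapply(profiles, function(p) {
    q <- get_q(p)
    if (!identical(names(q), ref))
      stop("profiles do not share one montage/node order", call. = FALSE)
    q
  }, numeric(length(ref))))
  colnames(feats) <- ref
  labels <- factor(labels)
  if (nlevels(labels) != 2)
    stop("exactly two classes are required", call. = FALSE)
  if (!is.null(m)) {
    m <- as.integer(m)
    if (m < 1 || m > ncol(feats))
      stop(sprintf("m must lie in [1, %d]", ncol(feats)), call. = FALSE)
  }
  if (identical(selection, "global") && !is.null(m) && m < ncol(feats)) {
    keep <- order(-colMeans(feats))[seq_len(m)]
    feats <- feats[, sort(keep), drop = FALSE]
  }
  structure(list(features = feats, labels = labels, m = m,
                 selection = selection, band = band, method = method),
            class = "state_dataset")
}

#' @export
print.state_dataset <- function(x, ...) {
  cat(sprintf("<state_dataset> %d samples x %d nodes (%s), classes: %s\n",
              nrow(x$features), ncol(x$features), x$method,
              paste(sprintf("%s=%d", levels(x$labels), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

# Stratified train/test split indices at the given train fraction.
.stratified_split <- function(labels, train_frac) {
  train <- unlist(lapply(levels(labels), function(lv) {
    idx <- which(labels == lv)
    sample(idx, round(length(idx) * train_frac))
  }))
  list(train = sort(train), test = setdiff(seq_along(labels), train))
}

#' Repeated-split SVM evaluation
#'
#' For each repetition: stratified random split at the train:test ratio
#' (default 3:2), optional top-`m` node selection by mean importance on the
#' training rows only, feature standardization with training-fold mean and
#' sd, RBF-kernel SVM fit (`C = 1`; kernel width `1/(m * var)` of the
#' training features), and test accuracy. Deterministic given `seed`.
#'
#' @param ds a [build_features()] dataset.
#' @param n_repetitions number of random splits (default 20).
#' @param seed integer seed.
#' @param train_frac training fraction (default 0.6, i.e. 3:2).
#' @param cost SVM regularization constant.
#' @return object of class `eval_report`: `accuracies`, `mean_accuracy`,
#'   `split_ratio`, `n_repetitions`, `seed`.
#' @export
evaluate_states <- function(ds, n_repetitions = 20, seed = 1,
                            train_frac = 0.6, cost = 1) {
  stopifnot(inherits(ds, "state_dataset"))
  if (nlevels(droplevels(ds$labels)) < 2)
    stop("both classes must be present", call. = FALSE)
  if (min(table(ds$labels)) < 10)
    stop("need at least 10 samples per class", call. = FALSE)
  feats <- ds$features
  acc <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_repetitions), function(r) {
      sp <- .stratified_split(ds$labels, train_frac)
      x <- feats
      if (!is.null(ds$m) && identical(ds$selection, "train_only") &&
          ds$m < ncol(feats)) {
        keep <- order(-colMeans(feats[sp$train, , drop = FALSE]))[seq_len(ds$m)]
        x <- feats[, sort(keep), drop = FALSE]
      }
      mu <- colMeans(x[sp$train, , drop = FALSE])
      sd_ <- apply(x[sp$train, , drop = FALSE], 2, stats::sd)
      sd_[sd_ == 0] <- 1
      xs <- sweep(sweep(x, 2, mu), 2, sd_, "/")
      tr <- xs[sp$train, , drop = FALSE]
      v <- stats::var(as.vector(tr))
      gamma <- if (is.finite(v) && v > 0) 1 / (ncol(tr) * v) else 1 / ncol(tr)
      fit <- e1071::svm(x = tr, y = ds$labels[sp$train], kernel = "radial",
                        cost = cost, gamma = gamma, scale = FALSE)
      pred <- stats::predict(fit, xs[sp$test, , drop = FALSE])
      mean(pred == ds$labels[sp$test])
    }, numeric(1))
  })
  structure(list(accuracies = acc, mean_accuracy = mean(acc),
                 split_ratio = c(train = train_frac, test = 1 - train_frac),
                 n_repetitions = n_repetitions, seed = as.integer(seed)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> mean accuracy %.3f over %d splits (%.0f/%.0f train/test)\n",
              x$mean_accuracy, x$n_repetitions,
              x$split_ratio[1] * 100, x$split_ratio[2] * 100))
  invisible(x)
}

#' Feature-length sweep
#'
#' Evaluates classification accuracy for a range of feature-vector lengths
#' `m`, sharing the seed (hence the split sequence) across lengths.
#'
#' @param ds a [build_features()] dataset (its `m` is overridden).
#' @param lengths integer vector of lengths within `[1, n]`.
#' @param n_repetitions,seed,... passed to [evaluate_states()].
#' @return list with `curve` (data.frame length, mean_accuracy) and
#'   `best_length` (smallest argmax).
#' @export
length_sweep <- function(ds, lengths, n_repetitions = 20, seed = 1, ...) {
  stopifnot(inherits(ds, "state_dataset"))
  lengths <- as.integer(lengths)
  if (any(lengths < 1 | lengths > ncol(ds$features)))
    stop(sprintf("lengths must lie in [1, %d]", ncol(ds$features)),
         call. = FALSE)
  accs <- vapply(lengths, function(m) {
    d2 <- ds; d2$m <- m
    evaluate_states(d2, n_repetitions = n_repetitions, seed = seed,
                    ...)$mean_accuracy
  }, numeric(1))
  curve <- data.frame(length = lengths, mean_accuracy = accs)
  list(curve = curve, best_length = lengths[which.max(accs)])
}

#' Compare importance-ranking methods on identical splits
#'
#' Evaluates one dataset per ranking method with a shared seed, so every
#' method sees exactly the same train/test partitions.
#'
#' @param datasets named list of [build_features()] datasets built from the
#'   same epochs (equal sample counts and labels).
#' @param n_repetitions,seed,... passed to [evaluate_states()].
#' @return named list of `eval_report`s.
#' @export
compare_methods <- function(datasets, n_repetitions = 20, seed = 1, ...) {
  stopifnot(length(datasets) >= 1)
  ref <- datasets[[1]]
  for (d in datasets) {
    if (nrow(d$features) != nrow(ref$features) ||
        !identical(d$labels, ref$labels))
      stop("datasets must share samples and labels", call. = FALSE)
  }
  lapply(datasets, evaluate_states, n_repetitions = n_repetitions,
         seed = seed, ...)
}
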