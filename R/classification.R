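#' Stratified pool/test split
#'
#' Splits instances into a compound pool and a held-out test set per
#' class, so the class distribution is preserved: each class contributes
#' `round(class_count * test_fraction)` instances to the test set. The
#' pool index order is shuffled once (seeded) at split time; this fixed
#' order is the deterministic tie-break used downstream by the active
#' learning loop.
#'
#' @param labels binding-mode labels for all instances.
#' @param test_fraction held-out fraction (default 0.1).
#' @param seed integer seed.
#' @return object of class `data_split`: list with `pool_indices`,
#'   `test_indices`, `test_fraction`, `seed`.
#' @export
stratified_split <- function(labels, test_fraction = 0.1, seed) {
  labels <- binding_mode_factor(labels)
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must lie strictly between 0 and 1")
  }
  counts <- table(labels)
  if (any(counts[BINDING_MODES] < 2L) || any(is.na(counts[BINDING_MODES]))) {
    stop("every class needs at least 2 members to stratify")
  }
  with_seed(seed, {
    test_idx <- integer(0)
    for (cl in BINDING_MODES) {
      members <- which(labels == cl)
      n_test <- round(length(members) * test_fraction)
      test_idx <- c(test_idx, sample(members, n_test))
    }
    pool_idx <- sample(setdiff(seq_along(labels), test_idx))
    structure(
      list(pool_indices = pool_idx, test_indices = sort(test_idx),
           test_fraction = test_fraction, seed = as.integer(seed)),
      class = "data_split"
    )
  })
}

#' Train a multi-class random forest
#'
#' 100-tree probability forest (Gini splitting) with inverse-frequency
#' class weights `n / (k * n_c)` to counter the strong class imbalance;
#' all other hyperparameters are the backing library's defaults.
#' Predicted class probabilities are the ensemble average of per-tree
#' terminal-node class fractions.
#'
#' @param x binary feature matrix (rows = instances).
#' @param labels binding-mode labels aligned with `x`.
#' @param seed integer seed (forest growth is reproducible under it).
#' @param num_trees number of trees (default 100).
#' @return object of class `bm_rf` wrapping the fitted ensemble.
#' @export
train_rf <- function(x, labels, seed, num_trees = 100L) {
  labels <- binding_mode_factor(labels)
  labels <- droplevels(labels)
  if (nrow(x) == 0L) stop("empty training data")
  if (nlevels(labels) < 2L) stop("training data must contain >= 2 classes")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  tab <- table(labels)
  class_weights <- as.numeric(length(labels) / (nlevels(labels) * tab))
  fit <- ranger::ranger(
    x = x, y = labels,
    num.trees = num_trees,
    probability = TRUE,
    splitrule = "gini",
    min.node.size = 1L,  # fully grown trees: distinct rows are memorized
    class.weights = class_weights,
    importance = "impurity",
    seed = as.integer(seed),
    num.threads = 1L
  )
  structure(
    list(fit = fit, class_levels = levels(labels),
         feature_names = colnames(x), n_trees = num_trees,
         seed = as.integer(seed)),
    class = "bm_rf"
  )
}

#' Predicted class probabilities
#'
#' @param model `bm_rf`.
#' @param x feature matrix with the training feature columns.
#' @return matrix n x k of probabilities; columns ordered I, I1/2, II
#'   (absent training classes get probability 0).
#' @export
predict_proba <- function(model, x) {
  stopifnot(inherits(model, "bm_rf"))
  if (is.null(colnames(x))) colnames(x) <- model$feature_names
  p <- stats::predict(model$fit, data = x, num.threads = 1L)$predictions
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L, dimnames = list(NULL, names(p)))
  out <- matrix(0, nrow = nrow(p), ncol = length(BINDING_MODES),
                dimnames = list(rownames(x), BINDING_MODES))
  out[, colnames(p)] <- p
  out
}

#' Predicted class labels
#'
#' Argmax of [predict_proba()]; probability ties resolve by the fixed
#' class order I, I1/2, II for determinism.
#'
#' @inheritParams predict_proba
#' @return binding-mode factor of length `nrow(x)`.
#' @export
predict_class <- function(model, x) {
  probs <- predict_proba(model, x)
  binding_mode_factor(BINDING_MODES[max.col(probs, ties.method = "first")])
}

#' Standard benchmark: repeated stratified train/test trials
#'
#' Runs `n_trials` independent trials (split seeds
#' `base_seed .. base_seed + n_trials - 1`): stratified split, one
#' forest trained on the pool, global and per-class MCC/BA measured on
#' the held-out test set. The default protocol is 20 trials at a 90/10
#' split; a 70/30 split is the customary robustness control.
#'
#' @param ds `fingerprint_dataset`.
#' @param n_trials number of trials (default 20).
#' @param test_fraction held-out fraction (default 0.1).
#' @param base_seed first trial seed.
#' @return object of class `benchmark_result`: list of
#'   `evaluation_result`s plus a tidy `summary()` method.
#' @export
benchmark_trials <- function(ds, n_trials = 20L, test_fraction = 0.1,
                             base_seed = 1L) {
  stopifnot(inherits(ds, "fingerprint_dataset"))
  results <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    seed_t <- as.integer(base_seed) + t - 1L
    split <- stratified_split(ds$labels, test_fraction, seed = seed_t)
    model <- train_rf(ds$matrix[split$pool_indices, , drop = FALSE],
                      ds$labels[split$pool_indices], seed = seed_t)
    pred <- predict_class(model, ds$matrix[split$test_indices, , drop = FALSE])
    results[[t]] <- evaluate_predictions(ds$labels[split$test_indices], pred)
  }
  structure(list(results = results, tag = ds$tag,
                 n_trials = as.integer(n_trials),
                 test_fraction = test_fraction,
                 base_seed = as.integer(base_seed)),
            class = "benchmark_result")
}

#' Tidy per-trial benchmark metrics
#'
#' @param x `benchmark_result`.
#' @param ... unused.
#' @return data frame: `trial`, `representation`, `metric`, `class`
#'   (`"all"` for global), `value`.
#' @export
as.data.frame.benchmark_result <- function(x, ...) {
  rows <- lapply(seq_along(x$results), function(t) {
    r <- x$results[[t]]
    rbind(
      data.frame(trial = t, representation = x$tag, metric = "mcc",
                 class = "all", value = r$mcc),
      data.frame(trial = t, representation = x$tag, metric = "ba",
                 class = "all", value = r$ba),
      data.frame(trial = t, representation = x$tag, metric = "mcc",
                 class = r$per_class$class, value = r$per_class$mcc),
      data.frame(trial = t, representation = x$tag, metric = "ba",
                 class = r$per_class$class, value = r$per_class$ba)
    )
  })
  do.call(rbind, rows)
}

#' Boxplot-style summary of a benchmark
#'
#' Median, quartiles and 1.5 IQR whiskers of each metric across trials.
#'
#' @param object `benchmark_result`.
#' @param ... unused.
#' @return data frame: `representation`, `metric`, `class`, `median`,
#'   `q1`, `q3`, `whisker_low`, `whisker_high`.
#' @export
summary.benchmark_result <- function(object, ...) {
  df <- as.data.frame(object)
  groups <- split(df, list(df$metric, df$class), drop = TRUE)
  rows <- lapply(groups, function(g) {
    v <- g$value[!is.na(g$value)]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    data.frame(representation = g$representation[[1]],
               metric = g$metric[[1]], class = g$class[[1]],
               median = q[2], q1 = q[1], q3 = q[3],
               whisker_low = max(min(v), q[1] - 1.5 * iqr),
               whisker_high = min(max(v), q[3] + 1.5 * iqr))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Label-permutation significance test
#'
#' For one fixed pool/test split, the observed forest is trained on the
#' true pool labels; `n_perm` null forests are trained on pool labels
#' shuffled within the pool (test labels untouched, shuffle seed
#' `seed + b` for permutation `b`). All models are scored by multi-class
#' MCC on the same test set, and
#' `p = max(#\{null >= observed\}, 1) / n_perm`, so the smallest
#' achievable p-value with 1000 permutations is 1/1000.
#'
#' @param ds `fingerprint_dataset`.
#' @param split `data_split` from [stratified_split()].
#' @param n_perm number of permutations (default 1000).
#' @param seed base seed.
#' @return object of class `permutation_test_result`: list with
#'   `observed_mcc`, `null_mccs`, `p_value`, `n_perm`.
#' @export
permutation_test <- function(ds, split, n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(ds, "fingerprint_dataset"), inherits(split, "data_split"))
  if (n_perm < 1L) stop("n_perm must be >= 1")
  pool_x <- ds$matrix[split$pool_indices, , drop = FALSE]
  pool_y <- ds$labels[split$pool_indices]
  test_x <- ds$matrix[split$test_indices, , drop = FALSE]
  test_y <- ds$labels[split$test_indices]
  model <- train_rf(pool_x, pool_y, seed = seed)
  observed <- multiclass_mcc(test_y, predict_class(model, test_x))
  null_mccs <- vapply(seq_len(n_perm), function(b) {
    y_shuf <- with_seed(as.integer(seed) + b, sample(pool_y))
    m <- train_rf(pool_x, y_shuf, seed = as.integer(seed) + b)
    multiclass_mcc(test_y, predict_class(m, test_x))
  }, numeric(1))
  c_count <- sum(null_mccs >= observed)
  structure(
    list(observed_mcc = observed, null_mccs = null_mccs,
         p_value = max(c_count, 1L) / n_perm, n_perm = as.integer(n_perm)),
    class = "permutation_test_result"
  )
}

#' @export
print.permutation_test_result <- function(x, ...) {
  cat(sprintf(
    "Permutation test: observed MCC %.3f, null median %.3f, p = %.4g (%d permutations)\n",
    x$observed_mcc, stats::median(x$null_mccs), x$p_value, x$n_perm))
  invisible(x)
}

#' Normalized Gini feature importances
#'
#' Mean decrease in Gini node impurity, accumulated per feature over all
#' trees and normalized to sum to 1.
#'
#' @param model `bm_rf`.
#' @return named non-negative numeric vector summing to 1 (uniform if
#'   the forest never split, e.g. constant features).
#' @export
extract_importances <- function(model) {
  stopifnot(inherits(model, "bm_rf"))
  imp <- ranger::importance(model$fit)
  imp[imp < 0] <- 0
  total <- sum(imp)
  if (total == 0) {
    imp[] <- 1 / length(imp)
  } else {
    imp <- imp / total
  }
  imp
}

#' Filter features by median importance across iterations
#'
#' Given an importance trace (features x iterations), computes each
#' feature's median importance over the iterations and keeps features
#' whose median is at least `fraction_of_max` times the largest median.
#' The customary thresholds are 0.2 for atom-environment features and
#' 0.1 for IFP features.
#'
#' @param trace numeric matrix, features x iterations, with feature row
#'   names (an `importance_trace` matrix works directly).
#' @param fraction_of_max threshold in `(0, 1]`.
#' @return character vector of retained feature names.
#' @export
filter_by_median_importance <- function(trace, fraction_of_max) {
  if (is.list(trace) && !is.null(trace$importances)) trace <- trace$importances
  if (!is.matrix(trace) || nrow(trace) == 0L || ncol(trace) == 0L) {
    stop("importance trace must be a non-empty features x iterations matrix")
  }
  if (fraction_of_max <= 0 || fraction_of_max > 1) {
    stop("fraction_of_max must lie in (0, 1]")
  }
  med <- apply(trace, 1L, stats::median)
  keep <- med >= fraction_of_max * max(med)
  rownames(trace)[keep] %||% which(keep)
}
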