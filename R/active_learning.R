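#' Active learning configuration
#'
#' @param strategy `"entropy"` (uncertainty sampling: pick the pool
#'   instances whose predicted class distribution has the largest
#'   Shannon entropy) or `"random"` (uniform control).
#' @param batch_size instances added per iteration after the first
#'   (default 10, the customary trade-off between retraining cost and
#'   batch redundancy).
#' @param initial_per_class instances per class in the first training
#'   set (default 1, i.e. 3 instances in total).
#' @param max_iterations cap on iterations; `Inf` (default) runs until
#'   the pool is exhausted.
#' @param seed per-trial seed: drives the initial selection, random
#'   batches, and the (fixed) forest seed, so curve noise reflects
#'   instance selection rather than refit randomness.
#' @param record_importances if `TRUE`, Gini importances of every
#'   iteration's model are collected into an importance trace.
#' @return object of class `al_config`.
#' @export
al_config <- function(strategy = c("entropy", "random"),
                      batch_size = 10L,
                      initial_per_class = 1L,
                      max_iterations = Inf,
                      seed = 1L,
                      record_importances = FALSE) {
  strategy <- match.arg(strategy)
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (initial_per_class < 1L) stop("initial_per_class must be >= 1")
  structure(
    list(strategy = strategy, batch_size = as.integer(batch_size),
         initial_per_class = as.integer(initial_per_class),
         max_iterations = max_iterations, seed = as.integer(seed),
         record_importances = isTRUE(record_importances)),
    class = "al_config"
  )
}

#' Initial per-class selection
#'
#' Uniformly selects `per_class` pool instances of each binding mode
#' (default one per class, three in total) to seed the first model.
#'
#' @param pool_labels binding-mode labels of the pool instances.
#' @param seed integer seed.
#' @param per_class instances per class (default 1).
#' @return integer positions into the pool vector.
#' @export
initial_selection <- function(pool_labels, seed, per_class = 1L) {
  pool_labels <- binding_mode_factor(pool_labels)
  if (any(table(pool_labels)[BINDING_MODES] < per_class)) {
    stop("every class must be present in the pool")
  }
  with_seed(seed, {
    unlist(lapply(BINDING_MODES, function(cl) {
      members <- which(pool_labels == cl)
      if (length(members) == 1L) members else sample(members, per_class)
    }))
  })
}

#' Entropy-based batch selection
#'
#' Picks the `n` pool instances with the largest Shannon entropy of
#' their predicted class probabilities (highest model uncertainty). If
#' fewer than `n` remain, all are returned. Entropy ties break by
#' ascending pool position, which is deterministic yet unbiased because
#' the pool order was shuffled once at split time.
#'
#' @param probs n_pool x k matrix of predicted class probabilities.
#' @param n batch size.
#' @return integer positions into the pool (rows of `probs`).
#' @export
select_batch_entropy <- function(probs, n) {
  if (is.null(dim(probs)) || nrow(probs) == 0L) stop("empty pool")
  if (n < 1L) stop("n must be >= 1")
  h <- row_entropies(probs)
  utils::head(order(-h, seq_along(h)), n)
}

#' Random batch selection (control)
#'
#' `n` uniform draws without replacement from the pool positions; if
#' fewer than `n` remain, all are returned.
#'
#' @param pool_size number of remaining pool instances.
#' @param n batch size.
#' @param seed integer seed.
#' @return integer positions into the pool.
#' @export
select_batch_random <- function(pool_size, n, seed) {
  if (pool_size < 1L) stop("empty pool")
  if (n < 1L) stop("n must be >= 1")
  if (n >= pool_size) return(seq_len(pool_size))
  with_seed(seed, sample.int(pool_size, n))
}

#' Run one active-learning trial
#'
#' Implements the iterative protocol: start from one instance per class;
#' at each iteration train a forest on the current training set, score
#' the held-out test set (MCC, BA), the remaining pool, and the full
#' original pool; then move the next batch -- the most uncertain
#' (entropy strategy) or random (control) pool instances -- into the
#' training set. Stops when the pool is exhausted (the last batch takes
#' whatever remains) or `max_iterations` is reached.
#'
#' @param ds `fingerprint_dataset`.
#' @param split `data_split`; its shuffled `pool_indices` order is the
#'   entropy tie-break order.
#' @param config `al_config`.
#' @return object of class `al_trace`: list with `curve` (data frame:
#'   `iteration`, `training_size`, `test_mcc`, `test_ba`,
#'   `pool_mcc_remaining`, `pool_mcc_full`), `selected_ids` (per
#'   iteration), `selection_entropies`, optional `importances`
#'   (features x iterations matrix), and the `config`.
#' @export
run_active_learning <- function(ds, split, config) {
  stopifnot(inherits(ds, "fingerprint_dataset"), inherits(split, "data_split"),
            inherits(config, "al_config"))
  pool <- split$pool_indices           # fixed shuffled order
  test_x <- ds$matrix[split$test_indices, , drop = FALSE]
  test_y <- ds$labels[split$test_indices]
  full_pool_x <- ds$matrix[pool, , drop = FALSE]
  full_pool_y <- ds$labels[pool]

  init <- initial_selection(ds$labels[pool], seed = config$seed,
                            per_class = config$initial_per_class)
  in_training <- logical(length(pool))
  in_training[init] <- TRUE

  curve <- list()
  selected_ids <- list(ds$inhibitor_ids[pool[init]])
  entropies <- list(rep(NA_real_, length(init)))
  importances <- list()
  iteration <- 0L
  repeat {
    iteration <- iteration + 1L
    train_pos <- which(in_training)
    model <- train_rf(full_pool_x[train_pos, , drop = FALSE],
                      full_pool_y[train_pos], seed = config$seed)
    test_pred <- predict_class(model, test_x)
    remaining <- which(!in_training)
    pool_mcc_remaining <- if (length(remaining) > 0L) {
      multiclass_mcc(full_pool_y[remaining],
                     predict_class(model, full_pool_x[remaining, , drop = FALSE]))
    } else {
      NA_real_
    }
    curve[[iteration]] <- data.frame(
      iteration = iteration,
      training_size = length(train_pos),
      test_mcc = multiclass_mcc(test_y, test_pred),
      test_ba = macro_balanced_accuracy(test_y, test_pred),
      pool_mcc_remaining = pool_mcc_remaining,
      pool_mcc_full = multiclass_mcc(full_pool_y,
                                     predict_class(model, full_pool_x))
    )
    if (config$record_importances) {
      importances[[iteration]] <- extract_importances(model)
    }
    if (length(remaining) == 0L || iteration >= config$max_iterations) break

    if (config$strategy == "entropy") {
      probs <- predict_proba(model, full_pool_x[remaining, , drop = FALSE])
      sel_local <- select_batch_entropy(probs, config$batch_size)
      entropies[[iteration + 1L]] <- row_entropies(probs)[sel_local]
    } else {
      sel_local <- select_batch_random(length(remaining), config$batch_size,
                                       seed = config$seed + iteration)
      entropies[[iteration + 1L]] <- rep(NA_real_, length(sel_local))
    }
    chosen <- remaining[sel_local]
    selected_ids[[iteration + 1L]] <- ds$inhibitor_ids[pool[chosen]]
    in_training[chosen] <- TRUE
  }

  trace <- list(
    curve = do.call(rbind, curve),
    selected_ids = selected_ids,
    selection_entropies = entropies,
    config = config,
    tag = ds$tag
  )
  if (config$record_importances) {
    trace$importances <- do.call(cbind, importances)
    rownames(trace$importances) <- ds$feature_names
    colnames(trace$importances) <- trace$curve$training_size
    trace$training_sizes <- trace$curve$training_size
  }
  class(trace) <- "al_trace"
  trace
}

#' @export
print.al_trace <- function(x, ...) {
  cat(sprintf("<al_trace %s/%s: %d iterations, final training size %d>\n",
              x$tag, x$config$strategy, nrow(x$curve),
              max(x$curve$training_size)))
  invisible(x)
}

#' Run the full multi-trial active learning experiment
#'
#' The standard design: `n_splits` independent stratified pool/test
#' splits, each with `n_executions` executions differing in the random
#' initial per-class selection (default 2 x 3 = 6 trials per strategy).
#' Entropy and random trials are paired: the trial with a given seed
#' starts from the same three instances under both strategies, isolating
#' the effect of the selection criterion.
#'
#' @param ds `fingerprint_dataset`.
#' @param n_splits number of pool/test splits (default 2).
#' @param n_executions executions per split (default 3).
#' @param strategies strategies to run (default both).
#' @param batch_size batch size N (default 10).
#' @param test_fraction held-out fraction (default 0.1).
#' @param base_seed base seed; split s uses seed `base_seed + s - 1`,
#'   execution e of split s uses trial seed
#'   `base_seed + 100 * s + e`.
#' @param max_iterations forwarded to [al_config()].
#' @param record_importances forwarded to [al_config()].
#' @return named list (by strategy) of lists of `al_trace`.
#' @export
run_al_experiment <- function(ds, n_splits = 2L, n_executions = 3L,
                              strategies = c("entropy", "random"),
                              batch_size = 10L, test_fraction = 0.1,
                              base_seed = 1L, max_iterations = Inf,
                              record_importances = FALSE) {
  out <- stats::setNames(vector("list", length(strategies)), strategies)
  for (strategy in strategies) {
    traces <- list()
    for (s in seq_len(n_splits)) {
      split <- stratified_split(ds$labels, test_fraction,
                                seed = as.integer(base_seed) + s - 1L)
      for (e in seq_len(n_executions)) {
        cfg <- al_config(strategy = strategy, batch_size = batch_size,
                         seed = as.integer(base_seed) + 100L * s + e,
                         max_iterations = max_iterations,
                         record_importances = record_importances)
        traces[[length(traces) + 1L]] <- run_active_learning(ds, split, cfg)
      }
    }
    out[[strategy]] <- traces
  }
  out
}

#' Aggregate active-learning traces
#'
#' Per-training-size mean and standard deviation of each curve metric
#' across trials. Traces whose training-size grids differ are aligned on
#' their common prefix (with a warning).
#'
#' @param traces list of `al_trace` objects sharing a configuration.
#' @return data frame: `training_size`, then `<metric>_mean` and
#'   `<metric>_sd` for `test_mcc`, `test_ba`, `pool_mcc_remaining`,
#'   `pool_mcc_full`.
#' @export
aggregate_trials <- function(traces) {
  stopifnot(length(traces) >= 1L,
            all(vapply(traces, inherits, logical(1), "al_trace")))
  grids <- lapply(traces, function(tr) tr$curve$training_size)
  n_common <- min(vapply(grids, length, integer(1)))
  prefix <- grids[[1L]][seq_len(n_common)]
  if (!all(vapply(grids, function(g) identical(g[seq_len(n_common)], prefix),
                  logical(1)))) {
    stop("traces have incompatible training-size grids")
  }
  if (any(vapply(grids, length, integer(1)) != n_common)) {
    warning("traces differ in length; aligned on common prefix of ",
            n_common, " iterations")
  }
  metrics <- c("test_mcc", "test_ba", "pool_mcc_remaining", "pool_mcc_full")
  out <- data.frame(training_size = prefix)
  for (m in metrics) {
    vals <- vapply(traces, function(tr) tr$curve[[m]][seq_len(n_common)],
                   numeric(n_common))
    vals <- matrix(vals, nrow = n_common)
    out[[paste0(m, "_mean")]] <- rowMeans(vals)
    out[[paste0(m, "_sd")]] <- apply(vals, 1L, stats::sd)
  }
  out
}

#' Entropy-minus-random difference curve
#'
#' Pointwise difference of the aggregated entropy and random mean curves
#' for a metric, with propagated standard deviation
#' `sqrt(sd_entropy^2 + sd_random^2)`, plus the peak difference and the
#' training size at which it occurs (first maximum). Large peaks flag
#' representations whose information the model can only exploit when
#' informative instances are chosen deliberately.
#'
#' @param entropy_agg,random_agg outputs of [aggregate_trials()] on the
#'   same training-size grid.
#' @param metric curve metric (default `"test_mcc"`).
#' @return object of class `difference_curve`: list with `curve` (data
#'   frame: `training_size`, `difference`, `sd`), `peak_value`,
#'   `peak_training_size`.
#' @export
difference_curve <- function(entropy_agg, random_agg, metric = "test_mcc") {
  if (!identical(entropy_agg$training_size, random_agg$training_size)) {
    stop("aggregated curves are on different training-size grids")
  }
  d <- entropy_agg[[paste0(metric, "_mean")]] -
    random_agg[[paste0(metric, "_mean")]]
  sd_ <- sqrt(entropy_agg[[paste0(metric, "_sd")]]^2 +
                random_agg[[paste0(metric, "_sd")]]^2)
  peak_at <- which.max(d)
  structure(
    list(curve = data.frame(training_size = entropy_agg$training_size,
                            difference = d, sd = sd_),
         peak_value = d[[peak_at]],
         peak_training_size = entropy_agg$training_size[[peak_at]],
         metric = metric),
    class = "difference_curve"
  )
}

#' @export
print.difference_curve <- function(x, ...) {
  cat(sprintf(
    "<difference_curve (%s): peak %+0.3f at training size %d>\n",
    x$metric, x$peak_value, x$peak_training_size))
  invisible(x)
}
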