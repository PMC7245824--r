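test_that("initial selection takes one instance per class", {
  pool <- c("I", "I1/2", "II")
  expect_setequal(initial_selection(pool, seed = 1), 1:3)
  pool2 <- sample(rep(BINDING_MODES, times = c(10, 6, 4)))
  idx <- initial_selection(pool2, seed = 2)
  expect_setequal(as.character(binding_mode_factor(pool2[idx])),
                  BINDING_MODES)
  expect_identical(initial_selection(pool2, seed = 3),
                   initial_selection(pool2, seed = 3))
  expect_error(initial_selection(c("I", "I", "I1/2"), seed = 1), "present")
})

test_that("entropy batches take the most uncertain pool instances", {
  probs <- rbind(c(1, 0, 0),            # H = 0
                 c(1 / 3, 1 / 3, 1 / 3), # H = log2(3)
                 c(0.5, 0.5, 0))        # H = 1
  expect_equal(select_batch_entropy(probs, 2), c(2L, 3L))
  expect_setequal(select_batch_entropy(probs, 5), 1:3)  # exhaustion rule
  expect_error(select_batch_entropy(probs[0, , drop = FALSE], 1), "empty")

  # brute-force sort oracle on random probability sets
  set.seed(13)
  for (i in 1:15) {
    p <- matrix(stats::runif(30), ncol = 3)
    p <- p / rowSums(p)
    h <- apply(p, 1, shannon_entropy)
    n <- sample(1:8, 1)
    expect_equal(select_batch_entropy(p, n),
                 order(-h, seq_along(h))[seq_len(n)])
  }
})

test_that("random batches are uniform, seeded, and exhaust the pool", {
  expect_setequal(select_batch_random(4, 10, seed = 1), 1:4)
  expect_identical(select_batch_random(50, 5, seed = 9),
                   select_batch_random(50, 5, seed = 9))
  # frequency check: each of 10 instances chosen with rate n/pool = 0.2
  reps <- 2000L
  counts <- integer(10)
  for (b in seq_len(reps)) {
    sel <- select_batch_random(10, 2, seed = 10000L + b)
    counts[sel] <- counts[sel] + 1L
  }
  p <- 0.2
  sigma <- sqrt(p * (1 - p) / reps)
  expect_true(all(abs(counts / reps - p) < 3 * sigma + 0.01))
})

test_that("the active-learning loop conserves the pool and is seeded", {
  cohort <- generate_dataset(separable_config(
    n_per_class = c("I" = 40L, "I1/2" = 16L, "II" = 12L)), seed = 3)
  ds <- build_ifp_datasets(cohort)$ifp595
  split <- stratified_split(ds$labels, 0.2, seed = 5)
  cfg <- al_config(strategy = "entropy", batch_size = 10L, seed = 6)
  trace <- run_active_learning(ds, split, cfg)

  n_pool <- length(split$pool_indices)
  sizes <- trace$curve$training_size
  # training sizes 3, 13, 23, ... until the final short batch
  expect_equal(sizes[-length(sizes)],
               3 + 10 * (seq_len(length(sizes) - 1) - 1))
  expect_equal(sizes[length(sizes)], n_pool)
  # conservation: selections are disjoint and cover the pool exactly
  all_ids <- unlist(trace$selected_ids)
  expect_length(all_ids, n_pool)
  expect_length(unique(all_ids), n_pool)
  expect_setequal(all_ids, ds$inhibitor_ids[split$pool_indices])

  # trivially separable data: both strategies hit MCC 1 before exhaustion
  expect_true(any(trace$curve$test_mcc == 1 &
                    trace$curve$training_size < n_pool))
  r_trace <- run_active_learning(ds, split,
                                 al_config("random", seed = 6))
  expect_true(any(r_trace$curve$test_mcc == 1 &
                    r_trace$curve$training_size < n_pool))
  # final model predicts its own training pool near-perfectly
  expect_gt(trace$curve$pool_mcc_full[nrow(trace$curve)], 0.99)

  expect_identical(run_active_learning(ds, split, cfg)$curve, trace$curve)
})

test_that("importance tracking follows the iterations", {
  cohort <- generate_dataset(separable_config(), seed = 8)
  ds <- build_ifp_datasets(cohort)$ifp85
  split <- stratified_split(ds$labels, 0.2, seed = 2)
  trace <- run_active_learning(
    ds, split, al_config("entropy", seed = 3, record_importances = TRUE))
  expect_equal(dim(trace$importances),
               c(85L, nrow(trace$curve)))
  expect_equal(unname(colSums(trace$importances)),
               rep(1, nrow(trace$curve)), tolerance = 1e-6)
  expect_equal(as.integer(colnames(trace$importances)),
               trace$curve$training_size)
})

test_that("trial aggregation and difference curves do their arithmetic", {
  mk <- function(mccs) {
    structure(list(curve = data.frame(
      iteration = seq_along(mccs), training_size = c(3, 13, 23),
      test_mcc = mccs, test_ba = mccs, pool_mcc_remaining = mccs,
      pool_mcc_full = mccs),
      config = al_config(seed = 1)), class = "al_trace")
  }
  same <- aggregate_trials(replicate(6, mk(c(0.1, 0.5, 0.9)),
                                     simplify = FALSE))
  expect_equal(same$test_mcc_sd, rep(0, 3))
  two <- aggregate_trials(list(mk(c(0.4, 0.4, 0.4)), mk(c(0.6, 0.6, 0.6))))
  expect_equal(two$test_mcc_mean, rep(0.5, 3))

  dc0 <- difference_curve(same, same)
  expect_equal(dc0$curve$difference, rep(0, 3))
  expect_equal(dc0$peak_value, 0)
  e <- aggregate_trials(list(mk(c(0.2, 0.5, 0.6))))
  r <- aggregate_trials(list(mk(c(0.2, 0.3, 0.6))))
  dc <- difference_curve(e, r)
  expect_equal(dc$peak_value, 0.2)
  expect_equal(dc$peak_training_size, 13)
  bad <- e; bad$training_size <- c(3, 13, 33)
  expect_error(difference_curve(bad, r), "grid")
})

test_that("the experiment design yields paired trials per strategy", {
  cohort <- generate_dataset(separable_config(), seed = 2)
  ds <- build_ifp_datasets(cohort)$ifp85
  ex <- run_al_experiment(ds, n_splits = 2L, n_executions = 3L,
                          test_fraction = 0.2, base_seed = 4,
                          max_iterations = 2L)
  expect_named(ex, c("entropy", "random"))
  expect_length(ex$entropy, 6L)
  expect_length(ex$random, 6L)
  # paired by seed: the initial three instances agree across strategies
  for (k in 1:6) {
    expect_identical(ex$entropy[[k]]$selected_ids[[1]],
                     ex$random[[k]]$selected_ids[[1]])
  }
})
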