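#' t-SNE embedding of a precomputed Tanimoto distance matrix
#'
#' Delegates the Kullback-Leibler-minimizing embedding to the Rtsne
#' implementation, configured for precomputed distances, two output
#' dimensions, and a fixed seed (random initialization). Perplexity
#' defaults to 30; embeddings are robust to moderate perplexity changes.
#'
#' @param dmat symmetric, finite distance matrix (e.g. from
#'   [distance_matrix()]).
#' @param perplexity t-SNE perplexity; must satisfy
#'   `3 * perplexity < n - 1`.
#' @param seed integer seed.
#' @param labels optional binding-mode labels carried into the result.
#' @param max_iter gradient-descent iterations (default 1000).
#' @return object of class `embedding2d`: list with `coordinates`
#'   (n x 2 matrix), `inhibitor_ids`, `labels`, `perplexity`, `seed`.
#' @export
tsne_embed <- function(dmat, perplexity = 30, seed = 1L, labels = NULL,
                       max_iter = 1000L) {
  if (!is.matrix(dmat) || nrow(dmat) != ncol(dmat)) {
    stop("dmat must be a square distance matrix")
  }
  if (any(!is.finite(dmat))) stop("dmat contains non-finite entries")
  if (max(abs(dmat - t(dmat))) > 1e-8) stop("dmat is not symmetric")
  n <- nrow(dmat)
  if (perplexity <= 0 || 3 * perplexity >= n - 1) {
    stop("perplexity must be positive with 3 * perplexity < n - 1")
  }
  ids <- rownames(dmat) %||% sprintf("inh_%04d", seq_len(n))
  fit <- with_seed(seed, {
    Rtsne::Rtsne(stats::as.dist(dmat), perplexity = perplexity, dims = 2L,
                 is_distance = TRUE, max_iter = as.integer(max_iter),
                 check_duplicates = FALSE, pca = FALSE, num_threads = 1L)
  })
  coords <- fit$Y
  dimnames(coords) <- list(ids, c("x", "y"))
  structure(
    list(coordinates = coords, inhibitor_ids = ids,
         labels = if (!is.null(labels)) binding_mode_factor(labels) else NULL,
         perplexity = perplexity, seed = as.integer(seed)),
    class = "embedding2d"
  )
}

#' Mean silhouette of an embedding with respect to class labels
#'
#' Quantitative proxy for how clearly a 2D embedding clusters by
#' binding mode: the mean silhouette width of the embedded points under
#' Euclidean distance, grouped by true label.
#'
#' @param embedding `embedding2d` with labels, or an n x 2 matrix.
#' @param labels labels (required when `embedding` is a matrix).
#' @return mean silhouette width in `[-1, 1]`.
#' @export
embedding_silhouette <- function(embedding, labels = NULL) {
  if (inherits(embedding, "embedding2d")) {
    labels <- labels %||% embedding$labels
    coords <- embedding$coordinates
  } else {
    coords <- embedding
  }
  if (is.null(labels)) stop("labels are required")
  sil <- cluster::silhouette(as.integer(factor(labels)), stats::dist(coords))
  mean(sil[, "sil_width"])
}

# fixed class colors used across all figures
binding_mode_colors <- c("I" = "#1f77b4", "I1/2" = "#ff7f0e", "II" = "#2ca02c")

#' Benchmark boxplot
#'
#' MCC and BA distributions across trials per representation.
#'
#' @param df tidy benchmark data frame(s) as produced by
#'   [as.data.frame.benchmark_result()] (rows with `class == "all"` are
#'   shown); multiple representations may be row-bound.
#' @return ggplot object.
#' @export
plot_benchmark <- function(df) {
  df <- df[df$class == "all", , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$representation,
                                   y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "value",
                  title = "Test-set performance across trials") +
    ggplot2::theme_bw()
}

#' Permutation-null histogram
#'
#' @param result `permutation_test_result`.
#' @return ggplot object: null MCC distribution, dashed line at 0, solid
#'   line at the observed MCC.
#' @export
plot_permutation <- function(result) {
  df <- data.frame(mcc = result$null_mccs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mcc)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = result$observed_mcc, colour = "#d62728") +
    ggplot2::labs(x = "MCC (shuffled labels)", y = "models",
                  title = sprintf("Permutation test (p = %.4g)",
                                  result$p_value)) +
    ggplot2::theme_bw()
}

#' Learning-curve plot
#'
#' @param agg_list named list (by strategy or representation) of
#'   [aggregate_trials()] outputs.
#' @param metric curve metric (default `"test_mcc"`).
#' @return ggplot object with mean curves and +-1 SD ribbons.
#' @export
plot_learning_curves <- function(agg_list, metric = "test_mcc") {
  df <- do.call(rbind, lapply(names(agg_list), function(nm) {
    a <- agg_list[[nm]]
    data.frame(series = nm, training_size = a$training_size,
               mean = a[[paste0(metric, "_mean")]],
               sd = a[[paste0(metric, "_sd")]])
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$training_size, y = .data$mean,
                                   colour = .data$series,
                                   fill = .data$series)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "training set size", y = metric,
                  title = "Active learning performance") +
    ggplot2::theme_bw()
}

#' Difference-curve plot
#'
#' @param curves named list (by representation) of `difference_curve`
#'   objects.
#' @return ggplot object.
#' @export
plot_difference_curves <- function(curves) {
  df <- do.call(rbind, lapply(names(curves), function(nm) {
    cv <- curves[[nm]]$curve
    data.frame(series = nm, training_size = cv$training_size,
               difference = cv$difference, sd = cv$sd)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$training_size,
                                   y = .data$difference,
                                   colour = .data$series,
                                   fill = .data$series)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$difference - .data$sd,
                                      ymax = .data$difference + .data$sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "training set size", y = "MCC (entropy - random)",
                  title = "Entropy-based versus random selection") +
    ggplot2::theme_bw()
}

#' Feature-importance heatmap over active-learning iterations
#'
#' @param trace importance matrix (features x iterations) or an
#'   `al_trace` with recorded importances.
#' @param fraction_of_max show only features whose median importance is
#'   at least this fraction of the maximum median (default 0.1).
#' @return ggplot tile plot.
#' @export
plot_importance_heatmap <- function(trace, fraction_of_max = 0.1) {
  if (inherits(trace, "al_trace")) trace <- trace$importances
  keep <- filter_by_median_importance(trace, fraction_of_max)
  m <- trace[keep, , drop = FALSE]
  df <- data.frame(
    feature = factor(rep(rownames(m), times = ncol(m)), levels = rownames(m)),
    training_size = rep(as.integer(colnames(m)), each = nrow(m)),
    importance = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$training_size),
                                   y = .data$feature,
                                   fill = .data$importance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "training set size", y = NULL,
                  title = "Feature importance across iterations") +
    ggplot2::theme_bw()
}

#' Embedding scatter plot
#'
#' @param embedding `embedding2d` with labels.
#' @return ggplot object with the fixed class colors (I blue,
#'   I1/2 orange, II green).
#' @export
plot_embedding <- function(embedding) {
  stopifnot(inherits(embedding, "embedding2d"))
  df <- data.frame(x = embedding$coordinates[, 1],
                   y = embedding$coordinates[, 2],
                   mode = embedding$labels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$mode)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::scale_colour_manual(values = binding_mode_colors) +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2", colour = "type",
                  title = "Fingerprint space (t-SNE, Tanimoto distance)") +
    ggplot2::theme_bw()
}

# the result files render_report() understands, with their figure
report_inputs <- c(
  benchmark = "benchmark.tsv",
  permutation = "permutation.tsv",
  learning_curves = "learning_curves.tsv",
  difference_curves = "difference_curves.tsv",
  embedding = "embedding.tsv"
)

#' Render figures and a machine-readable summary from result files
#'
#' Reads whichever of the known result TSVs are present in
#' `results_dir`, writes one figure per experiment into `output_dir`,
#' and a `summary.json` with recomputed headline statistics (benchmark
#' medians per representation/metric, permutation p-value, difference
#' peaks). Re-running on the same inputs reproduces the summary exactly.
#'
#' Expected files (any subset, but at least one):
#' `benchmark.tsv` (trial, representation, metric, class, value),
#' `permutation.tsv` (observed_mcc, p_value, then one `null_mcc` row per
#' model), `learning_curves.tsv` (series, training_size, mean, sd,
#' metric), `difference_curves.tsv` (series, training_size, difference,
#' sd), `embedding.tsv` (inhibitor_id, x, y, label).
#'
#' @param results_dir directory of result TSVs.
#' @param output_dir directory for figures and `summary.json`.
#' @param device figure device, `"png"` or `"pdf"`.
#' @return path to `summary.json`, invisibly.
#' @export
render_report <- function(results_dir, output_dir = results_dir,
                          device = c("png", "pdf")) {
  device <- match.arg(device)
  present <- file.path(results_dir, report_inputs)
  names(present) <- names(report_inputs)
  have <- stats::setNames(file.exists(present), names(present))
  if (!any(have)) {
    stop("no result files found in ", results_dir, "; expected one of: ",
         paste(report_inputs, collapse = ", "))
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list()
  save_fig <- function(p, name, width = 7, height = 5) {
    ggplot2::ggsave(file.path(output_dir, paste0(name, ".", device)), p,
                    width = width, height = height, dpi = 150)
  }
  if (have[["benchmark"]]) {
    df <- utils::read.delim(present[["benchmark"]])
    save_fig(plot_benchmark(df), "benchmark")
    glob <- df[df$class == "all", ]
    med <- stats::aggregate(value ~ representation + metric, glob,
                            stats::median)
    summary$benchmark_medians <- med
  }
  if (have[["permutation"]]) {
    df <- utils::read.delim(present[["permutation"]])
    res <- structure(list(observed_mcc = df$observed_mcc[[1]],
                          null_mccs = df$null_mcc,
                          p_value = df$p_value[[1]],
                          n_perm = length(df$null_mcc)),
                     class = "permutation_test_result")
    save_fig(plot_permutation(res), "permutation")
    summary$permutation <- list(observed_mcc = res$observed_mcc,
                                p_value = res$p_value,
                                null_median = stats::median(res$null_mccs))
  }
  if (have[["learning_curves"]]) {
    df <- utils::read.delim(present[["learning_curves"]])
    agg_list <- lapply(split(df, df$series), function(g) {
      out <- data.frame(training_size = g$training_size)
      out[[paste0(g$metric[[1]], "_mean")]] <- g$mean
      out[[paste0(g$metric[[1]], "_sd")]] <- g$sd
      out
    })
    save_fig(plot_learning_curves(agg_list, metric = df$metric[[1]]),
             "learning_curves")
  }
  if (have[["difference_curves"]]) {
    df <- utils::read.delim(present[["difference_curves"]])
    curves <- lapply(split(df, df$series), function(g) {
      peak_at <- which.max(g$difference)
      structure(list(curve = data.frame(training_size = g$training_size,
                                        difference = g$difference,
                                        sd = g$sd),
                     peak_value = g$difference[[peak_at]],
                     peak_training_size = g$training_size[[peak_at]],
                     metric = "test_mcc"),
                class = "difference_curve")
    })
    save_fig(plot_difference_curves(curves), "difference_curves")
    summary$difference_peaks <- lapply(curves, function(cv) {
      list(peak_value = cv$peak_value,
           peak_training_size = cv$peak_training_size)
    })
  }
  if (have[["embedding"]]) {
    df <- utils::read.delim(present[["embedding"]])
    emb <- structure(list(coordinates = cbind(x = df$x, y = df$y),
                          inhibitor_ids = df$inhibitor_id,
                          labels = binding_mode_factor(df$label)),
                     class = "embedding2d")
    save_fig(plot_embedding(emb), "embedding")
    summary$embedding_silhouette <- embedding_silhouette(emb)
  }
  out <- file.path(output_dir, "summary.json")
  jsonlite::write_json(summary, out, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(out)
}
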