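#' Binary Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' When any factor of the denominator is zero the coefficient is
#' undefined and 0 is returned (documented convention: a degenerate
#' confusion table carries no evidence of association).
#'
#' @param tp,tn,fp,fn non-negative integer counts.
#' @return MCC in `[-1, 1]`.
#' @export
binary_mcc <- function(tp, tn, fp, fn) {
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  # compute in double: the products overflow integers for large cohorts
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' Binary balanced accuracy
#'
#' `BA = (TP/(TP+FN) + TN/(TN+FP)) / 2`: the mean of sensitivity and
#' specificity, robust to class imbalance.
#'
#' @inheritParams binary_mcc
#' @return BA in `[0, 1]`.
#' @export
balanced_accuracy <- function(tp, tn, fp, fn) {
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  if (tp + fn == 0 || tn + fp == 0) {
    stop("balanced accuracy undefined: a class has no evaluated instances")
  }
  (tp / (tp + fn) + tn / (tn + fp)) / 2
}

#' Multi-class Matthews correlation coefficient
#'
#' Gorodkin's \eqn{R_K} statistic on the k x k contingency table of true
#' versus predicted labels; it reduces to the binary MCC for k = 2.
#' Degenerate tables (constant truth or constant prediction) return 0.
#'
#' @param y_true,y_pred equal-length label vectors (character or factor).
#' @return multi-class MCC in `[-1, 1]`.
#' @export
multiclass_mcc <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("label vectors differ in length")
  lev <- union(levels(factor(y_true)), levels(factor(y_pred)))
  ct <- table(factor(y_true, levels = lev), factor(y_pred, levels = lev))
  s <- sum(ct)
  c_corr <- sum(diag(ct))
  t_k <- rowSums(ct)  # true-class totals
  p_k <- colSums(ct)  # predicted-class totals
  cov_xy <- c_corr * s - sum(as.numeric(t_k) * p_k)
  cov_xx <- s^2 - sum(as.numeric(p_k)^2)
  cov_yy <- s^2 - sum(as.numeric(t_k)^2)
  if (cov_xx == 0 || cov_yy == 0) return(0)
  cov_xy / sqrt(cov_xx * cov_yy)
}

#' Multi-class balanced accuracy (macro-averaged recall)
#'
#' Mean of per-class recall over the classes present in `y_true`.
#'
#' @inheritParams multiclass_mcc
#' @return BA in `[0, 1]`.
#' @export
macro_balanced_accuracy <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("label vectors differ in length")
  if (length(y_true) == 0L) stop("empty test set")
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  classes <- unique(y_true)
  mean(vapply(classes, function(cl) {
    mean(y_pred[y_true == cl] == cl)
  }, numeric(1)))
}

#' Per-class one-vs-rest evaluation
#'
#' Each binding mode present is binarized against the rest and scored
#' with [binary_mcc()] and [balanced_accuracy()]. Classes absent from
#' `y_true` are reported as `NA` with a warning.
#'
#' @inheritParams multiclass_mcc
#' @param classes classes to evaluate (default [BINDING_MODES]).
#' @return data frame with columns `class`, `mcc`, `ba`.
#' @export
per_class_evaluation <- function(y_true, y_pred, classes = BINDING_MODES) {
  if (length(y_true) != length(y_pred)) stop("label vectors differ in length")
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  rows <- lapply(classes, function(cl) {
    if (!any(y_true == cl)) {
      warning("class ", cl, " absent from y_true; per-class metrics undefined")
      return(data.frame(class = cl, mcc = NA_real_, ba = NA_real_))
    }
    tp <- sum(y_true == cl & y_pred == cl)
    tn <- sum(y_true != cl & y_pred != cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    ba <- if (tn + fp == 0) NA_real_ else balanced_accuracy(tp, tn, fp, fn)
    data.frame(class = cl, mcc = binary_mcc(tp, tn, fp, fn), ba = ba)
  })
  do.call(rbind, rows)
}

#' Shannon entropy of a predicted class distribution
#'
#' `H = -sum_i p_i log2 p_i` in bits, with `0 * log2(0)` taken as 0.
#' Used to quantify model uncertainty for pool-based instance selection.
#'
#' @param p probability vector (non-negative, sums to 1 within 1e-9).
#' @return entropy in bits, in `[0, log2(length(p))]`.
#' @export
shannon_entropy <- function(p) {
  if (any(p < 0)) stop("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-9) stop("probabilities must sum to 1")
  p <- p[p > 0]
  -sum(p * log2(p))
}

# entropy of each row of a probability matrix (vectorized)
row_entropies <- function(probs) {
  logp <- ifelse(probs > 0, log2(pmax(probs, .Machine$double.xmin)), 0)
  -rowSums(probs * logp)
}

#' Tanimoto distance between two binary fingerprints
#'
#' `1 - |a AND b| / |a OR b|` (Jaccard distance on the "on" bit sets).
#' Two all-zero fingerprints are assigned distance 0 (documented
#' convention: identical, featureless objects).
#'
#' @param a,b equal-length 0/1 vectors or `fingerprint` objects.
#' @return distance in `[0, 1]`.
#' @export
tanimoto_distance <- function(a, b) {
  if (inherits(a, "fingerprint")) a <- a$bits
  if (inherits(b, "fingerprint")) b <- b$bits
  if (length(a) != length(b)) stop("fingerprints differ in length")
  a <- as.logical(a)
  b <- as.logical(b)
  union_ <- sum(a | b)
  if (union_ == 0L) return(0)
  1 - sum(a & b) / union_
}

#' Pairwise Tanimoto distance matrix of a fingerprint dataset
#'
#' @param ds `fingerprint_dataset`.
#' @return symmetric n x n matrix with zero diagonal, entries in
#'   `[0, 1]`, dimnames set to inhibitor ids.
#' @export
distance_matrix <- function(ds) {
  stopifnot(inherits(ds, "fingerprint_dataset"))
  x <- ds$matrix
  if (nrow(x) == 0L) stop("empty dataset")
  storage.mode(x) <- "double"
  inter <- tcrossprod(x)
  pop <- rowSums(x)
  union_ <- outer(pop, pop, "+") - inter
  d <- 1 - inter / union_
  d[union_ == 0] <- 0  # pairs of all-zero fingerprints
  diag(d) <- 0
  d <- (d + t(d)) / 2  # enforce exact symmetry against rounding
  dimnames(d) <- list(ds$inhibitor_ids, ds$inhibitor_ids)
  d
}

#' Evaluate predictions globally and per class
#'
#' @inheritParams multiclass_mcc
#' @return object of class `evaluation_result`: list with `mcc`, `ba`,
#'   `per_class` (data frame), `n_test`.
#' @export
evaluate_predictions <- function(y_true, y_pred) {
  structure(
    list(
      mcc = multiclass_mcc(y_true, y_pred),
      ba = macro_balanced_accuracy(y_true, y_pred),
      per_class = per_class_evaluation(y_true, y_pred),
      n_test = length(y_true)
    ),
    class = "evaluation_result"
  )
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("MCC %.3f | BA %.3f | n = %d\n", x$mcc, x$ba, x$n_test))
  for (i in seq_len(nrow(x$per_class))) {
    cat(sprintf("  %-5s MCC %.3f BA %.3f\n", x$per_class$class[i],
                x$per_class$mcc[i], x$per_class$ba[i]))
  }
  invisible(x)
}
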