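#' Confusion matrix over the four classes
#'
#' @param y_true,y_pred Equal-length label vectors (A/I/U/E).
#' @param labels Label ordering; default [opi_labels()].
#' @return A `labels x labels` integer matrix (rows = true, columns =
#'   predicted) of class `opi_confusion`.
#' @export
#' @examples
#' confusion(c("A", "A", "I"), c("U", "A", "I"))
confusion <- function(y_true, y_pred, labels = opi_labels()) {
  y_true <- factor(as.character(y_true), levels = labels)
  y_pred <- factor(as.character(y_pred), levels = labels)
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred have different lengths (",
         length(y_true), " vs ", length(y_pred), ")")
  }
  if (length(y_true) == 0L) stop("no items to evaluate")
  if (anyNA(y_true) || anyNA(y_pred)) stop("labels outside ",
                                           paste(labels, collapse = "/"))
  cm <- table(true = y_true, predicted = y_pred)
  structure(unclass(cm), class = c("opi_confusion", "matrix"))
}

# tp/fp/fn per class from a confusion matrix
cm_counts <- function(cm) {
  tp <- diag(cm)
  list(tp = tp, fp = colSums(cm) - tp, fn = rowSums(cm) - tp)
}

#' Per-class precision and recall
#'
#' Precision for a class with no predicted items is undefined; it is
#' reported as 0 and flagged (`undefined_precision`), so tabulated reports
#' never divide by zero. Likewise recall for an absent true class.
#'
#' @param cm An [confusion()] matrix.
#' @return Data frame with columns `class`, `precision`, `recall`,
#'   `undefined_precision`, `undefined_recall`.
#' @export
per_class_metrics <- function(cm) {
  stopifnot(inherits(cm, "opi_confusion"))
  k <- cm_counts(cm)
  pden <- k$tp + k$fp
  rden <- k$tp + k$fn
  data.frame(
    class = rownames(cm),
    precision = ifelse(pden > 0, k$tp / pden, 0),
    recall = ifelse(rden > 0, k$tp / rden, 0),
    undefined_precision = pden == 0,
    undefined_recall = rden == 0,
    row.names = NULL)
}

#' Micro-averaged F1
#'
#' tp, fp and fn are pooled over classes before computing precision and
#' recall; the harmonic mean of the pooled values is the micro-averaged F1.
#' For single-label multiclass prediction this equals accuracy
#' (trace / total), a useful cross-check that holds for every confusion
#' matrix.
#'
#' @param cm An [confusion()] matrix.
#' @return Numeric scalar in `[0, 1]`.
#' @export
#' @examples
#' micro_f1(confusion(c("A", "I", "U"), c("A", "I", "A")))
micro_f1 <- function(cm) {
  stopifnot(inherits(cm, "opi_confusion"))
  total <- sum(cm)
  if (total < 1) stop("empty confusion matrix")
  k <- cm_counts(cm)
  p <- sum(k$tp) / (sum(k$tp) + sum(k$fp))
  r <- sum(k$tp) / (sum(k$tp) + sum(k$fn))
  if (p + r == 0) return(0)
  2 * p * r / (p + r)
}

#' Expected micro-F1 of a random baseline classifier
#'
#' For a classifier assigning label c at random with probability equal to
#' its prevalence p_c, expected accuracy (= micro-F1) is the sum of squared
#' prevalences. The uniform variant assigns each of the four labels with
#' probability 1/4 and has expected accuracy 1/4 regardless of prevalence.
#'
#' @param dist Named prevalence vector (see [class_distribution()]), must
#'   sum to 1.
#' @param mode `"prevalence"` (default) or `"uniform"`.
#' @return Numeric scalar.
#' @export
#' @examples
#' expected_random_micro_f1(c(A = 0.194, I = 0.222, U = 0.536, E = 0.047))
expected_random_micro_f1 <- function(dist, mode = c("prevalence", "uniform")) {
  mode <- match.arg(mode)
  dist <- as.numeric(dist)
  if (abs(sum(dist) - 1) > 1e-6) stop("prevalences must sum to 1")
  if (any(dist < 0)) stop("negative prevalence")
  if (mode == "uniform") return(1 / length(dist))
  sum(dist^2)
}

#' Percentile bootstrap confidence interval for a classification metric
#'
#' Resamples item indices with replacement `n_resamples` times, recomputes
#' the metric on each resample, and returns the percentile interval.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param metric Function of `(y_true, y_pred)` returning a scalar; default
#'   micro-F1.
#' @param n_resamples Number of bootstrap resamples (default 1000; fewer
#'   than 100 draws a warning).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed; the interval is deterministic given the seed.
#' @return Named numeric vector `c(low, high)`.
#' @export
bootstrap_ci <- function(y_true, y_pred,
                         metric = function(t, p) micro_f1(confusion(t, p)),
                         n_resamples = 1000, level = 0.95, seed = 1) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2)
  if (n_resamples < 100) warning("n_resamples < 100: interval will be noisy")
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  n <- length(y_true)
  set.seed(as.integer(seed))
  stats <- vapply(seq_len(n_resamples), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    metric(y_true[idx], y_pred[idx])
  }, numeric(1))
  alpha <- (1 - level) / 2
  q <- unname(quantile(stats, c(alpha, 1 - alpha), type = 7))
  c(low = q[1], high = q[2])
}

#' Cohen's kappa
#'
#' Chance-corrected agreement between two label vectors:
#' kappa = (p_o - p_e) / (1 - p_e), with expected agreement p_e from the
#' marginal products. When both raters are constant and identical
#' (p_e = 1), kappa is defined as 1.
#'
#' @param labels_1,labels_2 Equal-length label vectors (length >= 2).
#' @return Numeric scalar in `[-1, 1]`.
#' @export
#' @examples
#' cohen_kappa(c("A", "A", "I", "U"), c("A", "I", "I", "U"))
cohen_kappa <- function(labels_1, labels_2) {
  labels_1 <- as.character(labels_1); labels_2 <- as.character(labels_2)
  stopifnot(length(labels_1) == length(labels_2), length(labels_1) >= 2)
  lev <- sort(unique(c(labels_1, labels_2)))
  t1 <- factor(labels_1, levels = lev); t2 <- factor(labels_2, levels = lev)
  tab <- table(t1, t2)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < 1e-12) return(1.0)
  (po - pe) / (1 - pe)
}

#' Tabulated evaluation report for one or more systems
#'
#' One row per system: per-class precision, per-class recall, micro-F1 and
#' its bootstrap 95% CI — the conventional report layout for imbalanced
#' multiclass surveillance classifiers.
#'
#' @param y_true True labels.
#' @param preds Named list of predicted label vectors (one per system), or a
#'   single vector.
#' @param n_resamples Bootstrap resamples for the CI.
#' @param seed Seed for the bootstrap.
#' @return Data frame of class `opi_metric_report`.
#' @export
metric_report <- function(y_true, preds, n_resamples = 1000, seed = 1) {
  if (!is.list(preds)) preds <- list(system = preds)
  if (is.null(names(preds))) names(preds) <- paste0("system_", seq_along(preds))
  rows <- lapply(names(preds), function(nm) {
    y_pred <- preds[[nm]]
    cm <- confusion(y_true, y_pred)
    pc <- per_class_metrics(cm)
    f1 <- micro_f1(cm)
    ci <- bootstrap_ci(y_true, y_pred, n_resamples = n_resamples, seed = seed)
    out <- data.frame(system = nm, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(pc))) {
      out[[paste0("precision_", pc$class[i])]] <- pc$precision[i]
      out[[paste0("recall_", pc$class[i])]] <- pc$recall[i]
    }
    out$micro_f1 <- f1
    out$ci_low <- ci[["low"]]
    out$ci_high <- ci[["high"]]
    out
  })
  structure(do.call(rbind, rows),
            class = c("opi_metric_report", "data.frame"))
}

#' @export
print.opi_metric_report <- function(x, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, 3)
  print(y, row.names = FALSE)
  invisible(x)
}
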