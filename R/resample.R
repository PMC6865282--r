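#' Class-imbalance resampling
#'
#' Rebalances a labeled feature matrix before training. `random_under`
#' shrinks the majority class U (without replacement) to the size of the
#' largest non-U class. `random_over` duplicates rows (with replacement) of
#' the content-rich minority classes A and I up to the size of U. `smote`
#' raises A and I to the size of U with synthetic rows interpolated between
#' a class member and one of its `smote_k` nearest same-class neighbours
#' (Euclidean). Original rows are never altered: undersampling only removes
#' rows, oversampling and SMOTE only append, and retained rows keep their
#' input order.
#'
#' @param x Feature matrix (`dgCMatrix` or dense), rows = posts.
#' @param y Labels aligned with `x`.
#' @param strategy `"random_under"`, `"random_over"` or `"smote"`.
#' @param seed Integer seed.
#' @param smote_k Neighbourhood size for SMOTE; every targeted class must
#'   have more than `smote_k` members.
#' @param majority_class,minority_classes The shrunk / grown classes.
#' @return List with resampled `x` and `y` (factor).
#' @export
resample_data <- function(x, y,
                          strategy = c("random_under", "random_over", "smote"),
                          seed = 1, smote_k = 5,
                          majority_class = "U",
                          minority_classes = c("A", "I")) {
  strategy <- match.arg(strategy)
  y <- as_label_factor(y)
  stopifnot(nrow(x) == length(y))
  set.seed(as.integer(seed))
  sizes <- table(y)

  if (strategy == "random_under") {
    target <- max(sizes[setdiff(names(sizes), majority_class)])
    u_idx <- which(y == majority_class)
    if (length(u_idx) <= target) return(list(x = x, y = y))
    drop <- sample(u_idx, length(u_idx) - target)
    keep <- setdiff(seq_along(y), drop)
    return(list(x = x[keep, , drop = FALSE], y = y[keep]))
  }

  target <- sizes[[majority_class]]
  add_i <- integer(0)
  synth <- NULL
  synth_y <- character(0)
  for (cl in minority_classes) {
    idx <- which(y == cl)
    need <- target - length(idx)
    if (need <= 0 || length(idx) == 0L) next  # absent class: nothing to grow
    if (strategy == "random_over") {
      add_i <- c(add_i, sample(idx, need, replace = TRUE))
    } else {
      if (length(idx) <= smote_k) {
        stop("smote: class ", cl, " has ", length(idx),
             " members, need more than smote_k = ", smote_k)
      }
      nn <- smote_neighbours(x[idx, , drop = FALSE], smote_k)
      a_loc <- sample(seq_along(idx), need, replace = TRUE)
      b_loc <- vapply(a_loc, function(a) nn[a, sample.int(smote_k, 1)],
                      integer(1))
      lam <- runif(need)
      xa <- x[idx[a_loc], , drop = FALSE]
      xb <- x[idx[b_loc], , drop = FALSE]
      new_rows <- xa * (1 - lam) + xb * lam
      synth <- if (is.null(synth)) new_rows else rbind2(synth, new_rows)
      synth_y <- c(synth_y, rep(cl, need))
    }
  }

  if (strategy == "random_over") {
    x2 <- rbind2(x, x[add_i, , drop = FALSE])
    y2 <- factor(c(as.character(y), as.character(y[add_i])),
                 levels = levels(y))
  } else {
    x2 <- if (is.null(synth)) x else rbind2(x, synth)
    y2 <- factor(c(as.character(y), synth_y), levels = levels(y))
  }
  list(x = x2, y = y2)
}

# k nearest same-class neighbours by Euclidean distance (self excluded);
# returns an n x k matrix of within-class row indices
smote_neighbours <- function(xc, k) {
  n <- nrow(xc)
  g <- as.matrix(Matrix::tcrossprod(xc))
  nr <- diag(g)
  d2 <- outer(nr, nr, "+") - 2 * g
  diag(d2) <- Inf
  t(apply(d2, 1L, function(r) order(r)[seq_len(k)]))
}
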