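#' Classifier specification
#'
#' Declares one classifier run: the family, its hyperparameters, the
#' resampling strategy applied to the training data, and the seed fixed
#' before any stochastic step. Defaults per family:
#' \describe{
#'   \item{naive_bayes}{multinomial with Laplace `alpha = 1`}
#'   \item{decision_tree}{CART/Gini, `max_depth = 20`, `min_node = 5`,
#'     `max_dense_features = 400`}
#'   \item{knn}{cosine similarity, `k = 5`}
#'   \item{random_forest}{`n_trees = 50`, `mtry = floor(sqrt(p))`,
#'     `max_depth = 25`, `min_node = 2`, `max_dense_features = 400`}
#'   \item{svm}{linear one-vs-rest, hinge loss with L2 penalty
#'     `lambda = 1e-4`, `epochs = 20`, `batch = 64`}
#'   \item{cnn}{embedding dim `d = 50`, filter widths `c(3, 4, 5)`,
#'     `n_filters = 32`, `max_len = 32`, Adam `lr = 1e-3`,
#'     `epochs = 8`, `batch = 128`, early stopping patience 2}
#' }
#'
#' @param family One of `"naive_bayes"`, `"decision_tree"`, `"knn"`,
#'   `"random_forest"`, `"svm"`, `"cnn"`.
#' @param hyper Named list overriding the family defaults above.
#' @param resampling `"none"`, `"random_under"`, `"random_over"` or
#'   `"smote"`.
#' @param seed Integer seed.
#' @return An object of class `opi_classifier_spec`.
#' @export
classifier_spec <- function(family = c("naive_bayes", "decision_tree", "knn",
                                       "random_forest", "svm", "cnn"),
                            hyper = list(), resampling = c("none",
                                                           "random_under",
                                                           "random_over",
                                                           "smote"),
                            seed = 1L) {
  family <- match.arg(family)
  resampling <- match.arg(resampling)
  defaults <- switch(family,
    naive_bayes = list(alpha = 1),
    decision_tree = list(max_depth = 20L, min_node = 5L,
                         max_dense_features = 400L),
    knn = list(k = 5L),
    random_forest = list(n_trees = 50L, mtry = NULL, max_depth = 25L,
                         min_node = 2L, max_dense_features = 400L),
    svm = list(lambda = 1e-4, epochs = 20L, batch = 64L),
    cnn = list(d = 50L, widths = c(3L, 4L, 5L), n_filters = 32L,
               max_len = 32L, lr = 1e-3, epochs = 8L, batch = 128L,
               patience = 2L))
  unknown <- setdiff(names(hyper), names(defaults))
  if (length(unknown)) {
    stop("hyperparameter(s) not used by family ", family, ": ",
         paste(unknown, collapse = ", "))
  }
  defaults[names(hyper)] <- hyper
  structure(list(family = family, hyper = defaults, resampling = resampling,
                 seed = as.integer(seed)),
            class = "opi_classifier_spec")
}

#' Train a classifier
#'
#' Applies the spec's resampling strategy to the training data (never to
#' validation or test data), fixes the spec's seed, and fits the requested
#' family. Training is deterministic given the spec.
#'
#' @param spec A [classifier_spec()].
#' @param x Features: a sparse/dense numeric matrix for the traditional
#'   families, or an integer id-sequence matrix (see [to_id_sequence()])
#'   for `"cnn"`.
#' @param y Training labels (A/I/U/E), at least two classes.
#' @param x_val,y_val Optional validation data; used by the CNN for early
#'   stopping (ignored by the other families).
#' @return An object of class `opi_model` with a [predict_labels()] method.
#' @export
train_classifier <- function(spec, x, y, x_val = NULL, y_val = NULL) {
  stopifnot(inherits(spec, "opi_classifier_spec"))
  y <- as_label_factor(y)
  if (nrow(x) != length(y)) stop("features and labels are not aligned (",
                                 nrow(x), " rows vs ", length(y), " labels)")
  if (length(unique(as.character(y))) < 2L) {
    stop("training labels contain a single class; need at least 2")
  }
  if (spec$resampling != "none") {
    rs <- resample_data(x, y, spec$resampling, seed = spec$seed)
    x <- rs$x; y <- rs$y
  }
  set.seed(spec$seed)
  fit <- switch(spec$family,
    naive_bayes = fit_nb(x, y, spec$hyper),
    decision_tree = fit_tree(x, y, spec$hyper),
    knn = fit_knn(x, y, spec$hyper),
    random_forest = fit_forest(x, y, spec$hyper),
    svm = fit_svm(x, y, spec$hyper),
    cnn = fit_cnn(x, y, spec$hyper, x_val, y_val))
  structure(list(family = spec$family, spec = spec, fit = fit,
                 levels = levels(y)), class = "opi_model")
}

#' Predict class labels
#'
#' @param model An [train_classifier()] model.
#' @param x Features in the same representation used at training time.
#' @return Factor of predicted labels (levels A/I/U/E), one per row.
#' @export
predict_labels <- function(model, x) {
  stopifnot(inherits(model, "opi_model"))
  idx <- switch(model$family,
    naive_bayes = predict_nb(model$fit, x),
    decision_tree = predict_tree_model(model$fit, x),
    knn = predict_knn(model$fit, x),
    random_forest = predict_forest(model$fit, x),
    svm = predict_svm(model$fit, x),
    cnn = predict_cnn(model$fit, x))
  factor(model$levels[idx], levels = opi_labels())
}

#' @export
print.opi_model <- function(x, ...) {
  cat(sprintf("<opi_model> family = %s, resampling = %s, seed = %d\n",
              x$family, x$spec$resampling, x$spec$seed))
  invisible(x)
}

# --- multinomial naive Bayes ---------------------------------------------

fit_nb <- function(x, y, h) {
  x <- methods::as(x, "CsparseMatrix")
  classes <- levels(droplevels(y))
  ind <- Matrix::sparseMatrix(i = as.integer(factor(y, levels = classes)),
                              j = seq_along(y), x = 1,
                              dims = c(length(classes), length(y)))
  cs <- as.matrix(ind %*% x)              # class x feature counts
  tot <- rowSums(cs)
  log_theta <- log(cs + h$alpha) - log(tot + h$alpha * ncol(x))
  prior <- log(as.numeric(table(factor(y, levels = classes))) / length(y))
  list(classes = classes, log_theta = log_theta, prior = prior)
}

predict_nb <- function(fit, x) {
  x <- methods::as(x, "CsparseMatrix")
  scores <- as.matrix(x %*% t(fit$log_theta))
  scores <- sweep(scores, 2L, fit$prior, "+")
  cl <- max.col(scores, ties.method = "first")
  match(fit$classes[cl], opi_labels())
}

# --- linear SVM (one-vs-rest, hinge + L2, mini-batch subgradient) --------

fit_svm <- function(x, y, h) {
  x <- methods::as(x, "CsparseMatrix")
  classes <- levels(droplevels(y))
  n <- nrow(x); p <- ncol(x); K <- length(classes)
  yi <- as.integer(factor(y, levels = classes))
  Ysign <- matrix(-1, n, K)
  Ysign[cbind(seq_len(n), yi)] <- 1

  W <- matrix(0, p, K)
  b <- numeric(K)
  t_step <- 0
  for (ep in seq_len(h$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = h$batch)
    for (s in starts) {
      idx <- ord[s:min(s + h$batch - 1L, n)]
      B <- length(idx)
      t_step <- t_step + 1
      eta <- 1 / (h$lambda * (t_step + 100))
      Xb <- x[idx, , drop = FALSE]
      S <- as.matrix(Xb %*% W)
      S <- sweep(S, 2L, b, "+")
      Yb <- Ysign[idx, , drop = FALSE]
      viol <- (Yb * S) < 1
      G <- -(Yb * viol) / B
      W <- W * (1 - eta * h$lambda) - eta * as.matrix(Matrix::crossprod(Xb, G))
      b <- b - eta * colSums(G)
    }
  }
  list(classes = classes, W = W, b = b)
}

predict_svm <- function(fit, x) {
  x <- methods::as(x, "CsparseMatrix")
  S <- sweep(as.matrix(x %*% fit$W), 2L, fit$b, "+")
  cl <- max.col(S, ties.method = "first")
  match(fit$classes[cl], opi_labels())
}

# --- cosine k-nearest neighbours -----------------------------------------

l2_normalize <- function(x) {
  x <- methods::as(x, "CsparseMatrix")
  nrm <- sqrt(Matrix::rowSums(x^2))
  nrm[nrm == 0] <- 1
  Matrix::Diagonal(x = 1 / nrm) %*% x
}

fit_knn <- function(x, y, h) {
  list(x = l2_normalize(x), y = as.integer(factor(y, levels = opi_labels())),
       k = h$k)
}

predict_knn <- function(fit, x) {
  xq <- l2_normalize(x)
  n <- nrow(xq)
  out <- integer(n)
  k <- min(fit$k, nrow(fit$x))
  block <- max(1L, floor(2e7 / nrow(fit$x)))
  for (s in seq(1L, n, by = block)) {
    e <- min(s + block - 1L, n)
    sim <- as.matrix(xq[s:e, , drop = FALSE] %*% Matrix::t(fit$x))
    for (i in seq_len(e - s + 1L)) {
      nb <- order(sim[i, ], decreasing = TRUE)[seq_len(k)]
      vote <- fit$y[nb]
      # majority; ties broken by total similarity then label order
      tab <- tapply(sim[i, nb], vote, sum)
      cnt <- table(vote)
      cand <- as.integer(names(cnt)[cnt == max(cnt)])
      if (length(cand) > 1L) {
        cand <- cand[order(-tab[as.character(cand)], cand)]
      }
      out[s + i - 1L] <- cand[1L]
    }
  }
  out
}

# --- decision tree / random forest (Rcpp CART core) ----------------------

# pick the densest columns so trees work on a manageable dense matrix
dense_select <- function(x, max_cols) {
  df <- Matrix::colSums(x != 0)
  sel <- order(df, decreasing = TRUE)[seq_len(min(max_cols, ncol(x)))]
  sort(sel)
}

fit_tree <- function(x, y, h) {
  sel <- dense_select(x, h$max_dense_features)
  xd <- as.matrix(x[, sel, drop = FALSE])
  yi <- as.integer(factor(y, levels = opi_labels())) - 1L
  tree <- .cpp_grow_tree(xd, yi, seq_len(nrow(xd)) - 1L, 4L,
                         ncol(xd), h$max_depth, h$min_node)
  list(tree = tree, sel = sel)
}

predict_tree_model <- function(fit, x) {
  xd <- as.matrix(x[, fit$sel, drop = FALSE])
  .cpp_predict_tree(fit$tree, xd) + 1L
}

fit_forest <- function(x, y, h) {
  sel <- dense_select(x, h$max_dense_features)
  xd <- as.matrix(x[, sel, drop = FALSE])
  yi <- as.integer(factor(y, levels = opi_labels())) - 1L
  n <- nrow(xd)
  mtry <- h$mtry %||% max(1L, floor(sqrt(ncol(xd))))
  trees <- lapply(seq_len(h$n_trees), function(t) {
    boot <- sample.int(n, n, replace = TRUE) - 1L
    .cpp_grow_tree(xd, yi, boot, 4L, mtry, h$max_depth, h$min_node)
  })
  list(trees = trees, sel = sel)
}

predict_forest <- function(fit, x) {
  xd <- as.matrix(x[, fit$sel, drop = FALSE])
  votes <- vapply(fit$trees, function(tr) .cpp_predict_tree(tr, xd) + 1L,
                  integer(nrow(xd)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1L)
  apply(votes, 1L, function(v) {
    cnt <- tabulate(v, nbins = 4L)
    which.max(cnt)  # ties broken toward the earlier label, deterministic
  })
}

#' Grid search by k-fold cross-validation
#'
#' Evaluates every hyperparameter combination of `grid` by k-fold
#' cross-validated micro-F1 on `(x, y)` (conventionally the pooled training
#' + validation data) and returns the spec refitted with the best
#' combination.
#'
#' @param spec A [classifier_spec()]; `grid` entries override its `hyper`.
#' @param x,y Features and labels.
#' @param grid Named list of hyperparameter value vectors, crossed.
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold assignment.
#' @return List: `spec` (best), `results` (data frame of mean micro-F1 per
#'   combination).
#' @export
tune_spec <- function(spec, x, y, grid, k = 10, seed = 1) {
  stopifnot(inherits(spec, "opi_classifier_spec"), length(grid) >= 1)
  y <- as_label_factor(y)
  combos <- expand.grid(grid, stringsAsFactors = FALSE)
  set.seed(as.integer(seed))
  fold <- sample(rep_len(seq_len(k), length(y)))
  scores <- numeric(nrow(combos))
  for (ci in seq_len(nrow(combos))) {
    h <- spec$hyper
    h[names(combos)] <- lapply(combos[ci, , drop = FALSE], identity)
    sp <- classifier_spec(spec$family, hyper = h,
                          resampling = spec$resampling, seed = spec$seed)
    f1 <- vapply(seq_len(k), function(f) {
      tr <- fold != f
      if (length(unique(as.character(y[tr]))) < 2L) return(NA_real_)
      m <- train_classifier(sp, x[tr, , drop = FALSE], y[tr])
      pred <- predict_labels(m, x[!tr, , drop = FALSE])
      micro_f1(confusion(y[!tr], pred))
    }, numeric(1))
    scores[ci] <- mean(f1, na.rm = TRUE)
  }
  best <- which.max(scores)
  h <- spec$hyper
  h[names(combos)] <- lapply(combos[best, , drop = FALSE], identity)
  list(spec = classifier_spec(spec$family, hyper = h,
                              resampling = spec$resampling, seed = spec$seed),
       results = cbind(combos, micro_f1 = scores))
}
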