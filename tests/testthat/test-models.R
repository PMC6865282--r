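# shared small synthetic split for the classifier tests
make_split <- function(n = 1200, separability = 0.9, seed = 42) {
  co <- gen_corpus(generator_config(n_posts = n, separability = separability,
                                    seed = seed))
  split_corpus(co, c(0.7, 0.1, 0.2), seed = seed)
}

featurize <- function(sp, n_clusters = 0) {
  toks <- preprocess(sp$train$text)
  space <- fit_feature_space(toks, n_clusters = n_clusters)
  list(space = space,
       x_tr = extract_features(toks, space),
       x_te = extract_features(preprocess(sp$test$text), space))
}

test_that("every traditional family separates a linearly separable toy corpus", {
  # class A posts contain token "aa", class U posts "uu"
  n <- 120
  df <- as_corpus(data.frame(
    id = as.character(1:n),
    text = rep(c("aa filler words", "uu other stuff"), n / 2),
    label = rep(c("A", "U"), n / 2)))
  toks <- preprocess(df$text)
  space <- fit_feature_space(toks, min_count = 1, n_clusters = 0)
  x <- extract_features(toks, space)
  for (fam in c("naive_bayes", "decision_tree", "knn", "random_forest",
                "svm")) {
    m <- train_classifier(classifier_spec(fam, seed = 3), x, df$label)
    acc <- mean(predict_labels(m, x) == df$label)
    expect_identical(acc, 1, info = fam)
  }
})

test_that("the CNN separates the toy corpus too", {
  n <- 200
  df <- as_corpus(data.frame(
    id = as.character(1:n),
    text = rep(c("aa bb cc dd ee", "uu vv ww xx yy"), n / 2),
    label = rep(c("A", "U"), n / 2)))
  toks <- preprocess(df$text, stem = FALSE)
  space <- fit_feature_space(toks, min_count = 1, n_clusters = 0)
  ids <- to_id_sequence(toks, space, 8)
  m <- train_classifier(classifier_spec("cnn", hyper = list(epochs = 4),
                                        seed = 3), ids, df$label)
  expect_identical(mean(predict_labels(m, ids) == df$label), 1)
})

test_that("training is deterministic given the spec seed", {
  sp <- make_split(600)
  fz <- featurize(sp)
  for (fam in c("random_forest", "svm")) {
    m1 <- train_classifier(classifier_spec(fam, seed = 11), fz$x_tr,
                           sp$train$label)
    m2 <- train_classifier(classifier_spec(fam, seed = 11), fz$x_tr,
                           sp$train$label)
    expect_identical(predict_labels(m1, fz$x_te), predict_labels(m2, fz$x_te),
                     info = fam)
  }
  ids <- to_id_sequence(preprocess(sp$train$text, stem = FALSE), fz$space, 16)
  m1 <- train_classifier(classifier_spec("cnn", hyper = list(epochs = 2),
                                         seed = 11), ids, sp$train$label)
  m2 <- train_classifier(classifier_spec("cnn", hyper = list(epochs = 2),
                                         seed = 11), ids, sp$train$label)
  expect_identical(predict_labels(m1, ids), predict_labels(m2, ids))
})

test_that("classifiers beat the prevalence-random baseline at default separability", {
  co <- gen_corpus(generator_config(n_posts = 1500, seed = 7))
  sp <- split_corpus(co, c(0.7, 0.1, 0.2), seed = 7)
  fz <- featurize(sp)
  baseline <- expected_random_micro_f1(class_distribution(co))
  for (fam in c("naive_bayes", "svm")) {
    m <- train_classifier(classifier_spec(fam, seed = 1), fz$x_tr,
                          sp$train$label)
    f1 <- micro_f1(confusion(sp$test$label, predict_labels(m, fz$x_te)))
    expect_gt(f1, baseline)
  }
})

test_that("single-class training and misaligned inputs error", {
  sp <- make_split(300)
  fz <- featurize(sp)
  y1 <- factor(rep("U", nrow(fz$x_tr)), levels = opi_labels())
  expect_error(train_classifier(classifier_spec("naive_bayes"), fz$x_tr, y1),
               "single class")
  expect_error(train_classifier(classifier_spec("naive_bayes"),
                                fz$x_tr[1:10, ], sp$train$label),
               "not aligned")
  expect_error(classifier_spec("svm", hyper = list(bogus = 1)), "bogus")
})

test_that("resampling strategies meet their size contracts", {
  set.seed(1)
  x <- Matrix::Matrix(matrix(rnorm(32 * 6), 32, 6), sparse = TRUE)
  y <- c(rep("A", 5), rep("I", 5), rep("U", 20), rep("E", 2))
  ru <- resample_data(x, y, "random_under", seed = 2)
  expect_identical(as.integer(table(ru$y)[c("A", "I", "U", "E")]),
                   c(5L, 5L, 5L, 2L))

  y2 <- c(rep("A", 5), rep("I", 8), rep("U", 20), rep("E", 2))
  x2 <- Matrix::Matrix(matrix(rnorm(35 * 6), 35, 6), sparse = TRUE)
  for (strat in c("random_over", "smote")) {
    rs <- resample_data(x2, y2, strat, seed = 2, smote_k = 3)
    expect_identical(as.integer(table(rs$y)[c("A", "I", "U", "E")]),
                     c(20L, 20L, 20L, 2L), info = strat)
    # originals untouched, appended rows only
    expect_equal(rs$x[seq_len(35), ], x2)
  }
  expect_error(resample_data(x2, y2, "smote", seed = 1, smote_k = 5),
               "class A")
})

test_that("SMOTE rows lie on segments between a member and a k-nearest neighbour", {
  set.seed(8)
  x <- Matrix::Matrix(matrix(rnorm(10 * 4), 10, 4), sparse = TRUE)
  y <- c(rep("A", 6), rep("U", 4))
  # target: raise A to |U| is not triggered (A is larger), so force growth
  # by treating U as majority and A as minority with more U rows
  y2 <- c(rep("A", 4), rep("U", 6))
  rs <- resample_data(x, y2, "smote", seed = 5, smote_k = 2)
  xa <- as.matrix(x[1:4, ])
  synth <- as.matrix(rs$x[seq(nrow(x) + 1, nrow(rs$x)), , drop = FALSE])
  # exhaustive check: each synthetic row is (1-l)a + l b with b among the
  # 2 nearest same-class neighbours of a
  d <- as.matrix(dist(xa))
  diag(d) <- Inf
  for (r in seq_len(nrow(synth))) {
    ok <- FALSE
    for (a in seq_len(4)) {
      for (b in order(d[a, ])[1:2]) {
        dir <- xa[b, ] - xa[a, ]
        rel <- synth[r, ] - xa[a, ]
        lam <- if (sum(dir^2) > 0) sum(rel * dir) / sum(dir^2) else 0
        if (lam >= -1e-9 && lam <= 1 + 1e-9 &&
            sqrt(sum((rel - lam * dir)^2)) < 1e-8) ok <- TRUE
      }
    }
    expect_true(ok, info = paste("synthetic row", r))
  }
})

test_that("tune_spec picks a hyperparameter by cross-validated micro-F1", {
  sp <- make_split(400, seed = 21)
  fz <- featurize(sp)
  tuned <- tune_spec(classifier_spec("knn"), fz$x_tr, sp$train$label,
                     grid = list(k = c(1L, 5L)), k = 3, seed = 5)
  expect_s3_class(tuned$spec, "opi_classifier_spec")
  expect_true(tuned$spec$hyper$k %in% c(1L, 5L))
  expect_identical(nrow(tuned$results), 2L)
  expect_true(all(is.finite(tuned$results$micro_f1)))
})
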