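test_that("gen_corpus hits the configured prevalences within sampling error", {
  cfg <- generator_config(n_posts = 10000, seed = 5)
  co <- gen_corpus(cfg)
  d <- class_distribution(co)
  for (cl in opi_labels()) {
    p <- cfg$prevalences[[cl]]
    se <- sqrt(p * (1 - p) / 10000)
    expect_lt(abs(d[[cl]] - p), 2.5 * se)
  }
})

test_that("generation is fully deterministic given the config", {
  cfg <- generator_config(n_posts = 300, seed = 123)
  expect_identical(gen_corpus(cfg), gen_corpus(cfg))
  tr <- c(a = 0.1, b = 0.3, c = 0.2, d = 0.5)
  expect_identical(gen_reference_metrics(tr, 0.5, seed = 9),
                   gen_reference_metrics(tr, 0.5, seed = 9))
})

test_that("region assignment skews toward populous regions", {
  cfg <- generator_config(n_posts = 8000, region_skew = 0.5, seed = 6)
  co <- gen_corpus(cfg)
  counts <- table(factor(co$region_id, levels = cfg$regions$region_id))
  top10 <- sum(counts[1:10]) / sum(counts)     # regions are ordered by size
  pop10 <- sum(cfg$regions$population[1:10]) / sum(cfg$regions$population)
  expect_gt(top10, pop10)  # strictly more concentrated than population share
})

test_that("timestamps cover the configured month range", {
  cfg <- generator_config(n_posts = 2000, months = c("2013-02", "2013-07"),
                          seed = 2)
  co <- gen_corpus(cfg)
  mo <- format(co$timestamp, "%Y-%m", tz = "UTC")
  expect_true(all(mo >= "2013-02" & mo <= "2013-07"))
  expect_identical(length(unique(mo)), 6L)
})

test_that("abuse/information posts carry (possibly misspelled) drug tokens", {
  lex <- default_lexicon(max_variants = 6)
  cfg <- generator_config(n_posts = 600, separability = 1,
                          misspell_rate = 0.3, seed = 8)
  co <- gen_corpus(cfg)
  ai <- co[co$label %in% c("A", "I"), ]
  hit <- vapply(ai$text, function(tx) length(match_post(tx, lex)) > 0,
                logical(1))
  # nearly every A/I post is retrievable by the expanded lexicon
  expect_gt(mean(hit), 0.9)
  # and misspellings do occur
  drugs <- c("oxycodone", "oxycontin", "percocet", "fentanyl", "heroin")
  toks <- unlist(preprocess(ai$text, stem = FALSE))
  exact <- sum(toks %in% drugs)
  variant_only <- sum(!(toks %in% drugs) &
                        vapply(toks, function(t) {
                          any(vapply(drugs, function(d) {
                            nchar(t) >= 3 && dl_distance(d, t) == 1
                          }, logical(1)))
                        }, logical(1)))
  expect_gt(variant_only, 0)
  expect_gt(exact, variant_only)  # misspell_rate < 0.5
})

test_that("fully separable corpora are nearly perfectly classifiable", {
  co <- gen_corpus(generator_config(n_posts = 1500, separability = 1,
                                    misspell_rate = 0, seed = 31))
  sp <- split_corpus(co, c(0.7, 0.1, 0.2), seed = 31)
  toks <- preprocess(sp$train$text)
  space <- fit_feature_space(toks, ngram = c(1, 1), n_clusters = 0)
  m <- train_classifier(classifier_spec("naive_bayes", seed = 1),
                        extract_features(toks, space), sp$train$label)
  pr <- predict_labels(m, extract_features(preprocess(sp$test$text), space))
  expect_gt(micro_f1(confusion(sp$test$label, pr)), 0.95)
})

test_that("no-signal corpora yield uninformative predictions (kappa ~ 0)", {
  co <- gen_corpus(generator_config(n_posts = 2500, separability = 0,
                                    seed = 19))
  sp <- split_corpus(co, c(0.7, 0.1, 0.2), seed = 19)
  toks <- preprocess(sp$train$text)
  space <- fit_feature_space(toks, n_clusters = 0)
  x_tr <- extract_features(toks, space)
  x_te <- extract_features(preprocess(sp$test$text), space)
  for (fam in c("naive_bayes", "decision_tree", "knn", "svm")) {
    m <- train_classifier(classifier_spec(fam, seed = 4), x_tr,
                          sp$train$label)
    pr <- predict_labels(m, x_te)
    expect_lt(abs(cohen_kappa(as.character(sp$test$label),
                              as.character(pr))), 0.1)
  }
})

test_that("gen_reference_metrics realizes the target correlation", {
  tr <- setNames(runif(67), sprintf("R%02d", 1:67))
  # noiseless limit
  m1 <- gen_reference_metrics(tr, 1, noise_sd = 0, seed = 1)
  expect_equal(cor(tr, m1$metric_value), 1)
  # null: |r| within 2/sqrt(n)
  m0 <- gen_reference_metrics(tr, 0, seed = 2)
  expect_lt(abs(cor(tr, m0$metric_value)), 2 / sqrt(67))
  # Monte-Carlo mean near 0.45 across replicate seeds
  rs <- vapply(1:200, function(s) {
    cor(tr, gen_reference_metrics(tr, 0.45, seed = s)$metric_value)
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.45), 0.03)
  expect_error(gen_reference_metrics(setNames(rep(1, 5), letters[1:5]), 0.5),
               "zero variance")
})

test_that("generator configs validate their inputs", {
  expect_error(generator_config(n_posts = 0), "n_posts")
  expect_error(generator_config(prevalences = c(A = 1, I = 1, U = 0, E = 0)))
  expect_error(generator_config(separability = 1.2))
  expect_error(generator_config(target_rho = 1.5))
})
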