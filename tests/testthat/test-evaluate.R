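test_that("confusion matrices match a brute-force tally", {
  cm <- confusion(c("A", "A", "I"), c("U", "A", "I"))
  expect_identical(cm["A", "A"], 1L)
  expect_identical(cm["A", "U"], 1L)
  k <- list(tp = diag(cm), fp = colSums(cm) - diag(cm),
            fn = rowSums(cm) - diag(cm))
  expect_equal(unname(k$fn["A"]), 1)
  expect_equal(unname(k$fp["U"]), 1)

  set.seed(31)
  for (rep in 1:5) {
    yt <- sample(opi_labels(), 50, replace = TRUE)
    yp <- sample(opi_labels(), 50, replace = TRUE)
    expect_equal(unclass(confusion(yt, yp)), oracle_confusion(yt, yp),
                 ignore_attr = TRUE)
  }
  expect_error(confusion(c("A", "I"), "A"), "different lengths")
})

test_that("per-class precision/recall equal brute-force tallies, with 0-flagging", {
  set.seed(12)
  yt <- sample(opi_labels(), 80, replace = TRUE, prob = c(.3, .3, .35, .05))
  yp <- sample(c("A", "I", "U"), 80, replace = TRUE)  # E never predicted
  pc <- per_class_metrics(confusion(yt, yp))
  for (cl in opi_labels()) {
    tp <- sum(yt == cl & yp == cl)
    prec <- if (sum(yp == cl) > 0) tp / sum(yp == cl) else 0
    rec <- if (sum(yt == cl) > 0) tp / sum(yt == cl) else 0
    row <- pc[pc$class == cl, ]
    expect_equal(row$precision, prec)
    expect_equal(row$recall, rec)
  }
  expect_true(pc$undefined_precision[pc$class == "E"])
})

test_that("micro-F1 equals accuracy on random confusion matrices", {
  yt <- yp <- rep(opi_labels(), 3)
  expect_identical(micro_f1(confusion(yt, yp)), 1)
  expect_equal(micro_f1(confusion(rep("A", 10),
                                  c(rep("A", 6), rep("U", 4)))), 0.6)
  set.seed(2)
  for (rep in 1:100) {
    yt <- sample(opi_labels(), 30, replace = TRUE)
    yp <- sample(opi_labels(), 30, replace = TRUE)
    cm <- confusion(yt, yp)
    expect_equal(micro_f1(cm), sum(diag(cm)) / sum(cm), tolerance = 1e-12)
  }
})

test_that("micro-F1 is invariant to relabeling the classes", {
  set.seed(3)
  yt <- sample(opi_labels(), 60, replace = TRUE)
  yp <- sample(opi_labels(), 60, replace = TRUE)
  f1 <- micro_f1(confusion(yt, yp))
  perm <- setNames(c("I", "U", "E", "A"), opi_labels())
  expect_equal(micro_f1(confusion(perm[yt], perm[yp])), f1)
})

test_that("the prevalence-random baseline follows the sum of squared prevalences", {
  expect_equal(expected_random_micro_f1(rep(0.25, 4)), 0.25)
  expect_equal(expected_random_micro_f1(c(1, 0, 0, 0)), 1)
  p <- c(A = 0.194, I = 0.222, U = 0.536, E = 0.047) / 0.999
  expect_equal(expected_random_micro_f1(p), sum(p^2))
  expect_equal(expected_random_micro_f1(p, mode = "uniform"), 0.25)
  # Monte-Carlo cross-check of the closed form
  set.seed(44)
  yt <- sample(opi_labels(), 2e5, replace = TRUE, prob = p)
  yp <- sample(opi_labels(), 2e5, replace = TRUE, prob = p)
  expect_equal(mean(yt == yp), sum(p^2), tolerance = 0.01)
})

test_that("bootstrap_ci is deterministic, degenerate-safe and covers the estimate", {
  yt <- rep(opi_labels(), 10)
  ci <- bootstrap_ci(yt, yt, n_resamples = 200, seed = 5)
  expect_identical(unname(ci), c(1, 1))

  set.seed(9)
  yp <- ifelse(runif(40) < 0.75, yt, sample(opi_labels(), 40, replace = TRUE))
  ci1 <- bootstrap_ci(yt, yp, n_resamples = 300, seed = 7)
  ci2 <- bootstrap_ci(yt, yp, n_resamples = 300, seed = 7)
  expect_identical(ci1, ci2)
  f1 <- micro_f1(confusion(yt, yp))
  expect_lte(ci1[["low"]], f1)
  expect_gte(ci1[["high"]], f1)
  expect_warning(bootstrap_ci(yt, yp, n_resamples = 50, seed = 1), "noisy")
})

test_that("cohen_kappa matches hand computation and behaves at the limits", {
  expect_identical(cohen_kappa(rep(c("A", "I"), 10), rep(c("A", "I"), 10)), 1)
  # 2x2 agreement table ((20,5),(10,15)): p_o = 0.70, p_e = 0.50, kappa 0.40
  r1 <- c(rep("A", 25), rep("I", 25))
  r2 <- c(rep("A", 20), rep("I", 5), rep("A", 10), rep("I", 15))
  expect_equal(cohen_kappa(r1, r2), 0.4)
  # constant identical raters: defined as 1
  expect_identical(cohen_kappa(rep("U", 5), rep("U", 5)), 1)
  # independent raters converge to 0
  set.seed(10)
  a <- sample(opi_labels(), 1e4, replace = TRUE)
  b <- sample(opi_labels(), 1e4, replace = TRUE)
  expect_lt(abs(cohen_kappa(a, b)), 0.05)
})

test_that("metric_report mirrors the tabular layout", {
  set.seed(13)
  yt <- sample(opi_labels(), 60, replace = TRUE)
  preds <- list(sys1 = yt,
                sys2 = sample(opi_labels(), 60, replace = TRUE))
  rep_ <- metric_report(yt, preds, n_resamples = 100, seed = 3)
  expect_identical(rep_$system, c("sys1", "sys2"))
  expect_true(all(c("precision_A", "recall_E", "micro_f1", "ci_low",
                    "ci_high") %in% names(rep_)))
  expect_identical(rep_$micro_f1[1], 1)
  expect_true(all(rep_$ci_low <= rep_$micro_f1 + 1e-9))
})
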