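make_geo_corpus <- function() {
  as_corpus(data.frame(
    id = as.character(1:6),
    text = rep("x y", 6),
    timestamp = c("2014-01-05", "2014-01-20", "2014-01-29",
                  "2014-03-02", "2014-03-15", "2014-03-30"),
    region_id = c("r1", "r1", "r2", "r1", "r2", "r2"),
    label = c("A", "I", "U", "U", "A", "U")))
}

test_that("monthly_series counts, proportions and flags empty months", {
  ms <- monthly_series(make_geo_corpus())
  expect_identical(ms$month, c("2014-01", "2014-02", "2014-03"))
  expect_identical(ms$frequency_A, c(1L, 0L, 1L))
  expect_equal(ms$proportion_A, c(1 / 3, NA, 1 / 3))
  expect_identical(ms$empty, c(FALSE, TRUE, FALSE))
  # class frequencies sum to the monthly total
  ms_all <- monthly_series(make_geo_corpus(), classes = opi_labels())
  freq <- as.matrix(ms_all[, paste0("frequency_", opi_labels())])
  expect_identical(unname(rowSums(freq)), as.numeric(ms_all$total))
})

test_that("monthly series recovers a generator-set abuse proportion", {
  cfg <- generator_config(n_posts = 6000,
                          prevalences = c(A = 0.05, I = 0.25, U = 0.65,
                                          E = 0.05), seed = 17)
  ms <- monthly_series(gen_corpus(cfg))
  p_hat <- sum(ms$frequency_A) / sum(ms$total)
  se <- sqrt(0.05 * 0.95 / sum(ms$total))
  expect_lt(abs(p_hat - 0.05), 2 * se)
})

test_that("region_rates matches hand tallies in both modes", {
  co <- make_geo_corpus()
  rr <- region_rates(co)
  expect_identical(rr$n_posts, c(3L, 3L))
  expect_identical(rr$n_abuse, c(1L, 1L))
  expect_equal(rr$abuse_rate, c(1 / 3, 1 / 3))
  # conservation: abuse posts are neither created nor lost by aggregation
  expect_identical(sum(rr$n_abuse), sum(co$label == "A"))

  rc <- region_rates(co, populations = c(r1 = 50000, r2 = 20000),
                     mode = "per_capita")
  expect_equal(rc$abuse_rate, c(1 / 50000 * 1e5, 1 / 20000 * 1e5))
  expect_error(region_rates(co, populations = c(r1 = 50000),
                            mode = "per_capita"), "r2")
  # a population-only region appears with zero posts, flagged
  r3 <- region_rates(co, populations = c(r1 = 1, r2 = 1, r9 = 1))
  expect_true(r3$empty[r3$region_id == "r9"])
})

test_that("correlate matches closed forms and the stats oracle", {
  r <- correlate(1:10, 2 * (1:10) + 1)
  expect_equal(r$pearson_r, 1)
  expect_equal(r$spearman_rho, 1)

  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 6)
  r2 <- correlate(x, y)
  # independent oracle: stats::cor.test
  ct_p <- cor.test(x, y)
  ct_s <- suppressWarnings(cor.test(x, y, method = "spearman",
                                    exact = FALSE))
  expect_equal(r2$pearson_r, unname(ct_p$estimate))
  expect_equal(r2$p_pearson, ct_p$p.value)
  expect_equal(r2$spearman_rho, unname(ct_s$estimate))
  expect_equal(r2$p_spearman, ct_s$p.value, tolerance = 1e-6)

  # symmetry and degenerate flagging
  r3 <- correlate(y, x)
  expect_equal(r3$pearson_r, r2$pearson_r)
  expect_equal(r3$spearman_rho, r2$spearman_rho)
  expect_true(correlate(rep(1, 5), 1:5)$degenerate)
  expect_error(correlate(1:2, 1:2), "n >= 3")
  expect_error(correlate(c(1, NA, 3), 1:3), "finite")
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(21)
  x <- rnorm(40); y <- rnorm(40)
  base <- correlate(x, y)$spearman_rho
  expect_equal(correlate(exp(x), y)$spearman_rho, base)
  expect_equal(correlate(x, y^3 + 5 * y)$spearman_rho, base)
})

test_that("threshold_filter retains high-death regions and errors when empty", {
  tb <- structure(data.frame(region_id = paste0("r", 1:5),
                             n_posts = 10L, n_abuse = 2L,
                             population = 1e5,
                             abuse_rate = runif(5), empty = FALSE),
                  class = c("opi_region_rates", "data.frame"))
  tb <- attach_reference(tb, data.frame(region_id = paste0("r", 1:5),
                                        metric_value = rnorm(5),
                                        death_count = c(10, 60, 120, 40, 200)))
  expect_identical(nrow(threshold_filter(tb, 0)), 5L)
  expect_identical(nrow(threshold_filter(tb, 50)), 3L)
  expect_error(threshold_filter(tb, 1000), "every region")
})

test_that("correlation rises with the death threshold under heteroscedastic noise", {
  # stated world: populous regions have many deaths and less noisy
  # reference rates; noise sd scales as 1/sqrt(deaths)
  set.seed(33)
  reps <- 30
  diffs <- replicate(reps, {
    n <- 60
    deaths <- round(exp(runif(n, log(20), log(400))))
    true_rate <- rnorm(n)
    metric <- true_rate + rnorm(n, sd = 6 / sqrt(deaths))
    tb <- structure(data.frame(region_id = as.character(1:n), n_posts = 1L,
                               n_abuse = 0L, population = 1,
                               abuse_rate = true_rate, empty = FALSE),
                    class = c("opi_region_rates", "data.frame"))
    tb <- attach_reference(tb, data.frame(region_id = as.character(1:n),
                                          metric_value = metric,
                                          death_count = deaths))
    r_all <- correlate(tb$abuse_rate, tb$reference_metric)$pearson_r
    t100 <- threshold_filter(tb, 100)
    r_100 <- correlate(t100$abuse_rate, t100$reference_metric)$pearson_r
    r_100 - r_all
  })
  # direction check: thresholding improves the correlation on average
  expect_gt(mean(diffs > 0), 0.8)
})

test_that("rate_bins produces the expected quantile shading", {
  b <- rate_bins(c(1:10, NA), n = 5)
  expect_identical(b[1:2], c(1L, 1L))
  expect_identical(b[9:10], c(5L, 5L))
  expect_true(is.na(b[11]))
})
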