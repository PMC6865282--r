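#' Default synthetic region table
#'
#' A deterministic table of `n` regions with Zipf-like populations
#' (largest about 1.5 million, heavy right skew), emulating the population
#' structure of a US state's counties. Used as the default `regions` of
#' [generator_config()].
#'
#' @param n Number of regions (default 67).
#' @return Data frame with `region_id`, `population`.
#' @export
default_regions <- function(n = 67) {
  stopifnot(is_count(n), n >= 1)
  rank <- seq_len(n)
  pop <- round(1.55e6 * rank^-0.95)
  data.frame(region_id = sprintf("R%02d", rank), population = pop,
             stringsAsFactors = FALSE)
}

# token pools for the generator: a shared Zipf background plus
# class-discriminative pools. Class E uses a disjoint pseudo-alphabet in
# place of a real second language; class A and I pools carry drug-name
# tokens so lexicon retrieval and the abuse-term feature have signal.
synth_vocab <- function() {
  drugs <- c("oxycodone", "oxycontin", "percocet", "vicodin", "hydrocodone",
             "codeine", "tramadol", "morphine", "methadone", "suboxone",
             "fentanyl", "dilaudid", "opana", "roxicodone", "heroin", "oxys",
             "percs")
  abuse <- c("high", "snort", "snorting", "popped", "popping", "craving",
             "withdrawal", "hooked", "nodding", "buzz", "faded", "railed",
             "crushed", "score", "fix", "blasted")
  info <- c("epidemic", "crisis", "overdose", "deaths", "awareness", "study",
            "article", "report", "naloxone", "treatment", "recovery",
            "prevention", "addiction", "prescribing", "policy", "news")
  unrel <- c("game", "weather", "music", "movie", "dinner", "coffee",
             "traffic", "weekend", "school", "football", "party", "birthday",
             "vacation", "photo", "concert", "shopping")
  background <- sprintf("w%03d", 1:300)
  e_alpha <- sprintf("zq%02dx", 1:40)
  list(drugs = drugs,
       profiles = list(A = c(drugs, abuse), I = c(drugs, info), U = unrel,
                       E = e_alpha),
       background = background)
}

#' Configuration for the synthetic corpus generator
#'
#' The defaults encode the corpus structure the pipeline is built for:
#' class prevalences A 19.4%, I 22.2%, U 53.6%, E 4.7%; bag-of-token texts
#' of 5-25 tokens; drug-name tokens in abuse/information posts, misspelled
#' at `misspell_rate` with the same edit operations as [expand_variants()];
#' posts concentrated in populous regions (probability proportional to
#' population^(1 + `region_skew`)); timestamps uniform over a three-year
#' monthly window; and a reference health metric correlated with the true
#' regional abuse rates at `target_rho`.
#'
#' @param n_posts Number of posts.
#' @param prevalences Named prevalence vector over A/I/U/E, summing to 1
#'   (small rounding slack is renormalized). The default is the exact
#'   19.4/22.2/53.6/4.7 percent mix expressed as count fractions.
#' @param separability Probability in `[0, 1]` that each token is drawn
#'   from the class profile rather than the shared background; 0 = no
#'   class signal at all, 1 = fully class-specific text.
#' @param misspell_rate Probability a drug-name token is perturbed.
#' @param regions Data frame `region_id`, `population`.
#' @param region_skew Concentration exponent (>= 0) of posts in
#'   high-population regions.
#' @param months Character length-2, first and last month `"YYYY-MM"`.
#' @param target_rho Desired correlation of the generated reference metric
#'   with true region abuse rates, `|target_rho| <= 1`.
#' @param noise_sd Scale of the reference-metric noise.
#' @param seed Integer seed; the whole bundle is deterministic given the
#'   config.
#' @return List of class `opi_generator_config`.
#' @export
generator_config <- function(n_posts = 10000,
                             prevalences = c(A = 1748, I = 2001,
                                             U = 4830, E = 427) / 9006,
                             separability = 0.8, misspell_rate = 0.1,
                             regions = default_regions(), region_skew = 0.3,
                             months = c("2012-01", "2014-12"),
                             target_rho = 0.45, noise_sd = 1, seed = 1) {
  stopifnot(is_count(n_posts), n_posts >= 1)
  stopifnot(abs(sum(prevalences) - 1) < 1e-3, all(prevalences >= 0))
  stopifnot(setequal(names(prevalences), opi_labels()))
  prevalences <- prevalences / sum(prevalences)
  stopifnot(separability >= 0, separability <= 1)
  stopifnot(misspell_rate >= 0, misspell_rate <= 1)
  stopifnot(is.data.frame(regions), nrow(regions) >= 1,
            all(c("region_id", "population") %in% names(regions)))
  stopifnot(region_skew >= 0, abs(target_rho) <= 1, noise_sd >= 0)
  structure(list(n_posts = n_posts,
                 prevalences = prevalences[opi_labels()],
                 separability = separability, misspell_rate = misspell_rate,
                 regions = regions, region_skew = region_skew,
                 months = months, target_rho = target_rho,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "opi_generator_config")
}

#' Generate a labeled synthetic corpus
#'
#' @param config A [generator_config()].
#' @return A corpus data frame (see [as_corpus()]) with gold labels.
#' @export
#' @examples
#' co <- gen_corpus(generator_config(n_posts = 100, seed = 7))
#' table(co$label)
gen_corpus <- function(config) {
  stopifnot(inherits(config, "opi_generator_config"))
  vocab <- synth_vocab()
  n <- config$n_posts
  set.seed(config$seed)

  labels <- sample(opi_labels(), n, replace = TRUE,
                   prob = config$prevalences)
  w <- config$regions$population^(1 + config$region_skew)
  region <- sample(config$regions$region_id, n, replace = TRUE, prob = w)

  t0 <- as.POSIXct(paste0(config$months[1], "-01 00:00:00"), tz = "UTC")
  t1 <- seq(as.POSIXct(paste0(config$months[2], "-01 00:00:00"), tz = "UTC"),
            by = "month", length.out = 2)[2]
  ts <- t0 + runif(n) * as.numeric(difftime(t1, t0, units = "secs"))

  # precompute misspelling variant sets of the drug tokens
  variants <- lapply(setNames(nm = vocab$drugs), function(dr) {
    setdiff(expand_variants(dr, 6), dr)
  })
  # Zipf weights for the background pool
  bg_w <- (seq_along(vocab$background))^-1

  len <- sample(5:25, n, replace = TRUE)
  post_of_token <- rep.int(seq_len(n), len)
  total <- sum(len)
  from_profile <- runif(total) < config$separability
  token <- character(total)
  if (any(!from_profile)) {
    token[!from_profile] <- sample(vocab$background, sum(!from_profile),
                                   replace = TRUE, prob = bg_w)
  }
  lab_of_token <- labels[post_of_token]
  for (cl in opi_labels()) {
    pick <- from_profile & lab_of_token == cl
    if (any(pick)) {
      token[pick] <- sample(vocab$profiles[[cl]], sum(pick), replace = TRUE)
    }
  }
  # misspell drug-name tokens
  if (config$misspell_rate > 0) {
    is_drug <- token %in% vocab$drugs
    flip <- is_drug & runif(total) < config$misspell_rate
    if (any(flip)) {
      token[flip] <- vapply(token[flip], function(dr) {
        v <- variants[[dr]]
        if (length(v)) sample(v, 1) else dr
      }, character(1), USE.NAMES = FALSE)
    }
  }
  texts <- vapply(split(token, factor(post_of_token, levels = seq_len(n))),
                  paste, character(1), collapse = " ")

  as_corpus(data.frame(id = sprintf("p%06d", seq_len(n)), text = unname(texts),
                       timestamp = ts, region_id = region, label = labels,
                       stringsAsFactors = FALSE))
}

#' Generate a reference health metric correlated with true abuse rates
#'
#' The metric is `a * standardized(true_rates) + e` with
#' `a = target_rho / sqrt(1 - target_rho^2) * noise_sd` and
#' `e ~ N(0, noise_sd^2)`, so the population correlation with the true
#' rates is exactly `target_rho` for any noise scale (at `|target_rho| = 1`
#' the metric is the standardized rates with no noise).
#'
#' @param true_rates Named numeric vector (region -> true abuse rate),
#'   at least 3 regions, non-constant.
#' @param target_rho Desired population correlation, `|target_rho| <= 1`.
#' @param noise_sd Noise scale (> 0 unless `|target_rho| = 1`).
#' @param seed Integer seed.
#' @return Data frame `region_id`, `metric_value`.
#' @export
gen_reference_metrics <- function(true_rates, target_rho, noise_sd = 1,
                                  seed = 1) {
  stopifnot(length(true_rates) >= 3, !is.null(names(true_rates)))
  stopifnot(abs(target_rho) <= 1, noise_sd >= 0)
  if (sd(true_rates) == 0) stop("true_rates have zero variance")
  z <- (true_rates - mean(true_rates)) / sd(true_rates)
  set.seed(as.integer(seed))
  if (abs(target_rho) == 1) {
    metric <- sign(target_rho) * z
  } else {
    if (noise_sd == 0) stop("noise_sd must be > 0 when |target_rho| < 1")
    a <- target_rho / sqrt(1 - target_rho^2) * noise_sd
    metric <- a * z + rnorm(length(z), sd = noise_sd)
  }
  data.frame(region_id = names(true_rates), metric_value = unname(metric),
             stringsAsFactors = FALSE)
}
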