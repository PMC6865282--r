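#' Monthly class frequencies and proportions
#'
#' Buckets labeled posts by calendar month (UTC) and reports, for each
#' requested class, the count and its proportion of all posts that month.
#' Months inside the observed range with no posts appear with frequency 0
#' and an undefined (NA, flagged) proportion.
#'
#' @param posts A labeled corpus data frame with timestamps.
#' @param classes Classes to report (default A and I, the content-rich
#'   categories).
#' @return Data frame: `month` ("YYYY-MM", chronological), `total`,
#'   `frequency_<c>` and `proportion_<c>` per class, `empty` flag.
#' @export
monthly_series <- function(posts, classes = c("A", "I")) {
  posts <- as_corpus(posts)
  if (anyNA(posts$timestamp)) stop("monthly_series requires timestamps")
  if (anyNA(posts$label)) stop("monthly_series requires labeled posts")
  classes <- match.arg(classes, opi_labels(), several.ok = TRUE)

  mo <- format(posts$timestamp, "%Y-%m", tz = "UTC")
  first <- min(posts$timestamp); last <- max(posts$timestamp)
  all_months <- format(seq(as.Date(format(first, "%Y-%m-01", tz = "UTC")),
                           as.Date(format(last, "%Y-%m-01", tz = "UTC")),
                           by = "month"), "%Y-%m")
  total <- as.integer(table(factor(mo, levels = all_months)))
  out <- data.frame(month = all_months, total = total,
                    stringsAsFactors = FALSE)
  for (cl in classes) {
    f <- as.integer(table(factor(mo[posts$label == cl], levels = all_months)))
    out[[paste0("frequency_", cl)]] <- f
    out[[paste0("proportion_", cl)]] <- ifelse(total > 0, f / total, NA_real_)
  }
  out$empty <- total == 0L
  out
}

#' Region-level abuse-indicating post rates
#'
#' Aggregates labeled posts by region and computes the abuse-indicating post
#' rate either as a share of the region's opioid-related posts (`per_post`,
#' default — robust to differences in regional user-base size) or per
#' 100,000 population (`per_capita`).
#'
#' @param posts A labeled corpus data frame with region ids.
#' @param populations Named numeric vector region_id -> population
#'   (required for `per_capita`; optional otherwise).
#' @param mode `"per_post"` or `"per_capita"`.
#' @param abuse_class Label counted as abuse-indicating (default `"A"`).
#' @return Data frame of class `opi_region_rates`: `region_id`, `n_posts`,
#'   `n_abuse`, `population`, `abuse_rate`, `empty` flag. Regions present
#'   only in `populations` appear with zero posts and are flagged.
#' @export
region_rates <- function(posts, populations = NULL,
                         mode = c("per_post", "per_capita"),
                         abuse_class = "A") {
  posts <- as_corpus(posts)
  mode <- match.arg(mode)
  if (anyNA(posts$label)) stop("region_rates requires labeled posts")
  if (anyNA(posts$region_id)) stop("region_rates requires region ids")
  regions <- sort(unique(c(posts$region_id, names(populations))))
  if (mode == "per_capita") {
    if (is.null(populations)) stop("per_capita mode requires populations")
    unknown <- setdiff(unique(posts$region_id), names(populations))
    if (length(unknown)) {
      stop("region id(s) missing from populations: ",
           paste(unknown, collapse = ", "))
    }
    if (any(populations <= 0)) stop("populations must be positive")
  }
  rf <- factor(posts$region_id, levels = regions)
  n_posts <- as.integer(table(rf))
  n_abuse <- as.integer(table(rf[posts$label == abuse_class]))
  pop <- if (is.null(populations)) rep(NA_real_, length(regions)) else
    unname(populations[regions])
  rate <- if (mode == "per_post") {
    ifelse(n_posts > 0, n_abuse / n_posts, NA_real_)
  } else {
    n_abuse / pop * 1e5
  }
  structure(data.frame(region_id = regions, n_posts = n_posts,
                       n_abuse = n_abuse, population = pop,
                       abuse_rate = rate, empty = n_posts == 0L,
                       stringsAsFactors = FALSE),
            class = c("opi_region_rates", "data.frame"))
}

#' Attach a reference metric (and optional death counts) to a rate table
#'
#' @param table An [region_rates()] table.
#' @param metrics Data frame with `region_id` and `metric_value` columns and
#'   optionally `death_count`, or a named numeric vector.
#' @return The table with `reference_metric` (and `death_count`) columns.
#' @export
attach_reference <- function(table, metrics) {
  stopifnot(inherits(table, "opi_region_rates"))
  if (is.numeric(metrics) && !is.null(names(metrics))) {
    metrics <- data.frame(region_id = names(metrics),
                          metric_value = unname(metrics))
  }
  stopifnot(all(c("region_id", "metric_value") %in% names(metrics)))
  i <- match(table$region_id, metrics$region_id)
  table$reference_metric <- metrics$metric_value[i]
  if ("death_count" %in% names(metrics)) {
    table$death_count <- metrics$death_count[i]
  }
  table
}

#' Pearson and Spearman correlation with two-tailed p-values
#'
#' Pearson on the raw values, Spearman on average ranks; both p-values from
#' the t approximation with n - 2 degrees of freedom, two-tailed.
#'
#' @param x,y Equal-length finite numeric vectors, n >= 3.
#' @return List of class `opi_correlation`: `pearson_r`, `p_pearson`,
#'   `spearman_rho`, `p_spearman`, `n`, `degenerate` (TRUE with all
#'   statistics NA when either vector has zero variance).
#' @export
#' @examples
#' correlate(1:10, (1:10)^2)
correlate <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("correlate requires n >= 3")
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y)))) {
    stop("correlate requires finite values")
  }
  out <- list(pearson_r = NA_real_, p_pearson = NA_real_,
              spearman_rho = NA_real_, p_spearman = NA_real_,
              n = n, degenerate = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    out$degenerate <- TRUE
    return(structure(out, class = "opi_correlation"))
  }
  pval <- function(r) {
    r <- min(max(r, -1), 1)
    if (abs(r) >= 1) return(0)
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(t), df = n - 2)
  }
  out$pearson_r <- cor(x, y)
  out$p_pearson <- pval(out$pearson_r)
  out$spearman_rho <- cor(rank(x), rank(y))
  out$p_spearman <- pval(out$spearman_rho)
  structure(out, class = "opi_correlation")
}

#' @export
print.opi_correlation <- function(x, ...) {
  if (x$degenerate) {
    cat("<opi_correlation> degenerate (zero variance), n =", x$n, "\n")
  } else {
    cat(sprintf("<opi_correlation> n = %d\n  Pearson r = %.3f (P = %.4g)\n  Spearman rho = %.3f (P = %.4g)\n",
                x$n, x$pearson_r, x$p_pearson, x$spearman_rho, x$p_spearman))
  }
  invisible(x)
}

#' Restrict a rate table to regions with enough deaths
#'
#' Surveillance correlations are often recomputed on the subset of regions
#' whose death counts exceed a threshold, where reference rates are less
#' noisy.
#'
#' @param table A rate table with a `death_count` column (see
#'   [attach_reference()]).
#' @param min_deaths Minimum death count to retain a region.
#' @return The filtered table (error if the filter removes every region).
#' @export
threshold_filter <- function(table, min_deaths) {
  stopifnot(is.data.frame(table), is_count(min_deaths))
  if (is.null(table$death_count)) {
    stop("table has no death_count column; attach one via attach_reference()")
  }
  keep <- !is.na(table$death_count) & table$death_count >= min_deaths
  if (!any(keep)) stop("threshold min_deaths = ", min_deaths,
                       " removes every region")
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Quantile bins for choropleth-style shading
#'
#' Assigns each value to one of `n` quantile bins (1 = lowest). Intended as
#' the data layer behind regional heat maps; rendering is left to the
#' caller's mapping tool of choice.
#'
#' @param x Numeric vector (NAs allowed, returned as NA bins).
#' @param n Number of bins (default 5).
#' @return Integer vector of bin indices.
#' @export
rate_bins <- function(x, n = 5) {
  stopifnot(is_count(n), n >= 2)
  qs <- quantile(x, probs = seq(0, 1, length.out = n + 1), na.rm = TRUE,
                 type = 7)
  qs[1] <- -Inf; qs[n + 1] <- Inf
  as.integer(cut(x, breaks = unique(qs), labels = FALSE))
}
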