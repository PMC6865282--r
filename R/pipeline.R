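#' Read a regional reference-metric table
#'
#' CSV with columns `region_id`, `metric_value` and optionally
#' `population`, `metric_name`, `death_count`.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_reference_metrics <- function(path) {
  if (!file.exists(path)) stop("reference metrics file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("region_id", "metric_value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("reference metrics missing column(s): ",
                         paste(miss, collapse = ", "), " in ", path)
  df$region_id <- as.character(df$region_id)
  df$metric_value <- as.numeric(df$metric_value)
  df
}

#' Pipeline run configuration
#'
#' @param corpus Corpus data frame or path to JSONL/CSV posts.
#' @param out_dir Output directory (created if absent).
#' @param lexicon An `opi_lexicon` or path to a lexicon TSV; `NULL` skips
#'   noise filtering.
#' @param metrics Reference-metric data frame or CSV path (see
#'   [read_reference_metrics()]); `NULL` skips the correlation stage.
#' @param seed Global seed; per-stage seeds are fanned out with a
#'   documented hash (see `stage_seed` in the package sources) so stages
#'   can be rerun in isolation reproducibly.
#' @param ratios Train/validation/test split ratios.
#' @param roster Classifier families for the ensemble, in roster order.
#' @param ensemble `"majority"` or `"biased"` — the rule used for the
#'   full-corpus classification stage (test-set reports always include
#'   both).
#' @param rate_mode `"per_post"` or `"per_capita"` abuse-rate denominator.
#' @param min_deaths Death-count thresholds (vector) at which to recompute
#'   the correlation when the metrics table has death counts.
#' @param n_resamples Bootstrap resamples for the evaluation report.
#' @return List of class `opi_run_config`.
#' @export
run_config <- function(corpus, out_dir, lexicon = NULL, metrics = NULL,
                       seed = 1, ratios = c(0.7, 0.1, 0.2),
                       roster = c("naive_bayes", "svm", "random_forest",
                                  "cnn"),
                       ensemble = c("majority", "biased"),
                       rate_mode = c("per_post", "per_capita"),
                       min_deaths = 0, n_resamples = 1000) {
  ensemble <- match.arg(ensemble)
  rate_mode <- match.arg(rate_mode)
  if (is.character(corpus) && !file.exists(corpus)) {
    stop("corpus file not found: ", corpus)
  }
  if (is.character(lexicon) && !file.exists(lexicon)) {
    stop("lexicon file not found: ", lexicon)
  }
  if (is.character(metrics) && !file.exists(metrics)) {
    stop("metrics file not found: ", metrics)
  }
  structure(list(corpus = corpus, out_dir = out_dir, lexicon = lexicon,
                 metrics = metrics, seed = seed, ratios = ratios,
                 roster = roster, ensemble = ensemble, rate_mode = rate_mode,
                 min_deaths = min_deaths, n_resamples = n_resamples),
            class = "opi_run_config")
}

# fit the roster on a split corpus; returns models, votes and validation
# scores. Shared by run_pipeline() and the model CLI.
build_models <- function(splits, roster, seed, resampling = "none") {
  toks_tr <- preprocess(splits$train$text, stem = TRUE)
  toks_tr_raw <- preprocess(splits$train$text, stem = FALSE)
  space <- fit_feature_space(toks_tr, raw_token_lists = toks_tr_raw)

  feats <- function(posts) {
    extract_features(preprocess(posts$text, stem = TRUE), space)
  }
  seqs <- function(posts, max_len) {
    to_id_sequence(preprocess(posts$text, stem = FALSE), space, max_len)
  }

  have_val <- nrow(splits$validation) > 0
  x_tr <- feats(splits$train)
  x_va <- if (have_val) feats(splits$validation)
  y_tr <- splits$train$label
  y_va <- splits$validation$label

  models <- list()
  val_f1 <- numeric(0)
  for (fam in roster) {
    spec <- classifier_spec(fam, resampling = resampling,
                            seed = stage_seed(seed, paste0("train_", fam)))
    if (fam == "cnn") {
      ml <- spec$hyper$max_len
      m <- train_classifier(spec, seqs(splits$train, ml), y_tr,
                            x_val = if (have_val) seqs(splits$validation, ml),
                            y_val = if (have_val) y_va)
      pv <- if (have_val) predict_labels(m, seqs(splits$validation, ml))
    } else {
      m <- train_classifier(spec, x_tr, y_tr)
      pv <- if (have_val) predict_labels(m, x_va)
    }
    models[[fam]] <- m
    val_f1[fam] <- if (have_val) micro_f1(confusion(y_va, pv)) else NA_real_
  }
  list(models = models, space = space, val_f1 = val_f1,
       best_index = if (have_val) unname(which.max(val_f1)) else 1L,
       feats = feats, seqs = seqs)
}

# predictions of every roster model on a corpus, as an n x m label matrix;
# the sparse feature matrix is built once and shared across the
# traditional families
roster_votes <- function(bundle, posts) {
  fams <- names(bundle$models)
  x_trad <- if (any(fams != "cnn")) bundle$feats(posts)
  vapply(fams, function(fam) {
    m <- bundle$models[[fam]]
    x <- if (fam == "cnn") {
      bundle$seqs(posts, m$spec$hyper$max_len)
    } else {
      x_trad
    }
    as.character(predict_labels(m, x))
  }, character(nrow(posts)))
}

#' Run the full toxicovigilance pipeline
#'
#' Executes filter -> split -> featurize -> train roster -> ensemble
#' evaluation -> full-corpus classification -> monthly series -> region
#' rates -> correlation, writing every artifact to `config$out_dir`:
#' `filtered.jsonl`, `split_manifest.csv`, `report.csv` (per-system
#' precision/recall/micro-F1 with CI), `monthly.csv`, `rates.csv`,
#' `correlations.csv` and `run_log.txt`. Rerunning with the same config
#' and seed reproduces all numeric outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the artifact paths and in-memory results
#'   (`report`, `correlations`, `val_f1`, ...).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "opi_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("opichatter %s | R %s",
                         as.character(utils::packageVersion("opichatter")),
                         paste(R.version$major, R.version$minor, sep = ".")),
                 sprintf("started %s", format(Sys.time(), tz = "UTC")),
                 sprintf("global seed %s", config$seed))
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))

  posts <- if (is.character(config$corpus)) read_posts(config$corpus) else
    as_corpus(config$corpus)
  say("corpus: %d posts", nrow(posts))

  # stage 1: noise filtering
  if (!is.null(config$lexicon)) {
    lex <- if (is.character(config$lexicon)) read_lexicon(config$lexicon)
           else config$lexicon
    fn <- filter_noise(posts, lex)
    posts <- fn$kept
    say("noise filter: removed %d, kept %d", fn$removed_count, nrow(posts))
  } else {
    say("noise filter: skipped (no lexicon)")
  }
  path_filtered <- file.path(config$out_dir, "filtered.jsonl")
  write_posts(posts, path_filtered)

  # stage 2: split (labeled posts only)
  labeled <- posts[!is.na(posts$label), , drop = FALSE]
  if (nrow(labeled) < 40) stop("too few labeled posts to train (",
                               nrow(labeled), ")")
  splits <- split_corpus(labeled, config$ratios,
                         seed = stage_seed(config$seed, "split"))
  manifest <- do.call(rbind, lapply(names(splits), function(s) {
    data.frame(id = splits[[s]]$id, set = s, stringsAsFactors = FALSE)
  }))
  path_manifest <- file.path(config$out_dir, "split_manifest.csv")
  utils::write.csv(manifest, path_manifest, row.names = FALSE)
  say("split: %s", paste(names(splits), vapply(splits, nrow, integer(1)),
                         sep = "=", collapse = ", "))

  # stage 3-4: features + models
  bundle <- build_models(splits, config$roster, config$seed)
  say("validation micro-F1: %s",
      paste(names(bundle$val_f1), round(bundle$val_f1, 3),
            sep = "=", collapse = ", "))
  say("best individual classifier: %s", names(bundle$models)[bundle$best_index])

  # stage 5: test-set evaluation of individuals + both ensembles
  votes_te <- roster_votes(bundle, splits$test)
  preds <- lapply(seq_along(config$roster),
                  function(j) votes_te[, j])
  names(preds) <- config$roster
  preds$ensemble_majority <- as.character(
    ensemble_predict(votes_te, "majority", bundle$best_index))
  preds$ensemble_biased <- as.character(
    ensemble_predict(votes_te, "biased", bundle$best_index))
  report <- metric_report(splits$test$label, preds,
                          n_resamples = config$n_resamples,
                          seed = stage_seed(config$seed, "bootstrap"))
  path_report <- file.path(config$out_dir, "report.csv")
  utils::write.csv(as.data.frame(report), path_report, row.names = FALSE)

  # stage 6: classify the full filtered corpus with the configured ensemble
  votes_all <- roster_votes(bundle, posts)
  posts$label <- ensemble_predict(votes_all, config$ensemble,
                                  bundle$best_index)

  # stage 7: monthly series
  path_monthly <- file.path(config$out_dir, "monthly.csv")
  if (!anyNA(posts$timestamp)) {
    utils::write.csv(monthly_series(posts), path_monthly, row.names = FALSE)
  } else {
    utils::write.csv(data.frame(), path_monthly, row.names = FALSE)
    say("monthly series: skipped (missing timestamps)")
  }

  # stage 8-9: region rates + correlations
  metrics <- config$metrics
  if (is.character(metrics)) metrics <- read_reference_metrics(metrics)
  pops <- NULL
  if (!is.null(metrics) && "population" %in% names(metrics)) {
    pops <- setNames(metrics$population, metrics$region_id)
  }
  rates <- region_rates(posts, populations = pops, mode = config$rate_mode)
  corr_df <- NULL
  if (!is.null(metrics)) {
    rates <- attach_reference(rates, metrics)
    use <- !rates$empty & !is.na(rates$reference_metric)
    corr_rows <- list()
    add_corr <- function(tag, tb) {
      cr <- correlate(tb$abuse_rate, tb$reference_metric)
      corr_rows[[length(corr_rows) + 1L]] <<- data.frame(
        measure = tag, pearson_r = cr$pearson_r, p_pearson = cr$p_pearson,
        spearman_rho = cr$spearman_rho, p_spearman = cr$p_spearman,
        n = cr$n)
    }
    add_corr("reference_metric", rates[use, ])
    if ("death_count" %in% names(rates)) {
      for (md in setdiff(config$min_deaths, 0)) {
        add_corr(sprintf("reference_metric_min%d_deaths", md),
                 threshold_filter(rates[use, ], md))
      }
    }
    corr_df <- do.call(rbind, corr_rows)
    say("correlation (all regions): pearson %.3f, spearman %.3f, n=%d",
        corr_df$pearson_r[1], corr_df$spearman_rho[1], corr_df$n[1])
  }
  path_rates <- file.path(config$out_dir, "rates.csv")
  utils::write.csv(as.data.frame(rates), path_rates, row.names = FALSE)
  path_corr <- file.path(config$out_dir, "correlations.csv")
  utils::write.csv(corr_df %||% data.frame(), path_corr, row.names = FALSE)

  path_log <- file.path(config$out_dir, "run_log.txt")
  writeLines(log_lines, path_log)

  invisible(list(
    paths = c(filtered = path_filtered, manifest = path_manifest,
              report = path_report, monthly = path_monthly,
              rates = path_rates, correlations = path_corr, log = path_log),
    report = report, correlations = corr_df, val_f1 = bundle$val_f1,
    best_index = bundle$best_index, classified = posts))
}
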