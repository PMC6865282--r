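#' Validate and normalize a corpus of posts
#'
#' A corpus is a plain data frame with columns `id` (unique character),
#' `text` (nonempty character), `timestamp` (POSIXct, UTC), `region_id`
#' (character) and `label` (factor with levels A/I/U/E, `NA` for unlabeled
#' posts). This mirrors the minimal record a toxicovigilance pipeline needs:
#' what was said, when, where, and (for annotated posts) the gold class.
#'
#' @param df A data frame with at least `id` and `text`; `timestamp` may be
#'   character (ISO-8601) or POSIXct; missing `region_id`/`label` columns are
#'   filled with `NA`.
#' @return The validated data frame (class `data.frame`).
#' @export
as_corpus <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("id", "text")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("corpus missing required column(s): ",
                         paste(miss, collapse = ", "))
  df$id <- as.character(df$id)
  df$text <- as.character(df$text)
  if (any(!nzchar(df$text) | is.na(df$text))) {
    bad <- which(!nzchar(df$text) | is.na(df$text))
    stop("empty text in row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  if (anyDuplicated(df$id)) {
    stop("duplicate post id(s): ",
         paste(utils::head(unique(df$id[duplicated(df$id)]), 5), collapse = ", "))
  }
  if (is.null(df$timestamp)) df$timestamp <- as.POSIXct(NA)
  if (!inherits(df$timestamp, "POSIXct")) {
    ts <- as.POSIXct(as.character(df$timestamp), tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                    "%Y-%m-%d"))
    if (any(is.na(ts) & !is.na(df$timestamp))) {
      stop("unparseable timestamp(s) in row(s): ",
           paste(utils::head(which(is.na(ts) & !is.na(df$timestamp)), 5),
                 collapse = ", "))
    }
    df$timestamp <- ts
  }
  attr(df$timestamp, "tzone") <- "UTC"
  if (is.null(df$region_id)) df$region_id <- NA_character_
  df$region_id <- as.character(df$region_id)
  if (is.null(df$label)) df$label <- NA_character_
  df$label <- as_label_factor(df$label, allow_na = TRUE)
  rownames(df) <- NULL
  df[, c("id", "text", "timestamp", "region_id", "label")]
}

#' Read posts from JSONL or CSV
#'
#' JSONL: one object per line with keys `id`, `text`, `timestamp`
#' (ISO-8601), `region_id`, `label`. CSV: same columns with a header row.
#' Malformed rows abort with their line numbers so annotation errors surface
#' immediately rather than silently shrinking the corpus.
#'
#' @param path File path.
#' @param format `"jsonl"` or `"csv"`; default guessed from the extension.
#' @return A corpus data frame (see [as_corpus()]).
#' @export
read_posts <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (!file.exists(path)) stop("posts file not found: ", path)
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("no posts in ", path)
    rows <- vector("list", length(lines))
    errs <- character(0)
    for (i in seq_along(lines)) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) NULL)
      if (is.null(rec) || is.null(rec$id) || is.null(rec$text)) {
        errs <- c(errs, as.character(i))
      } else {
        rows[[i]] <- data.frame(
          id = as.character(rec$id), text = as.character(rec$text),
          timestamp = as.character(rec$timestamp %||% NA),
          region_id = as.character(rec$region_id %||% NA),
          label = as.character(rec$label %||% NA),
          stringsAsFactors = FALSE)
      }
    }
    if (length(errs)) {
      stop(length(errs), " malformed JSONL row(s) in ", path, " (lines ",
           paste(utils::head(errs, 10), collapse = ", "), ")")
    }
    df <- do.call(rbind, rows)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
    if (!all(c("id", "text") %in% names(df))) {
      stop("CSV must have id and text columns: ", path)
    }
    if (any(!nzchar(df$text))) {
      bad <- which(!nzchar(df$text)) + 1L  # +1 for the header line
      stop("missing text on CSV line(s): ",
           paste(utils::head(bad, 10), collapse = ", "), " in ", path)
    }
  }
  as_corpus(df)
}

#' @rdname read_posts
#' @param posts A corpus data frame.
#' @export
write_posts <- function(posts, path, format = c("auto", "jsonl", "csv")) {
  posts <- as_corpus(posts)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  ts <- format(posts$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (format == "jsonl") {
    recs <- lapply(seq_len(nrow(posts)), function(i) {
      r <- list(id = posts$id[i], text = posts$text[i])
      if (!is.na(ts[i])) r$timestamp <- ts[i]
      if (!is.na(posts$region_id[i])) r$region_id <- posts$region_id[i]
      if (!is.na(posts$label[i])) r$label <- as.character(posts$label[i])
      jsonlite::toJSON(r, auto_unbox = TRUE)
    })
    writeLines(unlist(recs), path)
  } else {
    out <- data.frame(id = posts$id, text = posts$text, timestamp = ts,
                      region_id = posts$region_id,
                      label = as.character(posts$label),
                      stringsAsFactors = FALSE)
    utils::write.csv(out, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Split a corpus into training, validation and test sets
#'
#' Random split with deterministic sizes: `floor(n * r_train)` training
#' posts, `floor(n * r_val)` validation posts, remainder test. The
#' unstratified split is the default so the class mix of each set reflects
#' natural sampling variation; `stratify = TRUE` applies the same floor rule
#' within each class.
#'
#' @param posts A corpus data frame.
#' @param ratios Numeric length-3 (train, validation, test), positive,
#'   summing to 1.
#' @param seed Integer seed; the same seed always yields the same partition.
#' @param stratify Logical; requires all posts labeled when `TRUE`.
#' @return Named list `train`, `validation`, `test` of corpus data frames.
#' @export
#' @examples
#' co <- as_corpus(data.frame(id = as.character(1:10), text = letters[1:10]))
#' sp <- split_corpus(co, c(0.7, 0.1, 0.2), seed = 1)
#' vapply(sp, nrow, integer(1))  # 7 1 2
split_corpus <- function(posts, ratios = c(0.7, 0.1, 0.2), seed,
                         stratify = FALSE) {
  posts <- as_corpus(posts)
  n <- nrow(posts)
  if (n == 0L) stop("cannot split an empty corpus")
  stopifnot(length(ratios) == 3L, all(ratios > 0))
  if (abs(sum(ratios) - 1) > 1e-9) stop("ratios must sum to 1")
  stopifnot(is_count(abs(seed)))
  if (stratify && anyNA(posts$label)) {
    stop("stratified split requires every post to be labeled")
  }

  take <- function(idx) {
    m <- length(idx)
    n_tr <- floor(m * ratios[1])
    n_va <- floor(m * ratios[2])
    perm <- sample(idx)
    list(train = perm[seq_len(n_tr)],
         validation = perm[n_tr + seq_len(n_va)],
         test = perm[-seq_len(n_tr + n_va)])
  }

  set.seed(as.integer(seed))
  if (!stratify) {
    parts <- take(seq_len(n))
  } else {
    per_class <- lapply(split(seq_len(n), posts$label), take)
    parts <- list(
      train = sort(unlist(lapply(per_class, `[[`, "train"))),
      validation = sort(unlist(lapply(per_class, `[[`, "validation"))),
      test = sort(unlist(lapply(per_class, `[[`, "test"))))
  }
  lapply(parts, function(i) {
    out <- posts[sort(i), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Class distribution of a labeled corpus
#'
#' @param posts A fully labeled corpus data frame, or a factor/character
#'   vector of labels.
#' @return Named numeric vector of proportions over A/I/U/E (sums to 1),
#'   with counts in attribute `counts` and percentages (1 decimal) in
#'   attribute `percent`.
#' @export
#' @examples
#' class_distribution(c("A", "A", "I", "U", "U", "U", "E", "U"))
class_distribution <- function(posts) {
  labels <- if (is.data.frame(posts)) posts$label else posts
  labels <- as_label_factor(labels, allow_na = TRUE)
  if (anyNA(labels)) stop("class_distribution requires every post labeled (",
                          sum(is.na(labels)), " unlabeled)")
  if (length(labels) == 0L) stop("no posts")
  counts <- table(labels)
  p <- as.numeric(counts) / length(labels)
  names(p) <- names(counts)
  structure(p, counts = as.integer(counts), percent = round(100 * p, 1))
}
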