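#' Preprocess post text into tokens
#'
#' Lowercases, tokenizes on runs of ASCII letters/digits, and optionally
#' applies the Porter stemmer. The traditional (bag-of-words) classifiers
#' use stemmed tokens; the neural classifier uses unstemmed tokens so the
#' embedding layer sees surface forms.
#'
#' @param texts Character vector.
#' @param stem Logical; apply [porter_stem()] to each token.
#' @return List of character vectors, one per input text (possibly empty
#'   when a text contains no alphanumeric characters).
#' @export
#' @examples
#' preprocess("Taking OXYCONTIN daily")[[1]]
preprocess <- function(texts, stem = TRUE) {
  toks <- tokenize(texts)
  if (stem) {
    # stem the distinct tokens once, then map back
    all_tok <- unlist(toks, use.names = FALSE)
    if (length(all_tok)) {
      uniq <- unique(all_tok)
      stems <- setNames(porter_stem(uniq), uniq)
      toks <- lapply(toks, function(tk) unname(stems[tk]))
    }
  }
  toks
}

# contiguous word n-grams of one token vector, joined with "_"
ngrams_of <- function(tokens, nmin, nmax) {
  L <- length(tokens)
  out <- character(0)
  for (n in nmin:nmax) {
    if (L < n) break
    if (n == 1L) {
      out <- c(out, tokens)
    } else {
      idx <- seq_len(L - n + 1L)
      parts <- lapply(seq_len(n) - 1L, function(o) tokens[idx + o])
      out <- c(out, do.call(paste, c(parts, sep = "_")))
    }
  }
  out
}

#' Default abuse-indicating term list
#'
#' Small built-in set of (stemmed) terms whose presence in a post is a
#' strong cue of self-reported misuse; used for the engineered
#' presence/count feature. Extend or replace via the `abuse_terms` argument
#' of [fit_feature_space()].
#'
#' @return Character vector of stemmed terms.
#' @export
default_abuse_terms <- function() {
  unique(porter_stem(c(
    "high", "buzz", "faded", "nodding", "wasted", "blasted", "stoned",
    "popped", "popping", "snort", "snorting", "shoot", "shooting",
    "injecting", "craving", "withdrawal", "relapse", "fix", "score",
    "hooked", "addicted", "crushed", "railed")))
}

#' Fit a feature space on training tokens
#'
#' Builds the frozen vocabulary used by [extract_features()] (word n-gram
#' counts, bag of word-cluster ids, abuse-term presence and count) and by
#' [to_id_sequence()] (token ids for the embedding layer). Fit on training
#' data only: tokens unseen at fit time never create new columns.
#'
#' @param token_lists List of token vectors (stemmed) from the training set.
#' @param ngram Integer length-2 `(min_n, max_n)`, default `c(1, 3)`.
#' @param min_count Minimum corpus frequency for an n-gram to enter the
#'   vocabulary.
#' @param max_features Cap on n-gram vocabulary size (most frequent kept).
#' @param cluster_map Named integer vector mapping token to cluster id, or
#'   `NULL` to train one with [train_clusters()] (set `n_clusters = 0` to
#'   disable cluster features).
#' @param abuse_terms Character vector of abuse-indicating terms.
#' @param raw_token_lists Unstemmed token lists used to build the id-sequence
#'   vocabulary; defaults to `token_lists`.
#' @param seq_vocab_size Cap on the id-sequence vocabulary.
#' @param n_clusters Number of clusters for the fallback trainer.
#' @return An object of class `opi_feature_space`.
#' @export
fit_feature_space <- function(token_lists, ngram = c(1, 3), min_count = 2,
                              max_features = 50000, cluster_map = NULL,
                              abuse_terms = default_abuse_terms(),
                              raw_token_lists = NULL, seq_vocab_size = 5000,
                              n_clusters = 50) {
  stopifnot(length(ngram) == 2L, ngram[1] >= 1L, ngram[2] >= ngram[1])
  grams <- unlist(lapply(token_lists, ngrams_of, ngram[1], ngram[2]),
                  use.names = FALSE)
  tab <- sort(table(grams), decreasing = TRUE)
  tab <- tab[tab >= min_count]
  vocab <- utils::head(names(tab), max_features)

  if (is.null(cluster_map) && n_clusters > 0) {
    cluster_map <- train_clusters(token_lists, n_clusters = n_clusters)
  }
  cluster_ids <- if (length(cluster_map)) sort(unique(cluster_map)) else integer(0)

  raw <- raw_token_lists %||% token_lists
  rtab <- sort(table(unlist(raw, use.names = FALSE)), decreasing = TRUE)
  seq_vocab <- utils::head(names(rtab), seq_vocab_size)

  structure(list(
    ngram = as.integer(ngram),
    vocab = setNames(seq_along(vocab), vocab),
    cluster_map = cluster_map,
    cluster_ids = cluster_ids,
    abuse_terms = unique(tolower(abuse_terms)),
    # id-sequence vocabulary: 1 = pad, 2 = unk, tokens from 3
    seq_vocab = setNames(seq_along(seq_vocab) + 2L, seq_vocab),
    fitted = TRUE), class = "opi_feature_space")
}

#' @export
print.opi_feature_space <- function(x, ...) {
  cat(sprintf(paste0("<opi_feature_space> %d n-grams (%d..%d), %d clusters, ",
                     "%d abuse terms, %d sequence tokens\n"),
              length(x$vocab), x$ngram[1], x$ngram[2], length(x$cluster_ids),
              length(x$abuse_terms), length(x$seq_vocab)))
  invisible(x)
}

#' Extract sparse feature vectors
#'
#' Columns are the concatenation of n-gram counts (frozen vocabulary),
#' bag-of-cluster-id counts (tokens without a cluster are skipped), and two
#' engineered abuse-term features (presence 0/1, total count).
#' Out-of-vocabulary n-grams are ignored.
#'
#' @param token_lists List of token vectors (same preprocessing as at fit).
#' @param space A fitted [fit_feature_space()] object.
#' @return A `dgCMatrix` with `length(token_lists)` rows.
#' @export
extract_features <- function(token_lists, space) {
  if (!inherits(space, "opi_feature_space") || !isTRUE(space$fitted)) {
    stop("feature space is not fitted")
  }
  n <- length(token_lists)
  V <- length(space$vocab)
  K <- length(space$cluster_ids)
  p <- V + K + 2L

  i_all <- integer(0); j_all <- integer(0); x_all <- numeric(0)

  # aggregate (doc, col) pairs into counts via a single numeric key
  add_block <- function(doc, col, offset) {
    key <- (doc - 1) * p + (col + offset)
    agg <- rowsum(rep(1, length(key)), group = key, reorder = FALSE)
    k <- as.numeric(rownames(agg))
    i_all <<- c(i_all, as.integer((k - 1) %/% p) + 1L)
    j_all <<- c(j_all, as.integer((k - 1) %% p) + 1L)
    x_all <<- c(x_all, as.numeric(agg))
  }

  # n-gram block
  grams <- lapply(token_lists, ngrams_of, space$ngram[1], space$ngram[2])
  doc <- rep.int(seq_len(n), vapply(grams, length, integer(1)))
  col <- unname(space$vocab[unlist(grams, use.names = FALSE)])
  keep <- !is.na(col)
  if (any(keep)) add_block(doc[keep], col[keep], 0L)

  # cluster block
  if (K > 0) {
    doc_t <- rep.int(seq_len(n), vapply(token_lists, length, integer(1)))
    cl <- space$cluster_map[unlist(token_lists, use.names = FALSE)]
    keep <- !is.na(cl)
    if (any(keep)) add_block(doc_t[keep], match(cl[keep], space$cluster_ids), V)
  }

  # abuse-term block: presence then count
  ab <- vapply(token_lists, function(tk) sum(tk %in% space$abuse_terms),
               numeric(1))
  pres <- which(ab > 0)
  if (length(pres)) {
    i_all <- c(i_all, pres, pres)
    j_all <- c(j_all, rep(V + K + 1L, length(pres)),
               rep(V + K + 2L, length(pres)))
    x_all <- c(x_all, rep(1, length(pres)), ab[pres])
  }

  Matrix::sparseMatrix(i = i_all, j = j_all, x = x_all, dims = c(n, p),
                       dimnames = list(NULL, NULL))
}

#' Map tokens to a fixed-length id sequence
#'
#' Tokens are looked up in the fitted sequence vocabulary; unknown tokens map
#' to the reserved unk id (2), and sequences are truncated or right-padded
#' with the pad id (1) to exactly `max_len`.
#'
#' @param token_lists List of (unstemmed) token vectors.
#' @param space A fitted feature space.
#' @param max_len Positive integer sequence length.
#' @return Integer matrix `length(token_lists) x max_len`.
#' @export
to_id_sequence <- function(token_lists, space, max_len) {
  stopifnot(inherits(space, "opi_feature_space"), is_count(max_len),
            max_len >= 1)
  out <- matrix(1L, nrow = length(token_lists), ncol = max_len)
  for (i in seq_along(token_lists)) {
    tk <- utils::head(token_lists[[i]], max_len)
    if (length(tk) == 0L) next
    ids <- unname(space$seq_vocab[tk])
    ids[is.na(ids)] <- 2L
    out[i, seq_along(ids)] <- as.integer(ids)
  }
  attr(out, "vocab_size") <- length(space$seq_vocab) + 2L
  out
}

#' Train a fallback word-cluster map
#'
#' Hard distributional clusters for the cluster-id feature when no external
#' cluster file is supplied. Frequent tokens are represented by positive
#' pointwise-mutual-information co-occurrence signatures (within-post
#' co-occurrence against the most frequent context tokens) and merged
#' greedily by complete-linkage agglomeration on cosine distance; the tree
#' is cut at `n_clusters`.
#'
#' @param token_lists List of token vectors (training data).
#' @param n_clusters Number of clusters.
#' @param max_tokens Number of frequent tokens to cluster (rarer tokens get
#'   no cluster and are skipped by [extract_features()]).
#' @return Named integer vector token -> cluster id.
#' @export
train_clusters <- function(token_lists, n_clusters = 50, max_tokens = 500) {
  freq <- sort(table(unlist(token_lists, use.names = FALSE)),
               decreasing = TRUE)
  toks <- utils::head(names(freq), max_tokens)
  if (length(toks) < 2L) {
    return(setNames(rep(1L, length(toks)), toks))
  }
  n_clusters <- min(n_clusters, length(toks))
  ctx <- utils::head(toks, min(200L, length(toks)))
  # co-occurrence counts within posts
  C <- matrix(0, length(toks), length(ctx), dimnames = list(toks, ctx))
  for (tk in token_lists) {
    tk <- unique(tk)
    r <- tk[tk %in% toks]; s <- tk[tk %in% ctx]
    if (length(r) && length(s)) C[r, s] <- C[r, s] + 1
  }
  tot <- sum(C)
  if (tot == 0) return(setNames(rep(1L, length(toks)), toks))
  pmi <- log(pmax(C, 0) * tot /
               (outer(pmax(rowSums(C), 1), pmax(colSums(C), 1))))
  pmi[!is.finite(pmi) | pmi < 0] <- 0
  nrm <- sqrt(rowSums(pmi^2)); nrm[nrm == 0] <- 1
  X <- pmi / nrm
  d <- as.dist(1 - tcrossprod(X))
  hc <- hclust(d, method = "complete")
  cutree(hc, k = n_clusters)
}

#' Read a token-to-cluster map from TSV
#'
#' Two tab-separated columns: token, integer cluster id; `#` comments
#' ignored.
#'
#' @param path File path.
#' @return Named integer vector.
#' @export
read_cluster_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("cluster map needs 2 columns: ", path)
  setNames(as.integer(df[[2]]), tolower(df[[1]]))
}

#' Read a word-embedding table from TSV
#'
#' First column token, remaining columns the embedding values; all rows must
#' have the same dimension.
#'
#' @param path File path.
#' @return Numeric matrix with tokens as row names.
#' @export
read_embeddings <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("embedding table needs >= 2 columns: ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m) || anyNA(m)) stop("non-numeric embedding values in ", path)
  rownames(m) <- tolower(df[[1]])
  colnames(m) <- NULL
  m
}
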