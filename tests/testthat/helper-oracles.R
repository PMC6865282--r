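# Independent oracles used across tests. Deliberately naive: each one is a
# direct transcription of a definition, kept separate from the package's
# implementation paths.

# Damerau-Levenshtein distance (optimal string alignment), dynamic program
dl_distance <- function(a, b) {
  a <- strsplit(a, "", fixed = TRUE)[[1]]
  b <- strsplit(b, "", fixed = TRUE)[[1]]
  na <- length(a); nb <- length(b)
  d <- matrix(0L, na + 1L, nb + 1L)
  d[, 1] <- 0:na
  d[1, ] <- 0:nb
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      cost <- as.integer(a[i] != b[j])
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + cost)
      if (i > 1 && j > 1 && a[i] == b[j - 1] && a[i - 1] == b[j]) {
        d[i + 1, j + 1] <- min(d[i + 1, j + 1], d[i - 1, j - 1] + 1L)
      }
    }
  }
  d[na + 1, nb + 1]
}

# brute-force transcription of the majority rule: modal label, ties to the
# best classifier's vote
oracle_majority <- function(votes, best_index) {
  votes <- unname(as.character(votes))
  counts <- table(votes)
  winners <- names(counts)[counts == max(counts)]
  if (length(winners) == 1L) winners else votes[best_index]
}

# brute-force transcription of the minority-biased rule
oracle_biased <- function(votes, best_index, priority = c("A", "I"),
                          min_votes = 2L) {
  votes <- unname(as.character(votes))
  n_a <- sum(votes == priority[1])
  n_b <- sum(votes == priority[2])
  qa <- n_a >= min_votes
  qb <- n_b >= min_votes
  if (qa && !qb) return(priority[1])
  if (qb && !qa) return(priority[2])
  if (qa && qb) {
    if (n_a > n_b) return(priority[1])
    if (n_b > n_a) return(priority[2])
    if (votes[best_index] %in% priority) return(votes[best_index])
    return(priority[1])
  }
  oracle_majority(votes, best_index)
}

# all 4^m vote panels over the four labels
all_panels <- function(m = 4L) {
  as.matrix(expand.grid(rep(list(opi_labels()), m),
                        stringsAsFactors = FALSE))
}

# per-class tally oracle for confusion matrices
oracle_confusion <- function(y_true, y_pred, labels = opi_labels()) {
  cm <- matrix(0L, length(labels), length(labels),
               dimnames = list(labels, labels))
  for (i in seq_along(y_true)) {
    cm[y_true[i], y_pred[i]] <- cm[y_true[i], y_pred[i]] + 1L
  }
  cm
}

# closed-form 95% binomial (Wald) interval width for an accuracy estimate
binomial_ci_width <- function(p, n) 2 * 1.96 * sqrt(p * (1 - p) / n)

# small labeled corpus fixture
toy_corpus <- function(n = 40, seed = 99) {
  gen_corpus(generator_config(n_posts = n, seed = seed))
}
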