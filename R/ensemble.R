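#' Majority-vote ensemble rule
#'
#' The modal label across the panel of classifier votes wins; when the mode
#' is tied, the vote of the best-performing individual classifier (given by
#' `best_index`) decides.
#'
#' @param votes Character vector of predicted labels, one per classifier,
#'   in a fixed roster order.
#' @param best_index Index (into `votes`) of the best individual classifier.
#' @return A single label.
#' @export
#' @examples
#' majority_vote(c("A", "A", "I", "U"), best_index = 1)
#' majority_vote(c("A", "I", "A", "I"), best_index = 2)  # tie -> votes[2]
majority_vote <- function(votes, best_index = 1L) {
  votes <- as.character(votes)
  n <- length(votes)
  if (n < 1L) stop("empty vote panel")
  stopifnot(best_index >= 1L, best_index <= n)
  cnt <- table(votes)
  top <- names(cnt)[cnt == max(cnt)]
  if (length(top) == 1L) return(top)
  votes[best_index]
}

#' Minority-biased ensemble rule
#'
#' Recall-oriented variant for the content-rich minority classes: if at
#' least `min_votes` classifiers predict a priority label, that label is
#' assigned even when it is not the mode. When both priority labels reach
#' the threshold, the one with more votes wins; an exact tie between them is
#' broken by the best classifier's vote if that vote is itself a priority
#' label, otherwise by the first label of `priority` (abuse, the
#' surveillance-critical class, under the default ordering). When no
#' priority label reaches the threshold, [majority_vote()] applies.
#'
#' @inheritParams majority_vote
#' @param priority Labels given preferential treatment, default `c("A", "I")`
#'   (the first element is also the final tie-break).
#' @param min_votes Minimum votes for a priority label to win (default 2).
#' @return A single label.
#' @export
#' @examples
#' biased_vote(c("U", "U", "I", "I"), best_index = 1)  # I beats the U tie
#' biased_vote(c("U", "U", "U", "A"), best_index = 1)  # A below threshold
biased_vote <- function(votes, best_index = 1L, priority = c("A", "I"),
                        min_votes = 2L) {
  votes <- as.character(votes)
  n <- length(votes)
  if (n < min_votes) stop("panel smaller than min_votes")
  stopifnot(best_index >= 1L, best_index <= n)
  pc <- vapply(priority, function(l) sum(votes == l), integer(1))
  qual <- pc[pc >= min_votes]
  if (length(qual) == 1L) return(names(qual))
  if (length(qual) > 1L) {
    top <- names(qual)[qual == max(qual)]
    if (length(top) == 1L) return(top)
    if (votes[best_index] %in% top) return(votes[best_index])
    return(priority[priority %in% top][1L])
  }
  majority_vote(votes, best_index)
}

#' Apply an ensemble rule to a panel of classifier predictions
#'
#' @param vote_matrix Character matrix, rows = posts, columns = classifiers
#'   (fixed roster order), or a named list of equal-length label vectors.
#' @param rule `"majority"` or `"biased"`.
#' @param best_index Column index of the best individual classifier.
#' @param ... Passed to [biased_vote()] (`priority`, `min_votes`).
#' @return Factor of ensemble labels, one per row.
#' @export
ensemble_predict <- function(vote_matrix, rule = c("majority", "biased"),
                             best_index = 1L, ...) {
  rule <- match.arg(rule)
  if (is.list(vote_matrix) && !is.matrix(vote_matrix)) {
    vote_matrix <- do.call(cbind, lapply(vote_matrix, as.character))
  }
  vote_matrix <- as.matrix(vote_matrix)
  f <- if (rule == "majority") {
    function(v) majority_vote(v, best_index)
  } else {
    function(v) biased_vote(v, best_index, ...)
  }
  as_label_factor(apply(vote_matrix, 1L, f))
}
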