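#' Porter stemmer
#'
#' Reduces English words to their stems with the classic Porter suffix
#' stripping algorithm (original 1980 rule set). Used for the bag-of-words
#' feature pipeline of the traditional classifiers; the neural classifier
#' consumes unstemmed tokens.
#'
#' @param words Character vector of lowercase words.
#' @return Character vector of stems, same length as `words`. Words shorter
#'   than three characters are returned unchanged.
#' @export
#' @examples
#' porter_stem(c("running", "taking", "daily", "oxycontin"))
porter_stem <- function(words) {
  vapply(as.character(words), porter_stem1, character(1), USE.NAMES = FALSE)
}

# --- single-word implementation ------------------------------------------
# The word is held as a character vector of single letters; `measure` and the
# starred conditions (*v*, *d, *o) follow the original definitions with
# y counted as a vowel when preceded by a consonant.

porter_is_cons <- function(l, i) {
  ch <- l[i]
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") {
    if (i == 1L) return(TRUE)
    return(!porter_is_cons(l, i - 1L))
  }
  TRUE
}

porter_measure <- function(l, upto = length(l)) {
  if (upto < 1L) return(0L)
  types <- vapply(seq_len(upto), function(i) porter_is_cons(l, i), logical(1))
  # count VC transitions in the c/v sequence
  m <- 0L
  i <- 1L
  # skip initial consonants
  while (i <= upto && types[i]) i <- i + 1L
  while (i <= upto) {
    while (i <= upto && !types[i]) i <- i + 1L  # vowels
    if (i > upto) break
    m <- m + 1L
    while (i <= upto && types[i]) i <- i + 1L   # consonants
  }
  m
}

porter_has_vowel <- function(l, upto = length(l)) {
  if (upto < 1L) return(FALSE)
  any(!vapply(seq_len(upto), function(i) porter_is_cons(l, i), logical(1)))
}

porter_double_cons <- function(l) {
  n <- length(l)
  n >= 2L && l[n] == l[n - 1L] && porter_is_cons(l, n)
}

# *o: stem ends cvc where the final consonant is not w, x or y
porter_cvc <- function(l) {
  n <- length(l)
  n >= 3L &&
    porter_is_cons(l, n) && !porter_is_cons(l, n - 1L) &&
    porter_is_cons(l, n - 2L) &&
    !(l[n] %in% c("w", "x", "y"))
}

porter_ends <- function(w, suf) {
  nchar(w) > nchar(suf) && substring(w, nchar(w) - nchar(suf) + 1L) == suf
}

porter_stem1 <- function(word) {
  if (nchar(word) < 3L) return(word)
  w <- word

  chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
  stem_of <- function(x, suf) substring(x, 1L, nchar(x) - nchar(suf))
  m_of <- function(x) porter_measure(chars(x))

  # step 1a
  if (porter_ends(w, "sses")) {
    w <- paste0(stem_of(w, "sses"), "ss")
  } else if (porter_ends(w, "ies")) {
    w <- paste0(stem_of(w, "ies"), "i")
  } else if (!porter_ends(w, "ss") && porter_ends(w, "s")) {
    w <- stem_of(w, "s")
  }

  # step 1b
  step1b_fix <- FALSE
  if (porter_ends(w, "eed")) {
    if (m_of(stem_of(w, "eed")) > 0L) w <- stem_of(w, "d")
  } else if (porter_ends(w, "ed") &&
             porter_has_vowel(chars(stem_of(w, "ed")))) {
    w <- stem_of(w, "ed"); step1b_fix <- TRUE
  } else if (porter_ends(w, "ing") &&
             porter_has_vowel(chars(stem_of(w, "ing")))) {
    w <- stem_of(w, "ing"); step1b_fix <- TRUE
  }
  if (step1b_fix) {
    l <- chars(w)
    if (porter_ends(w, "at") || porter_ends(w, "bl") || porter_ends(w, "iz")) {
      w <- paste0(w, "e")
    } else if (porter_double_cons(l) && !(l[length(l)] %in% c("l", "s", "z"))) {
      w <- substring(w, 1L, nchar(w) - 1L)
    } else if (m_of(w) == 1L && porter_cvc(l)) {
      w <- paste0(w, "e")
    }
  }

  # step 1c
  if (porter_ends(w, "y") && porter_has_vowel(chars(stem_of(w, "y")))) {
    w <- paste0(stem_of(w, "y"), "i")
  }

  # step 2 (m > 0), longest match by suffix listing order
  step2 <- c(ational = "ate", tional = "tion", enci = "ence", anci = "ance",
             izer = "ize", abli = "able", alli = "al", entli = "ent",
             eli = "e", ousli = "ous", ization = "ize", ation = "ate",
             ator = "ate", alism = "al", iveness = "ive", fulness = "ful",
             ousness = "ous", aliti = "al", iviti = "ive", biliti = "ble")
  w <- porter_rule_map(w, step2, min_m = 1L)

  # step 3 (m > 0)
  step3 <- c(icate = "ic", ative = "", alize = "al", iciti = "ic",
             ical = "ic", ful = "", ness = "")
  w <- porter_rule_map(w, step3, min_m = 1L)

  # step 4 (m > 1), plain deletions; "ion" needs stem ending s or t
  step4 <- c("al", "ance", "ence", "er", "ic", "able", "ible", "ant",
             "ement", "ment", "ent", "ion", "ou", "ism", "ate", "iti",
             "ous", "ive", "ize")
  for (suf in step4[order(-nchar(step4))]) {
    if (porter_ends(w, suf)) {
      st <- stem_of(w, suf)
      if (suf == "ion" && !(substring(st, nchar(st)) %in% c("s", "t"))) next
      if (m_of(st) > 1L) w <- st
      break
    }
  }

  # step 5a
  if (porter_ends(w, "e")) {
    st <- stem_of(w, "e")
    m <- m_of(st)
    if (m > 1L || (m == 1L && !porter_cvc(chars(st)))) w <- st
  }
  # step 5b
  l <- chars(w)
  if (m_of(w) > 1L && porter_double_cons(l) && l[length(l)] == "l") {
    w <- substring(w, 1L, nchar(w) - 1L)
  }
  w
}

# apply the first (longest) matching suffix rule whose stem has measure
# >= min_m; rules are named suffix -> replacement
porter_rule_map <- function(w, rules, min_m) {
  sufs <- names(rules)
  for (suf in sufs[order(-nchar(sufs))]) {
    if (porter_ends(w, suf)) {
      st <- substring(w, 1L, nchar(w) - nchar(suf))
      if (porter_measure(strsplit(st, "", fixed = TRUE)[[1]]) >= min_m) {
        w <- paste0(st, rules[[suf]])
      }
      break
    }
  }
  w
}
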