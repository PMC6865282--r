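#' Construct a keyword entry
#'
#' A keyword is one opioid-related expression (a drug name, street name or
#' phrase) together with its spelling variants and metadata. Noise keywords
#' (`is_noise = TRUE`) mark terms that retrieve overwhelmingly non-opioid
#' content (for example slang senses of "dope") and whose posts are removed
#' wholesale by [filter_noise()].
#'
#' @param surface Lowercase term or phrase (words separated by single spaces).
#' @param drug_class `"prescription"` or `"illicit"`.
#' @param is_noise Logical; `TRUE` flags the keyword as a noise term.
#' @param variants Character vector of lowercase spelling variants. The
#'   surface itself is always included.
#' @return An object of class `opi_keyword`.
#' @export
#' @examples
#' keyword("percocet", "prescription", variants = c("percoset", "perkocet"))
keyword <- function(surface, drug_class = c("prescription", "illicit"),
                    is_noise = FALSE, variants = character()) {
  drug_class <- match.arg(drug_class)
  surface <- trimws(tolower(surface))
  if (!nzchar(surface)) stop("keyword surface must be nonempty")
  variants <- trimws(tolower(as.character(variants)))
  variants <- unique(c(surface, variants[nzchar(variants)]))
  structure(list(surface = surface, drug_class = drug_class,
                 is_noise = isTRUE(is_noise), variants = variants),
            class = "opi_keyword")
}

#' Construct a lexicon
#'
#' @param keywords A list of [keyword()] objects (duplicate surfaces are an
#'   error).
#' @return An object of class `opi_lexicon` with derived counts
#'   `n_expressions` (distinct surfaces) and `n_terms` (surfaces plus all
#'   distinct variants).
#' @export
#' @examples
#' lex <- lexicon(list(keyword("oxycodone"), keyword("heroin", "illicit")))
#' lex$n_expressions
lexicon <- function(keywords) {
  stopifnot(is.list(keywords), length(keywords) > 0)
  if (!all(vapply(keywords, inherits, logical(1), "opi_keyword"))) {
    stop("all entries must be opi_keyword objects")
  }
  surfaces <- vapply(keywords, `[[`, character(1), "surface")
  if (anyDuplicated(surfaces)) {
    stop("duplicate keyword surfaces: ",
         paste(unique(surfaces[duplicated(surfaces)]), collapse = ", "))
  }
  all_terms <- unique(unlist(lapply(keywords, `[[`, "variants")))
  structure(list(keywords = keywords,
                 n_expressions = length(surfaces),
                 n_terms = length(all_terms)),
            class = "opi_lexicon")
}

#' @export
print.opi_lexicon <- function(x, ...) {
  n_noise <- sum(vapply(x$keywords, `[[`, logical(1), "is_noise"))
  cat(sprintf("<opi_lexicon> %d expressions, %d terms incl. variants, %d noise\n",
              x$n_expressions, x$n_terms, n_noise))
  invisible(x)
}

#' Generate candidate spelling variants for a term
#'
#' Stand-in for a data-driven misspelling generator: candidates are the
#' single-character deletions, adjacent transpositions, double-letter
#' collapses and double-letter expansions of `surface`, restricted to those
#' that keep the first character (misspellings of drug names rarely alter the
#' initial letter, and anchoring the first character keeps the match set
#' tight). Every candidate is within Damerau-Levenshtein distance 1 of the
#' surface by construction. Candidates whose consonant skeleton (the word
#' with vowels removed) equals that of the surface are ranked first, as a
#' cheap phonetic-plausibility heuristic, and the list is truncated to
#' `max_variants` before the surface itself is added back.
#'
#' @param surface Lowercase single word, at least 3 characters.
#' @param max_variants Maximum number of generated variants (the returned set
#'   has at most `max_variants + 1` elements including `surface`).
#' @return Character vector: `surface` plus up to `max_variants` variants.
#' @export
#' @examples
#' expand_variants("percocet", 5)
expand_variants <- function(surface, max_variants) {
  surface <- tolower(trimws(surface))
  if (nchar(surface) < 3L) {
    stop("surface must have at least 3 characters (got '", surface, "'): ",
         "variant generation on very short terms floods matches")
  }
  stopifnot(is_count(max_variants))
  n <- nchar(surface)
  l <- strsplit(surface, "", fixed = TRUE)[[1]]

  cands <- character(0)
  # deletions
  for (i in seq_len(n)) cands <- c(cands, paste(l[-i], collapse = ""))
  # adjacent transpositions
  for (i in seq_len(n - 1L)) {
    v <- l; v[c(i, i + 1L)] <- v[c(i + 1L, i)]
    cands <- c(cands, paste(v, collapse = ""))
  }
  # double-letter collapse (covered by deletions but kept for clarity of
  # intent) and expansion (letter doubling = one insertion)
  for (i in seq_len(n)) {
    cands <- c(cands, paste(c(l[seq_len(i)], l[i:n]), collapse = ""))
  }

  cands <- unique(cands)
  cands <- cands[cands != surface & nzchar(cands)]
  cands <- cands[substring(cands, 1L, 1L) == substring(surface, 1L, 1L)]

  skel <- function(x) gsub("[aeiou]", "", x)
  same_skel <- skel(cands) == skel(surface)
  cands <- c(cands[same_skel], cands[!same_skel])
  unique(c(surface, utils::head(cands, max_variants)))
}

#' Expand every keyword of a lexicon with generated spelling variants
#'
#' @param lex An [lexicon()] object.
#' @param max_variants Variants generated per keyword (phrases are expanded
#'   word by word on their longest word).
#' @return A new `opi_lexicon` with the generated variants merged in.
#' @export
expand_lexicon <- function(lex, max_variants) {
  stopifnot(inherits(lex, "opi_lexicon"))
  kws <- lapply(lex$keywords, function(kw) {
    words <- strsplit(kw$surface, " ", fixed = TRUE)[[1]]
    if (length(words) == 1L && nchar(kw$surface) >= 3L) {
      vars <- expand_variants(kw$surface, max_variants)
    } else {
      # phrases: perturb the longest word, keep the others fixed
      j <- which.max(nchar(words))
      if (nchar(words[j]) < 3L) return(kw)
      wv <- expand_variants(words[j], max_variants)
      vars <- vapply(wv, function(v) {
        ws <- words; ws[j] <- v; paste(ws, collapse = " ")
      }, character(1))
    }
    keyword(kw$surface, kw$drug_class, kw$is_noise,
            variants = unique(c(kw$variants, vars)))
  })
  lexicon(kws)
}

# variant -> canonical surface lookup, one row per (term, surface, is_noise)
lexicon_table <- function(lex) {
  do.call(rbind, lapply(lex$keywords, function(kw) {
    data.frame(term = kw$variants, surface = kw$surface,
               is_noise = kw$is_noise, stringsAsFactors = FALSE)
  }))
}

# match one tokenized text against a term table; phrases are contiguous
# token sequences
match_tokens <- function(tokens, tab) {
  if (length(tokens) == 0L) return(character(0))
  hits <- character(0)
  single <- tab[!grepl(" ", tab$term, fixed = TRUE), ]
  m <- single$term %in% tokens
  if (any(m)) hits <- single$surface[m]
  multi <- tab[grepl(" ", tab$term, fixed = TRUE), ]
  if (nrow(multi)) {
    joined <- paste(tokens, collapse = " ")
    for (i in seq_len(nrow(multi))) {
      pat <- paste0("(^| )", multi$term[i], "( |$)")
      if (grepl(pat, joined)) hits <- c(hits, multi$surface[i])
    }
  }
  unique(hits)
}

#' Match a post's text against a lexicon
#'
#' Case-insensitive whole-token matching: single-word terms must match a
#' whole token (so "tar" does not match "guitar"); multi-word phrases must
#' appear as a contiguous token sequence. Variants map back to their
#' canonical surface.
#'
#' @param text Nonempty character string.
#' @param lex An [lexicon()] object.
#' @return Character vector of canonical surfaces matched (possibly empty).
#' @export
#' @examples
#' lex <- lexicon(list(keyword("percocet", variants = "percoset")))
#' match_post("Took Percocet again", lex)
match_post <- function(text, lex) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  stopifnot(inherits(lex, "opi_lexicon"))
  match_tokens(tokenize(text)[[1]], lexicon_table(lex))
}

#' Remove posts matching noise keywords
#'
#' Drops every post whose text contains a noise-flagged keyword or any of its
#' spelling variants (whole-token matches). Retained posts keep their input
#' order.
#'
#' @param posts A corpus data frame (see [as_corpus()]) or character vector
#'   of texts.
#' @param lex An [lexicon()] object with at least one `is_noise` keyword.
#' @return A list with `kept` (same type as `posts`) and `removed_count`.
#' @export
#' @examples
#' lex <- lexicon(list(keyword("oxycodone"), keyword("dope", "illicit", TRUE)))
#' filter_noise(c("that song is dope", "took oxycodone for pain"), lex)
filter_noise <- function(posts, lex) {
  stopifnot(inherits(lex, "opi_lexicon"))
  noise <- Filter(function(kw) kw$is_noise, lex$keywords)
  if (length(noise) == 0L) {
    stop("lexicon has no keywords flagged is_noise; ",
         "noise filtering would be a no-op (misconfiguration)")
  }
  texts <- if (is.data.frame(posts)) posts$text else posts
  tab <- lexicon_table(lexicon(noise))
  toks <- tokenize(texts)
  hit <- vapply(toks, function(tk) length(match_tokens(tk, tab)) > 0L,
                logical(1))
  kept <- if (is.data.frame(posts)) posts[!hit, , drop = FALSE] else posts[!hit]
  if (is.data.frame(kept)) rownames(kept) <- NULL
  list(kept = kept, removed_count = sum(hit))
}

#' Read / write a lexicon as TSV
#'
#' Columns: `surface`, `drug_class`, `is_noise`, `variants` (comma-joined).
#' Lines starting with `#` are ignored.
#'
#' @param path File path.
#' @return `read_lexicon()` returns an `opi_lexicon`; `write_lexicon()`
#'   returns `path` invisibly.
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  raw <- raw[!grepl("^\\s*#", raw) & nzchar(trimws(raw))]
  if (length(raw) == 0L) stop("lexicon file is empty: ", path)
  parts <- strsplit(raw, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 3L)
  if (length(bad)) {
    stop("malformed lexicon lines (need >= 3 tab-separated fields): ",
         paste(bad, collapse = ", "), " in ", path)
  }
  kws <- lapply(parts, function(p) {
    vars <- if (length(p) >= 4L && nzchar(p[4])) {
      strsplit(p[4], ",", fixed = TRUE)[[1]]
    } else character(0)
    keyword(p[1], p[2], tolower(p[3]) %in% c("true", "1", "yes"), vars)
  })
  lexicon(kws)
}

#' @rdname read_lexicon
#' @param lex An `opi_lexicon`.
#' @export
write_lexicon <- function(lex, path) {
  stopifnot(inherits(lex, "opi_lexicon"))
  lines <- vapply(lex$keywords, function(kw) {
    vars <- setdiff(kw$variants, kw$surface)
    paste(kw$surface, kw$drug_class, tolower(kw$is_noise),
          paste(vars, collapse = ","), sep = "\t")
  }, character(1))
  writeLines(c("# surface\tdrug_class\tis_noise\tvariants", lines), path)
  invisible(path)
}

#' Built-in demonstration lexicon
#'
#' A small opioid keyword lexicon (generic and brand prescription names,
#' common illicit street terms) with the four conventional noise terms
#' ("dope", "tar", "skunk", "smack") flagged `is_noise`. Intended for
#' examples, tests and the synthetic generator; real deployments should load
#' a curated lexicon with [read_lexicon()].
#'
#' @param max_variants Spelling variants generated per keyword via
#'   [expand_variants()]; 0 returns the bare terms.
#' @return An `opi_lexicon`.
#' @export
#' @examples
#' default_lexicon()
default_lexicon <- function(max_variants = 3) {
  rx <- c("oxycodone", "oxycontin", "percocet", "vicodin", "hydrocodone",
          "codeine", "tramadol", "morphine", "methadone", "suboxone",
          "fentanyl", "dilaudid", "opana", "roxicodone")
  il <- c("heroin", "china white", "oxys", "percs", "speedball")
  noise <- c("dope", "tar", "skunk", "smack")
  kws <- c(lapply(rx, keyword, drug_class = "prescription"),
           lapply(il, keyword, drug_class = "illicit"),
           lapply(noise, keyword, drug_class = "illicit", is_noise = TRUE))
  lex <- lexicon(kws)
  if (max_variants > 0) lex <- expand_lexicon(lex, max_variants) else lex
}
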