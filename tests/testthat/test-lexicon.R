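test_that("expand_variants satisfies its containment and edit-distance contract", {
  for (surface in c("percocet", "oxycodone", "heroin", "tramadol", "oxy")) {
    for (k in c(0L, 3L, 10L)) {
      v <- expand_variants(surface, k)
      expect_true(surface %in% v)
      expect_lte(length(v), k + 1L)
      expect_true(all(substring(v, 1L, 1L) == substring(surface, 1L, 1L)))
      # independent Damerau-Levenshtein oracle
      for (x in setdiff(v, surface)) expect_lte(dl_distance(surface, x), 1L)
    }
  }
  expect_identical(expand_variants("oxy", 0), "oxy")
  expect_error(expand_variants("ox", 5), "3 characters")
})

test_that("match_post does whole-token, variant-canonicalizing matching", {
  lex <- lexicon(list(
    keyword("percocet", "prescription", variants = c("percoset", "percocets")),
    keyword("china white", "illicit"),
    keyword("tar", "illicit", is_noise = TRUE)))
  expect_identical(match_post("Took Percocet again", lex), "percocet")
  # variant maps back to canonical surface (oracle: the lookup table itself)
  expect_identical(match_post("percoset helps", lex), "percocet")
  expect_identical(match_post("nice weather", lex), character(0))
  # whole-token: no substring hits
  expect_identical(match_post("playing guitar", lex), character(0))
  # phrases match as contiguous token sequences
  expect_identical(match_post("found china white today", lex), "china white")
  expect_identical(match_post("china is white", lex), character(0))
  # returned names are always surfaces, never variants
  co <- toy_corpus(30)
  for (tx in co$text) {
    m <- match_post(tx, lex)
    expect_true(all(m %in% c("percocet", "china white", "tar")))
  }
})

test_that("filter_noise removes noise-term posts, keeps order, is idempotent", {
  lex <- lexicon(list(keyword("oxycodone"),
                      keyword("dope", "illicit", is_noise = TRUE),
                      keyword("tar", "illicit", is_noise = TRUE)))
  texts <- c("that song is dope", "took oxycodone for pain")
  r <- filter_noise(texts, lex)
  expect_identical(r$kept, "took oxycodone for pain")
  expect_identical(r$removed_count, 1L)

  # 10 posts, 4 with "tar" as a token: brute-force token-scan oracle
  posts <- c("tar on the road", "guitar lessons", "fixing tar roof",
             "a b c", "tar pit", "star gazing", "hot tar", "plain text",
             "guitars", "more text")
  brute <- vapply(strsplit(tolower(posts), "[^a-z0-9]+"),
                  function(tk) "tar" %in% tk, logical(1))
  expect_identical(sum(brute), 4L)
  r2 <- filter_noise(posts, lex)
  expect_identical(r2$removed_count, 4L)
  expect_identical(r2$kept, posts[!brute])

  # idempotence and the no-noise identity
  r3 <- filter_noise(r2$kept, lex)
  expect_identical(r3$kept, r2$kept)
  expect_identical(r3$removed_count, 0L)

  expect_error(filter_noise(texts, lexicon(list(keyword("oxycodone")))),
               "is_noise")
})

test_that("noise variants are excluded too", {
  lex <- expand_lexicon(
    lexicon(list(keyword("oxycodone"),
                 keyword("smack", "illicit", is_noise = TRUE))), 5)
  smack_vars <- Filter(function(k) k$surface == "smack", lex$keywords)[[1]]$variants
  v <- setdiff(smack_vars, "smack")[1]
  expect_gt(length(v), 0)
  r <- filter_noise(c(paste("total", v), "oxycodone refill"), lex)
  expect_identical(r$removed_count, 1L)
})

test_that("lexicon counts and TSV round trip", {
  lex <- lexicon(list(keyword("percocet", variants = "percoset"),
                      keyword("heroin", "illicit")))
  expect_identical(lex$n_expressions, 2L)
  expect_identical(lex$n_terms, 3L)
  expect_error(lexicon(list(keyword("percocet"), keyword("percocet"))),
               "duplicate")

  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_lexicon(lex, tmp)
  lex2 <- read_lexicon(tmp)
  expect_identical(lex2$n_expressions, 2L)
  expect_identical(lex2$n_terms, 3L)
  expect_setequal(vapply(lex2$keywords, `[[`, character(1), "surface"),
                  c("percocet", "heroin"))
})

test_that("expand_lexicon grows variants for every keyword", {
  lex <- expand_lexicon(default_lexicon(max_variants = 0), 4)
  expect_gte(lex$n_terms, lex$n_expressions)
  for (kw in lex$keywords) {
    expect_true(kw$surface %in% kw$variants)
    expect_gte(length(kw$variants), 2L)
  }
})
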