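simple_kb <- function(names) {
  mk <- medlit:::new_concept
  build_kb(lapply(seq_along(names), function(i)
    mk(paste0("X", i), names[i])), stopwords = character())
}

test_that("char n-grams are boundary-padded", {
  expect_identical(char_ngrams("abc"), c("#ab", "abc", "bc#"))
  expect_identical(char_ngrams("a"), "#a#")
  expect_identical(char_ngrams("ab"), c("#ab", "ab#"))
})

test_that("TF-IDF vectors match hand arithmetic on a 3-concept fixture", {
  kb <- simple_kb(c("abc", "abd", "xyz"))
  idx <- build_index(kb)
  # hand computation with the stated formula, N = 3 alias strings:
  # "abc" -> #ab, abc, bc#; df(#ab) = 2 (abc, abd), df(abc) = df(bc#) = 1
  idf2 <- log(4 / 3) + 1     # df = 2
  idf1 <- log(4 / 2) + 1     # df = 1
  raw <- c(idf2, idf1, idf1)
  expected <- raw / sqrt(sum(raw^2))
  row <- which(idx$surfaces == "abc")
  v <- as.numeric(idx$M[row, ])
  got <- v[v > 0]
  cols <- idx$vocab[c("#ab", "abc", "bc#")]
  expect_equal(as.numeric(idx$M[row, cols]), expected, tolerance = 1e-12)
  expect_equal(sum(v^2), 1, tolerance = 1e-12)
})

test_that("every index row has unit norm and the vocab respects min_count", {
  spec <- synth_spec(seed = 13L, n_concepts = 30L)
  kb <- synth_kb(spec)
  idx <- build_index(kb)
  norms <- sqrt(Matrix::rowSums(idx$M^2))
  expect_true(all(abs(norms - 1) < 1e-9))
  idx5 <- build_index(kb, min_count = 5L)
  counts <- table(unlist(lapply(normalize_alias(idx$surfaces), char_ngrams)))
  expect_true(all(counts[names(idx5$vocab)] >= 5))
  expect_error(build_index(kb, min_count = 1e9), "filtered")
  expect_error(build_index(build_kb(list()), ), "empty")
})

test_that("a single-alias KB produces a single unit vector", {
  idx <- build_index(simple_kb("anemia"))
  expect_identical(nrow(idx$M), 1L)
  expect_equal(sum(idx$M[1, ]^2), 1, tolerance = 1e-12)
})

test_that("exact-alias mentions rank first with cosine 1", {
  kb <- simple_kb(c("anemia", "fracture", "sepsis"))
  idx <- build_index(kb)
  cs <- candidates(idx, "Anemia", k = 3)
  expect_identical(cs$candidates$concept_id[1], "X1")
  expect_equal(cs$candidates$score[1], 1, tolerance = 1e-9)
})

test_that("candidate ranking equals the exhaustive cosine oracle", {
  set.seed(19)
  for (rep in 1:5) {
    spec <- synth_spec(seed = rep, n_concepts = sample(20:60, 1))
    kb <- synth_kb(spec)
    idx <- build_index(kb)
    mention <- sample(names(kb$alias_index), 1)
    mention <- paste0(substr(mention, 1, max(nchar(mention) - 1, 2)), "x")
    v <- medlit:::index_vectorize(idx, mention)
    if (all(v == 0)) next
    # oracle: dense cosine against every entry, best alias per concept
    sims <- as.numeric(as.matrix(idx$M) %*% v)
    best <- tapply(sims, idx$concept_ids, max)
    oracle <- names(sort(best, decreasing = TRUE))
    # stable tie handling: compare score sequences, not just ids
    cs <- candidates(idx, mention, k = 10)
    expect_equal(cs$candidates$score,
                 as.numeric(sort(best, decreasing = TRUE))[1:nrow(cs$candidates)],
                 tolerance = 1e-9)
    expect_lte(nrow(cs$candidates), 10L)
    expect_true(all(cs$candidates$score >= 0 & cs$candidates$score <= 1 + 1e-12))
  }
})

test_that("growing k preserves the relative order of shared candidates", {
  spec <- synth_spec(seed = 23L, n_concepts = 40L)
  kb <- synth_kb(spec)
  idx <- build_index(kb)
  mention <- kb$concepts[[5]]$name
  c2 <- candidates(idx, mention, k = 2)$candidates$concept_id
  c8 <- candidates(idx, mention, k = 8)$candidates$concept_id
  expect_identical(c2, c8[1:2])
})

test_that("unmatchable mentions give an empty candidate set, not an error", {
  idx <- build_index(simple_kb(c("abc", "abd")))
  expect_message(cs <- candidates(idx, "qqq", k = 3), "no in-vocabulary")
  expect_identical(nrow(cs$candidates), 0L)
  expect_error(rank_candidates(cs), "empty")
})

test_that("disjoint-vocabulary senses are resolved from context", {
  fx <- synth_ambiguous_fixture(seed = 11L)
  idx <- build_index(fx$kb)
  sm <- train_sense_model(fx$kb, fx$train)
  correct <- 0L
  for (i in seq_len(nrow(fx$test))) {
    toks <- tokenize_text(fx$test$context[i])$token
    pos <- medlit:::locate_surface(toks, fx$alias)
    lm <- rank_candidates(candidates(idx, fx$alias, k = 5), toks, pos, sm)
    if (lm$concept_id == fx$test$concept[i]) correct <- correct + 1L
  }
  expect_identical(correct, nrow(fx$test))
})

test_that("single candidates and empty contexts use the documented fallbacks", {
  fx <- synth_ambiguous_fixture(seed = 3L)
  idx <- build_index(fx$kb)
  sm <- train_sense_model(fx$kb, fx$train)
  cs <- candidates(idx, fx$alias, k = 5)
  # empty context: generation order wins
  lm <- rank_candidates(cs, character(), NULL, sm)
  expect_identical(lm$concept_id, cs$candidates$concept_id[1])
  expect_identical(lm$provenance, "knn+wsd")
  one <- cs
  one$candidates <- one$candidates[1, , drop = FALSE]
  expect_identical(rank_candidates(one, character(), NULL, sm)$concept_id,
                   one$candidates$concept_id[1])
})

test_that("resolve_mention honors stop words and the exact-alias fast path", {
  kb <- fixture_kb()
  idx <- build_index(kb)
  expect_null(resolve_mention(kb, idx, "patient"))    # medical stop word
  hit <- resolve_mention(kb, idx, "Anemia")
  expect_identical(hit$concept_id, "C3")
  expect_identical(hit$provenance, "exact-alias")
  amb <- resolve_mention(kb, idx, "cold")             # shared alias -> kNN+WSD
  expect_identical(amb$provenance, "knn+wsd")
})

test_that("WSD context files and index artifacts round-trip", {
  fx <- synth_ambiguous_fixture(seed = 2L, n_train = 2L, n_test = 2L)
  path <- tempfile(fileext = ".jsonl")
  writeLines(vapply(seq_len(nrow(fx$train)), function(i)
    as.character(jsonlite::toJSON(as.list(fx$train[i, ]), auto_unbox = TRUE)),
    character(1)), path)
  back <- read_wsd_contexts(path)
  expect_equal(back, fx$train, ignore_attr = TRUE)
  idx <- build_index(fx$kb)
  p2 <- tempfile(fileext = ".rds")
  save_index(idx, p2)
  expect_equal(load_index(p2)$vocab, idx$vocab)
})
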