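test_that("the 6-annotator vote rule is exact over its whole domain", {
  expect_identical(votes_to_label(0:6),
                   c("difficult", "difficult", "difficult", "difficult",
                     "medium", "medium", "easy"))
  expect_error(votes_to_label(7), "0..6")
  expect_error(votes_to_label(-1), "0..6")
})

test_that("syllable counting follows the vowel-group rules", {
  expect_identical(count_syllables("cold"), 1L)
  expect_identical(count_syllables("anemia"), 3L)       # a | e | ia
  expect_identical(count_syllables("bone"), 1L)         # trailing silent e
  expect_identical(count_syllables("rhythm"), 1L)       # y as vowel... none else
  expect_identical(count_syllables("idea"), 2L)         # i | ea, e not silent
  expect_identical(count_syllables("bone marrow"), 3L)  # per-word sum
  expect_error(count_syllables(""), "non-empty")
})

test_that("character composition partitions every input", {
  f <- extract_features("cold")
  expect_identical(f$n_chars, 4L)
  expect_identical(f$n_consonants, 3L)
  expect_identical(f$n_vowels, 1L)
  expect_equal(f$pct_consonants, 75)
  expect_equal(f$pct_vowels, 25)
  set.seed(14)
  pool <- c(letters, LETTERS, " ", "-", "'", ",", "7", "é", "中")
  for (rep in 1:20) {
    w <- paste(sample(pool, sample(1:15, 1), replace = TRUE), collapse = "")
    f <- extract_features(w)
    expect_identical(f$n_consonants + f$n_vowels + f$n_other, f$n_chars)
    expect_equal(f$pct_consonants + f$pct_vowels + f$pct_other, 100,
                 tolerance = 1e-6)
    if (grepl("[aeiouy]", tolower(w))) expect_gte(f$n_syllables, 1L)
  }
})

test_that("resource lookups degrade to neutral values", {
  f <- extract_features("zzyzzx")
  expect_false(f$in_wordnet)
  expect_identical(f$freq_general, 0)
  expect_identical(f$freq_medical, 0)
  g <- extract_features("blood")
  expect_true(g$in_wordnet)
  expect_gt(g$freq_general, 0)
  kb <- fixture_kb()
  h <- extract_features("cold", kb)
  expect_identical(h$freq_medical, 2L)                 # two "cold" concepts
  expect_setequal(h$semtypes, c("Disease", "Problem"))
})

test_that("affix and category features fire on medical morphology", {
  f <- extract_features("hypertension")
  expect_identical(f$prefix, "hyper")
  g <- extract_features("appendectomy")
  expect_identical(g$suffix, "ectomy")
  expect_identical(extract_features("COPD")$syntactic_category, "abbreviation")
  expect_identical(extract_features("renal")$syntactic_category, "adjective")
})

test_that("the feature vector has a fixed documented dimension", {
  kb <- fixture_kb()
  res <- difficulty_resources()
  inv <- sort(unique(unlist(lapply(kb$concepts, `[[`, "semtypes"))))
  d <- length(extract_features("cold", kb, res, inv)$vector)
  for (w in c("a", "hyperlipidemia", "bone marrow", "X")) {
    expect_length(extract_features(w, kb, res, inv)$vector, d)
  }
  expect_error(extract_features(""), "non-empty")
})

test_that("the classifier separates the synthetic classes and is deterministic", {
  spec <- synth_spec(seed = 5L)
  ds <- synth_difficulty_dataset(spec)
  expect_identical(nrow(ds), 60L)
  cfg <- difficulty_config(epochs = 100L)
  m <- train_difficulty_classifier(ds[, c("term", "label")], config = cfg,
                                   seed = 5L)
  pred <- predict_difficulty(m, ds$term)
  acc <- mean(pred == ds$label)
  expect_gte(acc, 0.95)
  majority <- max(table(ds$label)) / nrow(ds)
  expect_gte(acc - majority, 0.30)
  expect_true(all(pred %in% c("easy", "medium", "difficult")))
  m2 <- train_difficulty_classifier(ds[, c("term", "label")], config = cfg,
                                    seed = 5L)
  expect_identical(predict_difficulty(m2, ds$term), pred)
  expect_true(all(predict_difficulty(m, c("qqq", "zzz-9")) %in%
                    c("easy", "medium", "difficult")))
})

test_that("the logistic fallback engine trains on features alone", {
  skip_if_not_installed("nnet")
  spec <- synth_spec(seed = 6L)
  ds <- synth_difficulty_dataset(spec)
  m <- train_difficulty_classifier(
    ds[, c("term", "label")],
    config = difficulty_config(engine = "logistic"), seed = 6L)
  acc <- mean(predict_difficulty(m, ds$term) == ds$label)
  expect_gte(acc, max(table(ds$label)) / nrow(ds))
})

test_that("training contracts reject unusable datasets", {
  expect_error(train_difficulty_classifier(
    data.frame(term = c("a", "b"), label = c("easy", "easy"))), "2 classes")
  expect_error(train_difficulty_classifier(
    data.frame(term = "a", label = "impossible")), "easy")
})

test_that("difficulty datasets round-trip through CSV and JSONL", {
  ds <- data.frame(term = c("cold", "hyperlipidemia"),
                   label = c("easy", "difficult"),
                   stringsAsFactors = FALSE)
  p <- tempfile(fileext = ".csv")
  utils::write.csv(ds, p, row.names = FALSE)
  expect_equal(read_difficulty_dataset(p), ds, ignore_attr = TRUE)
  p2 <- tempfile(fileext = ".jsonl")
  writeLines(c('{"term": "cold", "label": "easy"}',
               '{"term": "hyperlipidemia", "label": "difficult"}'), p2)
  expect_equal(read_difficulty_dataset(p2), ds, ignore_attr = TRUE)
})
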