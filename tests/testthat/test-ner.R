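test_that("CRF forward and Viterbi match exhaustive enumeration", {
  set.seed(42)
  for (rep in 1:40) {
    L <- sample(1:4, 1)
    T_ <- sample(1:4, 1)
    em <- matrix(rnorm(L * T_, sd = 2), L, T_)
    tr <- matrix(rnorm((T_ + 2)^2, sd = 2), T_ + 2, T_ + 2)
    expect_equal(crf_log_partition(em, tr), brute_log_partition(em, tr),
                 tolerance = 1e-8)
    v <- crf_viterbi(em, tr)
    bv <- brute_viterbi(em, tr)
    expect_equal(v$score, bv$score, tolerance = 1e-8)
    expect_identical(v$path, bv$path)
    # sum over paths dominates the best path
    expect_gte(crf_log_partition(em, tr), v$score)
  }
})

test_that("CRF closed forms: uniform scores and single-step sequences", {
  for (L in 1:4) for (T_ in 1:4) {
    em <- matrix(0, L, T_)
    tr <- matrix(0, T_ + 2, T_ + 2)
    expect_equal(crf_log_partition(em, tr), L * log(T_), tolerance = 1e-10)
    v <- crf_viterbi(em, tr)
    expect_identical(v$path, rep(1L, L))    # all-tie: smallest tag indices
  }
  em <- matrix(c(0.3, -1, 2), 1, 3)
  tr <- matrix(rnorm(25), 5, 5)
  lz <- crf_log_partition(em, tr)
  manual <- log(sum(exp(tr[4, 1:3] + em[1, ] + tr[1:3, 5])))
  expect_equal(lz, manual, tolerance = 1e-10)
})

test_that("Viterbi score beats random sampled paths", {
  set.seed(9)
  em <- matrix(rnorm(4 * 3), 4, 3)
  tr <- matrix(rnorm(25), 5, 5)
  best <- crf_viterbi(em, tr)$score
  for (i in 1:100) {
    p <- sample(1:3, 4, replace = TRUE)
    expect_gte(best, medlit:::crf_path_score(em, tr, p))
  }
})

test_that("CRF rejects malformed inputs", {
  expect_error(crf_log_partition(matrix(NA_real_, 1, 2), matrix(0, 4, 4)),
               "finite")
  expect_error(crf_log_partition(matrix(0, 2, 2), matrix(0, 3, 3)),
               "T\\+2")
})

test_that("the tagger memorizes a small corpus and learns monotonically", {
  corpus <- tiny_corpus()
  model <- train_tagger(corpus, fast_tagger_config(), seed = 3L)
  expect_equal(tagger_f1(model, corpus), 1)
  expect_lt(utils::tail(model$loss, 1), model$loss[1])
})

test_that("training is deterministic given the seed", {
  corpus <- tiny_corpus()
  cfg <- fast_tagger_config()
  cfg$epochs <- 30L
  m1 <- train_tagger(corpus, cfg, seed = 5L)
  m2 <- train_tagger(corpus, cfg, seed = 5L)
  held_out <- c("the", "zalprin", "panel", "was", "clear")
  expect_identical(medlit:::ner_predict_tags(m1, held_out),
                   medlit:::ner_predict_tags(m2, held_out))
  expect_identical(m1$par, m2$par)
})

test_that("tag_text returns gold mentions on memorized text with sane spans", {
  corpus <- tiny_corpus()
  model <- train_tagger(corpus, fast_tagger_config(), seed = 3L)
  expect_identical(tag_text(model, ""), list())
  for (s in corpus[1:3]) {
    found <- tag_text(model, s$text)
    gold <- medlit:::bio_decode(s$tokens, s$tags, s$start, s$end)
    expect_length(found, length(gold))
    for (i in seq_along(gold)) {
      expect_identical(found[[i]]$start, gold[[i]]$start)
      expect_identical(found[[i]]$end, gold[[i]]$end)
      expect_identical(found[[i]]$type, gold[[i]]$type)
      expect_identical(found[[i]]$surface,
                       substring(s$text, gold[[i]]$start + 1, gold[[i]]$end))
    }
  }
  doc <- "took zalprin daily. no rash today."
  for (m in tag_text(model, doc)) {
    expect_true(m$start >= 0 && m$start < m$end && m$end <= nchar(doc))
  }
})

test_that("constrained decoding never emits an invalid BIO sequence", {
  corpus <- tiny_corpus()
  cfg <- fast_tagger_config()
  cfg$epochs <- 5L                        # deliberately undertrained
  model <- train_tagger(corpus, cfg, seed = 2L)
  set.seed(8)
  for (rep in 1:10) {
    toks <- sample(c("the", "rash", "blood", "panel", "zalprin", "qqq"),
                   sample(3:7, 1), replace = TRUE)
    tags <- medlit:::ner_predict_tags(model, toks, constrained = TRUE)
    expect_true(bio_valid(tags))
  }
})

test_that("model save/load round-trip preserves predictions exactly", {
  corpus <- tiny_corpus()
  cfg <- fast_tagger_config()
  cfg$epochs <- 20L
  model <- train_tagger(corpus, cfg, seed = 4L)
  path <- tempfile(fileext = ".rds")
  save_tagger(model, path)
  loaded <- load_tagger(path)
  toks <- c("ordered", "blood", "panel", "for", "rash")
  expect_identical(medlit:::ner_predict_tags(model, toks),
                   medlit:::ner_predict_tags(loaded, toks))
})

test_that("CoNLL corpora round-trip through files", {
  corpus <- tiny_corpus()
  path <- tempfile(fileext = ".conll")
  write_conll(corpus, path)
  back <- read_conll(path)
  expect_length(back, length(corpus))
  for (i in seq_along(corpus)) {
    expect_identical(back[[i]]$tokens, corpus[[i]]$tokens)
    expect_identical(back[[i]]$tags, corpus[[i]]$tags)
    expect_identical(back[[i]]$start, corpus[[i]]$start)
  }
  expect_error(read_conll({
    p <- tempfile(); writeLines("token_without_tag", p); p
  }), "malformed")
})

test_that("training rejects contract violations", {
  expect_error(train_tagger(list()), "empty")
  bad <- tiny_corpus()
  bad[[1]]$tags[2] <- "B-Alien"
  expect_error(train_tagger(bad, types = c("Problem", "Drug", "Test")),
               "outside")
  invalid <- tiny_corpus()
  invalid[[1]]$tags <- c("O", "I-Problem", "O")
  expect_error(train_tagger(invalid), "BIO")
})

test_that("pretrained word vectors load and seed the embedding table", {
  path <- tempfile()
  writeLines(c("rash 0.1 0.2 0.3", "blood -1 0 1"), path)
  vec <- load_word_vectors(path)
  expect_identical(rownames(vec), c("rash", "blood"))
  expect_equal(vec["blood", ], c(-1, 0, 1), ignore_attr = TRUE)
  cfg <- fast_tagger_config()
  cfg$word_dim <- 3L
  cfg$epochs <- 1L
  cfg$pretrained <- vec
  m <- train_tagger(tiny_corpus(), cfg, seed = 1L)
  expect_true(all(is.finite(m$par$Eword)))
})
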