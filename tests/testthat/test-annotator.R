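# a small end-to-end world with known ground truth, built once per file
ann_world <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    spec <- synth_spec(seed = 7L)
    kb <- synth_kb(spec)
    corp <- synth_ner_corpus(kb, spec)
    tagger <- train_tagger(corp$sentences, seed = 7L)
    ds <- synth_difficulty_dataset(spec)
    diffm <- train_difficulty_classifier(
      ds[, c("term", "label")], kb = kb,
      config = difficulty_config(epochs = 60L), seed = 7L)
    cache <<- list(
      spec = spec, kb = kb, corp = corp,
      models = list(tagger = tagger, difficulty = diffm,
                    index = build_index(kb), kb = kb,
                    sense_model = train_sense_model(kb)))
    cache
  }
})

test_that("the literacy policy keeps exactly the warranted labels", {
  ms <- list(list(surface = "fever", difficulty = "easy"),
             list(surface = "anemia", difficulty = "medium"),
             list(surface = "cholecystectomy", difficulty = "difficult"))
  high <- select_by_policy(ms, "high")
  expect_identical(vapply(high, `[[`, character(1), "difficulty"), "difficult")
  low <- select_by_policy(ms, "low")
  expect_identical(vapply(low, `[[`, character(1), "difficulty"),
                   c("medium", "difficult"))
  expect_identical(select_by_policy(list(), "low"), list())
  expect_error(select_by_policy(ms, "medium"), "literacy")
})

test_that("overlap resolution keeps the longest span, leftmost on ties", {
  ms <- list(list(start = 0, end = 4, surface = "a"),
             list(start = 2, end = 10, surface = "b"),
             list(start = 12, end = 16, surface = "c"),
             list(start = 14, end = 18, surface = "d"))
  out <- medlit:::resolve_overlaps(ms)
  expect_identical(vapply(out, `[[`, character(1), "surface"), c("b", "c"))
})

test_that("annotating a fixture document yields verifiable annotations", {
  w <- ann_world()
  doc <- paste(vapply(w$corp$sentences[1:3], `[[`, character(1), "text"),
               collapse = ". ")
  out <- annotate_document(doc, "low", w$models)
  expect_s3_class(out, "medlit_annotated")
  starts <- vapply(out$annotations, `[[`, numeric(1), "start")
  ends <- vapply(out$annotations, `[[`, numeric(1), "end")
  expect_true(all(starts >= 0 & starts < ends & ends <= nchar(doc)))
  expect_identical(starts, sort(starts))
  expect_true(all(utils::head(ends, -1) <= utils::tail(starts, -1)))
  for (a in out$annotations) {
    # stored surface reconstructs from the text
    expect_identical(substring(doc, a$start + 1, a$end), a$surface)
    # resolved and related concepts exist in the KB
    expect_true(a$concept_id %in% names(w$kb$concepts))
    for (r in a$related) {
      expect_true(r$concept_id %in% names(w$kb$concepts))
    }
    expect_false(normalize_alias(a$surface) %in% w$kb$stopwords)
    expect_true(a$difficulty %in% c("medium", "difficult"))
  }
})

test_that("low-literacy annotations are a superset of high-literacy ones", {
  w <- ann_world()
  for (i in c(2L, 5L, 9L)) {
    doc <- w$corp$sentences[[i]]$text
    low <- annotate_document(doc, "low", w$models)
    high <- annotate_document(doc, "high", w$models)
    key <- function(x) vapply(x$annotations, function(a)
      sprintf("%d:%d:%s", a$start, a$end, a$concept_id), character(1))
    expect_true(all(key(high) %in% key(low)))
  }
})

test_that("documents without medical terms produce no annotations", {
  w <- ann_world()
  out <- annotate_document("the visit was on a good day", "low", w$models)
  expect_length(out$annotations, 0L)
  expect_identical(out$text, "the visit was on a good day")
})

test_that("repeated runs are byte-identical and artifacts are required", {
  w <- ann_world()
  doc <- w$corp$sentences[[4]]$text
  j1 <- annotated_json(annotate_document(doc, "low", w$models))
  j2 <- annotated_json(annotate_document(doc, "low", w$models))
  expect_identical(j1, j2)
  parsed <- jsonlite::fromJSON(j1, simplifyVector = FALSE)
  expect_identical(parsed$text, doc)
  expect_identical(parsed$literacy, "low")
  broken <- w$models
  broken$index <- NULL
  expect_error(annotate_document(doc, "low", broken), "index")
  expect_error(annotate_document(strrep("x", 20), "low", w$models,
                                 annotate_config(max_chars = 10L)), "limit")
})

test_that("the JSON writer and HTML view emit well-formed output", {
  w <- ann_world()
  doc <- w$corp$sentences[[1]]$text
  out <- annotate_document(doc, "low", w$models)
  path <- tempfile(fileext = ".json")
  write_annotated_json(out, path)
  expect_silent(jsonlite::fromJSON(path))
  html <- annotated_html(out)
  expect_match(html, "^<!DOCTYPE html>")
  expect_no_error(xml2::read_html(html))
})
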