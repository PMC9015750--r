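# Shared fixtures, all built in code at test time.

# three concepts, six alias strings, five distinct normalized keys; "cold"
# is deliberately shared by two concepts (a polysemous medical term)
fixture_concepts <- function() {
  list(
    list(id = "C1", name = "Common Cold", aliases = list("cold"),
         definition = "A viral infection of the nose and throat.",
         semtypes = list("Disease"),
         relations = list(list(type = "subclass_of", target = "C3"))),
    list(id = "C2", name = "Cold Sensation", aliases = list("cold", "chill"),
         definition = "A feeling of low temperature on the skin.",
         semtypes = list("Problem"), relations = list()),
    list(id = "C3", name = "Anemia", aliases = list(),
         definition = "A shortage of red blood cells.",
         semtypes = list("Disease"), relations = list())
  )
}

fixture_kb <- function(...) {
  build_kb(lapply(fixture_concepts(), function(r) {
    medlit:::new_concept(r$id, r$name, unlist(r$aliases), r$definition,
                         unlist(r$semtypes), r$relations)
  }), ...)
}

write_fixture_jsonl <- function(path = tempfile(fileext = ".jsonl"),
                                concepts = fixture_concepts()) {
  lines <- vapply(concepts, function(r)
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE)), character(1))
  writeLines(lines, path, useBytes = TRUE)
  path
}

# chain A -subclass_of-> B -subclass_of-> C for traversal tests
chain_kb <- function() {
  mk <- medlit:::new_concept
  build_kb(list(
    mk("A", "alpha", relations = list(list(type = "subclass_of", target = "B"))),
    mk("B", "beta", relations = list(list(type = "subclass_of", target = "C"))),
    mk("C", "gamma")
  ))
}

# brute-force CRF oracles by exhaustive path enumeration
enum_paths <- function(L, T_) {
  as.matrix(expand.grid(rep(list(seq_len(T_)), L)))
}

brute_log_partition <- function(em, tr) {
  paths <- enum_paths(nrow(em), ncol(em))
  scores <- apply(paths, 1L, function(p) medlit:::crf_path_score(em, tr, p))
  m <- max(scores)
  m + log(sum(exp(scores - m)))
}

brute_viterbi <- function(em, tr) {
  paths <- enum_paths(nrow(em), ncol(em))
  scores <- apply(paths, 1L, function(p) medlit:::crf_path_score(em, tr, p))
  list(path = as.integer(paths[which.max(scores), ]), score = max(scores))
}

# independent EAP oracle: fine Riemann sum over [-8, 8], coded without the
# package's quadrature helpers
oracle_eap <- function(responses, items, n = 10001L) {
  th <- seq(-8, 8, length.out = n)
  lw <- stats::dnorm(th, log = TRUE)
  for (i in seq_along(items)) {
    x <- responses[i]
    if (is.na(x)) next
    p <- items[[i]]$c + (1 - items[[i]]$c) /
      (1 + exp(-items[[i]]$a * (th - items[[i]]$b)))
    lw <- lw + if (x == 1) log(p) else log(1 - p)
  }
  w <- exp(lw - max(lw))
  sum(w * th) / sum(w)
}

# small memorizable corpus for fast tagger tests
tiny_corpus <- function() {
  mk <- function(tokens, tags) {
    ends <- cumsum(nchar(tokens) + 1L) - 1L
    list(tokens = tokens, tags = tags,
         start = c(0L, utils::head(ends, -1L) + 1L), end = ends,
         text = paste(tokens, collapse = " "))
  }
  list(
    mk(c("the", "rash", "itched"), c("O", "B-Problem", "O")),
    mk(c("took", "zalprin", "daily"), c("O", "B-Drug", "O")),
    mk(c("blood", "panel", "was", "clear"),
       c("B-Test", "I-Test", "O", "O")),
    mk(c("no", "rash", "today"), c("O", "B-Problem", "O")),
    mk(c("zalprin", "helps", "rash"), c("B-Drug", "O", "B-Problem")),
    mk(c("ordered", "blood", "panel"), c("O", "B-Test", "I-Test"))
  )
}

fast_tagger_config <- function() {
  tagger_config(char_dim = 8L, char_filters = 8L, word_dim = 12L,
                hidden = 10L, epochs = 120L, check_every = 10L)
}
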