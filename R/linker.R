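# Entity linking: candidate generation ranks knowledge-base concepts by
# cosine similarity between character-3-gram TF-IDF vectors of the mention
# and of every (concept, alias) entry; candidate ranking disambiguates with
# a vector-space model over context features (unigrams, salient bigrams and
# positional collocations), the classic supervised WSD feature families.

#' Character n-grams of a surface string
#'
#' The string is boundary-padded with \code{#} sentinels so surfaces shorter
#' than \code{n} still produce n-grams.
#'
#' @param s character scalar (normalized upstream).
#' @param n n-gram length.
#' @return character vector of n-grams.
#' @export
char_ngrams <- function(s, n = 3L) {
  p <- paste0("#", s, "#")
  while (nchar(p) < n) p <- paste0(p, "#")
  k <- nchar(p) - n + 1L
  substring(p, 1:k, n:(n + k - 1L))
}

#' Build the TF-IDF character n-gram index over a knowledge base
#'
#' One L2-normalized sparse vector per (concept, alias) entry, with the
#' canonical name counted as an alias.  TF is the raw n-gram count in the
#' alias; IDF is the smoothed \code{log((1 + N) / (1 + df)) + 1} over the N
#' alias strings.  Only n-grams occurring at least \code{min_count} times in
#' the knowledge base enter the vocabulary (the default 1 keeps everything;
#' around 10 is sensible for large vocabularies).
#'
#' @param kb a \code{medlit_kb}.
#' @param n n-gram length.
#' @param min_count minimum total n-gram frequency for vocabulary inclusion.
#' @return object of class \code{medlit_ngram_index}: \code{vocab} (n-gram
#'   to column), \code{idf}, \code{M} (sparse entry x n-gram matrix, unit
#'   rows), \code{concept_ids} and \code{surfaces} (row maps), \code{n}.
#' @export
build_index <- function(kb, n = 3L, min_count = 1L) {
  stopifnot(inherits(kb, "medlit_kb"))
  if (!length(kb$concepts)) contract_error("cannot index an empty KB")
  ids <- character(); surfaces <- character()
  for (co in kb$concepts) {
    al <- unique(normalize_alias(c(co$name, co$aliases)))
    al <- al[nzchar(al)]
    ids <- c(ids, rep(co$id, length(al)))
    surfaces <- c(surfaces, al)
  }
  grams <- lapply(surfaces, char_ngrams, n = n)
  tot <- table(unlist(grams))
  vocab_grams <- names(tot)[tot >= min_count]
  if (!length(vocab_grams)) {
    contract_error("min_count filtered out every n-gram; index would be empty")
  }
  vocab <- stats::setNames(seq_along(vocab_grams), sort(vocab_grams))

  N <- length(surfaces)
  df <- integer(length(vocab))
  trip_i <- integer(); trip_j <- integer(); trip_x <- numeric()
  for (r in seq_along(grams)) {
    tf <- table(grams[[r]])
    tf <- tf[names(tf) %in% names(vocab)]
    if (!length(tf)) next
    cols <- vocab[names(tf)]
    df[cols] <- df[cols] + 1L
    trip_i <- c(trip_i, rep.int(r, length(cols)))
    trip_j <- c(trip_j, unname(cols))
    trip_x <- c(trip_x, as.numeric(tf))
  }
  idf <- log((1 + N) / (1 + df)) + 1
  x <- trip_x * idf[trip_j]
  M <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = x,
                            dims = c(N, length(vocab)))
  norms <- sqrt(Matrix::rowSums(M^2))
  norms[norms == 0] <- 1
  M <- Matrix::Diagonal(x = 1 / norms) %*% M
  structure(list(vocab = vocab, idf = idf, M = methods::as(M, "CsparseMatrix"),
                 concept_ids = ids, surfaces = surfaces, n = n),
            class = "medlit_ngram_index")
}

#' @export
print.medlit_ngram_index <- function(x, ...) {
  cat(sprintf("<medlit_ngram_index> %d entries, %d %d-grams\n",
              nrow(x$M), length(x$vocab), x$n))
  invisible(x)
}

# TF-IDF vector of a mention in the index space (unit norm, dense)
index_vectorize <- function(index, mention) {
  tf <- table(char_ngrams(normalize_alias(mention), index$n))
  tf <- tf[names(tf) %in% names(index$vocab)]
  v <- numeric(length(index$vocab))
  if (!length(tf)) return(v)
  cols <- index$vocab[names(tf)]
  v[cols] <- as.numeric(tf) * index$idf[cols]
  nv <- sqrt(sum(v^2))
  if (nv > 0) v <- v / nv
  v
}

#' Generate ranked linking candidates for a mention
#'
#' Exact cosine k-nearest-neighbour search over all (concept, alias)
#' vectors; per concept the best alias similarity is kept, concepts are
#' ranked by similarity (ties by concept id) and the top \code{k} distinct
#' concepts returned.  A mention identical to a stored alias has cosine 1
#' against that alias.  A mention with no in-vocabulary n-grams yields an
#' empty candidate set.
#'
#' @param index a \code{medlit_ngram_index}.
#' @param mention surface string.
#' @param k maximum number of candidates.
#' @return object of class \code{medlit_candidates}: \code{mention} and
#'   \code{candidates} (data.frame \code{concept_id}, \code{score}).
#' @export
candidates <- function(index, mention, k = 25L) {
  stopifnot(inherits(index, "medlit_ngram_index"))
  if (k < 1L) contract_error("k must be >= 1")
  v <- index_vectorize(index, mention)
  empty <- data.frame(concept_id = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (all(v == 0)) {
    message(sprintf("mention '%s' has no in-vocabulary n-grams", mention))
    return(structure(list(mention = mention, candidates = empty),
                     class = "medlit_candidates"))
  }
  sims <- as.numeric(index$M %*% v)
  best <- tapply(sims, index$concept_ids, max)
  df <- data.frame(concept_id = names(best), score = as.numeric(best),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$score, df$concept_id), , drop = FALSE]
  df <- utils::head(df, k)
  rownames(df) <- NULL
  structure(list(mention = mention, candidates = df),
            class = "medlit_candidates")
}

# ---- word sense disambiguation --------------------------------------------

#' Context features for disambiguation
#'
#' Three feature families within a \code{window}-token span on each side of
#' the mention: unigrams, bigrams over adjacent window tokens, and
#' positional collocations (token at offset -2, -1, +1, +2 from the
#' mention).
#'
#' @param tokens character vector of context tokens (lowercased internally).
#' @param position integer range (indices into \code{tokens}) occupied by
#'   the mention, or NULL when unknown (collocations are then skipped).
#' @param window tokens considered on each side.
#' @return named numeric count vector.
#' @export
context_features <- function(tokens, position = NULL, window = 5L) {
  tokens <- tolower(tokens)
  feats <- character()
  if (is.null(position)) {
    sel <- seq_along(tokens)
    left <- integer(); right <- integer()
  } else {
    lo <- min(position); hi <- max(position)
    left <- seq_len(lo - 1L)
    left <- left[left >= lo - window]
    right <- seq_along(tokens)
    right <- right[right > hi & right <= hi + window]
    sel <- c(left, right)
  }
  if (length(sel)) feats <- c(feats, paste0("u:", tokens[sel]))
  runs <- if (is.null(position)) list(seq_along(tokens)) else list(left, right)
  for (r in runs) {
    if (length(r) >= 2L) {
      feats <- c(feats, paste0("b:", tokens[r[-length(r)]], "_", tokens[r[-1L]]))
    }
  }
  if (!is.null(position)) {
    lo <- min(position); hi <- max(position)
    for (off in c(-2L, -1L, 1L, 2L)) {
      idx <- if (off < 0L) lo + off else hi + off
      if (idx >= 1L && idx <= length(tokens)) {
        feats <- c(feats, sprintf("c:%d:%s", off, tokens[idx]))
      }
    }
  }
  if (!length(feats)) return(stats::setNames(numeric(0), character(0)))
  tab <- table(feats)
  stats::setNames(as.numeric(tab), names(tab))
}

#' Train the vector-space sense model
#'
#' Each concept's sense vector aggregates context features from its KB
#' definition (unigram + bigram families; there is no mention position in a
#' definition) and from any labeled training contexts (all three families,
#' locating the surface in the context when possible).  Works unsupervised
#' from definitions alone.
#'
#' @param kb a \code{medlit_kb}.
#' @param contexts optional data.frame with columns \code{surface},
#'   \code{concept}, \code{context} (free text), e.g. loaded from JSONL.
#' @param window context window size per side.
#' @return object of class \code{medlit_sense_model}: named list of sense
#'   vectors keyed by concept id.
#' @export
train_sense_model <- function(kb, contexts = NULL, window = 5L) {
  stopifnot(inherits(kb, "medlit_kb"))
  senses <- list()
  add <- function(id, v) {
    if (!length(v)) return()
    cur <- senses[[id]]
    if (is.null(cur)) senses[[id]] <<- v
    else {
      keys <- union(names(cur), names(v))
      merged <- stats::setNames(numeric(length(keys)), keys)
      merged[names(cur)] <- cur
      merged[names(v)] <- merged[names(v)] + v
      senses[[id]] <<- merged
    }
  }
  for (co in kb$concepts) {
    if (nzchar(co$definition)) {
      toks <- tokenize_text(co$definition)$token
      add(co$id, context_features(toks, position = NULL, window = window))
    }
  }
  if (!is.null(contexts) && nrow(contexts)) {
    for (r in seq_len(nrow(contexts))) {
      toks <- tokenize_text(contexts$context[r])$token
      pos <- locate_surface(toks, contexts$surface[r])
      add(contexts$concept[r], context_features(toks, pos, window = window))
    }
  }
  structure(list(senses = senses, window = window),
            class = "medlit_sense_model")
}

# find the token positions of a (possibly multi-token) surface, or NULL
locate_surface <- function(tokens, surface) {
  st <- tolower(tokenize_text(surface)$token)
  if (!length(st)) return(NULL)
  tl <- tolower(tokens)
  n <- length(st)
  if (length(tl) < n) return(NULL)
  for (i in seq_len(length(tl) - n + 1L)) {
    if (all(tl[i:(i + n - 1L)] == st)) return(i:(i + n - 1L))
  }
  NULL
}

cosine_named <- function(a, b) {
  if (!length(a) || !length(b)) return(0)
  common <- intersect(names(a), names(b))
  if (!length(common)) return(0)
  sum(a[common] * b[common]) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
}

#' Disambiguate a candidate set against its context
#'
#' The candidate whose sense vector has maximal cosine similarity to the
#' mention's context-feature vector wins.  A single candidate is returned
#' unchanged; an empty or uninformative context (all cosines zero) falls
#' back to candidate-generation order.
#'
#' @param cands a non-empty \code{medlit_candidates}.
#' @param context_tokens tokens of the surrounding text.
#' @param position indices of the mention within \code{context_tokens}
#'   (NULL if unknown).
#' @param sense_model a \code{medlit_sense_model}.
#' @return a linked mention: list with \code{surface}, \code{concept_id},
#'   \code{score} and \code{provenance} (\code{"knn+wsd"}).
#' @export
rank_candidates <- function(cands, context_tokens = character(),
                            position = NULL, sense_model = NULL) {
  stopifnot(inherits(cands, "medlit_candidates"))
  df <- cands$candidates
  if (!nrow(df)) contract_error("empty candidate set; skip linking instead")
  pick <- 1L
  score <- df$score[1L]
  if (nrow(df) > 1L && !is.null(sense_model) && length(context_tokens)) {
    ctx <- context_features(context_tokens, position,
                            window = sense_model$window)
    sims <- vapply(df$concept_id, function(id) {
      sv <- sense_model$senses[[id]]
      if (is.null(sv)) 0 else cosine_named(ctx, sv)
    }, numeric(1))
    if (any(sims > 0)) {
      pick <- which.max(sims)
      score <- sims[pick]
    }
  }
  list(surface = cands$mention, concept_id = df$concept_id[pick],
       score = unname(score), provenance = "knn+wsd")
}

#' Resolve one mention end to end
#'
#' Stop-word mentions are discarded (returns NULL).  A mention whose
#' normalized surface exactly matches a unique alias is resolved directly
#' (provenance \code{"exact-alias"}); otherwise kNN candidate generation
#' followed by word-sense disambiguation is used.  A mention with an empty
#' candidate set returns NULL.
#'
#' @param kb a \code{medlit_kb}.
#' @param index a \code{medlit_ngram_index} over \code{kb}.
#' @param surface mention surface string.
#' @param context_tokens,position,sense_model see \code{rank_candidates}.
#' @param k candidate list size.
#' @return linked-mention list or NULL.
#' @export
resolve_mention <- function(kb, index, surface, context_tokens = character(),
                            position = NULL, sense_model = NULL, k = 25L) {
  key <- normalize_alias(surface)
  if (key %in% kb$stopwords) return(NULL)
  hits <- lookup_alias(kb, surface)
  if (length(hits) == 1L) {
    return(list(surface = surface, concept_id = hits, score = 1,
                provenance = "exact-alias"))
  }
  cs <- candidates(index, surface, k = k)
  if (!nrow(cs$candidates)) return(NULL)
  rank_candidates(cs, context_tokens, position, sense_model)
}

#' Save / load an n-gram index
#'
#' @param index a \code{medlit_ngram_index}.
#' @param path artifact path.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "medlit_ngram_index"))
  saveRDS(index, path)
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, "medlit_ngram_index"))
  x
}

#' Read WSD training contexts from JSONL
#'
#' One object per line: \code{{"surface": ..., "concept": ..., "context": ...}}.
#'
#' @param path file path.
#' @return data.frame with columns \code{surface}, \code{concept},
#'   \code{context}.
#' @export
read_wsd_contexts <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON)
  data.frame(surface = vapply(recs, `[[`, character(1), "surface"),
             concept = vapply(recs, `[[`, character(1), "concept"),
             context = vapply(recs, `[[`, character(1), "context"),
             stringsAsFactors = FALSE)
}
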