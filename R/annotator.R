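# End-to-end document annotation: recognize medical mentions, drop stop
# words, classify term difficulty, keep only what the reader's literacy
# level warrants, link the survivors to the knowledge base, and attach each
# concept's definition plus its depth-1 taxonomic/associative neighbours.
# High-literacy readers see only difficult terms; low-literacy readers see
# medium and difficult terms; easy terms are never annotated.

#' Literacy-conditioned annotation policy
#'
#' @param mentions list of mentions, each carrying a \code{difficulty}
#'   field.
#' @param literacy \code{"low"} or \code{"high"}.
#' @return the filtered list, order preserved: high keeps only difficult;
#'   low keeps medium and difficult; easy is never kept.
#' @export
select_by_policy <- function(mentions, literacy) {
  if (!literacy %in% c("low", "high")) {
    contract_error("literacy must be 'low' or 'high'")
  }
  keep <- if (literacy == "high") "difficult" else c("medium", "difficult")
  Filter(function(m) m$difficulty %in% keep, mentions)
}

# overlapping spans: keep the longest, ties broken toward the leftmost
resolve_overlaps <- function(mentions) {
  if (length(mentions) <= 1L) return(mentions)
  lens <- vapply(mentions, function(m) m$end - m$start, numeric(1))
  starts <- vapply(mentions, function(m) m$start, numeric(1))
  ord <- order(-lens, starts)
  taken <- list()
  for (i in ord) {
    m <- mentions[[i]]
    clash <- any(vapply(taken, function(t)
      m$start < t$end && t$start < m$end, logical(1)))
    if (!clash) taken[[length(taken) + 1L]] <- m
  }
  taken[order(vapply(taken, function(m) m$start, numeric(1)))]
}

#' Annotation pipeline settings
#'
#' @param k candidate-list size for linking.
#' @param relation_depth hops of relation expansion per annotation.
#' @param relation_types relation types expanded into the \code{related}
#'   list.
#' @param max_chars refuse documents longer than this.
#' @param seed recorded in the output metadata (the pipeline itself is
#'   deterministic given its artifacts).
#' @return config list.
#' @export
annotate_config <- function(k = 25L, relation_depth = 1L,
                            relation_types = c(KB_TAXONOMIC_RELATIONS,
                                               "associative"),
                            max_chars = 100000L, seed = 1L) {
  list(k = k, relation_depth = relation_depth,
       relation_types = relation_types, max_chars = max_chars, seed = seed)
}

#' Annotate a medical document for a reader's literacy level
#'
#' Runs tag -> stop-word removal -> overlap resolution -> difficulty
#' classification -> literacy policy filter -> candidate generation -> word
#' sense disambiguation -> relation expansion.  Mentions with empty
#' candidate sets are dropped (with a message).  Deterministic given fixed
#' artifacts and seed.
#'
#' @param text document string.
#' @param literacy \code{"low"} or \code{"high"}.
#' @param models list with components \code{tagger}
#'   (\code{medlit_tagger}), \code{difficulty}
#'   (\code{medlit_difficulty_model}), \code{index}
#'   (\code{medlit_ngram_index}), \code{kb} (\code{medlit_kb}) and
#'   optionally \code{sense_model} (\code{medlit_sense_model}).
#' @param config from \code{annotate_config}.
#' @return object of class \code{medlit_annotated}: \code{text},
#'   \code{literacy}, \code{annotations} (each with \code{start},
#'   \code{end}, \code{surface}, \code{concept_id}, \code{difficulty},
#'   \code{definition}, \code{related}) and \code{metadata}.
#' @export
annotate_document <- function(text, literacy, models,
                              config = annotate_config()) {
  for (need in c("tagger", "difficulty", "index", "kb")) {
    if (is.null(models[[need]])) {
      contract_error(sprintf("missing pipeline artifact: %s", need))
    }
  }
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  if (nchar(text) > config$max_chars) {
    contract_error(sprintf("document exceeds the %d-character limit",
                           config$max_chars))
  }
  kb <- models$kb

  mentions <- tag_text(models$tagger, text)
  mentions <- Filter(function(m)
    !(normalize_alias(m$surface) %in% kb$stopwords), mentions)
  mentions <- resolve_overlaps(mentions)

  if (length(mentions)) {
    labels <- predict_difficulty(models$difficulty,
                                 vapply(mentions, `[[`, character(1),
                                        "surface"), kb)
    for (i in seq_along(mentions)) mentions[[i]]$difficulty <- labels[i]
  }
  mentions <- select_by_policy(mentions, literacy)

  toks <- tokenize_text(text)
  annotations <- list()
  for (m in mentions) {
    pos <- which(toks$start < m$end & toks$end > m$start)
    linked <- resolve_mention(kb, models$index, m$surface,
                              context_tokens = toks$token,
                              position = if (length(pos)) pos else NULL,
                              sense_model = models$sense_model,
                              k = config$k)
    if (is.null(linked)) {
      message(sprintf("dropping unlinkable mention '%s'", m$surface))
      next
    }
    cid <- linked$concept_id
    rel_ids <- neighborhood(kb, cid, config$relation_types,
                            depth = config$relation_depth)
    related <- lapply(sort(rel_ids), function(rid) {
      rt <- vapply(kb$concepts[[cid]]$relations, function(r)
        if (r$target == rid) r$type else NA_character_, character(1))
      rt <- rt[!is.na(rt)]
      list(type = if (length(rt)) rt[1] else "related",
           concept_id = rid, name = kb$concepts[[rid]]$name)
    })
    annotations[[length(annotations) + 1L]] <- list(
      start = m$start, end = m$end, surface = m$surface,
      concept_id = cid, difficulty = m$difficulty,
      definition = kb$concepts[[cid]]$definition, related = related)
  }

  structure(list(
    text = text, literacy = literacy, annotations = annotations,
    metadata = list(
      package = as.character(utils::packageVersion("medlit")),
      n_tags = length(models$tagger$tags),
      kb_concepts = length(kb$concepts),
      seed = config$seed)
  ), class = "medlit_annotated")
}

#' @export
print.medlit_annotated <- function(x, ...) {
  cat(sprintf("<medlit_annotated> literacy=%s, %d annotation(s)\n",
              x$literacy, length(x$annotations)))
  for (a in x$annotations) {
    cat(sprintf("  [%d,%d) %-18s %-9s -> %s\n", a$start, a$end, a$surface,
                a$difficulty, a$concept_id))
  }
  invisible(x)
}

#' Canonical JSON rendering of an annotated document
#'
#' Keys are emitted in sorted order and numbers with a fixed precision, so
#' repeated runs with identical artifacts produce byte-identical output.
#'
#' @param doc a \code{medlit_annotated}.
#' @return single JSON string.
#' @export
annotated_json <- function(doc) {
  stopifnot(inherits(doc, "medlit_annotated"))
  ann <- lapply(doc$annotations, function(a) {
    list(concept_id = a$concept_id,
         definition = a$definition,
         difficulty = a$difficulty,
         end = a$end,
         related = lapply(a$related, function(r)
           list(concept_id = r$concept_id, name = r$name, type = r$type)),
         start = a$start,
         surface = a$surface)
  })
  meta <- doc$metadata[order(names(doc$metadata))]
  as.character(jsonlite::toJSON(
    list(annotations = ann, literacy = doc$literacy, metadata = meta,
         text = doc$text),
    auto_unbox = TRUE, digits = 10))
}

#' @rdname annotated_json
#' @param path output file.
#' @export
write_annotated_json <- function(doc, path) {
  writeLines(annotated_json(doc), path, useBytes = TRUE)
  invisible(path)
}

#' Self-contained HTML view of an annotated document
#'
#' Presentational only: highlights each annotated span and shows the
#' definition and related concepts on hover.
#'
#' @param doc a \code{medlit_annotated}.
#' @return single HTML string.
#' @export
annotated_html <- function(doc) {
  stopifnot(inherits(doc, "medlit_annotated"))
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    s <- gsub(">", "&gt;", s, fixed = TRUE)
    gsub("\"", "&quot;", s, fixed = TRUE)
  }
  pieces <- character()
  cur <- 0L
  for (a in doc$annotations) {
    if (a$start > cur) {
      pieces <- c(pieces, esc(substring(doc$text, cur + 1L, a$start)))
    }
    rel <- paste(vapply(a$related, function(r)
      sprintf("%s: %s", r$type, r$name), character(1)), collapse = "; ")
    tip <- esc(paste0(a$definition, if (nzchar(rel)) paste0(" [", rel, "]")))
    pieces <- c(pieces, sprintf(
      '<mark class="medlit %s" title="%s">%s</mark>',
      a$difficulty, tip, esc(substring(doc$text, a$start + 1L, a$end))))
    cur <- a$end
  }
  if (cur < nchar(doc$text)) {
    pieces <- c(pieces, esc(substring(doc$text, cur + 1L)))
  }
  paste0(
    "<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\"/><style>",
    "mark.medlit{background:#fff3b0}mark.difficult{background:#ffc9c9}",
    "</style></head><body><p>", paste(pieces, collapse = ""),
    "</p></body></html>")
}
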