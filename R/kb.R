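# Knowledge-base schema: a license-free JSONL concept store with alias
# indexing, relation traversal and a medical stop-word list.  Each concept
# carries an opaque CUI-like id, a canonical name, aliases, a free-text
# definition, semantic-type strings, and typed relations to other concepts
# (instance_of / subclass_of / part_of / has_part plus labelled associative
# edges).

KB_TAXONOMIC_RELATIONS <- c("instance_of", "subclass_of", "part_of", "has_part")

#' Normalize an alias or mention surface
#'
#' NFC Unicode normalization, case folding and whitespace collapse.  No
#' stemming: stemming would merge distinct concepts unpredictably.  The
#' function is idempotent.
#'
#' @param s character vector.
#' @return normalized character vector.
#' @export
#' @examples
#' normalize_alias(c("  Common   Cold ", "COLD"))
normalize_alias <- function(s) {
  s <- enc2utf8(as.character(s))
  s <- stringi_nfc(s)
  s <- tolower(s)
  s <- gsub("\\s+", " ", s, perl = TRUE)
  trimws(s)
}

# NFC via base R; icu-backed stringi is not a dependency, and utf8 text from
# our own writers is already composed, so this is a light-touch pass.
stringi_nfc <- function(s) {
  out <- iconv(s, from = "UTF-8", to = "UTF-8")
  out[is.na(out) & !is.na(s)] <- s[is.na(out) & !is.na(s)]
  out
}

new_concept <- function(id, name, aliases = character(), definition = "",
                        semtypes = character(), relations = list()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(name), length(name) == 1L)
  rel <- lapply(relations, function(r) {
    list(type = as.character(r$type), target = as.character(r$target))
  })
  structure(list(id = id, name = name,
                 aliases = unique(as.character(aliases)),
                 definition = as.character(definition)[1],
                 semtypes = as.character(semtypes),
                 relations = rel),
            class = "medlit_concept")
}

#' Build a knowledge base from a list of concepts
#'
#' Validates ids, builds the normalized alias index (the canonical name is
#' always indexed), and checks relation targets.  Dangling targets are
#' dropped with a warning, or abort the build when \code{strict = TRUE}.
#'
#' @param concepts list of concept records (as produced by \code{load_kb} or
#'   assembled in code: each a list with \code{id}, \code{name},
#'   \code{aliases}, \code{definition}, \code{semtypes}, \code{relations}).
#' @param stopwords character vector of medical stop words (normalized
#'   internally).  Defaults to the list shipped with the package.
#' @param strict abort on dangling relation targets instead of dropping them.
#' @return object of class \code{medlit_kb} with elements \code{concepts}
#'   (named list), \code{alias_index} (named list of id vectors) and
#'   \code{stopwords}.
#' @export
build_kb <- function(concepts, stopwords = default_stopwords(), strict = FALSE) {
  ids <- vapply(concepts, function(x) x$id, character(1))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    contract_error(sprintf("duplicate concept id(s): %s",
                           paste(unique(dup), collapse = ", ")))
  }
  names(concepts) <- ids
  idset <- ids

  # drop or reject dangling relation targets
  concepts <- lapply(concepts, function(co) {
    if (!length(co$relations)) return(co)
    ok <- vapply(co$relations, function(r) r$target %in% idset, logical(1))
    if (!all(ok)) {
      bad <- vapply(co$relations[!ok], function(r) r$target, character(1))
      if (strict) {
        contract_error(sprintf(
          "concept %s has relation(s) to unknown target(s): %s",
          co$id, paste(unique(bad), collapse = ", ")))
      }
      warning(sprintf("concept %s: dropping relation(s) to unknown target(s): %s",
                      co$id, paste(unique(bad), collapse = ", ")),
              call. = FALSE)
      co$relations <- co$relations[ok]
    }
    co
  })

  alias_index <- list()
  for (co in concepts) {
    keys <- unique(normalize_alias(c(co$name, co$aliases)))
    keys <- keys[nzchar(keys)]
    for (k in keys) alias_index[[k]] <- c(alias_index[[k]], co$id)
  }
  alias_index <- lapply(alias_index, unique)

  structure(list(concepts = concepts,
                 alias_index = alias_index,
                 stopwords = unique(normalize_alias(stopwords))),
            class = "medlit_kb")
}

#' @export
print.medlit_kb <- function(x, ...) {
  cat(sprintf("<medlit_kb> %d concepts, %d alias keys, %d stop words\n",
              length(x$concepts), length(x$alias_index), length(x$stopwords)))
  invisible(x)
}

#' Load a knowledge base from a JSONL file
#'
#' One JSON object per line with fields \code{id}, \code{name},
#' \code{aliases}, \code{definition}, \code{semtypes} and \code{relations}
#' (a list of \code{{"type": ..., "target": ...}}).  Malformed lines raise a
#' parse error naming the line number; duplicate ids raise a validation
#' error naming the id.
#'
#' @inheritParams build_kb
#' @param path path to the JSONL file.
#' @return a \code{medlit_kb}.
#' @export
load_kb <- function(path, strict = FALSE, stopwords = default_stopwords()) {
  if (!file.exists(path)) contract_error(sprintf("KB file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  concepts <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e) {
                      contract_error(sprintf("line %d: malformed JSON (%s)",
                                             i, conditionMessage(e)))
                    })
    concepts[[i]] <- new_concept(
      id = rec$id, name = rec$name,
      aliases = unlist(rec$aliases),
      definition = if (is.null(rec$definition)) "" else rec$definition,
      semtypes = unlist(rec$semtypes),
      relations = if (is.null(rec$relations)) list() else rec$relations
    )
  }
  build_kb(concepts, stopwords = stopwords, strict = strict)
}

#' Write a knowledge base to JSONL
#'
#' Inverse of \code{load_kb} up to concept order; \code{load_kb(write_kb(kb))}
#' reproduces the same concepts, alias index and relations.
#'
#' @param kb a \code{medlit_kb}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_kb <- function(kb, path) {
  stopifnot(inherits(kb, "medlit_kb"))
  lines <- vapply(kb$concepts, function(co) {
    jsonlite::toJSON(list(
      id = co$id, name = co$name, aliases = as.list(co$aliases),
      definition = co$definition, semtypes = as.list(co$semtypes),
      relations = lapply(co$relations, function(r)
        list(type = r$type, target = r$target))
    ), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Concepts reachable along selected relation types
#'
#' Breadth-first traversal from \code{id} following outgoing edges whose type
#' is in \code{relation_types}, up to \code{depth} hops.  The start concept
#' itself is excluded.  Associative edges are matched either by their full
#' label (\code{"associative:<label>"}) or by the catch-all
#' \code{"associative"}.
#'
#' @param kb a \code{medlit_kb}.
#' @param id concept id present in \code{kb}.
#' @param relation_types character vector of relation types to follow.
#' @param depth non-negative integer number of hops.
#' @return character vector of reachable concept ids (unordered).
#' @export
neighborhood <- function(kb, id,
                         relation_types = KB_TAXONOMIC_RELATIONS,
                         depth = 1L) {
  stopifnot(inherits(kb, "medlit_kb"))
  if (!id %in% names(kb$concepts)) {
    contract_error(sprintf("unknown concept id: %s", id))
  }
  if (depth < 0) contract_error("depth must be >= 0")
  follow <- function(rt) {
    rt %in% relation_types ||
      (startsWith(rt, "associative:") && "associative" %in% relation_types)
  }
  seen <- character()
  frontier <- id
  d <- 0L
  while (d < depth && length(frontier)) {
    nxt <- character()
    for (cur in frontier) {
      for (r in kb$concepts[[cur]]$relations) {
        if (follow(r$type) && !(r$target %in% c(seen, id))) {
          nxt <- c(nxt, r$target)
        }
      }
    }
    nxt <- unique(nxt)
    seen <- unique(c(seen, nxt))
    frontier <- nxt
    d <- d + 1L
  }
  setdiff(seen, id)
}

#' Look up the concepts carrying an alias
#'
#' @param kb a \code{medlit_kb}.
#' @param surface raw surface string; normalized before lookup.
#' @return character vector of concept ids (possibly empty).
#' @export
lookup_alias <- function(kb, surface) {
  stopifnot(inherits(kb, "medlit_kb"))
  key <- normalize_alias(surface)
  ids <- kb$alias_index[[key]]
  if (is.null(ids)) character() else ids
}

#' The medical stop-word list shipped with the package
#'
#' Plain-text resource, one token per line, \code{#} comments allowed.
#' Users can pass their own list to \code{build_kb}/\code{load_kb}.
#'
#' @param path optional path to an alternative stop-word file.
#' @return character vector of stop words.
#' @export
default_stopwords <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "stopwords_medical.txt", package = "medlit")
  }
  if (!nzchar(path) || !file.exists(path)) return(character())
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}
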