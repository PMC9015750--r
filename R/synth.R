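# Synthetic-data generators: pseudo-medical knowledge bases with controlled
# alias ambiguity, gold-tagged corpora built from KB aliases, Bernoulli
# response matrices drawn from the 3PL model, vote-labelled difficulty
# datasets, and a deliberately ambiguous linking fixture.  Every generator
# is a pure function of (spec, seed): repeated runs are byte-identical.

#' Specification for the synthetic generators
#'
#' Defaults describe the desk-scale study conditions used throughout the
#' test-suite: a 50-concept KB with 10\% shared aliases, 30 training
#' sentences at 30\% entity-token density, a 30-item / 2000-person response
#' matrix with discriminations in [0.8, 2], difficulties in [-2, 2] and
#' guessing in [0, 0.25], and a 60-term difficulty set with balanced
#' classes labelled by a simulated 6-annotator panel.
#'
#' @param seed integer master seed.
#' @param n_concepts number of KB concepts.
#' @param ambiguity_rate fraction of aliases shared by >= 2 concepts.
#' @param n_sentences corpus size.
#' @param entity_density target fraction of entity tokens.
#' @param irt list: \code{n_items}, \code{n_persons}, \code{a_range},
#'   \code{b_range}, \code{c_range}.
#' @param difficulty list: \code{n_terms}, \code{proportions} (named, sums
#'   to 1), \code{vote_probs} (per-class probability of a positive vote).
#' @return validated spec list of class \code{medlit_synth_spec}.
#' @export
synth_spec <- function(seed = 1L, n_concepts = 50L, ambiguity_rate = 0.1,
                       n_sentences = 30L, entity_density = 0.3,
                       irt = list(n_items = 30L, n_persons = 2000L,
                                  a_range = c(0.8, 2), b_range = c(-2, 2),
                                  c_range = c(0, 0.25)),
                       difficulty = list(
                         n_terms = 60L,
                         proportions = c(easy = 1 / 3, medium = 1 / 3,
                                         difficult = 1 / 3),
                         vote_probs = c(easy = 0.99, medium = 0.75,
                                        difficult = 0.1))) {
  stopifnot(n_concepts > 0L, n_sentences > 0L,
            ambiguity_rate >= 0, ambiguity_rate <= 1,
            entity_density > 0, entity_density < 1,
            irt$n_items > 0L, irt$n_persons > 0L,
            difficulty$n_terms > 0L,
            abs(sum(difficulty$proportions) - 1) < 1e-8,
            all(difficulty$vote_probs >= 0 & difficulty$vote_probs <= 1))
  structure(list(seed = as.integer(seed), n_concepts = as.integer(n_concepts),
                 ambiguity_rate = ambiguity_rate,
                 n_sentences = as.integer(n_sentences),
                 entity_density = entity_density, irt = irt,
                 difficulty = difficulty),
            class = "medlit_synth_spec")
}

# pronounceable pseudo-words from consonant-vowel syllable templates
synth_word <- function(n_syll = 2L) {
  cons <- c("b", "c", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s",
            "t", "v", "z", "th", "br", "cl", "pr", "st")
  vow <- c("a", "e", "i", "o", "u", "ae", "ia", "io")
  paste(vapply(seq_len(n_syll), function(i)
    paste0(sample(cons, 1L), sample(vow, 1L)), character(1)), collapse = "")
}

synth_affixes <- function() {
  res <- difficulty_resources()
  list(prefixes = res$prefixes, suffixes = res$suffixes)
}

#' Generate a pseudo-medical knowledge base
#'
#' Concept names are pronounceable pseudo-words, some carrying medical
#' affixes; each concept gets 1-4 aliases, a templated definition built
#' from a shared symptom/anatomy vocabulary, a semantic type in
#' \{Disease, Problem, Drug, Test\}, and taxonomic relations forming a
#' forest (plus sparse associative edges).  Exactly
#' \code{round(ambiguity_rate * n_aliases)} aliases are shared by two
#' concepts.
#'
#' @param spec a \code{medlit_synth_spec}.
#' @param path optional JSONL output path (written deterministically).
#' @return the \code{medlit_kb} (invisibly returns the path when written).
#' @export
synth_kb <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "medlit_synth_spec"))
  kb <- with_seed(spec$seed, {
    n <- spec$n_concepts
    af <- synth_affixes()
    types <- c("Disease", "Problem", "Drug", "Test")
    # shared vocabulary for definitions, so sense vectors have structure
    organs <- replicate(8L, synth_word(2L))
    symptoms <- replicate(12L, synth_word(2L))

    names_ <- character(0)
    while (length(unique(names_)) < n) {
      base <- synth_word(sample(2:3, 1L))
      if (stats::runif(1) < 0.4) {
        base <- if (stats::runif(1) < 0.5 && length(af$prefixes))
          paste0(sample(af$prefixes, 1L), base)
        else if (length(af$suffixes)) paste0(base, sample(af$suffixes, 1L))
        else base
      }
      names_ <- unique(c(names_, base))
    }
    names_ <- names_[seq_len(n)]

    used <- names_                 # global uniqueness across all surfaces
    concepts <- vector("list", n)
    for (i in seq_len(n)) {
      ty <- sample(types, 1L)
      n_alias <- sample(1:4, 1L)
      aliases <- character(0)
      if (n_alias > 1L) {
        while (length(aliases) < n_alias - 1L) {
          cand <- if (stats::runif(1) < 0.3)
            paste(synth_word(1L), names_[i]) else synth_word(sample(2:3, 1L))
          if (!(cand %in% used)) {
            aliases <- c(aliases, cand)
            used <- c(used, cand)
          }
        }
      }
      def <- sprintf("A %s of the %s marked by %s and %s.",
                     tolower(ty), sample(organs, 1L),
                     sample(symptoms, 1L), sample(symptoms, 1L))
      relations <- list()
      if (i > 1L && stats::runif(1) < 0.6) {
        relations[[1]] <- list(type = sample(KB_TAXONOMIC_RELATIONS, 1L),
                               target = sprintf("C%04d", sample(i - 1L, 1L)))
      }
      if (i > 1L && stats::runif(1) < 0.2) {
        relations[[length(relations) + 1L]] <-
          list(type = "associative:related_finding",
               target = sprintf("C%04d", sample(i - 1L, 1L)))
      }
      concepts[[i]] <- new_concept(sprintf("C%04d", i), names_[i], aliases,
                                   def, ty, relations)
    }

    # inject the exact shared-alias count: a receiver concept swaps one of
    # its private aliases for a donor's canonical name, so the total alias
    # count is unchanged and exactly n_shared alias keys map to 2 concepts
    total_aliases <- sum(vapply(concepts, function(co)
      length(co$aliases) + 1L, integer(1)))
    n_shared <- round(spec$ambiguity_rate * total_aliases)
    if (n_shared > 0L && n > 1L) {
      donors <- sample(n, min(n_shared, n))
      for (d in donors) {
        cands <- which(vapply(seq_len(n), function(j)
          j != d && length(setdiff(concepts[[j]]$aliases, names_)) > 0L,
          logical(1)))
        if (!length(cands)) next
        recv <- if (length(cands) == 1L) cands else sample(cands, 1L)
        private <- setdiff(concepts[[recv]]$aliases, names_)
        drop_ <- private[1L]
        concepts[[recv]]$aliases <-
          c(setdiff(concepts[[recv]]$aliases, drop_), concepts[[d]]$name)
      }
    }
    build_kb(concepts)
  })
  if (!is.null(path)) write_kb(kb, path)
  kb
}

#' Generate a gold-tagged corpus from KB aliases
#'
#' Templated sentences embed KB aliases as gold entities (BIO tags, entity
#' type = the concept's semantic type).  Every gold surface is a KB alias.
#' The entity-token density matches \code{spec$entity_density} in
#' expectation; the construction is binomial per slot.
#'
#' @param kb a \code{medlit_kb}.
#' @param spec a \code{medlit_synth_spec} (uses \code{n_sentences},
#'   \code{entity_density} and \code{seed + 1}).
#' @param path optional CoNLL output path.
#' @return list with \code{sentences} (as \code{read_conll} returns) and
#'   \code{gold} (data.frame: sentence, start, end, surface, type,
#'   concept_id).
#' @export
synth_ner_corpus <- function(kb, spec, path = NULL) {
  stopifnot(inherits(kb, "medlit_kb"), inherits(spec, "medlit_synth_spec"))
  out <- with_seed(spec$seed + 1L, {
    fillers <- c("the", "patient", "was", "seen", "for", "a", "with", "and",
                 "mild", "severe", "after", "before", "no", "signs", "of",
                 "during", "visit", "noted", "on", "exam", "stable", "case")
    fillers <- setdiff(fillers, names(kb$alias_index))
    entries <- list()
    for (co in kb$concepts) {
      ty <- intersect(co$semtypes, NER_DEFAULT_TYPES)
      ty <- if (length(ty)) ty[1] else "Problem"
      for (al in unique(c(co$name, co$aliases))) {
        entries[[length(entries) + 1L]] <-
          list(surface = al, type = ty, id = co$id)
      }
    }
    m <- mean(vapply(entries, function(e)
      length(strsplit(e$surface, " ")[[1]]), numeric(1)))
    d <- spec$entity_density
    q <- d / (m * (1 - d) + d)     # per-slot entity probability

    sentences <- list()
    gold <- list()
    for (s in seq_len(spec$n_sentences)) {
      n_slots <- sample(8:12, 1L)
      toks <- character(); tags <- character()
      for (sl in seq_len(n_slots)) {
        if (stats::runif(1) < q) {
          e <- entries[[sample(length(entries), 1L)]]
          etoks <- strsplit(e$surface, " ")[[1]]
          toks <- c(toks, etoks)
          tags <- c(tags, paste0("B-", e$type),
                    rep(paste0("I-", e$type), length(etoks) - 1L))
          gold[[length(gold) + 1L]] <-
            data.frame(sentence = s, surface = e$surface, type = e$type,
                       concept_id = e$id, stringsAsFactors = FALSE)
        } else {
          toks <- c(toks, sample(fillers, 1L))
          tags <- c(tags, "O")
        }
      }
      ends <- cumsum(nchar(toks) + 1L) - 1L
      starts <- c(0L, utils::head(ends, -1L) + 1L)
      sentences[[s]] <- list(tokens = toks, tags = tags, start = starts,
                             end = ends, text = paste(toks, collapse = " "))
    }
    list(sentences = sentences,
         gold = if (length(gold)) do.call(rbind, gold) else
           data.frame(sentence = integer(), surface = character(),
                      type = character(), concept_id = character()))
  })
  if (!is.null(path)) write_conll(out$sentences, path)
  out
}

#' Simulate 3PL item parameters
#'
#' @param spec a \code{medlit_synth_spec} (uses \code{irt} ranges and
#'   \code{seed + 2}).
#' @return list of \code{medlit_item} drawn uniformly from the spec ranges.
#' @export
synth_items <- function(spec) {
  stopifnot(inherits(spec, "medlit_synth_spec"))
  with_seed(spec$seed + 2L, {
    k <- spec$irt$n_items
    a <- stats::runif(k, spec$irt$a_range[1], spec$irt$a_range[2])
    b <- stats::runif(k, spec$irt$b_range[1], spec$irt$b_range[2])
    cc <- stats::runif(k, spec$irt$c_range[1], spec$irt$c_range[2])
    lapply(seq_len(k), function(i)
      new_item(sprintf("item%02d", i), a[i], b[i], cc[i]))
  })
}

#' Draw a Bernoulli response matrix from the 3PL model
#'
#' Abilities are standard-normal; entry (j, i) is Bernoulli with
#' probability \code{prob_correct(item_i, theta_j)}.  The true theta vector
#' is returned alongside for recovery tests.
#'
#' @param items list of \code{medlit_item}.
#' @param n_persons number of simulated respondents.
#' @param seed integer seed.
#' @return list with \code{values} (persons x items 0/1 matrix) and
#'   \code{theta}.
#' @export
synth_responses <- function(items, n_persons, seed = 1L) {
  with_seed(seed, {
    theta <- stats::rnorm(n_persons)
    P <- vapply(items, function(it) prob_correct(it, theta),
                numeric(n_persons))
    values <- matrix(stats::rbinom(length(P), 1L, as.vector(P)),
                     nrow = n_persons)
    rownames(values) <- sprintf("p%04d", seq_len(n_persons))
    colnames(values) <- vapply(items, `[[`, character(1), "id")
    list(values = values, theta = theta)
  })
}

#' Generate a vote-labelled difficulty dataset
#'
#' Terms are drawn per class: easy terms are short common words (present in
#' the general-frequency and lexicon resources), medium terms are plain
#' pseudo-words, and difficult terms are long pseudo-words carrying medical
#' affixes.  Each term receives 6 simulated annotator votes, Bernoulli with
#' the class's positive-vote probability, and the gold label is derived
#' through \code{votes_to_label} -- exercising the panel labelling rule end
#' to end.
#'
#' @param spec a \code{medlit_synth_spec} (uses \code{difficulty} and
#'   \code{seed + 3}).
#' @param path optional CSV output path (\code{term,label}).
#' @return data.frame with \code{term}, \code{class} (generating class),
#'   \code{votes}, \code{label}.
#' @export
synth_difficulty_dataset <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "medlit_synth_spec"))
  out <- with_seed(spec$seed + 3L, {
    res <- difficulty_resources()
    easy_pool <- names(res$freq_general)
    easy_pool <- easy_pool[nchar(easy_pool) <= 6]
    af <- synth_affixes()
    n <- spec$difficulty$n_terms
    counts <- round(spec$difficulty$proportions * n)
    counts[1] <- n - sum(counts[-1])
    rows <- list()
    used <- character()
    for (cl in names(counts)) {
      for (i in seq_len(counts[[cl]])) {
        repeat {
          term <- switch(cl,
            easy = sample(easy_pool, 1L),
            medium = synth_word(sample(2:3, 1L)),
            difficult = paste0(sample(af$prefixes, 1L),
                               synth_word(sample(3:4, 1L)),
                               sample(af$suffixes, 1L)))
          if (!(term %in% used)) break
        }
        used <- c(used, term)
        votes <- sum(stats::rbinom(6L, 1L,
                                   spec$difficulty$vote_probs[[cl]]))
        rows[[length(rows) + 1L]] <- data.frame(
          term = term, class = cl, votes = votes,
          label = votes_to_label(votes), stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  if (!is.null(path)) {
    utils::write.csv(out[, c("term", "label")], path, row.names = FALSE)
  }
  out
}

#' Ambiguous-alias linking fixture with disjoint context vocabularies
#'
#' Builds a tiny KB in which one alias is shared by two concepts whose
#' definitions and training contexts use disjoint vocabularies (mirroring a
#' polysemous term like "cold"), plus seeded train and held-out context
#' sets for each sense.
#'
#' @param seed integer seed.
#' @param n_train labelled training contexts per sense.
#' @param n_test held-out contexts per sense.
#' @return list with \code{kb}, \code{alias}, \code{train} and \code{test}
#'   (data.frames: surface, concept, context).
#' @export
synth_ambiguous_fixture <- function(seed = 1L, n_train = 10L, n_test = 20L) {
  with_seed(seed, {
    alias <- "frigor"
    vocab_a <- c("sneezing", "cough", "runny", "nose", "fever", "virus",
                 "congestion", "throat")
    vocab_b <- c("shiver", "temperature", "exposure", "skin", "numb",
                 "frost", "extremity", "sensation")
    c1 <- new_concept("A01", "frigor infection", aliases = alias,
                      definition = paste("A viral infection with",
                                         paste(vocab_a[1:4], collapse = " ")),
                      semtypes = "Disease")
    c2 <- new_concept("A02", "frigor sensation", aliases = alias,
                      definition = paste("A sensation caused by",
                                         paste(vocab_b[1:4], collapse = " ")),
                      semtypes = "Problem")
    kb <- build_kb(list(c1, c2))
    mk <- function(concept, vocab, k) {
      data.frame(
        surface = rep(alias, k), concept = rep(concept, k),
        context = vapply(seq_len(k), function(i)
          paste("patient has", sample(vocab, 1L), "and",
                sample(vocab, 1L), alias, "with", sample(vocab, 1L)),
          character(1)),
        stringsAsFactors = FALSE)
    }
    list(kb = kb, alias = alias,
         train = rbind(mk("A01", vocab_a, n_train), mk("A02", vocab_b, n_train)),
         test = rbind(mk("A01", vocab_a, n_test %/% 2L),
                      mk("A02", vocab_b, n_test - n_test %/% 2L)))
  })
}
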