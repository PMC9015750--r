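# BiLSTM-CNN-CRF medical entity tagger.  Each token is encoded by the
# concatenation of a word embedding and a character-level CNN vector; a
# bidirectional LSTM contextualizes the sequence; a linear layer produces
# per-tag emission scores; a CRF layer scores whole tag paths and is decoded
# exactly by Viterbi.  Entity types cover diseases, medical problems, drug
# names and tests/examinations, in a BIO scheme.

NER_DEFAULT_TYPES <- c("Disease", "Problem", "Drug", "Test")

#' Default tagger architecture and optimizer settings
#'
#' Sizes are desk-scale: large enough for a CRF-backed tagger to memorize a
#' small training corpus, small enough to train in seconds per epoch on one
#' CPU.
#'
#' @param char_dim character embedding size.
#' @param char_filters number of width-3 character CNN filters.
#' @param word_dim word embedding size.
#' @param hidden LSTM hidden size per direction.
#' @param lr Adam learning rate.
#' @param epochs maximum training epochs.
#' @param check_every evaluate training F1 every this many epochs and stop
#'   early on a perfect score.
#' @param pretrained optional word-vector matrix (rownames = words) used to
#'   initialize known word embeddings; see \code{load_word_vectors}.
#' @return config list.
#' @export
tagger_config <- function(char_dim = 12L, char_filters = 16L, word_dim = 24L,
                          hidden = 20L, lr = 0.02, epochs = 200L,
                          check_every = 10L, pretrained = NULL) {
  list(char_dim = char_dim, char_filters = char_filters, word_dim = word_dim,
       hidden = hidden, lr = lr, epochs = epochs, check_every = check_every,
       pretrained = pretrained)
}

# ---- BIO utilities ---------------------------------------------------------

bio_tagset <- function(types) c("O", as.vector(rbind(paste0("B-", types),
                                                     paste0("I-", types))))

#' Validate a BIO tag sequence
#'
#' @param tags character vector of tags ("O", "B-Type", "I-Type").
#' @return TRUE if valid (no I-X after O, start, or a different type).
#' @export
bio_valid <- function(tags) {
  prev <- "O"
  for (tg in tags) {
    if (startsWith(tg, "I-")) {
      ty <- substring(tg, 3L)
      if (!(prev %in% paste0(c("B-", "I-"), ty))) return(FALSE)
    }
    prev <- tg
  }
  TRUE
}

# decode BIO tags into mention spans using per-token character offsets
bio_decode <- function(tokens, tags, starts, ends) {
  out <- list()
  i <- 1L
  n <- length(tags)
  while (i <= n) {
    if (startsWith(tags[i], "B-")) {
      ty <- substring(tags[i], 3L)
      j <- i
      while (j < n && tags[j + 1L] == paste0("I-", ty)) j <- j + 1L
      out[[length(out) + 1L]] <- list(
        surface = NA_character_, type = ty,
        start = starts[i], end = ends[j],
        token_start = i, token_end = j)
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# additive transition mask forbidding invalid BIO moves (start -> I-X and
# any transition into I-X not from B-X/I-X); -Inf entries
bio_transition_mask <- function(tags) {
  T_ <- length(tags)
  mask <- matrix(0, T_ + 2L, T_ + 2L)
  for (y in seq_len(T_)) {
    if (startsWith(tags[y], "I-")) {
      ty <- substring(tags[y], 3L)
      ok <- tags %in% paste0(c("B-", "I-"), ty)
      mask[seq_len(T_)[!ok], y] <- -Inf
      mask[T_ + 1L, y] <- -Inf               # start cannot enter I-X
    }
  }
  mask
}

# ---- CoNLL I/O -------------------------------------------------------------

#' Read a CoNLL-style tagged corpus
#'
#' Two-column format: token TAB tag, one token per line, blank line between
#' sentences.  Token character offsets are reconstructed by joining tokens
#' with single spaces.
#'
#' @param path file path.
#' @return list of sentences; each a list with \code{tokens}, \code{tags},
#'   \code{start}, \code{end} (0-based half-open offsets into the rebuilt
#'   sentence string) and \code{text}.
#' @export
read_conll <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  sents <- list()
  toks <- character(); tags <- character()
  flush <- function() {
    if (!length(toks)) return()
    ends <- cumsum(nchar(toks) + 1L) - 1L
    starts <- c(0L, utils::head(ends, -1L) + 1L)
    sents[[length(sents) + 1L]] <<- list(
      tokens = toks, tags = tags, start = starts, end = ends,
      text = paste(toks, collapse = " "))
    toks <<- character(); tags <<- character()
  }
  for (ln in lines) {
    if (!nzchar(trimws(ln))) { flush(); next }
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L) contract_error(sprintf("malformed CoNLL line: %s", ln))
    toks <- c(toks, parts[1]); tags <- c(tags, parts[2])
  }
  flush()
  sents
}

#' Write a corpus in CoNLL format
#'
#' @param sentences list of sentences with \code{tokens} and \code{tags}.
#' @param path output path.
#' @export
write_conll <- function(sentences, path) {
  blocks <- vapply(sentences, function(s)
    paste(paste(s$tokens, s$tags, sep = "\t"), collapse = "\n"), character(1))
  writeLines(paste(blocks, collapse = "\n\n"), path, useBytes = TRUE)
  invisible(path)
}

# ---- model -----------------------------------------------------------------

ner_build_vocab <- function(corpus) {
  words <- unique(tolower(unlist(lapply(corpus, `[[`, "tokens"))))
  chars <- unique(unlist(strsplit(unlist(lapply(corpus, `[[`, "tokens")), "")))
  list(word = stats::setNames(seq_along(words) + 1L, words),   # 1 = UNK
       char = stats::setNames(seq_along(chars) + 1L, chars))
}

ner_word_ids <- function(vocab, tokens) {
  ids <- unname(vocab$word[tolower(tokens)])
  ids[is.na(ids)] <- 1L
  ids
}

ner_char_ids <- function(vocab, token) {
  ids <- unname(vocab$char[strsplit(token, "")[[1]]])
  ids[is.na(ids)] <- 1L
  if (!length(ids)) ids <- 1L
  ids
}

ner_init_par <- function(vocab, tags, cfg) {
  nw <- length(vocab$word) + 1L
  nc <- length(vocab$char) + 1L
  T_ <- length(tags)
  D <- cfg$word_dim + cfg$char_filters
  H <- cfg$hidden
  par <- list(
    Echar = nn_init_matrix(nc, cfg$char_dim, 0.25),
    Wc = nn_init_matrix(3L * cfg$char_dim, cfg$char_filters),
    bc = numeric(cfg$char_filters),
    Eword = nn_init_matrix(nw, cfg$word_dim, 0.25),
    Wx_f = nn_init_matrix(D, 4L * H), Wh_f = nn_init_matrix(H, 4L * H),
    b_f = numeric(4L * H),
    Wx_b = nn_init_matrix(D, 4L * H), Wh_b = nn_init_matrix(H, 4L * H),
    b_b = numeric(4L * H),
    Wout = nn_init_matrix(2L * H, T_), bout = numeric(T_),
    trans = nn_init_matrix(T_ + 2L, T_ + 2L, 0.1)
  )
  # forget-gate bias at 1 helps short-sequence memorization
  par$b_f[(H + 1L):(2L * H)] <- 1
  par$b_b[(H + 1L):(2L * H)] <- 1
  if (!is.null(cfg$pretrained)) {
    hit <- intersect(rownames(cfg$pretrained), names(vocab$word))
    if (length(hit) && ncol(cfg$pretrained) == cfg$word_dim) {
      par$Eword[vocab$word[hit], ] <- cfg$pretrained[hit, , drop = FALSE]
    }
  }
  par
}

# forward pass for one sentence: emissions + caches for backprop
ner_sent_forward <- function(par, word_ids, char_ids_list, cfg) {
  L <- length(word_ids)
  cnn_out <- matrix(0, L, cfg$char_filters)
  cnn_caches <- vector("list", L)
  for (t in seq_len(L)) {
    cf <- charcnn_forward(char_ids_list[[t]], par$Echar, par$Wc, par$bc)
    cnn_out[t, ] <- cf$out
    cnn_caches[[t]] <- cf$cache
  }
  X <- cbind(par$Eword[word_ids, , drop = FALSE], cnn_out)
  fw <- lstm_forward(X, par$Wx_f, par$Wh_f, par$b_f, reverse = FALSE)
  bw <- lstm_forward(X, par$Wx_b, par$Wh_b, par$b_b, reverse = TRUE)
  Hcat <- cbind(fw$H, bw$H)
  emis <- sweep(Hcat %*% par$Wout, 2L, par$bout, "+")
  list(emissions = emis, X = X, Hcat = Hcat, fw = fw, bw = bw,
       cnn_caches = cnn_caches)
}

ner_sent_backward <- function(par, cfg, fcache, d_emis, grads, word_ids) {
  H <- cfg$hidden
  grads$Wout <- grads$Wout + crossprod(fcache$Hcat, d_emis)
  grads$bout <- grads$bout + colSums(d_emis)
  dHcat <- d_emis %*% t(par$Wout)
  bf <- lstm_backward(dHcat[, 1:H, drop = FALSE], fcache$fw$cache,
                      par$Wx_f, par$Wh_f,
                      list(Wx = grads$Wx_f, Wh = grads$Wh_f, b = grads$b_f))
  grads$Wx_f <- bf$grads$Wx; grads$Wh_f <- bf$grads$Wh; grads$b_f <- bf$grads$b
  bb <- lstm_backward(dHcat[, (H + 1L):(2L * H), drop = FALSE],
                      fcache$bw$cache, par$Wx_b, par$Wh_b,
                      list(Wx = grads$Wx_b, Wh = grads$Wh_b, b = grads$b_b))
  grads$Wx_b <- bb$grads$Wx; grads$Wh_b <- bb$grads$Wh; grads$b_b <- bb$grads$b
  dX <- bf$dX + bb$dX
  dw <- cfg$word_dim
  for (t in seq_along(word_ids)) {
    id <- word_ids[t]
    grads$Eword[id, ] <- grads$Eword[id, ] + dX[t, 1:dw]
    cc <- fcache$cnn_caches[[t]]
    g2 <- charcnn_backward(dX[t, (dw + 1L):ncol(dX)], cc, par$Wc,
                           list(E = grads$Echar, Wc = grads$Wc, bc = grads$bc))
    grads$Echar <- g2$E; grads$Wc <- g2$Wc; grads$bc <- g2$bc
  }
  grads
}

#' Train the BiLSTM-CNN-CRF tagger
#'
#' Minimizes the negative CRF log-likelihood (log-partition minus gold path
#' score) by per-sentence Adam updates.  Training is deterministic given
#' \code{seed}: parameters are initialized from the seeded RNG and sentences
#' are visited in a seeded shuffled order each epoch.  Training stops early
#' once the training-set entity F1 reaches 1.0 (checked every
#' \code{config$check_every} epochs).
#'
#' @param corpus list of tagged sentences (\code{tokens}, \code{tags}), e.g.
#'   from \code{read_conll} or \code{synth_ner_corpus}.
#' @param config from \code{tagger_config}.
#' @param seed integer seed controlling initialization and epoch order.
#' @param types entity type inventory; defaults to the union found in the
#'   corpus tags.
#' @return object of class \code{medlit_tagger} with the learned parameters,
#'   vocabularies, tag set, config, seed and the per-epoch \code{loss} trace.
#' @export
train_tagger <- function(corpus, config = tagger_config(), seed = 1L,
                         types = NULL) {
  if (!length(corpus)) contract_error("empty training corpus")
  seen_tags <- unique(unlist(lapply(corpus, `[[`, "tags")))
  if (is.null(types)) {
    types <- sort(unique(substring(seen_tags[seen_tags != "O"], 3L)))
  }
  tags <- bio_tagset(types)
  bad <- setdiff(seen_tags, tags)
  if (length(bad)) {
    contract_error(sprintf("corpus tag(s) outside the declared set: %s",
                           paste(bad, collapse = ", ")))
  }
  for (s in corpus) {
    if (length(s$tokens) != length(s$tags)) {
      contract_error("tokens and tags must align in every sentence")
    }
    if (!bio_valid(s$tags)) contract_error("BIO-invalid tag sequence in corpus")
  }

  vocab <- ner_build_vocab(corpus)
  model <- with_seed(seed, {
    par <- ner_init_par(vocab, tags, config)
    state <- adam_init(par)
    tag_ids <- lapply(corpus, function(s) match(s$tags, tags))
    word_ids <- lapply(corpus, function(s) ner_word_ids(vocab, s$tokens))
    char_ids <- lapply(corpus, function(s)
      lapply(s$tokens, ner_char_ids, vocab = vocab))
    loss_trace <- numeric(0)
    n <- length(corpus)

    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (si in ord) {
        fc <- ner_sent_forward(par, word_ids[[si]], char_ids[[si]], config)
        cg <- crf_nll_grad(fc$emissions, par$trans, tag_ids[[si]])
        ep_loss <- ep_loss + cg$nll
        grads <- nn_zero_like(par)
        grads$trans <- cg$d_transitions
        grads <- ner_sent_backward(par, config, fc, cg$d_emissions, grads,
                                   word_ids[[si]])
        upd <- adam_step(par, grads, state, lr = config$lr)
        par <- upd$par; state <- upd$state
      }
      loss_trace <- c(loss_trace, ep_loss / n)
      if (epoch %% config$check_every == 0L) {
        m <- structure(list(par = par, vocab = vocab, tags = tags,
                            types = types, config = config, seed = seed),
                       class = "medlit_tagger")
        if (tagger_f1(m, corpus) >= 1) break
      }
    }
    structure(list(par = par, vocab = vocab, tags = tags, types = types,
                   config = config, seed = seed, loss = loss_trace),
              class = "medlit_tagger")
  })
  model
}

#' @export
print.medlit_tagger <- function(x, ...) {
  cat(sprintf("<medlit_tagger> %d tags, |V|=%d words, %d epochs trained\n",
              length(x$tags), length(x$vocab$word), length(x$loss)))
  invisible(x)
}

# predict BIO tags for one pre-tokenized sentence
ner_predict_tags <- function(model, tokens, constrained = TRUE) {
  wid <- ner_word_ids(model$vocab, tokens)
  cid <- lapply(tokens, ner_char_ids, vocab = model$vocab)
  fc <- ner_sent_forward(model$par, wid, cid, model$config)
  trans <- model$par$trans
  if (constrained) trans <- trans + bio_transition_mask(model$tags)
  vit <- crf_viterbi(fc$emissions, trans)
  model$tags[vit$path]
}

#' Tag free text and return medical mentions
#'
#' Tokenizes the text (offset-preserving), splits on sentence-final
#' punctuation, decodes each sentence with constrained Viterbi (invalid BIO
#' transitions carry \code{-Inf} scores), and converts BIO runs into mention
#' spans with 0-based half-open character offsets into the original text.
#'
#' @param model a trained \code{medlit_tagger}.
#' @param text document string.
#' @param tokenizer offset-preserving tokenizer, by default
#'   \code{tokenize_text}.
#' @param constrained forbid BIO-invalid transitions during decoding.
#' @return list of mentions: \code{surface}, \code{type}, \code{start},
#'   \code{end}.
#' @export
tag_text <- function(model, text, tokenizer = tokenize_text,
                     constrained = TRUE) {
  stopifnot(inherits(model, "medlit_tagger"))
  toks <- tokenizer(text)
  if (!nrow(toks)) return(list())
  sent_break <- toks$token %in% c(".", "!", "?")
  sent_id <- cumsum(c(0L, utils::head(sent_break, -1L)))
  mentions <- list()
  for (sid in unique(sent_id)) {
    rows <- which(sent_id == sid & !sent_break)
    if (!length(rows)) next
    tags <- ner_predict_tags(model, toks$token[rows], constrained)
    dec <- bio_decode(toks$token[rows], tags,
                      toks$start[rows], toks$end[rows])
    for (m in dec) {
      m$surface <- substring(text, m$start + 1L, m$end)
      m$token_start <- NULL; m$token_end <- NULL
      mentions[[length(mentions) + 1L]] <- m
    }
  }
  mentions
}

#' Entity-level F1 of a tagger on a tagged corpus
#'
#' Exact span + type match, micro-averaged.
#'
#' @param model a \code{medlit_tagger}.
#' @param corpus list of tagged sentences.
#' @return F1 in [0, 1] (1 when both gold and predicted are empty).
#' @export
tagger_f1 <- function(model, corpus) {
  tp <- 0L; n_gold <- 0L; n_pred <- 0L
  for (s in corpus) {
    gold <- bio_decode(s$tokens, s$tags, seq_along(s$tokens), seq_along(s$tokens))
    pred_tags <- ner_predict_tags(model, s$tokens)
    pred <- bio_decode(s$tokens, pred_tags, seq_along(s$tokens),
                       seq_along(s$tokens))
    key <- function(m) sprintf("%d:%d:%s", m$token_start, m$token_end, m$type)
    gk <- vapply(gold, key, character(1))
    pk <- vapply(pred, key, character(1))
    tp <- tp + length(intersect(gk, pk))
    n_gold <- n_gold + length(gk); n_pred <- n_pred + length(pk)
  }
  if (n_gold == 0L && n_pred == 0L) return(1)
  prec <- if (n_pred) tp / n_pred else 0
  rec <- if (n_gold) tp / n_gold else 0
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

#' Save / load a trained tagger
#'
#' Single-file artifact containing vocabularies, parameters and config;
#' loading reproduces predictions bit-for-bit.
#'
#' @param model a \code{medlit_tagger}.
#' @param path artifact path.
#' @export
save_tagger <- function(model, path) {
  stopifnot(inherits(model, "medlit_tagger"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_tagger
#' @export
load_tagger <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "medlit_tagger"))
  m
}

#' Load word vectors in the standard text format
#'
#' One word per line: \code{word v1 v2 ...}.
#'
#' @param path file path.
#' @return numeric matrix with words as rownames.
#' @export
load_word_vectors <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, " +")
  words <- vapply(parts, `[[`, character(1), 1L)
  vecs <- t(vapply(parts, function(p) as.numeric(p[-1L]),
                   numeric(length(parts[[1]]) - 1L)))
  rownames(vecs) <- words
  vecs
}
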