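# Term-difficulty classification: is a medical term easy, medium or
# difficult for a lay reader?  Gold labels come from a 6-annotator vote rule;
# prediction combines a character-level neural encoder (BiLSTM + CNN over
# the term string) with a dense lexical/distributional feature vector:
# syntactic category, character and syllable counts, medical affixes,
# consonant/vowel composition, lexicon membership, general-corpus and
# medical-KB frequencies, KB semantic types and an optional word embedding.

DIFFICULTY_LEVELS <- c("easy", "medium", "difficult")

#' Derive a difficulty label from annotator votes
#'
#' A panel of 6 annotators states whether they understand the term.  All 6
#' positive: easy; 4 or 5 positive: medium; fewer than 4: difficult.
#'
#' @param positive_votes integer count of positive votes, 0..6 (vectorized).
#' @param panel_size the panel size (6).
#' @return character vector of labels.
#' @export
#' @examples
#' votes_to_label(0:6)
votes_to_label <- function(positive_votes, panel_size = 6L) {
  v <- as.integer(positive_votes)
  if (any(is.na(v)) || any(v < 0L) || any(v > panel_size)) {
    contract_error(sprintf("votes must lie in 0..%d", panel_size))
  }
  ifelse(v == panel_size, "easy", ifelse(v >= 4L, "medium", "difficult"))
}

#' Count syllables in a word
#'
#' Counts maximal vowel groups (a, e, i, o, u, y); a trailing silent-e group
#' (final \code{e} preceded by a consonant, with more than one group) is
#' dropped; the minimum is 1.  Multi-word surfaces sum over their alphabetic
#' chunks.
#'
#' @param word non-empty string.
#' @return integer syllable count.
#' @export
#' @examples
#' count_syllables("anemia")  # a | e | ia -> 3
#' count_syllables("bone")    # trailing silent e -> 1
count_syllables <- function(word) {
  if (!is.character(word) || length(word) != 1L || !nzchar(word)) {
    contract_error("word must be a non-empty string")
  }
  chunks <- regmatches(word, gregexpr("[A-Za-z]+", word))[[1]]
  if (!length(chunks)) return(1L)
  total <- 0L
  for (w in chunks) {
    wl <- tolower(w)
    groups <- gregexpr("[aeiouy]+", wl)[[1]]
    n <- if (groups[1] == -1L) 0L else length(groups)
    if (n > 1L && grepl("[^aeiouy]e$", wl)) {
      # the final group must be exactly that trailing 'e'
      last_start <- groups[n]
      last_len <- attr(groups, "match.length")[n]
      if (last_start + last_len - 1L == nchar(wl) && last_len == 1L &&
          substring(wl, last_start, last_start) == "e") {
        n <- n - 1L
      }
    }
    total <- total + max(n, 1L)
  }
  max(total, 1L)
}

#' Lexical resources for difficulty features
#'
#' All resources are plain-text and user-overridable: a general-corpus
#' frequency table (term TAB count), a lexicon word list standing in for
#' WordNet membership, an inventory of common medical prefixes/suffixes
#' (lines like \code{hyper-} and \code{-itis}), and an optional embedding
#' table in the standard text format.
#'
#' @param freq_general path to a frequency table, or a named numeric vector.
#' @param lexicon path to a word list, or a character vector.
#' @param affixes path to the affix inventory.
#' @param embeddings optional matrix (rownames = words) or path to a vector
#'   file readable by \code{load_word_vectors}.
#' @return list with \code{freq_general}, \code{lexicon}, \code{prefixes},
#'   \code{suffixes}, \code{embeddings}.
#' @export
difficulty_resources <- function(
    freq_general = system.file("extdata", "freq_general.tsv", package = "medlit"),
    lexicon = system.file("extdata", "lexicon_en.txt", package = "medlit"),
    affixes = system.file("extdata", "affixes_medical.txt", package = "medlit"),
    embeddings = NULL) {
  if (is.character(freq_general)) {
    tab <- utils::read.delim(freq_general, header = FALSE,
                             col.names = c("term", "count"),
                             stringsAsFactors = FALSE, comment.char = "#")
    freq_general <- stats::setNames(as.numeric(tab$count),
                                    normalize_alias(tab$term))
  }
  if (is.character(lexicon) && length(lexicon) == 1L && file.exists(lexicon)) {
    lx <- readLines(lexicon, encoding = "UTF-8", warn = FALSE)
    lx <- trimws(sub("#.*$", "", lx))
    lexicon <- lx[nzchar(lx)]
  }
  pre <- character(); suf <- character()
  if (is.character(affixes) && length(affixes) == 1L && file.exists(affixes)) {
    ln <- readLines(affixes, encoding = "UTF-8", warn = FALSE)
    ln <- trimws(sub("#.*$", "", ln))
    ln <- ln[nzchar(ln)]
    pre <- sub("-$", "", ln[grepl("-$", ln)])
    suf <- sub("^-", "", ln[grepl("^-", ln)])
  }
  if (is.character(embeddings) && length(embeddings) == 1L) {
    embeddings <- load_word_vectors(embeddings)
  }
  list(freq_general = freq_general,
       lexicon = normalize_alias(lexicon),
       prefixes = pre, suffixes = suf, embeddings = embeddings)
}

# rule-based syntactic category for an isolated term (fallback "noun")
syntactic_category <- function(term) {
  w <- trimws(term)
  first <- strsplit(w, "\\s+")[[1]][1]
  if (grepl("^[A-Z0-9]{2,}$", first)) return("abbreviation")
  if (grepl("(ing|ize|ise|ate|ify)$", tolower(first)) && nchar(first) > 4)
    return("verb")
  if (grepl("(ous|al|ic|ary|ive|able|ible|ent|ant)$", tolower(first)) &&
      nchar(first) > 4)
    return("adjective")
  if (grepl("^[A-Z][a-z]", first)) return("proper")
  "noun"
}

SYNTACTIC_CATEGORIES <- c("noun", "verb", "adjective", "proper",
                          "abbreviation", "other")

#' Extract difficulty features for a term
#'
#' Deterministic feature vector of fixed dimension given the resources and
#' knowledge base.  Character composition partitions every code point into
#' consonant / vowel (aeiou) / other (spaces, hyphens, digits, ...), so the
#' three counts always sum to the character count and the percentages to
#' 100.  Missing lookups take neutral values: frequency 0, lexicon
#' membership FALSE, zero embedding.
#'
#' @param term non-empty surface string.
#' @param kb optional \code{medlit_kb} supplying medical frequency and
#'   semantic types.
#' @param resources from \code{difficulty_resources}.
#' @param semtype_inventory character vector fixing the semantic-type
#'   multi-hot layout (defaults to all semtypes in \code{kb}).
#' @return list of class \code{medlit_term_features} with the named fields
#'   and \code{vector}, the flat numeric feature vector.
#' @export
extract_features <- function(term, kb = NULL,
                             resources = difficulty_resources(),
                             semtype_inventory = NULL) {
  if (!is.character(term) || length(term) != 1L || !nzchar(term)) {
    contract_error("term must be a non-empty string")
  }
  chars <- strsplit(term, "")[[1]]
  low <- tolower(chars)
  is_vowel <- low %in% c("a", "e", "i", "o", "u")
  is_cons <- grepl("^[a-z]$", low) & !is_vowel
  n_chars <- length(chars)
  n_vowels <- sum(is_vowel)
  n_consonants <- sum(is_cons)
  n_other <- n_chars - n_vowels - n_consonants
  pct <- c(consonants = 100 * n_consonants / n_chars,
           vowels = 100 * n_vowels / n_chars,
           other = 100 * n_other / n_chars)

  key <- normalize_alias(term)
  cat_ <- syntactic_category(term)
  tl <- tolower(gsub("[^a-z]", "", tolower(term)))
  pre_hit <- resources$prefixes[startsWith(tl, resources$prefixes)]
  prefix <- if (length(pre_hit)) pre_hit[which.max(nchar(pre_hit))] else "none"
  suf_hit <- resources$suffixes[endsWith(tl, resources$suffixes)]
  suffix <- if (length(suf_hit)) suf_hit[which.max(nchar(suf_hit))] else "none"

  in_wordnet <- key %in% resources$lexicon
  freq_general <- if (key %in% names(resources$freq_general))
    unname(resources$freq_general[key]) else 0
  freq_medical <- 0
  semtypes <- character()
  if (!is.null(kb)) {
    hits <- lookup_alias(kb, term)
    freq_medical <- length(hits)
    semtypes <- unique(unlist(lapply(hits, function(id)
      kb$concepts[[id]]$semtypes)))
    if (is.null(semtype_inventory)) {
      semtype_inventory <- sort(unique(unlist(lapply(kb$concepts,
                                                     `[[`, "semtypes"))))
    }
  }
  if (is.null(semtype_inventory)) semtype_inventory <- character()

  emb_dim <- if (is.null(resources$embeddings)) 0L else ncol(resources$embeddings)
  emb <- numeric(emb_dim)
  if (emb_dim && key %in% rownames(resources$embeddings)) {
    emb <- as.numeric(resources$embeddings[key, ])
  }

  onehot <- function(value, levels) as.numeric(levels == value)
  vec <- c(
    stats::setNames(onehot(cat_, SYNTACTIC_CATEGORIES),
                    paste0("cat_", SYNTACTIC_CATEGORIES)),
    n_chars = n_chars, n_syllables = count_syllables(term),
    stats::setNames(onehot(prefix, c(resources$prefixes, "none")),
                    paste0("pre_", c(resources$prefixes, "none"))),
    stats::setNames(onehot(suffix, c(resources$suffixes, "none")),
                    paste0("suf_", c(resources$suffixes, "none"))),
    n_consonants = n_consonants, n_vowels = n_vowels, n_other = n_other,
    pct_consonants = pct[["consonants"]], pct_vowels = pct[["vowels"]],
    pct_other = pct[["other"]],
    in_wordnet = as.numeric(in_wordnet),
    log_freq_general = log1p(freq_general),
    log_freq_medical = log1p(freq_medical),
    if (length(semtype_inventory))
      stats::setNames(as.numeric(semtype_inventory %in% semtypes),
                      paste0("sem_", semtype_inventory)),
    if (emb_dim) stats::setNames(emb, paste0("emb_", seq_len(emb_dim)))
  )
  structure(list(
    syntactic_category = cat_, n_chars = n_chars,
    n_syllables = count_syllables(term), prefix = prefix, suffix = suffix,
    n_consonants = n_consonants, n_vowels = n_vowels, n_other = n_other,
    pct_consonants = pct[["consonants"]], pct_vowels = pct[["vowels"]],
    pct_other = pct[["other"]], in_wordnet = in_wordnet,
    freq_general = freq_general, freq_medical = freq_medical,
    semtypes = semtypes, vector = vec
  ), class = "medlit_term_features")
}

#' Default difficulty-classifier settings
#'
#' @param char_dim,char_filters,hidden_char character encoder sizes
#'   (embedding, width-3 CNN filters, LSTM hidden per direction).
#' @param hidden width of the combined hidden layer.
#' @param lr Adam learning rate.
#' @param epochs training epochs.
#' @param engine \code{"neural"} (default: char BiLSTM-CNN encoder +
#'   features) or \code{"logistic"} (multinomial regression on the dense
#'   features only).
#' @return config list.
#' @export
difficulty_config <- function(char_dim = 12L, char_filters = 16L,
                              hidden_char = 16L, hidden = 24L, lr = 0.02,
                              epochs = 150L, engine = "neural") {
  list(char_dim = char_dim, char_filters = char_filters,
       hidden_char = hidden_char, hidden = hidden, lr = lr, epochs = epochs,
       engine = match.arg(engine, c("neural", "logistic")))
}

diff_char_ids <- function(vocab, term) {
  ids <- unname(vocab[strsplit(tolower(term), "")[[1]]])
  ids[is.na(ids)] <- 1L
  if (!length(ids)) ids <- 1L
  ids
}

# forward pass of the neural difficulty classifier for one term
diff_forward <- function(par, char_ids, feats, cfg) {
  cf <- charcnn_forward(char_ids, par$Echar, par$Wc, par$bc)
  X <- par$Echar[char_ids, , drop = FALSE]
  fw <- lstm_forward(X, par$Wx_f, par$Wh_f, par$b_f, reverse = FALSE)
  bw <- lstm_forward(X, par$Wx_b, par$Wh_b, par$b_b, reverse = TRUE)
  L <- length(char_ids)
  z <- c(cf$out, fw$H[L, ], bw$H[1L, ], feats)
  h1 <- tanh(drop(z %*% par$W1) + par$b1)
  logits <- drop(h1 %*% par$W2) + par$b2
  p <- exp(logits - logsumexp(logits))
  list(p = p, h1 = h1, z = z, cf = cf, fw = fw, bw = bw, L = L,
       char_ids = char_ids)
}

#' Train the term-difficulty classifier
#'
#' The default engine encodes the term string with a character-level
#' BiLSTM + CNN, concatenates the dense feature vector, and trains a
#' softmax output over \{easy, medium, difficult\} with Adam.  Deterministic
#' given \code{seed}.  The \code{"logistic"} engine fits a multinomial
#' logistic regression on the dense features alone (requires the
#' \pkg{nnet} package).
#'
#' @param dataset data.frame with columns \code{term}, \code{label} (easy /
#'   medium / difficult); at least two classes must be present.
#' @param kb optional \code{medlit_kb} for KB-derived features.
#' @param resources from \code{difficulty_resources}.
#' @param config from \code{difficulty_config}.
#' @param seed integer seed.
#' @return object of class \code{medlit_difficulty_model}.
#' @export
train_difficulty_classifier <- function(dataset, kb = NULL,
                                        resources = difficulty_resources(),
                                        config = difficulty_config(),
                                        seed = 1L) {
  stopifnot(is.data.frame(dataset), all(c("term", "label") %in% names(dataset)))
  labs <- as.character(dataset$label)
  if (!all(labs %in% DIFFICULTY_LEVELS)) {
    contract_error("labels must be easy / medium / difficult")
  }
  if (length(unique(labs)) < 2L) {
    contract_error("dataset must cover at least 2 classes")
  }
  semtype_inventory <- if (is.null(kb)) character() else
    sort(unique(unlist(lapply(kb$concepts, `[[`, "semtypes"))))
  F_ <- t(vapply(dataset$term, function(tm)
    extract_features(tm, kb, resources, semtype_inventory)$vector,
    extract_features(dataset$term[1], kb, resources,
                     semtype_inventory)$vector))
  mu <- colMeans(F_)
  sd_ <- apply(F_, 2L, stats::sd)
  sd_[sd_ < 1e-8] <- 1
  Fz <- sweep(sweep(F_, 2L, mu), 2L, sd_, "/")
  y <- match(labs, DIFFICULTY_LEVELS)

  if (config$engine == "logistic") {
    if (!requireNamespace("nnet", quietly = TRUE)) {
      contract_error("the logistic engine requires the nnet package")
    }
    df <- data.frame(Fz)
    df$.label <- factor(labs, levels = DIFFICULTY_LEVELS)
    fit <- with_seed(seed, nnet::multinom(.label ~ ., data = df,
                                          trace = FALSE, maxit = 300))
    return(structure(list(engine = "logistic", fit = fit, mu = mu, sd = sd_,
                          semtype_inventory = semtype_inventory,
                          resources = resources, seed = seed),
                     class = "medlit_difficulty_model"))
  }

  chars <- unique(unlist(strsplit(tolower(dataset$term), "")))
  vocab <- stats::setNames(seq_along(chars) + 1L, chars)  # 1 = UNK
  cfg <- config
  model <- with_seed(seed, {
    H <- cfg$hidden_char
    zdim <- cfg$char_filters + 2L * H + ncol(Fz)
    par <- list(
      Echar = nn_init_matrix(length(vocab) + 1L, cfg$char_dim, 0.25),
      Wc = nn_init_matrix(3L * cfg$char_dim, cfg$char_filters),
      bc = numeric(cfg$char_filters),
      Wx_f = nn_init_matrix(cfg$char_dim, 4L * H),
      Wh_f = nn_init_matrix(H, 4L * H), b_f = numeric(4L * H),
      Wx_b = nn_init_matrix(cfg$char_dim, 4L * H),
      Wh_b = nn_init_matrix(H, 4L * H), b_b = numeric(4L * H),
      W1 = nn_init_matrix(zdim, cfg$hidden), b1 = numeric(cfg$hidden),
      W2 = nn_init_matrix(cfg$hidden, 3L), b2 = numeric(3L)
    )
    par$b_f[(H + 1L):(2L * H)] <- 1
    par$b_b[(H + 1L):(2L * H)] <- 1
    state <- adam_init(par)
    cid <- lapply(dataset$term, diff_char_ids, vocab = vocab)
    n <- nrow(dataset)
    loss_trace <- numeric(0)
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (i in ord) {
        fc <- diff_forward(par, cid[[i]], Fz[i, ], cfg)
        ep_loss <- ep_loss - log(max(fc$p[y[i]], 1e-12))
        dlog <- fc$p
        dlog[y[i]] <- dlog[y[i]] - 1
        grads <- nn_zero_like(par)
        grads$W2 <- outer(fc$h1, dlog)
        grads$b2 <- dlog
        dh1 <- drop(par$W2 %*% dlog) * (1 - fc$h1^2)
        grads$W1 <- outer(fc$z, dh1)
        grads$b1 <- dh1
        dz <- drop(par$W1 %*% dh1)
        nf <- cfg$char_filters
        g2 <- charcnn_backward(dz[1:nf], fc$cf$cache, par$Wc,
                               list(E = grads$Echar, Wc = grads$Wc,
                                    bc = grads$bc))
        grads$Echar <- g2$E; grads$Wc <- g2$Wc; grads$bc <- g2$bc
        dHf <- matrix(0, fc$L, H); dHf[fc$L, ] <- dz[(nf + 1L):(nf + H)]
        bf <- lstm_backward(dHf, fc$fw$cache, par$Wx_f, par$Wh_f,
                            list(Wx = grads$Wx_f, Wh = grads$Wh_f,
                                 b = grads$b_f))
        grads$Wx_f <- bf$grads$Wx; grads$Wh_f <- bf$grads$Wh
        grads$b_f <- bf$grads$b
        dHb <- matrix(0, fc$L, H)
        dHb[1L, ] <- dz[(nf + H + 1L):(nf + 2L * H)]
        bb <- lstm_backward(dHb, fc$bw$cache, par$Wx_b, par$Wh_b,
                            list(Wx = grads$Wx_b, Wh = grads$Wh_b,
                                 b = grads$b_b))
        grads$Wx_b <- bb$grads$Wx; grads$Wh_b <- bb$grads$Wh
        grads$b_b <- bb$grads$b
        dX <- bf$dX + bb$dX
        for (t in seq_len(fc$L)) {
          id <- fc$char_ids[t]
          grads$Echar[id, ] <- grads$Echar[id, ] + dX[t, ]
        }
        upd <- adam_step(par, grads, state, lr = cfg$lr)
        par <- upd$par; state <- upd$state
      }
      loss_trace <- c(loss_trace, ep_loss / n)
    }
    list(par = par, loss = loss_trace)
  })
  structure(list(engine = "neural", par = model$par, loss = model$loss,
                 vocab = vocab, config = cfg, mu = mu, sd = sd_,
                 semtype_inventory = semtype_inventory,
                 resources = resources, seed = seed),
            class = "medlit_difficulty_model")
}

#' Predict difficulty labels for terms
#'
#' @param model a \code{medlit_difficulty_model}.
#' @param terms character vector.
#' @param kb optional \code{medlit_kb} (use the training KB for consistent
#'   features).
#' @return character vector of labels in \{easy, medium, difficult\}.
#' @export
predict_difficulty <- function(model, terms, kb = NULL) {
  stopifnot(inherits(model, "medlit_difficulty_model"))
  F_ <- t(vapply(terms, function(tm)
    extract_features(tm, kb, model$resources, model$semtype_inventory)$vector,
    numeric(length(model$mu))))
  Fz <- sweep(sweep(F_, 2L, model$mu), 2L, model$sd, "/")
  if (model$engine == "logistic") {
    df <- data.frame(Fz)
    return(as.character(stats::predict(model$fit, newdata = df)))
  }
  vapply(seq_along(terms), function(i) {
    cid <- diff_char_ids(model$vocab, terms[i])
    fc <- diff_forward(model$par, cid, Fz[i, ], model$config)
    DIFFICULTY_LEVELS[which.max(fc$p)]
  }, character(1))
}

#' Read a labeled difficulty dataset
#'
#' CSV with header \code{term,label} (optional \code{context}), or JSONL
#' with the same fields.
#'
#' @param path file path.
#' @return data.frame with \code{term}, \code{label} and optionally
#'   \code{context}.
#' @export
read_difficulty_dataset <- function(path) {
  if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(lines, jsonlite::fromJSON)
    out <- data.frame(term = vapply(recs, `[[`, character(1), "term"),
                      label = vapply(recs, `[[`, character(1), "label"),
                      stringsAsFactors = FALSE)
    if (all(vapply(recs, function(r) !is.null(r$context), logical(1)))) {
      out$context <- vapply(recs, `[[`, character(1), "context")
    }
    return(out)
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}
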