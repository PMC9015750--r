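# Minimal neural-network primitives used by the sequence tagger and the
# term-difficulty classifier: embedding tables, a width-3 character CNN with
# max-over-time pooling, an LSTM cell run forward/backward over a sequence,
# and Adam.  Everything is plain R matrix arithmetic with hand-written
# backpropagation; gradient correctness is pinned by finite-difference tests.

sigmoid <- function(x) 1 / (1 + exp(-x))

nn_init_matrix <- function(nrow, ncol, scale = NULL) {
  if (is.null(scale)) scale <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -scale, scale), nrow, ncol)
}

nn_zero_like <- function(par) lapply(par, function(p) p * 0)

# ---- character CNN ---------------------------------------------------------

# forward over one word: char_ids (>=1) into embedding table E (V x dc),
# width-3 convolution Wc (3dc x nf) + bc, tanh, max-over-time pooling.
# The character sequence is zero-padded by one position on each side.
charcnn_forward <- function(char_ids, E, Wc, bc) {
  k <- length(char_ids)
  dc <- ncol(E)
  emb <- E[char_ids, , drop = FALSE]                  # k x dc
  pad <- rbind(matrix(0, 1, dc), emb, matrix(0, 1, dc))
  win <- cbind(pad[1:k, , drop = FALSE],
               pad[2:(k + 1), , drop = FALSE],
               pad[3:(k + 2), , drop = FALSE])        # k x 3dc
  act <- tanh(sweep(win %*% Wc, 2L, bc, "+"))         # k x nf
  amax <- max.col(t(act), ties.method = "first")      # argmax row per filter
  pooled <- act[cbind(amax, seq_along(amax))]
  list(out = pooled, cache = list(char_ids = char_ids, win = win, act = act,
                                  amax = amax, k = k, dc = dc))
}

# backward: dout is the gradient at the pooled vector (length nf).
# Accumulates into grads$E, grads$Wc, grads$bc (mutated copies returned).
charcnn_backward <- function(dout, cache, Wc, grads) {
  k <- cache$k; dc <- cache$dc
  nf <- length(dout)
  dact <- matrix(0, k, nf)
  dact[cbind(cache$amax, seq_len(nf))] <- dout
  dpre <- dact * (1 - cache$act^2)
  grads$Wc <- grads$Wc + crossprod(cache$win, dpre)
  grads$bc <- grads$bc + colSums(dpre)
  dwin <- dpre %*% t(Wc)                              # k x 3dc
  # scatter window gradients back to (padded) embedding rows
  demb <- matrix(0, k + 2, dc)
  demb[1:k, ] <- demb[1:k, ] + dwin[, 1:dc, drop = FALSE]
  demb[2:(k + 1), ] <- demb[2:(k + 1), ] + dwin[, (dc + 1):(2 * dc), drop = FALSE]
  demb[3:(k + 2), ] <- demb[3:(k + 2), ] + dwin[, (2 * dc + 1):(3 * dc), drop = FALSE]
  demb <- demb[2:(k + 1), , drop = FALSE]             # drop pads
  for (j in seq_len(k)) {
    id <- cache$char_ids[j]
    grads$E[id, ] <- grads$E[id, ] + demb[j, ]
  }
  grads
}

# ---- LSTM ------------------------------------------------------------------

# X: L x D input; Wx: D x 4H; Wh: H x 4H; b: 4H. Gate order i, f, o, g.
# reverse = TRUE runs the recurrence from the last row to the first but
# returns hidden states aligned with the input rows.
lstm_forward <- function(X, Wx, Wh, b, reverse = FALSE) {
  L <- nrow(X); H <- nrow(Wh)
  idx <- if (reverse) L:1 else 1:L
  XW <- sweep(X %*% Wx, 2L, b, "+")                   # L x 4H
  Hs <- matrix(0, L, H); Cs <- matrix(0, L, H)
  gates <- vector("list", L)
  h <- numeric(H); cc <- numeric(H)
  for (t in idx) {
    z <- XW[t, ] + drop(h %*% Wh)
    i <- sigmoid(z[1:H]); f <- sigmoid(z[(H + 1):(2 * H)])
    o <- sigmoid(z[(2 * H + 1):(3 * H)]); g <- tanh(z[(3 * H + 1):(4 * H)])
    c_prev <- cc
    cc <- f * c_prev + i * g
    h <- o * tanh(cc)
    Hs[t, ] <- h; Cs[t, ] <- cc
    gates[[t]] <- list(i = i, f = f, o = o, g = g, c_prev = c_prev, tc = tanh(cc))
  }
  list(H = Hs, cache = list(X = X, Cs = Cs, gates = gates, idx = idx, HH = Hs))
}

# dH: L x H gradient on the hidden states; returns dX and accumulates
# parameter gradients into grads$Wx, grads$Wh, grads$b.
lstm_backward <- function(dH, cache, Wx, Wh, grads) {
  X <- cache$X; idx <- cache$idx
  L <- nrow(X); H <- ncol(dH)
  dX <- matrix(0, L, ncol(X))
  dh_next <- numeric(H); dc_next <- numeric(H)
  for (s in rev(seq_along(idx))) {
    t <- idx[s]
    gt <- cache$gates[[t]]
    dh <- dH[t, ] + dh_next
    do <- dh * gt$tc
    dtc <- dh * gt$o * (1 - gt$tc^2) + dc_next
    di <- dtc * gt$g; df <- dtc * gt$c_prev; dg <- dtc * gt$i
    dc_next <- dtc * gt$f
    dz <- c(di * gt$i * (1 - gt$i), df * gt$f * (1 - gt$f),
            do * gt$o * (1 - gt$o), dg * (1 - gt$g^2))
    h_prev <- if (s > 1L) cache$HH[idx[s - 1L], ] else numeric(H)
    grads$Wx <- grads$Wx + outer(X[t, ], dz)
    grads$Wh <- grads$Wh + outer(h_prev, dz)
    grads$b <- grads$b + dz
    dX[t, ] <- drop(Wx %*% dz)
    dh_next <- drop(Wh %*% dz)
  }
  list(dX = dX, grads = grads)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(par) {
  list(m = nn_zero_like(par), v = nn_zero_like(par), t = 0L)
}

adam_step <- function(par, grads, state, lr = 0.01,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(par)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    par[[nm]] <- par[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(par = par, state = state)
}
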