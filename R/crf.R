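# Linear-chain conditional random field layer: exact forward-algorithm
# normalization, forward-backward marginals for training, and Viterbi
# decoding.  A path y_1..y_L over T tags is scored
#
#   score = trans[start, y_1] + sum_t emis[t, y_t]
#         + sum_{t>1} trans[y_{t-1}, y_t] + trans[y_L, stop]
#
# where `trans` is (T+2) x (T+2) with row T+1 the start state and column
# T+2 the stop state.

crf_check <- function(emissions, transitions) {
  if (!is.matrix(emissions) || nrow(emissions) < 1L || ncol(emissions) < 1L) {
    contract_error("emissions must be a non-empty L x T matrix")
  }
  T_ <- ncol(emissions)
  if (!is.matrix(transitions) ||
      nrow(transitions) != T_ + 2L || ncol(transitions) != T_ + 2L) {
    contract_error("transitions must be (T+2) x (T+2)")
  }
  if (any(!is.finite(emissions))) contract_error("non-finite emission score")
  T_
}

#' CRF log-partition function (forward algorithm)
#'
#' Computes \code{log sum over all T^L tag paths of exp(path score)} by the
#' forward recursion in log space.
#'
#' @param emissions L x T matrix of per-token tag scores.
#' @param transitions (T+2) x (T+2) transition scores; row T+1 scores
#'   transitions out of the start state, column T+2 into the stop state.
#'   \code{-Inf} entries forbid a transition.
#' @return log-partition value (scalar).
#' @export
crf_log_partition <- function(emissions, transitions) {
  T_ <- crf_check(emissions, transitions)
  L <- nrow(emissions)
  start <- T_ + 1L; stop_ <- T_ + 2L
  alpha <- transitions[start, 1:T_] + emissions[1L, ]
  if (L > 1L) {
    for (t in 2:L) {
      alpha <- vapply(1:T_, function(y)
        logsumexp(alpha + transitions[1:T_, y]) + emissions[t, y], numeric(1))
    }
  }
  logsumexp(alpha + transitions[1:T_, stop_])
}

#' Viterbi decoding of the best tag path
#'
#' Exact argmax over all tag paths.  Ties are broken toward the smallest
#' tag index at every step, so an all-tie instance returns the
#' lexicographically smallest path.
#'
#' @inheritParams crf_log_partition
#' @return list with \code{path} (integer tag indices, length L) and
#'   \code{score} of that path.
#' @export
crf_viterbi <- function(emissions, transitions) {
  T_ <- crf_check(emissions, transitions)
  L <- nrow(emissions)
  start <- T_ + 1L; stop_ <- T_ + 2L
  delta <- transitions[start, 1:T_] + emissions[1L, ]
  back <- matrix(0L, L, T_)
  if (L > 1L) {
    for (t in 2:L) {
      new_delta <- numeric(T_)
      for (y in 1:T_) {
        sc <- delta + transitions[1:T_, y]
        j <- which.max(sc)
        back[t, y] <- j
        new_delta[y] <- sc[j] + emissions[t, y]
      }
      delta <- new_delta
    }
  }
  final <- delta + transitions[1:T_, stop_]
  last <- which.max(final)
  path <- integer(L)
  path[L] <- last
  if (L > 1L) for (t in L:2) path[t - 1L] <- back[t, path[t]]
  list(path = path, score = final[last])
}

# score of a given tag path (gold path during training)
crf_path_score <- function(emissions, transitions, path) {
  T_ <- ncol(emissions)
  L <- nrow(emissions)
  start <- T_ + 1L; stop_ <- T_ + 2L
  s <- transitions[start, path[1L]] + sum(emissions[cbind(1:L, path)])
  if (L > 1L) {
    s <- s + sum(transitions[cbind(path[1:(L - 1L)], path[2:L])])
  }
  s + transitions[path[L], stop_]
}

# forward-backward: negative log-likelihood of `path` and its gradients
# w.r.t. emissions and transitions (marginals minus gold indicators).
crf_nll_grad <- function(emissions, transitions, path) {
  T_ <- ncol(emissions)
  L <- nrow(emissions)
  start <- T_ + 1L; stop_ <- T_ + 2L

  alpha <- matrix(-Inf, L, T_)
  alpha[1L, ] <- transitions[start, 1:T_] + emissions[1L, ]
  if (L > 1L) for (t in 2:L) for (y in 1:T_) {
    alpha[t, y] <- logsumexp(alpha[t - 1L, ] + transitions[1:T_, y]) +
      emissions[t, y]
  }
  logZ <- logsumexp(alpha[L, ] + transitions[1:T_, stop_])

  beta <- matrix(-Inf, L, T_)
  beta[L, ] <- transitions[1:T_, stop_]
  if (L > 1L) for (t in (L - 1L):1L) for (y in 1:T_) {
    beta[t, y] <- logsumexp(transitions[y, 1:T_] + emissions[t + 1L, ] +
                              beta[t + 1L, ])
  }

  marg <- exp(alpha + beta - logZ)                     # L x T unary marginals

  d_emis <- marg
  d_emis[cbind(1:L, path)] <- d_emis[cbind(1:L, path)] - 1

  d_trans <- matrix(0, T_ + 2L, T_ + 2L)
  d_trans[start, 1:T_] <- marg[1L, ]
  d_trans[1:T_, stop_] <- marg[L, ]
  if (L > 1L) for (t in 2:L) {
    pair <- outer(alpha[t - 1L, ], emissions[t, ] + beta[t, ], "+") +
      transitions[1:T_, 1:T_]
    d_trans[1:T_, 1:T_] <- d_trans[1:T_, 1:T_] + exp(pair - logZ)
  }
  d_trans[start, path[1L]] <- d_trans[start, path[1L]] - 1
  d_trans[path[L], stop_] <- d_trans[path[L], stop_] - 1
  if (L > 1L) for (t in 2:L) {
    d_trans[path[t - 1L], path[t]] <- d_trans[path[t - 1L], path[t]] - 1
  }

  nll <- logZ - crf_path_score(emissions, transitions, path)
  list(nll = nll, d_emissions = d_emis, d_transitions = d_trans, logZ = logZ)
}
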