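# Three-parameter logistic (3PL) item response model for health-literacy
# screening.  Respondents answer a bank of right/wrong items; the latent
# ability theta has a standard-normal population prior, so theta = 0 is the
# population average (50th percentile), theta > 0 above average.  The model:
#
#   P(correct | theta) = c + (1 - c) / (1 + exp(-a (theta - b)))
#
# with discrimination a, difficulty b and guessing lower asymptote c.

#' Construct a 3PL item
#'
#' @param id item identifier.
#' @param a discrimination (finite; > 0 for a useful item).
#' @param b difficulty, on the theta scale (finite).
#' @param c guessing lower asymptote, in [0, 1).
#' @return list of class \code{medlit_item}.
#' @export
new_item <- function(id, a, b, c = 0) {
  stopifnot(is.finite(a), is.finite(b), is.finite(c))
  if (c < 0 || c >= 1) contract_error("guessing parameter c must lie in [0, 1)")
  structure(list(id = as.character(id), a = as.numeric(a),
                 b = as.numeric(b), c = as.numeric(c)),
            class = "medlit_item")
}

#' Read an item bank from CSV or JSON
#'
#' CSV with header \code{id,a,b,c} or a JSON array of objects with the same
#' fields.
#'
#' @param path file path.
#' @return list of \code{medlit_item}.
#' @export
read_item_bank <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    df <- as.data.frame(recs)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    new_item(df$id[i], df$a[i], df$b[i], if ("c" %in% names(df)) df$c[i] else 0)
  })
}

#' 3PL probability of a correct response
#'
#' @param item a \code{medlit_item}.
#' @param theta ability value(s).
#' @return probability in (c, 1), strictly increasing in theta when a > 0.
#' @export
#' @examples
#' it <- new_item("q1", a = 1.5, b = 0.5, c = 0.2)
#' prob_correct(it, theta = 1.0)
prob_correct <- function(item, theta) {
  item$c + (1 - item$c) * stats::plogis(item$a * (theta - item$b))
}

#' Fisher information of a 3PL item
#'
#' \code{I(theta) = a^2 (Q/P) (P - c)^2 / (1 - c)^2}; for c = 0 this reduces
#' to the familiar \code{a^2 P Q}.
#'
#' @inheritParams prob_correct
#' @return non-negative information value(s).
#' @export
item_information <- function(item, theta) {
  p <- prob_correct(item, theta)
  q <- 1 - p
  item$a^2 * (q / p) * ((p - item$c) / (1 - item$c))^2
}

#' Quadrature grid specification
#'
#' Equally spaced points on \code{[lo, hi]} with standard-normal prior
#' weights (renormalized).  Because the integrand decays like a Gaussian at
#' the interval ends, the equally weighted trapezoid-type rule converges
#' spectrally; 61 points are ample for screening-length tests.
#'
#' @param n_points number of grid points.
#' @param lo,hi interval endpoints on the theta scale.
#' @return list with \code{nodes} and normalized prior \code{weights}.
#' @export
quadrature_grid <- function(n_points = 61L, lo = -6, hi = 6) {
  stopifnot(n_points >= 3L, lo < hi)
  nodes <- seq(lo, hi, length.out = n_points)
  w <- stats::dnorm(nodes)
  list(nodes = nodes, weights = w / sum(w))
}

# log-likelihood of one response vector on a grid of theta nodes
resp_loglik_grid <- function(responses, items, nodes) {
  ll <- numeric(length(nodes))
  for (i in seq_along(items)) {
    x <- responses[i]
    if (is.na(x)) next
    p <- prob_correct(items[[i]], nodes)
    ll <- ll + if (x == 1) log(p) else log1p(-p)
  }
  ll
}

#' EAP ability estimate under a standard-normal prior
#'
#' Expected a posteriori estimate of theta: the posterior mean (and SD)
#' computed by fixed-grid quadrature.  With no usable responses the
#' posterior is the prior, so theta = 0, se = 1.
#'
#' @param responses numeric vector of 0/1/NA responses, aligned with
#'   \code{items}.
#' @param items list of \code{medlit_item}.
#' @param quadrature grid from \code{quadrature_grid}.
#' @return list of class \code{medlit_ability} with \code{theta}, \code{se}
#'   and \code{n_items} (count of non-missing responses used).
#' @export
#' @examples
#' its <- list(new_item("q1", 1, 0, 0.2), new_item("q2", 1, 0, 0.2))
#' estimate_ability_eap(c(1, 1), its)
estimate_ability_eap <- function(responses, items,
                                 quadrature = quadrature_grid()) {
  if (length(responses) != length(items)) {
    contract_error("responses and items must have the same length")
  }
  n_used <- sum(!is.na(responses))
  if (n_used == 0L) {
    return(structure(list(theta = 0, se = 1, n_items = 0L),
                     class = "medlit_ability"))
  }
  ll <- resp_loglik_grid(responses, items, quadrature$nodes)
  lw <- ll + log(quadrature$weights)
  post <- exp(lw - logsumexp(lw))
  m <- sum(post * quadrature$nodes)
  v <- sum(post * (quadrature$nodes - m)^2)
  structure(list(theta = m, se = sqrt(v), n_items = as.integer(n_used)),
            class = "medlit_ability")
}

#' @export
print.medlit_ability <- function(x, ...) {
  cat(sprintf("theta = %.3f (se %.3f, %d items) -> %s literacy\n",
              x$theta, x$se, x$n_items, classify_literacy(x)))
  invisible(x)
}

#' Two-level literacy classification
#'
#' Theta 0 is the population average; scores above 0 are above average and
#' below 0 below average.  The app-facing policy uses two levels only:
#' \code{"high"} iff theta >= 0, otherwise \code{"low"}.  The boundary value
#' theta = 0 is classified high.
#'
#' @param est a \code{medlit_ability} (or a bare theta value).
#' @return \code{"low"} or \code{"high"}.
#' @export
classify_literacy <- function(est) {
  theta <- if (inherits(est, "medlit_ability")) est$theta else as.numeric(est)
  if (theta >= 0) "high" else "low"
}

#' Validate a person-by-item response matrix
#'
#' @param values numeric matrix (persons x items) with entries 0, 1 or NA;
#'   rownames are person ids, colnames item ids.
#' @return the matrix, invisibly, after validation.
#' @export
validate_response_matrix <- function(values) {
  stopifnot(is.matrix(values))
  if (!nrow(values) || !ncol(values)) contract_error("empty response matrix")
  bad <- values[!is.na(values)]
  if (length(bad) && !all(bad %in% c(0, 1))) {
    contract_error("response entries must be 0, 1 or NA")
  }
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    contract_error("person and item ids must be unique")
  }
  invisible(values)
}

#' Read a response matrix from CSV
#'
#' First column is the person id; remaining columns are 0/1/NA responses,
#' one per item.
#'
#' @param path CSV file path.
#' @return numeric matrix with person rownames and item colnames.
#' @export
read_response_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "numeric"
  rownames(m) <- as.character(df[[1]])
  validate_response_matrix(m)
  m
}

# negative expected complete-data log-likelihood for one item given grid
# counts, plus a weak beta log-prior on the guessing parameter (the usual
# stabilizer for the 3PL c-a trade-off)
item_q_fn <- function(par, r, n, nodes, c_prior = c(2, 8),
                      a_prior = c(0, 0.5)) {
  it <- list(a = par[1], b = par[2], c = par[3])
  p <- pmin(pmax(it$c + (1 - it$c) * stats::plogis(it$a * (nodes - it$b)),
                 1e-10), 1 - 1e-10)
  cc <- min(max(it$c, 1e-6), 1 - 1e-6)
  logprior <- (c_prior[1] - 1) * log(cc) + (c_prior[2] - 1) * log1p(-cc) +
    stats::dlnorm(max(it$a, 1e-6), a_prior[1], a_prior[2], log = TRUE)
  -(sum(r * log(p) + (n - r) * log1p(-p)) + logprior)
}

#' Calibrate 3PL items by marginal maximum likelihood (EM)
#'
#' Bock-Aitkin style EM with a fixed quadrature grid: the E-step computes
#' each person's posterior over the grid under the current item parameters
#' and accumulates expected response counts per item and node; the M-step
#' maximizes each item's expected log-likelihood over (a, b, c) with
#' box-constrained quasi-Newton steps.  Two standard stabilizers tame the
#' well-known 3PL c-a non-identifiability: c is restricted to [0, 0.5] and
#' carries a weak beta prior (default Beta(2, 8), mode 0.125) and a carries
#' a lognormal prior (default meanlog 0, sdlog 0.5), making this a MAP-EM.
#' The reported objective (marginal log-likelihood plus the item log-priors)
#' is non-decreasing across iterations up to numerical tolerance.
#'
#' Items answered identically by every person carry no information; they are
#' excluded with a warning.
#'
#' @param values response matrix (persons x items; 0/1/NA) with item
#'   colnames.
#' @param quadrature grid from \code{quadrature_grid}.
#' @param tol EM stop when the marginal log-likelihood improves by less.
#' @param max_iter iteration cap.
#' @param bounds list with elements \code{a}, \code{b}, \code{c}, each a
#'   length-2 numeric of box constraints for the M-step.
#' @param c_prior shape parameters of the beta prior on c; \code{c(1, 1)}
#'   turns the prior off.
#' @param a_prior \code{c(meanlog, sdlog)} of the lognormal prior on a.
#' @param start optional list of \code{medlit_item} starting values.
#' @return list with \code{items} (calibrated \code{medlit_item}s),
#'   \code{loglik} (per-iteration penalized marginal log-likelihood trace),
#'   \code{converged}, \code{excluded} (degenerate item ids).
#' @export
calibrate_3pl_em <- function(values, quadrature = quadrature_grid(),
                             tol = 1e-5, max_iter = 500L,
                             bounds = list(a = c(0.05, 5), b = c(-6, 6),
                                           c = c(0, 0.5)),
                             c_prior = c(2, 8), a_prior = c(0, 0.5),
                             start = NULL) {
  validate_response_matrix(values)
  if (nrow(values) < 2L || ncol(values) < 2L) {
    contract_error("calibration needs at least 2 persons and 2 items")
  }

  # degenerate columns: constant (all-0 or all-1) among observed entries
  col_rate <- colMeans(values, na.rm = TRUE)
  degenerate <- colnames(values)[col_rate %in% c(0, 1) | is.nan(col_rate)]
  if (length(degenerate)) {
    warning(sprintf("excluding degenerate item(s): %s",
                    paste(degenerate, collapse = ", ")), call. = FALSE)
    values <- values[, !(colnames(values) %in% degenerate), drop = FALSE]
    if (ncol(values) < 2L) contract_error("fewer than 2 informative items")
  }

  nodes <- quadrature$nodes
  logw <- log(quadrature$weights)
  n_items <- ncol(values)
  ids <- colnames(values)

  if (is.null(start)) {
    # classical start: b from inverse-normal of difficulty, a = 1, c = 0.1
    pbar <- pmin(pmax(colMeans(values, na.rm = TRUE), 0.02), 0.98)
    items <- lapply(seq_len(n_items), function(i) {
      new_item(ids[i], a = 1, b = -stats::qnorm(pbar[i]), c = 0.1)
    })
  } else {
    items <- start
  }

  X <- values
  obs <- !is.na(X)
  X0 <- X; X0[!obs] <- 0

  loglik_trace <- numeric(0)
  converged <- FALSE

  for (iter in seq_len(max_iter)) {
    # E-step: log P(x_j | theta_g) for all persons x nodes
    logP <- vapply(seq_len(n_items), function(i)
      log(pmin(pmax(prob_correct(items[[i]], nodes), 1e-10), 1 - 1e-10)),
      numeric(length(nodes)))           # nodes x items
    logQ <- log1p(-exp(logP))
    # persons x nodes: sum_i [x log p + (1-x) log q] over observed entries
    LL <- X0 %*% t(logP) + (obs - X0) %*% t(logQ)
    lw <- sweep(LL, 2L, logw, "+")
    rowmax <- apply(lw, 1L, max)
    W <- exp(lw - rowmax)
    rs <- rowSums(W)
    cs <- pmin(pmax(vapply(items, `[[`, numeric(1), "c"), 1e-6), 1 - 1e-6)
    as_ <- pmax(vapply(items, `[[`, numeric(1), "a"), 1e-6)
    logprior <- sum((c_prior[1] - 1) * log(cs) +
                      (c_prior[2] - 1) * log1p(-cs) +
                      stats::dlnorm(as_, a_prior[1], a_prior[2], log = TRUE))
    loglik <- sum(rowmax + log(rs)) + logprior
    loglik_trace <- c(loglik_trace, loglik)
    post <- W / rs                       # persons x nodes posterior weights

    # expected counts per item/node
    # r_ig = sum_j post_jg x_ji (observed); n_ig = sum_j post_jg (observed)
    new_items <- items
    for (i in seq_len(n_items)) {
      oj <- obs[, i]
      r <- colSums(post[oj, , drop = FALSE] * X0[oj, i])
      n <- colSums(post[oj, , drop = FALSE])
      cur <- items[[i]]
      fit <- stats::optim(c(cur$a, cur$b, cur$c), item_q_fn,
                          r = r, n = n, nodes = nodes, c_prior = c_prior,
                          a_prior = a_prior, method = "L-BFGS-B",
                          lower = c(bounds$a[1], bounds$b[1], bounds$c[1]),
                          upper = c(bounds$a[2], bounds$b[2], bounds$c[2]))
      # guard the EM ascent property: keep the old value if optim worsened it
      if (fit$value <= item_q_fn(c(cur$a, cur$b, cur$c), r, n, nodes,
                                 c_prior, a_prior)) {
        new_items[[i]] <- new_item(ids[i], fit$par[1], fit$par[2], fit$par[3])
      }
    }
    items <- new_items

    if (iter > 1L &&
        abs(loglik_trace[iter] - loglik_trace[iter - 1L]) < tol) {
      converged <- TRUE
      break
    }
  }

  list(items = items, loglik = loglik_trace, converged = converged,
       excluded = degenerate)
}

#' Information-based short-form selection
#'
#' Reproduces the two-stage shortening of a screening test: items that
#' cannot distinguish high- from low-ability respondents (discrimination
#' \code{a <= a_min}) are removed first, then the \code{n} items with the
#' highest average Fisher information across the theta grid are selected.
#' Because test information is additive across items, picking the top-n by
#' mean information is the exact maximizer of average summed information.
#' Ties are broken by item-bank order.
#'
#' @param items list of \code{medlit_item}.
#' @param n number of items wanted (1 <= n <= length(items)).
#' @param theta_grid grid from \code{quadrature_grid}; mean information is
#'   an unweighted average over its nodes.
#' @param a_min removal threshold for non-discriminating items.
#' @return character vector of selected item ids, in item-bank order (all
#'   survivors if fewer than \code{n} remain after removal).
#' @export
shorten_test <- function(items, n, theta_grid = quadrature_grid(),
                         a_min = 0.2) {
  if (n < 1) contract_error("n must be >= 1")
  if (n > length(items)) contract_error("n exceeds the item bank size")
  keep <- vapply(items, function(it) it$a > a_min, logical(1))
  survivors <- items[keep]
  if (!length(survivors)) return(character())
  mean_info <- vapply(survivors, function(it)
    mean(item_information(it, theta_grid$nodes)), numeric(1))
  ord <- order(-mean_info)                     # stable: ties by bank order
  chosen <- ord[seq_len(min(n, length(survivors)))]
  ids <- vapply(survivors, function(it) it$id, character(1))
  ids[sort(chosen)]
}
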