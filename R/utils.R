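#' @keywords internal
"_PACKAGE"

#' Numerically stable log-sum-exp
#'
#' @param x numeric vector.
#' @return \code{log(sum(exp(x)))} computed without overflow.
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Run code with a temporarily seeded RNG
#'
#' Saves and restores \code{.Random.seed} so that library calls do not
#' perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simple whitespace/punctuation tokenizer with character offsets
#'
#' Splits on runs of letters/digits (Unicode-aware) and treats every other
#' non-space character as a single-character token.  Offsets are 0-based,
#' half-open, counted in code points so that \code{substr}-style extraction
#' round-trips.
#'
#' @param text character scalar.
#' @return data.frame with columns \code{token}, \code{start}, \code{end}.
#' @export
#' @examples
#' tokenize_text("Chest pain, mild.")
tokenize_text <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || nchar(text) == 0L) {
    return(data.frame(token = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  m <- gregexpr("[\\p{L}\\p{N}]+|[^\\p{L}\\p{N}\\s]", text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(token = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  len <- attr(m, "match.length")
  data.frame(
    token = substring(text, m, m + len - 1L),
    start = as.integer(m - 1L),
    end = as.integer(m + len - 1L),
    stringsAsFactors = FALSE
  )
}

# stop-on-contract-violation helper with a consistent error class
contract_error <- function(msg, class = "medlit_contract_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
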