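# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so
#' package functions never clobber the user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible sub-seed from a global seed and string labels
#'
#' Every random draw in the package flows from one global seed; stream
#' separation (per sample/drug pair, per simulation batch) uses this
#' deterministic fold of the label characters into a 31-bit integer.
#'
#' @param seed integer global seed.
#' @param ... labels (coerced to character) identifying the stream.
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(17, "S01", "drugA")
derive_seed <- function(seed, ...) {
  m <- 2147483647
  h <- as.double(as.integer(seed)) %% m
  for (lab in list(...)) {
    for (code in utf8ToInt(paste0("/", as.character(lab)))) {
      h <- (h * 31 + code) %% m
    }
  }
  as.integer(h)
}

# stopifnot with a custom message
.check <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

# column maxima / minima without apply (hot path)
.colmax <- function(M) {
  if (nrow(M) == 1L) return(as.vector(M))
  M[cbind(max.col(t(M), ties.method = "first"), seq_len(ncol(M)))]
}
.colmin <- function(M) -.colmax(-M)

# column-wise cumulative sums of a matrix
.colcumsum <- function(M) {
  v <- cumsum(as.vector(M))
  out <- matrix(v, nrow(M), ncol(M))
  if (ncol(M) > 1L) {
    base <- v[seq(nrow(M), by = nrow(M), length.out = ncol(M) - 1L)]
    out[, -1L] <- out[, -1L, drop = FALSE] -
      matrix(rep(base, each = nrow(M)), nrow(M))
  }
  out
}
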