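#' @keywords internal
"_PACKAGE"

## Shared helpers: seeded substreams, RNG hygiene, logging.

#' Derive a reproducible substream seed
#'
#' Maps a (seed, label) pair to a deterministic integer below 2^31 so that
#' independent pipeline stages draw from non-overlapping, individually
#' reproducible random streams. Toggling one stage therefore never shifts
#' another stage's randomness.
#'
#' @param seed Integer master seed.
#' @param label Character stage/substream label.
#' @return A single integer in \[0, 2^31 - 2\].
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 0
  for (ch in utf8ToInt(paste(label, collapse = "/"))) {
    h <- (h * 31 + ch) %% 2147483629
  }
  as.integer((h + round(seed) %% 2147483629 * 7919) %% 2147483629)
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Leveled stderr logging; level set via options(metacomm.verbose = TRUE).
log_msg <- function(..., level = "info") {
  if (identical(level, "debug") && !isTRUE(getOption("metacomm.verbose", FALSE))) {
    return(invisible(NULL))
  }
  message(sprintf("[metacomm:%s] %s", level, paste0(...)))
  invisible(NULL)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise logsumexp of a matrix.
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
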