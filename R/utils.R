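`%||%` <- function(x, y) if (is.null(x)) y else x

.assert <- function(cond, ..., call. = FALSE) {
  if (!isTRUE(cond)) stop(..., call. = call.)
}

.is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
}

.is_fraction <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}

#' Derive a per-stage seed from one global seed
#'
#' Deterministic fan-out of a global seed into per-stage seeds via a
#' polynomial string hash of the stage name, folded into
#' `[1, 2^31 - 2]` so `set.seed()` accepts it.  Used by the pipeline so
#' one seed reproduces every stochastic stage independently.
#'
#' @param seed non-negative integer global seed.
#' @param stage character stage label.
#' @return An integer seed.
#' @export
stage_seed <- function(seed, stage) {
  .assert(.is_count(seed + 1), "seed must be a non-negative integer")
  h <- 0
  for (k in utf8ToInt(as.character(stage))) {
    h <- (h * 131 + k) %% 2147483647
  }
  as.integer((h + (seed %% 2147483647) * 7919) %% 2147483646 + 1)
}

## Run expr with a temporarily-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## Column means of a dosage matrix ignoring NA, with all-NA columns -> NA
.col_means_narm <- function(X) {
  colMeans(X, na.rm = TRUE)
}

## Mean-impute missing entries column-wise (returns a double matrix)
impute_col_means <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    idx <- which(is.na(X))
    X[idx] <- mu[((idx - 1L) %/% nrow(X)) + 1L]
  }
  X
}
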