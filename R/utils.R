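# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

abort <- function(...) stop(..., call. = FALSE)

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    abs(x - round(x)) < .Machine$double.eps^0.5
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_symmetric <- function(m, tol = 1e-10, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    abort(what, " must be a square matrix")
  dev <- max(abs(m - t(m)))
  if (dev > tol)
    abort(what, " is not symmetric (max |m - t(m)| = ",
          format(dev, digits = 4), ", tolerance ", tol, ")")
  invisible(dev)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.  seed = NULL means "use the current stream".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is_count(seed, min = 0L)) abort("seed must be a single non-negative integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# 32-bit FNV-1a over a character scalar; used to stamp run logs so an output
# file can be matched to the configuration that produced it.
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    h <- (h * 16777619) %% 2^32   # double arithmetic is exact below 2^53
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

default_classes <- function(x) unique(as.character(x))
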