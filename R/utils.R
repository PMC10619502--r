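#' @import stats
#' @importFrom utils read.csv write.csv modifyList
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so generators are pure in (spec, seed).
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  set.seed(as.integer(seed))
  code
}

# Largest-remainder rounding: integer counts summing to `total`.
round_preserve_sum <- function(fractions, total) {
  raw <- fractions * total
  counts <- floor(raw)
  short <- total - sum(counts)
  if (short > 0) {
    idx <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[idx] <- counts[idx] + 1L
  }
  as.integer(counts)
}

# FNV-1a 32-bit hash of a character scalar; used to stamp pipeline outputs
# with a config fingerprint without a digest dependency.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "")))
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte since b < 256; done in doubles to
    # dodge bitwXor's 32-bit signed overflow
    h <- h - (h %% 256) + bitwXor(h %% 256, b)
    # 32-bit modular multiply by the FNV prime 16777619 (exact: < 2^53)
    h <- (h %% 65536) * 16777619 %% 4294967296 +
      ((h %/% 65536) * 16777619 %% 65536) * 65536
    h <- h %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

stop_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_fmt <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
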