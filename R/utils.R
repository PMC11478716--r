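# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG seed, runs `code`, and restores the caller's RNG state so
#' that library functions never clobber user-level reproducibility.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child-seed derivation; keeps results < 2^31 (R integers).
derive_seed <- function(seed, k) {
  s <- as.numeric(seed) %% 2147483647
  as.integer((s * 69069 + 12345 + as.numeric(k)) %% 2147483647)
}

# Centered moving average via cumulative sums; edges use shrinking windows.
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  n <- length(x)
  if (n == 0L || width == 1L) return(x)
  half <- width %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Pearson correlation of each row of M against a reference vector.
# Rows (or references) with zero variance yield NA.
row_cor <- function(M, ref) {
  M <- as.matrix(M)
  rc <- ref - mean(ref)
  den_ref <- sum(rc^2)
  Mc <- M - rowMeans(M)
  num <- as.vector(Mc %*% rc)
  den <- sqrt(rowSums(Mc^2) * den_ref)
  r <- ifelse(den > 0, num / den, NA_real_)
  r
}

hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * seq(0L, n - 1L) / (n - 1L))
}

#' Convert an RR interval in milliseconds to beats per minute
#'
#' The plausibility band of 333--2000 ms corresponds to heart rates of
#' 180 and 30 beats per minute.
#'
#' @param rr_ms RR interval(s) in milliseconds.
#' @return Heart rate(s) in beats per minute.
#' @export
#' @examples
#' round(rr_to_bpm(333))  # 180
#' rr_to_bpm(2000)        # 30
rr_to_bpm <- function(rr_ms) {
  stopifnot(is.numeric(rr_ms), all(rr_ms > 0))
  60000 / rr_ms
}

# FNV-1a 32-bit hash of a character string, hex encoded. Used for config
# manifests; not cryptographic.
fnv1a_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 32-bit modular multiply split into 16-bit halves to stay exact in doubles
    lo16 <- h %% 65536
    hi16 <- h %/% 65536
    h <- (lo16 * 16777619 + ((hi16 * 16777619) %% 65536) * 65536) %% 2^32
  }
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
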