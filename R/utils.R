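# Internal helpers shared across modules.

#' @importFrom stats median sd setNames rnorm runif rnbinom prcomp p.adjust
#'   pt qnorm pnorm t.test complete.cases
#' @importFrom utils combn read.delim write.table head modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn_fmt <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Deterministic 32-bit FNV-1a hash of a character scalar; used to derive
# independent RNG substreams and to fingerprint configurations.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\x1f"))
  h <- 2166136261
  for (b in bytes) {
    # xor with a byte only touches the low 8 bits, so it stays integer-safe
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b %% 256))
    # 32-bit modular multiply by the FNV prime 16777619, done in doubles;
    # split h to keep intermediate products inside 2^53
    h <- (h %% 65536 * 16777619 + h %/% 65536 * 16777619 %% 65536 * 65536) %% 4294967296
  }
  h
}

# Substream seed below 2^31, decorrelated from the master seed by stream name.
substream_seed <- function(seed, stream) {
  as.integer((fnv1a32(c(format(seed), stream))) %% 2147483647)
}

config_hash <- function(x) {
  flat <- vapply(rapply(x, format, how = "unlist"), paste, "", collapse = ",")
  h <- fnv1a32(paste(names(flat), flat, sep = "="))
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

is_count_scalar <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

assert_scalar_in <- function(x, name, lo, hi, open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open) x > lo && x < hi else x >= lo && x <= hi)
  if (!ok) {
    stop_fmt("'%s' must be a single number in %s%g, %g%s", name,
             if (open) "(" else "[", lo, hi, if (open) ")" else "]")
  }
  invisible(x)
}
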