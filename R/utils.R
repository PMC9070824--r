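`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a DNA string
#'
#' Operates on plain uppercase character strings over \{A,C,G,T,N\};
#' N maps to N.
#'
#' @param seq single character string.
#' @return the reverse-complemented string.
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", seq))))
}

# Split a sequence into a character vector of single bases.
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# state.  All stochastic operations in the package route through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a child seed from a parent seed and a stream index, staying inside
# 32-bit integer range so the result is a legal set.seed() argument.
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 9973) %% 2147483647)
}

stop_nonb <- function(...) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == floor(x)
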