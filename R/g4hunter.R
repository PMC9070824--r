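#' G4Hunter scan parameters
#'
#' @param window sliding-window width (bp), default 25.
#' @param threshold absolute window-mean score calling a hit; 1.5 is the
#'   stringent setting, 1.0 the permissive one.
#' @return a `g4_params` list.
#' @export
g4_params <- function(window = 25L, threshold = 1.5) {
  if (!is_count(window) || window < 2L) stop_nonb("window must be >= 2")
  if (!is.numeric(threshold) || threshold <= 0) stop_nonb("threshold must be > 0")
  structure(list(window = as.integer(window), threshold = threshold),
            class = "g4_params")
}

#' Per-base G4Hunter scores
#'
#' Every G in a maximal G-run of length n scores +min(n, 4); every C in a
#' C-run scores -min(n, 4); A, T and N score 0.  The sign encodes which
#' strand is G-rich.
#'
#' @param seq non-empty DNA string.
#' @return integer-valued numeric vector, one score per base.
#' @export
g4_base_scores <- function(seq) {
  if (!nzchar(seq)) stop_nonb("empty sequence")
  ch <- seq_chars(toupper(seq))
  rl <- rle(ch)
  val <- ifelse(rl$values == "G", pmin(rl$lengths, 4L),
                ifelse(rl$values == "C", -pmin(rl$lengths, 4L), 0L))
  rep(val, rl$lengths)
}

#' Sliding-window mean of G4Hunter base scores
#'
#' @param base_track vector from [g4_base_scores()].
#' @param params a [g4_params()].
#' @return numeric vector of `length - window + 1` window means (one per
#'   window start); empty with a warning when the sequence is shorter than
#'   the window.  The window size is recorded as attribute `window`.
#' @export
g4_window_scores <- function(base_track, params = g4_params()) {
  w <- params$window
  n <- length(base_track)
  if (n < w) {
    warning("sequence shorter than window; no scores")
    return(structure(numeric(0), window = w))
  }
  cs <- cumsum(c(0, base_track))
  structure((cs[(w + 1L):(n + 1L)] - cs[seq_len(n - w + 1L)]) / w,
            window = w)
}

#' Call G-quadruplex regions from window scores
#'
#' Windows with |mean| >= threshold qualify; overlapping or adjacent
#' qualifying windows are merged into maximal regions (no trimming back to
#' motif boundaries).  Each region carries its extreme window score; the
#' sign marks the G-rich (+) vs C-rich (-) strand.
#'
#' @param window_track vector from [g4_window_scores()].
#' @param params a [g4_params()].
#' @return data frame: `start`, `end` (0-based half-open), `score`
#'   (extreme signed window mean), `strand`.
#' @export
call_g4_hits <- function(window_track, params = g4_params()) {
  w <- attr(window_track, "window") %||% params$window
  empty <- data.frame(start = integer(), end = integer(),
                      score = numeric(), strand = character())
  # G-rich (+) and C-rich (-) windows are merged separately so a region's
  # sign is well defined; opposite-signed regions may overlap
  one_sign <- function(qual, sign) {
    if (length(qual) == 0L) return(empty)
    reg <- IRanges::reduce(IRanges::IRanges(start = qual, width = w))
    score <- vapply(seq_along(reg), function(i) {
      v <- window_track[qual[qual >= IRanges::start(reg)[i] &
                             qual <= IRanges::end(reg)[i]]]
      sign * max(sign * v)
    }, 0)
    data.frame(start = IRanges::start(reg) - 1L, end = IRanges::end(reg),
               score = score, strand = if (sign > 0) "+" else "-",
               stringsAsFactors = FALSE)
  }
  out <- rbind(one_sign(which(window_track >= params$threshold), 1),
               one_sign(which(window_track <= -params$threshold), -1))
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' G-quadruplex density of a sequence
#'
#' Distinct bases inside called regions divided by sequence length.
#'
#' @param hits data frame from [call_g4_hits()].
#' @param length sequence length (bp).
#' @param strand "both" (default), "+" or "-" to restrict which regions
#'   count.
#' @return fraction in \[0, 1\].
#' @export
g4_density <- function(hits, length, strand = c("both", "+", "-")) {
  strand <- match.arg(strand)
  if (strand != "both") hits <- hits[hits$strand == strand, , drop = FALSE]
  if (nrow(hits) == 0L) return(0)
  covered <- sum(IRanges::width(IRanges::reduce(
    IRanges::IRanges(start = hits$start + 1L, end = hits$end))))
  covered / length
}

#' One-call G4Hunter pipeline for a sequence
#'
#' @param seq DNA string.
#' @param params a [g4_params()].
#' @return list with `window_scores`, `hits`, `density`.
#' @export
g4hunter <- function(seq, params = g4_params()) {
  ws <- g4_window_scores(g4_base_scores(seq), params)
  hits <- call_g4_hits(ws, params)
  list(window_scores = ws, hits = hits,
       density = g4_density(hits, nchar(seq)))
}
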