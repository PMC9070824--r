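#' Motif-centered windows for kinetic validation
#'
#' One fixed-width window per hit with likelihood >= `min_stars`, centered
#' on the hit midpoint (floor of the midpoint for odd hit lengths).
#' Windows truncated by the contig edges are dropped and counted.
#'
#' @param hits hit data frame from [predict_motifs()] (plus strand is kept
#'   by default, matching the single-strand kinetics convention).
#' @param contig_length contig length (bp).
#' @param window_len window width (bp), default 300.
#' @param min_stars minimum likelihood (default 2).
#' @param strand strand filter: "+", "-" or "both".
#' @return data frame `start`, `end` (0-based half-open); attribute
#'   `n_dropped` counts edge-truncated windows.
#' @export
centered_windows <- function(hits, contig_length, window_len = 300L,
                             min_stars = 2L, strand = "+") {
  stopifnot(is_count(window_len), window_len >= 1L)
  keep <- hits$stars >= min_stars
  if (strand != "both") keep <- keep & hits$strand == strand
  hits <- hits[keep, , drop = FALSE]
  half <- window_len %/% 2L
  center <- (hits$start + hits$end) %/% 2L
  start <- center - half
  end <- start + as.integer(window_len)
  ok <- start >= 0L & end <= contig_length
  structure(data.frame(start = start[ok], end = end[ok]),
            n_dropped = sum(!ok))
}

#' Average an IPD track over motif-centered windows
#'
#' Windows containing no IPD values at all are filtered out; the remaining
#' windows are averaged lengthwise (position-wise, ignoring missing values
#' per position).
#'
#' @param track per-base numeric IPD vector (NA = missing).
#' @param windows data frame from [centered_windows()] (equal widths).
#' @return a `meta_profile`: list with `window_len`, `mean_profile`
#'   (vector of `window_len` values), `n_windows_used`,
#'   `n_windows_filtered`.
#' @export
meta_profile <- function(track, windows) {
  if (nrow(windows) == 0L) stop_nonb("no windows")
  widths <- unique(windows$end - windows$start)
  if (length(widths) != 1L) stop_nonb("windows must share one width")
  if (any(windows$start < 0L | windows$end > length(track)))
    stop_nonb("window outside track")
  mat <- t(vapply(seq_len(nrow(windows)), function(i)
    track[(windows$start[i] + 1L):windows$end[i]], numeric(widths)))
  empty <- rowSums(!is.na(mat)) == 0L
  if (all(empty))
    stop_nonb(sprintf("all %d windows contain no IPD values", nrow(mat)))
  mat <- mat[!empty, , drop = FALSE]
  structure(list(
    window_len = widths,
    mean_profile = colMeans(mat, na.rm = TRUE),
    n_windows_used = nrow(mat),
    n_windows_filtered = sum(empty)
  ), class = "meta_profile")
}

#' @export
print.meta_profile <- function(x, ...) {
  cat(sprintf("meta_profile: %d bp, %d windows used, %d filtered\n",
              x$window_len, x$n_windows_used, x$n_windows_filtered))
  invisible(x)
}

#' Center-over-flank fold enrichment of a meta-profile
#'
#' Mean of the central `core` positions divided by the mean of the
#' remaining flank positions.
#'
#' @param profile a [meta_profile()].
#' @param core number of central positions (default 50).
#' @return the fold ratio.
#' @export
center_fold_enrichment <- function(profile, core = 50L) {
  w <- profile$window_len
  if (core >= w) stop_nonb("core must be smaller than the window")
  lo <- (w - core) %/% 2L
  core_idx <- (lo + 1L):(lo + core)
  center <- mean(profile$mean_profile[core_idx], na.rm = TRUE)
  flank <- mean(profile$mean_profile[-core_idx], na.rm = TRUE)
  if (is.na(flank) || flank == 0) stop_nonb("zero/undefined flank mean")
  center / flank
}

#' Write a meta-profile as TSV
#'
#' Positions are reported relative to the window center
#' (-window/2 .. window/2 - 1).
#'
#' @param profile a [meta_profile()].
#' @param path output TSV.
#' @export
write_meta_profile <- function(profile, path) {
  half <- profile$window_len %/% 2L
  df <- data.frame(position = seq_len(profile$window_len) - half - 1L,
                   mean_ipd = profile$mean_profile)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
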