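#' Sliding-window plan for external structure-probability scans
#'
#' Sequences longer than `whole_below` bp are cut into `window`-bp windows
#' every `step` bp; the final window is truncated at the contig end and the
#' plan stops once a window reaches the end.  Shorter sequences get a single
#' whole-sequence window.
#'
#' @param contig_length sequence length (bp).
#' @param window window size (bp), default 5000.
#' @param step step size (bp), default 2500.
#' @param whole_below single-window cutoff (bp), default 10000.
#' @return data frame of 0-based half-open windows: `start`, `end`.
#' @export
window_plan <- function(contig_length, window = 5000L, step = 2500L,
                        whole_below = 10000L) {
  if (!is_count(contig_length) || contig_length < 1L)
    stop_nonb("bad contig length")
  if (!is_count(window) || !is_count(step) || window < step || step < 1L)
    stop_nonb("need window >= step >= 1")
  if (contig_length <= whole_below)
    return(data.frame(start = 0L, end = as.integer(contig_length)))
  starts <- integer()
  s <- 0L
  repeat {
    starts <- c(starts, s)
    if (s + window >= contig_length) break
    s <- s + as.integer(step)
  }
  data.frame(start = starts,
             end = pmin(starts + as.integer(window),
                        as.integer(contig_length)))
}

#' Reassemble per-window value vectors into one per-base track
#'
#' Overlapping windows are resolved by taking the per-base maximum.
#'
#' @param window_tracks list of numeric vectors, one per plan row, each of
#'   the corresponding window's length.
#' @param plan data frame from [window_plan()].
#' @param contig_length total track length (defaults to the plan's extent).
#' @return numeric vector of `contig_length` values.
#' @export
reassemble_max <- function(window_tracks, plan,
                           contig_length = max(plan$end)) {
  if (length(window_tracks) != nrow(plan))
    stop_nonb("one value vector per window required")
  widths <- plan$end - plan$start
  if (!all(lengths(window_tracks) == widths))
    stop_nonb("window value vector length mismatch")
  out <- rep(-Inf, contig_length)
  for (i in seq_len(nrow(plan))) {
    idx <- (plan$start[i] + 1L):plan$end[i]
    out[idx] <- pmax(out[idx], window_tracks[[i]])
  }
  out[is.infinite(out)] <- NA_real_
  out
}

#' Element-wise maximum of same-length tracks
#'
#' @param tracks list of equal-length numeric vectors.
#' @return numeric vector.
#' @export
combine_max <- function(tracks) {
  if (length(unique(lengths(tracks))) != 1L)
    stop_nonb("track length mismatch")
  Reduce(pmax, tracks)
}

#' Cumulative per-base asterisk profile
#'
#' Alias of [combine_likelihoods()], exposed at track level for plotting
#' the summed non-B likelihood across a whole contig.
#'
#' @inheritParams combine_likelihoods
#' @return numeric vector.
#' @export
cumulative_star_profile <- function(per_class_tracks)
  combine_likelihoods(per_class_tracks)

#' Mean of a track over an optional interval
#'
#' @param track numeric vector.
#' @param interval optional `c(start, end)` 0-based half-open.
#' @param na.rm drop missing values.
#' @return arithmetic mean.
#' @export
track_mean <- function(track, interval = NULL, na.rm = FALSE) {
  if (is.null(interval)) return(mean(track, na.rm = na.rm))
  if (length(interval) != 2L || interval[1L] < 0 ||
      interval[2L] > length(track) || interval[1L] >= interval[2L])
    stop_nonb("bad interval")
  mean(track[(interval[1L] + 1L):interval[2L]], na.rm = na.rm)
}

#' Read a SIST-style per-base probability table
#'
#' Tab-separated with a header; columns are located permissively by name
#' (position/pos, melt, cruciform/cruc, zdna/z-dna) or explicitly via
#' `col_map`.  A leading `# temperature: <T>` comment, when present, is
#' recorded in the `temperature` attribute.
#'
#' @param path TSV file.
#' @param col_map optional named character vector mapping the canonical
#'   names `position`, `melt`, `cruciform`, `zdna` to file column names.
#' @param temperature override/assign the table's temperature.
#' @return data frame `position` (0-based), `melt`, `cruciform`, `zdna`;
#'   attribute `temperature`.
#' @export
read_sist_table <- function(path, col_map = NULL, temperature = NULL) {
  if (!file.exists(path)) stop_nonb("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (is.null(temperature) && grepl("^#\\s*temperature", first))
    temperature <- as.numeric(sub(".*?([0-9.]+).*", "\\1", first))
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  locate <- function(canon, pattern) {
    if (!is.null(col_map) && canon %in% names(col_map))
      return(match(col_map[[canon]], names(df)))
    hit <- grep(pattern, names(df), ignore.case = TRUE)
    if (length(hit) == 0L) stop_nonb("cannot locate column: ", canon)
    hit[[1L]]
  }
  out <- data.frame(
    position = df[[locate("position", "^pos")]],
    melt = df[[locate("melt", "melt")]],
    cruciform = df[[locate("cruciform", "cruc")]],
    zdna = df[[locate("zdna", "^z")]]
  )
  for (s in SIST_STRUCTURES)
    if (any(out[[s]] < 0 | out[[s]] > 1, na.rm = TRUE))
      stop_nonb("probabilities outside [0,1] in column ", s)
  if (any(diff(out$position) != 1L))
    stop_nonb("positions must be contiguous")
  attr(out, "temperature") <- temperature
  out
}

#' Write a SIST-style table
#'
#' @param df data frame with `position`, `melt`, `cruciform`, `zdna`.
#' @param path output TSV.
#' @param temperature recorded as a `# temperature:` header comment.
#' @export
write_sist_table <- function(df, path,
                             temperature = attr(df, "temperature")) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(temperature))
    writeLines(sprintf("# temperature: %s", temperature), con)
  write.table(df[, c("position", "melt", "cruciform", "zdna")], con,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a per-base track as bedGraph
#'
#' Runs of equal value are collapsed; missing values are omitted (bedGraph
#' has no NA representation).
#'
#' @param values numeric vector.
#' @param contig contig id.
#' @param path output file.
#' @export
write_bedgraph <- function(values, contig, path) {
  keep <- !is.na(values)
  key <- values
  key[!keep] <- Inf   # break runs at NA
  rl <- rle(key)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths
  sel <- is.finite(rl$values)
  if (!any(sel)) {
    file.create(path)
    return(invisible(path))
  }
  df <- data.frame(contig, starts[sel], ends[sel], rl$values[sel])
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph file into per-base tracks
#'
#' @param path bedGraph file.
#' @param lengths named vector of contig lengths.
#' @return named list of numeric vectors (NA where no value is recorded).
#' @export
read_bedgraph <- function(path, lengths) {
  if (!file.exists(path)) stop_nonb("no such file: ", path)
  out <- lapply(lengths, function(n) rep(NA_real_, n))
  if (file.size(path) == 0L) return(out)
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("contig", "start", "end", "value")[seq_len(ncol(df))]
  bad <- setdiff(unique(df$contig), names(lengths))
  if (length(bad)) stop_nonb("unknown contig in bedGraph: ", bad[[1L]])
  for (ctg in unique(df$contig)) {
    sub <- df[df$contig == ctg, , drop = FALSE]
    w <- sub$end - sub$start
    idx <- sequence(w, from = sub$start + 1L)
    out[[ctg]][idx] <- rep(sub$value, w)
  }
  out
}
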