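#' Dyad-symmetry (inverted repeat) detection parameters
#'
#' Defaults follow the classical palindrome-finder settings used for
#' centromere dyad surveys: arms of 5-100 bp, loop (gap) up to 20 bp,
#' overlapping occurrences allowed, zero mismatches.
#'
#' @param min_stem minimum arm length (bp).
#' @param max_stem maximum arm length (bp).
#' @param gap_limit maximum loop length between arms (bp).
#' @param allow_overlap keep overlapping occurrences (FALSE keeps, per
#'   contig, a greedy non-overlapping subset by descending arm length).
#' @return a `dyad_params` list.
#' @export
dyad_params <- function(min_stem = 5L, max_stem = 100L, gap_limit = 20L,
                        allow_overlap = TRUE) {
  if (!is_count(min_stem) || !is_count(max_stem) || !is_count(gap_limit) ||
      min_stem < 1L || max_stem < min_stem || gap_limit < 0L)
    stop_nonb("invalid dyad params: need 1 <= min_stem <= max_stem, gap_limit >= 0")
  structure(list(min_stem = as.integer(min_stem),
                 max_stem = as.integer(max_stem),
                 gap_limit = as.integer(gap_limit),
                 allow_overlap = isTRUE(allow_overlap)),
            class = "dyad_params")
}

#' Find all maximal inverted repeats in a sequence
#'
#' An inverted repeat is a left arm, an optional gap, and a right arm equal
#' to the exact reverse complement of the left arm.  Occurrences are
#' *maximal*: arms cannot be extended outward by one base without breaking
#' complementarity (or exceeding `max_stem`), and the gap cannot be shrunk
#' while keeping the arms complementary.  N never pairs with anything.
#'
#' @param seq DNA string (or a [genome_assembly()] plus `contig`).
#' @param params a [dyad_params()].
#' @param contig contig id when `seq` is an assembly.
#' @return data frame with columns `left_start`, `arm_len`, `gap_len`,
#'   `right_start`, `end` (all 0-based half-open), sorted by position.
#'   Sequences shorter than `2 * min_stem` yield zero rows.
#' @export
find_inverted_repeats <- function(seq, params = dyad_params(),
                                  contig = NULL) {
  if (!inherits(params, "dyad_params")) params <- do.call(dyad_params, params)
  if (inherits(seq, "genome_assembly")) seq <- contig_seq(seq, contig)
  seq <- toupper(seq)
  if (nchar(seq) < 2L * params$min_stem) {
    return(data.frame(left_start = integer(), arm_len = integer(),
                      gap_len = integer(), right_start = integer(),
                      end = integer()))
  }
  df <- symmetric_scan_cpp(seq, params$min_stem, params$max_stem,
                           params$gap_limit, FALSE)
  df$right_start <- df$left_start + df$arm_len + df$gap_len
  df$end <- df$right_start + df$arm_len
  df <- df[order(df$left_start, df$arm_len, df$gap_len), , drop = FALSE]
  rownames(df) <- NULL
  if (!params$allow_overlap && nrow(df) > 1L) {
    # greedy non-overlapping subset: longest arms first, then position
    keep <- logical(nrow(df))
    covered <- rep(FALSE, max(df$end))
    for (i in order(-df$arm_len, df$left_start)) {
      span <- (df$left_start[i] + 1L):df$end[i]
      if (!any(covered[span])) {
        keep[i] <- TRUE
        covered[span] <- TRUE
      }
    }
    df <- df[sort(which(keep)), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Per-base dyad coverage track
#'
#' Marks bases lying inside inverted-repeat *arms* (loop/gap bases count 0).
#' The default is binary coverage ("part of a dyad" or not); `mode = "sum"`
#' counts arm multiplicity instead, and `include_loop = TRUE` also marks the
#' gap bases — both exposed because the upstream convention is ambiguous.
#'
#' @param length contig length in bp.
#' @param irs data frame from [find_inverted_repeats()].
#' @param mode "binary" (default) or "sum".
#' @param include_loop also cover gap bases.
#' @return numeric vector of `length` values.
#' @export
dyad_coverage <- function(length, irs, mode = c("binary", "sum"),
                          include_loop = FALSE) {
  mode <- match.arg(mode)
  if (!is_count(length) || length < 0) stop_nonb("bad length")
  track <- numeric(length)
  if (nrow(irs) == 0L) return(track)
  if (any(irs$left_start < 0L | irs$end > length))
    stop_nonb("inverted repeat out of contig bounds")
  for (i in seq_len(nrow(irs))) {
    left <- irs$left_start[i] + seq_len(irs$arm_len[i])
    right <- irs$right_start[i] + seq_len(irs$arm_len[i])
    idx <- c(left, right)
    if (include_loop && irs$gap_len[i] > 0L)
      idx <- c(idx, irs$left_start[i] + irs$arm_len[i] + seq_len(irs$gap_len[i]))
    if (mode == "binary") track[idx] <- 1 else
      track[idx] <- track[idx] + 1
  }
  track
}

#' Dyad density of a coverage track
#'
#' The fraction of bases that are part of a dyad: mean of the (binary)
#' coverage track.
#'
#' @param track numeric vector from [dyad_coverage()].
#' @return value in \[0, 1\] for binary tracks.
#' @export
dyad_density <- function(track) {
  if (length(track) == 0L) stop_nonb("empty track")
  mean(track)
}

#' Dyad density for every contig of an assembly
#'
#' @param assembly a [genome_assembly()].
#' @param params a [dyad_params()].
#' @return data frame: id, n_irs, dyad_density.
#' @export
dyad_density_table <- function(assembly, params = dyad_params()) {
  rows <- lapply(contig_ids(assembly), function(id) {
    irs <- find_inverted_repeats(contig_seq(assembly, id), params)
    len <- contig_length(assembly, id)
    data.frame(id = id, n_irs = nrow(irs),
               dyad_density = dyad_density(dyad_coverage(len, irs)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
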