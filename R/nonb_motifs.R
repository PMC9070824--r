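#' Rule set for the seven non-B motif classes
#'
#' Each class is predicted by a deterministic sequence rule with a 1-3
#' asterisk likelihood.  Every threshold is overridable; the defaults are
#' the package's normative definitions (documented in the methods vignette):
#'
#' * `G4` - >= 4 runs of >= 3 G separated by 1-7 nt loops; 2 stars when any
#'   loop exceeds 3 nt or the motif is exactly four G3 runs, else 3.
#' * `ZDNA` - >= 12 bp of alternating purine-pyrimidine dinucleotides from
#'   \{GC, CG, GT, TG, AC, CA\}; 3 stars for pure GC/CG tracts, else 2.
#' * `STR` - tandem repeat, unit 1-9 bp, >= 5 full copies, tract >= 15 bp;
#'   3 stars at >= 10 copies, else 2.
#' * `SLIPPED` - exact direct repeat, unit >= 10 bp, spacer <= 10 bp;
#'   3 stars at unit >= 20, else 2.
#' * `HDNA` - mirror repeat, arm >= 10 bp, spacer <= 8 bp, >= 90% purine or
#'   >= 90% pyrimidine over the whole span; 3 stars at 100%.
#' * `TFO` - homopurine tract >= 15 bp with >= 50% G; 3 stars at >= 25 bp.
#' * `APR` - >= 3 A-tracts of 3-9 bp with successive tract centers 10-11 bp
#'   apart; 3 stars at >= 4 tracts.
#'
#' @param ... named per-class overrides, e.g. `g4 = list(loop_max = 12)`.
#' @return a `motif_ruleset` list with one entry per class.
#' @export
motif_ruleset <- function(...) {
  rules <- list(
    apr  = list(tract_min = 3L, tract_max = 9L, spacing_min = 10,
                spacing_max = 11, min_tracts = 3L, tracts_3star = 4L),
    g4   = list(min_run = 3L, loop_min = 1L, loop_max = 7L, min_runs = 4L),
    hdna = list(arm_min = 10L, arm_max = 100L, spacer_max = 8L,
                purity = 0.9),
    slipped = list(unit_min = 10L, unit_max = 100L, spacer_max = 10L,
                   unit_3star = 20L),
    str  = list(unit_min = 1L, unit_max = 9L, min_copies = 5L,
                min_len = 15L, copies_3star = 10L),
    tfo  = list(min_len = 15L, min_g = 0.5, len_3star = 25L),
    zdna = list(min_len = 12L)
  )
  mods <- list(...)
  for (nm in names(mods)) {
    if (!nm %in% names(rules)) stop_nonb("unknown motif class rule: ", nm)
    rules[[nm]][names(mods[[nm]])] <- mods[[nm]]
  }
  v <- rules
  if (v$g4$min_runs < 2L || v$g4$min_run < 1L || v$g4$loop_min < 1L ||
      v$g4$loop_max < v$g4$loop_min)
    stop_nonb("invalid G4 rule parameters")
  if (v$str$unit_min < 1L || v$str$unit_max < v$str$unit_min)
    stop_nonb("invalid STR rule parameters")
  if (v$slipped$unit_min < 1L || v$slipped$unit_max < v$slipped$unit_min ||
      v$slipped$spacer_max < 0L)
    stop_nonb("invalid SLIPPED rule parameters")
  structure(rules, class = "motif_ruleset")
}

new_hits <- function(start = integer(), end = integer(),
                     strand = character(), stars = integer(),
                     detail = character(), motif_class = NA_character_) {
  df <- data.frame(start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand), stars = as.integer(stars),
                   detail = as.character(detail), stringsAsFactors = FALSE)
  attr(df, "motif_class") <- motif_class
  df
}

# Maximal runs of a regex pattern; 0-based starts.
find_runs <- function(seq, pattern) {
  m <- gregexpr(pattern, seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(data.frame(start = integer(), len = integer()))
  data.frame(start = as.integer(m) - 1L,
             len = attr(m, "match.length"))
}

# Partition an ordered run table into maximal chains whose inter-run gaps
# lie in [loop_min, loop_max]; returns a list of row-index vectors.
chain_runs <- function(runs, loop_min, loop_max) {
  n <- nrow(runs)
  if (n == 0L) return(list())
  gaps <- runs$start[-1L] - (runs$start[-n] + runs$len[-n])
  brk <- which(gaps < loop_min | gaps > loop_max)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, n)
  Map(seq, starts, ends)
}

scan_g4_strand <- function(seq, r, base) {
  runs <- find_runs(seq, sprintf("%s{%d,}", base, r$min_run))
  hits <- new_hits(motif_class = "G4")
  for (idx in chain_runs(runs, r$loop_min, r$loop_max)) {
    if (length(idx) < r$min_runs) next
    sub <- runs[idx, , drop = FALSE]
    loops <- if (nrow(sub) > 1L)
      sub$start[-1L] - (sub$start[-nrow(sub)] + sub$len[-nrow(sub)])
    else integer()
    stars <- if (any(loops > 3L) ||
                 (nrow(sub) == r$min_runs && all(sub$len == r$min_run))) 2L else 3L
    hits <- rbind(hits, new_hits(
      sub$start[1L], sub$start[nrow(sub)] + sub$len[nrow(sub)],
      if (base == "G") "+" else "-", stars,
      sprintf("runs=%d", nrow(sub)), "G4"))
  }
  attr(hits, "motif_class") <- "G4"
  hits
}

scan_zdna <- function(seq, r) {
  ch <- seq_chars(seq)
  n <- length(ch)
  hits <- new_hits(motif_class = "ZDNA")
  if (n < r$min_len) return(hits)
  pairs <- paste0(ch[-n], ch[-1L])
  ok <- pairs %in% c("GC", "CG", "GT", "TG", "AC", "CA")
  rl <- rle(ok)
  pos <- cumsum(c(0L, rl$lengths))
  for (i in seq_along(rl$lengths)) {
    if (!rl$values[i]) next
    len <- rl$lengths[i] + 1L          # bases spanned by the valid pairs
    if (len < r$min_len) next
    s <- pos[i]
    tract <- ch[(s + 1L):(s + len)]
    stars <- if (all(tract %in% c("G", "C"))) 3L else 2L
    hits <- rbind(hits, new_hits(s, s + len, "+", stars,
                                 sprintf("len=%d", len), "ZDNA"))
  }
  attr(hits, "motif_class") <- "ZDNA"
  hits
}

# True iff the string has exact period p (used to keep only primitive STRs).
has_period <- function(ch, p) {
  n <- length(ch)
  p < n && all(ch[seq_len(n - p)] == ch[(p + 1L):n])
}

scan_str <- function(seq, r) {
  ch <- seq_chars(seq)
  n <- length(ch)
  hits <- new_hits(motif_class = "STR")
  seen <- list()   # accepted tracts by smaller unit, for primitivity dedup
  for (u in r$unit_min:r$unit_max) {
    if (n < 2L * u) next
    m <- ch[seq_len(n - u)] == ch[(u + 1L):n] & ch[seq_len(n - u)] != "N"
    rl <- rle(m)
    pos <- cumsum(c(0L, rl$lengths))
    cand <- which(rl$values &
                    rl$lengths >= max(r$min_len - u,
                                      (r$min_copies - 1L) * u))
    for (i in cand) {
      len <- rl$lengths[i] + u
      copies <- len %/% u
      s <- pos[i]
      tract <- ch[(s + 1L):(s + len)]
      # skip if the tract has a smaller period (already reported)
      primitive <- TRUE
      for (d in seq_len(u - 1L)) if (has_period(tract, d)) {
        primitive <- FALSE; break
      }
      if (!primitive) next
      stars <- if (copies >= r$copies_3star) 3L else 2L
      hits <- rbind(hits, new_hits(s, s + len, "+", stars,
                                   sprintf("unit=%d;copies=%d", u, copies),
                                   "STR"))
    }
  }
  attr(hits, "motif_class") <- "STR"
  hits
}

scan_slipped <- function(seq, r) {
  ch <- seq_chars(seq)
  n <- length(ch)
  hits <- new_hits(motif_class = "SLIPPED")
  for (t in r$unit_min:(r$unit_max + r$spacer_max)) {
    if (n < t + r$unit_min) next
    m <- ch[seq_len(n - t)] == ch[(t + 1L):n] & ch[seq_len(n - t)] != "N"
    rl <- rle(m)
    pos <- cumsum(c(0L, rl$lengths))
    cand <- which(rl$values & rl$lengths >= r$unit_min)
    for (i in cand) {
      run <- rl$lengths[i]
      u <- min(run, t)                  # maximal unit at this shift
      d <- t - u
      if (u < r$unit_min || u > r$unit_max || d > r$spacer_max) next
      s <- pos[i]
      stars <- if (u >= r$unit_3star) 3L else 2L
      hits <- rbind(hits, new_hits(s, s + t + u, "+", stars,
                                   sprintf("unit=%d;spacer=%d", u, d),
                                   "SLIPPED"))
    }
  }
  attr(hits, "motif_class") <- "SLIPPED"
  hits
}

scan_hdna <- function(seq, r) {
  df <- symmetric_scan_cpp(toupper(seq), r$arm_min, r$arm_max,
                           r$spacer_max, TRUE)
  hits <- new_hits(motif_class = "HDNA")
  if (nrow(df) == 0L) return(hits)
  ch <- seq_chars(seq)
  for (i in seq_len(nrow(df))) {
    s <- df$left_start[i]
    e <- s + 2L * df$arm_len[i] + df$gap_len[i]
    span <- ch[(s + 1L):e]
    pur <- mean(span %in% c("A", "G"))
    pyr <- mean(span %in% c("C", "T"))
    frac <- max(pur, pyr)
    if (frac < r$purity) next
    stars <- if (frac == 1) 3L else 2L
    hits <- rbind(hits, new_hits(s, e, "+", stars,
                                 sprintf("arm=%d;spacer=%d", df$arm_len[i],
                                         df$gap_len[i]), "HDNA"))
  }
  attr(hits, "motif_class") <- "HDNA"
  hits
}

scan_tfo_strand <- function(seq, r, strand) {
  pat <- if (strand == "+") "[AG]+" else "[CT]+"
  rich <- if (strand == "+") "G" else "C"
  runs <- find_runs(seq, pat)
  runs <- runs[runs$len >= r$min_len, , drop = FALSE]
  hits <- new_hits(motif_class = "TFO")
  for (i in seq_len(nrow(runs))) {
    tract <- substr(seq, runs$start[i] + 1L, runs$start[i] + runs$len[i])
    gfrac <- mean(seq_chars(tract) == rich)
    if (gfrac < r$min_g) next
    stars <- if (runs$len[i] >= r$len_3star) 3L else 2L
    hits <- rbind(hits, new_hits(runs$start[i], runs$start[i] + runs$len[i],
                                 strand, stars,
                                 sprintf("len=%d;rich=%.2f", runs$len[i], gfrac),
                                 "TFO"))
  }
  attr(hits, "motif_class") <- "TFO"
  hits
}

scan_apr_strand <- function(seq, r, strand) {
  base <- if (strand == "+") "A" else "T"
  runs <- find_runs(seq, paste0(base, "+"))
  runs <- runs[runs$len >= r$tract_min & runs$len <= r$tract_max, ,
               drop = FALSE]
  hits <- new_hits(motif_class = "APR")
  n <- nrow(runs)
  if (n == 0L) return(hits)
  # doubled centers keep half-integer tract centers in integer arithmetic
  c2 <- 2L * runs$start + runs$len - 1L
  d2 <- if (n > 1L) diff(c2) else integer()
  ok <- d2 >= 2 * r$spacing_min & d2 <= 2 * r$spacing_max
  brk <- which(!ok)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, n)
  for (k in seq_along(starts)) {
    idx <- starts[k]:ends[k]
    if (length(idx) < r$min_tracts) next
    stars <- if (length(idx) >= r$tracts_3star) 3L else 2L
    hits <- rbind(hits, new_hits(
      runs$start[idx[1L]],
      runs$start[idx[length(idx)]] + runs$len[idx[length(idx)]],
      strand, stars, sprintf("tracts=%d", length(idx)), "APR"))
  }
  attr(hits, "motif_class") <- "APR"
  hits
}

#' Predict one class of non-B motifs
#'
#' Scans both strands; minus-strand occurrences (only possible for the
#' strand-asymmetric classes G4, TFO, APR) are reported in plus-strand
#' coordinates with strand "-".  N matches nothing in every rule.
#'
#' @param seq DNA string.
#' @param motif_class one of `r paste(MOTIF_CLASSES, collapse = ", ")`.
#' @param rules a [motif_ruleset()].
#' @return data frame of hits: `start`, `end` (0-based half-open),
#'   `strand`, `stars` (1-3), `detail`; attribute `motif_class`.
#' @export
predict_motifs <- function(seq, motif_class, rules = motif_ruleset()) {
  if (!motif_class %in% MOTIF_CLASSES)
    stop_nonb("unknown motif class: ", motif_class)
  if (!inherits(rules, "motif_ruleset")) stop_nonb("rules must be a motif_ruleset")
  if (!nzchar(seq)) stop_nonb("empty sequence")
  seq <- toupper(seq)
  hits <- switch(motif_class,
    G4 = rbind(scan_g4_strand(seq, rules$g4, "G"),
               scan_g4_strand(seq, rules$g4, "C")),
    ZDNA = scan_zdna(seq, rules$zdna),
    STR = scan_str(seq, rules$str),
    SLIPPED = scan_slipped(seq, rules$slipped),
    HDNA = scan_hdna(seq, rules$hdna),
    TFO = rbind(scan_tfo_strand(seq, rules$tfo, "+"),
                scan_tfo_strand(seq, rules$tfo, "-")),
    APR = rbind(scan_apr_strand(seq, rules$apr, "+"),
                scan_apr_strand(seq, rules$apr, "-"))
  )
  hits <- hits[order(hits$start, hits$end, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "motif_class") <- motif_class
  hits
}

#' Predict all seven classes at once
#'
#' @inheritParams predict_motifs
#' @return named list of hit data frames, one per class.
#' @export
predict_all_motifs <- function(seq, rules = motif_ruleset()) {
  out <- lapply(MOTIF_CLASSES, predict_motifs, seq = seq, rules = rules)
  names(out) <- MOTIF_CLASSES
  out
}

#' Per-base asterisk-likelihood track for one class
#'
#' Each base takes the maximum stars over same-class hits covering it
#' (0 where uncovered).  Hits lacking a star rating get the default of 2.
#'
#' @param length contig length (bp).
#' @param hits hit data frame from [predict_motifs()].
#' @param motif_class expected class (checked against the hits attribute).
#' @param default_stars likelihood assigned to hits with missing stars.
#' @return integer-valued numeric vector.
#' @export
stars_track <- function(length, hits, motif_class = NULL,
                        default_stars = 2L) {
  if (!is.null(motif_class) && !is.null(attr(hits, "motif_class")) &&
      !identical(attr(hits, "motif_class"), motif_class))
    stop_nonb("hits are of class ", attr(hits, "motif_class"),
              ", expected ", motif_class)
  track <- numeric(length)
  for (i in seq_len(nrow(hits))) {
    st <- hits$stars[i]
    if (is.na(st)) st <- default_stars
    idx <- (hits$start[i] + 1L):hits$end[i]
    track[idx] <- pmax(track[idx], st)
  }
  track
}

#' Combine per-class likelihood tracks into one cumulative track
#'
#' Where different non-B classes overlap their likelihoods are *added*
#' (within a class the maximum was already taken by [stars_track()]).
#'
#' @param per_class_tracks list of equal-length numeric vectors.
#' @return numeric vector, the element-wise sum (bounded by 21 = 7 classes
#'   x 3 stars when given one track per class).
#' @export
combine_likelihoods <- function(per_class_tracks) {
  lens <- lengths(per_class_tracks)
  if (length(unique(lens)) != 1L)
    stop_nonb("track length mismatch: ", paste(unique(lens), collapse = ", "))
  Reduce(`+`, per_class_tracks)
}

#' Distinct bases covered per class, and their pie-chart fractions
#'
#' @param hits_by_class named list of hit data frames (one per class).
#' @return data frame: class, bp (distinct covered bases), fraction of the
#'   all-class total.  All-zero input yields fractions 0 with attribute
#'   `empty = TRUE`.
#' @export
class_totals <- function(hits_by_class) {
  bp <- vapply(MOTIF_CLASSES, function(cl) {
    h <- hits_by_class[[cl]]
    if (is.null(h) || nrow(h) == 0L) return(0L)
    sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(start = h$start + 1L, end = h$end))))
  }, 0L)
  total <- sum(bp)
  out <- data.frame(class = MOTIF_CLASSES, bp = unname(bp),
                    fraction = if (total > 0) unname(bp) / total else
                      rep(0, length(bp)),
                    stringsAsFactors = FALSE)
  attr(out, "empty") <- total == 0
  out
}

#' Export motif hits as BED6+1
#'
#' @param hits hit data frame from [predict_motifs()].
#' @param contig contig id for column 1.
#' @param path output file.
#' @export
write_motif_bed <- function(hits, contig, path) {
  cl <- attr(hits, "motif_class") %||% "nonB"
  df <- data.frame(contig = rep(contig, nrow(hits)),
                   start = hits$start, end = hits$end,
                   name = rep(cl, nrow(hits)),
                   score = hits$stars, strand = hits$strand,
                   stringsAsFactors = FALSE)
  write_bed(df, path, score_max = 3)
}
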