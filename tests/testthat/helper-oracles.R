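# Independent oracles and fixture builders shared across the suite.
# These deliberately re-derive results by brute force / first principles
# and must stay independent of the package's own algorithms.

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# ---- inverted-repeat brute force ------------------------------------------
# Tests every (left_start, arm_len, gap_len) triple for exact reverse
# complementarity and then applies the maximality rules: the arms cannot be
# extended outward (unless capped at max_stem) and the gap cannot be shrunk.
ir_oracle <- function(seq, min_stem = 5L, max_stem = 100L,
                      gap_limit = 20L) {
  code <- utf8ToInt(toupper(seq))
  n <- length(code)
  comp_of <- integer(128)
  comp_of[utf8ToInt("A")] <- utf8ToInt("T")
  comp_of[utf8ToInt("T")] <- utf8ToInt("A")
  comp_of[utf8ToInt("G")] <- utf8ToInt("C")
  comp_of[utf8ToInt("C")] <- utf8ToInt("G")
  compcode <- comp_of[code]            # 0 for N
  # pm(p, q): 0-based positions pair under reverse complementarity
  pm <- function(p, q) compcode[q + 1L] != 0L &
    code[p + 1L] == compcode[q + 1L]
  out <- list()
  max_a <- min(max_stem, n %/% 2L)
  for (a in seq_len(max_a)) {
    if (a < min_stem) next
    for (g in 0:gap_limit) {
      tot <- 2L * a + g
      if (tot > n) next
      i <- 0:(n - tot)                 # candidate left starts, 0-based
      ok <- rep(TRUE, length(i))
      for (k in 0:(a - 1L))
        ok <- ok & pm(i + k, i + tot - 1L - k)
      for (s in i[ok]) {
        ext <- a < max_stem && s > 0L && s + tot < n && pm(s - 1L, s + tot)
        if (ext) next
        if (g >= 2L && pm(s + a, s + a + g - 1L)) next
        out[[length(out) + 1L]] <- c(s, a, g)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(left_start = integer(), arm_len = integer(),
                      gap_len = integer()))
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- c("left_start", "arm_len", "gap_len")
  df <- df[order(df$left_start, df$arm_len, df$gap_len), ]
  rownames(df) <- NULL
  df
}

# ---- KS statistic brute force ---------------------------------------------
ks_D_oracle <- function(a, b) {
  z <- sort(unique(c(a, b)))
  max(abs(vapply(z, function(v) mean(a <= v) - mean(b <= v), 0)))
}

# ---- post-hoc control-set checker -----------------------------------------
# Re-verifies every recorded constraint from raw sequence, independently of
# the sampler's own bookkeeping.
check_control_set <- function(set, assembly) {
  cs <- set$constraints
  seg <- set$segments
  probs <- character()
  for (i in seq_len(nrow(seg))) {
    if (seg$contig[i] %in% cs$excluded_contigs)
      probs <- c(probs, sprintf("segment %d on excluded contig", i))
    len <- seg$end[i] - seg$start[i]
    if (len != cs$length)
      probs <- c(probs, sprintf("segment %d length %d != %d", i, len,
                                cs$length))
    s <- substr(assembly$seqs[[seg$contig[i]]], seg$start[i] + 1L,
                seg$end[i])
    gc <- gc_fraction(s)
    if (gc < cs$gc_lo - 1e-12 || gc > cs$gc_hi + 1e-12)
      probs <- c(probs, sprintf("segment %d gc %.4f outside [%.4f, %.4f]",
                                i, gc, cs$gc_lo, cs$gc_hi))
  }
  n_overlapping <- 0L
  for (i in seq_len(nrow(seg))) for (j in seq_len(i - 1L)) {
    if (seg$contig[i] != seg$contig[j]) next
    ov <- min(seg$end[i], seg$end[j]) - max(seg$start[i], seg$start[j])
    if (ov > 0L) {
      n_overlapping <- n_overlapping + 1L
      if (ov > cs$max_overlap_bp)
        probs <- c(probs, sprintf("pair (%d,%d) overlap %d bp", i, j, ov))
    }
  }
  if (n_overlapping > cs$max_overlapping_pairs)
    probs <- c(probs, sprintf("%d overlapping pairs", n_overlapping))
  probs
}

# ---- small shared fixtures -------------------------------------------------
write_tmp_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  con <- file(path, "w")
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    writeLines(seqs[[id]], con)
  }
  close(con)
  path
}
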