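# Cumulative GC / non-N counts per contig, for O(1) segment GC lookups.
gc_cumsums <- function(assembly) {
  lapply(assembly$seqs, function(s) {
    code <- utf8ToInt(s)
    list(gc = cumsum(code == 71L | code == 67L),
         nn = cumsum(code != 78L))
  })
}

segment_gc <- function(cums, start, end) {
  gc <- cums$gc[end] - if (start > 0L) cums$gc[start] else 0L
  nn <- cums$nn[end] - if (start > 0L) cums$nn[start] else 0L
  if (nn == 0L) return(0)
  gc / nn
}

#' Sample GC- and length-matched random control segments
#'
#' Draws `n` random genome segments of exactly the centromere contig's
#' length whose GC content matches the centromere within a tolerance, from
#' non-centromeric contigs only, by seeded rejection sampling.  At most
#' `max_overlapping_pairs` accepted segment pairs may mutually overlap, and
#' no overlap may exceed `max_overlap_bp`; all other pairs are disjoint.
#'
#' @param assembly a [genome_assembly()] with `centromere_ids` set (or pass
#'   `centromere_id` of any contig).
#' @param centromere_id contig the controls are matched to.
#' @param n number of control segments (default 50).
#' @param gc_tolerance GC matching tolerance (default 0.10).
#' @param gc_mode "relative" (within 10% of the centromere's GC fraction,
#'   the default) or "absolute" (within 10 percentage points).
#' @param max_overlap_bp largest permitted pairwise overlap (default 50000).
#' @param max_overlapping_pairs number of overlapping pairs permitted
#'   (default 2).
#' @param exclude optional BED-like data frame (`contig`, `start`, `end`)
#'   of additional regions segments must not touch.
#' @param seed RNG seed (mandatory; sampling is deterministic given it).
#' @param max_attempts rejection-sampling budget (default `10000 * n`).
#' @return a `control_set`: list with `centromere_id`, `segments` (data
#'   frame `contig`, `start`, `end`, `gc`), `seed`, `constraints`,
#'   `attempts`.
#' @export
sample_controls <- function(assembly, centromere_id, n = 50L,
                            gc_tolerance = 0.10,
                            gc_mode = c("relative", "absolute"),
                            max_overlap_bp = 50000L,
                            max_overlapping_pairs = 2L,
                            exclude = NULL, seed,
                            max_attempts = 10000L * n) {
  gc_mode <- match.arg(gc_mode)
  if (missing(seed) || is.null(seed)) stop_nonb("seed is mandatory")
  if (!is_count(n) || n < 1L) stop_nonb("n must be >= 1")
  L <- contig_length(assembly, centromere_id)
  cen_gc <- assembly$gc[[match(centromere_id, contig_ids(assembly))]]
  gc_lo <- if (gc_mode == "relative") cen_gc * (1 - gc_tolerance) else
    cen_gc - gc_tolerance
  gc_hi <- if (gc_mode == "relative") cen_gc * (1 + gc_tolerance) else
    cen_gc + gc_tolerance
  excluded_contigs <- union(assembly$centromere_ids, centromere_id)
  pool <- setdiff(contig_ids(assembly), excluded_contigs)
  pool <- pool[assembly$lengths[match(pool, contig_ids(assembly))] >= L]
  if (length(pool) == 0L)
    stop_nonb("no eligible non-centromeric contig of length >= ", L)
  pool_len <- assembly$lengths[match(pool, contig_ids(assembly))]
  n_starts <- pool_len - L + 1L
  cums <- gc_cumsums(assembly)[pool]

  touches_exclude <- function(ctg, s, e) {
    if (is.null(exclude) || nrow(exclude) == 0L) return(FALSE)
    any(exclude$contig == ctg & exclude$start < e & exclude$end > s)
  }

  seg <- data.frame(contig = character(), start = integer(),
                    end = integer(), gc = numeric(),
                    stringsAsFactors = FALSE)
  rejected <- c(gc = 0L, overlap = 0L, exclude = 0L)
  attempts <- 0L
  overlapping_pairs <- 0L
  with_seed(seed, {
    while (nrow(seg) < n && attempts < max_attempts) {
      attempts <- attempts + 1L
      ci <- if (length(pool) == 1L) 1L else
        sample.int(length(pool), 1L, prob = n_starts)
      s <- sample.int(n_starts[ci], 1L) - 1L
      e <- s + L
      gc <- segment_gc(cums[[ci]], s, e)
      if (gc < gc_lo || gc > gc_hi) {
        rejected[["gc"]] <- rejected[["gc"]] + 1L
        next
      }
      if (touches_exclude(pool[ci], s, e)) {
        rejected[["exclude"]] <- rejected[["exclude"]] + 1L
        next
      }
      same <- seg[seg$contig == pool[ci], , drop = FALSE]
      ov <- pmax(0L, pmin(same$end, e) - pmax(same$start, s))
      if (any(ov > max_overlap_bp) ||
          overlapping_pairs + sum(ov > 0L) > max_overlapping_pairs) {
        rejected[["overlap"]] <- rejected[["overlap"]] + 1L
        next
      }
      overlapping_pairs <- overlapping_pairs + sum(ov > 0L)
      seg[nrow(seg) + 1L, ] <- list(pool[ci], s, e, gc)
    }
  })
  if (nrow(seg) < n) {
    binding <- names(rejected)[which.max(rejected)]
    stop_nonb(sprintf(
      "could only place %d/%d controls in %d attempts (binding constraint: %s)",
      nrow(seg), n, attempts, binding))
  }
  structure(list(
    centromere_id = centromere_id,
    segments = seg,
    seed = seed,
    constraints = list(length = L, gc_lo = gc_lo, gc_hi = gc_hi,
                       gc_mode = gc_mode, gc_tolerance = gc_tolerance,
                       max_overlap_bp = max_overlap_bp,
                       max_overlapping_pairs = max_overlapping_pairs,
                       excluded_contigs = excluded_contigs),
    attempts = attempts,
    rejected = rejected
  ), class = "control_set")
}

#' @export
print.control_set <- function(x, ...) {
  cat(sprintf("control_set: %d segments of %d bp matched to '%s' (seed %s)\n",
              nrow(x$segments), x$constraints$length, x$centromere_id,
              format(x$seed)))
  invisible(x)
}

#' Extract control segment sequences
#'
#' @param set a `control_set`.
#' @param assembly the assembly it was sampled from.
#' @return character vector of segment sequences.
#' @export
control_seqs <- function(set, assembly) {
  vapply(seq_len(nrow(set$segments)), function(i)
    substr(contig_seq(assembly, set$segments$contig[i]),
           set$segments$start[i] + 1L, set$segments$end[i]),
    "")
}

#' Apply a metric to every control segment
#'
#' @param set a `control_set`.
#' @param assembly the source [genome_assembly()].
#' @param metric_fn function mapping a DNA string to a single number
#'   (e.g. dyad density, G4 density, mean combined stars).
#' @return numeric vector, one value per segment, in segment order.
#' @export
control_metrics <- function(set, assembly, metric_fn) {
  seqs <- control_seqs(set, assembly)
  vapply(seq_along(seqs), function(i) {
    v <- tryCatch(metric_fn(seqs[[i]]), error = function(e)
      stop_nonb(sprintf("metric failed on control segment %d: %s",
                        i, conditionMessage(e))))
    as.numeric(v)
  }, 0)
}

#' Export a control set as BED plus a JSON manifest
#'
#' @param set a `control_set`.
#' @param bed_path BED output path.
#' @param manifest_path optional JSON manifest path.
#' @export
write_control_set <- function(set, bed_path, manifest_path = NULL) {
  df <- set$segments
  df$name <- sprintf("control_%03d", seq_len(nrow(df)))
  df$score <- NULL
  write_bed(df[, c("contig", "start", "end", "name")], bed_path)
  if (!is.null(manifest_path)) {
    jsonlite::write_json(list(
      centromere_id = set$centromere_id, seed = set$seed,
      n = nrow(set$segments), constraints = set$constraints,
      attempts = set$attempts,
      acceptance_rate = nrow(set$segments) / set$attempts
    ), manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(bed_path)
}
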