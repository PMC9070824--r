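#' Configuration for the synthetic assembly generator
#'
#' The generator emulates the input world of the analysis: a multi-contig
#' assembly whose designated centromere contig is an island of complex
#' (retroelement-like, i.i.d.-composition) sequence flanked by simple
#' satellite arrays, with non-B motifs planted at recorded coordinates,
#' plus matching synthetic IPD tracks and structure-probability tables.
#' The dodeca-like monomer is a GC-rich 12-mer *stand-in* (the real
#' satellite sequence is not bundled); AATAT and AATAACATAG are the
#' classical AT-rich satellite monomers.
#'
#' @param seed mandatory RNG seed (all outputs are deterministic given it;
#'   R's default Mersenne-Twister generator is used throughout).
#' @param n_background_contigs number of background contigs.
#' @param background_length_range min/max background contig length (bp).
#' @param background_gc background GC: either a single fraction applied to
#'   every contig or a `c(lo, hi)` range sampled per contig.
#' @param island_length centromere island length (bp).
#' @param island_gc island GC fraction.
#' @param satellites list of `left`/`right` flank specs, each a list of
#'   `list(monomer =, copies =)` arrays.
#' @param planted data frame `class`, `n`, `stars`, optional `len` (target
#'   motif length for the length-scalable classes ZDNA, TFO, STR).
#' @param plant_in "island" or "background".
#' @param min_separation minimum gap between planted motifs (bp).
#' @param ipd list: `background` level, `elevation` factor over planted
#'   motifs, `noise_sd` (lognormal sdlog), `missing_rate`.
#' @param sist list: `background` per-structure named vectors of mean
#'   probability by temperature, `elevation` per-structure named vectors
#'   of centromere fold-elevation by temperature, `concentration` of the
#'   beta noise, `digits` the table's stored precision.
#' @return a `synth_config` list.
#' @export
synth_config <- function(
    seed,
    n_background_contigs = 30L,
    background_length_range = c(40000L, 70000L),
    background_gc = c(0.30, 0.42),
    island_length = 8000L,
    island_gc = 0.45,
    satellites = list(
      left = list(list(monomer = "AATAT", copies = 240L),
                  list(monomer = "GCCGAGGCGGTC", copies = 70L)),
      right = list(list(monomer = "AATAACATAG", copies = 120L),
                   list(monomer = "AATAT", copies = 160L))
    ),
    planted = data.frame(class = MOTIF_CLASSES, n = 2L,
                         stars = c(2L, 3L, 3L, 2L, 3L, 2L, 3L)),
    plant_in = "island",
    min_separation = 300L,
    ipd = list(background = 1.0, elevation = 2.2, noise_sd = 0.08,
               missing_rate = 0.10),
    sist = list(
      background = list(
        melt = c("18" = 0.02, "22" = 0.03, "25" = 0.05, "30" = 0.08,
                 "35" = 0.12),
        cruciform = c("18" = 0.02, "22" = 0.02, "25" = 0.02, "30" = 0.02,
                      "35" = 0.02),
        zdna = c("18" = 0.03, "22" = 0.03, "25" = 0.03, "30" = 0.03,
                 "35" = 0.03)),
      elevation = list(
        melt = c("18" = 1, "22" = 1, "25" = 3, "30" = 3, "35" = 1),
        cruciform = c("18" = 1, "22" = 1, "25" = 1, "30" = 1, "35" = 1),
        zdna = c("18" = 1, "22" = 1, "25" = 1, "30" = 1, "35" = 1)),
      concentration = 60,
      digits = 4L
    )) {
  if (missing(seed) || is.null(seed)) stop_nonb("seed is mandatory")
  if (any(planted$n < 0)) stop_nonb("planted counts must be >= 0")
  if (!all(planted$class %in% MOTIF_CLASSES))
    stop_nonb("unknown planted class")
  if (any(vapply(unlist(lapply(satellites, function(x)
    lapply(x, `[[`, "monomer"))), nchar, 0L) == 0L))
    stop_nonb("satellite monomers must be non-empty")
  structure(as.list(environment()), class = "synth_config")
}

rand_bases <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

sample_from <- function(x) if (length(x) == 1L) x else sample(x, 1L)

# Draw one motif sequence of the requested class and star rating.
# `len` overrides the default size for the length-scalable classes.
make_motif_seq <- function(class, stars, len = NA) {
  rand_alpha <- function(n, alphabet, prob = NULL)
    paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
  switch(class,
    G4 = {
      n_runs <- if (stars == 3L) 5L else 4L
      loops <- vapply(seq_len(n_runs - 1L), function(i)
        rand_alpha(sample_from(1:3), c("A", "T", "C")), "")
      paste0(paste0(strrep("G", 3L), c(loops, "")), collapse = "")
    },
    ZDNA = {
      k <- if (!is.na(len)) max(6L, as.integer(len) %/% 2L) else
        sample_from(6:9)
      if (stars == 3L) strrep("GC", k) else {
        repeat {
          nxt <- list(G = c("C", "T"), C = c("G", "A"),
                      T = c("G"), A = c("C"))
          ch <- "G"
          for (i in seq_len(2L * k - 1L))
            ch <- c(ch, sample_from(nxt[[ch[length(ch)]]]))
          s <- paste(ch, collapse = "")
          if (grepl("[AT]", s)) break
        }
        s
      }
    },
    STR = {
      repeat {
        u <- sample_from(2:5)
        unit <- rand_alpha(u, c("A", "C", "G", "T"))
        uch <- seq_chars(unit)
        primitive <- TRUE
        for (d in seq_len(u - 1L))
          if (u %% d == 0L && has_period(uch, d)) {
            primitive <- FALSE; break
          }
        if (primitive) break
      }
      copies <- if (stars == 3L) 10L + sample_from(0:4) else
        max(5L, ceiling(15 / u)) + sample_from(0:2)
      if (stars == 2L && copies >= 10L) copies <- 9L
      strrep(unit, copies)
    },
    SLIPPED = {
      u <- if (stars == 3L) sample_from(20:28) else sample_from(10:18)
      unit <- rand_alpha(u, c("A", "C", "G", "T"))
      spacer <- rand_alpha(sample_from(0:10), c("A", "C", "G", "T"))
      paste0(unit, spacer, unit)
    },
    HDNA = {
      arm <- rand_alpha(sample_from(10:14), c("A", "G"))
      sp_len <- if (stars == 3L) sample_from(0:8) else sample_from(1:8)
      spacer <- seq_chars(rand_alpha(max(sp_len, 1L), c("A", "G")))[
        seq_len(sp_len)]
      if (stars == 2L && sp_len > 0L)
        spacer[sample_from(seq_len(sp_len))] <- "C"
      paste0(arm, paste(spacer, collapse = ""),
             intToUtf8(rev(utf8ToInt(arm))))
    },
    TFO = {
      n <- if (!is.na(len)) as.integer(len) else
        if (stars == 3L) sample_from(25:32) else sample_from(15:22)
      repeat {
        s <- rand_alpha(n, c("A", "G"), prob = c(0.4, 0.6))
        if (mean(seq_chars(s) == "G") >= 0.5) break
      }
      s
    },
    APR = {
      n_tracts <- if (stars == 3L) sample_from(4:5) else 3L
      gaps <- vapply(seq_len(n_tracts - 1L), function(i)
        rand_alpha(sample_from(5:6), c("C", "G", "T")), "")
      paste0(paste0(strrep("A", 5L), c(gaps, "")), collapse = "")
    },
    stop_nonb("unknown class: ", class))
}

# Verify that scanning a local window recovers exactly the planted hit.
plant_ok <- function(seq, start, end, class, stars, rules, margin = 150L) {
  lo <- max(0L, start - margin)
  hi <- min(nchar(seq), end + margin)
  hits <- predict_motifs(substr(seq, lo + 1L, hi), class, rules)
  any(hits$start == start - lo & hits$end == end - lo &
        hits$stars == stars & hits$strand == "+")
}

# Splice motifs into `seqs` (named list of mutable strings) at random
# positions within the given regions, honouring a minimum separation and
# re-scanning each placement for exact recoverability.
plant_motifs <- function(seqs, regions, planted, rules, min_separation,
                         max_tries = 200L) {
  truth <- data.frame(contig = character(), start = integer(),
                      end = integer(), class = character(),
                      stars = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  region_len <- regions$hi - regions$lo
  for (r in seq_len(nrow(planted))) {
    cls <- planted$class[r]
    for (k in seq_len(planted$n[r])) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        motif <- make_motif_seq(cls, planted$stars[r],
                                planted$len[r] %||% NA)
        mlen <- nchar(motif)
        ri <- if (nrow(regions) == 1L) 1L else
          sample.int(nrow(regions), 1L, prob = region_len)
        lim <- region_len[ri] - mlen
        if (lim < 1L) next
        s <- regions$lo[ri] + sample.int(lim, 1L) - 1L
        e <- s + mlen
        ctg <- regions$contig[ri]
        prior <- truth[truth$contig == ctg, , drop = FALSE]
        if (nrow(prior) > 0L &&
            any(prior$start - min_separation < e &
                prior$end + min_separation > s)) next
        cand <- seqs[[ctg]]
        substr(cand, s + 1L, e) <- motif
        if (!plant_ok(cand, s, e, cls, planted$stars[r], rules)) next
        seqs[[ctg]] <- cand
        truth[nrow(truth) + 1L, ] <-
          list(ctg, s, e, cls, planted$stars[r], "+")
        placed <- TRUE
        break
      }
      if (!placed)
        stop_nonb(sprintf(
          "could not place %s motif %d/%d: motif density infeasible",
          cls, k, planted$n[r]))
    }
  }
  list(seqs = seqs, truth = truth)
}

#' Generate a synthetic assembly with planted ground truth
#'
#' @param config a [synth_config()].
#' @param rules the [motif_ruleset()] used for the placement re-scan check.
#' @return list with `assembly` (a [genome_assembly()], centromere contig
#'   `cen_1`) and `truth` (list: `motifs` data frame, `annotation` data
#'   frame of island/satellite blocks, `config`).
#' @export
generate_assembly <- function(config, rules = motif_ruleset()) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    bg_ids <- sprintf("bg_%02d", seq_len(config$n_background_contigs))
    bg_len <- sample(config$background_length_range[1L]:
                       config$background_length_range[2L],
                     config$n_background_contigs, replace = TRUE)
    # per-contig GC drawn from the configured range emulates the regional
    # composition variation real control sampling has to cope with
    bg_gc <- if (length(config$background_gc) == 2L)
      runif(config$n_background_contigs, config$background_gc[1L],
            config$background_gc[2L])
    else rep(config$background_gc, config$n_background_contigs)
    seqs <- Map(rand_bases, bg_len, bg_gc)
    names(seqs) <- bg_ids

    flank_seq <- function(spec) paste(vapply(spec, function(a)
      strrep(toupper(a$monomer), a$copies), ""), collapse = "")
    left <- flank_seq(config$satellites$left)
    right <- flank_seq(config$satellites$right)
    island <- rand_bases(config$island_length, gc = config$island_gc)
    seqs$cen_1 <- paste0(left, island, right)
    island_lo <- nchar(left)
    island_hi <- island_lo + config$island_length

    annotation <- data.frame(
      contig = "cen_1",
      start = c(0L, island_lo, island_hi),
      end = c(island_lo, island_hi, nchar(seqs$cen_1)),
      name = c("satellite_left", "island", "satellite_right"),
      stringsAsFactors = FALSE)

    planted <- config$planted
    if (is.null(planted$len)) planted$len <- NA
    regions <- if (identical(config$plant_in, "island")) {
      data.frame(contig = "cen_1", lo = island_lo + 50L,
                 hi = island_hi - 50L, stringsAsFactors = FALSE)
    } else {
      data.frame(contig = bg_ids, lo = 200L, hi = bg_len - 200L,
                 stringsAsFactors = FALSE)
    }
    pl <- plant_motifs(seqs, regions, planted, rules,
                       config$min_separation)
    assembly <- genome_assembly(unlist(pl$seqs),
                                centromere_ids = "cen_1")
    list(assembly = assembly,
         truth = list(motifs = pl$truth, annotation = annotation,
                      config = config))
  })
}

#' Generate synthetic per-base IPD tracks
#'
#' Background level with multiplicative lognormal noise, scaled by the
#' configured elevation factor inside planted motifs; a configured
#' fraction of positions is missing (NA).
#'
#' @param assembly,truth from [generate_assembly()].
#' @param config the same [synth_config()].
#' @return named list of numeric vectors, one per contig.
#' @export
generate_ipd <- function(assembly, truth, config) {
  ipd <- config$ipd
  if (ipd$elevation <= 0) stop_nonb("elevation must be > 0")
  with_seed(child_seed(config$seed, 1L), {
    out <- lapply(contig_ids(assembly), function(id) {
      n <- contig_length(assembly, id)
      v <- ipd$background *
        if (ipd$noise_sd > 0) rlnorm(n, 0, ipd$noise_sd) else rep(1, n)
      m <- truth$motifs[truth$motifs$contig == id, , drop = FALSE]
      for (i in seq_len(nrow(m)))
        v[(m$start[i] + 1L):m$end[i]] <-
          v[(m$start[i] + 1L):m$end[i]] * ipd$elevation
      if (ipd$missing_rate > 0)
        v[runif(n) < ipd$missing_rate] <- NA_real_
      v
    })
    names(out) <- contig_ids(assembly)
    out
  })
}

#' Generate synthetic structure-probability tables
#'
#' Per contig, temperature and structure: beta-distributed per-base
#' probabilities around the configured background mean, with centromere
#' contigs elevated by the configured per-structure, per-temperature
#' factor.  Values are stored at the table format's precision.
#'
#' @param assembly,truth from [generate_assembly()].
#' @param config the same [synth_config()].
#' @param temperatures subset of 18, 22, 25, 30, 35.
#' @return nested list: `[["25"]][[contig]]` is a SIST-style data frame.
#' @export
generate_sist_tables <- function(assembly, truth, config,
                                 temperatures = SIST_TEMPERATURES) {
  if (!all(temperatures %in% SIST_TEMPERATURES))
    stop_nonb("unknown temperature")
  s <- config$sist
  with_seed(child_seed(config$seed, 2L), {
    out <- list()
    for (temp in temperatures) {
      tkey <- as.character(temp)
      per_contig <- lapply(contig_ids(assembly), function(id) {
        n <- contig_length(assembly, id)
        is_cen <- id %in% assembly$centromere_ids
        df <- data.frame(position = seq_len(n) - 1L)
        for (st in SIST_STRUCTURES) {
          mu <- s$background[[st]][[tkey]]
          if (is_cen) mu <- mu * s$elevation[[st]][[tkey]]
          mu <- min(mu, 0.95)
          a <- mu * s$concentration
          b <- (1 - mu) * s$concentration
          df[[st]] <- pmin(1, pmax(0, round(rbeta(n, a, b), s$digits)))
        }
        attr(df, "temperature") <- temp
        df
      })
      names(per_contig) <- contig_ids(assembly)
      out[[tkey]] <- per_contig
    }
    out
  })
}

#' Slice per-contig SIST tables into sweep input for a control set
#'
#' @param tables output of [generate_sist_tables()] (or tables read from
#'   disk, nested the same way).
#' @param centromere_id the centromere contig id.
#' @param controls a `control_set` over the same assembly.
#' @return input for [temperature_sweep_report()].
#' @export
sist_sets_for_controls <- function(tables, centromere_id, controls) {
  lapply(tables, function(per_contig) {
    list(
      centromere = per_contig[[centromere_id]],
      controls = lapply(seq_len(nrow(controls$segments)), function(i) {
        sg <- controls$segments[i, ]
        per_contig[[sg$contig]][(sg$start + 1L):sg$end, , drop = FALSE]
      })
    )
  })
}

#' Monte-Carlo calibration of the enrichment verdict
#'
#' Draws `n_controls` control metric values from a normal world and tests
#' them against a centromere value of `elevation * mean` — the metric of a
#' whole centromere contig concentrates at its expectation, so the null
#' (`elevation = 1`) hypothesizes the true control mean, which is the
#' setting in which the one-sample t's type-I error is defined.  Reports
#' the rate of "enriched" verdicts from [one_sample_t()]; with
#' `elevation = 3` this measures power under a threefold planted
#' elevation.
#'
#' @param n_reps number of replicates.
#' @param n_controls controls per replicate (default 50).
#' @param elevation centromere fold-elevation (default 1 = null).
#' @param mean,sd the metric world (defaults 0.8 +/- 0.12, a plausible
#'   per-segment combined-star mean).
#' @param alpha verdict significance level.
#' @param seed RNG seed.
#' @return verdict rate in \[0, 1\].
#' @export
simulate_enrichment_verdicts <- function(n_reps, n_controls = 50L,
                                         elevation = 1, mean = 0.8,
                                         sd = 0.12, alpha = 0.05, seed) {
  with_seed(seed, {
    hits <- vapply(seq_len(n_reps), function(i) {
      ctl <- rnorm(n_controls, mean, sd)
      cen <- elevation * mean
      suppressWarnings(
        one_sample_t(ctl, cen, alpha = alpha)$significant)
    }, NA)
    mean(hits)
  })
}
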