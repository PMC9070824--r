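test_that("worked examples for the class rules", {
  # G4: four G3 runs, TTA loops -> one 2-star hit spanning the chain
  h <- predict_motifs("GGGTTAGGGTTAGGGTTAGGG", "G4")
  expect_equal(nrow(h), 1L)
  expect_equal(c(h$start, h$end), c(0L, 21L))
  expect_equal(h$strand, "+")
  expect_equal(h$stars, 2L)
  # five runs with short loops -> 3 stars
  h5 <- predict_motifs("GGGAGGGAGGGAGGGAGGG", "G4")
  expect_equal(h5$stars, 3L)
  # a long loop demotes to 2 stars
  hl <- predict_motifs("GGGAGGGAGGGTTTTTGGGAGGG", "G4")
  expect_equal(hl$stars, 2L)

  # ZDNA: pure GC alternation -> 3 stars
  z <- predict_motifs("GCGCGCGCGCGC", "ZDNA")
  expect_equal(c(z$start, z$end, z$stars), c(0L, 12L, 3L))
  # mixed alternation (contains T) -> 2 stars
  z2 <- predict_motifs("GTGCGCGTGCGT", "ZDNA")
  expect_equal(z2$stars, 2L)
  # AT alternation is not a Z-tract
  expect_equal(nrow(predict_motifs(strrep("AT", 10), "ZDNA")), 0L)

  # STR: (AT)x10 -> unit 2, 10 copies, 3 stars
  s <- predict_motifs(strrep("AT", 10), "STR")
  expect_equal(c(s$start, s$end, s$stars), c(0L, 20L, 3L))
  expect_match(s$detail, "unit=2;copies=10")
  # 4-mer repeat has no G run of 3 -> no G4
  expect_equal(nrow(predict_motifs(strrep("ACGT", 13), "G4")), 0L)

  # SLIPPED: exact direct repeat unit 12, spacer 3
  unit <- "ACGGTCAATGCA"
  sl <- predict_motifs(paste0(unit, "TTT", unit), "SLIPPED")
  expect_equal(c(sl$start[1], sl$end[1]), c(0L, 27L))
  expect_equal(sl$stars[1], 2L)
  unit20 <- "ACGGTCAATGCAGTTCAGGT"
  sl3 <- predict_motifs(paste0(unit20, unit20), "SLIPPED")
  expect_equal(sl3$stars[1], 3L)

  # HDNA: all-purine mirror repeat -> 3 stars
  arm <- "AGGAAGAGGA"
  hd <- predict_motifs(paste0(arm, "AAG", paste(rev(strsplit(arm, "")[[1]]),
                                                collapse = "")), "HDNA")
  expect_true(any(hd$stars == 3L & hd$start == 0L & hd$end == 23L))

  # TFO: >= 15 bp homopurine with >= 50% G; >= 25 bp upgrades
  tf <- predict_motifs("AGGAGAGGAGGAGGA", "TFO")
  expect_equal(c(tf$start, tf$end, tf$stars), c(0L, 15L, 2L))
  tf3 <- predict_motifs(strrep("AGGAG", 5), "TFO")
  expect_equal(tf3$stars, 3L)
  # < 50% G fails
  expect_equal(nrow(predict_motifs(strrep("AAAG", 5), "TFO")), 0L)

  # APR: three A5 tracts, centers 10-11 bp apart
  ap <- predict_motifs("AAAAACGCGCAAAAACGCGGCAAAAA", "APR")
  expect_equal(c(ap$start, ap$end, ap$stars), c(0L, 26L, 2L))

  expect_error(predict_motifs("ACGT", "IMOTIF"), "unknown motif class")
})

test_that("minus-strand hits are reported in plus coordinates", {
  g4_plus <- "GGGTTAGGGTTAGGGTTAGGG"
  s <- paste0("TTTT", revcomp(g4_plus), "TTTT")
  h <- predict_motifs(s, "G4")
  expect_equal(nrow(h), 1L)
  expect_equal(h$strand, "-")
  expect_equal(c(h$start, h$end), c(4L, 25L))
  tf <- predict_motifs("CCTCTCCTCCTCCTC", "TFO")
  expect_equal(tf$strand, "-")
})

test_that("hit sets are strand-symmetric under reverse complement", {
  set.seed(41)
  for (i in 1:8) {
    n <- 600
    s <- rand_dna(n, gc = 0.55)
    for (cl in MOTIF_CLASSES) {
      fwd <- predict_motifs(s, cl)
      rev <- predict_motifs(revcomp(s), cl)
      flip <- c("+" = "-", "-" = "+")
      mirrored <- data.frame(start = n - fwd$end, end = n - fwd$start,
                             strand = unname(flip[fwd$strand]),
                             stars = fwd$stars)
      # strand-symmetric classes keep "+" on both strands
      if (cl %in% c("ZDNA", "STR", "SLIPPED", "HDNA") && nrow(mirrored))
        mirrored$strand <- "+"
      o <- function(d) {
        d <- d[order(d$start, d$end, d$strand, d$stars), ]
        rownames(d) <- NULL
        d
      }
      expect_equal(o(rev[, c("start", "end", "strand", "stars")]),
                   o(mirrored), info = paste(cl, i))
    }
  }
})

test_that("stars_track takes within-class maxima and defaults to 2", {
  h <- data.frame(start = c(2L, 3L), end = c(5L, 6L), strand = "+",
                  stars = c(3L, 2L), detail = "")
  attr(h, "motif_class") <- "G4"
  expect_equal(stars_track(8L, h), c(0, 0, 3, 3, 3, 2, 0, 0))
  h$stars <- c(NA_integer_, NA_integer_)
  expect_equal(max(stars_track(8L, h)), 2)
  expect_equal(stars_track(5L, h[0, ]), rep(0, 5))
  expect_error(stars_track(8L, h, motif_class = "STR"), "expected STR")
})

test_that("combine_likelihoods sums across classes and bounds at 21", {
  t1 <- c(0, 3, 3); t2 <- c(2, 2, 0)
  expect_equal(combine_likelihoods(list(t1, t2)), c(2, 5, 3))
  expect_error(combine_likelihoods(list(t1, c(1, 2))), "length mismatch")
  all3 <- replicate(7, rep(3, 4), simplify = FALSE)
  expect_equal(combine_likelihoods(all3), rep(21, 4))
  # dominates every component track
  set.seed(42)
  tracks <- replicate(7, sample(0:3, 20, replace = TRUE), simplify = FALSE)
  comb <- combine_likelihoods(tracks)
  for (tr in tracks) expect_true(all(comb >= tr))
})

test_that("class_totals counts distinct covered bases", {
  g4 <- data.frame(start = 0L, end = 21L, strand = "+", stars = 2L,
                   detail = "")
  str2 <- data.frame(start = c(0L, 10L), end = c(20L, 30L), strand = "+",
                     stars = 2L, detail = "")
  tot <- class_totals(list(G4 = g4, STR = str2))
  expect_equal(tot$bp[tot$class == "G4"], 21L)
  expect_equal(tot$bp[tot$class == "STR"], 30L)   # union, not sum
  expect_equal(sum(tot$fraction), 1)
  empty <- class_totals(list())
  expect_true(attr(empty, "empty"))
  expect_equal(sum(empty$fraction), 0)
})

test_that("rule overrides propagate and are validated", {
  r <- motif_ruleset(g4 = list(loop_max = 2L))
  expect_equal(nrow(predict_motifs("GGGTTAGGGTTAGGGTTAGGG", "G4", r)), 0L)
  expect_error(motif_ruleset(bogus = list(a = 1)), "unknown motif class")
  expect_error(motif_ruleset(g4 = list(loop_min = 5L, loop_max = 2L)),
               "invalid G4")
})
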