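# Small config for fast unit tests (the acceptance suite uses the defaults)
small_cfg <- function(seed, planted = data.frame(class = c("G4", "STR"),
                                                 n = 3L, stars = 3L),
                      ...) {
  synth_config(seed = seed, n_background_contigs = 4L,
               background_length_range = c(8000L, 12000L),
               island_length = 5000L,
               satellites = list(
                 left = list(list(monomer = "AATAT", copies = 100L)),
                 right = list(list(monomer = "AATAACATAG", copies = 50L))),
               planted = planted, ...)
}

test_that("generation is deterministic and architecture is as configured", {
  cfg <- small_cfg(seed = 5)
  g1 <- generate_assembly(cfg)
  g2 <- generate_assembly(cfg)
  expect_identical(g1$assembly$seqs, g2$assembly$seqs)
  expect_identical(g1$truth$motifs, g2$truth$motifs)
  expect_equal(length(g1$assembly), 5L)   # 4 background + centromere
  expect_equal(g1$assembly$centromere_ids, "cen_1")
  ann <- g1$truth$annotation
  expect_equal(ann$name, c("satellite_left", "island", "satellite_right"))
  expect_equal(ann$end[1] - ann$start[1], 500L)    # 100 x AATAT
  expect_equal(ann$end[2] - ann$start[2], 5000L)
  # satellite flank really is the configured monomer array
  cen <- g1$assembly$seqs[["cen_1"]]
  expect_equal(substr(cen, 1, 10), "AATATAATAT")
  # different seeds differ
  expect_false(identical(generate_assembly(small_cfg(seed = 6))$assembly$seqs,
                         g1$assembly$seqs))
  expect_error(synth_config(), "seed is mandatory")
})

test_that("planted motifs are recovered exactly by the scanners", {
  cfg <- small_cfg(seed = 8,
                   planted = data.frame(class = MOTIF_CLASSES, n = 1L,
                                        stars = c(2L, 3L, 2L, 3L, 2L, 3L, 2L)))
  gen <- generate_assembly(cfg)
  tm <- gen$truth$motifs
  expect_equal(nrow(tm), 7L)
  seqs <- gen$assembly$seqs
  for (i in seq_len(nrow(tm))) {
    h <- predict_motifs(seqs[[tm$contig[i]]], tm$class[i])
    expect_true(any(h$start == tm$start[i] & h$end == tm$end[i] &
                      h$stars == tm$stars[i] & h$strand == "+"),
                info = paste(tm$class[i], i))
  }
  # truth intervals lie within their contigs and respect separation
  expect_true(all(tm$start >= 0 & tm$end <= nchar(seqs[[tm$contig[1]]])))
})

test_that("a zero-plant config yields only chance hits (negative control)", {
  cfg <- small_cfg(seed = 9, planted = data.frame(class = "G4", n = 0L,
                                                  stars = 2L))
  gen <- generate_assembly(cfg)
  expect_equal(nrow(gen$truth$motifs), 0L)
  # chance hits on 40% GC background are rare: record the baseline rate
  bg <- gen$assembly$seqs[["bg_01"]]
  hits <- predict_motifs(bg, "G4")
  expect_lt(nrow(hits) / (nchar(bg) / 1e4), 2)   # < 2 hits per 10 kb
})

test_that("infeasible planting densities error out", {
  expect_error(generate_assembly(
    small_cfg(seed = 10, planted = data.frame(class = "SLIPPED", n = 200L,
                                              stars = 3L))),
    "infeasible")
})

test_that("synthetic IPD tracks elevate planted motifs", {
  cfg <- small_cfg(seed = 11,
                   planted = data.frame(class = "ZDNA", n = 3L, stars = 3L,
                                        len = 52L),
                   ipd = list(background = 1.0, elevation = 2.2,
                              noise_sd = 0, missing_rate = 0))
  gen <- generate_assembly(cfg)
  ipd <- generate_ipd(gen$assembly, gen$truth, cfg)
  tm <- gen$truth$motifs[1, ]
  v <- ipd[[tm$contig]]
  expect_equal(v[(tm$start + 1):tm$end], rep(2.2, tm$end - tm$start))
  expect_equal(v[tm$start], 1.0)          # sharp step at the boundary
  expect_equal(v[tm$end + 1], 1.0)
  # missing rate 1 gives an all-NA track (downstream filtering path)
  cfg2 <- small_cfg(seed = 11,
                    planted = data.frame(class = "ZDNA", n = 1L, stars = 3L),
                    ipd = list(background = 1.0, elevation = 2.2,
                               noise_sd = 0, missing_rate = 1.0))
  gen2 <- generate_assembly(cfg2)
  ipd2 <- generate_ipd(gen2$assembly, gen2$truth, cfg2)
  expect_true(all(is.na(ipd2[["cen_1"]])))
  cfg_bad <- cfg
  cfg_bad$ipd$elevation <- 0
  expect_error(generate_ipd(gen$assembly, gen$truth, cfg_bad), "elevation")
})

test_that("synthetic structure tables honour elevation config and bounds", {
  cfg <- small_cfg(seed = 12)
  gen <- generate_assembly(cfg)
  tabs <- generate_sist_tables(gen$assembly, gen$truth, cfg,
                               temperatures = c(18L, 25L))
  expect_named(tabs, c("18", "25"))
  t25 <- tabs[["25"]]
  expect_named(t25, names(gen$assembly$seqs), ignore.order = TRUE)
  cen <- t25[["cen_1"]]
  bg <- t25[["bg_01"]]
  for (s in c("melt", "cruciform", "zdna"))
    expect_true(all(cen[[s]] >= 0 & cen[[s]] <= 1))
  # melt elevated x3 at 25C in the centromere only (default stated world)
  expect_gt(mean(cen$melt), 2 * mean(bg$melt))
  # no elevation at 18C
  expect_lt(abs(mean(tabs[["18"]][["cen_1"]]$melt) -
                  mean(tabs[["18"]][["bg_01"]]$melt)), 0.01)
  expect_error(generate_sist_tables(gen$assembly, gen$truth, cfg,
                                    temperatures = 99), "unknown temperature")
})

test_that("verdict calibration helper is seeded and sane", {
  r1 <- simulate_enrichment_verdicts(50, seed = 1)
  r2 <- simulate_enrichment_verdicts(50, seed = 1)
  expect_identical(r1, r2)
  expect_equal(simulate_enrichment_verdicts(30, elevation = 3, seed = 2), 1)
})
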