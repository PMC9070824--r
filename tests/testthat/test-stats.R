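test_that("iqr_trim drops points beyond the 1.5 IQR fences", {
  expect_equal(iqr_trim(c(1, 2, 3, 4, 100)), c(1, 2, 3, 4))
  # zero-IQR data sit on the fences and are retained
  expect_equal(iqr_trim(rep(5, 5)), rep(5, 5))
  expect_warning(out <- iqr_trim(c(1, 2, 3)), "fewer than 4")
  expect_equal(out, c(1, 2, 3))
  # idempotent on its own output
  set.seed(71)
  x <- c(rnorm(50), 10, -12)
  once <- iqr_trim(x)
  expect_equal(iqr_trim(once), once)
  # expected trim fraction on clean normal data is ~0.7%
  set.seed(72)
  fr <- mean(replicate(400, {
    v <- rnorm(50)
    1 - length(iqr_trim(v)) / 50
  }))
  expect_gt(fr, 0.001)
  expect_lt(fr, 0.025)
})

test_that("one_sample_t tests controls against the centromere value", {
  ctl <- c(0.10, 0.12, 0.11, 0.09, 0.08)
  res <- one_sample_t(ctl, 0.20, trim = FALSE)
  # oracle: the standard t formula evaluated directly
  t_expect <- (mean(ctl) - 0.20) / (sd(ctl) / sqrt(5))
  p_expect <- 2 * pt(-abs(t_expect), 4)
  expect_equal(res$statistic, t_expect)
  expect_equal(res$p_value, p_expect)
  expect_equal(res$direction, "centromere_higher")
  expect_true(res$significant)
  # agreement with stats::t.test as an independent reference
  ref <- t.test(ctl, mu = 0.20)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)

  # centromere equal to the control mean: p = 1, not significant
  res2 <- one_sample_t(c(1, 2, 3, 4, 5), 3, trim = FALSE)
  expect_equal(res2$p_value, 1)
  expect_false(res2$significant)
  expect_equal(res2$direction, "none")

  # degenerate controls
  res3 <- one_sample_t(rep(0.5, 10), 0.5)
  expect_true(res3$degenerate)
  expect_equal(res3$p_value, 1)
  expect_false(res3$significant)
  res4 <- one_sample_t(rep(0.5, 10), 0.9)
  expect_equal(res4$p_value, 0)
  expect_equal(res4$direction, "centromere_higher")
  expect_true(res4$significant)

  # significance requires the centromere to be the higher side
  res5 <- one_sample_t(c(10, 11, 12, 13, 14), 2, trim = FALSE)
  expect_lt(res5$p_value, 0.05)
  expect_false(res5$significant)
  expect_equal(res5$direction, "controls_higher")
})

test_that("KS matches a brute-force ECDF oracle, including ties", {
  expect_equal(ks_two_sample(c(1, 2, 3, 4), c(3, 4, 5, 6))$statistic, 0.5)
  expect_equal(ks_two_sample(c(0, 0, 0), c(1, 1, 1))$statistic, 1)
  same <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  set.seed(73)
  for (i in 1:300) {
    na <- sample(1:8, 1); nb <- sample(1:8, 1)
    a <- sample(0:5, na, replace = TRUE)
    b <- sample(0:5, nb, replace = TRUE)
    expect_equal(ks_two_sample(a, b)$statistic, ks_D_oracle(a, b),
                 info = paste(paste(a, collapse = ","), "vs",
                              paste(b, collapse = ",")))
  }
  # p-value sanity against the reference implementation on tie-free data
  set.seed(74)
  a <- rnorm(40); b <- rnorm(35, 0.4)
  ours <- ks_two_sample(a, b)
  ref <- suppressWarnings(ks.test(a, b, exact = FALSE))
  expect_equal(ours$statistic, unname(ref$statistic))
  # asymptotic approximations differ slightly (small-sample correction)
  expect_lt(abs(ours$p_value - ref$p.value), 0.05)
  expect_error(ks_two_sample(numeric(0), 1:3), "empty")
})

test_that("rank_by_mean_likelihood ranks descending with min-tie ranks", {
  tracks <- list(a = rep(2, 10), b = rep(1, 10), c = rep(3, 10))
  r <- rank_by_mean_likelihood(data.frame(contig = c("a", "b", "c")), tracks)
  expect_equal(r$contig, c("c", "a", "b"))
  expect_equal(r$rank, 1:3)
  expect_equal(r$percentile, (1:3) / 3)
  # ties share the minimum rank and are flagged
  tracks2 <- list(a = rep(2, 4), b = rep(2, 4), c = rep(0, 4))
  r2 <- rank_by_mean_likelihood(data.frame(contig = c("a", "b", "c")),
                                tracks2)
  expect_equal(sort(r2$rank), c(1L, 1L, 3L))
  expect_equal(sum(r2$tied), 2L)
  # interval units use the track slice
  tr <- list(x = c(0, 0, 3, 3, 0, 0))
  r3 <- rank_by_mean_likelihood(
    data.frame(contig = "x", start = 2L, end = 4L, name = "rep1"), tr)
  expect_equal(r3$mean_likelihood, 3)
  expect_error(rank_by_mean_likelihood(
    data.frame(contig = "x", start = 2L, end = 2L, name = "zero"), tr),
    "zero-length")
})

test_that("temperature_sweep_report marks planted cells only", {
  set.seed(75)
  mk <- function(n, mu) data.frame(position = seq_len(n) - 1,
                                   melt = rbeta(n, mu * 50, (1 - mu) * 50),
                                   cruciform = rbeta(n, 1, 49),
                                   zdna = rbeta(n, 1, 49))
  # identical tables for all parties -> nothing significant
  base <- mk(400, 0.05)
  sets <- list("25" = list(centromere = base,
                           controls = replicate(10, base,
                                                simplify = FALSE)))
  rep0 <- temperature_sweep_report(sets)
  expect_true(all(rep0$verdict == "not_significant"))
  expect_true(all(rep0$p_value == 1))
  # strong melt elevation at one temperature is detected
  sets2 <- list(
    "25" = list(centromere = mk(400, 0.4),
                controls = replicate(10, mk(400, 0.05), simplify = FALSE)),
    "18" = list(centromere = mk(400, 0.05),
                controls = replicate(10, mk(400, 0.05), simplify = FALSE)))
  rep2 <- temperature_sweep_report(sets2)
  expect_equal(rep2$verdict[rep2$temperature == 25 &
                              rep2$structure == "melt"],
               "centromere_enriched")
  expect_warning(temperature_sweep_report(
    list("30" = list(centromere = NULL, controls = list()))), "missing")
})
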