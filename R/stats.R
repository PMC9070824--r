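#' Remove 1.5 x IQR outliers
#'
#' Drops values more than `k` interquartile ranges outside the first/third
#' quartile (quartiles by linear interpolation, `quantile type = 7`);
#' values exactly on a fence are retained.  Fewer than 4 values are
#' returned unchanged with a warning.
#'
#' @param values numeric vector.
#' @param k fence multiplier (default 1.5).
#' @param quartile_type passed to [stats::quantile()] (default 7, linear
#'   interpolation between order statistics).
#' @return the surviving values, in input order.
#' @export
iqr_trim <- function(values, k = 1.5, quartile_type = 7L) {
  if (length(values) < 4L) {
    warning("fewer than 4 values; returning unchanged")
    return(values)
  }
  q <- quantile(values, c(0.25, 0.75), type = quartile_type, names = FALSE)
  iqr <- q[2L] - q[1L]
  values[values >= q[1L] - k * iqr & values <= q[2L] + k * iqr]
}

new_enrichment_result <- function(metric, test, statistic, p_value,
                                  direction, alpha, centromere_value,
                                  control_values, degenerate = FALSE,
                                  n_trimmed = 0L) {
  structure(list(
    metric = metric, test = test, statistic = statistic,
    p_value = p_value, direction = direction, alpha = alpha,
    significant = !is.na(p_value) && p_value < alpha &&
      direction == "centromere_higher",
    centromere_value = centromere_value, control_values = control_values,
    degenerate = degenerate, n_trimmed = n_trimmed
  ), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "%s [%s]: statistic = %.4g, p = %.4g, direction = %s -> %s\n",
    x$metric %||% "metric", x$test, x$statistic, x$p_value, x$direction,
    if (x$significant) "ENRICHED in centromere" else "not significant"))
  invisible(x)
}

#' One-sample t-test of control values against a centromere value
#'
#' Tests the control sample against the centromere's single metric value as
#' the hypothesized mean (two-sided).  Controls are IQR-trimmed first by
#' default; the centromere value is never trimmed.  The enrichment verdict
#' requires p < alpha *and* the centromere value exceeding the control
#' mean.  Zero control variance yields an exact degenerate verdict (p = 0
#' when the value differs from the controls, p = 1 when equal).
#'
#' @param control_values numeric vector of per-control metric values.
#' @param centromere_value the centromere's metric value.
#' @param alpha significance level (default 0.05).
#' @param trim apply [iqr_trim()] to the controls first (default TRUE).
#' @param metric optional metric label carried into the result.
#' @return an `enrichment_result`.
#' @export
one_sample_t <- function(control_values, centromere_value, alpha = 0.05,
                         trim = TRUE, metric = NULL) {
  x <- if (trim) iqr_trim(control_values) else control_values
  n_trimmed <- length(control_values) - length(x)
  if (length(x) < 3L) stop_nonb("need >= 3 control values after trimming")
  m <- mean(x)
  s <- sd(x)
  direction <- if (centromere_value > m) "centromere_higher" else
    if (centromere_value < m) "controls_higher" else "none"
  if (s == 0) {
    p <- if (m == centromere_value) 1 else 0
    return(new_enrichment_result(metric, "one_sample_t", NA_real_, p,
                                 direction, alpha, centromere_value, x,
                                 degenerate = TRUE, n_trimmed = n_trimmed))
  }
  tstat <- (m - centromere_value) / (s / sqrt(length(x)))
  p <- 2 * pt(-abs(tstat), df = length(x) - 1L)
  new_enrichment_result(metric, "one_sample_t", tstat, p, direction,
                        alpha, centromere_value, x, n_trimmed = n_trimmed)
}

# Exact two-sample KS statistic D = sup |ECDF_a - ECDF_b|, evaluated at
# the pooled sorted jump points via cumulative counts (tie blocks are
# evaluated after the full block, where the ECDF difference is attained).
ks_statistic_fast <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  o <- order(pooled)
  grp <- c(rep(1 / na, na), rep(-1 / nb, nb))[o]
  cs <- cumsum(grp)
  x <- pooled[o]
  last <- c(x[-1L] != x[-length(x)], TRUE)   # evaluate after the full tie block
  max(abs(cs[last]))
}

# Asymptotic two-sided KS p-value (Kolmogorov distribution with the
# standard small-sample correction of the effective n).
ks_pvalue <- function(D, na, nb) {
  na <- as.numeric(na); nb <- as.numeric(nb)
  en <- sqrt(na * nb / (na + nb))
  lambda <- (en + 0.12 + 0.11 / en) * D
  # the alternating series degenerates as lambda -> 0, where Q -> 1
  if (lambda < 0.2) return(1)
  j <- 1:100
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
  min(1, max(0, p))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs; the p-value
#' is the asymptotic two-sided approximation.  Direction is taken from the
#' sample means.  Used for per-base likelihood and structure-probability
#' distributions.
#'
#' @param sample_a,sample_b non-empty numeric vectors (a = centromere,
#'   b = controls, for the enrichment verdict).
#' @param alpha significance level.
#' @param metric optional metric label.
#' @return an `enrichment_result` with `statistic` = D.
#' @export
ks_two_sample <- function(sample_a, sample_b, alpha = 0.05, metric = NULL) {
  if (length(sample_a) == 0L || length(sample_b) == 0L)
    stop_nonb("empty sample")
  D <- ks_statistic_fast(sample_a, sample_b)
  p <- ks_pvalue(D, length(sample_a), length(sample_b))
  ma <- mean(sample_a); mb <- mean(sample_b)
  direction <- if (ma > mb) "centromere_higher" else
    if (ma < mb) "controls_higher" else "none"
  new_enrichment_result(metric, "ks_two_sample", D, p, direction, alpha,
                        ma, sample_b)
}

#' Rank units by mean combined likelihood
#'
#' Ranks contigs (or annotated repeat intervals) by the average combined
#' asterisk likelihood, descending; ties share the minimum rank.
#'
#' @param units data frame with `contig` and optionally `start`, `end`,
#'   `name`; when `start`/`end` are absent each unit is a whole contig.
#' @param tracks named list of combined per-base likelihood tracks, one per
#'   contig.
#' @return data frame: name, contig, length, mean_likelihood, rank,
#'   percentile (rank / total), tied.
#' @export
rank_by_mean_likelihood <- function(units, tracks) {
  means <- vapply(seq_len(nrow(units)), function(i) {
    tr <- tracks[[units$contig[i]]]
    if (is.null(tr)) stop_nonb("no track for contig ", units$contig[i])
    iv <- if (!is.null(units$start)) c(units$start[i], units$end[i]) else
      NULL
    if (!is.null(iv) && iv[1L] >= iv[2L]) stop_nonb("zero-length unit")
    track_mean(tr, iv)
  }, 0)
  lens <- if (!is.null(units$start)) units$end - units$start else
    lengths(tracks)[units$contig]
  rk <- rank(-means, ties.method = "min")
  out <- data.frame(
    name = units$name %||% units$contig,
    contig = units$contig,
    length = as.integer(lens),
    mean_likelihood = means,
    rank = as.integer(rk),
    percentile = rk / nrow(units),
    tied = duplicated(rk) | duplicated(rk, fromLast = TRUE),
    stringsAsFactors = FALSE
  )
  out[order(out$rank), , drop = FALSE]
}

#' Temperature sweep enrichment report for structure-probability tables
#'
#' For each temperature and structure (melt, cruciform, zdna) compares the
#' centromere's per-base probabilities against the pooled control values
#' and reports means plus an enrichment verdict cell.
#'
#' @param sist_sets named list, one entry per temperature ("18", "22", ...),
#'   each a list with `centromere` (a SIST table data frame) and `controls`
#'   (a list of SIST table data frames).
#' @param test "ks" (two-sample KS on per-base values, the default) or "t"
#'   (one-sample t on per-control segment means).
#' @param alpha significance level.
#' @return data frame: temperature, structure, centromere_mean,
#'   control_mean, statistic, p_value, p_adj (Benjamini-Hochberg across the
#'   report, informational only), direction, verdict
#'   ("centromere_enriched", "controls_enriched", "not_significant").
#' @export
temperature_sweep_report <- function(sist_sets, test = c("ks", "t"),
                                     alpha = 0.05) {
  test <- match.arg(test)
  rows <- list()
  for (temp in names(sist_sets)) {
    set <- sist_sets[[temp]]
    if (is.null(set$centromere) || length(set$controls) == 0L) {
      warning("missing tables for temperature ", temp, "; row omitted")
      next
    }
    for (s in SIST_STRUCTURES) {
      cen <- set$centromere[[s]]
      ctl_each <- lapply(set$controls, `[[`, s)
      pooled <- unlist(ctl_each, use.names = FALSE)
      res <- if (test == "ks") ks_two_sample(cen, pooled, alpha = alpha)
      else one_sample_t(vapply(ctl_each, mean, 0), mean(cen),
                        alpha = alpha)
      verdict <- if (res$p_value < alpha) {
        if (res$direction == "centromere_higher") "centromere_enriched"
        else "controls_enriched"
      } else "not_significant"
      rows[[length(rows) + 1L]] <- data.frame(
        temperature = as.numeric(temp), structure = s,
        centromere_mean = mean(cen), control_mean = mean(pooled),
        statistic = res$statistic, p_value = res$p_value,
        direction = res$direction, verdict = verdict,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) out$p_adj <- p.adjust(out$p_value, method = "BH")
  out
}

#' Run the full enrichment comparison for one centromere
#'
#' Computes a metric on the centromere contig and on every control segment
#' and tests enrichment with the one-sample t-test (the convention for
#' scalar per-segment metrics such as dyad density and G4 density).
#'
#' @param assembly a [genome_assembly()].
#' @param centromere_id contig to test.
#' @param controls a `control_set` from [sample_controls()].
#' @param metric_fn function from DNA string to a single number.
#' @param metric label for the report.
#' @param alpha significance level.
#' @return an `enrichment_result`.
#' @export
enrichment_test <- function(assembly, centromere_id, controls, metric_fn,
                            metric = "metric", alpha = 0.05) {
  cen_value <- metric_fn(contig_seq(assembly, centromere_id))
  ctl_values <- control_metrics(controls, assembly, metric_fn)
  one_sample_t(ctl_values, cen_value, alpha = alpha, metric = metric)
}
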