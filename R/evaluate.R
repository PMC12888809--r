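#' Normalize an answer string for exact matching
#'
#' Trims whitespace, strips one layer of surrounding quote characters
#' (straight single/double quotes), and case-folds. Idempotent.
#'
#' @param text Character vector.
#' @return Normalized character vector.
#' @export
normalize_answer <- function(text) {
  out <- trimws(text)
  out <- sub("^[\"']+", "", out)
  out <- sub("[\"']+$", "", out)
  tolower(trimws(out))
}

#' Exact, case-insensitive answer match
#'
#' @param pred Predicted answer (may be `NA` for a parse failure, which
#'   scores incorrect).
#' @param gold Non-empty gold answer.
#' @return Logical.
#' @export
exact_match <- function(pred, gold) {
  stopifnot(all(nzchar(gold)))
  ifelse(is.na(pred), FALSE, normalize_answer(pred) == normalize_answer(gold))
}

#' Semantic concordance between an answer and the gold standard
#'
#' Cosine similarity of the scorer embeddings of prediction and gold. A
#' missing prediction (parse failure) scores 0.
#'
#' @param pred Predicted answer string or `NA`.
#' @param gold Non-empty gold answer string.
#' @param scorer Embedder function `text -> numeric vector`.
#' @return Similarity in `[-1, 1]`.
#' @export
semantic_similarity <- function(pred, gold, scorer) {
  stopifnot(is_scalar_chr(gold), nzchar(gold), is.function(scorer))
  if (is.na(pred) || !nzchar(pred)) return(0)
  cosine_similarity(scorer(pred), scorer(gold))
}

#' Count and fraction of scores at or above a threshold
#'
#' @param scores Numeric scores.
#' @param tau Threshold in `[0, 1]`; inclusive (`score >= tau` counts).
#' @return List with `count` and `fraction` (percentage, one decimal).
#' @export
threshold_accuracy <- function(scores, tau) {
  stopifnot(is.numeric(tau), length(tau) == 1L, tau >= 0, tau <= 1)
  if (length(scores) == 0L) stop_mechrag("no scores supplied")
  count <- sum(scores >= tau)
  list(count = count, fraction = round(count / length(scores) * 100, 1))
}

#' Paired 2x2 contingency counts
#'
#' @param baseline,treatment Logical vectors of per-item correctness,
#'   aligned by item.
#' @return Named list: `a` (both correct), `b` (baseline wrong, treatment
#'   right), `c` (baseline right, treatment wrong), `d` (both wrong).
#' @export
paired_contingency <- function(baseline, treatment) {
  if (length(baseline) != length(treatment)) {
    stop_mechrag("baseline and treatment must have equal length")
  }
  baseline <- as.logical(baseline); treatment <- as.logical(treatment)
  list(a = sum(baseline & treatment),
       b = sum(!baseline & treatment),
       c = sum(baseline & !treatment),
       d = sum(!baseline & !treatment))
}

#' McNemar test p-value from discordant counts
#'
#' `method = "exact"`: two-sided exact binomial on the discordant pairs,
#' `min(1, 2 P(X <= min(b, c)))` with `X ~ Binomial(b + c, 1/2)`.
#' `method = "chi2"`: `(b - c)^2 / (b + c)` referred to chi-square with 1 df
#' (no continuity correction). Both return 1 when `b + c = 0`.
#'
#' @param b,c Non-negative discordant counts.
#' @param method `"exact"` or `"chi2"`.
#' @return p-value.
#' @export
mcnemar_p <- function(b, c, method = c("exact", "chi2")) {
  method <- match.arg(method)
  if (b < 0 || c < 0) stop_mechrag("discordant counts must be non-negative")
  n_disc <- b + c
  if (n_disc == 0) return(1)
  if (method == "exact") {
    min(1, 2 * pbinom(min(b, c), n_disc, 0.5))
  } else {
    pchisq((b - c)^2 / n_disc, df = 1, lower.tail = FALSE)
  }
}

#' Net accuracy gain in percentage points
#'
#' `(b - c) / n * 100`, reported to one decimal: the absolute accuracy
#' improvement implied by the discordant counts.
#'
#' @param b,c Discordant counts (see [paired_contingency()]).
#' @param n Total number of paired items.
#' @return Percentage points (one decimal).
#' @export
net_gain <- function(b, c, n) {
  if (n <= 0) stop_mechrag("n must be positive")
  stopifnot(b + c <= n)
  round((b - c) / n * 100, 1)
}

#' Relative increase between two counts
#'
#' `(after - before) / before * 100`, rounded to the nearest integer for
#' reporting; the full-precision value is kept in the `"exact"` attribute.
#'
#' @param before Positive baseline count.
#' @param after Count under the comparison condition.
#' @return Rounded percent increase with attribute `exact`.
#' @export
relative_increase <- function(before, after) {
  if (before <= 0) stop_mechrag("before must be positive")
  exact <- (after - before) / before * 100
  structure(round(exact), exact = exact)
}

# Exact two-sided signed-rank p via generating-function convolution over
# doubled midranks (stays exact under ties), assuming every sign assignment
# of the nonzero differences is equally likely.
signed_rank_exact_p <- function(r2, w2_obs) {
  counts <- c(1, numeric(sum(r2)))  # counts[w + 1] over doubled-rank sums
  for (r in r2) {
    shifted <- c(numeric(r), counts[seq_len(length(counts) - r)])
    counts <- counts + shifted
  }
  total <- sum(counts)
  lower <- sum(counts[seq_len(w2_obs + 1)]) / total
  upper <- sum(counts[(w2_obs + 1):length(counts)]) / total
  min(1, 2 * min(lower, upper))
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped. For `n <= exact_limit` remaining
#' differences the two-sided p-value is exact (computed by convolution over
#' the signed-rank distribution, valid under ties); otherwise a normal
#' approximation with tie correction and continuity correction is used.
#' All-zero differences give p = 1.
#'
#' @param diffs Non-empty numeric vector of paired differences.
#' @param exact_limit Largest n for which the exact distribution is used.
#' @return Two-sided p-value.
#' @export
wilcoxon_signed_rank <- function(diffs, exact_limit = 25) {
  if (length(diffs) == 0L) stop_mechrag("diffs must be non-empty")
  d <- diffs[diffs != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  if (n <= exact_limit) {
    return(signed_rank_exact_p(as.integer(round(2 * r)),
                               as.integer(round(2 * w_plus))))
  }
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (abs(w_plus - mu) - 0.5) / sqrt(sigma2)
  min(1, 2 * pnorm(z, lower.tail = FALSE))
}

#' Cliff's delta effect size with confidence interval
#'
#' `delta = (#{x_i > y_j} - #{x_i < y_j}) / (|x| |y|)` over all pairs. The
#' confidence interval uses Cliff's consistent variance estimate with normal
#' quantiles, clipped to `[-1, 1]`.
#'
#' @param x,y Non-empty numeric score vectors (typically treatment and
#'   baseline similarity scores).
#' @param conf_level Confidence level (default 0.95).
#' @return List with `delta`, `ci_low`, `ci_high`.
#' @export
cliffs_delta <- function(x, y, conf_level = 0.95) {
  if (length(x) == 0L || length(y) == 0L) {
    stop_mechrag("x and y must be non-empty")
  }
  n1 <- length(x); n2 <- length(y)
  D <- sign(outer(x, y, "-"))
  delta <- mean(D)
  if (n1 > 1 && n2 > 1) {
    di <- rowMeans(D); dj <- colMeans(D)
    s2 <- (n2^2 * sum((di - delta)^2) + n1^2 * sum((dj - delta)^2) -
             sum((D - delta)^2)) / (n1 * n2 * (n1 - 1) * (n2 - 1))
    s2 <- max(s2, 0)
  } else {
    s2 <- 0
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  list(delta = delta,
       ci_low = max(-1, delta - z * sqrt(s2)),
       ci_high = min(1, delta + z * sqrt(s2)))
}

#' Mean paired difference with bootstrap confidence interval
#'
#' Percentile bootstrap of the mean under a fixed seed.
#'
#' @param diffs Non-empty numeric vector of paired differences.
#' @param level Confidence level.
#' @param reps Bootstrap replicates (>= 1000).
#' @param seed RNG seed for resampling.
#' @return List with `mean`, `ci_low`, `ci_high`.
#' @export
mean_diff_ci <- function(diffs, level = 0.95, reps = 10000, seed = 1) {
  if (length(diffs) == 0L) stop_mechrag("diffs must be non-empty")
  stopifnot(reps >= 1000)
  m <- mean(diffs)
  n <- length(diffs)
  boots <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * reps, replace = TRUE), nrow = reps)
    rowMeans(matrix(diffs[idx], nrow = reps))
  })
  qs <- unname(quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                        type = 7))
  list(mean = m, ci_low = qs[1], ci_high = qs[2])
}

#' Rank-ordered scores and histogram over [0, 1]
#'
#' @param scores Numeric scores in `[-1, 1]`; negative values are clamped
#'   into the first bin (their count is reported in a warning).
#' @param bin_width Bin width dividing 1 evenly (default 0.05). Bins are
#'   left-closed; the last bin is closed on both sides.
#' @return A `distribution_summary`: list with `sorted_scores`, `breaks`,
#'   `counts`, `n`.
#' @export
distribution_summary <- function(scores, bin_width = 0.05) {
  stopifnot(all(scores >= -1 & scores <= 1))
  nbins <- round(1 / bin_width)
  if (abs(nbins * bin_width - 1) > 1e-9) {
    stop_mechrag("bin_width must divide 1 evenly")
  }
  n_neg <- sum(scores < 0)
  if (n_neg > 0) {
    warn(sprintf("%d negative score(s) clamped into the first bin", n_neg))
  }
  clamped <- pmax(scores, 0)
  bin <- pmin(floor(clamped / bin_width) + 1, nbins)
  counts <- tabulate(bin, nbins)
  structure(list(sorted_scores = sort(scores),
                 breaks = seq(0, 1, by = bin_width),
                 counts = counts, n = length(scores)),
            class = "distribution_summary")
}

#' @export
print.distribution_summary <- function(x, ...) {
  cat(sprintf("<distribution_summary: n = %d, %d bins, median = %.3f>\n",
              x$n, length(x$counts), stats::median(x$sorted_scores)))
  invisible(x)
}

#' Score a run's answers against the benchmark gold standard
#'
#' @param answers Model-answer tibble from [run_benchmark()].
#' @param items Benchmark tibble from [build_benchmark()].
#' @param regime `"binary"` (exact match, gene-style) or `"score"` (semantic
#'   concordance, metabolite/drug-style).
#' @param scorer Embedder used for the score regime.
#' @return Tibble of item results: `item_id`, `mode`, and `correct` or
#'   `similarity`.
#' @export
score_answers <- function(answers, items, regime = c("binary", "score"),
                          scorer = NULL) {
  regime <- match.arg(regime)
  missing_items <- setdiff(answers$item_id, items$item_id)
  if (length(missing_items) > 0L) {
    stop_mechrag(sprintf("answers reference unknown item ids: %s",
                         paste(missing_items, collapse = ", ")))
  }
  gold <- items$gold_answer[match(answers$item_id, items$item_id)]
  out <- tibble(item_id = answers$item_id, mode = answers$mode)
  if (regime == "binary") {
    out$correct <- exact_match(answers$answer, gold)
  } else {
    if (is.null(scorer)) stop_mechrag("the score regime requires a scorer")
    out$similarity <- map_dbl(seq_along(gold), function(i) {
      semantic_similarity(answers$answer[i], gold[i], scorer)
    })
  }
  out
}

align_runs <- function(baseline, treatment) {
  only_b <- setdiff(baseline$item_id, treatment$item_id)
  only_t <- setdiff(treatment$item_id, baseline$item_id)
  if (length(only_b) > 0L || length(only_t) > 0L) {
    stop_mechrag(sprintf(
      "runs cover different items; only in baseline: [%s]; only in treatment: [%s]",
      paste(only_b, collapse = ", "), paste(only_t, collapse = ", ")))
  }
  treatment[match(baseline$item_id, treatment$item_id), , drop = FALSE]
}

#' Compare two paired runs
#'
#' Binary regime: paired contingency counts, exact and chi-square McNemar
#' p-values, accuracies, and net gain in percentage points. Score regime:
#' mean paired difference with bootstrap CI, Wilcoxon signed-rank p, Cliff's
#' delta with CI, a threshold-sensitivity table, and score distribution
#' summaries for both runs.
#'
#' @param baseline,treatment Item-result tibbles from [score_answers()]
#'   covering the same item ids.
#' @param regime `"binary"` or `"score"`.
#' @param thresholds Similarity cutoffs for the sensitivity table.
#' @param bin_width Histogram bin width.
#' @param conf_level Confidence level for intervals.
#' @param boot_reps,boot_seed Bootstrap settings for the mean-difference CI.
#' @return A `paired_binary_comparison` or `paired_score_comparison` object
#'   (see [tidy()]/[glance()] methods).
#' @export
compare_runs <- function(baseline, treatment,
                         regime = c("binary", "score"),
                         thresholds = c(0.85, 0.90, 0.95),
                         bin_width = 0.05, conf_level = 0.95,
                         boot_reps = 10000, boot_seed = 1) {
  regime <- match.arg(regime)
  treatment <- align_runs(baseline, treatment)
  n <- nrow(baseline)
  if (regime == "binary") {
    ct <- paired_contingency(baseline$correct, treatment$correct)
    out <- list(
      n = n, a = ct$a, b = ct$b, c = ct$c, d = ct$d,
      acc_baseline = mean(baseline$correct) * 100,
      acc_treatment = mean(treatment$correct) * 100,
      net_gain_points = net_gain(ct$b, ct$c, n),
      p_exact = mcnemar_p(ct$b, ct$c, "exact"),
      p_chi2 = mcnemar_p(ct$b, ct$c, "chi2"))
    return(structure(out, class = "paired_binary_comparison"))
  }
  diffs <- treatment$similarity - baseline$similarity
  mci <- mean_diff_ci(diffs, level = conf_level, reps = boot_reps,
                      seed = boot_seed)
  cd <- cliffs_delta(treatment$similarity, baseline$similarity, conf_level)
  thr <- bind_rows(lapply(thresholds, function(tau) {
    tb <- threshold_accuracy(baseline$similarity, tau)
    tt <- threshold_accuracy(treatment$similarity, tau)
    tibble(tau = tau, count_baseline = tb$count, count_treatment = tt$count,
           frac_baseline = tb$fraction, frac_treatment = tt$fraction)
  }))
  out <- list(
    n = n, mean_diff = mci$mean, ci_low = mci$ci_low, ci_high = mci$ci_high,
    wilcoxon_p = wilcoxon_signed_rank(diffs),
    cliffs_delta = cd$delta, delta_ci_low = cd$ci_low,
    delta_ci_high = cd$ci_high,
    threshold_table = thr,
    dist_baseline = distribution_summary(baseline$similarity, bin_width),
    dist_treatment = distribution_summary(treatment$similarity, bin_width))
  structure(out, class = "paired_score_comparison")
}

#' @export
print.paired_binary_comparison <- function(x, ...) {
  cat("Paired binary comparison (n =", x$n, ")\n")
  cat(sprintf("  contingency: a=%d b=%d c=%d d=%d\n", x$a, x$b, x$c, x$d))
  cat(sprintf("  accuracy: %.1f%% -> %.1f%% (net gain %.1f points)\n",
              x$acc_baseline, x$acc_treatment, x$net_gain_points))
  cat(sprintf("  McNemar: exact p = %.3g, chi-square p = %.3g\n",
              x$p_exact, x$p_chi2))
  invisible(x)
}

#' @export
print.paired_score_comparison <- function(x, ...) {
  cat("Paired score comparison (n =", x$n, ")\n")
  cat(sprintf("  mean diff = %.3f (%.0f%% CI %.3f to %.3f)\n",
              x$mean_diff, 95, x$ci_low, x$ci_high))
  cat(sprintf("  Wilcoxon p = %.3g; Cliff's delta = %.3f (%.3f to %.3f)\n",
              x$wilcoxon_p, x$cliffs_delta, x$delta_ci_low, x$delta_ci_high))
  print(x$threshold_table)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname compare_runs
#' @param x A comparison object.
#' @param ... Unused.
#' @export
tidy.paired_binary_comparison <- function(x, ...) {
  tibble(statistic = c("a", "b", "c", "d", "acc_baseline", "acc_treatment",
                       "net_gain_points", "p_exact", "p_chi2"),
         value = c(x$a, x$b, x$c, x$d, x$acc_baseline, x$acc_treatment,
                   x$net_gain_points, x$p_exact, x$p_chi2))
}

#' @rdname compare_runs
#' @export
glance.paired_binary_comparison <- function(x, ...) {
  tibble(n = x$n, a = x$a, b = x$b, c = x$c, d = x$d,
         acc_baseline = x$acc_baseline, acc_treatment = x$acc_treatment,
         net_gain_points = x$net_gain_points,
         p_exact = x$p_exact, p_chi2 = x$p_chi2)
}

#' @rdname compare_runs
#' @export
tidy.paired_score_comparison <- function(x, ...) {
  x$threshold_table
}

#' @rdname compare_runs
#' @export
glance.paired_score_comparison <- function(x, ...) {
  tibble(n = x$n, mean_diff = x$mean_diff, ci_low = x$ci_low,
         ci_high = x$ci_high, wilcoxon_p = x$wilcoxon_p,
         cliffs_delta = x$cliffs_delta, delta_ci_low = x$delta_ci_low,
         delta_ci_high = x$delta_ci_high)
}
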