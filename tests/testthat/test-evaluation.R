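test_that("answer normalization trims, unquotes, case-folds, and is idempotent", {
  expect_equal(normalize_answer(" TNF "), "tnf")
  expect_equal(normalize_answer("\"IL6\""), "il6")
  expect_equal(normalize_answer("'Aspirin' "), "aspirin")
  set.seed(51)
  strs <- c(random_strings(50), " \"Quoted thing\" ", "''", "  ")
  expect_equal(normalize_answer(normalize_answer(strs)),
               normalize_answer(strs))
})

test_that("exact match is case-insensitive and scores parse failures as wrong", {
  expect_true(exact_match("tnf", "TNF"))
  expect_false(exact_match("TNFA", "TNF"))
  expect_false(exact_match(NA_character_, "TNF"))
  expect_true(exact_match(" \"Tnf\" ", "TNF"))
})

test_that("semantic similarity equals the cosine of scorer embeddings", {
  emb <- hash_embedder(64, 7)
  expect_equal(semantic_similarity("lactate", "lactate", emb), 1)
  expect_equal(semantic_similarity(NA_character_, "lactate", emb), 0)
  for (pred in c("pyruvate", "lactic acid", "xyz")) {
    expect_equal(semantic_similarity(pred, "lactate", emb),
                 cosine_similarity(emb(pred), emb("lactate")))
  }
})

test_that("threshold counts match brute force and are monotone in the cutoff", {
  ta <- threshold_accuracy(c(0.95, 0.50, 0.91), 0.90)
  expect_equal(ta$count, 2L)
  expect_equal(ta$fraction, 66.7)
  expect_equal(threshold_accuracy(runif(10), 0)$fraction, 100)
  expect_error(threshold_accuracy(numeric(0), 0.5), "no scores")
  set.seed(61)
  for (rep_i in 1:10) {
    scores <- runif(sample(5:50, 1))
    prev <- length(scores)
    for (tau in seq(0, 1, by = 0.1)) {
      got <- threshold_accuracy(scores, tau)
      expect_equal(got$count, sum(vapply(scores, function(s) s >= tau,
                                         logical(1))))
      expect_lte(got$count, prev)
      prev <- got$count
    }
  }
})

test_that("paired contingency cells enumerate correctly and conserve n", {
  ct <- paired_contingency(c(TRUE, FALSE, TRUE, FALSE),
                           c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(ct, list(a = 1L, b = 1L, c = 1L, d = 1L))
  same <- paired_contingency(c(TRUE, FALSE), c(TRUE, FALSE))
  expect_equal(same$b + same$c, 0L)
  expect_error(paired_contingency(TRUE, c(TRUE, FALSE)), "equal length")
  set.seed(71)
  for (rep_i in 1:20) {
    n <- sample(1:100, 1)
    x <- runif(n) > 0.5; y <- runif(n) > 0.5
    ct <- paired_contingency(x, y)
    expect_equal(ct$a + ct$b + ct$c + ct$d, n)
  }
})

test_that("exact McNemar p equals the binomial-tail oracle for all small flip counts", {
  expect_equal(mcnemar_p(5, 5, "exact"), 1)
  expect_equal(mcnemar_p(0, 0, "exact"), 1)
  expect_equal(mcnemar_p(0, 0, "chi2"), 1)
  for (b in 0:20) for (c in 0:(20 - b)) {
    expect_equal(mcnemar_p(b, c, "exact"), mcnemar_enum_oracle(b, c),
                 info = sprintf("b=%d c=%d", b, c))
  }
  # chi-square agrees with the base-R statistic without continuity correction
  expect_equal(mcnemar_p(30, 12, "chi2"),
               mcnemar.test(matrix(c(5, 30, 12, 5), 2), correct = FALSE)$p.value)
  expect_error(mcnemar_p(-1, 2), "non-negative")
})

test_that("net gain and relative increase reproduce printed-precision arithmetic", {
  expect_equal(net_gain(245, 47, 798), 24.8)
  expect_equal(net_gain(119, 49, 798), 8.8)
  expect_equal(net_gain(0, 0, 100), 0)
  expect_error(net_gain(1, 1, 0), "positive")
  expect_equal(as.numeric(relative_increase(28, 51)), 82)
  expect_equal(as.numeric(relative_increase(30, 53)), 77)
  expect_equal(as.numeric(relative_increase(10, 10)), 0)
  expect_equal(attr(relative_increase(30, 53), "exact"), 230 / 3)
  expect_error(relative_increase(0, 5), "positive")
})

test_that("Wilcoxon signed-rank matches exhaustive sign-flip enumeration", {
  expect_equal(wilcoxon_signed_rank(rep(0, 5)), 1)
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3)), 0.25)
  expect_error(wilcoxon_signed_rank(numeric(0)), "non-empty")
  set.seed(81)
  for (rep_i in 1:30) {
    n <- sample(1:10, 1)
    d <- round(rnorm(n), 1)  # rounding induces occasional ties and zeros
    expect_equal(wilcoxon_signed_rank(d), wilcoxon_enum_oracle(d),
                 info = paste(d, collapse = ","))
  }
  # untied exact case agrees with the reference distribution
  d <- c(0.3, -1.1, 2.2, 0.7, -0.2, 1.4, 0.9)
  expect_equal(wilcoxon_signed_rank(d),
               wilcox.test(d, exact = TRUE)$p.value)
  # large-n path: consistent with the normal-approximation reference
  set.seed(82)
  big <- rnorm(60) + 0.3
  expect_equal(wilcoxon_signed_rank(big),
               wilcox.test(big, correct = TRUE)$p.value,
               tolerance = 1e-8)
})

test_that("Cliff's delta matches brute-force pair counting with a sane CI", {
  x <- c(3, 4, 5); y <- c(0, 1, 2)
  res <- cliffs_delta(x, y)
  expect_equal(res$delta, 1)
  res0 <- cliffs_delta(c(1, 2, 3), c(3, 1, 2))
  expect_equal(res0$delta, 0)
  set.seed(91)
  for (rep_i in 1:10) {
    n <- sample(2:200, 1); m <- sample(2:200, 1)
    x <- round(runif(n), 2); y <- round(runif(m), 2)
    res <- cliffs_delta(x, y)
    expect_equal(res$delta, cliffs_enum_oracle(x, y))
    expect_true(res$ci_low <= res$delta && res$delta <= res$ci_high)
    expect_gte(res$ci_low, -1)
    expect_lte(res$ci_high, 1)
  }
  expect_error(cliffs_delta(numeric(0), 1), "non-empty")
})

test_that("bootstrap mean-difference CI collapses on constants and is seeded", {
  const <- mean_diff_ci(rep(0.25, 12), reps = 1000, seed = 4)
  expect_equal(const, list(mean = 0.25, ci_low = 0.25, ci_high = 0.25))
  set.seed(101)
  d <- rnorm(40, 0.1)
  r1 <- mean_diff_ci(d, reps = 2000, seed = 9)
  r2 <- mean_diff_ci(d, reps = 2000, seed = 9)
  expect_identical(r1, r2)
  expect_equal(r1$mean, mean(d))
  expect_true(r1$ci_low <= r1$mean && r1$mean <= r1$ci_high)
})

test_that("distribution summaries bin correctly and conserve counts", {
  ds <- distribution_summary(c(0.92, 0.93, 0.10), bin_width = 0.05)
  expect_equal(ds$counts[which(ds$breaks == 0.90)], 2L)
  expect_equal(ds$counts[which(ds$breaks == 0.10)], 1L)
  expect_equal(sum(ds$counts), 3L)
  expect_equal(ds$sorted_scores, c(0.10, 0.92, 0.93))
  # score of exactly 1 lands in the last (right-closed) bin
  ds1 <- distribution_summary(c(1, 0.999))
  expect_equal(ds1$counts[20], 2L)
  # negatives clamp into the first bin with a warning
  expect_warning(dsn <- distribution_summary(c(-0.2, 0.5)), "clamped")
  expect_equal(dsn$counts[1], 1L)
  set.seed(111)
  for (rep_i in 1:10) {
    s <- runif(sample(1:200, 1))
    ds <- distribution_summary(s)
    expect_equal(sum(ds$counts), length(s))
    expect_equal(sort(s), ds$sorted_scores)
  }
  expect_error(distribution_summary(0.5, bin_width = 0.03), "evenly")
})

test_that("binary run comparison assembles contingency, accuracies, and McNemar", {
  base <- tibble::tibble(item_id = sprintf("i%03d", 1:100), mode = "llm_only",
                         correct = rep(c(TRUE, FALSE), c(40, 60)))
  treat <- base
  treat$mode <- "rag"
  treat$correct <- rep(c(TRUE, FALSE, TRUE, FALSE), c(35, 5, 30, 30))
  cmp <- compare_runs(base, treat, "binary")
  ct <- paired_contingency(base$correct, treat$correct)
  expect_equal(cmp$a, ct$a); expect_equal(cmp$b, ct$b)
  expect_equal(cmp$c, ct$c); expect_equal(cmp$d, ct$d)
  expect_equal(cmp$net_gain_points,
               round(cmp$acc_treatment - cmp$acc_baseline, 1))
  expect_equal(cmp$p_exact, mcnemar_p(cmp$b, cmp$c, "exact"))
  # identical runs: no discordance, p = 1, zero gain
  same <- compare_runs(base, base, "binary")
  expect_equal(same$b + same$c, 0L)
  expect_equal(same$p_exact, 1)
  expect_equal(same$net_gain_points, 0)
  # mismatched item sets are rejected with the symmetric difference
  expect_error(compare_runs(base[-1, ], treat, "binary"), "i001")
  g <- glance(cmp)
  expect_equal(g$net_gain_points, cmp$net_gain_points)
  expect_equal(nrow(tidy(cmp)), 9L)
})

test_that("score run comparison recovers a constant planted shift exactly", {
  n <- 60
  base <- tibble::tibble(item_id = sprintf("i%03d", 1:n), mode = "llm_only",
                         similarity = round(seq(0.05, 0.85, length.out = n), 4))
  treat <- base
  treat$mode <- "rag"
  treat$similarity <- base$similarity + 0.1
  cmp <- compare_runs(base, treat, "score", boot_reps = 1000)
  expect_equal(cmp$mean_diff, 0.1)
  expect_equal(cmp$ci_low, 0.1)
  expect_equal(cmp$ci_high, 0.1)
  expect_equal(cmp$cliffs_delta,
               cliffs_enum_oracle(treat$similarity, base$similarity))
  # a uniform positive shift is the most extreme signed-rank outcome for n
  expect_equal(cmp$wilcoxon_p,
               wilcoxon_signed_rank(rep(0.1, n)))
  expect_equal(cmp$threshold_table$tau, c(0.85, 0.90, 0.95))
  expect_equal(cmp$threshold_table$count_baseline,
               vapply(c(0.85, 0.90, 0.95), function(tau)
                 sum(base$similarity >= tau), numeric(1)))
  expect_equal(sum(cmp$dist_treatment$counts), n)
  gl <- glance(cmp)
  expect_equal(gl$mean_diff, 0.1)
  expect_equal(tidy(cmp), cmp$threshold_table)
})
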