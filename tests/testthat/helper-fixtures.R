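# Shared builders for the test suite. Everything is generated in code; no
# fixture files.

# A synthetic benchmark tibble without going through path filtering; used
# where a test only needs items with ids, questions, and gold answers.
make_items <- function(n, kind = "gene") {
  drug <- sprintf("Drugatol-%d", seq_len(n))
  disease <- sprintf("Malady-%d", seq_len(n))
  gold <- switch(kind,
    gene = sprintf("SYG%d", seq_len(n)),
    metabolite = sprintf("metabolyn-%d", seq_len(n)),
    drug = drug)
  process <- if (kind == "drug") sprintf("process-%d regulation", seq_len(n))
             else rep(NA_character_, n)
  question <- switch(kind,
    gene = render_question("gene", drug, disease),
    metabolite = render_question("metabolite", drug, disease),
    drug = render_question("drug", disease_name = disease,
                           process_name = process))
  tibble::tibble(
    item_id = sprintf("%s-%04d", kind, seq_len(n)),
    benchmark = kind, question = question,
    drug_curie = sprintf("MESH:D%04d", seq_len(n)), drug_name = drug,
    disease_curie = sprintf("MESH:E%04d", seq_len(n)),
    disease_name = disease,
    process_curie = if (kind == "drug") sprintf("GO:%07d", seq_len(n))
                    else rep(NA_character_, n),
    process_name = process,
    gold_answer = gold,
    gold_curie = sprintf("X:%04d", seq_len(n)),
    source_path_ids = as.list(sprintf("path-%04d", seq_len(n))))
}

# A small scored-statement tibble with given scores.
make_scored <- function(scores) {
  tibble::tibble(
    subject_name = sprintf("s%d", seq_along(scores)),
    predicate_text = "affects",
    object_name = sprintf("o%d", seq_along(scores)),
    source = "ctd",
    sentence = sprintf("s%d affects o%d", seq_along(scores),
                       seq_along(scores)),
    score = scores, retained = TRUE)
}

random_strings <- function(n, len = 12) {
  pool <- c(letters, LETTERS, 0:9, " ")
  vapply(seq_len(n), function(i) {
    paste(sample(pool, len, replace = TRUE), collapse = "")
  }, character(1))
}

# Independent oracle: two-sided exact signed-rank p by exhaustive sign-flip
# enumeration (feasible for n <= 12).
wilcoxon_enum_oracle <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  lower <- mean(w_all <= w_obs + 1e-9)
  upper <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(lower, upper))
}

# Independent oracle: exact two-sided McNemar p by direct binomial-tail
# summation over the discordant count.
mcnemar_enum_oracle <- function(b, c) {
  n <- b + c
  if (n == 0) return(1)
  k <- min(b, c)
  tail_p <- sum(choose(n, 0:k)) / 2^n
  min(1, 2 * tail_p)
}

# Independent oracle: Cliff's delta by explicit O(nm) pair counting.
cliffs_enum_oracle <- function(x, y) {
  gt <- 0; lt <- 0
  for (xi in x) for (yj in y) {
    if (xi > yj) gt <- gt + 1
    if (xi < yj) lt <- lt + 1
  }
  (gt - lt) / (length(x) * length(y))
}
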