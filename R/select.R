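#' Cosine similarity between two vectors
#'
#' `dot(u, v) / (||u|| ||v||)`, clipped to `[-1, 1]` against floating-point
#' rounding.
#'
#' @param u,v Numeric vectors of equal length; neither all-zero.
#' @return Similarity in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  stopifnot(is.numeric(u), is.numeric(v), length(u) == length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop_mechrag("cosine similarity is undefined for a zero vector")
  }
  min(1, max(-1, sum(u * v) / (nu * nv)))
}

#' Score context statements against a question
#'
#' Embeds the question and each statement sentence with `embedder` and
#' attaches the cosine similarity of each statement to the question. All
#' statements start retained; input order is preserved.
#'
#' @param question Question text.
#' @param statements Statement tibble from [verbalize_graph()].
#' @param embedder Function `text -> numeric vector` (e.g.
#'   [hash_embedder()]).
#' @return The statement tibble with `score` and `retained` columns.
#' @export
score_statements <- function(question, statements, embedder) {
  stopifnot(is.function(embedder))
  if (nrow(statements) == 0L) {
    return(mutate(statements, score = numeric(0), retained = logical(0)))
  }
  q <- embedder(question)
  score <- vapply(statements$sentence,
                  function(s) cosine_similarity(q, embedder(s)),
                  numeric(1), USE.NAMES = FALSE)
  mutate(statements, score = score, retained = TRUE)
}

# Rank statements best-first: higher score first; ties broken by original
# order (the earlier statement outranks the later one).
rank_best_first <- function(score) {
  order(-score, seq_along(score))
}

#' Prune scored statements by similarity percentile
#'
#' Rank-based percentile pruning. With `n` statements and percentile `p`:
#' `mode = "drop_bottom"` marks the `floor(p * n / 100)` lowest-scoring
#' statements not retained; `mode = "keep_top"` retains only statements
#' ranked strictly above the `p`-th percentile position, i.e.
#' `n - ceiling(p * n / 100)` statements; `mode = "full"` retains everything.
#' Ties are broken by original order and the relative order of retained
#' statements is preserved.
#'
#' @param scored Tibble from [score_statements()].
#' @param mode One of `"full"`, `"drop_bottom"`, `"keep_top"`.
#' @param percentile Percentile in `[0, 100]`; required unless
#'   `mode = "full"`.
#' @return `scored` with the `retained` flag updated.
#' @export
prune <- function(scored, mode = c("full", "drop_bottom", "keep_top"),
                  percentile = NULL) {
  mode <- match.arg(mode)
  n <- nrow(scored)
  if (mode == "full") {
    scored$retained <- rep(TRUE, n)
    return(scored)
  }
  if (is.null(percentile) || !is.numeric(percentile) ||
      percentile < 0 || percentile > 100) {
    stop_mechrag("percentile must be a number in [0, 100]")
  }
  if (n == 0L) return(scored)
  n_drop <- switch(mode,
    drop_bottom = floor(percentile * n / 100),
    keep_top = ceiling(percentile * n / 100))
  ranked <- rank_best_first(scored$score)
  drop_idx <- if (n_drop > 0) tail(ranked, n_drop) else integer(0)
  scored$retained <- !(seq_len(n) %in% drop_idx)
  scored
}

#' Truncate retained statements to a token budget
#'
#' Drops statements from the lowest-score end of the retained set until the
#' total estimated token count (`ceiling(characters / 4)` per sentence) fits
#' within the budget. Statements already pruned are untouched.
#'
#' @param scored Tibble from [prune()] (or [score_statements()]).
#' @param token_budget Positive integer budget.
#' @return `scored` with `retained` updated; possibly nothing retained.
#' @export
truncate_to_budget <- function(scored, token_budget) {
  stopifnot(is.numeric(token_budget), length(token_budget) == 1L,
            token_budget > 0)
  idx <- which(scored$retained)
  if (length(idx) == 0L) return(scored)
  worst_last <- idx[rank_best_first(scored$score[idx])]
  tokens_ranked <- estimate_tokens(scored$sentence[worst_last])
  total <- sum(tokens_ranked)
  k <- length(worst_last)
  while (k > 0L && total > token_budget) {
    total <- total - tokens_ranked[k]
    scored$retained[worst_last[k]] <- FALSE
    k <- k - 1L
  }
  scored
}

#' Score, prune, and budget context statements for one question
#'
#' Convenience composition of [score_statements()], [prune()], and
#' [truncate_to_budget()].
#'
#' @inheritParams score_statements
#' @inheritParams prune
#' @param token_budget Optional token budget; `NULL` disables budgeting.
#' @return Scored statement tibble with final `retained` flags.
#' @export
select_context <- function(question, statements, embedder,
                           mode = "full", percentile = NULL,
                           token_budget = NULL) {
  scored <- score_statements(question, statements, embedder)
  scored <- prune(scored, mode, percentile)
  if (!is.null(token_budget)) {
    scored <- truncate_to_budget(scored, token_budget)
  }
  scored
}
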