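#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Rank-ordered similarity curves for paired runs
#'
#' Plots each run's similarity scores ordered from lowest to highest, one
#' trace per run, so the separation between a baseline and a
#' retrieval-augmented run is visible across the whole score distribution.
#'
#' @param runs Named list of item-result tibbles (each with a `similarity`
#'   column), e.g. `list("llm_only" = res_base, "rag" = res_rag)`.
#' @return A ggplot object.
#' @export
plot_rank_similarity <- function(runs) {
  stopifnot(is.list(runs), length(runs) > 0L, !is.null(names(runs)))
  df <- bind_rows(lapply(names(runs), function(nm) {
    s <- sort(runs[[nm]]$similarity)
    tibble(run = nm, rank = seq_along(s), similarity = s)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$similarity,
                                   colour = .data$run)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "questions ranked by similarity",
                  y = "cosine similarity to gold answer",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn distribution_summary Histogram of the binned similarity
#'   scores over `[0, 1]`.
#' @param object A `distribution_summary`.
#' @param ... Unused.
#' @export
autoplot.distribution_summary <- function(object, ...) {
  mids <- head(object$breaks, -1) + diff(object$breaks) / 2
  df <- tibble(mid = mids, count = object$counts)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = diff(object$breaks)[1] * 0.92) +
    ggplot2::labs(x = "cosine similarity", y = "questions") +
    ggplot2::theme_minimal()
}

#' @describeIn compare_runs Side-by-side score histograms of the two runs
#'   (score regime).
#' @param object A `paired_score_comparison`.
#' @export
autoplot.paired_score_comparison <- function(object, ...) {
  mk <- function(ds, nm) {
    mids <- head(ds$breaks, -1) + diff(ds$breaks) / 2
    tibble(run = nm, mid = mids, count = ds$counts)
  }
  df <- bind_rows(mk(object$dist_baseline, "baseline"),
                  mk(object$dist_treatment, "treatment"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = 0.046) +
    ggplot2::facet_wrap(~run, ncol = 1) +
    ggplot2::labs(x = "cosine similarity", y = "questions") +
    ggplot2::theme_minimal()
}
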