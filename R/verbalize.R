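#' Humanize a biolink predicate
#'
#' Strips the `biolink:` prefix, replaces underscores with spaces, and
#' lowercases. Idempotent.
#'
#' @param predicate Biolink predicate string(s).
#' @return Human-readable relation text.
#' @export
humanize_predicate <- function(predicate) {
  stopifnot(is.character(predicate), all(nzchar(predicate)))
  out <- sub("^biolink:", "", predicate)
  out <- gsub("_", " ", out, fixed = TRUE)
  tolower(out)
}

render_statement <- function(subject_name, predicate_text, object_name,
                             source) {
  base <- paste(subject_name, predicate_text, object_name)
  ifelse(nzchar(source), paste0(base, " (source: ", source, ")"), base)
}

#' Verbalize one knowledge-graph edge
#'
#' Renders an edge as a declarative sentence
#' `"<subject> <predicate> <object> (source: <primary source>)"`; the source
#' parenthetical is omitted when the edge carries no primary source. Node
#' display names fall back to the CURIE when the name is absent.
#'
#' @param edge One edge (list or single-row tibble with `subject`,
#'   `predicate`, `object`, `primary_source`).
#' @param nodes Node tibble of the owning graph.
#' @return Single-row tibble: `subject_name`, `predicate_text`,
#'   `object_name`, `source`, `sentence`.
#' @export
verbalize_edge <- function(edge, nodes) {
  if (is.data.frame(edge)) {
    stopifnot(nrow(edge) == 1L)
    edge <- as.list(edge)
  }
  name_of <- function(curie) {
    i <- match(curie, nodes$curie)
    if (is.na(i)) {
      stop_mechrag(sprintf("edge endpoint '%s' not present in nodes", curie))
    }
    if (nzchar(nodes$name[i])) nodes$name[i] else curie
  }
  subject_name <- name_of(edge$subject)
  object_name <- name_of(edge$object)
  predicate_text <- humanize_predicate(edge$predicate)
  source <- as.character(edge$primary_source %||% "")
  tibble(subject_name = subject_name, predicate_text = predicate_text,
         object_name = object_name, source = source,
         sentence = render_statement(subject_name, predicate_text,
                                     object_name, source))
}

#' Verbalize a retrieved graph into context statements
#'
#' One declarative sentence per edge, in edge input order; sentences that
#' render identically are collapsed to their first occurrence.
#'
#' @param graph A `retrieved_graph`.
#' @return Tibble of context statements (`subject_name`, `predicate_text`,
#'   `object_name`, `source`, `sentence`).
#' @export
verbalize_graph <- function(graph) {
  stopifnot(inherits(graph, "retrieved_graph"))
  if (nrow(graph$edges) == 0L) {
    return(tibble(subject_name = character(), predicate_text = character(),
                  object_name = character(), source = character(),
                  sentence = character()))
  }
  name_map <- ifelse(nzchar(graph$nodes$name), graph$nodes$name,
                     graph$nodes$curie)
  names(name_map) <- graph$nodes$curie
  out <- tibble(
    subject_name = unname(name_map[graph$edges$subject]),
    predicate_text = humanize_predicate(graph$edges$predicate),
    object_name = unname(name_map[graph$edges$object]),
    source = graph$edges$primary_source)
  out$sentence <- render_statement(out$subject_name, out$predicate_text,
                                   out$object_name, out$source)
  out[!duplicated(out$sentence), , drop = FALSE]
}
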