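#' Specify a one-hop TRAPI query
#'
#' @param input_curie Pinned input entity CURIE.
#' @param input_category Biolink category of the input node (with the
#'   `biolink:` prefix).
#' @param output_category Biolink category requested for the free node.
#' @param predicate Optional biolink predicate constraint; by default all
#'   predicates are retrieved.
#' @return A `trapi_query_spec` list.
#' @export
trapi_query_spec <- function(input_curie, input_category, output_category,
                             predicate = NULL) {
  if (!is_scalar_chr(input_curie) || !nzchar(input_curie)) {
    stop_mechrag("input_curie must be a non-empty string")
  }
  if (!is_scalar_chr(output_category) || !nzchar(output_category)) {
    stop_mechrag("output_category must be a non-empty string")
  }
  structure(list(input_curie = input_curie,
                 input_category = input_category,
                 output_category = output_category,
                 predicate = predicate),
            class = "trapi_query_spec")
}

#' Build a TRAPI request document from a query spec
#'
#' Produces a one-hop query graph with a pinned node `n0` (ids =
#' input CURIE, categories = input category), a free node `n1` (categories =
#' output category), and a connecting edge `e0`. The document is a plain R
#' list; [canonical_json()] of equal specs is byte-identical.
#'
#' @param spec A [trapi_query_spec()].
#' @return A TRAPI request document (list with `message$query_graph`).
#' @export
build_trapi_query <- function(spec) {
  stopifnot(inherits(spec, "trapi_query_spec"))
  edge <- list(subject = "n0", object = "n1")
  if (!is.null(spec$predicate)) edge$predicates <- list(spec$predicate)
  list(message = list(query_graph = list(
    nodes = list(
      n0 = list(ids = list(spec$input_curie),
                categories = list(spec$input_category)),
      n1 = list(categories = list(spec$output_category))),
    edges = list(e0 = edge))))
}

#' Content-hash cache key for a TRAPI request
#'
#' SHA-256 hex digest of the canonical (sorted-key) JSON serialization of the
#' request, so equal specs share a key and distinct specs collide only with
#' negligible probability.
#'
#' @param request A TRAPI request document (list).
#' @return 64-character hex digest.
#' @export
cache_key <- function(request) {
  sha256_hex(canonical_json(request))
}

#' Parse a TRAPI response into a retrieved graph
#'
#' Extracts `message$knowledge_graph` nodes (name, categories) and edges
#' (subject, predicate, object, primary knowledge source). Exact-duplicate
#' edges are collapsed; edges referencing nodes absent from the node map are
#' dropped with a warning reporting the count. A response without a
#' `knowledge_graph` section yields an empty graph.
#'
#' @param document A TRAPI response document (list, or JSON string).
#' @return A `retrieved_graph`: list with tibbles `nodes` (`curie`, `name`,
#'   list-column `categories`) and `edges` (`subject`, `predicate`, `object`,
#'   `primary_source`).
#' @export
parse_trapi_response <- function(document) {
  if (is.character(document)) {
    document <- jsonlite::fromJSON(document, simplifyVector = FALSE)
  }
  kg <- document$message$knowledge_graph
  if (is.null(kg) || length(kg$nodes %||% list()) == 0L) {
    return(retrieved_graph())
  }
  nodes <- tibble(
    curie = names(kg$nodes),
    name = map_chr(kg$nodes, function(n) as.character(n$name %||% "")),
    categories = map(kg$nodes, function(n)
      as.character(unlist(n$categories %||% character(0)))))
  edges_raw <- kg$edges %||% list()
  edges <- tibble(
    subject = unname(map_chr(edges_raw, function(e)
      as.character(e$subject %||% ""))),
    predicate = unname(map_chr(edges_raw, function(e)
      as.character(e$predicate %||% ""))),
    object = unname(map_chr(edges_raw, function(e)
      as.character(e$object %||% ""))),
    primary_source = unname(map_chr(edges_raw, primary_source_of)))
  ok <- edges$subject %in% nodes$curie & edges$object %in% nodes$curie
  if (any(!ok)) {
    warn(sprintf("dropped %d edge(s) referencing nodes absent from the node map",
                 sum(!ok)))
    edges <- edges[ok, , drop = FALSE]
  }
  edges <- distinct(edges)
  retrieved_graph(nodes, edges)
}

primary_source_of <- function(edge) {
  srcs <- edge$sources %||% list()
  for (s in srcs) {
    if (identical(s$resource_role, "primary_knowledge_source")) {
      return(as.character(s$resource_id %||% ""))
    }
  }
  as.character(edge$primary_source %||% "")
}

#' Construct a retrieved knowledge graph
#'
#' @param nodes Tibble with `curie`, `name`, list-column `categories`.
#' @param edges Tibble with `subject`, `predicate`, `object`,
#'   `primary_source`.
#' @return A `retrieved_graph` object.
#' @export
retrieved_graph <- function(nodes = NULL, edges = NULL) {
  if (is.null(nodes)) {
    nodes <- tibble(curie = character(), name = character(),
                    categories = list())
  }
  if (is.null(edges)) {
    edges <- tibble(subject = character(), predicate = character(),
                    object = character(), primary_source = character())
  }
  bad <- setdiff(c(edges$subject, edges$object), nodes$curie)
  if (length(bad) > 0L) {
    stop_mechrag(sprintf("edge endpoint(s) missing from node map: %s",
                         paste(bad, collapse = ", ")))
  }
  structure(list(nodes = nodes, edges = distinct(edges)),
            class = "retrieved_graph")
}

#' @export
print.retrieved_graph <- function(x, ...) {
  cat(sprintf("<retrieved_graph: %d nodes, %d edges>\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Union of retrieved graphs
#'
#' @param ... `retrieved_graph` objects.
#' @return A `retrieved_graph` whose node set and edge set are the unions of
#'   the inputs (first-seen node names win; duplicate edges collapsed).
#' @export
union_graphs <- function(...) {
  graphs <- list(...)
  if (length(graphs) == 1L && is.list(graphs[[1]]) &&
      !inherits(graphs[[1]], "retrieved_graph")) {
    graphs <- graphs[[1]]
  }
  nodes <- bind_rows(lapply(graphs, function(g) g$nodes))
  nodes <- nodes[!duplicated(nodes$curie), , drop = FALSE]
  edges <- distinct(bind_rows(lapply(graphs, function(g) g$edges)))
  retrieved_graph(nodes, edges)
}

default_query_plan <- function() {
  list(
    gene = list(
      list(entity = "drug", input_category = "biolink:Drug",
           output_categories = c("biolink:Gene", "biolink:Protein")),
      list(entity = "disease", input_category = "biolink:Disease",
           output_categories = c("biolink:Gene", "biolink:Protein"))),
    metabolite = list(
      list(entity = "drug", input_category = "biolink:Drug",
           output_categories = "biolink:ChemicalEntity"),
      list(entity = "disease", input_category = "biolink:Disease",
           output_categories = "biolink:ChemicalEntity")),
    drug = list(
      list(entity = "disease", input_category = "biolink:Disease",
           output_categories = "biolink:ChemicalEntity"),
      list(entity = "process", input_category = "biolink:BiologicalProcess",
           output_categories = "biolink:ChemicalEntity")))
}

item_query_specs <- function(item, query_plan = default_query_plan()) {
  plan <- query_plan[[item$benchmark]]
  if (is.null(plan)) {
    stop_mechrag(sprintf("no query plan for benchmark '%s'", item$benchmark))
  }
  specs <- list()
  for (leg in plan) {
    curie <- item[[paste0(leg$entity, "_curie")]]
    if (is.null(curie) || is.na(curie) || !nzchar(curie)) {
      stop_mechrag(sprintf("item '%s' is missing its %s entity",
                           item$item_id, leg$entity))
    }
    for (outcat in leg$output_categories) {
      specs[[length(specs) + 1L]] <-
        trapi_query_spec(curie, leg$input_category, outcat)
    }
  }
  specs
}

cache_path_for <- function(cache_dir, key) {
  file.path(cache_dir, substr(key, 1, 2), paste0(key, ".json"))
}

resolve_request <- function(request, transport, cache_dir, offline) {
  if (!is.null(cache_dir)) {
    path <- cache_path_for(cache_dir, cache_key(request))
    if (file.exists(path)) {
      return(jsonlite::fromJSON(path, simplifyVector = FALSE))
    }
    if (offline) {
      stop_mechrag(sprintf(
        "offline mode: no cached response for request %s",
        cache_key(request)))
    }
  }
  if (is.null(transport)) {
    stop_mechrag("no transport available and request not cached")
  }
  response <- transport(request)
  if (!is.null(cache_dir)) {
    # store the response verbatim (original key order), keyed by the
    # canonical digest of the request
    path <- cache_path_for(cache_dir, cache_key(request))
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    writeLines(as.character(jsonlite::toJSON(response, auto_unbox = TRUE,
                                             null = "null", digits = NA)),
               path, useBytes = TRUE)
  }
  response
}

#' Retrieve the knowledge-graph neighborhood for a benchmark item
#'
#' Issues the benchmark-specific one-hop query set (gene: drug and disease
#' each to Gene and Protein; metabolite: drug and disease to ChemicalEntity;
#' drug: disease and biological process to ChemicalEntity) through the
#' transport, resolving each request through the cache first, and returns the
#' union graph.
#'
#' @param item One benchmark item (single-row tibble or list).
#' @param transport Function `request -> response` (e.g.
#'   [mock_trapi_transport()]), or `NULL` for cache-only operation.
#' @param cache_dir Optional cache directory (one JSON file per request,
#'   keyed by content digest under `<cache>/<first2>/<digest>.json`).
#' @param offline If `TRUE`, a cache miss is an error and the transport is
#'   never invoked.
#' @param query_plan Query plan; see `default_query_plan` in the source for
#'   the per-benchmark defaults.
#' @return A `retrieved_graph`.
#' @export
retrieve_for_item <- function(item, transport = NULL, cache_dir = NULL,
                              offline = FALSE,
                              query_plan = default_query_plan()) {
  if (is.data.frame(item)) {
    stopifnot(nrow(item) == 1L)
    item <- as.list(item)
  }
  specs <- item_query_specs(item, query_plan)
  graphs <- lapply(specs, function(spec) {
    request <- build_trapi_query(spec)
    response <- tryCatch(
      resolve_request(request, transport, cache_dir, offline),
      error = function(e) {
        stop_mechrag(sprintf(
          "retrieval failed for %s -> %s: %s",
          spec$input_curie, spec$output_category, conditionMessage(e)))
      })
    parse_trapi_response(response)
  })
  union_graphs(graphs)
}
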