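#' Parse drug-mechanism path records
#'
#' Reads a collection of curated mechanism-of-action path records (the
#' DrugMechDB convention: each record holds a graph id, a `nodes` list with
#' `id`/`label`/`name`, and a directed `links` list with
#' `source`/`target`/`key`) into a tibble of mechanistic paths. Each path runs
#' from a drug node through intermediate biological entities to a disease
#' node; the first node of a record is taken as the drug and the last as the
#' disease.
#'
#' @param input Path to a YAML or JSON file, a single string of YAML/JSON
#'   text, or an already-deserialized list of records.
#' @param on_error `"fail"` (default) aborts on the first malformed record;
#'   `"skip"` drops malformed records with a warning naming their path ids.
#' @return A tibble with one row per path: `path_id`, `drug_curie`,
#'   `drug_name`, `disease_curie`, `disease_name`, and list-columns `nodes`
#'   (tibbles with `curie`, `label`, `name`) and `links` (tibbles with
#'   `source`, `target`, `predicate`).
#' @export
parse_drugmechdb <- function(input, on_error = c("fail", "skip")) {
  on_error <- match.arg(on_error)
  records <- deserialize_records(input)
  if (length(records) == 0L) return(empty_paths())
  rows <- vector("list", length(records))
  bad <- character(0)
  for (i in seq_along(records)) {
    row <- tryCatch(parse_path_record(records[[i]], i),
                    mechrag_record_error = function(e) e)
    if (inherits(row, "condition")) {
      if (on_error == "fail") stop(row)
      bad <- c(bad, conditionMessage(row))
    } else {
      rows[[i]] <- row
    }
  }
  if (length(bad) > 0L) {
    warn(c("Skipped malformed path records:", bad))
  }
  out <- bind_rows(rows[!vapply(rows, is.null, logical(1))])
  if (nrow(out) == 0L) empty_paths() else out
}

empty_paths <- function() {
  tibble(path_id = character(), drug_curie = character(),
         drug_name = character(), disease_curie = character(),
         disease_name = character(), nodes = list(), links = list())
}

deserialize_records <- function(input) {
  if (is.list(input)) return(input)
  stopifnot(is.character(input), length(input) == 1L)
  if (file.exists(input)) {
    txt <- paste(readLines(input, warn = FALSE, encoding = "UTF-8"),
                 collapse = "\n")
  } else {
    txt <- input
  }
  trimmed <- trimws(txt)
  if (startsWith(trimmed, "[") || startsWith(trimmed, "{")) {
    jsonlite::fromJSON(txt, simplifyVector = FALSE)
  } else {
    yaml::yaml.load(txt)
  }
}

record_error <- function(path_id, msg) {
  abort(sprintf("path '%s': %s", path_id, msg),
        class = c("mechrag_record_error", "mechrag_error"))
}

parse_path_record <- function(rec, index) {
  path_id <- as.character(rec$graph$`_id` %||% rec$graph$id %||%
                            rec$path_id %||% sprintf("record-%d", index))
  nodes <- rec$nodes
  links <- rec$links
  if (is.null(nodes) || length(nodes) < 2L) {
    record_error(path_id, "needs at least a drug node and a disease node")
  }
  if (is.null(links) || length(links) == 0L) {
    record_error(path_id, "has no links")
  }
  node_tbl <- tibble(
    curie = map_chr(nodes, function(n) as.character(n$id %||% n$curie %||% "")),
    label = map_chr(nodes, function(n) as.character(n$label %||% "")),
    name  = map_chr(nodes, function(n) as.character(n$name %||% ""))
  )
  if (any(node_tbl$curie == "") || any(node_tbl$name == "")) {
    record_error(path_id, "node with empty curie or name")
  }
  if (anyDuplicated(node_tbl$curie)) {
    record_error(path_id, "duplicate node curies")
  }
  link_tbl <- tibble(
    source = map_chr(links, function(l) as.character(l$source %||% "")),
    target = map_chr(links, function(l) as.character(l$target %||% "")),
    predicate = map_chr(links, function(l) as.character(l$key %||% l$predicate %||% ""))
  )
  if (any(link_tbl$predicate == "")) {
    record_error(path_id, "link with empty predicate")
  }
  dangling <- setdiff(c(link_tbl$source, link_tbl$target), node_tbl$curie)
  if (length(dangling) > 0L) {
    record_error(path_id, sprintf("link endpoint(s) not in node list: %s",
                                  paste(dangling, collapse = ", ")))
  }
  drug <- node_tbl[1, ]
  disease <- node_tbl[nrow(node_tbl), ]
  if (!reaches(link_tbl, drug$curie, disease$curie)) {
    record_error(path_id, "disease not reachable from drug via directed links")
  }
  tibble(path_id = path_id,
         drug_curie = drug$curie, drug_name = drug$name,
         disease_curie = disease$curie, disease_name = disease$name,
         nodes = list(node_tbl), links = list(link_tbl))
}

# directed reachability from `from` to `to`
reaches <- function(links, from, to) {
  seen <- from
  frontier <- from
  while (length(frontier) > 0L) {
    nxt <- unique(links$target[links$source %in% frontier])
    nxt <- setdiff(nxt, seen)
    if (to %in% nxt) return(TRUE)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  to %in% seen
}

internal_nodes <- function(path_row) {
  nd <- path_row$nodes[[1]]
  nd[!(nd$curie %in% c(path_row$drug_curie, path_row$disease_curie)), ,
     drop = FALSE]
}

#' Build a gene-to-HGNC-symbol resolver from a mapping table
#'
#' The resolver maps a gene/protein CURIE to zero, one, or many HGNC symbols.
#' Paths whose gene resolves to zero symbols (deprecated identifiers) or to
#' two or more (ambiguous identifiers) are excluded from the gene benchmark.
#'
#' @param mapping A data frame with columns `curie` and `symbol` (one row per
#'   CURIE-symbol pair), or a named list of character vectors keyed by CURIE.
#' @return A function `curie -> character vector of symbols` (empty for
#'   unknown CURIEs).
#' @export
gene_resolver <- function(mapping) {
  if (is.data.frame(mapping)) {
    stopifnot(all(c("curie", "symbol") %in% names(mapping)))
    tab <- split(as.character(mapping$symbol), as.character(mapping$curie))
  } else {
    stopifnot(is.list(mapping))
    tab <- lapply(mapping, as.character)
  }
  function(curie) {
    out <- tab[[curie]]
    if (is.null(out)) character(0) else unique(out)
  }
}

#' Read a CURIE-to-HGNC-symbol mapping from a TSV file
#'
#' @param path TSV file with header columns `curie` and `symbol`.
#' @return A resolver function (see [gene_resolver()]).
#' @export
read_gene_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  gene_resolver(tab)
}

#' Select paths eligible for the gene-centric benchmark
#'
#' Retains paths with exactly one internal node (neither the drug nor the
#' disease endpoint) whose label is in `gene_labels` and whose CURIE resolves
#' to exactly one HGNC symbol.
#'
#' @param paths Tibble from [parse_drugmechdb()].
#' @param resolver Function from [gene_resolver()].
#' @param gene_labels Node labels counted as gene entities. Defaults to
#'   `c("Gene", "Protein")` because protein products stand in for their genes
#'   in mechanism paths.
#' @return Input rows that pass the filter, with `gene_curie`, `gene_name`,
#'   and `hgnc_symbol` columns appended.
#' @export
select_gene_paths <- function(paths, resolver,
                              gene_labels = c("Gene", "Protein")) {
  stopifnot(length(gene_labels) > 0L, is.function(resolver))
  if (nrow(paths) == 0L) {
    return(mutate(paths, gene_curie = character(0), gene_name = character(0),
                  hgnc_symbol = character(0)))
  }
  picks <- map(seq_len(nrow(paths)), function(i) {
    internal <- internal_nodes(paths[i, ])
    genes <- internal[internal$label %in% gene_labels, , drop = FALSE]
    if (nrow(genes) != 1L) return(NULL)
    symbols <- resolver(genes$curie)
    if (length(symbols) != 1L) return(NULL)
    tibble(gene_curie = genes$curie, gene_name = genes$name,
           hgnc_symbol = symbols)
  })
  keep <- !vapply(picks, is.null, logical(1))
  bind_cols_safe(paths[keep, , drop = FALSE], bind_rows(picks[keep]))
}

bind_cols_safe <- function(a, b) {
  if (nrow(a) == 0L) {
    for (nm in names(b)) a[[nm]] <- character(0)
    return(a)
  }
  dplyr::bind_cols(a, b)
}

#' Select paths eligible for the metabolite-centric benchmark
#'
#' Excludes paths whose links all carry taxonomic predicates, excludes
#' drug-disease indications represented by more than one path record
#' (indication multiplicity is assessed on the input collection, before the
#' other filters), and retains paths with exactly one internal node whose
#' CURIE is prefixed `"CHEBI:"`.
#'
#' @param paths Tibble from [parse_drugmechdb()].
#' @param taxonomic_predicates Either a character vector of exact predicates
#'   treated as taxonomic, or `NULL` (default) to treat any predicate
#'   containing the substring `"subclass"` as taxonomic.
#' @return Input rows that pass, with `metabolite_curie` and
#'   `metabolite_name` appended.
#' @export
select_metabolite_paths <- function(paths, taxonomic_predicates = NULL) {
  if (nrow(paths) == 0L) {
    return(mutate(paths, metabolite_curie = character(0),
                  metabolite_name = character(0)))
  }
  is_taxonomic <- function(pred) {
    if (is.null(taxonomic_predicates)) {
      grepl("subclass", pred, fixed = TRUE)
    } else {
      pred %in% taxonomic_predicates
    }
  }
  indication <- paste(paths$drug_curie, paths$disease_curie, sep = "")
  multiplicity <- table(indication)
  picks <- map(seq_len(nrow(paths)), function(i) {
    if (multiplicity[[indication[i]]] > 1L) return(NULL)
    preds <- paths$links[[i]]$predicate
    if (all(is_taxonomic(preds))) return(NULL)
    internal <- internal_nodes(paths[i, ])
    mets <- internal[startsWith(internal$curie, "CHEBI:"), , drop = FALSE]
    if (nrow(mets) != 1L) return(NULL)
    tibble(metabolite_curie = mets$curie, metabolite_name = mets$name)
  })
  keep <- !vapply(picks, is.null, logical(1))
  bind_cols_safe(paths[keep, , drop = FALSE], bind_rows(picks[keep]))
}

#' Select paths eligible for the drug-centric benchmark
#'
#' Retains paths containing exactly one node labeled `BiologicalProcess` and
#' whose drug CURIE starts with one of `drug_id_prefixes` (drugs lacking a
#' resolvable DrugBank or MeSH identifier are excluded).
#'
#' @param paths Tibble from [parse_drugmechdb()].
#' @param drug_id_prefixes Allowed drug identifier prefixes.
#' @return Input rows that pass, with `process_curie` and `process_name`
#'   appended.
#' @export
select_drug_paths <- function(paths, drug_id_prefixes = c("DB", "MESH")) {
  stopifnot(length(drug_id_prefixes) > 0L)
  if (nrow(paths) == 0L) {
    return(mutate(paths, process_curie = character(0),
                  process_name = character(0)))
  }
  picks <- map(seq_len(nrow(paths)), function(i) {
    ok_prefix <- any(startsWith(paths$drug_curie[i], drug_id_prefixes))
    if (!ok_prefix) return(NULL)
    nd <- paths$nodes[[i]]
    procs <- nd[nd$label == "BiologicalProcess", , drop = FALSE]
    if (nrow(procs) != 1L) return(NULL)
    tibble(process_curie = procs$curie, process_name = procs$name)
  })
  keep <- !vapply(picks, is.null, logical(1))
  bind_cols_safe(paths[keep, , drop = FALSE], bind_rows(picks[keep]))
}

#' Render a benchmark question from entity names
#'
#' Substitutes entity names into the fixed question template of each
#' benchmark, quoting the names.
#'
#' @param benchmark One of `"gene"`, `"metabolite"`, `"drug"`.
#' @param drug_name Drug display name (required for gene and metabolite).
#' @param disease_name Disease display name (always required).
#' @param process_name Biological-process name (required for drug).
#' @return The rendered question string (vectorized over the name arguments).
#' @export
render_question <- function(benchmark, drug_name = NULL, disease_name = NULL,
                            process_name = NULL) {
  benchmark <- match.arg(benchmark, c("gene", "metabolite", "drug"))
  req <- function(x, what) {
    if (is.null(x) || any(is.na(x)) || any(!nzchar(x))) {
      stop_mechrag(sprintf("%s name is required for the %s benchmark",
                           what, benchmark))
    }
    x
  }
  disease_name <- req(disease_name, "disease")
  switch(benchmark,
    gene = sprintf(paste0(
      "Which gene plays the most significant mechanistic role in how Drug ",
      "\"%s\" treats or impacts Disease \"%s\"?"),
      req(drug_name, "drug"), disease_name),
    metabolite = sprintf(paste0(
      "Which biochemical entity is affected by Drug \"%s\" via its ",
      "mechanism of action in treating Disease \"%s\"?"),
      req(drug_name, "drug"), disease_name),
    drug = sprintf(paste0(
      "Which drug can be used in the treatment of Disease \"%s\" by ",
      "targeting Biological Process \"%s\"?"),
      disease_name, req(process_name, "process")))
}

dedup_key <- function(items) {
  entity <- ifelse(items$benchmark == "drug",
                   items$process_name, items$drug_name)
  paste(tolower(entity), tolower(items$disease_name),
        tolower(items$gold_answer), sep = "")
}

#' Deduplicate benchmark items across indications
#'
#' Items are duplicates when they agree, case-insensitively, on the asked
#' entity (drug name, or process name for the drug benchmark), the disease
#' name, and the gold answer. The first occurrence in input order is kept
#' and the `source_path_ids` of dropped duplicates are merged into it.
#'
#' @param items Tibble of benchmark items from a single benchmark kind.
#' @return Deduplicated tibble, input order preserved.
#' @export
deduplicate_items <- function(items) {
  if (nrow(items) <= 1L) return(items)
  stopifnot(length(unique(items$benchmark)) == 1L)
  key <- dedup_key(items)
  keep_idx <- !duplicated(key)
  merged <- lapply(which(keep_idx), function(i) {
    unique(unlist(items$source_path_ids[key == key[i]]))
  })
  out <- items[keep_idx, , drop = FALSE]
  out$source_path_ids <- merged
  out
}

#' Build a mechanistic question-answer benchmark
#'
#' Composes the benchmark-specific path filter, the question template, and
#' deduplication into a finished benchmark: one templated question with a
#' gold answer per retained path group.
#'
#' @param kind One of `"gene"`, `"metabolite"`, `"drug"`.
#' @param paths Tibble from [parse_drugmechdb()].
#' @param resolver Resolver from [gene_resolver()]; required for
#'   `kind = "gene"`.
#' @param gene_labels,taxonomic_predicates,drug_id_prefixes Passed through to
#'   the corresponding `select_*` filter.
#' @return A tibble of benchmark items: `item_id`, `benchmark`, `question`,
#'   entity CURIE/name columns, `gold_answer`, `gold_curie`, and the
#'   list-column `source_path_ids`, sorted by `item_id`.
#' @export
build_benchmark <- function(kind, paths, resolver = NULL,
                            gene_labels = c("Gene", "Protein"),
                            taxonomic_predicates = NULL,
                            drug_id_prefixes = c("DB", "MESH")) {
  kind <- match.arg(kind, c("gene", "metabolite", "drug"))
  sel <- switch(kind,
    gene = {
      if (is.null(resolver)) {
        stop_mechrag("a gene resolver is required for the gene benchmark")
      }
      select_gene_paths(paths, resolver, gene_labels)
    },
    metabolite = select_metabolite_paths(paths, taxonomic_predicates),
    drug = select_drug_paths(paths, drug_id_prefixes))
  if (nrow(sel) == 0L) return(empty_benchmark(kind))
  items <- switch(kind,
    gene = tibble(
      benchmark = "gene",
      question = render_question("gene", sel$drug_name, sel$disease_name),
      drug_curie = sel$drug_curie, drug_name = sel$drug_name,
      disease_curie = sel$disease_curie, disease_name = sel$disease_name,
      process_curie = NA_character_, process_name = NA_character_,
      gold_answer = sel$hgnc_symbol, gold_curie = sel$gene_curie,
      source_path_ids = as.list(sel$path_id)),
    metabolite = tibble(
      benchmark = "metabolite",
      question = render_question("metabolite", sel$drug_name,
                                 sel$disease_name),
      drug_curie = sel$drug_curie, drug_name = sel$drug_name,
      disease_curie = sel$disease_curie, disease_name = sel$disease_name,
      process_curie = NA_character_, process_name = NA_character_,
      gold_answer = sel$metabolite_name, gold_curie = sel$metabolite_curie,
      source_path_ids = as.list(sel$path_id)),
    drug = tibble(
      benchmark = "drug",
      question = render_question("drug", disease_name = sel$disease_name,
                                 process_name = sel$process_name),
      drug_curie = sel$drug_curie, drug_name = sel$drug_name,
      disease_curie = sel$disease_curie, disease_name = sel$disease_name,
      process_curie = sel$process_curie, process_name = sel$process_name,
      gold_answer = sel$drug_name, gold_curie = sel$drug_curie,
      source_path_ids = as.list(sel$path_id)))
  items <- deduplicate_items(items)
  items <- mutate(items,
                  item_id = sprintf("%s-%04d", kind, row_number()),
                  .before = 1)
  arrange(items, .data$item_id)
}

empty_benchmark <- function(kind) {
  tibble(item_id = character(), benchmark = character(),
         question = character(), drug_curie = character(),
         drug_name = character(), disease_curie = character(),
         disease_name = character(), process_curie = character(),
         process_name = character(), gold_answer = character(),
         gold_curie = character(), source_path_ids = list())
}
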