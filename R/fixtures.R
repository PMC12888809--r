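#' Configuration for the synthetic mini path database
#'
#' Declares how many paths the generated database contains and how many of
#' them are eligible for each benchmark. The remaining paths are explicit
#' negatives cycling through every exclusion rule (multi-gene paths,
#' taxonomic-only paths, multi-path indications, non-resolvable drug
#' identifiers, ambiguous and deprecated gene identifiers), so each filter
#' clause has dedicated coverage.
#'
#' @param seed Integer seed; the generated document is a pure function of
#'   the config.
#' @param n_paths Total number of path records.
#' @param eligible_gene,eligible_metabolite,eligible_drug Planted numbers of
#'   paths passing each benchmark filter.
#' @param n_duplicate_groups Number of gene-eligible items duplicated (as
#'   case variants from a second path record) to exercise deduplication;
#'   must not exceed `eligible_gene`. Duplicates do not change the planted
#'   gene benchmark size.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(seed = 1, n_paths = 12, eligible_gene = 3,
                           eligible_metabolite = 2, eligible_drug = 4,
                           n_duplicate_groups = 0) {
  stopifnot(eligible_gene >= 0, eligible_metabolite >= 0, eligible_drug >= 0,
            n_duplicate_groups >= 0)
  if (n_duplicate_groups > eligible_gene) {
    stop_mechrag("n_duplicate_groups cannot exceed eligible_gene")
  }
  used <- eligible_gene + eligible_metabolite + eligible_drug +
    n_duplicate_groups
  if (used > n_paths) {
    stop_mechrag(sprintf(
      "infeasible config: %d planted paths exceed n_paths = %d",
      used, n_paths))
  }
  structure(list(seed = as.integer(seed), n_paths = as.integer(n_paths),
                 eligible_gene = as.integer(eligible_gene),
                 eligible_metabolite = as.integer(eligible_metabolite),
                 eligible_drug = as.integer(eligible_drug),
                 n_duplicate_groups = as.integer(n_duplicate_groups)),
            class = "fixture_config")
}

syn_drug_name <- function(i) sprintf("Drugatol-%d", i)
syn_disease_name <- function(i) sprintf("Malady-%d", i)
syn_symbol <- function(i) sprintf("SYG%d", i)
syn_metabolite_name <- function(i) sprintf("metabolyn-%d", i)
syn_process_name <- function(i) sprintf("process-%d regulation", i)

node <- function(id, label, name) list(id = id, label = label, name = name)
link <- function(source, target, key) {
  list(source = source, target = target, key = key)
}
path_record <- function(path_id, nodes, links) {
  list(graph = list(`_id` = path_id), nodes = nodes, links = links)
}

#' Generate a synthetic mini drug-mechanism path database
#'
#' Produces a YAML document parseable by [parse_drugmechdb()] in which
#' exactly the planted numbers of paths satisfy each benchmark filter,
#' together with the planted truth needed to drive the rest of the pipeline
#' offline (gold answers, gene resolver mapping, TRAPI neighborhoods with the
#' gold entity planted among distractors). The same config yields a
#' byte-identical document.
#'
#' @param config A [fixture_config()].
#' @return List with `document` (YAML text) and `truth` (list: `config`,
#'   `counts`, `paths` kind table, `gene_map`, `entity_names`,
#'   `neighborhoods`, per-benchmark `gold` tables).
#' @export
generate_mini_drugmechdb <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  with_seed(config$seed, build_mini_db(config))
}

build_mini_db <- function(config) {
  records <- list()
  kinds <- character(0)
  gene_map <- tibble(curie = character(), symbol = character())
  gold_gene <- tibble(path_id = character(), drug_curie = character(),
                      drug_name = character(), disease_curie = character(),
                      disease_name = character(), gene_curie = character(),
                      symbol = character())
  gold_met <- tibble(path_id = character(), drug_curie = character(),
                     drug_name = character(), disease_curie = character(),
                     disease_name = character(),
                     metabolite_curie = character(),
                     metabolite_name = character())
  gold_drug <- tibble(path_id = character(), drug_curie = character(),
                      drug_name = character(), disease_curie = character(),
                      disease_name = character(),
                      process_curie = character(),
                      process_name = character())
  neighborhoods <- list()
  entity_names <- character(0)
  distractor_id <- 0L
  sources <- c("ctd", "drugbank", "go", "hgnc")

  register_entity <- function(curie, name) {
    entity_names[[curie]] <<- name
  }
  add_neighbors <- function(input_curie, output_category, neighbors) {
    key <- paste(input_curie, output_category, sep = "|")
    existing <- neighborhoods[[key]]
    neighborhoods[[key]] <<- if (is.null(existing)) neighbors else
      bind_rows(existing, neighbors)
  }
  distractor <- function(category) {
    distractor_id <<- distractor_id + 1L
    tibble(curie = sprintf("MESH:X%04d", distractor_id),
           name = sprintf("entity-%d", distractor_id),
           category = category,
           predicate = "biolink:related_to",
           source = sources[(distractor_id %% length(sources)) + 1L])
  }
  planted_neighbor <- function(curie, name, category, predicate, src) {
    tibble(curie = curie, name = name, category = category,
           predicate = predicate, source = src)
  }

  idx <- 0L
  # --- gene-eligible paths -------------------------------------------------
  gene_labels_pool <- c("Gene", "Protein")
  for (i in seq_len(config$eligible_gene)) {
    idx <- idx + 1L
    pid <- sprintf("path-gene-%03d", i)
    drug_c <- sprintf("MESH:DG%03d", i); drug_n <- syn_drug_name(idx)
    dis_c <- sprintf("MESH:GD%03d", i); dis_n <- syn_disease_name(idx)
    gene_c <- sprintf("UniProt:PG%03d", i)
    sym <- syn_symbol(i)
    lab <- sample(gene_labels_pool, 1)
    records[[length(records) + 1L]] <- path_record(pid, list(
      node(drug_c, "Drug", drug_n),
      node(gene_c, lab, paste(sym, "protein")),
      node(dis_c, "Disease", dis_n)), list(
      link(drug_c, gene_c, "decreases activity of"),
      link(gene_c, dis_c, "causes")))
    kinds <- c(kinds, "gene_eligible")
    gene_map <- bind_rows(gene_map, tibble(curie = gene_c, symbol = sym))
    gold_gene <- bind_rows(gold_gene, tibble(
      path_id = pid, drug_curie = drug_c, drug_name = drug_n,
      disease_curie = dis_c, disease_name = dis_n, gene_curie = gene_c,
      symbol = sym))
    register_entity(drug_c, drug_n); register_entity(dis_c, dis_n)
    for (outcat in c("biolink:Gene", "biolink:Protein")) {
      gold_nb <- planted_neighbor(gene_c, sym, outcat,
                                  "biolink:interacts_with", "hgnc")
      add_neighbors(dis_c, outcat, bind_rows(gold_nb, distractor(outcat)))
      add_neighbors(drug_c, outcat,
                    bind_rows(gold_nb, distractor(outcat)))
    }
  }
  # --- duplicate gene paths (case-variant names, same symbol) -------------
  for (i in seq_len(config$n_duplicate_groups)) {
    pid <- sprintf("path-gene-dup-%03d", i)
    src <- gold_gene[i, ]
    gene_c <- sprintf("UniProt:PGD%03d", i)
    records[[length(records) + 1L]] <- path_record(pid, list(
      node(src$drug_curie, "Drug", toupper(src$drug_name)),
      node(gene_c, "Gene", paste(src$symbol, "protein")),
      node(src$disease_curie, "Disease", toupper(src$disease_name))), list(
      link(src$drug_curie, gene_c, "increases activity of"),
      link(gene_c, src$disease_curie, "contributes to")))
    kinds <- c(kinds, "gene_duplicate")
    gene_map <- bind_rows(gene_map,
                          tibble(curie = gene_c, symbol = src$symbol))
  }
  # --- metabolite-eligible paths ------------------------------------------
  for (i in seq_len(config$eligible_metabolite)) {
    idx <- idx + 1L
    pid <- sprintf("path-met-%03d", i)
    drug_c <- sprintf("MESH:DM%03d", i); drug_n <- syn_drug_name(idx)
    dis_c <- sprintf("MESH:MD%03d", i); dis_n <- syn_disease_name(idx)
    met_c <- sprintf("CHEBI:10%03d", i); met_n <- syn_metabolite_name(i)
    records[[length(records) + 1L]] <- path_record(pid, list(
      node(drug_c, "Drug", drug_n),
      node(met_c, "ChemicalSubstance", met_n),
      node(dis_c, "Disease", dis_n)), list(
      link(drug_c, met_c, "increases abundance of"),
      link(met_c, dis_c, "negatively regulates")))
    kinds <- c(kinds, "metabolite_eligible")
    gold_met <- bind_rows(gold_met, tibble(
      path_id = pid, drug_curie = drug_c, drug_name = drug_n,
      disease_curie = dis_c, disease_name = dis_n,
      metabolite_curie = met_c, metabolite_name = met_n))
    register_entity(drug_c, drug_n); register_entity(dis_c, dis_n)
    gold_nb <- planted_neighbor(met_c, met_n, "biolink:ChemicalEntity",
                                "biolink:affected_by", "ctd")
    add_neighbors(drug_c, "biolink:ChemicalEntity",
                  bind_rows(gold_nb, distractor("biolink:ChemicalEntity")))
    add_neighbors(dis_c, "biolink:ChemicalEntity",
                  distractor("biolink:ChemicalEntity"))
  }
  # --- drug-eligible paths -------------------------------------------------
  for (i in seq_len(config$eligible_drug)) {
    idx <- idx + 1L
    pid <- sprintf("path-drug-%03d", i)
    prefix <- if (i %% 2 == 0) "MESH:DC%03d" else "DB:C%03d"
    drug_c <- sprintf(prefix, i); drug_n <- syn_drug_name(idx)
    dis_c <- sprintf("MESH:CD%03d", i); dis_n <- syn_disease_name(idx)
    proc_c <- sprintf("GO:00%05d", i); proc_n <- syn_process_name(i)
    records[[length(records) + 1L]] <- path_record(pid, list(
      node(drug_c, "Drug", drug_n),
      node(proc_c, "BiologicalProcess", proc_n),
      node(dis_c, "Disease", dis_n)), list(
      link(drug_c, proc_c, "positively regulates"),
      link(proc_c, dis_c, "prevents")))
    kinds <- c(kinds, "drug_eligible")
    gold_drug <- bind_rows(gold_drug, tibble(
      path_id = pid, drug_curie = drug_c, drug_name = drug_n,
      disease_curie = dis_c, disease_name = dis_n,
      process_curie = proc_c, process_name = proc_n))
    register_entity(dis_c, dis_n); register_entity(proc_c, proc_n)
    gold_nb <- planted_neighbor(drug_c, drug_n, "biolink:ChemicalEntity",
                                "biolink:treats", "drugbank")
    add_neighbors(dis_c, "biolink:ChemicalEntity",
                  bind_rows(gold_nb, distractor("biolink:ChemicalEntity")))
    add_neighbors(proc_c, "biolink:ChemicalEntity", gold_nb)
  }
  # --- negatives -----------------------------------------------------------
  negative_kinds <- c("two_gene", "taxonomic_only", "multi_indication",
                      "bad_drug_prefix", "ambiguous_gene", "deprecated_gene")
  remaining <- config$n_paths - length(records)
  neg_i <- 0L
  while (remaining > 0L) {
    neg_i <- neg_i + 1L
    kind <- negative_kinds[((neg_i - 1L) %% length(negative_kinds)) + 1L]
    if (kind == "multi_indication" && remaining < 2L) kind <- "two_gene"
    idx <- idx + 1L
    drug_n <- syn_drug_name(idx); dis_n <- syn_disease_name(idx)
    if (kind == "two_gene") {
      pid <- sprintf("path-neg-twogene-%03d", neg_i)
      drug_c <- sprintf("MESH:NG%03d", neg_i)
      dis_c <- sprintf("MESH:NGD%03d", neg_i)
      g1 <- sprintf("UniProt:NA%03d", neg_i)
      g2 <- sprintf("UniProt:NB%03d", neg_i)
      records[[length(records) + 1L]] <- path_record(pid, list(
        node(drug_c, "Drug", drug_n), node(g1, "Gene", "gene A"),
        node(g2, "Gene", "gene B"), node(dis_c, "Disease", dis_n)), list(
        link(drug_c, g1, "decreases activity of"),
        link(g1, g2, "interacts with"),
        link(g2, dis_c, "causes")))
      gene_map <- bind_rows(gene_map,
        tibble(curie = c(g1, g2),
               symbol = c(sprintf("NGA%d", neg_i), sprintf("NGB%d", neg_i))))
      kinds <- c(kinds, kind); remaining <- remaining - 1L
    } else if (kind == "taxonomic_only") {
      pid <- sprintf("path-neg-taxo-%03d", neg_i)
      drug_c <- sprintf("MESH:NT%03d", neg_i)
      dis_c <- sprintf("MESH:NTD%03d", neg_i)
      met_c <- sprintf("CHEBI:90%03d", neg_i)
      records[[length(records) + 1L]] <- path_record(pid, list(
        node(drug_c, "Drug", drug_n),
        node(met_c, "ChemicalSubstance", syn_metabolite_name(900 + neg_i)),
        node(dis_c, "Disease", dis_n)), list(
        link(drug_c, met_c, "subclass of"),
        link(met_c, dis_c, "subclass of")))
      kinds <- c(kinds, kind); remaining <- remaining - 1L
    } else if (kind == "multi_indication") {
      drug_c <- sprintf("MESH:NM%03d", neg_i)
      dis_c <- sprintf("MESH:NMD%03d", neg_i)
      for (rep_i in 1:2) {
        pid <- sprintf("path-neg-multi-%03d-%d", neg_i, rep_i)
        met_c <- sprintf("CHEBI:80%03d", neg_i * 10L + rep_i)
        records[[length(records) + 1L]] <- path_record(pid, list(
          node(drug_c, "Drug", drug_n),
          node(met_c, "ChemicalSubstance",
               syn_metabolite_name(800 + neg_i * 10L + rep_i)),
          node(dis_c, "Disease", dis_n)), list(
          link(drug_c, met_c, "increases abundance of"),
          link(met_c, dis_c, "negatively regulates")))
        kinds <- c(kinds, kind)
      }
      remaining <- remaining - 2L
    } else if (kind == "bad_drug_prefix") {
      pid <- sprintf("path-neg-baddrug-%03d", neg_i)
      drug_c <- sprintf("UNII:U%03d", neg_i)
      dis_c <- sprintf("MESH:NBD%03d", neg_i)
      proc_c <- sprintf("GO:09%05d", neg_i)
      records[[length(records) + 1L]] <- path_record(pid, list(
        node(drug_c, "Drug", drug_n),
        node(proc_c, "BiologicalProcess", syn_process_name(900 + neg_i)),
        node(dis_c, "Disease", dis_n)), list(
        link(drug_c, proc_c, "positively regulates"),
        link(proc_c, dis_c, "prevents")))
      kinds <- c(kinds, kind); remaining <- remaining - 1L
    } else if (kind == "ambiguous_gene") {
      pid <- sprintf("path-neg-ambig-%03d", neg_i)
      drug_c <- sprintf("MESH:NAG%03d", neg_i)
      dis_c <- sprintf("MESH:NAD%03d", neg_i)
      gene_c <- sprintf("UniProt:AMB%03d", neg_i)
      records[[length(records) + 1L]] <- path_record(pid, list(
        node(drug_c, "Drug", drug_n),
        node(gene_c, "Gene", "ambiguous gene"),
        node(dis_c, "Disease", dis_n)), list(
        link(drug_c, gene_c, "decreases activity of"),
        link(gene_c, dis_c, "causes")))
      gene_map <- bind_rows(gene_map, tibble(
        curie = gene_c,
        symbol = c(sprintf("AMBA%d", neg_i), sprintf("AMBB%d", neg_i))))
      kinds <- c(kinds, kind); remaining <- remaining - 1L
    } else { # deprecated_gene: curie absent from the resolver map
      pid <- sprintf("path-neg-depr-%03d", neg_i)
      drug_c <- sprintf("MESH:NDG%03d", neg_i)
      dis_c <- sprintf("MESH:NDD%03d", neg_i)
      gene_c <- sprintf("UniProt:DEP%03d", neg_i)
      records[[length(records) + 1L]] <- path_record(pid, list(
        node(drug_c, "Drug", drug_n),
        node(gene_c, "Gene", "deprecated gene"),
        node(dis_c, "Disease", dis_n)), list(
        link(drug_c, gene_c, "decreases activity of"),
        link(gene_c, dis_c, "causes")))
      kinds <- c(kinds, kind); remaining <- remaining - 1L
    }
  }
  path_ids <- map_chr(records, function(r) r$graph$`_id`)
  truth <- list(
    config = config,
    counts = list(gene = config$eligible_gene,
                  metabolite = config$eligible_metabolite,
                  drug = config$eligible_drug),
    paths = tibble(path_id = path_ids, kind = kinds),
    gene_map = gene_map,
    entity_names = entity_names,
    neighborhoods = neighborhoods,
    gold = list(gene = gold_gene, metabolite = gold_met, drug = gold_drug))
  list(document = yaml::as.yaml(records), truth = truth)
}

#' Mock TRAPI transport over planted neighborhoods
#'
#' Returns a transport function that answers one-hop TRAPI requests built by
#' [build_trapi_query()] with well-formed responses containing exactly the
#' planted neighbor nodes and edges (with primary-source attribution) for
#' the pinned entity and requested output category. Unknown entities yield
#' an empty knowledge graph; malformed requests raise an error.
#'
#' @param truth Planted truth from [generate_mini_drugmechdb()].
#' @return Function `request -> response` (both TRAPI document lists).
#' @export
mock_trapi_transport <- function(truth) {
  neighborhoods <- truth$neighborhoods
  entity_names <- truth$entity_names
  function(request) {
    qg <- request$message$query_graph
    n0 <- qg$nodes$n0; n1 <- qg$nodes$n1
    if (is.null(n0$ids) || length(n0$ids) == 0L || is.null(n1$categories)) {
      stop_mechrag("malformed TRAPI request: missing pinned ids or categories")
    }
    input_curie <- n0$ids[[1]]
    output_category <- n1$categories[[1]]
    nb <- neighborhoods[[paste(input_curie, output_category, sep = "|")]]
    if (is.null(nb) || nrow(nb) == 0L) {
      return(list(message = list(knowledge_graph = list(
        nodes = stats::setNames(list(), character(0)),
        edges = stats::setNames(list(), character(0))))))
    }
    input_name <- entity_names[[input_curie]] %||% input_curie
    nodes <- list()
    nodes[[input_curie]] <- list(
      name = input_name,
      categories = list(n0$categories[[1]] %||% "biolink:NamedThing"))
    for (i in seq_len(nrow(nb))) {
      nodes[[nb$curie[i]]] <- list(name = nb$name[i],
                                   categories = list(nb$category[i]))
    }
    edges <- list()
    for (i in seq_len(nrow(nb))) {
      edges[[sprintf("e%03d", i)]] <- list(
        subject = input_curie, predicate = nb$predicate[i],
        object = nb$curie[i],
        sources = list(list(resource_id = nb$source[i],
                            resource_role = "primary_knowledge_source")))
    }
    list(message = list(knowledge_graph = list(nodes = nodes,
                                               edges = edges)))
  }
}

#' Deterministic hashing text embedder
#'
#' Maps text to a fixed-dimension vector by hashing character trigrams of
#' the code-point sequence (with boundary padding) into signed buckets, then
#' L2-normalizing. Identical texts always give identical vectors; distinct
#' texts have cosine < 1 with overwhelming probability. A stand-in for
#' sentence-embedding models in offline tests.
#'
#' @param dimension Vector dimension (>= 8; default 256).
#' @param seed Integer mixed into the hash.
#' @return Function `text -> numeric vector` of unit norm.
#' @export
hash_embedder <- function(dimension = 256, seed = 0) {
  stopifnot(dimension >= 8)
  mod <- 1000003
  function(text) {
    stopifnot(is_scalar_chr(text))
    cps <- utf8ToInt(enc2utf8(text))
    padded <- c(2L, cps, 3L)
    v <- numeric(dimension)
    n <- length(padded)
    width <- min(3L, n)
    for (start in seq_len(n - width + 1L)) {
      h <- (seed %% mod)
      for (k in seq_len(width)) {
        h <- (h * 31 + padded[start + k - 1L]) %% mod
      }
      bucket <- (h %% dimension) + 1L
      sgn <- if ((h %/% dimension) %% 2 == 0) 1 else -1
      v[bucket] <- v[bucket] + sgn
    }
    nv <- sqrt(sum(v^2))
    if (nv == 0) v[1] <- 1 else v <- v / nv
    v
  }
}

#' Embedder realizing prescribed prediction-gold similarities
#'
#' Builds a deterministic embedder over a closed vocabulary such that the
#' cosine similarity of each listed (prediction, gold) pair equals its
#' prescribed target: each distinct gold text gets its own basis axis and
#' each prediction is placed in the plane spanned by its gold's axis and a
#' private axis. Used to plant exact similarity structure in end-to-end
#' runs.
#'
#' @param targets Tibble with columns `pred`, `gold`, `similarity`
#'   (`pred` values must be distinct; similarities in `[-1, 1]`).
#' @return Function `text -> numeric vector`; errors on unknown text.
#' @export
planted_scorer <- function(targets) {
  stopifnot(all(c("pred", "gold", "similarity") %in% names(targets)),
            !anyDuplicated(targets$pred),
            all(targets$similarity >= -1 & targets$similarity <= 1))
  golds <- unique(targets$gold)
  n_g <- length(golds); n_p <- nrow(targets)
  dim <- n_g + n_p
  basis <- function(i) { v <- numeric(dim); v[i] <- 1; v }
  vocab <- list()
  for (k in seq_len(n_g)) vocab[[golds[k]]] <- basis(k)
  for (i in seq_len(n_p)) {
    g_axis <- match(targets$gold[i], golds)
    s <- targets$similarity[i]
    v <- numeric(dim)
    v[g_axis] <- s
    v[n_g + i] <- sqrt(max(0, 1 - s^2))
    vocab[[targets$pred[i]]] <- v
  }
  function(text) {
    v <- vocab[[text]]
    if (is.null(v)) {
      stop_mechrag(sprintf("planted scorer has no vector for '%s'", text))
    }
    v
  }
}

#' Scripted deterministic generation backend
#'
#' Replays pre-assigned responses keyed by (item id, mode); the item id and
#' mode arrive through the decoding-config metadata supplied by
#' [run_benchmark()]. Unscripted items raise an error.
#'
#' @param script Tibble with columns `item_id`, `mode`, `response`.
#' @return A backend function `(system_text, user_text, config) -> text`.
#' @export
scripted_llm <- function(script) {
  stopifnot(all(c("item_id", "mode", "response") %in% names(script)))
  key <- paste(script$item_id, script$mode, sep = "|")
  responses <- stats::setNames(script$response, key)
  function(system_text, user_text, config) {
    meta <- config$meta
    if (is.null(meta$item_id) || is.null(meta$mode)) {
      stop_mechrag("scripted backend requires item metadata in the config")
    }
    k <- paste(meta$item_id, meta$mode, sep = "|")
    if (!k %in% names(responses)) {
      stop_mechrag(sprintf("no scripted response for %s", k))
    }
    unname(responses[[k]])
  }
}

answer_json <- function(answer) {
  as.character(jsonlite::toJSON(list(answer = answer), auto_unbox = TRUE))
}

#' Script a run pair with planted contingency structure
#'
#' Assigns scripted responses to both inference modes so that the paired
#' binary comparison of the two runs reproduces exactly the requested 2x2
#' contingency: the first `a` items are correct in both modes, the next `b`
#' only under `treatment_mode`, the next `c` only under `baseline_mode`, and
#' the rest in neither.
#'
#' @param items Benchmark tibble.
#' @param a,b,c Planted cell counts (`d` is the remainder; the four must not
#'   exceed `nrow(items)`).
#' @param baseline_mode,treatment_mode Mode labels for the two runs.
#' @return Script tibble for [scripted_llm()] covering both modes.
#' @export
plant_contingency_script <- function(items, a, b, c,
                                     baseline_mode = "llm_only",
                                     treatment_mode = "rag") {
  n <- nrow(items)
  d <- n - a - b - c
  if (d < 0) stop_mechrag("a + b + c exceeds the number of items")
  cell <- rep(c("a", "b", "c", "d"), times = c(a, b, c, d))
  right <- items$gold_answer
  wrong <- paste0("not-", items$gold_answer)
  base_ans <- ifelse(cell %in% c("a", "c"), right, wrong)
  treat_ans <- ifelse(cell %in% c("a", "b"), right, wrong)
  bind_rows(
    tibble(item_id = items$item_id, mode = baseline_mode,
           response = map_chr(base_ans, answer_json)),
    tibble(item_id = items$item_id, mode = treatment_mode,
           response = map_chr(treat_ans, answer_json)))
}

#' Script one run with a planted accuracy
#'
#' The first `round(accuracy * n)` items answer with the gold answer, the
#' rest with a wrong answer; optionally the last `round(malformed_rate * n)`
#' items return non-JSON text (which downstream scoring counts as failed).
#'
#' @param items Benchmark tibble.
#' @param accuracy Planted fraction correct in `[0, 1]`.
#' @param mode Mode label of the run.
#' @param malformed_rate Fraction of items given unparseable responses.
#' @return Script tibble for [scripted_llm()].
#' @export
plant_accuracy_script <- function(items, accuracy, mode = "llm_only",
                                  malformed_rate = 0) {
  n <- nrow(items)
  stopifnot(accuracy >= 0, accuracy <= 1,
            malformed_rate >= 0, malformed_rate <= 1)
  k <- round(accuracy * n)
  ans <- ifelse(seq_len(n) <= k, items$gold_answer,
                paste0("not-", items$gold_answer))
  response <- map_chr(ans, answer_json)
  m <- round(malformed_rate * n)
  if (m > 0) {
    response[(n - m + 1L):n] <- "this response is not structured at all"
  }
  tibble(item_id = items$item_id, mode = mode, response = response)
}

#' Script a run pair with planted semantic similarities
#'
#' Gives each (item, mode) a distinct prediction text and builds a
#' [planted_scorer()] under which the prediction-gold cosine similarity of
#' every answer equals the prescribed value, so paired score comparisons
#' recover the planted shift exactly.
#'
#' @param items Benchmark tibble.
#' @param baseline_sims,treatment_sims Numeric vectors of length
#'   `nrow(items)` in `[-1, 1]`.
#' @param baseline_mode,treatment_mode Mode labels.
#' @return List with `script` (for [scripted_llm()]) and `scorer` (for
#'   [score_answers()]).
#' @export
plant_similarity_run <- function(items, baseline_sims, treatment_sims,
                                 baseline_mode = "llm_only",
                                 treatment_mode = "rag") {
  n <- nrow(items)
  stopifnot(length(baseline_sims) == n, length(treatment_sims) == n)
  pred_base <- sprintf("pred-%s-%s", items$item_id, baseline_mode)
  pred_treat <- sprintf("pred-%s-%s", items$item_id, treatment_mode)
  targets <- tibble(pred = c(pred_base, pred_treat),
                    gold = rep(items$gold_answer, 2),
                    similarity = c(baseline_sims, treatment_sims))
  script <- bind_rows(
    tibble(item_id = items$item_id, mode = baseline_mode,
           response = map_chr(pred_base, answer_json)),
    tibble(item_id = items$item_id, mode = treatment_mode,
           response = map_chr(pred_treat, answer_json)))
  list(script = script, scorer = planted_scorer(targets))
}
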