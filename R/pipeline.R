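#' Default pipeline configuration
#'
#' @param seed Master seed; every stochastic step derives from it.
#' @param out_dir Run output directory.
#' @param benchmarks Benchmark kinds to run.
#' @param fixture A [fixture_config()]; its `seed` is overridden by `seed`.
#' @param selection List with `mode`, `percentile`, `token_budget` for
#'   context selection.
#' @param planted Per-benchmark planted outcome structure for the scripted
#'   backend: for the binary (gene) benchmark a list `a`, `b`, `c` of
#'   contingency cells scaled to the benchmark size if fractional; for score
#'   benchmarks a list `shift` (treatment minus baseline similarity).
#' @return Config list for [orchestrate()].
#' @export
pipeline_config <- function(seed = 1, out_dir = tempfile("mechrag-run-"),
                            benchmarks = c("gene", "metabolite", "drug"),
                            fixture = fixture_config(n_paths = 16,
                                                     eligible_gene = 4,
                                                     eligible_metabolite = 3,
                                                     eligible_drug = 4),
                            selection = list(mode = "drop_bottom",
                                             percentile = 10,
                                             token_budget = NULL),
                            planted = list(
                              gene = list(a = 0.40, b = 0.30, c = 0.06),
                              metabolite = list(shift = 0.066),
                              drug = list(shift = 0.01))) {
  fixture$seed <- as.integer(seed)
  list(seed = as.integer(seed), out_dir = out_dir,
       benchmarks = match.arg(benchmarks, c("gene", "metabolite", "drug"),
                              several.ok = TRUE),
       fixture = fixture, selection = selection, planted = planted)
}

scale_cell <- function(x, n) if (x < 1) floor(x * n) else as.integer(x)

#' Run the full offline pipeline
#'
#' Executes fixture generation, benchmark construction, cached mock-TRAPI
#' retrieval, verbalization, similarity-based context selection, scripted
#' dual-mode inference, and paired evaluation, writing every artifact plus a
#' manifest with content digests to the run directory. Rerunning with the
#' same config reproduces byte-identical outputs.
#'
#' @param config From [pipeline_config()].
#' @return The run directory path, invisibly; the manifest is
#'   `manifest.json` inside it.
#' @export
orchestrate <- function(config = pipeline_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cache_dir <- file.path(config$out_dir, "cache")
  outputs <- character(0)
  emit <- function(name, writer) {
    path <- file.path(config$out_dir, name)
    writer(path)
    outputs <<- c(outputs, name)
    path
  }

  fix <- generate_mini_drugmechdb(config$fixture)
  emit("mini_db.yaml", function(p) writeLines(fix$document, p,
                                              useBytes = TRUE))
  paths <- parse_drugmechdb(fix$document)
  resolver <- gene_resolver(fix$truth$gene_map)
  transport <- mock_trapi_transport(fix$truth)
  embedder <- hash_embedder(dimension = 128, seed = config$seed)

  report <- list(seed = config$seed, benchmarks = list())
  for (kind in config$benchmarks) {
    items <- build_benchmark(kind, paths, resolver = resolver)
    emit(sprintf("benchmark-%s.jsonl", kind),
         function(p) write_benchmark(items, p))
    if (nrow(items) == 0L) next
    contexts <- list()
    for (i in seq_len(nrow(items))) {
      graph <- retrieve_for_item(items[i, ], transport, cache_dir)
      stmts <- verbalize_graph(graph)
      contexts[[items$item_id[i]]] <- select_context(
        items$question[i], stmts, embedder,
        mode = config$selection$mode %||% "full",
        percentile = config$selection$percentile,
        token_budget = config$selection$token_budget)
    }
    if (kind == "gene") {
      cells <- config$planted$gene
      n <- nrow(items)
      script <- plant_contingency_script(
        items, scale_cell(cells$a, n), scale_cell(cells$b, n),
        scale_cell(cells$c, n))
      scorer <- NULL
      regime <- "binary"
    } else {
      n <- nrow(items)
      base_sims <- round(seq(0.10, 0.90, length.out = n), 6)
      shift <- config$planted[[kind]]$shift %||% 0
      planted <- plant_similarity_run(items, base_sims,
                                      pmin(1, base_sims + shift))
      script <- planted$script
      scorer <- planted$scorer
      regime <- "score"
    }
    backend <- scripted_llm(script)
    ans_base <- run_benchmark(items, backend, "llm_only")
    ans_rag <- run_benchmark(items, backend, "rag", contexts = contexts)
    emit(sprintf("answers-%s-llm_only.jsonl", kind),
         function(p) write_answers(ans_base, p))
    emit(sprintf("answers-%s-rag.jsonl", kind),
         function(p) write_answers(ans_rag, p))
    res_base <- score_answers(ans_base, items, regime, scorer)
    res_rag <- score_answers(ans_rag, items, regime, scorer)
    cmp <- compare_runs(res_base, res_rag, regime,
                        boot_seed = config$seed)
    report$benchmarks[[kind]] <- c(
      list(kind = kind, regime = regime, n_items = nrow(items),
           mean_context_statements = mean(map_int(contexts, function(s)
             sum(s$retained)))),
      as.list(glance(cmp)))
  }
  emit("report.json", function(p) {
    jsonlite::write_json(report, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  })

  cache_files <- if (dir.exists(cache_dir)) {
    file.path("cache", list.files(cache_dir, recursive = TRUE))
  } else character(0)
  tracked <- sort(c(outputs, cache_files))
  digests <- vapply(tracked, function(f) {
    sha256_hex(readBin(file.path(config$out_dir, f), "raw",
                       file.size(file.path(config$out_dir, f))))
  }, character(1))
  manifest <- list(
    seed = config$seed,
    benchmarks = as.list(config$benchmarks),
    selection = config$selection,
    files = as.list(digests))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(config$out_dir)
}
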