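test_that("path records parse with content preserved and round-trip the generator", {
  doc <- '
- graph:
    _id: p1
  nodes:
    - {id: "MESH:D1", label: Drug, name: aspirin}
    - {id: "UniProt:P1", label: Protein, name: COX2 protein}
    - {id: "MESH:E1", label: Disease, name: fever}
  links:
    - {source: "MESH:D1", target: "UniProt:P1", key: decreases activity of}
    - {source: "UniProt:P1", target: "MESH:E1", key: causes}
- graph:
    _id: p2
  nodes:
    - {id: "MESH:D2", label: Drug, name: drugB}
    - {id: "MESH:E2", label: Disease, name: diseaseB}
  links:
    - {source: "MESH:D2", target: "MESH:E2", key: treats}
'
  paths <- parse_drugmechdb(doc)
  expect_equal(nrow(paths), 2L)
  expect_equal(paths$path_id, c("p1", "p2"))
  expect_equal(nrow(paths$nodes[[1]]), 3L)
  expect_equal(paths$nodes[[1]]$label, c("Drug", "Protein", "Disease"))
  expect_equal(paths$drug_name, c("aspirin", "drugB"))
  expect_equal(paths$disease_name, c("fever", "diseaseB"))
  expect_equal(paths$links[[1]]$predicate[1], "decreases activity of")

  # generated document round-trips: parsed content equals an independent
  # deserialization of the same YAML
  fix <- generate_mini_drugmechdb(fixture_config(seed = 1))
  parsed <- parse_drugmechdb(fix$document)
  raw <- yaml::yaml.load(fix$document)
  expect_equal(nrow(parsed), length(raw))
  expect_equal(parsed$path_id,
               vapply(raw, function(r) r$graph$`_id`, character(1)))
  expect_equal(purrr::map_int(parsed$nodes, nrow),
               vapply(raw, function(r) length(r$nodes), integer(1)))
  for (i in seq_along(raw)) {
    expect_equal(parsed$nodes[[i]]$curie,
                 vapply(raw[[i]]$nodes, `[[`, character(1), "id"))
  }
})

test_that("malformed records fail with the offending path id, or skip on request", {
  bad <- '
- graph:
    _id: dangling-link
  nodes:
    - {id: "MESH:D1", label: Drug, name: a}
    - {id: "MESH:E1", label: Disease, name: b}
  links:
    - {source: "MESH:D1", target: "MESH:MISSING", key: treats}
'
  expect_error(parse_drugmechdb(bad), "dangling-link")
  expect_warning(out <- parse_drugmechdb(bad, on_error = "skip"),
                 "dangling-link")
  expect_equal(nrow(out), 0L)

  disconnected <- '
- graph:
    _id: no-route
  nodes:
    - {id: "MESH:D1", label: Drug, name: a}
    - {id: "MESH:G1", label: Gene, name: g}
    - {id: "MESH:E1", label: Disease, name: b}
  links:
    - {source: "MESH:G1", target: "MESH:D1", key: affects}
    - {source: "MESH:G1", target: "MESH:E1", key: causes}
'
  expect_error(parse_drugmechdb(disconnected), "no-route")
})

make_gene_path_doc <- function() {
  '
- graph: {_id: one-gene}
  nodes:
    - {id: "MESH:D1", label: Drug, name: drugA}
    - {id: "UniProt:P1", label: Gene, name: gene one}
    - {id: "MESH:E1", label: Disease, name: disA}
  links:
    - {source: "MESH:D1", target: "UniProt:P1", key: inhibits}
    - {source: "UniProt:P1", target: "MESH:E1", key: causes}
- graph: {_id: two-genes}
  nodes:
    - {id: "MESH:D2", label: Drug, name: drugB}
    - {id: "UniProt:P2", label: Gene, name: gene two}
    - {id: "UniProt:P3", label: Protein, name: gene three}
    - {id: "MESH:E2", label: Disease, name: disB}
  links:
    - {source: "MESH:D2", target: "UniProt:P2", key: inhibits}
    - {source: "UniProt:P2", target: "UniProt:P3", key: interacts with}
    - {source: "UniProt:P3", target: "MESH:E2", key: causes}
- graph: {_id: ambiguous-gene}
  nodes:
    - {id: "MESH:D3", label: Drug, name: drugC}
    - {id: "UniProt:P4", label: Gene, name: gene four}
    - {id: "MESH:E3", label: Disease, name: disC}
  links:
    - {source: "MESH:D3", target: "UniProt:P4", key: inhibits}
    - {source: "UniProt:P4", target: "MESH:E3", key: causes}
'
}

test_that("gene filter keeps exactly single-gene paths with unique symbol resolution", {
  paths <- parse_drugmechdb(make_gene_path_doc())
  resolver <- gene_resolver(list(
    "UniProt:P1" = "GEN1",
    "UniProt:P2" = "GEN2", "UniProt:P3" = "GEN3",
    "UniProt:P4" = c("GEN4A", "GEN4B")))
  sel <- select_gene_paths(paths, resolver)
  expect_equal(sel$path_id, "one-gene")
  expect_equal(sel$hgnc_symbol, "GEN1")

  # unknown curie resolves to zero symbols -> excluded
  sel0 <- select_gene_paths(paths, gene_resolver(list()))
  expect_equal(nrow(sel0), 0L)

  # label set is configurable: counting only Gene labels makes the
  # two-gene path single-gene
  sel_gene_only <- select_gene_paths(paths, resolver, gene_labels = "Gene")
  expect_setequal(sel_gene_only$path_id, c("one-gene", "two-genes"))

  # bundled synthetic mapping table loads as a resolver
  bundled <- read_gene_map(system.file("extdata", "synthetic_gene_map.tsv",
                                       package = "mechrag"))
  expect_equal(bundled("NCBIGene:7124"), "TNF")
  expect_length(bundled("UniProt:AMB001"), 2L)
  expect_length(bundled("UNKNOWN:1"), 0L)
})

test_that("metabolite filter applies taxonomic, multiplicity, and CHEBI rules", {
  doc <- '
- graph: {_id: good}
  nodes:
    - {id: "MESH:D1", label: Drug, name: drugA}
    - {id: "CHEBI:11", label: ChemicalSubstance, name: metA}
    - {id: "MESH:E1", label: Disease, name: disA}
  links:
    - {source: "MESH:D1", target: "CHEBI:11", key: increases abundance of}
    - {source: "CHEBI:11", target: "MESH:E1", key: negatively regulates}
- graph: {_id: taxo}
  nodes:
    - {id: "MESH:D2", label: Drug, name: drugB}
    - {id: "CHEBI:12", label: ChemicalSubstance, name: metB}
    - {id: "MESH:E2", label: Disease, name: disB}
  links:
    - {source: "MESH:D2", target: "CHEBI:12", key: subclass of}
    - {source: "CHEBI:12", target: "MESH:E2", key: subclass of}
- graph: {_id: multi-1}
  nodes:
    - {id: "MESH:D3", label: Drug, name: drugC}
    - {id: "CHEBI:13", label: ChemicalSubstance, name: metC}
    - {id: "MESH:E3", label: Disease, name: disC}
  links:
    - {source: "MESH:D3", target: "CHEBI:13", key: increases abundance of}
    - {source: "CHEBI:13", target: "MESH:E3", key: negatively regulates}
- graph: {_id: multi-2}
  nodes:
    - {id: "MESH:D3", label: Drug, name: drugC}
    - {id: "CHEBI:14", label: ChemicalSubstance, name: metD}
    - {id: "MESH:E3", label: Disease, name: disC}
  links:
    - {source: "MESH:D3", target: "CHEBI:14", key: increases abundance of}
    - {source: "CHEBI:14", target: "MESH:E3", key: negatively regulates}
'
  paths <- parse_drugmechdb(doc)
  sel <- select_metabolite_paths(paths)
  expect_equal(sel$path_id, "good")
  expect_equal(sel$metabolite_curie, "CHEBI:11")
})

test_that("drug filter requires one biological process and a resolvable drug id", {
  doc <- '
- graph: {_id: good-db}
  nodes:
    - {id: "DB01234", label: Drug, name: drugA}
    - {id: "GO:1", label: BiologicalProcess, name: procA}
    - {id: "MESH:E1", label: Disease, name: disA}
  links:
    - {source: "DB01234", target: "GO:1", key: positively regulates}
    - {source: "GO:1", target: "MESH:E1", key: prevents}
- graph: {_id: no-process}
  nodes:
    - {id: "MESH:D2", label: Drug, name: drugB}
    - {id: "MESH:E2", label: Disease, name: disB}
  links:
    - {source: "MESH:D2", target: "MESH:E2", key: treats}
- graph: {_id: bad-prefix}
  nodes:
    - {id: "UNII:XYZ", label: Drug, name: drugC}
    - {id: "GO:2", label: BiologicalProcess, name: procC}
    - {id: "MESH:E3", label: Disease, name: disC}
  links:
    - {source: "UNII:XYZ", target: "GO:2", key: positively regulates}
    - {source: "GO:2", target: "MESH:E3", key: prevents}
'
  paths <- parse_drugmechdb(doc)
  sel <- select_drug_paths(paths)
  expect_equal(sel$path_id, "good-db")
  expect_equal(sel$process_name, "procA")
})

test_that("question templates render exactly, with quoted entity names", {
  expect_equal(
    render_question("gene", "Metformin", "Type 2 diabetes"),
    paste0("Which gene plays the most significant mechanistic role in how ",
           "Drug \"Metformin\" treats or impacts Disease \"Type 2 diabetes\"?"))
  expect_equal(
    render_question("metabolite", "Aspirin", "Fever"),
    paste0("Which biochemical entity is affected by Drug \"Aspirin\" via ",
           "its mechanism of action in treating Disease \"Fever\"?"))
  expect_equal(
    render_question("drug", disease_name = "Asthma",
                    process_name = "bronchodilation"),
    paste0("Which drug can be used in the treatment of Disease \"Asthma\" ",
           "by targeting Biological Process \"bronchodilation\"?"))
  expect_error(render_question("drug", disease_name = "Asthma"), "process")
  expect_error(render_question("gene", disease_name = "X"), "drug")
})

test_that("deduplication merges case-variant items and matches the set oracle", {
  items <- make_items(6)
  dup <- items[1, ]
  dup$drug_name <- toupper(dup$drug_name)
  dup$source_path_ids <- list("path-extra")
  items2 <- dplyr::bind_rows(items, dup)
  out <- deduplicate_items(items2)
  expect_equal(nrow(out), 6L)
  expect_setequal(out$source_path_ids[[1]], c("path-0001", "path-extra"))

  # differing gold answers are distinct keys
  dup2 <- items[2, ]
  dup2$gold_answer <- "OTHER"
  out2 <- deduplicate_items(dplyr::bind_rows(items, dup2))
  expect_equal(nrow(out2), 7L)

  # brute-force oracle on planted duplicate groups
  set.seed(42)
  for (rep_i in 1:20) {
    n <- sample(3:10, 1)
    base <- make_items(n)
    extra_idx <- sample(n, sample(0:n, 1), replace = TRUE)
    pool <- dplyr::bind_rows(base, base[extra_idx, ])
    pool <- pool[sample(nrow(pool)), ]
    key <- paste(tolower(pool$drug_name), tolower(pool$disease_name),
                 tolower(pool$gold_answer))
    expect_equal(nrow(deduplicate_items(pool)), length(unique(key)))
  }
})

test_that("build_benchmark composes filters, templates, ids, and is deterministic", {
  cfg <- fixture_config(seed = 5, n_paths = 15, eligible_gene = 3,
                        eligible_metabolite = 2, eligible_drug = 4)
  fix <- generate_mini_drugmechdb(cfg)
  paths <- parse_drugmechdb(fix$document)
  resolver <- gene_resolver(fix$truth$gene_map)
  bg <- build_benchmark("gene", paths, resolver)
  bm <- build_benchmark("metabolite", paths)
  bd <- build_benchmark("drug", paths)
  expect_equal(nrow(bg), 3L)
  expect_equal(nrow(bm), 2L)
  expect_equal(nrow(bd), 4L)
  expect_equal(bg$item_id, sprintf("gene-%04d", 1:3))
  expect_true(all(grepl("^[A-Z0-9-]+$", bg$gold_answer)))
  expect_true(all(startsWith(bm$gold_curie, "CHEBI:")))
  expect_true(all(!is.na(bd$process_curie)))
  expect_identical(bg, build_benchmark("gene", paths, resolver))
  expect_equal(nrow(build_benchmark("gene", parse_drugmechdb(list()),
                                    resolver)), 0L)

  # regeneration equality: stored question re-renders from stored entities
  expect_equal(bg$question,
               render_question("gene", bg$drug_name, bg$disease_name))
  expect_equal(bd$question,
               render_question("drug", disease_name = bd$disease_name,
                               process_name = bd$process_name))
})

test_that("benchmark filters are idempotent and monotone under path removal", {
  fix <- generate_mini_drugmechdb(fixture_config(seed = 9, n_paths = 16,
                                                 eligible_gene = 4,
                                                 eligible_metabolite = 3,
                                                 eligible_drug = 3))
  paths <- parse_drugmechdb(fix$document)
  resolver <- gene_resolver(fix$truth$gene_map)

  sel_g <- select_gene_paths(paths, resolver)
  again <- select_gene_paths(sel_g[names(paths)], resolver)
  expect_equal(again$path_id, sel_g$path_id)
  sel_d <- select_drug_paths(paths)
  expect_equal(select_drug_paths(sel_d[names(paths)])$path_id, sel_d$path_id)
  # metabolite filter re-applied to its own output keeps the same set (each
  # retained path is its indication's only record)
  sel_m <- select_metabolite_paths(paths)
  expect_equal(select_metabolite_paths(sel_m[names(paths)])$path_id,
               sel_m$path_id)

  # removing any one path never adds items to the gene or drug benchmarks;
  # the metabolite filter is monotone as long as the removal does not break
  # up a multi-path indication (deleting one of two records sharing an
  # indication legitimately promotes the survivor under the
  # single-record-per-indication rule)
  full_sizes <- c(nrow(build_benchmark("gene", paths, resolver)),
                  nrow(build_benchmark("drug", paths)))
  indication <- paste(paths$drug_curie, paths$disease_curie)
  for (i in seq_len(nrow(paths))) {
    reduced <- paths[-i, ]
    sizes <- c(nrow(build_benchmark("gene", reduced, resolver)),
               nrow(build_benchmark("drug", reduced)))
    expect_true(all(sizes <= full_sizes))
    if (sum(indication == indication[i]) == 1L) {
      expect_lte(nrow(build_benchmark("metabolite", reduced)),
                 nrow(build_benchmark("metabolite", paths)))
    }
  }
})

test_that("benchmarks survive a JSONL write-read round trip", {
  fix <- generate_mini_drugmechdb(fixture_config(seed = 3, n_paths = 12))
  paths <- parse_drugmechdb(fix$document)
  items <- build_benchmark("gene", paths,
                           gene_resolver(fix$truth$gene_map))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_benchmark(items, path)
  back <- read_benchmark(path)
  expect_equal(back$item_id, items$item_id)
  expect_equal(back$question, items$question)
  expect_equal(back$gold_answer, items$gold_answer)
  expect_equal(back$source_path_ids, items$source_path_ids)
})
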