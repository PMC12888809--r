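default_prompt_registry <- function() {
  json_rule <- paste0(
    "Respond only with a JSON object of the form {\"answer\": \"<answer>\"} ",
    "and no other text.")
  rag_rule <- paste0(
    "You are given context statements derived from a biomedical knowledge ",
    "graph, each with its source. Use them as mechanistic evidence when ",
    "answering. ")
  list(
    gene.llm_only = paste0(
      "You are a biomedical expert. Answer with the single human gene ",
      "(official HGNC symbol) that plays the most significant mechanistic ",
      "role in the drug-disease relationship asked about. ", json_rule),
    gene.rag = paste0(
      "You are a biomedical expert. ", rag_rule,
      "Answer with the single human gene (official HGNC symbol) that plays ",
      "the most significant mechanistic role in the drug-disease ",
      "relationship asked about. ", json_rule),
    metabolite.llm_only = paste0(
      "You are a biomedical expert. Answer with the single biochemical ",
      "entity (metabolite) affected by the drug's mechanism of action in ",
      "treating the disease asked about. ", json_rule),
    metabolite.rag = paste0(
      "You are a biomedical expert. ", rag_rule,
      "Answer with the single biochemical entity (metabolite) affected by ",
      "the drug's mechanism of action in treating the disease asked ",
      "about. ", json_rule),
    drug.llm_only = paste0(
      "You are a biomedical expert. Answer with the single drug that can ",
      "treat the disease by targeting the biological process asked ",
      "about. ", json_rule),
    drug.rag = paste0(
      "You are a biomedical expert. ", rag_rule,
      "Answer with the single drug that can treat the disease by targeting ",
      "the biological process asked about. ", json_rule))
}

#' Assemble the prompt for one benchmark item
#'
#' In `rag` mode the user text is the retained context statements (one per
#' line, retained order), a blank line, then the question; in `llm_only` mode
#' it is the question alone. The system prompt is selected from the prompt
#' registry by (benchmark, mode) and instructs a structured single-key JSON
#' response.
#'
#' @param item One benchmark item (single-row tibble or list).
#' @param statements Scored statement tibble (rag mode); only rows with
#'   `retained = TRUE` enter the prompt. May be `NULL` in `llm_only` mode.
#' @param mode `"llm_only"` or `"rag"`.
#' @param registry Named list of system prompts keyed `"<benchmark>.<mode>"`;
#'   entries override the built-in defaults.
#' @return A `prompt_bundle` list: `system_text`, `user_text`, `mode`,
#'   `benchmark`, `context_statement_count`.
#' @export
assemble_qa_prompt <- function(item, statements = NULL,
                               mode = c("llm_only", "rag"),
                               registry = NULL) {
  mode <- match.arg(mode)
  if (is.data.frame(item)) {
    stopifnot(nrow(item) == 1L)
    item <- as.list(item)
  }
  reg <- default_prompt_registry()
  if (!is.null(registry)) reg[names(registry)] <- registry
  key <- paste(item$benchmark, mode, sep = ".")
  system_text <- reg[[key]]
  if (is.null(system_text)) {
    stop_mechrag(sprintf("no system prompt registered for '%s'", key))
  }
  if (mode == "rag") {
    if (is.null(statements)) {
      stop_mechrag("rag mode requires a statements tibble (possibly empty)")
    }
    lines <- statements$sentence[statements$retained %||%
                                   rep(TRUE, nrow(statements))]
    user_text <- if (length(lines) > 0L) {
      paste0(paste(lines, collapse = "\n"), "\n\n", item$question)
    } else {
      item$question
    }
    n_ctx <- length(lines)
  } else {
    user_text <- item$question
    n_ctx <- 0L
  }
  structure(list(system_text = system_text, user_text = user_text,
                 mode = mode, benchmark = item$benchmark,
                 context_statement_count = as.integer(n_ctx)),
            class = "prompt_bundle")
}

#' Assemble the zero-shot entity-extraction prompt
#'
#' Builds a prompt instructing extraction of the drug, disease, and
#' biological-process mentions from a free-text question as a structured JSON
#' object with exactly those three keys (`null` for absent entities). No
#' examples are included (zero-shot).
#'
#' @param free_text_question Non-empty question text.
#' @return A `prompt_bundle` with `mode = "extraction"`.
#' @export
assemble_extraction_prompt <- function(free_text_question) {
  if (!is_scalar_chr(free_text_question) || !nzchar(free_text_question)) {
    stop_mechrag("the question must be a non-empty string")
  }
  system_text <- paste0(
    "You are a biomedical named-entity extractor. Identify the drug, the ",
    "disease, and the biological process mentioned in the user's question. ",
    "Respond only with a JSON object with exactly the keys \"drug\", ",
    "\"disease\", and \"biological_process\"; use null for any entity not ",
    "mentioned. No other text.")
  structure(list(system_text = system_text,
                 user_text = free_text_question,
                 mode = "extraction", benchmark = NA_character_,
                 context_statement_count = 0L),
            class = "prompt_bundle")
}

first_balanced_object <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L; start <- NA_integer_; in_str <- FALSE; esc <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (in_str) {
      if (esc) esc <- FALSE
      else if (ch == "\\") esc <- TRUE
      else if (ch == "\"") in_str <- FALSE
      next
    }
    if (ch == "\"" && depth > 0L) in_str <- TRUE
    else if (ch == "{") {
      if (depth == 0L) start <- i
      depth <- depth + 1L
    } else if (ch == "}") {
      if (depth > 0L) {
        depth <- depth - 1L
        if (depth == 0L) return(substr(text, start, i))
      }
    }
  }
  NA_character_
}

#' Parse a structured model answer
#'
#' Tries a direct JSON parse of the raw response for an object carrying
#' `expected_key`; failing that, a repair pass strips code fences, takes the
#' first balanced `{...}` substring, and parses that. The extracted value is
#' coerced to a trimmed string. Never raises: failures are encoded in
#' `parse_status`.
#'
#' @param raw_text Raw model response text (may be anything).
#' @param expected_key Key holding the answer (default `"answer"`).
#' @return List with `answer` (string or `NA`) and `parse_status`
#'   (`"ok"`, `"repaired"`, or `"failed"`).
#' @export
parse_structured_answer <- function(raw_text, expected_key = "answer") {
  fail <- list(answer = NA_character_, parse_status = "failed")
  if (!is_scalar_chr(raw_text)) return(fail)
  extract <- function(txt) {
    obj <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                    error = function(e) NULL)
    if (is.list(obj) && !is.null(obj[[expected_key]])) {
      val <- obj[[expected_key]]
      if (is.atomic(val) && length(val) == 1L && !is.na(val)) {
        return(trimws(as.character(val)))
      }
    }
    NULL
  }
  direct <- extract(raw_text)
  if (!is.null(direct)) {
    return(list(answer = direct, parse_status = "ok"))
  }
  repaired_text <- gsub("```[a-zA-Z]*", "", raw_text)
  candidate <- first_balanced_object(repaired_text)
  if (!is.na(candidate)) {
    rep_val <- extract(candidate)
    if (!is.null(rep_val)) {
      return(list(answer = rep_val, parse_status = "repaired"))
    }
  }
  fail
}

#' Run a benchmark through a generation backend
#'
#' Produces one model answer per item: the item's prompt is assembled for
#' `mode`, sent to `backend`, and the raw response parsed into a structured
#' answer. Backends are called as `backend(system_text, user_text, config)`
#' with `config$temperature = 0` and `config$meta` carrying the item id and
#' mode; with a deterministic backend the run is bit-reproducible.
#'
#' @param items Benchmark tibble from [build_benchmark()].
#' @param backend Generation backend, e.g. [scripted_llm()].
#' @param mode `"llm_only"` or `"rag"`.
#' @param contexts For `rag` mode, a named list of scored statement tibbles
#'   keyed by `item_id` (missing entries mean empty context).
#' @param model Model identifier string recorded in the config.
#' @param registry Optional prompt-registry overrides.
#' @param expected_key Answer key in the structured response.
#' @param fail_fast If `FALSE` (default) a backend error marks the item
#'   `parse_status = "failed"` and the run continues.
#' @return Tibble of model answers: `item_id`, `mode`, `raw_text`, `answer`,
#'   `parse_status`, in item order.
#' @export
run_benchmark <- function(items, backend, mode = c("llm_only", "rag"),
                          contexts = NULL, model = "scripted",
                          registry = NULL, expected_key = "answer",
                          fail_fast = FALSE) {
  mode <- match.arg(mode)
  stopifnot(is.function(backend))
  rows <- map(seq_len(nrow(items)), function(i) {
    item <- items[i, ]
    stmts <- if (mode == "rag") {
      contexts[[item$item_id]] %||%
        tibble(sentence = character(), retained = logical())
    } else NULL
    bundle <- assemble_qa_prompt(item, stmts, mode, registry)
    config <- list(temperature = 0, model = model,
                   meta = list(item_id = item$item_id, mode = mode))
    raw <- tryCatch(backend(bundle$system_text, bundle$user_text, config),
                    error = function(e) e)
    if (inherits(raw, "error")) {
      if (fail_fast) stop(raw)
      return(tibble(item_id = item$item_id, mode = mode,
                    raw_text = paste0("<backend error: ",
                                      conditionMessage(raw), ">"),
                    answer = NA_character_, parse_status = "failed"))
    }
    parsed <- parse_structured_answer(raw, expected_key)
    tibble(item_id = item$item_id, mode = mode, raw_text = raw,
           answer = parsed$answer, parse_status = parsed$parse_status)
  })
  bind_rows(rows)
}
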