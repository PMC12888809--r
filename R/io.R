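benchmark_fields <- c("item_id", "benchmark", "question", "drug_curie",
                      "drug_name", "disease_curie", "disease_name",
                      "process_curie", "process_name", "gold_answer",
                      "gold_curie", "source_path_ids")
answer_fields <- c("item_id", "mode", "raw_text", "answer", "parse_status")

row_to_json <- function(row, fields, array_fields = character(0)) {
  obj <- list()
  for (f in fields) {
    val <- row[[f]]
    if (f %in% array_fields) {
      obj[[f]] <- as.list(unlist(val))
    } else {
      obj[[f]] <- if (is.null(val) || (length(val) == 1L && is.na(val)))
        NULL else val
    }
  }
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null",
                                digits = NA))
}

write_jsonl <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Write a benchmark to JSON Lines
#'
#' One item per line, UTF-8, keys in fixed order; byte-stable for equal
#' inputs.
#'
#' @param items Benchmark tibble from [build_benchmark()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_benchmark <- function(items, path) {
  lines <- map_chr(seq_len(nrow(items)), function(i) {
    row_to_json(as.list(items[i, ]), benchmark_fields,
                array_fields = "source_path_ids")
  })
  write_jsonl(lines, path)
}

#' Read a benchmark from JSON Lines
#'
#' @param path File written by [write_benchmark()].
#' @return Benchmark tibble.
#' @export
read_benchmark <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) == 0L) return(empty_benchmark("gene"))
  rows <- map(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    vals <- lapply(benchmark_fields, function(f) {
      if (f == "source_path_ids") return(NULL)
      v <- obj[[f]]
      if (is.null(v)) NA_character_ else as.character(v)
    })
    names(vals) <- benchmark_fields
    vals$source_path_ids <- NULL
    row <- as_tibble(vals[!vapply(vals, is.null, logical(1))])
    row$source_path_ids <- list(as.character(unlist(obj$source_path_ids)))
    row
  })
  bind_rows(rows)
}

#' Write model answers to JSON Lines
#'
#' @param answers Tibble from [run_benchmark()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_answers <- function(answers, path) {
  lines <- map_chr(seq_len(nrow(answers)), function(i) {
    row_to_json(as.list(answers[i, ]), answer_fields)
  })
  write_jsonl(lines, path)
}

#' Read model answers from JSON Lines
#'
#' @param path File written by [write_answers()].
#' @return Answer tibble.
#' @export
read_answers <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  rows <- map(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    vals <- lapply(answer_fields, function(f) {
      v <- obj[[f]]
      if (is.null(v)) NA_character_ else as.character(v)
    })
    names(vals) <- answer_fields
    as_tibble(vals)
  })
  bind_rows(rows)
}
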