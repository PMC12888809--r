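#' @importFrom rlang abort warn %||% .data
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   bind_rows left_join row_number n distinct pull rename across all_of
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_chr map_int map_lgl map_dbl map2 pmap imap keep
#' @importFrom stats pbinom pchisq pnorm qnorm quantile
#' @importFrom utils head tail
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Recursively sort list names so that serialization is canonical.
sort_keys <- function(x) {
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm) && all(nzchar(nm))) x <- x[order(nm)]
    lapply(x, sort_keys)
  } else {
    x
  }
}

#' Canonical JSON serialization
#'
#' Serializes an R list to JSON with recursively sorted object keys and no
#' insignificant whitespace, so that structurally equal documents are
#' byte-equal. Used for request hashing and cache keys.
#'
#' @param x A list (typically a TRAPI request document).
#' @return A single JSON string.
#' @export
canonical_json <- function(x) {
  as.character(jsonlite::toJSON(sort_keys(x), auto_unbox = TRUE, null = "null",
                                digits = NA))
}

# Rough token estimate used for context budgeting: ceil(characters / 4).
estimate_tokens <- function(text) {
  as.integer(ceiling(nchar(text, type = "chars") / 4))
}

is_scalar_chr <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

stop_mechrag <- function(msg, class = "mechrag_error") {
  abort(msg, class = class)
}
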