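#' Render a name list as a numbered ranked list
#'
#' The structured output contract used for training targets and simulated
#' responses: one name per line, numbered `1.`, `2.`, ...
#'
#' @param names Character vector of names (no embedded newlines).
#' @return A single string.
#' @export
#' @examples
#' cat(format_ranked_list(c("colon", "bile duct")))
format_ranked_list <- function(names) {
  stopifnot(is.character(names))
  paste0(seq_along(names), ". ", names, collapse = "\n")
}

#' Parse a ranked list out of free response text
#'
#' Extracts numbered entries from a model's answer. Accepted bullet styles:
#' `1. name`, `2) name`, `(3) name`, and `- name`; lines that carry no
#' bullet are ignored. Numbering and surrounding whitespace are stripped;
#' order is preserved. Parsing never raises: an answer with no recognizable
#' entries yields `parse_ok = FALSE`.
#'
#' @param text Response text (character scalar; `NA` treated as empty).
#' @param expected_len If given, entries beyond this count are truncated and
#'   the result flagged with `truncated = TRUE`.
#' @return A `parsed_response` list: `names` (character vector), `parse_ok`,
#'   `truncated`.
#' @export
parse_ranked_list <- function(text, expected_len = NULL) {
  if (length(text) != 1 || is.na(text)) text <- ""
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  bullet <- "^\\s*(?:\\(?[0-9]+[.)]|-)\\s+"
  hit <- grepl(bullet, lines)
  names <- trimws(sub(bullet, "", lines[hit]))
  names <- names[nzchar(names)]
  truncated <- FALSE
  if (!is.null(expected_len) && length(names) > expected_len) {
    warning("response has ", length(names), " entries; truncating to ",
      expected_len,
      call. = FALSE
    )
    names <- names[seq_len(expected_len)]
    truncated <- TRUE
  }
  structure(
    list(names = names, parse_ok = length(names) > 0, truncated = truncated),
    class = "parsed_response"
  )
}

#' Read free-text responses from JSONL
#'
#' One object per line: `{id, text}`.
#'
#' @param path Path to a `.jsonl` file.
#' @return Named character vector: sample id -> response text.
#' @export
read_responses <- function(path) {
  objs <- read_jsonl(path)
  stats::setNames(
    vapply(objs, function(o) as.character(o$text), character(1)),
    vapply(objs, function(o) as.character(o$id), character(1))
  )
}
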