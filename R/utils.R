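#' Normalize a label string for lookup and matching
#'
#' Applies the package-wide canonical normal form used both for label-space
#' lookups and for fuzzy similarity: case-fold, trim leading/trailing
#' whitespace, collapse internal whitespace runs to a single space, and strip
#' trailing periods.
#'
#' @param x Character vector.
#' @return Character vector of the same length in normal form.
#' @export
#' @examples
#' normalize_label(c("  Colon ", "Bile   Duct."))
normalize_label <- function(x) {
  stopifnot(is.character(x))
  x <- tolower(x)
  x <- gsub("\\s+", " ", x)
  x <- sub("^ ", "", x)
  x <- sub(" $", "", x)
  x <- sub("\\.+$", "", x)
  x
}

#' Read a JSON-lines file
#'
#' One JSON object per line; blank lines are skipped. Returns a list of
#' parsed objects (each a named list), preserving line order.
#'
#' @param path Path to a `.jsonl` file.
#' @return List of named lists.
#' @export
read_jsonl <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
}

#' Write a list of records as JSON lines
#'
#' @param records List of named lists (one object per line).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_jsonl <- function(records, path) {
  lines <- vapply(
    records,
    function(r) jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA, null = "null"),
    character(1)
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# numerically stable -log(sigmoid(x)) = softplus(-x) = log1p(exp(-x))
log_sigmoid_neg <- function(x) {
  # softplus(-x); branch avoids overflow of exp for large |x|
  ifelse(x > 0, log1p(exp(-x)), -x + log1p(exp(x)))
}
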