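#' Construct a label space
#'
#' A label space is the closed vocabulary of candidate labels (disease names,
#' tissue types, ...) that an upstream classifier ranks and against which
#' free-text responses are graded. Each entry has a canonical name, an
#' optional abbreviation, and a stable integer `label_id` equal to its
#' position (0-based) in the input order.
#'
#' @param canonical_name Character vector of canonical label names.
#' @param abbreviation Optional character vector of abbreviations; `NA` or
#'   `""` mean absent. Recycled `NA` if omitted.
#' @return An object of class `label_space`: a tibble with columns
#'   `label_id`, `canonical_name`, `abbreviation`, `normalized`.
#' @export
#' @examples
#' label_space(c("bile duct", "colon", "liver"))
label_space <- function(canonical_name, abbreviation = NULL) {
  stopifnot(is.character(canonical_name))
  if (is.null(abbreviation)) abbreviation <- rep(NA_character_, length(canonical_name))
  abbreviation <- as.character(abbreviation)
  abbreviation[!is.na(abbreviation) & !nzchar(trimws(abbreviation))] <- NA_character_
  if (length(abbreviation) != length(canonical_name)) {
    stop("abbreviation must have the same length as canonical_name", call. = FALSE)
  }
  if (length(canonical_name) < 2) {
    stop("a label space needs at least 2 labels", call. = FALSE)
  }
  if (any(!nzchar(trimws(canonical_name)))) {
    stop("canonical names must be non-empty", call. = FALSE)
  }
  norm <- normalize_label(canonical_name)
  if (anyDuplicated(norm)) {
    dup <- canonical_name[duplicated(norm)][1]
    stop("duplicate canonical name after normalization: '", dup, "'", call. = FALSE)
  }
  ab_norm <- normalize_label(ifelse(is.na(abbreviation), "", abbreviation))
  ab_present <- nzchar(ab_norm)
  if (anyDuplicated(ab_norm[ab_present])) {
    dup <- abbreviation[ab_present][duplicated(ab_norm[ab_present])][1]
    stop("abbreviation maps to more than one entry: '", dup, "'", call. = FALSE)
  }
  out <- tibble::tibble(
    label_id = seq_along(canonical_name) - 1L,
    canonical_name = canonical_name,
    abbreviation = abbreviation,
    normalized = norm
  )
  class(out) <- c("label_space", class(out))
  out
}

#' @export
print.label_space <- function(x, ...) {
  cat("<label_space> ", nrow(x), " labels, ",
    sum(!is.na(x$abbreviation)), " with abbreviations\n",
    sep = ""
  )
  NextMethod()
}

#' Read a label space from a TSV file
#'
#' Expects a UTF-8, tab-separated file with a header row and columns
#' `canonical_name` and (optionally) `abbreviation`; an empty abbreviation
#' cell means absent. Row order determines `label_id`.
#'
#' @param path Path to a `.tsv` file.
#' @return A [label_space()].
#' @export
read_label_space <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path,
    sep = "\t", header = TRUE, quote = "",
    colClasses = "character", encoding = "UTF-8",
    check.names = FALSE
  )
  if (!"canonical_name" %in% names(df)) {
    stop("label TSV must have a 'canonical_name' column", call. = FALSE)
  }
  if (nrow(df) < 2) {
    stop("label TSV must have at least 2 data rows", call. = FALSE)
  }
  ab <- if ("abbreviation" %in% names(df)) df$abbreviation else NULL
  label_space(df$canonical_name, ab)
}

#' Write a label space to a TSV file
#'
#' Inverse of [read_label_space()]: `read_label_space(write_label_space(ls))`
#' reproduces the entries in order.
#'
#' @param space A [label_space()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_space <- function(space, path) {
  stopifnot(inherits(space, "label_space"))
  ab <- ifelse(is.na(space$abbreviation), "", space$abbreviation)
  lines <- c(
    "canonical_name\tabbreviation",
    paste0(space$canonical_name, "\t", ab)
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Look up a label-space entry by name
#'
#' Exact lookup in the normalized index (canonical names and abbreviations).
#'
#' @param space A [label_space()].
#' @param name Character scalar.
#' @return A one-row tibble (the entry), or `NULL` if absent.
#' @export
lookup_label <- function(space, name) {
  stopifnot(inherits(space, "label_space"), is.character(name), length(name) == 1)
  nn <- normalize_label(name)
  i <- match(nn, space$normalized)
  if (is.na(i)) {
    ab <- normalize_label(ifelse(is.na(space$abbreviation), "", space$abbreviation))
    i <- match(nn, ifelse(nzchar(ab), ab, NA_character_))
  }
  if (is.na(i)) NULL else space[i, ]
}

has_label <- function(space, name) !is.null(lookup_label(space, name))
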