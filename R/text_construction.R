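#' Read a phenotype-term dictionary from TSV
#'
#' A term dictionary maps phenotype-term identifiers (e.g. HPO ids such as
#' `HP:0000486`) to their human-readable term text. The file is tab-separated
#' with a header row and columns `term_id` and `term_text`.
#'
#' @param path Path to a `.tsv` file.
#' @return A named character vector: `term_id -> term_text`.
#' @export
read_term_dictionary <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path,
    sep = "\t", header = TRUE, quote = "",
    colClasses = "character", encoding = "UTF-8"
  )
  if (!all(c("term_id", "term_text") %in% names(df))) {
    stop("term dictionary TSV needs columns term_id, term_text", call. = FALSE)
  }
  term_dictionary(stats::setNames(df$term_text, df$term_id))
}

#' Validate a term dictionary
#'
#' @param mapping Named character vector, `term_id -> term_text`.
#' @return The validated mapping.
#' @export
term_dictionary <- function(mapping) {
  stopifnot(is.character(mapping), !is.null(names(mapping)))
  if (anyDuplicated(names(mapping))) {
    stop("duplicate term ids: ", names(mapping)[duplicated(names(mapping))][1],
      call. = FALSE
    )
  }
  if (any(!nzchar(mapping))) {
    stop("empty term text for id: ", names(mapping)[!nzchar(mapping)][1],
      call. = FALSE
    )
  }
  mapping
}

#' Render phenotype-term ids as clinical text
#'
#' Looks each id up in the dictionary and joins the term texts with `", "`,
#' preserving input order and the dictionary's casing. This is the standard
#' transformation from a structured phenotype-id list to the free-text
#' phenotype description used in prompts.
#'
#' @param ids Character vector of term ids (non-empty).
#' @param dict A [term_dictionary()].
#' @return A single string.
#' @export
#' @examples
#' d <- term_dictionary(c("HP:1" = "Strabismus", "HP:2" = "Seizure"))
#' hpo_terms_to_text(c("HP:1", "HP:2"), d)
hpo_terms_to_text <- function(ids, dict) {
  stopifnot(is.character(ids))
  if (length(ids) == 0) stop("at least one term id is required", call. = FALSE)
  missing <- setdiff(ids, names(dict))
  if (length(missing) > 0) {
    stop("unknown term id(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  paste(unname(dict[ids]), collapse = ", ")
}

#' Default demographic sentence template
#'
#' Fields appear in the order sex, age, ethnicity. `{sex}`, `{age}`,
#' `{ethnicity}` and `{phenotypes}` are substituted; the template is a plain
#' string so callers can supply their own ordering or phrasing.
#' @export
default_prompt_template <-
  "The patient is a {age} {ethnicity} {sex} with the following clinical features: {phenotypes}"

#' Build a patient prompt from a structured record
#'
#' Renders the demographic fields and the phenotype-term texts into a single
#' prompt string. Empty demographic fields are dropped without leaving
#' dangling whitespace; if all demographics are empty only the phenotype text
#' is returned. Deterministic for fixed inputs.
#'
#' @param record Named list with fields `age`, `sex`, `ethnicity` (character,
#'   possibly empty) and `hpo_ids` (character vector of term ids).
#' @param dict A [term_dictionary()].
#' @param template Template string; see [default_prompt_template].
#' @return A single prompt string.
#' @export
format_patient_prompt <- function(record, dict,
                                  template = default_prompt_template) {
  stopifnot(is.list(record), !is.null(record$hpo_ids))
  phen <- hpo_terms_to_text(as.character(record$hpo_ids), dict)
  demo <- vapply(c("age", "sex", "ethnicity"), function(f) {
    v <- record[[f]]
    if (is.null(v) || is.na(v)) "" else trimws(as.character(v))
  }, character(1))
  if (all(!nzchar(demo))) {
    return(phen)
  }
  out <- template
  out <- gsub("{age}", demo[["age"]], out, fixed = TRUE)
  out <- gsub("{sex}", demo[["sex"]], out, fixed = TRUE)
  out <- gsub("{ethnicity}", demo[["ethnicity"]], out, fixed = TRUE)
  out <- gsub("{phenotypes}", phen, out, fixed = TRUE)
  out <- gsub("\\s+", " ", out)
  trimws(out)
}

#' Read patient records from JSONL
#'
#' One object per line with keys `id`, `age`, `sex`, `ethnicity`,
#' `hpo_ids` (array), `true_label`. Each record must have at least one
#' phenotype-term id, and `true_label` must be in the label space.
#'
#' @param path Path to a `.jsonl` file.
#' @param space Optional [label_space()] used to validate `true_label`.
#' @return List of patient records (named lists).
#' @export
read_patients <- function(path, space = NULL) {
  recs <- read_jsonl(path)
  for (r in recs) {
    if (is.null(r$hpo_ids) || length(r$hpo_ids) == 0) {
      stop("patient ", r$id, " has no phenotype-term ids", call. = FALSE)
    }
    if (!is.null(space) && !has_label(space, r$true_label)) {
      stop("patient ", r$id, " true_label not in label space: ", r$true_label,
        call. = FALSE
      )
    }
  }
  recs
}
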