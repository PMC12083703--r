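#' Ratcliff/Obershelp similarity ratio
#'
#' The classic "gestalt pattern matching" ratio `2M / T`, where `M` is the
#' total length of all matching blocks found by recursively locating the
#' longest common substring (leftmost in `a`, then leftmost in `b`, on ties)
#' and `T` is the combined length of both strings. This is the sequence-
#' matcher ratio widely used for grading near-miss label names. Both inputs
#' are passed through [normalize_label()] first unless `raw = TRUE`.
#'
#' @param a,b Character scalars.
#' @param raw Skip normalization (compare byte-for-byte casing/spacing)?
#' @return Similarity in \[0, 1\]; identical strings give 1, disjoint give 0.
#' @export
#' @examples
#' similarity_ratio("colon", "colon") # 1
#' similarity_ratio("Bile Duct", "bile duct") # 1 after normalization
similarity_ratio <- function(a, b, raw = FALSE) {
  stopifnot(is.character(a), is.character(b), length(a) == 1, length(b) == 1)
  if (!raw) {
    a <- normalize_label(a)
    b <- normalize_label(b)
  }
  na <- nchar(a)
  nb <- nchar(b)
  if (na + nb == 0) return(1)
  if (na == 0 || nb == 0) return(0)
  sa <- strsplit(a, "", fixed = TRUE)[[1]]
  sb <- strsplit(b, "", fixed = TRUE)[[1]]
  m <- matching_blocks_total(sa, sb)
  2 * m / (na + nb)
}

# Total matched characters, computed iteratively with an explicit work stack.
# Each work item is a (a-range, b-range) pair; the longest common substring of
# the pair is counted and the flanking sub-ranges are pushed.
matching_blocks_total <- function(sa, sb) {
  total <- 0L
  stack <- list(c(1L, length(sa), 1L, length(sb)))
  while (length(stack) > 0) {
    w <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    alo <- w[1]; ahi <- w[2]; blo <- w[3]; bhi <- w[4]
    if (alo > ahi || blo > bhi) next
    lm <- longest_match(sa, alo, ahi, sb, blo, bhi)
    if (lm[3] == 0L) next
    total <- total + lm[3]
    stack[[length(stack) + 1L]] <- c(alo, lm[1] - 1L, blo, lm[2] - 1L)
    stack[[length(stack) + 1L]] <- c(lm[1] + lm[3], ahi, lm[2] + lm[3], bhi)
  }
  total
}

# Longest matching block within [alo,ahi] x [blo,bhi]; ties resolved toward
# the smallest start in a, then in b. Returns c(i, j, size).
longest_match <- function(sa, alo, ahi, sb, blo, bhi) {
  best_i <- alo; best_j <- blo; best_size <- 0L
  # j2len[j]: length of longest match ending at (i, j)
  j2len <- integer(bhi + 1L)
  for (i in alo:ahi) {
    new_j2len <- integer(bhi + 1L)
    hits <- which(sb[blo:bhi] == sa[i]) + blo - 1L
    for (j in hits) {
      k <- if (j > blo) j2len[j - 1L] + 1L else 1L
      new_j2len[j] <- k
      if (k > best_size) {
        best_i <- i - k + 1L
        best_j <- j - k + 1L
        best_size <- k
      }
    }
    j2len <- new_j2len
  }
  c(best_i, best_j, best_size)
}

#' Extract a parenthesized abbreviation from a candidate name
#'
#' Responses often carry the abbreviation in parentheses, e.g.
#' `"Cornelia de Lange Syndrome (CdLS)"`. Returns the stripped full form and
#' the parenthesized token (or `NA` if none).
#'
#' @param candidate Character scalar.
#' @return List with `full` (parens removed) and `abbr` (token or `NA`).
#' @export
split_abbreviation <- function(candidate) {
  m <- regmatches(candidate, regexpr("\\(([^()]*)\\)", candidate))
  abbr <- if (length(m) == 0) NA_character_ else sub("^\\((.*)\\)$", "\\1", m)
  full <- trimws(gsub("\\s*\\([^()]*\\)", "", candidate))
  if (!nzchar(full)) full <- candidate
  list(full = full, abbr = abbr)
}

#' Fuzzy-match a candidate name against a label-space entry
#'
#' Compares every relevant (candidate form x entry form) pair — the full
#' candidate against the canonical name, the candidate with any
#' parenthesized token stripped against the canonical name, and the
#' parenthesized token against the entry's abbreviation (and canonical name)
#' — and succeeds if the best similarity reaches `threshold`. This is what
#' lets `"CdLS"` match the entry for `"Cornelia de Lange Syndrome"`.
#'
#' @param candidate Free-text name from a response.
#' @param entry One row of a [label_space()] (tibble with `canonical_name`,
#'   `abbreviation`), or a list with those fields.
#' @param threshold Similarity threshold in \[0, 1\].
#' @return `TRUE` if any form pair reaches the threshold.
#' @export
match_label <- function(candidate, entry, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  parts <- split_abbreviation(candidate)
  entry_forms <- entry$canonical_name
  if (!is.null(entry$abbreviation) && !is.na(entry$abbreviation)) {
    entry_forms <- c(entry_forms, entry$abbreviation)
  }
  cand_forms <- unique(c(candidate, parts$full, if (!is.na(parts$abbr)) parts$abbr))
  best <- 0
  for (cf in cand_forms) {
    for (ef in entry_forms) {
      best <- max(best, similarity_ratio(cf, ef))
      if (best >= threshold) return(TRUE)
    }
  }
  best >= threshold
}

#' Best fuzzy match of a candidate within a label space
#'
#' @param candidate Free-text name.
#' @param space A [label_space()].
#' @param threshold Similarity threshold.
#' @return `TRUE` if any entry matches at `threshold`.
#' @export
match_any_label <- function(candidate, space, threshold) {
  for (i in seq_len(nrow(space))) {
    if (match_label(candidate, space[i, ], threshold)) return(TRUE)
  }
  FALSE
}
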