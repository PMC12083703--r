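#' Validate a ranked prediction
#'
#' An upstream classifier's output for one sample: a named probability
#' vector over labels plus the ground-truth label. Probabilities must sum to
#' 1; sums off by more than `tol` but within `renorm_tol` are renormalized
#' with a warning, and larger discrepancies are an error.
#'
#' @param sample_id Sample identifier (character scalar).
#' @param scores Named numeric vector: canonical name -> probability.
#' @param true_label Canonical name of the ground truth.
#' @param space A [label_space()].
#' @param tol Tolerance for the sum-to-one check (default `1e-6`).
#' @param renorm_tol Renormalize-with-warning band (default `1e-3`).
#' @return A `ranked_prediction` object (named list).
#' @export
ranked_prediction <- function(sample_id, scores, true_label, space,
                              tol = 1e-6, renorm_tol = 1e-3) {
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  bad <- names(scores)[!vapply(names(scores), function(n) has_label(space, n), logical(1))]
  if (length(bad) > 0) {
    stop("scored label(s) not in label space: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  if (!has_label(space, true_label)) {
    stop("true_label not in label space: ", true_label, call. = FALSE)
  }
  s <- sum(scores)
  if (abs(s - 1) > tol) {
    if (abs(s - 1) <= renorm_tol) {
      warning("probabilities for sample ", sample_id, " sum to ", format(s),
        "; renormalizing",
        call. = FALSE
      )
      scores <- scores / s
    } else {
      stop("probabilities for sample ", sample_id, " sum to ", format(s),
        " (beyond tolerance ", renorm_tol, ")",
        call. = FALSE
      )
    }
  }
  structure(
    list(sample_id = as.character(sample_id), scores = scores,
         true_label = true_label),
    class = "ranked_prediction"
  )
}

#' Rank labels by predicted probability
#'
#' Sorts the scored labels by probability, descending; ties are broken by
#' ascending `label_id` so the ordering is canonical regardless of the
#' iteration order of the input map.
#'
#' @param pred A [ranked_prediction()].
#' @param space A [label_space()].
#' @return Character vector of canonical names, best first.
#' @export
rank_labels <- function(pred, space) {
  nm <- names(pred$scores)
  ids <- vapply(nm, function(n) lookup_label(space, n)$label_id, integer(1))
  ord <- order(-pred$scores, ids)
  nm[ord]
}

#' Force the true label to the first position of a top-k slice
#'
#' Takes the top-`k` of a ranked list and guarantees the ground truth
#' occupies position 1: if it is already first, nothing changes; if it is
#' elsewhere within the top-`k`, it is swapped with position 1 (preserving
#' the set); if it is outside the top-`k`, it is inserted at position 1 and
#' the former k-th element is dropped. Relative order of the other elements
#' is preserved in all cases.
#'
#' @param ranked Character vector, best first.
#' @param truth Canonical name of the ground truth.
#' @param k Slice length (>= 1, <= length(ranked)).
#' @param space Optional [label_space()]; if given, `truth` must be in it.
#' @return Character vector of length `k` with `truth` first.
#' @export
#' @examples
#' enforce_truth_first(c("A", "B", "T", "D"), "T", 3)
enforce_truth_first <- function(ranked, truth, k, space = NULL) {
  stopifnot(k >= 1, length(ranked) >= k)
  if (!is.null(space) && !has_label(space, truth)) {
    stop("truth not in label space: ", truth, call. = FALSE)
  }
  top <- ranked[seq_len(k)]
  pos <- match(truth, top)
  if (is.na(pos)) {
    c(truth, top[seq_len(k - 1)])
  } else if (pos == 1L) {
    top
  } else {
    tmp <- top[1L]
    top[1L] <- top[pos]
    top[pos] <- tmp
    top
  }
}

#' Acceptance-over-Rejection ratio
#'
#' The AoR ratio k/q describes the balance between accepted (chosen) and
#' rejected labels in a preference record; `k = q` gives the balanced ratio 1.
#'
#' @param k Number of chosen labels.
#' @param q Number of rejected labels (>= 1).
#' @return `k / q` as a double.
#' @export
aor <- function(k, q) {
  if (q < 1) stop("q must be >= 1", call. = FALSE)
  as.numeric(k) / as.numeric(q)
}

#' Build one preference record from a ranked prediction
#'
#' The chosen list is the truth-first top-`k` ([enforce_truth_first()]); the
#' rejected list is the bottom-`q` by ascending probability, least probable
#' first. Disjointness is guaranteed: if the truth falls in the bottom-`q`
#' it is removed from the rejected list and the next-lowest label takes its
#' place.
#'
#' @param pred A [ranked_prediction()].
#' @param prompt Prompt text for the sample.
#' @param k,q Chosen / rejected list lengths (each >= 1, `k + q` at most the
#'   number of scored labels).
#' @param space A [label_space()].
#' @return A `preference_record`: named list with `sample_id`, `prompt`,
#'   `chosen`, `rejected`, `chosen_text`, `rejected_text`.
#' @export
build_preference_record <- function(pred, prompt, k, q, space) {
  n <- length(pred$scores)
  if (k < 1 || q < 1) stop("k and q must be >= 1", call. = FALSE)
  if (k + q > n) {
    stop("k + q = ", k + q, " exceeds the ", n,
      " scored labels; this AoR setting is infeasible",
      call. = FALSE
    )
  }
  ranked <- rank_labels(pred, space)
  chosen <- enforce_truth_first(ranked, pred$true_label, k, space)
  worst_first <- rev(ranked)
  pool <- setdiff(worst_first, pred$true_label) # truth never rejected
  rejected <- pool[seq_len(q)]
  structure(
    list(
      sample_id = pred$sample_id,
      prompt = prompt,
      chosen = chosen,
      rejected = rejected,
      chosen_text = format_ranked_list(chosen),
      rejected_text = format_ranked_list(rejected)
    ),
    class = "preference_record"
  )
}

#' Build an SFT record from a ranked prediction
#'
#' A supervised fine-tuning record: the prompt plus a target text naming the
#' true label exactly once.
#'
#' @param pred A [ranked_prediction()].
#' @param prompt Prompt text.
#' @param template Target template; `{label}` is substituted.
#' @return Named list with `sample_id`, `prompt`, `target`.
#' @export
build_sft_record <- function(pred, prompt, template = "{label}") {
  target <- gsub("{label}", pred$true_label, template, fixed = TRUE)
  list(sample_id = pred$sample_id, prompt = prompt, target = target)
}

#' Build a preference dataset from a stream of ranked predictions
#'
#' One record per prediction, input order preserved. Every prediction must
#' have a prompt keyed by its sample id.
#'
#' @param preds List of [ranked_prediction()] objects.
#' @param prompts Named character vector or list: sample_id -> prompt text.
#' @param k,q Chosen / rejected lengths.
#' @param space A [label_space()].
#' @param quiet Suppress the summary message.
#' @return List of preference records.
#' @export
build_preference_dataset <- function(preds, prompts, k, q, space, quiet = FALSE) {
  records <- vector("list", length(preds))
  for (i in seq_along(preds)) {
    p <- preds[[i]]
    if (!p$sample_id %in% names(prompts)) {
      stop("no prompt for sample id: ", p$sample_id, call. = FALSE)
    }
    prompt <- prompts[[p$sample_id]]
    records[[i]] <- build_preference_record(p, prompt, k, q, space)
  }
  if (!quiet) {
    message(
      "built ", length(records), " preference records (k=", k, ", q=", q,
      ", AoR=", format(aor(k, q)), ")"
    )
  }
  records
}

#' Read ranked predictions from JSONL
#'
#' One object per line: `{id, scores: {name: prob, ...}, true_label}`.
#'
#' @param path Path to a `.jsonl` file.
#' @param space A [label_space()].
#' @param ... Passed to [ranked_prediction()].
#' @return List of [ranked_prediction()] objects.
#' @export
read_rankings <- function(path, space, ...) {
  lapply(read_jsonl(path), function(o) {
    ranked_prediction(o$id, unlist(o$scores), o$true_label, space, ...)
  })
}

#' Write ranked predictions to JSONL
#'
#' @param preds List of [ranked_prediction()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rankings <- function(preds, path) {
  write_jsonl(lapply(preds, function(p) {
    list(id = p$sample_id, scores = as.list(p$scores), true_label = p$true_label)
  }), path)
}

#' Write preference records to JSONL
#'
#' Chosen/rejected are stored both as name arrays and as the numbered-list
#' text used for training targets.
#'
#' @param records List of preference records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_preferences <- function(records, path) {
  write_jsonl(lapply(records, function(r) {
    list(
      id = r$sample_id, prompt = r$prompt,
      chosen = r$chosen, rejected = r$rejected,
      chosen_text = r$chosen_text, rejected_text = r$rejected_text
    )
  }), path)
}
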