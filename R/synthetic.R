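#' Generate a synthetic label space
#'
#' Builds `n_labels` pronounceable pseudo-names (two syllable words each) for
#' use as a stand-in disease/tissue vocabulary. Names are rejection-sampled
#' so that no two canonical names reach the strict matching threshold (0.8)
#' under [similarity_ratio()], which keeps fuzzy grading unambiguous. About
#' `abbrev_frac` of the labels get an initial-letter abbreviation (dropped
#' on collision).
#'
#' @param n_labels Number of labels (>= 2).
#' @param seed Integer seed.
#' @param abbrev_frac Fraction of labels carrying an abbreviation.
#' @return A [label_space()].
#' @export
simulate_label_space <- function(n_labels, seed = 1L, abbrev_frac = 0.3) {
  stopifnot(n_labels >= 2)
  set.seed(seed)
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  word <- function(n_syl) {
    paste0(sample(cons, n_syl, TRUE), sample(vow, n_syl, TRUE), collapse = "")
  }
  names <- character(0)
  guard <- 0L
  while (length(names) < n_labels) {
    guard <- guard + 1L
    if (guard > 50L * n_labels) {
      stop("could not generate ", n_labels, " sufficiently distinct names",
        call. = FALSE
      )
    }
    cand <- paste(word(sample(2:3, 1)), word(sample(2:3, 1)))
    ok <- all(vapply(names, function(ex) {
      similarity_ratio(cand, ex) < 0.8
    }, logical(1)))
    if (ok) names <- c(names, cand)
  }
  has_ab <- stats::runif(n_labels) < abbrev_frac
  ab <- rep(NA_character_, n_labels)
  ab[has_ab] <- toupper(vapply(strsplit(names[has_ab], " "), function(w) {
    paste0(substr(w, 1, 2), collapse = "")
  }, character(1)))
  ab[duplicated(normalize_label(ifelse(is.na(ab), paste0(" ", seq_along(ab)), ab)))] <- NA_character_
  label_space(names, ab)
}

#' Generate a synthetic phenotype-term dictionary
#'
#' One characteristic term per label ("characteristic facies of <label>")
#' plus a pool of shared background terms, with HPO-style ids. The
#' characteristic term ends with the label name so that, with the term
#' placed last in the prompt, the prompt tail identifies the label — which
#' makes the prompt -> label mapping learnable by the character-level toy
#' language model.
#'
#' @param space A [label_space()].
#' @param n_background Number of label-independent background terms.
#' @param seed Integer seed.
#' @return A list with `dict` (a [term_dictionary()]), `label_term`
#'   (named vector label -> its characteristic term id), and
#'   `background_ids`.
#' @export
simulate_term_dictionary <- function(space, n_background = 10, seed = 1L) {
  set.seed(seed)
  n <- nrow(space)
  label_ids <- sprintf("HP:9%06d", seq_len(n))
  label_terms <- paste("characteristic facies of", space$canonical_name)
  bg_ids <- sprintf("HP:1%06d", seq_len(n_background))
  bg_terms <- paste("background feature", seq_len(n_background))
  dict <- term_dictionary(stats::setNames(
    c(label_terms, bg_terms), c(label_ids, bg_ids)
  ))
  list(
    dict = dict,
    label_term = stats::setNames(label_ids, space$canonical_name),
    background_ids = bg_ids
  )
}

#' Generate synthetic patient records
#'
#' Each patient draws a true label uniformly, carries that label's
#' characteristic phenotype term plus 1-2 background terms, and gets simple
#' demographics.
#'
#' @param n_samples Number of patients.
#' @param space A [label_space()].
#' @param terms Output of [simulate_term_dictionary()].
#' @param seed Integer seed.
#' @return List of patient records (`id`, `age`, `sex`, `ethnicity`,
#'   `hpo_ids`, `true_label`).
#' @export
simulate_patients <- function(n_samples, space, terms, seed = 1L) {
  set.seed(seed)
  sexes <- c("male", "female")
  eth <- c("Caucasian", "East Asian", "African", "South Asian", "Hispanic")
  lapply(seq_len(n_samples), function(i) {
    lab <- sample(space$canonical_name, 1)
    n_bg <- sample(1:2, 1)
    bg <- sample(terms$background_ids, n_bg)
    list(
      id = sprintf("s%05d", i),
      age = paste0(sample(1:70, 1), "-year-old"),
      sex = sample(sexes, 1),
      ethnicity = sample(eth, 1),
      # characteristic term last so the prompt tail identifies the label
      hpo_ids = c(bg, unname(terms$label_term[lab])),
      true_label = lab
    )
  })
}

#' Simulate an upstream classifier of controllable accuracy
#'
#' For each sample, draws label logits from a seeded symmetric Gaussian,
#' applies a softmax at `temperature`, and then places the truth at the top
#' with probability exactly `accuracy` (otherwise a uniformly chosen other
#' label wins, by swapping its score with the current maximum). The top-1
#' hit rate over samples is therefore Binomial(n, accuracy), which is what
#' the calibration tests check.
#'
#' @param truths Named character vector: sample id -> true canonical name.
#' @param space A [label_space()].
#' @param accuracy Target top-1 probability in \[0, 1\].
#' @param temperature Softmax temperature (> 0); lower = peakier scores.
#' @param seed Integer seed.
#' @return Named list of [ranked_prediction()]s keyed by sample id.
#' @export
simulate_upstream <- function(truths, space, accuracy = 0.8,
                              temperature = 1, seed = 1L) {
  stopifnot(accuracy >= 0, accuracy <= 1, temperature > 0)
  set.seed(seed)
  n_labels <- nrow(space)
  out <- lapply(names(truths), function(id) {
    truth <- truths[[id]]
    z <- stats::rnorm(n_labels) / temperature
    p <- exp(z - max(z))
    p <- p / sum(p)
    names(p) <- space$canonical_name
    ti <- match(normalize_label(truth), space$normalized)
    winner <- if (stats::runif(1) < accuracy) {
      ti
    } else {
      sample(setdiff(seq_len(n_labels), ti), 1)
    }
    top <- which.max(p)
    if (top != winner) { # swap so the intended winner holds the max score
      tmp <- p[winner]
      p[winner] <- p[top]
      p[top] <- tmp
    }
    ranked_prediction(id, p, truth, space)
  })
  stats::setNames(out, names(truths))
}

#' Simulate free-text ranked-list responses of controllable quality
#'
#' With probability `quality` a sample's response is the truth-first
#' top-`n_top` list from its upstream prediction, rendered as a numbered
#' block; otherwise it is a random label list. Independently, with
#' probability `corruption` one entry is replaced by a corrupted name to
#' exercise the hallucination check: `"fabricate"` substitutes a gibberish
#' string, `"misspell"` perturbs characters of a real name.
#'
#' @param preds Named list of [ranked_prediction()]s.
#' @param space A [label_space()].
#' @param quality Probability of emitting the truth-first top list.
#' @param n_top Response list length.
#' @param corruption Per-sample probability of injecting a corrupted name.
#' @param corruption_mode `"fabricate"` or `"misspell"`.
#' @param seed Integer seed.
#' @return List with `responses` (named character vector id -> text) and
#'   `corrupted` (named logical flags).
#' @export
simulate_responses <- function(preds, space, quality = 1, n_top = 10,
                               corruption = 0, corruption_mode = c("fabricate", "misspell"),
                               seed = 1L) {
  corruption_mode <- match.arg(corruption_mode)
  stopifnot(quality >= 0, quality <= 1, corruption >= 0, corruption <= 1)
  set.seed(seed)
  gibberish <- function() {
    paste0(sample(c("x", "q", "z", "w", "j", "y", "h", "c"), 12, TRUE),
      collapse = ""
    )
  }
  corrupted <- logical(length(preds))
  texts <- character(length(preds))
  for (i in seq_along(preds)) {
    pred <- preds[[i]]
    names_i <- if (stats::runif(1) < quality) {
      ranked <- rank_labels(pred, space)
      enforce_truth_first(ranked, pred$true_label, n_top, space)
    } else {
      sample(space$canonical_name, n_top)
    }
    if (corruption > 0 && stats::runif(1) < corruption) {
      corrupted[i] <- TRUE
      j <- sample(length(names_i), 1)
      names_i[j] <- if (corruption_mode == "fabricate") {
        gibberish()
      } else {
        nm <- strsplit(names_i[j], "")[[1]]
        k <- sample(seq_along(nm), min(3, length(nm)))
        nm[k] <- sample(letters, length(k), TRUE)
        paste0(nm, collapse = "")
      }
    }
    texts[i] <- format_ranked_list(names_i)
  }
  list(
    responses = stats::setNames(texts, names(preds)),
    corrupted = stats::setNames(corrupted, names(preds))
  )
}

#' Write responses to JSONL
#'
#' @param responses Named character vector: id -> response text.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(responses, path) {
  write_jsonl(
    mapply(function(id, text) list(id = id, text = text),
      names(responses), responses,
      SIMPLIFY = FALSE, USE.NAMES = FALSE
    ),
    path
  )
}
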