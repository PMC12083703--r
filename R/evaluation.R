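#' Evaluation configuration
#'
#' Collects the grading knobs: `n_top` (N of Top-N; 10 for the disease task,
#' 5 for tissues), the preference-list sizes `k` and `q` used for
#' coverage/avoidance, the CAR weight `lambda`, and the two similarity
#' thresholds — a permissive 0.6 for the hallucination check (plausibility,
#' not correctness) and a strict 0.8 for Top-N/Top-1/CAR matching.
#'
#' @param n_top Length of the graded prefix for Top-N.
#' @param k,q Chosen / rejected list sizes for coverage and avoidance.
#' @param lambda Weight in the CAR harmonic mean (>= 0; 1 = plain harmonic).
#' @param hfa_threshold Similarity threshold for the hallucination check.
#' @param match_threshold Similarity threshold for truth/coverage matching.
#' @param hfa_rule How many parsed names must be plausible for a response to
#'   pass the hallucination check: `"all"` (strictest, default), `"any"`,
#'   or `"majority"`.
#' @return An `eval_config` list.
#' @export
eval_config <- function(n_top = 10, k = 10, q = 10, lambda = 1,
                        hfa_threshold = 0.6, match_threshold = 0.8,
                        hfa_rule = c("all", "any", "majority")) {
  hfa_rule <- match.arg(hfa_rule)
  stopifnot(
    n_top >= 1, k >= 1, q >= 1, lambda >= 0,
    hfa_threshold >= 0, hfa_threshold <= 1,
    match_threshold >= 0, match_threshold <= 1
  )
  if (hfa_threshold > match_threshold) {
    stop("hfa_threshold must not exceed match_threshold", call. = FALSE)
  }
  structure(
    list(
      n_top = as.integer(n_top), k = as.integer(k), q = as.integer(q),
      lambda = lambda, hfa_threshold = hfa_threshold,
      match_threshold = match_threshold, hfa_rule = hfa_rule
    ),
    class = "eval_config"
  )
}

#' Hallucination check for one parsed response
#'
#' A name is plausible when it fuzzy-matches some label-space entry at the
#' permissive threshold. Under the default `"all"` rule the response passes
#' only if it parsed and every name is plausible.
#'
#' @param resp A [parse_ranked_list()] result.
#' @param space A [label_space()].
#' @param cfg An [eval_config()].
#' @return Logical flag.
#' @export
hfa_pass <- function(resp, space, cfg) {
  if (!resp$parse_ok) return(FALSE)
  ok <- vapply(resp$names, function(n) {
    match_any_label(n, space, cfg$hfa_threshold)
  }, logical(1))
  switch(cfg$hfa_rule,
    all = all(ok),
    any = any(ok),
    majority = mean(ok) > 0.5
  )
}

#' Hallucination-free accuracy over a response set
#'
#' @param responses List of [parse_ranked_list()] results.
#' @param space A [label_space()].
#' @param cfg An [eval_config()].
#' @return List with `rate` (percent) and `pass` (per-response flags).
#' @export
hfa <- function(responses, space, cfg) {
  if (length(responses) == 0) stop("empty response set", call. = FALSE)
  pass <- vapply(responses, hfa_pass, logical(1), space = space, cfg = cfg)
  list(rate = 100 * mean(pass), pass = pass)
}

#' Does the response's graded prefix contain the truth?
#'
#' Top-N asks whether any of the first `n_top` names matches the true label
#' at the strict threshold; Top-1 asks it of the first name only.
#'
#' @param resp A [parse_ranked_list()] result.
#' @param truth_entry The label-space row for the true label.
#' @param cfg An [eval_config()].
#' @return Logical flag.
#' @export
topn_hit <- function(resp, truth_entry, cfg) {
  if (!resp$parse_ok) return(FALSE)
  head_names <- utils::head(resp$names, cfg$n_top)
  any(vapply(head_names, match_label, logical(1),
    entry = truth_entry, threshold = cfg$match_threshold
  ))
}

#' @rdname topn_hit
#' @export
top1_hit <- function(resp, truth_entry, cfg) {
  if (!resp$parse_ok || length(resp$names) == 0) return(FALSE)
  match_label(resp$names[1], truth_entry, cfg$match_threshold)
}

# Greedy one-to-one fuzzy assignment: number of (response name, list member)
# pairs with similarity >= threshold, each side used at most once, pairs taken
# in decreasing similarity. At threshold 1 this reduces to exact-set
# intersection on normalized names.
count_fuzzy_matches <- function(resp_names, list_names, threshold) {
  if (length(resp_names) == 0 || length(list_names) == 0) return(0L)
  sims <- outer(
    seq_along(resp_names), seq_along(list_names),
    Vectorize(function(i, j) similarity_ratio(resp_names[i], list_names[j]))
  )
  used_r <- rep(FALSE, length(resp_names))
  used_l <- rep(FALSE, length(list_names))
  n <- 0L
  repeat {
    sims[used_r, ] <- -1
    sims[, used_l] <- -1
    best <- which.max(sims)
    if (sims[best] < threshold) break
    i <- (best - 1) %% nrow(sims) + 1
    j <- (best - 1) %/% nrow(sims) + 1
    used_r[i] <- TRUE
    used_l[j] <- TRUE
    n <- n + 1L
    if (all(used_r) || all(used_l)) break
  }
  n
}

#' Top-k coverage rate of one response
#'
#' `C = |matches between the chosen list T_k and the response| / |response|`,
#' with fuzzy one-to-one matching at the strict threshold. An empty response
#' scores 0.
#'
#' @param resp A [parse_ranked_list()] result.
#' @param t_k Character vector: the truth-first top-k chosen list.
#' @param cfg An [eval_config()].
#' @return Coverage in \[0, 1\].
#' @export
coverage_rate <- function(resp, t_k, cfg) {
  if (length(resp$names) == 0) return(0)
  count_fuzzy_matches(resp$names, t_k, cfg$match_threshold) / length(resp$names)
}

#' Bottom-q avoidance rate of one response
#'
#' `A = 1 - |matches between the response and the rejected list B_q| /
#' |response|`. An empty response scores 0 (flagged upstream).
#'
#' @param resp A [parse_ranked_list()] result.
#' @param b_q Character vector: the bottom-q rejected list.
#' @param cfg An [eval_config()].
#' @return Avoidance in \[0, 1\].
#' @export
avoidance_rate <- function(resp, b_q, cfg) {
  if (length(resp$names) == 0) return(0)
  1 - count_fuzzy_matches(resp$names, b_q, cfg$match_threshold) / length(resp$names)
}

#' Coverage-Avoidance Rate
#'
#' The weighted harmonic mean of per-sample coverage and avoidance:
#' \deqn{CAR = \frac{1}{N}\sum_i \frac{(1+\lambda)\,C_i A_i}
#'                               {\lambda C_i + A_i}}
#' At `lambda = 1` this is the plain harmonic mean; larger `lambda` weights
#' coverage more, smaller weights avoidance more. A per-sample term with
#' `lambda * C + A = 0` is defined as 0.
#'
#' @param coverage,avoidance Numeric vectors in \[0, 1\], same length.
#' @param lambda Weight (>= 0).
#' @return CAR in \[0, 1\].
#' @export
#' @examples
#' car_score(0.5, 0.8, lambda = 1) # 0.6153846
car_score <- function(coverage, avoidance, lambda = 1) {
  stopifnot(length(coverage) == length(avoidance), lambda >= 0)
  if (length(coverage) == 0) stop("empty coverage/avoidance list", call. = FALSE)
  stopifnot(all(coverage >= 0 & coverage <= 1), all(avoidance >= 0 & avoidance <= 1))
  denom <- lambda * coverage + avoidance
  term <- ifelse(denom == 0, 0, (1 + lambda) * coverage * avoidance / denom)
  mean(term)
}

#' Grade a set of responses
#'
#' Composes the whole evaluation: parse (if given raw text), hallucination
#' check, Top-N and Top-1 over hallucination-passing responses (a response
#' failing the hallucination check counts as a Top-N/Top-1 failure, so
#' `top1 <= topn <= hfa` holds by construction), and CAR against the
#' truth-first top-k / bottom-q lists derived from the upstream predictions.
#'
#' @param responses Named character vector (id -> response text) or named
#'   list of [parse_ranked_list()] results.
#' @param truths Named character vector: id -> true canonical name.
#' @param upstream_preds Named list of [ranked_prediction()]s keyed by id.
#' @param space A [label_space()].
#' @param cfg An [eval_config()].
#' @return An `eval_report`: list with `hfa_rate`, `topn_rate`, `top1_rate`,
#'   `car`, and `per_sample` (a tibble of per-sample diagnostics).
#' @export
evaluate_responses <- function(responses, truths, upstream_preds, space, cfg) {
  ids <- names(responses)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("responses must be named by sample id", call. = FALSE)
  }
  bad <- setdiff(ids, names(truths))
  bad <- c(bad, setdiff(ids, names(upstream_preds)))
  if (length(bad) > 0) {
    stop("sample id(s) missing from truths/upstream predictions: ",
      paste(unique(bad), collapse = ", "),
      call. = FALSE
    )
  }
  parsed <- lapply(responses, function(r) {
    # over-long answers are truncated to the output contract's length; the
    # per-sample `truncated` flag records it, so no warning here
    if (inherits(r, "parsed_response")) r else suppressWarnings(parse_ranked_list(r, cfg$n_top))
  })
  hfa_flags <- vapply(parsed, hfa_pass, logical(1), space = space, cfg = cfg)
  topn <- logical(length(ids))
  top1 <- logical(length(ids))
  cov <- numeric(length(ids))
  avd <- numeric(length(ids))
  empty <- logical(length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    pred <- upstream_preds[[id]]
    truth_entry <- lookup_label(space, truths[[id]])
    if (is.null(truth_entry)) {
      stop("truth for sample ", id, " not in label space: ", truths[[id]],
        call. = FALSE
      )
    }
    if (hfa_flags[i]) {
      topn[i] <- topn_hit(parsed[[i]], truth_entry, cfg)
      top1[i] <- top1_hit(parsed[[i]], truth_entry, cfg)
    }
    ranked <- rank_labels(pred, space)
    t_k <- enforce_truth_first(ranked, pred$true_label, cfg$k, space)
    b_q <- build_preference_record(pred, "", cfg$k, cfg$q, space)$rejected
    if (length(parsed[[i]]$names) == 0) {
      empty[i] <- TRUE
      cov[i] <- 0
      avd[i] <- 0
    } else {
      cov[i] <- coverage_rate(parsed[[i]], t_k, cfg)
      avd[i] <- avoidance_rate(parsed[[i]], b_q, cfg)
    }
  }
  structure(
    list(
      hfa_rate = 100 * mean(hfa_flags),
      topn_rate = 100 * mean(topn),
      top1_rate = 100 * mean(top1),
      car = car_score(cov, avd, cfg$lambda),
      config = cfg,
      per_sample = tibble::tibble(
        sample_id = ids, hfa = unname(hfa_flags), topn = topn, top1 = top1,
        coverage = cov, avoidance = avd, empty_response = empty
      )
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> n=%d  HFA %.2f%%  Top-%d %.2f%%  Top-1 %.2f%%  CAR %.4f\n",
    nrow(x$per_sample), x$hfa_rate, x$config$n_top, x$topn_rate,
    x$top1_rate, x$car
  ))
  invisible(x)
}
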