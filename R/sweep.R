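#' Run the full synthetic alignment pipeline once
#'
#' Convenience wrapper that wires every stage together on synthetic data:
#' generate a label space, term dictionary and patients; simulate the
#' upstream classifier; build truth-first preference records; optionally
#' align the toy language model with the odds-ratio objective; produce
#' responses (from the toy model, or from the response simulator); and grade
#' them. Useful for experiments and as the engine behind [sweep_aor()].
#'
#' @param n_labels,n_train,n_test Problem sizes.
#' @param k,q Chosen / rejected list sizes.
#' @param accuracy Upstream simulator accuracy.
#' @param quality Responder quality (used when `responder = "simulate"`).
#' @param n_top Graded list length.
#' @param lambda CAR weight.
#' @param responder `"simulate"` (response simulator) or `"toy"` (train the
#'   toy LM on the preference records and rank labels with it).
#' @param toy_cfg A [toy_lm_config()] (used when `responder = "toy"`).
#' @param seed Integer seed for all stages.
#' @return List with `report` (an `eval_report`), `space`, `records`, and —
#'   when the toy model is used — `fit` (the [train_toy_orpo()] result).
#' @export
run_synthetic_pipeline <- function(n_labels = 20, n_train = 60, n_test = 40,
                                   k = 5, q = 5, accuracy = 0.9, quality = 0.9,
                                   n_top = 5, lambda = 1,
                                   responder = c("simulate", "toy"),
                                   toy_cfg = toy_lm_config(), seed = 1L) {
  responder <- match.arg(responder)
  space <- simulate_label_space(n_labels, seed = seed)
  terms <- simulate_term_dictionary(space, seed = seed + 1L)
  patients <- simulate_patients(n_train + n_test, space, terms, seed = seed + 2L)
  prompts <- stats::setNames(
    vapply(patients, format_patient_prompt, character(1), dict = terms$dict),
    vapply(patients, `[[`, character(1), "id")
  )
  truths <- stats::setNames(
    vapply(patients, `[[`, character(1), "true_label"),
    names(prompts)
  )
  train_ids <- names(prompts)[seq_len(n_train)]
  test_ids <- setdiff(names(prompts), train_ids)
  preds <- simulate_upstream(truths, space, accuracy = accuracy, seed = seed + 3L)
  records <- build_preference_dataset(
    preds[train_ids], prompts[train_ids], k, q, space,
    quiet = TRUE
  )
  fit <- NULL
  if (responder == "toy") {
    fit <- train_toy_orpo(records, toy_cfg)
    responses <- stats::setNames(
      vapply(test_ids, function(id) {
        toy_lm_respond(fit$model, prompts[[id]], space, n_top)
      }, character(1)),
      test_ids
    )
  } else {
    responses <- simulate_responses(preds[test_ids], space,
      quality = quality,
      n_top = n_top, seed = seed + 4L
    )$responses
  }
  cfg <- eval_config(n_top = n_top, k = k, q = q, lambda = lambda)
  report <- evaluate_responses(responses, truths[test_ids], preds[test_ids], space, cfg)
  list(report = report, space = space, records = records, fit = fit)
}

#' Sweep the Acceptance-over-Rejection ratio
#'
#' Runs the synthetic pipeline once per `(k, q)` grid point and collects the
#' evaluation metrics, to study how the chosen/rejected balance affects
#' alignment quality. Grid points with `k + q` exceeding the label count are
#' infeasible and skipped with a warning.
#'
#' @param grid List of `c(k, q)` pairs (or a two-column matrix).
#' @param ... Passed through to [run_synthetic_pipeline()] (problem sizes,
#'   responder, seed, ...). `k` and `q` come from the grid.
#' @return A tibble with columns `k`, `q`, `aor`, `hfa`, `topn`, `top1`,
#'   `car`, one row per feasible grid point.
#' @export
sweep_aor <- function(grid, ...) {
  if (is.matrix(grid)) grid <- lapply(seq_len(nrow(grid)), function(i) grid[i, ])
  args <- list(...)
  n_labels <- if (is.null(args$n_labels)) 20 else args$n_labels
  rows <- list()
  for (kq in grid) {
    k <- kq[[1]]
    q <- kq[[2]]
    if (k + q > n_labels) {
      warning("grid point (k=", k, ", q=", q, ") infeasible for ",
        n_labels, " labels; skipped",
        call. = FALSE
      )
      next
    }
    res <- do.call(run_synthetic_pipeline, c(list(k = k, q = q), args))
    r <- res$report
    rows[[length(rows) + 1L]] <- tibble::tibble(
      k = as.integer(k), q = as.integer(q), aor = aor(k, q),
      hfa = r$hfa_rate, topn = r$topn_rate, top1 = r$top1_rate, car = r$car
    )
  }
  if (length(rows) == 0) {
    return(tibble::tibble(
      k = integer(), q = integer(), aor = numeric(), hfa = numeric(),
      topn = numeric(), top1 = numeric(), car = numeric()
    ))
  }
  do.call(rbind, rows)
}
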