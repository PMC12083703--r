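test_that("numbered-list parsing accepts common bullet styles and never raises", {
  r <- parse_ranked_list("1. Phelan-McDermid syndrome (PHMDS)\n2. Williams-Beuren syndrome (WBS)")
  expect_true(r$parse_ok)
  expect_equal(r$names, c(
    "Phelan-McDermid syndrome (PHMDS)",
    "Williams-Beuren syndrome (WBS)"
  ))
  styles <- c("1. colon\n2. liver", "1) colon\n2) liver", "(1) colon\n(2) liver", "- colon\n- liver")
  for (s in styles) {
    expect_equal(parse_ranked_list(s)$names, c("colon", "liver"), label = s)
  }
  expect_false(parse_ranked_list("")$parse_ok)
  expect_false(parse_ranked_list("no list here, just prose")$parse_ok)
  expect_false(parse_ranked_list(NA_character_)$parse_ok)
})

test_that("parsing truncates over-long lists with a flag", {
  txt <- format_ranked_list(paste("name", 1:12))
  expect_warning(r <- parse_ranked_list(txt, expected_len = 10), "truncating")
  expect_length(r$names, 10)
  expect_true(r$truncated)
})

test_that("render-then-parse is the identity on name lists", {
  set.seed(3)
  ls <- simulate_label_space(15, seed = 3)
  for (i in 1:25) {
    names_i <- sample(ls$canonical_name, sample(1:10, 1))
    r <- parse_ranked_list(format_ranked_list(names_i))
    expect_true(r$parse_ok)
    expect_identical(r$names, names_i)
  }
})

test_that("evaluation config enforces threshold ordering and ranges", {
  cfg <- eval_config()
  expect_equal(cfg$hfa_threshold, 0.6)
  expect_equal(cfg$match_threshold, 0.8)
  expect_error(eval_config(hfa_threshold = 0.9, match_threshold = 0.8), "exceed")
  expect_error(eval_config(lambda = -1), "lambda")
})

test_that("hallucination check counts fabricated names against the response", {
  ls <- tiny_space()
  cfg <- eval_config(n_top = 3, k = 2, q = 2)
  good <- parse_ranked_list(format_ranked_list(ls$canonical_name[1:3]))
  bad <- parse_ranked_list(format_ranked_list(c(ls$canonical_name[1], "xqzwjyhcq zwx")))
  expect_true(hfa_pass(good, ls, cfg))
  expect_false(hfa_pass(bad, ls, cfg))
  # rule switches
  cfg_any <- eval_config(n_top = 3, k = 2, q = 2, hfa_rule = "any")
  expect_true(hfa_pass(bad, ls, cfg_any))
  r <- hfa(c(replicate(9, good, simplify = FALSE), list(bad)), ls, cfg)
  expect_equal(r$rate, 90)
  expect_error(hfa(list(), ls, cfg), "empty")
})

test_that("hallucination rate tracks an injected corruption fraction exactly", {
  ls <- simulate_label_space(12, seed = 21)
  cfg <- eval_config(n_top = 4, k = 3, q = 3)
  set.seed(99)
  flagged <- stats::runif(40) < 0.3
  resp <- lapply(seq_len(40), function(i) {
    nm <- sample(ls$canonical_name, 4)
    if (flagged[i]) nm[sample(4, 1)] <- paste0(sample(c("x", "q", "z", "w", "j"), 10, TRUE), collapse = "")
    parse_ranked_list(format_ranked_list(nm))
  })
  r <- hfa(resp, ls, cfg)
  expect_equal(r$rate, 100 * (1 - mean(flagged)))
  expect_equal(unname(r$pass), !flagged)
})

test_that("top-N and top-1 hits respect position and the abbreviation path", {
  ls <- tiny_space()
  cfg <- eval_config(n_top = 10, k = 3, q = 3)
  truth <- lookup_label(ls, "Phelan-McDermid syndrome")
  filler <- rep(ls$canonical_name[5], 0) # none
  at7 <- parse_ranked_list(format_ranked_list(c(
    ls$canonical_name[c(2, 3, 4, 5, 6, 2)], "Phelan-McDermid syndrome"
  )))
  expect_true(topn_hit(at7, truth, cfg))
  expect_false(top1_hit(at7, truth, cfg))
  at1 <- parse_ranked_list(format_ranked_list(c("Phelan-McDermid syndrome", ls$canonical_name[2])))
  expect_true(topn_hit(at1, truth, cfg))
  expect_true(top1_hit(at1, truth, cfg))
  # abbreviation alone at position 1 counts via the abbreviation path
  ab <- parse_ranked_list(format_ranked_list(c("PHMDS", ls$canonical_name[2])))
  expect_true(top1_hit(ab, truth, cfg))
  expect_true(topn_hit(ab, truth, cfg))
})

test_that("coverage and avoidance are match counts over the response length", {
  ls <- simulate_label_space(30, seed = 5)
  cfg <- eval_config(n_top = 10, k = 10, q = 10)
  t_k <- ls$canonical_name[1:10]
  b_q <- ls$canonical_name[21:30]
  # R subset of T_k, disjoint from B_q
  r1 <- parse_ranked_list(format_ranked_list(t_k[1:5]))
  expect_equal(coverage_rate(r1, t_k, cfg), 1)
  expect_equal(avoidance_rate(r1, b_q, cfg), 1)
  # |R| = 10 with 5 matches in T_k and 2 in B_q
  r2 <- parse_ranked_list(format_ranked_list(c(
    t_k[1:5], b_q[1:2], ls$canonical_name[11:13]
  )))
  expect_equal(coverage_rate(r2, t_k, cfg), 0.5)
  expect_equal(avoidance_rate(r2, b_q, cfg), 0.8)
  # disjoint from both
  r3 <- parse_ranked_list(format_ranked_list(ls$canonical_name[11:14]))
  expect_equal(coverage_rate(r3, t_k, cfg), 0)
  expect_equal(avoidance_rate(r3, b_q, cfg), 1)
  # empty response scores zero on both
  r0 <- parse_ranked_list("")
  expect_equal(coverage_rate(r0, t_k, cfg), 0)
  expect_equal(avoidance_rate(r0, b_q, cfg), 0)
})

test_that("CAR matches its closed forms and limits", {
  expect_equal(car_score(0.5, 0.8, lambda = 1), 2 * 0.4 / 1.3, tolerance = 1e-12)
  # equal C = A = c gives CAR = c under the plain harmonic mean
  for (c in c(0.2, 0.5, 0.9)) expect_equal(car_score(c, c, 1), c, tolerance = 1e-12)
  expect_equal(car_score(rep(0, 5), stats::runif(5), 1), 0)
  expect_error(car_score(numeric(0), numeric(0), 1), "empty")
  # limits: lambda -> 0 recovers C (when A > 0); lambda -> Inf recovers A
  set.seed(11)
  C <- stats::runif(50, 0.05, 1)
  A <- stats::runif(50, 0.05, 1)
  expect_equal(car_score(C, A, 1e-8), mean(C), tolerance = 1e-6)
  expect_equal(car_score(C, A, 1e8), mean(A), tolerance = 1e-6)
})

test_that("CAR is symmetric under swapping coverage/avoidance with inverted lambda", {
  set.seed(23)
  for (i in 1:1000) {
    n <- sample(1:8, 1)
    C <- stats::runif(n)
    A <- stats::runif(n)
    lam <- stats::rexp(1) + 1e-3
    expect_equal(car_score(C, A, lam), car_score(A, C, 1 / lam), tolerance = 1e-12)
  }
})

test_that("swapping a non-matching response name never hurts the right metric", {
  ls <- simulate_label_space(20, seed = 31)
  cfg <- eval_config(n_top = 5, k = 5, q = 5)
  t_k <- ls$canonical_name[1:5]
  b_q <- ls$canonical_name[16:20]
  neutral <- ls$canonical_name[6:10]
  base <- parse_ranked_list(format_ranked_list(neutral))
  c0 <- coverage_rate(base, t_k, cfg)
  a0 <- avoidance_rate(base, b_q, cfg)
  car0 <- car_score(c0, a0, 1)
  for (j in 1:5) {
    into_b <- neutral
    into_b[j] <- b_q[j]
    rb <- parse_ranked_list(format_ranked_list(into_b))
    expect_lte(
      car_score(coverage_rate(rb, t_k, cfg), avoidance_rate(rb, b_q, cfg), 1),
      car0
    )
    into_t <- neutral
    into_t[j] <- t_k[j]
    rt <- parse_ranked_list(format_ranked_list(into_t))
    expect_gte(coverage_rate(rt, t_k, cfg), c0)
  }
})

test_that("the full pipeline agrees with a set-arithmetic oracle at threshold 1", {
  set.seed(57)
  for (rep in 1:60) {
    n_labels <- sample(6:12, 1)
    ls <- simulate_label_space(n_labels, seed = 1000 + rep)
    k <- sample(2:3, 1)
    q <- sample(2:3, 1)
    n_top <- sample(2:4, 1)
    n_samp <- sample(3:6, 1)
    ids <- sprintf("s%d", seq_len(n_samp))
    truths <- stats::setNames(sample(ls$canonical_name, n_samp, TRUE), ids)
    preds <- simulate_upstream(truths, ls, accuracy = 0.6, seed = 2000 + rep)
    resp_names <- lapply(ids, function(i) {
      nm <- sample(ls$canonical_name, sample(seq_len(min(6, n_labels)), 1))
      if (stats::runif(1) < 0.3) { # occasional fabricated name exercises HFA
        nm[sample(length(nm), 1)] <- paste0(sample(letters, 9, TRUE), collapse = "")
      }
      nm
    })
    names(resp_names) <- ids
    responses <- vapply(resp_names, format_ranked_list, character(1))
    cfg <- eval_config(
      n_top = n_top, k = k, q = q, lambda = 1,
      hfa_threshold = 1, match_threshold = 1
    )
    got <- evaluate_responses(responses, truths, preds, ls, cfg)
    t_k_list <- lapply(ids, function(i) {
      enforce_truth_first(rank_labels(preds[[i]], ls), truths[[i]], k, ls)
    })
    b_q_list <- lapply(ids, function(i) {
      build_preference_record(preds[[i]], "", k, q, ls)$rejected
    })
    want <- oracle_evaluate(
      resp_names, truths, t_k_list, b_q_list,
      ls$normalized, n_top, 1
    )
    expect_equal(got$hfa_rate, want$hfa_rate)
    expect_equal(got$topn_rate, want$topn_rate)
    expect_equal(got$top1_rate, want$top1_rate)
    expect_equal(got$car, want$car, tolerance = 1e-12)
  }
})

test_that("a perfect responder scores 100/100/100 and CAR 1; a worst-case responder 0", {
  ls <- simulate_label_space(15, seed = 41)
  ids <- sprintf("s%d", 1:8)
  truths <- stats::setNames(sample(ls$canonical_name, 8, TRUE), ids)
  preds <- simulate_upstream(truths, ls, accuracy = 0.7, seed = 6)
  cfg <- eval_config(n_top = 5, k = 5, q = 5)
  oracle_resp <- vapply(ids, function(i) {
    format_ranked_list(enforce_truth_first(rank_labels(preds[[i]], ls), truths[[i]], 5, ls))
  }, character(1))
  rep_good <- evaluate_responses(oracle_resp, truths, preds, ls, cfg)
  expect_equal(rep_good$hfa_rate, 100)
  expect_equal(rep_good$topn_rate, 100)
  expect_equal(rep_good$top1_rate, 100)
  expect_equal(rep_good$car, 1)
  bad_resp <- vapply(ids, function(i) {
    format_ranked_list(build_preference_record(preds[[i]], "", 5, 5, ls)$rejected)
  }, character(1))
  rep_bad <- evaluate_responses(bad_resp, truths, preds, ls, cfg)
  expect_equal(rep_bad$top1_rate, 0)
  expect_equal(rep_bad$car, 0)
})

test_that("misaligned sample ids are a hard error", {
  ls <- simulate_label_space(8, seed = 51)
  truths <- stats::setNames(sample(ls$canonical_name, 3), c("a", "b", "c"))
  preds <- simulate_upstream(truths, ls, accuracy = 0.5, seed = 2)
  cfg <- eval_config(n_top = 2, k = 2, q = 2)
  resp <- stats::setNames(rep(format_ranked_list(ls$canonical_name[1:2]), 3), c("a", "b", "zzz"))
  expect_error(evaluate_responses(resp, truths, preds, ls, cfg), "zzz")
})

test_that("the accuracy chain top1 <= topN <= HFA holds on random runs", {
  set.seed(71)
  for (rep in 1:5) {
    ls <- simulate_label_space(14, seed = 300 + rep)
    ids <- sprintf("s%d", 1:20)
    truths <- stats::setNames(sample(ls$canonical_name, 20, TRUE), ids)
    preds <- simulate_upstream(truths, ls, accuracy = 0.5, seed = 400 + rep)
    sim <- simulate_responses(preds, ls,
      quality = 0.5, n_top = 4,
      corruption = 0.3, seed = 500 + rep
    )
    cfg <- eval_config(n_top = 4, k = 4, q = 4)
    r <- evaluate_responses(sim$responses, truths, preds, ls, cfg)
    expect_lte(r$top1_rate, r$topn_rate)
    expect_lte(r$topn_rate, r$hfa_rate)
  }
})
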