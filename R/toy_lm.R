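#' Configuration for the toy character-level language model
#'
#' The harness trains a linear-softmax causal character model: the logits of
#' the next character are a linear function of the one-hot encodings of the
#' previous `context_len` characters. It is deliberately the smallest model
#' that can overfit a few dozen label names on a laptop CPU, so the whole
#' preference-alignment loop (build records, optimize the odds-ratio
#' objective, rank labels by completion likelihood) can be exercised end to
#' end in seconds.
#'
#' @param context_len Characters of context (default 8).
#' @param epochs Training epochs (default 5).
#' @param lr Learning-rate for plain gradient descent (default 0.5).
#' @param beta Odds-ratio term weight (default 0.25).
#' @param seed Integer seed for initialization and shuffling.
#' @return A `toy_lm_config` list.
#' @export
toy_lm_config <- function(context_len = 8, epochs = 5, lr = 0.5,
                          beta = 0.25, seed = 1L) {
  stopifnot(context_len >= 1, epochs >= 0, lr > 0, beta >= 0)
  structure(
    list(
      context_len = as.integer(context_len), epochs = as.integer(epochs),
      lr = lr, beta = beta, seed = as.integer(seed)
    ),
    class = "toy_lm_config"
  )
}

# vocabulary: characters observed in the corpus + BOS/UNK sentinels
toy_vocab <- function(texts) {
  chars <- sort(unique(unlist(strsplit(texts, "", fixed = TRUE))))
  c("<bos>", "<unk>", chars)
}

toy_encode <- function(text, vocab) {
  ch <- strsplit(text, "", fixed = TRUE)[[1]]
  i <- match(ch, vocab)
  i[is.na(i)] <- 2L # <unk>
  i
}

#' Initialize an untrained toy language model
#'
#' @param texts Character vector whose characters define the vocabulary.
#' @param cfg A [toy_lm_config()].
#' @return A `toy_lm` object (weight matrix + vocabulary + config).
#' @export
toy_lm_new <- function(texts, cfg = toy_lm_config()) {
  vocab <- toy_vocab(texts)
  v <- length(vocab)
  d <- cfg$context_len * v + 1L # + bias column
  set.seed(cfg$seed)
  W <- matrix(stats::rnorm(v * d, sd = 0.01), nrow = v, ncol = d)
  structure(
    list(W = W, vocab = vocab, cfg = cfg),
    class = "toy_lm"
  )
}

# Build the context design matrix and target indices for scoring `completion`
# after `prompt`. Row t encodes the context_len characters preceding the t-th
# completion character (BOS-padded); the final column is the bias.
toy_design <- function(model, prompt, completion) {
  v <- length(model$vocab)
  L <- model$cfg$context_len
  ids <- c(rep(1L, L), toy_encode(prompt, model$vocab), toy_encode(completion, model$vocab))
  n_c <- nchar(completion)
  t0 <- length(ids) - n_c # index before first completion char
  X <- matrix(0, nrow = n_c, ncol = L * v + 1L)
  for (t in seq_len(n_c)) {
    ctx <- ids[(t0 + t - L):(t0 + t - 1L)]
    X[t, (seq_len(L) - 1L) * v + ctx] <- 1
  }
  X[, L * v + 1L] <- 1
  list(X = X, y = ids[(t0 + 1L):(t0 + n_c)])
}

# log-softmax rows of a logits matrix
row_log_softmax <- function(Z) {
  m <- apply(Z, 1, max)
  Z <- Z - m
  Z - log(rowSums(exp(Z)))
}

#' Score a completion under the toy model
#'
#' @param model A `toy_lm`.
#' @param prompt Conditioning text.
#' @param completion Text to score.
#' @return A [completion_logprob()] for the completion.
#' @export
toy_lm_score <- function(model, prompt, completion) {
  stopifnot(inherits(model, "toy_lm"), nchar(completion) >= 1)
  d <- toy_design(model, prompt, completion)
  logp <- row_log_softmax(d$X %*% t(model$W))
  total <- sum(logp[cbind(seq_along(d$y), d$y)])
  completion_logprob(min(total, 0), length(d$y))
}

#' Rank label names by toy-model completion likelihood
#'
#' Scores every canonical name, rendered as the first line of the numbered
#' output contract (`"1. <name>"`, matching the training targets), as a
#' completion of the prompt, and orders by per-token mean log-probability
#' (length-normalized so long names are not penalized). This is the model's
#' "response": its ranked differential.
#'
#' @param model A `toy_lm`.
#' @param prompt Conditioning text.
#' @param space A [label_space()].
#' @return Character vector of canonical names, best first.
#' @export
toy_lm_rank <- function(model, prompt, space) {
  sc <- vapply(space$canonical_name, function(nm) {
    lp <- toy_lm_score(model, prompt, paste0("1. ", nm))
    lp$total_logprob / lp$token_count
  }, numeric(1))
  space$canonical_name[order(-sc, space$label_id)]
}

#' Render the toy model's answer as a numbered ranked list
#'
#' @param model A `toy_lm`.
#' @param prompt Conditioning text.
#' @param space A [label_space()].
#' @param n_top List length.
#' @return Response text (numbered block).
#' @export
toy_lm_respond <- function(model, prompt, space, n_top) {
  format_ranked_list(utils::head(toy_lm_rank(model, prompt, space), n_top))
}

#' Mean chosen-vs-rejected log-odds-ratio margin over preference records
#'
#' The diagnostic tracked during alignment: how much more likely (in odds)
#' the model finds the chosen list than the rejected list, averaged over
#' records.
#'
#' @param model A `toy_lm`.
#' @param records List of preference records.
#' @param normalize Length-normalize probabilities (default TRUE).
#' @return Mean log-odds-ratio (nats).
#' @export
toy_lm_margin <- function(model, records, normalize = TRUE) {
  mean(vapply(records, function(r) {
    w <- toy_lm_score(model, r$prompt, r$chosen_text)
    l <- toy_lm_score(model, r$prompt, r$rejected_text)
    orpo_loss(w, l, beta = 0, normalize = normalize)$log_odds_ratio
  }, numeric(1)))
}

#' Train the toy model with the odds-ratio preference objective
#'
#' Plain gradient descent on the per-record ORPO loss
#' (`sft_nll + beta * or_loss`, token-mean convention), with analytic
#' gradients through the linear-softmax parameterization. With `beta = 0`
#' the run reduces to supervised fine-tuning on the chosen completions. The
#' training log records the mean loss and the mean chosen-vs-rejected
#' log-odds-ratio margin at epoch 0 (untrained) and after each epoch.
#' Deterministic for a fixed config seed.
#'
#' @param records List of preference records (non-empty).
#' @param cfg A [toy_lm_config()].
#' @param model Optionally, a `toy_lm` to continue training.
#' @return List with `model` (trained `toy_lm`) and `log` (a tibble:
#'   `epoch`, `mean_loss`, `mean_margin`, `mean_sft_nll`).
#' @export
train_toy_orpo <- function(records, cfg = toy_lm_config(), model = NULL) {
  if (length(records) == 0) stop("no preference records to train on", call. = FALSE)
  corpus <- unlist(lapply(records, function(r) {
    c(r$prompt, r$chosen_text, r$rejected_text)
  }))
  if (is.null(model)) model <- toy_lm_new(corpus, cfg)
  beta <- cfg$beta
  v <- length(model$vocab)

  # cache design matrices; they do not depend on the weights
  designs <- lapply(records, function(r) {
    list(
      w = toy_design(model, r$prompt, r$chosen_text),
      l = toy_design(model, r$prompt, r$rejected_text)
    )
  })

  epoch_stats <- function() {
    losses <- vapply(seq_along(records), function(i) {
      w <- score_design(model, designs[[i]]$w)
      l <- score_design(model, designs[[i]]$l)
      parts <- orpo_loss(w, l, beta = beta)
      c(parts$total, parts$log_odds_ratio, parts$sft_nll)
    }, numeric(3))
    c(mean(losses[1, ]), mean(losses[2, ]), mean(losses[3, ]))
  }
  s0 <- epoch_stats()
  log <- list(c(0, s0))

  set.seed(cfg$seed)
  for (epoch in seq_len(cfg$epochs)) {
    order_i <- sample(seq_along(records))
    for (i in order_i) {
      model <- orpo_sgd_step(model, designs[[i]], beta, cfg$lr)
      if (any(!is.finite(model$W))) {
        stop("training diverged (non-finite weights) at epoch ", epoch,
          ", record ", i,
          call. = FALSE
        )
      }
    }
    log[[length(log) + 1L]] <- c(epoch, epoch_stats())
  }
  log_df <- do.call(rbind, log)
  list(
    model = model,
    log = tibble::tibble(
      epoch = as.integer(log_df[, 1]),
      mean_loss = log_df[, 2],
      mean_margin = log_df[, 3],
      mean_sft_nll = log_df[, 4]
    )
  )
}

score_design <- function(model, d) {
  logp <- row_log_softmax(d$X %*% t(model$W))
  total <- sum(logp[cbind(seq_along(d$y), d$y)])
  completion_logprob(min(total, 0), length(d$y))
}

# One gradient step on a single record's ORPO loss (token-mean convention).
orpo_sgd_step <- function(model, design, beta, lr) {
  fw <- forward_design(model, design$w)
  fl <- forward_design(model, design$l)
  m_w <- fw$mean_logprob
  m_l <- fl$mean_logprob
  # clamp as in sequence_prob so the odds stay finite
  eps <- 1e-12
  p_w <- min(max(exp(m_w), eps), 1 - eps)
  p_l <- min(max(exp(m_l), eps), 1 - eps)
  g <- (log(p_w) - log1p(-p_w)) - (log(p_l) - log1p(-p_l))
  sig <- 1 / (1 + exp(g)) # sigmoid(-g) = d(-log sigmoid(g))/d(-g)
  coef_w <- -1 + beta * (-sig / (1 - p_w)) # d total / d m_w
  coef_l <- beta * (sig / (1 - p_l)) # d total / d m_l
  grad <- grad_mean_logprob(fw, coef_w) + grad_mean_logprob(fl, coef_l)
  model$W <- model$W - lr * grad
  model
}

forward_design <- function(model, d) {
  Z <- d$X %*% t(model$W)
  m <- apply(Z, 1, max)
  E <- exp(Z - m)
  P <- E / rowSums(E)
  logp <- (Z - m) - log(rowSums(E))
  tot <- sum(logp[cbind(seq_along(d$y), d$y)])
  list(X = d$X, y = d$y, P = P, mean_logprob = tot / length(d$y), n = length(d$y))
}

# gradient of coef * mean token logprob w.r.t. W:
# d mean_logprob / d Z_t = (onehot(y_t) - p_t) / n; chain through Z = X W^T
grad_mean_logprob <- function(f, coef) {
  G <- -f$P
  G[cbind(seq_len(f$n), f$y)] <- G[cbind(seq_len(f$n), f$y)] + 1
  (coef / f$n) * t(G) %*% f$X
}
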