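#' Completion log-probability
#'
#' The summed token log-probability (nats, <= 0) and token count of one
#' completion under some language model. This is the only interface the
#' alignment objectives need, which keeps them model-agnostic.
#'
#' @param total_logprob Total log-probability in nats (<= 0).
#' @param token_count Number of tokens (>= 1).
#' @return A `completion_logprob` object.
#' @export
completion_logprob <- function(total_logprob, token_count) {
  stopifnot(is.numeric(total_logprob), length(total_logprob) == 1)
  stopifnot(token_count >= 1)
  if (total_logprob > 0) {
    stop("total_logprob must be <= 0 (log of a probability)", call. = FALSE)
  }
  structure(
    list(total_logprob = as.numeric(total_logprob),
         token_count = as.integer(token_count)),
    class = "completion_logprob"
  )
}

#' Sequence probability from a completion log-probability
#'
#' With `normalize = TRUE` (the default used by the ORPO objective) returns
#' the per-token geometric-mean probability `exp(total/tokens)`; otherwise
#' the joint probability `exp(total)`. Clamped to `(eps, 1 - eps)` so the
#' odds transform stays finite.
#'
#' @param lp A [completion_logprob()].
#' @param normalize Length-normalize (per-token geometric mean)?
#' @param eps Clamp width (default `1e-12`).
#' @return Probability in (0, 1).
#' @export
sequence_prob <- function(lp, normalize = TRUE, eps = 1e-12) {
  l <- if (normalize) lp$total_logprob / lp$token_count else lp$total_logprob
  p <- exp(l)
  min(max(p, eps), 1 - eps)
}

#' Odds of a probability
#'
#' `odds(p) = p / (1 - p)`; strictly increasing on (0, 1).
#'
#' @param p Probability strictly inside (0, 1).
#' @return Positive real.
#' @export
#' @examples
#' odds(0.5) # 1
#' odds(0.8) # 4
odds <- function(p) {
  if (any(p <= 0 | p >= 1)) stop("p must be in (0, 1)", call. = FALSE)
  p / (1 - p)
}

# log odds from a (possibly length-normalized) log-probability, in log space:
# log(p / (1-p)) = l - log(1 - exp(l)), with l = log p <= 0
log_odds_from_logprob <- function(l, eps = 1e-12) {
  l <- min(max(l, log(eps)), log1p(-eps))
  # log(1 - e^l) = log(-expm1(l)), stable for l < 0
  l - log(-expm1(l))
}

#' ORPO loss for one chosen/rejected pair
#'
#' Single-stage alignment objective combining supervised fine-tuning with an
#' odds-ratio preference term:
#' \deqn{L = L_{SFT} + \beta \, L_{OR},\qquad
#'       L_{OR} = -\log\sigma\!\big(\log \mathrm{odds}(P_w) -
#'                                  \log \mathrm{odds}(P_l)\big)}
#' where \eqn{P_w,P_l} are the (by default per-token geometric mean)
#' probabilities of the chosen and rejected completions and
#' \eqn{L_{SFT}} is the chosen completion's negative log-likelihood
#' (token-mean when `normalize = TRUE`). All arithmetic runs in log space,
#' so extreme log-probabilities do not overflow.
#'
#' @param chosen,rejected [completion_logprob()] objects for the preferred
#'   and dispreferred completions.
#' @param beta Weight on the odds-ratio term (>= 0; default 0.25).
#' @param normalize Length-normalize probabilities and the SFT term?
#' @return List with `sft_nll`, `or_loss`, `log_odds_ratio`, `total`.
#' @export
#' @examples
#' lp <- completion_logprob(-log(2), 1)
#' orpo_loss(lp, lp)$or_loss # log(2): even odds
orpo_loss <- function(chosen, rejected, beta = 0.25, normalize = TRUE) {
  stopifnot(beta >= 0)
  lw <- if (normalize) chosen$total_logprob / chosen$token_count else chosen$total_logprob
  ll <- if (normalize) rejected$total_logprob / rejected$token_count else rejected$total_logprob
  log_or <- log_odds_from_logprob(lw) - log_odds_from_logprob(ll)
  or_loss <- log_sigmoid_neg(log_or)
  sft_nll <- -lw
  list(
    sft_nll = sft_nll,
    or_loss = or_loss,
    log_odds_ratio = log_or,
    total = sft_nll + beta * or_loss
  )
}

#' DPO loss for one chosen/rejected pair
#'
#' Direct preference optimization against a frozen reference model:
#' \deqn{L = -\log\sigma\big(\beta[\log P_\theta(y_w) - \log P_{ref}(y_w)]
#'                        - \beta[\log P_\theta(y_l) - \log P_{ref}(y_l)]\big)}
#'
#' @param policy_w,policy_l [completion_logprob()]s under the trainable
#'   policy for the chosen and rejected completions.
#' @param ref_w,ref_l [completion_logprob()]s under the frozen reference.
#' @param beta Scale of the log-ratio margin (> 0; default 0.1).
#' @return List with `margin` and `loss`.
#' @export
dpo_loss <- function(policy_w, policy_l, ref_w, ref_l, beta = 0.1) {
  stopifnot(beta > 0)
  margin <- beta * (policy_w$total_logprob - ref_w$total_logprob) -
    beta * (policy_l$total_logprob - ref_l$total_logprob)
  list(margin = margin, loss = log_sigmoid_neg(margin))
}

#' Mean loss over a batch of preference pairs
#'
#' @param records List of records. For `kind = "orpo"` each record needs
#'   `chosen` and `rejected` ([completion_logprob()]s); for `kind = "dpo"`
#'   additionally `ref_chosen` and `ref_rejected`.
#' @param beta Objective weight, passed through.
#' @param kind `"orpo"` or `"dpo"`.
#' @param normalize Passed to [orpo_loss()].
#' @return List with `mean_loss` and `per_record` (list of per-pair parts).
#' @export
batch_loss <- function(records, beta, kind = c("orpo", "dpo"), normalize = TRUE) {
  kind <- match.arg(kind)
  if (length(records) == 0) stop("empty batch", call. = FALSE)
  per <- lapply(records, function(r) {
    if (kind == "orpo") {
      orpo_loss(r$chosen, r$rejected, beta = beta, normalize = normalize)
    } else {
      dpo_loss(r$chosen, r$rejected, r$ref_chosen, r$ref_rejected, beta = beta)
    }
  })
  totals <- vapply(per, function(p) if (kind == "orpo") p$total else p$loss, numeric(1))
  list(mean_loss = mean(totals), per_record = per)
}

#' Read completion log-probabilities from JSONL
#'
#' One object per line:
#' `{id, chosen: {logprob, tokens}, rejected: {logprob, tokens},
#'   ref_chosen?, ref_rejected?}`.
#'
#' @param path Path to a `.jsonl` file.
#' @return List of records suitable for [batch_loss()].
#' @export
read_logprobs <- function(path) {
  lapply(read_jsonl(path), function(o) {
    r <- list(
      sample_id = o$id,
      chosen = completion_logprob(o$chosen$logprob, o$chosen$tokens),
      rejected = completion_logprob(o$rejected$logprob, o$rejected$tokens)
    )
    if (!is.null(o$ref_chosen)) {
      r$ref_chosen <- completion_logprob(o$ref_chosen$logprob, o$ref_chosen$tokens)
      r$ref_rejected <- completion_logprob(o$ref_rejected$logprob, o$ref_rejected$tokens)
    }
    r
  })
}
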