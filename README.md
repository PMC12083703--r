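# prefalign

Tools for transferring a ranked-output classifier's decision pattern to a
generative language model through preference optimization — and for grading
the result.

The motivating setting is biomedical label prediction: an encoder classifier
(e.g. a multimodal model ranking ~500 rare-disease labels from clinical
phenotype text, or a pathology vision-language model ranking 19 tissue
types) produces calibrated ranked lists, while a general-purpose LLM asked
the same question hallucinates and misranks. `prefalign` builds the bridge:

* **Preference datasets.** For each sample, the classifier's top-*k* labels
  become the *chosen* completion and its bottom-*q* the *rejected* one, with
  a truth-first guarantee (the ground truth is swapped into, or inserted at,
  position 1 of the chosen list) and enforced chosen/rejected disjointness.
  The balance *k/q* is the Acceptance-over-Rejection (AoR) ratio.
* **Objectives.** ORPO and DPO as pure functions of completion
  log-probabilities, in nats, stable in log space:

  ```
  L_ORPO = L_SFT + β·(−log σ(log odds P(y_w|x) − log odds P(y_l|x))),  odds P = P/(1−P)
  L_DPO  = −log σ(β log[P_θ(y_w)/P_ref(y_w)] − β log[P_θ(y_l)/P_ref(y_l)])
  ```

* **Evaluation.** Free-text ranked-list answers are parsed, fuzzy-matched
  against the label vocabulary with the Ratcliff/Obershelp ratio
  (abbreviation-aware; permissive 0.6 threshold for the hallucination check,
  strict 0.8 for correctness), and summarized as Hallucination-Free Accuracy
  (HFA), Top-N, Top-1, and the Coverage-Avoidance Rate

  ```
  CAR = mean over samples of (1+λ)·C·A / (λ·C + A)
  ```

  where C is the fraction of the response covered by the classifier's
  truth-first top-*k* and A the fraction avoiding its bottom-*q*.
* **Synthetic harness.** A binomially calibrated upstream-classifier
  simulator, a patient-record generator over phenotype-term vocabularies,
  response simulators of controllable quality/corruption, and a toy
  character-level LM trained with the ORPO objective so the whole loop runs
  end to end in seconds on a CPU.

## Worked example

Build a synthetic cohort, align the toy model, and grade it:

```r
library(prefalign)

res <- run_synthetic_pipeline(
  n_labels = 12, n_train = 80, n_test = 40, k = 3, q = 3,
  accuracy = 0.95, n_top = 5, responder = "toy",
  toy_cfg = toy_lm_config(context_len = 8, epochs = 4, seed = 11), seed = 7
)
res$fit$log
#> # A tibble: 5 × 4
#>   epoch mean_loss mean_margin mean_sft_nll
#>   <int>     <dbl>       <dbl>        <dbl>
#> 1     0     4.02     0.000475        3.85
#> 2     1     1.78     0.0762          1.62
#> 3     2     1.21     0.140           1.05
#> 4     3     0.932    0.197           0.780
#> 5     4     0.778    0.240           0.632
res$report
#> <eval_report> n=40  HFA 100.00%  Top-5 70.00%  Top-1 37.50%  CAR 0.4385
```

The training log shows the ORPO dynamics: the supervised term
(`mean_sft_nll`) falls as the model memorizes chosen lists, while the mean
chosen-vs-rejected log-odds margin (`mean_margin`) grows from ~0 to
0.24 nats — the model increasingly prefers the classifier's likely labels
over its unlikely ones. On 40 held-out patients the aligned model answers
with real label names only (HFA 100%), places the true label in its top
five 70% of the time and first 37.5% of the time (untrained baseline:
chance, ~8%), and reaches a CAR of 0.44.

The pieces are available individually. One preference record:

```r
space <- simulate_label_space(12, seed = 7)
terms <- simulate_term_dictionary(space, seed = 8)
pts   <- simulate_patients(3, space, terms, seed = 9)
prompt <- format_patient_prompt(pts[[1]], terms$dict)
#> "The patient is a 59-year-old African female with the following clinical
#>  features: background feature 6, characteristic facies of nukabo lisu"

truths <- setNames(vapply(pts, `[[`, "", "true_label"), vapply(pts, `[[`, "", "id"))
preds  <- simulate_upstream(truths, space, accuracy = 0.9, seed = 10)
rec <- build_preference_record(preds[[1]], prompt, k = 3, q = 3, space)
cat(rec$chosen_text)
#> 1. nukabo lisu
#> 2. rute bolevo
#> 3. zomene vulara
```

and the loss at a known point (chosen per-token probability 0.8 vs rejected
0.5, so the log odds ratio is ln 4):

```r
orpo_loss(completion_logprob(log(0.8), 1), completion_logprob(log(0.5), 1), beta = 0.25)
#> $sft_nll 0.223  $or_loss 0.223  $log_odds_ratio 1.39  $total 0.279
```

A command-line wrapper over the same functions is installed at
`system.file("cli", "prefalign", package = "prefalign")`, with subcommands
`simulate`, `build-prefs`, `loss`, `eval`, and `sweep-aor`.

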