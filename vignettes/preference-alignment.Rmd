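---
title: "Preference alignment from ranked classifier outputs: models, metrics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Preference alignment from ranked classifier outputs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prefalign)
```

## The problem

A well-trained encoder classifier — say a multimodal model that predicts a
rare genetic disease from facial photographs and clinical phenotype text, or
a pathology vision-language model that classifies a tissue of origin from a
nucleus image — produces a calibrated *ranked list* over a closed label
vocabulary. A generative language model, asked the same question in free
text, has far weaker discrimination but much stronger language and reasoning
ability. Preference optimization lets us graft the classifier's decision
pattern onto the generative model: the classifier's most-probable labels
become *chosen* completions, its least-probable labels become *rejected*
completions, and the generative model is trained to prefer the former.

`prefalign` implements the computational core of that pipeline in a
model-agnostic way:

1. **dataset construction** — truth-first chosen/rejected records from
   ranked predictions;
2. **objectives** — the ORPO (odds-ratio) and DPO (direct preference)
   losses as pure functions of completion log-probabilities;
3. **evaluation** — fuzzy-matched grading of free-text ranked lists:
   hallucination-free accuracy (HFA), Top-N, Top-1, and the
   Coverage-Avoidance Rate (CAR);
4. **synthetic data** — a calibrated upstream-classifier simulator, a
   patient-record generator, and a toy character-level LM so the whole loop
   runs on a desktop in seconds.

## Preference records and the truth-first rule

For each sample the upstream classifier gives probabilities over the label
space. `rank_labels()` sorts descending, breaking ties by ascending
`label_id` so the ordering is canonical regardless of map iteration order.
A record for list sizes $(k, q)$ takes the top-$k$ as *chosen* and the
bottom-$q$ (least probable first) as *rejected*. The **truth-first rule**
guarantees the ground truth leads the chosen list:

* truth already first — unchanged;
* truth elsewhere in the top-$k$ — swapped with position 1 (the set is
  preserved);
* truth outside the top-$k$ — inserted at position 1, the former $k$-th
  element dropped.

The swap and the insert-and-truncate paths are both needed: swapping alone
cannot help when the classifier missed the truth entirely, and substitution
alone would discard a correct top-$k$ member. If the truth falls in the
bottom-$q$, it is removed from the rejected list and the next-lowest label
backfills, so chosen and rejected are always disjoint — a requirement for a
coherent preference pair. The **Acceptance-over-Rejection ratio**
$\mathrm{AoR} = k/q$ summarizes the balance of a setting; $k = q$ is the
balanced case.

## The objectives

Both objectives consume only `(total log-probability, token count)` pairs,
so they apply to any model that can score a completion.

**ORPO** performs supervised fine-tuning and preference separation in one
stage:

$$
L = L_{\mathrm{SFT}} + \beta\, L_{\mathrm{OR}}, \qquad
L_{\mathrm{OR}} = -\log \sigma\!\left(
  \log\frac{\mathrm{odds}\,P(y_w \mid x)}{\mathrm{odds}\,P(y_l \mid x)}
\right),
\qquad \mathrm{odds}\,P = \frac{P}{1 - P},
$$

where $y_w$, $y_l$ are the chosen and rejected completions. **DPO**
instead compares a trainable policy against a frozen reference model:

$$
L = -\log \sigma\!\left(
  \beta \log\frac{P_\theta(y_w \mid x)}{P_{\mathrm{ref}}(y_w \mid x)}
- \beta \log\frac{P_\theta(y_l \mid x)}{P_{\mathrm{ref}}(y_l \mid x)}
\right).
$$

Numerical choices:

* **Length normalization (default on).** The probability entering the odds
  is the per-token geometric mean $\exp(\ell/T)$. Joint sequence
  probabilities of realistic completions are astronomically small, which
  drives $\mathrm{odds}(P) \to P$ and makes $\beta$ uninterpretable across
  completion lengths; the token-mean convention keeps the odds in a useful
  range. The un-normalized mode is available (`normalize = FALSE`), and the
  SFT term follows the same convention (token-mean vs token-sum).
* **Log-space throughout.** $\log \mathrm{odds}(e^\ell) =
  \ell - \log(-\mathrm{expm1}(\ell))$ and $-\log\sigma(x) =
  \mathrm{softplus}(-x)$ via `log1p`, so inputs as extreme as
  $\ell = -10^4$ stay finite. Probabilities are clamped to
  $(10^{-12},\, 1 - 10^{-12})$.
* **Defaults** $\beta = 0.25$ (ORPO) and $\beta = 0.1$ (DPO). These are the
  conventional magnitudes for the two objectives; both are plain arguments.
  At $\beta = 0$ ORPO reduces exactly to supervised fine-tuning.

At zero margin both losses equal $\ln 2$, which the test suite pins to
$10^{-12}$; both are strictly positive and strictly decreasing in their
margin.

## Grading free-text ranked lists

Responses are parsed with a tolerant numbered-list parser (`1.`, `2)`,
`(3)`, and `-` bullets); parsing never raises, and an answer with no
recognizable entries simply fails. Entries beyond the expected list length
are truncated and flagged, since the output contract asks for exactly $N$
names.

Name comparison uses the Ratcliff/Obershelp ratio $2M/T$ (the classic
sequence-matcher gestalt ratio), computed after a shared normalization:
case-fold, trim, collapse internal whitespace, strip trailing periods. The
implementation resolves longest-match ties leftmost-in-first-string and is
cross-checked in the tests against an independently written recursive
reference and against the Python standard library's matcher. Two thresholds
are used, following standard practice for this grading task:

* **0.6 for plausibility (HFA).** The hallucination check only asks whether
  each name is a near-miss of *some* vocabulary entry, so it is permissive
  to minimize false alarms. Under the default `all` rule a single
  fabricated name fails the response; `any` and `majority` switches are
  provided.
* **0.8 for correctness.** Top-N, Top-1 and CAR matching require high
  precision. Abbreviations are handled by extracting any parenthesized
  token and comparing every candidate form against both the canonical name
  and the entry's abbreviation, so `"CdLS"` matches
  `"Cornelia de Lange Syndrome"`.

Top-N and Top-1 are computed only for responses that pass HFA and count as
failures otherwise, so $\text{Top-1} \le \text{Top-N} \le \text{HFA}$ holds
by construction on every run.

**Coverage and avoidance.** With $T_k$ the truth-first top-$k$ and $B_q$
the bottom-$q$ of the upstream prediction, a response $R$ scores

$$
C = \frac{|R \cap T_k|}{|R|}, \qquad
A = 1 - \frac{|R \cap B_q|}{|R|},
$$

where the "intersection" is a greedy one-to-one fuzzy assignment (pairs
taken in decreasing similarity, each name used at most once). Exact-string
set intersection is only well defined for identical strings; the greedy
rule extends it to fuzzy matches and reduces to plain intersection at
threshold 1.0 — which is exactly what the oracle-equivalence tests exploit.
The **Coverage-Avoidance Rate** aggregates per-sample pairs by a weighted
harmonic mean:

$$
\mathrm{CAR} = \frac{1}{N} \sum_{i=1}^{N}
\frac{(1+\lambda)\, C_i A_i}{\lambda C_i + A_i},
$$

with the $0/0$ term defined as 0 (conservative: a sample with no coverage
and no avoidance signal contributes nothing). $\lambda = 1$ is the plain
harmonic mean and the default, matching the balanced $k = q$ settings used
in both motivating tasks; the identity
$\mathrm{CAR}(C, A, \lambda) = \mathrm{CAR}(A, C, 1/\lambda)$ and the
$\lambda \to 0, \infty$ limits (recovering $C$ and $A$) are enforced in the
tests. An empty response receives $C = A = 0$ and a flag.

## What the synthetic generator emulates — and what it does not

The simulator stands in for the upstream multimodal classifier and for the
graded language model, at the scale of a desk experiment:

* `simulate_label_space(n)` builds pronounceable two-word pseudo-names,
  rejection-sampled so no two canonical names reach similarity 0.8 —
  grading on synthetic data is therefore unambiguous by construction.
  Roughly 30% of labels carry an initial-letter abbreviation.
* `simulate_upstream(..., accuracy = a)` draws Gaussian logits, applies a
  softmax at the requested temperature, then makes the truth the argmax
  with probability exactly $a$ (otherwise a uniformly chosen other label
  wins, by swapping scores). The top-1 hit rate is thus Binomial$(n, a)$,
  which the calibration tests verify at three accuracy levels within
  3 binomial standard deviations at $n = 2000$.
* `simulate_patients()` gives each label one characteristic phenotype term
  whose text ends with the label name, placed last in the prompt, plus
  shared background terms and simple demographics. The prompt *tail* thus
  identifies the label, which is what makes the mapping learnable by a
  character-level model with a short context window.
* `simulate_responses(..., quality, corruption)` emits the truth-first top
  list with probability `quality`, a random label list otherwise, and can
  inject fabricated or misspelled names to exercise the hallucination
  check.

What this does **not** emulate: real clinical language (narrative notes,
negations, synonymy), correlated classifier errors between visually or
phenotypically similar classes, ontology structure among phenotype terms,
and realistic label-name similarity (real disease names share long common
substrings; synthetic ones deliberately do not). Passing tests on synthetic
data therefore demonstrate the *correctness of the machinery* — list
construction, losses, grading arithmetic — not clinical performance of any
aligned model.

## The toy language model

The end-to-end harness trains the smallest model that can exercise the
alignment loop: a linear-softmax character model whose next-character
logits are a linear function of the one-hot encodings of the previous
`context_len` (default 8) characters — about $10^4$ parameters on a typical
vocabulary, trained by plain SGD with analytic gradients through the ORPO
loss (token-mean convention). A deliberate design choice is to keep it
linear rather than give it a hidden layer: the synthetic prompt-tail
signal is linearly separable, convergence is fast and monotone, and the
gradient derivation stays auditable against the finite-difference checks in
the test suite. With `beta = 0` training provably touches only the chosen
completions (verified by training on record sets that differ only in their
rejected lists).

The model "responds" by scoring each label name, rendered as the first line
of the numbered output contract, and ranking by per-token mean
log-probability; length normalization prevents short names from winning by
default. The training log records the mean chosen-vs-rejected log-odds
margin at epoch 0 and after each epoch; on the standard fixture
(12 labels, 80 training records, $k = q = 3$, 4 epochs) the margin grows by
roughly 0.2–0.3 nats and held-out Top-1 rises from chance (~8%) to ~50%.
These problem sizes were chosen as the smallest at which the effect is
unmistakable while a full run stays in the low seconds; the acceptance
script uses the same sizes.

## Degenerate inputs and tie-breaks

* Probability vectors must sum to 1 within $10^{-6}$; drifts up to
  $10^{-3}$ (typical of float dumps from real classifiers) are renormalized
  with a warning, larger discrepancies are an error.
* Score ties break by ascending `label_id`, so output never depends on the
  iteration order of a JSON map.
* $k + q$ exceeding the number of scored labels is an error naming the
  infeasible AoR setting; infeasible sweep grid points are skipped with a
  warning.
* Empty demographic fields drop out of the prompt without dangling
  punctuation; an all-empty demographic record yields the phenotype text
  alone.
* Duplicate canonical names (after normalization) and ambiguous
  abbreviations are rejected at label-space construction.

## Known limitations

* The greedy fuzzy assignment in $C$/$A$ is not a maximum bipartite
  matching; with pathological similarity patterns it can differ from the
  optimal assignment by one pair. At threshold 1.0 (and on synthetic
  spaces, by construction) the two coincide.
* The toy LM shares the vocabulary between training texts and scoring, and
  maps unseen characters to an unknown token; it is a harness for the
  objective, not a language model of any fidelity.
* CAR's $\lambda$ is a free parameter; reported values are only comparable
  at a fixed $\lambda$ (default 1).
* The evaluation treats each response name independently; it does not
  penalize duplicated names beyond the one-to-one matching rule.
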