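---
title: "Fuzzy rank-based ensemble fusion: model, pipeline, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy rank-based ensemble fusion: model, pipeline, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzrank)
```

## The fusion model

An ensemble of K text classifiers emits, for each test item, a
probability vector over C classes (here C = 2: 0 = genuine, 1 = fake).
Soft voting averages these vectors with fixed weights and takes the
argmax, treating a hesitant classifier the same as a confident one.
Fuzzy rank fusion instead lets each classifier's *confidence on this
particular item* set its influence.

Each confidence $p_{kc}$ is transformed into a fuzzy rank with a
reparameterized Gompertz function

$$R(p) = 1 - \exp(-\exp(-s\,p)), \qquad s > 0,$$

a double-exponential sigmoid that is strictly decreasing in $p$: full
confidence ($p=1$) earns the best rank $1-\exp(-e^{-s})$ (about 0.127 at
the default $s=2$), and no confidence ($p=0$) the worst, $1-e^{-1}
\approx 0.632$. Per class, the ranks are summed,
$RS_c = \sum_k R(p_{kc})$, and weighted by the complement confidence
factor $CCF_c = 1 - \tfrac1K \sum_k p_{kc}$, which is small exactly when
the ensemble collectively backs class $c$. The fused score is the
product $FS_c = RS_c \cdot CCF_c$ and the decision is $\arg\min_c FS_c$.
Both factors decrease as confidence in $c$ rises, so the fused score is
monotone in the evidence: with a single classifier, or with K identical
rows, the argmin provably reduces to the row argmax (the package's test
suite scans a 0.01 grid of two-class confidences to confirm this).

Ties between fused scores are broken toward the lowest class index — a
deterministic rule chosen for reproducibility; with continuous
confidences ties have measure zero.

### The ROC score for a decision-level fusion

The fusion is a decision rule, not a probability model, so an AUC needs a
documented score construction. We use
$$\mathrm{score} = \frac{FS_0}{FS_0 + FS_1},$$
i.e. the genuine class's share of the total fused score, which is
monotone in the evidence for "fake", bounded in $[0,1]$, equals 0.5 under
full symmetry, and is defined as 0.5 when both fused scores vanish. Any
strictly increasing transform of a score leaves the Mann–Whitney AUC
unchanged, so the choice among monotone constructions only matters up to
monotonicity — but it is a choice, and results quoting an AUC for the
fused decision depend on it.

### Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `gompertz_scale` (s) | 2.0 | Steepness of the rank transform; larger s compresses ranks for high confidences (unitless). |
| `tie_break` | lowest-class-index | Deterministic tie rule. |
| row-sum tolerance | 1e-6 | Validation slack for softmax float noise; optional renormalization instead of rejection. |

The scale s = 2 spans ranks over roughly [0.13, 0.63] on the unit
confidence interval, keeping the transform well away from saturation at
both ends; it is exposed in `fusion_config()` rather than hard-coded.

## The corpus pipeline

The pipeline mirrors how a misinformation corpus is actually assembled
from heterogeneous sources:

1. **Cleaning** removes URLs (`http(s)://`, `www.` forms) and emoji
   (standard emoji Unicode blocks), collapses whitespace, and trims;
   cleaning is idempotent, and records that become empty are flagged
   rather than dropped.
2. **Deduplication** removes exact matches on case-folded,
   whitespace-collapsed text, keeping the first occurrence. Nothing
   fuzzier is attempted: near-duplicate detection would need a similarity
   threshold that is itself a modeling decision.
3. **Keyword filtering** keeps texts containing at least one topic
   keyword (14 long-COVID/reinfection terms by default) as a
   case-insensitive substring. Substring semantics deliberately let
   "long-term" match "Long-Term effects" — and make "subvariant" imply a
   "variant" hit, which the profiling functions treat consistently.
4. **Label harmonization** maps each source's verdict vocabulary to
   binary genuine/fake via an explicit, swappable map
   (`default_label_map()`): PolitiFact keeps true/mostly-true as genuine;
   Snopes keeps true/mostly-true/correct-attribution as genuine and
   treats its other 11 verdicts as fake. Unmapped labels are errors that
   name the source and label — silent drops would corrupt the ledger.
5. **Stratified splitting** allocates a 10% test share by default. The
   total test size is round-half-up of `test_fraction × N`; per-class
   counts use largest-remainder apportionment so they sum exactly to the
   total. At N = 2927 with 2361 fake / 566 genuine this yields 293 test
   (236 fake + 57 genuine) and 2634 train records, exactly preserving
   the class imbalance the corpus exhibits.

```{r split}
g <- gen_corpus(corpus_gen_config())     # defaults: 2361 fake + 566 genuine
sp <- stratified_split(g$records, 0.1, seed = 20)
c(train = length(sp$train_ids), test = length(sp$test_ids))
```

## Text profiling

Polarity (−1..1) and subjectivity (0..1) scores come from any external
lexicon scorer — scoring internals are not this package's contribution,
so the profiling module consumes numbers, not text. Scores are bucketed
into five categories each, with cut points at −0.5, −0.1, 0.1, 0.5
(polarity) and 0.2, 0.4, 0.6, 0.8 (subjectivity). Prose descriptions of
such ranges are ambiguous at the boundaries (−0.5 belongs to two
"between" phrases); we resolve every interval as left-closed/right-open
with the final interval closed, making the mapping total, deterministic,
and order-preserving. Keyword occurrence is counted as per-record
*presence*, not per-mention frequency.

## Baselines

The TF-IDF + linear SVM baseline uses unigram features fit on the
training set only: raw term counts, smoothed inverse document frequency
$\mathrm{idf}(t) = \ln\frac{1+N}{1+\mathrm{df}(t)} + 1$, L2-normalized
rows, and out-of-vocabulary tokens ignored at transform time.
Tokenization lowercases, splits on non-alphanumeric runs, and keeps
tokens of length ≥ 2 — a deliberately plain scheme, stated so it can be
reproduced. The SVM (via `e1071`, C = 1, no class weighting) is trained
with stratified 5-fold cross-validation; the fold model with the highest
validation F1 for the fake class is kept, consistent with selecting
checkpoints by validation F1.

The parameter counter is purely analytic: it sums tensor sizes from an
architecture description (`arch_spec()`), including all biases and layer
norms and excluding non-trainable buffers. The three base presets
reproduce the published totals exactly:

```{r params}
sapply(c("bert-base", "roberta-base", "xlnet-base"),
       function(p) count_transformer_params(arch_preset(p)))
```

The three head styles (pooler+linear, dense+projection,
summary+projection) happen to contain identically many scalars at equal
widths; they are kept distinct in the API because they are structurally
different and future families may diverge. A DeBERTa-style count is not
offered: disentangled attention admits several tensor layouts with
different totals, and guessing one would produce a number with false
authority.

## Evaluation

Precision, recall and F1 take the fake class (label 1) as positive —
with a fake-heavy test set this is the convention under which high
recalls are informative. Undefined ratios (e.g. precision with no
positive predictions) are reported as `NA` with a reason, never silently
as 0. AUC is the Mann–Whitney statistic with half-credit ties, computed
via midranks and verified in the tests against an $O(n^2)$ pairwise
enumeration and against `pROC`.

## The synthetic-data generators

The corpus generator emulates the *statistical* structure the pipeline
assumes — not linguistically realistic misinformation. Texts are built
from a fixed neutral filler vocabulary (screened so no topic keyword
occurs as a substring, including across token boundaries) plus
class-conditionally planted keywords; duplicates, URLs and emoji are
planted at configured rates with exact bookkeeping. Defaults: 2361 fake
/ 566 genuine records; "immune" in 55% of fake vs 5% of genuine texts
and "recovery" in 25% vs 30%, with the remaining twelve keywords at low
background rates leaning fake; 5% duplicates; URL and emoji rates 0.3.
Duplicate copies stay within the class of their source and perturb only
case/whitespace, so the planted count equals exactly what
clean-then-dedup removes.

The ensemble generator draws, per item, a truth label (fake prior 0.8,
close to the corpus imbalance), couples the K classifiers' correctness
through a shared latent uniform (the `correlation` knob is the
probability of reusing the shared latent; at 1 with equal accuracies all
classifiers err on identical items), and gives the predicted class a
confidence $0.5 + 0.5\,\mathrm{Beta}(5, 2)$ — rescaling to $[0.5, 1]$
guarantees the predicted class is the row argmax, cleanly separating the
correctness knob from the calibration knob. Problem sizes used in the
checks (1,000 records per class for prevalence recovery, 5,000 items for
accuracy recovery and fusion comparisons) keep Monte-Carlo error well
inside the 99% binomial bands while the whole suite runs in under a
minute on one CPU.

What passing these tests shows — and does not show: the pipeline
recovers planted structure and the fusion arithmetic is exact, but
synthetic filler text says nothing about how real misinformation
vocabulary, style, or topical drift affect upstream classifiers. The
demonstration that fuzzy fusion beats the *mean* single-classifier
accuracy in the default regime (accuracies 0.9/0.8/0.7, correlation 0.3)
is regime-dependent, not a theorem: with highly correlated errors or one
dominant classifier, fusion can fall below the *best* member, and does
not claim otherwise.

## Numerical choices and degenerate inputs

- Probability rows must sum to 1 within 1e-6; optional renormalization
  handles softmax float noise without hiding genuinely malformed input.
- `fused_score = rank_sum × ccf` holds to 1e-12 by construction; the
  unanimous-certainty case drives one CCF, hence one fused score, to
  exactly 0, and the ROC score's 0/0 case is defined as 0.5.
- Splitting a class with fewer than one test candidate is an error, not
  a silent empty stratum.
- All randomness flows through explicit seeds (`withr::with_seed`); no
  function touches the global RNG state.

## Limitations

- Confidence calibration (Platt/isotonic) is out of scope; fuzzy ranks
  consume confidences as given, and badly calibrated classifiers shift
  the fusion's operating point.
- No learned meta-classifier: the fusion has no trainable weights by
  design.
- Rank clipping to a top-κ subset of classifiers (a variant of the rank
  fusion family) is not implemented; with K = 3 classifiers it would
  rarely bind.
- Exact-match deduplication misses paraphrased duplicates.
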