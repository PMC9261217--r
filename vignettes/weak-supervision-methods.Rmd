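---
title: "Methods: weak supervision for lifestyle-status sentence classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weak supervision for lifestyle-status sentence classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## Overview

`weaklabelr` implements a complete weak-supervision study for sentence-level
classification of lifestyle status in clinical-style text. Two tasks are
supported:

* **activity** — binary: `physical_activity` vs `physical_inactivity`;
* **diet** — five classes: `normal_diet`, `high_calorie_diet`,
  `high_fat_diet`, `high_salt_diet`, `nonspecific_abnormal`.

The study design is: a deterministic **rule-based labeler** assigns noisy
("weak") labels to a large unannotated sentence pool; supervised **TF-IDF
n-gram baselines** are trained on those weak labels; both the rules and the
trained models are evaluated against a held-out **gold-standard corpus (GSC)
stand-in** whose labels are correct by construction. Because real clinical
notes cannot be redistributed, the package ships a **synthetic template
generator** that plays the role of the private EHR corpus and provides exact
generation-trace gold labels.

## The rule-based weak labeler

A sentence is normalized (lower-cased, punctuation stripped, whitespace
collapsed — `normalize_text()` is idempotent) and tokenized on spaces.
Keyword phrases from a task lexicon are scanned left to right; at each
position the longest matching phrase shadows shorter ones. When several
candidate matches exist, ties are broken by (1) leftmost match, (2) longest
phrase, then (3) a fixed class priority (`high_calorie` > `high_fat` >
`high_salt` > `normal` for diet; `inactivity` > `activity` for activity).

Each matched keyword receives a rule **code**:

| code | meaning |
|---|---|
| 1 | keyword asserted (no modifier in scope) |
| −1 | negated: a negation term occurs within the **5 tokens before** the keyword |
| 0 | match voided (e.g. a negated high-X diet mention is dropped) |
| 4 | prospective trigger before "normal diet" (e.g. "can resume normal diet") → relabeled `nonspecific_abnormal` |

Negation semantics differ by task. For **activity**, negation flips to the
opposite class (`didnt exercise` → `physical_inactivity`). For **diet**,
a negated `normal_diet` becomes `nonspecific_abnormal`, while a negated
high-calorie/fat/salt mention is voided (code 0) and scanning continues with
the next candidate. Negation takes precedence over prospective triggers.
Sentences with no surviving match are excluded from the weak pool rather
than given a default class.

Two lexicon **profiles** ship per task: `strict` (the minimal published-style
keyword set) and `extended` (adds common paraphrases such as
*exercise/works out* style verbs and *fatty food*, *salt restrictions*).
Lexicons are plain YAML under `inst/lexicons/` and can be loaded, edited and
round-tripped with `read_lexicon()` / `write_lexicon()`.

```{r}
lx <- default_lexicon("activity", "extended")
classify_sentence(normalize_text("The patient didn't exercise last year."), lx)
```

## Synthetic corpus generator

Sentences are composed from a template grammar:

```
subject  verb  [negator  filler^(d-1)]  keyword-phrase  trailer
```

where the negator, when present, sits at an exact token distance `d` from the
keyword (`d − 1` neutral filler tokens in between). Key parameters, all fixed
a priori in `generator_config()`:

* **class priors** — activity 95.7/4.3 %; diet 33.8/17.4/15/28.2/5.6 %.
  These are the package's chosen defaults for a realistically imbalanced
  corpus; `make_gsc_standin()` also accepts explicit `class_counts`
  (e.g. 78/122 and 18/20/20/18/12) for fixed-composition evaluation sets.
* **negated_fraction = 0.15** — fraction of sentences carrying a negator.
  Chosen a priori as a compromise: large enough that negation handling
  matters to the learned models, small enough that class priors stay close
  to their nominal values.
* **distance distribution** — `d` uniform on 1..7, deliberately straddling
  the 5-token negation window so that some negators are out of scope.
* **template splits** — `train` and `heldout` template families use disjoint
  subject and verb inventories, so GSC sentences never reuse training
  surface forms; `run_pipeline()` additionally hard-errors on any literal
  text overlap between training data and the GSC.
* **out_of_lexicon_fraction** — optional share of sentences whose keyword is
  an out-of-lexicon paraphrase (e.g. *works out*, *salty snacks*). These are
  invisible to the rule labeler but carry correct gold labels, which is how
  the package demonstrates the recall ceiling of strict lexicons.

The **gold label is the rule semantics of the generation trace**: a negator
placed at `d > 5` does *not* flip the gold label, matching the labeler's
window definition. Consequently the rule labeler is an exact oracle on clean
in-lexicon corpora (`weak_label_oracle()` agreement is 100 %), and label
noise is introduced only explicitly via `derive_weak_labels(corpus, epsilon)`
which flips each weak label to a random other class with probability ε.

One identifiability caveat is recorded here deliberately: the baselines use
uni/bi/trigram features, so negator–keyword distances of 3..7 tokens are
indistinguishable to the models even though the rule labeler resolves them
exactly. This is a property of bag-of-n-grams representations, not a defect
of the generator.

## Baseline models

Features are hand-rolled sparse TF-IDF over word uni/bi/trigrams
(`fit_tfidf()` / `transform_tfidf()`): smoothed inverse document frequency
`log((1 + N) / (1 + df)) + 1` followed by L2 row normalization. The
vectorizer is always fitted on training folds only; `grid_search_cv()`
refits it per fold.

* **Logistic regression** — ridge-penalized `glmnet` at
  `lambda = 1 / (C · n)` with `C = 100`. The fit uses a decreasing warm-start
  lambda path ending at the target value (a single very small lambda
  under-converges); prediction is at the target lambda.
* **Linear SVM** — `e1071` with `C = 10`. Multiclass uses one-vs-rest with
  decision-value sign calibration (the sign is oriented by comparing mean
  decision values on positive vs negative training examples); a class absent
  from a training fold scores `-Inf`.
* **Random forest** — `randomForest` with `ntree = 10`.

These hyperparameters are the study's fixed defaults; `grid_search_cv()`
supports small grids selected by mean support-weighted F1 (first index wins
ties). Arbitrary user models plug into the roster as
`function(texts, labels, seed)` returning an object with a `predict` method.

## Evaluation protocol

`compute_metrics()` reports per-class precision/recall/F1/support plus
support-weighted and macro averages. Zero-denominator cells are reported as
0 with a warning (this convention, not NA, keeps seed averages defined).
Gold labels must lie inside `class_set`; predictions outside it (e.g. the
rule labeler's abstention) count as misses for every true class. For
single-label tasks with in-set predictions, weighted recall equals accuracy.

`run_pipeline()` performs, for each split seed in {24, 48, 128}: a 90/10
train/validation split of the weak pool, model training on the 90 %, and
evaluation on the fixed GSC; reports are then averaged metric-wise over
seeds (`average_over_seeds()`), and a `rule_based` row is always included.
`run_ablation()` trains on nested shuffle-prefix subsamples of the weak pool
(each smaller fraction is a prefix of the larger one) while the GSC is held
byte-identical across fractions (fingerprint-checked), so the curve isolates
the effect of weak-data quantity.

All stochastic steps run under `withr::with_seed()`; a config hash
(`rlang::hash`) ties run artifacts (manifest, weak labels, reports, event
log) to the exact configuration.

## Reproducing the study

```{r}
cfg <- experiment_config(task = "activity", n_sentences = 2000,
                         gsc_size = 500, seed = 1,
                         out_dir = "runs/activity_clean")
res <- run_pipeline(cfg)
res$table

abl <- run_ablation(cfg)
abl$curve
```

`scripts/acceptance.R` recomputes the headline quantities end to end from a
single `--seed` argument.
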