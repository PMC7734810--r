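---
title: "Methods: the two-stage screening cascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the two-stage screening cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(picoscreen)
```

## The screening problem

Systematic literature reviews select studies in two stages: title/abstract
screening followed by full-text review, with every exclusion recorded
against a PICOS eligibility criterion (population, intervention, comparator,
outcomes, study design, plus "other" and "time" in practice). picoscreen
automates the abstract stage as a *cyborg* workflow: a classifier excludes
citations it is confident about — with a stated reason — and leaves
everything else to the human reviewer. The design goal is asymmetric:
falsely excluding a relevant study is costly, while passing an irrelevant
one forward merely adds a little human work. Sensitivity is therefore
prioritized over specificity throughout.

## The cascade

A fitted `screening_model` contains an *overall* include/exclude classifier
and one *pairwise* classifier per exclusion reason, each trained on the
subset of includes plus the excludes carrying that reason. At prediction
time:

1. If the overall exclusion probability is below the threshold, the outcome
   is `include` (the citation goes to the reviewer as usual).
2. Otherwise the pairwise models are consulted. Reasons whose exclusion
   probability also meets the threshold *qualify*; the citation is excluded
   with the highest-priority qualifying reason under the fixed hierarchy
   `study_design > population > intervention > comparator > outcomes >
   other > time`.
3. If no reason qualifies, the outcome is `unclassified` and the citation is
   returned to the human.

The pairwise stage is only consulted after the overall gate: the flow runs
overall-first, and a citation is never excluded on reason evidence alone.
Comparison with the threshold is inclusive (`>=`), so a probability exactly
at the threshold qualifies; this boundary choice is pinned for
reproducibility. The default threshold is 0.90, selected as the ROC point
closest to the top-left corner in preliminary work; `select_threshold()`
implements that rule (ties toward the higher threshold). Every citation maps
to exactly one of the three outcomes, and raising the threshold can only
shrink the auto-excluded set.

Evaluation truth is always full-text-level inclusion, whatever labels the
model was trained on. The performance definitions are screening-specific:
a true include counts as a true positive when the cascade returns `include`
*or* `unclassified` (no decision costs nothing), and as a false negative
only when auto-excluded; a true exclude is a true negative only when
auto-excluded with a reason. `sensitivity = TP/(TP+FN)`,
`specificity = TN/(TN+FP)`, `precision = TP/(TP+FP)`,
`accuracy = (TP+TN)/(TP+FP+FN+TN)`; undefined ratios are flagged `NA`,
never silently zeroed.

## Training labels

Three label schemes are supported (`derive_labels()`): `abstract` uses
abstract-stage decisions for everything; `full_text` relabels abstract
includes by their full-text outcome (more informative, and preferred when
available); `modified_full_text` uses abstract decisions after *removing*
citations included at abstract level but excluded at full text — those
decisions were almost surely made on information outside the abstract, so
dropping them de-noises the training text. Reviewer reasons travel with the
labels, and `recode_reason()` supports folding one category into another
(e.g., short-follow-up `time` excludes into `other` when the category is
too thin to learn).

The 75/25 stratified split (`stratified_split()`) mimics a review *update*:
the earlier review is the training set. It is configurable and not a claim
about practice. Per-stratum training counts use round-half-up; the split is
deterministic given the seed. In the simulation harness the split is held
constant across all scenarios of one dataset, so scenario comparisons are
paired on identical test sets.

## Feature generation

Bag-of-words on the abstract (optionally title + abstract via
`include_title`; abstract-only is the default). The tokenizer lower-cases,
splits on any character that is neither letter nor digit, and removes
pure-number tokens and a pinned stopword list shipped with the package;
alphanumeric tokens containing a letter (e.g., `her2`) survive number
removal. No stemming or weighting is applied: features are raw counts,
the simplest rule consistent with a count-based bag of words.

Two feature filters mirror the experimental factor: a corpus-wide minimum
term frequency (5, 10, 100 or 500), or the top 50/100/500 terms by
algorithm-specific variable importance (CART: impurity-decrease aggregated
over bootstrap bags; naive Bayes: absolute difference of Laplace-smoothed
class-conditional log-probabilities; not defined for the SVM). Frequency
totals are computed across training *and* screening text when the screening
set is supplied to `fit_screening_model()` — its text is available before
any decision is made, so this is not leakage of labels. Zero-variance
predictors — terms constant within the training rows, or appearing
exclusively in one of the two sets — are then removed from both, since they
carry no usable signal and destabilize some fits.

## Learners and tuning

* **SVM**: linear kernel (standard for high-dimensional sparse text, and it
  makes cost the only tuning parameter), cost grid
  {0.25, 1, 2, 8, 32, 256}, Platt-sigmoid probabilities, via e1071.
* **Naive Bayes**: implemented in-package on count features. "No kernel"
  fits a Gaussian per term and class; "kernel" a per-term kernel density
  estimate; the Laplace correction (0, 0.5, 1) floors per-term likelihoods
  at `laplace * 1e-3` so unseen feature values never multiply the posterior
  to zero. Numerical guards: class-conditional standard deviations are
  floored at `1e-3` (a degenerate constant term becomes a narrow spike),
  densities at the smallest positive double, and posteriors are normalized
  in log space.
* **Bagged CART**: 25 bootstrap bags of unpruned `rpart` trees
  (`cp = 0`, `minsplit = 4`); the exclusion probability is the fraction of
  bags voting exclude, so probabilities are multiples of 1/25. (An
  alternative would average per-tree class probabilities; the vote fraction
  is the pinned contract.) No tuned parameter, hence no tuning metric.

`tune_and_train()` evaluates every grid point by stratified k-fold CV
(default 10 folds, randomized per model from the seed, shared across grid
points), scoring either fold-mean ROC AUC or fold-mean include-class
sensitivity at the 0.5 posterior cut. Fold-mean rather than pooled AUC is
an explicit assumption. Ties break toward the earlier grid point in
declared order; the winner is refit on all data. The 0.90 screening
threshold plays no role during tuning.

**Downsampling** (`downsample()`) balances classes 1:1 before tuning by
keeping every include and a seeded random subset of excludes of equal size.
Within pairwise reason subsets the reason class can be the minority; the
internal balancing then keeps that class whole instead — the 1:1 contract
is unchanged.

## The simulation harness

`enumerate_scenarios()` crosses datasets × 3 label schemes × 2 downsampling
levels × 7 feature settings × 3 algorithms × 2 tuning metrics, removing the
invalid cells (no importance filtering for SVM: 4 feature settings; no
metric for bagged CART). With five datasets this yields the full 870-cell
grid (420 naive Bayes, 240 SVM, 210 bagged CART). `run_scenarios()`
executes each cell end to end with per-cell seeds derived from a master
seed, records failures without aborting the batch, and
`paired_factor_test()` compares one factor at a time across matched pairs
with a two-sided paired t-test (zero-variance difference vectors are
flagged degenerate rather than tested). Averages over scenarios are simple
(unweighted) means.

## Synthetic corpora

The real screening corpora behind the reference profiles are proprietary,
so `generate_corpus()` emulates their *shape*: corpus sizes 3,089–12,769,
abstract-inclusion rates 1.7–13.8%, and full-text retention 20.6–33.1%
(rates derived from the published integer counts in `slr_profiles()`).
Class counts are deterministic (round-half-up) with randomized assignment,
so generator assertions are exact. Abstract text is a token bag drawn from
a shared background vocabulary, mixed with the citation's class-signature
vocabulary with probability `signature_strength`; abstract-include/
full-text-exclude citations draw their signature tokens from a 50/50 blend
of the include and reason signatures, emulating over-inclusive abstract
screening. Token counts are Poisson around `mean_abstract_length` (floored
at 3).

Defaults, chosen once as a plausible screening-text regime: 250 background
terms, 20 signature terms per class, signature strength 0.35 ("strong"
separation), 80 content tokens per abstract (roughly a 150-word abstract
after stopword removal), and a reason distribution weighted toward
study-design and population excludes (0.25 each) — the real per-reason
frequencies are unpublished, so this is a labelled synthetic assumption.

What passing tests on these corpora show — and do not show: the generator
produces exchangeable multinomial text with no syntax, no correlated
near-duplicates, no topic drift, and signatures that are literally
class-exclusive vocabularies. Success here demonstrates that the pipeline
is correct and recovers planted signal; it does not predict operating
characteristics on real abstracts, whose class boundaries are far softer.
At `signature_strength = 0` the class-conditional text distributions are
identical, so any apparent skill is a bug; the test suite checks that
auto-exclusions are then uncorrelated with truth.

## Problem sizes used by the test and acceptance harness

End-to-end checks run the best configuration (SVM, full-text labels, ROC
metric, downsampling, minimum frequency 5) on psoriasis-like corpora at
n = 2000 across five seeds, expecting held-out sensitivity at or above
0.95; the paired downsampling comparison uses 12 matched scenario pairs on
a 450-citation corpus with moderate separation (signature strength 0.15,
four active reasons, 5 CV folds). These sizes are the package's choice of a
desk-scale experiment that still exercises every stage; the full 870-cell
grid at real corpus sizes runs through exactly the same code path.

## Known limitations

* Unigram counts only: no n-grams, concept mapping, or embeddings.
* The naive Bayes kernel-density variant interpolates a fixed 256-point
  density grid; far outside the training range it falls back to the floor.
* SVM probabilities inherit Platt-calibration variance on small training
  sets; seeds make this deterministic but not less noisy.
* Auto-*inclusion* with a symmetric confidence threshold is deliberately
  not implemented; below-gate citations are simply routed to the reviewer.
* RIS import is minimal (TI/AB/ID tags plus a sidecar decision CSV).
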