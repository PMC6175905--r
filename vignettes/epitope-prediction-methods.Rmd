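---
title: "Class-restricted linear B-cell epitope prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Class-restricted linear B-cell epitope prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epitree)
```

## The problem and the modelling idea

Linear B-cell epitopes are short, contiguous antigen segments recognized
by antibodies.  Generic sequence-based predictors suffer from high false
positive rates, partly because they are trained across wildly
heterogeneous antigen classes.  epitree implements the alternative
strategy of *class restriction*: train a classifier only on curated
epitopes from a single protein class (the motivating application is
snake-venom metalloendopeptidases such as atroxlysin-I), so the model
learns the compositional signature that distinguishes epitopes from
non-epitopes *within that class*.

The pipeline has five stages, each exposed as ordinary functions and
bundled by the `epitree()` fitting function:

1. **K-mer decomposition.** Every annotated antigen is cut into all
   frame-shifted k-mers with k from 3 to 15 (stride 1).  K-mer lengths
   of 3–15 residues cover the common linear-epitope size distribution.
2. **Majority-overlap labeling.** A k-mer inherits the epitope (or
   nonepitope) class when at least 50% of its residues lie inside
   regions of that class — ties count, so a 6-mer with 3 epitopic
   residues is positive.  Two alternative rules are provided for
   comparison: `any_overlap` (a single residue suffices) and
   `full_containment` (every residue must belong).  The positives are
   nested (`full ⊆ majority ⊆ any`), and on antigens with one planted
   epitope the residue-level false positives satisfy the same ordering,
   which is the reason the majority rule is the default: it trades a
   little sensitivity at epitope borders for a markedly lower false
   positive rate.  When a k-mer simultaneously reaches the bar for both
   classes (possible with adjacent epitope/nonepitope annotation), the
   epitope class wins; the method is deliberately tuned towards epitope
   sensitivity, and is known to be weaker for very short epitopes
   (under 5 aa).
3. **Physicochemical featurization** (33 attributes, below).
4. **SMOTE rebalancing.** Epitope k-mers are the minority; SMOTE
   interpolation brings the classes to near 1:1 before tree induction.
5. **CART decision tree** with per-k-mer probability output, aggregated
   to per-residue score tracks from which regions are called.

## The 33-attribute feature space

Each k-mer is described by composition-only attributes (no positional
or structural information):

* mole percent of each of the 20 canonical residues;
* five group percents: positively charged (R, H, K), negatively charged
  (D, E), polar uncharged (S, T, N, Q), special (C, G, P), hydrophobic
  (A, V, I, L, M, F, W);
* GRAVY — the mean Kyte–Doolittle hydropathy, dimensionless;
* aliphatic index (Ikai): `AI = X_Ala + 2.9 X_Val + 3.9 (X_Ile +
  X_Leu)` with X in mole percent;
* atom percents of C, H, N, O and S over the peptide's molecular
  formula.  The formula uses free termini: the sum of free amino-acid
  formulas minus one water per peptide bond, so a 1-mer equals the free
  amino acid.  This convention is pinned and tested (`"G"` gives
  exactly C 20%, H 50%, N 10%, O 20%);
* isoelectric point from a Henderson–Hasselbalch net-charge model over
  the two termini and the R, K, H, D, E, C, Y side chains, using a
  Bjellqvist-style (Expasy-lineage) pKa set pinned in the package:
  N-terminus 7.5, C-terminus 3.55, D 4.05, E 4.45, C 9.0, Y 10.0,
  H 5.98, K 10.0, R 12.0.  The pI is located by bisection on pH 0–14;
  because the net-charge curve is nearly flat around the pI, the
  bisection is run to pH-interval convergence (50 halvings) rather than
  stopping at the first pH whose |charge| < 1e-4, which would leave the
  answer anywhere on a ±0.03 pH plateau.

K-mer length is deliberately *not* an attribute by default (the feature
count is 33); `include_length = TRUE` appends it as a 34th column for
experimentation.  Composition attributes (residue and group percents,
GRAVY, aliphatic index) are exactly length-scale invariant —
`featurize(s)` equals `featurize(paste0(s, s))` on those columns — while
the atom percents and pI shift very slightly with length because the
terminal water and terminal charges are diluted in longer peptides;
this is a property of the molecular definitions, not an implementation
artifact.

```{r}
featurize("VDLFIVVDHGMFMKY")[, c("pct_positive", "gravy",
                                 "aliphatic_index", "isoelectric_point")]
```

## Class rebalancing

Nonepitope k-mers outnumber epitope k-mers several-fold, and CART
overpredicts the majority class.  `smote()` creates synthetic minority
rows by interpolation: for each minority row `x`, a random point
`x + u (x_nn − x)` on the segment towards one of its `k = 5` nearest
minority neighbours (Euclidean distance in the raw attribute space —
the attributes are mostly commensurable percents; a `scale` flag
enables z-scaled distances).  Synthetic rows can never leave the convex
hull of the minority class.  The oversampling percent is a multiple of
100; `epitree()` picks the multiple that brings the classes closest to
1:1 without overshooting, which we take as the default target ratio.
SMOTE is applied to training data only — inside each cross-validation
training fold, never to held-out antigens — because fold leakage
through synthetic points would inflate every held-out metric.

## Tree induction and attribute importance

`train_tree()` is a deterministic CART: at every node the
(attribute, threshold) pair maximizing the Gini impurity decrease is
chosen over all attributes and all midpoints between sorted distinct
values, with pinned tie-breaking (lowest attribute index, then lowest
threshold) so that identical inputs always produce identical serialized
models.  Zero-gain splits are accepted when nothing better exists —
they are what allows XOR-structured signal to be found at depth 2 —
and recursion stops on purity, `max_depth` 12, `min_leaf` 5 or
`min_split` 10 (defaults chosen as conventional CART desk-scale
settings; all config-exposed).  The predicted epitope probability of a
k-mer is the epitope fraction of its leaf.  Small-instance behaviour is
verified in the tests against an exhaustive brute-force split search.

Attribute importance uses the classical random-forest measures
(mean decrease in Gini, mean decrease in out-of-bag accuracy under
permutation) through the randomForest package, with a default of
10,000 trees: at desk scale the quantity of interest is the stability
of attribute *ranks* across seeds, not the absolute importance values,
and 10,000 trees stabilizes ranks on panels of this size in seconds to
minutes.  On simulated panels the enriched-residue attributes are
expected among the top ranks (see the acceptance suite).

## From k-mer calls to epitope regions

The per-residue score is the fraction of covering k-mers predicted
positive (k-mer probability ≥ 0.5).  This aggregation is pinned as the
default; a `mean_prob` alternative (mean predicted probability of the
covering k-mers) is available behind a flag.  Scores live on a 0–1
scale and are rendered 0–100 in plots.  Regions are maximal runs of
residues with score ≥ 0.2 — the operating cutoff for calling a
sequence positive — discarding runs shorter than 3 residues (the
smallest k-mer; this suppresses 1–2-residue fragments).  A region-level
score is reported as the mean residue score over the region.  Predicted
cores are expanded by 3 residues per border (clamped to the sequence)
towards synthesis-ready peptides, so a 9-residue core becomes a 15-mer,
matching SPOT-array pentadecapeptide geometry.

SPOT reactivity tracks mirror the experimental readout: membranes tile
the antigen with 15-mers frame-shifted by 3; the reactivity score of a
residue is the number of reactive spots covering it, scaled so the
maximum is exactly 1.

## Evaluation framework

The evaluation unit is the **residue**: score tracks are compared
against experimentally mapped epitope regions position by position.
Residues covered by no annotation count as negatives during evaluation
(while being excluded from training), matching per-residue ROC analysis
over whole proteins.  `roc_auc()` sweeps all distinct scores and
integrates trapezoidally; the result provably equals the
pairwise-ranking probability with ties at 1/2, and the tests verify
this against a brute-force oracle and against pROC.  Three cutoff
policies are provided: the method's default cutoff, the cutoff
maximizing precision (ties towards higher specificity, then higher
sensitivity), and the Youden-optimal point maximizing TPR − FPR.  The
latter is our operationalization of "the cutoff that maximizes AUC":
AUC itself is cutoff-free, so the ROC point farthest above the diagonal
is the natural reading.  Multi-antigen panels are combined by averaging
per-antigen metrics (a `pool` flag pools residues instead).  Cohen's
kappa accompanies the rates as a chance-corrected agreement measure.

Pairwise panel identity (for judging how related the training class
members are) is computed by global Needleman–Wunsch/Gotoh alignment
with BLOSUM62, gap open 10, gap extend 0.5 (EMBOSS-needle-style
defaults), and percent identity counts identical columns over columns
where neither sequence is gapped.  These conventions are pinned because
published identity values depend on them.

## The synthetic antigen generator

`simulate_antigens()` makes the pipeline testable end to end without
any downloads.  Each antigen is a random sequence with one (or more)
planted epitope whose residues are drawn from the background
re-weighted by `exp(effect_size)` on an enriched residue set and
renormalized; flanks are labeled nonepitope.  The defaults are the
study conditions used throughout the tests and the acceptance script:

* enriched set {R, H, K, E, P, W} — the positively charged residues
  plus Glu, Pro and Trp, i.e. the attribute families that discriminate
  epitopes in the motivating protein class;
* uniform background (1/20 each), so enrichment is the only signal; a
  `"uniprot"` preset with Swiss-Prot-like frequencies is available for
  realism;
* antigen length 60–120 residues (small proteinase-domain scale),
  one epitope of 8–15 residues per antigen — planted epitopes are kept
  at ≥ 5 residues because the majority rule is insensitive below that;
* `effect_size = 3` as the strong-signal condition and
  `effect_size = 0` as the compositional null.

What the generator does *not* emulate: real epitopes are determined by
surface accessibility, structure and immunological context, not by
composition alone; real antigens have compositional autocorrelation,
homology between panel members, and annotation noise.  Passing the
recovery checks therefore demonstrates that the pipeline's machinery is
correct and self-consistent — it does not certify real-data accuracy,
which requires curated class-specific training data.

## Problem sizes and numerical choices

The end-to-end checks train on 150 of 200 simulated antigens
(≈ 160,000 labeled k-mers after majority labeling, roughly 1:6
epitope:nonepitope before SMOTE) and evaluate per-residue AUC and
region recovery on the 50 held-out antigens; at effect size 3 the
held-out AUC is ≈ 0.99 with every planted epitope recovered, and at
effect size 0 it stays at chance.  Degenerate inputs are handled
explicitly: sequences shorter than the smallest k yield zero k-mers,
single-class training data returns a warning leaf, all-identical
minority rows make SMOTE reproduce them exactly, and degenerate
single-class truth is an error in ROC analysis rather than a silent
0/0.  Model files print thresholds at `%.17g` so serialization round
trips are bit-exact.

## Known limitations

* Composition-only features cannot separate epitopes whose signal is
  structural; the class-restriction strategy presumes a curated,
  single-class training set.
* The majority rule under-calls epitopes shorter than 5 residues.
* Reported importance values depend on forest size and training data;
  only ranks are meaningful at desk scale.
* The curated metalloendopeptidase training set and the UniProt panel
  sequences are not redistributed with the package; the corresponding
  acceptance checks require the user to supply those files (see the
  README).
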