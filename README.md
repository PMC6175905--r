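# epitree

Class-restricted linear B-cell epitope prediction with k-mer decision
trees.

Linear B-cell epitopes — short contiguous antigen segments recognized
by antibodies — are hard to predict from sequence: generic predictors
trained across heterogeneous antigen classes produce many false
positives.  epitree implements the class-restricted alternative: train
a classifier only on curated epitopes from one protein class (the
motivating application is snake-venom metalloendopeptidases such as
atroxlysin-I, Bap1 and leucurolysin-a), so it learns the compositional
signature of epitopes *within that class*.  It is aimed at
immunologists and bioinformaticians selecting peptides for antibody
production and at method developers who need a transparent, fully
testable baseline.

## The method

Annotated antigens are decomposed into all frame-shifted k-mers with
k = 3..15 (stride 1).  A k-mer is labeled *epitope* (or *nonepitope*)
under the majority rule: at least 50% of its residues must lie inside
regions of that class, ties counting.  Each labeled k-mer is described
by 33 composition-only physicochemical attributes:

* mole percent of the 20 canonical residues;
* group percents — positive (R,H,K), negative (D,E), polar uncharged
  (S,T,N,Q), special (C,G,P), hydrophobic (A,V,I,L,M,F,W);
* GRAVY (mean Kyte–Doolittle hydropathy);
* aliphatic index, AI = X_Ala + 2.9 X_Val + 3.9 (X_Ile + X_Leu);
* atom percents of C, H, N, O, S of the peptide's molecular formula;
* isoelectric point (Henderson–Hasselbalch model, bisection).

Epitope k-mers are the minority class, so the matrix is rebalanced with
SMOTE (synthetic rows interpolated between minority nearest
neighbours) before a deterministic CART decision tree is grown on the
Gini criterion.  Per-k-mer epitope probabilities are aggregated to a
per-residue score track — score(i) = fraction of k-mers covering
residue i that are predicted positive — and epitope regions are called
as maximal runs of residues with score ≥ 0.2 (at least 3 residues
long), then padded by 3 residues per border into synthesis-ready
15-mer-scale peptides.

The package also ships the surrounding evaluation framework
(per-residue confusion counts, ROC/AUC, Cohen's kappa, cutoff policies
including the precision-maximizing and Youden-optimal points,
method-comparison tables), SPOT peptide-array reactivity tracks
(15-mers, frame shift 3, coverage counts scaled to max 1), pairwise
global-alignment percent-identity matrices (BLOSUM62, gap 10/0.5), and
a synthetic antigen generator that plants compositionally enriched
epitopes so the whole pipeline is testable without downloads.

## Worked example

```r
library(epitree)

panel <- simulate_antigens(40, effect_size = 3, seed = 42)
fit <- epitree(panel[1:30], seed = 1)
fit
#> Linear B-cell epitope classifier (k-mer decision tree)
#>   trained on 30 antigen(s): 4064 epitope / 27786 nonepitope k-mers (k 3-15, step 1, majority rule)
#>   SMOTE 500% (k = 5): 24384 / 27786 rows after balancing
#>   tree: 1103 nodes (552 leaves), depth 12
#>   cutoffs: k-mer 0.50, region 0.20

predict(fit, panel[31], type = "regions")[[1]]
#>   start end     label mean_score
#> 1    23  35 predicted   0.486522
panel[[31]]$regions[panel[[31]]$regions$label == "epitope", ]
#>   start end   label score
#> 2    27  34 epitope    NA
```

The single called region (positions 23–35, mean score 0.49) overlaps
the planted epitope (27–34); the extra flanking residues are the usual
border effect of overlap labeling.  Mean per-residue AUC over the ten
held-out antigens of this panel is 0.968.  `expand_region(23, 35, L)`
pads the call to a synthesis peptide (here 20–38).

A thin command-line wrapper over the same functions is installed at
`inst/cli/epitree.R`:

```sh
Rscript inst/cli/epitree.R simulate --n 50 --effect 3 --seed 7 --out-prefix sim/panel
Rscript inst/cli/epitree.R train --fasta sim/panel.fasta --regions sim/panel_regions.tsv --model m.model
Rscript inst/cli/epitree.R predict --fasta sim/panel.fasta --model m.model --out tracks/
Rscript inst/cli/epitree.R identity --fasta panel.fasta --out identity.csv
```

## External data

Two inputs are deliberately not bundled:

* **Curated training dataset** — the curated metalloendopeptidase
  epitope collection used to train the published class-restricted
  model.  Place it at `inst/extdata/curated_metalloendopeptidases.fasta`
  plus `inst/extdata/curated_metalloendopeptidases_epitopes.tsv`
  (regions TSV: `antigen_id  start  end  label`, 1-based inclusive).
* **Metalloproteinase panel** — UniProt P85420 (atroxlysin-I), P83512
  (Bap1) and P84907 (leucurolysin-a), fetched by you (e.g. from
  `rest.uniprot.org`) into `inst/extdata/svmp_panel.fasta` with the
  accessions as record ids.

The published epitope coordinates for that panel are included as plain
text in `inst/extdata/svmp_published_regions.tsv`.

## Package layout

* `R/` — antigen/region/track types and IO, k-merization and labeling,
  the 33-attribute featurizer, SMOTE, CART and random-forest
  importances, score-track aggregation and region calling, the
  evaluation framework, identity matrices, the synthetic generator,
  and the `epitree()` model object with print/summary/predict/plot
  methods.
* `tests/testthat/` — unit and property tests with independent oracles
  (brute-force enumeration, pairwise-ranking AUC, exhaustive split
  search, affine-gap dynamic programming), plus the acceptance suite.
* `vignettes/epitope-prediction-methods.Rmd` — the methods vignette:
  model assumptions, parameter meanings and defaults, numerical
  choices, what the simulation does and does not show.
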