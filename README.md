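# selforest

Selection-informed classification of cancer driver genes — oncogenes
(OG), tumour suppressor genes (TSG) and passengers (PG) — from tumour
exome mutation calls, with a random forest that can be **adapted to an
unlabelled cohort** (e.g. mouse tumour models) by distance-based tree
pruning and threshold shifting.

## Who this is for

Groups analysing tumour exomes of model organisms (or any cohort
without curated driver labels) who want to go beyond mutation frequency
and ortholog lookup: the package estimates evolutionary selection
directly from the data and transfers a classifier trained on a
labelled source domain to the unlabelled target domain.

## What it computes

**Short-term somatic selection.** For each gene, all possible single
base substitutions in its CDS are enumerated through the genetic code
to get neutral expectations (p_syn, p_mis, p_trunc). Observed counts
are modelled as a multinomial with category weights
(p_syn, ω·p_mis, φ·p_trunc); the MLE is

    ω̂ = (n_mis / n_syn) · (p_syn / p_mis)
    φ̂ = (n_trunc / n_syn) · (p_syn / p_trunc)

reported as natural logs clamped to [−5, 5]. Positive log(ω) =
positively selected missense mutations (OG signature); positive
log(φ) = positively selected truncations (TSG signature); both near 0 =
passenger.

**Long-term selection.** Per-site substitution rates (s/bys) by Fitch
parsimony on a protein alignment and dated species tree, summarised as
E.gene (mean rate over mutated positions) and E.summit (rate at the
most-mutated position).

**Mutation distribution.** R.missense, R.truncating, hotspot features
(R.peak, R.summit, C.summit) and mean relative truncation position
(R.length).

**Classifier and transfer.** A 200-tree CART/Gini forest on the 10
features, trained on labelled source genes; adaptation emits for every
tree a pruned variant (snip splits that fail to tighten target-gene
clusters) and a threshold-shifted variant (re-optimise each cutoff
against target cluster structure), giving a 400-tree adapted ensemble.
Driver calls require the class probability to exceed 0.5; genes with
fewer than 5 coding mutations are never classified. A 20/20 frequency
rule baseline and concordance summaries (accuracy, per-class
PPV/NPV/sensitivity/specificity over shared genes or ortholog pairs)
are included, along with a full synthetic source/target generator for
benchmarking.

## Worked example

Simulate a labelled source domain and a covariate-shifted unlabelled
target domain, train, adapt, classify:

```r
library(selforest)

sc <- synthetic_scenario(seed = 1)       # 150 source / 60 target genes per class
dt <- gen_domain_tables(sc)

forest <- train_forest(feature_matrix(dt$source$features),
                       dt$source$labels,
                       forest_config(n_trees = 200, seed = 2))
oob_accuracy(forest, feature_matrix(dt$source$features), dt$source$labels)
#> [1] 0.98

adapted <- build_rf_mouse(forest, feature_matrix(dt$target$features))
adapted
#> <selforest_forest RF_mouse> 400 trees, classes: OG/TSG/PG

calls <- classify(adapted, dt$target$features)
table(predicted = calls$class_label, hidden = dt$target$labels_hidden)
#>          hidden
#> predicted OG TSG PG
#>       OG  60   0  0
#>       PG   0   0 60
#>       TSG  0  60  0
```

The top calls show the saturated selection signature of strong
oncogenes — missense mutations under maximal positive selection
(log ω = 5), truncations absent (log φ = −5):

```r
head(prediction_records(calls, dt$target$features)[order(-calls$probability), ], 3)
#>        gene log_omega log_phi class_label probability
#>  tgt_OG_036         5      -5          OG   0.9973400
#>  tgt_OG_055         5      -5          OG   0.9966257
#>  tgt_OG_001         5      -5          OG   0.9943549
```

`write_predictions()` renders such records as a TSV whose first line is
always a `# accuracy unknown ...` comment: adapted models are fitted to
unlabelled data, so their real-world accuracy cannot be measured
directly and results should be interpreted with that caveat.

Real data enter through `read_mutation_table()` (MAF-like TSV: gene,
sample, protein_pos, consequence, protein_length) or
`read_vcf_annotated()` (SnpEff/VEP-annotated VCF), then
`filter_genes()` → `selection_table()` → `build_feature_matrix()`. A
thin command-line wrapper with subcommands (`select`, `features`,
`train`, `adapt`, `predict`, `rule2020`, `compare`, `simulate`,
`rates`) is installed at `inst/cli/selforest.R`.

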