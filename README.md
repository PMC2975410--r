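# purne

Positive-unlabeled learning for gene function prediction: synthetic
positive enlargement, representative negative extraction, and a
grid-searched final SVM, on precomputed gene-gene kernels.

## The problem

Predicting gene function is usually cast as one binary classification
task per functional term (e.g. a Gene Ontology term): genes annotated to
the term are positives, and a classifier must decide which other genes
belong to it. Annotation databases, however, only record *positive*
annotations — for most terms there are a few dozen annotated genes and
thousands of *unlabeled* ones, with no confirmed negatives at all.
Treating every unlabeled gene as negative creates severe class imbalance
(the classifier can collapse to "never positive", giving recall 0), and
the positives hidden among the unlabeled genes act as label noise.
Sampling only a handful of random negatives fixes the imbalance but
trains on so few examples that the classifier overfits.

`purne` implements a three-stage strategy (SPE-RNE: Synthetic Positive
Examples + Representative Negative Examples) for this
positive-unlabeled setting, together with the surrounding machinery a
practitioner needs: kernel construction and fusion for heterogeneous
genomic data, annotation handling, baselines, an evaluation layer, and a
simulator.

## The method

For a positive set *P* and unlabeled set *U* over a gene-gene kernel
*K*:

1. **Synthetic positive enlargement.** For each **e** ∈ *P*, find its
   *k* nearest neighbours within *P* (*k* = 10), pick *n* of them at
   random, and add the convex combinations
   *ẽ* = α **e** + (1 − α) **e**′, α ~ U(0,1), to form the enlarged set
   *P̃*. Any point of the segment between two positives lying strictly
   inside the positive half-space of a separating hyperplane is itself
   strictly inside it, so synthetic examples are likely positives. The
   amount of enlargement follows the annotation-group schedule
   (4×/2×/1×/0× for terms with <60, 60–100, 100–300, >300 positives).
   Synthetic points exist only as combinations, so the kernel is
   extended to them by bilinearity:
   *K(ẽ, x) = α K(e, x) + (1 − α) K(e′, x)*.
2. **Representative negative extraction.** After holding out 10% of *P̃*
   and *U* as a validation set, a one-class SVM (ν = 0.1) over
   *P̃* ∪ *U* flags the points far outside the data mass; the unlabeled
   ones among them are the initial negatives *N₁*. Then, while
   |*U′*| ≥ 4 |*P̃*|, a two-class SVM is trained on *P̃* vs the current
   negatives, the up-to-3 |*P̃*| most confidently negative unlabeled
   genes become the next predicted-negative set, and only the negative
   support vectors carry over — moving the boundary step by step toward
   the positives. Each iteration's classifier is scored by F1 on the
   validation set, and the negative set of the best classifier is kept
   as the representative negative set *RN*.
3. **Final training.** A soft-margin SVM is trained on *P̃* ∪ *RN* with
   its cost selected by stratified cross-validated F1 over a power-of-two
   grid.

Baselines with the same plumbing: `twoclass` (all of *U* negative),
`twoclassbal` (|P| random negatives), and `psol_lite` (greedy
max-min-dispersion initial negatives plus iterative expansion).

Evaluation follows the field's conventions: precision, recall and F1
with the *NaN → 0* rule (a classifier recalling no positives scores 0),
rank-based ROC scores from decision values, and per-annotation-size
group means and variances.

## Worked example

```r
library(purne)

ds <- simulate_pu_dataset(n_labeled_pos = 20, n_hidden_pos = 80,
                          n_neg = 900, d = 10, separation = 4, seed = 1)
ds
#> pu_dataset: 1000 examples (20 labelled positive, 80 hidden positive,
#>             900 negative), d = 10

K <- gaussian_kernel(ds$features, gamma = 0.1)
fit <- run_spe_rne(K, ds$P, ds$U, spe_rne_config(seed = 1))
trace_summary(fit$trace)
#>   iteration n_negatives n_pred n_svs u_remaining
#> 1         1         102    270    51         780
#> 2         2         321    270    75         510

fit$manifest[c("n_positives", "n_synthetic", "n_initial_negatives",
               "n_representative_negatives", "best_C")]
#>                n_positives                n_synthetic
#>                       20.0                       80.0
#>        n_initial_negatives n_representative_negatives
#>                      102.0                      102.0
#>                     best_C
#>                        0.5
```

The 20 labelled positives fall in the "<60" group, so each gains 4
synthetic neighbours (80 synthetic positives). The one-class boundary
flags 102 of the 880 unlabeled training genes as initial negatives; two
retraining iterations follow, and validation F1 selects iteration 1's
negative set as *RN*. Scoring the unlabeled genes:

```r
pred <- predict_unknowns(fit, K[ds$U, , drop = FALSE])
head(pred, 3)
#>       decision label
#> g1  0.33990870     1
#> g2 -0.08278726    -1
#> g3 -0.07565145    -1

hidden <- setdiff(which(ds$truth == 1), ds$P)
mean(pred[rownames(ds$features)[hidden], "label"] == 1)
#> [1] 0.7                                  # recall of hidden positives
roc_auc(ds$truth[ds$U], pred$decision)
#> [1] 0.943                                # ROC score vs hidden truth
```

A command-line wrapper with `simulate`, `kernels`, `train`, `predict`
and `compare` subcommands lives at `inst/cli/purne.R`.

## Limitations

The iterative extraction assumes the kernel gives the one-class stage a
meaningful notion of "far from the data mass" — kernels with unit
diagonal and non-negative entries (Gaussian, diffusion) behave best,
while strongly centred kernels can place the feature-space origin
inside the data cloud and inflate the one-class outlier fraction well
past ν. See the methods vignette (`vignettes/purne-methods.Rmd`) for
the modelling assumptions, parameter choices, and known failure modes.
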