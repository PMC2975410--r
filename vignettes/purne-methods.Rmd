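---
title: "Methods: positive-unlabeled training with synthetic positives and representative negatives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: positive-unlabeled training with synthetic positives and representative negatives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(purne)
```

## The setting and its assumptions

Gene function prediction is treated as one binary task per functional
term. The data available for a term are a small positive set $P$
(annotated genes) and a large unlabeled set $U$; $U$ contains all true
negatives *and* the positives that simply have not been annotated yet.
Two failure modes dominate naive treatments: class imbalance (training
$P$ against all of $U$ makes "always negative" a low-risk solution) and
overfitting (training $P$ against $|P|$ random unlabeled genes leaves
too few examples). The pipeline in this package attacks both at once —
enlarging the positive side with synthetic examples and extracting a
negative set of controlled, representative composition.

Everything operates on a precomputed gene–gene kernel: a symmetric PSD
matrix interpreted as an inner product in some feature space. Kernels
may come from heterogeneous sources (sequence similarity, expression,
interaction networks) and be fused by summation after per-source
double-centring and cosine normalization, the standard recipe for
putting sources on a comparable scale before adding them.

## Stage 1 — synthetic positive enlargement

For each $\mathbf e \in P$ the $k$ nearest neighbours *within* $P$ are
located ($k = 10$; ties broken by ascending index for determinism), $n$
of them are drawn uniformly without replacement, and a synthetic
example
$$\tilde{\mathbf e} = \alpha \mathbf e + (1-\alpha)\mathbf e', \qquad
\alpha \sim U(0,1),$$
is recorded per drawn neighbour $\mathbf e'$, giving exactly $n|P|$
synthetic points. If a separating hyperplane $f(\mathbf x) = \mathbf
w^\top\mathbf x + b$ has $f > 0$ on all of $P$, then
$f(\tilde{\mathbf e}) = \alpha f(\mathbf e) + (1-\alpha)f(\mathbf e')
> 0$: synthetic points can never leave the positive half-space of any
classifier that accepts the real positives, which is why this
enlargement adds very little negative noise (the package's test suite
verifies this exactly on 1000 random hyperplane/point-set draws).
Mining likely positives out of $U$ instead is deliberately avoided: at
low hidden-positive rates it mostly imports false positives.

The amount of enlargement is tied to the annotation-size group of the
term: terms with fewer than 60 positives get $n = 4$, 60–100 get 2,
100–300 get 1, and 300 or more get none (group boundaries are read as
half-open intervals $[0,60), [60,100), [100,300), [300,\infty)$ so
every count maps to exactly one group). $n$ relates to the enlargement
percentage by $n = \mathrm{round}(\text{percent}/100)$, clamped to
$[0, k]$ — a 500% enlargement uses 5 of the 10 nearest neighbours.

Synthetic points exist only as coefficient pairs, so the kernel is
extended to them by bilinearity,
$K(\tilde{\mathbf e}, \mathbf x) = \alpha K(\mathbf e, \mathbf x) +
(1-\alpha) K(\mathbf e', \mathbf x)$ (and the corresponding double
expansion for two synthetic points). For a PSD kernel this is exactly
the Gram matrix of the augmented point set in the kernel's feature
space, so PSD-ness is preserved; for a linear kernel it coincides with
augmenting the explicit coordinates, which the tests use as an oracle.
Note that for nonlinear kernels the combination happens in the
*feature* space induced by the kernel, not in the original input space;
that is the natural reading when inputs are only available as kernels.
When only a kernel is available, neighbour distances are induced from
it via $d(i,j) = \sqrt{K_{ii} + K_{jj} - 2K_{ij}}$.

## Stage 2 — representative negative extraction

A validation set $V$ (10% of $\tilde P$ and 10% of $U$, drawn uniformly)
is held out first. $V$ is drawn from the *enlarged* positive set; a
flag (`exclude_synthetics_from_validation`) restricts validation
positives to real ones for users worried about synthetic children of
held-out parents — the default follows the algorithm as specified,
which draws from $\tilde P$.

**Initial negatives.** A one-class SVM with $\nu = 0.1$ is fit on
$\tilde P \cup U$ (training portions); unlabeled points left outside
its boundary — roughly the $\nu$ fraction farthest from the data mass —
form $N_1$. This replaces the NP-hard "far from the positives and from
each other" dispersion selection with a convex problem. The $\nu$
property (outlier fraction $\approx \nu$) holds when the feature-space
origin lies outside the data, which is the case for kernels with unit
diagonal and non-negative entries (Gaussian, diffusion). Strongly
centred kernels can void it — the observed outlier fraction then far
exceeds $\nu$ — so the one-class stage is best run on uncentred
kernels; if the boundary degenerates and flags nothing, the fallback
takes the `percent`% of unlabeled genes with the lowest mean kernel
similarity to the positives, with a warning.

**Iteration.** While $|U'| \ge 4|\tilde P|$: train a two-class SVM
(cost fixed at $C = 1$; hyperparameter search is deliberately deferred
to Stage 3, since the iteration only needs a consistent ranking) on
$\tilde P$ vs the current negatives; record the pair; score $U'$; take
the at most $3|\tilde P|$ most negatively scored points predicted
negative as $N_{pred}$ (the cap keeps the next training set from
re-creating the imbalance problem); set the next negative set to
$N_{pred}$ plus the *negative support vectors* of the current
classifier — the compressed memory of all earlier negatives — and
remove $N_{pred}$ from $U'$. The loop also exits when no new negatives
are predicted. The stop rule reflects that once few unlabeled genes
remain, they are increasingly likely to be hidden positives and further
"negatives" would poison the training set.

Each recorded classifier is evaluated by F1 on $V$ (held-out positives
labelled $+1$, held-out unlabeled labelled $-1$), and the negative set
of the best one is the representative negative set $RN$; ties go to the
earliest iteration, and if every F1 is zero the last set is returned
with a warning. Scoring held-out unlabeled genes as negatives is biased
— hidden positives in $V$ count against precision — but it is the same
bias for every candidate, so it remains a consistent model-selection
signal.

A note on the boundary's motion: because later iterations train against
negatives ever closer to $\tilde P$ (and the one-class set $N_1$ is the
farthest), decision values of fixed points can only drift *downward* as
the boundary contracts toward the positives. The property tests assert
exactly this — hidden-positive mean decisions are non-increasing across
iterations while their ranking against true negatives (AUC) is
preserved — rather than any increase in raw decision values.

## Stage 3 — final classifier

The final SVM is trained on $\tilde P \cup RN$, with the soft-margin
cost selected by 5-fold stratified cross-validated F1 over
$C \in \{2^{-5}, 2^{-3}, \dots, 2^{15}\}$ and ties resolved toward the
smaller cost. Two kernel modes exist: the default precomputed mode
(grid over $C$ only — the one coherent choice when inputs are fused
kernels) and an RBF-on-features mode that also grids
$\gamma \in \{2^{-15}, \dots, 2^{3}\}$ for users with explicit feature
vectors. Folds without positives score F1 = 0 under the NaN→0
convention. Stage 2 is run once, not per grid point: the extraction is
a data-selection step, and re-running it inside the grid would entangle
model selection with training-set construction.

## Solver contract

All maximum-margin training goes through libsvm (via `e1071`).
Precomputed kernels are handled by an exact empirical kernel map: the
symmetric eigendecomposition $K = V\Lambda V^\top$ (negative
eigenvalues clamped at zero) yields coordinates $V\Lambda^{1/2}$ whose
linear-kernel SVM is exactly the kernel SVM on $K$. Models store their
support indices, sign-normalized dual coefficients and bias, so
decision values are recomputed from kernel rows alone,
$f(x) = \sum_i \alpha_i K(x, sv_i) - b$, independent of the solver
object; a test checks this reconstruction against the solver's own
decision values to $10^{-8}$. Positive decision values always mean
class $+1$ (binary) or inlier (one-class).

## Evaluation layer

Precision $= TP/(TP+FP)$, recall $= TP/(TP+FN)$,
$F1 = 2PR/(P+R)$; any $0/0$ gives NaN, reported as 0 by default — the
convention that scores an always-negative classifier 0 instead of
dropping it. ROC scores are rank-based (Mann–Whitney; ties count half)
computed from decision values, since binary predictions cannot trace a
curve. Group aggregation reports the NaN count before substitution, the
mean and the *population* variance of F1 (a flag switches to sample
variance), and mean ROC. The known-gene protocol holds out 20% of the
positives and 20% of the unlabeled genes, trains on the rest, and
scores the held-out genes with held-out unlabeled treated as negative.
Its F1 has a structural ceiling: genuinely recovered hidden positives
in the held-out unlabeled set are counted as false positives, so at a
hidden-positive rate of 8% and 4 held-out labelled positives no
classifier can exceed $F1 \approx 0.33$; comparisons between strategies
remain fair because every strategy faces the same ceiling.

## The simulator and what it does (not) show

`simulate_pu_dataset()` emulates the statistical structure the method
assumes: one Gaussian positive cloud (unit noise), negatives from a
3-component Gaussian mixture whose centres sit at distance `separation`
from the positive centre in random directions (negative classes in
function prediction are diverse — "not term X" is many things), and a
random subset of positives labelled while the rest hide in $U$. The
standard benchmark suite is 20 replicate datasets (seeds 1–20) with 20
labelled positives, 80 hidden positives, 900 negatives, $d = 10$,
separation 4; the benchmark kernel is the Gaussian kernel with
$\gamma = 1/d$ (the common 1/\#features default). These sizes keep a
full four-strategy comparison within a few minutes while leaving the
imbalance phenomenon intact: the all-negative `twoclass` baseline
collapses to F1 = 0 on every suite dataset, exactly the behaviour the
representative-negative extraction is designed to avoid.

What the simulator does *not* emulate: annotation DAG structure,
correlated expression features or batch effects, scale-free interaction
topology, and the high-dimensional noisy kernels of real genomic data.
That last gap matters for interpretation: on clean low-dimensional
Gaussian clouds the balanced random-negative baseline (`twoclassbal`)
does not overfit the way it does on real kernels, so the pipeline's
mean-F1 advantage over it — clear in the original setting this method
was designed for — is within seed noise here (means differ by under
0.01), even though the pipeline shows its defining qualitative
behaviours (no imbalance collapse on any dataset, high hidden-positive
recall, substantially better ROC than `twoclass`). Passing the suite
therefore demonstrates correctness of the machinery, not real-data
superiority.

## Numerical choices and degenerate inputs

* Kernel symmetry is enforced on read by averaging with the transpose;
  validation tolerance $10^{-8}$.
* `normalize_kernel()` lifts diagonal entries in $(0, 10^{-10}]$ to
  $10^{-10}$ before dividing and errors on nonpositive diagonals,
  naming the gene.
* The matrix exponential of the diffusion kernel uses a dense symmetric
  eigendecomposition (desk scale, up to a few thousand genes); rows of
  $\exp(\beta(A - D))$ sum to 1, which the tests verify numerically.
* KNN imputation measures distances over co-observed columns scaled by
  the co-observation fraction, weights neighbours by $1/d$ (exact-zero
  distances short-circuit to the plain mean of the duplicates), and
  falls back to the column mean when no neighbour observes the column.
  Fully missing rows are an error.
* $\alpha$ is resampled on the measure-zero event of hitting exactly 0
  or 1, keeping synthetic points strictly interior.
* $k > |P| - 1$ is clamped with a warning; synthesis with $|P| < 2$ is
  an error; a request for more neighbours than exist cycles with
  replacement and warns.
* If the unlabeled pool is already below the stop threshold, Stage 2
  records no iterations and the pipeline falls back to $N_1$ as $RN$
  with a warning.
* All randomness in a pipeline run derives from the single config seed;
  two runs with the same configuration are byte-for-byte identical in
  manifest and predictions.

## Known limitations

* The one-class stage needs the origin outside the data in feature
  space (see Stage 2); with strongly centred kernels the initial
  negative set can be several times larger than $\nu$ suggests, which
  shortens the iteration phase.
* With large $|\tilde P|$ relative to $|U|$ the loop bound
  $|U'| \ge 4|\tilde P|$ permits only one or two iterations, so $RN$
  stays close to $N_1$.
* The per-iteration cost is fixed; a kernel on a very different scale
  may need a different `iteration_C` to produce informative rankings.
* `psol_lite` implements only the two-step outline of the
  dispersion-based predecessor method (greedy max-min initial set,
  iterative expansion, last classifier returned) and is not a faithful
  reimplementation of the published algorithm.
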