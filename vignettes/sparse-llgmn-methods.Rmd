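---
title: "Sparse LLGMN: model, training, and evaluation choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse LLGMN: model, training, and evaluation choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the model and its assumptions, the tunable parameters and their defaults,
the numerical choices, what the synthetic-data generators do and do not
emulate, and the design decisions taken where the method left room.

## The model

The classifier is a two-stage network mapping a participant's index
vector $x \in \mathbb{R}^P$ to posterior probabilities of two classes
(class 1 is the positive class, e.g. *drivable*).

**Gating layer.** Each index is multiplied by a scalar gate,
$y_i = w_i x_i$. The gates carry no nonlinearity; their only job is to
let the L1 penalty remove indices *exactly*, because a gate stored as
zero makes every downstream computation independent of that index.

**Log-linearized Gaussian mixture network (LLGMN).** The gated vector is
expanded to
$X = \bigl(1,\; y_1,\dots,y_P,\; y_i y_j \ (i \le j)\bigr)$,
of length $H = 1 + P + P(P+1)/2$. A single weight layer
$W \in \mathbb{R}^{H \times CM}$ followed by a softmax over the $CM$
component units, and a sum over each class's $M$ units, yields
$p(c \mid x)$. This architecture is exactly a discriminative Gaussian
mixture: for any mixture parameters there are weights reproducing its
Bayes posteriors (the package's `log_linearize_gmm()` performs that
construction, and the test suite verifies forward equivalence to direct
mixture evaluation at $10^{-6}$). The softmax is computed with
max-subtraction, and one unit (class $C$, component $M$) is pinned to
zero weights as the identifiability anchor — softmax posteriors are
invariant to a shared shift, so the anchor costs nothing and removes a
degeneracy.

**Energy.** Training minimizes
$$E = -\sum_{n=1}^{N}\sum_{c=1}^{2} t_{nc}\,\ln p(c \mid x_n)
      \;+\; \lambda \sum_{i=1}^{P} |w_i|,$$
the summed cross-entropy plus an L1 penalty on the gates only. Note the
first term is a *sum*, not a mean: $\lambda$ therefore trades off
against total error mass, and comparable sparsity on larger cohorts
needs no rescaling of the learning rate.

## Training

Optimization is mini-batch stochastic gradient descent on $W$ and $w$
jointly (learning rate 0.01, batch size 50, at most 10,000 epochs — the
study protocol, kept as defaults in `analysis_config()`). The L1 term is
handled **proximally**: after every mini-batch gradient step the gates
are soft-thresholded,
$w_i \leftarrow \operatorname{sign}(w_i)\max(|w_i| - \eta\lambda, 0)$.
This is what makes gates *exactly* zero in finite time; a subgradient
treatment would only shrink them towards zero. Thresholded zeros are
bit-exact, and the test suite asserts `== 0`, never `< ε`.

Early stopping monitors the full-data energy recomputed after each
epoch: training stops when the loss has failed to improve by more than
`early_stop_min_delta` (default $10^{-4}$) for more than
`early_stop_patience` (default 5) consecutive epochs, and the
best-energy parameters seen are returned. Initialization is
deterministic — gates at 1 (an identity layer), LLGMN weights at 0,
which makes the initial posterior uniform — and the per-epoch shuffle
uses a dedicated seeded generator, so training is bit-reproducible from
the seed alone. The number of mixture components defaults to $M = 1$;
the posterior family is then a quadratic discriminant, which is already
flexible for tables with tens of participants per class, and $M$ remains
a config field for richer data.

With $\lambda = 0$ and unit gates the gated network spans exactly the
plain LLGMN family. On data whose empirical optimum is interior
(overlapping classes) both parameterizations converge to the same
cross-entropy, which the acceptance suite checks to $10^{-6}$ under a
matched schedule (full-batch updates, `min_delta` $10^{-10}$, patience
50). On linearly separable data that check would be meaningless — both
losses drift towards zero only polynomially in the epoch count — so the
equivalence fixture deliberately uses overlapping Gaussians.

## Choosing the regularization coefficient

$\lambda$ is tuned by a tree-structured Parzen estimator over a
log-uniform range ($10^{-5}$ to $10$ by default, 100 trials): random
startup trials, then a split of the history at the best quartile into
"good" and "rest" sets, Parzen (kernel) densities $l(x)$ and $g(x)$
over the two sets in log space, candidates drawn from $l$, and the next
trial placed at the candidate maximizing $l/g$. Each trial is scored by
the mean per-sample out-of-fold cross-entropy of an inner stratified
cross-validation (5 folds by default). The sampler is deterministic
under the seed, and nested budgets with a shared seed stream share their
trial prefix, so the best objective is monotone in the trial count —
both properties are under test. The implementation is intentionally
minimal (a single one-dimensional parameter does not need a full
hyperparameter-optimization framework), but it is the genuine
good/rest density-ratio algorithm, not random search.

Where tuning happens is a real design choice. `cross_validate()` with
`lambda = "tpe"` tunes per training fold, which is the strictly
leakage-free reading. `run_full_analysis()` instead tunes once on the
full standardized table by default (`tpe_scope = "global"`,
`"per_fold"` available): at 50-participant scale the per-fold inner
objective is extremely unstable (inner validation folds of 3–4
participants), the cost is K-fold larger, and a single $\lambda$ keeps
the per-fold gate vectors comparable, which the selection rule and the
gate-weight boxplots implicitly assume. The report records which scope
was used. Either way the *selection* inherits the optimism of reusing
the same cohort for tuning and evaluation; see Limitations.

## Cross-validation, selection, importance

Folds are stratified: per-class counts in any two folds differ by at
most one, and classes hand their remainder members to the currently
lightest folds so total sizes stay balanced (55 participants at
$K = 11$ give eleven folds of exactly five). Standardization — sample
mean and SD with the $n-1$ denominator — is computed on each fold's
training rows and applied to its validation rows. A rare binary index
can be constant inside a training fold; the CV internals then center
that column and record an SD of 1 rather than failing (the user-facing
`standardize()` keeps the hard error, naming the column).

An index is **selected** when its gate was non-zero in at least one
fold. Reported per index are the signed mean gate, the mean absolute
gate, and the number of non-zero folds; the ranking uses the mean
absolute gate, because signed means cancel across folds when a gate
flips sign (both are emitted, so the signed ordering is one `arrange()`
away).

**Permutation importance** follows the single-pass algorithm: on each
fold's validation rows, $e$ is the (clipped-log, summed) cross-entropy
of the intact table; shuffling column $i$ and recomputing gives $e_i$,
and $PI_i = e_i - e$; the final value is the arithmetic mean over folds.
A `repeats` argument averages several seeded shuffles for variance
reduction, off by default to match the single-pass definition. Two
exactness properties hold by construction and are under test: a dead
gate gives $PI_i = 0$ exactly (the forward pass is bit-identical), and
an identity permutation gives 0.

## Comparison methods

**Stepwise partial-KLI elimination.** The per-index partial
Kullback–Leibler information of a trained LLGMN is operationalized as
the increase in validation cross-entropy when that column is replaced by
its training-fold mean (zero after standardization). The published
formula behind the original method is not reproduced in the sources
available to this package, so the mean-substitution reading is isolated
behind `partial_kli()` where an alternative could be swapped in; it
preserves the intended semantics (contribution of one input to the
class-posterior fit) and is exactly zero for inputs the network ignores.
The stepwise loop trains a plain LLGMN by cross-validation on the
current set, records the pooled out-of-fold AUC, removes the index with
the smallest fold-averaged partial KLI, and repeats down to one index;
the selected set maximizes the AUC along the trace, with ties going to
the smaller set (parsimony is the method's purpose). Importance for the
selected set is the leave-one-out AUC drop,
$(\mathrm{AUC}_{\text{full}} - \mathrm{AUC}_{-i})/\mathrm{AUC}_{\text{full}} \times 100\%$,
which can legitimately be negative.

**Lasso.** Penalized *linear* regression of the 0/1 class label on the
standardized indices — deliberately not logistic, matching the
comparison as a linear-regression method. The objective
$(1/2N)\lVert y - \beta_0 - X\beta\rVert^2 + \lambda\lVert\beta\rVert_1$
is minimized by cyclic coordinate descent to a coefficient tolerance of
$10^{-8}$ (KKT conditions and a sign-pattern enumeration oracle are
under test; an independent solver cross-checks a random instance).
$\lambda$ comes from an inner 5-fold CV minimizing squared error (plain
minimum; no one-standard-error rule), per outer fold; the linear
predictor provides the ROC scores, and the full-data standardized
coefficients provide the importance ranking by $|\beta_i|$.

## Evaluation statistics

ROC curves are built from the **pooled out-of-fold scores** — one curve
per method over all participants — matching a single reported AUC per
method rather than averaging per-fold curves. Thresholds are midpoints
between consecutive distinct scores with $\pm\infty$ sentinels; AUC is
the pairwise concordance probability with ties counted $1/2$ (equal to
the trapezoidal area, an identity under test at $10^{-12}$); the
reported threshold maximizes sensitivity + specificity, ties broken by
higher sensitivity and then lower threshold (a convention — single
reported operating points need one). Predicted classes at that threshold
feed a 2×2 table tested by Fisher's exact test (two-sided by probability
ordering, the classical definition) and summarized by Yule's
$Q = (ad-bc)/(ad+bc)$, flagged as undefined when $ad + bc = 0$ rather
than silently zeroed.

Methods are compared by the DeLong test on their paired out-of-fold
scores — all methods share one fold assignment per run precisely so this
pairing is valid — with Holm step-down adjustment over the method pairs.
Identical score vectors give zero variance; the test then reports
$p = 1$ with a flag instead of dividing by zero. Group-wise baseline
comparisons route binary indices to Fisher's exact test and continuous
ones to the Brunner–Munzel test (midrank relative effect, studentized
statistic, Welch-type degrees of freedom), whose type-I error the
acceptance suite calibrates empirically.

## Synthetic data

**Cohort mode** draws each index independently from its per-group
summary — Normal(mean, SD) for continuous indices, Bernoulli(proportion)
for binary ones — with group sizes 41/14 and 65 indices transcribed from
published cohort summaries. Three motor-recovery sub-scores had no
published summaries; they are filled with plausible Brunnstrom-stage
values and flagged `synthetic` in the packaged CSV. Independence is the
deliberate default (no covariances are published); an optional `block`
column with equicorrelation `rho` exists to probe correlated-predictor
behavior. One transcribed oddity is kept as printed: one group SD of 0.1
that is likely a typo for 1.0 — faithfulness to the printed table wins.
Because real inter-index correlations are absent, the emulated cohort is
*easier* than the real one (many independently informative indices), and
pipeline results on it are structural checks only: they show the
machinery runs, selects, and discriminates, not that the real study's
AUCs are reproduced. A constant-within-group column (SD 0) is legal;
only fully constant columns refuse standardization.

**Sparse-signal mode** plants $k$ informative indices with a
standardized between-class mean difference $d$ among pure-noise columns
and returns the ground truth, so selection methods can be scored for
support recovery. All informative indices share the same $d$; "the
strongest planted index ranks first" is therefore read as "the
top-ranked index is a planted one".

## Problem sizes used by the packaged checks

The test and acceptance runs use the study conditions where stated —
cohort 41/14 with 65 indices and 11 folds, TPE reduced to 20 trials;
recovery study $N=200$, $P=30$, $k=5$, $d=1.5$, 10 replicates — with
two size choices made once for the packaged demonstrations: the
recovery study runs 5-fold CV (the replicate count, not the fold count,
carries the statistical claim), with $\lambda$ tuned by TPE on the
first replicate (20 trials, 3-fold inner objective) and reused across
replicates, and cohort-scale trainings cap `max_epochs` at 2500, far
past where early stopping typically triggers at these data sizes. The
statistics oracles use 200 random ROC instances, full Fisher
enumeration at margins ≤ 10, a 2000-replicate bootstrap for the DeLong
SE, and 2000 null simulations for the Brunner–Munzel calibration.

## Numerical choices

* Posteriors are clipped at $10^{-12}$ before logarithms, in training,
  permutation importance, and partial KLI alike.
* Softmax uses max-subtraction; weights and gates are finite-checked on
  input.
* Gate zeros are exact (proximal thresholding), never epsilon
  comparisons.
* Best-threshold ties are detected with a $10^{-12}$ tolerance on
  sensitivity + specificity before tie-breaking, since exact float
  equality splits arithmetically-equal candidates arbitrarily.
* CSV round trips are bit-exact: numerics are written with 17
  significant digits and parsed with strtod.
* All seeds derive from a single integer via a fixed affine map kept
  below $2^{31}$; stochastic functions restore the caller's RNG state.

## Limitations

* The gate/LLGMN composition is non-convex; training from the
  deterministic initialization finds a good stationary point in
  practice (the tests quantify this on planted-truth data) but no
  global-optimality claim is made.
* Selection and evaluation reuse the same cohort and folds, as the
  motivating workflow does; out-of-fold AUCs of *selected* models are
  optimistic relative to truly unseen data. A nested outer evaluation is
  out of scope.
* The cohort emulator reproduces marginal summaries only; correlations,
  floors/ceilings and score discreteness of real clinical instruments
  are not modeled (a clip option exists, off by default, since
  standardization makes ranges immaterial to the algorithms).
* Only two-class problems are supported in the user-facing surface,
  though the forward/gradient formulas are written C-generically.
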