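---
title: "Methods: PSSM feature encoding, resampling and jackknife evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PSSM feature encoding, resampling and jackknife evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pssmloc)
```

## The problem and the model

Protein subcellular localization from sequence is usually attacked by
(i) turning each variable-length protein into a fixed-length numeric
vector and (ii) feeding those vectors to a standard classifier. `pssmloc`
implements a profile-based variant of this recipe specialised to small,
imbalanced apoptosis-protein collections.

The raw representation is the position-specific scoring matrix (PSSM): for
a protein of length $L$, an $L \times 20$ matrix $M$ whose entry $M_{i,j}$
is the log-odds score of residue position $i$ mutating to amino-acid type
$j$ over evolution, as produced by an iterative profile search. Scores are
integers, typically in $[-10, 12]$. Before encoding, every entry is mapped
through the logistic function $f(x) = 1/(1+e^{-x})$, which bounds the
features and damps extreme scores. Whether the original method scaled
before *every* encoder is not documented; we apply it uniformly by default
and expose `scale = FALSE` for raw-score ablations.

## Encoders

All encoders share the 20 column means
$\bar M_j = \tfrac1L \sum_i M_{i,j}$ as their leading block; they differ in
how they summarise order information.

**Sequence-lag baseline (`psepssm`).** For each lag $d = 1..\xi$ and each
column $j$: $\tfrac{1}{L-d}\sum_{i=1}^{L-d}(M_{i,j}-M_{i+d,j})^2$.
Dimension $20 + 20\xi$.

**Column-lag encoder (`im_psepssm`).** The improved encoder lags across
*columns*: for $d = 1..\xi$ and left column $n = 1..20-d$,
$$T^{(d)}_n = \mathrm{norm}(d) \sum_{m=1}^{L} (M_{m,n}-M_{m,n+d})^2 .$$
Only $20-d$ pairs exist at distance $d$, so the dimension is
$(20+20\xi) - \xi(\xi+1)/2$: 182 at $\xi=12$, 189 at $\xi=13$, 132 at
$\xi=7$. The printed source formula overloads one index; the reading above
is the only one that reproduces those printed dimensions, which is why we
adopted it. Three cross-product variants replace the squared difference
with $M_{m,n} M_{m,n+d}$ (T1), or the same product centred by the mean of
the row sums (T2) or of the column sums (T3); the centring constant is a
single scalar, the reading consistent with its use as a centring constant.

**Normalisation prefactor.** The source prints $1/(L-\xi)$, although no
rows are offset in the column-lag reading. We default to the per-lag
analogue $1/(L-d)$ (`norm = "per_lag"`), and make the fixed $1/(L-\xi)$
(`"max_lag"`) and plain $1/L$ (`"global"`) selectable; the choice rescales
features within a lag and cannot change any dimension, and downstream SVMs
with tuned kernel width are insensitive to it.

**Bidirectional cross-correlation (`bid_cc`).** For residue distance $S$,
every ordered pair $(a, b)$ of amino-acid types contributes
$T^S_{a,b} = \sum_{i=1}^{L-S} M_{i,a} M_{i+S,b}$ — 400 features per $S$,
laid out row-major in the profile's native column order. Both $(a,b)$ and
$(b,a)$ appear, which is what "bidirectional" means here; there is no
separate backward pass. Note these sums are *not* length-normalised (the
source defines them without a prefactor), so their scale grows with $L$;
the SVM's kernel width absorbs this, but it is the reason the default
width grid must extend to very small values.

**Fusion.** The fused encoding concatenates the column-lag block and the
cross-correlation block(s): $189 + 400 = 589$ dimensions at $\xi = 13$ and
one $S$ value.

$\xi = 0$ is accepted as the degenerate pure-means 20-D encoding (an
extension; the source excludes it), and the feature layout is fixed as
means first, then lags ascending, columns ascending within a lag.

## Resampling

**SMOTE.** For each synthetic point: draw a minority parent $x$, one of
its $k$ (default 5, undocumented in the source) same-class Euclidean
nearest neighbours $y$, and $u \sim U[0,1)$; emit $x + u(y-x)$. With
magnification `N = "auto"` every class is raised to the majority count;
an integer `N` adds $N$ synthetics per minority sample, with neighbour
indices drawn with replacement. Originals are never modified; synthetics
carry `synthetic:<parent>` provenance and a full parent/neighbour/weight
log, which the test suite uses to re-derive every point geometrically.

**ENN.** One pass over the set: a sample is deleted when $\ge 2$ of its 3
nearest neighbours (in the original, pre-deletion set) belong to another
class. Deletions are simultaneous, not iterative. **SMOTEENN** is the
composition: oversample, then edit.

**Placement.** `train_fold_only` (default) resamples inside each
leave-one-out training fold, so a test sample never appears in its own
training set, directly or as a SMOTE parent. `before_cv` resamples the
whole set once before cross-validation; it is provided as the
"as-published mode" because near-perfect published resampling metrics are
consistent with that protocol. Reports always record which mode ran.

**Strategy 1 vs strategy 2.** Strategy 2 (default) fuses the feature
blocks and resamples the fused vectors. Strategy 1 resamples each block
separately and then fuses; to keep rows aligned we draw the SMOTE
synthesis schedule (parent, neighbour rank, $u$) once and apply it to
every block — each block's neighbour geometry is its own, but row $i$ of
every block descends from the same parent with the same weight. The ENN
step of strategy 1 votes on the fused matrix: per-block voting could
delete different rows in different blocks, and there is no principled way
to reconcile mismatched survivor sets. How the original work aligned
independently resampled blocks is unstated; this construction is our
design choice.

## Classifier and model selection

No SVM implementation ships with the target environment, so the binary
soft-margin C-SVM is solved in-package as its standard dual quadratic
program (with `quadprog`), with a small escalating ridge on the quadratic
term for the rank-deficient kernels that duplicated post-SMOTE points
produce. Multiclass uses one-vs-one voting (the canonical scheme for
RBF-SVMs), ties broken by accumulated decision margin and then by class
order, so prediction is deterministic.

Grid search over $(C, \gamma)$ is exhaustive; the default grids are the
conventional powers of two, $C \in 2^{-5..15}$, $\gamma \in 2^{-15..3}$,
step 2. Cells are scored by stratified inner-fold accuracy with a
*deterministic* fold assignment (class members dealt round-robin in data
order), ties resolved in grid order. Two placements exist because the
source does not say whether search was nested in the jackknife:
`tune = "once"` (default; one search, then fixed parameters across folds)
and `tune = "nested"` (search inside every training fold, ~n times
slower).

One selection rule is deliberate and worth flagging: **the grid is always
scored on original samples, never on a resampled set.** Synthetic SMOTE
points are convex combinations of originals, so they straddle inner-fold
boundaries; scoring on them inflates inner accuracy (we observed perfect
inner scores selecting a kernel width that *halved* minority sensitivity).

## Jackknife and metrics

Leave-one-out runs over the original samples only; synthetics are never
test points. For $n$ samples exactly $n$ models are fitted. Per class
(one-vs-rest): Sn, Sp, F-measure, Mcc and G-mean $=\sqrt{Sn \cdot Sp}$;
overall accuracy is the fraction of correctly labelled samples. A zero
denominator yields an explicit undefined (NA) value that is excluded from
the unweighted macro averages, with the exclusion count reported — never a
propagated NaN. Single-sample classes are evaluated (their fold simply
lacks the class) and flagged in the report metadata.

Determinism: the resampler derives a per-fold seed from the plan seed and
fold index, the fold assignment and tie-breaks contain no hidden RNG, and
two identical runs produce byte-identical serialised reports.

## The synthetic world

`generate_pssms()` draws each protein's raw scores as a class-specific
mean profile plus Gaussian noise (default sd 2, about half the profile
shift), rounds to integers and clips to $[-10, 12]$ — the numeric range of
real profile output. Default collection shape is 43/30/13/12, the class
distribution of the small four-compartment apoptosis benchmark; lengths
are uniform on 50–120, comfortably above the largest lags under test.
Class profiles shift disjoint blocks of five alphabet columns by +4 raw
log-odds units — a strong but not degenerate separation, chosen once so
that the end-to-end pipeline should recover the labels almost perfectly
(the parameter-recovery criterion). An optional `lag_signal` couples
adjacent columns with a class-dependent coefficient, planting covariance
exactly where the column-lag encoders look.

What the generator does **not** emulate: residue-level sequence structure,
homology between proteins, the heavy-tailed and position-correlated noise
of real profile searches, or any biological relation between compartments.
A green end-to-end test therefore establishes that the pipeline's plumbing
and statistics behave as specified — not that the published accuracies on
the real benchmarks are reproduced, which would require database-derived
profiles that are out of scope by design.

`generate_feature_blobs()` skips the PSSM layer entirely (Gaussian blobs
in feature space) and is used to probe the resampler and classifier in
isolation: the separable limit (accuracy 1), the chance limit (accuracy
within binomial error of $1/K$), and the overlap+imbalance regime where
SMOTEENN must not lower — and in practice raises — macro F-measure and
G-mean relative to no resampling.

## Numerical and degenerate-input choices

- Sigmoid scaling is refused when already applied (it is not idempotent).
- Distance ties in nearest-neighbour searches break by row order; random
  draws use one seed fanned out per stage, kept below $2^{31}$.
- SMOTE requires every oversampled class to have at least $k+1$ members;
  ENN requires $n \ge 4$ and returns single-class sets unchanged; a class
  wiped out by ENN warns rather than errors, as the downstream report
  makes the loss visible.
- The QP ridge starts at $10^{-8}$ and escalates $\times 100$ up to six
  attempts before failing; the intercept averages over free support
  vectors, falling back to all support vectors.
- Test suites and the acceptance harness use small explicit
  powers-of-two grids (e.g. $3 \times 3$) rather than the full default
  grid to stay inside a single-CPU time budget; the grids are user
  configuration, and nothing in the acceptance quantities depends on grid
  resolution.

## Known limitations

- The QP-based SVM is dense and $O(n^3)$-ish per binary machine: ample
  for the few-hundred-sample collections this field uses, unsuitable for
  thousands of samples.
- `before_cv` placement leaks synthetic information into training folds
  by construction; it exists for comparability, not as a recommendation.
- Only the ASCII PSSM dialect is parsed; binary checkpoint profiles and
  running the profile search itself are out of scope.
- ADASYN and Tomek-link variants of the resampling stage are not
  implemented; the plan enum is extensible.
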