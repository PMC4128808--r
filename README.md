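# fitscape

Nonlinear fitness landscapes for inverse protein folding (protein
design), built from a reduced support vector machine with a rectangular
Gaussian kernel and trained by a finite Newton method.

## The problem

Inverse protein folding asks for amino-acid sequences that fold into a
prescribed target structure. A usable fitness function `f` must rank, for
every target, the native sequence below all competing (decoy) sequences
mounted on the same structure:

    f(c_native) < f(c_decoy)   for every decoy of that structure,

where `c` is a 210-dimensional contact vector counting the non-bonded
residue-pair contacts of a (sequence, structure) pair — one slot per
unordered pair of the 20 amino-acid types. Linear functions `w · c`
provably cannot satisfy all such inequalities on large protein sets, so
`fitscape` fits the nonlinear landscape

    f(x) = sum_j  D_j u_j K(x, a_j)  -  gamma,
    K(x, y) = exp(-mu ||x - y||^2),

parameterized by a small *basis set* {a_j} of native and decoy contact
vectors with class signs `D_j` (native = -1, decoy = +1). Negative
fitness means native-like; the fitted landscape behaves as an energy.

The coefficients solve a reduced SVM: a quadratic program over the
rectangular kernel matrix K(A, Abar') between the full training pool A
(m rows) and the basis Abar (m-bar << m rows), with 2-norm slack, a
bias-squared term, and class-weighted costs so errors on the small
native class outweigh errors on the decoy mass. The equivalent
unconstrained piecewise-quadratic problem is minimized by a generalized
(finite) Newton iteration with an Armijo line search; each step solves
one (m-bar + 1)-dimensional linear system by LU factorization, and no
m x m matrix is ever formed.

Around that core the package provides:

* **contacts** — PDB chain parsing (via `bio3d`), Delaunay-filtered
  heavy-atom contact maps (empty-circumsphere edge test, 4.5 Å cutoff),
  210-type contact-count vectors, and length normalization by a fitted
  total-contacts-versus-length regression (`fit_length_model()`,
  `normalize_length()`).
* **decoys** — sequence decoys by gapless threading
  (`thread_decoys()`: every window of a longer guest sequence mounted on
  the host structure) and by composition-preserving random swaps
  (`swap_decoys()`).
* **selection** — iterative construction of the training pool C and the
  basis set: Strategy 1 recycles misclassified decoys, Strategy 2 mines
  the hardest correctly-classified decoys and natives
  (`run_training()`).
* **evaluate** — F-beta scores (beta = 10 by default, natives positive),
  misclassification bookkeeping over decoy streams larger than memory,
  per-native design-rank verdicts, swap-decoy misclassification curves.
* **synth** — synthetic toy structures and labeled contact-vector
  cohorts with controllable native/decoy separability, so the whole
  pipeline is testable without downloading structures.

## Worked example

Train on a synthetic cohort (100 proteins, 50 decoys each, 65/35
train/test split) with Strategy 2 and score the held-out proteins:

```r
library(fitscape)

co  <- make_vector_cohort(synth_config(seed = 1))
res <- run_training(co$train$natives, co$train$universe,
                    config = selection_config(strategy = 2, seed = 1))
res$reports
#>   round mis_natives mis_decoys total basis_size pool_size converged
#> 1     0           0          3     3         65       130      TRUE
#> 2     1           0          0     0        299       715      TRUE
#> 3     2           0          0     0        299       715      TRUE

ev <- evaluate_universe(res$model, co$test$natives$X, co$test$universe$X)
ev$counts
#> <confusion_counts> TP 33  FP 0  FN 2  TN 1750
round(fbeta(ev$counts, beta = 10), 3)
#> [1] 0.943
```

The per-round report shows the landscape improving as the pool and basis
are rebuilt from hard examples: 3 misclassified decoys before the first
strategy round, none after. On the held-out split, 2 of 35 natives drift
above the zero level set (positive fitness), yet the design-rank test —
is the native strictly the lowest-fitness sequence among itself and its
own 50 decoys? — succeeds for all 35:

```r
mean(vapply(seq_along(co$test$natives$ids), function(k) {
  rows <- co$test$universe$native_id == co$test$natives$ids[k]
  design_rank(res$model, co$test$natives$X[k, ],
              co$test$universe$X[rows, , drop = FALSE])$success
}, TRUE))
#> [1] 1
```

A command-line front-end (`exec/fitscape`) wraps the same functions:
`fitscape synth | contacts | decoys | train | score | evaluate`, with a
single `--seed` fanned out deterministically to every stage.

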