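---
title: "Block-wise non-negative matrix tri-factorization: model, equivalence, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Block-wise non-negative matrix tri-factorization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blocknmtf)
```

## The model

Non-negative matrix tri-factorization (NMTF) approximates a non-negative
data matrix $X \in \mathbb{R}_+^{n \times m}$ — rows are typically
instances (samples, genes), columns features — by three non-negative
latent factors,

$$X \approx U S V^\top, \qquad
U \in \mathbb{R}_+^{n \times k_1},\;
S \in \mathbb{R}_+^{k_1 \times k_2},\;
V \in \mathbb{R}_+^{m \times k_2},$$

minimizing the squared Frobenius reconstruction error
$F(U, S, V) = \lVert X - U S V^\top \rVert_F^2$.  Columns of $U$ span
row-space patterns, columns of $V$ column-space patterns, and $S$ encodes
how the two interact, which is what makes the tri-factorization (rather
than two-factor NMF) attractive for co-clustering: a pair (row cluster
$r$, column cluster $c$) has interaction strength $S_{rc}$.

`fit_serial()` minimizes $F$ by the classical multiplicative updates

$$U \leftarrow U \circ \frac{XVS^\top}{USV^\top VS^\top},\qquad
V \leftarrow V \circ \frac{X^\top US}{VS^\top U^\top US},\qquad
S \leftarrow S \circ \frac{U^\top XV}{U^\top USV^\top V},$$

which preserve non-negativity, leave zero entries at zero, and (for this
objective) never increase $F$.  The orthogonal variant
(`variant = "orthogonal"`) targets $U^\top U = I$, $V^\top V = I$ with the
square-root damped rules

$$U \leftarrow U \circ \sqrt{\frac{XVS^\top}{UU^\top XVS^\top}},\qquad
V \leftarrow V \circ \sqrt{\frac{X^\top US}{VV^\top X^\top US}},\qquad
S \leftarrow S \circ \sqrt{\frac{U^\top XV}{U^\top USV^\top V}}.$$

Orthogonality pushes the columns of $U$ and $V$ toward disjoint supports,
which is what makes their row-wise argmax interpretable as a hard
clustering.  Two properties worth noting, because the tests rely on them:

* any exact positive factorization is a fixed point of the plain rules,
  but the square-root rules for $U$ and $V$ are stationary only at
  *orthogonal* exact factorizations (the denominator $UU^\top XVS^\top$
  collapses to the numerator only when $U^\top U = I$), and a non-negative
  matrix cannot be orthogonal and strictly positive at once —
  `make_exact_orthogonal()` builds the disjoint-support fixture used to
  test them;
* $F$ is invariant under the rescaling $U \to UD$, $S \to D^{-1}S$ for any
  positive diagonal $D$, so the magnitudes of latent columns are
  arbitrary.

## Block-wise updates and why they are exact

For large matrices the updates are reformulated over an $N \times M$ grid
of contiguous blocks $X^{(i,j)}$; $U$ is partitioned into $N$ row bands
$U^{(i)}$, $V$ into $M$ bands $V^{(j)}$ following the columns of $X$, and
$S$ is never partitioned.  Every numerator and denominator of the serial
rules is a product whose rows (or columns) decompose over the grid, e.g.

$$\bigl(XVS^\top\bigr)^{(i)} = \sum_j X^{(i,j)} V^{(j)} S^\top,\qquad
V^\top V = \sum_j \bigl(V^{(j)}\bigr)^\top V^{(j)},$$

so band $i$ of the block-wise $U$ update equals band $i$ of the serial
update *exactly*, not approximately.  The only quantities a band update
needs besides its own blocks are $k$-dimensional aggregates (the Gram
matrices $\sum_i (U^{(i)})^\top U^{(i)}$, $\sum_j (V^{(j)})^\top V^{(j)}$,
and $\sum_{i,j} (U^{(i)})^\top X^{(i,j)} V^{(j)}$) — this is the whole
point: what must be shared between processing units is $O(k^2)$, not
$O(nm)$.  The same regrouping applies to the square-root damped variant,
with the band-local numerators $P^{(i)} = \sum_j X^{(i,j)}V^{(j)}S^\top$
and the global damping aggregate $A = \sum_i (U^{(i)})^\top P^{(i)}$.
(The printed block forms of the orthogonal $U$ and $V$ rules in the
source literature contain index slips; this package implements the forms
that are algebraically identical to the serial orthogonal rules, which is
the stated intent.)

`fit_blockwise()` runs full iterations in the fixed order $U$, then $V$,
then $S$, each rule consuming the freshest factors, recomputing the
aggregates at the point of use.  The update order is a package choice
(the rules are conventionally listed in this order); both execution paths
share it, and they also share the same kernel functions and the same
association of every matrix product, so a $1 \times 1$ grid reproduces
`fit_serial()` bit for bit.  For general grids, agreement is to floating
point rounding: single updates agree to about $10^{-16}$ and 50
iterations to about $10^{-13}$ in the shipped checks, comfortably inside
the $10^{-10}$ / $10^{-8}$ contract the tests enforce.

## Partitioning

`partition_dense(n, m, N, M)` places bound $i$ at
$\lfloor i \cdot n / N \rfloor$, so block heights and widths differ by at
most one — the right choice when work per entry is uniform.  For sparse
matrices work scales with nonzeros, so `partition_sparse()` balances
nonzeros instead: row bound $i$ is the smallest index at which the
cumulative row-nnz reaches $i/N$ of the total, columns analogously and
independently.  This marginal prefix-sum scheme (rather than a joint
block-level optimization) is deliberate: bands must be shared along whole
grid rows and columns, and the marginal rule is deterministic, $O(n + m)$,
and reproducible.  Rows or columns without nonzeros simply stay in the
band their index falls into.  When a single row concentrates so much mass
that a later band would be left without rows, the partitioner raises a
configuration error rather than silently producing empty bands.

Coordinates are stored 0-based with half-open intervals, so
concatenating extracted blocks reconstructs the matrix exactly; the grid
is serialized into the run log as its two bound vectors.

## Parallel execution and determinism

`run_parallel()` executes one grid block per worker ($p = N \cdot M$, or
$p = 1$).  Workers pin their block of $X$ once and compute all
block-local partial products each stage; reductions run on the
coordinating process in ascending block index, and band updates are
applied once and broadcast.  Because summation order is fixed and the
per-block arithmetic is the same compiled code in either path, the
factors are **bit-identical** to the single-process block-wise fit for
every worker count — worker-count invariance is a hard contract, tested
with `identical()`, not a tolerance.

`build_plan()` records the staged data movement — partials, their
exchange toward the reducing worker, the $k \times k$ aggregate
broadcast, the band update, and band redistribution.  Whole factor bands
travel only when both grid dimensions exceed one: on a $1 \times M$ grid
every worker spans the full row dimension and rebuilds $U$ from the
shared aggregates locally, and on $N \times 1$ grids the $U$-side partials
are complete without any exchange.  This asymmetry is why tall matrices
favor row-wise grids and wide matrices column-wise grids, and the plan
object makes it checkable.

## Interpreting factors, and when argmax is identifiable

`assign_clusters()` labels row $i$ by the argmax of $U_{i\cdot}$ (ties to
the lowest index), columns likewise from $V$, and ranks cluster pairs by
$S$.  A subtlety that shapes the whole interpretation module: a planted
co-cluster matrix with $k_1$ row and $k_2$ column clusters has matrix
rank $\min(k_1, k_2)$.  Whenever $k_1 > k_2$ the minimizer of $F$ is far
from unique — the factorization can always absorb $S$ into $U$ and
express the data with mixed columns — and the argmax of a random-start
fit need not align with any clustering, even at negligible noise and
reconstruction error at the noise floor.  Orthogonality pressure alone
(the multiplicative variant of it being soft) does not rescue this at
realistic sizes.

`fit_cocluster()` therefore follows common co-clustering practice: seed
$U$ and $V$ with k-means memberships of the rows and columns (membership
weight 1, off-cluster weight 0.2 so no entry is multiplicatively dead),
seed $S$ with the per-block means, and refine with the orthogonal update
rules.  Refinement keeps the factors near indicator structure while the
reconstruction error drops; the planted-recovery checks (adjusted Rand
index $\ge 0.9$ on 200 × 150 matrices with 4 × 3 clusters and noise at 5%
of the block-mean spread) pass in at least 18 of 20 seeded runs.

The same rank-deficiency dictates the design of `select_rank()`.  Fitting
candidates by fully joint mask-weighted updates cannot prefer the planted
$(3, 2)$ over $(2, 2)$: the collapse above gives $(2, 2)$ *identical*
expressive power, so held-out reconstruction ties up to optimization
noise.  The default mode instead scores each candidate as a clustering
model: memberships from k-means on the observed (row-mean-imputed)
entries are locked as indicator $U$ and $V$, only $S$ is refined with the
mask-weighted multiplicative rule, and errors on the held-out entries are
summed over several independent masks (5 by default — averaging exposes
the small but systematic penalty of over-segmented candidates).  The
fully joint mode remains available as `refine = "joint"` for studying the
unconstrained behavior.

## Synthetic data

Three generators give every module a ground truth:

* `make_exact()` — $X = U_0 S_0 V_0^\top$ from strictly positive uniform
  $(0.5, 1.5)$ factors: zero reconstruction error at the truth, numerical
  rank $\min(k_1, k_2)$.
* `make_cocluster()` — block-constant means plus Gaussian noise truncated
  at zero (truncation preserves non-negativity without reordering block
  means); block means default to uniform $(0.25, 2)$ draws and the noise
  standard deviation to 5% of the block-mean spread; optional Bernoulli
  sparsification with probability `density`.
* `make_skewed_sparse()` — exactly `nnz` positive entries allocated to
  rows by power-law weights $i^{-\mathrm{skew}}$ with water-filling
  against the per-row capacity $m$, so heavily loaded rows saturate and
  the uncapped tail keeps its skew.  This is the stress input for the
  nnz-balancing partitioner.

What these fixtures do *not* emulate: real methylation beta-value
distributions, correlated noise, network topology, or missing-data
mechanisms.  Passing tests demonstrate algorithmic correctness and
recovery under the planted model, not performance on any particular
biological data set.

## Numerical choices

* Initialization: entries uniform on $(0, s]$ with
  $s = \sqrt{\bar X / (k_1 k_2)}$, so the initial reconstruction is on
  the scale of $X$; strictly positive so no update starts dead;
  deterministic given `seed`, and the caller's RNG stream is left
  untouched.
* Denominator guard: `max(den, epsilon)` with $\varepsilon = 10^{-12}$,
  preserving multiplicative-zero semantics when sparse rows or columns
  zero a denominator.
* Convergence: $|F_t - F_{t-c}| / \max(F_{t-c}, \varepsilon) <$ `tol`
  (default $10^{-5}$) checked every `check_every` = 10 iterations;
  everything is double precision throughout, which the tight equivalence
  contracts require.
* All block reductions run in ascending block index; ties in argmax break
  to the lowest index; prefix-sum boundaries go to the first index
  reaching the target.

## Problem sizes in the shipped checks

The test suite and the acceptance script work at desk scale, chosen so
the full suite runs in well under a minute of compute: equivalence on
60 × 40 matrices over grids up to $3 \times 2$, monotonicity on 100 × 80
over 200 iterations and 20 seeds, parallel bit-identity on 40 × 30 with
four workers, recovery on 200 × 150 planted co-clusters, rank selection
on 80 × 60.  The block-wise algebra is size-independent — the equivalence
argument is exact at any scale — but wall-clock scaling claims are
outside what this package measures.

## Known limitations

* One block per worker; no multi-block scheduling, no overlap of
  communication and computation, no GPU path.
* The orthogonal variant enforces orthogonality only through the damped
  update, not exactly; $U^\top U$ approaches but does not reach $I$.
* Rank selection assumes the co-cluster interpretation of the factors;
  for purely low-rank (non-cluster) data the joint mode is the honest
  tool and will, correctly, report ties between candidates sharing
  $\min(k_1, k_2)$.
* The masked fitter densifies its input; holdout-based selection is
  intended for matrices that fit in memory densely.
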