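---
title: "Modelling stem cell differentiation as a non-Markov stochastic process"
author: "statefate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling stem cell differentiation as a non-Markov stochastic process}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statefate)
```

## The model family

`statefate` analyses snapshot time courses of differentiating embryonic
stem cells: at a handful of experiment times, populations of single cells
are destructively assayed and each cell is assigned to one of three
observable macrostates — naive pluripotent (ESC), epiblast-like (EPI) or
neuroprogenitor (NPC). The quantity all models predict is the macrostate
occupancy trajectory $p_A(t), p_B(t), p_C(t)$, starting from $p_A(0) = 1$.

**First-order kinetics** is the memoryless null: two sequential exponential
steps with rates $q_1, q_2$ per hour. Its constant exit hazard means the
ESC state empties fastest at $t = 0$, so it cannot produce the shoulder and
mid-course EPI accumulation seen in the data it is designed to be rejected
on. The closed form is implemented in `solveFirstOrder()`, with the
$q_1 = q_2$ degeneracy handled by the limiting form $q_1 t e^{-q_1 t}$.

**Paracrine feedback** (`solveParacrine()`) keeps the two-step structure
but lets residual ESCs inhibit the EPI-to-NPC step through a Hill factor
$K^h / (K^h + p_A^h)$; variants are $h = 1$, free $h$, and the
ultrasensitive limit $h \to \infty$, where the second step switches on only
once $p_A < K$. This is the cell-extrinsic alternative to hidden cellular
memory.

**The hidden microstate chain** (`chainMacrostates()`) is the central
model: cells traverse microstates $0..N$ by a homogeneous Poisson process
at rate $q$, and contiguous blocks map to macrostates ($0..n_A$ ESC,
$n_A{+}1..n_B$ EPI, the rest NPC; state $N$ absorbing). Microstate
occupancy is the Poisson pmf with absorbing mass at $N$, and the macrostate
proportions are Poisson-CDF block sums. Macrostate residence times are then
Erlang with shape equal to the block size (`waitTimeDistribution()`), so
the macrostate exit hazard *increases with the age in state* whenever the
block holds more than one microstate — the memory signature separating this
model from the first-order null. A reversible variant
(`solveReversible()`) adds a backward rate $q_b$ and is solved numerically
from the birth–death generator. An age-structured continuum formulation
(`solveAgeStructured()`) transports macrostate-age densities along
characteristics with the Erlang hazard as exit intensity and reproduces the
chain marginals; it exists to make the non-Markov structure explicit and is
validated against the analytic solution (sup-norm below $10^{-3}$ on a
0.05 h grid).

**The conveyor belt** (`solveConveyor()`) is the deterministic
counterpoint: all variability exists at $t = 0$ as a density $f_0(x)$ on a
reaction coordinate and is advected forward at constant speed, with
macrostates emitted by position. Uniform and Gaussian initial conditions
are supported; the uniform variant predicts straight-line loss of ESC
occupancy, which is its diagnostic signature.

### Printed-formula corrections

Three formula-level choices in the implemented equations deserve note, all
made so that proportions are nonnegative, sum to one, and reduce correctly
in limits, and all validated by independent routes in the test suite:

* the middle block sum is implemented as $F(n_B, qt) - F(n_A, qt)$ (the
  nonnegative ordering consistent with the block-sum definition), and the
  analogous ordering is used for the conveyor CDF differences;
* the reversible chain uses the standard probability-conserving birth–death
  generator with reflecting state 0 and absorbing state $N$, which reduces
  exactly to the irreversible system at $q_b = 0$;
* the age-structured exit term uses the Erlang hazard
  $\lambda(\tau) = f(\tau)/S(\tau)$ (pdf over survival) as the dimensionally
  consistent exit intensity, and the wait-time shapes are the block sizes
  ($n_A + 1$ for ESC, $n_B - n_A$ for EPI), the convention under which
  shape $\times$ step time reproduces the mean residence times the model
  reports.

## State calling

`callStates()` binarizes expression (detected / not detected), projects
cells onto the top two principal components, and clusters with k-means.
Binarization before PCA is deliberate: ET-scale level noise is large
relative to the on/off structure that separates the three states, and
retaining only detection makes the projection stable. Each component is
oriented so its largest-magnitude loading is positive, removing the
reflection nondeterminism of PCA. k-means uses 50 restarts with a threaded
seed.

The number of clusters is validated by the GAP statistic
(`gapStatistic()`, backed by `cluster::clusGap` with the
principal-axis-aligned uniform reference); the selection rule is the 1-SE
rule (smallest $k$ with $\mathrm{Gap}(k) \ge \mathrm{Gap}(k{+}1) -
\mathrm{SE}(k{+}1)$), which selects 3 on three-cluster fixtures while the
full curve is returned so the elbow can be inspected directly. Clusters are
mapped to macrostates by marker expression (naive-pluripotency markers
highest in ESC, neural markers in NPC, remainder EPI), falling back to
mean-sampling-time ordering with a warning when markers are absent.
Proportion uncertainty comes from percentile bootstrap over cells within
each timepoint (`macrostateProportions()`).

## Model fitting

All models are fitted by unweighted residual sum of squares over the three
states and all times. Continuous models use multistart Levenberg–Marquardt
(`minpack.lm::nls.lm`) on log-parameterized rates; the two non-smooth
models (ultrasensitive switch, uniform-conveyor boundary coupling) use
Nelder–Mead instead, since a quadratic local model is wrong at their kinks.

The chain fit (`fitChain()`) minimizes $\lVert y - f \rVert^2 +
\lambda(n_A + n_B)$ jointly over the integers $n_A < n_B$ (default bounds
$n_A \in [0, 30]$, $n_B \le 60$) and the rate $q$, by exhaustive outer
search with an inner 1-D optimization of $q$ per integer pair. $N$ is fixed
at $n_B + 1$: macrostate proportions carry no information about chain
length beyond the absorbing entry into NPC, so the terminal block is
collapsed (an override exists on `ChainParams()`). Because the penalty is
separable, the profile table RSS$(n_A, n_B)$ is computed once and reused
across the whole $\lambda$ path.

$\lambda$ is chosen by the L-curve (`selectLambdaLcurve()`). The trade-off
curve is built from the profile table itself — per total complexity
$n_A + n_B$, the best achievable misfit, monotonized — rather than from the
$\lambda$ path alone, because when the global minimizer is already the
corner model the path never visits the flat branch of the L and the corner
is invisible to it. The corner is the maximum Menger curvature over
log-penalty/log-misfit triples, restricted to convex corners; the chosen
$\lambda$ is the largest grid value that still selects at least the
corner's complexity (ties resolve toward parsimony). A flat curve falls
back to the smallest $\lambda$ with a warning.

Under the study conditions (7 snapshot times over 168 h, 200 cells per
time, chain $n_A = 7$, $n_B = 18$, $q = 1/5.3$ h$^{-1}$, marker-block
emission with 0.95/0.10 detection), the full pipeline — simulate, call
states at $k = 3$, fit with L-curve regularization — recovers the ESC and
EPI microstate counts with median absolute error at most 1 and the step
time $1/q$ within 15% over 50 seeds; this is asserted by the test suite and
recomputed by `scripts/acceptance.R`.

## Variability statistics

Cell-cell variability uses the mediancentre: the point minimizing total
$L_1$ distance to all cells, computed coordinatewise (exact, because the
$L_1$ objective separates by coordinate; even counts take the midpoint of
the central pair, a canonical point of the minimizing interval). Per-cell
distances to it are the dispersions; groups are compared with the two-sided
Wilcoxon rank-sum test, which holds its nominal 5% type-I error in a
5000-replicate null simulation in the test suite.

Per-gene entropy uses Bayesian-Blocks discretization: dynamic programming
over the block fitness $N_k(\log N_k - \log T_k)$ with the per-block prior
$4 - \log(73.53\, p_0 N^{-0.478})$ at the conventional false-alarm
probability $p_0 = 0.05$ (no value being dictated by the application, the
standard calibration is used). No installed package provides the algorithm,
so it is implemented here and checked against brute-force enumeration of
all contiguous partitions at small $n$. Two behaviours of the event-style
fitness are worth knowing: a perfectly balanced two-atom variable (exactly
two distinct values, equal counts) has uniform empirical density and
legitimately collapses to one block, and a boundary point of a dense
cluster can be assigned to the adjacent gap block (Voronoi edge effect).
Real ET data — exact zeros plus a spread expressed mode — is the favourable
case. Discretization pools all cells (both lines, all times) per gene, so
one binning serves the whole course; entropy is then plug-in Shannon
entropy of bin occupancy per timepoint, in bits, with the mean over genes
as a summary.

## Network inference

Gene-gene dependencies are scored with the partial information
decomposition under the Williams–Beer $I_{\min}$ redundancy measure (the
variant is isolated in `pidDecompose()`; the decomposition identities
$U_X + R = I(X;Z)$ and $S + U_X + U_Y + R = I(X,Y;Z)$ are enforced to
$10^{-9}$ in property tests). For each gene pair the proportional unique
contribution $u_{X,Z}$ sums, over every third gene, the unique-to-mutual
information ratio in both target directions; pairs with $I(X;Z) = 0$ get
$u = 0$ by convention (there is no dependency to apportion). Confidence
scores $c = F_X(u) + F_Y(u)$ use right-continuous per-gene empirical CDFs
(the point itself included), and the top 5% of pairs are retained as
undirected edges, ties at the cutoff all included. Node degree and
betweenness come from igraph over the unweighted retained edges. Stage
comparison infers early (ESC+EPI cells) and late (EPI+NPC) networks on a
shared pooled discretization and reports per-edge score changes. Community
detection by Markov-stability scanning is deliberately not reimplemented
(an existing published method); module-level summaries accept external
partitions.

## Lineage classifier

`makeSignature()` takes the top and bottom 5% of genes by expression change
versus the 0 h baseline; `scoreReference()` compares the up-set's values
against the down-set's values *within a reference profile* by Wilcoxon
rank-sum (exact for set sizes up to 10, normal approximation with tie
handling otherwise) and reports the signed $-\log_{10}$ one-sided p —
positive when the reference is high where the test sample went up. The
up-vs-down contrast is the default because it is self-contained within each
reference; the alternative contrast (each set against the background genes)
is available via `contrast = "background"`. p-values are floored at
$10^{-300}$ so scores stay finite.

## The synthetic-data generator

The generator defines the conditions every downstream claim is tested
under. `simulateChainCells()` draws exact exponential waiting times (no
time discretization), records cells at the experimental grid
0–168 h, and by default gives each sample time an independent cohort,
mirroring a destructive assay; a longitudinal mode follows the same cells
for path-property tests. `emitExpression()` is a deliberate stand-in for
the unmodelled microstate-to-expression link: a two-part detection × level
model with marker blocks per macrostate (detection 0.95 in the home state,
0.10 elsewhere — strong but imperfect markers, chosen as typical of curated
qPCR panels) and Gaussian levels clipped to the ET scale $[0, 28]$. What it
does *not* emulate: graded expression changes within a macrostate,
cell-cycle covariation, batch effects, or amplification noise — so passing
recovery tests demonstrates correctness of the inference machinery under
the model's own assumptions, not robustness to everything real data does.
`synthBulkTimecourse()` plants monotone log-scale drifts (half up, half
down, total drift 4 on a noise floor of 0.1) for the cumulative-relative-
expression DEG filter, and `synthReferenceLibrary()` plants one concordant
reference profile for the classifier. Ground-truth labels always travel
with the data.

## Preprocessing conventions

CT values are normalized per cell by the median control CT (Actb, Gapdh)
against a global target (the median of the per-cell control medians, or a
fixed value); normalized CT at or above 28 is absent, and
$ET = 28 - CT$ clipped to $[0, 28]$ — the linear transform pinned down by
its stated range. Cell filters: control CT above 15, or total ET outside
$[Q_1 - 2I,\, Q_3 + 2I]$ (type-7 linear-interpolation quantiles throughout,
documented because IQR fences are convention-sensitive). Genes absent in
strictly more than 80% of cells are dropped. Bulk DEG calling sums
log-scale changes against the 0 h column (one column per timepoint assumed)
and applies the $3I$ fence on the pooled CRE distribution.

## Numerical choices and limitations

Poisson pmf/CDF evaluations go through R's `dpois`/`ppois` (log-space
internally), with absorbing mass taken from the upper tail rather than
$1 - \sum$; ODEs use `lsoda` at rtol $10^{-10}$; Erlang hazards are
computed in log space and saturate at the step rate deep in the survival
tail. Problem sizes in the tests and acceptance script — $10^4$ cells for
Monte-Carlo agreement, 50 seeds × 200 cells/time for recovery, 5000 null
replicates for test calibration, 0.05 h grids for the age-structured solver
— were chosen so each check's sampling error sits well below the tolerance
it asserts.

Known limitations: the chain length $N$ beyond $n_B$ is unidentifiable from
proportions (fixed by convention); the emission model is plumbing, not
biology; PID scoring is $O(G^3)$ in the gene count and is intended for
low-plex panels (under ~100 genes after filtering); the classifier's
up-vs-down contrast is one of two defensible readings of a rank-sum
similarity score, and both are exposed; and bootstrap CIs on proportions
are available to the fit only as optional weights — the default objective
is the stated unweighted RSS.
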