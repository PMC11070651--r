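---
title: "Intercellular gene association networks: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intercellular gene association networks: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igan)
```

## The model

Most cell–cell communication (CCC) tools score the co-expression of annotated
ligand–receptor pairs between cell *types*. This package instead asks a
finer question: for two *individual, spatially adjacent* cells, which gene of
one cell is statistically associated with which gene of the other? The
answer is a directional binary network per adjacent cell pair, from which
ligand-level activity, pathway graphs, communication features and
pattern-consistency benchmarks are all derived.

### Cell pairs and scatters

Cells come with slide coordinates. Two cells are adjacent when their
Euclidean distance is positive and at most a threshold: for bead platforms
the 99th percentile (linear interpolation) of per-cell nearest-neighbor
distances, which ignores stray isolated beads; for regular-grid platforms
the minimum pairwise distance, i.e. the grid pitch.

For a directed cell-type combination $A \to B$ we collect all $n$ ordered
adjacent pairs $(a_k, b_k)$ with $a_k$ of type $A$ and $b_k$ of type $B$
(both orientations when $A = B$). A source gene $x$ and target gene $y$
define a scatter with one point per pair: $x$ measured in $a_k$, $y$ in
$b_k$, on library-size-normalized, `log1p`-transformed expression.

### The local window test

Around each focal pair $k$ we take the $w = \lceil b\,n \rceil$ pairs whose
$x$-values are nearest to $x_k$ (the focal pair always included) and
likewise for $y$; $n_{xy}$ counts the pairs inside both windows. If the two
genes are independent across pairs, knowing that a pair is near $k$ in $x$
says nothing about being near $k$ in $y$, so the joint occupancy matches the
product of the marginals. The classical standardized statistic is

$$\hat\rho_k \;=\; \frac{n_{xy}/n - (n_x/n)(n_y/n)}
  {\sqrt{n_x n_y (n-n_x)(n-n_y)\,/\,(n^4 (n-1))}},$$

approximately standard normal under independence
(`association_statistic()`).

Two numerical points matter in practice and shaped the default decision
rule in `test_gene_pair()`:

1. **The focal pair carries no evidence.** It sits in both windows by
   construction. Under independence the focal-excluded joint count follows
   exactly $n_{xy} - 1 \sim \mathrm{Hypergeometric}(n-1,\, w-1,\, w-1)$: the
   $w-1$ non-focal members of the $x$-window are an exchangeable subset of
   the other pairs, and independence makes the $y$-window membership a
   uniform draw against it. The statistic applied to the focal-excluded
   counts $(n-1, w-1, w-1, n_{xy}-1)$ has exactly mean 0 and variance 1
   under this law; applied to the inclusive counts it is biased upward by
   roughly $(1-w/n)^2$ standard deviations, which at $n$ in the hundreds
   inflates the false-positive rate several-fold.
2. **Counts are full of ties.** Nearest-by-value windows on zero-inflated
   counts must break large tie groups. Any *fixed* tie resolution shared
   across focal pairs couples the windows of different focals — one lucky
   overlap between the two genes' resolved tie classes then fires dozens of
   focal pairs at once — and index-ordered resolution additionally couples
   the $x$ and $y$ axes (measured null edge rate 0.21 at $\alpha = 0.01$ on
   negative-binomial counts). Ties are therefore resolved independently per
   focal pair by a deterministic random stream seeded from the gene's own
   values: reproducible, identical across call paths, and calibrated.

The default rule (`method = "exact"`) rejects when the hypergeometric upper
tail of $n_{xy}-1$ is at most $\alpha$; `method = "normal"` thresholds the
focal-excluded statistic at $\Phi^{-1}(1-\alpha)$. The test is one-sided
positive: downstream quantities count positive associations as
communication. Genes with zero variance across the pairs never fire.

Defaults: window fraction $b = 0.1$, level $\alpha = 0.01$, at least 10
pairs per combination (below that, $w \le 1$ and there is no usable
evidence anyway). At the grading scales used here ($n = 500$, $b = 0.1$,
$\alpha = 0.01$) the achieved level of the exact rule is about 0.004 —
conservative because the hypergeometric tail is discrete.

### From networks to activity, features and patterns

With $H^{(ab_k)}_{ij} \in \{0,1\}$ the association indicator from gene $i$
of $a$ to gene $j$ of its $k$-th neighbor, a cell's ligand-wise sending
signal is the neighbor-averaged row sum
$\mathrm{send}(a,i) = t_a^{-1}\sum_k \sum_j H^{(ab_k)}_{ij}$, receiving
mirrors it with the neighbor as source, and the cell's CCC strength is the
ligand sum of both. Isolated cells ($t_a = 0$) have zero activity by
convention; skipped type combinations contribute zero but their neighbors
still count in $t_a$, which stays a purely spatial quantity.

The cells × $2p$ feature matrix `build_feature_matrix()` is exactly
(send columns, recv columns). `cluster_cells()` standardizes
(`log1p` + z-score), reduces by PCA, builds a shared-nearest-neighbor graph
(Jaccard weights) and runs Louvain modularity at a given resolution, all
seed-deterministic; combined mode concatenates expression PCs with CCC PCs
scaled by a weight $w$, with $w = 0$ reproducing expression-only labels.

The cell-type × ligand communication matrix sums, over the other types
$i'$, the per-pair mean ligand row count of the $(i, i')$ (sending) or
$(i', i)$ (receiving) networks.

### Pathway (Sankey) graphs

For a directed type pair, high-activity ligands are the top 10 by mean
sending activity over the source type's cells with strictly positive mean
(there is no canonical cut-off in the field; the rule is recorded in every
run manifest). A ligand's downstream genes are those accumulating strictly
more than $0.01\,N$ association counts over the $N$ pairs. Pathways are
kept when they are both over-represented in the downstream set (one-sided
hypergeometric, Benjamini–Hochberg $q < 0.05$, universe = the tested target
genes, not the genome — the association test never saw the rest of the
genome) and contain at least one subunit of a cognate receptor unit. The
receptor→pathway link weight is the number of the ligand's downstream genes
inside the pathway; it is drawn identically for each receptor unit of the
ligand because the networks carry no receptor resolution. An ontology tier
is computed with the same hypergeometric machinery on the ligand list
against GO-style sets.

A caution on the $0.01\,N$ rule at small $N$: any test at level $\alpha$
leaves an expected $\alpha N$ null counts per gene pair, so at
$N \approx 200$ the threshold $0.01\,N = 2$ sits exactly at the null
expectation and single-run selections necessarily contain noise genes
(measured null selection probability 0.06–0.09 per gene, partly in bursts
because neighboring focal pairs share window structure). The rule is
designed for the $N \sim 10^3$–$10^4$ of real slides. Where a precise
selection is needed at small $N$, aggregate over replicates (the acceptance
experiments keep a gene only when selected in the majority of 20 runs) or
lower $\alpha$.

### Microenvironment-consistency benchmark

Communication patterns should mirror spatial microenvironment patterns. The
benchmark decomposes the cell-type × environment count matrix $E$ and each
cell-type × ligand matrix $C$ by NMF at a shared rank $k$ (multiplicative
updates, Frobenius objective, columns pre-scaled to maximum 1, five random
restarts keeping the lowest reconstruction error, seed-controlled), then
scores the two cell-type loading matrices with a weighted
Kullback–Leibler divergence: cell-type weights are cell-count proportions,
pattern weights are the row sums of $E$'s basis matrix.

Two choices make this score well-defined:

- **Weighted normalization.** With arbitrary pattern weights inside the
  pattern sum, the naive expression can go negative (weights break Gibbs'
  inequality; random search finds counterexamples). Each loading row is
  therefore normalized to unit mass *under the pattern-weight measure*
  ($\sum_j W^j\,p_{ij} = 1$, floor $10^{-12}$), which turns the same
  expression into a proper KL divergence: non-negative, zero iff the
  aligned rows agree, and identical to plain row-normalization whenever the
  pattern weights are constant.
- **Alignment.** NMF pattern order is arbitrary, so the communication
  patterns are first permuted to minimize the total score (exhaustive for
  $k \le 8$, greedy beyond); without alignment the score would depend on
  factor labeling.

A stand-in microenvironment caller is included
(`simple_microenvironments()`: k-means on neighborhood cell-type
compositions); matrices from dedicated tools can be supplied as plain CSV.

## The synthetic generator

`simulate_spatial()` produces unit-grid slides with zero-inflated
negative-binomial expression (per-gene means uniform on 1.5–5, ligand
means from the upper half of that range, dispersion 0.5, 10% structural
zeros). The expression floor matters: a gene near silence is ~75% zeros
and carries no recoverable rank signal, so planting a coupling on it would
only measure the noise floor — and ligands selected for analysis are well
expressed by construction. Counts arise from per-gene latent gaussians
through a monotone quantile transform, so planted couplings control rank
association while marginals stay exact.

Two planting mechanisms, chosen by layout:

- **Isolated pairs** (`"pairs"`): dominoes of one A and one B cell, each
  cell with exactly one neighbor. The target-gene latent is re-drawn
  against the partner's source-gene latent at exactly the nominal
  correlation $r$. This is the calibration layout: pairs are mutually
  independent, which no contiguous tissue can offer (cells there belong to
  several pairs), and it is the only layout where a per-pair copula is
  realizable at full strength — coupling a cell to one of $t_a$ partners
  dilutes the signal to a $1/t_a$ fraction of pairs, which is undetectable
  at desk scale.
- **Communication fields** (contiguous layouts): both sides load on a
  spatially smooth latent field (gaussian-kernel-smoothed noise,
  standardized over the participating interface cells), source gene in
  source-type cells and target genes in target-type cells, with loading
  $\sqrt{r}$ — every adjacent pair then carries correlation close to $r$.
  With `local_coupling = TRUE` (the boundary preset's default) only cells
  adjacent to the opposite type load, confining the planted structure to
  the interface.

Presets: `"checkerboard"` (12×12, every lattice edge inter-type, one
coupling), `"boundary"` (4×150 strip, three targets across the interface),
`"pairs"` (200 dominoes), and `"blocks"` for the benchmark: a 30×18 grid in
three vertical zones holding type pairs T1+T2 / T2+T3 / T3+T4, randomly
mixed 50/50 within each zone, with one ligand per zone driving three
target genes in each direction. Details that earned their place through
failed designs: zone types are randomly interleaved (a parity layout
alternates neighborhood compositions cell-by-cell and defeats
composition-based microenvironment calling) and balanced (unbalanced
mixing starves one zone's interface of pairs); zones are large enough that
each interface holds ≥ 150 ordered pairs, i.e. window size ≥ 15; the
baseline holds 60 genes so the 18 coupled genes stay a small share of the
library size (normalization otherwise spreads their smooth spatial
component into every gene as cross-ligand background); and benchmark
controls are row shuffles drawn excluding the automorphisms of the planted
zone/type chain (identity and full reversal), which pattern alignment
would — correctly — score as equivalent to the unshuffled matrix.

What the generator does not emulate: platform-specific noise (bead
dropout profiles, spot mixing), realistic gene–gene covariance within a
cell, tissue morphology, or database-scale ligand–receptor catalogs.
Passing tests show calibration, recovery and benchmark behavior under the
planted model, not biological validity on real slides.

## Problem sizes and determinism

The shipped experiments use: 100 random scatters ($n \le 200$) against an
exhaustive window oracle; type-I calibration on 500 independent pairs ×
50×50 genes; recovery over 20 replicates of 200 pairs with $r = 0.9$
(detection of the planted pair at the $0.01N$ rule, precision of the
majority-aggregated selection); 20 blocks seeds for the KL benchmark; and
byte-identity of two pipeline runs under one seed. Every stochastic step —
generator, tie resolution, NMF initialization, k-means, Louvain — is
seed-controlled; internal randomization uses private RNG streams that are
restored afterwards, so library calls never perturb a user's RNG sequence.

## Known limitations

- The exact null of the window test holds under exchangeability of pairs;
  in contiguous tissue the same cell appears in several pairs, which leaves
  the marginal level intact but thickens the tail of per-gene-pair edge
  totals (bursts). Treat small-$N$ downstream selections accordingly.
- Achieved levels differ slightly across type combinations with very
  different pair counts (discreteness of the hypergeometric cut), so
  comparing raw strength between cells whose pairs come from differently
  sized combinations carries a small systematic offset; `combinations =
  "inter"` restricts the fit to cross-type communication when that is the
  question.
- The NMF consistency score on very small matrices (a handful of types and
  ligands) is noisy; use restarts (default), summarize over several
  factorization seeds (the shipped experiments take the median of three),
  and report replicate rates, not single scores.
- One-sided positive association only; inhibitory coupling surfaces as
  absence of edges, not negative ones.
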