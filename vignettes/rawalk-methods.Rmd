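---
title: "Random-walk graph classification: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-walk graph classification: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rawalk)
```

## The classification model

`rawalk` treats classification as label propagation on a complete weighted
graph. Every labeled training vector $x_i$ is a node; edge weights are RBF
similarities $w_{ij} = e^{-\gamma\|x_i-x_j\|^2}$ with
$\gamma = 1/(2\sigma^2)$, so the graph is complete with self-weight
$w_{ii}=1$. Row-normalizing by the degree matrix, $P = D^{-1}W$ with
$D = \mathrm{diag}(W\mathbf{1}_n)$, turns $W$ into the one-step transition
matrix of a random walk. Labeled nodes are deliberately *not* absorbing:
a walk arriving at a labeled node keeps moving, which lets label evidence
mix through the graph rather than freeze at first contact. The laziness
parameter $\alpha$ interpolates toward that frozen regime:
$Q = \alpha I + (1-\alpha)P$ stays put with probability $\alpha$, and a
$t$-step walk uses $Q^t$.

Class information enters through the one-hot state matrix $Y$ ($m$ classes
$\times$ $n$ samples). A new point $x$ with similarity column $k(X,x)$ gets
the score vector

$$F(x) \;=\; \tilde{Y}\, Q^t\, (K+\lambda I)^{+}\, k(X,x),$$

where $K$ is the same RBF matrix serving as kernel, $\lambda$ is a small
ridge making the pseudo-inversion well-posed, and $\tilde{Y}$ is the
split-weighted state matrix described next. Entry $f_j$ is the aggregate
arrival score of a $t$-step walk from $x$ on nodes labeled $j$; the argmax
over classes is the prediction.

**Complementary-split weighting.** Biological labels are noisy. Instead of
minimizing a loss over many random partitions (accurate but expensive), the
training set is split once into stratified halves $S$ and $T$ that predict
each other with the same rule restricted to their own subgraphs. The two
squared-Frobenius losses $\varepsilon_S, \varepsilon_T$ weight the halves:
$\alpha_S = \varepsilon_T/(\varepsilon_S+\varepsilon_T)$ (and symmetrically
$\alpha_T$), so the half that predicts the other better — presumably the
cleaner half — contributes more. Column $i$ of $Y$ is scaled by the weight
of the half containing sample $i$, preserving sample order. The total loss
$\varepsilon_S\varepsilon_T/(\varepsilon_S+\varepsilon_T)$ is logged as a
fit diagnostic; it never exceeds the smaller of the two losses. When both
losses are zero (degenerate, e.g. duplicated data) the weights default to
$(0.5, 0.5)$, which also makes the model coincide with an unweighted
$\tilde Y = 0.5\,Y$ whenever the losses tie. An optional `splits = R`
argument averages the weights over $R$ seeded splits for users who want the
expensive variant.

**Assumptions.** The method assumes (i) similar feature vectors imply the
same class at the $\gamma$-scale chosen — the usual smoothness assumption
of graph-based semi-supervised learning; (ii) the complete graph is
meaningful, i.e. all pairwise distances carry signal (no manifold sparsity
is exploited); (iii) subset losses computed with the final model's
hyperparameters reflect subset quality for that deployed configuration —
the weights are therefore computed with the same $(\gamma, \alpha, t,
\lambda)$ as the final fit.

## Tunable parameters

| parameter | meaning | default | rationale |
|---|---|---|---|
| `gamma` | RBF width $1/(2\sigma^2)$, inverse squared feature units | 1, or grid-searched | scale-dependent; the canonical grid is the 12 odd powers of two $2^{-11}..2^{11}$, searched by CV (`gamma_grid_search()`), ties to the smaller (smoother) value |
| `alpha` | walk laziness, probability of staying put | 0.75 | values above 0.5 keep labeled states nearly deterministic while still letting them mix; 0.75 is the package's general-purpose default, with 0.95 worth trying on cleaner data |
| `t` | walk steps | 5 | accuracy typically peaks at small $t$; large $t$ drives $Q^t$ toward its trivial stationary limit and blurs classes, so the sweep caps at 30 (`parameter_sweep()`) |
| `lambda_reg` | kernel ridge, same units as $K$ entries | $10^{-4}$ | large enough to stabilize near-singular kernels, small enough not to perturb well-conditioned ones |
| `lambda_seq` | PseAA correlation tiers (residue-pair lags) | 49 | deepest lag still admissible for all but the shortest proteins; proteins with $L \le \lambda$ are excluded and logged |
| `weight` | PseAA tier weight vs composition | 0.05 | keeps composition dominant while retaining sequence-order signal |
| `k` | CV folds | 10 | standard stratified protocol |

The laziness endpoints are accepted as degenerate cases: $\alpha = 1$
freezes the walk ($Q = I$, predictions independent of $t$), $\alpha = 0$
is the non-lazy walk.

## The protein descriptor

A protein of length $L$ contributes two blocks:

1. **PSSM means** — the $L \times 20$ PSI-BLAST profile collapsed to the 20
   per-amino-acid column means, a length-free evolutionary summary. Only
   the log-odds block of the ASCII file is used (the weighted-percentage
   block is redundant with it for this purpose), and columns are remapped
   from BLAST's native order to alphabetical.
2. **PseAA** — amino-acid frequencies $f_u$ plus $\lambda$ correlation
   factors $\theta_k = \frac{1}{L-k}\sum_i \Theta(R_i, R_{i+k})$, where
   $\Theta$ is the mean squared difference of standardized hydrophobicity,
   hydrophilicity and side-chain mass. The shipped property tables
   (`inst/extdata/aa_properties.tsv`) are the classical triple of the
   type-1 construction, standardized to mean 0 / unit population SD over
   the 20 amino acids; they can be swapped via `pseaa_params()`. The full
   vector is normalized to sum to 1:
   $p_u = f_u / (\sum f + w\sum\theta)$,
   $p_{20+k} = w\,\theta_k / (\sum f + w\sum\theta)$.

The combined descriptor has $40 + \lambda$ entries — 89 at the default
$\lambda = 49$. Because $\Theta$ uses squared differences it is symmetric,
so the correlation factors are invariant under sequence reversal; this is a
property of the construction, not a bug. No feature standardization is
applied before classification — the $\gamma$ grid search absorbs overall
scale — but a `--zscore` flag exists on the CLI for data whose blocks live
on very different scales.

Published localization benchmarks (the UCI yeast attribute table; the
Cell-PLoc gram-negative set with PSI-BLAST profiles) can be run through
exactly this pipeline as external inputs. Exact numeric reproduction of
historical feature sets is not guaranteed, since the property tables and
score block conventions of older pipelines are not fully specified.

## Numerical choices

* **Pseudo-inverse.** $(K+\lambda I)^{+}$ uses a symmetric
  eigendecomposition with the standard Moore–Penrose cutoff
  ($n \cdot \epsilon_{mach} \cdot \max|\lambda_i|$); with $\lambda > 0$
  this is in practice the exact inverse, and at $\lambda = 0$ it degrades
  gracefully to the pseudo-inverse of a singular kernel.
* **Lazy powers.** The recursion $P^t = (\alpha I + (1-\alpha)P)P^{t-1}$
  with identity base case is implemented as $Q^t$ with $Q$ fixed, computed
  by repeated squaring. An alternative reading (one lazy step, then plain
  powers) was considered and rejected: the recursion unrolls exactly to
  $Q^t$.
* **Ties.** Argmax ties in `predict_labels()` go to the lowest class index
  in the sorted class order; ROC thresholds group tied scores; the gamma
  grid search breaks accuracy ties toward the smaller gamma. All three
  choices exist purely for determinism.
* **Degenerate inputs.** Single-sample subsets in the cross-prediction
  loss use $W_S = [1]$ with no further special-casing; single-class
  training warns and predicts that class; classes with fewer members than
  folds are spread over some folds with a warning.
* **Metric conventions.** Per-class sensitivity, precision *and*
  specificity are all reported: prose and table conventions in the
  localization literature disagree on which of the latter two to show, and
  computing both costs nothing. A class never predicted has undefined
  precision, stored as `NA` and rendered `-`. The "±" attached to total
  accuracy is the standard deviation of per-fold accuracies, labeled as
  such — repeated-CV SD is a different (unimplemented) convention.
* **Seeds.** Every stochastic operation takes an explicit integer seed and
  restores the caller's RNG state; CV fits derive per-fold seeds as
  `seed + fold` so folds are independently reproducible.

## What the synthetic generators do and do not show

`gaussian_mixture_dataset()` places class $c$ at $\mathrm{sep}\cdot e_c$
with unit isotropic within-class SD, so `separation` is directly the
between-mean distance in within-class SD units; beyond $d$ classes it falls
back to random unit directions. `random_protein_records()` and
`write_synthetic_pssm()` produce uniform-random sequences and integer score
files in the PSI-BLAST ASCII dialect (column widths included), so the
parser is exercised against the real format.

The test and acceptance suites run this generator at modest sizes chosen
for statistical clarity: 150 samples, 8 dimensions, separation 6 for the
recovery property (a regime where any reasonable classifier should exceed
95% 10-fold accuracy, so failures indicate implementation defects, not
hard data); separation 0 as a chance-level control; corpora of ~20
synthetic proteins for the descriptor pipeline. Passing these shows the
machinery is correct and calibrated, **not** that the method will match any
particular accuracy on real proteomes: synthetic mixtures are isotropic,
noise-free in their labels, and class-balanced, while real localization
data are none of these, and synthetic PSSMs carry no evolutionary
conservation structure. Claims about real data require running the
external benchmarks through `featurize`/`cv`.

## Known limitations

* Dense $O(n^3)$ linear algebra (eigendecomposition of $K$): tables beyond
  a few thousand samples become slow; no sparse/k-NN graph variant is
  provided.
* One split by default: the loss-derived weighting is a deliberate shortcut
  compared to optimizing the partition; `splits` averages a few seeded
  splits but no optimization is attempted.
* The gamma grid search is not nested inside the outer CV, so grid-selected
  accuracies are mildly optimistic; for unbiased estimates, hold out a
  final test set.
* Scores are raw walk-arrival masses, not calibrated probabilities.
* Type-2 (amphiphilic) PseAA, alternative property sets, and absorbing-state
  propagation are out of scope.
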