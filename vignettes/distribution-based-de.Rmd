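---
title: "Distribution-based differential expression across subjects: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distribution-based differential expression across subjects: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kernelde)
```

## The problem

Multi-subject single-cell studies (scRNA-seq, flow or mass cytometry)
compare two groups of subjects — cases and controls — where each subject
contributes hundreds of cells per cell type. Most differential-expression
tools reduce each subject's cells to a single aggregate (a pseudo-bulk
mean, median or sum) and test that scalar. This detects mean shifts but is
blind to changes in mixture proportions, modality or variance, which are
common in single-cell measurements. Testing cells directly, on the other
hand, treats cells as independent replicates and inflates false positives,
because cells within a subject are correlated (pseudoreplication).

kernelde treats each subject's per-gene expression, within one cell
cluster, as a *probability distribution*, and asks whether the
distribution differs between groups while keeping the subject as the
experimental unit.

## The procedure

For each (gene, cluster) pair that passes a sparsity filter:

1. **Common support.** Pool the cluster's cells across all subjects and
   min-max scale the pooled values onto $[0,1]$ with a single affine map,
   so every subject's density lives on one shared support.
2. **Per-subject density.** Estimate each subject's density with a
   Gaussian KDE on a shared grid of $R = 1024$ evenly spaced points,
   bandwidth per subject from Silverman's rule
   $h = 0.9\,\min(\hat\sigma, \mathrm{IQR}/1.34)\,n^{-1/5}$, and rescale
   each density row to sum to one.
3. **Distances.** Compare subjects $i, i'$ by the square root of the
   Jensen–Shannon divergence between their densities,
   $d_{ii'} = \sqrt{D_{JS}(\hat f_i, \hat f_{i'})}$ (natural logarithm,
   so $D_{JS} \in [0, 2\ln 2]$). The square root is a true metric and is
   conditionally negative definite, so the constructions below are
   well posed.
4. **Statistic.** Gower-center the squared distances,
   $G = H(-D^{\circ 2}/2)H$, take the positive semi-definite matrix square
   root $G^{1/2}$ (eigenvalues clipped at $10^{-10}\lambda_{\max}$), and
   form the square-root pseudo-F
   $$F_{\mathrm{sqrt}} =
     \frac{\operatorname{tr}(H_{X^*} G^{1/2} H_{X^*})}
          {\operatorname{tr}[(I - H_{X^*})\, G^{1/2}\, (I - H_{X^*})]},$$
   where $H_{X^*}$ projects onto the span of $[y, X]$ (group label plus
   covariates). Replacing eigenvalues $\lambda_k$ by $\sqrt{\lambda_k}$
   flattens the spectrum: a single dominant eigen-direction no longer
   dwarfs the moderate directions that carry much of the signal when
   features are correlated, which is what makes this variant more
   powerful than the plain pseudo-F at small $n$.
5. **Inference.** Because subject counts are small, p-values come from a
   hierarchical permutation test: individual cells are reshuffled among
   subjects (each subject keeps its cell count; the subject-to-group map
   is untouched) and the *entire* chain (bandwidths, KDEs, distances,
   centering, statistic) is recomputed per permutation. The empirical
   p-value is $\tilde p = (\#\{F^{perm} \ge F^{obs}\} + 1)/(P + 1)$.
   Permutations are staged adaptively: 100 first, escalating to 500,
   2000 and 10 000 when $\tilde p$ falls at or below 0.1, 0.01 and 0.001
   respectively, so only promising pairs pay for high resolution.
6. **Multiplicity.** Benjamini–Hochberg by default across all
   gene-cluster rows; Benjamini–Yekutieli as an option for strongly
   dependent gene sets, and a per-cluster scope as an option.

Two score-test modes share the same containers: `score_pb` builds a
Gaussian kernel $K_{ij} = \exp(-d_{ij}^2/\rho)$ from Euclidean distances
between per-subject pseudo-bulk aggregates, `score_sc` from the sqrt-JSD
distances; both test the variance component of a semiparametric logistic
model via $Q = r^\top K r/\hat\sigma^2$ with null-model residuals $r$,
with a weighted-$\chi^2$ null. The bandwidth $\rho$ is the median of the
off-diagonal pairwise distances (the median heuristic). These modes are
asymptotic and suit larger subject counts; `psrF` is the default because
typical studies have 3–10 subjects per group.

### Covariates and continuous outcomes

Cell-level permutation is only defined for the unadjusted two-group
comparison. With subject-level covariates the group label is replaced by
null-model residuals: for binary outcomes, a parametric bootstrap
(draw $y^*$ from the fitted null logistic model, refit, re-residualize,
recompute); for continuous outcomes, Freedman–Lane residual permutation.
In both cases the distance matrix is fixed and only the design-side
projection changes, which makes these paths cheap. Where the residuals
enter, they replace $y$ in the augmented design $[y, X]$.

## Tunable parameters

| Parameter | Default | Role |
|---|---|---|
| `R` | 1024 | grid points on $[0,1]$; divergences are stable for large `R` (refinement from 1024 to 4096 moves JSD by $<10^{-3}$ on smooth densities) |
| `min_nonzero` | 20 | a pair is tested only if *every* subject has at least this many non-zero cells in the cluster |
| `plan` | 100/500/2000/10000 at 0.1/0.01/0.001 | adaptive permutation schedule (cumulative totals) |
| `eps_h` | $10^{-3}$ | fallback bandwidth when a subject's values are constant |
| `fdr_method` | BH | BY available for dependent gene sets |
| `alpha` | 0.1 | reporting threshold on adjusted p-values |
| `rho` | median heuristic | Gaussian-kernel bandwidth for the score modes |

## Numerical choices

- **Natural logarithm** throughout the divergence; bounds are stated as
  $2\ln 2$. The metric and embedding properties are base-invariant.
- **$0 \log 0 \equiv 0$** rather than density flooring; Gaussian KDE rows
  are strictly positive on the grid, so this only matters for synthetic
  point-mass inputs.
- The discretized divergence sums renormalized point masses and ignores
  the grid spacing $\Delta x$; this follows the grid-approximation form
  directly and differs from trapezoid integration by $O(\Delta x)$.
- **No boundary correction** for KDE mass outside $[0,1]$; row
  renormalization absorbs it.
- The compiled permutation engine truncates the Gaussian kernel at six
  bandwidths (omitted tail mass $\approx 2\times 10^{-9}$, absorbed by
  renormalization); a test asserts engine and pure-R routes agree to
  $10^{-7}$.
- The matrix square root is taken of the **centered Gram matrix itself,
  before projection**. Taking it after projecting ($\widetilde G = H_{X^*}
  G H_{X^*}$) would leave the residual trace identically near zero and
  the statistic undefined; both orders were considered and the
  pre-projection root is the one that yields a usable denominator.
- The weighted-$\chi^2$ tail is computed by numerically inverting the
  characteristic function (Imhof's integral) with adaptive quadrature,
  matching closed-form $\chi^2_1$ and $\chi^2_2$ tails to $10^{-4}$ and
  better; a Liu-type moment-matched approximation is the fallback.
  $\hat\sigma^2$ is the mean null binomial variance; since the eigenvalue
  weights are scaled identically, the p-value is invariant to this
  normalization.
- **Eigenvalue clipping** at $10^{-10}\lambda_{\max}$ (relative) removes
  the small negative eigenvalues that finite-precision centering of a
  conditionally negative definite distance produces; a substantially
  negative spectrum ($\lambda_{\min} < -10^{-6}\lambda_{\max}$) is an
  error, not noise.
- **Seeds.** One master seed generates a per-pair seed table over the
  sorted (cluster, gene) keys, so results are identical regardless of the
  order in which pairs are processed.

## What the simulator emulates — and what it does not

`simulate_patterns()` generates a cells-by-genes matrix for two groups of
subjects across clusters. Per gene and cluster, a base mean is drawn
uniformly on 1–8 (normalized-expression scale) and a lognormal shape on
0.3–0.6; each subject's mean is jittered by $\exp(N(0, 0.1))$, making
cells within a subject correlated — without that jitter, cell-level
permutation would be exactly valid and calibration checks would be
vacuous. Ten percent of genes per cluster carry one of five archetypes,
in equal shares by default:

- **DE** — case mean multiplied by 2 (a one-unit shift in $\log_2$, the
  conventional "moderate-to-strong" single-cell effect);
- **DP** — shared modes at $M$ and $2M$, high-mode proportion 0.3 versus
  0.7 (the standard mixture-proportion benchmark);
- **DM** — unimodal versus an equal mixture of $M$ and $2M$;
- **DB** — unimodal at $M$ versus an equal mixture of $0.5M$ and $1.5M$:
  group means agree *exactly* because components are parametrized by
  their means and placed symmetrically;
- **DV** — equal means, case variance four times the control variance
  (the lognormal shape is solved so the natural-scale variance ratio is
  exact).

These magnitudes are fixed defaults grounded in the simulation
conventions of the single-cell differential-distribution literature; they
are deliberately not exposed as per-run knobs in the benchmark scripts.
Negative-binomial counts, per-gene dropout (zero inflation) and
cell-type-specific multiplicative batch effects with the partially
confounded 2+1/1+2 two-batch layout are available. The generator does
*not* emulate library-size variation, gene–gene correlation,
normalization artifacts, or empirically estimated mean–dispersion
relationships from any reference dataset — so passing benchmarks here
demonstrates correct behavior under the generative assumptions, not
performance on any particular real dataset.

## Problem sizes used by the test suite

The packaged benchmarks use 500 genes, 3 clusters, two groups of 3
subjects and 50 or 100 cells per subject-cluster (1500 gene-cluster
pairs), ranking genes by the observed square-root pseudo-F; the null
calibration uses 500 pairs with a 4-versus-3 subject split and the full
adaptive permutation path. These sizes give stable AUC and calibration
estimates while keeping a full run in minutes on one core.

## Known limitations

- Cell-level permutation does not fully satisfy exchangeability when
  subjects carry random effects; empirically the null p-value
  distribution is close to uniform but with a slight excess of small
  p-values, consistent with the method's published behavior on real
  null splits. The bootstrap/Freedman–Lane paths avoid this at the cost
  of resampling only the design side.
- Two groups only; multi-group comparisons would need pairwise
  divergences or a kernel analysis-of-variance and are out of scope.
- The min-max scaling to the unit interval is a pragmatic choice for a
  common KDE support; it is sensitive to single extreme cells in
  principle (the shared support shrinks every other subject's density
  toward a few grid points). It is applied jointly across subjects so
  distributions stay comparable, and is the one step with no canonical
  reference recipe — alternatives (quantile or robust range scaling) can
  be swapped in upstream of `density_profile()`.
- Cluster labels and normalization are *inputs*: the package neither
  clusters cells nor normalizes expression.
- HDF5 single-cell containers are not read in this build; MatrixMarket
  and CSV are.
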