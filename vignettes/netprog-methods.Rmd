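---
title: "Network-based survival prediction with higher-order module features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-based survival prediction with higher-order module features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netprog)
```

## The problem

In cancer prognosis studies with microarray expression data, the goal is a
risk score built from thousands of gene expressions that predicts
right-censored survival. Genes act in coordinated groups, and a
well-established way to capture that coordination without annotation is the
weighted gene-coexpression network: genes are nodes, connection strength is a
power of the absolute expression correlation, and tightly interconnected
branches of the resulting dendrogram are *modules*. Each module is then
summarised by a handful of principal components, and a Cox
proportional-hazards model is fitted to those summaries rather than to
individual genes.

Classically only the first principal component of each module (the
"eigengene") enters the survival model. `netprog` implements and evaluates
the richer alternative: higher-order *representative features* — additional
principal components per module, plus quadratics and pairwise interactions of
components within and across modules — fitted with a thresholded
gradient-ascent regularization that can search these larger feature spaces on
samples of typical clinical size.

## The pipeline

### Preprocessing

Expression matrices (genes × samples) are imputed by gene-wise K nearest
neighbours (default `k = 10`, the common choice for microarray data; distance
is the mean squared difference over co-observed samples), screened to the
`d_keep = 2000` genes of largest raw variance, and rescaled gene-wise to zero
median and unit variance. The order matters and is fixed: impute, then
screen, then rescale — screening operates on raw variances, and imputation
precedes screening because complete rows are needed to rank variances.
Rescaling uses the unbiased (n−1) variance and defines the median of an even
sample count as the midpoint of the two central order statistics; it is
idempotent to numerical precision.

### Network and modules

For genes $k, j$ the similarity is $S(k,j) = |\mathrm{cor}(k,j)|$ and the
adjacency is the soft-thresholded power $a_{k,j} = S(k,j)^b$. The default
$b = 6$ is the value conventionally used for unsigned coexpression networks;
`pick_power()` alternatively selects the smallest power whose connectivity
distribution satisfies the scale-free topology criterion ($R^2 \ge 0.8$ of
$\log_{10}$ frequency against $\log_{10}$ mean connectivity over ten
equal-width bins, empty bins dropped), falling back to 6 when no candidate
qualifies.

Connectivity is $C_k = \sum_{u \ne k} a_{k,u}$ and the topological-overlap
dissimilarity is

$$d_{k,j} = 1 - \frac{l_{k,j} + a_{k,j}}{\min(C_k, C_j) + 1 - a_{k,j}},
\qquad l_{k,j} = \sum_{u \ne k,j} a_{k,u}\, a_{j,u}.$$

Self-terms are excluded from both sums by default; with them included the
overlap can exceed 1, breaking $d \in [0,1]$. A `literal_sums` switch
evaluates the sums over every index for users who want the unmodified
formulas.

Modules are branches of the average-linkage dendrogram of $d$, cut at a
single fixed height, with branches below `min_module_size` genes (default
25) left unassigned (label 0) and the rest labelled 1..M by decreasing size.
When no height is supplied, it is chosen deterministically by scanning the
midpoints between consecutive distinct merge heights and keeping the height
that yields the most valid branches (ties towards the larger height, making
membership maximal). A fixed fraction of the maximum merge height — a
tempting default — fails whenever connectivities are small, because
topological-overlap dissimilarities then concentrate in a very narrow band
just below 1 and any fixed fraction lands below every branch point; the scan
adapts to the scale of the dendrogram actually at hand while remaining a
reproducible static cut.

### Representative features

Within each module, principal components are computed from the
column-centred samples × genes submatrix. Loading vectors have unit norm and
score columns are the centred data times the loadings, so scores are
orthogonal with variance equal to the corresponding eigenvalue. (The
alternative convention — unit-norm *score* columns — differs only by a
per-column scale, which the fitting step removes anyway; the eigenvalue
scale is used because it is what makes simulated coefficient draws of
realistic magnitude produce realistic signal strength, and because it is the
convention of `prcomp`.) Component signs are fixed deterministically: each
score column is flipped, if necessary, to correlate non-negatively with the
module's mean expression profile, ties broken by forcing the
largest-magnitude loading positive.

Four nested feature sets are built from these components:

* **R1** — the first component of every module ($M$ features);
* **R2** — R1 plus all pairwise products $Z_{0,i} Z_{0,j}$, $i \le j$,
  including quadratics ($M(M+3)/2$ features);
* **R3** — per module, the leading components explaining $\xi\% = 80\%$ of
  that module's variance, concatenated ($P = \sum_m m^*$ features);
* **R4** — R3 plus all pairwise products of its $P$ components
  ($P(P+3)/2$ features).

$\xi$ defaults to 80 because expression noise makes higher targets explode
the component count. Product columns are not re-centred or re-scaled at
construction; standardization is the fitter's concern. New samples are
always projected with the *training* centring and loadings, so test features
never touch training outcomes.

### Regularized Cox estimation (TGDR)

The Cox log partial likelihood, with Breslow handling of ties (risk set
$r_i = \{k : Y_k \ge Y_i\}$ exactly as defined), is maximised by threshold
gradient directed regularization: starting from $\beta = 0$, each of $K$
iterations computes the gradient $g$, the threshold vector
$f_j = I(|g_j| \ge \tau \max_l |g_l|)$, and the update
$\beta_j \mathrel{+}= \Delta\nu\, g_j f_j$ with $\Delta\nu = 10^{-3}$.
$\tau = 0$ is plain gradient ascent (no selection); $\tau = 1$ moves only
the steepest coordinates. For feature sets with products (R2, R4) the
modified variant enforces strong heredity: products are thresholded as
usual, and a first-order feature passes if its own gradient passes *or* any
selected product has it as a parent — so a selected interaction always
carries both parents. The printed form of this rule indexes first-order
features inconsistently; the implementation follows the stated contract
(parents of selected second-order terms are automatically included), the
only reading under which the rule does what it is said to do.

Features are centred and scaled to unit norm internally before fitting —
thresholding compares gradient magnitudes across features, which is only
meaningful on a common scale (components arrive on eigenvalue scale and
products on yet another) — and coefficients are mapped back to the input
scale on output.

$(\tau, K)$ are tuned by V-fold cross-validation ($V = 5$, grid
$\tau = 1.0, 0.95, \ldots, 0.05, 0$, $K \le K_{\max} = 2500$), stratified on
the event indicator, maximising the Verweij–van Houwelingen cross-validated
partial likelihood $\sum_v [R(\beta^{(-v)}) - R_{(-v)}(\beta^{(-v)})]$ — the
natural criterion when folds are too small for a stable partial likelihood
of their own. The criterion is evaluated at every iterate of a single
gradient pass per (fold, $\tau$), so the full $(\tau, K)$ surface costs one
path per fold and no early-stopping heuristic is needed. Ties are resolved
towards larger $\tau$ then smaller $K$ (the sparser model).

### Evaluation and gene-level reporting

Prediction is evaluated by V-fold cross-validation: per fold, tuning and
estimation are redone on the reduced data and the held-out subjects receive
risk scores $\hat\beta^{(-v)\prime} Z$. Out-of-fold scores are summarised by
(i) the two-group logrank chi-square after a median split (scores equal to
the median go to the low-risk group — deterministic) and (ii) Harrell's
concordance over usable pairs (smaller observed time is an event; tied
scores count 1/2; tied times are unused). Because network, module and
feature construction are unsupervised, they are built once on the full data
by default and only tuning/estimation is repeated per fold;
`rebuild_features = TRUE` instead rebuilds everything inside each fold and
projects the held-out samples, for a strictly leakage-free protocol. Both
modes are exposed because the evaluation narrative underdetermines the
choice; the default matches re-running only "cross-validation and
regularized estimation" on reduced data.

Models sparse in representative features are dense in genes: every
component is a linear combination of its module's genes.
`gene_level_coefficients()` expands a fit into per-gene linear terms,
per-gene quadratics and per-gene-pair interactions (including the constants
induced by centring, so the gene-level score equals $\beta'Z$ exactly), and
ranks the top 20 terms by absolute coefficient — comparable across term
types because all genes were rescaled to equal variance.

## The simulator

Real module-structured data were emulated rather than resampled: each module
draws a few latent factors per sample (3 by default, strengths decaying
geometrically by 0.6), and each member gene loads on a random unit direction
through those factors — the dominant factor entered positively by every
gene, giving the module a coherent eigengene — with loading drawn uniformly
from [0.3, 0.9]; the rest of the gene's variance is independent Gaussian
noise, and background genes (20% by default) are pure noise. Rows are then
rescaled exactly like real data. This preserves the property the evaluation
depends on — a block correlation structure with meaningful module principal
components — in a controllable form. What it does *not* emulate: heavy
tails, batch effects, correlated background, overlapping modules, or
signal spread over many weak effects; passing tests therefore demonstrate
correctness of the machinery under a clean factor structure, not performance
on any particular real dataset.

Survival follows the Cox model with constant baseline hazard
$\lambda_0 = 0.5$: 10 representative features drawn uniformly from the
generating feature set carry coefficients i.i.d. Unif[−0.5, 0.5], event
times are exponential with rate $\lambda_0 e^{\beta'Z}$, and censoring times
are independent exponentials whose rate is calibrated by monotone
root-finding so that the analytic censoring probability
$E[\lambda_c / (\lambda_c + \lambda_0 e^{lp})]$, averaged over the simulated
subjects, hits the 40% target (tolerance $10^{-6}$; the exponential family
is the simplest independent-censoring family with a closed-form censoring
probability). A study replicate generates 200 subjects, splits them
100/100, builds the network and all four feature sets on the training half
only, simulates survival from the generating set, fits all four sets
(modified TGDR for R2/R4), and records the test-set logrank statistic and
concordance; `run_study()` aggregates means over replicates, resampling a
replicate (bounded retries) if, say, too few modules are detected to host
the requested number of true features. A tuned fit that is exactly null
produces constant scores; these are recorded as logrank 0 and concordance
0.5, which is what a constant score earns.

## Problem sizes and defaults used in the tests

The package's test suite and examples run the study at a deliberately small
scale chosen once: 100 genes in 10 modules of 8 (so an R1 truth of 10 first
components is always drawable), loadings Unif[0.5, 0.9] and two factors per
module so that blocks of 8 genes are reliably recoverable, threshold grid
$\{1, 0.8, 0.6, 0.4, 0.2, 0\}$, $K_{\max} = 300$ and 3 folds; replicated
studies use 20 replicates. The default configuration (500 genes, modules of
40, loadings Unif[0.3, 0.9], full grid, $K_{\max} = 2500$, $V = 5$, 500
replicates) is the reference setting for actual use; it behaves the same
way, only slower. With loadings as weak as 0.3, explaining 80% of a
module's variance requires many components, so R3/R4 grow large — a real
property of the construction (the price of the richest feature set), not an
artifact of the implementation.

## Numerical choices and edge cases

* Log-sum-exp guard: the partial likelihood and gradient subtract the
  maximum linear predictor before exponentiating.
* A zero gradient stops the TGDR path early; remaining trace entries repeat.
* Constant feature columns get scale 1 during standardization and a zero
  gradient, so they are never selected.
* `detect_modules` warns and assigns everything to label 0 when there are
  fewer genes than `min_module_size`; an all-ones dissimilarity yields no
  modules.
* Fold assignment is stratified on the event indicator and re-drawn (bounded
  retries) if a training split ends up without events.
* PCA rank is the count of singular values above `1e-10` times the largest.
* Tie-breaks are deterministic everywhere: variance screening keeps first
  occurrences, module labels order by size then smallest member index,
  tuning prefers larger $\tau$ then smaller $K$.

## Known limitations

* The dynamic branch-cut of the original module-detection literature is
  approximated by a static cut with adaptive height; deeply nested module
  structure may be merged or split relative to the adaptive original.
* Breslow tie handling only (matching the risk-set definition used
  throughout); Efron weights are not offered.
* The simulator's factor structure is Gaussian and module-disjoint; it makes
  no attempt to mimic any particular platform's noise.
* Cross-study prediction, signed networks, module merging by eigengene
  correlation, supervised components and third-order features are out of
  scope.
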