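---
title: "Methods: graph-theoretical analysis of white-matter connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph-theoretical analysis of white-matter connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(wmconnect)
```

## The analysis problem

Diffusion-MRI tractography yields, for each subject, a symmetric
$N \times N$ matrix of fractional anisotropy (FA) values connecting the
regions of an anatomical atlas (by default the 90 cortical and
subcortical AAL regions).  `wmconnect` treats this matrix as a weighted
undirected graph and asks three questions typical of clinical
connectomics in motor-neuron disease:

1. Do patients differ from controls in global and regional network
   topology (segregation, integration, small-worldness, nodal
   centralities)?
2. Which specific sets of connections are weaker in patients
   (network-based statistic)?
3. Can the single-subject connection matrix predict a clinically
   meaningful outcome — here, the baseline progression rate
   $(48 - \text{ALSFRS-R}) / \text{months since onset}$, dichotomised at
   0.68 points/month into fast versus slow progressors?

## Sparsity thresholding and AUC summarisation

Raw FA networks differ in density, which confounds all topological
comparisons.  Every matrix is therefore thresholded to a fixed sparsity
$S$ (fraction of the $N(N-1)/2$ possible edges retained), keeping exactly
the top-$K$ edges by weight with $K = \operatorname{round}(S\,N(N-1)/2)$
(round half up).  Ties at the $K$-th weight are broken lexicographically
by node pair, which makes the edge sets deterministic and *nested* across
$S$.  Metrics are computed across $S \in [0.10, 0.34]$ in steps of 0.01
and summarised per subject by the trapezoidal area under the curve (AUC),
removing the dependence on any single threshold (a rectangle rule is
available for parity with toolboxes that use it).

The valid range is selected by two standard criteria, applied over a
candidate grid: the mean degree of every thresholded network must exceed
$2\ln N$, and small-worldness $\sigma$ must exceed 1.1 in every subject.
We read the degree criterion with the natural logarithm, the convention
of the small-world thresholding literature: for $N = 90$,
$2\ln 90 \approx 8.997$, and since the mean degree at sparsity $S$ is
$2K/N$ ($\approx S \cdot 89$), the criterion is first met at $S = 0.11$
on a 0.01 grid.  No choice of logarithm base makes $S = 0.10$ pass
strictly; `select_sparsity_range()` therefore reports per-criterion
diagnostics so the user can see exactly where each criterion binds.

## Graph metrics and random-network normalisation

Global metrics: clustering coefficient $C_p$, characteristic path length
$L_p$, local and global efficiency, and their normalised versions
$\gamma = C_p / \langle C_p^{rand}\rangle$,
$\lambda = L_p / \langle L_p^{rand}\rangle$,
$\sigma = \gamma / \lambda$.  Nodal metrics: degree (strength for
weighted networks), betweenness, and nodal efficiency.

Conventions, chosen to match standard FA-weighted connectomics:

* **Distance** on a kept edge is $1/w$: a stronger FA connection is a
  shorter effective path.
* **Weighted clustering** is Onnela's geometric-mean variant with weights
  normalised by the network maximum (the common toolbox default; igraph's
  built-in weighted transitivity implements Barrat's variant instead,
  which is why the Onnela form is computed directly here).
* **$L_p$ on fragmented networks** is the mean over *finite* ordered
  pairs, with the number of infinite pairs reported; efficiencies use
  $1/\infty = 0$.  A sparsest-threshold network can fragment, and
  dropping it silently would bias the AUC.
* **Random references** are degree-preserving Maslov–Sneppen double-edge
  swaps (10 swap attempts per edge); in the weighted case the rewired
  topology receives the original weight multiset in random order.  The
  number of references is configurable (`n_rand`); 100 is a safe default
  for one-off analyses, while the simulation studies in the test suite
  use 3–20 references, which is sufficient because AUC averaging across
  25 grid points already suppresses reference noise.
* Both weighted (default) and binary analyses are supported; the
  normalised metrics are always computed on the same representation as
  the raw ones.

Dense Floyd–Warshall shortest paths and the neighbour-subgraph local
efficiency are implemented in C++ (`src/metrics.cpp`): at $N = 90$ a
dense $O(N^3)$ sweep is faster than graph-object based algorithms, and
the cohort-times-grid-times-references loop is the computational
bottleneck of the whole pipeline.

## Group inference

AUCs are compared between groups with a nonparametric permutation test:
the statistic is the pooled-variance two-sample $t$, the null is built by
relabelling group membership, and the two-tailed p-value uses the
add-one estimator $p = (1 + \#\{|t^*| \ge |t|\})/(n_{perm}+1)$, which is
valid for finite permutation counts and never returns zero.  The seven
global metrics are reported at raw p-values (no multiplicity
correction), mirroring common practice for this small, correlated
family.  With covariates (e.g. the eight head-motion summaries), values
are residualised on the covariates before permutation
(Freedman–Lane-style); the permuted statistic is the $t$ value because
$t$ values are what such analyses report.

Nodal centralities use the *two-of-three rule*: a region is reported
only when at least two of degree, betweenness and efficiency differ
significantly *in the same direction* — a conventional compromise
between power and type-I risk for 270 correlated nodal tests.  An
optional FDR flag corrects across nodes instead; it is off by default.

Clinical associations use partial Pearson correlations: both variables
are residualised on age, sex and illness duration (intercept included)
and the p-value comes from the $t$ distribution with $n - k - 2$ degrees
of freedom.  With no covariates this reduces exactly to the ordinary
Pearson test, which the test suite asserts.

One approximation is worth stating: permutation p-values are bit-exact
reproducible under a fixed seed, but reordering the input subjects
changes which random relabellings are drawn, so p-values agree across
orderings only up to Monte-Carlo error (the $t$ statistic itself is
order-invariant).

## Network-based statistic

Connection-level inference uses the NBS: per-edge two-sample $t$
statistics are thresholded at a primary threshold ($t = 2.62$ by
default), connected components of the surviving edges are extracted, and
each component's family-wise-error-corrected p-value is the permutation
probability that the *maximum* component size (in edges) reaches the
observed size.  Design choices where the method leaves room:

* Raw FA weights of the unthresholded matrices are tested (the NBS is
  about connection strength, not a particular sparsity level).
* The tested edge universe is restricted to edges present (nonzero) in
  at least 50% of all subjects, because $t$ statistics on nearly absent
  tracts are unstable; this is configurable (`edge_universe`,
  `min_presence`).
* Decreases and increases are analysed as two separate one-sided
  contrasts (the conventional NBS formulation); a `"both"` mode runs the
  two directions with a shared permutation scheme.

## Single-subject progression classifier

Patients' upper-triangle edge vectors (4005 features for 90 nodes) are
reduced by centred PCA to the smallest number of components explaining
80% of the variance and fed to a linear SVM.  Accuracy is estimated by
nested cross-validation: 10 stratified outer folds estimate
generalisation; 5 inner folds on each outer training set choose the SVM
cost from $C \in \{10^{-3}, \dots, 10^3\}$ by balanced accuracy (ties go
to the smaller, more regularised $C$).  The PCA is refitted inside every
training split — outer and inner — so neither the transform nor the model
ever sees test data; a construction test corrupts test-fold labels and
asserts the fitted predictions do not change.  Fold counts and the grid
are defaults of this package (the method family does not fix them) and
are configurable.

Significance comes from a label-shuffle null in which the *entire*
pipeline, including fold construction and inner $C$ tuning, is re-run
per shuffle — the conservative choice when it is unclear whether
re-tuning was part of the original procedure.  Reported accuracy is the
mean outer-fold balanced accuracy, $(\text{sens}+\text{spec})/2$, robust
to the mild class imbalance around the 0.68 cut-off.

For interpretation, a final model is refitted on all patients with the
modal cross-validated $C$; the 10 components with the largest absolute
SVM weights are mapped back to edge space, scoring each connection by
$\sum_{pc} |w_{pc}|\,|v_{pc,edge}|$ (absolute loadings — a signed sum is
available behind a flag) and reporting the top 50 connections with
region names.

## The synthetic cohort generator

No patient imaging accompanies this package, so `simulate_cohort()`
generates cohorts carrying exactly the statistical structure the
pipeline assumes, at the study's scale: 73 patients and 100 controls by
default, 90 nodes.

* **Backbone**: a 6-module random template (round-robin node
  assignment), edge probability 0.9 within and 0.26 between modules, FA
  weights from a normal truncated to (0, 1) with mean 0.45 and SD 0.1.
  Within-module edges draw from a mean raised by 0.12: without this
  weight separation, top-$K$ thresholding would sample edges uniformly
  across the modular structure and destroy the very clustering the
  backbone is meant to provide; with it, the thresholded template is
  reliably small-world ($\sigma > 1.1$ at $S = 0.2$, asserted in the
  tests).  The raw density (~0.37) stays above the top of the analysis
  grid so every $S \le 0.34$ is meaningful.
* **Subjects** add i.i.d. normal jitter (SD 0.05) to every backbone
  edge, truncated to (0, 1).
* **Patients** have all within-module weights scaled by $1 - 0.15$,
  which lowers $C_p$, $\gamma$ and $\sigma$ — the planted analogue of the
  segregation deficit the pipeline is designed to detect.
* **NBS target**: a connected 5-edge path inside one module is weakened
  by a further 0.06 in patients.
* **Progression signal**: 20 within-module edges are weakened by 0.075
  (Cohen's $d \approx 1.5$ against the subject noise) in fast
  progressors.  Labels are *not* sampled directly: a progression rate is
  drawn from a lognormal matched to published clinical moments
  (mean 0.71, SD 0.63 per month), scaled so the configured fast fraction
  sits above the 0.68 cut-off, converted to an ALSFRS-R total via the
  rate formula, rounded, and the stored ALSFRS-R and duration then
  *re-derive* the rate and class — so the clinical formula is exercised
  end to end, including rounding effects near the cut-off.
* **Metadata** matches published cohort moments: age
  $\mathcal N(49.8, 8^2)$ years, duration lognormal with mean 10.58 and
  SD 5.86 months, ALSFRS-R subscores split so bulbar + motor +
  respiratory equals the total (respiratory pinned near its ceiling of
  12, as observed clinically), Hamilton-style anxiety/depression scores,
  and eight head-motion covariates.

What the generator deliberately does **not** emulate: spatial embedding
and distance-dependent connection probability, hemispheric symmetry,
subject-level topology variation (all subjects share the backbone edge
set), site/scanner effects, and any genuine coupling between network
metrics and the clinical scores beyond the planted progression signal.
Passing tests therefore demonstrate that the estimators recover planted
effects of realistic size under realistic noise — not that real FA
networks have these properties.

## Numerical and degenerate-input choices

* Matrix validation: symmetry within $10^{-9}$ (then symmetrised by
  averaging to absorb export noise), exact zero diagonal, nonnegative
  finite entries; violations are errors naming the subject.
* Zero-variance edges or metrics give $t = 0$ / $p = 1$ with a
  degenerate-data warning rather than NaN.
* $K = 0$ or $K = $ all edges at an interior $S$ warns (degenerate
  threshold) but proceeds.
* PCA eigenvalues below $10^{-12}$ of the largest are treated as null
  space.
* All stochastic stages take explicit integer seeds; identical seeds
  give bit-identical results end to end (`run_full_analysis()` writes a
  manifest with the seed and a configuration hash).

## Problem sizes used by the test suite

The acceptance-style tests run the oracle suite on 200 random graphs of
up to 7 nodes; threshold exactness on fuzzed 90-node matrices over the
full 0.10–0.34 grid; permutation calibration on 500 null and 200
powered replicates (1000 permutations each); NBS recovery on 50
full-size cohorts and FWER on 200 null cohorts (1000 permutations,
scaled down from the 10,000 a one-off analysis would use); the
group-effect recovery on twenty 16 + 16 cohorts over a 0.03-step grid
with 5 random references; and the classifier on one full-size cohort
with a 200-shuffle null.  These sizes were chosen so the whole suite
completes in well under half an hour while leaving each check enough
replicates to be sharp.

## Known limitations

* The two-of-three nodal rule is a reporting heuristic, not an error
  rate guarantee; the optional FDR mode is the principled alternative.
* Maslov–Sneppen rewiring preserves the binary degree sequence but not
  the weighted strength sequence; $\gamma$, $\lambda$ and $\sigma$ for
  weighted networks should be read with that convention in mind.
* The permutation and simulation machinery assumes exchangeable subjects
  under the null; covariate adjustment is linear.
* `select_sparsity_range()` with the $\sigma$ criterion is expensive
  (subjects × grid × references); use a modest `n_rand` there and the
  default grid once the range is established.
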