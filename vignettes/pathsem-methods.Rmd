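---
title: "Modeling differential expression variance and pathway wiring with pathsem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling differential expression variance and pathway wiring with pathsem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathsem)
```

# The problem

Most case/control expression studies compare group *means*. This package
implements the complementary analysis: whether the *variance* of gene
expression differs between two groups of samples (e.g., patients with a
neurodevelopmental disorder versus controls), whether that variance signal
concentrates in particular signaling pathways, how much of the disease
status is explained by the covariance structure of the implicated genes,
and — the core of the package — *which specific gene–gene relationships
within a pathway change strength between the groups*, inferred by
multigroup structural equation modeling (SEM) over the pathway graph.

The workflow has four stages, each usable on its own:

1. **Variance statistics** (`groupVariances`, `signTest`, `residualize`,
   `leveneOneSided`): per-gene group variances, an exact sign test of the
   genome-wide asymmetry, and residual-based one-sided Levene tests.
2. **Pathway enrichment** (`easeOra`, `nodeOra`, `gseaPreranked`,
   `nodeGsaFisher`, `bhFdr`): four enrichment procedures over the
   variance results, FDR-adjusted per method.
3. **Classification** (`pcaSelect`, `logisticStatusFit`, `cIndex`):
   principal components of the implicated genes' residuals as predictors
   of group status, summarized by the concordance index.
4. **SEM model search** (`enumerateAlternatives`, `fitMultigroup`,
   `searchBestModel`, `waldDifferenceTest`): expand every multi-gene
   ("complex") pathway node into all alternative single-gene models, fit
   each by multigroup covariance-structure ML, screen and select, and
   test each path coefficient for a between-group difference.

# The structural model

A pathway is a directed graph whose nodes carry one or more member genes
(a paralog family or protein complex). After substituting one gene per
node (a *resolved* network), the model for the variable vector is the
linear structural system

$$ \begin{pmatrix} y \\ \eta \end{pmatrix}
   = B \begin{pmatrix} y \\ \eta \end{pmatrix}
   + \Gamma \begin{pmatrix} x \\ \xi \end{pmatrix} + \zeta, \qquad
   z = \Lambda \begin{pmatrix} \eta \\ \xi \end{pmatrix} + \delta, $$

with observed endogenous $y$ and exogenous $x$ variables, latent
variables $\eta$ (no latent exogenous $\xi$ are used here), path
coefficients $B$ and $\Gamma$, loadings $\Lambda$, and mutually
uncorrelated Gaussian errors $\zeta$, $\delta$. Exogenous variables have
free variances with pairwise covariances fixed to zero; latent variables
are scaled by fixing their structural error variance to 1 (reference
scaling, mean 0) with free loadings, and a single-indicator measurement
error is fixed to 0. Provided $(I - B)$ is nonsingular the model implies
a covariance matrix $\Sigma(\theta)$ over the observed variables, and
estimation minimizes the ML discrepancy

$$ F_{ML}(\theta) = \ln|\Sigma(\theta)| + \mathrm{tr}\,(S\,\Sigma(\theta)^{-1})
   - \ln|S| - p $$

against the sample covariance $S$ of the $p$ observed variables.

**Internal formulation.** Rather than carrying the four LISREL blocks,
`SemModel` assembles one all-variable path matrix $A$ (paths and loadings
over observed and latent variables) and a diagonal residual covariance
$\Psi$, with a selection matrix $J$ to the observed rows:
$\Sigma = J (I-A)^{-1} \Psi (I-A)^{-T} J^T$ (the RAM form). It is
algebraically identical to the block form and keeps the code — and the
analytic gradient — uniform. The public grammar (`semModel`,
`semFromNetwork`, parameter labels `dst~src`, `lat=~ind`, `v~~v`) still
speaks in paths, loadings, and variances.

# Multigroup estimation and the covariate equations

To compare path coefficients between groups, the model is fitted to the
groups simultaneously. Each observed variable additionally gets a linear
covariate equation (age, sex, two expression PCs, and batch by default)
whose slopes are **constrained equal across groups**; all structural
parameters are group-specific.

Because no structural parameter is shared, the joint objective
$\sum_g (n_g - 1) F_g$ separates: `fitMultigroup` first residualizes the
mean structure by pooled least squares with shared covariate slopes and
group-specific intercepts (intercept equality is deliberately *not*
imposed — the covariance structure, not the group means, is the object
of inference), then fits the covariance structure to each group's
residual covariance. This is a two-stage ML estimator; the between-group
Wald calibration test in the test suite confirms that the resulting
p-values are uniform under the null at the sample sizes this package
targets.

`constraints = "all"` (all structural parameters equal across groups) is
supported through an exact reduction: with full equality the joint
objective is minimized by a single fit to the $(n_g-1)$-weighted mean of
the group covariance matrices. With identical data in each group this
reproduces the single-group fit exactly (tested); with equal group means
it matches the pooled fit on concatenated data up to the usual
$(N-1)/(N-2)$ rescaling of variance estimates, because between-group mean
structure is removed per group.

**Between-group tests.** For each free path,
$z = (\hat\theta_1 - \hat\theta_2)/\sqrt{SE_1^2 + SE_2^2}$ with a
two-sided normal p-value (`waldDifferenceTest`), annotated
`ns`/`*`/`**`/`***` at 0.05/0.01/0.001 (strict inequalities).

# Numerical choices

* **Optimizer**: BFGS on the unconstrained parameters with variances
  log-transformed. Starting values: paths 0.1, loadings 1, free
  variances half the observed variance. The optimizer runs with a
  relative function tolerance of 1e-12 and restarts once if the gradient
  norm exceeds 1e-6; a fit is declared converged when the final gradient
  norm is below 1e-4 on the $F_{ML}$ scale. These are this package's own
  defaults, chosen to match common SEM-software behavior; parameter
  recovery and confidence-interval coverage at these settings are
  verified by simulation in the test suite.
* **Standard errors**: inverse observed information of the
  $(n-1)F_{ML}/2$-scaled objective, with the information matrix obtained
  by central differences (relative step 1e-5) of the analytic gradient.
* **Analytic gradient**: for $E = (I-A)^{-1}$, $T = E \Psi E^T$ and
  $W = \Sigma^{-1} - \Sigma^{-1} S \Sigma^{-1}$ embedded at the observed
  coordinates, $\partial F/\partial A = 2\,E^T W T$ and
  $\partial F/\partial \Psi_{ii} = (E^T W E)_{ii}$. Agreement with finite
  differences is itself a test.
* **Empirical identifiability** (`checkIdentifiability`): a fit fails
  when the optimizer did not converge, the information matrix is not
  positive definite (smallest eigenvalue below 1e-8 of the largest), a
  standard error explodes (over 20 times the estimate and over 10
  absolute), or the implied covariance is not positive definite. Failed
  alternatives never abort a search; they are logged with the triggering
  criterion.
* **Fit indices**: $\chi^2 = \sum_g (n_g-1) F_g(\hat\theta)$; degrees of
  freedom count covariance moments only (the mean structure is
  saturated). RMSEA uses the multigroup convention
  $\sqrt{G}\,\sqrt{\max(\chi^2-df,0)/(df\,(N-G))}$ and is reported as 0
  with a warning when $df = 0$. CFI is computed against the independence
  baseline (free variances only, same mean structure), clamped to
  $[0,1]$; this baseline is nested in every target model so CFI stays
  interpretable under covariate adjustment. These conventions match the
  dominant ones in widely used SEM software and are stated here so
  results can be reconciled with alternatives. Per-group
  $AIC_g = -2\ln L_g + 2k_g$ and $BIC_g = -2\ln L_g + k_g \ln n_g$ use
  the group's Gaussian log-likelihood at the joint solution, with $k_g$
  the group's free structural parameters plus an equal share of the
  shared covariate slopes.

# The model search

`searchBestModel` enumerates the Cartesian product of member genes over
all nodes (`enumerateAlternatives`, capped at 10,000 by default, in a
fixed lexicographic order so model indices are stable across runs), fits
each alternative by multigroup SEM, and screens:

1. discard empirically non-identifiable fits;
2. discard fits with more than 3 non-significant control-group paths
   (two-sided Wald $p \ge 0.05$ on the control estimate — 0.05 is this
   package's default where only the count rule is standard);
3. discard fits with RMSEA $\ge$ 0.2.

Among survivors the model with the highest CFI wins; CFI ties within
1e-6 break to lower RMSEA, then enumeration order (a deterministic
tie-break the procedure itself does not prescribe). Networks are limited
to 14 nodes: beyond that the covariance structures in this design are
not reliably identifiable at realistic sample sizes. Runtime grows
linearly in the number of alternatives. Per-group AIC/BIC at the
selected solution indicate which group the pathway structure explains
better (`groupInformationComparison`).

# Enrichment decisions

* **EASE ORA**: hypergeometric upper tail after removing one hit from
  the overlap cell (floored at zero) — the conservative DAVID-style
  variant, so single-hit sets are never significant.
* **Node ORA**: the score is the number of nodes containing at least one
  flagged gene; the null permutes the flags over the analysis universe
  without replacement (default $10^6$ trials, Rcpp inner loop driven by
  R's RNG so a seed fixes the result bit-exactly). The p-value uses
  add-one smoothing, $(1 + \#\{score_{null} \ge score_{obs}\})/(1 + n_{trials})$,
  a deliberate choice so that a reported p is never exactly zero.
* **Preranked GSEA**: the classic weighted Kolmogorov–Smirnov running
  sum (weight exponent 1) with a gene-label permutation null, signed by
  the observed score; genes are ranked by ascending Levene p-value. The
  multilevel approximation found in optimized implementations is a speed
  device, not part of the statistic, and is out of scope; the installed
  `fgsea` implementation serves as a cross-check oracle in the tests.
* **Node-based GSA by Fisher's method**: gene p-values are combined
  within each node ($-2\sum\ln p \sim \chi^2_{2m}$), then node p-values
  across the pathway. The pooled single-stage alternative is available
  via `twoStage = FALSE`; the two-stage form is the default because the
  procedure is node-based by construction. Zero p-values are clamped to
  the smallest positive double with a warning.
* **Universe**: all analyzed genes in the supplied matrix (the
  post-filter expression universe), logged with the run; restricting to
  a database-annotated subset is a caller decision.
* Pathways with FDR-adjusted $p < 0.01$ in *any* method are merged into
  one selected set for the downstream stages.

# Variance-stage decisions

Residualization is per-gene ordinary least squares of the supplied
(already normalized) expression on the covariates over the pooled
samples. This replaces a normalization-model residual step from
dedicated count-model tooling: the package consumes a normalized matrix,
so a self-contained linear residualization keeps the stage testable; it
is a documented divergence, not an approximation of count-model
internals. The one-sided Levene test mean-centers by default (the
classic form; Brown–Forsythe median-centering via `center = "median"`)
and uses the two-group pooled-t form of the statistic — identical to the
ANOVA F for two groups — so the one-sided alternative "case deviations
larger" is well defined, and swapping the group labels maps $p \mapsto
1-p$ exactly. Exact variance ties are excluded from the sign-test count
and reported.

# The classifier

PCA is computed on centered, unscaled residuals (residual scales are
already comparable after covariate adjustment; `scale.` is available);
components individually explaining at least 1% of variance enter a
logistic regression as predictors of status — the only consistent
reading of the design — and goodness of fit is the concordance index
(midrank ties count one half, making it exactly the Mann–Whitney
statistic over case–control pairs). The pseudo-$R^2$ is Nagelkerke by
default, with McFadden behind a flag, since reports in this literature
rarely name the variant.

# The synthetic-data generator

`simulatePathwayExpression` draws from the same structural model the
fitting stage assumes: per-group path coefficients, shared covariate
effects (age uniform on 18–65, sex Bernoulli(1/2), batch categorical
with three levels, two standard-normal "expression PCs"), and Gaussian
structural errors; latent nodes are generated with residual variance 1
and mean 0, mirroring the reference scaling used in fitting.
`simulateBackgroundGenes` adds independent Gaussian genes of which a
configurable fraction has variance multiplied by a factor $\ge 1$ in the
target group. One master seed drives deterministically derived child
seeds per stage, so every dataset is bit-reproducible.

Everything downstream consumes normalized, residualized values, so the
generator works on that scale directly and emits Gaussian data only; a
count layer is intentionally not simulated. Consequently, passing tests
demonstrate correctness of the statistics under the model's own
assumptions (Gaussianity, linear covariate effects, independence of
background genes) — they do not certify behavior under count noise,
normalization artifacts, outliers, or correlated background structure
found in real RNA-seq data.

The bundled demonstration dataset (`demoDataset`) emulates the study
design this workflow targets: 144 case and 111 control samples, one
pathway (serine biosynthesis) whose case-group coefficients are stronger
and whose PSPH→SHMT2 path flips sign, one null pathway whose genes are
pure background, and 400 anonymous background genes with 30% of genes at
doubled variance in the case group — chosen so that roughly two thirds
of genes show larger case variance, the regime the variance statistics
are designed for.

# Problem sizes in the test suite

The simulation-backed tests run at the sizes the properties are stated
for: confidence-interval coverage over 500 single-group fits at
$n = 1000$; Wald-test calibration over 200 null replicates and power
over 100 replicates at $n = 500$ per group; model-selection consistency
over 50 replicates of an 8-alternative network at $n = 1000$ per group;
Levene type-I error over 10,000 null genes at $n = 100$ per group;
permutation-oracle agreement at $10^6$ trials on a 10-gene universe.
Monte-Carlo assertions use 3-standard-error bounds computed from the
quantity being estimated, fixed before the assertions were locked.

# Bundled pathway fixtures

Five reduced signaling-pathway networks ship with the package (serine
biosynthesis, PI3K–Akt, MAPK, neurotrophin, focal adhesion), with
complex nodes defined by paralog family or protein complex; the
partition is forced by the published node and gene counts (for MAPK this
requires RAP1A and RAP1B as separate single-gene nodes). The edge
topologies are reconstructed from the canonical KEGG diagrams and are
marked "reconstructed" in the files — the engine accepts any
user-supplied topology. The neurotrophin gene list keeps the symbols
MAP8/MAP9/MAP10 exactly as published (the probable intent is the JNK
family MAPK8/9/10); symbols are treated as opaque case-sensitive
strings throughout.

# Known limitations

* Covariance-based ML assumes multivariate normality; heavy-tailed
  expression will distort both the Levene stage (mean-centering is
  outlier-sensitive; use median centering) and SEM standard errors.
* The two-stage treatment of covariate equations ignores the sampling
  error of the shared slopes in the structural standard errors; at the
  sample sizes targeted here the effect is negligible (verified by the
  calibration tests), but it is not exact finite-sample ML.
* Equality constraints other than "none"/"all" (e.g., constraining a
  subset of paths) are not implemented.
* The search's non-significance filter uses the control group only, so
  pathways where the control wiring is genuinely weak may yield "no
  admissible model"; that outcome is reported with per-alternative
  reasons rather than forced.
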