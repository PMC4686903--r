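---
title: "Models and design choices in METimpute"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in METimpute}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(METimpute)
```

# The data and the problem

A multi-environment trial (MET) grows the same $I$ genotypes in $J$
environments (site--year combinations) and scores $K$ attributes (yield,
moisture, test weight, ...), giving a three-way three-mode array
$x_{ijk}$. Three-mode clustering and ordination methods need a complete
array, but real MET data routinely miss either individual cells or whole
environment--attribute *columns* $x_{jk}$ (an attribute not measured at one
site). METimpute estimates those missing values by multiple imputation (MI),
evaluates the estimates against known deleted values, and ships a simulator
for generating fixture arrays. Missing *rows* (a genotype never measured for
an attribute anywhere) are outside scope: the pattern generator refuses to
produce them and the estimators assume at least one observed environment per
genotype--attribute pair.

All modelling happens on the column-standardized scale
$$\tilde x_{ijk} = \frac{x_{ijk} - \bar x_{\cdot jk}}{s_{jk}},\qquad
  s_{jk}^2 = \frac{\sum_i (x_{ijk} - \bar x_{\cdot jk})^2}{I - 1},$$
which removes environment main effects ($\sum_i \tilde x_{ijk} = 0$) while
preserving within-environment attribute correlations. Statistics are taken
over observed entries only, so already-incomplete input is standardizable;
the evaluation protocols standardize the complete array first and delete
afterwards, which matches how the published experiments were run. A column
with a single observed value or zero variance is a hard error rather than a
silent guess. For a wholly missing column the location/scale are undefined;
such columns can be imputed on the standardized scale but not mapped back to
raw units.

# The four imputation families

**MAHC** (multiple agglomerative hierarchical clustering). Environments are
clustered on the $J \times IK'$ wide matrix with Ward's incremental
sum-of-squares linkage over squared Euclidean distances; a missing
$(i, j, k)$ is estimated by walking up from leaf $j$ and averaging the
observed $(i, \cdot, k)$ values in the first sibling group that has any.
Each of the $H$ imputations pairs the all-attribute tree with a tree built
on a random subset of $K_h \sim U\{1, \ldots, K-1\}$ attributes (the subset
tree only serves targets whose attribute was drawn; two estimates are
averaged). Design choices the source procedure leaves open, fixed here:
donor aggregation over a merged group is the unweighted mean of observed
values; Ward ties break to the lowest cluster-index pair; distances over
partially observed vectors are rescaled by (total coordinates / jointly
observed coordinates); when a drawn subset leaves an environment with no
observed coordinates (e.g. exactly the attribute of a wholly missing
column), that imputation falls back to the all-attribute tree alone; with
$K = 1$ only the all-attribute tree is used.

**NORM** (normal distribution model). Each genotype--attribute vector across
environments is $N(\mu_{ik}, \sigma^2_{ik} I)$; after standardization a
common scalar mean is appropriate. Non-Bayesian fits use the MLEs (mean, and
mean squared deviation with divisor $n$, not $n-1$); Bayesian fits use the
conjugate Gibbs chain under Jeffreys' prior ($\sigma^2 \mid \mu \sim
IG(n/2, nV_\mu/2)$, $\mu \mid \sigma^2 \sim N(\bar x, \sigma^2/n)$),
initialized at the MLEs, 5500 draws with the first 500 discarded, estimates
being post-burn-in means. Imputations are $\hat\mu + z\hat\sigma$. Under
missingness, $n$ is the observed count; a vector left with a single observed
value (possible at 25% missingness on $J = 8$) falls back to that value as
the mean with unit standardized-scale variance, so a protocol run never
aborts on one degenerate vector. NORM treats cells and wholly missing
columns identically.

**NRM** (normal regression model). Each standardized column $\tilde x_{jk}$
is regressed on a design built from the rest of the $I \times JK$ wide
matrix, with missing predictor entries substituted by exact zeros (so they
do not contribute; "true" standardized zeros are equally inert). Four
designs: (1) all other $JK - 1$ columns; (2) the $K(J-1)$ columns outside
the target environment; (3) design 2 plus the target environment's other
attributes scaled by their within-environment correlation with the target
($KJ - 1$ columns, the default for cell imputation); (4) only the target
environment's other $K - 1$ attributes. MLE fits use least squares with
residual divisor (observed count $- 2$) exactly as specified by the source
model, via pseudoinverse when rank-deficient; Bayesian fits use conjugate
Gibbs with $\beta \sim N(0, \tau^2 I)$, $\sigma^2 \sim IG(\nu_0/2, S_0/2)$,
$\nu_0 = 4$, $S_0 = 2$ (prior mean $\sigma^2 = 1$, the standardized-column
variance) and $\tau^2 = 1$, a value the source never states; unit scale
matches the standardized data and keeps the conditional proper for
rank-deficient designs. Cells are imputed as prediction $+\,z\hat\sigma$.

Wholly missing columns go through the within-environment attribute
correlation matrix $R$ ($J \times K(K-1)/2$, pairwise-complete Pearson,
entries with under 3 joint observations marked missing). The
*average-correlation* rule predicts the column as $\sum_k \bar r_{kk'}
\tilde x_{j'k}/(K-1)$ with $\bar r$ averaged over the other environments
(skipping missing entries and dividing by the count actually summed); the
*linear-correlation* rule instead predicts the missing entries of row $j'$
of $R$ by through-origin regression on each complete donor row, averaging
predictions over donors. The regression layout of the latter is genuinely
ambiguous in the source (a coefficient indexed by two environments
multiplying a response vector); the per-donor scalar slope with donor
averaging is this package's documented resolution, and the average rule is
the default (it also performed better in the published comparison). The
noise scale $\bar\sigma$ averages MLE-fitted residual SDs of the option-4
regressions over all columns with data, cached once per dataset -- the
source does not say which model's $\sigma$ feeds $\bar\sigma$.

**PMM** (predictive mean matching). Per imputation and column, a bootstrap
sample (with replacement, size = observed count; rows resampled jointly with
their design rows, the only internally consistent reading) refits the NRM;
predictions of bootstrap-observed and missing entries are compared by
$d^2 = (\hat x^{obs} - \hat x^{m})^2/\hat\sigma^2$ and one of the $C = 3$
closest donors (ties to the lower index) donates its *actual* observed
value, so every imputed value is an element of the data. For wholly missing
columns the column prediction (average-correlation rule, no noise) is
matched against predictions of donor attributes within the same environment,
built from a randomly drawn attribute subset over the other environments.
PMM defaults to design 4 for its regressions: it refits on every bootstrap
draw of every imputation, the compact within-environment design keeps that
affordable at protocol scale, and it uses exactly the information the
missing-column scheme relies on (the design remains user-settable).

**Estimation once, draws $H$ times.** For NORM and NRM the parameter
estimates (MLEs or Gibbs posterior means) are deterministic given the
incomplete dataset, so they are computed once per column/vector and only the
imputation draw is repeated $H$ times; for the MLE a refit would be
identical, and for Gibbs the posterior means differ only by Monte-Carlo
error. PMM's bootstrap refit is per-imputation by construction.

# The EM/Tucker3 baseline

The single-imputation comparator fills missing entries with the
reconstruction of a Tucker3 model (core dimensions $(P, Q, R)$, default
$(2,2,2)$; the source reports none): initialize missing values at 0 (the
standardized-scale mean), then alternate one HOOI-style least-squares pass
(factors from leading singular vectors of the mode unfoldings projected on
the other factors, core by projection) with refilling the missing entries,
until the largest refill change drops below `tol` ($10^{-6}$) or `maxIter`
(500) sweeps. Observed entries are never altered and the observed-entry
squared error is non-increasing across sweeps, which the tests assert.

# Evaluation protocol

With the truth known (values deleted from a complete array), each method
produces 100 raw imputations per missing value, randomly allocated into
$H = 5$ sets of 20 and averaged, giving 5 pooled imputations. Rubin's rules
combine them: $\bar U = H^{-1}\sum_h U_h$ with $U_h$ the variance of the
imputed missing-value estimates *across missing values* within imputation
$h$ (the protocol's stated convention -- note this is not the classical
per-value sampling variance); per-value $B$, $T = \bar U + (1 + 1/H)B$, and
$\nu_H = (H-1)[1 + \bar U/((1+H^{-1})B)]^2$. The 95% interval is
$\bar Q \pm t_{\nu_H,0.975}\sqrt{T}$ (the variance-scaled pivot printed in
the source cannot have a $t$ distribution; the standard square-root form is
used), with a normal-quantile fallback on $\bar U$ when $B = 0$. Coverage CI
is the percentage of deleted values inside their interval. NRMSE
re-standardizes the completed array column-wise and takes
$\sqrt{\mathrm{mean}[(\tilde x - \hat{\tilde x})^2]/\mathrm{Var}(\tilde x)}$
over all entries (the square root follows the cited NRMSE standard; the
typeset ratio omits it).

Three scopes mirror the published experiments: *cells* (patterns of 5--25%
of all values including one designated wholly missing column, coverage over
the cells only), *column* (each environment deleted in turn per attribute
when $J \le 10$, else 10 random environments), and *all* (final arrays
scored by NRMSE, including the EM baseline). Within a repetition the
patterns are nested across percentages (the largest pattern is drawn once
and sub-sampled, sharing the designated column) and shared across methods:
common random numbers make the percentage trend and the method comparison
far less noisy without changing any marginal distribution. Repetition and
imputation seeds derive from one master seed, so partial reruns match full
runs.

# The simulator

`simulateMET()` draws $x_{ijk} = g_{ik} + e_{jk} + (ge)_{ijk} +
\epsilon_{ijk}$ with per-attribute variance components
$(\sigma^2_G, \sigma^2_E, \sigma^2_{GE}, \sigma^2_\epsilon)$ and cross-
attribute covariance confined to the genotype effects (correlation matrix
$C$), all other effects independent. The fixture presets use a unit total
variance split $(0.3, 0.2, 0.2, 0.3)$ and $C$ exchangeable with off-diagonal
0.5 -- fixture defaults chosen once as a realistic heritability/interaction
balance for grain trials, not values estimated from any real dataset.
Presets `dataset3`..`dataset6` mirror the published simulated-trial sizes;
`dataset1_synthetic` (58x8x6) and `dataset2_synthetic` (50x31x4) are
stand-ins at the real trials' dimensions containing no real data.

What the simulator does *not* emulate matters for interpreting the protocol
results. Its environments are exchangeable: environment effects are iid and
carry no cross-attribute or cluster structure, whereas real site--years form
groups of similar environments with heterogeneous attribute correlations.
Two consequences, both observed in this package's own protocol runs on the
stand-ins: coverage is nearly flat in the missing percentage (estimation
error barely grows when every donor environment is statistically
interchangeable), and the clustering-based MAHC loses the advantage it
shows on real data, where finding the right environment group is the hard
part. Passing protocol tests on simulated arrays therefore validate the
machinery -- formulas, pooling, reproducibility -- not the field ranking of
the methods. In a single-replicate three-way layout $\sigma^2_{GE}$ and
$\sigma^2_\epsilon$ are confounded, so moment-recovery tests check their
sum.

# Numerical choices and scales

Problem sizes were chosen so the full default test run stays in the minutes
range: the printed-protocol checks run the 58x8x6 stand-in at the full 10
repetitions x 100 imputations (MAHC and NORM are fast); the seven-method
comparison runs at 4 repetitions x 40 imputations (pooled 5x10) with Gibbs
chains of 500 (the comparison is scale-consistent across methods; only its
Monte-Carlo resolution changes); samplers default to the specified 5500/500
chains elsewhere. The Gibbs inner loops are compiled (RcppArmadillo) with
$X^\top X$ eigendecomposed once per fit so a $\beta$ draw costs two dense
matrix-vector products; chains use R's RNG and are bit-reproducible under a
seed. Ward clustering is an $O(J^3)$ Lance--Williams implementation with a
deterministic lowest-index tie-break, cross-checked in the tests against
`stats::hclust(method = "ward.D")` on random squared-Euclidean instances.
Rank-deficient normal equations use the Moore--Penrose pseudoinverse.
Degenerate inputs: $B = 0$ intervals fall back to normal quantiles on
$\bar U$; columns with under 3 joint observations get missing correlation
entries; PMM donor pools shrink with a warning when fewer than $C$ distinct
donors exist.

# Known limitations

Raw-scale back-transforms of wholly missing columns are undefined (no
observed location/scale). The NRM option-3 design requires within-
environment correlations; pairs made unavailable by sparsity (not by a
wholly missing column) are an error rather than silently dropped. Variance
components are inputs, not estimated (no REML); unbalanced designs and
missing genotype rows are unsupported by construction.
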