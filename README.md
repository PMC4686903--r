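# METimpute

Multiple imputation for missing values in three-way three-mode
multi-environment trial (MET) data.

Plant-breeding trials grow the same *I* genotypes in *J* environments
(site–year combinations) and score *K* attributes, giving a three-way array
*x<sub>ijk</sub>*. Three-mode pattern analysis (clustering + ordination)
needs a complete array, but real MET data miss individual cells and —
commonly — whole environment–attribute columns (an attribute not measured at
one site). METimpute estimates those missing values and quantifies how well,
for breeders and biometricians who need a defensible completed array.

All methods work on the column-standardized scale
x̃<sub>ijk</sub> = (x<sub>ijk</sub> − x̄<sub>·jk</sub>) / s<sub>jk</sub>,
which removes environment main effects while preserving within-environment
attribute correlations. Four multiple-imputation families are implemented:

| Method | Idea | Estimation |
|---|---|---|
| **MAHC** | Ward-cluster the environments on the J × IK wide matrix; donate the first-merge sibling group's mean; repeat over H random attribute subsets | non-parametric |
| **NORM** | each genotype–attribute vector ~ N(μ, σ²I); impute μ̂ + zσ̂ | MLE or conjugate Gibbs (Jeffreys prior) |
| **NRM** | regress each column x̃<sub>jk</sub> on one of four designs built from the rest of the wide matrix (zeros for missing); wholly missing columns via the attribute-correlation matrix **R** | MLE or conjugate Gibbs (ν₀ = 4, S₀ = 2, τ² = 1) |
| **PMM** | bootstrap-refit the NRM, match predictions by d², donate one of the C = 3 closest *actual* observed values | MLE or Gibbs per bootstrap |

An EM/Tucker3 single-imputation baseline, Rubin's-rules 95% coverage and
NRMSE evaluation protocols, a variance-components simulator for fixture
arrays, and a `met-impute` command line round out the toolkit. See the
methods vignette (`vignettes/met-imputation-methods.Rmd`) for the models,
default parameters and design decisions.

## Worked example

```r
library(METimpute)

## a simulated 58 x 8 x 6 soybean-trial-sized array (fully observed)
raw <- simulateMET(metPresetConfig("dataset1_synthetic", seed = 101))
std <- standardizeMET(raw)

## designate 5% of values missing, including one whole column
pat <- generateMissingPattern(raw, percent = 0.05, nColumns = 1, seed = 7)
pat
#> MissingPattern: 81 cells + 1 column(s) on a 58x8x6 array (5.0% nominal, seed 7)

## impute with MAHC, 100 imputations
res <- mahcImpute(applyPattern(std, pat), H = 100, seed = 11)
res
#> ImputationResult (mahc): H = 100 imputations of 139 missing entries

## how good are the estimates? pool 100 -> 5 x 20 and check 95% CI coverage
pooled <- poolImputations(res@estimates, H = 5, seed = 11)
truth  <- metValues(std)[res@cells]
coverageCI(truth, pooled)$coverage
#> [1] 92.80576
```

A coverage of ~93% says that for ~93% of the deleted values the
Rubin's-rules 95% confidence interval built from the 5 pooled imputations
contains the true (deleted) standardized value. `runCellsProtocol()`,
`runColumnProtocol()` and `runNrmseProtocol()` repeat this over patterns,
percentages, methods and repetitions and return tidy data frames
(`summarizeProtocol()` adds means and standard errors).

The same operations are available from a shell:

```sh
Rscript inst/scripts/met-impute.R simulate --preset dataset3 --seed 1 --out long.csv
Rscript inst/scripts/met-impute.R mahc --input long.csv --h 100 --seed 2 --out imputed.csv
```

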