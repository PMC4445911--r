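# birdmarket

Phylogenetic comparative analysis of wildlife-market price data.

## The problem

Why do some bird species sell for US$1 in a pet shop while close relatives
fetch thousands? Cross-species regressions of price on traits (abundance in
the market, body mass, plumage colour, song, conservation status,
geographic origin) are confounded by shared ancestry: related species have
similar traits *and* similar prices, so residuals are phylogenetically
autocorrelated and ordinary least squares overstates certainty.
`birdmarket` is for ecologists and conservation scientists analysing trade
survey data who need the comparative-methods treatment of that problem,
end to end.

## The model

For species-level response $y = \ln(\text{price})$ and predictors $X$:

$$ y = X\beta + \varepsilon, \qquad
   \varepsilon \sim \mathcal{N}\big(0,\ \sigma^2 V(\lambda)\big) $$

where $V_{ij}$ is the shared root-to-MRCA branch length between species
$i$ and $j$ (Brownian-motion covariance) and Pagel's $\lambda \in [0,1]$
scales the off-diagonal: $\lambda$ is estimated by profile maximum
likelihood, so the data decide how much phylogenetic signal the residuals
carry. On top of single fits the package provides:

* **All-subsets AICc model selection** (`dredge_pgls()`): every submodel
  of a global predictor set, ranked by
  $\mathrm{AICc} = -2\ell + 2K + 2K(K{+}1)/(n{-}K{-}1)$, with Akaike
  weights, per-predictor importance (summed weights), conditional and
  full model-averaged coefficients, and a $\Delta\mathrm{AICc} < 4$
  candidate set.
* **Tree-ensemble uncertainty** (`run_univariate_ensemble()`,
  `identify_candidates()`, `refit_ensemble()`): every analysis repeated
  over a sample of candidate phylogenies, each statistic reported as
  median [5th, 95th percentile] across trees, with per-model rank tallies.
* **Data ingest and derived predictors**: colour coverage from a
  14-body-part × 11-colour presence sheet, colour diversity (≥ 3% coverage
  threshold), song attractiveness as residuals of log(recordings + 1) on
  log(range area), natural-log and arcsine-square-root transforms, and
  descriptive market tallies.
* **A synthetic-data generator**: Yule trees and traits drawn from the
  exact model class (`simulate_traits()`, `build_synthetic_study()`), so
  the whole pipeline is testable and parameter recovery is demonstrable
  without any external data.

## Worked example

```r
library(birdmarket)

study <- build_synthetic_study(seed = 42, n_species = 120,
                               n_trees_univariate = 20,
                               n_trees_candidate = 5)
tab <- transform_predictors(study$table)

fit <- pgls(log_price ~ log_n_for_sale + log_mass, tab, study$trees[[1]])
fit
#> PGLS fit (n = 120): lambda (ML) = 0.8605, logLik = -74.749, AICc = 160.024
#> r2 = 0.6916, adj r2 = 0.6864
#> # A tibble: 3 × 5
#>   term           estimate std.error statistic  p.value
#>   <chr>             <dbl>     <dbl>     <dbl>    <dbl>
#> 1 (Intercept)       4.18     0.374      11.2  3.68e-20
#> 2 log_n_for_sale   -0.292    0.0194    -15.1  3.70e-29
#> 3 log_mass          0.581    0.0720      8.07 7.06e-13
```

The fitted $\hat\lambda = 0.86$ says residual prices carry strong
phylogenetic signal; the slope −0.29 on log numbers means a species ten
times more available sells for about `exp(-0.29 * log(10))` ≈ half the
price, and heavier species cost more. Repeating over the 20-tree ensemble
summarizes the slope's sensitivity to the phylogeny:

```r
ens <- run_univariate_ensemble(tab, study$trees_univariate, "log_n_for_sale")
ens$summary[, c("term", "estimate_p05", "estimate_median", "estimate_p95")]
#>   term           estimate_p05 estimate_median estimate_p95
#> 1 log_n_for_sale       -0.265          -0.263       -0.262
```

Descriptive tallies of the same table:

```r
summary_tallies(study$table)
#> Market tallies: 120 species, 15580 individuals for sale
#>   alien: 80 species, 12657 individuals
#>   top 10 species hold 73.8% of individuals
#>   price range US$0.76 - US$85.49 (at 30 TWD/USD)
#>   displayed market value US$123822
```

The pipeline stages (`run_describe()`, `run_univariate()`, `run_dredge()`,
`run_passeriformes()`) wrap these steps with a seeded `run_config()`,
writing stamped CSV/JSON reports when an output directory is set. See the
vignette (`vignettes/pgls-market-analysis.Rmd`) for the model, design
decisions and validation-study sizes.

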