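---
title: "Phylogenetic comparative analysis of market prices: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic comparative analysis of market prices: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(birdmarket)
```

# The problem

Prices of bird species in pet markets are not independent observations:
closely related species share the evolved traits (size, colour, song) that
buyers pay for, so a regression of price on traits across species inherits
phylogenetic autocorrelation in its residuals. `birdmarket` implements the
standard comparative-methods response to this: phylogenetic generalized
least squares (PGLS) with maximum-likelihood estimation of Pagel's
$\lambda$, combined with information-theoretic multi-model inference (AICc,
Akaike weights, variable importance, model averaging) and explicit
propagation of *phylogenetic* uncertainty by repeating every analysis over
an ensemble of candidate trees.

# The model

For $n$ species with response $y$ (natural log of price) and design matrix
$X$, the model is

$$ y = X\beta + \varepsilon, \qquad
   \varepsilon \sim \mathcal{N}\!\big(0,\; \sigma^2\, V(\lambda)\big), $$

where $V$ is the phylogenetic variance–covariance matrix — $V_{ij}$ is the
shared branch length from the root to the most recent common ancestor of
tips $i$ and $j$, $V_{ii}$ the root-to-tip depth — and $V(\lambda)$
multiplies the off-diagonal of $V$ by $\lambda \in [0, 1]$ while keeping
the diagonal. $\lambda = 0$ makes species independent; $\lambda = 1$ is
full Brownian-motion covariance. Rather than assuming a value, $\lambda$ is
estimated from the data by profile maximum likelihood: at fixed $\lambda$,
$\hat\beta$ is the GLS solution and $\hat\sigma^2_{ML} = RSS_W / n$, giving

$$ \ell(\lambda) = -\tfrac12\left[n\log 2\pi + n \log \hat\sigma^2_{ML}
   + \log\det V(\lambda) + n\right]. $$

Numerically, every GLS solve goes through a Cholesky whitening of
$V(\lambda)$ (never an explicit inverse), and the 1-D maximization runs a
21-point grid pre-scan over $[0,1]$ followed by Brent-type bounded
refinement (tolerance $10^{-6}$) in the bracketing interval, with both
endpoints checked explicitly — the profile can be maximized at 0 or 1, and
the grid scan protects against local maxima near the boundaries.
$\lambda$ is bounded to $[0,1]$ rather than the feasible upper bound some
implementations allow, for interpretability; empirical estimates here sit
well inside the interval.

Reported per-model statistics follow GLS conventions: standard errors use
the unbiased $RSS_W/(n-p)$, $t = \hat\beta / se$ with $n - p$ degrees of
freedom, and the overall $F$ is the extra-sum-of-squares comparison against
the intercept-only model *in the whitened metric at the fitted* $\lambda$,
which doubles as the factor-level test for a single categorical predictor.
There is no universally agreed $r^2$ for PGLS; this package defines
$r^2 = 1 - RSS_W / TSS_W$ with $TSS_W$ the intercept-only residual sum of
squares in the same whitened metric, and records that convention in the fit
object (`$r2_definition`). It is a documented modelling choice, not a claim
of equivalence with any other implementation's $r^2$.

## Information criteria and multi-model inference

Model selection uses AICc, $-2\ell + 2K + 2K(K+1)/(n-K-1)$, with $K$
counting **every** estimated quantity: the $p$ regression coefficients,
$\sigma^2$, and $\lambda$ when estimated. Counting $\sigma^2$ follows the
convention of mainstream model-averaging tools; counting $\lambda$ is
consistent because every submodel re-estimates it, so the ranking is
unchanged up to this constant offset — but the absolute AICc values are
honest about the parameters actually fitted. Each submodel re-estimates
$\lambda$ by ML rather than inheriting the global model's value, since the
best-supported models can differ in how much phylogenetic signal their
residuals carry.

All-subsets enumeration treats a multi-level factor as one indivisible
block (2^m models for m blocks, guarded above 20 blocks). Before
enumeration the complete-case rows are fixed by the *global* model's
predictor set, so every submodel is fitted to the same observations —
information criteria are incomparable otherwise. Akaike weights are
$w_i = \exp(-\Delta_i/2) / \sum_j \exp(-\Delta_j/2)$; a predictor's
importance is the summed weight of models containing its block; the
candidate set keeps models with $\Delta$ strictly below 4.

Model-averaged coefficients are reported in both conventions: the
*conditional* (natural) average, weights renormalized over the models
containing the term, is primary because the per-model tables report
term-wise estimates; the *full* average (absent terms contribute 0) is
emitted alongside, since the two answer different questions and published
analyses do not always say which they used.

For the family of 11 per-colour univariate tests, significance is judged
by a Bonferroni threshold $\alpha / m$ with $\alpha = 0.05$, $m = 11$
(threshold 0.004545…): a colour at $p = 0.004$ is significant, one at
$p = 0.01$ is not.

## Tree-ensemble uncertainty

No single phylogeny is known without error, so each analysis is repeated
over a sample of candidate trees and each statistic is summarized as its
median and 5th/95th percentiles across trees (percentiles use R's default
linear interpolation, quantile type 7). The defaults mirror a common
design: 100 trees for univariate models; 10 trees for the all-subsets
search (the expensive stage — hundreds of models per tree); and an
independent 100-tree sample to refit the candidate set, with per-model
rank tallies (how many trees ranked a model 1st/2nd/3rd), weight and
importance summaries. Tree subsampling is a seeded uniform draw without
replacement and the seed is recorded in all outputs; given (trees, table,
seed) every ensemble result is reproducible bit-for-bit.

Two aggregation modes exist for the candidate search: keep models whose
*median* across-tree $\Delta$AICc is below the threshold (default), or
take the union of per-tree candidate sets. Neither is asserted to be the
canonical choice; the flag `mode` selects between them. Individual
posterior-sample trees can be pathological, so per-tree fit failures are
recorded and skipped rather than aborting the ensemble, with
`trees_used + failures` always equal to the trees supplied.

# Data ingest and derived predictors

The trait table is one row per species: price (TWD), number for sale,
native/alien status, biogeographic realm, IUCN category (LC/NT/VU/EN —
the categories observed in such surveys), CITES listing flag, body mass
(g), breeding range (km²), song-recording count, and colour scores.
Rows with missing values are retained and flagged; complete-case
subsetting happens per fitted model, logged via each fit's effective `n`.

Derived predictors:

* **Colour coverage** — plumage is scored as presence/absence of 11 colour
  categories (pink subsumes purple and violet) on 14 body parts; coverage
  of a colour is parts-present / 14. Parts are equally weighted: the
  scoring is plate-based and categorical, not an area measurement, so the
  score sheet is an input, never recomputed from images. A part may carry
  several colours, so coverages need not sum to 1.
* **Colour diversity** — the number of colours with coverage at or above
  3% of the body (threshold 0.03, configurable).
* **Song attractiveness** — the residual of $\ln(\text{recordings} + 1)$
  on $\ln(\text{range area})$ across species, an availability-corrected
  index of how much a species' song attracts recordists. The +1 offset
  applies to song counts, which can be zero; counts of birds for sale are
  at least 1 for any recorded species, so plain logs are used there.

Continuous predictors are natural-log transformed (price, mass, numbers,
range); colour coverages get the arcsine-square-root transform
$\arcsin\sqrt{p}$ (0 at 0, $\pi/4$ at 0.5, $\pi/2$ at 1). Categorical
predictors are reference-coded: status (reference "native"), 4-level IUCN
(reference "LC") for univariate models plus the binary LC/not-LC recode
used in the multivariate global model, 5-level realm (reference
"Afrotropic"). Whether coverage should *additionally* be log-transformed
is ambiguous in the field's usage; the arcsine-square-root version is the
primary implementation here.

Descriptive tallies (total individuals, alien species and individuals,
abundance ranking, top-k share, USD price extrema and total market value
at a configurable exchange rate defaulting to 30 TWD/USD) are computed by
`summary_tallies()` and are invariant to row order.

# The synthetic-data generator

Because real survey data cannot be redistributed, the package ships a
generator that emulates the *statistical structure* the analysis assumes,
making every stage testable end to end:

* **Trees** — pure-birth (Yule) trees: with $k$ lineages the next split
  waits $\text{Exp}(k b)$, the splitting lineage is uniform, and one extra
  waiting time after the $n$-th tip gives positive terminal branches.
  Birth rate defaults to 1 and trees are rescaled to unit height so
  $\lambda$ and $\sigma^2$ are comparable across runs. Tree uncertainty is
  emulated by multiplicative log-normal branch-length jitter around a base
  tree (topology held fixed — real posterior samples also vary
  topologically, which this does not emulate).
* **Traits** — the response is drawn exactly from the fitted model class:
  $y = X\beta + \varepsilon$, $\varepsilon \sim \mathcal N(0, \sigma^2
  V(\lambda))$ via the Cholesky factor. Predictors come from pluggable
  generators (Brownian-on-tree, i.i.d. normal, Bernoulli, clade-blocked
  binary, log-normal counts).
* **The study fixture** (`build_synthetic_study()`) — 217 species and
  100 + 10 trees, matching the scale of the motivating survey design. Alien
  status is clade-blocked (whole clades mostly alien), mimicking the
  observation that alien market species concentrate in particular
  families; abundances are long-tailed log-normal (1 to thousands);
  yellow colouration is enriched in one clade; log price is generated with
  strong effects of log numbers (−0.35), log mass (+0.55), alien status
  (+0.6), yellow coverage (+1.2) and a modest song effect (−0.1), with
  $\lambda = 0.9$, $\sigma^2 = 0.35$, intercept 6 (putting median prices
  in the hundreds of TWD). Marginals are stylized, not fitted to any real
  dataset.

Everything is a pure function of its seed: generators save and restore the
caller's RNG state.

What passing tests on synthetic data do and do not show: they verify that
the estimation machinery recovers known generating parameters under the
model's own assumptions (correct covariance class, exactly matching tips,
no measurement error, no topology uncertainty). They cannot certify
behaviour under model misspecification, trait-dependent sampling, or the
label-matching problems of real phylogeny databases.

# Study sizes used in validation

The validation studies fix their conditions once, at sizes a comparative
analysis would actually use:

* *Parameter recovery*: 100 datasets of 300 tips with $\lambda = 0.9$,
  $\beta = (2, -0.1, 0.6)$, $\sigma^2 = 0.5$. Expected outcome: median
  $\hat\lambda$ within $[0.85, 0.95]$, median $\hat\beta$ within 5% of
  truth, pooled 90% t-interval coverage near nominal.
* *Model-selection recovery*: 50 replicates of a 24-tip, 4-block design
  with three strong predictors ($\beta = 1.2, -1, 0.8$, $\sigma^2 = 0.2$)
  and one null. The small-sample regime is deliberate: it is where AICc's
  correction matters, raising the effective penalty for one spurious
  parameter to about 4.5 and making exact recovery of the generating
  model the typical outcome. At large $n$ the penalty tends to 2 and AICc
  admits a spurious extra predictor in roughly 15% of datasets *by
  design* — exact-recovery rates there are bounded away from 1 no matter
  how strong the effects, which is a property of AICc, not a defect of the
  implementation.
* *Ensemble pipeline*: the 217-species fixture with 100/10/100 trees.

# Degenerate inputs and numerical conventions

* Non-positive-definite $V(\lambda)$ (e.g. duplicated tips) fails in the
  Cholesky with a clear error; rank-deficient designs name the offending
  column.
* A perfect linear fit drives $\hat\sigma^2$ to 0; the log-likelihood is
  guarded against `log(0)` and $r^2$ tends to 1.
* Star phylogenies make the $\lambda$ profile flat; the optimizer then
  returns a grid point, and nothing downstream depends on which.
* AICc requires $n > K + 1$ and errors otherwise.
* Pruning preserves root-to-tip depths: the stem between the old and new
  root is kept as a root edge and added to the whole VCV, so the pruned
  VCV equals the corresponding submatrix of the full-tree VCV exactly.
  Requested taxa missing from a tree are warned about and reported, never
  silently dropped. Multifurcations are accepted as-is (the VCV is
  topology-tolerant); no random resolution is performed.
* Ties in AICc ranking break by fewer parameters, then lexicographic term
  string.

# Known limitations

* $r^2$ and adjusted $r^2$ for PGLS are conventions; comparisons with
  other software's values are not meaningful without checking definitions.
* The jittered-tree ensemble does not vary topology.
* The univariate realm/IUCN models with missing categorical data can have
  different effective $n$ than the multivariate analysis; each fit logs
  its own $n$, and cross-model comparisons should use the dredge path,
  which fixes rows globally.
* No Ornstein–Uhlenbeck or other branch-length transformations, no
  phylogenetic logistic regression, no measurement-error models.

# A minimal run

```{r example, eval = FALSE}
study <- build_synthetic_study(seed = 42, n_species = 120,
                               n_trees_univariate = 20,
                               n_trees_candidate = 5)
tab <- transform_predictors(study$table)

fit <- pgls(log_price ~ log_n_for_sale + log_mass, tab, study$trees[[1]])
glance(fit)

ens <- run_univariate_ensemble(tab, study$trees_univariate,
                               "log_n_for_sale")
tidy(ens)

cfg <- run_config(data = study$table, trees = study$trees,
                  n_trees_candidate = 5, n_trees_refit = 20, seed = 1)
res <- run_dredge(cfg, blocks = c("log_n_for_sale", "log_mass", "status",
                                  "asr_colour_yellow"))
res$refit$importance
```
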