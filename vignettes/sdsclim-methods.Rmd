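---
title: "Methods: breeding-season climate and sex-determination systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: breeding-season climate and sex-determination systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question and the data model

Reptiles determine offspring sex either genotypically (GSD) or through
incubation temperature (TSD). Long-standing theory predicts that climatic
fluctuation should select against TSD, while warm, stable climates should
permit it. `sdsclim` implements the comparative pipeline needed to test
those predictions: per-species breeding-window climate statistics over
gridded monthly climate, phylogenetic regressions of climate on the
sex-determination system (SDS), phylogeny-corrected variance contrasts, a
consecutive-month randomization null for breeding-window placement, and
d-separation path analysis to compare causal orderings of SDS, ambient
temperature and breeding-season length.

The pipeline consumes four inputs: a rooted ultrametric phylogeny with
branch lengths (Newick), a per-species trait table (CSV: SDS coded TSD = 1 /
GSD = 0, reproductive mode coded viviparous = 1 / oviparous = 0, breeding
window start and end months with January = 1, family, continent, range area,
and optional body length, body mass and longevity), monthly climate arrays
indexed (year, month, row, col), and per-species range masks (grid-cell
lists or GeoJSON polygons rasterized by cell-center containment). A species
whose season start is known but whose end is not has its window closed at
December.

## Breeding-window climate statistics

For a species with range mask $M$ and window months $W$ (a cyclic inclusive
month sequence; `start > end` wraps the year boundary), the range series
$s_{y,m}$ is the unweighted mean of the grid values over $M$ for year $y$
and month $m$. The three statistics are:

* **median ambient value** — the median of the pooled set
  $\{s_{y,m} : \text{all } y,\ m \in W\}$;
* **seasonality** — for each year the sample variance of
  $\{s_{y,m} : m \in W\}$, averaged over years (within-year spread of the
  window);
* **interannual fluctuation** — for each $m \in W$ the sample variance of
  $\{s_{y,m} : \text{all } y\}$, averaged over the window months
  (between-year spread of each month).

Conventions, chosen once and applied everywhere: sample ($n-1$) variances;
cells averaged before pooling months (the alternative order — pooling
cell-months before the median — is available through the per-cell series but
is not the default); wrap-around windows take their months from the same
calendar year, with no year splicing, because nothing in the data model ties
December of one year to January of the next; one-month windows have
seasonality 0 carried with a `single_month` flag rather than a missing
value, so one-month breeders stay in every analysis; cell means are
unweighted by latitude or area.

The randomization null asks whether an observed window is placed in an
unusually stable stretch of the year: seasonality is recomputed for
consecutive-month windows of the same length at all 12 cyclic start months
(the exact null — the sample space has only 12 points, so enumeration is the
default and sampling is offered only for symmetry), and the observed value's
quantile counts ties as below-or-equal. Twelve-month windows make the null
degenerate and are excluded with a flag.

## Phylogenetic regressions

`pgls_fit` maximizes the Gaussian likelihood of $y = X\beta + \varepsilon$,
$\varepsilon \sim N(0, \sigma^2 D^{1/2} C(\theta) D^{1/2})$ with $\beta$ and
$\sigma^2$ profiled out. Two correlation families are provided:

* **Ornstein–Uhlenbeck**: $C_{ij} = e^{-\alpha d_{ij}}$ with $d_{ij}$ the
  patristic distance — the stationary correlation of a mean-reverting trait;
  large $\alpha$ erases phylogenetic structure.
* **Pagel's lambda**: off-diagonal shared-path lengths scaled by $\lambda$,
  diagonal unchanged, normalized to a correlation. $\lambda$ may exceed 1 up
  to a positive-definiteness cap of 1.1, so estimates like 1.003 are
  representable.

$D$ carries per-species variance weights. Climate summaries are noisier for
wide-ranging species, so weights are derived from range areas: with
$a_i = \log_{10}(\text{area}_i)$, the weight is $w_i = a_i / \min_j a_j$ and
the residual variance of species $i$ scales with $w_i$ — the smallest range
has weight 1 and the largest ranges get the least influence. Areas must
exceed one area unit so the log is positive.

$\alpha$ (or $\lambda$) is profiled by bounded one-dimensional search:
golden-section on $\log \alpha$ over $[10^{-4}, 10^{4}]/T$ ($T$ = tree
depth), tolerance $10^{-8}$; $\lambda$ over $[0, 1.1]$ with the endpoints
checked explicitly. Coefficient $t$-tests use $n - p$ residual degrees of
freedom with the unbiased residual variance; the reported log-likelihood is
the ML one, which the likelihood-ratio contrast (`lr_anova`) consumes. The
binary SDS can sit on either side of the model: the Gaussian fit treats a
0/1 response as a linear-probability model, and the logistic variant below
is the robustness check.

The variance-heterogeneity contrast fits, with the same `y ~ group` mean
structure, a null with one residual variance against an alternative with a
free variance multiplier per group (reference fixed at 1; multipliers and
$\alpha$ jointly maximized by Nelder–Mead on log scale), and refers twice
the log-likelihood difference to $\chi^2$ with (groups − 1) degrees of
freedom. This is the phylogeny-corrected test of whether, e.g., GSD species
span a wider temperature range than TSD species. The ANCOVA
`temperature ~ SDS + length + SDS:length` is an ordinary OU-PGLS whose
interaction term asks whether the temperature–season-length slope differs
between systems.

**Phylogenetic logistic regression.** For a binary response the package
solves the quasi-score equation
$X^\top \Delta V^{-1}(y - \mu) + a(\beta) = 0$ with logistic mean
$\mu = \text{logit}^{-1}(X\beta)$, working covariance
$V = A^{1/2} R(\alpha) A^{1/2}$ ($A = \mu(1-\mu)$, $R$ the OU correlation)
and $a(\beta)$ the Firth (Jeffreys-prior) adjustment computed from the
logistic information. The Firth term keeps estimates finite under complete
separation (detected by checking whether the fitted score perfectly ranks
the classes, and flagged). On a star phylogeny the equation reduces exactly
to ordinary Firth-penalized logistic regression, which anchors the
correctness tests. When $\alpha$ is not supplied, it is profiled by
maximizing the Gaussian pseudo-likelihood of the Pearson residuals,
alternating with the coefficient update until the correlation strength
stabilizes; standard errors are model-based from the quasi-information.

## Path analysis

Each causal hypothesis is a DAG over the study variables. Its d-separation
basis set contains one claim per non-adjacent vertex pair — independence
given the union of both vertices' parents — ordered canonically
(topological order, ties broken lexicographically), so the output does not
depend on how the DAG was entered. A claim is tested by regressing the pair's
later vertex (in the DAG's causal order, a deterministic choice) on the
earlier vertex plus the conditioning set: Firth phylogenetic logistic
regression when the response is binary, OU-PGLS otherwise; the claim's
p-value is the earlier vertex's coefficient test. The claims combine into
Fisher's $C = -2\sum \ln p_i$ ($\chi^2_{2k}$ when the DAG is compatible) and
$\mathrm{CICc} = C + 2qn/(n - 1 - q)$, with $q$ = number of directed edges
(the path coefficients being the estimated parameters; an edges + vertices
convention is available as a switch because usage varies). Models within
$\Delta\mathrm{CICc} \le 2$ of the best are retained; Akaike-style weights
$\propto e^{-\Delta/2}$; the averaged model uses "full" averaging, where a
retained model lacking an edge contributes zero for it, with weights
renormalized over the retained set. Path coefficients are standardized by
z-scoring continuous variables before fitting; the binary SDS is left 0/1
(standardizing a Bernoulli indicator would make coefficients depend on the
class balance).

The four built-in hypotheses order SDS, breeding-season temperature and
breeding-season length as: A `sds→temp→length`, B `sds→length→temp`,
C `temp→sds→length`, D `temp→length→sds`. A fifth set over those vertices
plus the averaged life-history index is deliberately user-configurable
rather than hard-coded, since competing life-history scenarios are
study-specific. The life-history index itself is the mean of the available
per-trait Z scores ($Z_i = (x_i - \bar x)/s$ over non-missing species), so
species with partial trait coverage keep an index — this is what lets
index-based analyses run on far more species than have all three traits.

## The synthetic-study generator

Every stage is exercised offline by `simulate_study`, whose defaults are the
study conditions: 213 species in 38 families, exactly 11 GSD→TSD transitions
on the tree, 30 years of monthly climate, TSD range centroids on average 3
degrees C warmer than GSD ones (the empirical breeding-season group means
differ by about that much), and breeding windows placed on the warmest
months.

* **Tree**: birth–death simulation conditioned on the tip count
  (`ape::rphylo`), ultrametric with positive branch lengths.
* **SDS**: a two-state Markov chain run by the Gillespie algorithm along
  every branch, which yields the realized number of state changes; when a
  target count is requested the realization is rejection-sampled until the
  count matches exactly (cap 10 000 attempts — exact conditioning would be
  needless machinery for a 12-dimensional discrete event). The default gain
  rate is target/total-tree-length with a loss rate a quarter of that.
  Conditioning is on the transition count, not on the TSD species share, so
  the realized TSD fraction varies between realizations and is typically
  smaller than the empirical study's.
* **Climate**: temperature = latitudinal base gradient + seasonal cosine
  whose amplitude grows linearly with |latitude| (phase flipped in the
  southern hemisphere, peak July vs January) + a year effect shared by all
  months of a cell-year + independent month noise; precipitation analogous
  with a nonnegativity clamp. Rows map linearly to latitudes in [60, −60];
  this is the simplest monotone gradient that produces realistic
  window-placement and variance structure.
* **Ranges**: contiguous blobs grown by seeded breadth-first search from a
  centroid; sizes vary (Poisson around the configured mean, floor 4, capped
  at the grid) so area weights are informative. Centroids are
  temperature-matched: each species draws a target temperature equal to the
  grid mean plus the SDS effect times its state plus noise, and takes the
  nearest cell — with a zero effect the groups are exchangeable by
  construction, which is what the type-I calibration tests rely on.
* **Windows**: lengths drawn from a configurable distribution (uniform on
  1–12 by default; the empirical length distribution beyond the short/long
  split is not pinned down, so it is a knob rather than a guess), placed to
  maximize window mean temperature ("warmest"), minimize seasonality
  ("stablest"), or uniformly ("random"); ties break to the earliest start.
* **Life-history traits**: Ornstein–Uhlenbeck on the tree with shared
  structure across the three traits, observed independently with
  probability 0.6 per trait — matching the regime where roughly a fifth of
  species have all three traits but nearly all have at least one.
  Viviparity is concentrated in cold-range GSD species via a logistic in
  range coldness and SDS.

What the generator does **not** emulate: real geodesy (cells are abstract,
no area distortion, no oceans or coastlines), phylogenetically clustered
biogeography — ranges are placed by temperature, not by clade, so climate
variables carry much weaker phylogenetic signal than real data (the SDS
trait itself is strongly clustered and shows $\lambda \approx 1$) —
dispersal, topography, or observation error in the climate product. Passing
tests therefore demonstrate statistical correctness and calibration of the
machinery, not that the empirical effect sizes are recoverable from real
climate archives.

## Numerical choices and degenerate inputs

Likelihood evaluations whose correlation matrix fails its Cholesky
factorization (e.g. $\lambda$ beyond the positive-definite bound, or
$\alpha$ so small the matrix is numerically all-ones) return a large
negative log-likelihood instead of an error inside the optimizer. Exact
interpolation ($\text{RSS} = 0$) clamps the profiled variance at the
smallest positive double to keep the likelihood finite. Singular designs
are rejected with the collinear columns named. Zero p-values entering
Fisher's C are clamped to the smallest positive double with a warning. The
likelihood-ratio statistic is clamped to zero within a $10^{-6}$ tolerance,
and a more negative value raises an error since it indicates non-nested
fits. In the pipeline's reproductive-mode model, the SDS-by-viviparity
interaction column can be identically zero (viviparity is nearly confined
to GSD); the model battery then backs off to the largest estimable nested
model instead of failing.

## Problem sizes and verification

The simulation-backed guarantees are computed at the following sizes, chosen
to make Monte-Carlo error small relative to the tested bands: window
statistics versus independent brute-force loops at $10^{-10}$; star-tree
reductions of both regressions at $10^{-4}$ ($n = 100$); recovery of a
−3 degree SDS effect with 200 replicates at $n = 200$ (95% CI coverage
required in [90, 99]%); Pagel's lambda median over 50 Brownian-motion
replicates at $n = 200$ required in [0.9, 1.05]; path-model calibration with
200 replicates at $n = 200$ (generating hypothesis retained in ≥90%, its
C-test rejecting at roughly the nominal 5%); and the stablest-window null
check at 100 species, where every window must sit at the enumerated
minimum. Cross-checks against independent implementations (`nlme::gls` with
`ape::corMartins`, `phytools::phylosig`, direct penalized-likelihood
optimization for the Firth fit) pin the estimators to external references.

## Known limitations

The Gaussian PGLS treats a binary response as a linear-probability model —
the paper-level convention — with the Firth logistic fit as the principled
alternative; the logistic fit estimates its correlation strength from a
working pseudo-likelihood, not a full joint likelihood, so its $\alpha$ is a
nuisance calibration rather than an evolutionary-rate estimate. REML,
measurement-error models and multivariate responses are out of scope.
Wrap-around windows never splice calendar years. Rasterization uses
cell-center containment, adequate at coarse grids but lossy for slivers.
The life-history hypothesis set ships unconfigured by design.
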