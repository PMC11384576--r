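# hpagtwr

Text-derived **health policy attention (HPA)** indexing and
**geographically and temporally weighted regression (GTWR)**, with a
synthetic-data generator that gives the whole pipeline a known ground
truth.

## The problem

Local governments reveal their priorities in the language of their annual
work reports. The HPA index measures a government's attention to health
as the share of a report's term occurrences drawn from a curated health
vocabulary, times 100:

```
HPA = 100 x (health-lexicon term frequency) / (total term frequency)
```

The vocabulary itself is built by expanding a seed word set with CBOW
word embeddings (maximize Σ_{w∈C} log p(w | Context(w))) and cosine
similarity, then curating the candidates.

Given a city-by-year panel of HPA scores and socioeconomic covariates,
GTWR lets the association vary over space and time:

```
y_i = β0(u_i, v_i, t_i) + Σ_k βk(u_i, v_i, t_i) x_ik + ε_i
```

Each observation gets its own weighted least-squares fit, with kernel
weights `exp(-d²/h²)` on the squared spacetime distance
`d² = λ_s[(Δu)² + (Δv)²] + μ_t(Δt)²`; the bandwidth `h` is selected by
leave-one-out cross-validation. Diagnostics include Moran's I with
permutation inference, the IQR-vs-2SE nonstationarity test, coefficient
quantile summaries, and pre/during-pandemic period averages.

The package is for analysts who want this pipeline end to end — or just
the GTWR engine — with every stage testable against planted truth: the
corpora and yearbook covariates such studies use are typically
proprietary, so the package ships generators for city grids, coefficient
surfaces, covariate panels, co-occurrence corpora and document corpora
whose health-term shares are planted exactly.

## Worked example

One call runs the full synthetic study: simulate a city panel and
corpora, build the lexicon, score the documents, calibrate and fit the
regression, and write every artifact plus a manifest.

```r
library(hpagtwr)

cfg <- default_config(seed = 7)
cfg$simulate$n_cities <- 60            # a quick demo; the default is 323
cfg$simulate$doc_length <- 2000
cfg$simulate$vocab <- list(n_seeds = 10, n_synonyms = 30,
                           n_distractors = 20, n_filler = 300)
cfg$simulate$cooccurrence$n_sentences <- 2000
cfg$cbow$dim <- 40; cfg$cbow$epochs <- 10

res <- run_pipeline(cfg, out_dir = "runs/demo")
print(res$lexicon)
print(res$gtwr)
print(res$ols)
print(res$report)
```

```
Health lexicon: 10 seed + 30 expanded = 40 curated words
GTWR fit: n = 240, 9 covariates, h = 873.04 (lambda_s = 1, mu_t = 27317.1, gaussian kernel)
  trace(S) = 49.06, AICc = 8.670, adjusted R^2 = 0.4395
OLS fit: n = 240, 9 covariates, AICc = 72.385, adj R^2 = 0.0640
Moran's I = 0.5805 (permutation p = 0.001, knn(k=5), row-standardized)
GTWR AICc = 8.670, adj R^2 = 0.4395; OLS AICc = 72.385, adj R^2 = 0.0640
Nonstationary coefficients: 1 of 10
```

Reading this: all 30 planted synonyms were recovered by embedding
expansion, so the curated lexicon is complete; city-mean HPA is strongly
spatially autocorrelated (Moran's I = 0.58, smallest attainable
permutation p), justifying a spatial model; and the locally varying fit
beats the global OLS baseline on both AICc (8.7 vs 72.4) and adjusted R²
(0.44 vs 0.06), because the generator plants an east-west gradient the
global model cannot represent. Local coefficient tables mirror the usual
GTWR reporting layout:

```r
subset(res$report$coefficient_summary, variable %in% c("PGA", "AGE65"))
#>   variable      AVG     MIN      LQ      MED      UQ   MAX
#> 3      PGA  0.19822  0.0641  0.1244  0.17683 0.24610 0.427
#> 4    AGE65 -0.00254 -0.0204 -0.0123 -0.00147 0.00734 0.014
```

The numbered scripts under `analysis/` run the same study at full size
(323 cities × 4 years, a 411-word lexicon, 5000-token documents) as a
readable five-stage narrative, writing tables under `results/study/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_lexicon.R
Rscript analysis/03_score.R
Rscript analysis/04_fit_gtwr.R
Rscript analysis/05_diagnostics.R
```

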